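# Shared fixtures, all generated in code.

# tiny deterministic gene model set on two chromosomes
tiny_models <- function() {
  build_consensus_gene_models(tibble::tibble(
    gene_id = c("gA", "gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    strand = c("+", "+", "-", "+"),
    start = c(100L, 150L, 10000L, 500L),
    end = c(900L, 1200L, 12000L, 1500L)
  ))
}

# small simulated cohorts are expensive; cache them per test run
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, cfg) {
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(cfg)
  }
  .cohort_cache[[key]]
}

small_cohort <- function() {
  cached_cohort("small", simulate_config(
    n_samples = 60, n_probes = 2000, n_genes = 100, n_dmc = 80,
    n_pairs = 15, n_de_genes = 20, n_subgroup_dmc = 10, seed = 4242))
}

# brute-force oracles ------------------------------------------------------

oracle_jackknife <- function(x, y) {
  n <- length(x)
  rs <- c(stats::cor(x, y),
          vapply(seq_len(n), function(i) stats::cor(x[-i], y[-i]), numeric(1)))
  rs[which.min(abs(rs))]
}

# exact two-sided rank-sum p by full enumeration of group-1 index subsets
oracle_exact_wilcox <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x); n <- length(r)
  mu <- n1 * (n + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  sets <- utils::combn(n, n1, simplify = FALSE)
  hits <- vapply(sets, function(s) abs(sum(r[s]) - mu) >= obs - 1e-12, logical(1))
  mean(hits)
}

# distance from a 1-based position to a set of 1-based closed intervals
oracle_interval_distance <- function(pos, start1, end1) {
  d <- pmax(start1 - pos, pos - end1)
  max(min(d), 0)
}

oracle_cgi_context <- function(pos, start1, end1, shore_bp = 2000) {
  inside <- any(pos >= start1 & pos <= end1)
  if (inside) return("island")
  d <- min(pmax(start1 - pos, pos - end1))
  if (d <= shore_bp) "shore" else "ocean"
}
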