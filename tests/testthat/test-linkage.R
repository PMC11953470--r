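test_that("window mapping includes TSSs up to the inclusive 250 kb boundary", {
  models <- tibble::tibble(
    gene_id = c("near", "edge", "far", "minus"), chrom = "chr1", strand = c("+", "+", "+", "-"),
    tss = c(1240000L, 1250000L, 1260001L, 1100000L), tes = c(1250000L, 1260000L, 1270000L, 1090000L))
  man <- tibble::tibble(probe_id = "cg1", chrom = "chr1", pos = 1000000L)
  pr <- map_cpg_to_genes(man, models)
  expect_setequal(pr$gene_id, c("near", "edge", "minus"))
  expect_equal(pr$tss_distance[pr$gene_id == "near"], -240000)  # included, upstream
  expect_equal(pr$tss_distance[pr$gene_id == "edge"], -250000)  # inclusive bound
  expect_equal(pr$tss_distance[pr$gene_id == "minus"], 100000)  # signed by strand
  # empty result allowed
  man2 <- tibble::tibble(probe_id = "cg2", chrom = "chr9", pos = 1L)
  expect_equal(nrow(map_cpg_to_genes(man2, models)), 0)
})

test_that("eligibility filters apply the range and mean rules", {
  b <- rbind(wide = c(0.1, 0.4, 0.2), flat = c(0.3, 0.45, 0.5))
  colnames(b) <- sprintf("s%d", 1:3)
  f <- rbind(ok = c(5, 1, 3), lowmean = c(0.6, 0.2, 0.4), flatg = c(2, 2.5, 2.2))
  colnames(f) <- colnames(b)
  el <- filter_pair_inputs(b, f)
  expect_equal(el$probes$eligible, c(TRUE, FALSE))    # range 0.3 vs 0.2
  expect_equal(el$genes$eligible[el$genes$gene_id == "ok"], TRUE)
  expect_equal(el$genes$eligible[el$genes$gene_id == "lowmean"], FALSE)  # mean 0.4
  expect_equal(el$genes$eligible[el$genes$gene_id == "flatg"], FALSE)    # range < 1
  # FPKM transform arithmetic
  expect_equal(unname(transform_fpkm(matrix(1.9, 1, 1,
                                            dimnames = list("g", "s")))[1, 1]), 1)
})

test_that("jackknife correlation equals the brute-force oracle and damps outliers", {
  set.seed(111)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(as.numeric(jackknife_pearson(x, y)), oracle_jackknife(x, y),
                 tolerance = 1e-12)
  }
  x <- 1:10
  expect_equal(as.numeric(jackknife_pearson(x, 2 * x + 1)), 1)
  expect_equal(as.numeric(jackknife_pearson(x, -x)), -1)
  # outlier-driven full correlation collapses under LOO
  set.seed(112)
  x <- c(rnorm(19), 10); y <- c(rnorm(19), 10)
  jk <- jackknife_pearson(x, y)
  expect_lt(abs(jk), abs(cor(x, y)) / 2)
  expect_equal(as.numeric(jk), cor(x[-20], y[-20]) |>
                 (\(r_wo) {
                   rs <- c(cor(x, y),
                           sapply(1:20, function(i) cor(x[-i], y[-i])))
                   rs[which.min(abs(rs))]
                 })())
  # degenerate: constant after LOO
  xc <- c(rep(1, 9), 2)
  r <- jackknife_pearson(xc, rnorm(10))
  expect_true(is.na(r))
  expect_true(attr(r, "degenerate"))
  expect_error(jackknife_pearson(1:3, 1:3), "4")
  # estimate is inside the span of {full, LOO} correlations
  set.seed(113)
  for (i in 1:30) {
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- x * 0.5 + rnorm(n)
    rs <- c(cor(x, y), sapply(1:n, function(j) cor(x[-j], y[-j])))
    jk <- as.numeric(jackknife_pearson(x, y))
    expect_gte(jk, min(rs) - 1e-12)
    expect_lte(jk, max(rs) + 1e-12)
  }
})

test_that("pair calling uses strict cutoffs and flags planted pairs", {
  cuts <- structure(list(low = -0.3, high = 0.3), class = "null_cutoffs")
  pairs <- tibble::tibble(probe_id = "p", gene_id = letters[1:4],
                          jackknife_r = c(-0.3, 0, 0.31, NA))
  out <- call_significant_pairs(pairs, cuts)
  expect_equal(out$significant, c(FALSE, FALSE, TRUE, FALSE))  # boundary strict
  # planted pairs in a simulated cohort are detected as negative correlations
  co <- small_cohort()
  pr <- dplyr::inner_join(co$truth$pairs, co$manifest, by = "probe_id")
  pairs2 <- correlate_pairs(co$truth$pairs[c("probe_id", "gene_id")],
                            co$beta, co$fpkm)
  expect_gte(mean(pairs2$jackknife_r < -0.3, na.rm = TRUE), 0.9)
})

test_that("empirical null is seeded, reproducible, and warns on small universes", {
  co <- small_cohort()
  nc1 <- empirical_null(co$beta, co$fpkm, co$manifest, co$gene_models,
                        n_probes = 400, seed = 5)
  nc2 <- empirical_null(co$beta, co$fpkm, co$manifest, co$gene_models,
                        n_probes = 400, seed = 5)
  expect_identical(nc1$low, nc2$low)
  expect_identical(nc1$high, nc2$high)
  expect_lte(nc1$low, nc1$high)
  expect_warning(
    empirical_null(co$beta, co$fpkm, co$manifest[1:100, ], co$gene_models,
                   n_probes = 400, seed = 5),
    "replacement")
})

test_that("pair lists are invariant to gene and sample ordering", {
  co <- small_cohort()
  sub <- co$manifest[co$manifest$probe_id %in% co$truth$pairs$probe_id, ]
  p1 <- map_cpg_to_genes(sub, co$gene_models)
  p2 <- map_cpg_to_genes(sub, co$gene_models[sample(nrow(co$gene_models)), ])
  expect_equal(dplyr::arrange(p1, probe_id, gene_id),
               dplyr::arrange(p2, probe_id, gene_id))
  r1 <- correlate_pairs(p1, co$beta, co$fpkm)
  perm <- c(1, sample(2:ncol(co$beta)))
  r2 <- correlate_pairs(p1, co$beta[, perm], co$fpkm)
  expect_equal(r1$jackknife_r, r2$jackknife_r)
})

test_that("candidate gene filter applies all four rules", {
  mk_pairs <- function(gene, rs, d) {
    tibble::tibble(probe_id = sprintf("%s_p%d", gene, seq_along(rs)),
                   gene_id = gene, tss_distance = d, jackknife_r = rs,
                   significant = TRUE)
  }
  pairs <- dplyr::bind_rows(
    mk_pairs("keep", c(-0.6, -0.5, -0.7), 3000),
    mk_pairs("few", c(-0.6, -0.5), 3000),          # only 2 CpGs
    mk_pairs("pos", c(0.6, 0.5, 0.7), 3000),       # positive correlations
    mk_pairs("faraway", c(-0.6, -0.5, -0.7), 8000) # beyond 7 kbp
  )
  n <- 20
  fpkm <- rbind(keep = c(rep(10, n / 2), rep(2, n / 2)),
                few = c(rep(10, n / 2), rep(2, n / 2)),
                pos = c(rep(10, n / 2), rep(2, n / 2)),
                faraway = c(rep(10, n / 2), rep(2, n / 2)))
  colnames(fpkm) <- sprintf("s%02d", 1:n)
  groups <- setNames(rep(c("basal", "nonbasal"), each = n / 2), colnames(fpkm))
  de <- c("keep", "few", "pos", "faraway")
  out <- candidate_epigene_filter(pairs, de, fpkm, groups)
  expect_equal(out$gene_id, "keep")
  expect_equal(out$median_diff, 8)
  # not in DE list -> dropped
  out2 <- candidate_epigene_filter(pairs, c("few"), fpkm, groups)
  expect_equal(nrow(out2), 0)
  # fold-change refinement
  out3 <- candidate_epigene_filter(pairs, de, fpkm, groups, min_fold_change = 10)
  expect_equal(nrow(out3), 0)   # fold (10.1/2.1) < 10
})
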