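#' Map CpGs to genes with a TSS inside a genomic window
#'
#' All genes whose consensus TSS lies within half the window (inclusive) of
#' the probe position on the same chromosome, i.e. a 500 kb window centered
#' on the CpG by default.
#'
#' @param manifest Probe table `probe_id`, `chrom`, `pos` (1-based); may be a
#'   subset (e.g. significant CpGs only).
#' @param models Consensus gene models.
#' @param window_bp Full window width in bp centered on the CpG.
#' @return Tibble `probe_id`, `gene_id`, `tss_distance` (signed by gene
#'   strand, positive downstream). Probes with no gene in the window are
#'   absent from the output.
#' @export
map_cpg_to_genes <- function(manifest, models, window_bp = 500000) {
  half <- window_bp / 2
  out <- vector("list", length(unique(manifest$chrom)))
  i <- 0L
  for (ch in unique(manifest$chrom)) {
    i <- i + 1L
    pr <- manifest[manifest$chrom == ch, c("probe_id", "pos")]
    g <- models[models$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L || nrow(pr) == 0L) next
    g <- g[order(g$tss), , drop = FALSE]
    lo <- findInterval(pr$pos - half, g$tss, left.open = TRUE) + 1L
    hi <- findInterval(pr$pos + half, g$tss)
    keep <- hi >= lo
    if (!any(keep)) next
    idx <- which(keep)
    reps <- hi[idx] - lo[idx] + 1L
    gidx <- unlist(lapply(idx, function(j) seq.int(lo[j], hi[j])))
    pidx <- rep(idx, reps)
    out[[i]] <- tibble::tibble(
      probe_id = pr$probe_id[pidx],
      gene_id = g$gene_id[gidx],
      tss_distance = ifelse(g$strand[gidx] == "-",
                            g$tss[gidx] - pr$pos[pidx],
                            pr$pos[pidx] - g$tss[gidx])
    )
  }
  dplyr::bind_rows(out)
}

#' Eligibility filters for CpG-gene correlation inputs
#'
#' A probe is eligible when its beta range (max - min) exceeds
#' `min_beta_range`; a gene when its FPKM range exceeds `min_fpkm_range` and
#' its cohort mean FPKM is at least `min_mean_fpkm`. These filters damp
#' spurious correlations from near-constant rows.
#'
#' @param beta Beta table or matrix (probes x samples).
#' @param fpkm FPKM table or matrix (genes x samples), raw scale.
#' @param min_beta_range,min_fpkm_range,min_mean_fpkm Thresholds (strict for
#'   the ranges; mean uses `>=`).
#' @return List with tibbles `probes` (`probe_id`, `beta_range`, `eligible`)
#'   and `genes` (`gene_id`, `fpkm_range`, `mean_fpkm`, `eligible`).
#' @export
filter_pair_inputs <- function(beta, fpkm, min_beta_range = 0.25,
                               min_fpkm_range = 1, min_mean_fpkm = 0.5) {
  bm <- as_assay_matrix(beta, what = "beta")
  fm <- as_assay_matrix(fpkm, what = "fpkm")
  brange <- unname(apply(bm, 1L, function(x) diff(range(x, na.rm = TRUE))))
  frange <- unname(apply(fm, 1L, function(x) diff(range(x, na.rm = TRUE))))
  fmean <- unname(rowMeans(fm, na.rm = TRUE))
  list(
    probes = tibble::tibble(probe_id = rownames(bm), beta_range = brange,
                            eligible = brange > min_beta_range),
    genes = tibble::tibble(gene_id = rownames(fm), fpkm_range = frange,
                           mean_fpkm = fmean,
                           eligible = frange > min_fpkm_range &
                             fmean >= min_mean_fpkm)
  )
}

#' Jackknife Pearson correlation
#'
#' Pearson r is computed on the full data and on every leave-one-out
#' subsample; the returned estimate is the signed value of smallest absolute
#' magnitude among them. A single influential outlier can inflate the full
#' r, but the leave-one-out subsample excluding it will not follow, so this
#' estimator damps outlier-driven associations. A bias-corrected jackknife
#' estimate (`n*r_full - (n-1)*mean(r_loo)`) is available as an alternative.
#'
#' @param x,y Numeric vectors of equal length `n >= 4`, no missing values.
#' @param method `"min_abs"` (conservative minimum-magnitude, default) or
#'   `"bias_corrected"`.
#' @return The jackknife correlation, or `NA` (with attribute
#'   `degenerate = TRUE`) when the full data or any leave-one-out subsample
#'   is constant in either variable.
#' @export
jackknife_pearson <- function(x, y, method = c("min_abs", "bias_corrected")) {
  method <- rlang::arg_match(method)
  n <- length(x)
  if (length(y) != n) rlang::abort("x and y must have equal length")
  if (n < 4L) rlang::abort("need at least 4 observations")
  if (anyNA(x) || anyNA(y)) rlang::abort("missing values not supported")
  rs <- jackknife_pearson_all(x, y)
  if (anyNA(rs)) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  if (method == "min_abs") {
    rs[which.min(abs(rs))]
  } else {
    n * rs[1L] - (n - 1) * mean(rs[-1L])
  }
}

# All correlations {r_full, r_(-1), ..., r_(-n)} via downdated sums.
# Returns NA entries where a (sub)sample is constant in x or y.
jackknife_pearson_all <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); syy <- sum(y * y); sxy <- sum(x * y)
  r_of <- function(nn, sx, sy, sxx, syy, sxy) {
    vx <- sxx - sx^2 / nn
    vy <- syy - sy^2 / nn
    cv <- sxy - sx * sy / nn
    out <- cv / sqrt(vx * vy)
    out[vx <= .Machine$double.eps * pmax(sxx, 1) |
          vy <= .Machine$double.eps * pmax(syy, 1)] <- NA_real_
    out
  }
  r_full <- r_of(n, sx, sy, sxx, syy, sxy)
  r_loo <- r_of(n - 1, sx - x, sy - y, sxx - x * x, syy - y * y, sxy - x * y)
  c(r_full, r_loo)
}

#' Jackknife correlations for a table of CpG-gene pairs
#'
#' Applies the eligibility filters, log-transforms expression
#' (`log2(FPKM + 0.1)`), and computes the jackknife Pearson correlation for
#' every pair over the shared samples. Pairs whose inputs are degenerate
#' (constant in any leave-one-out subsample) are flagged and their
#' correlation is `NA`.
#'
#' @param pairs Tibble `probe_id`, `gene_id` (e.g. from
#'   [map_cpg_to_genes()]).
#' @param beta,fpkm Assay tables or matrices sharing sample columns; FPKM on
#'   the raw scale.
#' @param apply_filters Apply [filter_pair_inputs()] eligibility (default) or
#'   correlate all pairs.
#' @param method Jackknife estimator passed to [jackknife_pearson()].
#' @return `pairs` with `jackknife_r` and `degenerate` columns; ineligible
#'   pairs are dropped.
#' @export
correlate_pairs <- function(pairs, beta, fpkm, apply_filters = TRUE,
                            method = "min_abs") {
  bm <- as_assay_matrix(beta, what = "beta")
  fm <- as_assay_matrix(fpkm, what = "fpkm")
  samples <- intersect(colnames(bm), colnames(fm))
  if (length(samples) < 4L) rlang::abort("need at least 4 shared samples")
  bm <- bm[, samples, drop = FALSE]
  fm <- fm[, samples, drop = FALSE]
  pairs <- pairs[pairs$probe_id %in% rownames(bm) &
                   pairs$gene_id %in% rownames(fm), , drop = FALSE]
  if (apply_filters) {
    el <- filter_pair_inputs(bm, fm)
    okp <- el$probes$probe_id[el$probes$eligible]
    okg <- el$genes$gene_id[el$genes$eligible]
    pairs <- pairs[pairs$probe_id %in% okp & pairs$gene_id %in% okg, ,
                   drop = FALSE]
  }
  lm_ <- log2(fm + 0.1)
  r <- rep(NA_real_, nrow(pairs))
  degen <- rep(FALSE, nrow(pairs))
  bi <- match(pairs$probe_id, rownames(bm))
  gi <- match(pairs$gene_id, rownames(lm_))
  for (i in seq_len(nrow(pairs))) {
    x <- bm[bi[i], ]; y <- lm_[gi[i], ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 4L) { degen[i] <- TRUE; next }
    ri <- jackknife_pearson(x[ok], y[ok], method = method)
    if (is.na(ri)) degen[i] <- TRUE else r[i] <- as.numeric(ri)
  }
  pairs$jackknife_r <- r
  pairs$degenerate <- degen
  pairs
}

#' Empirical null distribution of CpG-gene jackknife correlations
#'
#' Samples `n_probes` probes uniformly (seeded), pairs each with every gene
#' whose TSS falls in the same genomic window, pushes the pairs through the
#' same eligibility filters and jackknife correlation as the real analysis,
#' pools all resulting correlations, and returns the 2.5th and 97.5th
#' percentiles (linear interpolation between order statistics) as
#' significance cutoffs.
#'
#' @param beta,fpkm Assay tables or matrices.
#' @param manifest Probe universe (`probe_id`, `chrom`, `pos`).
#' @param models Consensus gene models.
#' @param n_probes Number of probes to draw; when the universe is smaller,
#'   sampling is with replacement (with a warning).
#' @param seed Seed for the probe draw.
#' @param window_bp Window width passed to [map_cpg_to_genes()].
#' @param probs Percentile pair for the cutoffs.
#' @param method Jackknife estimator.
#' @return A `null_cutoffs` object: list with `low`, `high`, `n_pairs`,
#'   `n_probes`, `seed`.
#' @export
empirical_null <- function(beta, fpkm, manifest, models, n_probes = 50000,
                           seed = 221027, window_bp = 500000,
                           probs = c(0.025, 0.975), method = "min_abs") {
  universe <- unique(manifest$probe_id)
  replace <- length(universe) < n_probes
  if (replace) {
    rlang::warn(sprintf(
      "probe universe (%d) smaller than n_probes (%d); sampling with replacement",
      length(universe), n_probes))
  }
  drawn <- with_local_seed(seed, sample(universe, n_probes, replace = replace))
  sub <- manifest[match(unique(drawn), manifest$probe_id), , drop = FALSE]
  pairs <- map_cpg_to_genes(sub, models, window_bp = window_bp)
  pairs <- correlate_pairs(pairs, beta, fpkm, apply_filters = TRUE,
                           method = method)
  rs <- pairs$jackknife_r[!is.na(pairs$jackknife_r)]
  if (length(rs) == 0L) rlang::abort("no eligible null pairs")
  q <- stats::quantile(rs, probs = probs, type = 7, names = FALSE)
  structure(list(low = q[1L], high = q[2L], n_pairs = length(rs),
                 n_probes = n_probes, seed = seed),
            class = "null_cutoffs")
}

#' @export
print.null_cutoffs <- function(x, ...) {
  cat(sprintf("<null_cutoffs> low=%.4f high=%.4f (from %d pairs, %d probes, seed %d)\n",
              x$low, x$high, x$n_pairs, x$n_probes, x$seed))
  invisible(x)
}

#' Flag significant CpG-gene pairs against empirical null cutoffs
#'
#' Significant when the jackknife correlation is strictly below the low or
#' strictly above the high cutoff.
#'
#' @param pairs Tibble with a `jackknife_r` column.
#' @param cutoffs A `null_cutoffs` object (or list with `low`, `high`)
#'   computed on the same cohort.
#' @return `pairs` with a `significant` column.
#' @export
call_significant_pairs <- function(pairs, cutoffs) {
  pairs$significant <- !is.na(pairs$jackknife_r) &
    (pairs$jackknife_r < cutoffs$low | pairs$jackknife_r > cutoffs$high)
  pairs
}

#' Candidate epigenetically regulated genes
#'
#' Retains genes with (i) at least `min_cpgs` significant negatively
#' correlated CpG-gene pairs whose CpG lies within `tss_kbp` kbp of the TSS,
#' (ii) membership in the supplied differentially expressed gene set,
#' (iii) an absolute between-group median FPKM difference above
#' `min_median_diff`, and optionally (iv) a median fold change above
#' `min_fold_change` (computed on medians offset by 0.1 to keep zero medians
#' finite).
#'
#' @param pairs Pair table with `gene_id`, `tss_distance`, `jackknife_r`,
#'   `significant`.
#' @param de_genes Character vector of differentially expressed gene ids.
#' @param fpkm FPKM table or matrix (raw scale).
#' @param groups Two-group sample assignment for the median contrast.
#' @param tss_kbp TSS distance threshold in kbp (strict).
#' @param min_cpgs Minimum qualifying CpGs per gene.
#' @param min_median_diff Minimum absolute median FPKM difference (strict).
#' @param min_fold_change Optional minimum fold change (strict), `NULL` to
#'   skip.
#' @return Tibble of candidate genes with supporting counts and statistics.
#' @export
candidate_epigene_filter <- function(pairs, de_genes, fpkm, groups,
                                     tss_kbp = 7, min_cpgs = 3,
                                     min_median_diff = 5,
                                     min_fold_change = NULL) {
  fm <- as_assay_matrix(fpkm, what = "fpkm")
  g <- as_group_vector(groups, colnames(fm))
  lv <- sort(unique(g))
  if (length(lv) != 2L) rlang::abort("candidate filter needs exactly two groups")
  qual <- pairs %>%
    dplyr::filter(.data$significant,
                  !is.na(.data$jackknife_r), .data$jackknife_r < 0,
                  abs(.data$tss_distance) < tss_kbp * 1000) %>%
    dplyr::count(.data$gene_id, name = "n_cpgs") %>%
    dplyr::filter(.data$n_cpgs >= min_cpgs, .data$gene_id %in% de_genes)
  if (nrow(qual) == 0L) return(dplyr::mutate(qual, median_diff = double(0),
                                             fold_change = double(0)))
  idx <- match(qual$gene_id, rownames(fm))
  med1 <- unname(apply(fm[idx, g == lv[1L], drop = FALSE], 1L, stats::median,
                       na.rm = TRUE))
  med2 <- unname(apply(fm[idx, g == lv[2L], drop = FALSE], 1L, stats::median,
                       na.rm = TRUE))
  if (anyNA(idx) || anyNA(med1) || anyNA(med2)) {
    rlang::abort("missing group medians for candidate genes")
  }
  qual$median_diff <- abs(med1 - med2)
  qual$fold_change <- pmax(med1 + 0.1, med2 + 0.1) / pmin(med1 + 0.1, med2 + 0.1)
  qual <- dplyr::filter(qual, .data$median_diff > min_median_diff)
  if (!is.null(min_fold_change)) {
    qual <- dplyr::filter(qual, .data$fold_change > min_fold_change)
  }
  dplyr::arrange(qual, dplyr::desc(.data$n_cpgs), .data$gene_id)
}
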