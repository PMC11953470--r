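# Rank-sum (Wilcoxon / Mann-Whitney) p-value machinery ----------------------
#
# Two regimes, following common practice for array-scale testing:
#  * exact enumeration of rank permutations when both group sizes are small
#    (<= exact_max); two-sided p is the null probability of a rank sum at
#    least as far from its expectation as observed (valid under ties);
#  * normal approximation with tie and continuity correction otherwise,
#    reproducing the large-sample formula of the classical test.

# cache of choose(n, n1) index matrices for exact enumeration
combn_cache <- new.env(parent = emptyenv())

get_combn <- function(n, k) {
  key <- paste(n, k, sep = "_")
  if (is.null(combn_cache[[key]])) {
    combn_cache[[key]] <- utils::combn(n, k)
  }
  combn_cache[[key]]
}

wilcox_exact_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x); n <- length(r)
  t_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  cmb <- get_combn(n, n1)
  t_all <- colSums(matrix(r[cmb], nrow = n1))
  mean(abs(t_all - mu) >= abs(t_obs - mu) - 1e-12)
}

wilcox_normal_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  z <- u - n1 * n2 / 2
  nties <- tabulate(match(r, unique(r)))
  sigma <- sqrt((n1 * n2 / 12) *
                  ((n + 1) - sum(nties^3 - nties) / (n * (n - 1))))
  if (sigma == 0) return(1)
  z <- (z - sign(z) * 0.5) / sigma
  min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
}

rank_sum_p <- function(x, y, exact_max = 6L) {
  if (length(x) <= exact_max && length(y) <= exact_max) {
    wilcox_exact_p(x, y)
  } else {
    wilcox_normal_p(x, y)
  }
}

kruskal_p <- function(values, grp) {
  r <- rank(values)
  n <- length(values)
  ss <- tapply(r, grp, sum)
  ns <- tapply(r, grp, length)
  h <- 12 / (n * (n + 1)) * sum(ss^2 / ns) - 3 * (n + 1)
  nties <- tabulate(match(r, unique(r)))
  cor <- 1 - sum(nties^3 - nties) / (n^3 - n)
  if (cor == 0) return(1)
  stats::pchisq(h / cor, df = length(ss) - 1, lower.tail = FALSE)
}

# Shared per-feature engine for methylation and expression tables.
rank_test_table <- function(m, g, test, exact_max = 6L, min_coverage = 0.8) {
  groups <- sort(unique(g))
  ng <- length(groups)
  n <- nrow(m)
  p <- rep(NA_real_, n)
  skipped <- rep(FALSE, n)
  means <- matrix(NA_real_, n, ng, dimnames = list(NULL, groups))
  for (i in seq_len(n)) {
    x <- m[i, ]
    ok <- !is.na(x)
    if (mean(ok) < min_coverage) { skipped[i] <- TRUE; next }
    xs <- x[ok]; gs <- g[ok]
    if (length(unique(gs)) < ng || any(tabulate(factor(gs, groups)) < 1L)) {
      skipped[i] <- TRUE; next
    }
    means[i, ] <- tapply(xs, factor(gs, groups), mean)
    if (stats::sd(xs) == 0) { p[i] <- 1; next }
    p[i] <- if (test == "wilcoxon") {
      rank_sum_p(xs[gs == groups[1L]], xs[gs == groups[2L]], exact_max)
    } else {
      kruskal_p(xs, gs)
    }
  }
  list(p = p, means = means, skipped = skipped, groups = groups)
}

#' Differentially methylated CpGs between sample groups
#'
#' Per probe, a two-sided rank test across groups: Wilcoxon for two groups,
#' Kruskal-Wallis for more. A probe whose pooled (across-group) standard
#' deviation is 0 gets p = 1. P-values are adjusted across all tested probes
#' and a probe is significant when the adjusted p passes `p_cut` (or `p_cut`
#' is `NULL`, disabling the p filter) and the maximum pairwise absolute
#' difference of group mean betas exceeds `delta_cut`. For group sizes up to
#' 6 per group the Wilcoxon p-value is computed by exact enumeration of rank
#' permutations; the tie-corrected normal approximation is used above that.
#'
#' @param beta Beta table (first column probe id) or matrix.
#' @param groups Sample grouping: named vector or (`sample_id`, group) table;
#'   every group needs >= 2 samples.
#' @param test `"auto"` (Wilcoxon for 2 groups, Kruskal-Wallis otherwise),
#'   `"wilcoxon"` or `"kruskal"`.
#' @param adjust Multiple-testing adjustment: `"bonferroni"`, `"fdr"` or
#'   `"none"`.
#' @param p_cut Adjusted-p threshold (strict), or `NULL` to disable.
#' @param delta_cut Required max pairwise |delta mean beta| (strict).
#' @param min_coverage Minimum fraction of non-missing samples; probes below
#'   it are flagged `skipped` and excluded from testing and adjustment.
#' @return Tibble with `probe_id`, per-group `mean_*` columns, `delta`,
#'   `direction` (group with highest mean), `p`, `p_adj`, `skipped`,
#'   `significant`.
#' @export
diff_meth <- function(beta, groups, test = c("auto", "wilcoxon", "kruskal"),
                      adjust = c("bonferroni", "fdr", "none"), p_cut = 0.01,
                      delta_cut = 0.25, min_coverage = 0.8) {
  test <- rlang::arg_match(test)
  adjust <- rlang::arg_match(adjust)
  m <- as_assay_matrix(beta, what = "beta")
  g <- as_group_vector(groups, colnames(m))
  tab <- table(g)
  if (length(tab) < 2L) rlang::abort("need at least two groups")
  if (any(tab < 2L)) {
    rlang::abort(sprintf("group(s) with < 2 samples: %s",
                         paste(names(tab)[tab < 2L], collapse = ", ")))
  }
  if (test == "auto") test <- if (length(tab) == 2L) "wilcoxon" else "kruskal"
  if (test == "wilcoxon" && length(tab) != 2L) {
    rlang::abort("wilcoxon test requires exactly two groups")
  }
  res <- rank_test_table(m, g, test, min_coverage = min_coverage)
  adj_method <- c(bonferroni = "bonferroni", fdr = "fdr", none = "none")[adjust]
  p_adj <- rep(NA_real_, nrow(m))
  tested <- !is.na(res$p)
  p_adj[tested] <- stats::p.adjust(res$p[tested], method = adj_method)
  rng <- apply(res$means, 1L, function(x) {
    if (all(is.na(x))) c(NA_real_, NA_real_) else range(x, na.rm = TRUE)
  })
  delta <- rng[2L, ] - rng[1L, ]
  direction <- res$groups[apply(res$means, 1L, function(x) {
    if (all(is.na(x))) NA_integer_ else which.max(x)
  })]
  direction[is.na(delta) | delta == 0] <- NA_character_
  out <- tibble::tibble(probe_id = rownames(m))
  for (gx in res$groups) out[[paste0("mean_", gx)]] <- res$means[, gx]
  out$delta <- delta
  out$direction <- direction
  out$p <- res$p
  out$p_adj <- p_adj
  out$skipped <- res$skipped
  pass_p <- if (is.null(p_cut)) tested else (tested & !is.na(p_adj) & p_adj < p_cut)
  out$significant <- pass_p & !is.na(delta) & delta > delta_cut
  class(out) <- c("diff_meth_tbl", class(out))
  out
}

#' Annotate differential methylation records with the inferred-normal shift
#'
#' For a chosen tumor group, adds the difference between the group's mean
#' (tumor) beta and the mean inferred in-silico normal beta over the same
#' samples, plus the normal hypo/hyper background state
#' (see [classify_methylation_state()]).
#'
#' @param records Output of [diff_meth()].
#' @param inferred_normal Per-probe mean inferred normal beta over the
#'   relevant samples: named vector or (`probe_id`, `normal_mean`) table.
#' @param group Name of the tumor group whose mean is contrasted (must match
#'   a `mean_<group>` column of `records`).
#' @return `records` with `normal_mean`, `normal_shift` and `normal_state`.
#' @export
contrast_with_normal <- function(records, inferred_normal, group) {
  col <- paste0("mean_", group)
  if (!col %in% names(records)) {
    rlang::abort(sprintf("no column '%s' in records", col))
  }
  if (is.data.frame(inferred_normal)) {
    nm <- stats::setNames(inferred_normal[[2L]], inferred_normal[[1L]])
  } else {
    nm <- inferred_normal
  }
  if (is.null(nm) || !all(records$probe_id %in% names(nm))) {
    rlang::abort("inferred normal values missing for some probes")
  }
  nv <- unname(nm[records$probe_id])
  records$normal_mean <- nv
  records$normal_shift <- records[[col]] - nv
  records$normal_state <- classify_methylation_state(nv)
  records
}
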