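#' Select the most variable CpGs within a genomic context
#'
#' Probes passing the context filter are ranked by standard deviation across
#' samples (descending, ties broken by lexical probe id) and the top `n_top`
#' are returned. Probes with any missing beta are excluded so the SD ranking
#' is comparable across probes.
#'
#' @param beta Beta table (first column probe id) or matrix.
#' @param annotations Annotation table from [annotate_cpgs()].
#' @param context_filter Filter expression evaluated in the annotation table,
#'   e.g. `genic_context == "distal" & atac_overlap`; omit to keep all probes.
#' @param n_top Number of probes to keep.
#' @return Tibble `probe_id`, `sd` ordered by descending SD (a feature set);
#'   if fewer than `n_top` probes qualify, all are returned with a warning.
#' @export
select_top_variant <- function(beta, annotations = NULL, context_filter = NULL,
                               n_top = 5000) {
  m <- as_assay_matrix(beta, what = "beta")
  if (ncol(m) < 2L) rlang::abort("need at least two samples")
  keep <- rownames(m)
  qf <- rlang::enquo(context_filter)
  if (!rlang::quo_is_null(qf)) {
    if (is.null(annotations)) rlang::abort("context_filter needs an annotation table")
    sel <- rlang::eval_tidy(qf, data = annotations)
    keep <- intersect(keep, annotations$probe_id[sel])
  }
  m <- m[rownames(m) %in% keep, , drop = FALSE]
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) == 0L) rlang::abort("no probes pass the context filter")
  mu <- rowMeans(m)
  sds <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  ord <- order(-sds, rownames(m))
  if (length(ord) < n_top) {
    rlang::warn(sprintf("only %d probes eligible (< n_top = %d); returning all",
                        length(ord), n_top))
  }
  take <- ord[seq_len(min(n_top, length(ord)))]
  tibble::tibble(probe_id = rownames(m)[take], sd = unname(sds[take]))
}

# Kullback-Leibler divergence D(V || WH) with the usual convention for
# zero entries of V.
kl_divergence <- function(V, WH, eps = 1e-12) {
  WH <- pmax(WH, eps)
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

nmf_run_once <- function(V, k, max_iter, tol, eps = 1e-12) {
  n <- nrow(V); p <- ncol(V)
  W <- matrix(stats::runif(n * k, 0.1, 1), n, k)
  H <- matrix(stats::runif(k * p, 0.1, 1), k, p)
  .nmf_kl_fit(V, W, H, max_iter = max_iter, tol = tol, eps = eps)
}

#' Cluster samples by non-negative matrix factorization
#'
#' Multiplicative-update NMF with the Kullback-Leibler objective, restarted
#' `nrun` times from seeded random initialisations (restart seeds derived
#' deterministically as `seed + run index`); the best run by objective is
#' kept. Each sample is assigned to the factor with its largest mixture
#' coefficient. The result is fully deterministic given
#' `(matrix, k, nrun, seed)` and the caller's RNG state is left untouched.
#'
#' @param beta Non-negative probes x samples table (first column probe id)
#'   or matrix.
#' @param k Number of clusters / factors, `2 <= k < min(dim)`.
#' @param nrun Number of random restarts.
#' @param seed Master seed for the restart initialisations.
#' @param max_iter,tol Convergence controls: stop when the relative change
#'   of the objective falls below `tol`, or after `max_iter` iterations.
#' @return An `epitype_fit` object: `assignment` tibble (`sample_id`,
#'   `cluster`), basis `W`, mixture `H`, `objective`, `run_objectives`,
#'   and run metadata. Supports [tidy()], [glance()] and [autoplot()].
#' @export
nmf_cluster <- function(beta, k, nrun = 30, seed = 221027,
                        max_iter = 2000, tol = 1e-6) {
  V <- as_assay_matrix(beta, what = "beta")
  if (k < 2L) rlang::abort("k must be >= 2")
  if (k >= min(dim(V))) {
    rlang::abort(sprintf("k = %d must be < min(dim) = %d", k, min(dim(V))))
  }
  if (any(is.na(V))) rlang::abort("matrix contains missing values")
  if (any(V < 0)) rlang::abort("matrix must be non-negative")
  zero_col <- colSums(V) == 0
  if (any(zero_col)) {
    rlang::abort(sprintf("all-zero column for sample(s): %s",
                         paste(colnames(V)[zero_col], collapse = ", ")))
  }
  runs <- with_local_seed(seed, {
    lapply(seq_len(nrun), function(r) {
      set.seed(seed + r)
      nmf_run_once(V, k, max_iter = max_iter, tol = tol)
    })
  })
  objs <- vapply(runs, `[[`, numeric(1), "objective")
  best <- runs[[which.min(objs)]]
  cluster <- apply(best$H, 2L, which.max)
  assignment <- tibble::tibble(sample_id = colnames(V),
                               cluster = as.integer(cluster))
  structure(list(assignment = assignment, W = best$W, H = best$H,
                 k = k, objective = best$objective, run_objectives = objs,
                 iterations = best$iterations, nrun = nrun, seed = seed,
                 probes = rownames(V)),
            class = "epitype_fit")
}

#' @export
print.epitype_fit <- function(x, ...) {
  cat(sprintf("<epitype_fit> k=%d, %d samples, %d probes, KL objective %.4g (best of %d runs)\n",
              x$k, nrow(x$assignment), length(x$probes), x$objective, x$nrun))
  print(table(cluster = x$assignment$cluster))
  invisible(x)
}

#' Concordance between a two-cluster split and a binary label
#'
#' Accuracy maximised over the two possible cluster-to-label mappings, so the
#' measure is invariant to cluster relabeling.
#'
#' @param assignment Tibble (`sample_id`, `cluster`), named vector, or an
#'   `epitype_fit`.
#' @param labels Tibble (`sample_id`, label) or named vector with exactly two
#'   levels, defined on the same samples.
#' @return Accuracy fraction in [0.5, 1] for balanced labels.
#' @export
cluster_label_concordance <- function(assignment, labels) {
  if (inherits(assignment, "epitype_fit")) assignment <- assignment$assignment
  a <- as_group_vector(assignment)
  l <- as_group_vector(labels, samples = names(a))
  ua <- sort(unique(a)); ul <- sort(unique(l))
  if (length(ua) > 2L || length(ul) != 2L) {
    rlang::abort("concordance needs a <=2-cluster assignment and a binary label")
  }
  acc <- mean((a == ua[1L]) == (l == ul[1L]))
  max(acc, 1 - acc)
}

#' Row-cluster CpGs for heatmap structure
#'
#' Agglomerative clustering of probes with Euclidean distance and Ward's
#' minimum-variance linkage (`ward.D`), cut into `n_clusters` groups.
#'
#' @param beta Beta table (first column probe id) or matrix.
#' @param n_clusters Number of row clusters (>= 2).
#' @return Tibble `probe_id`, `row_cluster`.
#' @export
hier_cluster_cpgs <- function(beta, n_clusters) {
  if (n_clusters < 2L) rlang::abort("n_clusters must be >= 2")
  m <- as_assay_matrix(beta, what = "beta")
  if (nrow(m) < n_clusters) rlang::abort("fewer probes than clusters")
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "ward.D")
  cl <- stats::cutree(hc, k = n_clusters)
  tibble::tibble(probe_id = rownames(m), row_cluster = as.integer(cl))
}
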