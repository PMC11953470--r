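#' Fit a per-CpG purity model
#'
#' Bulk beta values mix the malignant and non-malignant methylation states in
#' proportion to tumor cell content, so per CpG the observed beta is close to
#' linear in purity within a homogeneous group of tumors. Samples are first
#' partitioned into up to `max_pops` methylation populations by 1-D k-means
#' on beta (k chosen by mean silhouette; k = 1 when no split reaches
#' `silhouette_min`), then each population gets a least-squares line
#' `beta ~ purity` with the slope confined to [-1, 1] (beta is a fraction of
#' a two-component mixture, so no line can move faster than the mixture
#' itself). When the slope is clipped the intercept is refit through the
#' population centroid.
#'
#' @param betas Named numeric vector of beta values for one probe
#'   (names = sample ids).
#' @param purities Named numeric vector of tumor purity fractions in (0, 1].
#' @param max_pops Maximum number of methylation populations (<= 3).
#' @param min_samples Minimum usable samples; below it the model is flagged
#'   unfit and adjustment returns its input unchanged.
#' @param silhouette_min Mean-silhouette threshold below which k = 1 is kept.
#' @param seed Unused placeholder kept for interface stability; population
#'   discovery is deterministic (quantile-initialised k-means).
#' @return An object of class `cpg_purity_model`: list with `fitted`,
#'   `populations` (slope, intercept, members) and `assignment`.
#' @export
fit_cpg_model <- function(betas, purities, max_pops = 3, min_samples = 10,
                          silhouette_min = 0.60, seed = 221027) {
  if (is.null(names(betas))) names(betas) <- names(purities)
  common <- intersect(names(betas), names(purities))
  b <- betas[common]; p <- purities[common]
  ok <- !is.na(b) & !is.na(p)
  b <- b[ok]; p <- p[ok]
  if (any(p <= 0 | p > 1)) rlang::abort("purity must be in (0, 1]")
  if (length(b) < min_samples) {
    return(structure(list(fitted = FALSE, populations = list(),
                          assignment = integer(0)),
                     class = "cpg_purity_model"))
  }
  k <- choose_k_1d(b, max_k = max_pops, silhouette_min = silhouette_min)
  cl <- kmeans_1d(b, k)
  pops <- lapply(seq_len(k), function(j) {
    members <- names(b)[cl == j]
    fit_population_line(b[cl == j], p[cl == j])[c("slope", "intercept")] |>
      c(list(members = members))
  })
  assignment <- stats::setNames(cl, names(b))
  structure(list(fitted = TRUE, populations = pops, assignment = assignment),
            class = "cpg_purity_model")
}

# Least-squares line beta ~ purity with slope clipped to [-1, 1]; intercept
# refit through the centroid after clipping. Degenerate inputs (constant
# beta or constant purity) give slope 0.
fit_population_line <- function(b, p) {
  if (length(b) < 2L || stats::sd(b) == 0 || stats::sd(p) == 0) {
    return(list(slope = 0, intercept = mean(b)))
  }
  slope <- stats::cov(b, p) / stats::var(p)
  slope <- max(-1, min(1, slope))
  list(slope = slope, intercept = mean(b) - slope * mean(p))
}

# Deterministic 1-D k-means: centers initialised at the (j - 0.5)/k
# quantiles, Lloyd iterations on the line until assignment is stable.
kmeans_1d <- function(x, k, max_iter = 100L) {
  if (k == 1L) return(rep(1L, length(x)))
  centers <- unname(stats::quantile(x, probs = (seq_len(k) - 0.5) / k, type = 7))
  if (length(unique(centers)) < k) {
    centers <- centers + seq_len(k) * 1e-9  # degenerate spread; split formally
  }
  cl <- rep(1L, length(x))
  for (i in seq_len(max_iter)) {
    d <- abs(outer(x, centers, "-"))
    new_cl <- max.col(-d, ties.method = "first")
    if (identical(new_cl, cl) && i > 1L) break
    cl <- new_cl
    centers <- vapply(seq_len(k), function(j) {
      if (any(cl == j)) mean(x[cl == j]) else centers[j]
    }, numeric(1))
  }
  # relabel so population 1 has the lowest center
  ord <- order(centers)
  match(cl, ord)
}

# Mean silhouette width from pairwise 1-D distances (vectorised: per-cluster
# distance sums via one matrix product).
mean_silhouette_1d <- function(x, cl) {
  k <- max(cl)
  n <- length(x)
  sizes <- tabulate(cl, k)
  if (k < 2L || any(sizes < 2L)) return(-Inf)
  D <- abs(outer(x, x, "-"))
  M <- matrix(0, n, k)
  M[cbind(seq_len(n), cl)] <- 1
  S <- D %*% M                        # S[i, c] = sum of |x_i - x_j|, j in c
  own <- cbind(seq_len(n), cl)
  a <- S[own] / (sizes[cl] - 1L)
  Sm <- sweep(S, 2L, sizes, "/")
  Sm[own] <- Inf
  b <- do.call(pmin, lapply(seq_len(k), function(j) Sm[, j]))
  mx <- pmax(a, b)
  s <- ifelse(mx == 0, 0, (b - a) / mx)
  mean(s)
}

choose_k_1d <- function(x, max_k = 3, silhouette_min = 0.60) {
  if (stats::sd(x) == 0) return(1L)
  best_k <- 1L; best_s <- -Inf
  for (k in 2:max_k) {
    if (length(unique(x)) < k) next
    cl <- kmeans_1d(x, k)
    s <- mean_silhouette_1d(x, cl)
    if (is.finite(s) && s > best_s) { best_s <- s; best_k <- k }
  }
  if (best_s >= silhouette_min) best_k else 1L
}

# Population index for a (beta, purity) pair: the sample's own population if
# it was fitted, otherwise the line with the smallest absolute residual.
population_for <- function(model, sample_id, beta_obs, purity) {
  if (!is.null(sample_id) && sample_id %in% names(model$assignment)) {
    return(unname(model$assignment[sample_id]))
  }
  resid <- vapply(model$populations, function(pop) {
    abs(beta_obs - (pop$intercept + pop$slope * purity))
  }, numeric(1))
  which.min(resid)
}

#' Adjust observed beta values to full tumor purity
#'
#' Each sample's population line is extrapolated to purity 1 while preserving
#' the sample's residual, so inter-tumor heterogeneity survives adjustment:
#' `adjusted = (intercept + slope) + (beta_obs - (intercept + slope * purity))`,
#' clamped to [0, 1]. At purity 1 the adjustment is the identity. Unfit models
#' return the input unchanged.
#'
#' @param model A `cpg_purity_model` (single probe) or `cpg_purity_fit`
#'   (cohort) object.
#' @param beta_obs Observed beta value(s); for a cohort fit, a beta table or
#'   matrix.
#' @param purity Purity value(s) aligned with `beta_obs`; for a cohort fit, a
#'   purity table (`sample_id`, `purity`) or named vector.
#' @param sample_id Optional sample id(s) used to look up the fitted
#'   population; samples not seen at fit time are assigned to the nearest
#'   line by residual.
#' @return Adjusted beta values with the shape of the input.
#' @export
adjust_beta <- function(model, beta_obs, purity, sample_id = NULL) {
  UseMethod("adjust_beta")
}

#' @export
adjust_beta.cpg_purity_model <- function(model, beta_obs, purity, sample_id = NULL) {
  if (!model$fitted) return(beta_obs)
  n <- length(beta_obs)
  if (is.null(sample_id)) sample_id <- names(beta_obs) %||% rep(NA_character_, n)
  slopes <- vapply(model$populations, `[[`, numeric(1), "slope")
  icepts <- vapply(model$populations, `[[`, numeric(1), "intercept")
  j <- unname(model$assignment[sample_id])
  if (anyNA(j)) {
    # samples unseen at fit time: nearest line by residual
    unk <- which(is.na(j) & !is.na(beta_obs) & !is.na(purity))
    if (length(unk) > 0L) {
      resid <- vapply(seq_along(slopes), function(p) {
        abs(beta_obs[unk] - (icepts[p] + slopes[p] * purity[unk]))
      }, numeric(length(unk)))
      resid <- matrix(resid, nrow = length(unk))
      j[unk] <- max.col(-resid, ties.method = "first")
    }
  }
  out <- clamp01(beta_obs + slopes[j] * (1 - purity))
  out[is.na(beta_obs) | is.na(purity)] <- NA_real_
  names(out) <- names(beta_obs)
  out
}

#' Inferred in-silico normal beta
#'
#' The population line evaluated at purity 0 (its intercept), clamped to
#' [0, 1]: the methylation state the non-malignant compartment of that sample
#' is estimated to carry. Unfit models give `NA`.
#'
#' @inheritParams adjust_beta
#' @param sample_id Sample id(s) to evaluate (fitted samples by default).
#' @return Named numeric vector of inferred normal beta values.
#' @export
infer_normal <- function(model, sample_id = NULL) {
  UseMethod("infer_normal")
}

#' @export
infer_normal.cpg_purity_model <- function(model, sample_id = NULL) {
  if (!model$fitted) {
    if (is.null(sample_id)) return(NA_real_)
    return(stats::setNames(rep(NA_real_, length(sample_id)), sample_id))
  }
  if (is.null(sample_id)) sample_id <- names(model$assignment)
  j <- unname(model$assignment[sample_id])
  icepts <- vapply(model$populations, `[[`, numeric(1), "intercept")
  stats::setNames(clamp01(icepts[j]), sample_id)
}

#' Classify the background methylation state of a CpG
#'
#' Hypomethylated when the mean beta across analysed tumors is <= 0.5,
#' hypermethylated otherwise.
#'
#' @param mean_beta Numeric vector of per-probe mean beta values.
#' @return Character vector, `"hypo"` or `"hyper"`.
#' @export
classify_methylation_state <- function(mean_beta) {
  if (any(is.na(mean_beta))) rlang::abort("mean beta contains missing values")
  ifelse(mean_beta <= 0.5, "hypo", "hyper")
}

#' Fit purity models for every probe of a cohort
#'
#' Applies [fit_cpg_model()] to each row of a beta table against a shared
#' purity vector.
#'
#' @param beta Beta table (first column probe id) or matrix, probes x samples.
#' @param purity Purity table (`sample_id`, `purity`) or named vector.
#' @inheritParams fit_cpg_model
#' @return An object of class `cpg_purity_fit` holding one `cpg_purity_model`
#'   per probe. Use [adjust_beta()], [infer_normal()], [tidy()] on it.
#' @export
fit_purity_models <- function(beta, purity, max_pops = 3, min_samples = 10,
                              silhouette_min = 0.60, seed = 221027) {
  m <- as_assay_matrix(beta, what = "beta")
  p <- as_purity_vector(purity, colnames(m))
  models <- lapply(seq_len(nrow(m)), function(i) {
    fit_cpg_model(m[i, ], p, max_pops = max_pops, min_samples = min_samples,
                  silhouette_min = silhouette_min, seed = seed)
  })
  names(models) <- rownames(m)
  structure(list(models = models, samples = colnames(m), purity = p),
            class = "cpg_purity_fit")
}

as_purity_vector <- function(purity, samples = NULL) {
  if (is.data.frame(purity)) {
    p <- stats::setNames(as.numeric(purity$purity), as.character(purity$sample_id))
  } else {
    if (is.null(names(purity))) rlang::abort("purity vector must be named by sample id")
    p <- purity
  }
  if (any(!is.na(p) & (p <= 0 | p > 1))) rlang::abort("purity must be in (0, 1]")
  if (!is.null(samples)) {
    missing <- setdiff(samples, names(p))
    if (length(missing) > 0L) {
      rlang::abort(sprintf("no purity for sample(s): %s",
                           paste(utils::head(missing, 5L), collapse = ", ")))
    }
    p <- p[samples]
  }
  p
}

#' @export
adjust_beta.cpg_purity_fit <- function(model, beta_obs, purity = NULL, sample_id = NULL) {
  m <- as_assay_matrix(beta_obs, what = "beta")
  p <- if (is.null(purity)) model$purity else as_purity_vector(purity, colnames(m))
  adj <- m
  for (i in seq_len(nrow(m))) {
    pm <- model$models[[rownames(m)[i]]]
    if (is.null(pm)) next
    adj[i, ] <- adjust_beta(pm, stats::setNames(m[i, ], colnames(m)), p)
  }
  if (is.matrix(beta_obs)) adj else matrix_to_tbl(adj, names(beta_obs)[1L])
}

#' @export
infer_normal.cpg_purity_fit <- function(model, sample_id = NULL) {
  samples <- sample_id %||% model$samples
  out <- t(vapply(model$models, function(pm) {
    unname(infer_normal(pm, samples))
  }, numeric(length(samples))))
  colnames(out) <- samples
  rownames(out) <- names(model$models)
  matrix_to_tbl(out, "probe_id")
}

#' @export
print.cpg_purity_fit <- function(x, ...) {
  nfit <- sum(vapply(x$models, function(m) m$fitted, logical(1)))
  cat(sprintf("<cpg_purity_fit> %d probes (%d fitted), %d samples\n",
              length(x$models), nfit, length(x$samples)))
  invisible(x)
}

#' @export
print.cpg_purity_model <- function(x, ...) {
  cat(sprintf("<cpg_purity_model> fitted=%s, %d population(s)\n",
              x$fitted, length(x$populations)))
  invisible(x)
}
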