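#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an epitype fit into per-sample assignments
#'
#' @param x An `epitype_fit`.
#' @param ... Unused.
#' @return Tibble `sample_id`, `cluster`, and the sample's mixture
#'   coefficients (`h_1` ... `h_k`).
#' @method tidy epitype_fit
#' @export
tidy.epitype_fit <- function(x, ...) {
  h <- t(x$H)
  colnames(h) <- paste0("h_", seq_len(x$k))
  dplyr::bind_cols(x$assignment, tibble::as_tibble(h))
}

#' One-row summary of an epitype fit
#'
#' @inheritParams tidy.epitype_fit
#' @return Tibble with `k`, `n_samples`, `n_probes`, `objective`,
#'   `best_run`, `nrun`, `seed`.
#' @method glance epitype_fit
#' @export
glance.epitype_fit <- function(x, ...) {
  tibble::tibble(k = x$k, n_samples = nrow(x$assignment),
                 n_probes = length(x$probes), objective = x$objective,
                 best_run = which.min(x$run_objectives), nrun = x$nrun,
                 seed = x$seed)
}

#' Tidy a cohort purity fit into per-population lines
#'
#' @param x A `cpg_purity_fit`.
#' @param ... Unused.
#' @return Tibble `probe_id`, `population`, `slope`, `intercept`,
#'   `n_samples`, `fitted`.
#' @method tidy cpg_purity_fit
#' @export
tidy.cpg_purity_fit <- function(x, ...) {
  purrr::imap(x$models, function(m, pid) {
    if (!m$fitted) {
      return(tibble::tibble(probe_id = pid, population = NA_integer_,
                            slope = NA_real_, intercept = NA_real_,
                            n_samples = 0L, fitted = FALSE))
    }
    tibble::tibble(
      probe_id = pid,
      population = seq_along(m$populations),
      slope = vapply(m$populations, `[[`, numeric(1), "slope"),
      intercept = vapply(m$populations, `[[`, numeric(1), "intercept"),
      n_samples = vapply(m$populations, function(p) length(p$members), integer(1)),
      fitted = TRUE
    )
  }) %>% dplyr::bind_rows()
}

#' One-row summary of a cohort purity fit
#'
#' @inheritParams tidy.cpg_purity_fit
#' @return Tibble with probe/sample counts and the population-count
#'   distribution.
#' @method glance cpg_purity_fit
#' @export
glance.cpg_purity_fit <- function(x, ...) {
  npop <- vapply(x$models, function(m) {
    if (m$fitted) length(m$populations) else NA_integer_
  }, integer(1))
  tibble::tibble(n_probes = length(x$models),
                 n_fitted = sum(!is.na(npop)),
                 n_samples = length(x$samples),
                 mean_populations = mean(npop, na.rm = TRUE))
}

#' Tidy a gene network set into a membership table
#'
#' @param x A `gene_network_set`.
#' @param ... Unused.
#' @return Tibble `network_id`, `gene_id`, `n_genes`.
#' @method tidy gene_network_set
#' @export
tidy.gene_network_set <- function(x, ...) {
  purrr::map(x$networks, function(nw) {
    tibble::tibble(network_id = nw$network_id, gene_id = nw$genes,
                   n_genes = length(nw$genes))
  }) %>% dplyr::bind_rows()
}

#' Per-sample network metagene scores for all networks
#'
#' @param networks A `gene_network_set`.
#' @return Tibble `sample_id`, `network_id`, `score`.
#' @export
network_scores <- function(networks) {
  purrr::map(networks$networks, function(nw) {
    dplyr::mutate(nw$scores, network_id = nw$network_id, .after = "sample_id")
  }) %>% dplyr::bind_rows()
}
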