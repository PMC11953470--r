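#' @importFrom rlang .data abort warn enquo eval_tidy quo_is_null
#' @importFrom dplyr %>%
NULL

# Coerce a wide assay table (first column = feature id, remaining columns =
# numeric sample values) to a numeric matrix with feature rownames. Accepts a
# matrix directly.
as_assay_matrix <- function(x, id_col = NULL, what = "assay") {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) {
      rlang::abort(sprintf("%s matrix must have rownames (feature ids)", what))
    }
    storage.mode(x) <- "double"
    return(x)
  }
  if (!is.data.frame(x)) {
    rlang::abort(sprintf("%s must be a data frame or matrix", what))
  }
  if (is.null(id_col)) id_col <- names(x)[1L]
  ids <- as.character(x[[id_col]])
  if (anyDuplicated(ids)) {
    rlang::abort(sprintf("duplicated feature ids in %s table", what))
  }
  num_cols <- setdiff(names(x), id_col)
  m <- as.matrix(x[num_cols])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

# Back to a tibble with an id column.
matrix_to_tbl <- function(m, id_col) {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out <- tibble::add_column(out, !!id_col := rownames(m), .before = 1L)
  out
}

# Group specification: named vector (names = sample ids) or two-column data
# frame (sample_id, <group>). Returns named character vector.
as_group_vector <- function(groups, samples = NULL) {
  if (is.data.frame(groups)) {
    if (ncol(groups) < 2L) rlang::abort("group table needs sample id and group columns")
    g <- as.character(groups[[2L]])
    names(g) <- as.character(groups[[1L]])
  } else {
    if (is.null(names(groups))) rlang::abort("group vector must be named by sample id")
    g <- as.character(groups)
    names(g) <- names(groups)
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, names(g))
    if (length(missing) > 0L) {
      rlang::abort(sprintf("no group for sample(s): %s",
                           paste(utils::head(missing, 5L), collapse = ", ")))
    }
    g <- g[samples]
  }
  g
}

# Evaluate a block with a private RNG stream, restoring the caller's state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @useDynLib epityper, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL
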