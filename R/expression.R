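#' Log-transform FPKM expression
#'
#' `x -> log2(x + 0.1)`; the offset keeps zeros finite while preserving
#' ordering.
#'
#' @param fpkm FPKM table (first column gene id) or matrix, values >= 0.
#' @return Transformed values with the shape of the input.
#' @export
transform_fpkm <- function(fpkm) {
  m <- as_assay_matrix(fpkm, what = "fpkm")
  if (any(m < 0, na.rm = TRUE)) rlang::abort("FPKM values must be non-negative")
  out <- log2(m + 0.1)
  if (is.matrix(fpkm)) out else matrix_to_tbl(out, names(fpkm)[1L])
}

#' Differentially expressed genes between sample groups
#'
#' Rank tests (Wilcoxon for two groups, Kruskal-Wallis for more) on
#' log-transformed FPKM, FDR adjustment across genes; a gene is significant
#' when the adjusted p is below `fdr` and the raw-scale difference between
#' the highest and lowest group median FPKM exceeds `min_fpkm_diff` (the
#' effect-size filter excludes low-expression genes significant only through
#' sample size). Direction is the group with the highest median.
#'
#' @param fpkm FPKM table (first column gene id) or matrix, raw scale.
#' @param groups Sample grouping (>= 2 groups, >= 2 samples each).
#' @param fdr Adjusted-p threshold.
#' @param min_fpkm_diff Required max - min group median FPKM (raw scale,
#'   strict).
#' @param min_coverage Minimum fraction of non-missing samples per gene.
#' @return Tibble `gene_id`, per-group `median_*`, `fpkm_diff`, `direction`,
#'   `p`, `p_adj`, `significant`.
#' @export
diff_expr <- function(fpkm, groups, fdr = 0.05, min_fpkm_diff = 1,
                      min_coverage = 0.8) {
  fm <- as_assay_matrix(fpkm, what = "fpkm")
  g <- as_group_vector(groups, colnames(fm))
  tab <- table(g)
  if (length(tab) < 2L) rlang::abort("need at least two groups")
  if (any(tab < 2L)) rlang::abort("every group needs >= 2 samples")
  test <- if (length(tab) == 2L) "wilcoxon" else "kruskal"
  lm_ <- log2(fm + 0.1)
  res <- rank_test_table(lm_, g, test, min_coverage = min_coverage)
  medians <- t(apply(fm, 1L, function(x) {
    tapply(x, factor(g, res$groups), stats::median, na.rm = TRUE)
  }))
  p_adj <- rep(NA_real_, nrow(fm))
  tested <- !is.na(res$p)
  p_adj[tested] <- stats::p.adjust(res$p[tested], method = "fdr")
  fpkm_diff <- apply(medians, 1L, function(x) diff(range(x)))
  direction <- res$groups[max.col(medians, ties.method = "first")]
  direction[fpkm_diff == 0] <- NA_character_
  out <- tibble::tibble(gene_id = rownames(fm))
  for (gx in res$groups) out[[paste0("median_", gx)]] <- medians[, gx]
  out$fpkm_diff <- fpkm_diff
  out$direction <- direction
  out$p <- res$p
  out$p_adj <- p_adj
  out$significant <- tested & !is.na(p_adj) & p_adj < fdr &
    fpkm_diff > min_fpkm_diff
  out
}

#' Group-specific differentially expressed genes for three groups
#'
#' Stepwise scheme: (i) restrict to genes significant in the overall
#' Kruskal-Wallis analysis (FDR p below `fdr` and median FPKM span above
#' `min_fpkm_diff`); (ii) on that restricted set compute the three pairwise
#' Wilcoxon tests and FDR-adjust each pairwise family separately; (iii) a
#' gene is specific to group g when both pairwise tests involving g are
#' significant and the remaining pairwise test is not. Direction compares
#' g's median with the other groups' medians.
#'
#' @inheritParams diff_expr
#' @return Tibble `gene_id`, `specific_group` (`NA` when none), `direction`
#'   (`"up"`/`"down"`), the three pairwise adjusted p-values, and the
#'   overall results.
#' @export
diff_expr_group_specific <- function(fpkm, groups, fdr = 0.05,
                                     min_fpkm_diff = 1) {
  fm <- as_assay_matrix(fpkm, what = "fpkm")
  g <- as_group_vector(groups, colnames(fm))
  lv <- sort(unique(g))
  if (length(lv) != 3L) rlang::abort("group-specific scheme needs exactly 3 groups")
  overall <- diff_expr(fm, g, fdr = fdr, min_fpkm_diff = min_fpkm_diff)
  sig <- overall$gene_id[overall$significant]
  out <- overall %>%
    dplyr::mutate(specific_group = NA_character_,
                  spec_direction = NA_character_)
  if (length(sig) == 0L) return(out)
  lm_ <- log2(fm[sig, , drop = FALSE] + 0.1)
  pair_names <- utils::combn(lv, 2L, paste, collapse = "|")
  pairwise <- matrix(NA_real_, length(sig), 3L,
                     dimnames = list(sig, pair_names))
  pairs <- utils::combn(lv, 2L, simplify = FALSE)
  for (j in seq_along(pairs)) {
    a <- pairs[[j]][1L]; b <- pairs[[j]][2L]
    praw <- vapply(seq_along(sig), function(i) {
      x <- lm_[i, g == a]; y <- lm_[i, g == b]
      ok_x <- !is.na(x); ok_y <- !is.na(y)
      if (sum(ok_x) < 2L || sum(ok_y) < 2L) return(NA_real_)
      if (stats::sd(c(x[ok_x], y[ok_y])) == 0) return(1)
      rank_sum_p(x[ok_x], y[ok_y])
    }, numeric(1))
    pairwise[, j] <- stats::p.adjust(praw, method = "fdr")
  }
  med_cols <- paste0("median_", lv)
  for (i in seq_along(sig)) {
    gene <- sig[i]
    padj <- pairwise[i, ]
    sig_pair <- !is.na(padj) & padj < fdr
    for (k in seq_along(lv)) {
      involves <- vapply(pairs, function(p) lv[k] %in% p, logical(1))
      if (all(sig_pair[involves]) && !any(sig_pair[!involves])) {
        row <- match(gene, out$gene_id)
        meds <- unlist(out[row, med_cols])
        others <- meds[-k]
        out$specific_group[row] <- lv[k]
        out$spec_direction[row] <-
          if (meds[k] > max(others)) "up" else "down"
        break
      }
    }
  }
  pw <- tibble::as_tibble(pairwise)
  names(pw) <- paste0("p_adj_", gsub("\\|", "_vs_", pair_names))
  pw$gene_id <- sig
  dplyr::left_join(out, pw, by = "gene_id")
}

#' Metagene rank score per sample
#'
#' Within each sample all genes are ranked ascending by FPKM (ties get
#' average ranks) and the score is the mean rank of the metagene members
#' divided by the total gene count, giving a value in (0, 1] that is
#' invariant under any monotone transform of the sample's expression vector.
#'
#' @param fpkm FPKM table (first column gene id) or matrix.
#' @param gene_set Character vector of member gene ids (non-empty overlap
#'   with the matrix required).
#' @return Tibble `sample_id`, `score`.
#' @export
metagene_rank_score <- function(fpkm, gene_set) {
  fm <- as_assay_matrix(fpkm, what = "fpkm")
  members <- intersect(gene_set, rownames(fm))
  if (length(members) == 0L) rlang::abort("gene set has no overlap with the matrix")
  G <- nrow(fm)
  scores <- apply(fm, 2L, function(x) {
    r <- rank(x, ties.method = "average")
    mean(r[match(members, rownames(fm))]) / G
  })
  tibble::tibble(sample_id = colnames(fm), score = unname(scores))
}

#' Extract co-expression gene networks
#'
#' All pairwise Spearman correlations on raw FPKM; genes are connected when
#' r >= `r_cut` (positive correlations only) and the connected components of
#' that graph with at least `min_genes` members are the networks. Each
#' network carries a per-sample score: the median raw FPKM over its member
#' genes. Constant genes are dropped with a warning (their rank correlation
#' is undefined).
#'
#' @param fpkm FPKM table (first column gene id) or matrix; >= `min_genes`
#'   genes and >= 10 samples.
#' @param r_cut Spearman threshold (inclusive).
#' @param min_genes Minimum component size.
#' @return A `gene_network_set` object: list with `networks` (each with
#'   `genes`, `edges`, `scores`), plus `r_cut`/`min_genes`. [tidy()] gives
#'   the membership table, [network_scores()] the sample x network scores.
#' @export
build_gene_networks <- function(fpkm, r_cut = 0.7, min_genes = 8) {
  fm <- as_assay_matrix(fpkm, what = "fpkm")
  if (ncol(fm) < 10L) rlang::abort("need at least 10 samples")
  const <- apply(fm, 1L, function(x) stats::sd(x, na.rm = TRUE) == 0)
  if (any(const)) {
    rlang::warn(sprintf("dropping %d constant gene(s)", sum(const)))
    fm <- fm[!const, , drop = FALSE]
  }
  if (nrow(fm) < min_genes) rlang::abort("fewer genes than min_genes")
  rho <- stats::cor(t(fm), method = "spearman", use = "pairwise.complete.obs")
  adj <- rho >= r_cut
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)
  keep <- which(comp$csize >= min_genes)
  networks <- lapply(seq_along(keep), function(i) {
    genes <- sort(names(comp$membership)[comp$membership == keep[i]])
    sub <- which(rownames(fm) %in% genes)
    ed <- which(adj[sub, sub, drop = FALSE] & upper.tri(adj[sub, sub]),
                arr.ind = TRUE)
    edges <- tibble::tibble(
      gene_a = rownames(fm)[sub][ed[, 1L]],
      gene_b = rownames(fm)[sub][ed[, 2L]],
      spearman_r = rho[cbind(sub[ed[, 1L]], sub[ed[, 2L]])]
    )
    scores <- network_score(fm, genes)
    list(network_id = i, genes = genes, edges = edges, scores = scores)
  })
  structure(list(networks = networks, r_cut = r_cut, min_genes = min_genes,
                 samples = colnames(fm)),
            class = "gene_network_set")
}

#' @export
print.gene_network_set <- function(x, ...) {
  cat(sprintf("<gene_network_set> %d network(s) at Spearman r >= %.2f, min %d genes\n",
              length(x$networks), x$r_cut, x$min_genes))
  for (nw in x$networks) {
    cat(sprintf("  network %d: %d genes, %d edges\n",
                nw$network_id, length(nw$genes), nrow(nw$edges)))
  }
  invisible(x)
}

#' Network metagene score
#'
#' Per sample, the median raw FPKM over the network's member genes.
#'
#' @param fpkm FPKM table (first column gene id) or matrix.
#' @param network Character vector of member gene ids, or a single network
#'   element of a `gene_network_set`.
#' @return Tibble `sample_id`, `score`.
#' @export
network_score <- function(fpkm, network) {
  fm <- as_assay_matrix(fpkm, what = "fpkm")
  genes <- if (is.list(network)) network$genes else network
  idx <- match(genes, rownames(fm))
  if (anyNA(idx)) rlang::abort("network genes missing from the matrix")
  sc <- apply(fm[idx, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
  tibble::tibble(sample_id = colnames(fm), score = unname(sc))
}

#' Write network edges as a SIF file
#'
#' One line per edge, `gene_a <relation> gene_b`, the standard simple
#' interaction format consumed by network viewers.
#'
#' @param networks A `gene_network_set`.
#' @param path Output file path.
#' @param relation Interaction label to write.
#' @return `path`, invisibly.
#' @export
write_sif <- function(networks, path, relation = "coexp") {
  edges <- dplyr::bind_rows(lapply(networks$networks, `[[`, "edges"))
  lines <- sprintf("%s\t%s\t%s", edges$gene_a, relation, edges$gene_b)
  writeLines(lines, path)
  invisible(path)
}
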