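#' Collapse transcript records into one consensus model per gene
#'
#' All exons of a gene's transcripts are pooled and the consensus
#' transcription start site (TSS) is the 5'-most base over all transcripts;
#' the consensus termination site (TES) is the 3'-most base. On the minus
#' strand the 5'-most base is the one with the largest coordinate, so minus
#' strand models have `tss > tes`.
#'
#' @param transcripts Data frame of exon/transcript intervals with columns
#'   `gene_id`, `chrom`, `strand` (`"+"` or `"-"`), `start`, `end`
#'   (1-based inclusive).
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `tss`, `tes`.
#' @export
build_consensus_gene_models <- function(transcripts) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(transcripts)))
  bad <- transcripts %>%
    dplyr::distinct(.data$gene_id, .data$strand) %>%
    dplyr::count(.data$gene_id) %>%
    dplyr::filter(.data$n > 1L)
  if (nrow(bad) > 0L) {
    rlang::abort(sprintf("transcripts on conflicting strands for gene(s): %s",
                         paste(bad$gene_id, collapse = ", ")))
  }
  transcripts %>%
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) %>%
    dplyr::summarise(lo = min(.data$start), hi = max(.data$end), .groups = "drop") %>%
    dplyr::mutate(
      tss = dplyr::if_else(.data$strand == "-", .data$hi, .data$lo),
      tes = dplyr::if_else(.data$strand == "-", .data$lo, .data$hi)
    ) %>%
    dplyr::select("gene_id", "chrom", "strand", "tss", "tes") %>%
    dplyr::arrange(.data$gene_id)
}

#' Assign probes a gene-centric context from the nearest consensus TSS
#'
#' Contexts follow the standard windows: promoter when the probe lies within
#' +/- 500 bp of a TSS, proximal within +/- 5 kbp (excluding the promoter
#' window), distal beyond 5 kbp. Both boundaries are inclusive. The signed
#' TSS distance is positive downstream of the gene (in the direction of
#' transcription). Ties between equidistant TSSs are broken by lexical
#' gene id so annotation is deterministic.
#'
#' @param manifest Data frame with `probe_id`, `chrom`, `pos` (1-based).
#' @param models Gene models from [build_consensus_gene_models()].
#' @param promoter_bp,proximal_bp Inclusive half-window sizes in bp.
#' @return Tibble `probe_id`, `genic_context`, `nearest_gene`, `tss_distance`.
#'   Probes on chromosomes with no gene are distal with `NA` gene/distance.
#' @export
annotate_genic_context <- function(manifest, models,
                                   promoter_bp = 500, proximal_bp = 5000) {
  stopifnot(all(c("probe_id", "chrom", "pos") %in% names(manifest)))
  n <- nrow(manifest)
  nearest_gene <- rep(NA_character_, n)
  tss_distance <- rep(NA_real_, n)
  for (ch in unique(manifest$chrom)) {
    idx <- which(manifest$chrom == ch)
    g <- models[models$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L) next
    # order by (tss, gene_id) so equidistant ties resolve to the lexically
    # smallest gene id among genes sharing a TSS
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    keep <- !duplicated(g$tss)          # first (lexically smallest) per TSS
    g <- g[keep, , drop = FALSE]
    pos <- manifest$pos[idx]
    j <- findInterval(pos, g$tss)       # g$tss[j] <= pos < g$tss[j+1]
    lo <- pmax(j, 1L)
    hi <- pmin(j + 1L, nrow(g))
    d_lo <- abs(pos - g$tss[lo])
    d_hi <- abs(pos - g$tss[hi])
    # prefer the closer TSS; on exact distance ties prefer the lexically
    # smaller gene id
    take_hi <- (d_hi < d_lo) |
      (d_hi == d_lo & g$gene_id[hi] < g$gene_id[lo])
    pick <- ifelse(take_hi, hi, lo)
    gi <- g[pick, , drop = FALSE]
    nearest_gene[idx] <- gi$gene_id
    tss_distance[idx] <- ifelse(gi$strand == "-", gi$tss - pos, pos - gi$tss)
  }
  absd <- abs(tss_distance)
  ctx <- dplyr::case_when(
    is.na(absd) ~ "distal",
    absd <= promoter_bp ~ "promoter",
    absd <= proximal_bp ~ "proximal",
    TRUE ~ "distal"
  )
  tibble::tibble(probe_id = manifest$probe_id,
                 genic_context = ctx,
                 nearest_gene = nearest_gene,
                 tss_distance = tss_distance)
}

# intervals: tibble with chrom, start, end in 0-based half-open coordinates
# (BED convention). Returns a GRanges in 1-based closed coordinates.
intervals_to_granges <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$end <= intervals$start)) {
    rlang::abort("intervals must satisfy start < end (0-based half-open)")
  }
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  )
}

probes_to_granges <- function(manifest) {
  GenomicRanges::GRanges(
    seqnames = manifest$chrom,
    ranges = IRanges::IRanges(start = manifest$pos, width = 1L)
  )
}

#' Assign probes a CpG-density context: island, shore or ocean
#'
#' A probe inside a CpG island (CGI) is `island`; within `shore_bp` (default
#' 2000, inclusive) of a CGI edge it is `shore`; otherwise `ocean`.
#'
#' @param manifest Data frame with `probe_id`, `chrom`, `pos` (1-based).
#' @param cgi Data frame of CGI intervals, `chrom`/`start`/`end` in 0-based
#'   half-open (BED) coordinates. Overlapping islands are merged first.
#' @param shore_bp Shore width in bp from the island edge, inclusive.
#' @return Tibble `probe_id`, `cgi_context`.
#' @export
annotate_cgi_context <- function(manifest, cgi, shore_bp = 2000) {
  pr <- probes_to_granges(manifest)
  gr <- GenomicRanges::reduce(intervals_to_granges(cgi))
  inside <- GenomicRanges::countOverlaps(pr, gr) > 0L
  # GenomicRanges::distance() counts intervening bases, so a probe 1 bp past
  # an island edge has distance 0; probe-to-edge distance d = distance + 1.
  hit <- GenomicRanges::distanceToNearest(pr, gr)
  gap <- rep(NA_integer_, length(pr))
  gap[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  ctx <- dplyr::case_when(
    inside ~ "island",
    !is.na(gap) & gap + 1 <= shore_bp ~ "shore",
    TRUE ~ "ocean"
  )
  tibble::tibble(probe_id = manifest$probe_id, cgi_context = ctx)
}

#' Flag probes overlapping a peak set
#'
#' The 1 bp probe position (1-based) is converted to 0-based and tested for
#' containment in any interval (0-based half-open).
#'
#' @inheritParams annotate_cgi_context
#' @param peaks Interval data frame in BED coordinates.
#' @return Logical vector, one element per probe.
#' @export
annotate_overlap <- function(manifest, peaks) {
  if (is.null(peaks) || nrow(peaks) == 0L) {
    return(rep(FALSE, nrow(manifest)))
  }
  pr <- probes_to_granges(manifest)
  gr <- intervals_to_granges(peaks)
  GenomicRanges::countOverlaps(pr, gr) > 0L
}

# Per-probe set of overlapping transcription-factor names.
annotate_tf_sets <- function(manifest, tfbs) {
  tf_set <- vector("list", nrow(manifest))
  tf_set[] <- list(character(0))
  if (is.null(tfbs) || nrow(tfbs) == 0L) return(tf_set)
  stopifnot("tf" %in% names(tfbs))
  pr <- probes_to_granges(manifest)
  gr <- intervals_to_granges(tfbs)
  ov <- GenomicRanges::findOverlaps(pr, gr)
  qh <- S4Vectors::queryHits(ov)
  th <- tfbs$tf[S4Vectors::subjectHits(ov)]
  if (length(qh) > 0L) {
    sets <- split(th, qh)
    tf_set[as.integer(names(sets))] <- lapply(sets, function(x) sort(unique(x)))
  }
  tf_set
}

#' Local CpG-density metrics and promoter density classes for a sequence
#'
#' The observed/expected CpG ratio over a window of length L is
#' `#CpG * L / (#C * #G)` (0 when the window has no C or no G); `gc_frac` is
#' `(#C + #G) / L`. The two-class split (`HCG`/`LCG`) uses an O/E threshold
#' of 0.48 on the full window. The three-class promoter scheme slides 500 bp
#' subwindows across the sequence: `HCP` when some subwindow has O/E >= 0.75
#' and GC fraction >= 0.55, `LCP` when every subwindow has O/E < 0.48, `ICP`
#' otherwise.
#'
#' @param sequence Character vector of DNA windows (alphabet ACGTN), each
#'   centred on a probe; windows of 1001 bp (+/- 500) are the convention.
#' @param subwindow_bp Width of the sliding subwindow for the three-class
#'   scheme.
#' @return Tibble with `oe_ratio`, `gc_frac`, `saxonov_class`, `weber_class`,
#'   one row per input sequence.
#' @export
compute_cpg_density <- function(sequence, subwindow_bp = 500) {
  if (length(sequence) == 0L) rlang::abort("no sequences supplied")
  if (any(!nzchar(sequence)) || any(is.na(sequence))) {
    rlang::abort("empty sequence")
  }
  one <- function(s) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
    L <- length(chars)
    if (L < 2L) rlang::abort("window length must be >= 2")
    is_c <- chars == "C"
    is_g <- chars == "G"
    cpg_at <- is_c[-L] & is_g[-1L]       # CpG dinucleotide starting at i
    nC <- sum(is_c); nG <- sum(is_g); nCpG <- sum(cpg_at)
    oe <- if (nC == 0L || nG == 0L) 0 else nCpG * L / (nC * nG)
    gc <- (nC + nG) / L
    sax <- if (oe >= 0.48) "HCG" else "LCG"
    w <- min(subwindow_bp, L)
    if (L >= w) {
      cum_c <- c(0, cumsum(is_c)); cum_g <- c(0, cumsum(is_g))
      cum_p <- c(0, cumsum(c(cpg_at, FALSE)))
      starts <- seq_len(L - w + 1L)
      cw <- cum_c[starts + w] - cum_c[starts]
      gw <- cum_g[starts + w] - cum_g[starts]
      # CpGs fully inside the subwindow: start positions in [s, s+w-2]
      pw <- cum_p[starts + w - 1L] - cum_p[starts]
      oe_w <- ifelse(cw == 0 | gw == 0, 0, pw * w / (cw * gw))
      gc_w <- (cw + gw) / w
      weber <- if (any(oe_w >= 0.75 & gc_w >= 0.55)) "HCP"
      else if (all(oe_w < 0.48)) "LCP"
      else "ICP"
    } else {
      weber <- NA_character_
    }
    list(oe_ratio = oe, gc_frac = gc, saxonov_class = sax, weber_class = weber)
  }
  purrr::map(sequence, one) %>% purrr::list_transpose() %>% tibble::as_tibble()
}

#' Build the full per-probe context annotation table
#'
#' Combines gene-centric context, CpG-density context, open-chromatin overlap,
#' transcription-factor overlap sets and (when sequences are supplied) local
#' CpG-density metrics into one annotation tibble keyed by probe.
#'
#' @param manifest Data frame `probe_id`, `chrom`, `pos` (1-based).
#' @param models Consensus gene models.
#' @param cgi,atac,tfbs Interval tables in BED (0-based half-open)
#'   coordinates; `tfbs` carries the TF name in a `tf` column. `atac`/`tfbs`
#'   may be `NULL`.
#' @param sequences Optional named character vector of probe-centred windows
#'   (names = probe ids); density fields are `NA` without it.
#' @param shore_bp Shore width for the island/shore/ocean call.
#' @return Tibble with one row per probe: contexts, overlap flags, `tf_set`
#'   list-column, density metrics and nearest-gene fields.
#' @export
annotate_cpgs <- function(manifest, models, cgi, atac = NULL, tfbs = NULL,
                          sequences = NULL, shore_bp = 2000) {
  ann <- annotate_genic_context(manifest, models) %>%
    dplyr::left_join(annotate_cgi_context(manifest, cgi, shore_bp = shore_bp),
                     by = "probe_id") %>%
    dplyr::mutate(atac_overlap = annotate_overlap(manifest, atac),
                  tf_set = annotate_tf_sets(manifest, tfbs))
  if (!is.null(sequences)) {
    dens <- compute_cpg_density(unname(sequences[manifest$probe_id]))
    ann <- dplyr::bind_cols(ann, dens)
  } else {
    ann$oe_ratio <- NA_real_
    ann$gc_frac <- NA_real_
    ann$saxonov_class <- NA_character_
    ann$weber_class <- NA_character_
  }
  dplyr::left_join(
    tibble::as_tibble(manifest[c("probe_id", "chrom", "pos")]), ann,
    by = "probe_id"
  )
}

#' Per-probe methylation variability by genomic context
#'
#' Computes the standard deviation of beta across samples for every probe
#' (missing values ignored) and attaches the requested context keys so the
#' per-context SD distributions can be summarised or plotted.
#'
#' @param beta Beta table (first column probe id, remaining columns samples)
#'   or matrix.
#' @param annotations Annotation table from [annotate_cpgs()].
#' @param by Character vector of annotation columns to group by.
#' @return Tibble `probe_id`, the `by` columns, and `sd`.
#' @export
variance_by_context <- function(beta, annotations,
                                by = c("genic_context", "cgi_context", "atac_overlap")) {
  missing_keys <- setdiff(by, names(annotations))
  if (length(missing_keys) > 0L) {
    rlang::abort(sprintf("context key(s) absent from annotations: %s",
                         paste(missing_keys, collapse = ", ")))
  }
  m <- as_assay_matrix(beta, what = "beta")
  if (ncol(m) < 2L) rlang::abort("need at least two samples")
  mu <- rowMeans(m, na.rm = TRUE)
  nn <- rowSums(!is.na(m))
  ss <- rowSums((m - mu)^2, na.rm = TRUE)
  sds <- unname(sqrt(ss / pmax(nn - 1, 1)))
  sds[nn < 2] <- NA_real_
  tibble::tibble(probe_id = rownames(m), sd = sds) %>%
    dplyr::left_join(annotations[c("probe_id", by)], by = "probe_id") %>%
    dplyr::select("probe_id", dplyr::all_of(by), "sd")
}

#' Transcription-factor overlap enrichment of a probe cluster
#'
#' For each TF observed in the background, a one-sided Fisher exact test
#' (alternative "greater") on the 2x2 table of cluster membership vs TF
#' overlap, with FDR adjustment across TFs.
#'
#' @param cluster_probes Character vector of probe ids (subset of background).
#' @param background_probes Character vector of probe ids forming the test
#'   universe.
#' @param annotations Annotation table carrying the `tf_set` list-column.
#' @return Tibble `tf`, counts, `odds_ratio`, `p`, `p_adj`, sorted by `p`.
#' @export
tfbs_enrichment <- function(cluster_probes, background_probes, annotations) {
  if (length(cluster_probes) == 0L) rlang::abort("empty probe cluster")
  if (!all(cluster_probes %in% background_probes)) {
    rlang::abort("cluster probes must be a subset of the background")
  }
  ann <- annotations[match(background_probes, annotations$probe_id), ]
  in_cluster <- background_probes %in% cluster_probes
  tfs <- sort(unique(unlist(ann$tf_set)))
  if (length(tfs) == 0L) {
    return(tibble::tibble(tf = character(), n_cluster_overlap = integer(),
                          n_cluster = integer(), n_background_overlap = integer(),
                          n_background = integer(), odds_ratio = double(),
                          p = double(), p_adj = double()))
  }
  res <- purrr::map(tfs, function(tf) {
    ov <- purrr::map_lgl(ann$tf_set, function(s) tf %in% s)
    a <- sum(in_cluster & ov); b <- sum(in_cluster & !ov)
    c_ <- sum(!in_cluster & ov); d <- sum(!in_cluster & !ov)
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE),
                             alternative = "greater")
    list(tf = tf, n_cluster_overlap = a, n_cluster = a + b,
         n_background_overlap = a + c_, n_background = length(background_probes),
         odds_ratio = unname(ft$estimate), p = ft$p.value)
  }) %>% purrr::list_transpose() %>% tibble::as_tibble()
  res$p_adj <- stats::p.adjust(res$p, method = "fdr")
  dplyr::arrange(res, .data$p, .data$tf)
}
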