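#' Read an interval file (BED / narrowPeak) as a 0-based half-open table
#'
#' Uses `rtracklayer` to parse BED-family formats and converts back to the
#' 0-based half-open interval tibble used throughout the package. For BED
#' files with a name column (e.g. TFBS peaks named by transcription factor)
#' the name is kept in a `tf` column.
#'
#' @param path BED or narrowPeak file.
#' @param format `"auto"` (by extension), `"bed"` or `"narrowPeak"`.
#' @return Tibble `chrom`, `start`, `end` (+ `tf` when names are present).
#' @export
read_bed <- function(path, format = c("auto", "bed", "narrowPeak")) {
  format <- rlang::arg_match(format)
  if (format == "auto") {
    format <- if (grepl("narrowPeak$", path, ignore.case = TRUE)) "narrowPeak" else "bed"
  }
  gr <- if (format == "narrowPeak") {
    rtracklayer::import(path, format = "BED",
                        extraCols = c(signalValue = "numeric",
                                      pValue = "numeric", qValue = "numeric",
                                      peak = "integer"))
  } else {
    rtracklayer::import(path, format = "BED")
  }
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  nm <- gr$name
  if (!is.null(nm) && !all(is.na(nm))) out$tf <- as.character(nm)
  out
}

#' Read an assay table (beta, FPKM) from TSV
#'
#' First column is the feature id, remaining columns are numeric sample
#' values.
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_assay_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing the emitted files.
#' @return List with the same tabular components as an `epityper_cohort`
#'   (truth matrices reloaded from their TSVs; `truth` from JSON).
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  rd <- function(f) readr::read_tsv(p(f), show_col_types = FALSE, progress = FALSE)
  bed3 <- function(f, extra = NULL) {
    cols <- c("chrom", "start", "end", extra)
    readr::read_tsv(p(f), col_names = cols, show_col_types = FALSE,
                    progress = FALSE)
  }
  truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  truth$tumor_beta <- as_assay_matrix(rd("truth_tumor_beta.tsv"))
  truth$normal_beta <- as_assay_matrix(rd("truth_normal_beta.tsv"))
  list(beta = rd("beta.tsv"), purity = rd("purity.tsv"), fpkm = rd("fpkm.tsv"),
       manifest = rd("probe_manifest.tsv"), gene_models = rd("gene_models.tsv"),
       labels = rd("labels.tsv"), cgi = bed3("cgi.bed"),
       atac = bed3("atac.bed"), tfbs = bed3("tfbs.bed", "tf"), truth = truth)
}
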