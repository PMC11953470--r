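test_that("consensus gene models take the 5'-most TSS and 3'-most TES", {
  m <- tiny_models()
  a <- m[m$gene_id == "gA", ]
  expect_equal(a$tss, 100)        # 5'-most over transcripts starting 100/150
  expect_equal(a$tes, 1200)
  b <- m[m$gene_id == "gB", ]     # minus strand: tss > tes
  expect_equal(b$tss, 12000)
  expect_equal(b$tes, 10000)
  c_ <- m[m$gene_id == "gC", ]    # single transcript: identity
  expect_equal(c(c_$tss, c_$tes), c(500, 1500))
  expect_error(build_consensus_gene_models(tibble::tibble(
    gene_id = "gX", chrom = "chr1", strand = c("+", "-"),
    start = c(1L, 5L), end = c(10L, 20L)
  )), "gX")
})

test_that("genic context follows the 500/5000 bp windows with inclusive bounds", {
  models <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "chr1",
                           strand = "+", tss = c(10000L, 30000L),
                           tes = c(15000L, 35000L))
  pos <- c(10300L, 10500L, 10501L, 15000L, 15001L, 16000L, 9500L, 4999L)
  man <- tibble::tibble(probe_id = sprintf("p%d", seq_along(pos)),
                        chrom = "chr1", pos = pos)
  ann <- annotate_genic_context(man, models)
  expect_equal(ann$genic_context,
               c("promoter",  # |d| = 300
                 "promoter",  # |d| = 500 inclusive
                 "proximal",  # |d| = 501
                 "proximal",  # |d| = 5000 inclusive
                 "distal",    # |d| = 5001
                 "distal",    # |d| = 6000
                 "promoter",  # |d| = 500 upstream
                 "distal"))   # |d| = 5001 upstream
  # nearest gene by distance: 3 kb from gA vs 17 kb from gB
  man2 <- tibble::tibble(probe_id = "q", chrom = "chr1", pos = 13000L)
  ann2 <- annotate_genic_context(man2, models)
  expect_equal(ann2$nearest_gene, "gA")
  expect_equal(ann2$tss_distance, 3000)
  expect_equal(ann2$genic_context, "proximal")
  # equidistant tie broken lexically
  man3 <- tibble::tibble(probe_id = "t", chrom = "chr1", pos = 20000L)
  expect_equal(annotate_genic_context(man3, models)$nearest_gene, "gA")
  # chromosome without genes: distal, NA gene
  man4 <- tibble::tibble(probe_id = "u", chrom = "chr9", pos = 100L)
  ann4 <- annotate_genic_context(man4, models)
  expect_equal(ann4$genic_context, "distal")
  expect_true(is.na(ann4$nearest_gene))
})

test_that("genic context agrees with a brute-force scan over all TSSs", {
  set.seed(71)
  models <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:200), chrom = "chr1",
    strand = sample(c("+", "-"), 200, TRUE),
    tss = sort(sample.int(2e6, 200)), tes = 0L)
  models$tes <- models$tss + ifelse(models$strand == "+", 1000L, -1000L)
  man <- tibble::tibble(probe_id = sprintf("p%04d", 1:500), chrom = "chr1",
                        pos = sample.int(2e6, 500))
  ann <- annotate_genic_context(man, models)
  for (i in sample.int(500, 80)) {
    d_all <- abs(man$pos[i] - models$tss)
    best <- min(d_all)
    cand <- models$gene_id[d_all == best]
    expect_equal(ann$nearest_gene[i], min(cand))
    expect_equal(abs(ann$tss_distance[i]), best)
    expect_equal(ann$genic_context[i],
                 if (best <= 500) "promoter" else if (best <= 5000) "proximal" else "distal")
  }
})

test_that("island/shore/ocean assignment matches a distance-to-interval oracle", {
  # cgi in BED coords: 1-based [1001, 2000] and [50001, 50500]
  cgi <- tibble::tibble(chrom = "chr1", start = c(1000L, 50000L),
                        end = c(2000L, 50500L))
  man <- tibble::tibble(probe_id = c("a", "b", "c", "d", "e"), chrom = "chr1",
                        pos = c(1500L, 3500L, 4000L, 4001L, 100000L))
  ctx <- annotate_cgi_context(man, cgi)$cgi_context
  expect_equal(ctx, c("island",  # inside
                      "shore",   # 1500 bp past edge
                      "shore",   # exactly 2000 bp
                      "ocean",   # 2001 bp
                      "ocean"))  # ~50 kb away
  set.seed(72)
  pos <- sample.int(120000, 400)
  man2 <- tibble::tibble(probe_id = sprintf("r%03d", seq_along(pos)),
                         chrom = "chr1", pos = pos)
  got <- annotate_cgi_context(man2, cgi)$cgi_context
  want <- vapply(pos, oracle_cgi_context,
                 character(1), start1 = c(1001, 50001), end1 = c(2000, 50500))
  expect_equal(got, want)
})

test_that("peak overlap respects the 1-based to 0-based conversion", {
  man <- tibble::tibble(probe_id = c("a", "b", "c"), chrom = "chr1",
                        pos = c(101L, 101L, 200L))
  # peak [100, 200) 0-based covers 1-based 101..200
  expect_equal(annotate_overlap(man, tibble::tibble(chrom = "chr1",
                                                    start = 100L, end = 200L)),
               c(TRUE, TRUE, TRUE))
  # peak [101, 200) 0-based covers 1-based 102..200: probe at 101 excluded
  expect_equal(annotate_overlap(man, tibble::tibble(chrom = "chr1",
                                                    start = 101L, end = 200L)),
               c(FALSE, FALSE, TRUE))
  expect_equal(annotate_overlap(man, tibble::tibble(chrom = character(0),
                                                    start = integer(0),
                                                    end = integer(0))),
               c(FALSE, FALSE, FALSE))
})

test_that("CpG density metrics follow the O/E definition", {
  d <- compute_cpg_density("CCGGCCGG")
  expect_equal(d$oe_ratio, 1.0)   # 2 CpG * 8 / (4 * 4)
  expect_equal(d$gc_frac, 1.0)
  d2 <- compute_cpg_density(c("GGGGGGGG", "ATATATAT"))
  expect_equal(d2$oe_ratio, c(0, 0))
  expect_equal(d2$gc_frac, c(1, 0))
  expect_error(compute_cpg_density(""), "empty")
  # reverse complement invariance of O/E
  set.seed(73)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    expect_equal(compute_cpg_density(s)$oe_ratio,
                 compute_cpg_density(rc)$oe_ratio)
  }
  # weber classes on designed windows
  hcp <- paste(rep("CG", 400), collapse = "")            # saturated CpG
  lcp <- paste(rep("ATTA", 200), collapse = "")
  expect_equal(compute_cpg_density(hcp)$weber_class, "HCP")
  expect_equal(compute_cpg_density(lcp)$weber_class, "LCP")
})

test_that("every probe gets exactly one genic and one cgi context", {
  co <- small_cohort()
  ann <- annotate_cpgs(co$manifest, co$gene_models, co$cgi, co$atac, co$tfbs)
  expect_equal(nrow(ann), nrow(co$manifest))
  expect_true(all(ann$genic_context %in% c("promoter", "proximal", "distal")))
  expect_true(all(ann$cgi_context %in% c("island", "shore", "ocean")))
  expect_equal(sum(table(ann$genic_context)), nrow(ann))
  expect_equal(sum(table(ann$cgi_context)), nrow(ann))
})

test_that("variance by context computes per-probe SD and orders planted groups", {
  b <- matrix(c(0, 1, 0.5, 0.5), 2, 2, byrow = TRUE,
              dimnames = list(c("p1", "p2"), c("s1", "s2")))
  ann <- tibble::tibble(probe_id = c("p1", "p2"),
                        genic_context = c("distal", "promoter"),
                        cgi_context = "ocean", atac_overlap = TRUE)
  v <- variance_by_context(b, ann)
  expect_equal(v$sd[v$probe_id == "p1"], sqrt(0.5), tolerance = 1e-12)
  expect_equal(v$sd[v$probe_id == "p2"], 0)
  expect_error(variance_by_context(b, ann, by = "nope"), "nope")
  # planted high/low variance contexts separate in the group medians
  set.seed(74)
  n <- 40
  hi <- matrix(runif(50 * n, 0, 1), 50, n)
  lo <- matrix(0.5 + rnorm(50 * n, 0, 0.01), 50, n)
  m <- rbind(hi, lo)
  dimnames(m) <- list(sprintf("p%03d", 1:100), sprintf("s%02d", 1:n))
  ann2 <- tibble::tibble(probe_id = rownames(m),
                         genic_context = rep(c("distal", "promoter"), each = 50),
                         cgi_context = "ocean", atac_overlap = FALSE)
  v2 <- variance_by_context(m, ann2, by = "genic_context")
  med <- tapply(v2$sd, v2$genic_context, median)
  expect_gt(med[["distal"]], med[["promoter"]])
})

test_that("TFBS enrichment matches the hypergeometric tail and handles edge cases", {
  bg <- sprintf("p%03d", 1:100)
  tf_set <- lapply(1:100, function(i) if (i <= 20) "TFX" else character(0))
  ann <- tibble::tibble(probe_id = bg, tf_set = tf_set)
  cl <- bg[c(1:8, 21, 22)]     # 8 of 10 overlap; background 20 of 100
  res <- tfbs_enrichment(cl, bg, ann)
  expect_equal(res$p, phyper(7, 20, 80, 10, lower.tail = FALSE),
               tolerance = 1e-12)
  # saturated TF: everything overlaps -> p = 1
  ann2 <- tibble::tibble(probe_id = bg, tf_set = rep(list("TFY"), 100))
  expect_equal(tfbs_enrichment(cl, bg, ann2)$p, 1)
  # cluster == background -> p = 1
  expect_equal(tfbs_enrichment(bg, bg, ann)$p, 1)
  expect_error(tfbs_enrichment(character(0), bg, ann), "empty")
  # random tables against phyper
  set.seed(75)
  for (i in 1:25) {
    N <- sample(20:200, 1); K <- sample(1:N, 1); n <- sample(2:N, 1)
    ts <- lapply(seq_len(N), function(j) if (j <= K) "TF" else character(0))
    bgx <- sprintf("q%03d", seq_len(N))
    annx <- tibble::tibble(probe_id = bgx, tf_set = ts)
    clx <- sample(bgx, n)
    a <- sum(clx %in% bgx[seq_len(K)])
    expect_equal(tfbs_enrichment(clx, bgx, annx)$p,
                 phyper(a - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})
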