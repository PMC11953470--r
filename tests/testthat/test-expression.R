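test_that("FPKM transform is log2(x + 0.1) with input validation", {
  m <- matrix(c(0, 1.9, 0.9), 1, 3,
              dimnames = list("g", sprintf("s%d", 1:3)))
  out <- transform_fpkm(m)
  expect_equal(unname(out[1, ]), c(log2(0.1), 1, 0), tolerance = 1e-12)
  m[1, 1] <- -1
  expect_error(transform_fpkm(m), "non-negative")
})

test_that("differential expression needs both significance and effect size", {
  set.seed(121)
  n <- 60
  g <- setNames(rep(c("a", "b"), each = n / 2), sprintf("s%02d", 1:n))
  # planted 2.5x gene, a null gene, and a tiny-effect significant gene
  fpkm <- rbind(
    planted = c(10 * 2^rnorm(n / 2, 0, 0.2), 25 * 2^rnorm(n / 2, 0, 0.2)),
    nullg = 8 * 2^rnorm(n, 0, 0.3),
    tiny = c(rep(0.30, n / 2), rep(0.80, n / 2)) * 2^rnorm(n, 0, 0.01))
  colnames(fpkm) <- names(g)
  r <- diff_expr(fpkm, g)
  expect_true(r$significant[r$gene_id == "planted"])
  expect_equal(r$direction[r$gene_id == "planted"], "b")
  expect_false(r$significant[r$gene_id == "nullg"])
  tiny <- r[r$gene_id == "tiny", ]
  expect_lt(tiny$p_adj, 0.05)           # significant by p
  expect_false(tiny$significant)        # but median span 0.5 < 1 FPKM
})

test_that("planted two-fold genes are detected with high power", {
  set.seed(122)
  n <- 60
  g <- setNames(rep(c("a", "b"), each = n / 2), sprintf("s%02d", 1:n))
  hits <- replicate(50, {
    fpkm <- matrix(c(10 * 2^rnorm(n / 2, 0, 0.4), 25 * 2^rnorm(n / 2, 0, 0.4)),
                   1, n, dimnames = list("g1", names(g)))
    r <- diff_expr(fpkm, g)
    r$significant && r$direction == "b"
  })
  expect_gte(mean(hits), 0.95)
})

test_that("group-specific scheme classifies planted median patterns", {
  set.seed(123)
  mk <- function(meds, n = 30, sd = 0.15) {
    unlist(lapply(meds, function(m) m * 2^rnorm(n, 0, sd)))
  }
  g <- setNames(rep(c("g1", "g2", "g3"), each = 30), sprintf("s%02d", 1:90))
  fpkm <- rbind(a = mk(c(30, 5, 5)), b = mk(c(20, 20, 5)), c = mk(c(10, 10, 10)))
  colnames(fpkm) <- names(g)
  r <- diff_expr_group_specific(fpkm, g)
  expect_equal(r$specific_group[r$gene_id == "a"], "g1")
  expect_equal(r$spec_direction[r$gene_id == "a"], "up")
  expect_equal(r$specific_group[r$gene_id == "b"], "g3")
  expect_equal(r$spec_direction[r$gene_id == "b"], "down")
  expect_true(is.na(r$specific_group[r$gene_id == "c"]))
  expect_error(diff_expr_group_specific(fpkm, setNames(rep(c("a", "b"), 45),
                                                       names(g))), "3 groups")
})

test_that("group-specific assignments permute with group relabeling", {
  set.seed(124)
  g <- setNames(rep(c("g1", "g2", "g3"), each = 20), sprintf("s%02d", 1:60))
  fpkm <- rbind(a = unlist(lapply(c(25, 4, 4), function(m) m * 2^rnorm(20, 0, 0.2))),
                b = unlist(lapply(c(4, 25, 4), function(m) m * 2^rnorm(20, 0, 0.2))))
  colnames(fpkm) <- names(g)
  r1 <- diff_expr_group_specific(fpkm, g)
  relab <- c(g1 = "g2", g2 = "g3", g3 = "g1")
  r2 <- diff_expr_group_specific(fpkm, setNames(unname(relab[g]), names(g)))
  expect_equal(unname(relab[r1$specific_group]), r2$specific_group)
})

test_that("metagene rank scores follow the mean-rank definition and are monotone-invariant", {
  fpkm <- matrix(c(1, 5, 20,
                   3, 2, 1), 3, 2,
                 dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  # singleton set holding s1's top gene: rank 3/3 = 1
  sc <- metagene_rank_score(fpkm, "g3")
  expect_equal(sc$score[sc$sample_id == "s1"], 1)
  expect_equal(sc$score[sc$sample_id == "s2"], 1 / 3)
  # all genes: (G+1)/(2G)
  sc_all <- metagene_rank_score(fpkm, c("g1", "g2", "g3"))
  expect_equal(sc_all$score, rep(4 / 6, 2))
  expect_error(metagene_rank_score(fpkm, "nope"), "overlap")
  # monotone transform invariance
  set.seed(125)
  m <- matrix(rlnorm(200), 20, 10,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  s1 <- metagene_rank_score(m, sprintf("g%02d", 1:5))
  s2 <- metagene_rank_score(m^3 + 1, sprintf("g%02d", 1:5))
  expect_equal(s1$score, s2$score)
})

test_that("network extraction applies the 0.7/8-gene rules and partitions genes", {
  set.seed(126)
  n <- 60
  z1 <- rnorm(n); z2 <- rnorm(n)
  block10 <- 2^(3 + 1.1 * matrix(z1, 10, n, byrow = TRUE) +
                  0.35 * matrix(rnorm(10 * n), 10, n))
  block7 <- 2^(3 + 1.1 * matrix(z2, 7, n, byrow = TRUE) +
                 0.35 * matrix(rnorm(7 * n), 7, n))
  noise <- 2^matrix(rnorm(40 * n, 3, 1), 40, n,
                    dimnames = list(sprintf("N%02d", 1:40),
                                    sprintf("s%02d", 1:n)))
  fpkm <- rbind(block10, block7, noise)
  rownames(fpkm) <- c(sprintf("B%02d", 1:10), sprintf("C%02d", 1:7),
                      sprintf("N%02d", 1:40))
  colnames(fpkm) <- sprintf("s%02d", 1:n)
  nets <- build_gene_networks(fpkm)
  expect_length(nets$networks, 1)
  expect_setequal(nets$networks[[1]]$genes, sprintf("B%02d", 1:10))
  td <- tidy(nets)
  expect_false(any(duplicated(td$gene_id)))   # partition: no gene twice
  # independent genes alone: no networks
  nets0 <- build_gene_networks(noise)
  expect_length(nets0$networks, 0)
  # constant genes dropped with a warning
  fpkm2 <- rbind(fpkm, const = rep(5, n))
  expect_warning(build_gene_networks(fpkm2), "constant")
  # network score = per-sample median FPKM of members
  m <- matrix(c(1, 3, 100), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(network_score(m, c("a", "b", "c"))$score, 3)
  expect_equal(network_score(m * 0, c("a", "b", "c"))$score, 0)
})

test_that("pairwise Spearman matches a rank-then-Pearson oracle", {
  set.seed(127)
  m <- matrix(rlnorm(12 * 30), 12, 30,
              dimnames = list(sprintf("g%02d", 1:12), sprintf("s%02d", 1:30)))
  rho <- cor(t(m), method = "spearman")
  oracle <- cor(apply(t(m), 2, rank))
  expect_lt(max(abs(rho - oracle)), 1e-10)
  # network edge weights reproduce spearman values at or above the cutoff
  z <- rnorm(30)
  blk <- 2^(3 + 1.1 * matrix(z, 9, 30, byrow = TRUE) +
              0.3 * matrix(rnorm(270), 9, 30))
  dimnames(blk) <- list(sprintf("B%d", 1:9), colnames(m))
  nets <- build_gene_networks(rbind(blk, m))
  expect_length(nets$networks, 1)
  ed <- nets$networks[[1]]$edges
  expect_true(all(ed$spearman_r >= 0.7))
  rho_all <- cor(t(rbind(blk, m)), method = "spearman")
  for (j in seq_len(min(nrow(ed), 10))) {
    expect_equal(ed$spearman_r[j], rho_all[ed$gene_a[j], ed$gene_b[j]],
                 tolerance = 1e-12)
  }
})

test_that("network scores separate a subgroup with planted high expression", {
  set.seed(128)
  n <- 50
  grp <- rep(c(TRUE, FALSE), each = n / 2)
  z <- rnorm(n) + 2 * grp
  fpkm <- 2^(3 + 1.1 * matrix(z, 10, n, byrow = TRUE) +
               0.3 * matrix(rnorm(10 * n), 10, n))
  rownames(fpkm) <- sprintf("B%02d", 1:10)
  colnames(fpkm) <- sprintf("s%02d", 1:n)
  sc <- network_score(fpkm, rownames(fpkm))
  expect_gt(median(sc$score[grp]), median(sc$score[!grp]))
  expect_lt(wilcox.test(sc$score[grp], sc$score[!grp],
                        alternative = "greater")$p.value, 0.01)
})
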