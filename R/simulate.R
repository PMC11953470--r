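#' Configuration for a synthetic methylation/expression cohort
#'
#' The generator lays probes on a single synthetic chromosome tiled with
#' evenly spaced genes (50 kb apart, so a 500 kb window holds ~10 TSSs),
#' places CpG islands and open-chromatin peaks so that every genic x
#' CpG-density x ATAC stratum is populated, and draws beta values as
#' purity-weighted mixtures of a tumor and a normal methylation state with
#' truncated-normal noise. Epitype-discriminating CpG blocks, subgroup
#' blocks, negatively coupled CpG-gene pairs and latent-factor co-expression
#' blocks are planted with known ground truth.
#'
#' @param n_samples Cohort size.
#' @param epitype_fractions Named fractions summing to 1 (two epitypes).
#' @param subgroup_fractions List (per epitype) of subgroup fractions, each
#'   summing to 1.
#' @param n_probes Total probe count.
#' @param n_genes Genes on the synthetic chromosome (one per 50 kb tile).
#' @param dmc_delta,n_dmc Size and count of the epitype-discriminating block
#'   (distal, ATAC-overlapping probes; half hypermethylated in the minor
#'   epitype, half hypomethylated).
#' @param subgroup_delta,n_subgroup_dmc Per-subgroup planted block size and
#'   count (0 disables subgroup blocks).
#' @param purity_range Min/max of the uniform tumor purity distribution.
#' @param noise_sd SD of the truncated-normal noise on the observed mixture.
#' @param n_pairs,pair_coupling,pair_sign Planted CpG-gene pairs: count,
#'   target correlation magnitude between tumor beta and log2 expression,
#'   and sign (-1 = methylation represses expression).
#' @param network_sizes Sizes of planted latent-factor co-expression blocks.
#' @param n_de_genes Genes differentially expressed between epitypes.
#' @param concordant_frac Fraction of probes whose normal state equals the
#'   tumor baseline state.
#' @param frac_variable Fraction of probes given continuous inter-tumor
#'   variation in the tumor methylation state, independent of epitype and of
#'   expression; these emulate the large pool of variably methylated CpGs
#'   real methylomes carry and populate the empirical-null universe.
#' @param seed Master seed; all outputs are deterministic given the config.
#' @return A validated `epityper_sim_config` list.
#' @export
simulate_config <- function(n_samples = 120,
                            epitype_fractions = c(basal = 0.75, nonbasal = 0.25),
                            subgroup_fractions = list(
                              basal = c(1 / 3, 1 / 3, 1 / 3),
                              nonbasal = c(0.5, 0.5)),
                            n_probes = 20000,
                            n_genes = 400,
                            dmc_delta = 0.4,
                            n_dmc = 200,
                            subgroup_delta = 0.3,
                            n_subgroup_dmc = 30,
                            purity_range = c(0.3, 0.9),
                            noise_sd = 0.03,
                            n_pairs = 50,
                            pair_coupling = 0.7,
                            pair_sign = -1,
                            network_sizes = c(10, 7),
                            n_de_genes = 60,
                            concordant_frac = 0.8,
                            frac_variable = 0.10,
                            seed = 221027) {
  cfg <- list(n_samples = n_samples, epitype_fractions = epitype_fractions,
              subgroup_fractions = subgroup_fractions, n_probes = n_probes,
              n_genes = n_genes, dmc_delta = dmc_delta, n_dmc = n_dmc,
              subgroup_delta = subgroup_delta, n_subgroup_dmc = n_subgroup_dmc,
              purity_range = purity_range, noise_sd = noise_sd,
              n_pairs = n_pairs, pair_coupling = pair_coupling,
              pair_sign = pair_sign, network_sizes = network_sizes,
              n_de_genes = n_de_genes, concordant_frac = concordant_frac,
              frac_variable = frac_variable, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "epityper_sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (abs(sum(epitype_fractions) - 1) > 1e-8) {
      rlang::abort("epitype fractions must sum to 1")
    }
    if (length(epitype_fractions) != 2L) {
      rlang::abort("exactly two epitypes are supported")
    }
    for (nm in names(epitype_fractions)) {
      sf <- subgroup_fractions[[nm]]
      if (is.null(sf) || abs(sum(sf) - 1) > 1e-8) {
        rlang::abort(sprintf("subgroup fractions for '%s' must sum to 1", nm))
      }
    }
    if (n_dmc > 0 && (dmc_delta <= 0 || dmc_delta >= 1)) {
      rlang::abort("dmc_delta must be in (0, 1)")
    }
    if (purity_range[1L] <= 0 || purity_range[2L] > 1 ||
        purity_range[1L] > purity_range[2L]) {
      rlang::abort("purity range must satisfy 0 < min <= max <= 1")
    }
    if (noise_sd < 0) rlang::abort("noise_sd must be >= 0")
    if (n_samples < 4 || n_probes < 100 || n_genes < 20) {
      rlang::abort("cohort dimensions too small")
    }
    if (pair_coupling < 0 || pair_coupling > 1) {
      rlang::abort("pair_coupling must be in [0, 1]")
    }
    if (frac_variable < 0 || frac_variable > 0.5) {
      rlang::abort("frac_variable must be in [0, 0.5]")
    }
    if (n_pairs + n_de_genes + sum(network_sizes) > 0.9 * n_genes) {
      rlang::abort("gene budget exceeded: n_pairs + n_de_genes + network sizes must stay below 90% of n_genes")
    }
  })
  invisible(cfg)
}

# Genome layout constants (bp)
.tile_bp <- 50000

# Per-gene tile geometry. Archetypes cycle A (CGI promoter), B (no promoter
# CGI), C (CGI shore promoter); every tile carries a distal CGI. Zones are
# chosen so the intended (genic, cgi) context is exact under the 500/5000 bp
# and 2000 bp shore conventions.
sim_gene_table <- function(n_genes) {
  g <- seq_len(n_genes)
  tile <- (g - 1L) * .tile_bp
  strand <- ifelse(g %% 2L == 1L, "+", "-")
  tss <- ifelse(strand == "+", tile + 5000L, tile + 15000L)
  tes <- ifelse(strand == "+", tss + 10000L, tss - 10000L)
  tibble::tibble(
    gene_id = sprintf("G%04d", g),
    chrom = "chr1", strand = strand, tss = tss, tes = tes,
    tile = tile, archetype = c("A", "B", "C")[(g - 1L) %% 3L + 1L]
  )
}

# 1-based closed interval helper -> BED (0-based half-open) tibble
bed_tbl <- function(start1, end1, extra = NULL) {
  out <- tibble::tibble(chrom = "chr1", start = start1 - 1L, end = end1)
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  dplyr::arrange(out, .data$start)
}

sim_cgi <- function(genes) {
  a <- genes[genes$archetype == "A", ]
  c_ <- genes[genes$archetype == "C", ]
  bed_tbl(
    c(a$tss - 400L, c_$tss + 800L, genes$tile + 22001L),
    c(a$tss + 400L, c_$tss + 1600L, genes$tile + 23000L)
  )
}

# Zone catalog: rows of (genic, cgi, lo, hi) in 1-based coordinates.
sim_zones <- function(genes) {
  z <- list()
  add <- function(gc, cc, sub, lo, hi) {
    tibble::tibble(genic = gc, cgi = cc, lo = lo, hi = hi,
                   gene_id = sub$gene_id)
  }
  a <- genes[genes$archetype == "A", ]
  b <- genes[genes$archetype == "B", ]
  c_ <- genes[genes$archetype == "C", ]
  dplyr::bind_rows(
    add("promoter", "island", a, a$tss - 380L, a$tss + 380L),
    add("promoter", "shore", c_, c_$tss - 450L, c_$tss + 450L),
    add("promoter", "ocean", b, b$tss - 450L, b$tss + 450L),
    add("proximal", "island", c_, c_$tss + 850L, c_$tss + 1550L),
    add("proximal", "shore", a, a$tss + 600L, a$tss + 2300L),
    add("proximal", "shore", c_, c_$tss + 1700L, c_$tss + 3500L),
    add("proximal", "ocean", b, b$tss + 600L, b$tss + 4700L),
    add("proximal", "ocean", a, a$tss + 3100L, a$tss + 4700L),
    add("distal", "island", genes, genes$tile + 22050L, genes$tile + 22950L),
    add("distal", "shore", genes, genes$tile + 23100L, genes$tile + 24900L),
    add("distal", "ocean", genes, genes$tile + 27600L, genes$tile + 44900L)
  )
}

# stratum target fractions over (genic, cgi)
.strata <- tibble::tribble(
  ~genic, ~cgi, ~frac,
  "promoter", "island", 0.10,
  "promoter", "shore", 0.04,
  "promoter", "ocean", 0.04,
  "proximal", "island", 0.03,
  "proximal", "shore", 0.08,
  "proximal", "ocean", 0.11,
  "distal", "island", 0.05,
  "distal", "shore", 0.10,
  "distal", "ocean", 0.45
)

sim_manifest <- function(cfg, zones) {
  counts <- round(.strata$frac * cfg$n_probes)
  counts[length(counts)] <- cfg$n_probes - sum(counts[-length(counts)])
  rows <- list()
  for (s in seq_len(nrow(.strata))) {
    zz <- zones[zones$genic == .strata$genic[s] & zones$cgi == .strata$cgi[s], ]
    pick <- sample.int(nrow(zz), counts[s], replace = TRUE)
    pos <- zz$lo[pick] + floor(stats::runif(counts[s]) * (zz$hi[pick] - zz$lo[pick] + 1L))
    rows[[s]] <- tibble::tibble(chrom = "chr1", pos = as.integer(pos),
                                genic_truth = .strata$genic[s],
                                cgi_truth = .strata$cgi[s])
  }
  m <- dplyr::bind_rows(rows) %>% dplyr::arrange(.data$pos)
  m$probe_id <- sprintf("cg%07d", seq_len(nrow(m)))
  dplyr::select(m, "probe_id", "chrom", "pos", "genic_truth", "cgi_truth")
}

#' Simulate a full synthetic cohort with ground truth
#'
#' See [simulate_config()] for the generative model. Observed beta values are
#' `purity * tumor + (1 - purity) * normal + noise`, clipped to [0, 1]; the
#' expression matrix is log-normal FPKM with planted epitype effects, planted
#' CpG-coupled genes and latent-factor network blocks. Deterministic given
#' the config (including its seed); the caller's RNG state is untouched.
#'
#' @param config An `epityper_sim_config` from [simulate_config()].
#' @return An `epityper_cohort` list: `beta`, `purity`, `fpkm` (tibbles),
#'   `manifest`, `gene_models`, `cgi`, `atac`, `tfbs` interval tables,
#'   `labels`, and a `truth` list (planted labels, probe/pair/network sets,
#'   true tumor/normal matrices, generating parameters).
#' @export
simulate_cohort <- function(config = simulate_config()) {
  validate_sim_config(config)
  with_local_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_samples
  sample_id <- sprintf("S%03d", seq_len(n))

  # -- sample labels ---------------------------------------------------------
  epis <- names(cfg$epitype_fractions)
  n_epi <- round(cfg$epitype_fractions * n)
  n_epi[2L] <- n - n_epi[1L]
  epitype <- sample(rep(epis, n_epi))
  subgroup <- character(n)
  for (e in epis) {
    idx <- which(epitype == e)
    sf <- cfg$subgroup_fractions[[e]]
    k <- length(sf)
    cnt <- round(sf * length(idx))
    cnt[k] <- length(idx) - sum(cnt[-k])
    subgroup[idx] <- sample(rep(paste0(e, seq_len(k)), cnt))
  }
  purity <- stats::runif(n, cfg$purity_range[1L], cfg$purity_range[2L])

  # -- genome, probes, intervals --------------------------------------------
  genes <- sim_gene_table(cfg$n_genes)
  zones <- sim_zones(genes)
  manifest <- sim_manifest(cfg, zones)
  np <- nrow(manifest)
  cgi <- sim_cgi(genes)

  atac_prob <- c(promoter = 0.50, proximal = 0.35, distal = 0.30)
  atac_flag <- stats::runif(np) < atac_prob[manifest$genic_truth]

  distal_idx <- which(manifest$genic_truth == "distal" &
                        manifest$cgi_truth != "island")
  dmc_idx <- sort(sample(distal_idx, cfg$n_dmc))
  atac_flag[dmc_idx] <- TRUE
  remaining <- setdiff(distal_idx, dmc_idx)

  # subgroup blocks, one per subgroup, also distal-ATAC
  subgroups <- unique(subgroup)
  sub_blocks <- list()
  if (cfg$n_subgroup_dmc > 0) {
    for (sg in subgroups) {
      idx <- sort(sample(remaining, cfg$n_subgroup_dmc))
      remaining <- setdiff(remaining, idx)
      atac_flag[idx] <- TRUE
      sub_blocks[[sg]] <- manifest$probe_id[idx]
    }
  }

  # planted CpG-gene pair probes: distal, forced outside open chromatin
  pair_idx <- sort(sample(remaining, cfg$n_pairs))
  atac_flag[pair_idx] <- FALSE

  atac <- bed_tbl(pmax(manifest$pos[atac_flag] - 75L, 1L),
                  manifest$pos[atac_flag] + 75L)
  # realized overlap: peaks of one probe can cover a close neighbour
  atac_realized <- annotate_overlap(manifest, atac)

  # -- TFBS peaks: generic TFs over random probes; the first TF is enriched
  #    in the epitype block to give enrichment analyses signal ---------------
  tf_names <- c("FOXA1", "GATA3", "FOS", "STAT3", "JUN", "POLR2A",
                "EZH2", "CTCF", "ESR1", "TP53", "MYC", "SPI1")
  tf_rows <- list()
  for (tf in tf_names) {
    hit <- which(stats::runif(np) < 0.05)
    if (tf == "FOXA1") {
      hit <- union(hit, sample(dmc_idx, ceiling(0.4 * length(dmc_idx))))
    }
    if (length(hit) > 0L) {
      tf_rows[[tf]] <- bed_tbl(pmax(manifest$pos[hit] - 50L, 1L),
                               manifest$pos[hit] + 50L,
                               extra = tibble::tibble(tf = tf))
    }
  }
  tfbs <- dplyr::bind_rows(tf_rows) %>% dplyr::arrange(.data$start)

  # -- methylation states ----------------------------------------------------
  hypo_prob <- c(island = 0.85, shore = 0.60, ocean = 0.25)
  base_state <- stats::runif(np) < hypo_prob[manifest$cgi_truth]
  t_base <- ifelse(base_state, 0.06, 0.94) +
    stats::rnorm(np, 0, 0.01)
  t_base <- clamp01(t_base)
  concord <- stats::runif(np) < cfg$concordant_frac
  normal <- ifelse(concord, t_base,
                   clamp01(ifelse(base_state, 0.94, 0.06) +
                             stats::rnorm(np, 0, 0.01)))

  # tumor beta per probe x sample: baseline + planted shifts + jitter
  minor <- epis[which.min(n_epi)]
  t_mat <- matrix(rep(t_base, n), np, n)
  dmc_dir <- rep(c(+1, -1), length.out = length(dmc_idx))
  dmc_up <- dmc_idx[dmc_dir > 0]
  dmc_dn <- dmc_idx[dmc_dir < 0]
  t_mat[dmc_up, ] <- clamp01(matrix(0.06, length(dmc_up), n) +
                               stats::rnorm(length(dmc_up), 0, 0.01))
  t_mat[dmc_dn, ] <- clamp01(matrix(0.94, length(dmc_dn), n) +
                               stats::rnorm(length(dmc_dn), 0, 0.01))
  is_minor <- epitype == minor
  t_mat[dmc_up, is_minor] <- clamp01(t_mat[dmc_up, is_minor] + cfg$dmc_delta)
  t_mat[dmc_dn, is_minor] <- clamp01(t_mat[dmc_dn, is_minor] - cfg$dmc_delta)
  normal[dmc_up] <- clamp01(0.06 + stats::rnorm(length(dmc_up), 0, 0.01))
  normal[dmc_dn] <- clamp01(0.94 + stats::rnorm(length(dmc_dn), 0, 0.01))

  for (sg in names(sub_blocks)) {
    idx <- match(sub_blocks[[sg]], manifest$probe_id)
    base_dir <- ifelse(t_base[idx] <= 0.5, +1, -1)
    t_mat[idx, ] <- clamp01(matrix(ifelse(base_dir > 0, 0.06, 0.94),
                                   length(idx), n))
    in_sg <- subgroup == sg
    t_mat[idx, in_sg] <- clamp01(t_mat[idx, in_sg] +
                                   base_dir * cfg$subgroup_delta)
  }

  # pair probes vary continuously across samples, independent of epitype
  t_mat[pair_idx, ] <- 0.1 + 0.8 * matrix(stats::rbeta(length(pair_idx) * n, 2, 2),
                                          length(pair_idx), n)
  normal[pair_idx] <- 0.5

  # variably methylated probes: continuous tumor variation unrelated to
  # epitype or expression (milder spread than the planted blocks)
  var_pool <- setdiff(seq_len(np), c(dmc_idx, pair_idx,
                                     match(unlist(sub_blocks), manifest$probe_id)))
  var_idx <- sort(sample(var_pool, round(cfg$frac_variable * np)))
  if (length(var_idx) > 0L) {
    t_mat[var_idx, ] <- 0.1 + 0.8 * matrix(stats::rbeta(length(var_idx) * n, 8, 8),
                                           length(var_idx), n)
    normal[var_idx] <- 0.5
  }

  # within-tumor jitter (all probes) then mixture + noise
  t_mat <- clamp01(t_mat + matrix(stats::rnorm(np * n, 0, 0.015), np, n))
  n_mat <- matrix(rep(normal, n), np, n)
  beta_obs <- t_mat * rep(purity, each = np) + n_mat * rep(1 - purity, each = np)
  beta_obs <- clamp01(beta_obs + matrix(stats::rnorm(np * n, 0, cfg$noise_sd),
                                        np, n))
  dimnames(beta_obs) <- list(manifest$probe_id, sample_id)
  dimnames(t_mat) <- dimnames(beta_obs)
  dimnames(n_mat) <- dimnames(beta_obs)

  # -- expression ------------------------------------------------------------
  ng <- cfg$n_genes
  gene_id <- genes$gene_id
  mu_g <- stats::rnorm(ng, 2.5, 1.2)
  log_expr <- matrix(mu_g, ng, n) + matrix(stats::rnorm(ng * n, 0, 0.6), ng, n)
  rownames(log_expr) <- gene_id
  colnames(log_expr) <- sample_id

  special <- integer(0)

  # planted CpG-gene pairs: gene in a tile near the probe, log expression
  # coupled to the probe's tumor beta at the configured correlation
  pair_gene <- character(length(pair_idx))
  for (i in seq_along(pair_idx)) {
    tile_i <- manifest$pos[pair_idx[i]] %/% .tile_bp
    cand <- which(genes$tile %/% .tile_bp %in%
                    ((tile_i - 2):(tile_i + 2)))
    cand <- setdiff(cand, special)
    gj <- if (length(cand) > 0L) cand[1L] else setdiff(seq_len(ng), special)[1L]
    special <- c(special, gj)
    z <- as.numeric(scale(t_mat[pair_idx[i], ]))
    e <- stats::rnorm(n)
    mu_g[gj] <- max(mu_g[gj], 1.5)
    log_expr[gj, ] <- mu_g[gj] + 0.6 * sign(cfg$pair_sign) *
      (cfg$pair_coupling * z + sqrt(1 - cfg$pair_coupling^2) * e)
    pair_gene[i] <- gene_id[gj]
  }

  # epitype-differential genes
  de_pool <- setdiff(seq_len(ng), special)
  de_idx <- sort(sample(de_pool, min(cfg$n_de_genes, length(de_pool))))
  special <- c(special, de_idx)
  de_dir <- rep(c(1, -1), length.out = length(de_idx))
  shift <- outer(de_dir * 1.5, as.numeric(is_minor))
  log_expr[de_idx, ] <- log_expr[de_idx, ] + shift
  mu_lift <- pmax(1.5 - mu_g[de_idx], 0)
  log_expr[de_idx, ] <- log_expr[de_idx, ] + mu_lift

  # latent-factor network blocks
  net_genes <- list()
  pool <- setdiff(seq_len(ng), special)
  for (b in seq_along(cfg$network_sizes)) {
    sz <- cfg$network_sizes[b]
    idx <- sort(sample(pool, sz))
    pool <- setdiff(pool, idx)
    z <- stats::rnorm(n)
    base <- pmax(mu_g[idx], 1.5)
    log_expr[idx, ] <- matrix(base, sz, n) + 1.1 * matrix(z, sz, n, byrow = TRUE) +
      0.35 * matrix(stats::rnorm(sz * n), sz, n)
    net_genes[[b]] <- gene_id[idx]
  }

  fpkm <- 2^log_expr

  # -- assemble --------------------------------------------------------------
  labels <- tibble::tibble(sample_id = sample_id, epitype = epitype,
                           subgroup = subgroup)
  truth <- list(
    labels = labels,
    probe_context = tibble::tibble(probe_id = manifest$probe_id,
                                   genic_context = manifest$genic_truth,
                                   cgi_context = manifest$cgi_truth,
                                   atac_overlap = atac_realized),
    purity = stats::setNames(purity, sample_id),
    dmc_probes = manifest$probe_id[dmc_idx],
    dmc_direction = stats::setNames(
      ifelse(dmc_dir > 0, "up_in_minor", "down_in_minor"),
      manifest$probe_id[dmc_idx]),
    minor_epitype = minor,
    subgroup_blocks = sub_blocks,
    variable_probes = manifest$probe_id[var_idx],
    pairs = tibble::tibble(probe_id = manifest$probe_id[pair_idx],
                           gene_id = pair_gene,
                           coupling = cfg$pair_coupling,
                           sign = sign(cfg$pair_sign)),
    de_genes = gene_id[de_idx],
    network_genes = net_genes,
    tumor_beta = t_mat,
    normal_beta = n_mat,
    config = cfg
  )
  structure(list(
    beta = matrix_to_tbl(beta_obs, "probe_id"),
    purity = tibble::tibble(sample_id = sample_id, purity = purity),
    fpkm = matrix_to_tbl(fpkm, "gene_id"),
    manifest = manifest[c("probe_id", "chrom", "pos")],
    gene_models = genes[c("gene_id", "chrom", "strand", "tss", "tes")],
    cgi = cgi, atac = atac, tfbs = tfbs,
    labels = labels, truth = truth
  ), class = "epityper_cohort")
}

#' @export
print.epityper_cohort <- function(x, ...) {
  cat(sprintf("<epityper_cohort> %d probes x %d samples; %d genes; %d planted DMCs, %d pairs\n",
              nrow(x$manifest), nrow(x$labels), nrow(x$gene_models),
              length(x$truth$dmc_probes), nrow(x$truth$pairs)))
  invisible(x)
}

#' Write a simulated cohort to disk in pipeline-ready formats
#'
#' Emits the exact file formats the analysis functions ingest: probe manifest,
#' beta/FPKM/purity/label TSVs, gene models TSV, CGI/ATAC/TFBS BED files
#' (0-based half-open, sorted), the planted truth as JSON, and the true
#' tumor/normal beta matrices as TSVs.
#'
#' @param cohort An `epityper_cohort`.
#' @param dir Output directory (created if missing).
#' @return Tibble manifest of emitted files (`name`, `path`).
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) rlang::abort(sprintf("cannot create '%s'", dir))
  }
  p <- function(f) file.path(dir, f)
  readr::write_tsv(cohort$beta, p("beta.tsv"))
  readr::write_tsv(cohort$purity, p("purity.tsv"))
  readr::write_tsv(cohort$fpkm, p("fpkm.tsv"))
  readr::write_tsv(cohort$manifest, p("probe_manifest.tsv"))
  readr::write_tsv(cohort$gene_models, p("gene_models.tsv"))
  readr::write_tsv(cohort$labels, p("labels.tsv"))
  write_bed <- function(x, f) {
    readr::write_tsv(x, p(f), col_names = FALSE)
  }
  write_bed(cohort$cgi, "cgi.bed")
  write_bed(cohort$atac, "atac.bed")
  write_bed(cohort$tfbs, "tfbs.bed")
  truth_small <- cohort$truth
  truth_small$tumor_beta <- NULL
  truth_small$normal_beta <- NULL
  truth_small$purity <- as.list(truth_small$purity)
  jsonlite::write_json(truth_small, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  readr::write_tsv(matrix_to_tbl(cohort$truth$tumor_beta, "probe_id"),
                   p("truth_tumor_beta.tsv"))
  readr::write_tsv(matrix_to_tbl(cohort$truth$normal_beta, "probe_id"),
                   p("truth_normal_beta.tsv"))
  files <- c("beta.tsv", "purity.tsv", "fpkm.tsv", "probe_manifest.tsv",
             "gene_models.tsv", "labels.tsv", "cgi.bed", "atac.bed",
             "tfbs.bed", "truth.json", "truth_tumor_beta.tsv",
             "truth_normal_beta.tsv")
  tibble::tibble(name = files, path = vapply(files, p, character(1)))
}
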