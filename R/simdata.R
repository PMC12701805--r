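#' Build a simulation configuration
#'
#' Defines a cattle-like synthetic cohort: LD-structured phased haplotypes with
#' ancestral-allele labels, a planted partial selective sweep, correlated
#' quantitative traits driven by a shared pleiotropic causal block plus a
#' polygenic background, cis-regulated gene expression with hidden batch
#' factors, a beta-distributed CpG methylome with planted hypomethylated
#' islands, and TSS-enriched annotation tracks. All downstream modules are
#' exercised against the ground truth this generator emits.
#'
#' @param seed integer master seed; every stochastic stage derives a
#'   substream from it, so the full bundle is bit-for-bit reproducible.
#' @param n_individuals number of diploid individuals.
#' @param n_chromosomes,variants_per_chrom,chrom_length_bp genome dimensions.
#' @param n_founder_haplotypes size of the founder haplotype pool; individuals
#'   are recombinant mosaics of founder draws.
#' @param recomb_rate_per_bp per-bp probability of a founder switch between
#'   adjacent sites (1e-8 approximates 1 cM/Mb).
#' @param ld_scale_bp decay length of the founder-chain allele-copying
#'   probability; sets the LD horizon.
#' @param n_traits,trait_corr number of traits and their cross-trait effect
#'   correlation matrix (default exchangeable 0.4).
#' @param n_causal_polygenic polygenic background causal variants per genome.
#' @param pleiotropic_block list(chrom, start_bp, end_bp, n_causal,
#'   effect_scale): the shared causal block driving pleiotropy.
#' @param trait_h2 per-trait narrow-sense heritability (recycled).
#' @param n_genes,frac_genes_with_eqtl,eqtl_effect_sd expression design; eQTL
#'   effects are drawn N(0, eqtl_effect_sd) on the log2 scale.
#' @param n_hidden_factors hidden technical factors added to expression.
#' @param n_expression_samples size of the expression sub-cohort.
#' @param expr_noise_sd residual sd of log2(TPM+1).
#' @param sweep list(chrom, core_bp, final_derived_freq, half_width_bp).
#' @param methylome list(n_cpg, island_meth_mean, background_meth_mean,
#'   coverage_mean, n_islands).
#' @param mechanism_gene if TRUE the strongest pleiotropic causal variant is
#'   also planted as the eQTL of its nearest gene, creating a full
#'   variant -> expression -> multi-trait chain for end-to-end recovery.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_individuals = 300L,
                       n_chromosomes = 2L,
                       variants_per_chrom = 1500L,
                       chrom_length_bp = 5e6,
                       n_founder_haplotypes = 120L,
                       recomb_rate_per_bp = 2e-8,
                       ld_scale_bp = 25000,
                       n_traits = 5L,
                       trait_corr = NULL,
                       n_causal_polygenic = 50L,
                       pleiotropic_block = list(chrom = 1L, start_bp = 2.0e6,
                                                end_bp = 2.3e6, n_causal = 3L,
                                                effect_scale = 0.5),
                       trait_h2 = 0.4,
                       n_genes = 60L,
                       frac_genes_with_eqtl = 0.4,
                       eqtl_effect_sd = 1.0,
                       n_hidden_factors = 2L,
                       n_expression_samples = NULL,
                       expr_noise_sd = 0.5,
                       sweep = list(chrom = 2L, core_bp = 2.5e6,
                                    final_derived_freq = 0.8,
                                    half_width_bp = 3e5),
                       methylome = list(n_cpg = 4000L, island_meth_mean = 0.05,
                                        background_meth_mean = 0.85,
                                        coverage_mean = 20, n_islands = 6L),
                       mechanism_gene = TRUE) {
  cfg <- list(
    seed = check_count(seed, "seed", 0),
    n_individuals = check_count(n_individuals, "n_individuals", 2),
    n_chromosomes = check_count(n_chromosomes, "n_chromosomes"),
    variants_per_chrom = check_count(variants_per_chrom, "variants_per_chrom", 2),
    chrom_length_bp = as.numeric(chrom_length_bp),
    n_founder_haplotypes = check_count(n_founder_haplotypes, "n_founder_haplotypes", 2),
    recomb_rate_per_bp = check_fraction(recomb_rate_per_bp, "recomb_rate_per_bp"),
    ld_scale_bp = as.numeric(ld_scale_bp),
    n_traits = check_count(n_traits, "n_traits"),
    n_causal_polygenic = check_count(n_causal_polygenic, "n_causal_polygenic", 0),
    pleiotropic_block = pleiotropic_block,
    n_genes = check_count(n_genes, "n_genes"),
    frac_genes_with_eqtl = check_fraction(frac_genes_with_eqtl, "frac_genes_with_eqtl"),
    eqtl_effect_sd = as.numeric(eqtl_effect_sd),
    n_hidden_factors = check_count(n_hidden_factors, "n_hidden_factors", 0),
    expr_noise_sd = as.numeric(expr_noise_sd),
    sweep = sweep,
    methylome = methylome,
    mechanism_gene = isTRUE(mechanism_gene)
  )
  cfg$trait_h2 <- rep_len(as.numeric(trait_h2), cfg$n_traits)
  if (any(cfg$trait_h2 < 0 | cfg$trait_h2 >= 1))
    stop("trait_h2 must lie in [0, 1)", call. = FALSE)
  if (is.null(trait_corr)) {
    trait_corr <- matrix(0.4, cfg$n_traits, cfg$n_traits)
    diag(trait_corr) <- 1
  }
  trait_corr <- as.matrix(trait_corr)
  if (nrow(trait_corr) != cfg$n_traits || ncol(trait_corr) != cfg$n_traits)
    stop("trait_corr must be n_traits x n_traits", call. = FALSE)
  if (max(abs(trait_corr - t(trait_corr))) > 1e-8 ||
      any(abs(diag(trait_corr) - 1) > 1e-8))
    stop("trait_corr must be symmetric with unit diagonal", call. = FALSE)
  ev <- eigen(trait_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("trait_corr is not positive semi-definite", call. = FALSE)
  cfg$trait_corr <- trait_corr
  fdf <- sweep$final_derived_freq
  if (!is.numeric(fdf) || fdf <= 0 || fdf >= 1)
    stop("sweep$final_derived_freq must be in (0, 1)", call. = FALSE)
  if (cfg$chrom_length_bp < cfg$variants_per_chrom * 10)
    stop("chrom_length_bp too small for the requested variant count", call. = FALSE)
  cfg$n_expression_samples <- if (is.null(n_expression_samples)) {
    min(cfg$n_individuals, 200L)
  } else check_count(n_expression_samples, "n_expression_samples", 10)
  if (cfg$n_expression_samples > cfg$n_individuals)
    stop("n_expression_samples exceeds n_individuals", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

chrom_name <- function(i) paste0("chr", i)

# Founder pool by a first-order Markov chain over sites: allele at site j
# copies the founder's allele at j-1 with probability exp(-d/ld_scale), else
# is a fresh Bernoulli(f_j) draw. Individuals are recombinant founder mosaics.
simulate_chromosome <- function(cfg, chrom_idx) {
  m <- cfg$variants_per_chrom
  H <- cfg$n_founder_haplotypes
  nh <- 2L * cfg$n_individuals
  pos <- sort(sample.int(cfg$chrom_length_bp - 1L, m)) + 1L
  f <- runif(m, 0.1, 0.9)
  d <- diff(pos)
  copy_p <- exp(-d / cfg$ld_scale_bp)

  founders <- matrix(0L, H, m)
  founders[, 1] <- rbinom(H, 1L, f[1])
  for (j in 2:m) {
    keep <- runif(H) < copy_p[j - 1]
    founders[, j] <- ifelse(keep, founders[, j - 1], rbinom(H, 1L, f[j]))
  }

  # mosaic paths: per haplotype, founder index per site
  switch_p <- -expm1(-cfg$recomb_rate_per_bp * d)
  haps <- matrix(0L, nh, m)
  paths <- matrix(0L, nh, m)
  for (h in seq_len(nh)) {
    sw <- c(TRUE, runif(m - 1) < switch_p)
    seg <- cumsum(sw)
    fo <- sample.int(H, max(seg), replace = TRUE)
    path <- fo[seg]
    paths[h, ] <- path
    haps[h, ] <- founders[cbind(path, seq_len(m))]
  }

  sweep_info <- NULL
  if (!is.null(cfg$sweep) && cfg$sweep$chrom == chrom_idx) {
    # core = the low-frequency variant nearest the requested position, so the
    # sweep lifts a rare derived allele (the signature iHS is built to see)
    near <- which(abs(pos - cfg$sweep$core_bp) <= 1e5)
    if (!length(near)) near <- which.min(abs(pos - cfg$sweep$core_bp))
    base_freq <- colMeans(haps[, near, drop = FALSE])
    core_j <- near[which.min(abs(base_freq - 0.15))]
    hw <- cfg$sweep$half_width_bp %||% 2e5
    region <- c(max(0, pos[core_j] - 1 - hw), min(cfg$chrom_length_bp, pos[core_j] + hw))
    # sweep haplotype = founder 1, forced to carry the derived (ALT) allele
    founders[1, core_j] <- 1L
    f0 <- mean(haps[, core_j])
    target <- cfg$sweep$final_derived_freq
    pi_carry <- max(0, min(1, (target - f0) / (1 - f0)))
    carriers <- which(runif(nh) < pi_carry)
    # each carrier inherits the sweep haplotype over a tract around the core
    # with exponential one-sided lengths (mean hw), mimicking the decaying
    # shared-haplotype lengths of a recent partial sweep
    for (h in carriers) {
      lo <- pos[core_j] - stats::rexp(1, 1 / hw)
      hi <- pos[core_j] + stats::rexp(1, 1 / hw)
      tract <- which(pos >= lo & pos <= hi)
      haps[h, tract] <- founders[1, tract]
      haps[h, core_j] <- 1L
    }
    sweep_info <- list(chrom = chrom_name(chrom_idx), start = region[1],
                       end = region[2], core_variant_index = core_j,
                       target_freq = target,
                       observed_freq = mean(haps[, core_j]))
  }

  dr2 <- round(pmin(1, 0.55 + rbeta(m, 8, 1) * 0.45), 3)
  af <- colMeans(haps)
  variants <- data.frame(
    chrom = chrom_name(chrom_idx), pos = pos,
    id = sprintf("rs%d_%06d", chrom_idx, seq_len(m)),
    ref = sample(c("A", "C", "G", "T"), m, replace = TRUE),
    alt = NA_character_, aa = NA_character_, dr2 = dr2,
    maf = pmin(af, 1 - af), stringsAsFactors = FALSE
  )
  alt_choices <- c(A = "G", C = "T", G = "A", T = "C")
  variants$alt <- unname(alt_choices[variants$ref])
  variants$aa <- variants$ref  # ancestral allele = REF by construction
  list(variants = variants, haps = haps, sweep = sweep_info)
}

simulate_genotypes <- function(cfg) {
  with_seed(substream_seed(cfg$seed, "genotypes"), {
    per_chrom <- lapply(seq_len(cfg$n_chromosomes),
                        function(i) simulate_chromosome(cfg, i))
    variants <- do.call(rbind, lapply(per_chrom, `[[`, "variants"))
    haps <- do.call(cbind, lapply(per_chrom, `[[`, "haps"))
    rownames(variants) <- NULL
    sweep_info <- Filter(Negate(is.null), lapply(per_chrom, `[[`, "sweep"))
    sweep_info <- if (length(sweep_info)) sweep_info[[1]] else NULL
    if (!is.null(sweep_info)) {
      chrom_offset <- (cfg$sweep$chrom - 1L) * cfg$variants_per_chrom
      sweep_info$core_variant <- variants$id[chrom_offset + sweep_info$core_variant_index]
      sweep_info$core_variant_index <- NULL
    }
    samples <- sprintf("ind%04d", seq_len(cfg$n_individuals))
    panel <- new_haplotype_panel(samples, variants, haps)
    list(panel = panel, sweep = sweep_info)
  })
}

#' Simulate correlated phenotypes from a genotype panel
#'
#' Trait model: y_t = sum_k x_k beta_kt + e_t plus categorical nuisance
#' effects (farm, sex analogues). Causal effects for the pleiotropic block and
#' the polygenic background are drawn with cross-trait correlation
#' `trait_corr`; the genetic component is rescaled so each trait's
#' Var(genetic)/Var(total) equals `trait_h2`.
#'
#' @param panel a `haplotype_panel`.
#' @param cfg a `sim_config`.
#' @return list with `phenotypes` (adjusted trait table), `covariates`
#'   (farm/sex table), `causal` truth table, and the per-trait genetic values.
#' @export
simulate_phenotypes <- function(panel, cfg) {
  with_seed(substream_seed(cfg$seed, "phenotypes"), {
    n <- length(panel$samples)
    v <- panel$variants
    blk <- cfg$pleiotropic_block
    in_blk <- which(v$chrom == chrom_name(blk$chrom) &
                    v$pos >= blk$start_bp & v$pos <= blk$end_bp &
                    v$maf >= 0.1)
    if (length(in_blk) < blk$n_causal)
      stop("pleiotropic block contains too few common variants", call. = FALSE)
    blk_idx <- sort(sample(in_blk, blk$n_causal))
    poly_pool <- setdiff(which(v$maf >= 0.05), blk_idx)
    poly_idx <- sort(sample(poly_pool, min(cfg$n_causal_polygenic, length(poly_pool))))

    Lc <- chol(cfg$trait_corr + diag(1e-10, cfg$n_traits))
    draw_effects <- function(k, scale_) {
      matrix(rnorm(k * cfg$n_traits), k) %*% Lc * scale_
    }
    B_blk <- draw_effects(length(blk_idx), blk$effect_scale)
    # make the first block variant the strongest, shared across traits
    B_blk[1, ] <- blk$effect_scale * (1.5 + 0.1 * abs(rnorm(cfg$n_traits))) *
      sign(B_blk[1, 1] + 1e-9)
    poly_scale <- if (length(poly_idx)) 0.15 else 0
    B_poly <- draw_effects(length(poly_idx), poly_scale)

    X <- panel_dosage(panel)
    causal_idx <- c(blk_idx, poly_idx)
    B <- rbind(B_blk, B_poly)
    G <- X[, causal_idx, drop = FALSE] %*% B

    y <- matrix(0, n, cfg$n_traits)
    scale_t <- numeric(cfg$n_traits)
    for (t in seq_len(cfg$n_traits)) {
      vg <- stats::var(G[, t])
      h2 <- cfg$trait_h2[t]
      s <- if (h2 > 0 && vg > 0) sqrt(h2 / vg) else 0
      scale_t[t] <- s
      y[, t] <- s * G[, t] + rnorm(n, 0, sqrt(max(1 - h2, 1e-12)))
    }
    colnames(y) <- sprintf("trait%02d", seq_len(cfg$n_traits))

    farm <- factor(sample(paste0("farm", 1:3), n, replace = TRUE))
    sex <- factor(sample(c("F", "M"), n, replace = TRUE))
    farm_eff <- c(farm1 = -0.5, farm2 = 0, farm3 = 0.5)
    y <- y + farm_eff[as.character(farm)] + 0.3 * (sex == "M")

    causal <- do.call(rbind, lapply(seq_len(cfg$n_traits), function(t) {
      data.frame(variant = v$id[causal_idx], trait = colnames(y)[t],
                 beta = B[, t] * scale_t[t],
                 block = c(rep(TRUE, length(blk_idx)), rep(FALSE, length(poly_idx))),
                 stringsAsFactors = FALSE)
    }))
    causal <- causal[abs(causal$beta) > 0, ]

    list(
      phenotypes = data.frame(sample = panel$samples, y,
                              check.names = FALSE, stringsAsFactors = FALSE),
      covariates = data.frame(sample = panel$samples, farm = as.character(farm),
                              sex = as.character(sex), stringsAsFactors = FALSE),
      causal = causal,
      genetic_values = sweep(G, 2, scale_t, `*`),
      block_variants = v$id[blk_idx]
    )
  })
}

#' Simulate gene models and cis-regulated expression
#'
#' log2(TPM+1) = baseline + cis-eQTL effect x dosage + hidden-factor term +
#' noise, back-transformed to TPM (pseudocount 1, consistent with the aFC
#' estimator). A configurable fraction of genes carries one planted cis-eQTL
#' within 1 Mb of the TSS.
#'
#' @inheritParams simulate_phenotypes
#' @param mechanism_variant optional variant id forced to be the eQTL of its
#'   nearest gene (the planted regulatory mechanism).
#' @return list with `gene_models`, `tpm` (genes x samples), `eqtl_truth`,
#'   `hidden_factors` (samples x k), `expr_samples`.
#' @export
simulate_expression <- function(panel, cfg, mechanism_variant = NULL) {
  with_seed(substream_seed(cfg$seed, "expression"), {
    v <- panel$variants
    ng <- cfg$n_genes
    chrom <- chrom_name(sample.int(cfg$n_chromosomes, ng, replace = TRUE))
    tss <- sample.int(cfg$chrom_length_bp - 30000L, ng) + 10000L
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    glen <- pmin(5000L + stats::rgeom(ng, 1 / 15000), 60000L)
    gstart <- ifelse(strand == "+", tss, pmax(1L, tss - glen))
    gend <- ifelse(strand == "+", pmin(cfg$chrom_length_bp, tss + glen), tss)
    gene_models <- data.frame(
      gene = sprintf("gene%04d", seq_len(ng)), chrom = chrom, tss = tss,
      strand = strand, start = as.integer(gstart), end = as.integer(gend),
      stringsAsFactors = FALSE
    )
    gene_models <- gene_models[order(gene_models$chrom, gene_models$tss), ]
    gene_models$gene <- sprintf("gene%04d", seq_len(ng))  # keep ids ordered
    rownames(gene_models) <- NULL

    expr_samples <- sort(sample.int(length(panel$samples), cfg$n_expression_samples))
    X <- panel_dosage(panel)[expr_samples, , drop = FALSE]
    ns <- length(expr_samples)

    n_eqtl <- round(cfg$frac_genes_with_eqtl * ng)
    eqtl_genes <- sort(sample.int(ng, n_eqtl))
    truth <- NULL
    if (n_eqtl > 0) {
      rows <- lapply(eqtl_genes, function(g) {
        cis <- which(v$chrom == gene_models$chrom[g] &
                     abs(v$pos - gene_models$tss[g]) <= 1e6 & v$maf >= 0.05)
        if (!length(cis))
          stop(sprintf("gene %s has no common cis variant for its planted eQTL",
                       gene_models$gene[g]), call. = FALSE)
        j <- sample(cis, 1)
        data.frame(gene = gene_models$gene[g], variant = v$id[j],
                   effect = rnorm(1, 0, cfg$eqtl_effect_sd),
                   stringsAsFactors = FALSE)
      })
      truth <- do.call(rbind, rows)
    }
    if (!is.null(mechanism_variant)) {
      j <- match(mechanism_variant, v$id)
      if (is.na(j)) stop("mechanism variant not in panel", call. = FALSE)
      same_chrom <- which(gene_models$chrom == v$chrom[j] &
                          abs(gene_models$tss - v$pos[j]) <= 1e6)
      if (length(same_chrom)) {
        g <- same_chrom[which.min(abs(gene_models$tss[same_chrom] - v$pos[j]))]
        mech_effect <- 1.0 * sign(rnorm(1) + 1e-9)
        truth <- truth[is.null(truth$gene) | truth$gene != gene_models$gene[g], ,
                       drop = FALSE]
        truth <- rbind(truth, data.frame(gene = gene_models$gene[g],
                                         variant = mechanism_variant,
                                         effect = mech_effect,
                                         stringsAsFactors = FALSE))
      }
    }

    k <- cfg$n_hidden_factors
    Fmat <- if (k > 0) matrix(rnorm(ns * k), ns) else matrix(0, ns, 0)
    Lmat <- if (k > 0) matrix(rnorm(ng * k, 0, 0.6), ng) else matrix(0, ng, 0)
    baseline <- rnorm(ng, 3, 1)

    logx <- matrix(baseline, ng, ns) + Lmat %*% t(Fmat) +
      matrix(rnorm(ng * ns, 0, cfg$expr_noise_sd), ng)
    if (!is.null(truth) && nrow(truth)) {
      gi <- match(truth$gene, gene_models$gene)
      vi <- match(truth$variant, v$id)
      for (r in seq_len(nrow(truth)))
        logx[gi[r], ] <- logx[gi[r], ] + truth$effect[r] * X[, vi[r]]
    }
    tpm <- pmax(2^logx - 1, 0)
    dimnames(tpm) <- list(gene_models$gene, panel$samples[expr_samples])
    if (k > 0) dimnames(Fmat) <- list(panel$samples[expr_samples],
                                      paste0("factor", seq_len(k)))
    list(gene_models = gene_models, tpm = tpm,
         eqtl_truth = truth %||% data.frame(gene = character(), variant = character(),
                                            effect = numeric()),
         hidden_factors = Fmat, hidden_loadings = Lmat,
         expr_samples = panel$samples[expr_samples])
  })
}

# Random genome with planted CpG islands (GC-rich, CpG-dense) on chr1, plus a
# CpG count table whose methylation is low inside planted hypomethylated
# islands and high elsewhere.
simulate_methylome <- function(cfg) {
  with_seed(substream_seed(cfg$seed, "methylome"), {
    L <- as.integer(min(cfg$chrom_length_bp, 1e6))
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c(0.29, 0.21, 0.21, 0.29))
    mc <- cfg$methylome
    n_isl <- mc$n_islands %||% 6L
    isl_len <- 700L
    starts <- sort(sample.int(L - 2 * isl_len, n_isl))
    # enforce spacing so islands never merge
    for (i in seq_len(n_isl)[-1])
      starts[i] <- max(starts[i], starts[i - 1] + 5000L)
    starts <- starts[starts + isl_len < L]
    cgi <- data.frame(chrom = "chr1", start = starts, end = starts + isl_len)
    for (i in seq_len(nrow(cgi))) {
      idx <- (cgi$start[i] + 1):cgi$end[i]
      # CpG-dense block: heavy CG dinucleotide content
      blk <- rep(c("C", "G"), length.out = length(idx))
      mix <- runif(length(idx)) < 0.25
      blk[mix] <- sample(c("A", "C", "G", "T"), sum(mix), replace = TRUE,
                         prob = c(0.15, 0.35, 0.35, 0.15))
      base[idx] <- blk
    }
    seqs <- paste(base, collapse = "")

    cpg_pos <- gregexpr("CG", seqs, fixed = TRUE)[[1]]
    cpg_pos <- as.integer(cpg_pos)
    if (length(cpg_pos) > mc$n_cpg)
      cpg_pos <- sort(sample(cpg_pos, mc$n_cpg))
    in_isl <- rep(FALSE, length(cpg_pos))
    for (i in seq_len(nrow(cgi)))
      in_isl <- in_isl | (cpg_pos > cgi$start[i] & cpg_pos <= cgi$end[i])
    mu <- ifelse(in_isl, mc$island_meth_mean, mc$background_meth_mean)
    s <- 30
    level <- rbeta(length(cpg_pos), mu * s, (1 - mu) * s)
    coverage <- rpois(length(cpg_pos), mc$coverage_mean) + 1L
    methylated <- rbinom(length(cpg_pos), coverage, level)
    cpg <- data.frame(chrom = "chr1", pos = cpg_pos, strand = "+",
                      coverage = coverage, methylated = methylated,
                      stringsAsFactors = FALSE)
    list(fasta_seq = seqs, cpg = cpg, cgi_truth = cgi, hmr_truth = cgi)
  })
}

# Annotation tracks: promoter-proximal peaks, chromatin-state tiling, and a
# non-overlapping TAD tiling per chromosome.
simulate_tracks <- function(cfg, gene_models) {
  with_seed(substream_seed(cfg$seed, "tracks"), {
    gm <- gene_models
    pk_genes <- sort(sample.int(nrow(gm), round(0.5 * nrow(gm))))
    peaks <- data.frame(chrom = gm$chrom[pk_genes],
                        start = pmax(0, gm$tss[pk_genes] - 1000L),
                        end = gm$tss[pk_genes] + 1000L,
                        label = "peak", stringsAsFactors = FALSE)
    nbg <- round(0.3 * nrow(gm))
    bg_chrom <- chrom_name(sample.int(cfg$n_chromosomes, nbg, replace = TRUE))
    bg_start <- sample.int(cfg$chrom_length_bp - 2000L, nbg)
    peaks <- rbind(peaks, data.frame(chrom = bg_chrom, start = bg_start,
                                     end = bg_start + 2000L, label = "peak"))
    peaks <- peaks[order(peaks$chrom, peaks$start), ]

    tads <- do.call(rbind, lapply(seq_len(cfg$n_chromosomes), function(i) {
      bounds <- sort(sample.int(cfg$chrom_length_bp - 1L,
                                max(1, round(cfg$chrom_length_bp / 5e5) - 1)))
      edges <- unique(c(0, bounds, cfg$chrom_length_bp))
      data.frame(chrom = chrom_name(i), start = edges[-length(edges)],
                 end = edges[-1],
                 label = sprintf("TAD_%d_%02d", i, seq_len(length(edges) - 1)),
                 stringsAsFactors = FALSE)
    }))

    states <- do.call(rbind, lapply(seq_len(cfg$n_chromosomes), function(i) {
      edges <- seq(0, cfg$chrom_length_bp, by = 50000)
      if (edges[length(edges)] < cfg$chrom_length_bp)
        edges <- c(edges, cfg$chrom_length_bp)
      data.frame(chrom = chrom_name(i), start = edges[-length(edges)],
                 end = edges[-1],
                 label = paste0("E", sample.int(14, length(edges) - 1, replace = TRUE)),
                 stringsAsFactors = FALSE)
    }))
    list(peaks = new_interval_track("peaks", peaks),
         tads = new_interval_track("tads", tads),
         states = new_interval_track("states", states))
  })
}

#' Generate the full synthetic cohort bundle
#'
#' Writes a phased VCF (INFO keys `AA`, ancestral allele, and `DR2`,
#' imputation-quality analogue), phenotype and covariate tables, gene models,
#' a TPM matrix, a CpG methylation count table, a genome FASTA with CpG-dense
#' islands, BED annotation tracks, and a JSON truth manifest. The same
#' (config, seed) always reproduces the bundle byte for byte.
#'
#' @param cfg a [sim_config()].
#' @param out_dir directory to write the bundle into (created if missing).
#' @return invisibly, a list with `paths`, the `truth` manifest, and the
#'   in-memory objects (`panel`, `phenotypes`, `covariates`, `gene_models`,
#'   `tpm`, `cpg`, `tracks`).
#' @export
simulate_cohort <- function(cfg, out_dir = tempfile("cohort")) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  geno <- simulate_genotypes(cfg)
  panel <- geno$panel
  phen <- simulate_phenotypes(panel, cfg)
  mech_var <- if (cfg$mechanism_gene) phen$block_variants[1] else NULL
  expr <- simulate_expression(panel, cfg, mechanism_variant = mech_var)
  meth <- simulate_methylome(cfg)
  tracks <- simulate_tracks(cfg, expr$gene_models)

  paths <- list(
    vcf = file.path(out_dir, "genotypes.vcf"),
    phenotypes = file.path(out_dir, "phenotypes.tsv"),
    covariates = file.path(out_dir, "covariates.tsv"),
    gene_models = file.path(out_dir, "gene_models.tsv"),
    tpm = file.path(out_dir, "tpm.tsv"),
    cpg = file.path(out_dir, "cpg_counts.tsv"),
    fasta = file.path(out_dir, "genome.fa"),
    peaks = file.path(out_dir, "peaks.bed"),
    tads = file.path(out_dir, "tads.bed"),
    states = file.path(out_dir, "states.bed"),
    truth = file.path(out_dir, "truth.json")
  )

  write_vcf(panel, paths$vcf)
  write_tsv(phen$phenotypes, paths$phenotypes)
  write_tsv(phen$covariates, paths$covariates)
  write_tsv(expr$gene_models, paths$gene_models)
  tpm_df <- data.frame(gene = rownames(expr$tpm), expr$tpm,
                       check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(tpm_df, paths$tpm)
  write_tsv(meth$cpg, paths$cpg)
  seq_set <- Biostrings::DNAStringSet(meth$fasta_seq)
  names(seq_set) <- "chr1"
  Biostrings::writeXStringSet(seq_set, paths$fasta, width = 80L)
  write_bed(tracks$peaks, paths$peaks)
  write_bed(tracks$tads, paths$tads)
  write_bed(tracks$states, paths$states)

  truth <- list(
    causal_variants = phen$causal,
    pleiotropic_block_variants = phen$block_variants,
    mechanism_variant = mech_var,
    eqtl_truth = expr$eqtl_truth,
    sweep_region = geno$sweep,
    hmr_truth = meth$hmr_truth,
    cgi_truth = meth$cgi_truth,
    hidden_factors = expr$hidden_factors,
    expr_samples = expr$expr_samples
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)

  invisible(list(paths = paths, truth = truth, panel = panel,
                 phenotypes = phen$phenotypes, covariates = phen$covariates,
                 genetic_values = phen$genetic_values,
                 gene_models = expr$gene_models, tpm = expr$tpm,
                 cpg = meth$cpg, fasta_seq = meth$fasta_seq, tracks = tracks))
}
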