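# Orchestration: simulate -> QC -> GWAS -> multi-trait -> gene-based ->
# sweep -> eQTL -> TWAS -> coloc/SMR -> enrichment -> methylome -> report,
# with per-stage substream seeds so toggling one stage never shifts the
# random stream of another.

#' Run the integrated pipeline on a synthetic cohort
#'
#' Executes the enabled stages in dependency order against one simulated
#' cohort and writes per-stage tables plus a provenance manifest into
#' `out_dir`. Reruns with the same config produce identical outputs.
#'
#' @param cfg a [sim_config()].
#' @param out_dir run directory.
#' @param stages named logical list toggling stages: gwas, multitrait,
#'   gene_gwas, sweep, eqtl, twas, coloc_smr, enrich, methylome.
#' @param n_perm_eqtl permutations per gene for the eQTL pass.
#' @param n_draws_top Monte-Carlo draws for the SNP-wise Top test.
#' @param n_perm_enrich,n_perm_tad enrichment permutation counts.
#' @return list of per-stage results (also serialized as tables under
#'   `out_dir`).
#' @export
run_pipeline <- function(cfg, out_dir = tempfile("run"),
                         stages = list(),
                         n_perm_eqtl = 1000, n_draws_top = 2000,
                         n_perm_enrich = 1000, n_perm_tad = 1000) {
  on <- function(s) !identical(stages[[s]], FALSE)
  need <- function(s, dep) {
    if (on(s) && !on(dep))
      stop(sprintf("stage '%s' requires stage '%s'", s, dep), call. = FALSE)
  }
  need("multitrait", "gwas"); need("twas", "eqtl"); need("twas", "gwas")
  need("coloc_smr", "eqtl"); need("coloc_smr", "gwas")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = cfg, out_dir = out_dir)

  sim <- simulate_cohort(cfg, file.path(out_dir, "cohort"))
  res$sim <- sim
  qc <- variant_qc(sim$panel)
  panel <- qc$panel
  res$qc <- qc["exclusions"]
  traits <- setdiff(names(sim$phenotypes), "sample")
  covars <- sim$covariates[, c("farm", "sex")]

  gwas_stats <- NULL
  if (on("gwas")) {
    K <- build_grm(panel)
    eig <- eigen(K, symmetric = TRUE)
    gwas_stats <- lapply(traits, function(tr) {
      y <- sim$phenotypes[[tr]]
      vc <- reml_variance(y, covars, eig)
      st <- snp_association(panel, y, covars, vc)
      attr(st, "vc") <- vc[c("sigma2_a", "sigma2_e", "h2")]
      st
    })
    names(gwas_stats) <- traits
    res$gwas <- gwas_stats
    for (tr in traits)
      write_tsv(gwas_stats[[tr]], file.path(out_dir, paste0("gwas_", tr, ".tsv")))
  }

  if (on("multitrait")) {
    tmat <- do.call(cbind, lapply(gwas_stats, `[[`, "t"))
    rownames(tmat) <- gwas_stats[[1]]$id
    res$multitrait <- multitrait_chi2(tmat)
    write_tsv(res$multitrait$stats, file.path(out_dir, "multitrait.tsv"))
  }

  if (on("gene_gwas") && !is.null(gwas_stats)) {
    res$gene_gwas <- gene_gwas(sim$gene_models, panel, gwas_stats[[1]],
                               n_draws = n_draws_top,
                               seed = substream_seed(cfg$seed, "genegwas"))
    write_tsv(res$gene_gwas, file.path(out_dir, "gene_gwas.tsv"))
  }

  if (on("sweep")) {
    scan <- standardize_ihs(ihs_scan(panel))
    res$sweep_scores <- scan
    res$sweep_windows <- call_sweep_windows(scan)
    write_tsv(res$sweep_windows, file.path(out_dir, "sweep_windows.tsv"))
  }

  eqtl_res <- NULL
  if (on("eqtl")) {
    expr_samples <- colnames(sim$tpm)
    sub_idx <- match(expr_samples, panel$samples)
    keep_rows <- as.vector(rbind(2 * sub_idx - 1, 2 * sub_idx))
    epanel <- new_haplotype_panel(expr_samples, panel$variants,
                                  panel$haps[keep_rows, , drop = FALSE])
    keep_genes <- filter_expressed_genes(sim$tpm)
    norm <- normalize_expression(sim$tpm[keep_genes, , drop = FALSE])
    k_hidden <- min(cfg$n_hidden_factors + 3, ncol(norm) - 3, 10)
    hf <- hidden_factors(norm, k = max(k_hidden, 0))
    gpc <- genotype_pcs(epanel, k = 2)
    covmat <- cbind(hf, gpc)
    gm <- sim$gene_models[sim$gene_models$gene %in% keep_genes, ]
    scan <- cis_scan(epanel, norm, gm, covmat)
    perm <- do.call(rbind, lapply(names(scan$genes), function(g) {
      if (!length(scan$genes[[g]]$variant_idx)) return(NULL)
      as.data.frame(permutation_pass(scan, g, n_perm = n_perm_eqtl,
                                     seed = substream_seed(cfg$seed, paste0("perm_", g))),
                    stringsAsFactors = FALSE)
    }))
    called <- egene_calling(perm)
    afc_val <- vapply(seq_len(nrow(called)), function(i) {
      if (!called$egene[i]) return(NA_real_)
      g <- called$gene[i]
      j <- match(called$top_variant[i], epanel$variants$id)
      afc(sim$tpm[g, ], panel_dosage(epanel)[, j], covmat)
    }, numeric(1))
    called$afc <- afc_val
    eqtl_res <- list(scan = scan, genes = called, panel = epanel,
                     norm = norm, covmat = covmat, gene_models = gm)
    res$eqtl <- eqtl_res
    write_tsv(called, file.path(out_dir, "eqtl_genes.tsv"))
    write_tsv(scan$pairs, file.path(out_dir, "eqtl_pairs.tsv"))
  }

  if (on("twas")) {
    eg <- eqtl_res$genes
    gm <- eqtl_res$gene_models
    weights <- list()
    for (g in eg$gene[eg$egene]) {
      gi <- match(g, gm$gene)
      cisj <- which(panel$variants$chrom == gm$chrom[gi] &
                    abs(panel$variants$pos - gm$tss[gi]) <= 1e6)
      if (length(cisj) < 10) next
      cis_sub <- panel_subset(eqtl_res$panel, cisj)
      expr_g <- eqtl_res$norm[g, ]
      h2fit <- try(cis_h2(cis_sub, expr_g, eqtl_res$covmat), silent = TRUE)
      if (inherits(h2fit, "try-error") || !isTRUE(h2fit$pass)) next
      weights[[g]] <- train_weights(cis_sub, expr_g, h2fit$h2,
                                    seed = substream_seed(cfg$seed, paste0("twas_", g)))
    }
    res$twas_weights <- weights
    res$twas <- lapply(traits, function(tr)
      twas_associate(weights, panel, sim$phenotypes[[tr]], covars))
    names(res$twas) <- traits
    twas_all <- do.call(rbind, Map(function(d, tr) {
      if (nrow(d)) d$trait <- tr; d
    }, res$twas, traits))
    if (!is.null(twas_all)) write_tsv(twas_all, file.path(out_dir, "twas.tsv"))
  }

  if (on("coloc_smr")) {
    eg <- eqtl_res$genes
    gm <- eqtl_res$gene_models
    pairs <- eqtl_res$scan$pairs
    coloc_rows <- list(); smr_rows <- list()
    for (tr in traits) {
      gst <- gwas_stats[[tr]]
      for (g in eg$gene[eg$egene]) {
        ep <- pairs[pairs$gene == g, ]
        gsub <- gst[match(ep$variant, gst$id), ]
        if (min(gsub$p, na.rm = TRUE) > 1e-5) next  # GWAS locus filter
        cl <- try(coloc_abf(data.frame(id = gsub$id, beta = gsub$beta, se = gsub$se),
                            data.frame(id = ep$variant, beta = ep$beta, se = ep$se)),
                  silent = TRUE)
        if (!inherits(cl, "try-error"))
          coloc_rows[[paste(tr, g)]] <- data.frame(
            trait = tr, gene = g, t(cl$posteriors), n_snps = cl$n_snps,
            stringsAsFactors = FALSE)
      }
      inst <- do.call(rbind, lapply(which(eg$egene), function(i) {
        g <- eg$gene[i]
        ep <- pairs[pairs$gene == g, ]
        top <- which.min(ep$p)
        if (!is.na(eg$nominal_threshold[i]) && ep$p[top] <= eg$nominal_threshold[i])
          data.frame(gene = g, variant = ep$variant[top], beta_e = ep$beta[top],
                     se_e = ep$se[top], stringsAsFactors = FALSE)
        else NULL
      }))
      if (!is.null(inst) && nrow(inst)) {
        sm <- smr(inst, gst)
        if (nrow(sm)) { sm$trait <- tr; smr_rows[[tr]] <- sm }
      }
    }
    res$coloc <- do.call(rbind, coloc_rows)
    res$smr <- do.call(rbind, smr_rows)
    if (!is.null(res$coloc)) write_tsv(res$coloc, file.path(out_dir, "coloc.tsv"))
    if (!is.null(res$smr)) write_tsv(res$smr, file.path(out_dir, "smr.tsv"))
  }

  if (on("enrich") && !is.null(gwas_stats)) {
    tested <- panel$variants[, c("id", "chrom", "pos", "maf")]
    cand <- unique(unlist(lapply(gwas_stats, function(s) s$id[!is.na(s$p) & s$p <= 1e-6])))
    if (length(cand) >= 3) {
      res$enrich_peaks <- interval_enrichment(
        cand, tested, sim$tracks$peaks, n_perm = n_perm_enrich,
        seed = substream_seed(cfg$seed, "enrich_peaks"))
      if (!is.null(eqtl_res)) {
        ev <- unique(eqtl_res$genes$top_variant[eqtl_res$genes$egene])
        res$enrich_eqtl <- gwas_in_eqtl_enrichment(
          cand, tested, ev, n_perm = n_perm_enrich,
          seed = substream_seed(cfg$seed, "enrich_eqtl"))
      }
    }
    if (!is.null(eqtl_res)) {
      eg <- eqtl_res$genes
      prs <- data.frame(gene = eg$gene[eg$egene],
                        variant = eg$top_variant[eg$egene],
                        stringsAsFactors = FALSE)
      if (nrow(prs) >= 3)
        res$tad <- tad_cooccurrence(prs, eqtl_res$gene_models, tested,
                                    sim$tracks$tads, n_perm = n_perm_tad,
                                    seed = substream_seed(cfg$seed, "tad"))
    }
  }

  if (on("methylome")) {
    ccgi <- cgi_scan(stats::setNames(sim$fasta_seq, "chr1"))
    res$ccgi <- ccgi
    res$ecgi <- ecgi_filter(ccgi, sim$cpg)
    res$hmr <- hmr_call(sim$cpg)
    write_bed(res$ccgi, file.path(out_dir, "ccgi.bed"))
    write_bed(res$hmr, file.path(out_dir, "hmr.bed"))
  }

  res$report <- make_report(res)
  write_tsv(res$report$evidence, file.path(out_dir, "evidence_matrix.tsv"))
  manifest <- list(seed = cfg$seed,
                   stages_run = names(Filter(function(x) !is.null(x), res)),
                   n_variants = nrow(panel$variants),
                   n_samples = length(panel$samples))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Cross-analysis evidence report
#'
#' Joins candidate evidence per gene across the analyses that ran: a
#' boolean per analysis (single-SNP GWAS signal in the gene window,
#' multi-trait signal, eGene, TWAS, colocalization PP.H4 > 0.8, SMR FDR) and
#' the per-gene evidence count.
#'
#' @param res a [run_pipeline()] result (possibly with stages missing).
#' @return list(evidence = per-gene data.frame, intersections = counts).
#' @export
make_report <- function(res) {
  gm <- res$sim$gene_models
  if (is.null(gm)) return(list(evidence = data.frame(), intersections = integer()))
  ev <- data.frame(gene = gm$gene, stringsAsFactors = FALSE)
  win_lo <- gm$start - 50000; win_hi <- gm$end + 50000
  gene_hits <- function(stats_df, psel) {
    hit <- rep(FALSE, nrow(gm))
    if (is.null(stats_df)) return(hit)
    sig <- stats_df[psel(stats_df), , drop = FALSE]
    if (!nrow(sig)) return(hit)
    for (g in seq_len(nrow(gm)))
      hit[g] <- any(sig$chrom == gm$chrom[g] & sig$pos >= win_lo[g] &
                    sig$pos <= win_hi[g])
    hit
  }
  if (!is.null(res$gwas)) {
    allsig <- do.call(rbind, lapply(res$gwas, function(s)
      s[!is.na(s$p) & s$p < 5e-8, c("chrom", "pos")]))
    ev$gwas <- gene_hits(allsig, function(d) rep(TRUE, nrow(d)))
  }
  if (!is.null(res$multitrait)) {
    mt <- res$multitrait$stats
    v <- res$sim$panel$variants
    sig <- v[match(mt$variant[mt$significant], v$id), c("chrom", "pos")]
    ev$multitrait <- gene_hits(sig, function(d) rep(TRUE, nrow(d)))
  }
  if (!is.null(res$gene_gwas))
    ev$gene_gwas <- res$gene_gwas$significant[match(ev$gene, res$gene_gwas$gene)]
  if (!is.null(res$sweep_windows)) {
    sw <- res$sweep_windows[res$sweep_windows$candidate, , drop = FALSE]
    ev$sweep <- vapply(seq_len(nrow(gm)), function(g)
      any(sw$chrom == gm$chrom[g] & sw$start < gm$end[g] & sw$end > gm$start[g]),
      logical(1))
  }
  if (!is.null(res$eqtl))
    ev$eqtl <- ev$gene %in% res$eqtl$genes$gene[res$eqtl$genes$egene]
  if (!is.null(res$twas)) {
    sig_genes <- unique(unlist(lapply(res$twas, function(d)
      d$gene[d$significant])))
    ev$twas <- ev$gene %in% sig_genes
  }
  if (!is.null(res$coloc))
    ev$coloc <- ev$gene %in% res$coloc$gene[res$coloc$PP.H4 > 0.8]
  if (!is.null(res$smr))
    ev$smr <- ev$gene %in% res$smr$gene[res$smr$significant]
  flags <- ev[, setdiff(names(ev), "gene"), drop = FALSE]
  flags[is.na(flags)] <- FALSE
  ev$n_evidence <- rowSums(flags)
  counts <- table(ev$n_evidence)
  list(evidence = ev, intersections = counts)
}
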