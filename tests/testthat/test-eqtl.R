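eqtl_fixture <- function() {
  cached("eqtl_fixture", function() {
    sim <- test_cohort()
    ep <- expr_panel(sim)
    norm <- normalize_expression(sim$tpm)
    hf <- hidden_factors(norm, k = 5)
    gpc <- genotype_pcs(ep, k = 2)
    scan <- cis_scan(ep, norm, sim$gene_models, cbind(hf, gpc))
    list(sim = sim, ep = ep, norm = norm, cov = cbind(hf, gpc), scan = scan)
  })
}

test_that("normalization produces exact Blom normal scores, rank-invariantly", {
  set.seed(31)
  tpm <- matrix(rexp(20 * 11), 20, 11,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:11)))
  norm <- normalize_expression(tpm)
  # quantile normalization can introduce ties (average ranks), so the
  # marginals are Blom scores up to tie-handling
  blom_var <- var(qnorm((1:11 - 3 / 8) / (11 + 1 / 4)))
  expect_lt(max(abs(rowMeans(norm))), 0.05)
  expect_true(all(abs(apply(norm, 1, var) - blom_var) < 0.15))
  # a monotone transform of the whole matrix preserves all ranks, hence
  # the normalized output exactly
  norm2 <- normalize_expression(tpm^2)
  expect_equal(norm2, norm, tolerance = 1e-12)
  # hand-evaluated Blom scores for n = 5 with distinct values
  x <- c(3, 1, 4, 1.5, 5)
  blom <- qnorm((rank(x) - 3 / 8) / (5 + 1 / 4))
  one <- matrix(x, 1, dimnames = list("g", paste0("s", 1:5)))
  expect_equal(as.vector(normalize_expression(one)), blom, tolerance = 1e-12)
  # constant gene collapses to zero with a warning
  tpm3 <- tpm; tpm3[1, ] <- 2
  expect_warning(n3 <- normalize_expression(tpm3), "constant")
  expect_true(all(n3[1, ] == 0))
})

test_that("hidden factor extraction is well behaved", {
  fx <- eqtl_fixture()
  hf <- hidden_factors(fx$norm, k = 4)
  ve <- attr(hf, "var_explained")
  expect_true(all(diff(ve) <= 1e-12))
  expect_error(hidden_factors(fx$norm, k = ncol(fx$norm)), "smaller")
  h0 <- hidden_factors(fx$norm, k = 0)
  expect_equal(ncol(h0), 0)
})

test_that("cis window boundary is inclusive at 1 Mb", {
  sim <- test_cohort()
  ep <- expr_panel(sim)
  gm <- data.frame(gene = c("gA", "gB"), chrom = "chr1",
                   tss = c(2e6, 2e6), strand = "+", start = 2e6, end = 2.01e6)
  norm <- matrix(rnorm(2 * length(ep$samples)), 2,
                 dimnames = list(c("gA", "gB"), ep$samples))
  scan <- cis_scan(ep, norm, gm, NULL)
  d <- abs(scan$pairs$pos - 2e6)
  expect_true(all(d <= 1e6))
  v <- ep$variants
  in_window <- sum(v$chrom == "chr1" & abs(v$pos - 2e6) <= 1e6)
  expect_equal(sum(scan$pairs$gene == "gA"), in_window)
})

test_that("nominal p-values are uniform under permuted expression", {
  fx <- eqtl_fixture()
  # permuted expression rows are independent across genes; sample one cis
  # variant per gene per permutation so LD cannot distort the KS reference
  set.seed(33)
  pvals <- c()
  for (r in 1:3) {
    perm_norm <- fx$norm[, sample(ncol(fx$norm))]
    colnames(perm_norm) <- colnames(fx$norm)
    scan <- cis_scan(fx$ep, perm_norm, fx$sim$gene_models, fx$cov)
    one_per_gene <- vapply(split(scan$pairs$p, scan$pairs$gene),
                           function(p) p[sample.int(length(p), 1)], numeric(1))
    pvals <- c(pvals, one_per_gene)
  }
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("permutation pass calibrates gene-level empirical p-values", {
  fx <- eqtl_fixture()
  scan <- fx$scan
  # a gene whose observed min p exceeds every permuted one scores ~1
  g <- names(scan$genes)[1]
  pp <- permutation_pass(scan, g, n_perm = 200, seed = 4)
  expect_true(pp$empirical_p > 0 && pp$empirical_p <= 1)
  expect_gte(pp$direct_p, 1 / 201)
  # beta-approximated and direct p agree within a factor of 3 when resolvable
  genes <- names(scan$genes)[vapply(scan$genes, function(g)
    length(g$variant_idx) > 0, logical(1))][1:25]
  for (g in genes) {
    pp <- permutation_pass(scan, g, n_perm = 500, seed = 5)
    if (pp$direct_p >= 3 / 501 && pp$direct_p <= 0.9) {
      ratio <- pp$empirical_p / pp$direct_p
      expect_gt(ratio, 1 / 3)
      expect_lt(ratio, 3)
    }
  }
})

test_that("gene-level empirical p is uniform under a null cohort", {
  # genes with no planted eQTLs at all
  cfg <- sim_config(seed = 77, n_individuals = 150, variants_per_chrom = 600,
                    n_genes = 120, frac_genes_with_eqtl = 0,
                    mechanism_gene = FALSE, n_hidden_factors = 0)
  sim <- simulate_cohort(cfg, file.path(tempdir(), "null_eqtl"))
  ep <- expr_panel(sim)
  norm <- normalize_expression(sim$tpm)
  scan <- cis_scan(ep, norm, sim$gene_models, genotype_pcs(ep, 2))
  emp <- vapply(names(scan$genes), function(g) {
    if (!length(scan$genes[[g]]$variant_idx)) return(NA_real_)
    permutation_pass(scan, g, n_perm = 300,
                     seed = pleioscan:::substream_seed(77, g))$empirical_p
  }, numeric(1))
  emp <- emp[!is.na(emp)]
  expect_gt(ks.test(emp, "punif")$p.value, 0.01)
  # and BH at 5% calls essentially nothing
  called <- egene_calling(data.frame(gene = names(emp), a = 1, b = 1,
                                     empirical_p = emp))
  expect_lte(sum(called$egene), 2)
})

test_that("eGene calling follows the BH hand computation", {
  perm <- data.frame(gene = paste0("g", 1:4), a = c(1, 1, 2, 1),
                     b = c(1, 1, 30, 1),
                     empirical_p = c(0.001, 0.01, 0.02, 0.8))
  out <- egene_calling(perm, fdr = 0.05)
  expect_equal(unname(out$qvalue), c(0.004, 0.02, 0.08 / 3, 0.8),
               tolerance = 1e-9)
  expect_equal(out$egene, c(TRUE, TRUE, TRUE, FALSE))
  cutoff <- attr(out, "global_cutoff")
  expect_equal(cutoff, 0.02)
  # uniform-beta gene: nominal threshold equals the global cutoff
  expect_equal(out$nominal_threshold[1], qbeta(0.02, 1, 1))
  expect_equal(out$nominal_threshold[1], cutoff)
})

test_that("planted eQTLs are recovered as eGenes with matching signs", {
  fx <- eqtl_fixture()
  scan <- fx$scan
  truth <- fx$sim$truth$eqtl_truth
  strong <- truth[abs(truth$effect) > 0.8, ]
  X <- panel_dosage(fx$ep)
  hits <- 0
  for (i in seq_len(nrow(strong))) {
    g <- strong$gene[i]
    info <- scan$genes[[g]]
    if (is.null(info) || !length(info$variant_idx)) next
    top <- info$top_variant
    r2 <- cor(X[, top], X[, strong$variant[i]])^2
    if (top == strong$variant[i] || r2 > 0.8) hits <- hits + 1
  }
  expect_gte(hits / nrow(strong), 0.9)
})

test_that("allelic fold change follows its closed form and cap", {
  n <- 200
  set.seed(34)
  dosage <- rbinom(n, 2, 0.4)
  # mu = 10, beta = 5 -> aFC = log2(1 + 2*5/10) = 1
  y <- 10 + 5 * dosage
  expect_equal(afc(y, dosage), 1.0, tolerance = 1e-10)
  expect_equal(afc(rep(8, n) + 0 * dosage, dosage), 0)
  # enormous ratio clamps at log2(100)
  y2 <- 0.001 + 1000 * dosage
  expect_equal(afc(y2, dosage), log2(100))
  # sign of aFC equals sign of the slope whenever defined
  for (b in c(-2, -0.5, 0.7, 3)) {
    yb <- 10 + b * dosage + rnorm(n, 0, 0.1)
    a <- afc(yb, dosage)
    expect_equal(sign(a), sign(b))
  }
})

test_that("stepwise search separates independent planted signals", {
  set.seed(35)
  sim <- test_cohort()
  ep <- expr_panel(sim)
  X <- panel_dosage(ep)
  v <- ep$variants
  recovered2 <- 0; single_ok <- 0
  reps <- 8
  for (r in seq_len(reps)) {
    # pick two cis variants in weak LD near a TSS
    gm <- sim$gene_models[sample(nrow(sim$gene_models), 1), ]
    cis <- which(v$chrom == gm$chrom & abs(v$pos - gm$tss) <= 1e6 & v$maf > 0.2)
    pair <- NULL
    for (a in sample(cis, min(40, length(cis)))) {
      lows <- cis[abs(cor(X[, a], X[, cis])) < 0.22]
      if (length(lows)) { pair <- c(a, lows[1]); break }
    }
    if (is.null(pair)) next
    yv <- 0.8 * scale(X[, pair[1]]) + 0.8 * scale(X[, pair[2]]) + rnorm(nrow(X))
    norm1 <- matrix(as.vector(scale(yv)), 1, dimnames = list(gm$gene, ep$samples))
    scan1 <- cis_scan(ep, norm1, gm, NULL)
    ind <- independent_eqtls(scan1, gm$gene, threshold = 1e-4)
    found <- vapply(pair, function(j)
      any(abs(cor(X[, j], X[, ind$variant, drop = FALSE])) > 0.9), logical(1))
    if (all(found)) recovered2 <- recovered2 + 1
    # single planted signal yields exactly one
    y1 <- 0.9 * scale(X[, pair[1]]) + rnorm(nrow(X))
    norm2 <- matrix(as.vector(scale(y1)), 1, dimnames = list(gm$gene, ep$samples))
    scan2 <- cis_scan(ep, norm2, gm, NULL)
    ind1 <- independent_eqtls(scan2, gm$gene, threshold = 1e-4)
    if (nrow(ind1) == 1) single_ok <- single_ok + 1
  }
  expect_gte(recovered2, round(0.8 * reps) - 1)
  expect_gte(single_ok, round(0.9 * reps) - 1)
})

test_that("pi1 recovers the planted alternative fraction", {
  set.seed(36)
  p_null <- runif(5000)
  expect_lt(storey_pi1(p_null), 0.05)
  p_mix <- c(runif(3500), rbeta(1500, 0.05, 10))  # 30% near-zero alternatives
  pi1 <- storey_pi1(p_mix)
  expect_gt(pi1, 0.25)
  expect_lt(pi1, 0.35)
  expect_equal(storey_pi1(rep(1e-10, 200)), 1)
  expect_error(storey_pi1(numeric(0)), "empty")
})
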