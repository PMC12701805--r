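make_dosage_panel <- function(X, pos = NULL, chrom = "chr1") {
  # expand a dosage matrix into an arbitrary phased panel (dosage-preserving)
  haps <- matrix(0L, 2 * nrow(X), ncol(X))
  haps[seq(1, 2 * nrow(X), 2), ] <- (X >= 1) * 1L
  haps[seq(2, 2 * nrow(X), 2), ] <- (X == 2) * 1L
  toy_panel(haps, pos = pos, chrom = chrom)
}

test_that("GRM matches hand computation and GCTA conventions", {
  # 2 samples x 2 variants, by hand
  X <- rbind(c(0, 2), c(2, 1))
  p <- colMeans(X) / 2                    # (0.5, 0.75)
  Zh <- sweep(X, 2, 2 * p)
  Zh <- sweep(Zh, 2, sqrt(2 * p * (1 - p)), `/`)
  Kh <- tcrossprod(Zh) / 2
  K <- build_grm(X)
  expect_equal(unname(K), unname(Kh), tolerance = 1e-12)

  sim <- test_cohort()
  Xs <- panel_dosage(sim$panel)[1:120, ]
  poly <- apply(Xs, 2, function(x) length(unique(x)) > 1)
  Xs <- Xs[, poly]
  K <- build_grm(Xs)
  expect_gt(mean(diag(K)), 0.95)
  expect_lt(mean(diag(K)), 1.05)
  # duplicated sample: off-diagonal ~ diagonal
  Xd <- rbind(Xs, Xs[1, ])
  Kd <- build_grm(Xd)
  n <- nrow(Xd)
  expect_equal(Kd[n, 1], Kd[1, 1], tolerance = 1e-12)
  expect_error(build_grm(cbind(Xs, 0)), "monomorphic")
})

test_that("REML recovers heritability and respects the null", {
  sim <- test_cohort()
  X <- panel_dosage(sim$panel)
  K <- build_grm(X)
  eig <- eigen(K, symmetric = TRUE)
  n <- nrow(X)
  # pure noise: estimated h2 small
  set.seed(41)
  y0 <- rnorm(n)
  vc0 <- reml_variance(y0, NULL, eig)
  expect_lt(vc0$h2, 0.15)
  # h2 = 0.5 built directly from the GRM covariance structure
  L <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)))
  set.seed(42)
  y1 <- as.vector(L %*% rnorm(n)) * sqrt(0.5) + rnorm(n, 0, sqrt(0.5))
  vc1 <- reml_variance(y1, NULL, eig)
  expect_gt(vc1$h2, 0.3)
  expect_lt(vc1$h2, 0.7)
  # GRM = I: variance split unidentifiable, flagged
  vcI <- reml_variance(y0, NULL, diag(n))
  expect_false(vcI$identifiable)
  expect_equal(vcI$sigma2_a, 0)
})

test_that("association reduces to OLS when the genetic variance is zero", {
  sim <- test_cohort()
  panel <- panel_subset(sim$panel, 1:200)
  n <- length(panel$samples)
  set.seed(51)
  y <- rnorm(n)
  covd <- sim$covariates[, c("farm", "sex")]
  vc0 <- list(sigma2_a = 0, sigma2_e = 1,
              eig = list(vectors = diag(n), values = rep(1, n)))
  st <- snp_association(panel, y, covd, vc0)
  X <- panel_dosage(panel)
  C <- model.matrix(~ farm + sex, covd)
  for (j in c(1, 50, 200)) {
    fit <- lm(y ~ X[, j] + C - 1)
    expect_lt(abs(st$beta[j] - coef(fit)[1]), 1e-8)
  }
})

test_that("single-SNP scan is calibrated under permuted phenotypes", {
  sim <- test_cohort()
  panel <- panel_subset(sim$panel, 1:2000)
  set.seed(61)
  y <- sample(sim$phenotypes$trait01)   # break genotype-phenotype link
  K <- build_grm(panel_dosage(sim$panel))
  vc <- reml_variance(y, NULL, eigen(K, symmetric = TRUE))
  st <- snp_association(panel, y, NULL, vc)
  frac <- mean(st$p < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("a large planted effect reaches genome-wide significance", {
  sim <- test_cohort()
  panel <- sim$panel
  X <- panel_dosage(panel)
  n <- nrow(X)
  j <- which(panel$variants$maf > 0.3)[100]
  set.seed(71)
  y <- X[, j] * 1.0 + rnorm(n)          # beta = 1 residual sd
  K <- build_grm(X)
  vc <- reml_variance(y, NULL, eigen(K, symmetric = TRUE))
  st <- snp_association(panel, y, NULL, vc)
  expect_lt(st$p[j], 5e-8)
  expect_equal(st$label[j], "significant")
})

test_that("conditioning on the causal variant removes its LD partners", {
  sim <- test_cohort()
  panel <- sim$panel
  X <- panel_dosage(panel)
  j <- which(panel$variants$maf > 0.3)[50]
  set.seed(81)
  y <- X[, j] * 1.0 + rnorm(nrow(X))
  K <- build_grm(X)
  vc <- reml_variance(y, NULL, eigen(K, symmetric = TRUE))
  st0 <- snp_association(panel, y, NULL, vc)
  r2 <- as.vector(cor(X[, j], X))^2
  partners <- which(r2 > 0.8)
  expect_true(any(st0$p[partners] < 5e-8))
  stc <- conditional_association(panel, y, NULL, vc,
                                 target_id = panel$variants$id[j])
  pc <- stc$p[match(panel$variants$id[setdiff(partners, j)], stc$id)]
  expect_true(all(pc > 5e-8))
  # conditioning on another chromosome barely moves effect estimates
  far <- which(panel$variants$chrom == "chr2" & panel$variants$maf > 0.3)[1]
  stf <- conditional_association(panel, y, NULL, vc,
                                 target_id = panel$variants$id[far])
  common <- intersect(st0$id, stf$id)
  d <- abs(st0$beta[match(common, st0$id)] - stf$beta[match(common, stf$id)])
  # variants not in LD with the conditioning variant are untouched
  r2far <- as.vector(cor(X[, far], X[, match(common, panel$variants$id)]))^2
  expect_lt(max(d[r2far < 0.1], na.rm = TRUE), 0.05)
  # duplicated covariate column -> collinearity error
  dup <- X[, far]
  expect_error(conditional_association(panel, y, data.frame(dup = dup), vc,
                                       target_id = panel$variants$id[far]),
               "collinear")
})

test_that("per-variant genetic variance follows the closed form", {
  expect_equal(varg_explained(beta = 1, p = 0.5, sigma2_a = 2), 25.0)
  expect_equal(varg_explained(beta = 2, p = 0.5, sigma2_a = 2),
               4 * varg_explained(beta = 1, p = 0.5, sigma2_a = 2))
  expect_lt(varg_explained(beta = 1, p = 1e-9, sigma2_a = 2), 1e-6)
  expect_error(varg_explained(1, 0.5, 0), "positive")
})

test_that("variance explained by the top pleiotropic variant is recovered", {
  cfg <- sim_config(seed = 301, n_individuals = 1000, variants_per_chrom = 600)
  sim <- simulate_cohort(cfg, file.path(tempdir(), "varg_cohort"))
  panel <- sim$panel
  X <- panel_dosage(panel)
  tr <- sim$truth$causal_variants
  top <- sim$truth$pleiotropic_block_variants[1]
  beta_true <- tr$beta[tr$variant == top & tr$trait == "trait01"]
  j <- match(top, panel$variants$id)
  p_eff <- mean(X[, j]) / 2
  y <- sim$phenotypes$trait01
  covd <- sim$covariates[, c("farm", "sex")]
  K <- build_grm(X)
  vc <- reml_variance(y, covd, eigen(K, symmetric = TRUE))
  st <- snp_association(panel, y, covd, vc)
  est <- varg_explained(st$beta[j], st$eaf[j], vc$sigma2_a)
  truth <- varg_explained(beta_true, p_eff, vc$sigma2_a)
  expect_lt(abs(est - truth) / truth, 0.30)
})

test_that("multi-trait chi-square reduces correctly in identity cases", {
  # identity-V reduction: chi2 = sum of squared t-values
  set.seed(111)
  big <- matrix(rnorm(1000 * 3), 1000)
  big[1, ] <- c(1, 2, 2)
  rownames(big) <- paste0("v", seq_len(1000))
  res_i <- multitrait_chi2(big, V = diag(3))
  expect_equal(res_i$stats$chi2[1], 9)
  expect_equal(res_i$stats$df[1], 3)
  expect_equal(res_i$stats$chi2, unname(rowSums(big^2)))
  # single trait with V = 1: chi2 = t^2 and p = two-sided normal p
  one <- matrix(rnorm(500), dimnames = list(sprintf("v%03d", 1:500), NULL))
  r1 <- multitrait_chi2(one, V = matrix(1, 1, 1))
  expect_equal(r1$stats$chi2, unname(one[, 1]^2))
  expect_equal(r1$stats$p, unname(2 * pnorm(-abs(one[, 1]))))
})

test_that("duplicated traits trigger shrinkage and contribute once", {
  set.seed(91)
  t1 <- rnorm(2000)
  tmat <- cbind(t1, t1)
  rownames(tmat) <- sprintf("v%04d", seq_len(2000))
  res <- multitrait_chi2(tmat)
  expect_true(res$shrunk)
  expect_true(all(is.finite(res$stats$chi2)))
  # pseudo-inverse oracle on the unshrunk singular V: chi2 = t^2 (the
  # duplicate carries no extra information)
  V <- cor(tmat)
  chi_pinv <- vapply(seq_len(nrow(tmat)), function(i) {
    ev <- eigen(V, symmetric = TRUE)
    keep <- ev$values > 1e-8
    Vp <- ev$vectors[, keep, drop = FALSE] %*%
      diag(1 / ev$values[keep], sum(keep)) %*% t(ev$vectors[, keep, drop = FALSE])
    drop(t(tmat[i, ]) %*% Vp %*% tmat[i, ])
  }, numeric(1))
  # shrunken statistic tracks the pseudo-inverse one closely
  expect_gt(cor(res$stats$chi2, chi_pinv), 0.999)
  expect_lt(max(abs(res$stats$chi2 - chi_pinv) / pmax(chi_pinv, 1)), 0.15)
})

test_that("multi-trait test is calibrated under a correlated null", {
  set.seed(101)
  n_var <- 3000; k <- 4
  R <- matrix(0.5, k, k); diag(R) <- 1
  L <- chol(R)
  tmat <- matrix(rnorm(n_var * k), n_var) %*% L
  rownames(tmat) <- sprintf("v%05d", seq_len(n_var))
  res <- multitrait_chi2(tmat)
  frac <- mean(res$stats$p < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})
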