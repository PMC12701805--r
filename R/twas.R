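# TWAS: cis-heritability screening, cross-validated expression weight
# training over a model menu (top1 / ridge-BLUP / lasso / elastic net), and
# association of genetically predicted expression with traits.

#' Cis-heritability screen for an expressed gene
#'
#' Single-component REML on the GRM of the gene's cis variants; the null
#' sigma2_a = 0 is tested by a likelihood-ratio test with the boundary null
#' 0.5 chi2_0 + 0.5 chi2_1. Genes with h2 > 0 and p <= 0.05 pass.
#'
#' @param cis_panel `haplotype_panel` restricted to the gene's cis variants
#'   (>= 10 required).
#' @param expr normalized expression vector for the gene.
#' @param covariates fixed covariates (matrix or NULL).
#' @return list(h2, sigma2_a, sigma2_e, lrt, p, pass).
#' @export
cis_h2 <- function(cis_panel, expr, covariates = NULL) {
  m <- nrow(cis_panel$variants)
  if (m < 10) stop("fewer than 10 cis variants; gene skipped", call. = FALSE)
  K <- build_grm(cis_panel)
  vc <- reml_variance(expr, covariates, K)
  lrt <- max(0, 2 * (vc$loglik - vc$loglik_null))
  p <- if (lrt <= 0) 1 else 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  list(h2 = vc$h2, sigma2_a = vc$sigma2_a, sigma2_e = vc$sigma2_e,
       lrt = lrt, p = p, pass = vc$h2 > 0 & p <= 0.05)
}

standardize_dosage <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(Z = sweep(sweep(X, 2, mu), 2, sdv, `/`), mu = mu, sd = sdv)
}

adjusted_r2 <- function(pred, obs) {
  # held-out predictive R^2 = 1 - SS_res/SS_tot (negative when the model
  # predicts worse than the mean), with the usual small-sample adjustment
  n <- length(obs)
  if (any(!is.finite(pred))) return(-Inf)
  r2 <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  1 - (1 - r2) * (n - 1) / (n - 2)
}

fit_model_weights <- function(model, Z, y, h2, foldid_inner) {
  m <- ncol(Z)
  w <- numeric(m)
  switch(model,
    top1 = {
      b <- as.vector(crossprod(Z, y)) / colSums(Z^2)
      se2 <- vapply(seq_len(m), function(j) {
        r <- y - Z[, j] * b[j]
        sum(r^2) / ((length(y) - 2) * sum(Z[, j]^2))
      }, numeric(1))
      z2 <- b^2 / se2
      j <- which.max(z2)
      w[j] <- b[j]
    },
    blup_ridge = {
      lam <- m * (1 - h2) / max(h2, 0.01)
      w <- solve(crossprod(Z) + diag(lam, m), crossprod(Z, y))[, 1]
    },
    lasso = ,
    enet = {
      alpha <- if (model == "lasso") 1 else 0.5
      cv <- glmnet::cv.glmnet(Z, y, alpha = alpha, foldid = foldid_inner,
                              standardize = FALSE)
      w <- as.vector(stats::coef(cv, s = "lambda.min"))[-1]
    }
  )
  w
}

#' Train cross-validated expression weights for one gene
#'
#' Four weight models on standardized cis dosages: single best eQTL (top1),
#' ridge regression with the BLUP penalty m (1 - h2) / h2, lasso, and
#' elastic net (mixing 0.5) with penalties chosen by inner cross-validation.
#' Outer k-fold CV accuracy is the pooled held-out predictive R2
#' (1 - SS_res / SS_tot, negative when the model predicts worse than the
#' mean) with a small-sample adjustment; the selected model is the argmax.
#'
#' @param cis_panel `haplotype_panel` of the gene's cis variants.
#' @param expr normalized expression vector.
#' @param h2 cis-heritability estimate from [cis_h2()].
#' @param k_folds outer CV folds.
#' @param seed fold-assignment seed (weights are deterministic given it).
#' @return a `gene_weights` list: weights per model, cv_r2 per model,
#'   selected model name, variant ids, and the dosage standardization. NULL
#'   when every model has CV accuracy <= 0 (gene dropped from TWAS).
#' @export
train_weights <- function(cis_panel, expr, h2, k_folds = 5, seed = 1) {
  X <- panel_dosage(cis_panel)
  std <- standardize_dosage(X)
  Z <- std$Z
  n <- length(expr)
  models <- c("top1", "blup_ridge", "lasso", "enet")
  folds <- with_seed(substream_seed(seed, "folds"),
                     sample(rep(seq_len(k_folds), length.out = n)))
  preds <- matrix(NA_real_, n, length(models), dimnames = list(NULL, models))
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    Ztr <- Z[tr, , drop = FALSE]
    ytr <- expr[tr]
    inner <- with_seed(substream_seed(seed, paste0("inner", f)),
                       sample(rep(seq_len(5), length.out = sum(tr))))
    for (mdl in models) {
      w <- fit_model_weights(mdl, Ztr, ytr, h2, inner)
      preds[!tr, mdl] <- Z[!tr, , drop = FALSE] %*% w
    }
  }
  cv_r2 <- vapply(models, function(mdl) adjusted_r2(preds[, mdl], expr),
                  numeric(1))
  if (all(cv_r2 <= 0)) return(NULL)
  inner_all <- with_seed(substream_seed(seed, "inner_all"),
                         sample(rep(seq_len(5), length.out = n)))
  weights <- lapply(models, function(mdl)
    fit_model_weights(mdl, Z, expr, h2, inner_all))
  names(weights) <- models
  selected <- models[which.max(cv_r2)]
  structure(list(variant_ids = cis_panel$variants$id, weights = weights,
                 cv_r2 = cv_r2, selected = selected,
                 dosage_mean = std$mu, dosage_sd = std$sd),
            class = "gene_weights")
}

#' Associate predicted expression with a trait
#'
#' Predicted expression = standardized GWAS-cohort dosage x selected-model
#' weights; the trait is regressed on the prediction plus covariates and the
#' slope tested (two-sided). Weight variants absent from the GWAS panel are
#' dropped with a warning. BH correction is applied across genes.
#'
#' @param weights_list named list of `gene_weights` (one per gene).
#' @param panel GWAS-cohort `haplotype_panel`.
#' @param y trait vector.
#' @param covariates fixed covariates.
#' @param fdr FDR level for the significance flag.
#' @return data.frame gene, model, z, p, qvalue, significant.
#' @export
twas_associate <- function(weights_list, panel, y, covariates = NULL,
                           fdr = 0.05) {
  X <- panel_dosage(panel)
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  n <- length(y)
  C <- covar_design(covariates, n)
  qrC <- qr(C)
  yr <- qr.resid(qrC, y)
  rows <- lapply(names(weights_list), function(g) {
    gw <- weights_list[[g]]
    if (is.null(gw)) return(NULL)
    w <- gw$weights[[gw$selected]]
    j <- match(gw$variant_ids, panel$variants$id)
    ok <- !is.na(j)
    if (!all(ok)) {
      warning(sprintf("gene %s: %d weight variant(s) missing from GWAS panel",
                      g, sum(!ok)))
      w <- w[ok]; j <- j[ok]
    }
    if (!length(j) || all(w == 0)) return(NULL)
    Zg <- sweep(sweep(X[, j, drop = FALSE], 2, gw$dosage_mean[ok]), 2,
                gw$dosage_sd[ok], `/`)
    pred <- as.vector(Zg %*% w)
    if (stats::sd(pred) < 1e-12) return(NULL)
    pr <- qr.resid(qrC, pred)
    df <- n - 1 - ncol(C)
    r <- sum(pr * yr) / sqrt(sum(pr^2) * sum(yr^2))
    r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    z <- r * sqrt(df / (1 - r^2))
    data.frame(gene = g, model = gw$selected, z = z,
               p = 2 * stats::pt(-abs(z), df), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(gene = character(), model = character(),
                                      z = numeric(), p = numeric(),
                                      qvalue = numeric(), significant = logical()))
  out$qvalue <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$qvalue <= fdr
  rownames(out) <- NULL
  out
}
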