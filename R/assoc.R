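# Mixed-model single-SNP association, conditional analysis, per-variant
# genetic variance explained, and the multi-trait chi-square meta-analysis.

#' Genomic relationship matrix (GRM)
#'
#' K = (1/m) * sum_k (x_k - 2 p_k)(x_k - 2 p_k)' / (2 p_k (1 - p_k)), the
#' standard allele-frequency-standardized GRM. Missing dosages are
#' mean-imputed for this computation only.
#'
#' @param panel a `haplotype_panel` (or an N x M dosage matrix).
#' @return N x N symmetric matrix with mean diagonal near 1.
#' @export
build_grm <- function(panel) {
  X <- if (inherits(panel, "haplotype_panel")) panel_dosage(panel) else panel
  p <- colMeans(X, na.rm = TRUE) / 2
  if (any(p <= 0 | p >= 1))
    stop("monomorphic variant in GRM input; filter first", call. = FALSE)
  Z <- sweep(X, 2, 2 * p)
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), `/`)
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(rownames(X), rownames(X))
  K
}

# design matrix (with intercept) from a covariate data.frame/matrix/NULL
covar_design <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  if (is.data.frame(covariates)) {
    covariates <- covariates[, setdiff(names(covariates), "sample"), drop = FALSE]
    return(stats::model.matrix(~ ., data = covariates))
  }
  cbind(`(Intercept)` = 1, as.matrix(covariates))
}

#' Single-component REML by eigendecomposition of the GRM
#'
#' Rotates phenotype and covariates by the GRM eigenvectors and maximizes the
#' one-parameter restricted likelihood in lambda = sigma2_a / sigma2_e by
#' bracketed scalar optimization on the log scale.
#'
#' @param y numeric phenotype vector.
#' @param covariates data.frame/matrix of fixed covariates (or NULL); an
#'   intercept is always included.
#' @param grm N x N GRM, or a precomputed `eigen()` of it.
#' @return list with sigma2_a, sigma2_e, lambda, h2, loglik, `boundary`
#'   (optimum at the search bracket), `identifiable` (FALSE when the GRM has
#'   no eigenvalue spread, e.g. K = I), and the eigendecomposition for reuse.
#' @export
reml_variance <- function(y, covariates, grm) {
  n <- length(y)
  eig <- if (is.list(grm) && !is.null(grm$vectors)) grm else {
    if (min(eigen(grm, symmetric = TRUE, only.values = TRUE)$values) < -1e-6 * n)
      stop("GRM is not positive semi-definite", call. = FALSE)
    eigen(grm, symmetric = TRUE)
  }
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  X <- covar_design(covariates, n)
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  p <- ncol(X)

  restricted_ll <- function(log_lambda) {
    lam <- exp(log_lambda)
    w <- lam * d + 1
    sw <- 1 / sqrt(w)
    Xs <- Xt * sw
    ys <- yt * sw
    qrX <- qr(Xs)
    res <- qr.resid(qrX, ys)
    rss <- sum(res^2)
    s2e <- rss / (n - p)
    R <- qr.R(qrX)
    ldXX <- 2 * sum(log(abs(diag(R))))
    -0.5 * ((n - p) * log(s2e) + sum(log(w)) + ldXX + (n - p))
  }

  ll_null <- restricted_ll(-30)  # sigma2_a -> 0 boundary
  identifiable <- (max(d) - min(d)) > 1e-8
  if (!identifiable) {
    lam <- 0
    res <- qr.resid(qr(Xt), yt)
    s2e <- sum(res^2) / (n - p)
    out <- list(sigma2_a = 0, sigma2_e = s2e, lambda = 0, h2 = 0,
                loglik = ll_null, loglik_null = ll_null, boundary = TRUE,
                identifiable = FALSE, eig = eig)
    return(out)
  }
  opt <- stats::optimize(restricted_ll, interval = c(-12, 12), maximum = TRUE,
                         tol = 1e-7)
  # compare with the lambda -> 0 boundary (no genetic variance)
  at_boundary <- FALSE
  if (ll_null >= opt$objective - 1e-9 || opt$maximum < -11.5) {
    lam <- 0
    ll <- ll_null
    at_boundary <- TRUE
  } else {
    lam <- exp(opt$maximum)
    ll <- opt$objective
    at_boundary <- opt$maximum > 11.5
  }
  w <- lam * d + 1
  sw <- 1 / sqrt(w)
  res <- qr.resid(qr(Xt * sw), yt * sw)
  s2e <- sum(res^2) / (n - p)
  s2a <- lam * s2e
  list(sigma2_a = s2a, sigma2_e = s2e, lambda = lam,
       h2 = s2a / (s2a + s2e), loglik = ll, loglik_null = ll_null,
       boundary = at_boundary, identifiable = TRUE, eig = eig)
}

#' Mixed-model single-SNP association scan
#'
#' MLMA convention: the variance components are estimated once on the null
#' model (no SNP) and reused for every variant; each variant's effect is then
#' a GLS slope under covariance sigma2_a K + sigma2_e I, applied through the
#' precomputed eigen-rotation. Wald p-values from the standard normal.
#' Genome-wide significant and suggestive labels use 5e-8 and 1e-6.
#'
#' @param panel a `haplotype_panel`.
#' @param y phenotype vector (one trait).
#' @param covariates fixed covariates (data.frame / matrix / NULL).
#' @param vc output of [reml_variance()] fitted on this trait's null model.
#' @param p_significant,p_suggestive significance thresholds.
#' @return data.frame of per-variant summary statistics: chrom, pos, id,
#'   effect_allele, other_allele, eaf, beta, se, t, p, n, label. Zero-variance
#'   variants are returned with NA statistics (attribute `skipped`).
#' @export
snp_association <- function(panel, y, covariates = NULL, vc,
                            p_significant = 5e-8, p_suggestive = 1e-6) {
  X <- panel_dosage(panel)
  n <- nrow(X)
  stopifnot(length(y) == n)
  U <- vc$eig$vectors
  d <- pmax(vc$eig$values, 0)
  w <- vc$sigma2_a * d + vc$sigma2_e
  sw <- 1 / sqrt(w)

  C <- covar_design(covariates, n)
  # mean-impute missing dosages at association time (panel stays untouched)
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  yt <- crossprod(U, y) * sw
  Ct <- crossprod(U, C) * sw
  Xt <- crossprod(U, X) * sw
  qrC <- qr(Ct)
  yr <- qr.resid(qrC, yt)
  Xr <- qr.resid(qrC, Xt)
  sxx <- colSums(Xr^2)
  skipped <- sxx < 1e-12
  beta <- se <- rep(NA_real_, ncol(X))
  beta[!skipped] <- colSums(Xr[, !skipped, drop = FALSE] * as.vector(yr)) /
    sxx[!skipped]
  se[!skipped] <- sqrt(1 / sxx[!skipped])
  tval <- beta / se
  pval <- 2 * stats::pnorm(-abs(tval))
  v <- panel$variants
  out <- data.frame(
    chrom = v$chrom, pos = v$pos, id = v$id,
    effect_allele = v$alt, other_allele = v$ref,
    eaf = colMeans(X) / 2, beta = beta, se = se, t = tval, p = pval,
    n = n, stringsAsFactors = FALSE
  )
  out$label <- ifelse(is.na(out$p), "skipped",
                      ifelse(out$p < p_significant, "significant",
                             ifelse(out$p < p_suggestive, "suggestive", "ns")))
  attr(out, "skipped") <- v$id[skipped]
  rownames(out) <- NULL
  out
}

#' Conditional association on a target variant
#'
#' Re-runs the mixed-model scan with the target variant's dosage appended to
#' the fixed covariates; the target itself is excluded from the scan.
#'
#' @inheritParams snp_association
#' @param target_id variant id to condition on.
#' @export
conditional_association <- function(panel, y, covariates = NULL, vc, target_id,
                                    ...) {
  j <- match(target_id, panel$variants$id)
  if (is.na(j)) stop("target variant not in panel", call. = FALSE)
  dose <- panel_dosage(panel)[, j]
  if (anyNA(dose)) dose[is.na(dose)] <- mean(dose, na.rm = TRUE)
  C <- covar_design(covariates, length(y))
  aug <- cbind(C, target = dose)
  if (qr(aug)$rank < ncol(aug)) {
    # name the offending covariate column
    cors <- suppressWarnings(abs(stats::cor(dose, C[, -1, drop = FALSE])))
    hit <- if (length(cors) && any(!is.na(cors))) {
      colnames(C)[-1][which.max(cors)]
    } else "(Intercept)"
    stop(sprintf("conditioning variant %s is collinear with covariate '%s'",
                 target_id, hit), call. = FALSE)
  }
  sub <- panel_subset(panel, setdiff(seq_len(nrow(panel$variants)), j))
  cov2 <- cbind(if (is.null(covariates)) NULL else covar_design(covariates, length(y))[, -1, drop = FALSE],
                target_dosage = dose)
  snp_association(sub, y, cov2, vc, ...)
}

#' Percentage of additive genetic variance explained by a variant
#'
#' Var_g% = 2 p (1 - p) beta^2 / sigma2_a x 100, with p the effect-allele
#' frequency and beta the allelic substitution effect.
#'
#' @param beta allelic substitution effect.
#' @param p effect-allele frequency.
#' @param sigma2_a additive genetic variance of the trait.
#' @return percentage (0-100 scale, may exceed 100 for mis-specified inputs).
#' @export
varg_explained <- function(beta, p, sigma2_a) {
  if (any(sigma2_a <= 0)) stop("sigma2_a must be positive", call. = FALSE)
  2 * p * (1 - p) * beta^2 / sigma2_a * 100
}

#' Multi-trait chi-square meta-analysis
#'
#' For each variant, chi2 = t' V^-1 t where t is the vector of signed
#' t-values across traits and V the trait-trait correlation matrix estimated
#' from the signed t-values over all variants. Referred to chi-square with
#' df = n_traits; the Bonferroni threshold 0.05 / n_variants is attached.
#' A near-singular V is shrunk linearly toward the identity.
#'
#' @param tmat variants x traits matrix of signed t-values (rownames =
#'   variant ids). Variants with any missing trait are dropped (logged via
#'   the `dropped` attribute).
#' @param shrinkage shrinkage weight applied when V is near-singular.
#' @param max_kappa condition-number trigger for shrinkage.
#' @param null_only when TRUE, estimate V only from variants with all
#'   |t| < 2 (guards against true signals inflating V); default uses all.
#' @param V optional fixed trait-correlation matrix; when NULL (default) V is
#'   estimated from the signed t-values themselves.
#' @return list(stats = per-variant data.frame, V, shrunk, threshold).
#' @export
multitrait_chi2 <- function(tmat, shrinkage = 0.05, max_kappa = 1e6,
                            null_only = FALSE, V = NULL) {
  tmat <- as.matrix(tmat)
  complete <- stats::complete.cases(tmat)
  dropped <- rownames(tmat)[!complete]
  tmat <- tmat[complete, , drop = FALSE]
  k <- ncol(tmat)
  est <- tmat
  if (null_only) {
    nullrows <- rowSums(abs(tmat) >= 2) == 0
    if (sum(nullrows) >= 10 * k) est <- tmat[nullrows, , drop = FALSE]
  }
  if (is.null(V)) V <- stats::cor(est)
  shrunk <- FALSE
  kap <- kappa(V, exact = TRUE)
  if (!is.finite(kap) || kap > max_kappa) {
    V <- (1 - shrinkage) * V + shrinkage * diag(k)
    shrunk <- TRUE
    kap <- kappa(V, exact = TRUE)
    if (!is.finite(kap) || kap > 1e12)
      stop(sprintf("trait correlation matrix singular after shrinkage (condition number %.3g)",
                   kap), call. = FALSE)
  }
  Vi <- solve(V)
  chi2 <- rowSums((tmat %*% Vi) * tmat)
  p <- stats::pchisq(chi2, df = k, lower.tail = FALSE)
  stats_df <- data.frame(variant = rownames(tmat) %||% seq_len(nrow(tmat)),
                         chi2 = chi2, df = k, p = p,
                         stringsAsFactors = FALSE)
  rownames(stats_df) <- NULL
  threshold <- 0.05 / nrow(tmat)
  stats_df$significant <- stats_df$p < threshold
  out <- list(stats = stats_df, V = V, shrunk = shrunk, threshold = threshold)
  attr(out, "dropped") <- dropped
  out
}
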