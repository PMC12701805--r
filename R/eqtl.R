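# cis-eQTL mapping: expression normalization, hidden-covariate estimation,
# nominal cis scan, permutation/beta gene-level calibration, eGene calling at
# FDR <= 0.05 with per-gene nominal thresholds, allelic fold change,
# stepwise independent signals, and Storey's pi1 replication statistic.

#' Normalize an expression matrix for eQTL mapping
#'
#' Step 1: quantile-normalize the sample columns to a common distribution.
#' Step 2: per gene, rank-based inverse normal transform with the Blom
#' offset, qnorm((rank - 3/8) / (n + 1/4)); ties receive average ranks.
#'
#' @param tpm genes x samples matrix (pre-filtered by
#'   [filter_expressed_genes()]).
#' @return matrix of the same shape; each gene row has mean 0 and exact
#'   normal-score marginals. Constant genes come back all zero with a warning.
#' @export
normalize_expression <- function(tpm) {
  tpm <- as.matrix(tpm)
  constant <- apply(tpm, 1, stats::sd) == 0
  qn <- if (nrow(tpm) > 1) limma::normalizeQuantiles(tpm) else tpm
  n <- ncol(qn)
  out <- t(apply(qn, 1, function(x) {
    if (stats::sd(x) == 0) return(rep(0, n))
    stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))
  }))
  if (any(constant)) {
    out[constant, ] <- 0
    warning("constant gene(s) set to all-zero normalized scores")
  }
  dimnames(out) <- dimnames(tpm)
  out
}

#' Hidden expression covariates by principal components
#'
#' Top-k principal components of the sample x gene matrix, used in place of
#' factor-analysis confounder estimation. Deterministic sign convention: the
#' largest-|loading| entry of each component is positive.
#'
#' @param norm_expr genes x samples normalized matrix.
#' @param k number of components.
#' @return samples x k matrix of factor scores (plus `var_explained` attr).
#' @export
hidden_factors <- function(norm_expr, k = 10) {
  ns <- ncol(norm_expr)
  if (k >= ns) stop("k must be smaller than the number of samples", call. = FALSE)
  if (k == 0) {
    out <- matrix(0, ns, 0)
    rownames(out) <- colnames(norm_expr)
    return(out)
  }
  X <- scale(t(norm_expr), center = TRUE, scale = FALSE)
  sv <- svd(X, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    l <- sv$v[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k),
                  2, flip, `*`)
  dimnames(scores) <- list(colnames(norm_expr), paste0("PC", seq_len(k)))
  attr(scores, "var_explained") <- (sv$d[seq_len(k)]^2) / sum(svd(X, nu = 0, nv = 0)$d^2)
  scores
}

#' Genotype principal components
#' @param panel a `haplotype_panel`.
#' @param k number of components.
#' @return samples x k score matrix.
#' @export
genotype_pcs <- function(panel, k = 2) {
  X <- panel_dosage(panel)
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  X <- scale(X)
  X[, !is.finite(colSums(X))] <- 0
  sv <- svd(X, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  dimnames(scores) <- list(panel$samples, paste0("gPC", seq_len(k)))
  scores
}

#' Nominal cis-eQTL scan
#'
#' For every gene and every variant within `window_bp` of its TSS:
#' expression and dosage are residualized on the covariates and the slope is
#' tested with df = n - 2 - n_covariates (two-sided).
#'
#' @param panel a `haplotype_panel` restricted to the expression cohort's
#'   samples (same order as the expression columns).
#' @param norm_expr genes x samples normalized expression.
#' @param gene_models table with gene, chrom, tss.
#' @param covariates samples x k numeric matrix (hidden factors + genotype
#'   PCs), or NULL.
#' @param window_bp cis window half-width around the TSS.
#' @return an `eqtl_scan` object: `pairs` (nominal statistics), `genes`
#'   (per-gene index + top association), and the residualized internals the
#'   permutation pass reuses.
#' @export
cis_scan <- function(panel, norm_expr, gene_models, covariates = NULL,
                     window_bp = 1e6) {
  stopifnot(identical(colnames(norm_expr), panel$samples))
  n <- length(panel$samples)
  X <- panel_dosage(panel)
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  C <- covar_design(covariates, n)
  qrC <- qr(C)
  df <- n - 2 - (ncol(C) - 1)
  Xr <- qr.resid(qrC, X)
  sx <- sqrt(colSums(Xr^2))
  Yr <- t(qr.resid(qrC, t(norm_expr)))
  v <- panel$variants
  genes <- list()
  pair_rows <- list()
  for (g in seq_len(nrow(gene_models))) {
    gid <- gene_models$gene[g]
    tss <- gene_models$tss[g]
    j <- which(v$chrom == gene_models$chrom[g] & abs(v$pos - tss) <= window_bp &
               sx > 1e-10)
    if (!length(j)) {
      genes[[gid]] <- list(gene = gid, variant_idx = integer(0),
                           top_variant = NA_character_, min_p = NA_real_)
      next
    }
    yr <- Yr[gid, ]
    sy <- sqrt(sum(yr^2))
    r <- as.vector(crossprod(Xr[, j, drop = FALSE], yr)) / (sx[j] * sy)
    r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    tval <- r * sqrt(df / (1 - r^2))
    beta <- r * sy / sx[j]
    se <- beta / tval
    p <- 2 * stats::pt(-abs(tval), df)
    top <- which.min(p)
    pair_rows[[gid]] <- data.frame(
      gene = gid, variant = v$id[j], chrom = v$chrom[j], pos = v$pos[j],
      distance = v$pos[j] - tss, beta = beta, se = abs(se), t = tval, p = p,
      stringsAsFactors = FALSE)
    genes[[gid]] <- list(gene = gid, variant_idx = j,
                         top_variant = v$id[j][top], min_p = p[top])
  }
  structure(list(
    pairs = do.call(rbind, pair_rows), genes = genes,
    internals = list(Xr = Xr, sx = sx, Yr = Yr, df = df, qrC = qrC,
                     n = n, variants = v)
  ), class = "eqtl_scan")
}

#' Permutation pass with beta approximation for one gene
#'
#' The gene's residualized expression is permuted `n_perm` times; the
#' per-permutation minimum nominal p is recorded, a Beta(a, b) null is fitted
#' by maximum likelihood (method-of-moments fallback), and the gene-level
#' empirical p is BetaCDF(observed min p). The direct permutation p,
#' (1 + #\{perm <= obs\}) / (n_perm + 1), is reported alongside.
#'
#' @param scan an `eqtl_scan`.
#' @param gene gene id.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list(gene, a, b, empirical_p, direct_p, min_p, top_variant,
#'   mle_converged).
#' @export
permutation_pass <- function(scan, gene, n_perm = 1000, seed = 1) {
  info <- scan$genes[[gene]]
  if (is.null(info) || !length(info$variant_idx))
    stop("gene has no cis variants in the scan", call. = FALSE)
  int <- scan$internals
  j <- info$variant_idx
  Xs <- sweep(int$Xr[, j, drop = FALSE], 2, int$sx[j], `/`)
  yr <- int$Yr[gene, ]
  df <- int$df
  minp_perm <- with_seed(seed, {
    P <- replicate(n_perm, sample(yr))
    P <- qr.resid(int$qrC, P)       # re-residualize the permuted phenotype
    sy <- sqrt(colSums(P^2))
    R <- crossprod(Xs, P) / rep(sy, each = length(j))
    R <- pmin(pmax(R, -1 + 1e-15), 1 - 1e-15)
    rmax <- apply(abs(R), 2, max)
    tmax <- rmax * sqrt(df / (1 - rmax^2))
    2 * stats::pt(-tmax, df)
  })
  fit <- fit_beta_ml(minp_perm)
  emp <- stats::pbeta(info$min_p, fit$a, fit$b)
  direct <- (1 + sum(minp_perm <= info$min_p)) / (n_perm + 1)
  list(gene = gene, a = fit$a, b = fit$b,
       empirical_p = max(emp, .Machine$double.xmin),
       direct_p = direct, min_p = info$min_p,
       top_variant = info$top_variant, mle_converged = fit$converged)
}

# Beta(a,b) maximum-likelihood fit with method-of-moments fallback
fit_beta_ml <- function(x) {
  x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
  m <- mean(x); v <- stats::var(x)
  v <- max(v, 1e-12)
  k0 <- max(m * (1 - m) / v - 1, 0.1)
  init <- log(c(max(m * k0, 1e-3), max((1 - m) * k0, 1e-3)))
  nll <- function(lp) {
    a <- exp(lp[1]); b <- exp(lp[2])
    -sum(stats::dbeta(x, a, b, log = TRUE))
  }
  opt <- try(stats::optim(init, nll, method = "Nelder-Mead"), silent = TRUE)
  if (inherits(opt, "try-error") || opt$convergence != 0) {
    list(a = exp(init[1]), b = exp(init[2]), converged = FALSE)
  } else {
    list(a = exp(opt$par[1]), b = exp(opt$par[2]), converged = TRUE)
  }
}

#' Call eGenes at FDR and derive per-gene nominal thresholds
#'
#' Benjamini-Hochberg on the gene-level empirical p-values; the global
#' empirical cutoff is the largest empirical p called significant, and each
#' gene's nominal threshold is BetaQuantile(global cutoff; a_g, b_g). cis
#' variants with nominal p below their gene's threshold are eVariants.
#'
#' @param perm data.frame with columns gene, a, b, empirical_p (rows from
#'   [permutation_pass()]).
#' @param fdr FDR level.
#' @return `perm` with qvalue, egene flag and nominal_threshold columns, plus
#'   the global cutoff as attribute `global_cutoff`.
#' @export
egene_calling <- function(perm, fdr = 0.05) {
  q <- stats::p.adjust(perm$empirical_p, method = "BH")
  sig <- q <= fdr
  cutoff <- if (any(sig)) max(perm$empirical_p[sig]) else NA_real_
  thr <- rep(NA_real_, nrow(perm))
  if (!is.na(cutoff))
    thr[sig] <- stats::qbeta(cutoff, perm$a[sig], perm$b[sig])
  perm$qvalue <- q
  perm$egene <- sig
  perm$nominal_threshold <- thr
  attr(perm, "global_cutoff") <- cutoff
  perm
}

#' Allelic fold change of a cis-eVariant
#'
#' Linear-scale estimator: TPM is residualized on the covariates (grand mean
#' restored), mu + beta * dosage is fitted, and
#' aFC = log2(1 + 2 beta / mu) with mu the fitted mean of the
#' reference-homozygote class, clamped to +/- log2(100) = 6.64. Undefined
#' (NA) when mu <= 0.
#'
#' @param tpm_gene TPM vector for the gene across samples.
#' @param dosage ALT-dosage vector.
#' @param covariates numeric covariate matrix or NULL.
#' @param cap absolute cap on log2 aFC.
#' @return log2 aFC (NA when undefined).
#' @export
afc <- function(tpm_gene, dosage, covariates = NULL, cap = log2(100)) {
  n <- length(tpm_gene)
  y <- if (!is.null(covariates)) {
    stats::resid(stats::lm.fit(covar_design(covariates, n), tpm_gene)) +
      mean(tpm_gene)
  } else tpm_gene
  fit <- stats::lm.fit(cbind(1, dosage), y)
  mu <- fit$coefficients[1]
  beta <- fit$coefficients[2]
  if (!is.finite(mu) || mu <= 0 || !is.finite(beta)) return(NA_real_)
  ratio <- 1 + 2 * beta / mu
  val <- if (ratio <= 0) -cap else log2(ratio)
  unname(pmin(pmax(val, -cap), cap))
}

#' Forward-stepwise independent cis-eQTL signals for an eGene
#'
#' Adds the top cis variant, re-scans conditioning on the selected set, and
#' stops once the best conditional p exceeds the gene's nominal threshold.
#' A backward pass then re-tests each selected variant conditioned on the
#' others and drops those no longer passing.
#'
#' @param scan an `eqtl_scan`.
#' @param gene gene id (must be an eGene).
#' @param threshold the gene's nominal p threshold.
#' @param max_signals safety cap on the number of signals.
#' @return data.frame(variant, p_conditional) ranked by discovery order.
#' @export
independent_eqtls <- function(scan, gene, threshold, max_signals = 10) {
  info <- scan$genes[[gene]]
  int <- scan$internals
  j <- info$variant_idx
  X <- int$Xr[, j, drop = FALSE]
  y <- int$Yr[gene, ]
  ids <- int$variants$id[j]
  n <- length(y)
  base_df <- int$df
  cond_scan <- function(sel, test_idx) {
    C <- cbind(1, X[, sel, drop = FALSE])
    qrC <- qr(C)
    yr <- qr.resid(qrC, y)
    Xr <- qr.resid(qrC, X[, test_idx, drop = FALSE])
    df <- base_df - length(sel)
    sy <- sqrt(sum(yr^2)); sxx <- sqrt(colSums(Xr^2))
    okv <- sxx > 1e-10
    p <- rep(NA_real_, length(test_idx))
    if (any(okv)) {
      r <- as.vector(crossprod(Xr[, okv, drop = FALSE], yr)) / (sxx[okv] * sy)
      r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
      p[okv] <- 2 * stats::pt(-abs(r) * sqrt(df / (1 - r^2)), df)
    }
    p
  }
  selected <- integer(0)
  p_sel <- numeric(0)
  repeat {
    remaining <- setdiff(seq_along(j), selected)
    if (!length(remaining) || length(selected) >= max_signals) break
    p <- cond_scan(selected, remaining)
    if (all(is.na(p))) break
    best <- which.min(p)
    if (p[best] > threshold) break
    selected <- c(selected, remaining[best])
    p_sel <- c(p_sel, p[best])
  }
  # backward refinement
  if (length(selected) > 1) {
    keep <- rep(TRUE, length(selected))
    for (i in seq_along(selected)) {
      others <- selected[keep & seq_along(selected) != i]
      p_i <- cond_scan(others, selected[i])
      if (is.na(p_i) || p_i > threshold) keep[i] <- FALSE
    }
    selected <- selected[keep]
    p_sel <- p_sel[keep]
  }
  data.frame(variant = ids[selected], p_conditional = p_sel,
             stringsAsFactors = FALSE)
}

#' Storey's pi1 replication statistic
#'
#' pi0 is estimated on the lambda grid 0.05, 0.10, ..., 0.95 as
#' mean(p > lambda) / (1 - lambda), smoothed with a cubic spline and
#' extrapolated to lambda -> 1; pi1 = 1 - pi0, clamped to [0, 1].
#'
#' @param p vector of replication p-values.
#' @return pi1 estimate.
#' @export
storey_pi1 <- function(p) {
  if (!length(p)) stop("empty p-value vector", call. = FALSE)
  if (length(p) < 100)
    warning("pi1 is unstable below ~100 p-values")
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0 <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0, df = 3)
  pi0_hat <- stats::predict(fit, x = max(lambda))$y
  pi0_hat <- min(max(pi0_hat, 0), 1)
  1 - pi0_hat
}
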