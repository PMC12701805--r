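# Colocalization of GWAS and eQTL signals via Wakefield approximate Bayes
# factors, and the SMR (summary-data-based Mendelian randomization) test.

wakefield_labf <- function(beta, se, prior_sd) {
  z <- beta / se
  V <- se^2
  W <- prior_sd^2
  r <- W / (V + W)
  0.5 * (log1p(-r) + r * z^2)
}

#' Colocalization by approximate Bayes factors
#'
#' Per variant and dataset, the Wakefield log-ABF is
#' 0.5 [log(1 - r) + r z^2] with r = W / (V + W), V = se^2, W = prior_sd^2.
#' Posteriors over the five hypotheses (H0 no signal, H1/H2 signal in one
#' dataset, H3 two distinct causal variants, H4 one shared causal variant)
#' come from prior-weighted sums over single- and paired-variant
#' configurations, evaluated with log-sum-exp.
#'
#' @param gwas,eqtl data.frames with columns id, beta, se (effect alleles
#'   pre-harmonized on ref/alt; only the id intersection is used).
#' @param p1,p2,p12 per-variant prior probabilities of a GWAS-only,
#'   eQTL-only, and shared causal variant.
#' @param prior_sd prior effect-size sd for both (quantitative) datasets.
#' @return list: posteriors (named PP.H0..PP.H4), n_snps, h4 flag at > 0.8,
#'   per-variant H4 posterior weights.
#' @export
coloc_abf <- function(gwas, eqtl, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd = 0.15) {
  ok_g <- is.finite(gwas$se) & gwas$se > 0
  ok_e <- is.finite(eqtl$se) & eqtl$se > 0
  gwas <- gwas[ok_g, , drop = FALSE]
  eqtl <- eqtl[ok_e, , drop = FALSE]
  shared <- intersect(gwas$id, eqtl$id)
  if (!length(shared)) stop("no shared variants between datasets", call. = FALSE)
  g <- gwas[match(shared, gwas$id), ]
  e <- eqtl[match(shared, eqtl$id), ]
  l1 <- wakefield_labf(g$beta, g$se, prior_sd)
  l2 <- wakefield_labf(e$beta, e$se, prior_sd)
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  lh <- c(
    H0 = 0,
    H1 = log(p1) + ls1,
    H2 = log(p2) + ls2,
    H3 = log(p1) + log(p2) + logdiff(ls1 + ls2, ls12),
    H4 = log(p12) + ls12
  )
  denom <- logsumexp(lh)
  pp <- exp(lh - denom)
  names(pp) <- paste0("PP.", names(lh))
  w4 <- exp((l1 + l2) - ls12)
  list(posteriors = pp, n_snps = length(shared),
       h4 = unname(pp["PP.H4"] > 0.8),
       h4_variant_weights = stats::setNames(w4, shared),
       priors = c(p1 = p1, p2 = p2, p12 = p12))
}

#' SMR test for one gene
#'
#' Instrument = the gene's top cis-eQTL. With z_e and z_g the eQTL and GWAS
#' z-scores at the instrument, T_SMR = z_g^2 z_e^2 / (z_g^2 + z_e^2),
#' referred to the 1-df chi-square upper tail; b_xy = beta_g / beta_e is the
#' implied effect of expression on the trait.
#'
#' @param beta_g,se_g GWAS effect and se at the instrument.
#' @param beta_e,se_e eQTL effect and se at the instrument.
#' @return list(b_xy, t_smr, p).
#' @export
smr_test <- function(beta_g, se_g, beta_e, se_e) {
  z_g <- beta_g / se_g
  z_e <- beta_e / se_e
  if (!is.finite(z_e) || z_e == 0)
    stop("eQTL z-score is zero; gene has no usable instrument", call. = FALSE)
  t_smr <- (z_g^2 * z_e^2) / (z_g^2 + z_e^2)
  list(b_xy = beta_g / beta_e, t_smr = t_smr,
       p = stats::pchisq(t_smr, df = 1, lower.tail = FALSE))
}

#' SMR over a set of eGenes with BH correction
#'
#' @param instruments data.frame with gene, variant (the top cis-eQTL
#'   passing the gene's nominal threshold), beta_e, se_e.
#' @param gwas per-variant GWAS summary statistics (id, beta, se).
#' @param fdr FDR level.
#' @return data.frame gene, variant, b_xy, t_smr, p, qvalue, significant.
#' @export
smr <- function(instruments, gwas, fdr = 0.05) {
  rows <- lapply(seq_len(nrow(instruments)), function(i) {
    gi <- match(instruments$variant[i], gwas$id)
    if (is.na(gi)) return(NULL)
    res <- try(smr_test(gwas$beta[gi], gwas$se[gi],
                        instruments$beta_e[i], instruments$se_e[i]),
               silent = TRUE)
    if (inherits(res, "try-error")) return(NULL)
    data.frame(gene = instruments$gene[i], variant = instruments$variant[i],
               b_xy = res$b_xy, t_smr = res$t_smr, p = res$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene = character(), variant = character(),
                      b_xy = numeric(), t_smr = numeric(), p = numeric(),
                      qvalue = numeric(), significant = logical()))
  out$qvalue <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$qvalue <= fdr
  rownames(out) <- NULL
  out
}
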