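# Methylome feature calling: CpG-island scanning on sequence, experimental
# support filtering from WGBS counts, and hypomethylated-region segmentation
# by a two-state beta-binomial hidden Markov model.

# GC content, CpG count, and ObsCpG/ExpCpG for a 0-based half-open interval,
# from precomputed cumulative sums
region_cgi_stats <- function(cum_c, cum_g, cum_cg, start, end) {
  L <- end - start
  nC <- cum_c[end + 1] - cum_c[start + 1]
  nG <- cum_g[end + 1] - cum_g[start + 1]
  # CpG dinucleotides fully inside: first base in [start, end-1)
  nCG <- if (end - 1 > start) cum_cg[end] - cum_cg[start + 1] else 0
  gc <- (nC + nG) / L
  expected <- (nC * nG) / L
  oe <- if (expected > 0) nCG / expected else 0
  list(gc = gc, oe = oe, length = L)
}

#' Scan a sequence for computational CpG islands (cCGIs)
#'
#' Slides 500-bp windows at 100-bp steps; windows with GC >= 0.55 and
#' ObsCpG/ExpCpG >= 0.65 (Exp = #C x #G / L) are marked, overlapping marked
#' windows merged, and each merged region trimmed in 10-bp steps from both
#' ends until the whole region satisfies both criteria at length >= 500
#' (discarded otherwise). Thresholds are inclusive; N counts as non-GC.
#'
#' @param seqs named character vector of sequences (or a
#'   `Biostrings::DNAStringSet`), one per chromosome.
#' @param min_len,gc_min,oe_min island criteria.
#' @param window_bp,step_bp scan geometry.
#' @return an `interval_track` of islands (0-based half-open).
#' @export
cgi_scan <- function(seqs, min_len = 500, gc_min = 0.55, oe_min = 0.65,
                     window_bp = 500, step_bp = 100) {
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("chr", seq_along(seqs))
  all_rows <- list()
  for (cc in names(seqs)) {
    s <- toupper(seqs[[cc]])
    L <- nchar(s)
    if (L < window_bp) next
    ch <- strsplit(s, "")[[1]]
    isC <- ch == "C"
    isG <- ch == "G"
    cum_c <- c(0, cumsum(isC))
    cum_g <- c(0, cumsum(isG))
    is_cg <- c(isC[-L] & isG[-1], FALSE)
    cum_cg <- c(0, cumsum(is_cg))

    starts <- seq(0, L - window_bp, by = step_bp)
    nC <- cum_c[starts + window_bp + 1] - cum_c[starts + 1]
    nG <- cum_g[starts + window_bp + 1] - cum_g[starts + 1]
    nCG <- cum_cg[starts + window_bp] - cum_cg[starts + 1]
    gc <- (nC + nG) / window_bp
    expd <- nC * nG / window_bp
    oe <- ifelse(expd > 0, nCG / expd, 0)
    marked <- gc >= gc_min & oe >= oe_min
    if (!any(marked)) next
    # merge overlapping marked windows
    ms <- starts[marked]
    me <- ms + window_bp
    keep <- list()
    cur_s <- ms[1]; cur_e <- me[1]
    if (length(ms) > 1) for (i in 2:length(ms)) {
      if (ms[i] <= cur_e) cur_e <- max(cur_e, me[i])
      else { keep[[length(keep) + 1]] <- c(cur_s, cur_e); cur_s <- ms[i]; cur_e <- me[i] }
    }
    keep[[length(keep) + 1]] <- c(cur_s, cur_e)
    for (reg in keep) {
      a <- reg[1]; b <- reg[2]
      repeat {
        if (b - a < min_len) { a <- NULL; break }
        st <- region_cgi_stats(cum_c, cum_g, cum_cg, a, b)
        if (st$gc >= gc_min && st$oe >= oe_min) break
        a <- a + 10; b <- b - 10
      }
      if (!is.null(a))
        all_rows[[length(all_rows) + 1]] <-
          data.frame(chrom = cc, start = a, end = b, label = "cCGI",
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(all_rows))
    return(structure(list(name = "cCGI",
                          intervals = data.frame(chrom = character(),
                                                 start = numeric(),
                                                 end = numeric(),
                                                 label = character())),
                     class = "interval_track"))
  new_interval_track("cCGI", do.call(rbind, all_rows))
}

#' Filter cCGIs to experimentally supported islands (eCGIs)
#'
#' An eCGI is a cCGI that, in at least one WGBS sample, holds at least
#' `min_sites` CpG sites with coverage strictly above `min_cov` whose
#' coverage-weighted mean methylation is below `meth_max`.
#'
#' @param ccgi `interval_track` of cCGIs.
#' @param cpg_samples list of CpG count tables (chrom, pos, coverage,
#'   methylated), one per sample.
#' @param min_sites,min_cov,meth_max support criteria.
#' @return `interval_track` of eCGIs.
#' @export
ecgi_filter <- function(ccgi, cpg_samples, min_sites = 5, min_cov = 5,
                        meth_max = 0.30) {
  if (is.data.frame(cpg_samples)) cpg_samples <- list(cpg_samples)
  iv <- ccgi$intervals
  supported <- rep(FALSE, nrow(iv))
  for (cpg in cpg_samples) {
    ok <- cpg$coverage > min_cov
    cc <- cpg[ok, , drop = FALSE]
    for (i in which(!supported)) {
      sel <- cc$chrom == iv$chrom[i] & cc$pos > iv$start[i] & cc$pos <= iv$end[i]
      if (sum(sel) >= min_sites) {
        lvl <- sum(cc$methylated[sel]) / sum(cc$coverage[sel])
        if (lvl < meth_max) supported[i] <- TRUE
      }
    }
  }
  out <- iv[supported, , drop = FALSE]
  if (!nrow(out))
    return(structure(list(name = "eCGI",
                          intervals = data.frame(chrom = character(),
                                                 start = numeric(),
                                                 end = numeric(),
                                                 label = character())),
                     class = "interval_track"))
  out$label <- "eCGI"
  new_interval_track("eCGI", out)
}

dbetabinom_log <- function(k, n, a, b) {
  lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

# Baum-Welch for the two-state beta-binomial HMM. Emissions are
# re-estimated numerically (generalized EM: a parameter update is accepted
# only if it improves the expected complete-data log-likelihood), so the
# observed-data log-likelihood is non-decreasing across iterations.
fit_bb_hmm <- function(k, n, max_iter = 100, tol = 1e-4) {
  S <- 2
  ab <- matrix(c(1, 9, 8, 2), 2, byrow = TRUE)  # hypo mean .1, hyper mean .8
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  init <- c(0.5, 0.5)
  Tn <- length(k)
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    le <- cbind(dbetabinom_log(k, n, ab[1, 1], ab[1, 2]),
                dbetabinom_log(k, n, ab[2, 1], ab[2, 2]))
    # scaled forward-backward
    alpha <- matrix(0, Tn, S); beta_m <- matrix(0, Tn, S); cvec <- numeric(Tn)
    e <- exp(le - apply(le, 1, max))
    emax <- apply(le, 1, max)
    a0 <- init * e[1, ]
    cvec[1] <- sum(a0); alpha[1, ] <- a0 / cvec[1]
    for (t in 2:Tn) {
      a0 <- (alpha[t - 1, ] %*% A) * e[t, ]
      cvec[t] <- sum(a0); alpha[t, ] <- a0 / cvec[t]
    }
    beta_m[Tn, ] <- 1
    for (t in (Tn - 1):1)
      beta_m[t, ] <- (A %*% (e[t + 1, ] * beta_m[t + 1, ])) / cvec[t + 1]
    ll <- sum(log(cvec)) + sum(emax)
    ll_trace <- c(ll_trace, ll)
    gamma <- alpha * beta_m
    gamma <- gamma / rowSums(gamma)
    xi_num <- matrix(0, S, S)
    for (i in 1:S) for (j in 1:S)
      xi_num[i, j] <- sum(alpha[-Tn, i] * A[i, j] * e[-1, j] * beta_m[-1, j] /
                          cvec[-1])
    A_new <- xi_num / rowSums(xi_num)
    init_new <- gamma[1, ]
    ab_new <- ab
    for (s in 1:S) {
      w <- gamma[, s]
      qfun <- function(lp) {
        a <- exp(lp[1]); b <- exp(lp[2])
        -sum(w * dbetabinom_log(k, n, a, b))
      }
      cur <- log(ab[s, ])
      opt <- try(stats::optim(cur, qfun, method = "Nelder-Mead"), silent = TRUE)
      if (!inherits(opt, "try-error") && opt$value < qfun(cur))
        ab_new[s, ] <- exp(opt$par)
    }
    # keep state identity: row 1 = hypo (smaller mean)
    means <- ab_new[, 1] / rowSums(ab_new)
    if (means[1] > means[2]) {
      ab_new <- ab_new[2:1, ]; A_new <- A_new[2:1, 2:1]; init_new <- init_new[2:1]
    }
    delta <- if (it > 1) ll - ll_trace[it - 1] else Inf
    A <- A_new; init <- init_new; ab <- ab_new
    if (is.finite(delta) && abs(delta) < tol) break
  }
  # final posteriors under the last accepted parameters
  le <- cbind(dbetabinom_log(k, n, ab[1, 1], ab[1, 2]),
              dbetabinom_log(k, n, ab[2, 1], ab[2, 2]))
  e <- exp(le - apply(le, 1, max))
  alpha <- matrix(0, Tn, S); beta_m <- matrix(0, Tn, S); cvec <- numeric(Tn)
  a0 <- init * e[1, ]; cvec[1] <- sum(a0); alpha[1, ] <- a0 / cvec[1]
  for (t in 2:Tn) {
    a0 <- (alpha[t - 1, ] %*% A) * e[t, ]
    cvec[t] <- sum(a0); alpha[t, ] <- a0 / cvec[t]
  }
  beta_m[Tn, ] <- 1
  for (t in (Tn - 1):1)
    beta_m[t, ] <- (A %*% (e[t + 1, ] * beta_m[t + 1, ])) / cvec[t + 1]
  gamma <- alpha * beta_m
  gamma <- gamma / rowSums(gamma)
  list(ab = ab, A = A, init = init, posterior = gamma, loglik = ll_trace)
}

#' Call hypomethylated regions (HMRs) from CpG counts
#'
#' Sites below `min_coverage` are dropped; a two-state (hypo / hyper)
#' beta-binomial HMM is fitted by Baum-Welch (fixed initialization: state
#' means 0.1 and 0.8, self-transition 0.9; max 100 iterations, log-likelihood
#' tolerance 1e-4) and posterior-decoded. HMRs are maximal hypo-state runs,
#' split wherever the gap between consecutive retained CpGs exceeds
#' `desert_bp`.
#'
#' @param cpg CpG count table: chrom, pos (1-based), coverage, methylated.
#' @param min_coverage minimum per-site coverage.
#' @param desert_bp maximum intra-HMR CpG gap.
#' @param min_sites minimum usable sites (error below).
#' @return `interval_track` of HMRs with the fitted model as attribute
#'   `model`.
#' @export
hmr_call <- function(cpg, min_coverage = 10, desert_bp = 10000,
                     min_sites = 50) {
  cpg <- cpg[cpg$coverage >= min_coverage, , drop = FALSE]
  cpg <- cpg[order(cpg$chrom, cpg$pos), ]
  if (nrow(cpg) < min_sites)
    stop(sprintf("only %d usable CpG sites (need >= %d)", nrow(cpg), min_sites),
         call. = FALSE)
  rows <- list()
  models <- list()
  for (cc in unique(cpg$chrom)) {
    d <- cpg[cpg$chrom == cc, ]
    fit <- fit_bb_hmm(d$methylated, d$coverage)
    models[[cc]] <- fit
    hypo <- fit$posterior[, 1] > 0.5
    gap_break <- c(FALSE, diff(d$pos) > desert_bp)
    run_id <- cumsum(!hypo | gap_break)
    for (rid in unique(run_id[hypo])) {
      sel <- which(hypo & run_id == rid)
      if (!length(sel)) next
      rows[[length(rows) + 1]] <- data.frame(
        chrom = cc, start = d$pos[sel[1]] - 1, end = d$pos[sel[length(sel)]] + 1,
        label = "HMR", n_cpg = length(sel), stringsAsFactors = FALSE)
    }
  }
  iv <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               label = character(), n_cpg = integer())
  tr <- if (nrow(iv)) new_interval_track("HMR", iv) else
    structure(list(name = "HMR", intervals = iv), class = "interval_track")
  if (nrow(iv)) tr$intervals$n_cpg <- iv$n_cpg[order(iv$chrom, iv$start)]
  attr(tr, "model") <- models
  tr
}

#' Union-merge HMR tracks from multiple samples
#' @param tracks list of `interval_track`s.
#' @return merged `interval_track` (interval union per chromosome).
#' @export
merge_hmr_tracks <- function(tracks) {
  iv <- do.call(rbind, lapply(tracks, function(t)
    t$intervals[, c("chrom", "start", "end")]))
  if (is.null(iv) || !nrow(iv))
    return(structure(list(name = "HMR_merged",
                          intervals = data.frame(chrom = character(),
                                                 start = numeric(),
                                                 end = numeric(),
                                                 label = character())),
                     class = "interval_track"))
  out <- list()
  for (cc in unique(iv$chrom)) {
    d <- iv[iv$chrom == cc, ]
    d <- d[order(d$start), ]
    r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end))
    out[[cc]] <- data.frame(chrom = cc, start = IRanges::start(r) - 1,
                            end = IRanges::end(r), label = "HMR",
                            stringsAsFactors = FALSE)
  }
  new_interval_track("HMR_merged", do.call(rbind, out))
}
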