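# Permutation-based enrichment of variant sets in annotation tracks, eQTL
# membership enrichment, and TAD co-occurrence of eGene-eVariant pairs.

# core permutation engine on a precomputed membership vector
membership_enrichment <- function(candidate_idx, membership, maf = NULL,
                                  n_perm = 1000, maf_match = TRUE, seed = 1,
                                  alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  n_tested <- length(membership)
  k <- length(candidate_idx)
  if (!k) return(list(observed = NA_real_, expected = NA_real_,
                      fold = NA_real_, p = NA_real_, n_perm = n_perm))
  obs <- mean(membership[candidate_idx])
  bins <- if (maf_match && !is.null(maf)) {
    pmin(floor(maf / 0.02), 24L)
  } else rep(0L, n_tested)
  by_bin <- split(seq_len(n_tested), bins)
  cand_bins <- table(bins[candidate_idx])
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      draw <- unlist(lapply(names(cand_bins), function(bn) {
        pool <- by_bin[[bn]]
        nb <- cand_bins[[bn]]
        if (length(pool) <= nb) pool else sample(pool, nb)
      }), use.names = FALSE)
      mean(membership[draw])
    }, numeric(1))
  })
  expected <- mean(perm)
  fold <- if (expected > 0) obs / expected else NA_real_
  # mid-p tie handling: the overlap statistic is discrete, so ties between
  # permuted and observed deviations carry half weight; keeps the null
  # near-uniform without giving up the 1/(n_perm+1) floor
  p <- if (all(abs(perm - obs) <= 1e-12)) {
    1  # degenerate null: the statistic never varies, no evidence either way
  } else if (alternative == "two.sided") {
    dp <- abs(perm - expected); do_ <- abs(obs - expected)
    (1 + sum(dp > do_ + 1e-12) + 0.5 * sum(abs(dp - do_) <= 1e-12)) /
      (n_perm + 1)
  } else {
    (1 + sum(perm > obs + 1e-12) + 0.5 * sum(abs(perm - obs) <= 1e-12)) /
      (n_perm + 1)
  }
  list(observed = obs, expected = expected, fold = fold, p = p, n_perm = n_perm)
}

#' Enrichment of a candidate variant set in an interval track
#'
#' Observed = fraction of candidate variants inside the track; the null is
#' `n_perm` equal-size draws from the tested variants (within 2%-MAF bins
#' when `maf_match`). Two-sided empirical p relative to the permutation mean
#' (mid-p tie convention), so both enrichment and depletion are detectable.
#'
#' @param candidate_ids candidate variant ids (subset of tested).
#' @param tested data.frame of all tested variants: id, chrom, pos, maf.
#' @param track an `interval_track`.
#' @param n_perm,maf_match,seed permutation controls.
#' @return list(observed, expected, fold, p, n_perm).
#' @export
interval_enrichment <- function(candidate_ids, tested, track, n_perm = 1000,
                                maf_match = TRUE, seed = 1) {
  if (is.null(track$intervals) || !nrow(track$intervals))
    stop("annotation track is empty", call. = FALSE)
  idx <- match(candidate_ids, tested$id)
  if (anyNA(idx)) stop("candidate variants must be a subset of tested",
                       call. = FALSE)
  membership <- points_in_intervals(tested$chrom, tested$pos, track)
  membership_enrichment(idx, membership, tested$maf, n_perm, maf_match, seed)
}

#' Enrichment of GWAS candidate SNPs in the eVariant set
#'
#' Same permutation engine as [interval_enrichment()] with the annotation
#' being membership in the eVariant id set rather than genomic intervals.
#'
#' @param candidate_ids per-trait candidate SNP ids.
#' @param tested data.frame of tested variants (id, maf).
#' @param evariant_ids eVariant id set.
#' @inheritParams interval_enrichment
#' @export
gwas_in_eqtl_enrichment <- function(candidate_ids, tested, evariant_ids,
                                    n_perm = 1000, maf_match = TRUE, seed = 1) {
  idx <- match(candidate_ids, tested$id)
  if (anyNA(idx)) stop("candidate variants must be a subset of tested",
                       call. = FALSE)
  membership <- tested$id %in% evariant_ids
  membership_enrichment(idx, membership, tested$maf, n_perm, maf_match, seed)
}

# TAD index lookup for 1-based positions; NA when outside every TAD
tad_index <- function(chrom, pos, tads) {
  iv <- tads$intervals
  out <- rep(NA_integer_, length(pos))
  for (cc in unique(chrom)) {
    sel <- which(chrom == cc)
    ivc <- which(iv$chrom == cc)
    if (!length(ivc)) next
    o <- ivc[order(iv$start[ivc])]
    i <- findInterval(pos[sel] - 1, iv$start[o])
    hit <- i >= 1 & (pos[sel] - 1) < iv$end[o][pmax(i, 1)]
    out[sel[hit]] <- o[i[hit]]
  }
  out
}

#' TAD co-occurrence of eGene-eVariant pairs
#'
#' Observed = fraction of pairs whose gene TSS and top eVariant fall inside
#' the same TAD. Each permutation rebuilds every pair at a random gene with a
#' random tested variant at the same |TSS distance| (+/- `distance_tol_bp`;
#' tolerance doubled with a note when no match exists). One-sided
#' empirical p (excess co-occurrence).
#'
#' @param pairs data.frame gene, variant.
#' @param gene_models gene table (gene, chrom, tss).
#' @param tested data.frame of tested variants (id, chrom, pos).
#' @param tads non-overlapping `interval_track` of TADs.
#' @param n_perm,distance_tol_bp,seed permutation controls.
#' @return list(observed, expected, fold, p, null, n_perm).
#' @export
tad_cooccurrence <- function(pairs, gene_models, tested, tads, n_perm = 5000,
                             distance_tol_bp = 10000, seed = 1) {
  gm <- gene_models[match(pairs$gene, gene_models$gene), ]
  vr <- tested[match(pairs$variant, tested$id), ]
  d_obs <- abs(vr$pos - gm$tss)
  ti_g <- tad_index(gm$chrom, gm$tss, tads)
  ti_v <- tad_index(vr$chrom, vr$pos, tads)
  obs <- mean(!is.na(ti_g) & !is.na(ti_v) & ti_g == ti_v)

  by_chrom <- split(seq_len(nrow(tested)), tested$chrom)
  sorted_pos <- lapply(by_chrom, function(i) {
    o <- i[order(tested$pos[i])]
    list(idx = o, pos = tested$pos[o])
  })
  tss_tad <- tad_index(gene_models$chrom, gene_models$tss, tads)
  tested_tad <- tad_index(tested$chrom, tested$pos, tads)

  draw_variant <- function(g, d, tol) {
    sp <- sorted_pos[[gene_models$chrom[g]]]
    repeat {
      lo1 <- gene_models$tss[g] - d - tol; hi1 <- gene_models$tss[g] - d + tol
      lo2 <- gene_models$tss[g] + d - tol; hi2 <- gene_models$tss[g] + d + tol
      a <- findInterval(c(lo1 - 1, hi1, lo2 - 1, hi2), sp$pos)
      cand <- c(if (a[2] > a[1]) (a[1] + 1):a[2],
                if (a[4] > a[3]) (a[3] + 1):a[4])
      if (length(cand)) return(sp$idx[cand[sample.int(length(cand), 1)]])
      tol <- tol * 2
      if (tol > 5e7) return(NA_integer_)
    }
  }
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      g_draw <- sample.int(nrow(gene_models), nrow(pairs), replace = TRUE)
      same <- vapply(seq_len(nrow(pairs)), function(i) {
        vi <- draw_variant(g_draw[i], d_obs[i], distance_tol_bp)
        if (is.na(vi)) return(NA)
        tv <- tested_tad[vi]
        tg <- tss_tad[g_draw[i]]
        !is.na(tg) && !is.na(tv) && tg == tv
      }, logical(1))
      mean(same, na.rm = TRUE)
    }, numeric(1))
  })
  expected <- mean(null)
  list(observed = obs, expected = expected,
       fold = if (expected > 0) obs / expected else NA_real_,
       p = (1 + sum(null >= obs - 1e-12)) / (n_perm + 1),
       null = null, n_perm = n_perm)
}
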