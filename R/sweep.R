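# EHH / iHS selective-sweep scan: extended haplotype homozygosity from phased
# haplotypes, integration to iHH in physical distance, standardization within
# derived-allele-frequency bins, and 50-kb window candidate calling.

# group-homozygosity EHH at one marker set: sum C(n_h,2) / C(n,2)
ehh_from_groups <- function(group_sizes, n) {
  if (n < 2) return(NA_real_)
  sum(choose(group_sizes, 2)) / choose(n, 2)
}

#' Extended haplotype homozygosity from a core allele
#'
#' Among the carrier haplotypes of `allele` at the core variant, EHH at each
#' successive marker is the probability that two randomly drawn carriers are
#' identical over all markers between the core and that marker:
#' EHH = sum_h C(n_h, 2) / C(n_carriers, 2) over distinct extended
#' haplotypes h. EHH(0) = 1 and EHH is non-increasing with distance.
#'
#' @param panel a `haplotype_panel` (phased, ancestral alleles known).
#' @param core_id core variant id.
#' @param allele 0 (REF/ancestral-coded) or 1 (ALT) carrier class.
#' @param direction +1 (downstream in position) or -1 (upstream).
#' @param ehh_cutoff stop extending once EHH falls below this value.
#' @param max_markers hard cap on the walk length.
#' @return data.frame(pos, distance_bp, ehh), first row the core itself.
#' @export
ehh <- function(panel, core_id, allele, direction = 1, ehh_cutoff = 0,
                max_markers = Inf) {
  v <- panel$variants
  j <- match(core_id, v$id)
  if (is.na(j)) stop("core variant not in panel", call. = FALSE)
  chrom_idx <- which(v$chrom == v$chrom[j])
  carriers <- which(panel$haps[, j] == allele)
  if (length(carriers) < 2)
    return(data.frame(pos = integer(0), distance_bp = numeric(0), ehh = numeric(0)))
  if (direction > 0) path <- chrom_idx[chrom_idx > j]
  else path <- rev(chrom_idx[chrom_idx < j])
  n <- length(carriers)
  ids <- rep(1L, n)
  out_pos <- v$pos[j]; out_d <- 0; out_e <- 1
  for (k in path) {
    if (length(out_e) - 1 >= max_markers) break
    a <- panel$haps[carriers, k]
    a[is.na(a)] <- 2L
    key <- ids * 3L + a
    ids <- match(key, unique(key))
    e <- ehh_from_groups(tabulate(ids), n)
    out_pos <- c(out_pos, v$pos[k])
    out_d <- c(out_d, abs(v$pos[k] - v$pos[j]))
    out_e <- c(out_e, e)
    if (e < ehh_cutoff) break
  }
  data.frame(pos = out_pos, distance_bp = out_d, ehh = out_e)
}

# one-sided iHH by trapezoid integration of EHH outward until decay below
# cutoff; returns NA with a reason when a gap exceeds max_gap_bp or the
# chromosome ends before decay
ihh_one_side <- function(panel, j, allele, direction, ehh_cutoff, max_gap_bp) {
  v <- panel$variants
  chrom_idx <- which(v$chrom == v$chrom[j])
  path <- if (direction > 0) chrom_idx[chrom_idx > j] else rev(chrom_idx[chrom_idx < j])
  carriers <- which(panel$haps[, j] == allele)
  n <- length(carriers)
  if (n < 2) return(list(ihh = NA_real_, reason = "too_few_carriers"))
  ids <- rep(1L, n)
  prev_pos <- v$pos[j]; prev_e <- 1; ihh <- 0
  for (k in path) {
    gap <- abs(v$pos[k] - prev_pos)
    if (gap > max_gap_bp) return(list(ihh = NA_real_, reason = "gap"))
    a <- panel$haps[carriers, k]
    a[is.na(a)] <- 2L
    key <- ids * 3L + a
    ids <- match(key, unique(key))
    e <- ehh_from_groups(tabulate(ids), n)
    ihh <- ihh + 0.5 * (prev_e + e) * gap
    prev_pos <- v$pos[k]; prev_e <- e
    if (e < ehh_cutoff) return(list(ihh = ihh, reason = NULL))
  }
  list(ihh = NA_real_, reason = "chrom_end")
}

#' Unstandardized iHS scan
#'
#' For each core SNP: iHH_A and iHH_D are the trapezoid integrals of EHH over
#' physical distance for the ancestral- and derived-allele carrier classes,
#' extended in both directions until EHH < `ehh_cutoff`. A core is skipped
#' (NA, with a reason) when an inter-marker gap exceeds `max_gap_bp` or the
#' chromosome ends before EHH decays. uniHS = ln(iHH_A / iHH_D).
#'
#' @param panel phased `haplotype_panel` with ancestral alleles in
#'   `variants$aa`.
#' @param maf_min minimum MAF for core SNPs.
#' @param ehh_cutoff EHH decay threshold.
#' @param max_gap_bp maximum allowed gap between consecutive markers.
#' @return data.frame chrom, pos, id, daf, ihh_a, ihh_d, unihs, skip_reason.
#' @export
ihs_scan <- function(panel, maf_min = 0.05, ehh_cutoff = 0.05,
                     max_gap_bp = 800000) {
  if (anyNA(panel$haps))
    warning("missing alleles treated as private haplotypes in EHH")
  v <- panel$variants
  derived_is_alt <- v$aa == v$ref
  if (anyNA(derived_is_alt))
    stop("ancestral allele unavailable; iHS needs allele polarity", call. = FALSE)
  daf_all <- colMeans(panel$haps == 1, na.rm = TRUE)
  daf_all[!derived_is_alt] <- 1 - daf_all[!derived_is_alt]
  reason_labels <- c(NA_character_, "too_few_carriers", "gap", "chrom_end",
                     "maf", "zero_ihh")
  rows <- lapply(unique(v$chrom), function(cc) {
    j <- which(v$chrom == cc)
    sub <- .ihs_scan_chrom(panel$haps[, j, drop = FALSE],
                           as.integer(v$pos[j]), derived_is_alt[j],
                           as.numeric(v$maf[j]), maf_min, ehh_cutoff,
                           max_gap_bp)
    data.frame(chrom = cc, pos = v$pos[j], id = v$id[j], daf = daf_all[j],
               ihh_a = sub$ihh_a, ihh_d = sub$ihh_d, unihs = sub$unihs,
               skip_reason = reason_labels[sub$reason + 1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' Scores are z-standardized within equal-width DAF bins; bins holding fewer
#' than 2 scores are merged with their nearest occupied neighbor so the
#' procedure stays deterministic.
#'
#' @param scan output of [ihs_scan()].
#' @param n_bins number of equal-width DAF bins on (0, 1).
#' @return `scan` with an `ihs` column (standardized score).
#' @export
standardize_ihs <- function(scan, n_bins = 100) {
  ok <- which(!is.na(scan$unihs))
  if (!length(ok)) { scan$ihs <- NA_real_; return(scan) }
  bin <- pmin(pmax(ceiling(scan$daf[ok] * n_bins), 1L), n_bins)
  counts <- tabulate(bin, n_bins)
  occupied <- which(counts > 0)
  # merge sparse bins into the nearest occupied neighbor, nearest-first
  merged <- bin
  for (b in occupied[counts[occupied] < 2]) {
    others <- occupied[counts[occupied] >= 2]
    if (!length(others)) next
    tgt <- others[which.min(abs(others - b))]
    merged[bin == b] <- tgt
  }
  if (length(unique(merged)) == 1 && stats::sd(scan$unihs[ok]) == 0)
    stop("degenerate DAF bin with zero variance; cannot standardize",
         call. = FALSE)
  z <- rep(NA_real_, length(ok))
  for (b in unique(merged)) {
    sel <- merged == b
    x <- scan$unihs[ok][sel]
    s <- stats::sd(x)
    z[sel] <- if (length(x) >= 2 && s > 0) (x - mean(x)) / s else 0
  }
  scan$ihs <- NA_real_
  scan$ihs[ok] <- z
  scan
}

#' Call candidate sweep windows
#'
#' Non-overlapping windows tiled from position 0 of each chromosome; the
#' window statistic is the mean |iHS| over the SNPs inside. Candidates are
#' the windows ranked in the top `top_frac` of the statistic (among windows
#' with at least one scored SNP) that also hold strictly more than
#' `min_snps` SNPs.
#'
#' @param scan standardized scan (needs `ihs`).
#' @param window_bp window width.
#' @param top_frac top fraction by mean |iHS| (0.01 = top 1%).
#' @param min_snps strict lower bound on SNPs per candidate window.
#' @return data.frame chrom, start, end (0-based half-open), n_snps,
#'   mean_abs_ihs, top_window, candidate.
#' @export
call_sweep_windows <- function(scan, window_bp = 50000, top_frac = 0.01,
                               min_snps = 10) {
  ok <- scan[!is.na(scan$ihs), , drop = FALSE]
  if (!nrow(ok)) return(data.frame())
  win <- floor((ok$pos - 1) / window_bp)
  key <- paste(ok$chrom, sprintf("%012d", as.integer(win)))
  n_snps <- as.vector(table(key))
  sums <- rowsum(abs(ok$ihs), key)
  ord_keys <- sort(unique(key))
  first <- match(ord_keys, key)
  agg <- data.frame(chrom = ok$chrom[first], start = win[first] * window_bp,
                    end = (win[first] + 1) * window_bp,
                    n_snps = n_snps,
                    mean_abs_ihs = as.vector(sums[ord_keys, ]) / n_snps,
                    stringsAsFactors = FALSE)
  agg <- agg[order(agg$chrom, agg$start), ]
  rownames(agg) <- NULL
  n_top <- max(1L, floor(top_frac * nrow(agg)))
  rank_ <- rank(-agg$mean_abs_ihs, ties.method = "first")
  agg$top_window <- rank_ <= n_top
  agg$candidate <- agg$top_window & agg$n_snps > min_snps
  agg
}
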