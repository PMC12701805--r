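# Containers and readers/writers for the standard formats, plus the variant
# and expression QC filters applied ahead of association and eQTL mapping.

#' Construct a haplotype panel
#'
#' @param samples character vector of sample ids (length N).
#' @param variants data.frame with columns chrom, pos (1-based bp), id, ref,
#'   alt, aa (ancestral allele), dr2 (imputation-quality analogue), maf.
#' @param haps 2N x M matrix of phased 0/1 alleles; rows 2i-1 and 2i are the
#'   two haplotypes of sample i. NA marks missing alleles.
#' @return object of class `haplotype_panel`.
#' @export
new_haplotype_panel <- function(samples, variants, haps) {
  stopifnot(nrow(haps) == 2 * length(samples), ncol(haps) == nrow(variants))
  vals <- haps[!is.na(haps)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    stop("haplotype entries must be 0/1", call. = FALSE)
  if (is.null(variants$maf)) {
    af <- colMeans(haps, na.rm = TRUE)
    variants$maf <- pmin(af, 1 - af)
  }
  structure(list(samples = samples, variants = variants, haps = haps),
            class = "haplotype_panel")
}

#' @exportS3Method base::print
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d samples x %d variants on %d chromosome(s)\n",
              length(x$samples), nrow(x$variants),
              length(unique(x$variants$chrom))))
  invisible(x)
}

#' Diploid dosage view of a panel (N x M, ALT-allele count 0/1/2)
#' @param panel a `haplotype_panel`.
#' @export
panel_dosage <- function(panel) {
  n <- length(panel$samples)
  d <- panel$haps[seq(1, 2 * n, 2), , drop = FALSE] +
       panel$haps[seq(2, 2 * n, 2), , drop = FALSE]
  rownames(d) <- panel$samples
  colnames(d) <- panel$variants$id
  d
}

#' Subset a panel to a variant index or id set
#' @param panel a `haplotype_panel`.
#' @param j integer index, logical mask, or character variant ids.
#' @export
panel_subset <- function(panel, j) {
  if (is.character(j)) j <- match(j, panel$variants$id)
  v <- panel$variants[j, , drop = FALSE]
  rownames(v) <- NULL
  new_haplotype_panel(panel$samples, v, panel$haps[, j, drop = FALSE])
}

#' Write a panel as phased VCF 4.2
#'
#' INFO carries `AA` (ancestral allele) and `DR2` (imputation quality
#' analogue); genotypes are phased `a|b`.
#' @param panel a `haplotype_panel`.
#' @param path output path.
#' @export
write_vcf <- function(panel, path) {
  v <- panel$variants
  n <- length(panel$samples)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##INFO=<ID=DR2,Number=1,Type=Float,Description=\"Imputation dosage r-squared\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t")
  ), con)
  h1 <- panel$haps[seq(1, 2 * n, 2), , drop = FALSE]
  h2 <- panel$haps[seq(2, 2 * n, 2), , drop = FALSE]
  gt <- matrix(paste0(ifelse(is.na(h1), ".", h1), "|",
                      ifelse(is.na(h2), ".", h2)), n)
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS",
                sprintf("AA=%s;DR2=%s", v$aa, format(v$dr2, trim = TRUE)),
                "GT", apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Load phased genotypes from a VCF
#'
#' @param path VCF path (plain or gzip; parsed with vcfR).
#' @param region optional list(chrom, start, end) filter on 1-based positions.
#' @param require_phased reject unphased genotype records when TRUE.
#' @return a [new_haplotype_panel()] with per-variant MAF computed from the
#'   non-missing alleles.
#' @export
load_genotypes <- function(path, region = NULL, require_phased = TRUE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt_raw <- vcf@gt[, -1, drop = FALSE]
  samples <- colnames(gt_raw)
  info <- fix$INFO
  get_info <- function(key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
    out <- rep(NA_character_, length(info))
    hit <- grepl(paste0(key, "="), info)
    out[hit] <- sub(paste0(".*", key, "="), "", m)
    out
  }
  variants <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), id = fix$ID,
    ref = fix$REF, alt = fix$ALT, aa = get_info("AA"),
    dr2 = suppressWarnings(as.numeric(get_info("DR2"))),
    stringsAsFactors = FALSE
  )
  keep <- rep(TRUE, nrow(variants))
  if (!is.null(region)) {
    keep <- variants$chrom == region$chrom &
      variants$pos >= region$start & variants$pos <= region$end
  }
  variants <- variants[keep, , drop = FALSE]
  gt_raw <- gt_raw[keep, , drop = FALSE]
  m <- nrow(variants)
  n <- length(samples)
  haps <- matrix(NA_integer_, 2 * n, m)
  if (m > 0) {
    gt <- sub(":.*", "", gt_raw)
    if (require_phased && any(grepl("/", gt, fixed = TRUE)))
      stop("unphased genotype records present but phasing is required",
           call. = FALSE)
    a1 <- substr(gt, 1, 1)
    a2 <- substr(gt, 3, 3)
    if (any(nchar(gt) != 3 & gt != "."))
      stop("unsupported (non-diploid or multi-allelic) genotype record",
           call. = FALSE)
    conv <- function(a) {
      out <- suppressWarnings(as.integer(a))
      out
    }
    # vcfR returns variants x samples; our haps are haplotypes x variants
    haps[seq(1, 2 * n, 2), ] <- t(matrix(conv(a1), m, n))
    haps[seq(2, 2 * n, 2), ] <- t(matrix(conv(a2), m, n))
  }
  af <- if (m > 0) colMeans(haps, na.rm = TRUE) else numeric(0)
  variants$maf <- pmin(af, 1 - af)
  rownames(variants) <- NULL
  new_haplotype_panel(samples, variants, haps)
}

#' Construct a named interval track (BED semantics: 0-based half-open)
#' @param name track name.
#' @param intervals data.frame with chrom, start, end and optional label.
#' @export
new_interval_track <- function(name, intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start >= intervals$end))
    stop("interval track requires start < end", call. = FALSE)
  if (is.null(intervals$label)) intervals$label <- name
  intervals <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(name = name,
                 intervals = intervals[, c("chrom", "start", "end", "label")]),
            class = "interval_track")
}

#' Read a BED3+name file into an interval track
#' @param path BED path (plain or gzip).
#' @param name track name (defaults to the file name).
#' @export
read_bed <- function(path, name = sub("\\.bed(\\.gz)?$", "", basename(path))) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "label"
  new_interval_track(name, df)
}

#' Write an interval track as BED
#' @param track an `interval_track`.
#' @param path output path.
#' @export
write_bed <- function(track, path) {
  utils::write.table(track$intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a headered tab-separated table
#' @param path file path (plain or gzip).
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Hardy-Weinberg chi-square test from genotype counts
#'
#' 1-df chi-square comparing observed genotype counts (n_AA, n_Aa, n_aa) with
#' Hardy-Weinberg expectations at the sample allele frequency.
#' @param n_rr,n_ra,n_aa genotype counts (ref-hom, het, alt-hom).
#' @return list(chisq, p).
#' @export
hwe_test <- function(n_rr, n_ra, n_aa) {
  n <- n_rr + n_ra + n_aa
  if (n == 0) return(list(chisq = NA_real_, p = NA_real_))
  p <- (2 * n_rr + n_ra) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  o <- c(n_rr, n_ra, n_aa)
  nz <- e > 0
  chisq <- sum((o[nz] - e[nz])^2 / e[nz])
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Variant quality control
#'
#' Filters applied in order per-variant call rate, MAF, Hardy-Weinberg
#' equilibrium, then imputation quality; a variant is attributed to the first
#' filter it fails, so the per-filter exclusion counts partition the excluded
#' set. A per-sample call-rate threshold is exposed separately
#' (`sample_call_rate_min`) and drops samples before the variant filters run.
#'
#' @param panel a `haplotype_panel`.
#' @param maf_min minimum minor allele frequency (exclusive: MAF < min fails).
#' @param hwe_p_min minimum HWE chi-square p-value.
#' @param call_rate_min minimum per-variant genotype call rate.
#' @param dr2_min minimum imputation quality (NA passes: array-typed data).
#' @param sample_call_rate_min optional per-sample call-rate threshold.
#' @return list(panel, exclusions, samples_dropped).
#' @export
variant_qc <- function(panel, maf_min = 0.05, hwe_p_min = 1e-5,
                       call_rate_min = 0.90, dr2_min = 0.8,
                       sample_call_rate_min = NULL) {
  haps <- panel$haps
  samples_dropped <- character(0)
  if (!is.null(sample_call_rate_min)) {
    n <- length(panel$samples)
    h1 <- haps[seq(1, 2 * n, 2), , drop = FALSE]
    h2 <- haps[seq(2, 2 * n, 2), , drop = FALSE]
    cr <- rowMeans(!is.na(h1) & !is.na(h2))
    bad <- cr < sample_call_rate_min
    if (any(bad)) {
      samples_dropped <- panel$samples[bad]
      keep_rows <- rep(!bad, each = 2)
      panel <- new_haplotype_panel(panel$samples[!bad],
                                   panel$variants, haps[keep_rows, , drop = FALSE])
      haps <- panel$haps
    }
  }
  n <- length(panel$samples)
  h1 <- haps[seq(1, 2 * n, 2), , drop = FALSE]
  h2 <- haps[seq(2, 2 * n, 2), , drop = FALSE]
  ok <- !is.na(h1) & !is.na(h2)
  call_rate <- colMeans(ok)
  dos <- h1 + h2
  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hwe_p <- vapply(seq_len(ncol(dos)), function(j) {
    d <- dos[ok[, j], j]
    hwe_test(sum(d == 0), sum(d == 1), sum(d == 2))$p
  }, numeric(1))
  dr2 <- panel$variants$dr2
  fail_cr <- call_rate < call_rate_min
  fail_maf <- !fail_cr & maf < maf_min
  fail_hwe <- !fail_cr & !fail_maf & !is.na(hwe_p) & hwe_p < hwe_p_min
  fail_dr2 <- !fail_cr & !fail_maf & !fail_hwe & !is.na(dr2) & dr2 <= dr2_min
  keep <- !(fail_cr | fail_maf | fail_hwe | fail_dr2)
  exclusions <- c(call_rate = sum(fail_cr), maf = sum(fail_maf),
                  hwe = sum(fail_hwe), dr2 = sum(fail_dr2))
  out <- panel_subset(panel, which(keep))
  out$variants$maf <- maf[keep]
  list(panel = out, exclusions = exclusions,
       samples_dropped = samples_dropped)
}

#' Filter genes by minimum expression
#'
#' Keeps genes with TPM >= `tpm_min` in at least `ceil(frac_samples * N)`
#' samples (both boundaries inclusive).
#' @param tpm genes x samples non-negative matrix.
#' @param tpm_min TPM threshold.
#' @param frac_samples required fraction of samples at or above the threshold.
#' @return character vector of retained gene ids.
#' @export
filter_expressed_genes <- function(tpm, tpm_min = 0.1, frac_samples = 0.20) {
  if (is.null(dim(tpm)) || !nrow(tpm) || !ncol(tpm))
    stop("empty expression matrix", call. = FALSE)
  if (any(tpm < 0)) stop("TPM values must be non-negative", call. = FALSE)
  need <- ceiling(frac_samples * ncol(tpm))
  keep <- rowSums(tpm >= tpm_min) >= need
  rownames(tpm)[keep]
}
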