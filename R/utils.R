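# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when they cancel numerically
logdiff <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# Derive a reproducible sub-seed from a master seed and a stage label, so
# toggling one stage never shifts another stage's random stream. Kept below
# 2^31 (R integers are 32-bit).
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Membership of 1-based point positions in a 0-based half-open interval set.
# Intervals may overlap; membership means "inside at least one".
points_in_intervals <- function(chrom, pos, track) {
  stopifnot(length(chrom) == length(pos))
  hit <- logical(length(pos))
  iv <- track$intervals
  if (is.null(iv) || !nrow(iv)) return(hit)
  for (cc in unique(chrom)) {
    sel <- which(chrom == cc)
    ivc <- iv[iv$chrom == cc, , drop = FALSE]
    if (!nrow(ivc)) next
    q <- IRanges::IRanges(start = pos[sel], width = 1L)
    s <- IRanges::IRanges(start = ivc$start + 1L, end = ivc$end)
    hit[sel] <- IRanges::overlapsAny(q, s)
  }
  hit
}

# Any-overlap between one 0-based half-open query interval and a track.
interval_overlaps_track <- function(chrom, start, end, track) {
  iv <- track$intervals
  if (is.null(iv) || !nrow(iv)) return(FALSE)
  ivc <- iv[iv$chrom == chrom, , drop = FALSE]
  if (!nrow(ivc)) return(FALSE)
  any(ivc$start < end & ivc$end > start)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be in [%g, %g]", name, lo, hi), call. = FALSE)
  as.numeric(x)
}
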