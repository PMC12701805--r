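# Shared fixtures: small simulated cohorts, cached per test process so the
# expensive ones are built once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# default-size cohort used by most module tests
test_cohort <- function() {
  cached("cohort_default", function() {
    cfg <- sim_config(seed = 101, n_individuals = 250, variants_per_chrom = 1200)
    simulate_cohort(cfg, file.path(tempdir(), "fixture_cohort"))
  })
}

# expression sub-panel of a cohort (samples matched to the TPM columns)
expr_panel <- function(sim) {
  es <- colnames(sim$tpm)
  i <- match(es, sim$panel$samples)
  rows <- as.vector(rbind(2 * i - 1, 2 * i))
  new_haplotype_panel(es, sim$panel$variants, sim$panel$haps[rows, , drop = FALSE])
}

# hand-built tiny phased panel from a haplotype matrix
toy_panel <- function(haps, pos = NULL, chrom = "chr1") {
  m <- ncol(haps)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  v <- data.frame(chrom = chrom, pos = as.integer(pos),
                  id = sprintf("v%03d", seq_len(m)),
                  ref = "A", alt = "G", aa = "A", dr2 = 1,
                  maf = pmin(colMeans(haps), 1 - colMeans(haps)),
                  stringsAsFactors = FALSE)
  new_haplotype_panel(sprintf("s%02d", seq_len(nrow(haps) / 2)), v, haps)
}

# brute-force EHH oracle: average over all carrier pairs of the indicator
# "identical at every marker between core and this marker"
ehh_bruteforce <- function(haps, core, allele, direction) {
  carriers <- which(haps[, core] == allele)
  n <- length(carriers)
  if (n < 2) return(NULL)
  m <- ncol(haps)
  path <- if (direction > 0) seq(core + 1, m) else rev(seq_len(core - 1))
  if (direction > 0 && core == m) path <- integer(0)
  if (direction < 0 && core == 1) path <- integer(0)
  pairs <- utils::combn(carriers, 2)
  out <- numeric(length(path))
  for (k in seq_along(path)) {
    span <- if (direction > 0) (core + 1):path[k] else path[k]:(core - 1)
    ident <- apply(pairs, 2, function(pr)
      all(haps[pr[1], span] == haps[pr[2], span]))
    out[k] <- mean(ident)
  }
  list(path = path, ehh = out)
}

# literal configuration-enumeration oracle for coloc posteriors
coloc_enumerate <- function(bf1, bf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  m <- length(bf1)
  s1 <- 0; s2 <- 0; s12 <- 0; s3 <- 0
  for (i in seq_len(m)) {
    s1 <- s1 + p1 * bf1[i]
    s2 <- s2 + p2 * bf2[i]
    s12 <- s12 + p12 * bf1[i] * bf2[i]
  }
  for (i in seq_len(m)) for (j in seq_len(m)) if (i != j)
    s3 <- s3 + p1 * p2 * bf1[i] * bf2[j]
  tot <- 1 + s1 + s2 + s3 + s12
  c(PP.H0 = 1 / tot, PP.H1 = s1 / tot, PP.H2 = s2 / tot,
    PP.H3 = s3 / tot, PP.H4 = s12 / tot)
}
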