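test_that("a pure CpG repeat is called as one island", {
  s <- paste0(strrep("A", 700), strrep("CG", 300), strrep("A", 700))
  tr <- cgi_scan(c(chr1 = s))
  expect_equal(nrow(tr$intervals), 1)
  iv <- tr$intervals[1, ]
  expect_lt(iv$start, 750)
  expect_gt(iv$end, 1250)
  expect_gte(iv$end - iv$start, 500)
})

test_that("sequence without CpG structure yields no islands", {
  expect_equal(nrow(cgi_scan(c(chr1 = strrep("A", 10000)))$intervals), 0)
  # shorter than one window
  expect_equal(nrow(cgi_scan(c(chr1 = strrep("CG", 100)))$intervals), 0)
})

test_that("island thresholds are inclusive at the GC boundary", {
  # 500-bp block with GC exactly 0.55 and very high ObsCpG/ExpCpG
  block <- paste0(strrep("CG", 137), "G", strrep("T", 225))
  stopifnot(nchar(block) == 500)
  s <- paste0(strrep("T", 500), block, strrep("T", 500))
  tr <- cgi_scan(c(chr1 = s))
  expect_gte(nrow(tr$intervals), 1)
  # drop one G: GC = 0.548 < 0.55 -> no island
  block2 <- paste0(strrep("CG", 137), "T", strrep("T", 225))
  s2 <- paste0(strrep("T", 500), block2, strrep("T", 500))
  expect_equal(nrow(cgi_scan(c(chr1 = s2))$intervals), 0)
})

test_that("called islands satisfy the criteria on independent re-checking", {
  sim <- test_cohort()
  tr <- cgi_scan(c(chr1 = sim$fasta_seq))
  expect_gt(nrow(tr$intervals), 0)
  ch <- strsplit(toupper(sim$fasta_seq), "")[[1]]
  for (i in seq_len(nrow(tr$intervals))) {
    a <- tr$intervals$start[i]; b <- tr$intervals$end[i]
    seg <- ch[(a + 1):b]
    L <- length(seg)
    nC <- sum(seg == "C"); nG <- sum(seg == "G")
    nCG <- sum(seg[-L] == "C" & seg[-1] == "G")
    expect_gte(L, 500)
    expect_gte((nC + nG) / L, 0.55)
    expect_gte(nCG / (nC * nG / L), 0.65)
  }
})

test_that("planted islands are recovered and experimentally supported", {
  sim <- test_cohort()
  tr <- cgi_scan(c(chr1 = sim$fasta_seq))
  truth <- sim$truth$cgi_truth
  # Jaccard between call set and truth set (interval-wise overlap match)
  overlaps <- function(a, b)
    sum(vapply(seq_len(nrow(a)), function(i)
      any(b$start < a$end[i] & b$end > a$start[i]), logical(1)))
  inter <- overlaps(truth, tr$intervals)
  union_n <- nrow(truth) + nrow(tr$intervals) - inter
  expect_gt(inter / union_n, 0.9)
  ecgi <- ecgi_filter(tr, sim$cpg)
  expect_lte(nrow(ecgi$intervals), nrow(tr$intervals))
  expect_gt(nrow(ecgi$intervals) / nrow(tr$intervals), 0.9)
})

test_that("eCGI support rules count sites and samples correctly", {
  ccgi <- new_interval_track("cCGI", data.frame(chrom = "chr1", start = 1000,
                                                end = 1600))
  mk_cpg <- function(n_sites, level, cov = 20) data.frame(
    chrom = "chr1", pos = seq(1100, by = 50, length.out = n_sites),
    coverage = cov, methylated = round(level * cov))
  # only 4 covered sites -> excluded
  expect_equal(nrow(ecgi_filter(ccgi, mk_cpg(4, 0.1))$intervals), 0)
  # 5 sites at coverage exactly 5 ("more than 5x" is strict) -> excluded
  expect_equal(nrow(ecgi_filter(ccgi, mk_cpg(5, 0.1, cov = 5))$intervals), 0)
  # low methylation in one of three samples -> included
  samples <- list(mk_cpg(6, 0.8), mk_cpg(6, 0.1), mk_cpg(6, 0.8))
  expect_equal(nrow(ecgi_filter(ccgi, samples)$intervals), 1)
  # high methylation everywhere -> excluded
  expect_equal(nrow(ecgi_filter(ccgi, mk_cpg(6, 0.8))$intervals), 0)
})

test_that("HMR segmentation recovers a planted hypomethylated block", {
  set.seed(71)
  n <- 200
  pos <- sort(sample.int(2e5, n))
  level <- rep(0.85, n)
  block <- 80:120
  level[block] <- 0.05
  cov <- rpois(n, 20) + 10L
  cpg <- data.frame(chrom = "chr1", pos = pos, coverage = cov,
                    methylated = rbinom(n, cov, level))
  tr <- hmr_call(cpg)
  expect_equal(nrow(tr$intervals), 1)
  # boundaries within +/- 3 CpGs of the planted block
  called_sites <- which(pos > tr$intervals$start[1] & pos <= tr$intervals$end[1])
  expect_lte(abs(min(called_sites) - min(block)), 3)
  expect_lte(abs(max(called_sites) - max(block)), 3)
})

test_that("uniform high methylation yields no HMRs", {
  set.seed(72)
  n <- 150
  cov <- rpois(n, 25) + 10L
  cpg <- data.frame(chrom = "chr1", pos = sort(sample.int(1e5, n)),
                    coverage = cov, methylated = rbinom(n, cov, 0.85))
  expect_equal(nrow(hmr_call(cpg)$intervals), 0)
})

test_that("a methylation desert splits an HMR in two", {
  set.seed(73)
  n <- 120
  pos <- c(sort(sample.int(5e4, 60)), sort(sample.int(5e4, 60)) + 65000L)
  cov <- rpois(n, 25) + 10L
  level <- rep(0.85, n)
  level[41:80] <- 0.05       # hypo block straddling the 15-kb gap
  cpg <- data.frame(chrom = "chr1", pos = pos, coverage = cov,
                    methylated = rbinom(n, cov, level))
  tr <- hmr_call(cpg)
  expect_equal(nrow(tr$intervals), 2)
})

test_that("Baum-Welch log-likelihood is non-decreasing and data rules hold", {
  set.seed(74)
  n <- 160
  cov <- rpois(n, 20) + 10L
  level <- rep(0.8, n); level[50:90] <- 0.1
  cpg <- data.frame(chrom = "chr1", pos = sort(sample.int(1e5, n)),
                    coverage = cov, methylated = rbinom(n, cov, level))
  tr <- hmr_call(cpg)
  ll <- attr(tr, "model")$chr1$loglik
  expect_true(all(diff(ll) > -1e-6))
  # state identity: hypo mean below hyper mean
  ab <- attr(tr, "model")$chr1$ab
  means <- ab[, 1] / rowSums(ab)
  expect_lt(means[1], means[2])
  expect_error(hmr_call(cpg[1:30, ]), "usable CpG")
  # low-coverage sites are dropped before fitting
  cpg2 <- cpg; cpg2$coverage[1:120] <- 5L
  expect_error(hmr_call(cpg2), "usable CpG")
})

test_that("merged multi-sample HMR track is the interval union", {
  t1 <- new_interval_track("a", data.frame(chrom = "chr1",
                                           start = c(100, 500), end = c(300, 700)))
  t2 <- new_interval_track("b", data.frame(chrom = "chr1", start = 250,
                                           end = 550))
  m <- merge_hmr_tracks(list(t1, t2))
  expect_equal(nrow(m$intervals), 1)
  expect_equal(m$intervals$start, 100)
  expect_equal(m$intervals$end, 700)
})
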