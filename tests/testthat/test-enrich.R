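enrich_universe <- function(n = 2000, seed = 61) {
  set.seed(seed)
  data.frame(id = sprintf("v%04d", seq_len(n)), chrom = "chr1",
             pos = sort(sample.int(1e7, n)), maf = runif(n, 0.05, 0.5),
             stringsAsFactors = FALSE)
}

test_that("a track covering everything gives fold 1 and p near 1", {
  tested <- enrich_universe()
  track <- new_interval_track("all", data.frame(chrom = "chr1", start = 0,
                                                end = 1.1e7))
  res <- interval_enrichment(tested$id[1:100], tested, track, n_perm = 200,
                             seed = 1)
  expect_equal(res$fold, 1)
  expect_gt(res$p, 0.9)
})

test_that("constructed enrichment is detected at the permutation floor", {
  tested <- enrich_universe()
  # track covering ~1% of the genome
  track <- new_interval_track("small", data.frame(chrom = "chr1",
                                                  start = 4e6, end = 4.1e6))
  inside <- tested$id[tested$pos > 4e6 & tested$pos <= 4.1e6]
  outside <- setdiff(tested$id, inside)
  k_in <- min(length(inside), 15)
  # candidate set whose inside-rate is 10x the realized background rate
  bg <- length(inside) / nrow(tested)
  n_out <- round(k_in / (10 * bg)) - k_in
  set.seed(62)
  cand <- c(inside[seq_len(k_in)], sample(outside, n_out))
  res <- interval_enrichment(cand, tested, track, n_perm = 500, seed = 2,
                             maf_match = FALSE)
  expect_gt(res$fold, 7)
  expect_lt(res$fold, 13)
  expect_equal(res$p, 1 / 501)
})

test_that("enrichment p-values are uniform for random candidate sets", {
  tested <- enrich_universe(1000)
  track <- new_interval_track("t", data.frame(chrom = "chr1",
                                              start = c(1e6, 6e6),
                                              end = c(2e6, 7e6)))
  set.seed(63)
  pvals <- vapply(1:150, function(r) {
    cand <- sample(tested$id, 50)
    interval_enrichment(cand, tested, track, n_perm = 200, seed = 1000 + r,
                        maf_match = FALSE)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
  expect_true(all(pvals >= 1 / 201))
})

test_that("eVariant-set enrichment mirrors the interval engine", {
  tested <- enrich_universe(800)
  # annotation = every tested variant -> fold exactly 1
  res <- gwas_in_eqtl_enrichment(tested$id[1:40], tested, tested$id,
                                 n_perm = 100, seed = 3)
  expect_equal(res$fold, 1)
  # candidates that are the planted eVariants -> floor p
  ev <- tested$id[1:60]
  res2 <- gwas_in_eqtl_enrichment(ev[1:40], tested, ev, n_perm = 400,
                                  seed = 4, maf_match = FALSE)
  expect_equal(res2$p, 1 / 401)
  expect_gt(res2$fold, 5)
  # disjoint sets: depleted or null
  res3 <- gwas_in_eqtl_enrichment(tested$id[700:760], tested, ev,
                                  n_perm = 400, seed = 5, maf_match = FALSE)
  expect_true(is.na(res3$fold) || res3$fold < 1 || res3$p > 0.05)
})

test_that("fold estimates are stable in the number of permutations", {
  tested <- enrich_universe(1000)
  track <- new_interval_track("t", data.frame(chrom = "chr1", start = 2e6,
                                              end = 4e6))
  cand <- tested$id[tested$pos > 2e6 & tested$pos <= 3.5e6][1:50]
  r1 <- interval_enrichment(cand, tested, track, n_perm = 500, seed = 6)
  r2 <- interval_enrichment(cand, tested, track, n_perm = 1000, seed = 7)
  expect_lt(abs(r1$fold - r2$fold) / r1$fold, 0.05)
})

test_that("TAD co-occurrence: degenerate, planted, and random cases", {
  tested <- enrich_universe(1500, seed = 65)
  gm <- data.frame(gene = paste0("g", 1:40), chrom = "chr1",
                   tss = sort(sample.int(1e7, 40)))
  # whole-chromosome TAD: everything co-occurs, p ~ 1
  tad_all <- new_interval_track("tad", data.frame(chrom = "chr1", start = 0,
                                                  end = 1.1e7))
  prs <- data.frame(gene = gm$gene[1:10],
                    variant = vapply(1:10, function(i)
                      tested$id[which.min(abs(tested$pos - gm$tss[i] - 5e4))],
                      character(1)))
  res_all <- tad_cooccurrence(prs, gm, tested, tad_all, n_perm = 200, seed = 8)
  expect_equal(res_all$observed, 1)
  expect_gt(res_all$p, 0.9)
  # TADs covering ~10% of the genome, pairs planted inside them
  edges <- seq(0, 1e7, by = 5e5)
  tads <- new_interval_track("tad", data.frame(chrom = "chr1",
                                               start = edges[-length(edges)],
                                               end = edges[-length(edges)] + 5e4))
  in_tad <- function(pos) any(pos > tads$intervals$start &
                              pos <= tads$intervals$end)
  g_in <- which(vapply(gm$tss, in_tad, logical(1)))
  prs2 <- do.call(rbind, lapply(g_in, function(i) {
    iv <- tads$intervals[gm$tss[i] > tads$intervals$start &
                         gm$tss[i] <= tads$intervals$end, ][1, ]
    vs <- tested[tested$pos > iv$start & tested$pos <= iv$end, ]
    if (!nrow(vs)) return(NULL)
    data.frame(gene = gm$gene[i], variant = vs$id[which.min(abs(vs$pos - gm$tss[i]))])
  }))
  if (!is.null(prs2) && nrow(prs2) >= 5) {
    res2 <- tad_cooccurrence(prs2, gm, tested, tads, n_perm = 300, seed = 9)
    expect_equal(res2$observed, 1)
    expect_lte(res2$p, 0.05)
  }
  # random pairing: observed within the central mass of its own null
  set.seed(66)
  prs3 <- data.frame(gene = sample(gm$gene, 12),
                     variant = sample(tested$id, 12))
  res3 <- tad_cooccurrence(prs3, gm, tested, tads, n_perm = 300, seed = 10)
  qs <- quantile(res3$null, c(0.025, 0.975))
  expect_gte(res3$observed, qs[1] - 1e-9)
  expect_lte(res3$observed, qs[2] + 1 / 12 + 1e-9)
})
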