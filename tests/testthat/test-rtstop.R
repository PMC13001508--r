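test_that("seed detection respects the threshold and the 5' exclusion zone", {
  track <- rep(0, 200)
  expect_equal(length(find_seeds(track)), 0L)
  track[10] <- 100  # inside the promoter pileup zone
  track[30] <- 6
  track[40] <- 5
  expect_equal(find_seeds(track), 30L)
})

test_that("peak assembly enforces 3-nt width and 2-of-3 support", {
  track <- rep(0, 200)
  track[29:31] <- c(0, 6, 2)
  pk <- peaks_from_seeds(find_seeds(track), track)
  expect_equal(pk[, c("start", "end")], data.frame(start = 29L, end = 31L))
  # an isolated seed with empty neighbors is dropped
  track2 <- rep(0, 200)
  track2[50] <- 10
  expect_equal(nrow(peaks_from_seeds(find_seeds(track2), track2)), 0L)
  # nearby seeds: the stronger one claims the window, the other is absorbed
  track3 <- rep(0, 200)
  track3[30] <- 20
  track3[32] <- 8
  track3[c(29, 31, 33)] <- 1
  pk3 <- peaks_from_seeds(find_seeds(track3), track3)
  expect_equal(nrow(pk3), 1L)
  expect_equal(pk3$center, 30L)
  # peaks are clipped away from the promoter zone and the construct end
  track4 <- rep(0, 200)
  track4[19] <- 9
  track4[20] <- 1
  pk4 <- peaks_from_seeds(find_seeds(track4), track4)
  expect_equal(pk4$start, 19L)
  expect_true(all(pk4$start >= 19L))
})

test_that("condition peak merging deduplicates and recenters", {
  comb <- rep(0, 200)
  comb[29:32] <- c(3, 5, 8, 2)
  same <- data.frame(start = 29L, end = 31L, center = 30L, reads = 10)
  m1 <- merge_condition_peaks(same, same, comb)
  expect_equal(nrow(m1), 1L)
  shifted <- data.frame(start = 30L, end = 32L, center = 31L, reads = 9)
  m2 <- merge_condition_peaks(same, shifted, comb)
  expect_equal(nrow(m2), 1L)
  expect_equal(c(m2$start, m2$end), c(30L, 32L))  # centered on max at 31
  far <- data.frame(start = 60L, end = 62L, center = 61L, reads = 5)
  m3 <- merge_condition_peaks(same, far, comb)
  expect_equal(nrow(m3), 2L)
})

test_that("construct filtering removes low and condition-variable totals", {
  cond <- rep(c("KCl", "NaCl"), each = 3)
  totals <- rbind(
    ok = c(1000, 1100, 900, 1050, 950, 1000),
    low = c(50, 60, 40, 55, 45, 50),
    variable = c(4000, 4200, 3800, 1000, 950, 1050))
  kept <- filter_constructs(totals, cond)
  expect_true("ok" %in% kept)
  expect_false("low" %in% kept)
  expect_false("variable" %in% kept)
  # the literal lessAbs mode flags the *stable* constructs instead
  kept_lit <- filter_constructs(totals, cond,
                                variability = "literal_lessAbs")
  expect_false("ok" %in% kept_lit)
  expect_true("variable" %in% kept_lit)
})

test_that("differential test calls strong KCl-specific stops as rG4", {
  set.seed(101)
  cond <- rep(c("KCl", "NaCl"), each = 3)
  n_sim <- 200
  calls <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    k <- cbind(matrix(rnbinom(3 * 30, mu = 50, size = 10), 30, 3),
               matrix(rnbinom(3 * 30, mu = 5, size = 10), 30, 3))
    rownames(k) <- sprintf("p%02d", 1:30)
    res <- differential_rg4_test(k, cond, sf = rep(1, 6))
    calls[i] <- res$is_rg4[1L]
  }
  expect_gte(mean(calls), 0.95)
})

test_that("differential test controls false calls under the null", {
  set.seed(202)
  cond <- rep(c("KCl", "NaCl"), each = 3)
  null_calls <- replicate(25, {
    k <- matrix(rnbinom(6 * 40, mu = 30, size = 10), 40, 6)
    rownames(k) <- sprintf("p%02d", 1:40)
    res <- differential_rg4_test(k, cond, sf = rep(1, 6))
    res$is_rg4
  })
  expect_lte(mean(null_calls), 0.05)
})

test_that("the sign rule rejects NaCl-enriched peaks", {
  set.seed(7)
  cond <- rep(c("KCl", "NaCl"), each = 3)
  k <- cbind(matrix(rnbinom(3 * 20, mu = 5, size = 10), 20, 3),
             matrix(rnbinom(3 * 20, mu = 80, size = 10), 20, 3))
  rownames(k) <- sprintf("p%02d", 1:20)
  res <- differential_rg4_test(k, cond, sf = rep(1, 6))
  expect_false(any(res$is_rg4))
  # an all-zero peak is not tested
  k[1, ] <- 0
  res0 <- differential_rg4_test(k, cond, sf = rep(1, 6))
  expect_true(is.na(res0$padj[1L]))
})

test_that("fold-change estimates agree with DESeq2 on a shared fixture", {
  skip_if_not_installed("DESeq2")
  set.seed(55)
  cond <- rep(c("KCl", "NaCl"), each = 3)
  mu_nacl <- rep(c(rep(8, 20), rep(60, 40)), 3)  # peaks 1-20 lose signal
  k <- cbind(matrix(rnbinom(3 * 60, mu = 60, size = 8), 60, 3),
             matrix(rnbinom(3 * 60, mu = mu_nacl, size = 8), 60, 3))
  rownames(k) <- sprintf("p%02d", 1:60)
  ours <- differential_rg4_test(k, cond, sf = rep(1, 6))
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = k,
    colData = data.frame(condition = factor(cond, c("KCl", "NaCl"))),
    design = ~condition)
  DESeq2::sizeFactors(dds) <- rep(1, 6)
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  ref <- DESeq2::results(dds, contrast = c("condition", "NaCl", "KCl"))
  expect_gt(cor(ours$l2fc, ref$log2FoldChange), 0.98)
  # significance decisions largely coincide for the strong effects
  strong <- which(!is.na(ref$padj) & ref$padj < 0.01 &
                    ref$log2FoldChange < -1)
  expect_gt(length(strong), 5L)
  expect_gt(mean(ours$is_rg4[strong]), 0.9)
})

test_that("region classification follows the 2-of-4 / zero-tolerance rule", {
  flags <- data.frame(
    construct_id = sprintf("c%d", 1:12),
    region_id = rep(c("r1", "r2", "r3"), each = 4),
    is_rg4 = c(TRUE, TRUE, FALSE, FALSE,
               TRUE, FALSE, FALSE, FALSE,
               FALSE, FALSE, FALSE, FALSE),
    total_reads = c(10, 90, 20, 30, 50, 60, 10, 5, 1, 2, 3, 100))
  cls <- classify_regions(flags)
  expect_equal(cls$status, c("rG4", "inconsistent", "non_rG4"))
  expect_equal(cls$representative_construct, c("c2", "c6", "c12"))
})

test_that("propensity scores follow their ratio definitions", {
  p1 <- propensity(peak_reads = 20, total_reads = 100, rg4_flags = TRUE)
  expect_equal(p1$ratios, 0.2)
  expect_equal(p1$total_construct_ratio, 0.2)
  p2 <- propensity(c(20, 10), 100, c(TRUE, TRUE))
  expect_equal(p2$g4_propensity, 0.3)
  expect_equal(p2$total_construct_ratio, 0.15)
  expect_equal(p2$representative_peak, 1L)
  p0 <- propensity(numeric(0), 100, logical(0))
  expect_equal(p0$g4_propensity, 0)
  pna <- propensity(c(5, 5), 0, c(TRUE, FALSE))
  expect_true(is.na(pna$g4_propensity))
  # ratios are invariant to uniform count scaling
  p3 <- propensity(c(200, 100), 1000, c(TRUE, TRUE))
  expect_equal(p3$ratios, p2$ratios)
})

test_that("the end-to-end pipeline recovers planted rG4 regions", {
  cfg <- sim_config(seed = 17, n_regions = 40, stall_intensity = 30)
  lib <- gen_oligo_library(cfg)
  kcl <- gen_rtstop_counts(lib, cfg, "KCl_GTP")
  nacl <- gen_rtstop_counts(lib, cfg, "NaCl_GTP")
  counts <- array(c(kcl, nacl),
                  dim = c(dim(kcl)[1:2], dim(kcl)[3] + dim(nacl)[3]),
                  dimnames = list(dimnames(kcl)[[1]], NULL,
                                  c(dimnames(kcl)[[3]], dimnames(nacl)[[3]])))
  res <- rtstop_pipeline(counts, lib$manifest)
  truth <- unique(lib$manifest[, c("region_id", "has_rg4")])
  m <- merge(res$regions, truth, by = "region_id")
  sens <- mean(m$status[m$has_rg4] == "rG4")
  fpr <- mean(m$status[!m$has_rg4] == "rG4")
  expect_gte(sens, 0.9)
  expect_lte(fpr, 0.05)
})

test_that("the pipeline makes no rG4 calls under the null generator", {
  cfg <- sim_config(seed = 23, n_regions = 30, stall_intensity = 0)
  lib <- gen_oligo_library(cfg)
  kcl <- gen_rtstop_counts(lib, cfg, "KCl_GTP")
  nacl <- gen_rtstop_counts(lib, cfg, "NaCl_GTP")
  counts <- array(c(kcl, nacl),
                  dim = c(dim(kcl)[1:2], 6),
                  dimnames = list(dimnames(kcl)[[1]], NULL,
                                  c(dimnames(kcl)[[3]], dimnames(nacl)[[3]])))
  res <- rtstop_pipeline(counts, lib$manifest)
  expect_lte(mean(res$regions$status == "rG4"), 0.05)
})
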