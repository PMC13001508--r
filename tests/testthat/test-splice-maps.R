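# one plus-strand and one minus-strand cassette event on a toy contig
toy_events <- data.frame(
  event_id = c("ev_plus", "ev_minus"),
  contig = "chr_t",
  strand = c("+", "-"),
  up_start = c(101L, 2101L), up_end = c(200L, 2200L),
  cass_start = c(401L, 1801L), cass_end = c(480L, 1880L),
  down_start = c(701L, 1501L), down_end = c(800L, 1600L),
  psi = c(0.5, 0.5), group = "control",
  stringsAsFactors = FALSE)

test_that("window extraction normalizes and orients correctly", {
  track <- rep(0, 3000)
  track[151:400] <- 2             # flat baseline across the whole window
  track[201:203] <- c(2, 4, 6)    # intron positions +1..+3 after the 5'ss
  profs <- extract_profiles(toy_events[1, ], list(chr_t = track))
  p <- profs$upstream_5ss["ev_plus", ]
  # min-max over the window maps the baseline to 0 and the peak to 1
  expect_equal(unname(p[c("1", "2", "3")]), c(0, 0.5, 1))
  expect_true(all(p[setdiff(colnames(profs$upstream_5ss),
                            c("1", "2", "3"))] == 0, na.rm = TRUE))
  # an all-zero window maps to all zeros, not NaN
  expect_true(all(profs$cassette_5ss["ev_plus", ] == 0, na.rm = TRUE))
})

test_that("minus-strand windows are reported in transcript orientation", {
  track <- rep(0, 3000)
  # minus-strand event: upstream 5'ss sits at genomic position 2101 and
  # its intron runs leftward; transcript-intron positions +1,+2,+3 are
  # genomic 2100, 2099, 2098
  track[c(2100, 2099, 2098)] <- c(3, 6, 9)
  profs <- extract_profiles(toy_events[2, ], list(chr_t = track))
  p <- profs$upstream_5ss["ev_minus", ]
  expect_equal(unname(p[c("1", "2", "3")]), c(1 / 3, 2 / 3, 1))
})

test_that("normalization is scale-invariant and windows truncate", {
  track <- rep(0, 3000)
  set.seed(2)
  track[201:400] <- rpois(200, 3)
  p1 <- extract_profiles(toy_events[1, ], list(chr_t = track))
  track10 <- track * 10
  p2 <- extract_profiles(toy_events[1, ], list(chr_t = track10))
  expect_equal(p1, p2)
  # intron is 200 nt, so intron positions beyond 200 are NA
  up <- p1$upstream_5ss["ev_plus", ]
  expect_true(all(is.na(up[as.character(201:300)])))
  # unknown contig is skipped with a warning
  bad <- toy_events[1, ]
  bad$contig <- "chr_missing"
  expect_warning(extract_profiles(bad, list(chr_t = track)), "skipped")
})

test_that("meta-profile aggregation averages then smooths", {
  m <- matrix(rep(c(0, 0.2, 0.9, 0.2, 0), each = 4), nrow = 4)
  colnames(m) <- 1:5
  prof <- aggregate_smooth(m, span = 0.9)
  expect_equal(prof$mean, c(0, 0.2, 0.9, 0.2, 0))
  # smoothing a constant curve changes nothing
  cm <- matrix(0.4, 3, 30, dimnames = list(NULL, 1:30))
  pc <- aggregate_smooth(cm, span = 0.3)
  expect_equal(pc$smoothed, rep(0.4, 30), tolerance = 1e-9)
  expect_error(aggregate_smooth(cm[1, , drop = FALSE]), "2 events")
})

test_that("a planted intronic enrichment surfaces in the smoothed map", {
  set.seed(33)
  n_ev <- 30
  width <- 350
  m <- matrix(runif(n_ev * width, 0, 0.2), n_ev, width)
  m[, 71:100] <- m[, 71:100] + 0.6  # intron positions +21..+50
  colnames(m) <- c(-50:-1, 1:300)
  prof <- aggregate_smooth(m, span = 0.15)
  peak_at <- prof$position[which.max(prof$smoothed)]
  expect_gte(peak_at, 21)
  expect_lte(peak_at, 50)
})

test_that("PSI-matched control sampling matches the target distribution", {
  set.seed(4)
  target <- rbeta(200, 0.7, 2)
  controls <- runif(2000)  # deliberately mismatched but covering pool
  # the lowest target-PSI bin is deliberately narrow, so replacement
  # sampling warnings are expected here
  idx <- suppressWarnings(sample_matched_controls(controls, target, seed = 9))
  expect_equal(length(idx), 4 * ceiling(200 / 4))
  d_matched <- suppressWarnings(
    ks.test(controls[idx], target)$statistic)
  d_naive <- suppressWarnings(
    ks.test(sample(controls, length(idx)), target)$statistic)
  expect_lt(d_matched, d_naive)
  # reproducibility and the stated quantile sets
  idx2 <- suppressWarnings(sample_matched_controls(controls, target, seed = 9))
  expect_identical(idx, idx2)
  idx_rep <- suppressWarnings(
    sample_matched_controls(controls, target,
                            probs = c(0, 0.10, 0.65, 0.90, 1), seed = 9))
  expect_false(identical(idx, idx_rep))
  # an undersized bin falls back to sampling with replacement
  w <- capture_warnings(
    sample_matched_controls(c(0.01, 0.99), target, seed = 1))
  expect_true(any(grepl("replacement", w)))
})

test_that("window testing flags planted differences and only those", {
  set.seed(5)
  n_ev <- 40
  width <- 120
  base <- function() matrix(runif(n_ev * width, 0, 0.4), n_ev, width,
                            dimnames = list(NULL, 1:width))
  target <- base()
  control <- base()
  target[, 61:90] <- target[, 61:90] * 3  # planted enrichment
  res <- window_test(target, control)
  expect_true(any(res$significant))
  sig <- res[res$significant, ]
  expect_true(all(sig$end >= 55 & sig$start <= 95))
  # identical inputs produce no significant windows at all
  res0 <- window_test(target, target)
  expect_false(any(res0$significant))
  expect_true(all(res0$p == 1 | is.na(res0$p) | res0$p > 0.9))
})

test_that("the window test holds its false discovery rate under the null", {
  set.seed(6)
  n_sig <- replicate(50, {
    t <- matrix(runif(25 * 80, 0, 0.4), 25, 80, dimnames = list(NULL, 1:80))
    c <- matrix(runif(25 * 80, 0, 0.4), 25, 80, dimnames = list(NULL, 1:80))
    mean(window_test(t, c)$significant)
  })
  expect_lte(mean(n_sig), 0.02)
})

test_that("junction PSI follows the count-threshold rules", {
  expect_equal(junction_psi(20, 10), 20 / 30, tolerance = 1e-9)
  expect_true(is.na(junction_psi(10, 10)))
  expect_equal(junction_psi(c(20, 10), c(10, 10)),
               c(20 / 30, NA_real_))
  expect_equal(junction_psi_nmd(10, 10, 5), 20 / 30, tolerance = 1e-9)
  expect_true(is.na(junction_psi_nmd(5, 5, 2)))
  # within range and monotone in inclusion counts
  psi <- junction_psi(seq(0, 100, 10), 50)
  psi <- psi[!is.na(psi)]
  expect_true(all(psi >= 0 & psi <= 1))
  expect_true(all(diff(psi) > 0))
})
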