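#' Seed positions of reverse-transcriptase stops
#'
#' Positions on a 200-nt construct with at least \code{min_count} stacked
#' read starts in the replicate-summed track of one buffer condition. The
#' first 18 nt (the T7 promoter, where full-length cDNAs of unstructured
#' constructs pile up) are excluded from the search.
#'
#' @param track numeric vector of replicate-summed read starts per
#'   position (1-based).
#' @param min_count seed threshold (default 6).
#' @param exclude_5prime number of 5'-terminal positions excluded
#'   (default 18).
#' @return Integer vector of seed positions.
#' @export
find_seeds <- function(track, min_count = 6, exclude_5prime = 18L) {
  stopifnot(is.numeric(track))
  pos <- which(track >= min_count)
  pos[pos > exclude_5prime]
}

#' Assemble 3-nt RTstop peaks from seed positions
#'
#' Seeds are processed in order of descending signal (leftmost first on
#' ties); each seed claims the 3-nt window centered on it, shifted inward
#' where necessary so that peaks never start before position
#' \code{exclude_5prime + 1} nor run past the construct end. A window
#' overlapping an already-placed peak is absorbed; a window is kept only
#' if at least \code{min_support} of its 3 positions carry read starts.
#'
#' @param seeds seed positions from [find_seeds()].
#' @param track replicate-summed read-start counts.
#' @param min_support minimal covered positions per window (default 2).
#' @param exclude_5prime as in [find_seeds()].
#' @return Data frame of peaks: \code{start}, \code{end}, \code{center},
#'   \code{reads} (summed read starts in the window).
#' @export
peaks_from_seeds <- function(seeds, track, min_support = 2L,
                             exclude_5prime = 18L) {
  n <- length(track)
  if (length(seeds) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      center = integer(0), reads = numeric(0)))
  }
  seeds <- seeds[order(-track[seeds], seeds)]
  occupied <- logical(n)
  out <- list()
  for (s in seeds) {
    start <- max(exclude_5prime + 1L, s - 1L)
    start <- min(start, n - 2L)
    win <- seq.int(start, start + 2L)
    if (any(occupied[win])) next
    if (sum(track[win] > 0) < min_support) next
    occupied[win] <- TRUE
    out[[length(out) + 1L]] <-
      data.frame(start = start, end = start + 2L, center = start + 1L,
                 reads = sum(track[win]))
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      center = integer(0), reads = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Merge RTstop peaks called in the KCl and NaCl conditions
#'
#' Identical peaks are deduplicated. Partially overlapping peaks are
#' replaced by a single 3-nt peak centered on the position of maximal
#' combined (KCl + NaCl) coverage within their union (leftmost on ties).
#'
#' @param peaks_kcl,peaks_nacl peak data frames from
#'   [peaks_from_seeds()].
#' @param combined_track numeric vector of KCl + NaCl summed read starts.
#' @param exclude_5prime lower bound for peak starts (default 18).
#' @return Unified, non-overlapping peak data frame with \code{start},
#'   \code{end}, \code{center}.
#' @export
merge_condition_peaks <- function(peaks_kcl, peaks_nacl, combined_track,
                                  exclude_5prime = 18L) {
  pk <- rbind(peaks_kcl[, c("start", "end"), drop = FALSE],
              peaks_nacl[, c("start", "end"), drop = FALSE])
  pk <- unique(pk)
  pk <- pk[order(pk$start), , drop = FALSE]
  n <- length(combined_track)
  for (iter in seq_len(10L)) {
    if (nrow(pk) < 2L) break
    overl <- which(pk$start[-1L] <= pk$end[-nrow(pk)])
    if (length(overl) == 0L) break
    i <- overl[1L]
    u <- seq.int(pk$start[i], max(pk$end[i], pk$end[i + 1L]))
    ctr <- u[which.max(combined_track[u])]
    start <- min(max(exclude_5prime + 1L, ctr - 1L), n - 2L)
    merged <- data.frame(start = start, end = start + 2L)
    pk <- rbind(pk[seq_len(i - 1L), , drop = FALSE], merged,
                pk[-seq_len(i + 1L), , drop = FALSE])
    pk <- unique(pk[order(pk$start), , drop = FALSE])
  }
  if (nrow(pk) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      center = integer(0)))
  }
  pk$center <- pk$start + 1L
  rownames(pk) <- NULL
  pk
}

#' Median-of-ratios size factors
#'
#' @param counts matrix of totals (features x samples).
#' @return Numeric vector of one size factor per sample.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts))
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use)) return(rep(1, ncol(counts)))
  apply(counts[use, , drop = FALSE], 2L, function(cnts) {
    exp(stats::median(log(cnts) - loggeo[use]))
  })
}

# Normal-approximation Wald test of a log2 fold change between two groups
# of NB counts, with a method-of-moments dispersion (floored).
.nb_l2fc <- function(k1, k2, sf1, sf2, disp_floor = 0.01) {
  x1 <- k1 / sf1
  x2 <- k2 / sf2
  mu1 <- mean(x1)
  mu2 <- mean(x2)
  mom <- function(x, mu) if (mu <= 0) NA_real_ else (stats::var(x) - mu) / mu^2
  a <- c(mom(x1, mu1), mom(x2, mu2))
  alpha <- max(disp_floor, mean(a[is.finite(a)], na.rm = TRUE), na.rm = TRUE)
  ps <- 0.5
  l2fc <- log2((mu2 + ps) / (mu1 + ps))
  vlog <- function(mu, n) (1 / (mu + ps) + alpha) / n
  se <- sqrt(vlog(mu1, length(k1)) + vlog(mu2, length(k2))) / log(2)
  c(l2fc = l2fc, se = se, mu1 = mu1, mu2 = mu2)
}

#' Quality filters for library constructs
#'
#' Removes (1) lowly covered constructs, with fewer than
#' \code{min_normalized} normalized reads on average (median-of-ratios
#' size factors across all samples), and (2) constructs whose total read
#' count differs strongly between the buffer conditions. Under the default
#' intent-based filter a construct is excluded when its between-condition
#' |log2 fold change| is significantly above 1 (BH-adjusted p < 0.05);
#' \code{variability = "literal_lessAbs"} instead excludes constructs
#' significant for |L2FC| < 1, reproducing the literal lessAbs behavior
#' (which flags the stable constructs).
#'
#' @param totals matrix of per-construct total counts
#'   (constructs x samples), with rownames.
#' @param condition factor/character of sample conditions
#'   (\code{"KCl"} / \code{"NaCl"}).
#' @param min_normalized expression cutoff (default 100).
#' @param variability \code{"intent"} (default) or
#'   \code{"literal_lessAbs"}.
#' @param alpha significance level of the variability filter.
#' @return Character vector of retained construct ids.
#' @export
filter_constructs <- function(totals, condition, min_normalized = 100,
                              variability = c("intent", "literal_lessAbs"),
                              alpha = 0.05) {
  variability <- match.arg(variability)
  stopifnot(is.matrix(totals), !is.null(rownames(totals)),
            length(condition) == ncol(totals))
  sf <- size_factors(totals)
  norm <- sweep(totals, 2L, sf, "/")
  expressed <- rowMeans(norm) >= min_normalized
  grp1 <- condition == condition[1L]
  stat <- t(apply(totals, 1L, function(k) {
    .nb_l2fc(k[grp1], k[!grp1], sf[grp1], sf[!grp1])
  }))
  l2fc <- stat[, "l2fc"]
  se <- stat[, "se"]
  if (variability == "intent") {
    # H0: |l2fc| <= 1 -- significance marks high variability
    z <- (abs(l2fc) - 1) / se
    p <- stats::pnorm(z, lower.tail = FALSE)
    variable <- stats::p.adjust(p, "BH") < alpha
  } else {
    # H0: |l2fc| >= 1 -- significance marks stability (literal behavior)
    p <- pmax(stats::pnorm((l2fc - 1) / se),
              stats::pnorm((l2fc + 1) / se, lower.tail = FALSE))
    variable <- stats::p.adjust(p, "BH") < alpha
  }
  rownames(totals)[expressed & !variable]
}

#' Differential RTstop test (NaCl vs KCl) at peak level
#'
#' A self-contained negative-binomial Wald test of the read-start counts
#' within each peak: size-factor-normalized means per condition, a
#' method-of-moments dispersion with a floor, a Wald z on the log2 fold
#' change (NaCl relative to KCl), Benjamini-Hochberg correction, and
#' empirical-Bayes shrinkage of the fold changes toward 0 with a normal
#' prior whose variance is estimated from the cross-peak L2FC
#' distribution. A peak is called an rG4 when its adjusted p value is
#' below \code{alpha} and its shrunken L2FC is negative (signal lost in
#' NaCl, where the quadruplex cannot fold).
#'
#' @param peak_counts matrix of in-peak read-start counts
#'   (peaks x samples) with rownames.
#' @param condition sample conditions (\code{"KCl"} / \code{"NaCl"}).
#' @param sf size factors (typically from construct totals); defaults to
#'   median-of-ratios on \code{peak_counts}.
#' @param alpha significance level (default 0.05).
#' @param disp_floor dispersion floor (default 0.01).
#' @return Data frame with one row per peak: \code{l2fc}, \code{se},
#'   \code{shrunken_l2fc}, \code{pvalue}, \code{padj}, \code{is_rg4}.
#'   All-zero peaks are not tested (all statistics \code{NA}).
#' @export
differential_rg4_test <- function(peak_counts, condition, sf = NULL,
                                  alpha = 0.05, disp_floor = 0.01) {
  stopifnot(is.matrix(peak_counts), length(condition) == ncol(peak_counts))
  kcl <- condition == "KCl"
  nacl <- condition == "NaCl"
  if (sum(kcl) < 2L || sum(nacl) < 2L) {
    stop("need at least 2 replicates per condition")
  }
  if (is.null(sf)) sf <- size_factors(peak_counts)
  testable <- rowSums(peak_counts) > 0
  l2fc <- se <- rep(NA_real_, nrow(peak_counts))
  for (i in which(testable)) {
    st <- .nb_l2fc(peak_counts[i, kcl], peak_counts[i, nacl],
                   sf[kcl], sf[nacl], disp_floor)
    l2fc[i] <- st[["l2fc"]]
    se[i] <- st[["se"]]
  }
  z <- l2fc / se
  p <- 2 * stats::pnorm(-abs(z))
  padj <- rep(NA_real_, length(p))
  padj[testable] <- stats::p.adjust(p[testable], "BH")
  ok <- testable & is.finite(l2fc) & is.finite(se)
  # normal prior centered at 0: its variance is the excess of the
  # zero-centered second moment of the observed fold changes over the
  # average sampling variance
  tau2 <- max(0, mean(l2fc[ok]^2) - mean(se[ok]^2))
  shrunken <- l2fc * tau2 / (tau2 + se^2)
  out <- data.frame(l2fc = l2fc, se = se, shrunken_l2fc = shrunken,
                    pvalue = p, padj = padj,
                    is_rg4 = !is.na(padj) & padj < alpha & shrunken < 0)
  rownames(out) <- rownames(peak_counts)
  out
}

#' Classify 4-barcode transcript regions
#'
#' Each transcript region is represented by up to four barcoded
#' constructs. Regions with two or more rG4-containing constructs are
#' classified \code{"rG4"}; regions with none are \code{"non_rG4"};
#' a region with exactly one rG4-containing construct is
#' \code{"inconsistent"} (a non-rG4 verdict tolerates no rG4-flagged
#' construct). The construct with the highest read count is recorded as
#' the region's representative.
#'
#' @param flags data frame with columns \code{construct_id},
#'   \code{region_id}, \code{is_rg4} (logical) and \code{total_reads}.
#' @return Data frame with one row per region: \code{region_id},
#'   \code{status}, \code{n_rg4_constructs}, \code{n_constructs},
#'   \code{representative_construct}.
#' @export
classify_regions <- function(flags) {
  stopifnot(all(c("construct_id", "region_id", "is_rg4", "total_reads")
                %in% names(flags)))
  ids <- unique(flags$region_id)
  rows <- lapply(ids, function(r) {
    d <- flags[flags$region_id == r, , drop = FALSE]
    n_rg4 <- sum(d$is_rg4, na.rm = TRUE)
    status <- if (nrow(d) == 0L) "unclassified"
      else if (n_rg4 >= 2L) "rG4"
      else if (n_rg4 == 0L) "non_rG4"
      else "inconsistent"
    data.frame(region_id = r, status = status, n_rg4_constructs = n_rg4,
               n_constructs = nrow(d),
               representative_construct =
                 d$construct_id[which.max(d$total_reads)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' rG4 propensity scores of a construct
#'
#' Each peak's ratio is its read starts divided by the total reads on the
#' construct. The representative peak is the rG4 peak with the highest
#' ratio; the G4 propensity is the sum of ratios over rG4 peaks; the total
#' construct ratio is that sum divided by the number of called peaks.
#'
#' @param peak_reads read starts within each called peak.
#' @param total_reads total reads on the construct.
#' @param rg4_flags logical, which peaks were called rG4.
#' @return List with \code{ratios}, \code{representative_peak} (index into
#'   the peak vector, or \code{NA}), \code{g4_propensity} and
#'   \code{total_construct_ratio}. With no peaks all scores are 0; with
#'   zero total reads the scores are \code{NA}.
#' @export
propensity <- function(peak_reads, total_reads, rg4_flags) {
  if (length(peak_reads) == 0L) {
    return(list(ratios = numeric(0), representative_peak = NA_integer_,
                g4_propensity = 0, total_construct_ratio = 0))
  }
  stopifnot(length(rg4_flags) == length(peak_reads))
  if (is.na(total_reads) || total_reads <= 0) {
    return(list(ratios = rep(NA_real_, length(peak_reads)),
                representative_peak = NA_integer_,
                g4_propensity = NA_real_, total_construct_ratio = NA_real_))
  }
  ratios <- peak_reads / total_reads
  rep_peak <- if (any(rg4_flags)) which(rg4_flags)[which.max(ratios[rg4_flags])]
              else NA_integer_
  g4 <- sum(ratios[rg4_flags])
  list(ratios = ratios, representative_peak = rep_peak,
       g4_propensity = g4,
       total_construct_ratio = g4 / length(peak_reads))
}

#' End-to-end RTstop rG4 pipeline on a count array
#'
#' Glues the caller together for a whole library: per construct, replicate
#' sums per condition feed the seed search and peak assembly, peaks from
#' both conditions are merged, constructs are quality-filtered on their
#' totals, the peak-level differential test flags rG4 peaks, and the
#' 4-barcode regions are classified.
#'
#' @param counts 3-dimensional array \code{[construct, position, sample]}
#'   with dimnames; sample names must start with the condition
#'   (\code{"KCl"} / \code{"NaCl"}), e.g. \code{"KCl_1"}.
#' @param manifest data frame with columns \code{construct_id},
#'   \code{region_id}.
#' @param min_normalized,alpha passed to the filter and test.
#' @return List with \code{peaks} (per-construct merged peaks),
#'   \code{test} (differential results per peak), \code{flags}
#'   (per-construct rG4 verdicts) and \code{regions} (region
#'   classifications).
#' @export
rtstop_pipeline <- function(counts, manifest, min_normalized = 100,
                            alpha = 0.05) {
  stopifnot(length(dim(counts)) == 3L)
  samples <- dimnames(counts)[[3L]]
  condition <- sub("_.*$", "", samples)
  stopifnot(all(condition %in% c("KCl", "NaCl")))
  constructs <- dimnames(counts)[[1L]]

  totals <- apply(counts, c(1L, 3L), sum)
  retained <- filter_constructs(totals, condition, min_normalized)
  sf <- size_factors(totals)

  peak_list <- list()
  peak_counts <- list()
  peak_meta <- list()
  for (cid in retained) {
    mat <- counts[cid, , , drop = TRUE]  # position x sample
    kcl_sum <- rowSums(mat[, condition == "KCl", drop = FALSE])
    nacl_sum <- rowSums(mat[, condition == "NaCl", drop = FALSE])
    pk <- peaks_from_seeds(find_seeds(kcl_sum), kcl_sum)
    pn <- peaks_from_seeds(find_seeds(nacl_sum), nacl_sum)
    merged <- merge_condition_peaks(pk, pn, kcl_sum + nacl_sum)
    peak_list[[cid]] <- merged
    for (j in seq_len(nrow(merged))) {
      win <- seq.int(merged$start[j], merged$end[j])
      peak_counts[[length(peak_counts) + 1L]] <- colSums(mat[win, , drop = FALSE])
      peak_meta[[length(peak_meta) + 1L]] <-
        data.frame(construct_id = cid, start = merged$start[j],
                   end = merged$end[j], stringsAsFactors = FALSE)
    }
  }
  if (length(peak_counts) == 0L) {
    test <- data.frame()
    flags <- data.frame(construct_id = retained,
                        region_id = manifest$region_id[
                          match(retained, manifest$construct_id)],
                        is_rg4 = FALSE,
                        total_reads = rowSums(totals)[retained],
                        stringsAsFactors = FALSE)
    return(list(peaks = peak_list, test = test, flags = flags,
                regions = classify_regions(flags)))
  }
  pc <- do.call(rbind, peak_counts)
  meta <- do.call(rbind, peak_meta)
  rownames(pc) <- sprintf("%s:%d-%d", meta$construct_id, meta$start, meta$end)
  test <- differential_rg4_test(pc, condition, sf = sf, alpha = alpha)
  test <- cbind(meta, test)

  is_rg4 <- tapply(test$is_rg4, test$construct_id, any)
  flags <- data.frame(
    construct_id = retained,
    region_id = manifest$region_id[match(retained, manifest$construct_id)],
    is_rg4 = ifelse(retained %in% names(is_rg4),
                    as.logical(is_rg4[retained]), FALSE),
    total_reads = rowSums(totals)[retained],
    stringsAsFactors = FALSE)
  flags$is_rg4[is.na(flags$is_rg4)] <- FALSE
  list(peaks = peak_list, test = test, flags = flags,
       regions = classify_regions(flags))
}
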