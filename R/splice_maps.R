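#' Extract normalized crosslink windows around cassette-exon splice sites
#'
#' For each event, four anchor windows are opened: the 5' splice site of
#' the upstream exon, the 3' and 5' splice sites of the alternative exon,
#' and the 3' splice site of the downstream exon. Each window reaches up
#' to \code{exon_len} nt into the exon and up to \code{intron_len} nt into
#' the intron (truncated at short exons/introns) and is reported in
#' transcript orientation. Crosslink counts in each window are min-max
#' normalized to \[0, 1\]; windows with all-equal counts map to all zeros.
#'
#' @param events data frame with columns \code{event_id}, \code{contig},
#'   \code{strand} (\code{"+"}/\code{"-"}), \code{up_start},
#'   \code{up_end}, \code{cass_start}, \code{cass_end},
#'   \code{down_start}, \code{down_end} (1-based inclusive exon
#'   coordinates on the genome) and optionally \code{psi}, \code{group}.
#' @param tracks named list of numeric crosslink-count vectors, one per
#'   contig (index = genomic position).
#' @param exon_len,intron_len window extents (defaults 50 and 300).
#' @return A list of four matrices (\code{upstream_5ss},
#'   \code{cassette_3ss}, \code{cassette_5ss}, \code{downstream_3ss}),
#'   each events x positions. Columns run 5' to 3' in transcript
#'   orientation; positions beyond a short exon/intron are \code{NA}.
#'   Column names give the offset relative to the splice site (exonic
#'   positions negative or positive according to side).
#' @export
extract_profiles <- function(events, tracks, exon_len = 50L,
                             intron_len = 300L) {
  req <- c("event_id", "contig", "strand", "up_start", "up_end",
           "cass_start", "cass_end", "down_start", "down_end")
  stopifnot(all(req %in% names(events)))
  anchors <- c("upstream_5ss", "cassette_3ss", "cassette_5ss",
               "downstream_3ss")
  width <- exon_len + intron_len
  mats <- lapply(anchors, function(a) {
    matrix(NA_real_, nrow(events), width,
           dimnames = list(events$event_id, NULL))
  })
  names(mats) <- anchors
  normalize <- function(v) {
    if (all(is.na(v))) return(v)
    rng <- range(v, na.rm = TRUE)
    if (diff(rng) == 0) return(ifelse(is.na(v), NA_real_, 0))
    (v - rng[1L]) / diff(rng)
  }
  # genomic positions of a window given the splice-site boundary and the
  # exonic/intronic truncation limits; oriented 5'->3' in transcript space
  fetch <- function(track, gpos) {
    v <- rep(NA_real_, length(gpos))
    ok <- !is.na(gpos) & gpos >= 1L & gpos <= length(track)
    v[ok] <- track[gpos[ok]]
    v
  }
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    track <- tracks[[e$contig]]
    if (is.null(track)) {
      warning("event ", e$event_id, " on unknown contig ", e$contig,
              "; skipped")
      next
    }
    minus <- e$strand == "-"
    # exon boundaries in transcript orientation
    if (!minus) {
      b <- c(up_don = e$up_end, cass_acc = e$cass_start,
             cass_don = e$cass_end, down_acc = e$down_start)
      lims <- list(
        up_exon = c(e$up_start, e$up_end),
        intron1 = c(e$up_end + 1L, e$cass_start - 1L),
        cass = c(e$cass_start, e$cass_end),
        intron2 = c(e$cass_end + 1L, e$down_start - 1L),
        down_exon = c(e$down_start, e$down_end))
      clip <- function(gpos, lim) ifelse(gpos >= lim[1L] & gpos <= lim[2L],
                                         gpos, NA_integer_)
      win <- list(
        upstream_5ss = c(clip(seq.int(b["up_don"] - exon_len + 1L, b["up_don"]),
                              lims$up_exon),
                         clip(seq.int(b["up_don"] + 1L, b["up_don"] + intron_len),
                              lims$intron1)),
        cassette_3ss = c(clip(seq.int(b["cass_acc"] - intron_len, b["cass_acc"] - 1L),
                              lims$intron1),
                         clip(seq.int(b["cass_acc"], b["cass_acc"] + exon_len - 1L),
                              lims$cass)),
        cassette_5ss = c(clip(seq.int(b["cass_don"] - exon_len + 1L, b["cass_don"]),
                              lims$cass),
                         clip(seq.int(b["cass_don"] + 1L, b["cass_don"] + intron_len),
                              lims$intron2)),
        downstream_3ss = c(clip(seq.int(b["down_acc"] - intron_len, b["down_acc"] - 1L),
                                lims$intron2),
                           clip(seq.int(b["down_acc"], b["down_acc"] + exon_len - 1L),
                                lims$down_exon)))
    } else {
      # minus strand: transcript 5'->3' runs right to left on the genome
      b <- c(up_don = e$up_start, cass_acc = e$cass_end,
             cass_don = e$cass_start, down_acc = e$down_end)
      lims <- list(
        up_exon = c(e$up_start, e$up_end),
        intron1 = c(e$cass_end + 1L, e$up_start - 1L),
        cass = c(e$cass_start, e$cass_end),
        intron2 = c(e$down_end + 1L, e$cass_start - 1L),
        down_exon = c(e$down_start, e$down_end))
      clip <- function(gpos, lim) ifelse(gpos >= lim[1L] & gpos <= lim[2L],
                                         gpos, NA_integer_)
      win <- list(
        upstream_5ss = c(clip(seq.int(b["up_don"] + exon_len - 1L, b["up_don"]),
                              lims$up_exon),
                         clip(seq.int(b["up_don"] - 1L, b["up_don"] - intron_len),
                              lims$intron1)),
        cassette_3ss = c(clip(seq.int(b["cass_acc"] + intron_len, b["cass_acc"] + 1L),
                              lims$intron1),
                         clip(seq.int(b["cass_acc"], b["cass_acc"] - exon_len + 1L),
                              lims$cass)),
        cassette_5ss = c(clip(seq.int(b["cass_don"] + exon_len - 1L, b["cass_don"]),
                              lims$cass),
                         clip(seq.int(b["cass_don"] - 1L, b["cass_don"] - intron_len),
                              lims$intron2)),
        downstream_3ss = c(clip(seq.int(b["down_acc"] + intron_len, b["down_acc"] + 1L),
                                lims$intron2),
                           clip(seq.int(b["down_acc"], b["down_acc"] - exon_len + 1L),
                                lims$down_exon)))
    }
    for (a in anchors) {
      mats[[a]][i, ] <- normalize(fetch(track, win[[a]]))
    }
  }
  # offset labels: exon-first anchors run -exon_len..-1 then +1..+intron_len
  exon_first <- c(-rev(seq_len(exon_len)), seq_len(intron_len))
  intron_first <- c(-rev(seq_len(intron_len)), seq_len(exon_len))
  colnames(mats$upstream_5ss) <- exon_first
  colnames(mats$cassette_5ss) <- exon_first
  colnames(mats$cassette_3ss) <- intron_first
  colnames(mats$downstream_3ss) <- intron_first
  mats
}

#' Aggregate per-event profiles into a smoothed meta-profile
#'
#' Position-wise mean of the normalized per-event windows followed by
#' loess smoothing.
#'
#' @param profiles events x positions matrix from [extract_profiles()]
#'   (one anchor).
#' @param span loess span (default 0.2).
#' @return Data frame with \code{position} (column offset), \code{mean}
#'   and \code{smoothed}.
#' @export
aggregate_smooth <- function(profiles, span = 0.2) {
  stopifnot(is.matrix(profiles))
  if (nrow(profiles) < 2L) stop("need at least 2 events per group")
  m <- colMeans(profiles, na.rm = TRUE)
  pos <- as.numeric(colnames(profiles))
  if (any(is.na(pos))) pos <- seq_along(m)
  ok <- is.finite(m)
  sm <- rep(NA_real_, length(m))
  fit <- stats::loess(m[ok] ~ pos[ok], span = span, degree = 2,
                      family = "gaussian")
  sm[ok] <- stats::predict(fit)
  data.frame(position = pos, mean = m, smoothed = sm)
}

#' Sample PSI-matched control events
#'
#' The PSI quantiles of the target group (at the given probabilities)
#' define four bins; a fixed number of control events is sampled from each
#' bin so that the control set approximately matches the target group in
#' size and PSI distribution. Bins with too few controls are sampled with
#' replacement, with a warning.
#'
#' @param control_psi PSI values of the candidate control events.
#' @param target_psi PSI values of the target (regulated) group.
#' @param probs quantile probabilities; the defaults used for enhanced
#'   events are \code{c(0, .05, .70, .80, 1)} and for repressed events
#'   \code{c(0, .10, .65, .90, 1)}.
#' @param n_per_bin controls sampled per bin; defaults to
#'   \code{ceiling(length(target_psi) / 4)}.
#' @param seed integer seed.
#' @return Integer indices into \code{control_psi}.
#' @export
sample_matched_controls <- function(control_psi, target_psi,
                                    probs = c(0, 0.05, 0.70, 0.80, 1),
                                    n_per_bin = NULL, seed = 1L) {
  stopifnot(length(probs) == 5L, !is.unsorted(probs))
  if (is.null(n_per_bin)) n_per_bin <- ceiling(length(target_psi) / 4)
  qs <- stats::quantile(target_psi, probs = probs, na.rm = TRUE,
                        names = FALSE)
  qs[1L] <- -Inf
  qs[length(qs)] <- Inf
  bins <- cut(control_psi, breaks = qs, labels = FALSE,
              include.lowest = TRUE)
  set.seed(as.integer(seed))
  idx <- integer(0)
  for (b in 1:4) {
    members <- which(bins == b)
    if (length(members) == 0L) {
      warning("no control events in PSI bin ", b)
      next
    }
    replace <- length(members) < n_per_bin
    if (replace) {
      warning("PSI bin ", b, " has only ", length(members),
              " controls; sampling with replacement")
    }
    idx <- c(idx, sample(members, n_per_bin, replace = replace))
  }
  idx
}

#' Sliding-window rank-sum test of differential binding
#'
#' In overlapping windows (width 10 nt, step 1 nt), the per-event mean
#' normalized crosslink signal of the target group is compared against the
#' control group with a two-sample Wilcoxon rank-sum test; p values are
#' BH-corrected and windows with FDR at or below the threshold are flagged
#' significant. Windows in which all values are tied receive p = 1.
#'
#' @param target_profiles,control_profiles events x positions matrices on
#'   the same positions (one anchor).
#' @param width window width in nt (default 10).
#' @param step step size in nt (default 1).
#' @param fdr significance threshold on the adjusted p value
#'   (default 0.01).
#' @return Data frame with one row per window: \code{start}, \code{end}
#'   (column offsets of the window bounds), \code{p}, \code{padj},
#'   \code{significant}.
#' @export
window_test <- function(target_profiles, control_profiles, width = 10L,
                        step = 1L, fdr = 0.01) {
  stopifnot(ncol(target_profiles) == ncol(control_profiles))
  pos <- as.numeric(colnames(target_profiles))
  if (any(is.na(pos))) pos <- seq_len(ncol(target_profiles))
  starts <- seq.int(1L, ncol(target_profiles) - width + 1L, by = step)
  p <- vapply(starts, function(s) {
    cols <- seq.int(s, s + width - 1L)
    tv <- rowMeans(target_profiles[, cols, drop = FALSE], na.rm = TRUE)
    cv <- rowMeans(control_profiles[, cols, drop = FALSE], na.rm = TRUE)
    tv <- tv[is.finite(tv)]
    cv <- cv[is.finite(cv)]
    if (length(tv) == 0L || length(cv) == 0L) return(NA_real_)
    if (length(unique(c(tv, cv))) == 1L) return(1)
    suppressWarnings(stats::wilcox.test(tv, cv, exact = FALSE)$p.value)
  }, numeric(1))
  padj <- stats::p.adjust(p, "BH")
  data.frame(start = pos[starts], end = pos[starts + width - 1L],
             p = p, padj = padj,
             significant = !is.na(padj) & padj <= fdr)
}

#' Junction-based percent-spliced-in
#'
#' \eqn{PSI = inclusion / (inclusion + skipping)}, reported only when the
#' summed junction counts reach \code{min_total} (otherwise \code{NA}).
#'
#' @param inclusion,skipping junction read counts (vectorized).
#' @param min_total minimal summed count to quantify (default 25).
#' @return PSI values in \[0, 1\] or \code{NA}.
#' @examples
#' junction_psi(20, 10) # 0.667
#' junction_psi(10, 10) # NA (total below 25)
#' @export
junction_psi <- function(inclusion, skipping, min_total = 25) {
  stopifnot(all(inclusion >= 0, na.rm = TRUE),
            all(skipping >= 0, na.rm = TRUE))
  total <- inclusion + skipping
  ifelse(total >= min_total, inclusion / total, NA_real_)
}

#' PSI of an NMD-coupled cassette exon from two inclusion junctions
#'
#' For an exon whose skipping isoform is degraded by nonsense-mediated
#' decay, PSI is computed from the two inclusion junctions and the
#' skipping junction as
#' \eqn{(i_1 + i_2) / (i_1 + i_2 + 2 s)}; the skipping junction is counted
#' twice because each skipping event removes both inclusion junctions.
#'
#' @param inclusion1,inclusion2 counts of the two inclusion junctions.
#' @param skipping counts of the skipping junction.
#' @param min_total minimal total junction count
#'   (\code{i1 + i2 + s}) to quantify (default 25).
#' @return PSI values or \code{NA}.
#' @export
junction_psi_nmd <- function(inclusion1, inclusion2, skipping,
                             min_total = 25) {
  total <- inclusion1 + inclusion2 + skipping
  ifelse(total >= min_total,
         (inclusion1 + inclusion2) / (inclusion1 + inclusion2 + 2 * skipping),
         NA_real_)
}
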