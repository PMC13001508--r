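#' Merge significant crosslink positions into candidate regions
#'
#' Neighboring significant crosslink positions at a distance of 3 nt or
#' less are merged into regions potentially containing binding sites;
#' regions shorter than 2 nt are removed immediately.
#'
#' Coordinates are 1-based and closed throughout the caller (positions are
#' nucleotides); use [sites_to_bed()] to obtain 0-based BED records.
#'
#' @param positions integer vector of significant crosslink positions on
#'   one contig/strand (need not be sorted; duplicates ignored).
#' @param max_gap maximal distance between positions to merge (default 3).
#' @param min_width minimal region width to retain (default 2).
#' @return Data frame with columns \code{start}, \code{end}.
#' @examples
#' merge_positions(c(100, 102, 105, 120)) # one region [100, 105]
#' @export
merge_positions <- function(positions, max_gap = 3L, min_width = 2L) {
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  brk <- c(0L, which(diff(positions) > max_gap), length(positions))
  starts <- positions[brk[-length(brk)] + 1L]
  ends <- positions[brk[-1L]]
  keep <- (ends - starts + 1L) >= min_width
  data.frame(start = starts[keep], end = ends[keep])
}

#' Iteratively place 5-nt binding sites into candidate regions
#'
#' Within each region, the position with the highest crosslink count is
#' extended by 2 nt on both sides into a 5-nt site; the site plus 4 nt on
#' either side is then excised from the region and the procedure repeats
#' on the remainders until no further placement is possible. Ties at the
#' maximal count go to the leftmost position. Positions whose +-2
#' extension would leave the contig are discarded as placement candidates;
#' positions with zero crosslink counts never seed a site.
#'
#' @param regions data frame from [merge_positions()].
#' @param counts integer vector of crosslink counts per position for the
#'   whole contig (index = position).
#' @return Data frame of candidate sites: \code{start}, \code{end},
#'   \code{center}, \code{score} (crosslink count at the center).
#' @export
place_sites <- function(regions, counts) {
  stopifnot(is.data.frame(regions), is.numeric(counts))
  n <- length(counts)
  out <- list()
  for (i in seq_len(nrow(regions))) {
    avail <- seq.int(regions$start[i], regions$end[i])
    repeat {
      cand <- avail[counts[avail] > 0 & avail - 2L >= 1L & avail + 2L <= n]
      if (length(cand) == 0L) break
      peak <- cand[which.max(counts[cand])]  # which.max is leftmost on ties
      out[[length(out) + 1L]] <-
        data.frame(start = peak - 2L, end = peak + 2L, center = peak,
                   score = counts[peak])
      avail <- setdiff(avail, seq.int(peak - 6L, peak + 6L))
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      center = integer(0), score = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Final cleanup of placed binding sites
#'
#' Removes sites whose center fails the centrality rule and sites with
#' fewer than 3 positions carrying crosslink events. Under the default
#' \code{rule = "or"}, a site is kept when its center is a significant
#' crosslink position \emph{or} the position with the highest count within
#' the site; \code{rule = "and"} requires both.
#'
#' @param sites data frame from [place_sites()].
#' @param significant_positions integer vector of significant crosslink
#'   positions.
#' @param counts crosslink counts per position.
#' @param min_covered minimal number of in-site positions with crosslink
#'   events (default 3).
#' @param rule \code{"or"} (default) or \code{"and"}; see Details.
#' @return The retained sites.
#' @export
cleanup_sites <- function(sites, significant_positions, counts,
                          min_covered = 3L, rule = c("or", "and")) {
  rule <- match.arg(rule)
  if (nrow(sites) == 0L) return(sites)
  keep <- vapply(seq_len(nrow(sites)), function(i) {
    win <- seq.int(sites$start[i], sites$end[i])
    ctr <- sites$center[i]
    is_sig <- ctr %in% significant_positions
    is_max <- counts[ctr] == max(counts[win])
    central <- if (rule == "or") is_sig || is_max else is_sig && is_max
    central && sum(counts[win] > 0) >= min_covered
  }, logical(1))
  sites[keep, , drop = FALSE]
}

#' Call 5-nt binding sites from a crosslink track
#'
#' Runs the full iterative procedure: merge significant positions into
#' regions, place 5-nt sites at crosslink maxima with excision of placed
#' sites plus 4-nt margins, then apply the final cleanup.
#'
#' @param counts crosslink counts per position of one contig/strand.
#' @param significant_positions significant crosslink positions (e.g. from
#'   a peak caller such as PureCLIP, or the synthetic surrogate).
#' @param max_gap,min_width,min_covered,rule passed to the three stages.
#' @return Data frame of final sites: \code{start}, \code{end},
#'   \code{center}, \code{score}; all widths are exactly 5 and centers sit
#'   at \code{start + 2}.
#' @examples
#' counts <- c(rep(0, 99), 2, 1, 9, 3, 2, rep(0, 95))
#' call_binding_sites(counts, significant_positions = c(100, 102, 104))
#' @export
call_binding_sites <- function(counts, significant_positions,
                               max_gap = 3L, min_width = 2L,
                               min_covered = 3L, rule = "or") {
  regions <- merge_positions(significant_positions, max_gap, min_width)
  sites <- place_sites(regions, counts)
  cleanup_sites(sites, significant_positions, counts, min_covered, rule)
}

#' Convert called sites to BED6 records
#'
#' @param sites data frame from [call_binding_sites()].
#' @param contig contig name.
#' @param strand \code{"+"} or \code{"-"}.
#' @return Data frame in BED6 column order (0-based half-open
#'   \code{start}, \code{end}; \code{score} = crosslink count at the site
#'   center), suitable for \code{write.table(..., sep = "\t")}.
#' @export
sites_to_bed <- function(sites, contig, strand = "+") {
  stopifnot(strand %in% c("+", "-"))
  data.frame(chrom = rep(contig, nrow(sites)),
             start = sites$start - 1L,
             end = sites$end,
             name = sprintf("site_%d", seq_len(max(nrow(sites), 0L))[seq_len(nrow(sites))]),
             score = sites$score,
             strand = rep(strand, nrow(sites)),
             stringsAsFactors = FALSE)
}
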