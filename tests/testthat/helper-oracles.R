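# Independent reference implementations used as oracles.

# Brute-force partition function of the contiguous-binding model:
# enumerate every occupancy mask of the n sites and, within each maximal
# run of occupied sites, every composition into blocks of length <= q
# (each block = one protein). Sums explicit configuration weights without
# any grouping, so it shares no code path with the package's grouped
# enumeration.
brute_force_partition <- function(c, g_rG4, g_bind, g_backfold,
                                  n = 4L, q = 3L, temperature = 298) {
  rt <- 1.987e-3 * temperature
  compositions <- function(total, maxpart) {
    if (total == 0L) return(list(integer(0)))
    out <- list()
    for (first in seq_len(min(total, maxpart))) {
      for (rest in compositions(total - first, maxpart)) {
        out[[length(out) + 1L]] <- c(first, rest)
      }
    }
    out
  }
  z_unbound <- 1
  z_folded <- exp(g_rG4 / rt)
  z_bound <- 0
  n_masks <- 2L^n
  for (mask in seq_len(n_masks) - 1L) {
    occ <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(occ) == 0L) next
    # maximal runs of consecutive occupied sites
    runs <- rle(occ)
    run_lens <- runs$lengths[runs$values == 1L]
    # ways to split each run into ordered blocks of length <= q
    per_run <- lapply(run_lens, compositions, maxpart = q)
    if (any(vapply(per_run, length, integer(1)) == 0L)) next
    combos <- expand.grid(lapply(per_run, seq_along))
    for (ri in seq_len(nrow(combos))) {
      blocks <- unlist(lapply(seq_along(per_run), function(j) {
        per_run[[j]][[combos[ri, j]]]
      }))
      m <- length(blocks)
      sumk <- sum(blocks)
      nb <- sumk - m
      z_bound <- z_bound +
        c^m * exp((sumk * g_bind - nb * g_backfold) / rt)
    }
  }
  list(Z = z_unbound + z_folded + z_bound,
       bound = z_bound / (z_unbound + z_folded + z_bound))
}

# Literal step-by-step reference for the binding-site caller: re-evaluates
# the textual rules with explicit position sets and while loops.
naive_site_caller <- function(counts, sig, max_gap = 3, min_width = 2,
                              min_covered = 3) {
  sig <- sort(unique(sig))
  # 1. merge positions at distance <= max_gap into regions
  regions <- list()
  if (length(sig) > 0) {
    cur <- c(sig[1], sig[1])
    for (p in sig[-1]) {
      if (p - cur[2] <= max_gap) cur[2] <- p
      else {
        regions[[length(regions) + 1]] <- cur
        cur <- c(p, p)
      }
    }
    regions[[length(regions) + 1]] <- cur
  }
  # 2. drop regions shorter than min_width nt
  regions <- Filter(function(r) (r[2] - r[1] + 1) >= min_width, regions)
  # 3. iterative placement with excision of site + 4 nt margins
  sites <- data.frame(start = integer(0), end = integer(0),
                      center = integer(0), score = numeric(0))
  for (r in regions) {
    pool <- seq(r[1], r[2])
    while (TRUE) {
      ok <- pool[counts[pool] > 0 & pool >= 3 & pool <= length(counts) - 2]
      if (length(ok) == 0) break
      best <- ok[counts[ok] == max(counts[ok])][1]
      sites <- rbind(sites, data.frame(start = best - 2, end = best + 2,
                                       center = best,
                                       score = counts[best]))
      pool <- pool[pool < best - 6 | pool > best + 6]
    }
  }
  # 4. cleanup: center significant OR in-site maximum; >= min_covered
  keep <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    win <- seq(sites$start[i], sites$end[i])
    keep[i] <- (sites$center[i] %in% sig ||
                  counts[sites$center[i]] == max(counts[win])) &&
      sum(counts[win] > 0) >= min_covered
  }
  sites <- sites[keep, , drop = FALSE]
  sites[order(sites$start), , drop = FALSE]
}

# Dense-grid EC10/EC90 lookup used as an oracle for Hill coefficients:
# evaluates a response function on a very fine log grid and reads the EC
# levels off the nearest grid points (no interpolation).
brute_force_hill <- function(f, lo, hi, n = 2e5) {
  x <- exp(seq(log(lo), log(hi), length.out = n))
  y <- f(x)
  y <- (y - min(y)) / (max(y) - min(y))
  ec10 <- x[which.min(abs(y - 0.1))]
  ec90 <- x[which.min(abs(y - 0.9))]
  log(81) / log(ec90 / ec10)
}
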