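#' Configuration of the synthetic-data generators
#'
#' Bundles the knobs of all generators. With a fixed seed every generator
#' is byte-reproducible. Defaults emulate a realistic experimental design: 12
#' titration levels log-spaced between 46% and 176% of control protein,
#' triplicate observations, the 18+146+15+21-nt oligonucleotide layout
#' with 4 barcodes per transcript region, and triplicate RTstop libraries
#' per buffer condition.
#'
#' @param seed integer seed.
#' @param n_events number of splicing events to simulate.
#' @param protein_levels relative protein levels (1 = control).
#' @param noise_sd Gaussian delta-PSI noise (default 0.02).
#' @param n_replicates replicate observations per level / condition.
#' @param track_length crosslink-track length in nt.
#' @param site_spec list of \code{c(position, amplitude)} pairs for
#'   planted crosslink sites.
#' @param background_rate expected background crosslink counts per nt.
#' @param sig_quantile background quantile above which a position is
#'   flagged significant (default 0.999).
#' @param n_regions transcript regions in the oligonucleotide library.
#' @param barcodes_per_region barcodes per region (default 4).
#' @param rg4_fraction fraction of regions carrying a planted rG4.
#' @param stall_intensity expected read starts at the position immediately
#'   3' of a folded rG4 (default 50).
#' @param nb_dispersion negative-binomial dispersion of the stall counts.
#' @param rt_background uniform RTstop background rate per nt.
#' @param five_prime_rate expected read starts per nt over positions 1-18
#'   (full-length cDNA pileup).
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L, n_events = 20L,
                       protein_levels = NULL, noise_sd = 0.02,
                       n_replicates = 3L,
                       track_length = 1000L, site_spec = list(),
                       background_rate = 0.1, sig_quantile = 0.999,
                       n_regions = 20L, barcodes_per_region = 4L,
                       rg4_fraction = 0.5,
                       stall_intensity = 50, nb_dispersion = 0.1,
                       rt_background = 0.2, five_prime_rate = 5) {
  if (is.null(protein_levels)) {
    protein_levels <- exp(seq(log(0.46), log(1.76), length.out = 12L))
  }
  stopifnot(all(protein_levels > 0), noise_sd >= 0, background_rate >= 0,
            stall_intensity >= 0, nb_dispersion >= 0, rt_background >= 0,
            barcodes_per_region >= 1L, n_replicates >= 1L)
  structure(list(seed = as.integer(seed), n_events = n_events,
                 protein_levels = protein_levels, noise_sd = noise_sd,
                 n_replicates = n_replicates, track_length = track_length,
                 site_spec = site_spec, background_rate = background_rate,
                 sig_quantile = sig_quantile, n_regions = n_regions,
                 barcodes_per_region = barcodes_per_region,
                 rg4_fraction = rg4_fraction,
                 stall_intensity = stall_intensity,
                 nb_dispersion = nb_dispersion,
                 rt_background = rt_background,
                 five_prime_rate = five_prime_rate),
            class = "sim_config")
}

.ll4_curve <- function(x, min, max, ec50, b) {
  min + (max - min) / (1 + exp(b * (log(x) - log(ec50))))
}

#' Simulate splicing titration series with known dose-response truth
#'
#' Delta-PSI observations are generated from four-parameter logistic
#' curves (the generating truth) plus Gaussian noise, replicated per
#' protein level.
#'
#' @param config a [sim_config()]; \code{protein_levels}, \code{noise_sd},
#'   \code{n_replicates} and \code{seed} are used.
#' @param truth data frame with one row per event and columns \code{min},
#'   \code{max}, \code{ec50}, \code{b} (signed slope); an optional
#'   \code{event_id} column is respected.
#' @return List with \code{data} (columns \code{event_id}, \code{levels},
#'   \code{delta_psi}) and \code{truth} (the input truth with
#'   \code{event_id} and \code{n_H = |b|} attached).
#' @export
gen_titration <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(truth))
  if (nrow(truth) == 0L) stop("truth must contain at least one event")
  stopifnot(all(c("min", "max", "ec50", "b") %in% names(truth)))
  if (is.null(truth$event_id)) {
    truth$event_id <- sprintf("event_%03d", seq_len(nrow(truth)))
  }
  truth$n_H <- abs(truth$b)
  set.seed(config$seed)
  levels <- rep(config$protein_levels, each = config$n_replicates)
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    mu <- .ll4_curve(levels, tr$min, tr$max, tr$ec50, tr$b)
    data.frame(event_id = tr$event_id, levels = levels,
               delta_psi = mu + stats::rnorm(length(levels), 0,
                                             config$noise_sd),
               stringsAsFactors = FALSE)
  })
  list(data = do.call(rbind, rows), truth = truth)
}

#' Simulate a crosslink track with planted binding sites
#'
#' Poisson background counts plus a triangular signal kernel (half-width
#' 2 nt) around each planted site center emulate an iCLIP crosslink
#' track. Positions whose count exceeds the \code{sig_quantile} quantile
#' of the background distribution are flagged significant, standing in
#' for a peak caller's significant crosslink positions.
#'
#' @param config a [sim_config()]; uses \code{track_length},
#'   \code{site_spec} (list of \code{c(position, amplitude)}),
#'   \code{background_rate}, \code{sig_quantile} and \code{seed}.
#' @return List with \code{counts}, \code{significant} (positions) and
#'   \code{truth} (data frame of planted site centers and amplitudes).
#' @export
gen_crosslink_data <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$track_length
  sites <- config$site_spec
  if (length(sites)) {
    centers <- vapply(sites, `[`, numeric(1), 1L)
    amps <- vapply(sites, `[`, numeric(1), 2L)
    if (any(centers > L)) stop("track_length is smaller than a site position")
    if (any(amps <= config$background_rate)) {
      stop("site amplitudes must exceed the background rate")
    }
  } else {
    centers <- numeric(0)
    amps <- numeric(0)
  }
  set.seed(config$seed)
  counts <- stats::rpois(L, config$background_rate)
  kernel <- c(1, 2, 3, 2, 1) / 3
  for (i in seq_along(centers)) {
    off <- (-2L):(2L)
    pos <- centers[i] + off
    ok <- pos >= 1L & pos <= L
    counts[pos[ok]] <- counts[pos[ok]] +
      stats::rpois(sum(ok), amps[i] * kernel[ok])
  }
  thr <- stats::qpois(config$sig_quantile, config$background_rate)
  list(counts = counts,
       significant = which(counts > thr),
       truth = data.frame(center = centers, amplitude = amps))
}

.T7_PROMOTER <- "TAATACGACTCACTATAG"          # 18 nt
.L3_LINKER <- "AGATCGGAAGAGCGGTTCAGC"          # 21 nt

# random sequence without G-runs of 3+ (rewrites every third G of a run)
.random_seq_no_g3 <- function(n) {
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (n >= 3L) {
    for (i in 3:n) {
      if (s[i] == "G" && s[i - 1L] == "G" && s[i - 2L] == "G") {
        s[i] <- sample(c("A", "C", "T"), 1L)
      }
    }
  }
  paste(s, collapse = "")
}

# canonical rG4: four runs of >= 3 G separated by 1-7 nt loops
.random_rg4 <- function(run_len = 3L, loop_lens = NULL) {
  if (is.null(loop_lens)) loop_lens <- sample(1:7, 3L, replace = TRUE)
  loops <- vapply(loop_lens, function(l) {
    paste(sample(c("A", "C", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
  paste0(strrep("G", run_len), loops[1L], strrep("G", run_len), loops[2L],
         strrep("G", run_len), loops[3L], strrep("G", run_len))
}

.hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

# barcodes: 15-mers, pairwise Hamming >= 5, no more than two consecutive Gs
.gen_barcodes <- function(n, len = 15L, min_dist = 5L,
                          max_tries = 50L * n + 1000L) {
  acc <- matrix(character(0), nrow = 0L, ncol = len)
  tries <- 0L
  while (nrow(acc) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not generate ", n, " barcodes satisfying the ",
           "Hamming-distance/G-run constraints in ", max_tries, " attempts")
    }
    cand <- strsplit(.random_seq_no_g3(len), "")[[1L]]
    if (nrow(acc) > 0L) {
      d <- rowSums(acc != matrix(cand, nrow(acc), len, byrow = TRUE))
      if (any(d < min_dist)) next
    }
    acc <- rbind(acc, cand)
  }
  apply(acc, 1L, paste, collapse = "")
}

#' Simulate a barcoded 200-nt oligonucleotide library
#'
#' Each construct is the concatenation of an 18-nt T7 promoter, a 146-nt
#' transcript insert, a 15-nt unique barcode and a 21-nt L3 linker (200 nt
#' total). A configurable fraction of transcript regions carries a planted
#' canonical rG4 (four runs of >= 3 G separated by 1-7 nt loops) whose
#' site of interest starts at position 51 of the construct; the remaining
#' inserts are free of G-triplets. Each region is present once per
#' barcode, barcodes are pairwise Hamming-distance >= 5 apart and contain
#' no more than two consecutive Gs.
#'
#' @param config a [sim_config()]; uses \code{n_regions},
#'   \code{barcodes_per_region}, \code{rg4_fraction} and \code{seed}.
#' @return List with \code{sequences} (named character vector, one 200-nt
#'   construct per entry) and \code{manifest} (data frame with
#'   \code{construct_id}, \code{region_id}, \code{barcode},
#'   \code{has_rg4}, \code{g4_start}, \code{g4_end}, \code{stall_pos}).
#' @export
gen_oligo_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_reg <- config$n_regions
  bpr <- config$barcodes_per_region
  barcodes <- .gen_barcodes(n_reg * bpr)
  n_rg4 <- round(config$rg4_fraction * n_reg)
  has_rg4 <- rep(c(TRUE, FALSE), c(n_rg4, n_reg - n_rg4))
  site_insert_start <- 51L - nchar(.T7_PROMOTER)  # construct pos 51
  seqs <- character(0)
  manifest <- list()
  k <- 0L
  for (r in seq_len(n_reg)) {
    if (has_rg4[r]) {
      g4 <- .random_rg4()
      left <- .random_seq_no_g3(site_insert_start - 1L)
      right <- .random_seq_no_g3(146L - (site_insert_start - 1L) - nchar(g4))
      insert <- paste0(left, g4, right)
      g4_start <- 51L
      g4_end <- 51L + nchar(g4) - 1L
    } else {
      insert <- .random_seq_no_g3(146L)
      g4_start <- NA_integer_
      g4_end <- NA_integer_
    }
    for (b in seq_len(bpr)) {
      k <- k + 1L
      cid <- sprintf("region_%03d_bc%d", r, b)
      seqs[cid] <- paste0(.T7_PROMOTER, insert, barcodes[k], .L3_LINKER)
      manifest[[k]] <- data.frame(
        construct_id = cid, region_id = sprintf("region_%03d", r),
        barcode = barcodes[k], has_rg4 = has_rg4[r],
        g4_start = g4_start, g4_end = g4_end,
        stall_pos = if (is.na(g4_end)) NA_integer_ else g4_end + 1L,
        stringsAsFactors = FALSE)
    }
  }
  list(sequences = seqs, manifest = do.call(rbind, manifest))
}

#' Validate a simulated oligonucleotide library
#'
#' Re-checks the layout (18/146/15/21 segment lengths, 200 nt total),
#' the barcode constraints (pairwise Hamming distance >= 5, no GGG) and
#' the planted-rG4 consensus at position 51 of rG4-bearing constructs.
#'
#' @param library result of [gen_oligo_library()].
#' @return \code{TRUE} invisibly, or an error describing the violation.
#' @export
validate_library <- function(library) {
  seqs <- library$sequences
  man <- library$manifest
  if (any(nchar(seqs) != 200L)) stop("construct length is not 200 nt")
  if (!all(startsWith(seqs, .T7_PROMOTER))) stop("missing T7 promoter")
  if (!all(substr(seqs, 180L, 200L) == .L3_LINKER)) stop("missing L3 linker")
  bc_in_seq <- substr(seqs, 165L, 179L)
  if (!all(bc_in_seq == man$barcode[match(names(seqs), man$construct_id)])) {
    stop("barcode segment does not match the manifest")
  }
  bcs <- unique(man$barcode)
  if (any(grepl("GGG", bcs))) stop("barcode contains three consecutive Gs")
  if (length(bcs) > 1L) {
    for (i in seq_len(length(bcs) - 1L)) {
      d <- vapply(bcs[(i + 1L):length(bcs)], .hamming, numeric(1), bcs[i])
      if (any(d < 5)) stop("barcode pair below Hamming distance 5")
    }
  }
  g4_pat <- "^G{3,}[ACT]{1,7}G{3,}[ACT]{1,7}G{3,}[ACT]{1,7}G{3,}"
  for (i in which(man$has_rg4)) {
    s <- seqs[man$construct_id[i]]
    if (!grepl(g4_pat, substr(s, 51L, 110L))) {
      stop("construct ", man$construct_id[i],
           " lacks the planted rG4 at position 51")
    }
  }
  invisible(TRUE)
}

#' Write a simulated library to FASTA
#'
#' @param library result of [gen_oligo_library()].
#' @param path output FASTA path.
#' @return The path, invisibly.
#' @export
write_library_fasta <- function(library, path) {
  x <- Biostrings::DNAStringSet(library$sequences)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Simulate RTstop read-start counts for a library
#'
#' All constructs receive a uniform Poisson background plus a 5'-end
#' pileup over positions 1-18 (full-length cDNAs of unimpeded reverse
#' transcription). Under K+ with GTP, rG4-bearing constructs additionally
#' receive a negative-binomial read-start pileup at the position
#' immediately 3' of the planted quadruplex (reverse transcriptase walks
#' 3'->5' and stalls at the folded structure). Under Na+ (no quadruplex
#' stabilization) or 7-deaza-GTP (Hoogsteen pairing blocked during
#' transcription) the stall pileup is absent.
#'
#' @param library result of [gen_oligo_library()].
#' @param config a [sim_config()]; uses \code{stall_intensity},
#'   \code{nb_dispersion}, \code{rt_background}, \code{five_prime_rate},
#'   \code{n_replicates} and \code{seed}.
#' @param condition one of \code{"KCl_GTP"}, \code{"NaCl_GTP"},
#'   \code{"KCl_7dGTP"}, \code{"NaCl_7dGTP"}.
#' @return Integer array \code{[construct, position, replicate]} with
#'   dimnames; replicate names are \code{<salt>_<i>}.
#' @export
gen_rtstop_counts <- function(library, config, condition = "KCl_GTP") {
  stopifnot(inherits(config, "sim_config"))
  valid <- c("KCl_GTP", "NaCl_GTP", "KCl_7dGTP", "NaCl_7dGTP")
  if (!condition %in% valid) {
    stop("unknown condition '", condition, "'; expected one of ",
         paste(valid, collapse = ", "))
  }
  salt <- sub("_.*$", "", condition)
  stall_active <- condition == "KCl_GTP"
  man <- library$manifest
  n_c <- nrow(man)
  L <- 200L
  reps <- config$n_replicates
  set.seed(config$seed + match(condition, valid))
  arr <- array(0L, dim = c(n_c, L, reps),
               dimnames = list(man$construct_id, NULL,
                               paste0(salt, "_", seq_len(reps))))
  for (j in seq_len(reps)) {
    bg <- matrix(stats::rpois(n_c * L, config$rt_background), n_c, L)
    bg[, 1:18] <- bg[, 1:18] +
      matrix(stats::rpois(n_c * 18L, config$five_prime_rate), n_c, 18L)
    if (stall_active && config$stall_intensity > 0) {
      idx <- which(man$has_rg4 & !is.na(man$stall_pos))
      stalls <- stats::rnbinom(length(idx), mu = config$stall_intensity,
                               size = 1 / max(config$nb_dispersion, 1e-8))
      # reverse transcriptase stutters by a nucleotide at the structure
      # edge: read starts concentrate on the stall position with small
      # shoulders on its direct neighbors
      for (u in seq_along(idx)) {
        spread <- stats::rmultinom(1L, stalls[u], c(0.15, 0.7, 0.15))[, 1L]
        pos <- man$stall_pos[idx[u]] + (-1L):1L
        ok <- pos >= 1L & pos <= L
        bg[idx[u], pos[ok]] <- bg[idx[u], pos[ok]] + spread[ok]
      }
    }
    arr[, , j] <- bg
  }
  arr
}

#' Simulate an in vitro binding titration from the equilibrium model
#'
#' Bound-signal observations across a protein concentration series,
#' generated as the model's bound fraction plus Gaussian noise --
#' suitable for refitting a Hill equation.
#'
#' @param params an [energy_params()] object.
#' @param concentrations protein concentrations in mol/l.
#' @param noise_sd Gaussian noise on the bound signal.
#' @param seed integer seed.
#' @return Data frame with \code{concentration}, \code{signal} and
#'   \code{truth} (the noiseless bound fraction).
#' @export
gen_invitro_binding <- function(params, concentrations, noise_sd = 0.02,
                                seed = 1L) {
  stopifnot(inherits(params, "energy_params"))
  set.seed(as.integer(seed))
  mu <- bound_fraction(params, concentrations)
  data.frame(concentration = concentrations,
             signal = mu + stats::rnorm(length(mu), 0, noise_sd),
             truth = mu)
}

#' Fit a Hill binding equation to a titration
#'
#' Least-squares fit of \eqn{y = A x^{n} / (x^{n} + K^{n})} by bounded
#' multi-start optimization; used to recover apparent cooperativity from
#' simulated (or measured) binding signals.
#'
#' @param concentration,signal the titration.
#' @param amplitude_bounds bounds on the saturation amplitude A.
#' @return List with \code{n_H}, \code{K}, \code{amplitude} and
#'   \code{sse}.
#' @export
fit_hill <- function(concentration, signal, amplitude_bounds = c(0.2, 2)) {
  stopifnot(length(concentration) == length(signal),
            all(concentration > 0))
  lx <- log(concentration)
  sse <- function(p) {
    # p = (log n, log K, A)
    n <- exp(p[1L])
    mu <- p[3L] / (1 + exp(-n * (lx - p[2L])))
    sum((signal - mu)^2)
  }
  k0 <- stats::median(lx)
  best <- NULL
  for (n0 in c(1, 2, 4)) {
    fit <- tryCatch(
      stats::optim(c(log(n0), k0, max(signal)), sse, method = "L-BFGS-B",
                   lower = c(log(0.05), min(lx) - 5, amplitude_bounds[1L]),
                   upper = c(log(50), max(lx) + 5, amplitude_bounds[2L]),
                   control = list(factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("Hill fit failed")
  list(n_H = exp(best$par[1L]), K = exp(best$par[2L]),
       amplitude = best$par[3L], sse = best$value)
}
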