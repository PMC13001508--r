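#' @title Equilibrium model of cooperative HNRNPH binding to an unfolded rG4
#'
#' @description
#' An RNA G-quadruplex (rG4) with four G-runs can either fold into the
#' quadruplex or expose its G-runs as single-stranded binding sites for the
#' quasi-RRM (qRRM) domains of HNRNPH. The model describes the system with
#' three characteristic free energies (all entered as positive magnitudes,
#' kcal/mol):
#' \itemize{
#'   \item \code{g_rG4}: stabilization of the folded quadruplex relative to
#'     the unfolded RNA (larger favors folding);
#'   \item \code{g_bind}: free-energy gain per qRRM--G-run contact (larger
#'     favors binding);
#'   \item \code{g_backfold}: entropic penalty paid each time an
#'     already-bound protein folds back so that an additional qRRM of the
#'     same protein engages a further G-run.
#' }
#' Taking the unfolded, unbound RNA as the reference state (statistical
#' weight 1), a binding mode in which \eqn{m} proteins contact
#' \eqn{k_1, ..., k_m} G-runs has weight
#' \deqn{\Omega \, (c/c_0)^m \exp[(\sum_i k_i g_{bind} -
#'       \sum_i (k_i - 1) g_{backfold}) / RT]}
#' where \eqn{\Omega} is the number of distinct placements of the (unlabeled)
#' proteins on the linear array of G-runs, each protein occupying a
#' contiguous block of 1..\code{max_qrrm} runs. The folded, unbound RNA has
#' weight \eqn{\exp(g_{rG4}/RT)}; an optional helper mode \code{1^F}, in
#' which one protein binds the still-folded quadruplex with energy
#' \code{g_rG4_bind}, has weight
#' \eqn{(c/c_0)\exp[(g_{rG4} + g_{rG4,bind})/RT]}.
#'
#' @param g_rG4 rG4 folding stabilization (kcal/mol, > 0 favors folded).
#' @param g_bind free-energy gain per qRRM--G-run contact (kcal/mol).
#' @param g_backfold penalty per backfolding event (kcal/mol).
#' @param g_rG4_bind optional helper-state energy for binding the folded rG4
#'   (kcal/mol); \code{NULL} disables the helper state.
#' @param temperature temperature in Kelvin (default 298).
#' @param n_sites number of exposable G-runs (default 4).
#' @param max_qrrm qRRMs per protein, i.e. maximal contacts per protein
#'   (default 3). \code{max_qrrm = 1} is the "no backfolding" model.
#' @param c0 reference concentration in mol/l (default 1).
#' @param contiguous if \code{TRUE} (default), a protein's contacts occupy
#'   contiguous G-runs (tandem tethered domains); if \code{FALSE}, any
#'   subset of free runs may be engaged.
#' @return An object of class \code{"energy_params"}.
#' @examples
#' p <- energy_params(g_rG4 = 23, g_bind = 9.2, g_backfold = 0.8)
#' transition_concentration(p)
#' @export
energy_params <- function(g_rG4, g_bind, g_backfold = 0, g_rG4_bind = NULL,
                          temperature = 298, n_sites = 4L, max_qrrm = 3L,
                          c0 = 1, contiguous = TRUE) {
  stopifnot(is.numeric(g_rG4), is.numeric(g_bind), is.numeric(g_backfold),
            length(g_rG4) == 1L, length(g_bind) == 1L,
            length(g_backfold) == 1L)
  if (!is.null(g_rG4_bind)) stopifnot(is.numeric(g_rG4_bind),
                                      length(g_rG4_bind) == 1L)
  n_sites <- as.integer(n_sites)
  max_qrrm <- as.integer(max_qrrm)
  if (n_sites < 1L) stop("n_sites must be >= 1")
  if (max_qrrm < 1L) stop("max_qrrm must be >= 1")
  if (temperature <= 0) stop("temperature must be positive")
  if (c0 <= 0) stop("c0 must be positive")
  structure(
    list(g_rG4 = g_rG4, g_bind = g_bind, g_backfold = g_backfold,
         g_rG4_bind = g_rG4_bind, temperature = temperature,
         n_sites = n_sites, max_qrrm = max_qrrm, c0 = c0,
         contiguous = contiguous),
    class = "energy_params")
}

# gas constant in kcal/(mol K)
.RGAS <- 1.987e-3

.rt <- function(params) .RGAS * params$temperature

#' Enumerate the binding modes of the equilibrium model
#'
#' Lists every state of the model: the unfolded-unbound reference, the
#' folded-unbound quadruplex, all modes in which unlabeled proteins occupy
#' G-runs (each protein contacting 1..\code{max_qrrm} runs), and -- when
#' \code{g_rG4_bind} is set -- the helper mode \code{1^F} of a single
#' protein bound to the folded quadruplex. Labels follow the
#' \code{m^\{k1 k2 ...\}} notation, e.g. \code{"2^31"} for two proteins
#' contacting 3 and 1 runs.
#'
#' @param params an [energy_params()] object.
#' @return A data frame with one row per state: \code{label},
#'   \code{contacts} (contact counts as a dash-separated string), \code{m}
#'   (number of bound proteins), \code{total_contacts},
#'   \code{n_backfolds} (\eqn{\sum_i (k_i - 1)}), \code{multiplicity}
#'   (number of distinct site placements) and \code{folded}.
#' @examples
#' st <- enumerate_states(energy_params(23, 9.2, 0.8))
#' st[st$label %in% c("2^22", "2^31"), ]
#' @export
enumerate_states <- function(params) {
  stopifnot(inherits(params, "energy_params"))
  n <- params$n_sites
  q <- params$max_qrrm
  if (isTRUE(params$contiguous)) {
    placements <- list()
    rec <- function(pos, blocks) {
      if (pos > n) {
        placements[[length(placements) + 1L]] <<- blocks
        return(invisible())
      }
      rec(pos + 1L, blocks)
      for (L in seq_len(q)) {
        if (pos + L - 1L <= n) rec(pos + L, c(blocks, L))
      }
    }
    rec(1L, integer(0))
    keys <- vapply(placements, function(b) {
      paste(sort(b, decreasing = TRUE), collapse = "-")
    }, character(1))
    tab <- table(keys)
    contact_sets <- names(tab)
    mult <- as.integer(tab)
  } else {
    # non-contiguous: proteins engage arbitrary subsets of free runs;
    # multiplicity is the number of ways to choose disjoint site sets for
    # the unlabeled proteins
    contact_sets <- character(0)
    mult <- integer(0)
    multisets <- .contact_multisets(n, q)
    for (ks in multisets) {
      sumk <- sum(ks)
      sizes <- table(ks)
      m1 <- factorial(n) / (factorial(n - sumk) * prod(factorial(ks)))
      m1 <- m1 / prod(factorial(as.integer(sizes)))
      contact_sets <- c(contact_sets,
                        paste(sort(ks, decreasing = TRUE), collapse = "-"))
      mult <- c(mult, as.integer(round(m1)))
    }
  }
  ks_list <- lapply(strsplit(contact_sets, "-"), as.integer)
  empty <- vapply(ks_list, function(k) length(k) == 1L && is.na(k[1L]),
                  logical(1)) | contact_sets == ""
  ks_list <- ks_list[!empty]
  mult <- mult[!empty]
  m <- vapply(ks_list, length, integer(1))
  sumk <- vapply(ks_list, sum, integer(1))
  labels <- vapply(seq_along(ks_list), function(i) {
    paste0(m[i], "^", paste(ks_list[[i]], collapse = ""))
  }, character(1))
  out <- data.frame(
    label = c("unbound", "folded", labels),
    contacts = c("", "", vapply(ks_list, paste, character(1), collapse = "-")),
    m = c(0L, 0L, m),
    total_contacts = c(0L, 0L, sumk),
    n_backfolds = c(0L, 0L, sumk - m),
    multiplicity = c(1L, 1L, mult),
    folded = c(FALSE, TRUE, rep(FALSE, length(m))),
    stringsAsFactors = FALSE)
  if (!is.null(params$g_rG4_bind)) {
    out <- rbind(out, data.frame(
      label = "1^F", contacts = "F", m = 1L, total_contacts = 0L,
      n_backfolds = 0L, multiplicity = 1L, folded = TRUE,
      stringsAsFactors = FALSE))
  }
  ord <- order(out$m, out$total_contacts, out$label)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# all multisets {k_1 >= k_2 >= ...} with 1 <= k_i <= q and sum <= n
.contact_multisets <- function(n, q) {
  res <- list()
  rec <- function(remaining, maxpart, acc) {
    if (length(acc) > 0L) res[[length(res) + 1L]] <<- acc
    for (k in seq_len(min(maxpart, remaining))) {
      rec(remaining - k, k, c(acc, k))
    }
  }
  rec(n, q, integer(0))
  res
}

# log statistical weights for all states at concentrations cs;
# returns states x length(cs) matrix
.state_log_weights <- function(params, cs, states = enumerate_states(params)) {
  rt <- .rt(params)
  lc <- log(cs / params$c0)
  le <- numeric(nrow(states))
  for (i in seq_len(nrow(states))) {
    s <- states[i, ]
    if (s$label == "unbound") {
      le[i] <- 0
    } else if (s$label == "folded") {
      le[i] <- params$g_rG4 / rt
    } else if (s$label == "1^F") {
      le[i] <- (params$g_rG4 + params$g_rG4_bind) / rt
    } else {
      le[i] <- log(s$multiplicity) +
        (s$total_contacts * params$g_bind -
           s$n_backfolds * params$g_backfold) / rt
    }
  }
  outer(states$m, lc) + le
}

.logsumexp_cols <- function(lw) {
  mx <- apply(lw, 2L, max)
  mx + log(colSums(exp(sweep(lw, 2L, mx))))
}

#' Fraction of rG4s bound by at least one protein at equilibrium
#'
#' Sums the statistical weights of all modes with at least one bound
#' protein (including the helper mode \code{1^F} when enabled) and divides
#' by the full partition function. Weights are accumulated in log space, so
#' large energies do not overflow.
#'
#' @param params an [energy_params()] object.
#' @param c protein concentration(s) in mol/l (vectorized).
#' @return Bound fraction(s) in \[0, 1\], same length as \code{c}.
#' @examples
#' p <- energy_params(23, 9.2, 0.8)
#' bound_fraction(p, c(1e-8, 3e-6, 1e-4))
#' @export
bound_fraction <- function(params, c) {
  stopifnot(inherits(params, "energy_params"), is.numeric(c))
  if (any(c < 0)) stop("concentration must be non-negative")
  out <- numeric(length(c))
  pos <- c > 0
  if (any(pos)) {
    states <- enumerate_states(params)
    lw <- .state_log_weights(params, c[pos], states)
    bound <- states$m >= 1L
    lZ <- .logsumexp_cols(lw)
    lB <- .logsumexp_cols(lw[bound, , drop = FALSE])
    out[pos] <- exp(lB - lZ)
  }
  out
}

#' Per-state occupation probabilities
#'
#' @param params an [energy_params()] object.
#' @param c a single protein concentration in mol/l.
#' @return The state table of [enumerate_states()] with an extra
#'   \code{probability} column summing to 1.
#' @export
state_probabilities <- function(params, c) {
  stopifnot(length(c) == 1L, c > 0)
  states <- enumerate_states(params)
  lw <- .state_log_weights(params, c, states)
  p <- exp(lw[, 1L] - .logsumexp_cols(lw))
  states$probability <- p / sum(p)
  states
}

#' Transition concentration (activity coefficient K)
#'
#' The protein concentration at which half of the rG4 molecules are bound,
#' found by root bisection of \code{bound_fraction(c) - 1/2} on a log
#' concentration scale.
#'
#' @param params an [energy_params()] object.
#' @param lower,upper guard interval for the root search (mol/l).
#' @return K in mol/l.
#' @export
transition_concentration <- function(params, lower = 1e-30, upper = 1e10) {
  states <- enumerate_states(params)
  f <- function(lc) {
    lw <- .state_log_weights(params, exp(lc), states)
    bound <- states$m >= 1L
    exp(.logsumexp_cols(lw[bound, , drop = FALSE]) - .logsumexp_cols(lw)) - 0.5
  }
  flo <- f(log(lower))
  fhi <- f(log(upper))
  if (flo * fhi > 0) {
    stop("bound_fraction does not cross 1/2 in [", lower, ", ", upper, "]")
  }
  r <- stats::uniroot(f, c(log(lower), log(upper)), tol = 1e-12)
  exp(r$root)
}

#' Model Hill coefficient of the bound-fraction curve
#'
#' Evaluates the bound fraction on a log-spaced concentration grid centered
#' on the transition concentration and applies [hill_coefficient_ec()].
#'
#' @param params an [energy_params()] object.
#' @param n_grid number of grid points (default 121; use more for
#'   convergence studies).
#' @param decades total width of the grid in log10 decades (default 6).
#' @return The EC10/EC90 Hill coefficient of the binding curve.
#' @export
model_hill <- function(params, n_grid = 121L, decades = 6) {
  K <- transition_concentration(params)
  cs <- 10^seq(log10(K) - decades / 2, log10(K) + decades / 2,
               length.out = n_grid)
  hill_coefficient_ec(cs, bound_fraction(params, cs))
}

#' Per-contact binding energy from a dissociation constant
#'
#' \eqn{g_{bind} = -RT \ln(K_d / c_0)} with
#' \eqn{R = 1.987 \times 10^{-3}} kcal/(mol K). For the HNRNPH-family
#' dissociation constant \eqn{K_d = 0.2} uM at 298 K this gives
#' ~9.2 kcal/mol.
#'
#' @param kd dissociation constant in mol/l.
#' @param temperature temperature in Kelvin (default 298).
#' @param c0 reference concentration in mol/l (default 1).
#' @return Binding free energy in kcal/mol.
#' @examples
#' binding_energy_from_kd(0.2e-6) # ~ 9.2
#' @export
binding_energy_from_kd <- function(kd, temperature = 298, c0 = 1) {
  stopifnot(kd > 0, temperature > 0, c0 > 0)
  -.RGAS * temperature * log(kd / c0)
}

#' Invert the backfolding penalty from a target transition concentration
#'
#' Root-finds \code{g_backfold} such that the model's transition
#' concentration equals \code{K_target}, holding the other energies fixed.
#' The transition concentration is monotone non-decreasing in the penalty,
#' so the root is unique on the bracket.
#'
#' @param g_rG4 rG4 folding energy (kcal/mol).
#' @param g_bind per-contact binding energy (kcal/mol).
#' @param K_target target transition concentration (mol/l).
#' @param params optional [energy_params()] template supplying temperature,
#'   site geometry and reference concentration.
#' @param bracket search interval for the penalty (kcal/mol).
#' @return g_backfold in kcal/mol (relative accuracy ~1e-6).
#' @export
invert_backfold_penalty <- function(g_rG4, g_bind, K_target,
                                    params = NULL,
                                    bracket = c(-10, 20)) {
  stopifnot(K_target > 0)
  template <- if (is.null(params)) {
    energy_params(g_rG4, g_bind, 0)
  } else {
    params
  }
  f <- function(gb) {
    p <- template
    p$g_rG4 <- g_rG4
    p$g_bind <- g_bind
    p$g_backfold <- gb
    log(transition_concentration(p)) - log(K_target)
  }
  flo <- f(bracket[1L])
  fhi <- f(bracket[2L])
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
    gbs <- seq(bracket[1L], bracket[2L], length.out = 13L)
    diag <- vapply(gbs, function(g) tryCatch(f(g), error = function(e) NA_real_),
                   numeric(1))
    stop("no root for g_backfold in [", bracket[1L], ", ", bracket[2L],
         "]; log-K residuals along the bracket: ",
         paste(sprintf("%.3g", diag), collapse = ", "))
  }
  r <- stats::uniroot(f, bracket, tol = 1e-9)
  r$root
}

#' Bound fraction of the reduced double-backfolding model
#'
#' Retains only the two dominant binding modes \code{2^31} and \code{2^22}
#' (two proteins, two backfolding events, all four G-runs occupied) next to
#' the unfolded-unbound and folded-unbound states. For moderate backfolding
#' penalties this reduced model tracks the full model closely; for large
#' penalties the full model shifts toward four singly-bound proteins and
#' the reduction loses validity.
#'
#' @param params an [energy_params()] object with \code{n_sites = 4} and
#'   \code{max_qrrm >= 3}.
#' @param c protein concentration(s) in mol/l.
#' @return Bound fraction(s) under the reduced model.
#' @export
reduced_double_backfold <- function(params, c) {
  stopifnot(inherits(params, "energy_params"))
  if (params$n_sites != 4L || params$max_qrrm < 3L) {
    stop("reduced model is defined for n_sites = 4, max_qrrm >= 3")
  }
  if (any(c < 0)) stop("concentration must be non-negative")
  states <- enumerate_states(params)
  keep <- states$label %in% c("unbound", "folded", "2^31", "2^22")
  states <- states[keep, , drop = FALSE]
  out <- numeric(length(c))
  pos <- c > 0
  if (any(pos)) {
    lw <- .state_log_weights(params, c[pos], states)
    bound <- states$m >= 1L
    out[pos] <- exp(.logsumexp_cols(lw[bound, , drop = FALSE]) -
                      .logsumexp_cols(lw))
  }
  out
}

#' Hill-coefficient sweep of the zero-penalty (unrestricted backfolding) model
#'
#' Scans the 4-site model with \code{g_backfold = 0} over a grid of
#' folding and binding energies, recording the transition concentration
#' and the EC10/EC90 Hill coefficient at every grid point. Where the rG4
#' folding energy gates the transition the Hill coefficient plateaus at 2
#' (two proteins bound through two backfolds each dominate); where binding
#' overwhelms folding the transition collapses to single-protein capture
#' and the coefficient falls toward 1.
#'
#' @param g_rG4_grid,g_bind_grid energy grids in kcal/mol.
#' @param n_grid Hill evaluation grid points per curve.
#' @return Data frame with columns \code{g_rG4}, \code{g_bind}, \code{K}
#'   (mol/l) and \code{n_H}.
#' @export
zero_penalty_sweep <- function(g_rG4_grid = seq(15, 35, by = 2.5),
                               g_bind_grid = seq(8, 15, by = 1),
                               n_grid = 1001L) {
  grid <- expand.grid(g_rG4 = g_rG4_grid, g_bind = g_bind_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- energy_params(grid$g_rG4[i], grid$g_bind[i], 0)
    K <- transition_concentration(p)
    data.frame(g_rG4 = grid$g_rG4[i], g_bind = grid$g_bind[i], K = K,
               n_H = model_hill(p, n_grid = n_grid))
  })
  do.call(rbind, res)
}

#' Effect of the folded-rG4 helper state on cooperativity
#'
#' Adds the helper mode \code{1^F} (one protein bound to the still-folded
#' quadruplex with energy \code{g_rG4_bind}) and recomputes the model Hill
#' coefficient across a grid of helper energies. Weak helper binding leaves
#' the cooperativity untouched while kinetically assisting unfolding;
#' helper binding comparable to \code{g_bind} makes the folded-bound mode
#' dominate the transition and collapses the Hill coefficient toward 1.
#'
#' @param params a baseline [energy_params()] object (helper disabled).
#' @param g_rG4_bind_grid numeric vector of helper energies (kcal/mol).
#' @param ... passed to [model_hill()].
#' @return Data frame with columns \code{g_rG4_bind} and \code{n_H}.
#' @export
helper_state_effect <- function(params, g_rG4_bind_grid, ...) {
  stopifnot(inherits(params, "energy_params"), is.numeric(g_rG4_bind_grid))
  n_H <- vapply(g_rG4_bind_grid, function(g) {
    p <- params
    p$g_rG4_bind <- g
    model_hill(p, ...)
  }, numeric(1))
  data.frame(g_rG4_bind = g_rG4_bind_grid, n_H = n_H)
}
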