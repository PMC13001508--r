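#' Parameters of the three-level splicing cascade
#'
#' Splicing regulation by HNRNPH is modeled as three consecutive
#' biochemical levels: (1) cooperative HNRNPH binding to the pre-mRNA,
#' (2) regulation of multi-step spliceosome recruitment by bound HNRNPH,
#' and (3) the kinetic exon-inclusion decision during the
#' transcription-coupled commitment window.
#'
#' @param n_H1 Hill coefficient of HNRNPH binding (level 1).
#' @param K1 half-saturation HNRNPH level (level 1).
#' @param n_H2 spliceosome-regulation exponent (level 2).
#' @param K2 exon-definition threshold constant (level 2, enters the
#'   denominator un-exponentiated).
#' @param alpha fold-effect of bound HNRNPH on spliceosome recruitment.
#' @param k_CE competing (exon-skipping) rate, 1/time.
#' @param k_spl_AE alternative-exon splicing rate scale, 1/time.
#' @param tau commitment time window.
#' @param parse which reading of the level-3 expression to use:
#'   \code{"survival"} (default) is the competition-times-survival form
#'   \eqn{PSI = 1 - [k_{CE}/(k_{CE}+k_{AE}E)] e^{-k_{AE}E\tau}}, which is
#'   monotone and sigmoidal; \code{"literal"} places the factor
#'   \eqn{k_{AE}E e^{-k_{AE}E\tau}} inside the denominator and can be
#'   non-monotone.
#' @return An object of class \code{"cascade_params"}.
#' @examples
#' p <- cascade_params()
#' cascade_response(1, p)
#' @export
cascade_params <- function(n_H1 = 2, K1 = 1, n_H2 = 2, K2 = 1, alpha = 10,
                           k_CE = 1, k_spl_AE = 10, tau = 1,
                           parse = c("survival", "literal")) {
  parse <- match.arg(parse)
  vals <- c(n_H1 = n_H1, K1 = K1, n_H2 = n_H2, K2 = K2, alpha = alpha,
            k_CE = k_CE, k_spl_AE = k_spl_AE)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all cascade parameters must be positive and finite")
  }
  if (!is.finite(tau) || tau < 0) stop("tau must be >= 0")
  structure(list(n_H1 = n_H1, K1 = K1, n_H2 = n_H2, K2 = K2, alpha = alpha,
                 k_CE = k_CE, k_spl_AE = k_spl_AE, tau = tau, parse = parse),
            class = "cascade_params")
}

#' Evaluate the three cascade levels
#'
#' @param H HNRNPH level(s), >= 0 (vectorized).
#' @param params a [cascade_params()] object.
#' @return A data frame with columns \code{H}, \code{bound} (level 1:
#'   fraction of pre-mRNA bound), \code{exon_defined} (level 2: degree of
#'   exon definition) and \code{psi} (level 3: inclusion). All outputs lie
#'   in \[0, 1\].
#' @export
cascade_response <- function(H, params) {
  stopifnot(inherits(params, "cascade_params"), is.numeric(H))
  if (any(H < 0)) stop("H must be non-negative")
  p <- params
  bound <- H^p$n_H1 / (H^p$n_H1 + p$K1^p$n_H1)
  bound[H == 0] <- 0
  up <- (1 + (p$alpha - 1) * bound)^p$n_H2
  exon_defined <- up / (up + p$K2)
  rate <- p$k_spl_AE * exon_defined
  psi <- switch(p$parse,
    survival = 1 - (p$k_CE / (p$k_CE + rate)) * exp(-rate * p$tau),
    literal = 1 - p$k_CE / (p$k_CE + rate * exp(-rate * p$tau)))
  data.frame(H = H, bound = bound, exon_defined = exon_defined, psi = psi)
}

.cascade_grid <- function(params, decades = 6, n_grid = 1001L) {
  10^seq(log10(params$K1) - decades / 2, log10(params$K1) + decades / 2,
         length.out = n_grid)
}

#' Overall Hill coefficient of the cascade
#'
#' Evaluates PSI over a log-spaced HNRNPH grid centered on \code{K1},
#' min-max normalizes the curve and applies [hill_coefficient_ec()].
#' A non-monotone PSI curve (possible under the literal level-3 parse)
#' raises an error naming the parse.
#'
#' @param params a [cascade_params()] object.
#' @param decades,n_grid evaluation grid (log10 width and points).
#' @param flat_tol PSI curves spanning less than this range over the grid
#'   are treated as flat (no measurable dose-response) and raise an error
#'   rather than having numerical noise normalized into a pseudo-switch.
#' @return Overall EC10/EC90 Hill coefficient.
#' @export
overall_hill <- function(params, decades = 6, n_grid = 1001L,
                         flat_tol = 1e-6) {
  H <- .cascade_grid(params, decades, n_grid)
  psi <- cascade_response(H, params)$psi
  if (diff(range(psi)) < flat_tol) {
    stop("flat response: PSI spans less than ", flat_tol,
         " over the evaluation grid")
  }
  tryCatch(
    hill_coefficient_ec(H, psi),
    error = function(e) {
      if (grepl("not monotone", conditionMessage(e))) {
        stop("PSI(H) is not monotone under the '", params$parse,
             "' level-3 parse", call. = FALSE)
      }
      stop(e)
    })
}

#' Hill coefficient of each cascade level in isolation
#'
#' Level 1 is a pure Hill function of H (its coefficient is exactly
#' \code{n_H1}); levels 2 and 3 are evaluated against their own inputs
#' (bound fraction and degree of exon definition) on log-spaced grids in
#' (0, 1\]. A flat level (e.g. level 2 when \code{alpha = 1}) is reported
#' as \code{NA}.
#'
#' @param params a [cascade_params()] object.
#' @param n_grid grid points per level.
#' @return Named numeric vector \code{c(level1, level2, level3)}.
#' @export
per_level_hill <- function(params, n_grid = 2001L) {
  p <- params
  safe_hill <- function(x, y) {
    tryCatch(hill_coefficient_ec(x, y), error = function(e) NA_real_)
  }
  H <- .cascade_grid(p, 6, n_grid)
  l1 <- safe_hill(H, H^p$n_H1 / (H^p$n_H1 + p$K1^p$n_H1))
  b <- 10^seq(-6, 0, length.out = n_grid)
  up <- (1 + (p$alpha - 1) * b)^p$n_H2
  l2 <- safe_hill(b, up / (up + p$K2))
  e <- 10^seq(-6, 0, length.out = n_grid)
  rate <- p$k_spl_AE * e
  psi <- switch(p$parse,
    survival = 1 - (p$k_CE / (p$k_CE + rate)) * exp(-rate * p$tau),
    literal = 1 - p$k_CE / (p$k_CE + rate * exp(-rate * p$tau)))
  l3 <- safe_hill(e, psi)
  c(level1 = l1, level2 = l2, level3 = l3)
}

#' Population of cascades with log-normally distributed parameters
#'
#' Samples \code{n_runs} parameter sets, each parameter drawn independently
#' from a log-normal distribution specified by its median and log-sd, and
#' records the overall Hill coefficient per run. Runs with flat or
#' non-monotone PSI responses are flagged \code{excluded}, not dropped.
#'
#' @param n_runs number of simulation runs (default 1000).
#' @param medians named list/vector of parameter medians; defaults to the
#'   [cascade_params()] defaults.
#' @param log_sd standard deviation of log parameter values, either a
#'   single value applied to every parameter or a named vector.
#' @param seed integer seed; the draw is fully reproducible.
#' @param parse level-3 parse, see [cascade_params()].
#' @return Data frame with one row per run: the sampled parameters,
#'   \code{n_H} and \code{excluded}.
#' @export
sample_population <- function(n_runs = 1000L, medians = NULL, log_sd = 0.5,
                              seed = 1L, parse = "survival") {
  defaults <- c(n_H1 = 2, K1 = 1, n_H2 = 2, K2 = 1, alpha = 10,
                k_CE = 1, k_spl_AE = 10, tau = 1)
  if (!is.null(medians)) {
    medians <- unlist(medians)
    bad <- setdiff(names(medians), names(defaults))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    defaults[names(medians)] <- medians
  }
  if (any(defaults <= 0)) stop("medians must be positive")
  if (length(log_sd) == 1L) {
    log_sd <- stats::setNames(rep(log_sd, length(defaults)), names(defaults))
  }
  if (any(log_sd < 0)) stop("log-sd must be >= 0")
  set.seed(as.integer(seed))
  draws <- vapply(names(defaults), function(nm) {
    defaults[[nm]] * exp(stats::rnorm(n_runs, 0, log_sd[[nm]]))
  }, numeric(n_runs))
  draws <- matrix(draws, nrow = n_runs,
                  dimnames = list(NULL, names(defaults)))
  n_H <- rep(NA_real_, n_runs)
  excluded <- logical(n_runs)
  for (i in seq_len(n_runs)) {
    pr <- as.list(draws[i, ])
    pr$parse <- parse
    fit <- tryCatch(overall_hill(do.call(cascade_params, pr)),
                    error = function(e) NA_real_)
    if (is.na(fit)) excluded[i] <- TRUE else n_H[i] <- fit
  }
  out <- as.data.frame(draws)
  out$run <- seq_len(n_runs)
  out$n_H <- n_H
  out$excluded <- excluded
  out
}

#' Maximal overall Hill coefficient of a chain of three Hill stages
#'
#' Composes three pure Hill functions \eqn{h_i(x) = x^{n_i}/(x^{n_i} +
#' K_i^{n_i})} and maximizes the overall EC10/EC90 Hill coefficient of the
#' min-max-normalized composite over the two downstream thresholds
#' \eqn{K_2, K_3} (\eqn{K_1 = 1} without loss of generality). The overall
#' coefficient is bounded above by the product \eqn{n_1 n_2 n_3}; with
#' moderate per-stage cooperativity of 2 the bound is 8 and tuned
#' thresholds closely approach it.
#'
#' @param n1,n2,n3 the per-stage Hill exponents.
#' @param log10_bounds search interval for log10 of the downstream
#'   thresholds.
#' @param n_grid points of the composite evaluation grid (12 decades).
#' @return List with \code{achieved} (maximized overall n_H),
#'   \code{bound} (\code{n1 * n2 * n3}) and \code{thresholds}
#'   (the optimal \code{c(K2, K3)}).
#' @examples
#' max_chain_hill(2, 1, 1)$achieved # ~ 2
#' @export
max_chain_hill <- function(n1, n2, n3, log10_bounds = c(-6, 0),
                           n_grid = 4001L) {
  stopifnot(n1 > 0, n2 > 0, n3 > 0)
  x <- 10^seq(-6, 6, length.out = n_grid)
  obj <- function(lk) {
    y1 <- x^n1 / (x^n1 + 1)
    K2 <- 10^lk[1L]
    y2 <- y1^n2 / (y1^n2 + K2^n2)
    K3 <- 10^lk[2L]
    y3 <- y2^n3 / (y2^n3 + K3^n3)
    if (diff(range(y3)) < 1e-12) return(NA_real_)
    tryCatch(hill_coefficient_ec(x, y3), error = function(e) NA_real_)
  }
  grid <- seq(log10_bounds[1L], log10_bounds[2L], by = 0.5)
  best <- c(NA_real_, NA_real_)
  best_v <- -Inf
  for (a in grid) {
    for (b in grid) {
      v <- obj(c(a, b))
      if (!is.na(v) && v > best_v) {
        best_v <- v
        best <- c(a, b)
      }
    }
  }
  opt <- stats::optim(best, function(p) {
    v <- obj(pmin(pmax(p, log10_bounds[1L]), log10_bounds[2L]))
    if (is.na(v)) Inf else -v
  }, method = "Nelder-Mead")
  lk <- pmin(pmax(opt$par, log10_bounds[1L]), log10_bounds[2L])
  achieved <- max(best_v, -opt$value)
  list(achieved = achieved, bound = n1 * n2 * n3, thresholds = 10^lk)
}
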