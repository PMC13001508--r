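#' Constrained four-parameter logistic fit of a splicing titration
#'
#' Fits the LL.4 model
#' \deqn{f(x) = min + \frac{max - min}{1 + \exp[b(\log x - \log ec50)]}}
#' to observed splicing changes (delta PSI) across relative HNRNPH protein
#' levels by bounded least squares, with the parameter box constraints
#' \itemize{
#'   \item \code{min} in \[-max(psi_kd_control, psi_oe_control), 0\],
#'   \item \code{max} in \[0, 1 - min(psi_kd_control, psi_oe_control)\],
#'   \item \code{ec50 >= 0}, slope \code{b} unconstrained in sign.
#' }
#' The Hill coefficient is reported as \code{|b|}, with the regulatory
#' direction (enhanced / repressed by HNRNPH) carried separately from the
#' sign of the response at the extreme protein levels. Replicate
#' observations are fitted pointwise, without averaging. The optimizer is
#' multi-start L-BFGS-B over slopes \code{+-1, +-5, +-15} and midpoints
#' \code{0.7, 1.0, 1.3}; the best sum of squares wins, ties broken by the
#' smallest \code{|b|}.
#'
#' @param series data frame with numeric columns \code{levels} (relative
#'   protein level, > 0) and \code{delta_psi} (splicing change, in
#'   \[-1, 1\]); one row per observation.
#' @param psi_kd_control,psi_oe_control control-condition inclusion levels
#'   (fractions in \[0, 1\]) used for the asymptote bounds.
#' @return An object of class \code{"ll4_fit"}: a list with \code{n_H},
#'   \code{b} (signed slope), \code{min}, \code{max}, \code{ec50},
#'   \code{sse}, \code{pseudo_r2}, \code{direction}
#'   (\code{"enhanced"} / \code{"repressed"}), \code{category} (see
#'   [classify_event()]), \code{converged} and \code{fitted_fn}.
#' @examples
#' x <- exp(seq(log(0.46), log(1.76), length.out = 12))
#' y <- -0.3 + (0.05 + 0.3) / (1 + exp(10 * (log(x) - log(1))))
#' fit <- fit_ll4(data.frame(levels = x, delta_psi = y),
#'                psi_kd_control = 0.6, psi_oe_control = 0.6)
#' fit$n_H
#' @export
fit_ll4 <- function(series, psi_kd_control = 0.5, psi_oe_control = 0.5) {
  stopifnot(is.data.frame(series),
            all(c("levels", "delta_psi") %in% names(series)))
  x <- series$levels
  y <- series$delta_psi
  if (any(x <= 0)) stop("protein levels must be strictly positive")
  if (any(abs(y) > 1 + 1e-9)) stop("delta PSI must lie in [-1, 1]")
  if (any(c(psi_kd_control, psi_oe_control) < 0) ||
      any(c(psi_kd_control, psi_oe_control) > 1)) {
    stop("control PSI values must lie in [0, 1]")
  }
  if (length(unique(x)) < 5L) {
    stop("need at least 5 distinct protein levels to fit")
  }
  lo_min <- -max(psi_kd_control, psi_oe_control)
  hi_max <- 1 - min(psi_kd_control, psi_oe_control)

  degenerate <- (max(y) - min(y)) == 0
  lx <- log(x)
  model <- function(p) {
    # p = (b, mn, mx, log_e)
    p[2L] + (p[3L] - p[2L]) / (1 + exp(p[1L] * (lx - p[4L])))
  }
  sse <- function(p) sum((y - model(p))^2)

  mn0 <- min(0, max(lo_min, min(y)))
  mx0 <- max(0, min(hi_max, max(y)))
  lower <- c(-50, lo_min, 0, log(1e-3))
  upper <- c(50, 0, hi_max, log(1e3))

  best <- NULL
  if (!degenerate) {
    for (b0 in c(1, -1, 5, -5, 15, -15)) {
      for (e0 in c(0.7, 1.0, 1.3)) {
        start <- c(b0, mn0, mx0, log(e0))
        fit <- tryCatch(
          stats::optim(start, sse, method = "L-BFGS-B", lower = lower,
                       upper = upper,
                       control = list(maxit = 500L, factr = 1e4)),
          error = function(e) NULL)
        if (is.null(fit)) next
        better <- is.null(best) ||
          fit$value < best$value * (1 - 1e-9) ||
          (abs(fit$value - best$value) <= 1e-9 * max(best$value, 1e-300) &&
             abs(fit$par[1L]) < abs(best$par[1L]))
        if (better) best <- fit
      }
    }
  }

  converged <- !degenerate && !is.null(best) && best$convergence == 0L
  if (!converged) {
    out <- list(n_H = NA_real_, b = NA_real_, min = NA_real_, max = NA_real_,
                ec50 = NA_real_, sse = NA_real_, pseudo_r2 = NA_real_,
                direction = NA_character_, category = "excluded",
                converged = FALSE, fitted_fn = NULL)
    class(out) <- "ll4_fit"
    return(out)
  }

  p <- best$par
  fitted_fn <- function(xn) {
    p[2L] + (p[3L] - p[2L]) / (1 + exp(p[1L] * (log(xn) - p[4L])))
  }
  direction <- if (fitted_fn(max(x)) >= fitted_fn(min(x))) "enhanced"
               else "repressed"
  out <- list(n_H = abs(p[1L]), b = p[1L], min = p[2L], max = p[3L],
              ec50 = exp(p[4L]), sse = best$value, pseudo_r2 = NA_real_,
              direction = direction, category = NA_character_,
              converged = TRUE, fitted_fn = fitted_fn)
  class(out) <- "ll4_fit"
  out$pseudo_r2 <- pseudo_r2(out, series)
  out$category <- classify_event(out)
  out
}

#' Pseudo R-squared of a dose-response fit
#'
#' \eqn{1 - SS_{res} / SS_{tot}}, with the total sum of squares taken
#' around the mean of the observed delta PSI. May be negative for fits
#' worse than the mean; undefined (returned as \code{NA}) when the
#' observations have zero variance.
#'
#' @param fit an [fit_ll4()] result.
#' @param series the titration data frame the fit was computed on.
#' @return A single number, or \code{NA} when undefined.
#' @export
pseudo_r2 <- function(fit, series) {
  stopifnot(inherits(fit, "ll4_fit"))
  if (!isTRUE(fit$converged)) return(NA_real_)
  y <- series$delta_psi
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(NA_real_)
  ss_res <- sum((y - fit$fitted_fn(series$levels))^2)
  1 - ss_res / ss_tot
}

#' Classify a splicing event by cooperativity and direction
#'
#' Events with pseudo R-squared below 0.75 (or an unconverged /
#' undefined fit) are \code{"excluded"}. The remainder are cooperative
#' when \code{n_H >= 2}, crossed with the regulatory direction:
#' \code{"coop_enhanced"}, \code{"coop_repressed"},
#' \code{"noncoop_enhanced"}, \code{"noncoop_repressed"}.
#'
#' @param fit an [fit_ll4()] result (with \code{pseudo_r2} filled in).
#' @param r2_threshold goodness-of-fit cutoff (default 0.75).
#' @param coop_threshold Hill-coefficient cutoff for cooperativity
#'   (default 2).
#' @return A category string.
#' @export
classify_event <- function(fit, r2_threshold = 0.75, coop_threshold = 2) {
  stopifnot(inherits(fit, "ll4_fit"))
  if (!isTRUE(fit$converged) || is.na(fit$pseudo_r2) ||
      fit$pseudo_r2 < r2_threshold) {
    return("excluded")
  }
  coop <- if (fit$n_H >= coop_threshold) "coop" else "noncoop"
  paste(coop, fit$direction, sep = "_")
}

#' Fit and classify a table of titration series
#'
#' Convenience wrapper applying [fit_ll4()] per event.
#'
#' @param titrations data frame with columns \code{event_id},
#'   \code{levels}, \code{delta_psi} and optionally
#'   \code{psi_kd_control}, \code{psi_oe_control} (constant per event;
#'   default 0.5).
#' @return Data frame with one row per event: \code{event_id}, \code{n_H},
#'   \code{min}, \code{max}, \code{ec50}, \code{pseudo_r2},
#'   \code{direction}, \code{category}.
#' @export
fit_titration_table <- function(titrations) {
  stopifnot(all(c("event_id", "levels", "delta_psi") %in% names(titrations)))
  ids <- unique(titrations$event_id)
  rows <- lapply(ids, function(id) {
    d <- titrations[titrations$event_id == id, , drop = FALSE]
    kd <- if ("psi_kd_control" %in% names(d)) d$psi_kd_control[1L] else 0.5
    oe <- if ("psi_oe_control" %in% names(d)) d$psi_oe_control[1L] else 0.5
    f <- fit_ll4(d, psi_kd_control = kd, psi_oe_control = oe)
    data.frame(event_id = id, n_H = f$n_H, min = f$min, max = f$max,
               ec50 = f$ec50, pseudo_r2 = f$pseudo_r2,
               direction = if (is.na(f$direction)) NA_character_
                           else f$direction,
               category = f$category, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
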