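#' Profile-likelihood confidence interval for a scalar quantity
#'
#' Generic penalized profiling over an arbitrary smooth scalar function of
#' the parameter vector. For each trial value `g0` the objective
#' `m2ll(par) + w (q(par) - g0)^2` is minimized (warm-started from the
#' previous solution), giving the profiled -2LL; the interval endpoint is
#' the value of `g0` at which the profile crosses
#' `m2ll_hat + qchisq(level, 1)`. The initial step size is chosen from the
#' local curvature of the profile, and the crossing is refined by
#' bisection. Endpoints clamped at `bounds` indicate the quantity is at its
#' natural boundary (e.g. a proportion at 0 or 1).
#'
#' @param objective function(par) returning the -2 log-likelihood.
#' @param par_hat parameter vector at the optimum.
#' @param m2ll_hat -2LL at the optimum.
#' @param qfun function(par) returning the scalar quantity.
#' @param level confidence level (default 0.95).
#' @param bounds length-2 numeric, natural range of the quantity.
#' @param penalty_weight weight of the quadratic pin; large enough that the
#'   constraint is effectively exact for quantities of magnitude ~1.
#' @param tol absolute tolerance on the interval endpoint.
#' @return named numeric `c(lower, upper)`.
#' @export
profile_interval <- function(objective, par_hat, m2ll_hat, qfun,
                             level = 0.95, bounds = c(-Inf, Inf),
                             penalty_weight = 1e7, tol = 5e-4) {
  crit <- m2ll_hat + qchisq(level, 1)
  ghat <- unname(qfun(par_hat))
  ctrl <- list(eval.max = 2000, iter.max = 500, rel.tol = 1e-9)
  pfit <- function(g0, start) {
    pen <- function(p) objective(p) + penalty_weight * (qfun(p) - g0)^2
    r <- tryCatch(nlminb(start, pen, control = ctrl),
                  error = function(e) NULL)
    if (is.null(r)) return(list(par = start, m2 = Inf))
    list(par = r$par, m2 = objective(r$par))
  }
  side <- function(dir) {
    bound <- if (dir > 0) bounds[2] else bounds[1]
    if (is.finite(bound) && dir * (bound - ghat) <= tol) return(bound)
    # curvature probe to scale the step
    probe <- min(0.02, if (is.finite(bound)) abs(bound - ghat) / 2 else Inf)
    if (probe <= 0) return(ghat)
    fp <- pfit(ghat + dir * probe, par_hat)
    curv <- max(fp$m2 - m2ll_hat, 1e-4) / probe^2
    halfwidth <- sqrt((crit - m2ll_hat) / curv)
    step <- max(min(0.6 * halfwidth, 0.25), 0.005)
    par <- fp$par
    gprev <- ghat
    for (i in seq_len(200)) {
      g0 <- ghat + dir * step * i
      clamped <- FALSE
      if (is.finite(bound) && dir * (g0 - bound) >= 0) {
        g0 <- bound
        clamped <- TRUE
      }
      f <- pfit(g0, par)
      par <- f$par
      if (f$m2 > crit) {
        lo <- gprev
        hi <- g0
        while (abs(hi - lo) > tol) {
          mid <- (lo + hi) / 2
          fm <- pfit(mid, par)
          par <- fm$par
          if (fm$m2 > crit) hi <- mid else lo <- mid
        }
        return((lo + hi) / 2)
      }
      if (clamped) return(bound)
      gprev <- g0
    }
    gprev
  }
  c(lower = side(-1), upper = side(+1))
}
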