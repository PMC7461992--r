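#' CNS-OT index of a continuous hyperoxic exposure
#'
#' Computes the power-law dose index \eqn{K = t^2 \cdot PO_2^{\,c}} for a
#' single uninterrupted oxygen exposure. The product is evaluated in the log
#' domain so that large exponents (c up to ~13) cannot overflow
#' intermediate terms.
#'
#' @param t Exposure time, minutes (>= 0). Vectorised.
#' @param po2 Oxygen partial pressure, bar (> 0). Vectorised.
#' @param c PO2 exponent, e.g. \code{cns_params("DRY_REST")$c}.
#' @return The CNS-OT index in min^2 * bar^c; 0 where \code{t = 0}.
#' @examples
#' cns_ot_index(60, 2.5, cns_params("DRY_REST")$c)
#' @export
cns_ot_index <- function(t, po2, c) {
  stopifnot(is.numeric(t), is.numeric(po2), is.numeric(c))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (any(po2 <= 0)) stop("po2 must be > 0", call. = FALSE)
  ifelse(t == 0, 0, exp(2 * log(t) + c * log(po2)))
}

.check_risk_capable <- function(params) {
  if (inherits(params, "met_interp")) {
    stop("interpolated-MET parameter sets carry no sigma; ",
         "risk computation is only available at 1 and 4.4 MET",
         call. = FALSE)
  }
  if (!inherits(params, "risk_params")) {
    stop("params must be a risk_params object (see cns_params())",
         call. = FALSE)
  }
  invisible(params)
}

#' Risk of CNS oxygen toxicity at a given index
#'
#' The model takes \eqn{\frac{1}{2}\ln K} at symptom onset to be normally
#' distributed with location \code{mu} and scale \code{sigma}, so the risk
#' accumulated by the time the index reaches K is
#' \eqn{\Phi\!\left((\tfrac{1}{2}\ln K - \mu)/\sigma\right)}.
#' \code{K = 0} maps to risk 0 (the continuous limit), so empty profiles
#' evaluate cleanly.
#'
#' @param K CNS-OT index (>= 0). Vectorised.
#' @param params A \code{\link{risk_params}} object.
#' @return Probability of CNS-OT in [0, 1].
#' @examples
#' p <- cns_params("IMMERSED_REST")
#' cns_ot_risk(p$kc, p)  # ~0.5 at the critical index
#' @export
cns_ot_risk <- function(K, params) {
  .check_risk_capable(params)
  stopifnot(is.numeric(K))
  if (any(K < 0)) stop("K must be >= 0", call. = FALSE)
  ifelse(K == 0, 0, stats::pnorm((0.5 * log(K) - params$mu) / params$sigma))
}

#' Standard-normal deviate of the risk transform
#'
#' @inheritParams cns_ot_risk
#' @param K CNS-OT index (> 0).
#' @return \eqn{(\tfrac{1}{2}\ln K - \mu)/\sigma}; \code{cns_ot_risk(K, p)}
#'   equals \code{pnorm(cns_ot_z(K, p))} exactly.
#' @export
cns_ot_z <- function(K, params) {
  .check_risk_capable(params)
  stopifnot(is.numeric(K))
  if (any(K <= 0)) stop("K must be > 0", call. = FALSE)
  (0.5 * log(K) - params$mu) / params$sigma
}

#' Oxygen time reaching a target risk
#'
#' Inverts the risk model: the continuous exposure time at \code{po2} for
#' which the accumulated risk equals \code{p}. Closed form
#' \eqn{t = \exp\{\mu + \sigma\Phi^{-1}(p) - (c/2)\ln PO_2\}}.
#'
#' @param p Target probability, strictly in (0, 1). Vectorised.
#' @param po2 Oxygen partial pressure, bar (> 0).
#' @param params A \code{\link{risk_params}} object.
#' @return Time in minutes.
#' @examples
#' time_for_risk(0.5, 2.83, cns_params("IMMERSED_REST"))
#' @export
time_for_risk <- function(p, po2, params) {
  .check_risk_capable(params)
  stopifnot(is.numeric(p), is.numeric(po2))
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)", call. = FALSE)
  if (any(po2 <= 0)) stop("po2 must be > 0", call. = FALSE)
  exp(params$mu + params$sigma * stats::qnorm(p) - (params$c / 2) * log(po2))
}

#' Interpolate power-equation parameters over metabolic rate
#'
#' For submerged humans the PO2 exponent falls linearly with metabolic rate,
#' \eqn{c = 12.14 - 1.21 \cdot MET}, while the critical index stays at
#' \eqn{K_c = 6.57 \times 10^7}. The scale sigma is unknown between the two
#' fitted endpoints, so the interpolated set cannot be used for risk
#' computation: \code{cns_ot_risk} and friends refuse it.
#'
#' @param met Metabolic rate in MET units, within [1, 4.4] unless
#'   \code{extrapolate = TRUE}.
#' @param extrapolate Allow MET outside [1, 4.4]; the result then carries a
#'   \code{"warning"} attribute and a warning is raised.
#' @return An object of class \code{"met_interp"} with fields \code{met},
#'   \code{c} and \code{kc} (no \code{sigma}).
#' @examples
#' interpolate_met(1)$c    # 10.93
#' interpolate_met(2.7)$c
#' @export
interpolate_met <- function(met, extrapolate = FALSE) {
  stopifnot(is.numeric(met), length(met) == 1L)
  out <- structure(list(met = met, c = 12.14 - 1.21 * met, kc = 6.57e7),
                   class = "met_interp")
  if (met < 1 || met > 4.4) {
    if (!extrapolate) {
      stop("met must lie within [1, 4.4]; pass extrapolate = TRUE to override",
           call. = FALSE)
    }
    msg <- sprintf("MET %.3g lies outside the calibrated range [1, 4.4]", met)
    warning(msg, call. = FALSE)
    attr(out, "warning") <- msg
  }
  if (out$c <= 0) stop("interpolated exponent is non-positive at met = ", met,
                       call. = FALSE)
  out
}

#' @export
print.met_interp <- function(x, ...) {
  cat(sprintf("Interpolated power-equation parameters at %.2f MET\n", x$met))
  cat(sprintf("  c = %.4g   Kc = %.3e   (no sigma: not risk-capable)\n",
              x$c, x$kc))
  if (!is.null(attr(x, "warning"))) cat("  note:", attr(x, "warning"), "\n")
  invisible(x)
}
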