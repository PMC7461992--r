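# Maximum-likelihood fitting of the lognormal accelerated-failure-time model
# underlying the power equation, from right-censored exposure records.
#
# Model: for a record at pressure po2, the log symptom-onset time is
#   ln T ~ Normal(mu - (c/2) ln po2, sigma),
# which is exactly "half the log CNS-OT index at toxicity ~ Normal(mu, sigma)":
# 0.5 ln K = ln t + (c/2) ln po2.

#' Exposure records for survival fitting
#'
#' @param po2 Oxygen partial pressure per record, bar (> 0).
#' @param time Minutes: symptom-onset time for events, exposure end for
#'   censored records (> 0).
#' @param event Logical or 0/1: did CNS-OT symptoms occur.
#' @param condition Optional condition label ("immersed"/"dry") recycled
#'   across records.
#' @param source Optional source tag.
#' @return A data.frame of class \code{"exposure_dataset"} with columns
#'   \code{po2}, \code{time}, \code{event} (and optional \code{condition},
#'   \code{source}).
#' @export
exposure_dataset <- function(po2, time, event, condition = NULL,
                             source = NULL) {
  stopifnot(is.numeric(po2), is.numeric(time))
  event <- as.logical(event)
  n <- length(po2)
  if (length(time) != n || length(event) != n) {
    stop("po2, time and event must have equal length", call. = FALSE)
  }
  if (any(time <= 0)) stop("time must be > 0", call. = FALSE)
  if (any(po2 <= 0)) stop("po2 must be > 0", call. = FALSE)
  if (any(is.na(event))) stop("event must be 0/1 with no NAs", call. = FALSE)
  df <- data.frame(po2 = po2, time = time, event = event)
  if (!is.null(condition)) df$condition <- rep_len(condition, n)
  if (!is.null(source)) df$source <- rep_len(source, n)
  class(df) <- c("exposure_dataset", "data.frame")
  df
}

.as_dataset <- function(x) {
  if (inherits(x, "exposure_dataset")) return(x)
  if (is.data.frame(x) && all(c("po2", "time", "event") %in% names(x))) {
    return(exposure_dataset(x$po2, x$time, x$event,
                            condition = x$condition, source = x$source))
  }
  stop("expected an exposure_dataset or a data.frame with columns ",
       "po2, time, event", call. = FALSE)
}

#' Read and write exposure-record files
#'
#' Delimited text with a header and columns
#' \code{po2_bar,time_min,event,condition[,source,excluded]}; \code{event}
#' coded 0/1. Records flagged \code{excluded=1} are dropped on reading unless
#' \code{keep_excluded = TRUE}.
#'
#' @param path File path.
#' @param dataset An \code{\link{exposure_dataset}}.
#' @param keep_excluded Keep rows flagged as excluded.
#' @export
read_records <- function(path, keep_excluded = FALSE) {
  if (!file.exists(path)) stop("no such records file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("po2_bar", "time_min", "event")
  if (!all(need %in% names(df))) {
    stop("records file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!keep_excluded && "excluded" %in% names(df)) {
    df <- df[!(df$excluded %in% c(1, TRUE, "1", "TRUE")), , drop = FALSE]
  }
  exposure_dataset(df$po2_bar, df$time_min, df$event,
                   condition = df$condition, source = df$source)
}

#' @rdname read_records
#' @export
write_records <- function(dataset, path) {
  ds <- .as_dataset(dataset)
  out <- data.frame(po2_bar = ds$po2, time_min = ds$time,
                    event = as.integer(ds$event))
  if (!is.null(ds$condition)) out$condition <- ds$condition
  if (!is.null(ds$source)) out$source <- ds$source
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Negative log-likelihood of the lognormal AFT model
#'
#' Events contribute the negative log lognormal density of the onset time at
#' location \eqn{\mu - (c/2)\ln PO_2} and scale \eqn{\sigma}; censored
#' records contribute the negative log survival. Evaluating the model's
#' event-time CDF at (t, po2) reproduces the closed-form risk transform
#' exactly.
#'
#' @param c,mu,sigma Model parameters; \code{sigma > 0}.
#' @param dataset An \code{\link{exposure_dataset}} (or compatible
#'   data.frame) with at least one record.
#' @return The scalar negative log-likelihood.
#' @export
neg_log_likelihood <- function(c, mu, sigma, dataset) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  ds <- .as_dataset(dataset)
  if (nrow(ds) == 0L) stop("empty dataset", call. = FALSE)
  r <- (log(ds$time) - (mu - (c / 2) * log(ds$po2))) / sigma
  ll_event <- stats::dnorm(r, log = TRUE) - log(sigma) - log(ds$time)
  ll_cens <- stats::pnorm(r, lower.tail = FALSE, log.p = TRUE)
  -sum(ifelse(ds$event, ll_event, ll_cens))
}

# nll and analytic gradient in theta = (c, mu, log sigma); vectorised over
# records. Used by the optimiser; neg_log_likelihood() is the public surface.
.nll_obj <- function(theta, lt, lp, event) {
  cc <- theta[1]; mu <- theta[2]; sigma <- exp(theta[3])
  r <- (lt - mu + (cc / 2) * lp) / sigma
  -sum(ifelse(event,
              stats::dnorm(r, log = TRUE) - log(sigma) - lt,
              stats::pnorm(r, lower.tail = FALSE, log.p = TRUE)))
}

.nll_grad <- function(theta, lt, lp, event) {
  cc <- theta[1]; mu <- theta[2]; sigma <- exp(theta[3])
  r <- (lt - mu + (cc / 2) * lp) / sigma
  # d(-ll)/dr: events r; censored inverse Mills ratio phi(r)/Phi(-r)
  dr <- ifelse(event, r,
               exp(stats::dnorm(r, log = TRUE) -
                   stats::pnorm(r, lower.tail = FALSE, log.p = TRUE)))
  g_c <- sum(dr * lp / (2 * sigma))
  g_mu <- sum(-dr / sigma)
  # d(-ll)/dsigma: events (1 - r^2)/sigma... careful: events add log sigma
  g_ls <- sum(ifelse(event, 1 - r^2, -dr * r))
  c(g_c, g_mu, g_ls)
}

#' Fit the power-equation parameters by maximum likelihood
#'
#' Minimises the right-censored lognormal AFT negative log-likelihood over
#' \eqn{(c, \mu, \ln\sigma)} by multi-start quasi-Newton (BFGS with analytic
#' gradient, five deterministic starting points). Standard errors come from
#' the inverse observed information; the critical index and its lognormal CI
#' are derived as \eqn{\exp(2\mu \pm 1.96 \cdot 2\,SE_\mu)}.
#'
#' @param dataset An \code{\link{exposure_dataset}} with at least one event
#'   and at least two distinct PO2 levels (otherwise c is unidentifiable).
#' @param init Optional named start point \code{c(c=, mu=, sigma=)}; when
#'   given it replaces the multi-start sweep.
#' @return An object of class \code{"cnsot_fit"}: estimates, SEs, 95\% CIs,
#'   \code{kc} with CI, \code{loglik}, \code{vcov} (on the
#'   \eqn{(c,\mu,\sigma)} scale), convergence flag and evaluation counts.
#' @examples
#' des <- simulation_design(po2 = c(2.4, 3.0), n = 150, censor_time = 120,
#'                          c = 10.93, mu = 8.99, sigma = 0.81, seed = 1)
#' fit_mle(simulate_records(des))
#' @export
fit_mle <- function(dataset, init = NULL) {
  ds <- .as_dataset(dataset)
  if (!any(ds$event)) {
    stop("dataset has no events; the model is not identifiable from ",
         "censored records alone", call. = FALSE)
  }
  if (length(unique(ds$po2)) < 2L) {
    stop("dataset has a single po2 level; the exponent c is not ",
         "identifiable", call. = FALSE)
  }
  lt <- log(ds$time); lp <- log(ds$po2); event <- ds$event

  starts <- if (!is.null(init)) {
    list(c(init[["c"]], init[["mu"]], log(init[["sigma"]])))
  } else {
    s0 <- max(stats::sd(lt[event]), 0.2, na.rm = TRUE)
    lapply(c(2, 6, 10, 14, 18), function(c0) {
      c(c0, mean(lt[event]) + (c0 / 2) * mean(lp[event]), log(s0))
    })
  }

  best <- NULL
  for (th0 in starts) {
    op <- tryCatch(
      stats::optim(th0, .nll_obj, gr = .nll_grad, lt = lt, lp = lp,
                   event = event, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best)) stop("optimisation failed from every start", call. = FALSE)

  th <- best$par
  grad <- .nll_grad(th, lt, lp, event)
  converged <- best$convergence == 0 &&
    sqrt(sum(grad^2)) < 1e-4 * max(1, abs(best$value))

  H <- stats::optimHess(th, .nll_obj, gr = .nll_grad, lt = lt, lp = lp,
                        event = event)
  V_theta <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 3, 3))
  sigma <- exp(th[3])
  J <- diag(c(1, 1, sigma))           # delta method: log sigma -> sigma
  V <- J %*% V_theta %*% J
  dimnames(V) <- list(c("c", "mu", "sigma"), c("c", "mu", "sigma"))

  est <- c(c = th[1], mu = th[2], sigma = sigma)
  se <- sqrt(pmax(diag(V), 0))
  z <- stats::qnorm(0.975)
  ci <- cbind(lower95 = est - z * se, upper95 = est + z * se)
  kc <- exp(2 * th[2])
  kc_ci <- exp(2 * th[2] + c(-1, 1) * z * 2 * se["mu"])

  structure(list(estimates = est, se = se, ci = ci, vcov = V,
                 kc = kc, kc_ci = kc_ci,
                 loglik = -best$value, converged = converged,
                 counts = best$counts, n = nrow(ds),
                 n_events = sum(event)),
            class = "cnsot_fit")
}

#' @export
print.cnsot_fit <- function(x, ...) {
  cat(sprintf("Power-equation MLE fit: %d records, %d events, logLik %.3f%s\n",
              x$n, x$n_events, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(estimate = x$estimates, se = x$se,
                    lower95 = x$ci[, 1], upper95 = x$ci[, 2])
  tab <- rbind(tab, Kc = c(x$kc, NA, x$kc_ci))
  print(signif(as.matrix(tab), 4))
  invisible(x)
}

#' Export a fit as a JSON report
#'
#' Structured text mirroring the published solution table: one entry per term
#' (\code{c}, \code{mu}, \code{sigma}, \code{Kc}) with estimate, SE and 95\%
#' confidence bounds.
#'
#' @param fit A \code{cnsot_fit}.
#' @param path Optional file path; when \code{NULL} the JSON string is
#'   returned.
#' @export
fit_report <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "cnsot_fit"))
  terms <- lapply(c("c", "mu", "sigma"), function(tm) {
    list(term = tm, estimate = unname(fit$estimates[tm]),
         se = unname(fit$se[tm]),
         lower95 = unname(fit$ci[tm, 1]), upper95 = unname(fit$ci[tm, 2]))
  })
  terms <- c(terms, list(list(term = "Kc", estimate = fit$kc,
                              lower95 = fit$kc_ci[1],
                              upper95 = fit$kc_ci[2])))
  doc <- list(terms = terms, loglik = fit$loglik, n = fit$n,
              n_events = fit$n_events, converged = fit$converged)
  if (is.null(path)) {
    jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
  }
}

#' Wald test for equality of immersed and dry parameters
#'
#' Joint chi-square test on the 3-vector of parameter differences
#' \eqn{(c, \mu, \sigma)} between two fits, using the sum of their
#' covariance matrices; 3 degrees of freedom.
#'
#' @param fit1,fit2 Converged \code{cnsot_fit} objects.
#' @return A \code{"cnsot_test"} with the statistic, df and p-value.
#' @export
wald_test <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "cnsot_fit"), inherits(fit2, "cnsot_fit"))
  if (!fit1$converged || !fit2$converged) {
    stop("both fits must have converged", call. = FALSE)
  }
  d <- fit1$estimates - fit2$estimates
  V <- fit1$vcov + fit2$vcov
  stat <- drop(t(d) %*% solve(V, d))
  structure(list(method = "wald", statistic = stat, df = 3L,
                 p_value = stats::pchisq(stat, df = 3, lower.tail = FALSE)),
            class = "cnsot_test")
}

#' Likelihood-ratio test for equality of immersed and dry parameters
#'
#' Fits the two datasets separately and pooled; the statistic is twice the
#' log-likelihood gain of the separate model, chi-square with 3 df under
#' equality.
#'
#' @param dataset1,dataset2 Two \code{\link{exposure_dataset}}s.
#' @return A \code{"cnsot_test"}; the component fits are attached as
#'   \code{fits}.
#' @export
lr_test <- function(dataset1, dataset2) {
  ds1 <- .as_dataset(dataset1); ds2 <- .as_dataset(dataset2)
  f1 <- fit_mle(ds1)
  f2 <- fit_mle(ds2)
  pooled <- exposure_dataset(c(ds1$po2, ds2$po2), c(ds1$time, ds2$time),
                             c(ds1$event, ds2$event))
  fp <- fit_mle(pooled)
  stat <- max(0, 2 * (f1$loglik + f2$loglik - fp$loglik))
  structure(list(method = "likelihood_ratio", statistic = stat, df = 3L,
                 p_value = stats::pchisq(stat, df = 3, lower.tail = FALSE),
                 fits = list(fit1 = f1, fit2 = f2, pooled = fp)),
            class = "cnsot_test")
}

#' @export
print.cnsot_test <- function(x, ...) {
  lab <- switch(x$method, wald = "Wald", likelihood_ratio = "Likelihood ratio")
  cat(sprintf("%s test of parameter equality: chi-sq = %.4g, df = %d, p = %.3g\n",
              lab, x$statistic, x$df, x$p_value))
  invisible(x)
}
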