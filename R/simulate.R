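# Synthetic exposure records drawn from the fitted lognormal AFT model, and
# the embedded compilation of historical group-level exposures at rest.

#' Design of a simulated exposure experiment
#'
#' @param po2 PO2 levels, bar (at least 2 distinct levels for a fit-ready
#'   dataset).
#' @param n Records per level (scalar or per level, >= 1).
#' @param censor_time Maximum exposure (censoring) time per level, minutes
#'   (> 0; scalar or per level).
#' @param c,mu,sigma True model parameters; \code{sigma >= 0}
#'   (\code{sigma = 0} is the degenerate deterministic limit, allowed for
#'   testing).
#' @param seed Integer RNG seed.
#' @param condition Condition label attached to the records.
#' @return An object of class \code{"simulation_design"}.
#' @export
simulation_design <- function(po2, n, censor_time, c, mu, sigma, seed = 1L,
                              condition = "immersed") {
  stopifnot(is.numeric(po2), length(po2) >= 1L, all(po2 > 0))
  n <- rep_len(as.integer(n), length(po2))
  censor_time <- rep_len(censor_time, length(po2))
  if (any(n < 1L)) stop("n must be >= 1 per level", call. = FALSE)
  if (any(censor_time <= 0)) stop("censor times must be > 0", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (c <= 0) stop("c must be > 0", call. = FALSE)
  structure(list(po2 = po2, n = n, censor_time = censor_time,
                 c = c, mu = mu, sigma = sigma,
                 seed = as.integer(seed), condition = condition),
            class = "simulation_design")
}

#' Simulate right-censored exposure records from the model
#'
#' For each record at level \code{po2}, a symptom-onset time is drawn
#' lognormal with location \eqn{\mu - (c/2)\ln PO_2} and scale \eqn{\sigma}.
#' Onsets at or before the level's censor time become events at their onset
#' time; later onsets become censored records at the censor time. The draw is
#' deterministic given the design's seed.
#'
#' @param design A \code{\link{simulation_design}}.
#' @return An \code{\link{exposure_dataset}}.
#' @examples
#' des <- simulation_design(po2 = c(2.3, 2.9), n = 50, censor_time = 120,
#'                          c = 10.93, mu = 8.99, sigma = 0.81, seed = 7)
#' head(simulate_records(des))
#' @export
simulate_records <- function(design) {
  if (!inherits(design, "simulation_design")) {
    stop("design must be a simulation_design", call. = FALSE)
  }
  po2 <- rep(design$po2, design$n)
  cens <- rep(design$censor_time, design$n)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(design$seed)
  loc <- design$mu - (design$c / 2) * log(po2)
  onset <- if (design$sigma == 0) exp(loc) else
    exp(stats::rnorm(length(po2), loc, design$sigma))
  event <- onset <= cens
  exposure_dataset(po2, time = pmin(onset, cens), event = event,
                   condition = design$condition)
}

# Historical at-rest hyperoxic exposure groups (1946-1986 naval compilations):
# immersed in thermoneutral water (n = 219) or dry chamber (n = 507), plus
# one dry group of 14 symptom-free 120-min exposures at 2.54 bar that was
# excluded from the original fit on goodness-of-fit grounds.
.exposure_groups <- data.frame(
  condition = c(rep("immersed", 3), rep("dry", 8)),
  po2       = c(4.08, 3.44, 2.83,
                2.83, 3.44, 4.08, 2.83, 3.74, 4.05, 2.80, 2.54),
  time_mean = c(18.4, 33.0, 57.2,
                117.6, 62.1, 15.8, 122.0, 28.4, 26.3, 29.9, 120.0),
  time_sd   = c(12.5, 23.0, 22.8,
                17.0, 36.0, 6.7, 45.4, 20.8, 11.2, 1.0, 0.0),
  n         = c(13L, 51L, 155L,
                17L, 54L, 8L, 6L, 36L, 17L, 369L, 14L),
  events    = c(11L, 46L, 48L,
                14L, 52L, 1L, 5L, 36L, 17L, 11L, 0L),
  excluded  = c(rep(FALSE, 10), TRUE),
  stringsAsFactors = FALSE
)

#' Historical at-rest exposure groups
#'
#' Group-level summaries of the hyperoxic exposures at rest used to fit the
#' at-rest power equations: condition, PO2, mean (SD) exposure time, group
#' size and CNS-OT symptom count. One dry group (PO2 2.54 bar, 120 min, 14
#' exposures, no symptoms) is carried with \code{excluded = TRUE}: it was
#' left out of the original analysis after a goodness-of-fit assessment, and
#' the default here drops it the same way.
#'
#' @param keep_excluded Include the excluded group.
#' @return A data.frame with columns \code{condition}, \code{po2},
#'   \code{time_mean}, \code{time_sd}, \code{n}, \code{events},
#'   \code{excluded}.
#' @examples
#' g <- rest_exposure_groups()
#' aggregate(cbind(n, events) ~ condition, g, sum)
#' @export
rest_exposure_groups <- function(keep_excluded = FALSE) {
  g <- .exposure_groups
  if (!keep_excluded) g <- g[!g$excluded, , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Write group summaries as delimited text
#'
#' @param groups A data.frame as returned by
#'   \code{\link{rest_exposure_groups}}.
#' @param path File path.
#' @export
write_groups <- function(groups, path) {
  utils::write.csv(groups, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Expand group summaries into individual demonstration records
#'
#' The individual exposure logs behind the group summaries are not published,
#' so this reconstruction is demonstration data only, not inference-grade:
#' each group's times are drawn from a lognormal whose mean and SD match the
#' printed moments (exact ties when SD = 0), with the first \code{events}
#' draws labelled events and the rest censored.
#'
#' Moment match: \eqn{s_{log}^2 = \ln(1 + SD^2/m^2)},
#' \eqn{m_{log} = \ln m - s_{log}^2/2}.
#'
#' @param groups Group summaries (see \code{\link{rest_exposure_groups}}).
#' @param seed Integer RNG seed.
#' @return An \code{\link{exposure_dataset}} with attribute
#'   \code{reconstructed = TRUE}.
#' @export
expand_groups <- function(groups, seed = 1L) {
  stopifnot(is.data.frame(groups),
            all(c("po2", "time_mean", "time_sd", "n", "events") %in%
                  names(groups)))
  if (any(groups$time_mean <= 0) || any(groups$time_sd < 0)) {
    stop("group moments must satisfy mean > 0 and SD >= 0", call. = FALSE)
  }
  if (any(groups$events < 0 | groups$events > groups$n)) {
    stop("events must lie in [0, n] per group", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  recs <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    if (g$time_sd == 0) {
      tms <- rep(g$time_mean, g$n)
    } else {
      s2 <- log(1 + (g$time_sd / g$time_mean)^2)
      tms <- stats::rlnorm(g$n, meanlog = log(g$time_mean) - s2 / 2,
                           sdlog = sqrt(s2))
    }
    data.frame(po2 = g$po2, time = tms,
               event = seq_len(g$n) <= g$events,
               condition = if ("condition" %in% names(g)) g$condition else NA)
  })
  df <- do.call(rbind, recs)
  out <- exposure_dataset(df$po2, df$time, df$event,
                          condition = df$condition)
  attr(out, "reconstructed") <- TRUE
  out
}
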