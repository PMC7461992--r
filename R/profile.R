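# Exposure profiles: ordered oxygen / air-break segments and the
# equivalent-time accumulation of the CNS-OT index across them.

#' Recovery rate of the CNS-OT index on air, per minute
#' @export
CNS_RECOVERY_RATE <- 0.079

#' One segment of an exposure profile
#'
#' @param po2 Oxygen partial pressure during the segment, bar. For air
#'   segments this is the (low) inspired PO2 and contributes no accrual.
#' @param duration Segment duration, minutes (>= 0).
#' @param kind \code{"oxygen"}, \code{"air"}, or \code{NA} to auto-classify
#'   by PO2 against \code{threshold} (below it = air).
#' @param threshold Auto-classification cutoff in bar; exposures that accrue
#'   CNS-OT all sit well above 1 bar, so the default is conservative.
#' @return A one-row data.frame with columns po2, duration, kind.
#' @export
segment <- function(po2, duration, kind = NA_character_, threshold = 1.0) {
  stopifnot(is.numeric(po2), length(po2) == 1L,
            is.numeric(duration), length(duration) == 1L)
  if (duration < 0) stop("duration must be >= 0", call. = FALSE)
  if (po2 < 0) stop("po2 must be >= 0", call. = FALSE)
  if (is.na(kind)) kind <- if (po2 < threshold) "air" else "oxygen"
  kind <- match.arg(kind, c("oxygen", "air"))
  if (kind == "oxygen" && po2 <= 0) {
    stop("oxygen segments need po2 > 0", call. = FALSE)
  }
  data.frame(po2 = po2, duration = duration, kind = kind,
             stringsAsFactors = FALSE)
}

#' Multi-segment exposure profile
#'
#' An ordered sequence of oxygen and air-break segments, e.g. a hyperbaric
#' treatment table, bound to the parameter set used to score it.
#'
#' @param segments A list of \code{\link{segment}} rows, or a data.frame with
#'   columns \code{po2}, \code{duration} and optionally \code{kind}.
#' @param params A \code{\link{risk_params}} object or a registry name
#'   (see \code{\link{cns_params}}).
#' @param threshold Air/oxygen auto-classification cutoff, bar.
#' @return An object of class \code{"exposure_profile"}.
#' @examples
#' pr <- exposure_profile(list(segment(2.5, 30), segment(0.5, 10),
#'                             segment(2.5, 30)), "DRY_REST")
#' accumulate_profile(pr)
#' @export
exposure_profile <- function(segments, params, threshold = 1.0) {
  if (is.character(params)) params <- cns_params(params)
  if (is.data.frame(segments)) {
    if (!"kind" %in% names(segments)) segments$kind <- NA_character_
    segments <- lapply(seq_len(nrow(segments)), function(i) {
      segment(segments$po2[i], segments$duration[i], segments$kind[i],
              threshold = threshold)
    })
  }
  if (!is.list(segments) || length(segments) == 0L) {
    stop("profile needs at least one segment", call. = FALSE)
  }
  seg <- do.call(rbind, segments)
  if (!all(is.finite(seg$duration))) {
    stop("segment durations must be finite", call. = FALSE)
  }
  structure(list(segments = seg, params = params),
            class = "exposure_profile")
}

#' @export
print.exposure_profile <- function(x, ...) {
  nm <- if (is.null(x$params$name)) x$params$condition else x$params$name
  cat(sprintf("Exposure profile: %d segments, %.4g min total, params %s\n",
              nrow(x$segments), sum(x$segments$duration), nm))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Exponential recovery of the CNS-OT index during an air break
#'
#' \eqn{K_{rec} = K e^{-0.079\, t_{rec}}} with the recovery time in minutes.
#'
#' @param K CNS-OT index (>= 0). Vectorised.
#' @param trec Recovery (air-breathing) time, minutes (>= 0).
#' @param rate Recovery rate constant per minute.
#' @return The decayed index.
#' @export
decay_index <- function(K, trec, rate = CNS_RECOVERY_RATE) {
  stopifnot(is.numeric(K), is.numeric(trec))
  if (any(K < 0)) stop("K must be >= 0", call. = FALSE)
  if (any(trec < 0)) stop("trec must be >= 0", call. = FALSE)
  K * exp(-rate * trec)
}

#' Equivalent oxygen time at a given PO2
#'
#' The continuous oxygen time at \code{po2} that would have produced the
#' current index: \eqn{t_{eq} = \sqrt{K / PO_2^{\,c}}}, evaluated in the log
#' domain. Used to resume accumulation after an air break or a PO2 change.
#'
#' @param K CNS-OT index (>= 0). Vectorised.
#' @param po2 Oxygen partial pressure, bar (> 0).
#' @param c PO2 exponent.
#' @return Equivalent time in minutes.
#' @export
equivalent_time <- function(K, po2, c) {
  stopifnot(is.numeric(K), is.numeric(po2), is.numeric(c))
  if (any(K < 0)) stop("K must be >= 0", call. = FALSE)
  if (any(po2 <= 0)) stop("po2 must be > 0", call. = FALSE)
  ifelse(K == 0, 0, exp(0.5 * (log(K) - c * log(po2))))
}

#' Accumulate CNS-OT index and risk across an exposure profile
#'
#' Walks the segments left to right with a running index K (starting at 0).
#' An oxygen segment of d minutes at \code{po2} advances
#' \eqn{K \leftarrow (t_{eq}(K, PO_2) + d)^2 PO_2^{\,c}}; an air segment
#' decays \eqn{K \leftarrow K e^{-0.079 d}}. Index and risk are recorded at
#' every segment boundary (and optionally on a finer time grid).
#'
#' @param profile An \code{\link{exposure_profile}}.
#' @param step Optional sampling step in minutes for a dense trajectory;
#'   \code{NULL} records segment boundaries only.
#' @return A data.frame of class \code{"risk_trajectory"} with columns
#'   \code{time_min}, \code{K}, \code{risk}, and attributes
#'   \code{final_K} / \code{final_risk}.
#' @examples
#' pr <- exposure_profile(list(segment(2.8, 20), segment(0.6, 5),
#'                             segment(2.8, 20), segment(0.6, 5),
#'                             segment(2.8, 20)), "DRY_REST")
#' tr <- accumulate_profile(pr)
#' attr(tr, "final_risk")
#' @export
accumulate_profile <- function(profile, step = NULL) {
  if (!inherits(profile, "exposure_profile")) {
    stop("profile must be an exposure_profile", call. = FALSE)
  }
  params <- profile$params
  .check_risk_capable(params)
  seg <- profile$segments
  if (nrow(seg) == 0L) stop("empty profile", call. = FALSE)

  advance <- function(K, s, d) {
    if (s$kind == "oxygen") {
      teq <- equivalent_time(K, s$po2, params$c)
      cns_ot_index(teq + d, s$po2, params$c)
    } else {
      decay_index(K, d)
    }
  }

  time <- 0
  K <- 0
  out_t <- 0
  out_K <- 0
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    if (!is.null(step) && s$duration > 0) {
      grid <- seq(step, s$duration, by = step)
      if (length(grid) == 0L || grid[length(grid)] < s$duration) {
        grid <- c(grid, s$duration)
      }
      for (d in grid) {
        out_t <- c(out_t, time + d)
        out_K <- c(out_K, advance(K, s, d))
      }
    } else {
      out_t <- c(out_t, time + s$duration)
      out_K <- c(out_K, advance(K, s, s$duration))
    }
    K <- advance(K, s, s$duration)
    time <- time + s$duration
  }
  tr <- data.frame(time_min = out_t, K = out_K,
                   risk = cns_ot_risk(out_K, params))
  structure(tr,
            class = c("risk_trajectory", "data.frame"),
            final_K = K,
            final_risk = cns_ot_risk(K, params),
            params = params)
}

#' @export
print.risk_trajectory <- function(x, ...) {
  cat("CNS-OT risk trajectory\n")
  print.data.frame(x, row.names = FALSE, ...)
  cat(sprintf("final K = %.6e   final risk = %.4g (%.3g%%)\n",
              attr(x, "final_K"), attr(x, "final_risk"),
              100 * attr(x, "final_risk")))
  invisible(x)
}

#' Read and write exposure-profile files
#'
#' Profiles are stored as YAML (or JSON) with a \code{condition} naming a
#' registry entry and \code{segments} as a list of
#' \code{\{po2_bar, duration_min, kind\}} entries; \code{kind} may be omitted
#' and is then auto-classified by PO2. Writing then reading a profile
#' reproduces it exactly.
#'
#' @param path File path; format inferred from the extension
#'   (\code{.json} = JSON, anything else = YAML).
#' @param profile An \code{\link{exposure_profile}}.
#' @param threshold Air/oxygen auto-classification cutoff, bar.
#' @return \code{read_profile} returns an \code{exposure_profile}.
#' @export
read_profile <- function(path, threshold = 1.0) {
  if (!file.exists(path)) stop("no such profile file: ", path, call. = FALSE)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(doc$condition) || is.null(doc$segments) ||
      length(doc$segments) == 0L) {
    stop("profile file needs a 'condition' and a non-empty 'segments' list",
         call. = FALSE)
  }
  segs <- lapply(doc$segments, function(s) {
    segment(as.numeric(s$po2_bar), as.numeric(s$duration_min),
            if (is.null(s$kind)) NA_character_ else s$kind,
            threshold = threshold)
  })
  exposure_profile(segs, doc$condition, threshold = threshold)
}

#' @rdname read_profile
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "exposure_profile"))
  nm <- if (!is.null(profile$params$name)) profile$params$name else
    profile$params$condition
  seg <- profile$segments
  doc <- list(condition = nm,
              segments = lapply(seq_len(nrow(seg)), function(i) {
                list(po2_bar = seg$po2[i], duration_min = seg$duration[i],
                     kind = seg$kind[i])
              }))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

#' Read and write trajectory tables
#'
#' Plain CSV with columns \code{time_min}, \code{K}, \code{risk}; full
#' double precision is kept so a written trajectory re-reads bit-exactly.
#'
#' @param trajectory A \code{risk_trajectory} (any data.frame with the three
#'   columns is accepted for writing).
#' @param path File path.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- as.data.frame(trajectory)[, c("time_min", "K", "risk")]
  # format with full precision so the round-trip is exact
  out <- data.frame(time_min = sprintf("%.17g", df$time_min),
                    K = sprintf("%.17g", df$K),
                    risk = sprintf("%.17g", df$risk))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  df[, c("time_min", "K", "risk")]
}
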