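#' Fitted parameter set for the CNS-OT power equation
#'
#' Bundles the parameters of the power-equation risk model for one exposure
#' condition: the PO2 exponent \code{c}, the location \code{mu} and scale
#' \code{sigma} of the normal distribution of half the log CNS-OT index at
#' symptom onset, and the critical index \code{kc} at which risk reaches 50\%.
#'
#' The model states that for an exposure of \code{t} minutes at partial
#' pressure \code{po2} bar, the index is \eqn{K = t^2 \cdot PO_2^c}, and
#' \eqn{\frac{1}{2}\ln K} at symptom onset is Normal(\code{mu}, \code{sigma}).
#' Consequently \eqn{K_c = e^{2\mu}} up to rounding of the published values.
#'
#' @param condition One of \code{"immersed"}, \code{"dry"}, \code{"active"}.
#' @param met Metabolic rate in MET units (>= 1).
#' @param c Dimensionless PO2 exponent (> 0).
#' @param mu Location of half the log index at toxicity, log units.
#' @param sigma Scale of half the log index, log units (> 0).
#' @param kc Critical CNS-OT index, min^2 * bar^c (> 0).
#' @param name Optional registry-style name for printing.
#' @return An object of class \code{"risk_params"}.
#' @examples
#' p <- risk_params("dry", met = 1, c = 12.99, mu = 11.34, sigma = 0.65,
#'                  kc = 7.10e9)
#' cns_ot_risk(cns_ot_index(60, 2.5, p$c), p)
#' @export
risk_params <- function(condition = c("immersed", "dry", "active"),
                        met, c, mu, sigma, kc, name = NULL) {
  condition <- match.arg(condition)
  stopifnot(is.numeric(met), length(met) == 1L,
            is.numeric(c), length(c) == 1L,
            is.numeric(mu), length(mu) == 1L,
            is.numeric(sigma), length(sigma) == 1L,
            is.numeric(kc), length(kc) == 1L)
  if (met < 1) stop("met must be >= 1", call. = FALSE)
  if (c <= 0) stop("c must be > 0", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (kc <= 0) stop("kc must be > 0", call. = FALSE)
  structure(list(condition = condition, met = met, c = c, mu = mu,
                 sigma = sigma, kc = kc, name = name),
            class = "risk_params")
}

#' @export
print.risk_params <- function(x, ...) {
  nm <- if (is.null(x$name)) x$condition else x$name
  cat("CNS-OT risk parameters:", nm, "\n")
  cat(sprintf("  condition: %s (%.1f MET)\n", x$condition, x$met))
  cat(sprintf("  c = %.4g   mu = %.4g   sigma = %.4g   Kc = %.3e\n",
              x$c, x$mu, x$sigma, x$kc))
  invisible(x)
}

# Published at-rest solutions plus the active-diving (4.4 MET) set.
# ACTIVE_4_4 stores Kc = exp(18.02) as published alongside mu = 9.63; the two
# are not exactly exp(2*mu)-consistent in the source and are kept as printed.
.registry <- list(
  IMMERSED_REST = list(condition = "immersed", met = 1, c = 10.93,
                       mu = 8.99, sigma = 0.81, kc = 6.42e7),
  DRY_REST      = list(condition = "dry", met = 1, c = 12.99,
                       mu = 11.34, sigma = 0.65, kc = 7.10e9),
  ACTIVE_4_4    = list(condition = "active", met = 4.4, c = 6.8,
                       mu = 9.63, sigma = 2.02, kc = exp(18.02))
)

#' Registry of published CNS-OT parameter sets
#'
#' Read-only lookup of the fitted power-equation parameter sets:
#' \code{IMMERSED_REST} (1 MET, thermoneutral immersion),
#' \code{DRY_REST} (1 MET, dry chamber) and \code{ACTIVE_4_4}
#' (4.4 MET active diving).
#'
#' @param name Registry entry name; case-insensitive. The aliases
#'   \code{"immersed"}, \code{"dry"} and \code{"active"} resolve to the
#'   corresponding entries.
#' @return For \code{cns_params}, a \code{\link{risk_params}} object; for
#'   \code{cns_registry}, a named list of all entries.
#' @examples
#' cns_params("DRY_REST")
#' names(cns_registry())
#' @export
cns_params <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- toupper(name)
  key <- switch(key, IMMERSED = "IMMERSED_REST", DRY = "DRY_REST",
                ACTIVE = "ACTIVE_4_4", key)
  if (!key %in% names(.registry)) {
    stop("unknown parameter set '", name, "'; available: ",
         paste(names(.registry), collapse = ", "), call. = FALSE)
  }
  e <- .registry[[key]]
  risk_params(e$condition, met = e$met, c = e$c, mu = e$mu,
              sigma = e$sigma, kc = e$kc, name = key)
}

#' @rdname cns_params
#' @export
cns_registry <- function() {
  out <- lapply(names(.registry), cns_params)
  names(out) <- names(.registry)
  out
}

#' Read and write parameter-set files
#'
#' Parameter sets are stored as Debian-control-style text: one named block of
#' key-value pairs per set, so fitted sets from \code{\link{fit_mle}} can be
#' saved next to the published registry entries.
#'
#' @param params A \code{risk_params} object or a list of them.
#' @param path File path.
#' @return \code{read_params} returns a named list of \code{risk_params}.
#' @export
write_params <- function(params, path) {
  if (inherits(params, "risk_params")) params <- list(params)
  rows <- lapply(seq_along(params), function(i) {
    p <- params[[i]]
    nm <- if (!is.null(p$name)) p$name else if (!is.null(names(params)[i]) &&
      nzchar(names(params)[i])) names(params)[i] else p$condition
    data.frame(name = nm, condition = p$condition, met = p$met, c = p$c,
               mu = p$mu, sigma = p$sigma, kc = p$kc)
  })
  write.dcf(do.call(rbind, rows), file = path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  m <- read.dcf(path)
  out <- lapply(seq_len(nrow(m)), function(i) {
    r <- as.list(m[i, ])
    risk_params(r$condition, met = as.numeric(r$met), c = as.numeric(r$c),
                mu = as.numeric(r$mu), sigma = as.numeric(r$sigma),
                kc = as.numeric(r$kc), name = r$name)
  })
  names(out) <- m[, "name"]
  out
}

#' Convert oxygen partial pressures to bar
#'
#' The whole package works in bar; this helper converts from other common
#' pressure units. It is never applied implicitly.
#'
#' @param x Numeric vector of pressures.
#' @param from Unit of \code{x}: \code{"bar"}, \code{"ata"} (standard
#'   atmospheres), \code{"kPa"} or \code{"mmHg"}.
#' @return Pressures in bar.
#' @examples
#' convert_po2(2.8, "ata")
#' @export
convert_po2 <- function(x, from = c("bar", "ata", "kPa", "mmHg")) {
  from <- match.arg(from)
  switch(from,
         bar = x,
         ata = x * 1.01325,
         kPa = x / 100,
         mmHg = x * 0.00133322)
}
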