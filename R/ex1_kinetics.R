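#' Fit single- and two-binomial models to an isotopic envelope
#'
#' Deconvolutes a deuterated isotopic envelope into deuteration
#' distributions convolved with a fixed natural-abundance envelope. Two
#' models are fitted by least squares: a single binomial
#' `Binom(n_exchangeable, p)` (EX2-like gradual exchange) and a two-binomial
#' mixture `w * Binom(n, p_low) + (1-w) * Binom(n, p_high)` (EX1-like
#' bimodality). Model selection uses an information criterion
#' `K * log(RSS/K) + penalty * n_par` with `K` the number of isotope
#' channels; `penalty = log(K)` by default (BIC-like).
#'
#' @param envelope an `isotopic_envelope` (see [simulate_envelopes()]) or a
#'   bare intensity vector on the 0..K isotope grid.
#' @param n_exchangeable number of exchangeable amides (taken from the
#'   envelope object when available).
#' @param natural natural-abundance envelope to convolve with; defaults to
#'   a delta at 0 for bare vectors, or is recomputed internally for
#'   simulator envelopes carrying a peptide mass.
#' @param penalty information-criterion penalty per parameter
#'   (default `log(K)`).
#' @return Object of class `bimodal_fit` with elements `single`
#'   (`p`, `rss`), `mixture` (`p_low`, `p_high`, `w_low`, `rss`),
#'   `preferred` (`"single"` or `"mixture"`), `class`
#'   (`"EX1"`, `"EX2"` or `"ambiguous"` at the single-envelope level) and
#'   `separation` (mode separation `n * (p_high - p_low)`, Da on the
#'   1-Da isotope grid).
#' @export
fit_envelope <- function(envelope, n_exchangeable = NULL, natural = NULL,
                         penalty = NULL) {
  if (inherits(envelope, "isotopic_envelope")) {
    if (is.null(n_exchangeable)) n_exchangeable <- envelope$n_exchangeable
    if (is.null(natural)) natural <- envelope$natural
    y <- envelope$intensity
  } else {
    y <- as.numeric(envelope)
  }
  if (is.null(n_exchangeable))
    stop("n_exchangeable must be supplied", call. = FALSE)
  K <- length(y)
  if (K < 4L) stop("need at least 4 isotope channels", call. = FALSE)
  if (sum(y) <= 0) stop("empty envelope", call. = FALSE)
  y <- y / sum(y)
  n <- as.integer(n_exchangeable)
  if (is.null(natural)) {
    # infer the undeuterated part: channels beyond n belong to the natural
    # envelope tail; use a delta unless the envelope is wider than n + 1
    natural <- if (K > n + 1L) .natural_envelope_from_width(K - n - 1L) else 1
  }
  pred <- function(deut) {
    z <- .dconv(natural, deut)
    z <- z[seq_len(K)]
    z / sum(z)
  }
  rss1 <- function(p) sum((pred(stats::dbinom(0:n, n, p)) - y)^2)
  rss2 <- function(par) {  # par = (p_low, p_high, w_low)
    d <- par[3] * stats::dbinom(0:n, n, par[1]) +
      (1 - par[3]) * stats::dbinom(0:n, n, par[2])
    sum((pred(d) - y)^2)
  }
  # single-binomial: initialise from the centroid, then refine
  cent <- envelope_centroid(y) - envelope_centroid(natural)
  p0 <- min(max(cent / n, 1e-4), 1 - 1e-4)
  s <- stats::optim(p0, function(p) rss1(p), method = "Brent",
                    lower = 0, upper = 1)
  # mixture: initialise from percentiles of the deuteration scale and a
  # small deterministic start grid
  starts <- list(c(max(p0 / 4, 1e-3), min(2 * p0 + 0.05, 0.99), 0.5),
                 c(1e-3, min(max(2 * p0, 0.1), 0.99), 0.5),
                 c(max(p0 - 0.2, 1e-3), min(p0 + 0.2, 0.99), 0.5))
  m <- NULL
  for (st in starts) {
    fit <- stats::optim(st, rss2, method = "L-BFGS-B",
                        lower = c(1e-6, 1e-6, 0), upper = c(1, 1, 1))
    if (is.null(m) || fit$value < m$value) m <- fit
  }
  # canonical order p_low < p_high
  p_lo <- min(m$par[1], m$par[2]); p_hi <- max(m$par[1], m$par[2])
  w_lo <- if (m$par[1] <= m$par[2]) m$par[3] else 1 - m$par[3]
  if (is.null(penalty)) penalty <- log(K)
  ic1 <- K * log(max(s$value, 1e-300) / K) + penalty * 1
  ic2 <- K * log(max(m$value, 1e-300) / K) + penalty * 3
  flat <- stats::sd(y) < 1e-12
  preferred <- if (ic2 < ic1) "mixture" else "single"
  cls <- if (flat) "ambiguous" else if (preferred == "mixture") "EX1"
         else "EX2"
  structure(list(single = list(p = s$par, rss = s$value),
                 mixture = list(p_low = p_lo, p_high = p_hi, w_low = w_lo,
                                rss = m$value),
                 ic = c(single = ic1, mixture = ic2),
                 preferred = preferred,
                 separation = n * (p_hi - p_lo),
                 class = cls, n_exchangeable = n),
            class = "bimodal_fit")
}

.natural_envelope_from_width <- function(extra) {
  # small Poisson envelope matched to the channel surplus; used when the
  # caller supplies a bare vector without a peptide mass
  lambda <- max(extra / 6, 0.2)
  stats::dpois(0:extra, lambda) / stats::ppois(extra, lambda)
}

#' @export
print.bimodal_fit <- function(x, ...) {
  cat("<bimodal_fit> preferred:", x$preferred,
      sprintf("(p = %.3f | p_low = %.3f, p_high = %.3f, w_low = %.2f)",
              x$single$p, x$mixture$p_low, x$mixture$p_high,
              x$mixture$w_low), "\n")
  invisible(x)
}

#' Classify exchange kinetics of a peptide from an envelope time series
#'
#' A peptide is classified EX1 when (i) the two-binomial mixture is
#' preferred at two or more consecutive exposure times, (ii) the mode
#' separation `n * (p_high - p_low)` is at least `delta_min` at those
#' times, and (iii) the low-mass (closed) population weight `w_low` is
#' non-increasing over those times (monotone population transfer from the
#' closed to the opened state). Flat, non-exchanging series are
#' `"ambiguous"`; everything else is `"EX2"`.
#'
#' @param series an `envelope_series` (see [simulate_envelopes()]) or a
#'   list of envelopes sorted by exposure.
#' @param n_exchangeable exchangeable amides (default: from the series).
#' @param delta_min minimum mode separation in Da (default 2).
#' @param w_tol tolerance on the monotone decrease of `w_low`
#'   (default 0.1).
#' @param ... passed to [fit_envelope()].
#' @return List of class `kinetics_call`: `class` (`"EX1"`, `"EX2"` or
#'   `"ambiguous"`), plus the per-timepoint `fits`.
#' @export
classify_kinetics <- function(series, n_exchangeable = NULL, delta_min = 2,
                              w_tol = 0.1, ...) {
  if (is.null(n_exchangeable))
    n_exchangeable <- attr(series, "n_exchangeable")
  if (length(series) < 3L)
    stop("need at least 3 exposure times", call. = FALSE)
  fits <- lapply(series, fit_envelope, n_exchangeable = n_exchangeable, ...)
  flat <- all(vapply(fits, function(f) f$class == "ambiguous", logical(1)))
  if (flat)
    return(structure(list(class = "ambiguous", fits = fits),
                     class = "kinetics_call"))
  bimodal <- vapply(fits, function(f)
    f$preferred == "mixture" && f$separation >= delta_min, logical(1))
  cls <- "EX2"
  runs <- rle(bimodal)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in which(runs$values & runs$lengths >= 2L)) {
    idx <- starts[k]:ends[k]
    w <- vapply(fits[idx], function(f) f$mixture$w_low, numeric(1))
    if (all(diff(w) <= w_tol)) { cls <- "EX1"; break }
  }
  structure(list(class = cls, fits = fits), class = "kinetics_call")
}

#' @export
print.kinetics_call <- function(x, ...) {
  cat("<kinetics_call>", x$class, "over", length(x$fits),
      "exposure times\n")
  invisible(x)
}
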