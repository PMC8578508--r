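#' milliBRET units from raw emissions
#'
#' `1000 * acceptor(610 nm) / donor(450 nm)`. Invariant under common
#' scaling of both channels.
#'
#' @param a610 acceptor emission (arbitrary units).
#' @param d450 donor emission (must be > 0).
#' @return milliBRET units (vectorised).
#' @examples
#' millibret(200, 100)  # 2000
#' @export
millibret <- function(a610, d450) {
  if (any(d450 <= 0))
    stop("donor emission must be positive", call. = FALSE)
  1000 * a610 / d450
}

#' One-site total binding fit
#'
#' Fits `Y = Bmax * X / (Kd + X) + NS * X` (specific saturable binding plus
#' a linear non-specific component) by nonlinear least squares.
#' Initialisation: `Bmax` from the upper data range, `Kd` from the
#' half-maximum crossing, `NS` from the terminal slope; `Kd` is kept
#' positive by bounded optimisation.
#'
#' @param x dose (non-negative).
#' @param y response.
#' @param fix_ns optionally fix `NS` (e.g. 0 for a pure rectangular
#'   hyperbola).
#' @return Object of class `one_site_fit` with `coefficients`
#'   (`Bmax`, `Kd`, `NS`), `residual` (sum of squared residuals) and the
#'   underlying `nls` fit.
#' @export
fit_one_site_total <- function(x, y, fix_ns = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 5L, all(x >= 0))
  bmax0 <- max(y) - min(y)
  if (bmax0 <= 0) bmax0 <- max(abs(y), 1)
  half <- min(y) + bmax0 / 2
  kd0 <- x[which.min(abs(y - half))]
  if (kd0 <= 0) kd0 <- stats::median(x[x > 0])
  ns0 <- 0
  df <- data.frame(x = x, y = y)
  if (is.null(fix_ns)) {
    fit <- minpack.lm::nlsLM(y ~ Bmax * x / (Kd + x) + NS * x, data = df,
                             start = list(Bmax = bmax0, Kd = kd0, NS = ns0),
                             lower = c(-Inf, 1e-12, -Inf),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    co <- stats::coef(fit)
  } else {
    fit <- minpack.lm::nlsLM(y ~ Bmax * x / (Kd + x) + fix_ns * x, data = df,
                             start = list(Bmax = bmax0, Kd = kd0),
                             lower = c(-Inf, 1e-12),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    co <- c(stats::coef(fit), NS = fix_ns)
  }
  if (!fit$convInfo$isConv)
    stop("one-site fit did not converge: ", fit$convInfo$stopMessage,
         call. = FALSE)
  structure(list(coefficients = co,
                 residual = sum(stats::resid(fit)^2), fit = fit),
            class = "one_site_fit")
}

#' Four-parameter logistic (4PL) dose-response fit
#'
#' Fits `Y = Bottom + (Top - Bottom) / (1 + 10^((LogXmid - X) * HillSlope))`
#' with `X` on a log10-dose scale. With `mode = "EC50"` the midpoint is
#' reported as `LogEC50` (rising curves, positive HillSlope expected); with
#' `mode = "IC50"` as `LogIC50` (falling curves). The functional form is
#' identical; the canonical parameterisation keeps `Top > Bottom` and
#' encodes the curve direction in the sign of `HillSlope`.
#'
#' @param x_log log10 dose.
#' @param y response.
#' @param mode `"EC50"` or `"IC50"` (labelling of the midpoint).
#' @return Object of class `four_pl_fit` with `coefficients`
#'   (`Top`, `Bottom`, `LogEC50`/`LogIC50`, `HillSlope`), `residual`, and
#'   the underlying `nls` fit.
#' @export
fit_4pl <- function(x_log, y, mode = c("EC50", "IC50")) {
  mode <- match.arg(mode)
  stopifnot(length(x_log) == length(y), length(x_log) >= 5L)
  top0 <- max(y); bot0 <- min(y)
  if (top0 == bot0) stop("flat response; 4PL fit is uninformative",
                         call. = FALSE)
  half <- (top0 + bot0) / 2
  mid0 <- x_log[which.min(abs(y - half))]
  rising <- stats::cor(x_log, y) >= 0
  slope0 <- if (rising) 1 else -1
  df <- data.frame(x = x_log, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ Bottom + (Top - Bottom) / (1 + 10^((mid - x) * Hill)), data = df,
    start = list(Top = top0, Bottom = bot0, mid = mid0, Hill = slope0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$convInfo$isConv)
    stop("4PL fit did not converge: ", fit$convInfo$stopMessage,
         call. = FALSE)
  co <- stats::coef(fit)
  # canonical form: Top > Bottom, direction in the sign of HillSlope
  if (co[["Top"]] < co[["Bottom"]]) {
    co[c("Top", "Bottom")] <- co[c("Bottom", "Top")]
    co[["Hill"]] <- -co[["Hill"]]
  }
  names(co) <- c("Top", "Bottom", if (mode == "EC50") "LogEC50" else
    "LogIC50", "HillSlope")
  structure(list(coefficients = co, residual = sum(stats::resid(fit)^2),
                 mode = mode, fit = fit),
            class = "four_pl_fit")
}

#' @export
coef.one_site_fit <- function(object, ...) object$coefficients
#' @export
coef.four_pl_fit <- function(object, ...) object$coefficients

#' @export
print.one_site_fit <- function(x, ...) {
  cat("<one_site_fit> Bmax =", signif(x$coefficients[["Bmax"]], 5),
      " Kd =", signif(x$coefficients[["Kd"]], 5),
      " NS =", signif(x$coefficients[["NS"]], 5),
      " RSS =", signif(x$residual, 4), "\n")
  invisible(x)
}

#' @export
print.four_pl_fit <- function(x, ...) {
  co <- x$coefficients
  cat("<four_pl_fit>", paste(names(co), signif(co, 5), sep = " = ",
                             collapse = ", "),
      " RSS =", signif(x$residual, 4), "\n")
  invisible(x)
}

#' @export
predict.one_site_fit <- function(object, newdata = NULL, ...) {
  co <- object$coefficients
  x <- if (is.null(newdata)) object$fit$m$getEnv()$x else
    if (is.data.frame(newdata)) newdata$x else newdata
  co[["Bmax"]] * x / (co[["Kd"]] + x) + co[["NS"]] * x
}

#' @export
predict.four_pl_fit <- function(object, newdata = NULL, ...) {
  co <- object$coefficients
  x <- if (is.null(newdata)) object$fit$m$getEnv()$x else
    if (is.data.frame(newdata)) newdata$x else newdata
  mid <- co[[3L]]
  co[["Bottom"]] + (co[["Top"]] - co[["Bottom"]]) /
    (1 + 10^((mid - x) * co[["HillSlope"]]))
}

#' Simulate BRET dose-response measurements
#'
#' Generates measurements from a one-site-total or 4PL model with optional
#' Gaussian noise; deterministic under a fixed seed, exact in noiseless
#' mode.
#'
#' @param model `"one_site"` or `"4pl"`.
#' @param params named parameters: one_site needs `Bmax`, `Kd`, `NS`; 4pl
#'   needs `Top`, `Bottom`, `LogEC50` (or `LogIC50`), `HillSlope`.
#' @param doses dose vector (linear scale for one_site, log10 scale
#'   for 4pl).
#' @param noise_sd Gaussian noise SD (response units, default 0).
#' @param seed RNG seed.
#' @return data.frame with `x` and `y`.
#' @export
simulate_bret_series <- function(model = c("one_site", "4pl"), params,
                                 doses, noise_sd = 0, seed = 1) {
  model <- match.arg(model)
  if (model == "one_site") {
    stopifnot(all(doses >= 0))
    y <- params[["Bmax"]] * doses / (params[["Kd"]] + doses) +
      params[["NS"]] * doses
  } else {
    mid <- if ("LogEC50" %in% names(params)) params[["LogEC50"]] else
      params[["LogIC50"]]
    y <- params[["Bottom"]] + (params[["Top"]] - params[["Bottom"]]) /
      (1 + 10^((mid - doses) * params[["HillSlope"]]))
  }
  if (noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(length(doses), 0, noise_sd))
  data.frame(x = doses, y = y)
}
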