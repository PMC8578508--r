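#' Solvent conditions for sedimentation corrections
#'
#' @param density solvent density rho, g/cm^3 (> 0).
#' @param viscosity solvent viscosity eta, poise (> 0).
#' @param label free-text label.
#' @return Object of class `solvent_conditions`.
#' @export
solvent_conditions <- function(density, viscosity, label = "") {
  stopifnot(density > 0, viscosity > 0)
  structure(list(density = density, viscosity = viscosity, label = label),
            class = "solvent_conditions")
}

#' Water at 20 degrees C (the s20,w reference state)
#' @return A [solvent_conditions()] object: rho = 0.998234 g/cm^3,
#'   eta = 0.010016 poise.
#' @export
water_20C <- function() {
  solvent_conditions(0.998234, 0.010016, "water, 20 C")
}

.AVOGADRO <- 6.02214076e23

#' Correct an observed sedimentation coefficient to standard conditions
#'
#' `s20,w = s_obs * (eta_buffer / eta_20,w) *
#'  ((1 - vbar * rho_20,w) / (1 - vbar * rho_buffer))`.
#'
#' @param s_obs observed sedimentation coefficient (Svedberg).
#' @param buffer a [solvent_conditions()] for the experimental buffer.
#' @param vbar partial specific volume, cm^3/g (default 0.73).
#' @param reference reference conditions (default [water_20C()]).
#' @return s20,w in Svedberg.
#' @export
s20w <- function(s_obs, buffer, vbar = 0.73, reference = water_20C()) {
  b1 <- 1 - vbar * reference$density
  b2 <- 1 - vbar * buffer$density
  if (b1 <= 0 || b2 <= 0)
    stop("buoyancy term 1 - vbar * rho must be positive", call. = FALSE)
  s_obs * (buffer$viscosity / reference$viscosity) * (b1 / b2)
}

#' Frictional ratio and sphere-limit sedimentation coefficient
#'
#' From the Svedberg relation, the translational friction coefficient of a
#' species of molar mass `M` (g/mol) sedimenting at `s` (Svedberg) is
#' `f = M (1 - vbar rho) / (N_A s)`; the friction of the equivalent
#' anhydrous sphere of equal mass and density is `f0 = 6 pi eta r0` with
#' `r0 = (3 M vbar / (4 pi N_A))^(1/3)`. `frictional_ratio()` returns
#' f/f0 (1 for a compact sphere, larger for elongated shapes; hydration is
#' ignored, the anhydrous-sphere convention). `sphere_s()` returns the s of
#' that sphere, i.e. the s at which f/f0 = 1, and `mass_from_s_ffr()`
#' inverts the pair (s, f/f0) back to M.
#'
#' @param M molar mass, g/mol (Da).
#' @param s sedimentation coefficient, Svedberg (1 S = 1e-13 s).
#' @param vbar partial specific volume, cm^3/g (default 0.73).
#' @param solvent a [solvent_conditions()] (default [water_20C()]).
#' @return `frictional_ratio()`: f/f0 (with a warning below 1);
#'   `sphere_s()`: Svedberg; `mass_from_s_ffr()`: Da.
#' @export
frictional_ratio <- function(M, s, vbar = 0.73, solvent = water_20C()) {
  stopifnot(M > 0, s > 0)
  buoy <- 1 - vbar * solvent$density
  if (buoy <= 0) stop("1 - vbar * rho must be positive", call. = FALSE)
  f <- M * buoy / (.AVOGADRO * s * 1e-13)
  r0 <- (3 * M * vbar / (4 * pi * .AVOGADRO))^(1 / 3)
  f0 <- 6 * pi * solvent$viscosity * r0
  ratio <- f / f0
  if (any(ratio < 1 - 1e-9))
    warning("f/f0 < 1: physically inconsistent (M, s, vbar) combination")
  ratio
}

#' @rdname frictional_ratio
#' @export
sphere_s <- function(M, vbar = 0.73, solvent = water_20C()) {
  stopifnot(M > 0)
  buoy <- 1 - vbar * solvent$density
  if (buoy <= 0) stop("1 - vbar * rho must be positive", call. = FALSE)
  r0 <- (3 * M * vbar / (4 * pi * .AVOGADRO))^(1 / 3)
  f0 <- 6 * pi * solvent$viscosity * r0
  (M * buoy / (.AVOGADRO * f0)) / 1e-13
}

#' @rdname frictional_ratio
#' @param ffr frictional ratio f/f0.
#' @export
mass_from_s_ffr <- function(s, ffr, vbar = 0.73, solvent = water_20C()) {
  stopifnot(s > 0, ffr > 0)
  buoy <- 1 - vbar * solvent$density
  if (buoy <= 0) stop("1 - vbar * rho must be positive", call. = FALSE)
  # f = ffr * 6 pi eta (3 M vbar / 4 pi N_A)^(1/3)  and
  # f = M buoy / (N_A s)  =>  M^(2/3) = ffr 6 pi eta (3 vbar/4 pi N_A)^(1/3)
  #                                   * N_A s / buoy
  rhs <- ffr * 6 * pi * solvent$viscosity *
    (3 * vbar / (4 * pi * .AVOGADRO))^(1 / 3) *
    .AVOGADRO * (s * 1e-13) / buoy
  rhs^(3 / 2)
}
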