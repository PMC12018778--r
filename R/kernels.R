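## Pointwise model kernels: effective diffusion, diurnal water flux,
## Michaelis-Menten uptake, the homogenized root-hair sink and the gypsum
## precipitation driving term. The PDE right-hand side in solver.R inlines
## these expressions for speed; these exported forms are the documented,
## validated reference implementations and are what the tests exercise.

#' Effective diffusion coefficient in soil
#'
#' `De = D * theta * f`: liquid diffusion reduced by the water-filled pore
#' fraction and the diffusion impedance (tortuosity) factor.
#'
#' @param D liquid diffusion coefficient, cm2 s-1.
#' @param theta volumetric water content, cm3 cm-3.
#' @param f diffusion impedance factor (dimensionless, typically 0.3).
#' @return effective diffusion coefficient, cm2 s-1.
#' @examples
#' effective_diffusion(7.92e-6, 0.22, 0.3)  # 5.227e-7
#' @export
effective_diffusion <- function(D, theta, f) {
  .check_positive(D = D, theta = theta, f = f)
  D * theta * f
}

#' Diurnal water flux at the root surface
#'
#' Sinusoidal day/night cycle around the daily mean,
#' `Jw(t) = Jw_daily * (sin(2*pi*t/24 - pi/2) + 1)`:
#' zero at midnight, twice the mean at noon, 24-h mean equal to `Jw_daily`.
#'
#' @param t_hours time after midnight, hours (vectorized; periodic in 24 h).
#' @param Jw_daily daily-mean water flux, cm s-1.
#' @return water flux to the root at `t_hours`, cm s-1 (non-negative).
#' @export
water_flux_at <- function(t_hours, Jw_daily) {
  .check_positive(Jw_daily = Jw_daily, .allow_zero = TRUE)
  stopifnot(is.numeric(t_hours))
  Jw_daily * (sin(2 * pi * t_hours / 24 - pi / 2) + 1)
}

#' Michaelis-Menten uptake flux
#'
#' @param c pore water concentration at the uptake surface, mol cm-3
#'   (non-negative; vectorized).
#' @param Fm maximum uptake rate, mol cm-2 s-1.
#' @param Km half-saturation concentration, mol cm-3.
#' @return uptake flux `Fm * c / (Km + c)`, mol cm-2 s-1; bounded by `Fm`.
#' @export
mm_uptake_flux <- function(c, Fm, Km) {
  if (any(!is.finite(c) | c < 0)) stop("'c' must be non-negative", call. = FALSE)
  .check_positive(Km = Km)
  .check_positive(Fm = Fm, .allow_zero = TRUE)
  Fm * c / (Km + c)
}

#' Mean spacing between neighbouring root hairs
#'
#' Two readings of the published spacing formula are supported (they differ
#' only in which radius enters):
#' `"hair-radius"`: `l = sqrt(2*pi*a_h/N)` (the literal printed form);
#' `"root-surface"`: `l = sqrt(2*pi*a_root/N)`, the square root of the root
#' surface area associated with a single hair. See the vignette for why the
#' package defaults to the first.
#'
#' @param a_root root radius, cm.
#' @param N root hair density per unit root length, cm-1.
#' @param a_h root hair radius, cm.
#' @param mode `"hair-radius"` or `"root-surface"`.
#' @return hair spacing `l`, cm.
#' @examples
#' hair_spacing(0.05, 165, mode = "root-surface")  # 0.0436 cm
#' hair_spacing(0.05, 165)                         # 0.0039 cm
#' @export
hair_spacing <- function(a_root, N, a_h = 4e-4,
                         mode = c("hair-radius", "root-surface")) {
  mode <- match.arg(mode)
  .check_positive(a_root = a_root, N = N, a_h = a_h)
  if (mode == "hair-radius") sqrt(2 * pi * a_h / N) else sqrt(2 * pi * a_root / N)
}

#' Volumetric coefficient of the homogenized root-hair sink
#'
#' The hair sink in the hair zone is
#' `Q_rh = (L/l) * (2*pi*a_h/l^2) * Fmh * c / (Kmh + c)`,
#' where `2*pi*a_h/l^2` is the hair surface area per soil volume and `L/l`
#' the homogenization scale factor. This returns the concentration-independent
#' coefficient `(L/l) * (2*pi*a_h/l^2)` (cm-1) together with the spacing used.
#' A low hair density (`a_h/l` well below 1) underlies the homogenization; if
#' `a_h/l >= 0.15` a configuration warning (not an error) is raised.
#'
#' @inheritParams hair_spacing
#' @param L characteristic root length, cm.
#' @return list with `l` (cm), `coef` (cm-1) and `ratio` (`a_h/l`).
#' @export
hair_sink_coefficient <- function(a_root, N, a_h = 4e-4, L = 1,
                                  mode = c("hair-radius", "root-surface")) {
  mode <- match.arg(mode)
  .check_positive(L = L)
  l <- hair_spacing(a_root, N, a_h, mode)
  ratio <- a_h / l
  if (ratio >= 0.15) {
    warning(sprintf(
      "hair spacing l = %.3g cm gives a_h/l = %.2f >= 0.15; the dilute-hair assumption is strained",
      l, ratio), call. = FALSE)
  }
  list(l = l, coef = (L / l) * (2 * pi * a_h / l^2), ratio = ratio)
}

#' Homogenized root-hair sink term
#'
#' Volumetric uptake by root hairs, active only within the hair zone
#' (`r - a < l_rh`), while the hairs are alive (`t < lifetime`) and when the
#' segment carries hairs at all.
#'
#' @param c pore water concentration, mol cm-3 (vectorized over radius).
#' @param r radial position of each concentration, cm.
#' @param t_s simulation time, s.
#' @param a root radius, cm.
#' @param l_rh mean root hair length, cm.
#' @param lifetime_s functional hair lifetime, s.
#' @param has_hairs logical.
#' @param coef volumetric sink coefficient from [hair_sink_coefficient()], cm-1.
#' @param Fmh,Kmh hair uptake parameters (mol cm-2 s-1, mol cm-3).
#' @return sink `Q_rh`, mol cm-3 s-1 (zero outside the active zone/time).
#' @export
hair_sink <- function(c, r, t_s, a, l_rh, lifetime_s, has_hairs, coef, Fmh, Kmh) {
  stopifnot(length(c) == length(r))
  Q <- numeric(length(c))
  if (!has_hairs || Fmh <= 0 || t_s >= lifetime_s) return(Q)
  zone <- (r - a) < l_rh
  cz <- pmax(c[zone], 0)
  Q[zone] <- coef * Fmh * cz / (Kmh + cz)
  Q
}

#' Gypsum supersaturation driving concentration
#'
#' `M = max(min(c_Ca - sqrt(Ksp), c_S - sqrt(Ksp)), 0)`: the CaSO4
#' concentration still to be deposited before solution equilibrium; positive
#' only when both ions exceed the solubility threshold `sqrt(Ksp)`.
#'
#' @param c_ca,c_s pore water concentrations of Ca and S, mol cm-3
#'   (vectorized).
#' @param Ksp solubility product, mol2 cm-6.
#' @return driving concentration `M`, mol cm-3 (non-negative).
#' @export
precip_driving <- function(c_ca, c_s, Ksp) {
  .check_positive(Ksp = Ksp)
  s <- sqrt(Ksp)
  pmax(pmin(c_ca - s, c_s - s), 0)
}
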