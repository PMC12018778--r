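#' Load the packaged model parameter set
#'
#' Reads the packaged parameter tables (per-nutrient transport/uptake
#' constants, substrate properties and reaction/root-hair constants), converts
#' everything to the internal cm / s / mol unit system and returns a validated
#' parameter object.
#'
#' @param hair_spacing_mode how the mean distance `l` between neighbouring
#'   root hairs is computed for the homogenized hair sink:
#'   `"hair-radius"` (default) uses `l = sqrt(2*pi*a_h/N)` (the literal form
#'   of the published spacing formula); `"root-surface"` uses
#'   `l = sqrt(2*pi*a_root/N)`, i.e. the square root of the root surface area
#'   associated with one hair. The two readings differ by roughly two orders
#'   of magnitude in sink strength; see the package vignette.
#' @return an object of class `rg_params`: a list with components
#'   `nutrients` (per-element `D`, `Fm`, `Km`, `b` by substrate),
#'   `substrates` (`theta`, `Jw_daily`, `c_tot_ini`, root radii, hair length
#'   and density), `hairs` (`a_h`, `L`, `lifetime_s`, `spacing_mode`),
#'   `precip` (`k` in cm3 mol-1 s-1, `Ksp` in mol2 cm-6) and `f` (diffusion
#'   impedance factor).
#' @examples
#' p <- rg_parameters()
#' p$nutrients$Ca$Fm
#' sqrt(p$precip$Ksp)  # gypsum solubility threshold, mol cm-3
#' @export
rg_parameters <- function(hair_spacing_mode = c("hair-radius", "root-surface")) {
  hair_spacing_mode <- match.arg(hair_spacing_mode)
  ext <- function(f) system.file("extdata", f, package = "rhizograd", mustWork = TRUE)
  nut <- read.csv(ext("nutrient_params.csv"), comment.char = "#")
  sub <- read.csv(ext("substrate_params.csv"), comment.char = "#")
  rea <- read.csv(ext("reaction_params.csv"), comment.char = "#")

  rval <- function(name) {
    i <- match(name, rea$parameter)
    if (is.na(i)) stop("missing reaction parameter: ", name)
    rea$value[i]
  }
  sval <- function(name, substrate) {
    i <- match(name, sub$parameter)
    if (is.na(i)) stop("missing substrate parameter: ", name)
    sub[[substrate]][i]
  }

  nutrients <- list()
  for (i in seq_len(nrow(nut))) {
    nutrients[[nut$element[i]]] <- nutrient_spec(
      name = nut$element[i],
      D = nut$D_cm2_s[i],
      Fm = nut$Fm_mol_cm2_s[i],
      Km = nut$Km_mol_cm3[i],
      b = c(loam = nut$b_loam[i], sand = nut$b_sand[i])
    )
  }

  substrates <- list()
  for (s in c("loam", "sand")) {
    substrates[[s]] <- substrate_spec(
      name = s,
      theta = sval("theta", s),
      Jw_daily = sval("Jw_daily", s),
      c_tot_ini = c(Ca = sval("c_tot_ini_Ca", s),
                    S = sval("c_tot_ini_S", s),
                    P = sval("c_tot_ini_P", s)),
      a_primary = sval("a_primary", s),
      a_tip = sval("a_tip", s),
      RL_tot = sval("RL_tot", s),
      RWU21 = sval("RWU21", s),
      l_rh = convert_units(sval("l_rh", s), "um", "cm"),
      N_hairs = sval("N_hairs", s)
    )
  }

  p <- structure(list(
    nutrients = nutrients,
    substrates = substrates,
    hairs = list(
      a_h = rval("a_h"),
      L = rval("L_char"),
      lifetime_s = convert_units(rval("hair_lifetime"), "d", "s"),
      spacing_mode = hair_spacing_mode
    ),
    precip = precipitation_spec(
      k = convert_units(rval("k_precip"), "l mol-1 min-1", "cm3 mol-1 s-1"),
      Ksp = convert_units(rval("Ksp_CaSO4"), "mol2 l-2", "mol2 cm-6")
    ),
    f = rval("f_impedance")
  ), class = "rg_params")
  p
}

#' Per-nutrient transport and uptake constants
#'
#' @param name element label, one of `"Ca"`, `"S"`, `"P"`.
#' @param D liquid diffusion coefficient, cm2 s-1.
#' @param Fm maximum root uptake rate, mol cm-2 s-1.
#' @param Km half-saturation concentration, mol cm-3.
#' @param b soil buffer power (dimensionless), possibly a named vector by
#'   substrate.
#' @param Fmh,Kmh root-hair uptake parameters; default equal to the root's.
#' @return a validated list of class `rg_nutrient`.
#' @export
nutrient_spec <- function(name, D, Fm, Km, b, Fmh = Fm, Kmh = Km) {
  name <- .match_one(name, c("Ca", "S", "P"), "name")
  .check_positive(D = D, Fm = Fm, Km = Km, b = b, Kmh = Kmh)
  .check_positive(Fmh = Fmh, .allow_zero = TRUE)
  structure(list(name = name, D = D, Fm = Fm, Km = Km, b = b,
                 Fmh = Fmh, Kmh = Kmh), class = "rg_nutrient")
}

#' Substrate properties
#'
#' @param name substrate label (`"loam"` or `"sand"`).
#' @param theta volumetric water content, cm3 cm-3 (0 < theta < 1).
#' @param Jw_daily daily-mean water flux to the root surface, cm s-1.
#' @param c_tot_ini named vector of total (dissolved + sorbed) initial
#'   concentrations per soil volume, mol cm-3.
#' @param a_primary,a_tip root radii of primary root segments and root tips, cm.
#' @param RL_tot total root length in the column, cm.
#' @param RWU21 root water uptake around day 21, cm3 d-1.
#' @param l_rh mean root hair length, cm.
#' @param N_hairs mean root hair density per unit root length, cm-1.
#' @return a validated list of class `rg_substrate`.
#' @export
substrate_spec <- function(name, theta, Jw_daily, c_tot_ini,
                           a_primary, a_tip, RL_tot, RWU21, l_rh, N_hairs) {
  name <- .match_one(name, c("loam", "sand"), "name")
  .check_positive(theta = theta, c_tot_ini = c_tot_ini, a_primary = a_primary,
                  a_tip = a_tip, RL_tot = RL_tot, RWU21 = RWU21,
                  l_rh = l_rh, N_hairs = N_hairs)
  .check_positive(Jw_daily = Jw_daily, .allow_zero = TRUE)
  if (theta >= 1) stop("'theta' must be < 1", call. = FALSE)
  structure(list(name = name, theta = theta, Jw_daily = Jw_daily,
                 c_tot_ini = c_tot_ini, a_primary = a_primary, a_tip = a_tip,
                 RL_tot = RL_tot, RWU21 = RWU21, l_rh = l_rh,
                 N_hairs = N_hairs), class = "rg_substrate")
}

#' Gypsum precipitation constants
#'
#' Second-order irreversible CaSO4 precipitation: the sink is `k * M^2` where
#' `M = max(min(c_Ca - sqrt(Ksp), c_S - sqrt(Ksp)), 0)` is the concentration
#' of CaSO4 still to be deposited before equilibrium.
#'
#' @param k reaction rate constant, cm3 mol-1 s-1.
#' @param Ksp solubility product, mol2 cm-6.
#' @return a validated list of class `rg_precip`.
#' @export
precipitation_spec <- function(k, Ksp) {
  .check_positive(k = k, Ksp = Ksp)
  structure(list(k = k, Ksp = Ksp), class = "rg_precip")
}

#' One simulated root segment
#'
#' @param a root radius, cm.
#' @param duration_d simulated duration, days.
#' @param has_hairs logical; whether the segment carries functional root hairs.
#' @return list of class `rg_segment`.
#' @export
root_segment <- function(a, duration_d, has_hairs = TRUE) {
  .check_positive(a = a, duration_d = duration_d)
  stopifnot(is.logical(has_hairs), length(has_hairs) == 1L)
  structure(list(a = a, duration_d = duration_d, has_hairs = has_hairs),
            class = "rg_segment")
}

#' @export
print.rg_params <- function(x, ...) {
  cat("rhizosphere model parameter set\n")
  cat("  nutrients :", paste(names(x$nutrients), collapse = ", "), "\n")
  cat("  substrates:", paste(names(x$substrates), collapse = ", "), "\n")
  cat(sprintf("  precipitation: k = %.4g cm3 mol-1 s-1, sqrt(Ksp) = %.4g mol cm-3\n",
              x$precip$k, sqrt(x$precip$Ksp)))
  cat(sprintf("  hair spacing mode: %s, lifetime %.0f d\n",
              x$hairs$spacing_mode, x$hairs$lifetime_s / 86400))
  invisible(x)
}
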