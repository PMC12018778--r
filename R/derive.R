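## Derivation of model inputs from measured quantities: initial pore water
## concentrations, root-surface water flux, clay-scaled buffer powers and the
## half-mean inter-root distance used to justify the isolated-root assumption.

#' Initial pore water concentration from a total pool
#'
#' Under instantaneous linear sorption, a total (dissolved + sorbed)
#' concentration per soil volume partitions as
#' `c_pw = c_tot / (theta + b)`.
#'
#' @param c_tot_ini total initial concentration, mol cm-3 soil.
#' @param theta volumetric water content, cm3 cm-3.
#' @param b soil buffer power (dimensionless).
#' @return initial pore water concentration, mol cm-3 solution.
#' @examples
#' pore_water_init(1.27e-4, 0.22, 2)     # Ca in loam: 5.72e-5
#' pore_water_init(2.99e-6, 0.22, 239)   # P in loam:  1.25e-8
#' @export
pore_water_init <- function(c_tot_ini, theta, b) {
  .check_positive(c_tot_ini = c_tot_ini, theta = theta)
  .check_positive(b = b, .allow_zero = TRUE)
  if (any(theta + b <= 0)) stop("theta + b must be positive", call. = FALSE)
  c_tot_ini / (theta + b)
}

#' Mean water flux at the root surface from whole-plant water uptake
#'
#' Distributes the measured root water uptake uniformly over the root system
#' surface: `Jw = RWU21 / (RL21 * 2 * pi * a_mean)`, with `RWU21` converted
#' from cm3 d-1 to cm3 s-1. The mean root radius is an explicit input (it is
#' not part of the packaged tables); the packaged per-substrate `Jw_daily`
#' values are the authoritative model inputs and this function documents how
#' they arise.
#'
#' @param RWU21 root water uptake, cm3 d-1.
#' @param RL21 total root length, cm.
#' @param a_mean mean root radius, cm.
#' @return daily-mean water flux to the root, cm s-1.
#' @examples
#' jw_from_rwu(73.3, 10917, 0.023)  # about 5.38e-7 cm/s
#' @export
jw_from_rwu <- function(RWU21, RL21, a_mean) {
  .check_positive(RL21 = RL21, a_mean = a_mean)
  .check_positive(RWU21 = RWU21, .allow_zero = TRUE)
  (RWU21 / 86400) / (RL21 * 2 * pi * a_mean)
}

#' Scale a buffer power by relative clay content
#'
#' Buffer power correlates with clay content through reactive surface area;
#' the sand substrate's buffer powers derive from the loam's by direct
#' proportionality, `b_sand = b_loam * clay_ratio`.
#'
#' @param b_reference reference buffer power (dimensionless).
#' @param clay_ratio clay content ratio target/reference (dimensionless).
#' @return scaled buffer power.
#' @examples
#' buffer_from_clay(239, 0.1728)  # 41.3
#' @export
buffer_from_clay <- function(b_reference, clay_ratio) {
  .check_positive(b_reference = b_reference, clay_ratio = clay_ratio)
  b_reference * clay_ratio
}

#' Inner volume of a cylindrical growth column
#'
#' @param diameter inner diameter, cm (default 7).
#' @param height fill height, cm (default 23).
#' @return volume, cm3.
#' @export
column_volume <- function(diameter = 7, height = 23) {
  .check_positive(diameter = diameter, height = height)
  pi * (diameter / 2)^2 * height
}

#' Half-mean distance between neighbouring roots
#'
#' Gardner's estimate from the root length density `RLD = RL / V`:
#' `r_half = (pi * RLD)^(-1/2)`. Used to check that simulated rhizosphere
#' extents stay below the spacing at which neighbouring roots would interact.
#'
#' @param RL_total total root length, cm.
#' @param volume soil volume containing it, cm3.
#' @return half-mean inter-root distance, cm.
#' @examples
#' half_mean_root_distance(10917, column_volume())  # 0.161 cm = 1.6 mm
#' @export
half_mean_root_distance <- function(RL_total, volume) {
  .check_positive(RL_total = RL_total, volume = volume)
  1 / sqrt(pi * RL_total / volume)
}

#' Report the derived model inputs for the packaged parameter set
#'
#' @param params a parameter set from [rg_parameters()].
#' @return a data frame with one row per derived quantity (initial pore water
#'   concentrations per substrate and nutrient, half-mean root distances,
#'   converted reaction constants) including the formula used and units.
#' @export
derivation_report <- function(params = rg_parameters()) {
  rows <- list()
  for (s in names(params$substrates)) {
    sub <- params$substrates[[s]]
    for (el in names(params$nutrients)) {
      b <- params$nutrients[[el]]$b[[s]]
      rows[[length(rows) + 1L]] <- data.frame(
        quantity = sprintf("c_pw_ini_%s_%s", el, s),
        formula = "c_tot_ini/(theta+b)",
        value = pore_water_init(sub$c_tot_ini[[el]], sub$theta, b),
        unit = "mol cm-3")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = sprintf("r_half_%s", s),
      formula = "(pi*RL/V)^-0.5",
      value = half_mean_root_distance(sub$RL_tot, column_volume()),
      unit = "cm")
  }
  rows[[length(rows) + 1L]] <- data.frame(
    quantity = "k_precip", formula = "2 l mol-1 min-1 -> cm3 mol-1 s-1",
    value = params$precip$k, unit = "cm3 mol-1 s-1")
  rows[[length(rows) + 1L]] <- data.frame(
    quantity = "sqrt_Ksp", formula = "sqrt(2.4e-5 mol2 l-2 -> mol2 cm-6)",
    value = sqrt(params$precip$Ksp), unit = "mol cm-3")
  do.call(rbind, rows)
}
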