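## Unit conversion for the small set of unit pairs this model needs.
## Everything internal to the package is cm / s / mol; printed sources mix
## litres, minutes, days and micromoles, which is exactly the class of error
## a factor-of-10^6 slip in Ksp would produce, so conversions are centralised
## here and round-trip exactly.

.unit_factors <- local({
  pairs <- list(
    c("l mol-1 min-1", "cm3 mol-1 s-1", 1000 / 60),
    c("mol2 l-2",      "mol2 cm-6",     1e-6),
    c("mol l-1",       "mol cm-3",      1e-3),
    c("mm(ca)",        "mol cm-3",      1e-6),   # millimolar, see normalisation
    c("d",             "s",             86400),
    c("h",             "s",             3600),
    c("min",           "s",             60),
    c("umol",          "mol",           1e-6),
    c("umol cm-3",     "mol cm-3",      1e-6),
    c("um",            "cm",            1e-4),
    c("mm",            "cm",            0.1)
  )
  tab <- list()
  for (p in pairs) {
    f <- as.numeric(p[3])
    tab[[paste(p[1], p[2], sep = " => ")]] <- f
    tab[[paste(p[2], p[1], sep = " => ")]] <- 1 / f
  }
  tab
})

.normalize_unit <- function(u) {
  u <- tolower(trimws(gsub("\\s+", " ", u)))
  u <- gsub("−", "-", u)               # unicode minus
  u <- gsub("\\^", "", u)                   # cm^2 -> cm2
  if (u %in% c("mm (molar)", "mmolar", "mmol l-1")) u <- "mm(ca)"
  u
}

#' Convert a value between supported unit pairs
#'
#' Exact factor conversion between the unit pairs used by the transport model
#' (litre/minute based reaction constants, solubility products, days, microns,
#' micromoles and millimolar concentrations versus the internal cm/s/mol
#' system). Conversions round-trip exactly. Note `"mM"` (millimolar) must be
#' written as `"mmol l-1"` to avoid ambiguity with millimetres.
#'
#' @param value numeric vector to convert.
#' @param from,to unit strings, e.g. `"l mol-1 min-1"`, `"cm3 mol-1 s-1"`,
#'   `"mol2 l-2"`, `"mol2 cm-6"`, `"d"`, `"s"`, `"um"`, `"cm"`, `"umol cm-3"`,
#'   `"mol cm-3"`, `"mmol l-1"`.
#' @return `value` expressed in `to` units.
#' @examples
#' convert_units(2, "l mol-1 min-1", "cm3 mol-1 s-1")   # 33.33
#' convert_units(2.4e-5, "mol2 l-2", "mol2 cm-6")       # 2.4e-11
#' @export
convert_units <- function(value, from, to) {
  stopifnot(is.numeric(value))
  from <- .normalize_unit(from)
  to <- .normalize_unit(to)
  if (identical(from, to)) return(value)
  key <- paste(from, to, sep = " => ")
  f <- .unit_factors[[key]]
  if (is.null(f)) {
    stop(sprintf("unsupported unit conversion '%s' -> '%s'", from, to),
         call. = FALSE)
  }
  value * f
}
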