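## Method-of-lines solver for the radially symmetric transport model
##
## (theta + b) dc/dt = (1/r) d/dr ( r De dc/dr + a Jw(t) c ) - Q_hair - k M^2
##
## with a Michaelis-Menten uptake boundary at the root surface
## ( De dc/dr + Jw c = Fm c/(Km + c) at r = a ) and a Dirichlet condition
## c = c_pw,ini at the outer radius. Ca and S are advanced as a coupled pair
## sharing the precipitation sink with 1:1 stoichiometry; the precipitated
## pool is a per-cell, non-transported, irreversibly growing state. P runs
## alone without precipitation.
##
## Discretization: conservative finite volumes on the geometric grid from
## radial_grid(), central (arithmetic-mean) face concentrations for the
## advective term (cell Peclet << 1 at these water fluxes), stiff implicit
## integration with deSolve's lsodes. Transported states are interleaved by
## cell (c_Ca, c_S, pool, next cell, ...) which keeps the Jacobian tightly
## banded; cumulative uptake, hair uptake and outer-boundary influx are
## appended as pure integral states so mass balance can be audited exactly.
## Integration is split at the root-hair lifetime so the sink switch-off is
## a segment boundary, not a discontinuity inside the integrator.

#' Solver control settings
#'
#' @param n_cells number of radial cells (default 300).
#' @param first_cell innermost cell width, cm (default 2.5e-4).
#' @param r_out outer domain radius, cm (default 6).
#' @param rtol,atol relative/absolute integrator tolerances (defaults 1e-8 and
#'   1e-14 mol cm-3).
#' @param maxsteps maximum internal steps per output interval.
#' @param outer_bc `"dirichlet"` (concentration pinned at the initial pore
#'   water value) or `"closed"` (zero flux; used for mass-balance audits).
#' @param save_every_s spacing of saved output times, s (default daily).
#' @return list of class `rg_control`.
#' @export
solver_control <- function(n_cells = 300, first_cell = 2.5e-4, r_out = 6,
                           rtol = 1e-8, atol = 1e-14, maxsteps = 2e5,
                           outer_bc = c("dirichlet", "closed"),
                           save_every_s = 86400) {
  outer_bc <- match.arg(outer_bc)
  .check_positive(n_cells = n_cells, first_cell = first_cell, r_out = r_out,
                  rtol = rtol, atol = atol, maxsteps = maxsteps,
                  save_every_s = save_every_s)
  structure(list(n_cells = as.integer(n_cells), first_cell = first_cell,
                 r_out = r_out, rtol = rtol, atol = atol,
                 maxsteps = as.integer(maxsteps), outer_bc = outer_bc,
                 save_every_s = save_every_s), class = "rg_control")
}

#' Define a single simulation scenario
#'
#' @param substrate `"loam"` or `"sand"`.
#' @param segment `"primary"` (default duration 21 d) or `"tip"` (7 d).
#' @param uptake_variant `"WT-full"` (hairs with `Fmh = Fm`), `"WT-half"`
#'   (`Fmh = Fm/2`) or `"rth3"` (hairless mutant: hair sink off).
#' @param radius root radius override, cm (default from the packaged tables).
#' @param duration_d simulated duration override, days.
#' @param id scenario identifier; constructed from the factors if missing.
#' @param core logical, whether the scenario belongs to the core factorial.
#' @return list of class `rg_scenario`.
#' @export
scenario <- function(substrate, segment, uptake_variant,
                     radius = NULL, duration_d = NULL, id = NULL, core = TRUE) {
  substrate <- .match_one(substrate, c("loam", "sand"), "substrate")
  segment <- .match_one(segment, c("primary", "tip"), "segment")
  uptake_variant <- .match_one(uptake_variant, c("WT-full", "WT-half", "rth3"),
                               "uptake_variant")
  if (is.null(duration_d)) duration_d <- if (segment == "tip") 7 else 21
  hair_mult <- switch(uptake_variant, "WT-full" = 1, "WT-half" = 0.5, "rth3" = 0)
  if (is.null(id)) {
    id <- sprintf("%s_%s_%s_%gd", substrate, segment, uptake_variant, duration_d)
  }
  structure(list(id = id, substrate = substrate, segment = segment,
                 uptake_variant = uptake_variant, hair_mult = hair_mult,
                 has_hairs = hair_mult > 0, radius = radius,
                 duration_d = duration_d, core = isTRUE(core)),
            class = "rg_scenario")
}

## Right-hand side factory for one (possibly coupled) transport solve.
## els: character vector of elements; precip TRUE couples the first two
## elements (Ca, S) through the shared -k M^2 sink and adds the pool state.
.make_rhs <- function(els, grid, env) {
  n <- grid$n
  ne <- length(els)
  np <- if (env$precip) 1L else 0L
  stride <- ne + np
  idx <- lapply(seq_len(ne), function(j) seq(j, stride * n, by = stride))
  ipool <- if (np) seq(ne + 1L, stride * n, by = stride) else integer(0)
  n_trans <- stride * n
  faces_in <- grid$faces[2:n]
  f_out <- grid$faces[n + 1]
  r_n <- grid$r[n]
  V2 <- grid$V2
  dc <- grid$dc
  a <- grid$a

  function(t, y, parms) {
    hairs_on <- parms$hairs_on
    Jw <- env$Jw_daily * (sin(2 * pi * (t / 3600) / 24 - pi / 2) + 1)
    ## transport acts on the raw states (clipping there would break both
    ## smoothness and conservation); only the reaction terms see clipped
    ## concentrations
    conc <- lapply(idx, function(ii) y[ii])
    if (env$precip) {
      M <- pmax(pmin(conc[[1]] - env$sqrt_Ksp, conc[[2]] - env$sqrt_Ksp), 0)
      pr <- env$k_precip * M * M
    } else pr <- 0
    dy <- numeric(n_trans + 3L * ne)
    for (j in seq_len(ne)) {
      cj <- conc[[j]]
      De <- env$De[j]
      ## r * (De dc/dr + a Jw c / r) at each face
      rG <- numeric(n + 1)
      rG[2:n] <- faces_in * De * (cj[2:n] - cj[1:(n - 1)]) / dc +
        a * Jw * 0.5 * (cj[2:n] + cj[1:(n - 1)])
      c1 <- max(cj[1], 0)
      up <- env$Fm[j] * c1 / (env$Km[j] + c1)
      rG[1] <- a * up
      if (env$dirichlet) {
        rG[n + 1] <- f_out * De * (env$cpw_ini[j] - cj[n]) / (f_out - r_n) +
          a * Jw * env$cpw_ini[j]
      }
      Q <- numeric(n)
      if (hairs_on && env$Fmh[j] > 0) {
        cz <- pmax(cj[env$hair_zone], 0)
        Q[env$hair_zone] <- env$hair_coef * env$Fmh[j] * cz / (env$Kmh[j] + cz)
      }
      dy[idx[[j]]] <- diff(rG) / (env$thb[j] * V2) - (Q + pr) / env$thb[j]
      dy[n_trans + j] <- 2 * pi * a * up                 # root uptake, mol/cm
      dy[n_trans + ne + j] <- 2 * pi * sum(Q * V2)       # hair uptake, mol/cm
      dy[n_trans + 2L * ne + j] <- 2 * pi * rG[n + 1]    # boundary influx
    }
    if (env$precip) dy[ipool] <- pr
    list(dy)
  }
}

## One transport solve (one element, or the Ca+S coupled pair).
.solve_block <- function(els, sc, params, control) {
  sub <- params$substrates[[sc$substrate]]
  nspec <- params$nutrients[els]
  a <- if (is.null(sc$radius)) {
    if (sc$segment == "tip") sub$a_tip else sub$a_primary
  } else sc$radius
  grid <- radial_grid(a, r_out = control$r_out, n = control$n_cells,
                      first_width = control$first_cell)
  hsc <- hair_sink_coefficient(a, sub$N_hairs, params$hairs$a_h,
                               params$hairs$L, params$hairs$spacing_mode)
  precip <- all(c("Ca", "S") %in% els)
  env <- list(
    precip = precip,
    dirichlet = control$outer_bc == "dirichlet",
    De = vapply(nspec, function(x) effective_diffusion(x$D, sub$theta, params$f), 0),
    Fm = vapply(nspec, `[[`, 0, "Fm"),
    Km = vapply(nspec, `[[`, 0, "Km"),
    Fmh = vapply(nspec, `[[`, 0, "Fm") * sc$hair_mult,
    Kmh = vapply(nspec, `[[`, 0, "Km"),
    thb = sub$theta + vapply(nspec, function(x) x$b[[sc$substrate]], 0),
    cpw_ini = vapply(els, function(el) {
      pore_water_init(sub$c_tot_ini[[el]], sub$theta,
                      params$nutrients[[el]]$b[[sc$substrate]])
    }, 0),
    Jw_daily = sub$Jw_daily,
    k_precip = params$precip$k,
    sqrt_Ksp = sqrt(params$precip$Ksp),
    hair_zone = (grid$r - a) < sub$l_rh,
    hair_coef = hsc$coef
  )
  rhs <- .make_rhs(els, grid, env)

  ne <- length(els)
  stride <- ne + if (precip) 1L else 0L
  n <- grid$n
  y0 <- numeric(stride * n + 3L * ne)
  for (j in seq_len(ne)) y0[seq(j, stride * n, by = stride)] <- env$cpw_ini[j]

  T_s <- sc$duration_d * 86400
  t_switch <- min(params$hairs$lifetime_s, T_s)
  hairs_first <- sc$has_hairs && sc$hair_mult > 0
  segments <- if (hairs_first && t_switch < T_s) {
    list(list(t = c(0, t_switch), on = TRUE), list(t = c(t_switch, T_s), on = FALSE))
  } else {
    list(list(t = c(0, T_s), on = hairs_first))
  }

  out <- NULL
  y <- y0
  for (seg in segments) {
    tt <- unique(c(seq(seg$t[1], seg$t[2], by = control$save_every_s), seg$t[2]))
    o <- deSolve::ode(y, tt, rhs, parms = list(hairs_on = seg$on),
                      method = "lsodes", rtol = control$rtol,
                      atol = control$atol, maxsteps = control$maxsteps)
    if (attr(o, "istate")[1] < 0) {
      stop(sprintf("transport solve failed for %s [%s] at t=%.0f s (istate %d)",
                   sc$id, paste(els, collapse = "+"),
                   o[nrow(o), 1], attr(o, "istate")[1]), call. = FALSE)
    }
    out <- if (is.null(out)) o else rbind(out, o[-1, , drop = FALSE])
    y <- o[nrow(o), -1]
  }

  times <- out[, 1]
  nt <- length(times)
  conc <- array(NA_real_, c(nt, n, ne), dimnames = list(NULL, NULL, els))
  for (j in seq_len(ne)) conc[, , j] <- out[, 1 + seq(j, stride * n, by = stride)]
  pool <- if (precip) out[, 1 + seq(ne + 1L, stride * n, by = stride)] else NULL
  extra <- out[, 1 + stride * n + seq_len(3 * ne), drop = FALSE]
  list(times = times, grid = grid, conc = conc, pool = pool,
       U_root = matrix(extra[, seq_len(ne)], nt, dimnames = list(NULL, els)),
       U_hair = matrix(extra[, ne + seq_len(ne)], nt, dimnames = list(NULL, els)),
       influx = matrix(extra[, 2 * ne + seq_len(ne)], nt, dimnames = list(NULL, els)),
       cpw_ini = env$cpw_ini, thb = env$thb,
       b = env$thb - sub$theta, theta = sub$theta, a = a)
}

#' Run one rhizosphere simulation scenario
#'
#' Solves the coupled Ca+S pair (with gypsum precipitation) and P (without)
#' over the scenario's duration and returns profile time series, cumulative
#' uptake and mass-balance diagnostics.
#'
#' @param sc a scenario from [scenario()] or one row of [scenario_matrix()].
#' @param params parameter set from [rg_parameters()].
#' @param control solver settings from [solver_control()].
#' @return an object of class `rg_sim`: list with `times` (s), `grid`,
#'   per-element pore-water concentration arrays `conc[time, cell, element]`,
#'   the precipitated CaSO4 pool `pool[time, cell]` (mol cm-3 soil),
#'   cumulative root/hair uptake and boundary influx (mol per cm root length),
#'   buffer powers and initial pore water concentrations.
#' @examples
#' \donttest{
#' sc <- scenario("loam", "primary", "rth3")
#' sim <- run_simulation(sc, control = solver_control(n_cells = 120))
#' mass_balance(sim)
#' }
#' @export
run_simulation <- function(sc, params = rg_parameters(),
                           control = solver_control()) {
  stopifnot(inherits(sc, "rg_scenario"))
  cas <- .solve_block(c("Ca", "S"), sc, params, control)
  p <- .solve_block("P", sc, params, control)
  conc <- array(NA_real_, c(length(cas$times), cas$grid$n, 3),
                dimnames = list(NULL, NULL, c("Ca", "S", "P")))
  conc[, , c("Ca", "S")] <- cas$conc
  conc[, , "P"] <- p$conc[, , 1]
  structure(list(
    scenario = sc, params = params, control = control,
    times = cas$times, grid = cas$grid,
    conc = conc, pool = cas$pool,
    U_root = cbind(cas$U_root, P = p$U_root[, 1]),
    U_hair = cbind(cas$U_hair, P = p$U_hair[, 1]),
    influx = cbind(cas$influx, P = p$influx[, 1]),
    cpw_ini = c(cas$cpw_ini, P = unname(p$cpw_ini)),
    b = c(cas$b, P = unname(p$b)),
    theta = cas$theta, a = cas$a
  ), class = "rg_sim")
}

#' @export
print.rg_sim <- function(x, ...) {
  cat(sprintf("rhizosphere simulation '%s': %d cells, %.0f d, a = %.4g cm\n",
              x$scenario$id, x$grid$n, max(x$times) / 86400, x$a))
  mb <- mass_balance(x)
  cat("  cumulative uptake (mol/cm):",
      paste(sprintf("%s %.3g", colnames(x$U_root),
                    x$U_root[nrow(x$U_root), ] + x$U_hair[nrow(x$U_hair), ]),
            collapse = ", "), "\n")
  cat(sprintf("  max mass-balance residual: %.2e\n", max(mb$residual)))
  invisible(x)
}

#' Nutrient pools per soil volume
#'
#' Converts a simulated pore-water profile into per-soil-volume pools:
#' dissolved (`theta * c`), sorbed (`b * c`), precipitated (tracked CaSO4
#' pool; counts fully toward both Ca and S) and the mapped-comparison
#' quantity an element map would see (sorbed + precipitated for Ca and S,
#' sorbed for P — dehydrated samples carry no dissolved phase).
#'
#' @param sim result of [run_simulation()].
#' @param element `"Ca"`, `"S"` or `"P"`.
#' @param time_index row of `sim$times` (default: final time).
#' @return data frame with columns `r`, `c_pw`, `dissolved`, `sorbed`,
#'   `precipitated`, `mapped` (all mol cm-3).
#' @export
pools_per_soil_volume <- function(sim, element, time_index = NULL) {
  stopifnot(inherits(sim, "rg_sim"))
  element <- .match_one(element, c("Ca", "S", "P"), "element")
  if (is.null(time_index)) time_index <- length(sim$times)
  cpw <- pmax(sim$conc[time_index, , element], 0)
  b <- sim$b[[element]]
  prec <- if (element %in% c("Ca", "S")) sim$pool[time_index, ] else 0
  data.frame(r = sim$grid$r, c_pw = cpw,
             dissolved = sim$theta * cpw, sorbed = b * cpw,
             precipitated = prec,
             mapped = b * cpw + prec)
}

#' Mass-balance audit of a simulation
#'
#' For each element and saved time, compares the domain inventory
#' (dissolved + sorbed + precipitated, integrated over the annulus) plus
#' cumulative root and hair uptake against the initial inventory plus the
#' cumulative influx through the outer boundary. The residual is relative to
#' the initial inventory; on closed-domain runs the influx term is zero.
#'
#' @param sim result of [run_simulation()].
#' @return data frame with one row per element: initial and final inventory
#'   (mol per cm root length) and the maximum relative residual over time.
#' @export
mass_balance <- function(sim) {
  stopifnot(inherits(sim, "rg_sim"))
  V2 <- sim$grid$V2
  out <- lapply(c("Ca", "S", "P"), function(el) {
    thb <- sim$theta + sim$b[[el]]
    prec <- if (el %in% c("Ca", "S")) sim$pool else matrix(0, length(sim$times), sim$grid$n)
    inv <- 2 * pi * (sim$conc[, , el] %*% V2 * thb + prec %*% V2)
    total <- inv + sim$U_root[, el] + sim$U_hair[, el] - sim$influx[, el]
    data.frame(element = el, inventory_ini = inv[1], inventory_fin = inv[length(inv)],
               uptake = sim$U_root[nrow(sim$U_root), el] + sim$U_hair[nrow(sim$U_hair), el],
               residual = max(abs(total - total[1])) / total[1])
  })
  do.call(rbind, out)
}
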