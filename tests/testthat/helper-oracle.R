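## Independent oracles used to validate the package's solvers and profilers.
## These deliberately use different discretizations/algorithms than the
## package code.

## Explicit forward-Euler finite-difference solver for the coupled radial
## transport problem on a uniform node-centered grid. Used only on short,
## small-domain cases. `els` is a subset of c("Ca", "S", "P"); Ca+S couple
## through the precipitation sink when both are present.
oracle_transport <- function(substrate = "loam", a = 0.05, T_d = 1,
                             els = c("Ca", "S"), hair_mult = 1,
                             r_out = 2, dr = 2e-3, dt = NULL,
                             params = rg_parameters()) {
  sub <- params$substrates[[substrate]]
  ne <- length(els)
  D <- sapply(els, function(e) params$nutrients[[e]]$D)
  b <- sapply(els, function(e) params$nutrients[[e]]$b[[substrate]])
  Fm <- sapply(els, function(e) params$nutrients[[e]]$Fm)
  Km <- sapply(els, function(e) params$nutrients[[e]]$Km)
  De <- D * sub$theta * params$f
  thb <- sub$theta + b
  cpw <- sapply(els, function(e) sub$c_tot_ini[[e]] / (sub$theta + params$nutrients[[e]]$b[[substrate]]))
  precip <- all(c("Ca", "S") %in% els)
  sKsp <- sqrt(params$precip$Ksp)
  kpre <- params$precip$k
  hsc <- hair_sink_coefficient(a, sub$N_hairs, params$hairs$a_h, params$hairs$L,
                               params$hairs$spacing_mode)
  Fmh <- Fm * hair_mult

  r <- seq(a, r_out, by = dr)
  m <- length(r)
  if (is.null(dt)) dt <- 0.4 * dr^2 * min(thb) / max(De)
  nstep <- ceiling(T_d * 86400 / dt)
  dt <- T_d * 86400 / nstep

  hz <- (r - a) < sub$l_rh
  C <- matrix(rep(cpw, each = m), m, ne)
  rp <- r + dr / 2   # face radii (right)
  rm <- r - dr / 2
  V2_0 <- (rp[1]^2 - a^2) / 2          # half cell at the root node
  lifetime <- params$hairs$lifetime_s

  t <- 0
  for (s in seq_len(nstep)) {
    Jw <- water_flux_at(t / 3600, sub$Jw_daily)
    hairs_on <- (t < lifetime) && hair_mult > 0
    pr <- if (precip) kpre * precip_driving(C[, 1], C[, 2], params$precip$Ksp)^2 else 0
    Cn <- C
    for (j in seq_len(ne)) {
      cj <- C[, j]
      ## face fluxes r*(De dc/dr + a Jw c / r)
      rG <- rp[-m] * De[j] * (cj[-1] - cj[-m]) / dr + a * Jw * 0.5 * (cj[-1] + cj[-m])
      up <- Fm[j] * max(cj[1], 0) / (Km[j] + max(cj[1], 0))
      Q <- numeric(m)
      if (hairs_on) Q[hz] <- hsc$coef * Fmh[j] * pmax(cj[hz], 0) /
          (Km[j] + pmax(cj[hz], 0))
      dc <- numeric(m)
      dc[1] <- (rG[1] - a * up) / (thb[j] * V2_0)
      ii <- 2:(m - 1)
      dc[ii] <- (rG[ii] - rG[ii - 1]) / (thb[j] * (rp[ii]^2 - rm[ii]^2) / 2)
      dc <- dc - (Q + pr) / thb[j]
      dc[m] <- 0  # Dirichlet
      Cn[, j] <- cj + dt * dc
    }
    C <- Cn
    t <- t + dt
  }
  list(r = r, C = C, els = els, cpw = cpw)
}

## Brute-force per-pixel radial aggregation (group-by), the oracle for
## radial_profile().
oracle_profile <- function(map, distances, pore_mask = NULL, bin_width = 20) {
  keep <- distances > 0
  if (!is.null(pore_mask)) keep <- keep & !(pore_mask > 0)
  df <- data.frame(v = map[keep], bin = floor(distances[keep] / bin_width))
  agg <- lapply(split(df$v, df$bin), function(v) {
    c(n = length(v), mean = mean(v), sd = sqrt(mean((v - mean(v))^2)))
  })
  out <- do.call(rbind, agg)
  data.frame(bin = as.integer(rownames(out)), n = out[, "n"],
             mean = out[, "mean"], sd = out[, "sd"])
}

## Direct weighted-moment computation, the oracle for bulk_stats().
oracle_weighted_stats <- function(values, weights) {
  m <- sum(weights * values) / sum(weights)
  list(mean = m, sd = sqrt(sum(weights * (values - m)^2) / sum(weights)))
}

## Small, fast solver settings used across tests.
fast_control <- function(n_cells = 150, ...) {
  solver_control(n_cells = n_cells, ...)
}
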