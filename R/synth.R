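## Seeded generator of synthetic micro-XRF-like element maps with known
## ground truth, so the radial-profile pipeline is testable end to end
## without experimental data. Two substrate styles are emulated: "sand"
## (well-sorted grains that pack in shells against the root, producing the
## undulating porosity imprint granular substrates show in radial profiles)
## and "loam" (a fine-textured matrix with sparse pores). Enrichment with a
## known radial envelope is deposited on matrix pixels, optionally
## concentrated at grain/pore contacts, and Poisson count noise is applied
## last.

#' Recipe for one synthetic element map
#'
#' @param style `"loam"` or `"sand"`.
#' @param size_px map edge length, pixels (default 401, i.e. a 4 mm
#'   half-width field of view at 20 um pixels).
#' @param pixel_um pixel size, um (default 20).
#' @param root_radius_um radius of the central root disc, um.
#' @param background mean background count level on matrix pixels.
#' @param amplitude enrichment amplitude at the root surface, counts.
#' @param extent_um envelope extent `E`, um.
#' @param envelope `"exponential"` (`amplitude * exp(-d/E)`) or `"step"`
#'   (`amplitude` for `d < E`, 0 beyond).
#' @param patchiness fraction of the enrichment mass concentrated at
#'   grain/pore contact pixels (0..1).
#' @param noise logical; apply Poisson count noise.
#' @param grain_radius_um mean sand grain radius, um.
#' @param pore_fraction pore area fraction for the loam style.
#' @param texture_cv coefficient of variation of the loam matrix texture
#'   field (large-scale bulk heterogeneity; default 0.15).
#' @param texture_sigma correlation scale of the texture field, pixels.
#' @param seed integer random seed; identical recipe + seed give identical
#'   maps.
#' @return list of class `rg_recipe`.
#' @export
map_recipe <- function(style = c("loam", "sand"), size_px = 401, pixel_um = 20,
                       root_radius_um = 500, background = 50, amplitude = 30,
                       extent_um = 300, envelope = c("exponential", "step"),
                       patchiness = 0.5, noise = TRUE, grain_radius_um = 100,
                       pore_fraction = 0.04, texture_cv = 0.15,
                       texture_sigma = 2, seed = 1L) {
  style <- match.arg(style)
  envelope <- match.arg(envelope)
  .check_positive(size_px = size_px, pixel_um = pixel_um,
                  root_radius_um = root_radius_um, extent_um = extent_um,
                  grain_radius_um = grain_radius_um)
  .check_positive(background = background, amplitude = amplitude,
                  patchiness = patchiness, pore_fraction = pore_fraction,
                  texture_cv = texture_cv, .allow_zero = TRUE)
  .check_positive(texture_sigma = texture_sigma)
  if (patchiness > 1) stop("'patchiness' must be in [0, 1]", call. = FALSE)
  half_um <- (size_px - 1) / 2 * pixel_um
  if (extent_um >= half_um) {
    stop("envelope extent must be smaller than the half field of view",
         call. = FALSE)
  }
  structure(list(style = style, size_px = as.integer(size_px),
                 pixel_um = pixel_um, root_radius_um = root_radius_um,
                 background = background, amplitude = amplitude,
                 extent_um = extent_um, envelope = envelope,
                 patchiness = patchiness, noise = isTRUE(noise),
                 grain_radius_um = grain_radius_um,
                 pore_fraction = pore_fraction, texture_cv = texture_cv,
                 texture_sigma = texture_sigma, seed = as.integer(seed)),
            class = "rg_recipe")
}

## run code under a local RNG seed without disturbing the caller's stream
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## smooth unit-variance random field (value noise) via separable blur
.smooth_field <- function(nr, nc, sigma_px) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  z <- as.matrix(EBImage::gblur(z, sigma = sigma_px))
  (z - mean(z)) / sd(z)
}

## rasterize grain discs packed in jittered concentric shells around the root
.sand_grains <- function(size_px, root_px, grain_px) {
  grain <- matrix(FALSE, size_px, size_px)
  c0 <- (size_px + 1) / 2
  max_r <- sqrt(2) * (size_px / 2) + grain_px
  Rk <- root_px + 1.05 * grain_px
  k <- 0L
  while (Rk < max_r) {
    k <- k + 1L
    m <- max(4L, floor(2 * pi * Rk / (2.09 * grain_px)))
    ang <- 2 * pi * (seq_len(m) - 1) / m + runif(1, 0, 2 * pi) +
      runif(m, -0.5, 0.5) * (2 * pi / m) * 0.25
    rjit <- rnorm(m, 0, min(0.05 * grain_px * (k - 1), 0.5 * grain_px))
    gx <- c0 + (Rk + rjit) * cos(ang)
    gy <- c0 + (Rk + rjit) * sin(ang)
    gr <- grain_px * runif(m, 0.9, 1.1)
    for (i in seq_len(m)) {
      x_lo <- max(1L, floor(gx[i] - gr[i])); x_hi <- min(size_px, ceiling(gx[i] + gr[i]))
      y_lo <- max(1L, floor(gy[i] - gr[i])); y_hi <- min(size_px, ceiling(gy[i] + gr[i]))
      if (x_hi < x_lo || y_hi < y_lo) next
      xs <- x_lo:x_hi
      ys <- y_lo:y_hi
      dd <- outer((ys - gy[i])^2, (xs - gx[i])^2, "+")
      grain[ys, xs] <- grain[ys, xs] | (dd <= gr[i]^2)
    }
    Rk <- Rk + 2.04 * grain_px
  }
  grain
}

#' Generate a synthetic element map with known ground truth
#'
#' @param recipe a recipe from [map_recipe()].
#' @return list of class `rg_synthmap` with elements `map` (counts),
#'   `root`/`pore` (binary masks), `distance` (um, from [distance_map()]),
#'   `background_field` and `enrichment` (the noiseless components on the
#'   same grid), `truth` (the injected envelope parameters) and the `recipe`.
#' @examples
#' sm <- generate_map(map_recipe("loam", size_px = 121, seed = 7))
#' range(sm$map)
#' @export
generate_map <- function(recipe) {
  stopifnot(inherits(recipe, "rg_recipe"))
  .with_seed(recipe$seed, {
    n <- recipe$size_px
    c0 <- (n + 1) / 2
    px <- recipe$pixel_um
    dd_px <- sqrt(outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, "+"))
    root <- dd_px * px <= recipe$root_radius_um

    if (recipe$style == "sand") {
      grain <- .sand_grains(n, recipe$root_radius_um / px,
                            recipe$grain_radius_um / px)
      grain <- grain & !root
      pore <- !grain & !root
    } else {
      f <- .smooth_field(n, n, sigma_px = 1.5)
      pore <- (f > quantile(f, 1 - recipe$pore_fraction)) & !root
    }

    d <- distance_map(root, pixel_size = px)
    support <- !root & !pore

    env <- matrix(0, n, n)
    env[support] <- if (recipe$envelope == "exponential") {
      recipe$amplitude * exp(-d[support] / recipe$extent_um)
    } else {
      recipe$amplitude * (d[support] < recipe$extent_um)
    }

    ## concentrate a fraction of the enrichment mass at pore-contact pixels,
    ## preserving the per-distance-bin mass exactly
    if (recipe$patchiness > 0 && any(pore)) {
      contact <- .neighbors_any(pore) & support
      if (any(contact & env > 0)) {
        bin <- floor(d / px)
        enr <- env * (1 - recipe$patchiness)
        sup_i <- which(support & env > 0)
        con_i <- which(contact & env > 0)
        moved <- rowsum((recipe$patchiness * env[sup_i]), bin[sup_i])
        con_w <- rowsum(env[con_i], bin[con_i])
        bins_ok <- intersect(rownames(moved), rownames(con_w))
        ## bins without contact pixels keep their full envelope on the matrix
        lost <- setdiff(rownames(moved), bins_ok)
        if (length(lost)) {
          li <- sup_i[as.character(bin[sup_i]) %in% lost]
          enr[li] <- env[li]
        }
        scale <- moved[bins_ok, 1] / con_w[bins_ok, 1]
        names(scale) <- bins_ok
        sel <- as.character(bin[con_i]) %in% bins_ok
        enr[con_i[sel]] <- enr[con_i[sel]] +
          env[con_i[sel]] * scale[as.character(bin[con_i[sel]])]
        env <- enr
      }
    }

    bg <- matrix(0, n, n)
    if (recipe$style == "loam") {
      tex <- pmax(1 + recipe$texture_cv * .smooth_field(n, n, recipe$texture_sigma), 0.2)
      bg[support] <- recipe$background * tex[support] / mean(tex[support])
    } else {
      bg[support] <- recipe$background
    }
    bg[pore] <- 0.08 * recipe$background
    bg[root] <- 0.4 * recipe$background

    signal <- bg + env
    map <- if (recipe$noise) {
      matrix(rpois(n * n, lambda = signal), n, n)
    } else signal

    structure(list(map = map, root = root, pore = pore, distance = d,
                   background_field = bg, enrichment = env,
                   truth = list(extent_um = recipe$extent_um,
                                amplitude = recipe$amplitude,
                                background = recipe$background,
                                envelope = recipe$envelope,
                                style = recipe$style, seed = recipe$seed),
                   recipe = recipe), class = "rg_synthmap")
  })
}

## TRUE where any 8-neighbor of a TRUE pixel lies (excluding border wrap)
.neighbors_any <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (s in shifts) {
    ri <- seq_len(nr) - s[1]
    ci <- seq_len(nc) - s[2]
    ok_r <- ri >= 1 & ri <= nr
    ok_c <- ci >= 1 & ci <= nc
    out[ok_r, ok_c] <- out[ok_r, ok_c] | m[ri[ok_r], ci[ok_c]]
  }
  out & !m
}

#' Deterministic radial-profile fixture
#'
#' Builds an `rg_profile` object directly from bin weights and values, for
#' unit testing the bulk statistics and the extent rule without generating a
#' map. With `values = NULL` and a seed, reproducible lognormal values are
#' drawn.
#'
#' @param n_bins number of bins.
#' @param weights per-bin evaluable pixel counts (recycled).
#' @param values per-bin mean counts (length `n_bins`), or `NULL` to draw.
#' @param sd per-bin standard deviations (default 0).
#' @param bin_width bin width, um (default 20).
#' @param seed seed used when `values` is `NULL`.
#' @return an `rg_profile` data frame (see [radial_profile()]).
#' @export
generate_profile_fixture <- function(n_bins, weights = 1, values = NULL,
                                     sd = 0, bin_width = 20, seed = 1L) {
  .check_positive(n_bins = n_bins, bin_width = bin_width)
  weights <- rep_len(weights, n_bins)
  if (is.null(values)) {
    values <- .with_seed(seed, exp(rnorm(n_bins, log(50), 0.05)))
  }
  if (length(values) != n_bins) {
    stop("'values' must have length 'n_bins'", call. = FALSE)
  }
  out <- data.frame(lo = (0:(n_bins - 1)) * bin_width,
                    hi = (1:n_bins) * bin_width,
                    mid = ((0:(n_bins - 1)) + 0.5) * bin_width,
                    n = weights, mean = values, sd = rep_len(sd, n_bins))
  attr(out, "bin_width") <- bin_width
  class(out) <- c("rg_profile", "data.frame")
  out
}
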