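#' Geometrically graded radial finite-volume grid
#'
#' Cell faces run from the root surface `a` to the outer domain radius,
#' with cell widths growing geometrically so that the steep gradients at the
#' root surface are resolved by micron-scale cells while the far field stays
#' cheap.
#'
#' @param a root radius, cm (inner face).
#' @param r_out outer domain radius, cm (default 6, far enough that the
#'   rhizosphere never reaches the boundary over a 21-day simulation).
#' @param n number of cells (default 300).
#' @param first_width width of the innermost cell, cm (default 2.5e-4, i.e.
#'   2.5 um; must not exceed 5e-4).
#' @return an object of class `rg_grid`: list with `faces` (length n+1),
#'   cell centers `r`, widths `w`, per-radian cell volumes `V2`
#'   (`(f_i^2 - f_{i-1}^2)/2`), center spacings `dc` and the growth ratio `g`.
#' @export
radial_grid <- function(a, r_out = 6, n = 300, first_width = 2.5e-4) {
  .check_positive(a = a, r_out = r_out, n = n, first_width = first_width)
  if (r_out <= a) stop("'r_out' must exceed the root radius", call. = FALSE)
  if (first_width > 5e-4) stop("'first_width' must be <= 5e-4 cm (5 um)", call. = FALSE)
  span <- r_out - a
  if (n * first_width >= span) stop("grid over-resolved: n * first_width >= domain", call. = FALSE)
  g <- uniroot(function(g) first_width * (g^n - 1) / (g - 1) - span,
               c(1 + 1e-9, 2), tol = 1e-14)$root
  w <- first_width * g^(0:(n - 1))
  faces <- a + c(0, cumsum(w))
  faces[n + 1] <- r_out  # absorb rounding
  r <- (faces[-1] + faces[-(n + 1)]) / 2
  structure(list(faces = faces, r = r, w = diff(faces),
                 V2 = (faces[-1]^2 - faces[-(n + 1)]^2) / 2,
                 dc = diff(r), n = n, a = a, r_out = r_out, g = g),
            class = "rg_grid")
}

#' @export
print.rg_grid <- function(x, ...) {
  cat(sprintf("radial grid: %d cells, r = %.4g..%.4g cm, first cell %.3g um, growth %.4f\n",
              x$n, x$a, x$r_out, x$w[1] * 1e4, x$g))
  invisible(x)
}
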