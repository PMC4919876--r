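# Cell geometry: randomized polygons, phenotype-driven size sampling,
# stromal rescaling, and spline closure + rasterization.

#' Randomized polygon on the unit circle
#'
#' `k` vertices at equidistant angles, each displaced by `U(-alpha, alpha)`
#' per coordinate and by an angular jitter `U(-beta, beta)`:
#' `x_i = U(-alpha, alpha) + cos(theta_i + U(-beta, beta))` (same for `y`
#' with `sin`). `alpha` grows with grade as `alpha = 0.1 (S + 1)` so nuclei
#' get more irregular in higher-grade tissue; `beta` defaults to 0.05.
#'
#' @param k number of vertices (>= 3).
#' @param alpha radial randomness.
#' @param beta angular randomness (radians).
#' @return list of class `polygon_shape` with `x`, `y` vertex vectors.
#' @export
random_polygon <- function(k = 10L, alpha = 0.1, beta = 0.05) {
  if (k < 3L) fail_field("k", "must be >= 3")
  if (alpha < 0 || beta < 0) fail_field("alpha/beta", "must be >= 0")
  theta <- 2 * pi * (seq_len(k) - 1L) / k
  x <- stats::runif(k, -alpha, alpha) + cos(theta + stats::runif(k, -beta, beta))
  y <- stats::runif(k, -alpha, alpha) + sin(theta + stats::runif(k, -beta, beta))
  structure(list(x = x, y = y, k = k), class = "polygon_shape")
}

#' Grade-dependent vertex randomness
#' @param grade differentiation grade 0-3.
#' @return `alpha = 0.1 (S + 1)`.
#' @export
shape_alpha <- function(grade) 0.1 * (grade + 1)

#' Fixed epithelial cytoplasm template
#'
#' Deterministic `k = 10` columnar template used to seed epithelial
#' cytoplasm before per-cell scaling: a decagon with the minor axis
#' compressed so the major:minor extent ratio is exactly 2 (tall columnar
#' cells). The same template is returned on every call.
#'
#' @return a `polygon_shape`.
#' @export
epithelial_template <- function() {
  theta <- 2 * pi * (0:9) / 10
  x <- cos(theta)
  y <- 0.5 * sin(theta) / max(sin(theta))   # exact 2:1 vertex extents
  structure(list(x = x, y = y, k = 10L), class = "polygon_shape")
}

#' Sample nuclear axes for a phenotype
#'
#' Semi-axes are normal, `mu_l^n ~ N(mu_l, sigma_l)` and
#' `mu_w^n ~ N(mu_w, sigma_w)` (already converted to pixels by the caller),
#' truncated below at `0.3 * mean` by redrawing so axes stay positive, and
#' swapped if necessary so the minor axis never exceeds the major.
#'
#' @param mu_l,sigma_l,mu_w,sigma_w normal parameters in pixels.
#' @return named vector `c(l = major, w = minor)`.
#' @export
sample_nucleus_axes <- function(mu_l, sigma_l, mu_w, sigma_w) {
  draw_trunc <- function(mu, sigma) {
    if (sigma <= 0) return(mu)
    for (i in seq_len(100L)) {
      v <- stats::rnorm(1, mu, sigma)
      if (v >= 0.3 * mu) return(v)
    }
    0.3 * mu
  }
  l <- draw_trunc(mu_l, sigma_l)
  w <- draw_trunc(mu_w, sigma_w)
  if (w > l) { tmp <- l; l <- w; w <- tmp }
  c(l = l, w = w)
}

#' Cytoplasm axes from nuclear axes
#'
#' Each cytoplasm semi-axis is the corresponding nuclear semi-axis times a
#' `U(1.5, 2.2)` factor; factors are drawn independently per axis by
#' default (set `independent = FALSE` for one shared factor).
#'
#' @param nucleus_axes vector `c(l, w)` in pixels, both positive.
#' @param independent independent factors per axis?
#' @return named vector `c(l, w)`.
#' @export
cytoplasm_axes <- function(nucleus_axes, independent = TRUE) {
  if (any(nucleus_axes <= 0)) fail_field("nucleus_axes", "must be positive")
  f <- if (independent) stats::runif(2, 1.5, 2.2) else rep(stats::runif(1, 1.5, 2.2), 2)
  c(l = nucleus_axes[["l"]] * f[1L], w = nucleus_axes[["w"]] * f[2L])
}

#' Stromal subtype rescaling
#'
#' Fibroblasts get a thinner nucleus (minor x0.8; major unchanged) and a
#' long thin cytoplasm (major x1.8, minor x0.5); lymphocytes shrink
#' uniformly (nucleus x0.8, cytoplasm x0.7) so they end up smaller than
#' epithelial cells. Other subtypes are returned unchanged.
#'
#' @param subtype one of `"epithelial"`, `"fibroblast"`, `"lymphocyte"`,
#'   `"tumour"`.
#' @param nucleus_axes,cytoplasm_axes vectors `c(l, w)`.
#' @return list with rescaled `nucleus_axes` and `cytoplasm_axes`.
#' @export
rescale_stromal <- function(subtype, nucleus_axes, cytoplasm_axes) {
  if (subtype == "fibroblast") {
    nucleus_axes[["w"]] <- 0.8 * nucleus_axes[["w"]]
    cytoplasm_axes[["l"]] <- 1.8 * cytoplasm_axes[["l"]]
    cytoplasm_axes[["w"]] <- 0.5 * cytoplasm_axes[["w"]]
  } else if (subtype == "lymphocyte") {
    nucleus_axes <- 0.8 * nucleus_axes
    cytoplasm_axes <- 0.7 * cytoplasm_axes
  }
  list(nucleus_axes = nucleus_axes, cytoplasm_axes = cytoplasm_axes)
}

#' Scale, place, close and rasterize a polygon shape
#'
#' Vertices are scaled anisotropically (`x_i * mu_l`, `y_i * mu_w`), rotated
#' by `orientation`, translated to `position`, closed with a periodic cubic
#' spline sampled at `>= 8 k` points, and rasterized with pixel-centre
#' membership, clipped to the image.
#'
#' @param shape a `polygon_shape`.
#' @param mu_l,mu_w semi-axis scales in pixels.
#' @param orientation rotation in radians.
#' @param position centre `c(x, y)` in pixels.
#' @param i_h,i_w image dimensions.
#' @param dense_factor spline sampling density per vertex.
#' @return list with `mask` (linear pixel indices; may be empty for a
#'   degenerate shape) and `curve` (the closed dense curve).
#' @export
scale_and_close <- function(shape, mu_l, mu_w, orientation, position,
                            i_h, i_w, dense_factor = 8L) {
  xs <- shape$x * mu_l
  ys <- shape$y * mu_w
  cs <- cos(orientation); sn <- sin(orientation)
  xr <- xs * cs - ys * sn + position[1L]
  yr <- xs * sn + ys * cs + position[2L]
  curve <- close_curve(xr, yr, n_out = max(32L, dense_factor * shape$k))
  mask <- rasterize_polygon(curve, i_h, i_w)
  list(mask = mask, curve = curve)
}

#' Boundary roughness of a mask (isoperimetric quotient inverse)
#'
#' `perimeter^2 / (4 pi area)`; 1 for a perfect disc, larger for rougher
#' shapes. Perimeter is estimated from the boundary pixel count.
#'
#' @param mask linear pixel indices.
#' @param i_h,i_w image dimensions.
#' @return roughness scalar (>= roughly 1).
#' @export
mask_roughness <- function(mask, i_h, i_w) {
  if (length(mask) < 4L) return(NA_real_)
  img <- matrix(FALSE, i_h, i_w); img[mask] <- TRUE
  xy <- index_to_xy(mask, i_h)
  nb <- function(dx, dy) {
    x <- xy[, 1L] + dx; y <- xy[, 2L] + dy
    out <- x < 1L | x > i_w | y < 1L | y > i_h
    inside <- !out
    res <- rep(FALSE, nrow(xy))
    res[inside] <- img[(x[inside] - 1L) * i_h + y[inside]]
    !res   # neighbour missing from the mask (or outside the image)
  }
  boundary <- nb(1L, 0L) | nb(-1L, 0L) | nb(0L, 1L) | nb(0L, -1L)
  p <- sum(boundary)
  p^2 / (4 * pi * length(mask))
}
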