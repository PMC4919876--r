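# Crypt architecture: how many glands, their sizes, deformed-ellipse
# outlines, and grade-dependent placement with overlap rules.

#' Fraction of the sample covered by crypts
#'
#' Healthy and well differentiated tissue is fully glandular (`f_c = 1`);
#' moderately differentiated samples draw `f_c ~ U(0.5, 0.95)` and poorly
#' differentiated `f_c ~ U(0, 0.5)`, matching the TNM grading bands for the
#' glandular fraction of the tumour.
#'
#' @param grade differentiation grade 0-3.
#' @return a single coverage fraction.
#' @export
crypt_coverage_fraction <- function(grade) {
  if (!length(grade) == 1L || !grade %in% 0:3)
    fail_field("grade", "must be one of 0, 1, 2, 3")
  if (grade <= 1L) return(1)
  if (grade == 2L) stats::runif(1, 0.5, 0.95) else stats::runif(1, 0, 0.5)
}

#' Number of crypts for an image
#'
#' `N_c = round(f_c * floor(i_h / (2 mu_b)) * floor(i_w / (2 mu_b)))` where
#' `mu_b` is the mean crypt semi-minor axis in pixels: the image is tiled by
#' nominal crypt-sized blocks and a fraction `f_c` of them is filled.
#'
#' @param config a `sim_config`.
#' @param mu_b_px mean semi-minor axis in pixels.
#' @param f_c coverage fraction from [crypt_coverage_fraction()].
#' @return non-negative integer crypt count.
#' @export
crypt_count <- function(config, mu_b_px, f_c) {
  if (mu_b_px <= 0) fail_field("mu_b", "must be > 0")
  n <- round(f_c * floor(config$image_height / (2 * mu_b_px)) *
               floor(config$image_width / (2 * mu_b_px)))
  max(0L, as.integer(n))
}

#' Sample the semi-axes of one crypt
#'
#' The semi-minor axis `b` is Gamma distributed (shape `alpha_b`, scale
#' `beta_b`, micrometres, converted to pixels); the axis ratio `e = b/a` is
#' Gamma distributed (shape `alpha_e`, scale `beta_e`) and redrawn until it
#' falls in `(0.2, 1]` so the major axis satisfies `a = b/e >= b`.
#'
#' @param gp_row one-row grade-parameter record ([grade_params_for()]).
#' @param config a `sim_config` (for the unit conversion).
#' @return list with `a`, `b` (pixels) and `e`.
#' @export
sample_crypt_axes <- function(gp_row, config) {
  b_um <- stats::rgamma(1, shape = gp_row$alpha_b, scale = gp_row$beta_b)
  b <- microns_to_pixels(b_um, config)
  e <- NA_real_
  for (i in seq_len(1000L)) {
    e <- stats::rgamma(1, shape = gp_row$alpha_e, scale = gp_row$beta_e)
    if (e > 0.2 && e <= 1) break
    e <- NA_real_
  }
  if (is.na(e))
    stop("degenerate axis-ratio parameters: no draw in (0.2, 1] after 1000 tries",
         call. = FALSE)
  list(a = b / e, b = b, e = e)
}

#' Deformed-ellipse crypt outline
#'
#' The polar radius of an ellipse with semi-axes `a >= b` rotated by `phi`,
#' `R(theta) = a b sqrt(2) / sqrt((b^2 - a^2) cos(2 theta - 2 phi) + a^2 +
#' b^2)`, is perturbed per vertex by `u = (S^2 + 1) U(-0.06, 0.1) b` and the
#' perturbed radii are closed by a periodic cubic spline. Because the curve
#' is a single-valued radius function of the angle it is star-shaped, hence
#' always simple. Offsets are size-relative (scaled by `b`) so deformation
#' is comparable across crypt sizes, and grow quadratically with grade.
#'
#' @param a,b semi-axes in pixels.
#' @param phi rotation of the major axis in radians.
#' @param grade differentiation grade 0-3.
#' @param n_vertices number of perturbed vertices (evenly spaced angles).
#' @param n_dense number of points on the dense closed outline.
#' @return list with `theta` (vertex angles), `u` (radial offsets, pixels),
#'   `radius` (perturbed vertex radii), and `outline`, a closed two-column
#'   (x, y) polygon centred on the origin.
#' @export
crypt_outline <- function(a, b, phi, grade, n_vertices = 72L,
                          n_dense = 8L * n_vertices) {
  if (a <= 0 || b <= 0) fail_field("a/b", "semi-axes must be > 0")
  theta <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  base <- a * b * sqrt(2) /
    sqrt((b^2 - a^2) * cos(2 * theta - 2 * phi) + a^2 + b^2)
  u <- (grade^2 + 1) * stats::runif(n_vertices, -0.06, 0.1) * b
  radius <- pmax(base + u, 0.05 * b)
  # periodic spline on the radius as a function of angle keeps the curve
  # star-shaped (simple by construction)
  t_out <- seq(0, n_vertices, length.out = n_dense + 1L)
  r_dense <- stats::spline(0:n_vertices, c(radius, radius[1L]),
                           method = "periodic", xout = t_out)$y
  th_dense <- 2 * pi * t_out / n_vertices
  outline <- cbind(x = r_dense * cos(th_dense), y = r_dense * sin(th_dense))
  list(theta = theta, u = u, radius = radius, outline = outline)
}

# interpolate the outline radius at arbitrary angles (used by goblet seeds)
outline_radius_at <- function(crypt, angles) {
  n_vertices <- length(crypt$theta)
  t_q <- (angles %% (2 * pi)) / (2 * pi) * n_vertices
  stats::spline(0:n_vertices, c(crypt$radius, crypt$radius[1L]),
                method = "periodic", xout = t_q)$y
}

#' Place crypts in the image
#'
#' Samples size, rotation and outline for each of `n_crypts` crypts and
#' chooses centres from a randomly offset grid with spacing `0.6 b` of the
#' candidate crypt. Healthy and well differentiated tissue (`S <= 1`) admits
#' no outline intersections; for `S >= 2` a crypt may intersect at most one
#' other, the pairwise overlap area may not exceed half the smaller crypt,
#' and intersecting pairs share a `gland_group` ("gland within gland"). If a
#' crypt cannot be placed within the retry budget it is dropped and the
#' shortfall logged.
#'
#' @param config a `sim_config`.
#' @param grade_params grade-parameter table.
#' @param f_c coverage fraction; drawn via [crypt_coverage_fraction()] when
#'   `NULL`.
#' @param max_candidates candidate grid points tried per crypt.
#' @return list with `crypts` (list of crypt records), `f_c`, `n_requested`,
#'   `n_placed`, and `label` (integer crypt label matrix).
#' @export
place_crypts <- function(config, grade_params = default_grade_params(),
                         f_c = NULL, max_candidates = 400L) {
  i_h <- config$image_height; i_w <- config$image_width
  S <- config$grade
  gp <- grade_params_for(grade_params, S)
  if (is.null(f_c)) f_c <- crypt_coverage_fraction(S)
  mu_b_px <- microns_to_pixels(gp$mu_b, config)
  n_req <- crypt_count(config, mu_b_px, f_c)
  label <- matrix(0L, i_h, i_w)
  crypts <- list()
  next_group <- 1L
  for (ci in seq_len(n_req)) {
   for (attempt in 1:4) {   # re-draw size/offset when a crypt cannot fit
    ax <- sample_crypt_axes(gp, config)
    phi <- stats::runif(1, 0, 2 * pi)
    out <- crypt_outline(ax$a, ax$b, phi, S, config$n_vertices_crypt)
    rel <- out$outline
    rel_bb <- c(min(rel[, 1L]), max(rel[, 1L]), min(rel[, 2L]), max(rel[, 2L]))
    spacing <- max(2, 0.6 * ax$b)
    gx <- seq(stats::runif(1, 0, spacing), i_w, by = spacing)
    gy <- seq(stats::runif(1, 0, spacing), i_h, by = spacing)
    cand <- expand.grid(x = gx, y = gy)
    if (nrow(cand) == 0L) next
    # scan the grid from a random start: crypts pack closely, like the
    # quasi-regular tiling of real mucosa
    start <- sample.int(nrow(cand), 1L)
    ord <- (seq_len(nrow(cand)) + start - 2L) %% nrow(cand) + 1L
    cand <- cand[ord, , drop = FALSE]
    n_try <- min(nrow(cand), max_candidates)
    placed <- FALSE
    for (t in seq_len(n_try)) {
      cx <- cand$x[t]; cy <- cand$y[t]
      # fields may cut glands at the border, but a crypt must be mostly in
      # view: reject centres leaving > 40% of the outline outside the image
      out_frac <- mean(rel[, 1L] + cx < 1 | rel[, 1L] + cx > i_w |
                         rel[, 2L] + cy < 1 | rel[, 2L] + cy > i_h)
      if (out_frac > 0.4) next
      bb <- c(cx + rel_bb[1L], cx + rel_bb[2L], cy + rel_bb[3L], cy + rel_bb[4L])
      # exact outline-intersection predicate against bbox-near crypts
      hits <- integer(0)
      for (j in seq_along(crypts)) {
        bj <- crypts[[j]]$bbox
        if (bb[2L] < bj[1L] || bb[1L] > bj[2L] ||
            bb[4L] < bj[3L] || bb[3L] > bj[4L]) next
        if (polygons_intersect(cbind(rel[, 1L] + cx, rel[, 2L] + cy),
                               crypts[[j]]$outline))
          hits <- c(hits, j)
        if (length(hits) > 1L) break
      }
      ok <- if (S <= 1L) length(hits) == 0L else
        length(hits) == 0L ||
          (length(hits) == 1L && is.na(crypts[[hits]]$partner))
      if (!ok) next
      poly <- cbind(rel[, 1L] + cx, rel[, 2L] + cy)
      mask <- rasterize_polygon(poly, i_h, i_w)
      if (length(mask) == 0L) next
      if (length(hits) == 1L) {
        # "overlap to a certain extent": at most half the smaller crypt
        ov <- overlap_count(mask, crypts[[hits]]$mask)
        if (ov > 0.5 * min(length(mask), length(crypts[[hits]]$mask))) next
      }
      group <- if (length(hits) == 1L) crypts[[hits]]$gland_group else {
        g <- next_group; next_group <- next_group + 1L; g
      }
      id <- length(crypts) + 1L
      if (length(hits) == 1L) crypts[[hits]]$partner <- id
      crypts[[id]] <- list(
        id = id, centre = c(cx, cy), a = ax$a, b = ax$b, e = ax$e, phi = phi,
        theta = out$theta, u = out$u, radius = out$radius,
        outline = poly, mask = mask,
        area = length(mask),
        perimeter = curve_perimeter_clipped(poly, i_h, i_w),
        perimeter_nominal = ellipse_perimeter(ax$a, ax$b),
        bbox = bb,
        gland_group = group,
        partner = if (length(hits) == 1L) hits else NA_integer_,
        lumen_class = NA_character_)
      label[mask] <- id
      placed <- TRUE
      break
    }
    if (placed) break
   }
  }
  # lumen texture class per crypt: single normal class when healthy, a
  # uniformly drawn cancer class per crypt otherwise
  for (j in seq_along(crypts)) {
    crypts[[j]]$lumen_class <- if (S == 0L) "lumen_healthy" else
      sprintf("lumen_cancer_%d", sample.int(config$n_cancer_lumen, 1L))
  }
  list(crypts = crypts, f_c = f_c, n_requested = n_req,
       n_placed = length(crypts), label = label)
}

#' Per-crypt ground-truth table
#'
#' @param crypts crypt list from [place_crypts()].
#' @return data frame with one row per crypt.
#' @export
crypt_table <- function(crypts) {
  if (length(crypts) == 0L)
    return(data.frame(crypt_id = integer(0), gland_group = integer(0),
                      x_c = numeric(0), y_c = numeric(0), a_px = numeric(0),
                      b_px = numeric(0), e = numeric(0), phi_rad = numeric(0),
                      area_px = numeric(0), perimeter_px = numeric(0),
                      lumen_class = character(0)))
  data.frame(
    crypt_id = vapply(crypts, `[[`, 1L, "id"),
    gland_group = vapply(crypts, `[[`, 1L, "gland_group"),
    x_c = vapply(crypts, function(c) c$centre[1L], 1),
    y_c = vapply(crypts, function(c) c$centre[2L], 1),
    a_px = vapply(crypts, `[[`, 1, "a"),
    b_px = vapply(crypts, `[[`, 1, "b"),
    e = vapply(crypts, `[[`, 1, "e"),
    phi_rad = vapply(crypts, `[[`, 1, "phi"),
    area_px = vapply(crypts, `[[`, 1, "area"),
    perimeter_px = vapply(crypts, `[[`, 1, "perimeter"),
    lumen_class = vapply(crypts, `[[`, "", "lumen_class"),
    stringsAsFactors = FALSE)
}
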