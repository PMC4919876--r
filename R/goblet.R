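# Goblet-cell honeycomb inside healthy crypts: deterministic seed rings +
# rasterized Voronoi tessellation with dilated, rounded walls.

#' Goblet-cell Voronoi seeds for a healthy crypt
#'
#' An outer ring of `gamma = round(a/r)` seeds at even angular increments,
#' each one cell radius inside the crypt boundary, models the goblet ring of
#' a round crypt. For elongated crypts (`kappa = round(1/e) > 1`) the slice
#' cuts the crypt obliquely and `2 kappa (kappa - 1)` additional seeds
#' appear near the ends of the major axis: along the `2 kappa` ring angles
#' closest to the major axis, extra rows are placed at depths
#' `d_i = (2 i - 2) r` from the boundary for `i = 2..kappa` (one cell
#' diameter per row). One seed sits at the crypt centre and every seed is
#' jittered by `U(-0.2 r, 0.2 r)` per coordinate.
#'
#' @param crypt a crypt record from [place_crypts()].
#' @param r_px cell radius in pixels.
#' @return list with `seeds` (two-column matrix, absolute pixels), `kappa`,
#'   `gamma`, or `NULL` when the crypt is too small to host a ring of 3
#'   (structure omitted, crypt rendered lumen-only).
#' @export
goblet_seeds <- function(crypt, r_px) {
  gamma <- round(crypt$a / r_px)
  if (gamma < 3) return(NULL)
  kappa <- max(1L, as.integer(round(1 / crypt$e)))
  ang <- 2 * pi * (seq_len(gamma) - 1L) / gamma
  R_out <- outline_radius_at(crypt, ang)
  if (any(R_out - r_px <= 0)) return(NULL)
  seeds <- cbind((R_out - r_px) * cos(ang), (R_out - r_px) * sin(ang))
  if (kappa > 1L) {
    # the 2*kappa ring angles closest to the major axis (phi and phi + pi)
    d_major <- pmin(abs(((ang - crypt$phi) + pi) %% (2 * pi) - pi),
                    abs(((ang - crypt$phi - pi) + pi) %% (2 * pi) - pi))
    sel <- order(d_major)[seq_len(min(2L * kappa, gamma))]
    for (i in 2:kappa) {
      depth <- (2 * i - 2) * r_px
      keep <- R_out[sel] - depth > 0
      if (!any(keep)) next
      a_sel <- ang[sel][keep]
      seeds <- rbind(seeds, cbind((R_out[sel][keep] - depth) * cos(a_sel),
                                  (R_out[sel][keep] - depth) * sin(a_sel)))
    }
  }
  seeds <- rbind(seeds, c(0, 0))
  seeds <- seeds + matrix(stats::runif(length(seeds), -0.2 * r_px, 0.2 * r_px),
                          ncol = 2L)
  seeds <- sweep(seeds, 2L, crypt$centre, `+`)
  list(seeds = seeds, kappa = kappa, gamma = gamma)
}

#' Expected goblet seed count
#'
#' `gamma + 2 kappa (kappa - 1) + 1`, before any omission of rows that
#' would fall outside a small crypt.
#'
#' @param gamma ring seed count.
#' @param kappa elongation class `round(1/e)`.
#' @return integer seed count.
#' @export
goblet_seed_count <- function(gamma, kappa) {
  as.integer(gamma + 2L * kappa * (kappa - 1L) + 1L)
}

#' Rasterized Voronoi walls of a goblet structure
#'
#' Labels every crypt-interior pixel with its nearest seed (the rasterized
#' Voronoi tessellation clipped to the crypt), takes the boundary pixels
#' between distinct labels, dilates them to `wall_width` and rounds the
#' vertices with an extra disc dilation.
#'
#' @param seeds two-column seed matrix (absolute pixels).
#' @param crypt_mask linear indices of the crypt interior.
#' @param i_h,i_w image dimensions.
#' @param wall_width wall thickness in pixels.
#' @return list with `walls` (linear indices of wall pixels) and `labels`
#'   (nearest-seed label per crypt pixel, same order as `crypt_mask`).
#' @export
goblet_walls <- function(seeds, crypt_mask, i_h, i_w, wall_width = 2) {
  if (nrow(seeds) < 4L) fail_field("seeds", "need at least 4 seeds")
  xy <- index_to_xy(crypt_mask, i_h)
  # nearest-seed labelling (brute force over seeds; seed counts are small)
  d_best <- rep(Inf, nrow(xy)); lab <- integer(nrow(xy))
  for (s in seq_len(nrow(seeds))) {
    d <- (xy[, 1L] - seeds[s, 1L])^2 + (xy[, 2L] - seeds[s, 2L])^2
    upd <- d < d_best
    d_best[upd] <- d[upd]; lab[upd] <- s
  }
  lab_img <- matrix(0L, i_h, i_w)
  lab_img[crypt_mask] <- lab
  # boundary: pixel whose right or lower neighbour carries a different label
  boundary <- logical(nrow(xy))
  for (off in list(c(1L, 0L), c(0L, 1L), c(-1L, 0L), c(0L, -1L))) {
    x2 <- xy[, 1L] + off[1L]; y2 <- xy[, 2L] + off[2L]
    inside <- x2 >= 1L & x2 <= i_w & y2 >= 1L & y2 <= i_h
    nb <- rep(0L, nrow(xy))
    nb[inside] <- lab_img[(x2[inside] - 1L) * i_h + y2[inside]]
    boundary <- boundary | (inside & nb != 0L & nb != lab)
  }
  walls <- crypt_mask[boundary]
  if (wall_width > 1) {
    walls <- dilate_mask(walls, i_h, i_w, (wall_width - 1) / 2)
    walls <- walls[walls %in% crypt_mask]
  }
  # vertex rounding: pixels adjacent to >= 3 labels get an extra disc
  corners <- find_voronoi_corners(lab_img, crypt_mask, xy, lab, i_h, i_w)
  if (length(corners) > 0L) {
    rounded <- dilate_mask(corners, i_h, i_w, max(1, wall_width / 2) + 0.5)
    walls <- sort(unique(c(walls, rounded[rounded %in% crypt_mask])))
  }
  list(walls = walls, labels = lab)
}

# pixels touching three or more distinct Voronoi labels (tessellation vertices)
find_voronoi_corners <- function(lab_img, crypt_mask, xy, lab, i_h, i_w) {
  n <- nrow(xy)
  l1 <- lab
  l2 <- integer(n); l3 <- integer(n)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 0L),
                   c(0L, -1L), c(-1L, 1L), c(1L, -1L), c(-1L, -1L))) {
    x2 <- xy[, 1L] + off[1L]; y2 <- xy[, 2L] + off[2L]
    inside <- x2 >= 1L & x2 <= i_w & y2 >= 1L & y2 <= i_h
    nb <- rep(0L, n)
    nb[inside] <- lab_img[(x2[inside] - 1L) * i_h + y2[inside]]
    new2 <- nb != 0L & nb != l1 & l2 == 0L
    l2[new2] <- nb[new2]
    new3 <- nb != 0L & nb != l1 & nb != l2 & l2 != 0L & l3 == 0L
    l3[new3] <- nb[new3]
  }
  crypt_mask[l3 != 0L]
}

#' Render a goblet structure for one healthy crypt
#'
#' Builds seeds and walls, modulates a procedural texture onto the walls and
#' blurs them with a Gaussian; the result is composited into the cytoplasm
#' (eosin) channel by the renderer. Degenerate (near-collinear) seed sets
#' are re-jittered once, then omitted with a log entry.
#'
#' @param crypt crypt record.
#' @param r_px cell radius in pixels.
#' @param i_h,i_w image dimensions.
#' @param wall_width wall thickness in pixels.
#' @param wall_intensity peak eosin intensity of the walls.
#' @return list with `seeds`, `kappa`, `gamma`, `walls`, `layer` (sparse
#'   contribution: `idx` + `values`), or `NULL` when omitted.
#' @export
goblet_structure <- function(crypt, r_px, i_h, i_w, wall_width = 2,
                             wall_intensity = 0.75) {
  gs <- goblet_seeds(crypt, r_px)
  if (is.null(gs)) return(NULL)
  gw <- tryCatch(goblet_walls(gs$seeds, crypt$mask, i_h, i_w, wall_width),
                 error = function(e) NULL)
  if (is.null(gw)) {
    gs <- goblet_seeds(crypt, r_px)   # one re-jittered retry
    if (is.null(gs)) return(NULL)
    gw <- tryCatch(goblet_walls(gs$seeds, crypt$mask, i_h, i_w, wall_width),
                   error = function(e) NULL)
    if (is.null(gw)) return(NULL)
  }
  if (length(gw$walls) == 0L)
    return(c(gs, list(walls = integer(0), layer = NULL)))
  # texture the walls, then blur the wall layer before compositing
  bb_xy <- index_to_xy(gw$walls, i_h)
  x0 <- min(bb_xy[, 1L]); y0 <- min(bb_xy[, 2L])
  bw <- max(bb_xy[, 1L]) - x0 + 1L; bh <- max(bb_xy[, 2L]) - y0 + 1L
  tex <- synth_procedural(c(bh, bw), octaves = 3L, base_frequency = 6)
  layer <- matrix(0, bh, bw)
  li <- (bb_xy[, 1L] - x0) * bh + (bb_xy[, 2L] - y0 + 1L)
  layer[li] <- wall_intensity * (0.7 + 0.3 * tex[li])
  layer <- gaussian_convolve(layer, 0.8)
  keep <- which(layer > 1e-4)
  kx <- (keep - 1L) %/% bh + x0; ky <- (keep - 1L) %% bh + y0
  ok <- kx >= 1L & kx <= i_w & ky >= 1L & ky <= i_h
  idx <- (kx[ok] - 1L) * i_h + ky[ok]
  inside <- idx %in% crypt$mask
  c(gs, list(walls = gw$walls,
             layer = list(idx = idx[inside], values = layer[keep][ok][inside])))
}
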