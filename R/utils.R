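# Internal helpers shared across modules.

#' Derive a per-stage or per-image random seed from a master seed
#'
#' One master seed spawns independent streams for the simulation stages
#' (architecture, cells, textures, noise) and for each image of a batch, so
#' that changing how much randomness one stage consumes does not perturb the
#' others. The derivation is a fixed affine hash modulo the Mersenne prime
#' 2^31 - 1; all arithmetic stays below 2^53 so it is exact in doubles.
#'
#' @param seed master seed (integer-valued scalar).
#' @param stream non-negative integer identifying the stream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  m <- 2147483647
  s <- (abs(as.double(seed)) %% m) * 48271 + as.double(stream) * 10007 + 1
  as.integer(s %% m + 1)
}

# Stage identifiers for derive_seed(); offsets are arbitrary but frozen.
.stage_offset <- c(architecture = 11L, cells = 23L, textures = 37L,
                   noise = 53L, misc = 71L)

stage_seed <- function(seed, stage) {
  derive_seed(seed, .stage_offset[[stage]])
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert (x, y) pixel coordinates to linear indices of an i_h x i_w matrix
#'
#' Images are stored as base-R matrices indexed `[y, x]` (row = y from the
#' top, column = x). Out-of-image points are dropped.
#' @noRd
xy_to_index <- function(x, y, i_h, i_w) {
  x <- as.integer(round(x)); y <- as.integer(round(y))
  keep <- x >= 1L & x <= i_w & y >= 1L & y <= i_h
  (x[keep] - 1L) * i_h + y[keep]
}

index_to_xy <- function(idx, i_h) {
  idx <- as.integer(idx - 1L)
  cbind(x = idx %/% i_h + 1L, y = idx %% i_h + 1L)
}

#' Rasterize a simple closed polygon with pixel-centre membership
#'
#' Membership uses the even-odd rule on pixel centres (integer coordinates);
#' points exactly on an edge follow `mgcv::in.out`'s convention, which is the
#' documented tie-break for the package.
#'
#' @param poly two-column matrix of (x, y) vertices, closed or open.
#' @param i_h,i_w image dimensions; the mask is clipped to the image.
#' @return integer vector of linear pixel indices.
#' @noRd
rasterize_polygon <- function(poly, i_h, i_w) {
  if (nrow(poly) < 3L) return(integer(0))
  # close the loop for in.out
  if (any(poly[1L, ] != poly[nrow(poly), ])) poly <- rbind(poly, poly[1L, ])
  x0 <- max(1L, floor(min(poly[, 1L]))); x1 <- min(i_w, ceiling(max(poly[, 1L])))
  y0 <- max(1L, floor(min(poly[, 2L]))); y1 <- min(i_h, ceiling(max(poly[, 2L])))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1; ys <- y0:y1
  grid <- cbind(rep(xs, each = length(ys)), rep(ys, times = length(xs)))
  inside <- mgcv::in.out(poly, grid)
  idx <- (grid[inside, 1L, drop = TRUE] - 1L) * i_h + grid[inside, 2L, drop = TRUE]
  as.integer(idx)
}

#' Periodic cubic-spline closure of an ordered vertex ring
#'
#' @param xv,yv vertex coordinates (not repeated at the end).
#' @param n_out number of points on the closed dense curve.
#' @return two-column matrix; first and last points coincide.
#' @noRd
close_curve <- function(xv, yv, n_out = 8L * length(xv)) {
  k <- length(xv)
  t_in <- 0:k
  t_out <- seq(0, k, length.out = n_out + 1L)
  xs <- stats::spline(t_in, c(xv, xv[1L]), method = "periodic", xout = t_out)$y
  ys <- stats::spline(t_in, c(yv, yv[1L]), method = "periodic", xout = t_out)$y
  cbind(x = xs, y = ys)
}

#' Polyline length of a closed curve
#' @noRd
curve_perimeter <- function(curve) {
  dx <- diff(curve[, 1L]); dy <- diff(curve[, 2L])
  sum(sqrt(dx^2 + dy^2))
}

#' Ellipse perimeter (Ramanujan's second approximation)
#' @noRd
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' In-image polyline length: only segments whose midpoint is in view count
#' (the visible gland boundary, which is where epithelial cells are seeded)
#' @noRd
curve_perimeter_clipped <- function(curve, i_h, i_w) {
  dx <- diff(curve[, 1L]); dy <- diff(curve[, 2L])
  mx <- (curve[-1L, 1L] + curve[-nrow(curve), 1L]) / 2
  my <- (curve[-1L, 2L] + curve[-nrow(curve), 2L]) / 2
  inside <- mx >= 0.5 & mx <= i_w + 0.5 & my >= 0.5 & my <= i_h + 0.5
  sum(sqrt(dx^2 + dy^2)[inside])
}

#' Binary dilation by a disc (or square for radius < 1) structuring element
#' @noRd
dilate_mask <- function(idx, i_h, i_w, radius) {
  if (length(idx) == 0L || radius <= 0) return(as.integer(idx))
  r <- ceiling(radius)
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= radius^2 + 1e-9, , drop = FALSE]
  xy <- index_to_xy(idx, i_h)
  out <- integer(0)
  for (i in seq_len(nrow(off))) {
    out <- c(out, xy_to_index(xy[, 1L] + off$dx[i], xy[, 2L] + off$dy[i], i_h, i_w))
  }
  sort(unique(out))
}

#' Separable Gaussian convolution with replicated edges
#'
#' Kernel truncated at 4 standard deviations and normalised to unit sum, so a
#' constant image is preserved exactly.
#' @noRd
gaussian_convolve <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n_r <- nrow(mat); n_c <- ncol(mat)
  # columns pass (blur along y)
  out <- matrix(0, n_r, n_c)
  for (j in seq_along(k)) {
    o <- j - r - 1L
    rows <- pmin(pmax(seq_len(n_r) + o, 1L), n_r)
    out <- out + k[j] * mat[rows, , drop = FALSE]
  }
  # rows pass (blur along x)
  out2 <- matrix(0, n_r, n_c)
  for (j in seq_along(k)) {
    o <- j - r - 1L
    cols <- pmin(pmax(seq_len(n_c) + o, 1L), n_c)
    out2 <- out2 + k[j] * out[, cols, drop = FALSE]
  }
  out2
}

#' Fast intersection size of two integer index vectors
#' @noRd
overlap_count <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(0L)
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  sum(a %in% b)
}

#' Exact intersection predicate for two simple closed polylines
#'
#' TRUE when the polygons overlap: either one contains a vertex of the
#' other, or their boundaries cross. Segment tests are restricted to the
#' overlap of the two bounding boxes.
#' @noRd
polygons_intersect <- function(a, b) {
  abb <- c(min(a[, 1L]), max(a[, 1L]), min(a[, 2L]), max(a[, 2L]))
  bbb <- c(min(b[, 1L]), max(b[, 1L]), min(b[, 2L]), max(b[, 2L]))
  if (abb[2L] < bbb[1L] || abb[1L] > bbb[2L] ||
      abb[4L] < bbb[3L] || abb[3L] > bbb[4L]) return(FALSE)
  if (mgcv::in.out(b, a[1L, , drop = FALSE])[1L]) return(TRUE)
  if (mgcv::in.out(a, b[1L, , drop = FALSE])[1L]) return(TRUE)
  # boundary crossing: only segments near the bbox overlap can cross
  ov <- c(max(abb[1L], bbb[1L]), min(abb[2L], bbb[2L]),
          max(abb[3L], bbb[3L]), min(abb[4L], bbb[4L])) + c(-1, 1, -1, 1)
  seg_sel <- function(p) {
    x1 <- p[-nrow(p), 1L]; y1 <- p[-nrow(p), 2L]
    x2 <- p[-1L, 1L]; y2 <- p[-1L, 2L]
    keep <- pmax(x1, x2) >= ov[1L] & pmin(x1, x2) <= ov[2L] &
      pmax(y1, y2) >= ov[3L] & pmin(y1, y2) <= ov[4L]
    cbind(x1, y1, x2, y2)[keep, , drop = FALSE]
  }
  sa <- seg_sel(a); sb <- seg_sel(b)
  na <- nrow(sa); nb <- nrow(sb)
  if (na == 0L || nb == 0L) return(FALSE)
  cross <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  A1x <- matrix(sa[, 1L], na, nb); A1y <- matrix(sa[, 2L], na, nb)
  A2x <- matrix(sa[, 3L], na, nb); A2y <- matrix(sa[, 4L], na, nb)
  B1x <- matrix(sb[, 1L], na, nb, byrow = TRUE); B1y <- matrix(sb[, 2L], na, nb, byrow = TRUE)
  B2x <- matrix(sb[, 3L], na, nb, byrow = TRUE); B2y <- matrix(sb[, 4L], na, nb, byrow = TRUE)
  d1 <- cross(A1x, A1y, A2x, A2y, B1x, B1y)
  d2 <- cross(A1x, A1y, A2x, A2y, B2x, B2y)
  d3 <- cross(B1x, B1y, B2x, B2y, A1x, A1y)
  d4 <- cross(B1x, B1y, B2x, B2y, A2x, A2y)
  any(d1 * d2 <= 0 & d3 * d4 <= 0)
}

#' Stop with a field-named validation error
#' @noRd
fail_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}
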