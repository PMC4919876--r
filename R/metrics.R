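# Evaluation metrics: pixel/object Dice, moment-ellipse morphometrics,
# Gamma fitting, GLCM texture features, affinity-propagation phenotyping.

#' Pixel-level Dice index
#'
#' `Dice(g, o) = 2 |g intersect o| / (|g| + |o|)`; defined as 1 when both
#' masks are empty (documented convention).
#'
#' @param g_mask,o_mask binary masks (logical/0-1 matrices of equal shape)
#'   or integer vectors of pixel indices.
#' @return a value in `[0, 1]`.
#' @export
dice_pixel <- function(g_mask, o_mask) {
  if (is.matrix(g_mask) || is.matrix(o_mask)) {
    if (!all(dim(g_mask) == dim(o_mask)))
      stop("mask shapes differ", call. = FALSE)
    g_mask <- which(g_mask != 0)
    o_mask <- which(o_mask != 0)
  }
  ng <- length(g_mask); no <- length(o_mask)
  if (ng + no == 0L) return(1)
  2 * overlap_count(g_mask, o_mask) / (ng + no)
}

#' Object-level Dice index
#'
#' For labelled images `g` (ground truth) and `o` (prediction):
#' `Dice_obj = 1/2 [ sum_i w_i Dice(g_i, o_i) + sum_i w^_i Dice(g^_i, o^_i) ]`
#' where `o_i` is the i-th predicted object, `g_i` the union of ground-truth
#' pixels intersecting it (and symmetrically `g^_i`, `o^_i`), and the
#' weights are the object sizes normalised within each direction. Objects
#' intersecting nothing contribute a Dice of 0 at their weight. An empty
#' prediction against a non-empty truth returns the truth-side half only.
#'
#' @param g,o non-negative integer label matrices of equal shape
#'   (0 = background).
#' @return a value in `[0, 1]`.
#' @export
dice_object <- function(g, o) {
  if (!all(dim(g) == dim(o))) stop("label shapes differ", call. = FALSE)
  half <- function(pred, truth) {
    ids <- sort(setdiff(unique(as.integer(pred)), 0L))
    if (length(ids) == 0L) return(0)
    sizes <- numeric(length(ids)); d <- numeric(length(ids))
    for (k in seq_along(ids)) {
      oi <- which(pred == ids[k])
      sizes[k] <- length(oi)
      hit_labels <- setdiff(unique(as.integer(truth[oi])), 0L)
      gi <- if (length(hit_labels) == 0L) integer(0) else
        which(matrix(truth %in% hit_labels, nrow(truth)))
      d[k] <- if (length(gi) == 0L) 0 else dice_pixel(gi, oi)
    }
    sum(sizes / sum(sizes) * d)
  }
  (half(o, g) + half(g, o)) / 2
}

#' Moment-equivalent ellipse morphometrics of a mask
#'
#' Axes of the ellipse with the same second central moments as the pixel
#' set (lengths `4 sqrt(lambda)` for the two eigenvalues, the regionprops
#' convention, with the 1/12 pixel-variance correction); the ratio
#' `e = minor/major` lies in `(0, 1]` and is rotation invariant.
#'
#' @param mask logical/0-1 matrix or vector of pixel indices.
#' @param i_h image height (needed when `mask` is an index vector).
#' @return named vector `c(major, minor, e)` (axis lengths in pixels).
#' @export
ellipse_morphometrics <- function(mask, i_h = NULL) {
  if (is.matrix(mask)) {
    i_h <- nrow(mask)
    mask <- which(mask != 0)
  }
  if (length(mask) == 0L) stop("empty mask", call. = FALSE)
  xy <- index_to_xy(mask, i_h)
  cx <- xy[, 1L] - mean(xy[, 1L]); cy <- xy[, 2L] - mean(xy[, 2L])
  # central moments with the unit-square pixel correction
  mxx <- mean(cx^2) + 1 / 12; myy <- mean(cy^2) + 1 / 12; mxy <- mean(cx * cy)
  tr <- mxx + myy; det <- mxx * myy - mxy^2
  disc <- sqrt(max(0, tr^2 / 4 - det))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 1e-12)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  c(major = major, minor = minor, e = minor / major)
}

#' Maximum-likelihood Gamma fit
#'
#' Shape-scale parameterization (mean = shape * scale), fitted by ML via
#' `fitdistrplus`; reports the log-likelihood. Degenerate (constant)
#' samples make the shape diverge and are reported as an error.
#'
#' @param samples positive numeric vector, length >= 30.
#' @return list with `shape`, `scale`, `loglik`.
#' @export
fit_gamma <- function(samples) {
  if (length(samples) < 30L) stop("need at least 30 samples", call. = FALSE)
  if (any(samples <= 0)) stop("samples must be positive", call. = FALSE)
  if (stats::sd(samples) < 1e-12 * mean(samples))
    stop("degenerate (constant) samples: Gamma shape diverges", call. = FALSE)
  fit <- fitdistrplus::fitdist(as.numeric(samples), "gamma", method = "mle")
  list(shape = unname(fit$estimate[["shape"]]),
       scale = 1 / unname(fit$estimate[["rate"]]),
       loglik = fit$loglik)
}

# ---------------------------------------------------------------------------
# GLCM texture features

#' The 13 classical co-occurrence texture statistics
#'
#' Quantizes a grayscale patch to `levels` grey levels, accumulates the
#' grey-level co-occurrence matrix at each offset (symmetrized and
#' normalised), computes the 13 classical Haralick statistics and averages
#' them over the offsets. A constant patch yields the documented degenerate
#' vector (energy 1, entropy 0, correlation undefined, returned as 0 with a
#' warning). Entropies use base-2 logarithms.
#'
#' @param patch grayscale matrix.
#' @param levels number of quantization levels.
#' @param offsets list of integer offset vectors `c(dr, dc)`.
#' @return named numeric vector of length 13.
#' @export
haralick13 <- function(patch, levels = 32L,
                       offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
  rng <- range(patch)
  constant <- diff(rng) <= 0
  q <- if (constant) matrix(1L, nrow(patch), ncol(patch)) else
    matrix(pmin(as.integer(floor((patch - rng[1L]) / diff(rng) * levels)) + 1L,
                levels), nrow(patch), ncol(patch))
  if (constant)
    warning("constant patch: correlation undefined, reported as 0")
  acc <- matrix(0, length(offsets), 13L)
  for (k in seq_along(offsets)) {
    glcm <- glcm_accumulate(q, levels, offsets[[k]])
    acc[k, ] <- haralick_from_glcm(glcm)
  }
  out <- colMeans(acc)
  names(out) <- c("asm", "contrast", "correlation", "variance", "idm",
                  "sum_average", "sum_variance", "sum_entropy", "entropy",
                  "difference_variance", "difference_entropy",
                  "imc1", "imc2")
  out
}

# symmetric, normalised GLCM for one offset
glcm_accumulate <- function(q, levels, offset) {
  nr <- nrow(q); nc <- ncol(q)
  dr <- offset[1L]; dc <- offset[2L]
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  glcm <- matrix(0, levels, levels)
  tab <- table(factor(a, levels = 1:levels), factor(b, levels = 1:levels))
  glcm <- glcm + tab + t(tab)      # symmetrize
  glcm / sum(glcm)
}

haralick_from_glcm <- function(p) {
  n <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum((1:n) * px); mu_y <- sum((1:n) * py)
  sd_x <- sqrt(sum(((1:n) - mu_x)^2 * px))
  sd_y <- sqrt(sum(((1:n) - mu_y)^2 * py))
  lg <- function(x) ifelse(x > 0, log2(x), 0)
  asm <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  correlation <- if (sd_x * sd_y <= 1e-15) 0 else
    sum((i - mu_x) * (j - mu_y) * p) / (sd_x * sd_y)
  variance <- sum((i - mu_x)^2 * p)     # sum of squares about the mean
  idm <- sum(p / (1 + (i - j)^2))
  # p_{x+y} over k = 2..2n and p_{x-y} over k = 0..n-1
  sums <- i + j; diffs <- abs(i - j)
  pxy_sum <- vapply(2:(2 * n), function(k) sum(p[sums == k]), 1)
  pxy_diff <- vapply(0:(n - 1), function(k) sum(p[diffs == k]), 1)
  ks <- 2:(2 * n); kd <- 0:(n - 1)
  sum_average <- sum(ks * pxy_sum)
  sum_entropy <- -sum(pxy_sum * lg(pxy_sum))
  sum_variance <- sum((ks - sum_average)^2 * pxy_sum)
  entropy <- -sum(p * lg(p))
  diff_avg <- sum(kd * pxy_diff)
  difference_variance <- sum((kd - diff_avg)^2 * pxy_diff)
  difference_entropy <- -sum(pxy_diff * lg(pxy_diff))
  hx <- -sum(px * lg(px)); hy <- -sum(py * lg(py))
  pxpy <- outer(px, py)
  hxy1 <- -sum(p * lg(pxpy))
  hxy2 <- -sum(pxpy * lg(pxpy))
  imc1 <- if (max(hx, hy) <= 1e-15) 0 else (entropy - hxy1) / max(hx, hy)
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - entropy))))
  c(asm, contrast, correlation, variance, idm, sum_average, sum_variance,
    sum_entropy, entropy, difference_variance, difference_entropy, imc1, imc2)
}

# ---------------------------------------------------------------------------
# Affinity propagation

#' Affinity-propagation clustering of feature rows
#'
#' Exemplar-based clustering by responsibility/availability message passing
#' on negative squared Euclidean similarities, requiring no preset cluster
#' count. The shared preference defaults to the median off-diagonal
#' similarity; messages are damped; exemplars are the points whose
#' `a + r` diagonal is positive, and every point is assigned to its best
#' exemplar. Non-convergence within `max_iter` returns labels with a
#' warning flag.
#'
#' @param features numeric matrix, one row per observation (standardize
#'   first if the columns are on different scales).
#' @param preference shared preference (diagonal similarity); `NULL` uses
#'   the median similarity.
#' @param damping message damping in `[0.5, 1)`.
#' @param max_iter iteration budget.
#' @param conv_iter stop after this many iterations without exemplar change.
#' @return list with `labels` (1..K, relabelled by exemplar order),
#'   `exemplars` (row indices), `iterations`, `converged`.
#' @export
phenotype_cluster <- function(features, preference = NULL, damping = 0.9,
                              max_iter = 1000L, conv_iter = 50L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 1L) stop("need at least one feature row", call. = FALSE)
  if (n == 1L)
    return(list(labels = 1L, exemplars = 1L, iterations = 0L, converged = TRUE))
  d2 <- as.matrix(stats::dist(features))^2
  s <- -d2
  off <- s[row(s) != col(s)]
  if (max(off) - min(off) <= 1e-15) {
    # all points identical: one cluster
    return(list(labels = rep(1L, n), exemplars = 1L, iterations = 0L,
                converged = TRUE))
  }
  pref <- preference %||% stats::median(off)
  diag(s) <- pref
  # tiny deterministic jitter removes degenerate ties (scaled to data)
  s <- s + 1e-12 * max(abs(s)) * matrix(seq_len(n * n) %% 7 - 3, n, n)
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  last_ex <- integer(0); stable <- 0L; it <- 0L
  for (it in seq_len(max_iter)) {
    # responsibilities
    AS <- A + s
    mx1 <- apply(AS, 1L, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS; AS2[cbind(seq_len(n), which1)] <- -Inf
    mx2 <- apply(AS2, 1L, max)
    Rnew <- s - mx1
    Rnew[cbind(seq_len(n), which1)] <- s[cbind(seq_len(n), which1)] - mx2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0); diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0); diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A) + diag(R) > 0)
    if (identical(ex, last_ex) && length(ex) > 0L) stable <- stable + 1L
    else { stable <- 0L; last_ex <- ex }
    if (stable >= conv_iter) break
  }
  converged <- stable >= conv_iter
  ex <- which(diag(A) + diag(R) > 0)
  if (length(ex) == 0L) ex <- which.max(diag(A) + diag(R))
  assign <- apply(s[, ex, drop = FALSE], 1L, which.max)
  assign[ex] <- seq_along(ex)
  if (!converged)
    warning(sprintf("affinity propagation did not converge in %d iterations", max_iter))
  list(labels = as.integer(assign), exemplars = as.integer(ex),
       iterations = it, converged = converged)
}

#' Compare two phenotype label distributions
#'
#' Per-phenotype frequency histograms over the union of labels plus their
#' total-variation distance, `TV = 1/2 sum_k |f_a(k) - f_b(k)|`: 0 for
#' identical compositions, 1 for disjoint ones.
#'
#' @param labels_a,labels_b label vectors over a shared clustering.
#' @return list with `table` (data frame of frequencies) and `distance`.
#' @export
compare_phenotype_distributions <- function(labels_a, labels_b) {
  if (length(labels_a) == 0L || length(labels_b) == 0L)
    stop("empty label vector", call. = FALSE)
  lev <- sort(unique(c(labels_a, labels_b)))
  fa <- as.numeric(table(factor(labels_a, levels = lev))) / length(labels_a)
  fb <- as.numeric(table(factor(labels_b, levels = lev))) / length(labels_b)
  list(table = data.frame(phenotype = lev, freq_a = fa, freq_b = fb),
       distance = sum(abs(fa - fb)) / 2)
}
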