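# Shared fixtures and independent oracles for the test suite.

# small, fast configuration: 20x so the default crypts fit a small field
small_config <- function(...) {
  args <- list(...)
  defaults <- list(image_height = 256L, image_width = 256L, magnification = 20,
                  grade = 0L, seed = 42L, render = "layout",
                  canvas_size = 48L, window_radius = 2L)
  defaults[names(args)] <- args
  do.call(simulation_config, defaults)
}

# a deterministic-ish crypt record for unit tests (outline drawn at grade 0)
make_test_crypt <- function(a, b, phi = 0, centre = c(150, 150),
                            i_h = 300L, i_w = 300L, seed = 7L) {
  set.seed(seed)
  out <- crypt_outline(a, b, phi, grade = 0L)
  poly <- cbind(out$outline[, 1L] + centre[1L], out$outline[, 2L] + centre[2L])
  mask <- which(matrix(seq_len(i_h * i_w), i_h, i_w) %in% integer(0))
  # rasterize via the package path: even-odd on pixel centres
  grid <- expand.grid(x = seq_len(i_w), y = seq_len(i_h))
  inside <- mgcv::in.out(rbind(poly, poly[1, ]), as.matrix(grid))
  mask <- (grid$x[inside] - 1L) * i_h + grid$y[inside]
  list(id = 1L, centre = centre, a = a, b = b, e = b / a, phi = phi,
       theta = out$theta, u = out$u, radius = out$radius,
       outline = poly, mask = as.integer(mask), area = length(mask),
       perimeter = sum(sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)),
       bbox = c(min(poly[, 1]), max(poly[, 1]), min(poly[, 2]), max(poly[, 2])),
       gland_group = 1L, partner = NA_integer_, lumen_class = "lumen_healthy")
}

# brute-force pixel Dice on index vectors
oracle_dice_pixel <- function(g, o) {
  if (length(g) + length(o) == 0) return(1)
  2 * length(intersect(g, o)) / (length(g) + length(o))
}

# literal transcription of the object-level Dice definition
oracle_dice_object <- function(g, o) {
  one_direction <- function(pred, truth) {
    ids <- setdiff(sort(unique(as.vector(pred))), 0)
    if (length(ids) == 0) return(0)
    total <- sum(pred != 0)
    acc <- 0
    for (id in ids) {
      oi <- which(pred == id)
      gl <- setdiff(unique(truth[oi]), 0)
      gi <- which(truth %in% gl)
      d <- if (length(gi) == 0) 0 else oracle_dice_pixel(gi, oi)
      acc <- acc + (length(oi) / total) * d
    }
    acc
  }
  (one_direction(o, g) + one_direction(g, o)) / 2
}

# random labelled instance image for Dice fuzzing: a few rectangles per side
random_label_image <- function(h, w, n_obj) {
  img <- matrix(0L, h, w)
  for (k in seq_len(n_obj)) {
    x0 <- sample.int(w, 1); y0 <- sample.int(h, 1)
    x1 <- min(w, x0 + sample.int(6, 1)); y1 <- min(h, y0 + sample.int(6, 1))
    img[y0:y1, x0:x1] <- k
  }
  # relabel contiguously from 1
  ids <- setdiff(sort(unique(as.vector(img))), 0L)
  out <- matrix(0L, h, w)
  for (i in seq_along(ids)) out[img == ids[i]] <- i
  out
}

# naive affinity propagation: direct transcription of the update rules
oracle_affinity_propagation <- function(s, damping = 0.9, iters = 200) {
  n <- nrow(s)
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  for (it in seq_len(iters)) {
    Rn <- matrix(0, n, n)
    for (i in seq_len(n)) for (k in seq_len(n)) {
      others <- setdiff(seq_len(n), k)
      Rn[i, k] <- s[i, k] - max(A[i, others] + s[i, others])
    }
    R <- damping * R + (1 - damping) * Rn
    An <- matrix(0, n, n)
    for (i in seq_len(n)) for (k in seq_len(n)) {
      others <- setdiff(seq_len(n), c(i, k))
      if (i == k) An[i, k] <- sum(pmax(R[others, k], 0))
      else An[i, k] <- min(0, R[k, k] + sum(pmax(R[others, k], 0)))
    }
    A <- damping * A + (1 - damping) * An
  }
  ex <- which(diag(A) + diag(R) > 0)
  if (length(ex) == 0) ex <- which.max(diag(A) + diag(R))
  lab <- apply(s[, ex, drop = FALSE], 1, which.max)
  lab[ex] <- seq_along(ex)
  list(labels = as.integer(lab), exemplars = ex)
}

# partitions equal up to relabelling?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}
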