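# Grayscale texture synthesis: non-parametric exemplar-based growth for
# chromatin and lumen, procedural coherent noise for cytoplasm and goblet
# walls, synthetic exemplar generation, and the texture bank.

#' Non-parametric exemplar-based texture synthesis
#'
#' Grows an `out_size` texture from a grayscale exemplar: a seed patch is
#' copied from the exemplar, then each frontier pixel is assigned the centre
#' value of an exemplar patch drawn uniformly among all patches whose
#' Gaussian-weighted, masked SSD to the already-known neighbourhood is
#' within `(1 + error_threshold)` of the best match. Every output value is
#' therefore an exemplar value, and the result is deterministic given the
#' exemplar, the parameters and the RNG state.
#'
#' @param exemplar grayscale matrix with values in `[0, 1]`.
#' @param out_size output size, one integer (square) or `c(h, w)`.
#' @param window_radius neighbourhood radius in pixels.
#' @param error_threshold relative tolerance for the candidate set.
#' @return a numeric matrix in `[0, 1]`.
#' @export
synth_nonparametric <- function(exemplar, out_size, window_radius = 5L,
                                error_threshold = 0.1) {
  if (length(out_size) == 1L) out_size <- c(out_size, out_size)
  if (any(out_size < 1L)) fail_field("out_size", "must be positive")
  win <- 2L * window_radius + 1L
  if (nrow(exemplar) < win || ncol(exemplar) < win)
    fail_field("exemplar", sprintf("must be at least %dx%d for window radius %d",
                                   win, win, window_radius))
  synth_nonparametric_cpp(exemplar, as.integer(out_size[1L]),
                          as.integer(out_size[2L]),
                          as.integer(window_radius), error_threshold)
}

#' Procedural coherent-noise texture
#'
#' Sum of smoothed value-noise octaves with persistence 0.5: octave `i`
#' places uniform random values on a lattice of frequency
#' `base_frequency * 2^(i-1)` and interpolates them smoothly; octaves are
#' combined with weights `0.5^(i-1)`, recentred on 0.5 and scaled by
#' `amplitude`. `amplitude = 0` yields a flat 0.5 image; `amplitude <= 1`
#' keeps all values inside `[0, 1]`.
#'
#' @param out_size output size, one integer (square) or `c(h, w)`.
#' @param octaves number of octaves.
#' @param base_frequency lattice cells across the image for the first octave.
#' @param amplitude contrast in `[0, 1]`.
#' @return a numeric matrix in `[0, 1]`.
#' @export
synth_procedural <- function(out_size, octaves = 4L, base_frequency = 4,
                             amplitude = 1) {
  if (length(out_size) == 1L) out_size <- c(out_size, out_size)
  h <- as.integer(out_size[1L]); w <- as.integer(out_size[2L])
  if (h < 1L || w < 1L) fail_field("out_size", "must be positive")
  acc <- matrix(0, h, w)
  wsum <- 0
  for (o in seq_len(octaves)) {
    f <- base_frequency * 2^(o - 1L)
    nx <- max(2L, as.integer(f) + 1L)
    ny <- max(2L, as.integer(f) + 1L)
    lattice <- matrix(stats::runif(nx * ny), ny, nx)
    # smooth bicubic-like interpolation via smoothstep-weighted bilinear
    gx <- seq(1, nx, length.out = w)
    gy <- seq(1, ny, length.out = h)
    ix <- pmin(floor(gx), nx - 1L); fx <- gx - ix
    iy <- pmin(floor(gy), ny - 1L); fy <- gy - iy
    sx <- fx * fx * (3 - 2 * fx)   # smoothstep
    sy <- fy * fy * (3 - 2 * fy)
    v00 <- lattice[cbind(rep(iy, times = w), rep(ix, each = h))]
    v01 <- lattice[cbind(rep(iy, times = w), rep(ix + 1L, each = h))]
    v10 <- lattice[cbind(rep(iy + 1L, times = w), rep(ix, each = h))]
    v11 <- lattice[cbind(rep(iy + 1L, times = w), rep(ix + 1L, each = h))]
    SX <- rep(sx, each = h); SY <- rep(sy, times = w)
    oct <- matrix((v00 * (1 - SX) + v01 * SX) * (1 - SY) +
                    (v10 * (1 - SX) + v11 * SX) * SY, h, w)
    wgt <- 0.5^(o - 1L)
    acc <- acc + wgt * (oct - 0.5)
    wsum <- wsum + wgt
  }
  out <- 0.5 + amplitude * acc / wsum
  pmin(pmax(out, 0), 1)
}

#' Generate a synthetic grayscale texture exemplar
#'
#' The package ships no real hand-marked textures; instead each texture
#' class gets a synthetic exemplar: a blob/speckle field built from
#' procedural noise at a class-specific granularity and contrast, optionally
#' posterised to a few grey levels (chromatin clumps). Users may substitute
#' their own grayscale exemplars in the bank.
#'
#' @param size exemplar side in pixels.
#' @param granularity lattice frequency of the speckle field (higher =
#'   finer).
#' @param contrast value spread around the base level.
#' @param base mean grey level.
#' @param levels optional posterisation level count (`NULL` keeps the field
#'   continuous).
#' @return matrix in `[0, 1]`.
#' @export
synthetic_exemplar <- function(size = 48L, granularity = 6, contrast = 0.8,
                               base = 0.5, levels = 8L) {
  x <- synth_procedural(size, octaves = 3L, base_frequency = granularity,
                        amplitude = 1)
  if (!is.null(levels)) x <- round(x * (levels - 1L)) / (levels - 1L)
  pmin(pmax(base + contrast * (x - 0.5), 0), 1)
}

# class parameter table for the shipped synthetic exemplars
texture_class_params <- function(profiles, n_cancer_lumen = 7L) {
  chroma <- data.frame(
    class = profiles$sizes$texture_class,
    granularity = 4 + (profiles$sizes$phenotype_id %% 5),
    contrast = 0.5 + 0.03 * (profiles$sizes$phenotype_id %% 7),
    base = 0.55 + 0.02 * (profiles$sizes$phenotype_id %% 4),
    stringsAsFactors = FALSE)
  lumen <- data.frame(
    class = c("lumen_healthy", sprintf("lumen_cancer_%d", seq_len(n_cancer_lumen))),
    granularity = c(3, 3 + seq_len(n_cancer_lumen) %% 4),
    contrast = c(0.25, rep(0.45, n_cancer_lumen)),
    base = c(0.25, 0.30 + 0.04 * (seq_len(n_cancer_lumen) %% 3)),
    stringsAsFactors = FALSE)
  rbind(chroma, lumen)
}

#' Build a texture bank
#'
#' Synthesizes one canvas per texture class (phenotype chromatin classes,
#' one healthy-lumen class, `n_cancer_lumen` cancer-lumen classes) from the
#' given exemplars, or from shipped synthetic exemplars when the user
#' supplies none. Canvases can be cached on disk keyed by exemplar hash and
#' synthesis parameters, because the non-parametric synthesis is the cost
#' bottleneck of the pipeline.
#'
#' @param config a `sim_config`.
#' @param profiles `phenotype_profiles` (defines the chromatin classes).
#' @param exemplars optional named list of grayscale matrices; missing
#'   classes fall back to the synthetic generator.
#' @param classes character vector restricting which classes to build
#'   (default: all).
#' @param cache_dir optional directory for canvas caching.
#' @return a `texture_bank`: list with `exemplars`, `canvases`, `params`.
#' @export
build_texture_bank <- function(config, profiles = default_phenotype_profiles(),
                               exemplars = NULL, classes = NULL,
                               cache_dir = NULL) {
  cp <- texture_class_params(profiles, config$n_cancer_lumen)
  if (!is.null(classes)) {
    missing <- setdiff(classes, cp$class)
    if (length(missing) > 0L && !all(missing %in% names(exemplars %||% list())))
      fail_field("classes", paste("unknown texture class:",
                                  paste(missing, collapse = ", ")))
    cp <- cp[cp$class %in% classes, , drop = FALSE]
  }
  exe <- list(); canv <- list()
  manifest <- list()
  for (i in seq_len(nrow(cp))) {
    cls <- cp$class[i]
    ex <- if (!is.null(exemplars) && !is.null(exemplars[[cls]]))
      exemplars[[cls]] else
      synthetic_exemplar(granularity = cp$granularity[i],
                         contrast = cp$contrast[i], base = cp$base[i])
    key <- NULL
    if (!is.null(cache_dir)) {
      key <- sprintf("%s_%d_%d_%g_%s.tif", cls, config$canvas_size,
                     config$window_radius, config$error_threshold,
                     substr(paste(format(sum(ex) * 1e6), format(stats::var(as.numeric(ex)) * 1e9)), 1, 24))
      key <- gsub("[^A-Za-z0-9_.-]", "", key)
      path <- file.path(cache_dir, key)
      if (file.exists(path)) {
        canv[[cls]] <- tiff::readTIFF(path)
        exe[[cls]] <- ex
        manifest[[cls]] <- list(file = key, cached = TRUE)
        next
      }
    }
    canvas <- synth_nonparametric(ex, config$canvas_size,
                                  config$window_radius, config$error_threshold)
    if (!is.null(cache_dir)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      tiff::writeTIFF(canvas, file.path(cache_dir, key), bits.per.sample = 32L)
      manifest[[cls]] <- list(file = key, cached = FALSE)
    }
    exe[[cls]] <- ex
    canv[[cls]] <- canvas
  }
  if (!is.null(cache_dir)) {
    jsonlite::write_json(manifest, file.path(cache_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  structure(list(exemplars = exe, canvases = canv, params = cp),
            class = "texture_bank")
}

#' Random crop from a texture-bank canvas
#'
#' Uniformly random axis-aligned crop, with replacement across calls (two
#' crops may coincide). A request larger than the canvas errors by default;
#' with `tile = TRUE` the canvas is mirror-tiled first, which the renderer
#' uses for whole-crypt lumen fills.
#'
#' @param bank a `texture_bank`.
#' @param class texture class name.
#' @param size crop size, one integer or `c(h, w)`.
#' @param tile mirror-tile the canvas when the request exceeds it.
#' @return matrix of the requested size.
#' @export
crop_texture <- function(bank, class, size, tile = FALSE) {
  canvas <- bank$canvases[[class]]
  if (is.null(canvas)) fail_field("class", paste("not in bank:", class))
  if (length(size) == 1L) size <- c(size, size)
  if ((size[1L] > nrow(canvas) || size[2L] > ncol(canvas))) {
    if (!tile)
      stop(sprintf("crop %dx%d exceeds canvas %dx%d for class '%s'; regenerate a larger canvas",
                   size[1L], size[2L], nrow(canvas), ncol(canvas), class),
           call. = FALSE)
    canvas <- mirror_tile(canvas, size)
  }
  r0 <- if (nrow(canvas) == size[1L]) 1L else
    sample.int(nrow(canvas) - size[1L] + 1L, 1L)
  c0 <- if (ncol(canvas) == size[2L]) 1L else
    sample.int(ncol(canvas) - size[2L] + 1L, 1L)
  canvas[r0:(r0 + size[1L] - 1L), c0:(c0 + size[2L] - 1L), drop = FALSE]
}

# mirror-tile a matrix until it covers `size`
mirror_tile <- function(m, size) {
  while (nrow(m) < size[1L]) m <- rbind(m, m[rev(seq_len(nrow(m))), , drop = FALSE])
  while (ncol(m) < size[2L]) m <- cbind(m, m[, rev(seq_len(ncol(m))), drop = FALSE])
  m
}
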