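# Rendering: ideal haematoxylin/eosin concentration channels, acquisition
# degradation, Beer-Lambert stain composition, scalebar, and file output.

# fixed rendering intensities (eosin = cytoplasm channel, haematoxylin =
# nuclei channel); chosen for visual plausibility and kept bit-exact
.render_levels <- list(
  lumen_scale = 0.45,       # lumen crop contribution to the eosin channel
  cytoplasm_base = 0.35, cytoplasm_span = 0.30,
  chromatin_base = 0.55, chromatin_span = 0.45,
  goblet_wall = 0.75)

#' Compose the ideal channel stack and ground truth
#'
#' Draw order: lumen crops into each crypt, goblet walls (healthy crypts),
#' cell cytoplasm (procedural texture), cell nuclei (phenotype chromatin
#' crops). Overlapping intensities combine by per-pixel maximum within each
#' channel, so channel values stay in `[0, 1]` before staining. Instance
#' labels use later-drawn-wins tie-breaking; the full per-cell masks are
#' kept in the simulation object so overlaps remain recoverable.
#'
#' @param config a `sim_config`.
#' @param arch architecture from [place_crypts()].
#' @param pop population from [build_cell_population()].
#' @param bank a `texture_bank` covering the lumen classes and every
#'   phenotype present.
#' @param profiles `phenotype_profiles`.
#' @return list with `nuclei`, `cytoplasm` (matrices in `[0, 1]`), `labels`
#'   (list of label matrices/masks), and `goblet` (per-crypt structures).
#' @export
compose_ideal <- function(config, arch, pop, bank,
                          profiles = default_phenotype_profiles()) {
  i_h <- config$image_height; i_w <- config$image_width
  r_px <- microns_to_pixels(config$cell_radius, config)
  I_n <- matrix(0, i_h, i_w)
  I_c <- matrix(0, i_h, i_w)
  lumen_mask <- matrix(FALSE, i_h, i_w)
  goblet_mask <- matrix(FALSE, i_h, i_w)
  lv <- .render_levels
  spp <- specimen_pixel_size(config)
  wall_px <- max(1, round(0.55 / spp))   # ~0.55 um walls
  goblets <- list()
  for (crypt in arch$crypts) {
    if (length(crypt$mask) == 0L) next
    xy <- index_to_xy(crypt$mask, i_h)
    bw <- max(xy[, 1L]) - min(xy[, 1L]) + 1L
    bh <- max(xy[, 2L]) - min(xy[, 2L]) + 1L
    crop <- crop_texture(bank, crypt$lumen_class, c(bh, bw), tile = TRUE)
    li <- (xy[, 1L] - min(xy[, 1L])) * bh + (xy[, 2L] - min(xy[, 2L]) + 1L)
    I_c[crypt$mask] <- pmax(I_c[crypt$mask], lv$lumen_scale * crop[li])
    lumen_mask[crypt$mask] <- TRUE
    if (config$grade == 0L) {
      gst <- goblet_structure(crypt, r_px, i_h, i_w, wall_px, lv$goblet_wall)
      if (!is.null(gst)) {
        goblets[[length(goblets) + 1L]] <- gst
        if (!is.null(gst$layer)) {
          I_c[gst$layer$idx] <- pmax(I_c[gst$layer$idx], gst$layer$values)
          goblet_mask[gst$walls] <- TRUE
        }
      }
    }
  }
  nuc_label <- matrix(0L, i_h, i_w)
  cyt_label <- matrix(0L, i_h, i_w)
  cells <- pop$cells
  tex_class <- profiles$sizes$texture_class
  for (i in seq_len(nrow(cells))) {
    cyt_idx <- pop$cytoplasm_masks[[i]]
    if (length(cyt_idx) > 0L) {
      xy <- index_to_xy(cyt_idx, i_h)
      bh <- max(xy[, 2L]) - min(xy[, 2L]) + 1L
      bw <- max(xy[, 1L]) - min(xy[, 1L]) + 1L
      tex <- synth_procedural(c(bh, bw), octaves = 2L, base_frequency = 3)
      li <- (xy[, 1L] - min(xy[, 1L])) * bh + (xy[, 2L] - min(xy[, 2L]) + 1L)
      I_c[cyt_idx] <- pmax(I_c[cyt_idx],
                           lv$cytoplasm_base + lv$cytoplasm_span * tex[li])
      cyt_label[cyt_idx] <- cells$cell_id[i]
    }
    nuc_idx <- pop$nucleus_masks[[i]]
    if (length(nuc_idx) > 0L) {
      xy <- index_to_xy(nuc_idx, i_h)
      bh <- max(xy[, 2L]) - min(xy[, 2L]) + 1L
      bw <- max(xy[, 1L]) - min(xy[, 1L]) + 1L
      crop <- crop_texture(bank, tex_class[cells$phenotype_id[i]], c(bh, bw),
                           tile = TRUE)
      li <- (xy[, 1L] - min(xy[, 1L])) * bh + (xy[, 2L] - min(xy[, 2L]) + 1L)
      I_n[nuc_idx] <- pmax(I_n[nuc_idx],
                           lv$chromatin_base + lv$chromatin_span * crop[li])
      nuc_label[nuc_idx] <- cells$cell_id[i]
    }
  }
  list(nuclei = I_n, cytoplasm = I_c,
       labels = list(nuclei = nuc_label, cytoplasm = cyt_label,
                     crypt = arch$label, lumen = lumen_mask,
                     goblet = goblet_mask),
       goblets = goblets)
}

#' Acquisition degradation of an ideal channel
#'
#' `I_hat = I * G + N_G`: convolution with a unit-sum 2-D Gaussian kernel of
#' standard deviation `psf_sigma` (truncated at 4 sigma) models photon
#' leakage between CCD pixels, then zero-mean Gaussian noise of variance
#' `noise_variance` models detector noise. The result is clipped to
#' `[0, 1]`.
#'
#' @param channel matrix in `[0, 1]`.
#' @param psf_sigma PSF standard deviation in pixels (0 = no blur).
#' @param noise_variance noise variance (0 = no noise).
#' @return degraded matrix in `[0, 1]`.
#' @export
degrade <- function(channel, psf_sigma, noise_variance) {
  if (psf_sigma < 0) fail_field("psf_sigma", "must be >= 0")
  if (noise_variance < 0) fail_field("noise_variance", "must be >= 0")
  out <- gaussian_convolve(channel, psf_sigma)
  if (noise_variance > 0)
    out <- out + stats::rnorm(length(out), 0, sqrt(noise_variance))
  pmin(pmax(out, 0), 1)
}

#' Beer-Lambert H&E composition
#'
#' Treats the two ideal channels as stain concentrations and composes RGB
#' transmitted light: `RGB = exp(-(I_n M_1 + I_c M_2))` per pixel, with
#' `M_1` the haematoxylin and `M_2` the eosin optical-density row. Pixels
#' with both channels zero render white; intensity is monotone decreasing
#' in each channel.
#'
#' @param nuclei,cytoplasm channel matrices.
#' @param stain_matrix 2x3 optical-density matrix.
#' @return an `i_h x i_w x 3` RGB array in `(0, 1]`.
#' @export
to_hne <- function(nuclei, cytoplasm, stain_matrix) {
  if (!all(is.finite(stain_matrix)))
    fail_field("stain_matrix", "entries must be finite")
  rgb <- array(0, dim = c(nrow(nuclei), ncol(nuclei), 3L))
  for (ch in 1:3) {
    rgb[, , ch] <- exp(-(nuclei * stain_matrix[1L, ch] +
                           cytoplasm * stain_matrix[2L, ch]))
  }
  rgb
}

#' Invert the stain composition (round-trip check)
#'
#' Recovers the two concentration channels from a noise-free H&E render by
#' applying the right pseudo-inverse of the stain matrix to the optical
#' densities `-log(RGB)`.
#'
#' @param rgb RGB array from [to_hne()].
#' @param stain_matrix the matrix used to render.
#' @return list with `nuclei` and `cytoplasm` matrices.
#' @export
stain_deconvolve <- function(rgb, stain_matrix) {
  od <- -log(pmax(rgb, .Machine$double.xmin))
  n <- dim(rgb)[1L] * dim(rgb)[2L]
  odm <- cbind(as.numeric(od[, , 1L]), as.numeric(od[, , 2L]),
               as.numeric(od[, , 3L]))
  pinv <- t(stain_matrix) %*% solve(stain_matrix %*% t(stain_matrix))
  conc <- odm %*% pinv
  list(nuclei = matrix(conc[, 1L], dim(rgb)[1L], dim(rgb)[2L]),
       cytoplasm = matrix(conc[, 2L], dim(rgb)[1L], dim(rgb)[2L]))
}

# scalebar constants: bit-exact contract
.scalebar_height_px <- 4L
.scalebar_margin_px <- 10L

#' Draw the scalebar
#'
#' An opaque black bar of physical length `scalebar_length` (converted to
#' pixels, rounded to nearest) at the bottom-right corner, 4 px high with a
#' 10 px margin. A bar longer than the image is clipped with a warning; an
#' unset scalebar leaves the image unchanged.
#'
#' @param rgb RGB array.
#' @param config a `sim_config`.
#' @return the RGB array with the bar burnt in.
#' @export
add_scalebar <- function(rgb, config) {
  if (is.null(config$scalebar_length)) return(rgb)
  len <- as.integer(round(config$scalebar_length / specimen_pixel_size(config)))
  i_h <- dim(rgb)[1L]; i_w <- dim(rgb)[2L]
  if (len > i_w) {
    warning("scalebar longer than the image; clipping")
    len <- i_w
  }
  x1 <- i_w - .scalebar_margin_px
  x0 <- max(1L, x1 - len + 1L)
  y1 <- i_h - .scalebar_margin_px
  y0 <- max(1L, y1 - .scalebar_height_px + 1L)
  if (x0 > x1 || y0 > y1) return(rgb)
  rgb[y0:y1, x0:x1, ] <- 0
  rgb
}

#' Write a simulation result to disk
#'
#' Writes `rgb.png` (8-bit), `nuclei.tif`/`cytoplasm.tif` (32-bit float
#' channels), label masks as 16-bit TIFF, the per-cell and per-crypt ground
#' truth CSVs, and `manifest.json` holding the fully resolved configuration
#' and seed so the run can be reproduced bit-exactly.
#'
#' @param sim a `crypt_sim` object from [simulate_image()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the vector of written file paths.
#' @export
write_outputs <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(name) { p <- file.path(out_dir, name); paths <<- c(paths, p); p }
  if (!is.null(sim$rgb)) png::writePNG(sim$rgb, wr("rgb.png"))
  if (!is.null(sim$channels)) {
    tiff::writeTIFF(sim$channels$nuclei, wr("nuclei.tif"), bits.per.sample = 32L)
    tiff::writeTIFF(sim$channels$cytoplasm, wr("cytoplasm.tif"), bits.per.sample = 32L)
  }
  if (!is.null(sim$labels)) {
    for (nm in names(sim$labels)) {
      m <- sim$labels[[nm]]
      if (is.logical(m)) m <- m * 1L
      if (max(m) > 65535L) stop("label overflow: more than 65535 instances")
      tiff::writeTIFF(m / 65535, wr(sprintf("labels_%s.tif", nm)),
                      bits.per.sample = 16L)
    }
  }
  utils::write.csv(sim$cells, wr("cells.csv"), row.names = FALSE)
  utils::write.csv(sim$crypts_table, wr("crypts.csv"), row.names = FALSE)
  manifest <- list(
    config = config_manifest(sim$config),
    seed = sim$config$seed,
    grade = sim$config$grade,
    f_c = sim$f_c,
    counts = sim$counts,
    n_cells_placed = nrow(sim$cells),
    n_skipped = nrow(sim$skips),
    package_version = as.character(utils::packageVersion("cryptsim")),
    files = basename(paths))
  jsonlite::write_json(manifest, wr("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

# serializable form of a sim_config
config_manifest <- function(config) {
  x <- unclass(config)
  x$stain_matrix <- lapply(seq_len(nrow(config$stain_matrix)),
                           function(i) as.numeric(config$stain_matrix[i, ]))
  x
}

#' Read back a run's label mask written by [write_outputs()]
#' @param path a `labels_*.tif` file.
#' @return integer matrix of instance labels.
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
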