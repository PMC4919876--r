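# Simulation configuration: every user-facing knob, unit conversion and
# validation. All lengths are stored in micrometres; conversion to pixels
# happens once at simulation start via the specimen pixel size.

#' Default haematoxylin/eosin stain matrices
#'
#' Two optical-density row vectors per stain (rows: haematoxylin, eosin;
#' columns: R, G, B). `"separation"` is a matrix estimated from a real H&E
#' image by a stain-separation method and is the package default;
#' `"ruifrok"` is the classical colour-deconvolution pair of Ruifrok and
#' Johnston (normalised to unit row norm).
#'
#' @param name `"separation"` or `"ruifrok"`.
#' @return a 2x3 numeric matrix with rownames `haematoxylin`, `eosin`.
#' @export
default_stain_matrix <- function(name = c("separation", "ruifrok")) {
  name <- match.arg(name)
  m <- switch(name,
    separation = rbind(c(0.6402, 0.6479, 0.4128),
                       c(0.3906, 0.7662, 0.5102)),
    ruifrok = {
      h <- c(0.650, 0.704, 0.286)
      e <- c(0.072, 0.990, 0.105)
      rbind(h / sqrt(sum(h^2)), e / sqrt(sum(e^2)))
    })
  dimnames(m) <- list(c("haematoxylin", "eosin"), c("R", "G", "B"))
  m
}

#' Create a simulation configuration
#'
#' Gathers every user-facing parameter of the tissue model. Lengths are in
#' micrometres unless the name says pixels; fractions are in `[0, 1]`.
#'
#' @param image_height,image_width output size in pixels.
#' @param magnification objective magnification (e.g. 20 or 40).
#' @param ccd_pixel_size physical CCD pixel size in micrometres.
#' @param scalebar_length optional scalebar length in micrometres (`NULL`
#'   draws no bar).
#' @param grade differentiation grade `S`: 0 healthy, 1 well, 2 moderately,
#'   3 poorly differentiated.
#' @param cellularity_epithelial,cellularity_stromal densities `nu_e`, `nu_s`
#'   in `[0, 1]` scaling the epithelial and stromal cell counts.
#' @param max_overlap maximum tolerated pairwise cell overlap ratio `L_max`;
#'   0 forbids any overlap, 1 imposes no restriction.
#' @param overlap_domain whether overlap is controlled on `"nuclei"` or
#'   `"cytoplasm"` masks.
#' @param psf_sigma Gaussian point-spread standard deviation in pixels.
#' @param noise_variance variance of the additive CCD noise (intensities on
#'   the `[0, 1]` scale).
#' @param stain_matrix 2x3 optical-density matrix, or a name accepted by
#'   [default_stain_matrix()].
#' @param cell_radius nominal cell radius `r` in micrometres.
#' @param seed master seed; per-stage streams are derived from it so the run
#'   is reproducible bit-exactly.
#' @param n_images number of images in a batch run.
#' @param render `"full"` renders textures, stains and degradation;
#'   `"layout"` stops after placement and ground truth (fast mode for
#'   architecture/count studies).
#' @param canvas_size side of the synthesized texture canvases in pixels.
#' @param window_radius,error_threshold neighbourhood radius and relative
#'   error tolerance of the non-parametric texture synthesis.
#' @param n_cancer_lumen number of distinct cancer-lumen texture classes.
#' @param max_attempts placement retries per cell before it is skipped.
#' @param tumour_prob_per_grade slope of the stromal tumour-cell probability
#'   `p_t(S) = min(slope * S, 1)`.
#' @param n_vertices_crypt vertices of the crypt outline before spline
#'   closure (72 = 5 degree steps).
#' @param k_polygon vertex count of the randomized cell polygons.
#' @param beta_shape angular jitter of the randomized polygons (radians).
#' @param independent_cyto_factors if `TRUE` the two cytoplasm/nucleus size
#'   factors are drawn independently per axis.
#' @return a validated object of class `sim_config`.
#' @export
simulation_config <- function(image_height = 1000L,
                              image_width = 1000L,
                              magnification = 40,
                              ccd_pixel_size = 11,
                              scalebar_length = NULL,
                              grade = 0L,
                              cellularity_epithelial = 1,
                              cellularity_stromal = 1,
                              max_overlap = 0.6,
                              overlap_domain = c("nuclei", "cytoplasm"),
                              psf_sigma = 1,
                              noise_variance = 0.00025,
                              stain_matrix = "separation",
                              cell_radius = 6,
                              seed = 1L,
                              n_images = 1L,
                              render = c("full", "layout"),
                              canvas_size = 256L,
                              window_radius = 5L,
                              error_threshold = 0.1,
                              n_cancer_lumen = 7L,
                              max_attempts = 100L,
                              tumour_prob_per_grade = 0.2,
                              n_vertices_crypt = 72L,
                              k_polygon = 10L,
                              beta_shape = 0.05,
                              independent_cyto_factors = TRUE) {
  if (is.character(stain_matrix)) stain_matrix <- default_stain_matrix(stain_matrix)
  cfg <- list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    magnification = magnification,
    ccd_pixel_size = ccd_pixel_size,
    scalebar_length = scalebar_length,
    grade = as.integer(grade),
    cellularity_epithelial = cellularity_epithelial,
    cellularity_stromal = cellularity_stromal,
    max_overlap = max_overlap,
    overlap_domain = match.arg(overlap_domain),
    psf_sigma = psf_sigma,
    noise_variance = noise_variance,
    stain_matrix = stain_matrix,
    cell_radius = cell_radius,
    seed = as.integer(seed),
    n_images = as.integer(n_images),
    render = match.arg(render),
    canvas_size = as.integer(canvas_size),
    window_radius = as.integer(window_radius),
    error_threshold = error_threshold,
    n_cancer_lumen = as.integer(n_cancer_lumen),
    max_attempts = as.integer(max_attempts),
    tumour_prob_per_grade = tumour_prob_per_grade,
    n_vertices_crypt = as.integer(n_vertices_crypt),
    k_polygon = as.integer(k_polygon),
    beta_shape = beta_shape,
    independent_cyto_factors = isTRUE(independent_cyto_factors)
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks every invariant (fractions in range, grade in 0..3, positive
#' kernel/noise parameters, stain rows with positive norm) and reports each
#' violation with its field name. Returns the config unchanged when valid.
#'
#' @param config a `sim_config` (or a bare list with the same fields).
#' @return the validated `sim_config`.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "sim_config")) {
    config <- structure(config, class = "sim_config")
  }
  frac_fields <- c("cellularity_epithelial", "cellularity_stromal", "max_overlap",
                   "error_threshold")
  for (f in frac_fields) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      fail_field(f, "must be a fraction in [0, 1]")
  }
  if (!config$grade %in% 0:3) fail_field("grade", "must be one of 0, 1, 2, 3")
  if (config$image_height < 1L) fail_field("image_height", "must be >= 1")
  if (config$image_width < 1L) fail_field("image_width", "must be >= 1")
  if (!is.numeric(config$magnification) || config$magnification <= 0)
    fail_field("magnification", "must be > 0")
  if (config$ccd_pixel_size <= 0) fail_field("ccd_pixel_size", "must be > 0")
  if (config$psf_sigma < 0) fail_field("psf_sigma", "must be >= 0")
  if (config$noise_variance < 0) fail_field("noise_variance", "must be >= 0")
  if (config$cell_radius <= 0) fail_field("cell_radius", "must be > 0")
  if (!is.null(config$scalebar_length) && config$scalebar_length <= 0)
    fail_field("scalebar_length", "must be > 0 when set")
  m <- config$stain_matrix
  if (!is.matrix(m) || !all(dim(m) == c(2L, 3L)) || any(!is.finite(m)))
    fail_field("stain_matrix", "must be a finite 2x3 matrix")
  if (any(sqrt(rowSums(m^2)) <= 0))
    fail_field("stain_matrix", "each stain row must have positive norm")
  if (config$k_polygon < 3L) fail_field("k_polygon", "must be >= 3")
  if (config$n_vertices_crypt < 8L) fail_field("n_vertices_crypt", "must be >= 8")
  if (config$max_attempts < 1L) fail_field("max_attempts", "must be >= 1")
  if (config$tumour_prob_per_grade < 0 || config$tumour_prob_per_grade > 1)
    fail_field("tumour_prob_per_grade", "must be in [0, 1]")
  config
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %dx%d px, %gx (%.4g um/px), grade %d, L_max %.2f, nu_e %.2f, nu_s %.2f, seed %d, render '%s'\n",
    x$image_width, x$image_height, x$magnification, specimen_pixel_size(x),
    x$grade, x$max_overlap, x$cellularity_epithelial, x$cellularity_stromal,
    x$seed, x$render))
  invisible(x)
}

#' Specimen-plane pixel size
#'
#' Physical size of one image pixel at the specimen, i.e. CCD pixel size
#' divided by magnification.
#'
#' @param config a `sim_config`.
#' @return micrometres per pixel.
#' @export
specimen_pixel_size <- function(config) {
  if (!is.numeric(config$magnification) || config$magnification <= 0)
    fail_field("magnification", "must be > 0")
  config$ccd_pixel_size / config$magnification
}

#' Convert micrometres to pixels (and back)
#'
#' Real-valued conversion; any rounding is the caller's decision.
#'
#' @param length length in micrometres (pixels for the inverse).
#' @param config a `sim_config`.
#' @return length in pixels (micrometres for the inverse).
#' @export
microns_to_pixels <- function(length, config) {
  if (any(length < 0)) fail_field("length", "must be >= 0")
  length / specimen_pixel_size(config)
}

#' @rdname microns_to_pixels
#' @export
pixels_to_microns <- function(length, config) {
  if (any(length < 0)) fail_field("length", "must be >= 0")
  length * specimen_pixel_size(config)
}

# ---------------------------------------------------------------------------
# Grade-dependent crypt morphometry

#' Default crypt morphometry parameters per grade class
#'
#' One record per class (`healthy` for grade 0, `cancerous` for grades 1-3):
#' Gamma shape/scale for the crypt semi-minor axis `b` (micrometres,
#' shape-scale parameterization so that `alpha_b * beta_b = mu_b`) and Gamma
#' shape/scale for the axis ratio `e = b/a`. The numeric defaults are the
#' package's own morphometric choices, calibrated so that the default image
#' conditions reproduce the typical published cell-count ranges; they can be
#' replaced by tables fitted from annotations via [learn_parameters()].
#'
#' @return a data frame with columns `class`, `mu_b`, `alpha_b`, `beta_b`,
#'   `alpha_e`, `beta_e`.
#' @export
default_grade_params <- function() {
  gp <- data.frame(
    class = c("healthy", "cancerous"),
    mu_b = c(57, 65),
    alpha_b = c(25, 12),
    beta_b = c(2.28, 65 / 12),
    alpha_e = c(20, 12),
    beta_e = c(0.68 / 20, 0.70 / 12),
    stringsAsFactors = FALSE
  )
  validate_grade_params(gp)
}

#' Validate a grade-parameter table
#'
#' @param gp data frame as returned by [default_grade_params()].
#' @return the table, invisibly checked.
#' @export
validate_grade_params <- function(gp) {
  need <- c("class", "mu_b", "alpha_b", "beta_b", "alpha_e", "beta_e")
  if (!all(need %in% names(gp))) fail_field("grade_params", "missing columns")
  num <- gp[setdiff(need, "class")]
  if (any(!vapply(num, is.numeric, TRUE)) || any(unlist(num) <= 0))
    fail_field("grade_params", "shapes and scales must be strictly positive")
  if (any(abs(gp$alpha_b * gp$beta_b - gp$mu_b) > 1e-6))
    fail_field("grade_params", "alpha_b * beta_b must equal mu_b (shape-scale)")
  gp
}

#' Grade-parameter record for a grade
#' @param gp grade-parameter table.
#' @param grade integer grade 0-3.
#' @return one-row data frame.
#' @export
grade_params_for <- function(gp, grade) {
  cls <- if (grade == 0L) "healthy" else "cancerous"
  row <- gp[gp$class == cls, , drop = FALSE]
  if (nrow(row) != 1L) fail_field("grade_params", paste("no record for class", cls))
  row
}

# ---------------------------------------------------------------------------
# Nuclear phenotype profiles

#' Default nuclear phenotype profiles
#'
#' 17 phenotypes, each with normal mean/sd of the nuclear semi-major and
#' semi-minor axes (micrometres), a chromatin texture class, and a frequency
#' table per (grade, compartment). Phenotypes 1-6 represent regular columnar
#' epithelial nuclei, 7-10 enlarged atypical/tumour nuclei, 11-14 small round
#' stromal (lymphocyte-like) nuclei, and 15-17 elongated fibroblast-like
#' nuclei. The frequencies shift mass from regular towards atypical
#' phenotypes as the grade increases. These defaults are editable (YAML) and
#' are the package's own plausible tables, not measured values.
#'
#' @return list with elements `sizes` (data frame) and `freq` (17 x 4 x 2
#'   array, dimensions phenotype x grade x compartment), class
#'   `phenotype_profiles`.
#' @export
default_phenotype_profiles <- function() {
  id <- 1:17
  mu_l <- c(3.6, 3.9, 4.2, 4.5, 4.8, 5.0,          # columnar epithelial
            5.4, 6.0, 6.6, 7.2,                    # atypical / tumour
            2.2, 2.5, 2.8, 3.1,                    # small round stromal
            3.6, 4.0, 4.4)                         # fibroblast-like
  ratio <- c(0.62, 0.58, 0.66, 0.60, 0.64, 0.56,
             0.72, 0.68, 0.75, 0.70,
             0.88, 0.92, 0.85, 0.90,
             0.42, 0.38, 0.46)
  sizes <- data.frame(
    phenotype_id = id,
    mu_l = mu_l,
    sigma_l = 0.15 * mu_l,
    mu_w = mu_l * ratio,
    sigma_w = 0.15 * mu_l * ratio,
    texture_class = sprintf("chromatin_%02d", id),
    stringsAsFactors = FALSE
  )
  freq <- array(0, dim = c(17L, 4L, 2L),
                dimnames = list(phenotype = id, grade = 0:3,
                                compartment = c("epithelial", "stromal")))
  groups <- list(regular = 1:6, atypical = 7:10, small = 11:14, spindle = 15:17)
  # epithelial compartment: regular -> atypical with grade
  epi_mix <- rbind(c(0.97, 0.03), c(0.70, 0.30), c(0.40, 0.60), c(0.15, 0.85))
  for (g in 1:4) {
    freq[groups$regular, g, 1L] <- epi_mix[g, 1L] / length(groups$regular)
    freq[groups$atypical, g, 1L] <- epi_mix[g, 2L] / length(groups$atypical)
  }
  # stromal compartment: small + spindle, with atypical mass rising in cancer
  str_mix <- rbind(c(0.55, 0.42, 0.03), c(0.50, 0.35, 0.15),
                   c(0.45, 0.25, 0.30), c(0.35, 0.15, 0.50))
  for (g in 1:4) {
    freq[groups$small, g, 2L] <- str_mix[g, 1L] / length(groups$small)
    freq[groups$spindle, g, 2L] <- str_mix[g, 2L] / length(groups$spindle)
    freq[groups$atypical, g, 2L] <- str_mix[g, 3L] / length(groups$atypical)
  }
  profiles <- structure(list(sizes = sizes, freq = freq),
                        class = "phenotype_profiles")
  validate_phenotype_profiles(profiles)
}

#' Validate (and optionally renormalize) phenotype profiles
#'
#' Each (grade, compartment) frequency column must sum to 1 within 1e-9.
#' With `renormalize = TRUE` user-edited tables are rescaled instead of
#' rejected; all-zero columns are always an error.
#'
#' @param profiles a `phenotype_profiles` list.
#' @param renormalize rescale near-miss columns instead of failing.
#' @return the validated profiles.
#' @export
validate_phenotype_profiles <- function(profiles, renormalize = FALSE) {
  s <- profiles$sizes
  if (any(s$mu_l <= 0 | s$mu_w <= 0 | s$sigma_l < 0 | s$sigma_w < 0))
    fail_field("phenotype_profiles", "all sizes must be positive")
  fr <- profiles$freq
  if (!is.array(fr) || length(dim(fr)) != 3L || dim(fr)[1L] != nrow(s))
    fail_field("phenotype_profiles", "freq must be phenotype x grade x compartment")
  if (any(fr < 0)) fail_field("phenotype_profiles", "frequencies must be >= 0")
  for (g in seq_len(dim(fr)[2L])) {
    for (cp in seq_len(dim(fr)[3L])) {
      tot <- sum(fr[, g, cp])
      if (tot <= 0)
        fail_field("phenotype_profiles",
                   sprintf("all-zero frequencies for grade %d, %s",
                           g - 1L, dimnames(fr)[[3L]][cp]))
      if (abs(tot - 1) > 1e-9) {
        if (renormalize) fr[, g, cp] <- fr[, g, cp] / tot
        else fail_field("phenotype_profiles",
                        sprintf("frequencies for grade %d, %s sum to %.12f, not 1",
                                g - 1L, dimnames(fr)[[3L]][cp], tot))
      }
    }
  }
  profiles$freq <- fr
  profiles
}

# ---------------------------------------------------------------------------
# YAML interchange

#' Read and write configurations and parameter tables as YAML
#'
#' The YAML keys mirror the `sim_config` field names; `overrides` (e.g.
#' command-line flags) take precedence over file values. Grade parameters
#' and phenotype profiles round-trip through their own files with
#' frequencies stored as nested grade/compartment maps.
#'
#' @param path file path.
#' @param config,gp,profiles objects to serialize.
#' @param overrides named list overriding file values.
#' @name config_yaml
NULL

#' @rdname config_yaml
#' @export
write_config_yaml <- function(config, path) {
  x <- unclass(config)
  x$stain_matrix <- lapply(seq_len(nrow(config$stain_matrix)),
                           function(i) as.numeric(config$stain_matrix[i, ]))
  yaml::write_yaml(x, path, precision = 12L)
  invisible(path)
}

#' @rdname config_yaml
#' @export
read_config_yaml <- function(path, overrides = list()) {
  x <- yaml::read_yaml(path)
  x[names(overrides)] <- overrides
  if (!is.null(x$stain_matrix) && is.list(x$stain_matrix))
    x$stain_matrix <- do.call(rbind, x$stain_matrix)
  do.call(simulation_config, x)
}

#' @rdname config_yaml
#' @export
write_grade_params_yaml <- function(gp, path) {
  yaml::write_yaml(lapply(seq_len(nrow(gp)), function(i) as.list(gp[i, ])), path,
                   precision = 12L)
  invisible(path)
}

#' @rdname config_yaml
#' @export
read_grade_params_yaml <- function(path) {
  validate_grade_params(do.call(rbind, lapply(yaml::read_yaml(path), as.data.frame)))
}

#' @rdname config_yaml
#' @export
write_phenotype_yaml <- function(profiles, path) {
  fr <- profiles$freq
  freq_map <- lapply(seq_len(dim(fr)[2L]), function(g) {
    out <- lapply(seq_len(dim(fr)[3L]), function(cp) as.numeric(fr[, g, cp]))
    names(out) <- dimnames(fr)[[3L]]
    out
  })
  names(freq_map) <- paste0("grade_", dimnames(fr)[[2L]])
  yaml::write_yaml(list(
    sizes = lapply(seq_len(nrow(profiles$sizes)),
                   function(i) as.list(profiles$sizes[i, ])),
    freq = freq_map), path, precision = 12L)
  invisible(path)
}

#' @rdname config_yaml
#' @export
read_phenotype_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  sizes <- do.call(rbind, lapply(x$sizes, as.data.frame))
  n <- nrow(sizes)
  grades <- names(x$freq)
  comps <- names(x$freq[[1L]])
  fr <- array(0, dim = c(n, length(grades), length(comps)),
              dimnames = list(phenotype = sizes$phenotype_id,
                              grade = sub("^grade_", "", grades),
                              compartment = comps))
  for (g in seq_along(grades)) for (cp in seq_along(comps))
    fr[, g, cp] <- as.numeric(x$freq[[g]][[cp]])
  validate_phenotype_profiles(
    structure(list(sizes = sizes, freq = fr), class = "phenotype_profiles"),
    renormalize = TRUE)
}
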