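# Top-level orchestration: one simulated visual field from a configuration.

#' Simulate one histology visual field
#'
#' Runs the full pipeline: grade-dependent crypt architecture, cell counts
#' and placement, goblet/lumen/texture synthesis, acquisition degradation,
#' and Beer-Lambert H&E rendering, returning the image together with the
#' complete ground truth. With `config$render = "layout"` the pipeline stops
#' after placement (no textures, channels or RGB), which is the fast mode
#' for architecture and count studies; all ground-truth tables and label
#' masks are still produced.
#'
#' Each stage consumes an independent RNG stream derived from the master
#' seed, so identical configurations reproduce bit-identical results on one
#' platform.
#'
#' @param config a `sim_config`.
#' @param grade_params grade-parameter table ([default_grade_params()]).
#' @param profiles `phenotype_profiles` ([default_phenotype_profiles()]).
#' @param bank optional pre-built [build_texture_bank()] (reused across a
#'   batch; built on demand otherwise).
#' @return an object of class `crypt_sim`: list with `config`, `f_c`,
#'   `crypts` (list), `crypts_table`, `cells` (data frame), `counts`,
#'   `clusters`, `skips`, `nucleus_masks`, `cytoplasm_masks`, `labels`,
#'   and (full render only) `channels`, `channels_ideal`, `rgb`, `goblets`.
#' @export
simulate_image <- function(config,
                           grade_params = default_grade_params(),
                           profiles = default_phenotype_profiles(),
                           bank = NULL) {
  config <- validate_config(config)
  t0 <- proc.time()[["elapsed"]]
  timing <- c()

  set.seed(stage_seed(config$seed, "architecture"))
  arch <- place_crypts(config, grade_params)
  timing["architecture"] <- proc.time()[["elapsed"]] - t0

  set.seed(stage_seed(config$seed, "cells"))
  pop <- build_cell_population(config, arch, profiles)
  timing["cells"] <- proc.time()[["elapsed"]] - t0 - sum(timing)

  sim <- list(config = config, f_c = arch$f_c,
              crypts = arch$crypts, crypts_table = crypt_table(arch$crypts),
              cells = pop$cells, counts = pop$counts,
              clusters = pop$clusters, skips = pop$skips,
              nucleus_masks = pop$nucleus_masks,
              cytoplasm_masks = pop$cytoplasm_masks,
              stromal_area_px = pop$stromal_area_px,
              perimeter_px = pop$perimeter_px,
              labels = list(crypt = arch$label))

  if (config$render == "full") {
    set.seed(stage_seed(config$seed, "textures"))
    if (is.null(bank)) {
      needed <- c(unique(vapply(arch$crypts, `[[`, "", "lumen_class")),
                  unique(profiles$sizes$texture_class[pop$cells$phenotype_id]))
      bank <- build_texture_bank(config, profiles, classes = needed)
    }
    ideal <- compose_ideal(config, arch, pop, bank, profiles)
    sim$channels_ideal <- list(nuclei = ideal$nuclei, cytoplasm = ideal$cytoplasm)
    sim$labels <- ideal$labels
    sim$goblets <- ideal$goblets
    timing["textures"] <- proc.time()[["elapsed"]] - t0 - sum(timing)

    set.seed(stage_seed(config$seed, "noise"))
    sim$channels <- list(
      nuclei = degrade(ideal$nuclei, config$psf_sigma, config$noise_variance),
      cytoplasm = degrade(ideal$cytoplasm, config$psf_sigma, config$noise_variance))
    rgb <- to_hne(sim$channels$nuclei, sim$channels$cytoplasm, config$stain_matrix)
    sim$rgb <- add_scalebar(rgb, config)
    timing["render"] <- proc.time()[["elapsed"]] - t0 - sum(timing)
  } else {
    # layout mode: build the instance label masks without texture synthesis
    i_h <- config$image_height; i_w <- config$image_width
    nuc_label <- matrix(0L, i_h, i_w); cyt_label <- matrix(0L, i_h, i_w)
    for (i in seq_len(nrow(pop$cells))) {
      cyt_label[pop$cytoplasm_masks[[i]]] <- pop$cells$cell_id[i]
      nuc_label[pop$nucleus_masks[[i]]] <- pop$cells$cell_id[i]
    }
    sim$labels <- list(nuclei = nuc_label, cytoplasm = cyt_label,
                       crypt = arch$label, lumen = arch$label > 0L,
                       goblet = matrix(FALSE, i_h, i_w))
  }
  sim$timing <- timing
  class(sim) <- "crypt_sim"
  sim
}

#' @export
print.crypt_sim <- function(x, ...) {
  cat(sprintf(
    "<crypt_sim> grade %d, %dx%d px: %d crypts (f_c %.3f), %d cells placed (%d epithelial, %d stromal requested, %d skipped)\n",
    x$config$grade, x$config$image_width, x$config$image_height,
    length(x$crypts), x$f_c, nrow(x$cells), x$counts$N_e, x$counts$N_s,
    nrow(x$skips)))
  invisible(x)
}

#' Generate a batch of simulations
#'
#' Runs `n_images` independent simulations; image `i` uses the derived seed
#' `derive_seed(master, i)` so batches are reproducible and extensible. A
#' texture bank is built once (full render) and shared. When `out_dir` is
#' given each image is written to `out_dir/image_###/` via
#' [write_outputs()] and a batch manifest is stored alongside.
#'
#' @param config a `sim_config` (its `seed` is the master seed).
#' @param n_images number of images (defaults to `config$n_images`).
#' @param out_dir optional output directory.
#' @param grade_params,profiles parameter tables.
#' @param progress print one line per image.
#' @return invisibly, the list of `crypt_sim` objects.
#' @export
generate_batch <- function(config, n_images = config$n_images, out_dir = NULL,
                           grade_params = default_grade_params(),
                           profiles = default_phenotype_profiles(),
                           progress = FALSE) {
  bank <- NULL
  if (config$render == "full") {
    set.seed(stage_seed(config$seed, "textures"))
    bank <- build_texture_bank(config, profiles)
  }
  sims <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, i)
    sims[[i]] <- simulate_image(cfg_i, grade_params, profiles, bank)
    if (progress)
      cat(sprintf("image %d/%d: %d cells, %d crypts, f_c=%.3f\n", i, n_images,
                  nrow(sims[[i]]$cells), length(sims[[i]]$crypts), sims[[i]]$f_c))
    if (!is.null(out_dir))
      write_outputs(sims[[i]], file.path(out_dir, sprintf("image_%03d", i)))
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(master_seed = config$seed, n_images = n_images,
           derived_seeds = vapply(seq_len(n_images),
                                  function(i) derive_seed(config$seed, i), 1L),
           config = config_manifest(config)),
      file.path(out_dir, "batch_manifest.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  invisible(sims)
}
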