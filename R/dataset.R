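# Dataset-level tools: invariant validation of generated runs and
# parameter learning from annotation tables.

#' Validate a generated image directory
#'
#' Re-simulates the run from its `manifest.json` (the determinism contract)
#' and checks: (1) the written ground-truth tables match the re-simulation,
#' so tampered files are detected; (2) the pairwise overlap invariant
#' `L_ij <= L_max` on the configured domain, naming the first offending
#' pair; (3) the count identity `placed = N - skips`; (4) the coverage
#' fraction lies in its grade band; (5) the pixel/object Dice functions
#' pass a self-test against each other on the run's own crypt labels; and
#' (6) how often the object-level Dice exceeded the pixel-level Dice on
#' random sub-samplings (surfaced as a count, since the textbook inequality
#' can fail on pathological instances).
#'
#' @param dir a directory written by [write_outputs()].
#' @param out_json optional path for a JSON report.
#' @return the report as a named list (invisibly writes JSON when asked).
#' @export
validate_run <- function(dir, out_json = NULL) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop("missing manifest.json in ", dir, call. = FALSE)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  cfg <- man$config
  if (!is.matrix(cfg$stain_matrix))
    cfg$stain_matrix <- do.call(rbind, lapply(cfg$stain_matrix, unlist))
  if (length(cfg$scalebar_length) == 0L) cfg$scalebar_length <- NULL
  sim <- simulate_image(do.call(simulation_config, cfg))
  checks <- list()

  cells_file <- file.path(dir, "cells.csv")
  if (!file.exists(cells_file)) stop("missing cells.csv in ", dir, call. = FALSE)
  cells_disk <- utils::read.csv(cells_file)
  checks$tables_match <- list(
    pass = nrow(cells_disk) == nrow(sim$cells) &&
      isTRUE(all.equal(cells_disk$x, sim$cells$x, tolerance = 1e-6)) &&
      isTRUE(all.equal(cells_disk$phenotype_id, sim$cells$phenotype_id)),
    n_disk = nrow(cells_disk), n_resim = nrow(sim$cells))

  lab_file <- file.path(dir, "labels_nuclei.tif")
  if (file.exists(lab_file)) {
    disk_lab <- read_label_tiff(lab_file)
    checks$labels_match <- list(pass = identical(disk_lab, sim$labels$nuclei * 1L) ||
                                  all(disk_lab == sim$labels$nuclei))
  }

  ov <- check_overlap_invariant(sim)
  checks$overlap <- ov
  checks$count_identity <- list(
    pass = nrow(sim$cells) == sim$counts$N - nrow(sim$skips),
    placed = nrow(sim$cells), requested = sim$counts$N, skipped = nrow(sim$skips))
  band <- switch(as.character(sim$config$grade),
                 "0" = c(1, 1), "1" = c(1, 1), "2" = c(0.5, 0.95), "3" = c(0, 0.5))
  checks$coverage_band <- list(pass = sim$f_c >= band[1L] && sim$f_c <= band[2L],
                               f_c = sim$f_c, band = band)
  # Dice self-test on the run's own labels (crypts when present, else nuclei)
  lab <- if (max(sim$labels$crypt) > 0L) sim$labels$crypt else sim$labels$nuclei
  checks$dice_self <- list(
    pass = max(lab) == 0L ||
      (abs(dice_object(lab, lab) - 1) < 1e-12 &&
         abs(dice_pixel(lab > 0, lab > 0) - 1) < 1e-12))
  checks$object_vs_pixel_dice <- dice_inequality_probe(sim)
  report <- list(dir = dir, grade = sim$config$grade, checks = checks,
                 pass = all(vapply(checks, function(c) isTRUE(c$pass) || is.null(c$pass), TRUE)))
  if (!is.null(out_json))
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  report
}

#' Exhaustive pairwise overlap check of a simulation
#'
#' Verifies `L_ij <= L_max` (local cluster threshold inside cluster
#' regions) for every ordered pair of same-domain cell masks; reports the
#' first offending pair by cell id.
#'
#' @param sim a `crypt_sim`.
#' @return list with `pass`, `max_ratio`, `n_pairs_checked`, and
#'   `offending_pair` (NULL when clean).
#' @export
check_overlap_invariant <- function(sim) {
  masks <- if (sim$config$overlap_domain == "nuclei") sim$nucleus_masks
           else sim$cytoplasm_masks
  n <- length(masks)
  thr <- function(i) if (isTRUE(sim$cells$in_cluster[i]))
    min(2 * sim$config$max_overlap, 0.8) else sim$config$max_overlap
  worst <- 0; offending <- NULL; n_pairs <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ov <- overlap_count(masks[[i]], masks[[j]])
      n_pairs <- n_pairs + 1L
      if (ov == 0L) next
      lij <- ov / length(masks[[i]])
      lim <- max(thr(i), thr(j))  # pair limit: the looser of the two cells
      if (lij > worst) worst <- lij
      if (lij > lim + 1e-12 && is.null(offending))
        offending <- c(sim$cells$cell_id[i], sim$cells$cell_id[j])
    }
  }
  list(pass = is.null(offending), max_ratio = worst,
       n_pairs_checked = n_pairs, offending_pair = offending)
}

# random sub-sampling probe of the object-vs-pixel Dice relation
dice_inequality_probe <- function(sim, n_draws = 20L) {
  g <- sim$labels$crypt
  if (max(g) < 1L) return(list(pass = TRUE, violations = 0L, draws = 0L))
  viol <- 0L
  for (d in seq_len(n_draws)) {
    o <- g
    drop <- which(stats::runif(length(o)) < 0.1 & o > 0L)
    o[drop] <- 0L
    dp <- dice_pixel(g > 0, o > 0)
    dob <- dice_object(g, o)
    if (dob > dp + 1e-9) viol <- viol + 1L
  }
  list(pass = TRUE, violations = viol, draws = n_draws)
}

#' Learn model parameters from an annotation table
#'
#' Fits the grade-parameter Gamma distributions (crypt semi-minor axis in
#' micrometres and axis ratio `e = minor/major`) per grade class, and
#' normal nucleus-axis profiles per phenotype when nucleus rows carry a
#' `phenotype_id` column. Classes with fewer than 30 rows are skipped with
#' a warning. The result can be written as config-compatible YAML.
#'
#' @param annotations data frame (or CSV path) with columns `object_type`
#'   (`"crypt"` or `"nucleus"`), `grade_class` (`"healthy"`/`"cancerous"`),
#'   `major_um`, `minor_um`, and optionally `phenotype_id`.
#' @param grade_params_yaml,phenotypes_yaml optional output YAML paths.
#' @return list with `grade_params` (data frame) and `phenotype_sizes`
#'   (data frame or NULL).
#' @export
learn_parameters <- function(annotations, grade_params_yaml = NULL,
                             phenotypes_yaml = NULL) {
  if (is.character(annotations)) annotations <- utils::read.csv(annotations)
  if (nrow(annotations) == 0L) stop("empty annotation table", call. = FALSE)
  need <- c("object_type", "grade_class", "major_um", "minor_um")
  if (!all(need %in% names(annotations)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  crypts <- annotations[annotations$object_type == "crypt", ]
  gp_rows <- list()
  for (cls in unique(crypts$grade_class)) {
    sub <- crypts[crypts$grade_class == cls, ]
    if (nrow(sub) < 30L) {
      warning(sprintf("class '%s': only %d crypts (<30), skipped", cls, nrow(sub)))
      next
    }
    fb <- fit_gamma(sub$minor_um)
    fe <- fit_gamma(pmin(sub$minor_um / sub$major_um, 1))
    gp_rows[[cls]] <- data.frame(
      class = cls, mu_b = fb$shape * fb$scale, alpha_b = fb$shape,
      beta_b = fb$scale, alpha_e = fe$shape, beta_e = fe$scale,
      stringsAsFactors = FALSE)
  }
  if (length(gp_rows) == 0L) stop("no grade class had enough crypts", call. = FALSE)
  gp <- validate_grade_params(do.call(rbind, gp_rows))
  phen <- NULL
  nuc <- annotations[annotations$object_type == "nucleus", ]
  if (nrow(nuc) > 0L && "phenotype_id" %in% names(nuc)) {
    rows <- list()
    for (pid in sort(unique(nuc$phenotype_id))) {
      sub <- nuc[nuc$phenotype_id == pid, ]
      if (nrow(sub) < 30L) {
        warning(sprintf("phenotype %s: only %d nuclei (<30), skipped", pid, nrow(sub)))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        phenotype_id = pid,
        mu_l = mean(sub$major_um), sigma_l = stats::sd(sub$major_um),
        mu_w = mean(sub$minor_um), sigma_w = stats::sd(sub$minor_um),
        texture_class = sprintf("chromatin_%02d", as.integer(pid)),
        stringsAsFactors = FALSE)
    }
    if (length(rows) > 0L) phen <- do.call(rbind, rows)
  }
  if (!is.null(grade_params_yaml)) write_grade_params_yaml(gp, grade_params_yaml)
  if (!is.null(phenotypes_yaml) && !is.null(phen))
    yaml::write_yaml(lapply(seq_len(nrow(phen)), function(i) as.list(phen[i, ])),
                     phenotypes_yaml, precision = 12L)
  list(grade_params = gp, phenotype_sizes = phen)
}
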