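# Cell population: counts from architecture + cellularity, compartment and
# phenotype assignment, and rejection placement under the overlap constraint.

#' Nominal area claimed by one stromal cell
#'
#' `A = pi ((1.7 - 0.7 L_max) r)^2`: the effective radius shrinks from
#' `1.7 r` (no overlap allowed, sparse packing) to `r` (unrestricted
#' overlap), strictly decreasing in `L_max` and never below `r`.
#'
#' @param L_max maximum overlap ratio in `[0, 1]`.
#' @param r_px cell radius in pixels.
#' @return area in pixels squared.
#' @export
stromal_cell_area <- function(L_max, r_px) {
  if (L_max < 0 || L_max > 1) fail_field("max_overlap", "must be in [0, 1]")
  if (r_px <= 0) fail_field("cell_radius", "must be > 0")
  pi * ((1.7 - 0.7 * L_max) * r_px)^2
}

#' Cell counts from the placed architecture
#'
#' `N_s = round(nu_s A_s / A)` with `A_s` the pixel count outside all crypt
#' outlines, and `N_e = round(nu_e P / (2 (1.25 - L_max) r))` with `P` the
#' summed crypt outline perimeters: epithelial cells are strung along the
#' gland boundaries at an overlap-dependent spacing, stromal cells fill the
#' remaining area.
#'
#' @param config a `sim_config`.
#' @param stromal_area_px pixels outside all crypts (`A_s`).
#' @param perimeter_px summed crypt perimeters (`P`).
#' @return list with `N_s`, `N_e`, `N`.
#' @export
cell_counts <- function(config, stromal_area_px, perimeter_px) {
  r_px <- microns_to_pixels(config$cell_radius, config)
  A <- stromal_cell_area(config$max_overlap, r_px)
  N_s <- if (stromal_area_px <= 0) 0L else
    as.integer(round(config$cellularity_stromal * stromal_area_px / A))
  N_e <- as.integer(round(config$cellularity_epithelial * perimeter_px /
                            (2 * (1.25 - config$max_overlap) * r_px)))
  list(N_s = N_s, N_e = N_e, N = N_s + N_e)
}

#' Pairwise overlap ratio of two pixel sets
#'
#' `L_ij = |R_i intersect R_j| / |R_i|`; asymmetric by definition.
#'
#' @param region_i,region_j integer vectors of linear pixel indices.
#' @return a fraction in `[0, 1]`.
#' @export
overlap_ratio <- function(region_i, region_j) {
  if (length(region_i) == 0L) fail_field("region_i", "must be non-empty")
  overlap_count(region_i, region_j) / length(region_i)
}

#' Rejection placement under the overlap constraint
#'
#' Draws candidate placements until one satisfies `L_ij <= local_L_max` and
#' `L_ji <= local_L_max` against every existing mask, or the attempt budget
#' is exhausted (the cell is then skipped; skipping is a logged outcome, not
#' an error). `L_max = 1` accepts the first candidate; `L_max = 0` forbids
#' any shared pixel.
#'
#' @param candidate_fn function of the attempt number returning an arbitrary
#'   candidate descriptor (e.g. a position).
#' @param mask_fn function mapping a candidate to its pixel-index mask.
#' @param neighbours_fn function mapping a candidate to the list of existing
#'   masks it must be checked against (pre-filtered for locality; return all
#'   masks for an exhaustive check).
#' @param local_L_max overlap threshold applying to this cell (cluster cells
#'   use `min(2 L_max, 0.8)`).
#' @param max_attempts attempt budget.
#' @return list with `candidate`, `mask`, `attempts`, or `NULL` when skipped.
#' @export
place_with_overlap_control <- function(candidate_fn, mask_fn, neighbours_fn,
                                       local_L_max, max_attempts = 100L) {
  for (t in seq_len(max_attempts)) {
    cand <- candidate_fn(t)
    mask <- mask_fn(cand)
    if (length(mask) == 0L) next
    ok <- TRUE
    if (local_L_max < 1) {
      for (nb in neighbours_fn(cand)) {
        ov <- overlap_count(mask, nb)
        if (ov > local_L_max * length(mask) || ov > local_L_max * length(nb)) {
          ok <- FALSE; break
        }
      }
    }
    if (ok) return(list(candidate = cand, mask = mask, attempts = t))
  }
  NULL
}

#' Assign subtype, phenotype and cluster membership to one cell
#'
#' Epithelial-compartment cells keep subtype `"epithelial"`. Stromal cells
#' in cancer grades become `"tumour"` with probability
#' `p_t(S) = min(slope * S, 1)` (tumour cells infiltrating the stroma,
#' increasing with grade), otherwise fibroblast or lymphocyte with equal
#' probability. In poorly differentiated tissue (`S = 3`) each stromal
#' tumour cell joins a cluster region with probability 0.5. The phenotype
#' is drawn from the (grade, compartment) frequency table.
#'
#' @param compartment `"epithelial"` or `"stromal"`.
#' @param grade differentiation grade 0-3.
#' @param profiles `phenotype_profiles`.
#' @param tumour_prob_per_grade slope of `p_t(S)`.
#' @return list with `subtype`, `phenotype_id`, `in_cluster`.
#' @export
assign_subtype_and_phenotype <- function(compartment, grade, profiles,
                                         tumour_prob_per_grade = 0.2) {
  p <- profiles$freq[, grade + 1L, compartment]
  if (sum(p) <= 0)
    fail_field("phenotype_profiles",
               sprintf("missing frequency table for grade %d, %s", grade, compartment))
  phen <- sample.int(length(p), 1L, prob = p)
  in_cluster <- FALSE
  if (compartment == "epithelial") {
    subtype <- "epithelial"
  } else {
    p_t <- min(tumour_prob_per_grade * grade, 1)
    if (grade > 0L && stats::runif(1) < p_t) {
      subtype <- "tumour"
      if (grade == 3L) in_cluster <- stats::runif(1) < 0.5
    } else {
      subtype <- if (stats::runif(1) < 0.5) "fibroblast" else "lymphocyte"
    }
  }
  list(subtype = subtype, phenotype_id = phen, in_cluster = in_cluster)
}

#' One epithelial placement candidate on a crypt outline
#'
#' A point `(x0, y0)` is drawn uniformly by arc length on the outline and
#' displaced per coordinate by `r S U(-0.25, 0.08)`, so healthy cells sit
#' exactly on the boundary and higher grades scatter, preferentially
#' inwards. The orientation points towards the crypt centre.
#'
#' @param crypt a crypt record from [place_crypts()].
#' @param grade differentiation grade.
#' @param r_px cell radius in pixels.
#' @return list with `position`, `orientation`, `outline_point`.
#' @export
epithelial_candidate <- function(crypt, grade, r_px, i_h = Inf, i_w = Inf) {
  ol <- crypt$outline
  seg <- sqrt(diff(ol[, 1L])^2 + diff(ol[, 2L])^2)
  if (is.finite(i_h)) {
    # seed only on the visible part of the gland boundary
    mx <- (ol[-1L, 1L] + ol[-nrow(ol), 1L]) / 2
    my <- (ol[-1L, 2L] + ol[-nrow(ol), 2L]) / 2
    seg[!(mx >= 0.5 & mx <= i_w + 0.5 & my >= 0.5 & my <= i_h + 0.5)] <- 0
  }
  cs <- cumsum(seg)
  s <- stats::runif(1, 0, cs[length(cs)])
  i <- findInterval(s, cs) + 1L
  i <- min(i, length(seg))
  frac <- (s - if (i > 1L) cs[i - 1L] else 0) / seg[i]
  p0 <- ol[i, ] + frac * (ol[i + 1L, ] - ol[i, ])
  u <- stats::runif(2, -0.25, 0.08)
  pos <- p0 + r_px * grade * u
  if (is.finite(i_h)) pos <- pmin(pmax(pos, 1), c(i_w, i_h))
  orient <- atan2(crypt$centre[2L] - pos[2L], crypt$centre[1L] - pos[1L])
  list(position = as.numeric(pos), orientation = orient,
       outline_point = as.numeric(p0))
}

#' Sample epithelial positions and orientations for one crypt
#'
#' Convenience wrapper drawing `count` independent candidates (no overlap
#' control; the full pipeline applies it mask-wise).
#'
#' @inheritParams epithelial_candidate
#' @param count number of cells.
#' @return data frame with `x`, `y`, `orientation`, `x0`, `y0`.
#' @export
place_epithelial <- function(crypt, count, grade, r_px) {
  draws <- lapply(seq_len(count), function(i) epithelial_candidate(crypt, grade, r_px))
  data.frame(
    x = vapply(draws, function(d) d$position[1L], 1),
    y = vapply(draws, function(d) d$position[2L], 1),
    orientation = vapply(draws, `[[`, 1, "orientation"),
    x0 = vapply(draws, function(d) d$outline_point[1L], 1),
    y0 = vapply(draws, function(d) d$outline_point[2L], 1))
}

#' Sample stromal positions and orientations
#'
#' Positions are uniform over the stromal pixels (outside every crypt);
#' orientations follow the dominant tissue direction `phi` with a
#' `U(-pi/6, pi/6)` spread. An empty stromal region reduces the count to 0
#' with a warning.
#'
#' @param count number of cells.
#' @param stroma_idx linear indices of stromal pixels.
#' @param phi_dominant dominant direction in radians.
#' @param i_h image height.
#' @return data frame with `x`, `y`, `orientation`.
#' @export
place_stromal <- function(count, stroma_idx, phi_dominant, i_h) {
  if (length(stroma_idx) == 0L) {
    if (count > 0L) warning("empty stromal region: stromal count reduced to 0")
    return(data.frame(x = numeric(0), y = numeric(0), orientation = numeric(0)))
  }
  pick <- stroma_idx[sample.int(length(stroma_idx), count, replace = TRUE)]
  xy <- index_to_xy(pick, i_h)
  data.frame(x = xy[, 1L], y = xy[, 2L],
             orientation = phi_dominant + stats::runif(count, -pi / 6, pi / 6))
}

# ---------------------------------------------------------------------------

#' Build the full cell population for a placed architecture
#'
#' Allocates epithelial cells to crypts proportionally to outline perimeter,
#' assigns subtypes and phenotypes, samples per-cell geometry, and places
#' every cell under the overlap constraint (on the configured domain,
#' nuclei or cytoplasm). Stromal tumour cells in grade-3 tissue may join
#' cluster regions (`10 r` squares with local threshold
#' `min(2 L_max, 0.8)`). Cells that cannot be placed within the attempt
#' budget are skipped and logged.
#'
#' @param config a `sim_config`.
#' @param arch architecture from [place_crypts()].
#' @param profiles `phenotype_profiles`.
#' @return list with `cells` (ground-truth data frame), `nucleus_masks`,
#'   `cytoplasm_masks` (lists of pixel-index vectors), `counts`, `clusters`
#'   (data frame of cluster squares), and `skips` (data frame log).
#' @export
build_cell_population <- function(config, arch,
                                  profiles = default_phenotype_profiles()) {
  i_h <- config$image_height; i_w <- config$image_width
  S <- config$grade
  r_px <- microns_to_pixels(config$cell_radius, config)
  spp <- specimen_pixel_size(config)
  crypts <- arch$crypts
  stroma_idx <- which(arch$label == 0L)
  A_s <- length(stroma_idx)
  # N_e uses the nominal (elliptical) gland perimeter: the grade-dependent
  # outline deformation should change the boundary's look, not the number
  # of cells strung along it
  P <- sum(vapply(crypts, `[[`, 1, "perimeter_nominal"))
  counts <- cell_counts(config, A_s, P)
  N_e <- if (length(crypts) == 0L) 0L else counts$N_e
  N_s <- counts$N_s
  if (A_s == 0L && counts$N_s > 0L) {
    warning("empty stromal region: stromal count reduced to 0")
    N_s <- 0L
  }

  # dominant stromal direction: circular mean of crypt rotations
  phi_dom <- if (length(crypts) > 0L) {
    phis <- vapply(crypts, `[[`, 1, "phi")
    atan2(mean(sin(phis)), mean(cos(phis)))
  } else stats::runif(1, 0, 2 * pi)

  # epithelial allocation proportional to perimeter, exact total
  alloc <- integer(length(crypts))
  if (N_e > 0L && length(crypts) > 0L) {
    share <- vapply(crypts, `[[`, 1, "perimeter_nominal") / P
    cum <- round(cumsum(share) * N_e)
    alloc <- as.integer(diff(c(0, cum)))
  }

  # grade-3 cluster regions, one per ~8 expected members
  clusters <- data.frame(x = numeric(0), y = numeric(0), side = numeric(0))
  if (S == 3L && N_s > 0L && A_s > 0L) {
    expected_members <- N_s * min(config$tumour_prob_per_grade * S, 1) * 0.5
    n_cl <- max(1L, as.integer(ceiling(expected_members / 8)))
    ctr <- index_to_xy(stroma_idx[sample.int(A_s, n_cl, replace = TRUE)], i_h)
    clusters <- data.frame(x = ctr[, 1L], y = ctr[, 2L], side = 10 * r_px)
  }

  use_nuclei <- config$overlap_domain == "nuclei"
  n_total <- N_e + N_s
  placed_x <- numeric(0); placed_y <- numeric(0); placed_reach <- numeric(0)
  domain_masks <- vector("list", n_total)
  n_placed <- 0L
  rows <- vector("list", n_total)
  nucleus_masks <- vector("list", n_total)
  cytoplasm_masks <- vector("list", n_total)
  skips <- list()
  sizes_px <- profiles$sizes
  sizes_px[c("mu_l", "sigma_l", "mu_w", "sigma_w")] <-
    sizes_px[c("mu_l", "sigma_l", "mu_w", "sigma_w")] / spp

  neighbours_for <- function(pos, reach) {
    if (n_placed == 0L) return(list())
    sel <- which(abs(placed_x - pos[1L]) <= placed_reach + reach &
                   abs(placed_y - pos[2L]) <= placed_reach + reach)
    domain_masks[sel]
  }

  make_cell <- function(compartment, crypt_id, candidate_fn, orientation_fixed) {
    asn <- assign_subtype_and_phenotype(compartment, S, profiles,
                                        config$tumour_prob_per_grade)
    ph <- sizes_px[asn$phenotype_id, ]
    nuc <- sample_nucleus_axes(ph$mu_l, ph$sigma_l, ph$mu_w, ph$sigma_w)
    cyt <- cytoplasm_axes(nuc, config$independent_cyto_factors)
    sc <- rescale_stromal(asn$subtype, nuc, cyt)
    nuc <- sc$nucleus_axes; cyt <- sc$cytoplasm_axes
    alpha <- shape_alpha(S)
    nuc_poly <- random_polygon(config$k_polygon, alpha, config$beta_shape)
    cyt_poly <- if (asn$subtype == "epithelial") epithelial_template()
                else random_polygon(config$k_polygon, alpha, config$beta_shape)
    local_L <- if (asn$in_cluster) min(2 * config$max_overlap, 0.8)
               else config$max_overlap
    # cluster members draw positions inside their cluster square
    cluster_id <- NA_integer_
    cand_fn <- candidate_fn
    if (asn$in_cluster && nrow(clusters) > 0L) {
      cluster_id <- sample.int(nrow(clusters), 1L)
      cl <- clusters[cluster_id, ]
      half <- cl$side / 2
      cand_fn <- function(t) {
        pos <- c(stats::runif(1, cl$x - half, cl$x + half),
                 stats::runif(1, cl$y - half, cl$y + half))
        pos <- pmin(pmax(pos, 1), c(i_w, i_h))
        list(position = pos, orientation = orientation_fixed())
      }
    }
    reach <- max(cyt) * (1 + alpha)
    basal_shift <- if (compartment == "epithelial" && S < 2L) 0.25 * cyt[["l"]] else 0
    contained <- asn$subtype %in% c("epithelial", "lymphocyte", "tumour")
    nucleus_centre <- function(cand, shift) {
      if (shift == 0) return(cand$position)
      # displace the nucleus outwards (towards the crypt edge): basal
      # orientation of low-grade epithelium
      cand$position + shift * c(-cos(cand$orientation), -sin(cand$orientation))
    }
    # rasterize both compartments for a candidate; the nucleus of a
    # contained subtype is clipped to its cytoplasm *before* the overlap
    # check, so the committed masks are exactly the checked ones
    last_masks <- NULL
    build_masks <- function(cand) {
      nc <- nucleus_centre(cand, basal_shift)
      nuc_mask <- scale_and_close(nuc_poly, nuc[["l"]], nuc[["w"]],
                                  cand$orientation, nc, i_h, i_w)$mask
      cyt_mask <- scale_and_close(cyt_poly, cyt[["l"]], cyt[["w"]],
                                  cand$orientation, cand$position, i_h, i_w)$mask
      if (contained) nuc_mask <- nuc_mask[nuc_mask %in% cyt_mask]
      last_masks <<- list(nucleus = nuc_mask, cytoplasm = cyt_mask)
      last_masks
    }
    mask_fn <- function(cand) {
      m <- build_masks(cand)
      if (use_nuclei) m$nucleus else m$cytoplasm
    }
    res <- place_with_overlap_control(
      cand_fn, mask_fn,
      function(cand) neighbours_for(cand$position, reach),
      local_L, config$max_attempts)
    if (is.null(res)) {
      return(list(skip = list(compartment = compartment, subtype = asn$subtype,
                              reason = "overlap budget exhausted")))
    }
    cand <- res$candidate
    nc <- nucleus_centre(cand, basal_shift)
    nuc_mask <- last_masks$nucleus
    cyt_mask <- last_masks$cytoplasm
    if (length(nuc_mask) == 0L || length(cyt_mask) == 0L) {
      return(list(skip = list(compartment = compartment, subtype = asn$subtype,
                              reason = "degenerate raster")))
    }
    list(row = data.frame(
      compartment = compartment, subtype = asn$subtype,
      phenotype_id = asn$phenotype_id,
      x = cand$position[1L], y = cand$position[2L],
      orientation_rad = cand$orientation,
      nucleus_l_px = nuc[["l"]], nucleus_w_px = nuc[["w"]],
      cytoplasm_l_px = cyt[["l"]], cytoplasm_w_px = cyt[["w"]],
      nucleus_x = nc[1L], nucleus_y = nc[2L],
      in_cluster = asn$in_cluster, cluster_id = cluster_id,
      crypt_id = crypt_id, attempts = res$attempts,
      stringsAsFactors = FALSE),
      nuc_mask = nuc_mask, cyt_mask = cyt_mask,
      domain_mask = if (use_nuclei) nuc_mask else cyt_mask, reach = reach)
  }

  commit <- function(cell) {
    n_placed <<- n_placed + 1L
    rows[[n_placed]] <<- cell$row
    nucleus_masks[[n_placed]] <<- cell$nuc_mask
    cytoplasm_masks[[n_placed]] <<- cell$cyt_mask
    domain_masks[[n_placed]] <<- cell$domain_mask
    placed_x[n_placed] <<- cell$row$x
    placed_y[n_placed] <<- cell$row$y
    placed_reach[n_placed] <<- cell$reach
  }

  for (ci in seq_along(crypts)) {
    crypt <- crypts[[ci]]
    for (k in seq_len(alloc[ci])) {
      cell <- make_cell("epithelial", crypt$id,
                        function(t) epithelial_candidate(crypt, S, r_px, i_h, i_w),
                        NULL)
      if (!is.null(cell$skip)) skips[[length(skips) + 1L]] <- cell$skip
      else commit(cell)
    }
  }
  if (N_s > 0L && A_s > 0L) {
    for (k in seq_len(N_s)) {
      orient_fn <- function() phi_dom + stats::runif(1, -pi / 6, pi / 6)
      orientation <- orient_fn()
      cell <- make_cell("stromal", NA_integer_,
                        function(t) {
                          pick <- stroma_idx[sample.int(A_s, 1L)]
                          xy <- index_to_xy(pick, i_h)
                          list(position = c(xy[1L, 1L], xy[1L, 2L]),
                               orientation = orientation)
                        },
                        orient_fn)
      if (!is.null(cell$skip)) skips[[length(skips) + 1L]] <- cell$skip
      else commit(cell)
    }
  }

  cells <- if (n_placed > 0L) {
    df <- do.call(rbind, rows[seq_len(n_placed)])
    df <- cbind(cell_id = seq_len(n_placed), df)
    df
  } else data.frame(cell_id = integer(0))
  skips_df <- if (length(skips) > 0L)
    do.call(rbind, lapply(skips, as.data.frame)) else
    data.frame(compartment = character(0), subtype = character(0),
               reason = character(0))
  list(cells = cells,
       nucleus_masks = nucleus_masks[seq_len(n_placed)],
       cytoplasm_masks = cytoplasm_masks[seq_len(n_placed)],
       counts = counts, clusters = clusters, skips = skips_df,
       stromal_area_px = A_s, perimeter_px = P)
}
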