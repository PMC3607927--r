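#' Geometry parameters for synthetic cells
#'
#' Describes the population of star-convex cells drawn by [generate_cell()].
#' Cell outlines are radial perturbations of a circle: low-order harmonics
#' (orders 2-5) modulate the base radius, which mimics the smooth, slightly
#' irregular outline of an adherent cell. The base radius is drawn so that
#' every realized boundary radius stays inside `radius_range`.
#'
#' @param radius_range Length-2 numeric, min/max boundary radius in pixels.
#' @param irregularity_range Length-2 numeric in `[0, 0.5)`: the maximum
#'   relative radial perturbation is drawn uniformly from this range
#'   (0 gives a perfect circle).
#' @param membrane_band_width True width of the membrane annulus, pixels.
#' @param expression_range Length-2 numeric, mean receptor-channel intensity
#'   (arbitrary counts) of the membrane band.
#' @param n_puncta Number of QD puncta per cell.
#' @param n_theta Angular samples used to store the radial profile.
#' @return A `cell_geometry` list.
#' @export
cell_geometry <- function(radius_range = c(26, 36),
                          irregularity_range = c(0.02, 0.12),
                          membrane_band_width = 3,
                          expression_range = c(800, 1200),
                          n_puncta = 40,
                          n_theta = 256) {
  stopifnot(
    length(radius_range) == 2, radius_range[1] > 0,
    radius_range[2] >= radius_range[1],
    length(irregularity_range) == 2,
    irregularity_range[1] >= 0, irregularity_range[2] < 0.5,
    membrane_band_width >= 1, n_puncta >= 0, n_theta >= 16
  )
  structure(
    list(
      radius_range = radius_range,
      irregularity_range = irregularity_range,
      membrane_band_width = membrane_band_width,
      expression_range = expression_range,
      n_puncta = n_puncta,
      n_theta = n_theta
    ),
    class = "cell_geometry"
  )
}

#' Imaging noise specification
#'
#' @param background_level Additive background, counts (per channel).
#' @param read_noise_sd Gaussian read noise standard deviation, counts.
#' @param shot_noise Logical; apply Poisson shot noise to signal+background.
#' @param psf_sigma Gaussian point-spread sigma in pixels, applied to the
#'   receptor signal and to each QD punctum.
#' @return An `imaging_noise` list.
#' @export
imaging_noise <- function(background_level = 100,
                          read_noise_sd = 5,
                          shot_noise = TRUE,
                          psf_sigma = 1.5) {
  stopifnot(background_level >= 0, read_noise_sd >= 0, psf_sigma >= 0)
  structure(
    list(
      background_level = background_level,
      read_noise_sd = read_noise_sd,
      shot_noise = isTRUE(shot_noise),
      psf_sigma = psf_sigma
    ),
    class = "imaging_noise"
  )
}

#' Generate one ground-truth synthetic cell
#'
#' Draws a star-convex cell: a base radius, an irregularity amplitude and
#' random harmonic phases (orders 2-5), normalized so the maximum relative
#' perturbation equals the drawn irregularity. The base radius is sampled
#' from the sub-interval of `radius_range` that keeps all realized radii
#' within `radius_range`.
#'
#' @param geometry A [cell_geometry()].
#' @param seed Integer seed; the same seed reproduces the identical cell.
#' @param field_shape Length-2 integer (rows, cols) the cell must fit into.
#' @param center Optional (row, col) center; drawn uniformly inside the
#'   field (with a margin keeping the whole cell inside) when `NULL`.
#' @param allow_border Logical; if `TRUE` the center may fall so close to
#'   the field edge that the boundary is clipped, and the cell is flagged
#'   `border_touching`.
#' @param cell_id Identifier stored in the result.
#' @return A `cell_truth` list with fields `cell_id`, `center`, `theta`,
#'   `radii`, `membrane_band_width`, `expression_level`,
#'   `true_interior_fraction` (filled at render time), `n_puncta`, `seed`,
#'   `border_touching`.
#' @export
generate_cell <- function(geometry = cell_geometry(), seed,
                          field_shape = c(256, 256), center = NULL,
                          allow_border = FALSE, cell_id = 1L) {
  stopifnot(inherits(geometry, "cell_geometry"), length(field_shape) == 2)
  rmin <- geometry$radius_range[1]
  rmax <- geometry$radius_range[2]
  if (2 * rmax >= min(field_shape)) {
    abort("requested cell radius does not fit in the field")
  }
  withr::with_seed(seed, {
    irr <- runif(1, geometry$irregularity_range[1], geometry$irregularity_range[2])
    r_lo <- rmin / max(1 - irr, 1e-6)
    r_hi <- rmax / (1 + irr)
    base_r <- runif(1, min(r_lo, r_hi), max(r_lo, r_hi))
    theta <- seq(0, 2 * pi, length.out = geometry$n_theta + 1)[-(geometry$n_theta + 1)]
    pert <- rep(0, length(theta))
    if (irr > 0) {
      for (m in 2:5) {
        pert <- pert + rnorm(1) * cos(m * theta) + rnorm(1) * sin(m * theta)
      }
      amp <- max(abs(pert))
      if (amp > 0) pert <- pert / amp * irr
    } else {
      rnorm(8) # keep the RNG stream aligned with the irregular branch
    }
    radii <- base_r * (1 + pert)
    expr <- runif(1, geometry$expression_range[1], geometry$expression_range[2])
    margin <- max(radii) + 1
    border <- FALSE
    if (is.null(center)) {
      if (allow_border) {
        center <- c(runif(1, 1, field_shape[1]), runif(1, 1, field_shape[2]))
      } else {
        center <- c(
          runif(1, margin, field_shape[1] - margin + 1),
          runif(1, margin, field_shape[2] - margin + 1)
        )
      }
    }
    border <- (center[1] - margin < 0 || center[1] + margin > field_shape[1] + 1 ||
      center[2] - margin < 0 || center[2] + margin > field_shape[2] + 1)
    if (border && !allow_border) {
      abort("cell does not fit inside the field at the requested center")
    }
    structure(
      list(
        cell_id = cell_id, center = center, theta = theta, radii = radii,
        membrane_band_width = geometry$membrane_band_width,
        expression_level = expr, true_interior_fraction = NA_real_,
        n_puncta = geometry$n_puncta, seed = seed,
        border_touching = border
      ),
      class = "cell_truth"
    )
  })
}

#' Rasterize a synthetic cell into ground-truth masks
#'
#' @param cell A `cell_truth` from [generate_cell()].
#' @param field_shape Length-2 integer (rows, cols).
#' @param endosomal_zone_fraction Radial fraction of the cell defining the
#'   perinuclear endosomal zone that holds internalized puncta (internalized
#'   cargo accumulates in endosomes well inside the cell, away from the
#'   plasma membrane).
#' @return List of logical matrices `cell`, `membrane` (true annulus of
#'   width `membrane_band_width`), `interior` and `endosomal` (pixels
#'   within `endosomal_zone_fraction` of the boundary radius).
#' @export
rasterize_cell <- function(cell, field_shape, endosomal_zone_fraction = 0.6) {
  stopifnot(inherits(cell, "cell_truth"))
  nr <- field_shape[1]
  nc <- field_shape[2]
  rows <- matrix(seq_len(nr), nr, nc) - cell$center[1]
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cell$center[2]
  dist <- sqrt(rows^2 + cols^2)
  ang <- atan2(cols, rows) %% (2 * pi)
  # periodic linear interpolation of the radial profile
  th <- c(cell$theta, 2 * pi)
  rr <- c(cell$radii, cell$radii[1])
  r_at <- stats::approx(th, rr, xout = as.vector(ang), rule = 2)$y
  r_at <- matrix(r_at, nr, nc)
  cell_mask <- dist <= r_at
  interior <- dist <= (r_at - cell$membrane_band_width)
  # inner half of the band: where membrane-bound puncta are centered, so
  # their blurred flux stays on cell pixels (as in real membrane staining,
  # which images as a band just inside the segmented outline)
  inner_half <- !interior & dist <= (r_at - cell$membrane_band_width / 2)
  list(
    cell = cell_mask, membrane = cell_mask & !interior, interior = interior,
    membrane_inner = inner_half,
    endosomal = dist <= endosomal_zone_fraction * r_at
  )
}

# Add one Gaussian punctum (total flux `flux`, sigma `sigma`) at a subpixel
# position; the discretized kernel is normalized over its 4-sigma support so
# rendered flux is conserved exactly unless clipped by the field edge.
add_punctum <- function(img, row, col, flux, sigma) {
  if (sigma <= 0) {
    r <- round(row)
    c <- round(col)
    if (r >= 1 && r <= nrow(img) && c >= 1 && c <= ncol(img)) {
      img[r, c] <- img[r, c] + flux
    }
    return(img)
  }
  half <- ceiling(4 * sigma)
  rs <- max(1, round(row) - half):min(nrow(img), round(row) + half)
  cs <- max(1, round(col) - half):min(ncol(img), round(col) + half)
  w <- exp(-outer((rs - row)^2, (cs - col)^2, "+") / (2 * sigma^2))
  full <- sum(exp(-((-half:half) - (row - round(row)))^2 / (2 * sigma^2))) *
    sum(exp(-((-half:half) - (col - round(col)))^2 / (2 * sigma^2)))
  img[rs, cs] <- img[rs, cs] + flux * w / full
  img
}

#' Render a two-channel synthetic field
#'
#' Builds the receptor channel (membrane annulus at the cell's expression
#' level plus a dimmer cytoplasmic haze, blurred by the PSF) and the QD
#' channel (point sources partitioned between interior and membrane band
#' according to each cell's interior fraction), then adds background, shot
#' noise and read noise. Internalized puncta are placed uniformly in the
#' perinuclear endosomal zone (the inner `endosomal_zone_fraction` of the
#' cell radius), mimicking endosomal accumulation of internalized cargo;
#' surface puncta are placed uniformly on the true membrane band.
#'
#' @param cells List of `cell_truth` objects (non-overlapping).
#' @param fractions Numeric vector, one interior fraction in `[0, 1]` per
#'   cell; the number of interior puncta is binomial(`n_puncta`, fraction).
#' @param noise An [imaging_noise()].
#' @param field_shape Length-2 integer (rows, cols).
#' @param seed Integer seed (placement and noise).
#' @param field_id,ligand,time_min Metadata copied into the result.
#' @param punctum_flux Total flux per punctum, counts.
#' @param haze_fraction Cytoplasmic receptor haze relative to the membrane
#'   band intensity.
#' @param endosomal_zone_fraction Passed to [rasterize_cell()]; radial
#'   fraction of the cell holding internalized puncta.
#' @param allow_overlap Logical; if `FALSE` (default) overlapping cells are
#'   an error.
#' @return List with `field` (a [field_of_view()]) and `truth` (one-row-per-
#'   cell tibble: identifiers, nominal and realized interior fraction, true
#'   per-compartment punctum flux, expression level).
#' @export
render_field <- function(cells, fractions, noise = imaging_noise(),
                         field_shape = c(256, 256), seed,
                         field_id = "F1", ligand = NA_character_,
                         time_min = NA_real_, punctum_flux = 2200,
                         haze_fraction = 0.3, endosomal_zone_fraction = 0.6,
                         allow_overlap = FALSE) {
  stopifnot(length(cells) == length(fractions), all(fractions >= 0), all(fractions <= 1))
  if (length(cells) >= 2 && !allow_overlap) {
    for (i in seq_along(cells)) {
      for (j in seq_len(i - 1)) {
        d <- sqrt(sum((cells[[i]]$center - cells[[j]]$center)^2))
        if (d <= max(cells[[i]]$radii) + max(cells[[j]]$radii)) {
          abort("cells overlap; regenerate placement or set allow_overlap = TRUE")
        }
      }
    }
  }
  nr <- field_shape[1]
  nc <- field_shape[2]
  receptor <- matrix(0, nr, nc)
  qd <- matrix(0, nr, nc)
  truth <- vector("list", length(cells))
  withr::with_seed(seed, {
    for (i in seq_along(cells)) {
      cell <- cells[[i]]
      masks <- rasterize_cell(cell, field_shape, endosomal_zone_fraction)
      receptor[masks$membrane] <- receptor[masks$membrane] + cell$expression_level
      receptor[masks$interior] <- receptor[masks$interior] +
        haze_fraction * cell$expression_level
      n_int <- rbinom(1, cell$n_puncta, fractions[i])
      n_mem <- cell$n_puncta - n_int
      int_px <- which(masks$endosomal)
      if (length(int_px) == 0) int_px <- which(masks$interior)
      mem_px <- which(masks$membrane_inner)
      if (length(mem_px) == 0) mem_px <- which(masks$membrane)
      place <- function(n, px) {
        if (n == 0 || length(px) == 0) {
          return(matrix(numeric(0), 0, 2))
        }
        idx <- px[sample.int(length(px), n, replace = TRUE)]
        cbind(
          ((idx - 1) %% nr) + 1 + runif(n, -0.5, 0.5),
          ((idx - 1) %/% nr) + 1 + runif(n, -0.5, 0.5)
        )
      }
      pts <- rbind(place(n_int, int_px), place(n_mem, mem_px))
      for (k in seq_len(nrow(pts))) {
        qd <- add_punctum(qd, pts[k, 1], pts[k, 2], punctum_flux, noise$psf_sigma)
      }
      truth[[i]] <- tibble(
        field_id = field_id, cell_id = cell$cell_id, ligand = ligand,
        time_min = time_min, true_interior_fraction = fractions[i],
        realized_interior_fraction = if (cell$n_puncta > 0) n_int / cell$n_puncta else NA_real_,
        true_interior_flux = n_int * punctum_flux,
        true_membrane_flux = n_mem * punctum_flux,
        n_puncta = cell$n_puncta, expression_level = cell$expression_level,
        center_row = cell$center[1], center_col = cell$center[2],
        max_radius = max(cell$radii), seed = cell$seed
      )
    }
    if (noise$psf_sigma > 0) {
      receptor <- as.matrix(EBImage::gblur(receptor, sigma = noise$psf_sigma))
    }
    receptor <- receptor + noise$background_level
    qd <- qd + noise$background_level
    if (noise$shot_noise) {
      receptor <- matrix(rpois(length(receptor), receptor), nr, nc)
      qd <- matrix(rpois(length(qd), qd), nr, nc)
    }
    if (noise$read_noise_sd > 0) {
      receptor <- receptor + matrix(rnorm(length(receptor), 0, noise$read_noise_sd), nr, nc)
      qd <- qd + matrix(rnorm(length(qd), 0, noise$read_noise_sd), nr, nc)
    }
    receptor <- pmax(receptor, 0)
    qd <- pmax(qd, 0)
  })
  list(
    field = field_of_view(receptor, qd,
      field_id = field_id, ligand = ligand, time_min = time_min
    ),
    truth = dplyr::bind_rows(truth)
  )
}

# Deterministic dart-throwing placement of n non-overlapping cells.
place_cells <- function(geometry, n_cells, field_shape, seed, max_tries = 2000) {
  cells <- list()
  withr::with_seed(seed, {
    seeds <- sample.int(2^30, n_cells + max_tries)
  })
  tries <- 0
  k <- 1
  while (length(cells) < n_cells && tries < max_tries) {
    tries <- tries + 1
    cand <- generate_cell(geometry,
      seed = seeds[k], field_shape = field_shape,
      cell_id = length(cells) + 1L
    )
    k <- k + 1
    ok <- TRUE
    # keep blurred halos from bridging neighbours into one component
    for (c2 in cells) {
      d <- sqrt(sum((cand$center - c2$center)^2))
      if (d <= max(cand$radii) + max(c2$radii) + 12) {
        ok <- FALSE
        break
      }
    }
    if (ok) cells[[length(cells) + 1]] <- cand
  }
  if (length(cells) < n_cells) {
    abort("could not place the requested number of non-overlapping cells")
  }
  cells
}

#' Configuration for a synthetic imaging dataset
#'
#' Defaults describe the emulated study conditions: two ligands with
#' power-logistic internalization kinetics mirroring the measured IGF-II and
#' insulin time courses through IR-B, imaged at 0, 10, 20 and 150 minutes at
#' 37 degrees C, with about 20 analyzable cells per ligand x time condition.
#'
#' @param ligands Named list of [kinetics_spec()] objects.
#' @param times Numeric vector of times (minutes at 37 degrees C).
#' @param fields_per_time,cells_per_field Integers.
#' @param geometry A [cell_geometry()].
#' @param noise An [imaging_noise()].
#' @param punctum_flux Flux per QD punctum, counts.
#' @param field_shape Length-2 integer.
#' @param seed Master seed.
#' @return An `image_dataset_config` list.
#' @export
image_dataset_config <- function(ligands = list(
                                   "IGF-II" = kinetics_spec(0.17, 0.96, 9.6, 1.2),
                                   "insulin" = kinetics_spec(0.06, 0.95, 24, 1.2)
                                 ),
                                 times = c(0, 10, 20, 150),
                                 fields_per_time = 5,
                                 cells_per_field = 4,
                                 geometry = cell_geometry(),
                                 noise = imaging_noise(),
                                 punctum_flux = 2200,
                                 field_shape = c(256, 256),
                                 seed = 1L) {
  if (length(times) == 0) abort("times must be a non-empty vector")
  stopifnot(
    length(ligands) >= 1, !is.null(names(ligands)),
    all(vapply(ligands, inherits, logical(1), "kinetics_spec")),
    fields_per_time >= 1, cells_per_field >= 1
  )
  structure(
    list(
      ligands = ligands, times = times, fields_per_time = fields_per_time,
      cells_per_field = cells_per_field, geometry = geometry, noise = noise,
      punctum_flux = punctum_flux, field_shape = field_shape,
      seed = as.integer(seed)
    ),
    class = "image_dataset_config"
  )
}

#' Generate a full synthetic imaging dataset
#'
#' Produces fields across every ligand x time combination of the
#' configuration. Per-cell interior fractions follow each ligand's
#' [interior_fraction_timecourse()]. Deterministic for a fixed config.
#'
#' @param config An [image_dataset_config()].
#' @return An `image_dataset` list: `fields` (named list of
#'   [field_of_view()]) and `truth` (the per-cell manifest tibble).
#' @export
generate_image_dataset <- function(config = image_dataset_config()) {
  stopifnot(inherits(config, "image_dataset_config"))
  fields <- list()
  truth <- list()
  counter <- 0L
  for (lig in names(config$ligands)) {
    spec <- config$ligands[[lig]]
    for (tm in config$times) {
      f_nominal <- interior_fraction_timecourse(spec, tm)
      for (fi in seq_len(config$fields_per_time)) {
        counter <- counter + 1L
        fseed <- (config$seed + 104729L * counter) %% 2147483647L
        fid <- sprintf("%s_t%03d_f%02d", gsub("[^A-Za-z0-9]", "", lig), round(tm), fi)
        cells <- place_cells(
          config$geometry, config$cells_per_field,
          config$field_shape,
          seed = fseed
        )
        out <- render_field(cells,
          fractions = rep(f_nominal, length(cells)),
          noise = config$noise, field_shape = config$field_shape,
          seed = fseed + 1L, field_id = fid, ligand = lig, time_min = tm,
          punctum_flux = config$punctum_flux
        )
        fields[[fid]] <- out$field
        truth[[fid]] <- out$truth
      }
    }
  }
  structure(
    list(fields = fields, truth = dplyr::bind_rows(truth), config = config),
    class = "image_dataset"
  )
}

#' @export
print.image_dataset <- function(x, ...) {
  cat(sprintf(
    "<image_dataset> %d fields, %d cells, ligands: %s; times: %s min\n",
    length(x$fields), nrow(x$truth),
    paste(names(x$config$ligands), collapse = ", "),
    paste(x$config$times, collapse = ", ")
  ))
  invisible(x)
}
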