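#' Simulate a two-cell immunofluorescence scene
#'
#' Renders a pair of adjacent elliptical cells with a marker channel whose
#' signal is split between a membrane shell and a uniform cytoplasmic pool,
#' plus a nuclear (DAPI-like) channel with one bright disk per cell. The
#' fraction of marker signal in the membrane shell is the ground-truth
#' localization the profile pipeline is asked to recover. Where the two
#' membrane shells appose at the junction the expected intensity doubles,
#' as it does for cadherin staining of a real junction. Photon noise is
#' Poisson on the expected per-pixel counts.
#'
#' Ground truth (nuclei centroids, junction midpoint, membrane fraction) is
#' recorded from the construction, never measured from the rendered image.
#'
#' @param image_size `c(height, width)` in pixels.
#' @param pixel_size physical pixel size, um/pixel.
#' @param cell_centers list of two `c(row, col)` centers.
#' @param cell_radii list of two `c(row_semiaxis, col_semiaxis)` in pixels.
#' @param nucleus_radii two nuclear disk radii in pixels; each nucleus must
#'   fit inside its cell.
#' @param membrane_fraction fraction of marker signal in the membrane shell,
#'   in `[0, 1]`; the remainder is uniform over the cytoplasm.
#' @param membrane_thickness shell thickness in pixels.
#' @param base_intensity expected marker photons/pixel attributed to a cell.
#' @param background expected background photons/pixel.
#' @param noise `"poisson"` for photon noise, `"none"` for the noiseless
#'   expectation.
#' @param seed integer seed; identical parameters and seed give identical
#'   pixels.
#' @param require_junction error if the two cells do not touch (membranes
#'   further apart than `membrane_thickness`).
#' @return A list with elements `marker` and `nuclei` (both
#'   [fluor_image()]) and `truth` (list: `nuclei_centroids` tibble,
#'   `junction_midpoint`, `membrane_fraction`).
#' @examples
#' sc <- sim_cell_pair_scene(membrane_fraction = 1, noise = "none", seed = 1)
#' sc$truth$junction_midpoint
#' @export
sim_cell_pair_scene <- function(image_size = c(128, 128),
                                pixel_size = 0.2,
                                cell_centers = list(c(64, 37), c(64, 92)),
                                cell_radii = list(c(30, 27), c(30, 27)),
                                nucleus_radii = c(9, 9),
                                membrane_fraction = 0.8,
                                membrane_thickness = 3,
                                base_intensity = 50,
                                background = 5,
                                noise = c("poisson", "none"),
                                seed,
                                require_junction = TRUE) {
  noise <- match.arg(noise)
  if (missing(seed)) abort("`seed` is required: generators are pure functions of (params, seed).")
  if (membrane_fraction < 0 || membrane_fraction > 1) {
    abort("`membrane_fraction` must lie in [0, 1].")
  }
  radii <- unlist(cell_radii)
  if (any(radii <= 0) || any(nucleus_radii <= 0)) abort("all radii must be positive.")
  for (i in 1:2) {
    if (nucleus_radii[i] >= min(cell_radii[[i]])) {
      abort(sprintf("nucleus %d does not fit inside its cell.", i))
    }
  }
  H <- image_size[1]; W <- image_size[2]
  ca <- cell_centers[[1]]; cb <- cell_centers[[2]]
  d <- sqrt(sum((cb - ca)^2))
  if (d <= 0) abort("cell centers must be distinct.")
  dir <- (cb - ca) / d
  # semi-axis length of each ellipse along the internuclear direction
  r_along <- function(rad) 1 / sqrt((dir[1] / rad[1])^2 + (dir[2] / rad[2])^2)
  ra <- r_along(cell_radii[[1]]); rb <- r_along(cell_radii[[2]])
  gap <- d - ra - rb
  if (require_junction && gap > membrane_thickness) {
    abort(sprintf(
      "cells must touch to form a junction (membrane gap %.1f px > thickness %g px).",
      gap, membrane_thickness
    ))
  }

  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  expected <- matrix(background, H, W)
  for (i in 1:2) {
    cc <- cell_centers[[i]]; rad <- cell_radii[[i]]
    rho <- sqrt(((yy - cc[1]) / rad[1])^2 + ((xx - cc[2]) / rad[2])^2)
    # signed distance to the cell boundary in pixels (negative = inside);
    # the membrane shell straddles the boundary, so the apposed shells of
    # two touching cells overlap at the junction and their expected
    # intensities add (double-weighted junction).
    dist_px <- (rho - 1) * mean(rad)
    inside <- rho <= 1
    shell <- abs(dist_px) <= membrane_thickness / 2
    expected <- expected + base_intensity *
      ((1 - membrane_fraction) * inside + membrane_fraction * shell)
  }

  nuc_expected <- matrix(1, H, W)
  for (i in 1:2) {
    cc <- cell_centers[[i]]
    rho <- sqrt((yy - cc[1])^2 + (xx - cc[2])^2)
    nuc_expected <- nuc_expected + 100 * (rho <= nucleus_radii[i])
  }

  marker <- expected; nuclei <- nuc_expected
  if (noise == "poisson") {
    withr::with_seed(seed, {
      marker <- matrix(rpois(H * W, expected), H, W)
      nuclei <- matrix(rpois(H * W, nuc_expected), H, W)
    })
  }

  junction_mid <- ca + dir * (ra + d - rb) / 2
  list(
    marker = fluor_image(marker, pixel_size = pixel_size, channel = "marker"),
    nuclei = fluor_image(nuclei, pixel_size = pixel_size, channel = "DAPI"),
    truth = list(
      nuclei_centroids = tibble(
        cell = 1:2,
        row = c(ca[1], cb[1]),
        col = c(ca[2], cb[2])
      ),
      junction_midpoint = c(row = junction_mid[1], col = junction_mid[2]),
      membrane_fraction = membrane_fraction
    )
  )
}

#' Simulate an ensemble of jittered 1D intensity profiles
#'
#' Emulates the cell-size and cell-shape variability seen across extracted
#' internuclear profiles: each output profile is the template shifted by a
#' random integer number of positions (replicate-padded at the ends, so the
#' boundaries stay boundary-like), amplitude-scaled, resampled to a random
#' raw length, and optionally Poisson-corrupted. The true shifts are
#' returned in profile order so registration can be scored against them.
#'
#' @param template non-negative numeric vector, the noiseless profile shape.
#' @param n_profiles number of profiles to generate (0 gives an empty
#'   ensemble).
#' @param max_shift maximum absolute integer shift; must be smaller than a
#'   quarter of the template length.
#' @param amplitude_jitter relative standard deviation of the per-profile
#'   amplitude factor `1 + e`, `e ~ N(0, amplitude_jitter)`.
#' @param raw_length_range `c(min, max)` raw sample counts before length
#'   normalization; minimum 8.
#' @param noise `"none"` or `"poisson"`.
#' @param seed integer seed.
#' @return A list with `profiles` (list of unnormalized [intensity_profile()]
#'   objects, kind `"IN"`) and `shifts` (integer vector, positive = peak
#'   moved toward higher positions).
#' @export
sim_profile_ensemble <- function(template,
                                 n_profiles,
                                 max_shift = 5,
                                 amplitude_jitter = 0,
                                 raw_length_range = c(length(template), length(template)),
                                 noise = c("none", "poisson"),
                                 seed) {
  noise <- match.arg(noise)
  if (missing(seed)) abort("`seed` is required.")
  Tn <- length(template)
  if (Tn < 8 || any(template < 0)) abort("`template` must be non-negative with length >= 8.")
  if (max_shift >= Tn / 4) abort("`max_shift` must be smaller than template length / 4.")
  if (raw_length_range[1] < 8) abort("raw lengths must be >= 8.")
  if (n_profiles == 0) {
    return(list(profiles = list(), shifts = integer(0)))
  }
  withr::with_seed(seed, {
    shifts <- sample.int(2 * max_shift + 1, n_profiles, replace = TRUE) - max_shift - 1L
    profiles <- vector("list", n_profiles)
    for (j in seq_len(n_profiles)) {
      idx <- pmin(pmax(seq_len(Tn) - shifts[j], 1L), Tn)  # replicate-pad ends
      vals <- template[idx] * (1 + rnorm(1, 0, amplitude_jitter))
      lens <- seq(raw_length_range[1], raw_length_range[2])
      raw_len <- lens[sample.int(length(lens), 1)]
      if (raw_len != Tn) {
        vals <- approx(seq_len(Tn), vals, xout = seq(1, Tn, length.out = raw_len))$y
      }
      vals <- pmax(vals, 0)
      if (noise == "poisson") vals <- rpois(length(vals), vals)
      profiles[[j]] <- intensity_profile(vals, kind = "IN", source = sprintf("sim_%02d", j))
    }
  })
  list(profiles = profiles, shifts = as.integer(shifts))
}

#' Simulate an AFM cell-cell force-distance curve
#'
#' Builds a retract segment carrying a single adhesive (negative-force)
#' detachment event of known shape and analytically known area, plus a flat
#' approach segment, with optional Gaussian force noise. The event can be
#' specified either by its enclosed work or by its peak force; the other is
#' derived from the shape geometry. Internal breakpoints of the noiseless
#' waveform are inserted into the sampling grid so the recorded ground-truth
#' work is the exact trapezoidal area of the constructed waveform.
#'
#' @param true_work_J detachment work in joules (area between baseline and
#'   the adhesive part of the retract curve). Give this or `f_max_pN`.
#' @param f_max_pN peak downward force in piconewtons.
#' @param shape `"triangular"` (single ramped rupture, area `F d / 2`),
#'   `"rectangular"` (sustained plateau, area `F d` up to the short release
#'   ramps), or `"multi_step"` (three descending plateaus).
#' @param pull_um total retract distance in micrometres.
#' @param event_um length of the adhesive event in micrometres.
#' @param noise_sd_pN Gaussian force noise standard deviation.
#' @param n samples per segment.
#' @param spring_constant cantilever spring constant, N/m.
#' @param seed integer seed (required when `noise_sd_pN > 0`).
#' @return A list with `curve` (a [force_curve()]) and `truth`
#'   (list: `work_J`, `f_max_pN`).
#' @examples
#' fc <- sim_force_curve(f_max_pN = 200, shape = "triangular", event_um = 2,
#'                       noise_sd_pN = 0, seed = 1)
#' fc$truth$work_J  # 0.5 * 200e-12 * 2e-6 = 2e-16 J
#' @export
sim_force_curve <- function(true_work_J = NULL,
                            f_max_pN = NULL,
                            shape = c("triangular", "rectangular", "multi_step"),
                            pull_um = 10,
                            event_um = 2,
                            noise_sd_pN = 0,
                            n = 1000,
                            spring_constant = 0.03,
                            seed) {
  shape <- match.arg(shape)
  if (missing(seed)) abort("`seed` is required.")
  if (spring_constant <= 0) abort("`spring_constant` must be positive.")
  if (event_um <= 0 || event_um > pull_um) abort("`event_um` must lie in (0, pull_um].")
  if (is.null(true_work_J) == is.null(f_max_pN)) {
    abort("give exactly one of `true_work_J` or `f_max_pN`.")
  }
  # area factors in pN * um (1 pN um = 1e-18 J)
  area_factor <- switch(shape,
    triangular  = 0.5 * event_um,
    rectangular = event_um,        # release ramps subtract a negligible sliver
    multi_step  = 2 / 3 * event_um
  )
  if (is.null(f_max_pN)) {
    if (true_work_J < 0) abort("`true_work_J` must be >= 0.")
    f_max_pN <- true_work_J / 1e-18 / area_factor
  }
  if (f_max_pN < 0) abort("`f_max_pN` must be >= 0.")

  e <- event_um
  w <- e * 2e-4  # ramp width for plateau edges; keeps displacement monotone
  knots <- switch(shape,
    triangular  = list(x = c(0, e / 2, e), f = c(0, -f_max_pN, 0)),
    rectangular = list(x = c(0, w, e - w, e), f = c(0, -f_max_pN, -f_max_pN, 0)),
    multi_step  = list(
      x = c(0, w, e / 3 - w, e / 3 + w, 2 * e / 3 - w, 2 * e / 3 + w, e - w, e),
      f = -f_max_pN * c(0, 1, 1, 2 / 3, 2 / 3, 1 / 3, 1 / 3, 0)
    )
  )
  if (f_max_pN == 0) knots <- list(x = c(0, pull_um), f = c(0, 0))
  h <- sort(unique(c(seq(0, pull_um, length.out = n), knots$x)))
  f_clean <- approx(knots$x, knots$f, xout = h, yleft = 0, yright = 0, rule = 2)$y
  f_clean[h > max(knots$x)] <- 0
  work_true <- trapz(h, pmax(0, -f_clean)) * 1e-18

  f_retract <- f_clean
  f_approach <- rep(0, length(h))
  if (noise_sd_pN > 0) {
    withr::with_seed(seed, {
      f_approach <- f_approach + rnorm(length(h), 0, noise_sd_pN)
      f_retract <- f_retract + rnorm(length(h), 0, noise_sd_pN)
    })
  }
  dat <- bind_rows(
    tibble(segment = "approach", height_um = h, force_pN = f_approach),
    tibble(segment = "retract", height_um = h, force_pN = f_retract)
  )
  list(
    curve = force_curve(dat, spring_constant = spring_constant),
    truth = list(work_J = work_true, f_max_pN = f_max_pN)
  )
}

#' Simulate a proximity ligation assay scene
#'
#' Places isotropic Gaussian spots ("blobs", one per protein-protein
#' interaction event) at random positions with a minimum separation of four
#' blob sigmas, over a uniform background, plus a nuclear channel with
#' `n_cells` bright disks. Per-cell blob counts are Poisson draws around
#' `blobs_per_cell` unless an exact total is requested.
#'
#' @param image_size `c(height, width)` pixels.
#' @param n_cells number of cells (nuclei) in the field; must be >= 1.
#' @param blobs_per_cell mean blob count per cell.
#' @param n_blobs optional exact total blob count, overriding the Poisson
#'   draws.
#' @param blob_sigma spot Gaussian sigma in pixels.
#' @param blob_intensity peak expected photons of one spot.
#' @param background expected background photons/pixel.
#' @param noise `"none"` or `"poisson"`.
#' @param seed integer seed.
#' @param max_tries placement attempts before giving up on the separation
#'   constraint.
#' @return A list with `image` and `nuclei` ([fluor_image()]) and `truth`
#'   (list: `blob_centers` tibble with `row`/`col`, `n_cells`).
#' @export
sim_pla_scene <- function(image_size = c(128, 128),
                          n_cells = 4,
                          blobs_per_cell = 8,
                          n_blobs = NULL,
                          blob_sigma = 2,
                          blob_intensity = 200,
                          background = 2,
                          noise = c("none", "poisson"),
                          seed,
                          max_tries = 5000) {
  noise <- match.arg(noise)
  if (missing(seed)) abort("`seed` is required.")
  if (n_cells < 1) abort("`n_cells` must be >= 1.")
  if (blobs_per_cell < 0) abort("`blobs_per_cell` must be >= 0.")
  H <- image_size[1]; W <- image_size[2]
  margin <- 4 * blob_sigma
  min_sep <- 4 * blob_sigma

  withr::with_seed(seed, {
    total <- if (!is.null(n_blobs)) as.integer(n_blobs) else sum(rpois(n_cells, blobs_per_cell))
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(centers) < total) {
      tries <- tries + 1
      if (tries > max_tries) {
        abort(sprintf(
          "could not place %d spots with separation >= %.1f px in %d tries.",
          total, min_sep, max_tries
        ))
      }
      cand <- c(runif(1, 1 + margin, H - margin), runif(1, 1 + margin, W - margin))
      if (nrow(centers) == 0 ||
          min(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)) >= min_sep) {
        centers <- rbind(centers, cand)
      }
    }

    expected <- matrix(background, H, W)
    half <- ceiling(5 * blob_sigma)
    for (k in seq_len(nrow(centers))) {
      cy <- centers[k, 1]; cx <- centers[k, 2]
      rows <- max(1, floor(cy - half)):min(H, ceiling(cy + half))
      cols <- max(1, floor(cx - half)):min(W, ceiling(cx + half))
      g <- blob_intensity *
        exp(-(outer((rows - cy)^2, (cols - cx)^2, `+`)) / (2 * blob_sigma^2))
      expected[rows, cols] <- expected[rows, cols] + g
    }

    grid_n <- ceiling(sqrt(n_cells))
    gy <- seq(H / (grid_n + 1), H * grid_n / (grid_n + 1), length.out = grid_n)
    gx <- seq(W / (grid_n + 1), W * grid_n / (grid_n + 1), length.out = grid_n)
    nuc_centers <- expand.grid(row = gy, col = gx)[seq_len(n_cells), ]
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    nuc_expected <- matrix(1, H, W)
    for (k in seq_len(n_cells)) {
      rho <- sqrt((yy - nuc_centers$row[k])^2 + (xx - nuc_centers$col[k])^2)
      nuc_expected <- nuc_expected + 100 * (rho <= 8)
    }

    img <- expected; nuc <- nuc_expected
    if (noise == "poisson") {
      img <- matrix(rpois(H * W, expected), H, W)
      nuc <- matrix(rpois(H * W, nuc_expected), H, W)
    }
  })

  list(
    image = fluor_image(img, channel = "PLA"),
    nuclei = fluor_image(nuc, channel = "DAPI"),
    truth = list(
      blob_centers = tibble(row = centers[, 1], col = centers[, 2]),
      n_cells = n_cells
    )
  )
}

# exact trapezoidal rule
trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
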