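#' 1D fluorescence intensity profile
#'
#' An ordered sequence of non-negative intensities sampled along a straight
#' path in a fluorescence image: internuclear (`"IN"`, between the nuclei of
#' two contiguous cells) or radial (`"RD"`, from a nucleus toward the cell
#' periphery). Stored as a tibble with `position` and `intensity` columns;
#' the extraction kind, raw length and normalization state travel as
#' attributes.
#'
#' @param values numeric vector of non-negative finite intensities.
#' @param kind `"IN"` or `"RD"`.
#' @param normalized `TRUE` once resampled to the common length (see
#'   [normalize_profile_length()]); normalized profiles must have exactly
#'   the normalized length.
#' @param source free-text identifier of the image/pair the profile came
#'   from.
#' @param raw_length sample count at extraction time.
#' @return An `intensity_profile` tibble.
#' @export
intensity_profile <- function(values, kind = c("IN", "RD"), normalized = FALSE,
                              source = NA_character_,
                              raw_length = length(values)) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) < 1 || any(!is.finite(values)) || any(values < 0)) {
    abort("profile values must be non-negative, finite, and non-empty.")
  }
  out <- tibble(position = seq_along(values), intensity = values)
  structure(out,
    kind = kind, normalized = isTRUE(normalized), source = source,
    raw_length = as.integer(raw_length),
    class = c("intensity_profile", class(out))
  )
}

profile_values <- function(profile) {
  if (inherits(profile, "intensity_profile")) profile$intensity else as.numeric(profile)
}

profile_kind <- function(profile) attr(profile, "kind") %||% "IN"

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf(
    "<intensity_profile> kind %s, length %d%s, source %s\n",
    attr(x, "kind"), nrow(x),
    if (isTRUE(attr(x, "normalized"))) " (normalized)" else
      sprintf(" (raw, %d samples)", attr(x, "raw_length")),
    attr(x, "source")
  ))
  NextMethod()
}

#' Detect nuclei in a DAPI channel
#'
#' Global thresholding (Otsu by default) followed by connected-component
#' labeling; components below `min_area` are discarded. Supports the
#' semi-automated pair selection workflow: detected centroids are candidate
#' anchor points for internuclear profiles.
#'
#' @param nuclei_channel a [fluor_image()] of the nuclear stain.
#' @param min_area minimum component area in pixels squared.
#' @param method `"otsu"` for Otsu's threshold, `"quantile"` for a fixed
#'   upper-quantile threshold.
#' @param quantile_level threshold quantile when `method = "quantile"`.
#' @return A tibble with one row per nucleus: `label`, sub-pixel centroid
#'   `row`/`col`, and `area` (px^2). A blank image yields zero rows.
#' @export
detect_nuclei <- function(nuclei_channel, min_area = 30,
                          method = c("otsu", "quantile"),
                          quantile_level = 0.99) {
  method <- match.arg(method)
  m <- unclass(nuclei_channel)
  attributes(m) <- list(dim = dim(m))
  empty <- tibble(label = integer(0), row = numeric(0), col = numeric(0), area = numeric(0))
  rng <- range(m)
  if (diff(rng) == 0) return(empty)
  scaled <- (m - rng[1]) / diff(rng)
  thr <- switch(method,
    otsu = EBImage::otsu(EBImage::Image(scaled), range = c(0, 1)),
    quantile = as.numeric(quantile(scaled, quantile_level))
  )
  mask <- scaled > thr
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  labv <- as.integer(lab)
  keep <- labv > 0
  if (!any(keep)) return(empty)
  idx <- which(keep)
  rows <- (idx - 1) %% nrow(m) + 1
  cols <- (idx - 1) %/% nrow(m) + 1
  out <- tibble(label = labv[keep], row = rows, col = cols) |>
    group_by(label) |>
    summarise(row = mean(row), col = mean(col), area = n(), .groups = "drop") |>
    filter(.data$area >= min_area) |>
    arrange(.data$label)
  out$label <- seq_len(nrow(out))
  out
}

#' Select pairs of contiguous cells for internuclear profiling
#'
#' The profile pipeline analyses pairs of neighbouring cells. Selection is
#' semi-automated: an explicit `manual_pairs` table (labels chosen by the
#' analyst) is validated and returned verbatim; otherwise all
#' mutual-nearest-neighbour nucleus pairs closer than `max_distance_um` are
#' returned, each nucleus used at most once.
#'
#' @param nuclei tibble from [detect_nuclei()] (`label`, `row`, `col`).
#' @param max_distance_um maximum internuclear distance in micrometres.
#' @param pixel_size um/pixel used to convert pixel distances.
#' @param manual_pairs optional tibble/data.frame with columns `label_a`,
#'   `label_b` referencing `nuclei$label`.
#' @return A tibble with one row per pair: labels, both centroids, and
#'   `distance_um`.
#' @export
select_cell_pairs <- function(nuclei, max_distance_um = Inf, pixel_size = 1,
                              manual_pairs = NULL) {
  empty <- tibble(
    label_a = integer(0), label_b = integer(0),
    row_a = numeric(0), col_a = numeric(0),
    row_b = numeric(0), col_b = numeric(0), distance_um = numeric(0)
  )
  pair_row <- function(la, lb) {
    a <- nuclei[match(la, nuclei$label), ]
    b <- nuclei[match(lb, nuclei$label), ]
    tibble(
      label_a = la, label_b = lb,
      row_a = a$row, col_a = a$col, row_b = b$row, col_b = b$col,
      distance_um = sqrt((a$row - b$row)^2 + (a$col - b$col)^2) * pixel_size
    )
  }
  if (!is.null(manual_pairs)) {
    unknown <- setdiff(
      unique(c(manual_pairs$label_a, manual_pairs$label_b)),
      nuclei$label
    )
    if (length(unknown) > 0) {
      abort(sprintf("manual pair references unknown nucleus label(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    return(bind_rows(purrr::map2(manual_pairs$label_a, manual_pairs$label_b, pair_row)))
  }
  if (nrow(nuclei) < 2) return(empty)
  dmat <- as.matrix(stats::dist(nuclei[, c("row", "col")])) * pixel_size
  diag(dmat) <- Inf
  nn <- apply(dmat, 1, which.min)
  out <- empty
  used <- logical(nrow(nuclei))
  for (i in seq_len(nrow(nuclei))) {
    j <- nn[i]
    if (i < j && nn[j] == i && !used[i] && !used[j] && dmat[i, j] <= max_distance_um) {
      out <- bind_rows(out, pair_row(nuclei$label[i], nuclei$label[j]))
      used[i] <- used[j] <- TRUE
    }
  }
  out
}

# Shared sampler: mean of bilinear samples across a perpendicular band at
# each position along the segment from `from` to `to` (row, col).
sample_profile_band <- function(image, from, to, sampling_step, band_halfwidth) {
  m <- unclass(image)
  attributes(m) <- list(dim = dim(m))
  d <- sqrt(sum((to - from)^2))
  if (d <= 0) abort("profile path has zero length: the two anchor points coincide.")
  n_samples <- floor(d / sampling_step) + 1
  t_along <- (seq_len(n_samples) - 1) * sampling_step
  dir <- (to - from) / d
  perp <- c(-dir[2], dir[1])
  offsets <- seq(-band_halfwidth, band_halfwidth, by = 1)
  vals <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    p <- from + t_along[i] * dir
    rows <- p[1] + offsets * perp[1]
    cols <- p[2] + offsets * perp[2]
    vals[i] <- mean(bilinear_at(m, rows, cols))
  }
  vals
}

#' Extract an internuclear (IN) intensity profile
#'
#' Samples the marker image along the straight segment joining the two
#' nuclei of a cell pair, averaging bilinear interpolations over a
#' perpendicular band of `2 * band_halfwidth + 1` points spaced one pixel
#' apart. A membrane-localized marker produces a peak near the middle of
#' the profile, at the cell-cell junction.
#'
#' @param image marker-channel [fluor_image()].
#' @param pair one row of [select_cell_pairs()] output (or any list with
#'   `row_a`, `col_a`, `row_b`, `col_b`).
#' @param sampling_step spacing between consecutive samples, pixels.
#' @param band_halfwidth half-width of the averaging band, pixels; 0 means a
#'   single-pixel-wide line.
#' @return An unnormalized [intensity_profile()] of kind `"IN"` with
#'   `raw_length = floor(distance / step) + 1` samples.
#' @export
extract_internuclear_profile <- function(image, pair, sampling_step = 1,
                                         band_halfwidth = 2) {
  from <- c(pair$row_a[1], pair$col_a[1])
  to <- c(pair$row_b[1], pair$col_b[1])
  vals <- sample_profile_band(image, from, to, sampling_step, band_halfwidth)
  la <- if ("label_a" %in% names(pair)) pair$label_a[1] else "a"
  lb <- if ("label_b" %in% names(pair)) pair$label_b[1] else "b"
  intensity_profile(pmax(vals, 0), kind = "IN",
    source = paste0(attr(image, "channel"), ":", la, "-", lb))
}

#' Extract a radial (RD) intensity profile
#'
#' Samples along the ray from a nucleus centroid to a user-supplied boundary
#' point within one cell. Orientation is nucleus-to-boundary by default; set
#' `reverse = TRUE` for boundary-to-nucleus.
#'
#' @inheritParams extract_internuclear_profile
#' @param nucleus `c(row, col)` nucleus centroid.
#' @param boundary_point `c(row, col)` point on (or near) the cell boundary;
#'   must differ from `nucleus`.
#' @param reverse sample boundary-to-nucleus instead.
#' @return An unnormalized [intensity_profile()] of kind `"RD"`.
#' @export
extract_radial_profile <- function(image, nucleus, boundary_point,
                                   sampling_step = 1, band_halfwidth = 2,
                                   reverse = FALSE) {
  if (all(nucleus == boundary_point)) {
    abort("`boundary_point` equals `nucleus`: zero-length radial path.")
  }
  from <- if (reverse) boundary_point else nucleus
  to <- if (reverse) nucleus else boundary_point
  vals <- sample_profile_band(image, from, to, sampling_step, band_halfwidth)
  intensity_profile(pmax(vals, 0), kind = "RD",
                    source = attr(image, "channel"))
}

#' Normalize a profile to a constant length
#'
#' Resamples a raw profile onto `L` equally spaced positions spanning its
#' first to last sample by linear interpolation, so profiles from cells of
#' different sizes share a common position axis of `L` arbitrary units
#' (100 by default). Endpoints are preserved exactly and interpolation never
#' leaves the range of the raw values.
#'
#' @param profile an [intensity_profile()] with at least 2 samples.
#' @param L target length in arbitrary units.
#' @return A normalized [intensity_profile()] of length `L`.
#' @export
normalize_profile_length <- function(profile, L = 100) {
  vals <- profile_values(profile)
  if (length(vals) < 2) abort("profile must have at least 2 samples to normalize.")
  out <- approx(seq_along(vals), vals,
                xout = seq(1, length(vals), length.out = L))$y
  intensity_profile(out,
    kind = profile_kind(profile), normalized = TRUE,
    source = attr(profile, "source") %||% NA_character_,
    raw_length = attr(profile, "raw_length") %||% length(vals)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
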