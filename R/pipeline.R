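#' Internuclear-profile localization pipeline for one scene
#'
#' Runs the full analysis chain on one two-cell scene: detect nuclei in the
#' DAPI channel, pick the cell pair, extract the internuclear profile from
#' the marker channel, and normalize it to the common length. Falls back to
#' the supplied `manual_pairs` when nuclei detection is not wanted.
#'
#' @param marker,nuclei_channel [fluor_image()] objects for the marker and
#'   the nuclear stain.
#' @param band_halfwidth,sampling_step passed to
#'   [extract_internuclear_profile()].
#' @param L normalized profile length.
#' @param min_area passed to [detect_nuclei()].
#' @param manual_pairs optional pair table bypassing detection (see
#'   [select_cell_pairs()]).
#' @return A normalized [intensity_profile()] of kind `"IN"`.
#' @export
scene_internuclear_profile <- function(marker, nuclei_channel,
                                       band_halfwidth = 2, sampling_step = 1,
                                       L = 100, min_area = 30,
                                       manual_pairs = NULL) {
  if (is.null(manual_pairs)) {
    nuclei <- detect_nuclei(nuclei_channel, min_area = min_area)
    if (nrow(nuclei) < 2) abort("fewer than 2 nuclei detected in the scene.")
    pairs <- select_cell_pairs(nuclei, pixel_size = pixel_size(marker))
  } else {
    pairs <- manual_pairs
  }
  if (nrow(pairs) < 1) abort("no cell pair available in the scene.")
  extract_internuclear_profile(marker, pairs[1, ],
    sampling_step = sampling_step, band_halfwidth = band_halfwidth
  ) |>
    normalize_profile_length(L = L)
}

#' Profile-map analysis of a group of scenes
#'
#' Stacks normalized internuclear profiles into a map, denoises it under
#' the Poisson model, geometrically compensates the columns, and reports
#' the summary profile plus the two localization statistics (maximum mean
#' ratio and membrane-window mean intensity).
#'
#' @param profiles list of normalized [intensity_profile()] objects.
#' @param lambda denoising smoothness weight (see [denoise_map()]).
#' @param n_knots,gamma compensation parameters (see [compensate_map()]).
#' @param window membrane window (see [membrane_mean_intensity()]).
#' @param denoise_first run denoising before compensation (the default
#'   pipeline order); set `FALSE` to swap the two steps for sensitivity
#'   analysis.
#' @return A list: `map` (raw), `compensation`, `summary`, and a one-row
#'   `stats` tibble with `mmr`, `membrane_mean`, `n_profiles`.
#' @export
analyze_profile_group <- function(profiles, lambda = 10, n_knots = 3,
                                  gamma = 1, window = c(46, 55),
                                  denoise_first = TRUE) {
  map <- build_profile_map(profiles)
  if (denoise_first) {
    comp <- compensate_map(denoise_map(map, lambda = lambda),
                           n_knots = n_knots, gamma = gamma)
  } else {
    comp <- compensate_map(map, n_knots = n_knots, gamma = gamma)
    comp$compensated <- denoise_map(comp$compensated, lambda = lambda)
  }
  summ <- summarize_map(comp$compensated)
  list(
    map = map,
    compensation = comp,
    summary = summ,
    stats = tibble(
      mmr = compute_mmr(summ),
      membrane_mean = membrane_mean_intensity(summ, window = window),
      n_profiles = ncol(map)
    )
  )
}
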