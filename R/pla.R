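#' Detect PLA dots by scale-space blob detection
#'
#' Proximity ligation assay signals are near-diffraction-limited bright
#' dots, one per protein-protein interaction event. Detection uses the
#' scale-normalized Laplacian of Gaussian: the image is Gaussian-smoothed
#' at a geometric ladder of sigmas spanning `sigma_range`, the negated
#' Laplacian is scale-normalized by `sigma^2`, and blob centers are local
#' maxima (over space and scale) whose response exceeds `threshold` times
#' the global maximum response. The relative threshold makes detection
#' invariant to overall intensity scaling. Overlapping detections are
#' suppressed, keeping the stronger one.
#'
#' @param image a [fluor_image()] (PLA channel, max-projected).
#' @param sigma_range `c(min, max)` blob sigmas in pixels, both positive.
#' @param n_scales number of sigma steps in the ladder.
#' @param threshold relative response threshold in (0, 1).
#' @return A tibble with one row per blob: `row`, `col`, `sigma`
#'   (best-responding scale), `response`, and `intensity` (image value at
#'   the center pixel).
#' @export
detect_blobs <- function(image, sigma_range = c(1, 4), n_scales = 5,
                         threshold = 0.1) {
  if (length(sigma_range) != 2 || any(sigma_range <= 0) ||
      sigma_range[1] > sigma_range[2]) {
    abort("`sigma_range` must be c(min, max) with 0 < min <= max.")
  }
  m <- unclass(image)
  attributes(m) <- list(dim = dim(m))
  empty <- tibble(row = numeric(0), col = numeric(0), sigma = numeric(0),
                  response = numeric(0), intensity = numeric(0))
  if (diff(range(m)) == 0) return(empty)
  sigmas <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                    length.out = max(n_scales, 1)))
  H <- nrow(m); W <- ncol(m)
  responses <- lapply(sigmas, function(s) {
    sm <- as.matrix(EBImage::gblur(EBImage::Image(m), sigma = s))
    lap <- matrix(0, H, W)
    lap[2:(H - 1), 2:(W - 1)] <-
      sm[1:(H - 2), 2:(W - 1)] + sm[3:H, 2:(W - 1)] +
      sm[2:(H - 1), 1:(W - 2)] + sm[2:(H - 1), 3:W] -
      4 * sm[2:(H - 1), 2:(W - 1)]
    -s^2 * lap  # bright blobs give positive scale-normalized response
  })
  rmax <- max(vapply(responses, max, numeric(1)))
  if (rmax <= 0) return(empty)
  thr <- threshold * rmax

  peaks <- list()
  for (k in seq_along(sigmas)) {
    r <- responses[[k]]
    core <- r[2:(H - 1), 2:(W - 1)]
    is_peak <- core > thr &
      core >= r[1:(H - 2), 2:(W - 1)] & core >= r[3:H, 2:(W - 1)] &
      core >= r[2:(H - 1), 1:(W - 2)] & core >= r[2:(H - 1), 3:W] &
      core >= r[1:(H - 2), 1:(W - 2)] & core >= r[3:H, 1:(W - 2)] &
      core >= r[1:(H - 2), 3:W] & core >= r[3:H, 3:W]
    if (k > 1) is_peak <- is_peak & core >= responses[[k - 1]][2:(H - 1), 2:(W - 1)]
    if (k < length(sigmas)) is_peak <- is_peak & core >= responses[[k + 1]][2:(H - 1), 2:(W - 1)]
    idx <- which(is_peak)
    if (length(idx) > 0) {
      pr <- (idx - 1) %% (H - 2) + 2
      pc <- (idx - 1) %/% (H - 2) + 2
      peaks[[length(peaks) + 1]] <- tibble(
        row = pr, col = pc, sigma = sigmas[k], response = core[idx]
      )
    }
  }
  if (length(peaks) == 0) return(empty)
  cand <- bind_rows(peaks) |> arrange(dplyr::desc(.data$response))
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      later <- (i + 1):nrow(cand)
      d <- sqrt((cand$row[later] - cand$row[i])^2 + (cand$col[later] - cand$col[i])^2)
      # suppress detections whose blob disks (radius sqrt(2) sigma) overlap
      too_close <- d < sqrt(2) * pmax(cand$sigma[later], cand$sigma[i]) * 1.5
      keep[later][too_close] <- FALSE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out$intensity <- m[cbind(out$row, out$col)]
  out$row <- as.numeric(out$row); out$col <- as.numeric(out$col)
  arrange(out, .data$row, .data$col)
}

#' Blobs per cell
#'
#' The PLA readout: total interaction-dot count divided by the number of
#' cells (nuclei) in the field.
#'
#' @param blobs tibble from [detect_blobs()] (or anything with one row per
#'   blob).
#' @param nuclei tibble from [detect_nuclei()] (one row per nucleus).
#' @return A one-row tibble: `n_blobs`, `n_cells`, `blobs_per_cell`.
#' @export
blobs_per_cell <- function(blobs, nuclei) {
  n_cells <- nrow(nuclei)
  if (n_cells < 1) abort("no nuclei: blobs-per-cell is undefined.")
  tibble(
    n_blobs = nrow(blobs),
    n_cells = n_cells,
    blobs_per_cell = nrow(blobs) / n_cells
  )
}

#' Normalize a condition to its control
#'
#' Fold change of mean blobs-per-cell across independent experiments in a
#' condition relative to the control condition.
#'
#' @param condition,control numeric vectors of per-experiment
#'   blobs-per-cell values (or one-row tibbles from [blobs_per_cell()]
#'   row-bound across experiments, in which case the `blobs_per_cell`
#'   column is used).
#' @return The fold change `mean(condition) / mean(control)`.
#' @export
normalize_to_control <- function(condition, control) {
  take <- function(x) {
    if (is.data.frame(x)) x$blobs_per_cell else as.numeric(x)
  }
  a <- take(condition); b <- take(control)
  if (length(a) == 0 || length(b) == 0) abort("condition and control must be non-empty.")
  mb <- mean(b)
  if (!is.finite(mb) || mb <= 0) abort("control mean must be positive.")
  mean(a) / mb
}
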