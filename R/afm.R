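#' AFM force-distance curve
#'
#' One cell-cell pulling cycle from single-cell force spectroscopy: an
#' approach and a retract segment of piezo height versus force. Adhesion
#' (downward cantilever deflection) is negative force; the detachment work
#' is the area between the baseline and the negative part of the retract
#' curve.
#'
#' @param data tibble/data.frame with columns `segment` (`"approach"` /
#'   `"retract"`), `height_um`, and `force_pN`; height must be strictly
#'   monotone within each segment.
#' @param spring_constant cantilever spring constant, N/m (> 0).
#' @param metadata named list (cell ids, condition label, ...).
#' @return A `force_curve` tibble.
#' @export
force_curve <- function(data, spring_constant = 0.03, metadata = list()) {
  data <- as_tibble(data)
  need <- c("segment", "height_um", "force_pN")
  if (!all(need %in% names(data))) {
    abort("`data` needs columns segment, height_um, force_pN.")
  }
  if (spring_constant <= 0) abort("`spring_constant` must be > 0.")
  for (seg in unique(data$segment)) {
    h <- data$height_um[data$segment == seg]
    if (length(h) > 1 && !(all(diff(h) > 0) || all(diff(h) < 0))) {
      abort(sprintf("height must be strictly monotone within segment '%s'.", seg))
    }
  }
  structure(data,
    spring_constant = spring_constant, metadata = metadata,
    class = c("force_curve", class(data))
  )
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(
    "<force_curve> %d samples (%s), k = %g N/m%s\n",
    nrow(x), paste(unique(x$segment), collapse = " + "),
    attr(x, "spring_constant"),
    if (!is.null(attr(x, "baseline_pN"))) sprintf(", baseline %.3g pN corrected", attr(x, "baseline_pN")) else ""
  ))
  NextMethod()
}

retract_of <- function(curve) {
  r <- curve[curve$segment == "retract", , drop = FALSE]
  r[order(r$height_um), , drop = FALSE]
}

#' Convert cantilever deflection to force
#'
#' Hooke's law for the calibrated cantilever: force equals the spring
#' constant times the deflection, returned in piconewtons.
#'
#' @param deflection_nm cantilever deflection in nanometres.
#' @param spring_constant spring constant in N/m (nominally 0.03 for the
#'   tipless cantilevers used for cell-cell adhesion).
#' @return Force in pN.
#' @examples
#' deflection_to_force(10, 0.03)  # 300 pN
#' @export
deflection_to_force <- function(deflection_nm, spring_constant = 0.03) {
  if (any(!is.finite(deflection_nm)) || !is.finite(spring_constant)) {
    abort("inputs must be finite.")
  }
  # N/m * nm = 1e-9 N = 1e3 pN per unit
  spring_constant * deflection_nm * 1e3
}

#' Baseline-correct a force curve
#'
#' Subtracts the median force of the final fraction of the retract segment
#' (the fully detached region, far from the surface) from the whole curve.
#' The subtracted baseline is recorded in the curve attributes.
#'
#' @param curve a [force_curve()] whose retract segment has at least 20
#'   samples.
#' @param tail_fraction fraction of the retract end used to estimate the
#'   baseline.
#' @return The corrected `force_curve` with attribute `baseline_pN`.
#' @export
baseline_correct <- function(curve, tail_fraction = 0.1) {
  r <- retract_of(curve)
  if (nrow(r) < 20) abort("retract segment must have at least 20 samples.")
  n_tail <- max(2, floor(nrow(r) * tail_fraction))
  baseline <- median(tail(r$force_pN, n_tail))
  out <- curve
  out$force_pN <- out$force_pN - baseline
  attr(out, "baseline_pN") <- baseline
  out
}

#' Detachment work and maximum adhesion force of a retract curve
#'
#' Integrates the adhesive (negative) part of the baseline-corrected
#' retract curve by the trapezoidal rule, from contact to the detachment
#' point, giving the total energy needed to separate the two cells in
#' joules. Detachment is the first position after the deepest adhesion
#' where the force stays within a noise band of the baseline for at least
#' `sustain` consecutive samples; the band is three times the standard
#' deviation of the detached tail (or `noise_band_pN` if supplied).
#'
#' @param curve a baseline-corrected [force_curve()].
#' @param tail_fraction fraction of the retract end used to estimate the
#'   noise band.
#' @param noise_band_pN optional explicit half-width of the baseline band.
#' @param sustain consecutive in-band samples required to call detachment.
#' @return A one-row tibble: `work_J`, `f_max_pN` (maximum downward force),
#'   `baseline_pN`, `detach_index`.
#' @export
compute_detachment_work <- function(curve, tail_fraction = 0.1,
                                    noise_band_pN = NULL, sustain = 10) {
  r <- curve[curve$segment == "retract", , drop = FALSE]
  if (nrow(r) < 2) abort("retract segment missing or too short.")
  h <- r$height_um
  if (any(diff(h) <= 0)) abort("retract height must be strictly increasing.")
  f <- r$force_pN
  n <- length(f)
  n_tail <- max(2, floor(n * tail_fraction))
  band <- if (!is.null(noise_band_pN)) noise_band_pN else 3 * sd(tail(f, n_tail))
  if (!is.finite(band) || band <= 0) band <- 1e-9

  f_max <- max(0, -min(f))
  i_min <- which.min(f)
  detach_index <- n
  if (f_max == 0) {
    detach_index <- 1L
  } else {
    in_band <- f >= -band
    run <- 0
    for (i in seq(i_min, n)) {
      run <- if (in_band[i]) run + 1 else 0
      if (run >= min(sustain, n - i_min + 1)) {
        detach_index <- i - run + 1L
        break
      }
    }
  }
  idx <- seq_len(max(detach_index, 2))
  work_pN_um <- trapz(h[idx], pmax(0, -f[idx]))
  tibble(
    work_J = work_pN_um * 1e-18,
    f_max_pN = f_max,
    baseline_pN = attr(curve, "baseline_pN") %||% 0,
    detach_index = as.integer(detach_index)
  )
}

#' Read and write force curves in the plain-text TSV dialect
#'
#' Curves are stored one per file: `# key: value` header lines carrying the
#' spring constant (N/m), optional deflection sensitivity (nm/V) and
#' metadata, `# segment:` markers switching between approach and retract
#' blocks, a column header line, and tab-separated data rows
#' (`height_um` + `force_pN`, or `height_um` + `deflection_V` which is
#' converted through the sensitivity and Hooke's law). A directory is read
#' in lexicographic order.
#'
#' @param path a file or directory.
#' @return `read_force_curves()` returns a list of [force_curve()] objects;
#'   `write_force_curve()` returns `path` invisibly.
#' @export
read_force_curves <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE, pattern = "\\.(tsv|txt)$"))
    return(purrr::map(files, read_force_curve_file))
  }
  list(read_force_curve_file(path))
}

read_force_curve_file <- function(file) {
  lines <- readLines(file)
  meta <- list()
  segment <- NA_character_
  rows <- list()
  col_names <- NULL
  bad <- integer(0)
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "") next
    if (startsWith(line, "#")) {
      kv <- sub("^#\\s*", "", line)
      key <- trimws(sub(":.*$", "", kv))
      val <- trimws(sub("^[^:]*:", "", kv))
      if (key == "segment") segment <- val else meta[[key]] <- val
      next
    }
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (any(grepl("[a-df-zA-DF-Z_]", parts))) {
      col_names <- parts
      next
    }
    num <- suppressWarnings(as.numeric(parts))
    if (length(num) < 2 || any(is.na(num))) {
      bad <- c(bad, ln)
      next
    }
    rows[[length(rows) + 1]] <- c(num[1], num[2], match(segment, c("approach", "retract")))
  }
  if (length(bad) > 0) {
    warn(sprintf("%s: skipped malformed data row(s) at line(s) %s.",
                 basename(file), paste(bad, collapse = ", ")))
  }
  if (length(rows) == 0) abort(sprintf("%s: no data rows found.", file))
  m <- do.call(rbind, rows)
  k <- as.numeric(meta[["spring_constant_N_per_m"]])
  if (!length(k) || is.na(k)) abort(sprintf("%s: missing spring_constant_N_per_m header.", file))
  value_col <- if (!is.null(col_names)) col_names[2] else "force_pN"
  force <- m[, 2]
  if (identical(value_col, "deflection_V")) {
    sens <- as.numeric(meta[["deflection_sensitivity_nm_per_V"]])
    if (!length(sens) || is.na(sens)) {
      abort(sprintf(
        "%s: deflection is in volts but no deflection_sensitivity_nm_per_V header is present.",
        basename(file)
      ))
    }
    force <- deflection_to_force(m[, 2] * sens, k)
  }
  seg <- c("approach", "retract")[m[, 3]]
  if (any(is.na(seg))) abort(sprintf("%s: data rows before any '# segment:' marker.", file))
  meta$spring_constant_N_per_m <- NULL
  meta$deflection_sensitivity_nm_per_V <- NULL
  force_curve(
    tibble(segment = seg, height_um = m[, 1], force_pN = force),
    spring_constant = k, metadata = meta
  )
}

#' @rdname read_force_curves
#' @param curve a [force_curve()].
#' @export
write_force_curve <- function(curve, path) {
  meta <- attr(curve, "metadata") %||% list()
  lines <- c(
    sprintf("# spring_constant_N_per_m: %.10g", attr(curve, "spring_constant")),
    purrr::imap_chr(meta, ~ sprintf("# %s: %s", .y, .x))
  )
  for (seg in c("approach", "retract")) {
    d <- curve[curve$segment == seg, , drop = FALSE]
    if (nrow(d) == 0) next
    lines <- c(lines, sprintf("# segment: %s", seg), "height_um\tforce_pN",
               sprintf("%.10g\t%.10g", d$height_um, d$force_pN))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Frequency histogram with Gaussian fit
#'
#' Histograms a sample of detachment-work (or force) values and fits a
#' Gaussian curve `A exp(-(x - mu)^2 / (2 sigma^2))` to the bin centers and
#' counts by least squares, initialized from the sample mean and SD — the
#' distribution model used to characterize adhesion-strength populations.
#'
#' @param values numeric sample, at least 10 values with positive variance.
#' @param bins `"fd"` for Freedman-Diaconis binning or an integer bin
#'   count.
#' @return A `gaussian_hist_fit` object: list with `histogram` (tibble
#'   `mid`, `count`), `mu`, `sigma`, `amplitude`, `rss`.
#' @export
fit_gaussian_histogram <- function(values, bins = "fd") {
  values <- values[is.finite(values)]
  if (length(values) < 10) abort("need at least 10 finite values.")
  if (sd(values) == 0) abort("sample has zero variance; Gaussian fit undefined.")
  breaks <- if (identical(bins, "fd")) {
    "FD"
  } else {
    seq(min(values), max(values), length.out = as.integer(bins) + 1)
  }
  hh <- graphics::hist(values, breaks = breaks, plot = FALSE)
  df <- tibble(mid = hh$mids, count = hh$counts)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200)
  mu0 <- mean(values)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      count ~ A * exp(-(mid - mu)^2 / (2 * sigma^2)),
      data = df,
      start = list(A = max(df$count), mu = mu0, sigma = sd(values)),
      control = ctrl
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # exactly symmetric histograms make the location gradient vanish at the
    # sample-mean start; hold mu there and fit amplitude and width only
    fit <- minpack.lm::nlsLM(
      count ~ A * exp(-(mid - mu0)^2 / (2 * sigma^2)),
      data = df,
      start = list(A = max(df$count), sigma = sd(values)),
      control = ctrl
    )
  }
  est <- stats::coef(fit)
  structure(list(
    histogram = df,
    mu = if ("mu" %in% names(est)) unname(est["mu"]) else mu0,
    sigma = abs(unname(est["sigma"])),
    amplitude = unname(est["A"]),
    rss = sum(stats::resid(fit)^2),
    n = length(values)
  ), class = "gaussian_hist_fit")
}

#' @export
print.gaussian_hist_fit <- function(x, ...) {
  cat(sprintf(
    "<gaussian_hist_fit> mu = %.4g, sigma = %.4g, amplitude = %.4g (%d values, %d bins, rss %.4g)\n",
    x$mu, x$sigma, x$amplitude, x$n, nrow(x$histogram), x$rss
  ))
  invisible(x)
}

#' @describeIn fit_gaussian_histogram parameter table (`term`, `estimate`).
#' @param x a `gaussian_hist_fit`.
#' @param ... unused.
#' @export
tidy.gaussian_hist_fit <- function(x, ...) {
  tibble(
    term = c("mu", "sigma", "amplitude"),
    estimate = c(x$mu, x$sigma, x$amplitude)
  )
}

#' @describeIn fit_gaussian_histogram one-row fit summary.
#' @export
glance.gaussian_hist_fit <- function(x, ...) {
  tibble(mu = x$mu, sigma = x$sigma, amplitude = x$amplitude,
         rss = x$rss, n = x$n, n_bins = nrow(x$histogram))
}

#' Two-sample Student's t-test between conditions
#'
#' Pooled-variance two-sided Student's t-test, the comparison used for
#' per-condition detachment-work and intensity summaries.
#'
#' @param group_a,group_b numeric samples, each with at least 2 values.
#' @return A one-row tibble: `t`, `df`, `p`.
#' @export
compare_groups_ttest <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 values.")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = TRUE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

#' Summarize detachment work for a set of curves
#'
#' Convenience wrapper running baseline correction and work computation on
#' a list of curves and binding per-curve metrics, with the per-curve
#' condition label pulled from metadata when present.
#'
#' @param curves list of [force_curve()] objects.
#' @param tail_fraction passed to [baseline_correct()].
#' @return A tibble with one row per curve: `curve`, `condition`, `work_J`,
#'   `f_max_pN`, `baseline_pN`, `detach_index`.
#' @export
detachment_work_table <- function(curves, tail_fraction = 0.1) {
  purrr::imap(curves, function(cv, i) {
    met <- compute_detachment_work(baseline_correct(cv, tail_fraction))
    meta <- attr(cv, "metadata") %||% list()
    mutate(met,
      curve = meta$curve_id %||% as.character(i),
      condition = meta$condition %||% NA_character_,
      .before = 1
    )
  }) |> bind_rows()
}
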