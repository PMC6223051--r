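#' Build a profile map from normalized profiles
#'
#' Stacks length-normalized intensity profiles as the columns of an `L x n`
#' matrix (the "profile map"): rows index the common normalized position
#' axis (1..L arbitrary units), columns index individual profiles. The map
#' is the object that is denoised, geometrically compensated, and
#' summarized.
#'
#' @param profiles a list of normalized [intensity_profile()] objects, all
#'   of the same kind and length.
#' @return A `profile_map` object: the matrix plus `kind` and per-column
#'   `provenance` attributes.
#' @export
build_profile_map <- function(profiles) {
  if (length(profiles) < 1) abort("need at least one profile.")
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    if (!isTRUE(attr(p, "normalized"))) {
      abort(sprintf("profile %d is not length-normalized.", i))
    }
  }
  lens <- purrr::map_int(profiles, ~ nrow(.x))
  if (length(unique(lens)) != 1) {
    abort(sprintf("profile %d has length %d, expected %d.",
                  which(lens != lens[1])[1], lens[lens != lens[1]][1], lens[1]))
  }
  kinds <- purrr::map_chr(profiles, profile_kind)
  if (length(unique(kinds)) != 1) {
    abort(sprintf("profile %d has kind %s; all profiles must share one kind.",
                  which(kinds != kinds[1])[1], kinds[kinds != kinds[1]][1]))
  }
  m <- vapply(profiles, profile_values, numeric(lens[1]))
  profile_map(m, kind = kinds[1],
              provenance = purrr::map_chr(profiles, ~ attr(.x, "source") %||% NA_character_))
}

#' @rdname build_profile_map
#' @param matrix numeric `L x n` matrix, finite and non-negative.
#' @param kind profile kind shared by all columns.
#' @param provenance character vector of column identifiers.
#' @export
profile_map <- function(matrix, kind = "IN", provenance = NULL) {
  if (!is.matrix(matrix) || any(!is.finite(matrix)) || any(matrix < 0)) {
    abort("profile map must be a finite non-negative numeric matrix.")
  }
  if (is.null(provenance)) provenance <- sprintf("col_%02d", seq_len(ncol(matrix)))
  structure(matrix,
    kind = kind, provenance = provenance,
    class = c("profile_map", "matrix", "array")
  )
}

#' @export
print.profile_map <- function(x, ...) {
  cat(sprintf("<profile_map> L = %d positions x n = %d profiles (kind %s)\n",
              nrow(x), ncol(x), attr(x, "kind")))
  invisible(x)
}

#' @describeIn build_profile_map long-format view of a map: one row per
#'   (position, profile) cell with columns `position`, `profile`,
#'   `intensity`.
#' @param x a `profile_map`.
#' @param ... unused.
#' @export
tidy.profile_map <- function(x, ...) {
  prov <- attr(x, "provenance")
  tibble(
    position = rep(seq_len(nrow(x)), times = ncol(x)),
    profile = rep(prov, each = nrow(x)),
    intensity = as.numeric(x)
  )
}

#' Denoise a profile map under a Poisson noise model
#'
#' Fluorescence counts carry Poisson photon noise. Each column is replaced
#' by the maximum a posteriori estimate under a Poisson likelihood with a
#' quadratic first-difference smoothness prior along the position axis:
#' minimize `sum(u - y * log u) + lambda * sum(diff(u)^2)` over `u > 0`.
#' Solved per column by damped Newton iterations with backtracking, so the
#' objective decreases monotonically. `lambda = 0` returns the input (zeros
#' lifted to a small positive floor, since the Poisson mean must be
#' positive).
#'
#' @param map a [profile_map()].
#' @param lambda smoothness weight, >= 0.
#' @param max_iter,tol Newton iteration cap and relative objective change
#'   tolerance.
#' @return A denoised `profile_map` of the same shape.
#' @export
denoise_map <- function(map, lambda = 10, max_iter = 100, tol = 1e-10) {
  if (any(!is.finite(map))) abort("map contains non-finite values.")
  if (lambda < 0) abort("`lambda` must be >= 0.")
  y <- unclass(map)
  attributes(y) <- list(dim = dim(y))
  floor_u <- 1e-8
  if (lambda == 0) {
    out <- pmax(y, floor_u)
    return(profile_map(out, kind = attr(map, "kind"), provenance = attr(map, "provenance")))
  }
  L <- nrow(y)
  # D'D for first differences: tridiagonal second-difference operator
  DtD <- diag(c(1, rep(2, max(L - 2, 0)), 1)[seq_len(L)])
  if (L >= 2) {
    for (i in seq_len(L - 1)) {
      DtD[i, i + 1] <- -1
      DtD[i + 1, i] <- -1
    }
  }
  objective <- function(u, yc) sum(u - ifelse(yc > 0, yc * log(u), 0)) +
    lambda * sum(diff(u)^2)
  out <- y
  for (j in seq_len(ncol(y))) {
    yc <- y[, j]
    u <- pmax(yc, 1)
    f <- objective(u, yc)
    for (it in seq_len(max_iter)) {
      grad <- 1 - yc / u + 2 * lambda * as.numeric(DtD %*% u)
      hess <- DtD * (2 * lambda)
      diag(hess) <- diag(hess) + yc / u^2 + 1e-12
      step <- as.numeric(solve(hess, grad))
      alpha <- 1
      repeat {
        u_new <- u - alpha * step
        if (all(u_new > 0)) {
          f_new <- objective(u_new, yc)
          if (f_new <= f) break
        }
        alpha <- alpha / 2
        if (alpha < 1e-12) { u_new <- u; f_new <- f; break }
      }
      done <- abs(f - f_new) <= tol * (abs(f) + 1e-12)
      u <- u_new; f <- f_new
      if (done) break
    }
    out[, j] <- pmax(u, floor_u)
  }
  profile_map(out, kind = attr(map, "kind"), provenance = attr(map, "provenance"))
}

# piecewise-linear endpoint-fixed warp evaluated at positions p
warp_eval <- function(knot_x, knot_t, p) {
  approx(knot_x, knot_t, xout = p, rule = 2)$y
}

#' Geometrically compensate a profile map
#'
#' The registration step of the internuclear profile algorithm: each column
#' profile is re-parameterized by a monotone, endpoint-fixed,
#' piecewise-linear warp of the position axis so that the across-profile
#' variability of the map along the rows is minimized. The compensated
#' column `j` at position `p` is column `j` evaluated at `w_j(p)`. Warps are
#' penalized for deviating from the identity (a Gaussian prior on knot
#' displacements with weight `gamma`), which regularizes the fit in flat
#' profile regions. Fitting is block-coordinate descent: the row-wise mean
#' profile is the running reference, each column's interior knots are
#' refined in turn by a grid search plus local optimization, and updates
#' are only accepted when they lower the penalized objective, so the
#' objective trace is non-increasing.
#'
#' @param map a [profile_map()] with at least 1 column (a single column is
#'   returned untouched with an identity warp).
#' @param n_knots number of interior warp knots (>= 1); must leave room on
#'   the position axis.
#' @param gamma weight of the identity prior on knot displacements, >= 0.
#' @param max_iter outer iteration cap.
#' @param tol relative objective-change convergence tolerance.
#' @param max_knot_shift largest allowed knot displacement, positions.
#' @return A `profile_compensation` object: list with `compensated`
#'   (profile_map), `warps` (list of tibbles `knot_position`, `knot_image`
#'   including fixed endpoints), `iterations`, `objective_trace`,
#'   `converged`.
#' @export
compensate_map <- function(map, n_knots = 3, gamma = 1, max_iter = 50,
                           tol = 1e-6, max_knot_shift = 15) {
  L <- nrow(map); n <- ncol(map)
  if (n_knots < 1 || n_knots > L - 2) {
    abort(sprintf("`n_knots` must be between 1 and L - 2 = %d.", L - 2))
  }
  y <- unclass(map)
  attributes(y) <- list(dim = dim(y))
  knot_x <- seq(1, L, length.out = n_knots + 2)
  identity_t <- knot_x

  col_warped <- function(col, knot_t) {
    approx(seq_len(L), col, xout = warp_eval(knot_x, knot_t, seq_len(L)))$y
  }
  col_objective <- function(col, knot_t, ref) {
    sum((col_warped(col, knot_t) - ref)^2) + gamma * sum((knot_t - knot_x)^2)
  }

  knots <- matrix(rep(identity_t, n), nrow = n_knots + 2)
  compensated <- y
  zero_var <- apply(y, 2, function(v) var(v) == 0)

  total_objective <- function(comp, kn) {
    r <- rowMeans(comp)
    sum((comp - r)^2) + gamma * sum((kn - identity_t)^2)
  }
  trace <- total_objective(compensated, knots)
  converged <- FALSE
  iterations <- 0

  if (n >= 2) {
    for (iter in seq_len(max_iter)) {
      iterations <- iter
      ref <- rowMeans(compensated)
      for (j in seq_len(n)) {
        if (zero_var[j]) next
        kt <- knots[, j]
        f_cur <- col_objective(y[, j], kt, ref)
        for (k in seq_len(n_knots) + 1) {
          lo <- max(kt[k - 1] + 0.5, knot_x[k] - max_knot_shift)
          hi <- min(kt[k + 1] - 0.5, knot_x[k] + max_knot_shift)
          if (lo >= hi) next
          cand <- seq(lo, hi, length.out = 25)
          fc <- vapply(cand, function(tk) {
            kt2 <- kt; kt2[k] <- tk
            col_objective(y[, j], kt2, ref)
          }, numeric(1))
          best <- which.min(fc)
          blo <- cand[max(best - 1, 1)]; bhi <- cand[min(best + 1, length(cand))]
          opt <- stats::optimize(function(tk) {
            kt2 <- kt; kt2[k] <- tk
            col_objective(y[, j], kt2, ref)
          }, interval = c(blo, bhi))
          tk_new <- if (opt$objective < fc[best]) opt$minimum else cand[best]
          kt2 <- kt; kt2[k] <- tk_new
          f_new <- col_objective(y[, j], kt2, ref)
          if (f_new < f_cur) { kt <- kt2; f_cur <- f_new }
        }
        knots[, j] <- kt
        compensated[, j] <- col_warped(y[, j], kt)
      }
      f_total <- total_objective(compensated, knots)
      trace <- c(trace, min(f_total, trace[length(trace)]))
      rel_change <- (trace[iter] - trace[iter + 1]) / (abs(trace[iter]) + 1e-12)
      if (rel_change < tol) { converged <- TRUE; break }
    }
  } else {
    converged <- TRUE
  }

  warps <- purrr::map(seq_len(n), function(j) {
    tibble(knot_position = knot_x, knot_image = knots[, j])
  })
  structure(list(
    compensated = profile_map(pmax(compensated, 0),
                              kind = attr(map, "kind"),
                              provenance = attr(map, "provenance")),
    warps = warps,
    iterations = iterations,
    objective_trace = trace,
    converged = converged
  ), class = "profile_compensation")
}

#' @export
print.profile_compensation <- function(x, ...) {
  cat(sprintf(
    "<profile_compensation> %d columns, %d iteration(s), %sconverged\n  objective %.4g -> %.4g\n",
    ncol(x$compensated), x$iterations, if (x$converged) "" else "NOT ",
    x$objective_trace[1], x$objective_trace[length(x$objective_trace)]
  ))
  invisible(x)
}

#' Warp-implied displacement of a compensation result
#'
#' The displacement `w_j(p) - p` of each column's warp at a reference
#' position (typically the template peak). For a column that is the common
#' shape shifted right by `s` positions, the displacement at the shape's
#' landmarks recovers `s`.
#'
#' @param compensation a `profile_compensation`.
#' @param position position (1..L) at which to evaluate the warps.
#' @return A tibble with `profile`, `shift` (positions).
#' @export
warp_shift_at <- function(compensation, position) {
  prov <- attr(compensation$compensated, "provenance")
  shifts <- purrr::map_dbl(compensation$warps, function(w) {
    warp_eval(w$knot_position, w$knot_image, position) - position
  })
  tibble(profile = prov, shift = shifts)
}

#' @describeIn compensate_map broom-style per-column warp knots.
#' @param x a `profile_compensation`.
#' @param ... unused.
#' @export
tidy.profile_compensation <- function(x, ...) {
  prov <- attr(x$compensated, "provenance")
  purrr::imap(x$warps, function(w, j) {
    mutate(w, profile = prov[[j]], .before = 1)
  }) |> bind_rows()
}

#' @describeIn compensate_map one-row fit summary (iterations, convergence,
#'   initial/final objective).
#' @export
glance.profile_compensation <- function(x, ...) {
  tibble(
    n_profiles = ncol(x$compensated),
    iterations = x$iterations,
    converged = x$converged,
    objective_initial = x$objective_trace[1],
    objective_final = x$objective_trace[length(x$objective_trace)]
  )
}

#' Summarize a profile map
#'
#' Per-position arithmetic mean and population standard deviation across the
#' columns of a (typically denoised and compensated) profile map: the
#' average and standard-deviation profiles.
#'
#' @param map a [profile_map()].
#' @return A `profile_summary` tibble: `position`, `mean`, `sd`, `n`.
#' @export
summarize_map <- function(map) {
  m <- unclass(map)
  attributes(m) <- list(dim = dim(m))
  mu <- rowMeans(m)
  sdv <- sqrt(rowMeans((m - mu)^2))  # population SD; 0 when n = 1
  out <- tibble(position = seq_len(nrow(m)), mean = mu, sd = sdv, n = ncol(m))
  structure(out, kind = attr(map, "kind"),
            class = c("profile_summary", class(out)))
}

#' Maximum mean ratio (MMR) of a profile
#'
#' The localization statistic of the internuclear profile analysis: the
#' maximum fluorescence value divided by the mean fluorescence of the
#' profile. A membrane-localized marker concentrates signal at the junction
#' peak, giving MMR well above 1; a uniformly cytoplasmic marker gives MMR
#' close to 1. The ratio is scale-invariant and always >= 1.
#'
#' @param profile an [intensity_profile()], a `profile_summary` (its mean
#'   profile is used), or a bare numeric vector.
#' @return The MMR, a unitless ratio >= 1.
#' @examples
#' compute_mmr(c(0, 0, 10, 0, 0))  # 5
#' @export
compute_mmr <- function(profile) {
  v <- if (inherits(profile, "profile_summary")) profile$mean else profile_values(profile)
  if (length(v) < 1 || any(!is.finite(v))) abort("profile must be finite and non-empty.")
  m <- mean(v)
  if (m <= 0) abort("MMR is undefined for an all-zero profile (mean must be > 0).")
  max(v) / m
}

#' Mean intensity over the membrane window
#'
#' Mean fluorescence over a window of normalized positions covering the
#' cell-cell junction. For internuclear profiles normalized to 100 a.u. the
#' junction lies midway between the nuclei, so the default window is the
#' central positions 46..55.
#'
#' @param profile an [intensity_profile()], `profile_summary` (mean profile
#'   used), or numeric vector.
#' @param window `c(start, end)` positions, inclusive, within the profile.
#' @return Mean intensity over the window (arbitrary units).
#' @export
membrane_mean_intensity <- function(profile, window = c(46, 55)) {
  v <- if (inherits(profile, "profile_summary")) profile$mean else profile_values(profile)
  if (window[1] >= window[2]) abort("`window` must satisfy start < end.")
  if (window[1] < 1 || window[2] > length(v)) {
    abort(sprintf("window [%d, %d] out of profile range [1, %d].",
                  window[1], window[2], length(v)))
  }
  mean(v[window[1]:window[2]])
}
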