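test_that("Hooke conversion is exact and linear", {
  expect_equal(deflection_to_force(10, 0.03), 300)
  expect_equal(deflection_to_force(0, 0.03), 0)
  d <- runif(5, -50, 50)
  expect_equal(deflection_to_force(2 * d, 0.03), 2 * deflection_to_force(d, 0.03))
})

test_that("baseline correction centers the detached tail", {
  fc <- sim_force_curve(f_max_pN = 150, shape = "triangular", event_um = 2,
                        noise_sd_pN = 0, seed = 1)
  # already at baseline 0: unchanged
  b0 <- baseline_correct(fc$curve)
  expect_equal(b0$force_pN, fc$curve$force_pN)
  expect_equal(attr(b0, "baseline_pN"), 0)

  # constant offset is removed exactly
  off <- fc$curve
  off$force_pN <- off$force_pN + 50
  b1 <- baseline_correct(off)
  expect_equal(attr(b1, "baseline_pN"), 50)
  expect_equal(b1$force_pN, fc$curve$force_pN)

  # noisy offset: residual tail median within 3 * sd / sqrt(n_tail)
  noisy <- sim_force_curve(f_max_pN = 150, shape = "triangular", event_um = 2,
                           noise_sd_pN = 10, n = 2000, seed = 5)$curve
  noisy$force_pN <- noisy$force_pN + 37
  b2 <- baseline_correct(noisy)
  r <- b2[b2$segment == "retract", ]
  tail_med <- median(tail(r$force_pN[order(r$height_um)], 200))
  expect_lt(abs(tail_med), 3 * 10 / sqrt(200))

  short <- force_curve(tibble::tibble(
    segment = "retract", height_um = 1:10, force_pN = 0
  ))
  expect_error(baseline_correct(short), "at least 20")
})

test_that("detachment work matches the analytic event areas", {
  tri <- sim_force_curve(f_max_pN = 200, shape = "triangular", event_um = 2,
                         noise_sd_pN = 0, seed = 1)
  m <- compute_detachment_work(baseline_correct(tri$curve))
  expect_equal(m$work_J, 2.0e-16, tolerance = 1e-3)
  expect_equal(m$f_max_pN, 200)

  rect <- sim_force_curve(f_max_pN = 100, shape = "rectangular", event_um = 1,
                          noise_sd_pN = 0, seed = 1)
  m2 <- compute_detachment_work(baseline_correct(rect$curve))
  expect_equal(m2$work_J, 1.0e-16, tolerance = 1e-3)

  steps <- sim_force_curve(f_max_pN = 90, shape = "multi_step", event_um = 3,
                           noise_sd_pN = 0, seed = 1)
  m3 <- compute_detachment_work(baseline_correct(steps$curve))
  expect_equal(m3$work_J, steps$truth$work_J, tolerance = 1e-3)

  flat <- sim_force_curve(true_work_J = 0, shape = "rectangular", seed = 1)
  m4 <- compute_detachment_work(baseline_correct(flat$curve))
  expect_equal(m4$work_J, 0)
  expect_equal(m4$f_max_pN, 0)

  # bilinearity on synthetic events: work scales with force and distance
  half_f <- sim_force_curve(f_max_pN = 100, shape = "triangular", event_um = 2,
                            noise_sd_pN = 0, seed = 1)
  expect_equal(
    compute_detachment_work(baseline_correct(half_f$curve))$work_J,
    m$work_J / 2,
    tolerance = 1e-3
  )
  half_d <- sim_force_curve(f_max_pN = 200, shape = "triangular", event_um = 1,
                            noise_sd_pN = 0, seed = 1)
  expect_equal(
    compute_detachment_work(baseline_correct(half_d$curve))$work_J,
    m$work_J / 2,
    tolerance = 1e-3
  )

  # resampling density: dense and sparse grids agree to trapezoid error
  sparse <- sim_force_curve(f_max_pN = 200, shape = "triangular", event_um = 2,
                            n = 200, noise_sd_pN = 0, seed = 1)
  expect_equal(
    compute_detachment_work(baseline_correct(sparse$curve))$work_J,
    2.0e-16, tolerance = 1e-3
  )

  bad <- force_curve(tibble::tibble(
    segment = "retract", height_um = c(1:30), force_pN = 0
  ))
  bad$height_um[5] <- 10  # break monotonicity after construction
  expect_error(compute_detachment_work(bad), "monotone|increasing")
})

test_that("mean recovered work tracks generator truth under noise", {
  works <- vapply(1:100, function(s) {
    fc <- sim_force_curve(f_max_pN = 200, shape = "triangular", event_um = 2,
                          noise_sd_pN = 10, n = 600, seed = s)
    compute_detachment_work(baseline_correct(fc$curve))$work_J
  }, numeric(1))
  expect_lt(abs(mean(works) - 2.0e-16) / 2.0e-16, 0.05)
})

test_that("the TSV dialect round-trips and resolves units", {
  fc <- sim_force_curve(f_max_pN = 120, shape = "multi_step", event_um = 2,
                        noise_sd_pN = 5, seed = 9)$curve
  attr(fc, "metadata") <- list(condition = "Mock", curve_id = "c01")
  tf <- tempfile(fileext = ".tsv")
  write_force_curve(fc, tf)
  back <- read_force_curves(tf)[[1]]
  expect_equal(back$height_um, fc$height_um, tolerance = 1e-8)
  expect_equal(back$force_pN, fc$force_pN, tolerance = 1e-8)
  expect_equal(back$segment, fc$segment)
  expect_equal(attr(back, "spring_constant"), 0.03)
  expect_equal(attr(back, "metadata")$condition, "Mock")

  # volts + sensitivity convert through Hooke's law
  tv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "# spring_constant_N_per_m: 0.03",
    "# deflection_sensitivity_nm_per_V: 50",
    "# segment: retract",
    "height_um\tdeflection_V",
    paste(seq(0, 2, length.out = 25), rep(0.2, 25), sep = "\t")
  ), tv)
  cv <- read_force_curves(tv)[[1]]
  expect_equal(unique(cv$force_pN), 0.03 * 0.2 * 50 * 1e3)  # 300 pN

  # volts without sensitivity is an error
  tv2 <- tempfile(fileext = ".tsv")
  writeLines(c(
    "# spring_constant_N_per_m: 0.03",
    "# segment: retract",
    "height_um\tdeflection_V",
    "0\t0.1", "1\t0.1"
  ), tv2)
  expect_error(read_force_curves(tv2), "sensitivity")

  # a directory reads in lexicographic order
  dd <- file.path(tempdir(), "curves_dir")
  dir.create(dd, showWarnings = FALSE)
  file.remove(list.files(dd, full.names = TRUE))
  for (nm in c("b.tsv", "a.tsv", "c.tsv")) {
    cc <- sim_force_curve(f_max_pN = 10, shape = "triangular", seed = 1)$curve
    attr(cc, "metadata") <- list(curve_id = nm)
    write_force_curve(cc, file.path(dd, nm))
  }
  lst <- read_force_curves(dd)
  expect_equal(
    vapply(lst, function(x) attr(x, "metadata")$curve_id, character(1)),
    c("a.tsv", "b.tsv", "c.tsv")
  )
})

test_that("Gaussian histogram fits recover known parameters", {
  set.seed(77)
  x <- rnorm(1e4, 5, 1)
  fit <- fit_gaussian_histogram(x, bins = 30)
  expect_gt(fit$mu, 4.95); expect_lt(fit$mu, 5.05)
  expect_gt(fit$sigma, 0.95); expect_lt(fit$sigma, 1.05)
  expect_equal(nrow(fit$histogram), 30)

  # symmetric two-point sample: fitted mean near 0
  sym <- rep(c(-1, 1), each = 50)
  fsym <- fit_gaussian_histogram(sym, bins = 10)
  expect_lt(abs(fsym$mu), 0.05)

  expect_error(fit_gaussian_histogram(rep(3, 50)), "zero variance")
  expect_error(fit_gaussian_histogram(1:5), "at least 10")

  td <- tidy(fit)
  expect_equal(td$term, c("mu", "sigma", "amplitude"))
  expect_equal(glance(fit)$n_bins, 30)
})

test_that("pooled t-test matches the textbook formula oracle", {
  a <- c(30.02, 29.99, 30.11)
  b <- c(29.89, 29.93, 29.72)
  res <- compare_groups_ttest(a, b)
  expect_equal(res$t, pooled_t_oracle(a, b), tolerance = 1e-6)
  expect_equal(res$df, 4)

  same <- compare_groups_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(compare_groups_ttest(1, c(1, 2)), "at least 2")
})

test_that("detachment work tables carry per-curve metadata", {
  curves <- lapply(1:3, function(s) {
    cv <- sim_force_curve(f_max_pN = 100 * s, shape = "triangular", event_um = 2,
                          noise_sd_pN = 0, seed = s)$curve
    attr(cv, "metadata") <- list(curve_id = sprintf("c%02d", s), condition = "Pcad")
    cv
  })
  tab <- detachment_work_table(curves)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$curve, c("c01", "c02", "c03"))
  expect_equal(tab$work_J, c(1, 2, 3) * 1e-16, tolerance = 1e-3)
})
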