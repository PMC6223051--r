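norm_prof <- function(v, kind = "IN", source = NA) {
  intensity_profile(v, kind = kind, normalized = TRUE, source = source)
}

test_that("profile maps stack normalized profiles as columns in order", {
  v <- gauss_template()
  m <- build_profile_map(list(norm_prof(v, source = "a"),
                              norm_prof(v, source = "b"),
                              norm_prof(v, source = "c")))
  expect_equal(dim(m), c(100, 3))
  expect_equal(unclass(m)[, 2], v, ignore_attr = TRUE)
  expect_equal(attr(m, "provenance"), c("a", "b", "c"))

  one <- build_profile_map(list(norm_prof(v)))
  expect_equal(dim(one), c(100, 1))

  expect_error(
    build_profile_map(list(norm_prof(v), norm_prof(v[1:50]))),
    "length"
  )
  expect_error(
    build_profile_map(list(norm_prof(v), norm_prof(v, kind = "RD"))),
    "kind"
  )
  expect_error(
    build_profile_map(list(intensity_profile(v))),  # not normalized
    "normalized"
  )

  # tidy() gives the long view back
  td <- tidy(m)
  expect_equal(nrow(td), 300)
  expect_equal(td$intensity[td$profile == "b"], v)
})

test_that("Poisson MAP denoising obeys its closed-form and oracle contracts", {
  v <- gauss_template()
  m <- profile_map(cbind(v, v))

  # lambda = 0 is the identity (up to the positivity floor on zeros)
  withz <- profile_map(cbind(c(0, v[-1]), v))
  d0 <- denoise_map(withz, lambda = 0)
  expect_equal(unclass(d0)[-1, 1], v[-1], ignore_attr = TRUE)
  expect_gt(unclass(d0)[1, 1], 0)
  expect_lte(unclass(d0)[1, 1], 1e-6)

  # constant columns are stationary for any lambda
  cm <- profile_map(matrix(50, 100, 3))
  dc <- denoise_map(cm, lambda = 25)
  expect_equal(as.numeric(unclass(dc)), rep(50, 300), tolerance = 1e-6)

  # Monte-Carlo oracle: denoising a Poisson-corrupted constant map moves it
  # toward the true rate
  set.seed(31)
  y <- matrix(rpois(100 * 20, 50), 100, 20)
  den <- denoise_map(profile_map(y), lambda = 10)
  expect_lt(mean(abs(unclass(den) - 50)), mean(abs(y - 50)))

  # soft mass conservation at moderate smoothing
  expect_lt(abs(sum(den) / sum(y) - 1), 0.05)

  expect_error(denoise_map(profile_map(cbind(v)), lambda = -1), "lambda")
})

test_that("geometric compensation aligns shifted ensembles and recovers shifts", {
  tmpl <- gauss_template()
  ens <- sim_profile_ensemble(tmpl, 12, max_shift = 5, noise = "none", seed = 11)
  m <- build_profile_map(lapply(ens$profiles, normalize_profile_length))

  pre_sd <- mean(summarize_map(m)$sd)
  comp <- compensate_map(m)
  post_sd <- mean(summarize_map(comp$compensated)$sd)
  expect_lte(post_sd, 0.5 * pre_sd)

  # objective trace is non-increasing and shapes are preserved
  expect_true(all(diff(comp$objective_trace) <= 1e-8))
  expect_equal(dim(comp$compensated), dim(m))

  # warp-implied displacement at the template peak recovers the true shift
  shifts <- warp_shift_at(comp, which.max(tmpl))$shift
  expect_gte(mean(abs(shifts - ens$shifts) <= 1), 0.9)

  # warps are monotone bijections of [1, L] with fixed endpoints
  for (w in comp$warps) {
    expect_true(all(diff(w$knot_image) > 0))
    expect_equal(w$knot_image[1], 1)
    expect_equal(w$knot_image[length(w$knot_image)], 100)
  }

  # glance/tidy views
  g <- glance(comp)
  expect_equal(g$n_profiles, 12)
  expect_lte(g$objective_final, g$objective_initial)
  expect_equal(nrow(tidy(comp)), 12 * 5)
})

test_that("compensation is a no-op on degenerate maps", {
  v <- gauss_template()
  same <- profile_map(cbind(v, v, v))
  comp <- compensate_map(same)
  expect_equal(unclass(comp$compensated), unclass(same),
               tolerance = 1e-10, ignore_attr = TRUE)
  for (w in comp$warps) expect_equal(w$knot_image, w$knot_position)

  single <- compensate_map(profile_map(cbind(v)))
  expect_equal(unclass(single$compensated), cbind(v), ignore_attr = TRUE)
  expect_true(single$converged)

  expect_error(compensate_map(same, n_knots = 200), "n_knots")
})

test_that("map summaries match an independent loop-based oracle", {
  ident <- profile_map(cbind(gauss_template(), gauss_template()))
  s <- summarize_map(ident)
  expect_equal(s$mean, gauss_template())
  expect_true(all(s$sd == 0))

  two <- profile_map(cbind(rep(0, 10), rep(2, 10)))
  s2 <- summarize_map(two)
  expect_true(all(s2$mean == 1))
  expect_true(all(s2$sd == 1))

  set.seed(12)
  y <- matrix(runif(100 * 10, 0, 5), 100, 10)
  s3 <- summarize_map(profile_map(y))
  mu_oracle <- numeric(100); sd_oracle <- numeric(100)
  for (i in 1:100) {
    mu_oracle[i] <- sum(y[i, ]) / 10
    sd_oracle[i] <- sqrt(sum((y[i, ] - mu_oracle[i])^2) / 10)
  }
  expect_equal(s3$mean, mu_oracle, tolerance = 1e-12)
  expect_equal(s3$sd, sd_oracle, tolerance = 1e-12)
})

test_that("MMR follows its closed forms and scale invariance", {
  expect_equal(compute_mmr(rep(4.2, 100)), 1)
  expect_equal(compute_mmr(c(0, 0, 10, 0, 0)), 5)
  spike <- c(rep(0, 99), 7)
  expect_equal(compute_mmr(spike), 100)
  expect_error(compute_mmr(rep(0, 10)), "all-zero")

  set.seed(3)
  for (i in 1:20) {
    v <- runif(50, 0, 10)
    c0 <- runif(1, 0.1, 100)
    expect_equal(compute_mmr(c0 * v), compute_mmr(v))
  }

  # membrane-peaked beats uniform
  expect_gt(compute_mmr(gauss_template()), compute_mmr(rep(10, 100)))

  # works on summaries too
  s <- summarize_map(profile_map(cbind(gauss_template())))
  expect_equal(compute_mmr(s), max(gauss_template()) / mean(gauss_template()))
})

test_that("membrane-window means follow their closed forms", {
  expect_equal(membrane_mean_intensity(rep(3, 100), c(20, 80)), 3)
  ramp <- 0:99
  expect_equal(membrane_mean_intensity(ramp, c(45, 55)), 49)
  expect_error(membrane_mean_intensity(ramp, c(90, 120)), "out of profile range")
  expect_error(membrane_mean_intensity(ramp, c(55, 45)), "start < end")
})

test_that("the grouped pipeline discriminates membrane from cytoplasmic marker", {
  gen_group <- function(mf, seeds) {
    lapply(seeds, function(s) {
      sc <- sim_cell_pair_scene(membrane_fraction = mf, seed = s)
      scene_internuclear_profile(sc$marker, sc$nuclei)
    })
  }
  mem <- gen_group(0.8, 1:8)
  cyt <- gen_group(0.2, 101:108)
  res_mem <- analyze_profile_group(mem)
  res_cyt <- analyze_profile_group(cyt)
  # the membrane marker concentrates signal at the junction: higher MMR and
  # higher junction-window enrichment relative to the profile's own mean
  expect_gt(res_mem$stats$mmr, res_cyt$stats$mmr)
  enrich <- function(res) res$stats$membrane_mean / mean(res$summary$mean)
  expect_gt(enrich(res_mem), 1.2)
  expect_lt(abs(enrich(res_cyt) - 1), 0.1)
  expect_equal(res_mem$stats$n_profiles, 8)
})
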