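# Synthetic neuropil generator: populations, calibrated pairs, meshes,
# vesicle clouds.

test_that("population generation is deterministic and respects invariants", {
  cfg <- population_config(n_spines = 120, seed = 17)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 120)
  num <- c("head_volume", "head_area", "psd_area", "neck_length",
           "neck_diameter", "neck_volume", "whole_spine_volume")
  expect_true(all(sapply(a[num], function(x) all(x > 0))))
  expect_true(all(a$docked_vesicles >= 0))
  expect_true(all(a$docked_vesicles == round(a$docked_vesicles)))
  # additive volume identity
  expect_equal(a$whole_spine_volume, a$head_volume + a$neck_volume)
  expect_true(all(a$whole_spine_volume >= a$head_volume))
  # unique axons before pair planting
  expect_false(anyDuplicated(a$axon_id) > 0)
})

test_that("invalid population configs name the offending field", {
  expect_error(population_config(n_spines = 1), "n_spines")
  expect_error(population_config(log_sigma = 0), "log_sigma")
  expect_error(population_config(range_factor_target = 0.5),
               "range_factor_target")
  mc <- default_metric_coupling()
  mc$head_area$log_noise_sd <- -0.1
  expect_error(population_config(metric_coupling = mc),
               "head_area.log_noise_sd")
})

test_that("noiseless power-law coupling gives a perfect log-log fit", {
  mc <- default_metric_coupling()
  mc$head_area$log_noise_sd <- 0
  pop <- generate_population(population_config(n_spines = 80,
                                               metric_coupling = mc,
                                               seed = 3))
  fit <- loglog_regression(pop$head_volume, pop$head_area)
  expect_equal(fit$r2, 1)
  expect_equal(fit$slope, 2 / 3)
})

test_that("default coupling reproduces the strong/weak/null correlations", {
  strong <- 0L
  nullcorr <- 0L
  for (s in 1:20) {
    pop <- generate_population(population_config(seed = s))
    if (loglog_regression(pop$head_volume, pop$head_area)$r2 >= 0.98) {
      strong <- strong + 1L
    }
    if (loglog_regression(pop$head_volume, pop$neck_length)$p_slope > 0.05) {
      nullcorr <- nullcorr + 1L
    }
  }
  expect_equal(strong, 20L)
  expect_gte(nullcorr, 18L)
})

test_that("head volumes follow the configured log-normal", {
  rejections <- 0L
  for (s in 1:30) {
    pop <- generate_population(population_config(seed = s))
    p <- suppressWarnings(
      ks.test(pop$head_volume, plnorm, meanlog = log(0.05),
              sdlog = 0.6)$p.value)
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 2L)  # >= 95% of seeds retain the log-normal
})

test_that("dynamic range falls in the Monte-Carlo calibrated band", {
  # at n = 287, log_sigma = 0.6 the max/min ratio has central mass
  # ~[18, 64]; [14, 80] covers > 99% of seeds (2000-rep calibration)
  for (s in 1:20) {
    v <- generate_population(population_config(seed = s))$head_volume
    expect_gt(max(v) / min(v), 14)
    expect_lt(max(v) / min(v), 80)
  }
})

test_that("within-pair jitter calibration has the right fixed points", {
  expect_equal(calibrate_within_pair_sd(0), 0)
  expect_equal(calibrate_within_pair_sd(0.083), 0.1742, tolerance = 2e-4)
  expect_error(calibrate_within_pair_sd(1.2), "\\[0, 1\\)")
  expect_error(calibrate_within_pair_sd(-0.1), "\\[0, 1\\)")
  # Monte-Carlo round trip: 1e5 simulated pairs recover the target median
  sig <- calibrate_within_pair_sd(0.083)
  set.seed(123)
  delta <- rnorm(1e5, 0, sig)
  cvs <- pair_cv(exp(delta / 2), exp(-delta / 2))
  expect_equal(median(cvs), 0.083, tolerance = 0.02)
  # forward map agrees with the inverse
  pc <- pair_config(within_pair_log_sd = sig,
                    target_median_pair_cv = NULL)
  expect_equal(pc$target_median_pair_cv, 0.083, tolerance = 1e-10)
})

test_that("pair config requires exactly one free parameter", {
  expect_error(pair_config(within_pair_log_sd = NULL,
                           target_median_pair_cv = NULL), "one of")
  expect_equal(pair_config()$within_pair_log_sd,
               calibrate_within_pair_sd(0.083))
})

test_that("coupled pairs are planted with shared labels and exact ground
           truth", {
  pop <- generate_population(population_config(seed = 41))
  cp <- generate_coupled_pairs(pop, pair_config(seed = 41))
  pairs <- find_axon_coupled_pairs(cp$population)
  sd_pairs <- pairs[pairs$same_dendrite, ]
  expect_equal(nrow(sd_pairs), 17)
  expect_false(any(sd_pairs$multi_contact))
  # recovered CVs equal the generator's ground truth
  expect_equal(sort(sd_pairs$cv_head_volume), sort(cp$truth$pair_cv))
  # members share axon and dendrite
  for (k in seq_len(nrow(cp$truth))) {
    a <- cp$population[cp$population$spine_id == cp$truth$spine_a[k], ]
    b <- cp$population[cp$population$spine_id == cp$truth$spine_b[k], ]
    expect_identical(a$axon_id, b$axon_id)
    expect_identical(a$dendrite_id, b$dendrite_id)
  }
})

test_that("zero jitter produces exactly matched pairs", {
  pop <- generate_population(population_config(n_spines = 40, seed = 2))
  cp <- generate_coupled_pairs(pop, pair_config(n_pairs = 5,
                                                within_pair_log_sd = 0,
                                                target_median_pair_cv = NULL,
                                                seed = 2))
  expect_true(all(cp$truth$pair_cv == 0))
  pairs <- find_axon_coupled_pairs(cp$population)
  expect_true(all(pairs$cv_head_volume[pairs$same_dendrite] == 0))
})

test_that("oversized pair requests are a sizing error", {
  pop <- generate_population(population_config(n_spines = 20, seed = 1))
  expect_error(generate_coupled_pairs(pop, pair_config(n_pairs = 11)),
               "exceeds")
})

test_that("spine meshes are watertight with analytic ground truth", {
  mesh <- generate_spine_mesh(0.524, 0.7, 0.2)
  expect_true(mesh_is_watertight(mesh))
  truth <- attr(mesh, "truth")
  # sphere radius recovers the nominal volume
  expect_equal(4 / 3 * pi * truth$sphere_radius^3, 0.524)
  # cap volume is just below the nominal sphere volume (thin neck)
  expect_lt(truth$head_volume, 0.524)
  expect_gt(truth$head_volume, 0.95 * 0.524)
  expect_true(all(c("head", "whole_spine", "psd", "active_zone") %in%
                    names(mesh$regions)))
  # head tags are a subset of whole-spine tags
  expect_true(all(mesh$regions$head %in% mesh$regions$whole_spine))
  expect_true(all(mesh$regions$psd %in% mesh$regions$head))
})

test_that("degenerate mesh dimensions are rejected", {
  expect_error(generate_spine_mesh(-1, 0.5, 0.1), "positive")
  expect_error(generate_spine_mesh(0.3, 0.5, -0.1), "positive")
  expect_error(generate_spine_mesh(0.3, 0, 0.1), "allow_zero_neck")
  expect_true(mesh_is_watertight(
    generate_spine_mesh(0.3, 0, 0.1, allow_zero_neck = TRUE)))
  # neck wider than the head cannot join
  expect_error(generate_spine_mesh(0.004, 0.5, 0.5), "smaller than")
})

test_that("vesicle clouds carry exact ground-truth docked labels", {
  mesh <- generate_spine_mesh(0.4, 0.6, 0.18)
  cloud <- generate_vesicle_cloud(200, mesh, docked_fraction_target = 0.25,
                                  seed = 5)
  expect_equal(nrow(cloud), 200)
  expect_equal(sum(cloud$docked), 50)
  expect_true(all(is.finite(as.matrix(cloud[, c("x_nm", "y_nm", "z_nm")]))))
  expect_equal(count_docked(cloud, mesh), 50)
  # empty cloud
  empty <- generate_vesicle_cloud(0, mesh)
  expect_equal(nrow(empty), 0)
  expect_equal(count_docked(empty, mesh), 0L)
  # missing active zone tag
  naked <- tagged_mesh(mesh$vertices, mesh$triangles,
                       regions = mesh$regions["head"])
  expect_error(generate_vesicle_cloud(10, naked), "active_zone")
})

test_that("generation is reproducible across the whole synthetic stack", {
  mesh <- generate_spine_mesh(0.4, 0.6, 0.18)
  c1 <- generate_vesicle_cloud(50, mesh, seed = 8)
  c2 <- generate_vesicle_cloud(50, mesh, seed = 8)
  expect_identical(c1, c2)
  p1 <- generate_coupled_pairs(
    generate_population(population_config(seed = 6)), pair_config(seed = 6))
  p2 <- generate_coupled_pairs(
    generate_population(population_config(seed = 6)), pair_config(seed = 6))
  expect_identical(p1, p2)
})
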