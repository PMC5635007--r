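test_that("grain-1 means reduce to all-or-nothing per-cell limits", {
  L <- generate_random_landscape(64, 0.10, seed = 31)
  p <- 3686 / 4096 # modified fraction
  res <- mean_extinction_at_scale(L, 1, "classic", z = 0.2)
  expect_equal(res$mean_epsilon, p, tolerance = 1e-12)
  expect_equal(res$sd_epsilon, sqrt(p * (1 - p)), tolerance = 1e-12)
  # countryside at grain 1: per-cell eps is 0 or sigma = 1 - (h2/h1)^z
  sigma <- 1 - 0.01024^0.2
  resc <- mean_extinction_at_scale(L, 1, "countryside", z = 0.2, h2 = 0.01024)
  expect_equal(resc$mean_epsilon, p * sigma, tolerance = 1e-12)
  expect_true(all(resc$epsilon %in% c(0, sigma)))
  # equal to the linear model at that grain
  resl <- mean_extinction_at_scale(L, 1, "linear", sigma = sigma)
  expect_equal(resc$mean_epsilon, resl$mean_epsilon, tolerance = 1e-12)
})

test_that("linear-model mean is the overall modified fraction times sigma at every grain", {
  L <- generate_random_landscape(32, 0.4, seed = 32)
  p <- mean(L$cells == 0L)
  for (omega in window_sizes(32)) {
    res <- mean_extinction_at_scale(L, omega, "linear", sigma = 0.6)
    expect_equal(res$mean_epsilon, 0.6 * p, tolerance = 1e-12)
  }
})

test_that("worked-example fixtures give exact hand-enumerable window means", {
  fx <- worked_example_landscapes()
  for (omega in c(1, 2, 4)) {
    expect_equal(
      mean_extinction_at_scale(fx$all_modified, omega, "classic", z = 0.2)$mean_epsilon,
      1
    )
    for (model in c("classic", "countryside", "linear")) {
      expect_equal(
        mean_extinction_at_scale(fx$all_native, omega, model,
          z = 0.2, sigma = 0.6
        )$mean_epsilon,
        0
      )
    }
  }
  # half_block: one 2x4 modified block; the four omega = 2 windows have
  # fractions 1, 1, 0, 0 (hand enumeration)
  hb <- partition_windows(fx$half_block, 2)
  expect_equal(sort(hb$modified_fractions), c(0, 0, 1, 1))
  expect_equal(
    mean_extinction_at_scale(fx$half_block, 2, "classic", z = 0.2)$mean_epsilon,
    2 / 4 # two fully converted windows contribute eps = 1, two contribute 0
  )
  # omega = 4: single window, half converted
  expect_equal(
    mean_extinction_at_scale(fx$half_block, 4, "classic", z = 0.2)$mean_epsilon,
    1 - 0.5^0.2,
    tolerance = 1e-12
  )
  expect_equal(
    mean_extinction_at_scale(fx$checkerboard, 2, "linear", sigma = 0.6)$mean_epsilon,
    0.3,
    tolerance = 1e-12
  )
})

test_that("mean extinction is non-increasing at every doubling (Jensen)", {
  for (seed in 1:5) {
    L <- generate_random_landscape(32, 0.25, seed = 40 + seed)
    for (model in c("classic", "countryside")) {
      means <- sapply(window_sizes(32), function(om) {
        mean_extinction_at_scale(L, om, model, z = 0.2, h2 = 0.05)$mean_epsilon
      })
      expect_true(all(diff(means) <= 1e-12))
    }
  }
})

test_that("countryside extinction never exceeds classic, per window and in the mean", {
  L <- generate_random_landscape(32, 0.25, seed = 50)
  for (omega in window_sizes(32)) {
    cl <- mean_extinction_at_scale(L, omega, "classic", z = 0.2)
    cs <- mean_extinction_at_scale(L, omega, "countryside", z = 0.2, h2 = 0.05)
    expect_true(all(cs$epsilon <= cl$epsilon + 1e-12))
    expect_lte(cs$mean_epsilon, cl$mean_epsilon + 1e-12)
  }
})

test_that("matrix parameters are reconciled through the affinity relation", {
  p <- resolve_matrix_params(z = 0.2, sigma = 0.6)
  expect_equal(p$h2, 0.4^5, tolerance = 1e-12)
  p2 <- resolve_matrix_params(z = 0.2, h2 = 0.01)
  expect_equal(p2$sigma, 1 - 0.01^0.2, tolerance = 1e-12)
  expect_error(resolve_matrix_params(z = 0.2, h2 = 0.5, sigma = 0.6), "inconsistent")
  expect_silent(resolve_matrix_params(z = 0.2, h2 = 0.4^5, sigma = 0.6))
  expect_error(resolve_matrix_params(z = 0.2), "supply")
  expect_error(
    mean_extinction_at_scale(
      worked_example_landscapes()$checkerboard, 2, "nonsense"
    ),
    "arg"
  )
})

test_that("single-replicate experiment equals per-grain means directly", {
  cfg <- scaling_config(
    side = 16, native_fraction = 0.25, n_replicates = 1,
    base_seed = 7, h2 = 0.01
  )
  curve <- run_scaling_experiment(cfg)
  set.seed(7)
  seed1 <- sample.int(.Machine$integer.max, 1)
  L <- generate_random_landscape(16, 0.25, seed = seed1)
  for (model in cfg$models) {
    for (omega in window_sizes(16)) {
      direct <- mean_extinction_at_scale(L, omega, model,
        z = 0.2, h2 = 0.01
      )
      row <- curve[curve$model == model & curve$omega == omega, ]
      expect_equal(row$mean_epsilon, direct$mean_epsilon, tolerance = 1e-12)
      expect_equal(row$sd_epsilon, direct$sd_epsilon, tolerance = 1e-12)
    }
  }
  # single landscape, whole-lattice window: no spread
  expect_true(all(curve$sd_epsilon[curve$omega == 16] == 0))
})

test_that("hospitable matrix gives an identically zero countryside curve", {
  cfg <- scaling_config(
    side = 16, n_replicates = 3, base_seed = 9, h2 = 1,
    native_fraction = 0.25, models = "countryside"
  )
  curve <- run_scaling_experiment(cfg)
  expect_true(all(abs(curve$mean_epsilon) < 1e-12))
})

test_that("experiment is reproducible and respects the replicate-sd mode", {
  cfg <- scaling_config(side = 16, n_replicates = 5, base_seed = 13, h2 = 0.01)
  c1 <- run_scaling_experiment(cfg)
  c2 <- run_scaling_experiment(cfg)
  expect_identical(c1$mean_epsilon, c2$mean_epsilon)
  cfg_rep <- scaling_config(
    side = 16, n_replicates = 5, base_seed = 13, h2 = 0.01,
    sd_mode = "replicate"
  )
  c3 <- run_scaling_experiment(cfg_rep)
  expect_identical(c1$mean_epsilon, c3$mean_epsilon)
  # at the full-lattice grain the pooled sd (over 5 identical-count windows)
  # and the sd of replicate means coincide up to the n vs n-1 denominator
  full1 <- c1$sd_epsilon[c1$omega == 16]
  full3 <- c3$sd_epsilon[c3$omega == 16]
  expect_equal(full3, full1 * sqrt(5 / 4), tolerance = 1e-9)
})

test_that("variance decay summary orders models linear, countryside, classic", {
  cfg <- scaling_config(n_replicates = 30, base_seed = 17, h2 = 0.01)
  curve <- run_scaling_experiment(cfg)
  vd <- variance_decay_summary(curve)
  expect_equal(vd$ordering, c("linear", "countryside", "classic"))
  # spread shrinks with grain from the first aggregated scale onwards
  for (m in c("classic", "countryside", "linear")) {
    sds <- vd$table$sd_epsilon[vd$table$model == m & vd$table$omega >= 2]
    expect_true(all(diff(sds) <= 1e-9))
  }
  # intermediate-grain ordering of the spread
  mid <- vd$table[vd$table$omega == 8, ]
  expect_lte(
    mid$sd_epsilon[mid$model == "linear"],
    mid$sd_epsilon[mid$model == "countryside"]
  )
  expect_lte(
    mid$sd_epsilon[mid$model == "countryside"],
    mid$sd_epsilon[mid$model == "classic"]
  )
})
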