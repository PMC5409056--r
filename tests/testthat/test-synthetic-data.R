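test_that("simulated communities follow the log-normal abundance model", {
  expect_equal(simulate_community(1, seed = 1)$abundance, 1)
  even <- simulate_community(1000, sdlog = 0, seed = 1)
  expect_equal(even$abundance, rep(1 / 1000, 1000))
  expect_error(simulate_community(0), "n_otus")

  # with sdlog = 2 the top decile of OTUs holds the log-normal's closed-form
  # share of total abundance: P-share above q90 = pnorm(sdlog - qnorm(0.9))
  share <- mean(purrr::map_dbl(1:5, function(s) {
    a <- sort(simulate_community(1000, sdlog = 2, seed = s)$abundance,
      decreasing = TRUE
    )
    sum(a[1:100])
  }))
  expect_gt(share, 0.5)
  expect_lt(abs(share - pnorm(2 - qnorm(0.9))), 0.05)

  # deterministic under a seed
  expect_identical(
    simulate_community(50, seed = 9),
    simulate_community(50, seed = 9)
  )
})

test_that("profile perturbation scales community shift with sigma", {
  prof <- simulate_community(50, sdlog = 1, seed = 3)
  expect_identical(perturb_profile(prof, 0, seed = 1), prof)
  expect_error(perturb_profile(prof, -1), "sigma")
  expect_false(identical(
    perturb_profile(prof, 1, seed = 1),
    perturb_profile(prof, 1, seed = 2)
  ))
  bc <- function(sigma, seed) {
    bray_curtis_dissimilarity(
      prof$abundance,
      perturb_profile(prof, sigma, seed = seed)$abundance
    )
  }
  small <- mean(purrr::map_dbl(1:100, ~ bc(0.1, .x)))
  large <- mean(purrr::map_dbl(1:100, ~ bc(2, .x)))
  expect_gt(large, small)
})

test_that("technical replicates are depth-exact random samples of the profile", {
  prof <- simulate_community(10, sdlog = 1, seed = 4)

  z <- simulate_technical_replicates(prof, 0, n_reps = 2, seed = 1)
  expect_equal(nrow(z), 10L)
  expect_true(all(library_depths(z)$depth == 0))

  # column sums equal the requested depth under every noise regime
  for (args in list(
    list(epsilon = 0, theta = Inf), list(epsilon = 0.01, theta = Inf),
    list(epsilon = 0.01, theta = 20), list(epsilon = 0, theta = 5)
  )) {
    tab <- simulate_technical_replicates(prof, 700,
      n_reps = 3,
      epsilon = args$epsilon, theta = args$theta, seed = 5
    )
    expect_true(all(library_depths(tab)$depth == 700L))
  }

  # multinomial regime recovers the profile within binomial sampling error
  big <- simulate_technical_replicates(prof, 1e6, n_reps = 1, seed = 6)
  p_hat <- big[[2]] / 1e6
  se <- sqrt(prof$abundance * (1 - prof$abundance) / 1e6)
  expect_true(all(abs(p_hat - prof$abundance) <= 3 * se + 1e-12))

  expect_error(simulate_technical_replicates(prof, 100, epsilon = 2), "epsilon")
  expect_error(simulate_technical_replicates(prof, 100, theta = 0), "theta")
})

test_that("artifact OTUs arrive at the Poisson rate and count 1", {
  prof <- simulate_community(50, sdlog = 1, seed = 8)
  n_art <- purrr::map_int(1:200, function(s) {
    tab <- simulate_technical_replicates(prof, 1e4,
      n_reps = 1,
      epsilon = 1e-3, seed = s
    )
    art <- tab[!tab$otu_id %in% prof$otu_id, ]
    expect_true(all(art[[2]] == 1L))
    nrow(art)
  })
  # K ~ Poisson(epsilon * N) with mean 10
  expect_lt(abs(mean(n_art) - 10), 3 * sqrt(10 / 200))

  # artifact load grows linearly in depth with slope epsilon
  depths <- c(2000L, 5000L, 10000L, 20000L)
  mean_art <- purrr::map_dbl(depths, function(n) {
    mean(purrr::map_int(1:50, function(s) {
      tab <- simulate_technical_replicates(prof, n,
        n_reps = 1,
        epsilon = 1e-3, seed = 1000 + 7 * n + s
      )
      sum(!tab$otu_id %in% prof$otu_id)
    }))
  })
  fit <- stats::lm(mean_art ~ depths)
  slope <- stats::coef(fit)[["depths"]]
  slope_se <- summary(fit)$coefficients["depths", "Std. Error"]
  expect_lt(abs(slope - 1e-3), 3 * slope_se + 2e-4)

  # artifact_size >= 2 exercises the unique-OTU (not singleton) regime
  tab2 <- simulate_technical_replicates(prof, 5000,
    n_reps = 1, epsilon = 5e-3,
    artifact_size = 2, seed = 3
  )
  art2 <- tab2[!tab2$otu_id %in% prof$otu_id, ]
  expect_true(nrow(art2) > 0 && all(art2[[2]] == 2L))
})

test_that("a full experiment reproduces the nested design", {
  sim <- simulate_experiment(small_recipe(seed = 2))
  expect_equal(length(library_ids(sim$table)), 54L) # 3 x 2 x 3 x 3
  expect_equal(nrow(sim$design), 54L)
  expect_setequal(library_ids(sim$table), sim$design$library)
  expect_true(all(library_depths(sim$table)$depth == 800L))
  expect_equal(dplyr::n_distinct(sim$design$sample), 18L)

  # determinism
  expect_identical(sim, simulate_experiment(small_recipe(seed = 2)))

  # collapse case: no treatment/biological effects, one location -> all
  # ground-truth profiles identical
  flat <- simulate_experiment(simulation_recipe(
    n_otus = 60, depth = 300, epsilon = 0, theta = Inf,
    sigma_treatment = 0, sigma_biological = 0, locations = 1, seed = 3
  ))
  by_sample <- split(flat$profiles$abundance, flat$profiles$sample)
  for (p in by_sample) expect_equal(p, by_sample[[1]])

  expect_error(simulation_recipe(locations = 0), "dimensions")
  expect_error(simulation_recipe(epsilon = -1), "epsilon")
})
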