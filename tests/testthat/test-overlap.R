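test_that("overlap formulas reproduce hand-computed values", {
  a <- c(o1 = 1, o2 = 2, o3 = 3, o4 = 0, o5 = 0)
  b <- c(o1 = 0, o2 = 5, o3 = 1, o4 = 2, o5 = 4)
  expect_equal(pairwise_overlap(a, b), 4 / 7, tolerance = 1e-12)
  expect_equal(pairwise_overlap(b, a), 4 / 7, tolerance = 1e-12)
  expect_equal(pairwise_overlap(a, a), 1)
  expect_equal(pairwise_overlap(c(1, 0), c(0, 2)), 0)

  expect_equal(
    triple_overlap(c(1, 1, 0, 0), c(0, 1, 1, 0), c(0, 1, 0, 1)),
    0.5,
    tolerance = 1e-12
  ) # 3 * 1 / 6
  expect_equal(triple_overlap(a, a, a), 1)
  expect_equal(triple_overlap(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), 0)

  wa <- c(5, 3, 2, 0)
  wb <- c(0, 4, 0, 6)
  expect_equal(weighted_pairwise_overlap(wa, wb), 0.35, tolerance = 1e-12)
  expect_equal(weighted_pairwise_overlap(wa, wa), 1)
  expect_equal(
    weighted_triple_overlap(
      c(1, 9, 0, 0), c(0, 9, 1, 0), c(0, 9, 0, 1)
    ),
    0.9,
    tolerance = 1e-12
  ) # 27 / 30
  expect_equal(weighted_triple_overlap(wa, wa, wa), 1)
  expect_equal(weighted_triple_overlap(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2)), 0)
})

test_that("overlap statistics respect their contracts and symmetries", {
  expect_error(pairwise_overlap(c(0, 0), c(0, 0)), "empty")
  expect_warning(z <- pairwise_overlap(c(0, 0), c(1, 0)), "no OTUs")
  expect_equal(z, 0)
  expect_error(weighted_pairwise_overlap(c(0, 0), c(1, 2)), "zero total")
  expect_error(pairwise_overlap(1:3, 1:4), "aligned")

  withr::with_seed(11, {
    for (i in 1:20) {
      a <- rpois(10, 2) + c(1, rep(0, 9))
      b <- rpois(10, 2) + c(1, rep(0, 9))
      c_ <- rpois(10, 2) + c(1, rep(0, 9))
      # permutation invariance
      expect_equal(triple_overlap(a, b, c_), triple_overlap(c_, a, b))
      expect_equal(
        weighted_triple_overlap(a, b, c_),
        weighted_triple_overlap(b, c_, a)
      )
      # OTU relabeling / row-order invariance
      p <- sample(10)
      expect_equal(pairwise_overlap(a[p], b[p]), pairwise_overlap(a, b))
      expect_equal(
        weighted_pairwise_overlap(a[p], b[p]),
        weighted_pairwise_overlap(a, b)
      )
      # triple overlap never exceeds the largest pairwise overlap
      tri <- triple_overlap(a, b, c_)
      expect_lte(tri, max(
        pairwise_overlap(a, b), pairwise_overlap(a, c_),
        pairwise_overlap(b, c_)
      ) + 1e-12)
      # weighted and unweighted agree on presence/absence data
      bin <- function(x) as.numeric(x > 0)
      expect_equal(
        pairwise_overlap(bin(a), bin(b)),
        weighted_pairwise_overlap(bin(a), bin(b))
      )
    }
  })
})

test_that("removing singletons never lowers unweighted overlap", {
  withr::with_seed(5, {
    for (i in 1:50) {
      t <- random_otu_table(10, 3, lambda = 1.2, force_singletons = 4)
      f <- remove_singletons(t)
      m <- as.matrix(t[-1])
      fm <- as.matrix(f[-1])
      suppressWarnings({
        expect_gte(
          pairwise_overlap(fm[, 1], fm[, 2]),
          pairwise_overlap(m[, 1], m[, 2])
        )
        expect_gte(
          triple_overlap(fm[, 1], fm[, 2], fm[, 3]),
          triple_overlap(m[, 1], m[, 2], m[, 3])
        )
      })
    }
  })
})

test_that("overlap_summary aggregates pairs and triples over the design", {
  # identical replicates: every overlap is 1, sd 0
  m <- cbind(s1_t1 = c(3L, 1L, 0L), s1_t2 = c(3L, 1L, 0L), s1_t3 = c(3L, 1L, 0L))
  t <- otu_table(paste0("o", 1:3), m)
  os <- overlap_summary(t, triplicate_design(colnames(m)))
  expect_s3_class(os, "overlap_summary")
  expect_equal(nrow(os), 4L) # 3 pairs + 1 triple
  expect_true(all(os$unweighted == 1 & os$weighted == 1))
  ex <- attr(os, "experiment")
  expect_true(all(ex$mean == 1))
  expect_equal(sort(unique(ex$reduction)), c("per_sample_mean", "pooled"))

  # well-sampled multinomial replicates: overlap close to complete
  sim <- simulate_experiment(simulation_recipe(
    n_otus = 50, sdlog = 1, depth = 1e4, epsilon = 0,
    locations = 3, seed = 21
  ))
  g <- glance(overlap_summary(sim$table, sim$design))
  expect_gt(g$unweighted_pairwise_mean, 0.95)

  # artifact injection strictly lowers overlap at matched seeds
  art <- simulate_experiment(simulation_recipe(
    n_otus = 50, sdlog = 1, depth = 1e4, epsilon = 1e-2,
    locations = 3, seed = 21
  ))
  ga <- glance(overlap_summary(art$table, art$design))
  expect_lt(ga$unweighted_pairwise_mean, g$unweighted_pairwise_mean)

  # samples with a lone replicate are excluded with a warning
  lone <- validate_design(dplyr::bind_rows(
    triplicate_design(c("s1_t1", "s1_t2", "s1_t3"), "s1"),
    tibble::tibble(
      library = "x", sample = "s2", technical_rep = 1L,
      biological_rep = "b1", treatment = "planted", location = "L1"
    )
  ))
  t2 <- otu_table(paste0("o", 1:3), cbind(m, x = c(1L, 0L, 2L)))
  expect_warning(os2 <- overlap_summary(t2, lone), "fewer than 2")
  expect_false("s2" %in% os2$sample)
})

test_that("depth profiling recovers the overlap curve and its plateau", {
  prof <- simulate_community(300, sdlog = 1.5, seed = 31)
  tab <- simulate_technical_replicates(prof, 4000, 3, epsilon = 0, seed = 32)
  des <- triplicate_design(library_ids(tab))

  dp <- depth_profile(tab, des,
    depths = c(100, 500, 1000, 2000, 4000),
    n_resamples = 4, seed = 33
  )
  expect_s3_class(dp, "depth_profile")
  expect_equal(sort(unique(dp$depth)), c(100L, 500L, 1000L, 2000L, 4000L))

  # at the full depth rarefaction is the identity, so the profile point
  # equals the plain overlap summary
  ex <- attr(overlap_summary(tab, des), "experiment")
  full <- dp[dp$depth == 4000 & dp$statistic == "pairwise" &
    dp$weighting == "unweighted", ]
  expect_equal(
    full$mean,
    ex$mean[ex$statistic == "pairwise" & ex$weighting == "unweighted" &
      ex$reduction == "per_sample_mean"]
  )
  expect_equal(full$sd, 0)

  # without artifacts the mean curve rises with depth (2 MC sd per step)
  up <- dp[dp$statistic == "pairwise" & dp$weighting == "unweighted", ]
  up <- up[order(up$depth), ]
  step_sd <- sqrt(up$sd[-nrow(up)]^2 + up$sd[-1]^2) / sqrt(attr(dp, "n_resamples"))
  expect_true(all(diff(up$mean) >= -2 * step_sd))

  expect_error(depth_profile(tab, des, depths = c(100, 1e6)), "shallowest")
  expect_error(depth_profile(tab, des, depths = 100), "two values")
})
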