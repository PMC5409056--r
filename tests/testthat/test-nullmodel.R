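test_that("the average profile is the mean of replicate relative abundances", {
  t <- otu_table(c("a", "b"), cbind(r1 = c(4L, 0L), r2 = c(0L, 4L)))
  p <- average_profile(t)
  expect_equal(p$abundance, c(0.5, 0.5))

  # identical replicates recover each replicate's own profile
  ident <- otu_table(c("a", "b", "c"), cbind(r1 = c(6L, 3L, 1L), r2 = c(6L, 3L, 1L)))
  expect_equal(average_profile(ident)$abundance, c(0.6, 0.3, 0.1))

  withr::with_seed(61, {
    for (i in 1:10) {
      rt <- random_otu_table(12, 3, lambda = 2)
      expect_equal(sum(average_profile(rt)$abundance), 1, tolerance = 1e-12)
    }
  })
  expect_error(average_profile(otu_table("a", cbind(r1 = 2L)))) # one replicate
  expect_error(
    average_profile(otu_table("a", cbind(r1 = 2L, r2 = 0L))),
    "zero depth"
  )
})

test_that("null replicates are multinomial draws from the profile", {
  one <- tibble::tibble(otu_id = "a", abundance = 1)
  nr <- generate_null_replicates(one, depth = 50, n_reps = 3, seed = 1)
  expect_true(all(unlist(nr[-1]) == 50L))

  prof <- simulate_community(20, sdlog = 1, seed = 62)
  nr <- generate_null_replicates(prof, depth = 400, n_reps = 1000, seed = 63)
  mean_counts <- rowMeans(as.matrix(nr[-1]))
  se <- sqrt(400 * prof$abundance * (1 - prof$abundance)) / sqrt(1000)
  expect_true(all(abs(mean_counts - 400 * prof$abundance) <= 3 * se + 0.05))

  expect_false(identical(
    generate_null_replicates(prof, 100, 2, seed = 1),
    generate_null_replicates(prof, 100, 2, seed = 2)
  ))
  # per-replicate depths
  nr2 <- generate_null_replicates(prof, depth = c(100, 200), n_reps = 2, seed = 3)
  expect_equal(library_depths(nr2)$depth, c(100L, 200L))
  expect_error(generate_null_replicates(prof, 0), "depth")
})

test_that("group dispersion embeds dissimilarities with known geometry", {
  # coincident points
  ident <- otu_table(c("a", "b"), cbind(r1 = c(2L, 1L), r2 = c(2L, 1L), r3 = c(2L, 1L)))
  expect_equal(group_dispersion(ident, "bray_curtis"), 0)

  # two points at dissimilarity 1 sit 1/2 from their midpoint
  two <- otu_table(c("a", "b"), cbind(r1 = c(3L, 0L), r2 = c(0L, 3L)))
  expect_equal(group_dispersion(two, "sorensen"), 0.5, tolerance = 1e-12)

  # an equilateral triangle of side 1 has centroid distance 1/sqrt(3)
  tri <- otu_table(c("a", "b", "c"), cbind(
    r1 = c(2L, 0L, 0L),
    r2 = c(0L, 2L, 0L), r3 = c(0L, 0L, 2L)
  ))
  expect_equal(group_dispersion(tri, "sorensen"), 1 / sqrt(3), tolerance = 1e-12)

  expect_error(group_dispersion(otu_table("a", cbind(r1 = 1L))), "group of >= 2")

  # matches vegan::betadisper centroid distances on random groups
  withr::with_seed(64, {
    for (i in 1:5) {
      rt <- random_otu_table(15, 5, lambda = 3)
      m <- t(as.matrix(rt[-1]))
      for (metric in c("sorensen", "bray_curtis")) {
        d <- vegan::vegdist(m, "bray", binary = metric == "sorensen")
        bd <- suppressWarnings(vegan::betadisper(d, rep("g", 5), type = "centroid"))
        expect_equal(group_dispersion(rt, metric), mean(bd$distances),
          tolerance = 1e-8
        )
      }
    }
  })
})

test_that("the null-model dispersion test behaves at its boundaries", {
  # identical observed replicates: zero observed dispersion, p = 1
  ident <- otu_table(
    paste0("o", 1:3),
    cbind(r1 = c(5L, 3L, 2L), r2 = c(5L, 3L, 2L), r3 = c(5L, 3L, 2L))
  )
  r <- permdisp_null_test(ident, "sorensen", n_iter = 99, seed = 1)
  expect_equal(r$d_obs, 0)
  expect_equal(r$p, 1)

  tab <- simulate_technical_replicates(simulate_community(40, seed = 65),
    depth = 500, n_reps = 3, seed = 66
  )
  r1 <- permdisp_null_test(tab, "bray_curtis", n_iter = 99, seed = 7)
  expect_gt(r1$p, 0) # add-one rule
  expect_lte(r1$p, 1)
  expect_equal(r1$n_iter, 99L)
  # deterministic under a seed
  expect_equal(r1, permdisp_null_test(tab, "bray_curtis", n_iter = 99, seed = 7))
  # the observed dispersion is invariant to OTU relabeling / row order;
  # the Monte-Carlo p fluctuates only within its sampling error
  shuffled <- tab[withr::with_seed(8, sample(nrow(tab))), ]
  r2 <- permdisp_null_test(shuffled, "bray_curtis", n_iter = 99, seed = 7)
  expect_equal(r2$d_obs, r1$d_obs)
  expect_lt(abs(r2$p - r1$p), 4 * sqrt(0.25 / 99))

  expect_error(
    permdisp_null_test(tab[, 1:3], "sorensen"),
    "at least 3"
  )
})

test_that("permdisp_summary tests every sample and metric", {
  sim <- simulate_experiment(simulation_recipe(
    n_otus = 60, depth = 400,
    locations = 1, seed = 67
  ))
  res <- permdisp_summary(sim$table, sim$design, n_iter = 49, seed = 68)
  expect_s3_class(res, "dispersion_test")
  expect_equal(nrow(res), 6L * 2L) # 6 samples x 2 metrics
  expect_setequal(unique(res$metric), c("sorensen", "bray_curtis"))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(res$d_obs >= 0 & res$d_null_mean >= 0))
  g <- glance(res)
  expect_equal(g$n_tests, c(6L, 6L))
})
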