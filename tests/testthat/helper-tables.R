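# fixtures built in code: random OTU tables and replicate designs

random_otu_table <- function(n_otu = 12, n_lib = 3, lambda = 2, seed = NULL,
                             force_singletons = 0) {
  draw <- function() {
    m <- matrix(stats::rpois(n_otu * n_lib, lambda), n_otu, n_lib)
    # guarantee no empty library
    for (j in seq_len(n_lib)) if (sum(m[, j]) == 0) m[1, j] <- m[1, j] + 1L
    if (force_singletons > 0) {
      extra <- matrix(0L, force_singletons, n_lib)
      for (i in seq_len(force_singletons)) extra[i, sample.int(n_lib, 1)] <- 1L
      m <- rbind(m, extra)
    }
    rownames(m) <- paste0("o", seq_len(nrow(m)))
    colnames(m) <- paste0("l", seq_len(n_lib))
    otu_table(rownames(m), m)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

triplicate_design <- function(libs, sample = "s1") {
  tibble::tibble(
    library = libs, sample = sample,
    technical_rep = seq_along(libs),
    biological_rep = "b1", treatment = "planted", location = "L1"
  )
}

small_recipe <- function(...) {
  simulation_recipe(n_otus = 100, depth = 800, sdlog = 1.5, ...)
}
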