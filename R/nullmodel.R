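#' Average relative-abundance profile of a replicate group
#'
#' The null hypothesis of the dispersion test is that a sample's technical
#' replicates are random sequence samples of one underlying community.
#' That community is estimated as the mean of the replicates' relative
#' abundance vectors (each replicate first normalized by its own depth),
#' renormalized to sum to one.
#'
#' @param table An OTU table whose columns are the replicate libraries (or
#'   a larger table with `libraries` selecting them).
#' @param libraries Optional character vector naming the replicate columns.
#' @return A profile tibble (`otu_id`, `abundance`).
#' @export
average_profile <- function(table, libraries = NULL) {
  m <- as_otu_matrix(table)
  if (!is.null(libraries)) {
    missing <- setdiff(libraries, colnames(m))
    if (length(missing)) stop("unknown library: ", missing[1], call. = FALSE)
    m <- m[, libraries, drop = FALSE]
  }
  if (ncol(m) < 2) stop("need at least 2 replicates", call. = FALSE)
  depths <- colSums(m)
  if (any(depths == 0)) {
    stop("replicate '", colnames(m)[depths == 0][1], "' has zero depth",
      call. = FALSE
    )
  }
  rel <- sweep(m, 2, depths, "/")
  p <- rowMeans(rel)
  tibble::tibble(otu_id = rownames(m), abundance = unname(p / sum(p)))
}

#' Generate null replicates from a profile
#'
#' Draws `n_reps` independent multinomial libraries of size `depth` from
#' the profile — communities that differ only by random sequence sampling.
#' `depth` may be a vector of per-replicate depths.
#'
#' @param profile A community profile tibble.
#' @param depth Reads per null replicate (scalar or length `n_reps`).
#' @param n_reps Number of null replicates.
#' @inheritParams simulate_community
#' @return An OTU table tibble with columns `null1..nullK`.
#' @export
generate_null_replicates <- function(profile, depth, n_reps = 3, seed = NULL) {
  profile <- validate_profile(profile)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  depth <- as.integer(depth)
  if (any(depth < 1)) stop("depth must be >= 1", call. = FALSE)
  depth <- rep_len(depth, n_reps)
  draw <- function() {
    m <- vapply(
      depth, function(n) as.integer(stats::rmultinom(1, n, profile$abundance)),
      integer(nrow(profile))
    )
    m <- matrix(m, nrow = nrow(profile))
    colnames(m) <- paste0("null", seq_len(n_reps))
    rownames(m) <- profile$otu_id
    otu_matrix_to_table(m)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# distances of each point to the group centroid in the principal-coordinate
# embedding of a dissimilarity matrix, with the standard negative-eigenvalue
# correction. For the Gower-centered matrix G of D, the corrected squared
# centroid distance of point j is exactly G_jj (real-part minus
# imaginary-part contributions), so no eigendecomposition is needed.
centroid_distances <- function(D) {
  A <- -0.5 * D^2
  rm <- rowMeans(A)
  g_diag <- diag(A) - 2 * rm + mean(A)
  sqrt(pmax(g_diag, 0))
}

dispersion_from_matrix <- function(counts, metric) {
  D <- as.matrix(vegan::vegdist(t(counts),
    method = "bray",
    binary = metric == "sorensen"
  ))
  mean(centroid_distances(D))
}

#' Dispersion of a replicate group
#'
#' Mean distance of the group's libraries to their centroid in a
#' principal-coordinate embedding of the pairwise dissimilarity matrix
#' (with the standard negative-eigenvalue correction) — the group
#' dispersion of PERMDISP. Zero exactly when all pairwise dissimilarities
#' are zero.
#'
#' @param table OTU table whose columns are the group's libraries.
#' @param metric `"sorensen"` or `"bray_curtis"`.
#' @param libraries Optional character vector selecting the group columns.
#' @return A non-negative dispersion in the metric's distance units.
#' @export
group_dispersion <- function(table, metric = c("sorensen", "bray_curtis"),
                             libraries = NULL) {
  metric <- match.arg(metric)
  m <- as_otu_matrix(table)
  if (!is.null(libraries)) m <- m[, libraries, drop = FALSE]
  if (ncol(m) < 2) stop("a dispersion needs a group of >= 2 libraries", call. = FALSE)
  if (any(colSums(m) == 0)) stop("empty library in group", call. = FALSE)
  dispersion_from_matrix(m, metric)
}

#' Null-model dispersion test for one sample's technical replicates
#'
#' Tests whether the observed technical replicates are more dispersed than
#' random sequence sampling of a shared community predicts. The observed
#' dispersion `d_obs` is computed once from the replicates; then, for each
#' of `n_iter` iterations, `n_null_reps` null replicates are drawn
#' multinomially from the replicates' [average_profile()] at the observed
#' depths and their dispersion recorded. The Monte-Carlo p-value is
#' `(1 + #\{d_null >= d_obs\}) / (1 + n_iter)` (never exactly zero), the
#' relative dispersion excess is
#' `delta_d_pct = 100 (d_obs - mean(d_null)) / mean(d_null)`, and a
#' descriptive classic one-way ANOVA F compares the distances-to-own-
#' centroid of the observed group against one representative null group.
#'
#' @param table OTU table whose columns are one sample's >= 3 technical
#'   replicates, rarefied to a common depth.
#' @param metric `"sorensen"` or `"bray_curtis"`.
#' @param n_iter Null iterations (default 1000).
#' @param n_null_reps Null replicates per iteration (default 3, one per
#'   observed replicate).
#' @inheritParams simulate_community
#' @return A one-row tibble of class `dispersion_test`: `sample`, `metric`,
#'   `d_obs`, `d_null_mean`, `d_null_sd`, `delta_d_pct`, `f`, `p`,
#'   `n_iter`.
#' @export
permdisp_null_test <- function(table, metric = c("sorensen", "bray_curtis"),
                               n_iter = 1000, n_null_reps = 3, seed = NULL) {
  metric <- match.arg(metric)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  m <- as_otu_matrix(table)
  if (ncol(m) < 3) {
    stop("the dispersion test needs at least 3 technical replicates", call. = FALSE)
  }
  depths <- colSums(m)
  if (any(depths == 0)) stop("empty replicate library", call. = FALSE)
  prof <- average_profile(table)
  p_vec <- prof$abundance
  run <- function() {
    d_obs_dists <- centroid_distances(as.matrix(vegan::vegdist(t(m),
      method = "bray", binary = metric == "sorensen"
    )))
    d_obs <- mean(d_obs_dists)
    d_null <- numeric(n_iter)
    first_null_dists <- NULL
    for (i in seq_len(n_iter)) {
      nm <- vapply(
        rep_len(depths, n_null_reps),
        function(n) as.integer(stats::rmultinom(1, n, p_vec)),
        integer(length(p_vec))
      )
      dists <- centroid_distances(as.matrix(vegan::vegdist(t(nm),
        method = "bray", binary = metric == "sorensen"
      )))
      if (i == 1L) first_null_dists <- dists
      d_null[i] <- mean(dists)
    }
    d_null_mean <- mean(d_null)
    grp <- factor(rep(c("observed", "null"), c(length(d_obs_dists), length(first_null_dists))))
    vals <- c(d_obs_dists, first_null_dists)
    f <- tryCatch(
      unname(stats::oneway.test(vals ~ grp, var.equal = TRUE)$statistic),
      error = function(e) NA_real_
    )
    tibble::tibble(
      sample = NA_character_,
      metric = metric,
      d_obs = d_obs,
      d_null_mean = d_null_mean,
      d_null_sd = stats::sd(d_null),
      delta_d_pct = 100 * (d_obs - d_null_mean) / d_null_mean,
      f = f,
      p = (1 + sum(d_null >= d_obs)) / (1 + n_iter),
      n_iter = as.integer(n_iter)
    )
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(res, class = c("dispersion_test", class(res)))
}

#' Null-model dispersion tests across all samples of a design
#'
#' Runs [permdisp_null_test()] for every sample's technical-replicate
#' group, for each requested metric.
#'
#' @param table A rarefied OTU table.
#' @param design Replicate design covering the table.
#' @param metrics Character vector of metrics to test.
#' @inheritParams permdisp_null_test
#' @return A tibble of class `dispersion_test`, one row per sample x
#'   metric.
#' @export
permdisp_summary <- function(table, design,
                             metrics = c("sorensen", "bray_curtis"),
                             n_iter = 1000, n_null_reps = 3, seed = NULL) {
  design <- validate_design(design, table)
  metrics <- match.arg(metrics, c("sorensen", "bray_curtis"), several.ok = TRUE)
  run <- function() {
    rows <- list()
    for (s in unique(design$sample)) {
      libs <- design$library[design$sample == s]
      sub <- table[, c("otu_id", libs)]
      for (met in metrics) {
        r <- permdisp_null_test(sub,
          metric = met, n_iter = n_iter,
          n_null_reps = n_null_reps
        )
        r$sample <- s
        rows[[length(rows) + 1L]] <- r
      }
    }
    dplyr::bind_rows(rows)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(res, class = c("dispersion_test", class(tibble::as_tibble(res))))
}
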