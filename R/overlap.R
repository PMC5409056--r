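#' OTU overlap statistics between and among technical replicates
#'
#' The core reproducibility statistics. For two replicate libraries the
#' unweighted overlap is `2 * shared OTUs / (OTUs of A + OTUs of B)`
#' (Sørensen similarity on presence/absence); for three it is
#' `3 * shared-by-all-three / (OTUs of A + OTUs of B + OTUs of C)`. The
#' weighted counterparts replace OTU counts by sequence counts: the
#' fraction of all sequences that reside in shared OTUs. "Shared" and
#' richness are always evaluated on the nonzero counts of the vectors as
#' given — i.e. after whatever filtering and rarefaction the pipeline has
#' applied.
#'
#' @param a,b,c Aligned numeric count vectors for the replicate libraries
#'   (element i of each is the same OTU).
#' @return A fraction in `[0, 1]`.
#' @examples
#' pairwise_overlap(c(1, 1, 1, 0, 0), c(0, 1, 1, 1, 1)) # 4/7
#' @export
pairwise_overlap <- function(a, b) {
  check_aligned(a, b)
  ra <- sum(a > 0)
  rb <- sum(b > 0)
  if (ra + rb == 0) stop("both libraries are empty", call. = FALSE)
  if (ra == 0 || rb == 0) {
    warning("one library has no OTUs; overlap is 0")
    return(0)
  }
  2 * sum(a > 0 & b > 0) / (ra + rb)
}

#' @rdname pairwise_overlap
#' @export
triple_overlap <- function(a, b, c) {
  check_aligned(a, b, c)
  r <- c(sum(a > 0), sum(b > 0), sum(c > 0))
  if (sum(r) == 0) stop("all three libraries are empty", call. = FALSE)
  if (any(r == 0)) {
    warning("a library has no OTUs; overlap is 0")
    return(0)
  }
  3 * sum(a > 0 & b > 0 & c > 0) / sum(r)
}

#' @rdname pairwise_overlap
#' @export
weighted_pairwise_overlap <- function(a, b) {
  check_aligned(a, b)
  ta <- sum(a)
  tb <- sum(b)
  if (ta == 0 || tb == 0) stop("zero total depth in a library", call. = FALSE)
  shared <- a > 0 & b > 0
  (sum(a[shared]) + sum(b[shared])) / (ta + tb)
}

#' @rdname pairwise_overlap
#' @export
weighted_triple_overlap <- function(a, b, c) {
  check_aligned(a, b, c)
  tot <- c(sum(a), sum(b), sum(c))
  if (any(tot == 0)) stop("zero total depth in a library", call. = FALSE)
  shared <- a > 0 & b > 0 & c > 0
  (sum(a[shared]) + sum(b[shared]) + sum(c[shared])) / sum(tot)
}

check_aligned <- function(...) {
  ls <- lengths(list(...))
  if (length(unique(ls)) != 1L) {
    stop("count vectors must be aligned to the same OTU set", call. = FALSE)
  }
  invisible(NULL)
}

#' Summarize OTU overlap over a replicated design
#'
#' Computes, for every sample with at least two technical replicates, all
#' pairwise overlaps (and the triple overlap when the sample has exactly
#' three replicates), unweighted and weighted, then summarizes at the
#' experiment level as mean and sd. Two reductions are reported: the mean
#' over per-sample means (`per_sample_mean`) and the mean over all pairs
#' pooled (`pooled`); they coincide for balanced designs' means but differ
#' in sd. The table should already be rarefied to a common depth.
#'
#' @param table An OTU table tibble.
#' @param design A replicate design covering the table's libraries.
#' @return A tibble of class `overlap_summary` with one row per sample x
#'   comparison: columns `sample`, `comparison` (e.g. `"1-2"` or
#'   `"1-2-3"`), `statistic` (`"pairwise"`/`"triple"`), `unweighted`,
#'   `weighted`. The experiment-level summary is attached as attribute
#'   `"experiment"` and retrievable with [glance()].
#' @export
overlap_summary <- function(table, design) {
  m <- as_otu_matrix(table)
  design <- validate_design(design, table)
  rows <- list()
  for (s in unique(design$sample)) {
    d <- design[design$sample == s, ]
    d <- d[order(d$technical_rep), ]
    if (nrow(d) < 2) {
      warning("sample '", s, "' has fewer than 2 technical replicates; excluded")
      next
    }
    cols <- lapply(d$library, function(l) m[, l])
    pairs <- utils::combn(seq_len(nrow(d)), 2, simplify = FALSE)
    for (pr in pairs) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample = s,
        comparison = paste(d$technical_rep[pr], collapse = "-"),
        statistic = "pairwise",
        unweighted = pairwise_overlap(cols[[pr[1]]], cols[[pr[2]]]),
        weighted = weighted_pairwise_overlap(cols[[pr[1]]], cols[[pr[2]]])
      )
    }
    if (nrow(d) == 3) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample = s,
        comparison = paste(d$technical_rep, collapse = "-"),
        statistic = "triple",
        unweighted = triple_overlap(cols[[1]], cols[[2]], cols[[3]]),
        weighted = weighted_triple_overlap(cols[[1]], cols[[2]], cols[[3]])
      )
    }
  }
  if (!length(rows)) stop("no sample with >= 2 technical replicates", call. = FALSE)
  res <- dplyr::bind_rows(rows)
  long <- tidyr::pivot_longer(res, c("unweighted", "weighted"),
    names_to = "weighting", values_to = "value"
  )
  per_sample <- dplyr::summarise(
    dplyr::group_by(long, .data$sample, .data$statistic, .data$weighting),
    value = mean(.data$value), .groups = "drop"
  )
  experiment <- dplyr::bind_rows(
    dplyr::summarise(
      dplyr::group_by(per_sample, .data$statistic, .data$weighting),
      reduction = "per_sample_mean", mean = mean(.data$value),
      sd = stats::sd(.data$value), n = dplyr::n(), .groups = "drop"
    ),
    dplyr::summarise(
      dplyr::group_by(long, .data$statistic, .data$weighting),
      reduction = "pooled", mean = mean(.data$value),
      sd = stats::sd(.data$value), n = dplyr::n(), .groups = "drop"
    )
  )
  structure(res,
    experiment = experiment,
    class = c("overlap_summary", class(res))
  )
}

#' Default sequencing-depth grid for overlap profiling
#'
#' @return An increasing integer vector from 100 to 160,000 reads.
#' @export
default_depth_grid <- function() {
  c(100L, 500L, 1000L, 2000L, 5000L, 10000L, 20000L, 30000L, 50000L, 80000L, 120000L, 160000L)
}

#' Profile OTU overlap as a function of sequencing depth
#'
#' For each depth on the grid, rarefies every library to that depth
#' (`n_resamples` independent draws) and records the experiment-level mean
#' of each overlap statistic, summarized as mean and sd across resamples.
#' A saturation (plateau) depth is estimated per statistic as the smallest
#' grid depth beyond which the gain per additional `saturation_window`
#' reads stays below `saturation_threshold`; this rule is a reporting
#' convention of this package, not an inherited definition.
#'
#' @param table An OTU table; every library must reach `max(depths)`.
#' @param design Replicate design covering the table.
#' @param depths Strictly increasing depth grid.
#' @param n_resamples Independent rarefactions per depth (>= 1); sd is
#'   reported only when > 1.
#' @param saturation_threshold Absolute overlap gain per
#'   `saturation_window` reads below which the curve is declared flat.
#' @param saturation_window Reads per saturation-slope unit (default 10,000).
#' @inheritParams simulate_community
#' @return A tibble of class `depth_profile` with columns `depth`,
#'   `statistic`, `weighting`, `mean`, `sd`; the per-statistic saturation
#'   depths are attached as attribute `"saturation"` (see [glance()]).
#' @export
depth_profile <- function(table, design, depths = default_depth_grid(),
                          n_resamples = 1, seed = NULL,
                          saturation_threshold = 0.005,
                          saturation_window = 10000) {
  depths <- as.integer(sort(unique(depths)))
  if (any(depths < 0) || length(depths) < 2) {
    stop("depths must be >= 0 and contain at least two values", call. = FALSE)
  }
  if (n_resamples < 1) stop("n_resamples must be >= 1", call. = FALSE)
  avail <- min_depth(table)
  if (max(depths) > avail) {
    stop("depth grid reaches ", max(depths), " but the shallowest library has only ",
      avail, " sequences",
      call. = FALSE
    )
  }
  design <- validate_design(design, table)
  run <- function() {
    per <- list()
    for (d in depths) {
      for (r in seq_len(n_resamples)) {
        sub <- rarefy(table, d)
        ex <- attr(overlap_summary(sub, design), "experiment")
        ex <- ex[ex$reduction == "per_sample_mean", c("statistic", "weighting", "mean")]
        per[[length(per) + 1L]] <- dplyr::mutate(ex,
          depth = d, resample = r,
          .before = 1
        )
      }
    }
    long <- dplyr::bind_rows(per)
    prof <- dplyr::summarise(
      dplyr::group_by(long, .data$depth, .data$statistic, .data$weighting),
      sd = if (n_resamples > 1) stats::sd(.data$mean) else NA_real_,
      mean = mean(.data$mean), .groups = "drop"
    )
    prof <- prof[, c("depth", "statistic", "weighting", "mean", "sd")]
    sat <- dplyr::summarise(
      dplyr::group_by(prof, .data$statistic, .data$weighting),
      saturation_depth = saturation_depth(
        .data$depth, .data$mean,
        saturation_threshold, saturation_window
      ),
      .groups = "drop"
    )
    structure(prof,
      saturation = sat, n_resamples = n_resamples,
      saturation_threshold = saturation_threshold,
      saturation_window = saturation_window,
      class = c("depth_profile", class(prof))
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# smallest grid depth from which every later per-window gain is below the
# threshold; NA when the curve never flattens on the grid
saturation_depth <- function(depth, mean_value, threshold, window) {
  o <- order(depth)
  depth <- depth[o]
  mean_value <- mean_value[o]
  slopes <- diff(mean_value) / diff(depth) * window
  flat <- slopes < threshold
  for (i in seq_along(flat)) {
    if (all(flat[i:length(flat)])) {
      return(depth[i])
    }
  }
  NA_integer_
}
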