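#' Per-library alpha diversity
#'
#' For every library: observed richness `s_obs` (nonzero OTUs), Shannon
#' index `H'` in nats, Pielou evenness `J = H'/ln(s_obs)` (reported as
#' `NA` when `s_obs < 2`), a Chao1 richness estimate, and OTU coverage
#' defined as `s_obs / chao1` — the standard reading of coverage "based on
#' Chao1 estimation". The default Chao1 is the bias-corrected form
#' `s_obs + F1(F1 - 1) / (2(F2 + 1))` (`F1`, `F2` = number of OTUs with
#' exactly one and two sequences), which never divides by zero; the
#' classic form `s_obs + F1^2 / (2 F2)` is available and falls back to the
#' bias-corrected form when `F2 = 0`.
#'
#' @param table An OTU table tibble; every library must have at least one
#'   sequence.
#' @param chao1 `"bias_corrected"` (default) or `"classic"`.
#' @return A tibble with one row per library: `library`, `depth`, `s_obs`,
#'   `shannon`, `pielou`, `chao1`, `coverage`.
#' @examples
#' t <- otu_table(c("a", "b", "c"), cbind(l1 = c(5L, 3L, 2L)))
#' alpha_diversity(t)
#' @export
alpha_diversity <- function(table, chao1 = c("bias_corrected", "classic")) {
  chao1 <- match.arg(chao1)
  m <- as_otu_matrix(table)
  depths <- colSums(m)
  if (any(depths == 0)) {
    stop("library '", colnames(m)[depths == 0][1], "' is empty", call. = FALSE)
  }
  h <- as.numeric(vegan::diversity(t(m), index = "shannon"))
  purrr::map_dfr(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    s_obs <- sum(x > 0)
    f1 <- sum(x == 1L)
    f2 <- sum(x == 2L)
    ch <- chao1_estimate(s_obs, f1, f2, chao1)
    tibble::tibble(
      library = colnames(m)[j],
      depth = as.integer(depths[j]),
      s_obs = s_obs,
      shannon = h[j],
      pielou = if (s_obs >= 2) h[j] / log(s_obs) else NA_real_,
      chao1 = ch,
      coverage = s_obs / ch
    )
  })
}

chao1_estimate <- function(s_obs, f1, f2, form) {
  if (form == "classic" && f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  }
}

#' Pairwise beta-diversity dissimilarities
#'
#' The complements of Sørensen and Bray-Curtis similarity between two
#' libraries: `sorensen = 1 - 2|shared| / (S_a + S_b)` on presence/absence
#' (exactly `1 - pairwise_overlap()`), and
#' `bray_curtis = 1 - 2 sum(min(a_i, b_i)) / (sum(a) + sum(b))` on counts.
#'
#' @inheritParams pairwise_overlap
#' @return A dissimilarity in `[0, 1]`.
#' @examples
#' bray_curtis_dissimilarity(c(5, 3, 2, 0), c(0, 4, 0, 6)) # 0.7
#' @export
sorensen_dissimilarity <- function(a, b) {
  1 - pairwise_overlap(a, b)
}

#' @rdname sorensen_dissimilarity
#' @export
bray_curtis_dissimilarity <- function(a, b) {
  check_aligned(a, b)
  ta <- sum(a)
  tb <- sum(b)
  if (ta == 0 || tb == 0) stop("zero total depth in a library", call. = FALSE)
  1 - 2 * sum(pmin(a, b)) / (ta + tb)
}

#' Full dissimilarity matrix between libraries
#'
#' Computes the symmetric library-by-library dissimilarity matrix for one
#' metric via [vegan::vegdist()] (Bray-Curtis, or its binary form for the
#' Sørensen complement).
#'
#' @param table An OTU table tibble.
#' @param metric `"sorensen"` or `"bray_curtis"`.
#' @return A symmetric numeric matrix with library dimnames, zero
#'   diagonal, values in `[0, 1]`.
#' @export
dissimilarity_matrix <- function(table, metric = c("sorensen", "bray_curtis")) {
  metric <- match.arg(metric)
  m <- as_otu_matrix(table)
  if (any(colSums(m) == 0)) stop("empty library in table", call. = FALSE)
  d <- vegan::vegdist(t(m), method = "bray", binary = metric == "sorensen")
  as.matrix(d)
}

#' Long tibble of pairwise dissimilarities
#'
#' @inheritParams dissimilarity_matrix
#' @return A tibble of unordered library pairs: `library_1`, `library_2`,
#'   `metric`, `dissimilarity`.
#' @export
beta_pairs <- function(table, metric = c("sorensen", "bray_curtis")) {
  metric <- match.arg(metric)
  dm <- dissimilarity_matrix(table, metric)
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  tibble::tibble(
    library_1 = rownames(dm)[idx[, 1]],
    library_2 = colnames(dm)[idx[, 2]],
    metric = metric,
    dissimilarity = dm[idx]
  )
}

#' Summarize beta diversity by design level
#'
#' Partitions every unordered library pair into one level of the comparison
#' hierarchy and reports the pair count and mean dissimilarity per level:
#'
#' * `technical` — same sample (same DNA extract, different barcode);
#' * `biological` — same location and treatment, different field replicate;
#' * `treatment_within_location` — same location, different treatment;
#' * `<treatment>_across_locations` — same treatment, different location
#'   (one level per treatment label, e.g. planted/unplanted);
#' * `other` — different location and different treatment.
#'
#' The partition is exhaustive and disjoint. Means are over pooled pairs,
#' consistent with reporting the number of pairwise data points per level.
#'
#' @param dissimilarity A symmetric matrix from [dissimilarity_matrix()] or a
#'   long pair tibble from [beta_pairs()].
#' @param design A replicate design covering all libraries involved.
#' @return A tibble: `level`, `n_pairs`, `mean_dissimilarity`.
#' @export
beta_level_summary <- function(dissimilarity, design) {
  design <- validate_design(design)
  if (is.matrix(dissimilarity)) {
    idx <- which(upper.tri(dissimilarity), arr.ind = TRUE)
    pairs <- tibble::tibble(
      library_1 = rownames(dissimilarity)[idx[, 1]],
      library_2 = colnames(dissimilarity)[idx[, 2]],
      dissimilarity = dissimilarity[idx]
    )
  } else {
    pairs <- tibble::as_tibble(dissimilarity)
  }
  libs <- unique(c(pairs$library_1, pairs$library_2))
  missing <- setdiff(libs, design$library)
  if (length(missing)) {
    stop("library missing from design: ", missing[1], call. = FALSE)
  }
  meta <- design[, c("library", "sample", "treatment", "location")]
  pairs <- dplyr::left_join(pairs, meta, by = c(library_1 = "library"))
  pairs <- dplyr::left_join(pairs, meta,
    by = c(library_2 = "library"),
    suffix = c("_1", "_2")
  )
  pairs$level <- assign_pair_level(pairs)
  out <- dplyr::summarise(
    dplyr::group_by(pairs, .data$level),
    n_pairs = dplyr::n(),
    mean_dissimilarity = mean(.data$dissimilarity), .groups = "drop"
  )
  lvl_order <- c(
    "technical", "biological", "treatment_within_location",
    paste0(sort(unique(design$treatment)), "_across_locations"), "other"
  )
  out$level <- factor(out$level, levels = lvl_order)
  dplyr::arrange(out, .data$level)
}

assign_pair_level <- function(pairs) {
  dplyr::case_when(
    pairs$sample_1 == pairs$sample_2 ~ "technical",
    pairs$location_1 == pairs$location_2 &
      pairs$treatment_1 == pairs$treatment_2 ~ "biological",
    pairs$location_1 == pairs$location_2 ~ "treatment_within_location",
    pairs$treatment_1 == pairs$treatment_2 ~
      paste0(pairs$treatment_1, "_across_locations"),
    TRUE ~ "other"
  )
}
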