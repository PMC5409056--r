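#' Remove singleton OTUs
#'
#' A singleton is an OTU represented by exactly one sequence, necessarily
#' in a single technical replicate; such OTUs are treated as likely
#' sequencing artifacts and removed before rarefaction. The default scope
#' (`"table"`) tests the total count over the whole table — the strictest
#' reading of "only one sequence, present in only one technical replicate
#' across all samples". Scope `"sample"` instead tests each sample's
#' replicate group separately: an OTU with exactly one sequence within a
#' sample is zeroed there (it may keep counts in other samples); OTUs left
#' with no counts anywhere are dropped. The scope must be chosen
#' explicitly when the distinction matters; results are labelled by scope
#' in pipeline logs.
#'
#' @param table An OTU table tibble.
#' @param scope `"table"` (default) or `"sample"`; see Details.
#' @param design Replicate design, required for `scope = "sample"`.
#' @return The filtered OTU table.
#' @examples
#' t <- otu_table(c("a", "b"), cbind(l1 = c(1, 4), l2 = c(0, 2)))
#' remove_singletons(t) # drops "a"
#' @export
remove_singletons <- function(table, scope = c("table", "sample"),
                              design = NULL) {
  scope <- match.arg(scope)
  m <- as_otu_matrix(table)
  if (scope == "table") {
    keep <- rowSums(m) != 1L
    return(validate_otu_table(table[keep, , drop = FALSE]))
  }
  if (is.null(design)) {
    stop("scope = \"sample\" needs a replicate design", call. = FALSE)
  }
  design <- validate_design(design, table)
  for (s in unique(design$sample)) {
    libs <- design$library[design$sample == s]
    sub <- m[, libs, drop = FALSE]
    single <- rowSums(sub) == 1L
    m[single, libs] <- 0L
  }
  validate_otu_table(otu_matrix_to_table(m[rowSums(m) > 0L, , drop = FALSE]))
}

#' Remove unique OTUs
#'
#' A unique OTU has nonzero counts in exactly one library (one technical
#' replicate) regardless of how many sequences it holds. OTUs that are
#' unique AND have total count `<= min_count` are removed; `min_count = 1`
#' removes only single-sequence unique OTUs, `min_count = Inf` removes all
#' unique OTUs. Applied after rarefaction in the standard pipeline, where
#' resampling can leave behind newly unique OTUs.
#'
#' @param table An OTU table tibble.
#' @param min_count Count threshold (>= 1, may be `Inf`).
#' @return The filtered OTU table.
#' @export
remove_unique_otus <- function(table, min_count = 1) {
  if (!is.numeric(min_count) || length(min_count) != 1L || min_count < 1) {
    stop("min_count must be >= 1", call. = FALSE)
  }
  m <- as_otu_matrix(table)
  unique_otu <- rowSums(m > 0L) == 1L
  drop <- unique_otu & rowSums(m) <= min_count
  validate_otu_table(table[!drop, , drop = FALSE])
}

#' Rarefy an OTU table without replacement
#'
#' Independently subsamples each library to exactly `depth` sequences
#' without replacement (a multivariate hypergeometric draw): sequences are
#' drawn from the library's pool and excluded from further rounds once
#' drawn, equalizing sampling effort across libraries. Libraries shallower
#' than `depth` fail loudly by default; `shallow = "drop"` removes them
#' with a warning instead.
#'
#' @param table An OTU table tibble.
#' @param depth Target depth (>= 0).
#' @param shallow What to do with libraries whose total is below `depth`:
#'   `"error"` (default) or `"drop"`.
#' @inheritParams simulate_community
#' @return An OTU table with every remaining column summing to `depth`.
#' @examples
#' t <- otu_table(c("a", "b"), cbind(l1 = c(3L, 1L)))
#' rarefy(t, 2, seed = 1)
#' @export
rarefy <- function(table, depth, seed = NULL, shallow = c("error", "drop")) {
  shallow <- match.arg(shallow)
  if (!is.numeric(depth) || length(depth) != 1L || depth < 0) {
    stop("depth must be a single count >= 0", call. = FALSE)
  }
  depth <- as.integer(depth)
  m <- as_otu_matrix(table)
  depths <- colSums(m)
  too_shallow <- depths < depth
  if (any(too_shallow)) {
    if (shallow == "error") {
      stop("library '", colnames(m)[too_shallow][1], "' has only ",
        depths[too_shallow][1], " sequences, fewer than the rarefaction depth ",
        depth,
        call. = FALSE
      )
    }
    warning(
      "dropping ", sum(too_shallow), " librar",
      if (sum(too_shallow) == 1) "y" else "ies",
      " shallower than depth ", depth, ": ",
      paste(colnames(m)[too_shallow], collapse = ", ")
    )
    m <- m[, !too_shallow, drop = FALSE]
  }
  draw <- function() {
    if (ncol(m) == 0L) {
      return(validate_otu_table(otu_matrix_to_table(m)))
    }
    # vegan advises when a table has no count-1 cells; irrelevant for
    # simulated or pre-filtered data, so muffle that advisory alone
    res <- withCallingHandlers(
      t(vegan::rrarefy(t(m), depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    storage.mode(res) <- "integer"
    validate_otu_table(otu_matrix_to_table(res))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Analytic expected richness under rarefaction
#'
#' Closed-form expectation of the number of OTUs observed when `n`
#' sequences are drawn without replacement from one library:
#' `sum_i [1 - C(N - N_i, n) / C(N, n)]` with `N` the library total and
#' `N_i` each OTU's count. Computed with log-combinatorics so large depths
#' do not overflow. Serves as the independent oracle for [rarefy()] and
#' for rarefaction curves.
#'
#' @param counts Integer vector of one library's OTU counts.
#' @param n Subsample depth, `0 <= n <= sum(counts)`.
#' @return Expected number of OTUs observed (a double).
#' @examples
#' expected_richness(c(3, 1), 2) # 1.5
#' @export
expected_richness <- function(counts, n) {
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  total <- sum(counts)
  if (n < 0 || n > total) {
    stop("n must lie in [0, ", total, "]", call. = FALSE)
  }
  if (n == 0) {
    return(0)
  }
  counts <- counts[counts > 0]
  # P(OTU i unseen) = C(N - N_i, n) / C(N, n), zero when N - N_i < n
  log_unseen <- ifelse(total - counts >= n,
    lchoose(total - counts, n) - lchoose(total, n),
    -Inf
  )
  sum(1 - exp(log_unseen))
}
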