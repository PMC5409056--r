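#' OTU count tables as tibbles
#'
#' Throughout repamp an OTU table is an ordinary tibble whose first column,
#' `otu_id`, holds unique OTU identifiers and whose remaining columns hold
#' non-negative integer sequence counts, one column per sequencing library
#' (a tagged PCR library, i.e. one technical replicate). This keeps tables
#' pipeable through dplyr/tidyr while [validate_otu_table()] enforces the
#' count-matrix contract.
#'
#' @param otu_ids Character vector of unique OTU identifiers.
#' @param counts Matrix (or data frame) of non-negative integer counts,
#'   one row per OTU, one column per library; column names are library ids.
#' @return A tibble with columns `otu_id` and one integer column per library.
#' @examples
#' otu_table(c("otu1", "otu2"), matrix(c(3, 1, 0, 2), 2, 2,
#'   dimnames = list(NULL, c("libA", "libB"))))
#' @export
otu_table <- function(otu_ids, counts) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("lib", seq_len(ncol(counts)))
  }
  tbl <- tibble::tibble(otu_id = as.character(otu_ids))
  for (j in seq_len(ncol(counts))) tbl[[colnames(counts)[j]]] <- as.integer(counts[, j])
  validate_otu_table(tbl)
}

#' Validate an OTU table
#'
#' Checks the OTU-table contract: an `otu_id` column of unique identifiers
#' followed by at least one library column of non-negative integer counts.
#'
#' @param table An OTU table tibble (see [otu_table()]).
#' @return The table, invisibly unchanged, coerced to a tibble with integer
#'   count columns.
#' @export
validate_otu_table <- function(table) {
  table <- tibble::as_tibble(table)
  if (ncol(table) < 1L || names(table)[1] != "otu_id") {
    stop("an OTU table must have 'otu_id' as its first column", call. = FALSE)
  }
  ids <- table$otu_id
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate OTU identifiers: ", paste(utils::head(dup, 5), collapse = ", "),
      call. = FALSE
    )
  }
  libs <- names(table)[-1]
  if (anyDuplicated(libs)) {
    stop("duplicate library identifiers", call. = FALSE)
  }
  for (lib in libs) {
    x <- table[[lib]]
    if (!is.numeric(x)) {
      stop("library '", lib, "' has non-numeric counts", call. = FALSE)
    }
    bad <- which(is.na(x) | x < 0 | x != floor(x))
    if (length(bad)) {
      stop("library '", lib, "', OTU '", ids[bad[1]],
        "': count must be a non-negative integer",
        call. = FALSE
      )
    }
    table[[lib]] <- as.integer(x)
  }
  table
}

# internal: counts as matrix, OTUs in rows, rownames = otu ids
as_otu_matrix <- function(table) {
  table <- validate_otu_table(table)
  m <- as.matrix(table[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- table$otu_id
  m
}

# internal: matrix back to tibble
otu_matrix_to_table <- function(m) {
  tbl <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  tbl <- dplyr::mutate(tbl, dplyr::across(dplyr::everything(), as.integer))
  dplyr::bind_cols(tibble::tibble(otu_id = rownames(m)), tbl)
}

#' Library identifiers and sequencing depths
#'
#' @param table An OTU table tibble.
#' @return For `library_ids()`, a character vector; for `library_depths()`,
#'   a tibble with columns `library` and `depth` (column sum); for
#'   [min_depth()], the smallest library depth — the depth the study design
#'   rarefies to ("the sample with the fewest number of sequences").
#' @export
library_ids <- function(table) {
  names(validate_otu_table(table))[-1]
}

#' @rdname library_ids
#' @export
library_depths <- function(table) {
  m <- as_otu_matrix(table)
  tibble::tibble(library = colnames(m), depth = as.integer(colSums(m)))
}

#' @rdname library_ids
#' @export
min_depth <- function(table) {
  d <- library_depths(table)
  if (nrow(d) == 0L) stop("OTU table has no libraries", call. = FALSE)
  min(d$depth)
}

#' Read and write tab-delimited OTU tables
#'
#' The on-disk dialect is tab-delimited text with OTUs as rows and libraries
#' as columns: the first header field names the OTU-id column, remaining
#' fields are library ids, and every cell is a non-negative integer.
#' `transposed = TRUE` accepts the transposed dialect (libraries as rows).
#' Zero-count OTUs are preserved on both read and write.
#'
#' @param path Path to a tab-delimited file.
#' @param transposed If `TRUE` the file stores libraries as rows and OTUs as
#'   columns; it is transposed on read.
#' @return `read_otu_table()` returns a validated OTU table tibble;
#'   `write_otu_table()` invisibly returns `path`.
#' @export
read_otu_table <- function(path, transposed = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(raw) < 1L) stop("empty OTU table file: ", path, call. = FALSE)
  ids <- raw[[1]]
  counts <- raw[, -1, drop = FALSE]
  for (lib in names(counts)) {
    x <- suppressWarnings(as.numeric(counts[[lib]]))
    bad <- which(is.na(x) | x < 0 | x != floor(x))
    if (length(bad)) {
      stop("parse error in '", path, "': row '", ids[bad[1]], "', column '",
        lib, "': '", counts[[lib]][bad[1]], "' is not a non-negative integer",
        call. = FALSE
      )
    }
    counts[[lib]] <- as.integer(x)
  }
  tbl <- dplyr::bind_cols(tibble::tibble(otu_id = as.character(ids)), counts)
  tbl <- validate_otu_table(tbl)
  if (transposed) {
    m <- t(as_otu_matrix(tbl))
    tbl <- validate_otu_table(otu_matrix_to_table(m))
  }
  tbl
}

#' @rdname read_otu_table
#' @param table An OTU table tibble.
#' @export
write_otu_table <- function(table, path) {
  table <- validate_otu_table(table)
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

design_columns <- c(
  "library", "sample", "technical_rep", "biological_rep", "treatment",
  "location"
)

#' Read, write and validate replicate-design files
#'
#' A replicate design maps every library to its place in the nested sampling
#' hierarchy: `sample` (one DNA extract, sequenced as several technical
#' replicates), `technical_rep` (1..T within the sample), `biological_rep`
#' (field replicate), `treatment` (e.g. planted/unplanted) and `location`.
#' Files are tab-delimited with those six named columns.
#'
#' @param path Path to a tab-delimited design file.
#' @return A validated design tibble.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_design(d)
}

#' @rdname read_design
#' @param design A design tibble.
#' @export
write_design <- function(design, path) {
  design <- validate_design(design)
  readr::write_tsv(design, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_design
#' @param table Optional OTU table; if supplied, the design and table must
#'   cover exactly the same libraries.
#' @export
validate_design <- function(design, table = NULL) {
  design <- tibble::as_tibble(design)
  missing_cols <- setdiff(design_columns, names(design))
  if (length(missing_cols)) {
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  design <- design[, design_columns]
  design$library <- as.character(design$library)
  design$sample <- as.character(design$sample)
  design$technical_rep <- as.integer(design$technical_rep)
  if (anyDuplicated(design$library)) {
    stop("library listed more than once in design: ",
      design$library[duplicated(design$library)][1],
      call. = FALSE
    )
  }
  key <- paste(design$sample, design$technical_rep)
  if (anyDuplicated(key)) {
    stop("duplicate (sample, technical_rep) pair: ", key[duplicated(key)][1],
      call. = FALSE
    )
  }
  if (!is.null(table)) {
    libs <- library_ids(table)
    extra <- setdiff(design$library, libs)
    absent <- setdiff(libs, design$library)
    if (length(extra)) {
      stop("design names library absent from the table: ", extra[1], call. = FALSE)
    }
    if (length(absent)) {
      stop("table library missing from the design: ", absent[1], call. = FALSE)
    }
  }
  design
}
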