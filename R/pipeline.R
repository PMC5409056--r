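#' Configure an end-to-end reproducibility analysis
#'
#' Collects every parameter of [run_analysis()] in one validated object so
#' a run is fully described by its config plus seed. Exactly one input
#' source must be given: paths to an OTU table and design file, in-memory
#' tibbles, or a [simulation_recipe()].
#'
#' @param table,design An OTU table and replicate design, either as file
#'   paths or as tibbles.
#' @param recipe A [simulation_recipe()] used to simulate the input
#'   instead.
#' @param rarefaction_depth `"min"` (default: the shallowest library's
#'   depth, the standard rarefaction level) or a count.
#' @param remove_singletons Apply the singleton filter (default `TRUE`).
#' @param singleton_scope Scope of the singleton filter, `"table"` or
#'   `"sample"`.
#' @param filter_order `"pre_rarefaction"` (default: singletons removed
#'   before resampling, the standard order) or `"post_rarefaction"`; the
#'   order is recorded in the run log because it affects results.
#' @param remove_unique_otus Apply the unique-OTU filter after rarefaction
#'   (default `FALSE`).
#' @param unique_min_count Count threshold of the unique-OTU filter.
#' @param metrics Beta-diversity metrics to compute.
#' @param run_depth_profile Compute an overlap-versus-depth profile.
#' @param depth_grid Depth grid for the profile (defaults to the grid
#'   points of [default_depth_grid()] that the data can support).
#' @param n_resamples Resamples per profile depth.
#' @param run_nullmodel Run the null-model dispersion test per sample.
#' @param n_iter Null-model iterations.
#' @param shallow_libraries `"error"` or `"drop"`: what to do with
#'   libraries shallower than the rarefaction depth.
#' @param seed Integer seed governing every random step of the run.
#' @param output_dir Optional directory; when given, every result table is
#'   written there as tab-delimited text.
#' @param log_level `"info"` to narrate stages via [message()], `"quiet"`
#'   to stay silent.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(table = NULL, design = NULL, recipe = NULL,
                            rarefaction_depth = "min",
                            remove_singletons = TRUE,
                            singleton_scope = c("table", "sample"),
                            filter_order = c("pre_rarefaction", "post_rarefaction"),
                            remove_unique_otus = FALSE, unique_min_count = 1,
                            metrics = c("sorensen", "bray_curtis"),
                            run_depth_profile = FALSE,
                            depth_grid = NULL, n_resamples = 1,
                            run_nullmodel = FALSE, n_iter = 1000,
                            shallow_libraries = c("error", "drop"),
                            seed = NULL, output_dir = NULL,
                            log_level = c("info", "quiet")) {
  has_data <- !is.null(table) && !is.null(design)
  if (is.null(recipe) == !has_data) {
    stop("give either a table + design or a simulation recipe (not both)",
      call. = FALSE
    )
  }
  structure(
    list(
      table = table, design = design, recipe = recipe,
      rarefaction_depth = rarefaction_depth,
      remove_singletons = remove_singletons,
      singleton_scope = match.arg(singleton_scope),
      filter_order = match.arg(filter_order),
      remove_unique_otus = remove_unique_otus,
      unique_min_count = unique_min_count,
      metrics = match.arg(metrics, c("sorensen", "bray_curtis"), several.ok = TRUE),
      run_depth_profile = run_depth_profile,
      depth_grid = depth_grid, n_resamples = n_resamples,
      run_nullmodel = run_nullmodel, n_iter = n_iter,
      shallow_libraries = match.arg(shallow_libraries),
      seed = seed, output_dir = output_dir,
      log_level = match.arg(log_level)
    ),
    class = "analysis_config"
  )
}

#' Run the end-to-end reproducibility analysis
#'
#' Loads (or simulates) an OTU table and replicate design, applies the
#' configured filters, rarefies every library to a common depth, and
#' computes the overlap summary, alpha diversity, level-wise beta
#' diversity, and optionally the overlap-versus-depth profile and the
#' per-sample null-model dispersion tests. Every parameter, the
#' rarefaction depth actually used, and the per-filter OTU removals are
#' recorded in the returned `log` tibble. Identical config and seed give
#' identical outputs.
#'
#' @param config An [analysis_config()].
#' @return A list of class `analysis_report`: `table` (rarefied, filtered
#'   OTU table), `design`, `overlap` ([overlap_summary()]), `alpha`
#'   ([alpha_diversity()]), `beta_pairs`, `beta_levels`, `depth_profile`
#'   (or `NULL`), `dispersion` (or `NULL`), and `log`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  say <- function(...) if (config$log_level == "info") message("[repamp] ", ...)
  logs <- list()
  note <- function(param, value) {
    logs[[length(logs) + 1L]] <<- tibble::tibble(
      parameter = param,
      value = paste(format(value), collapse = ",")
    )
  }
  run <- function() {
    # --- input ---------------------------------------------------------
    if (!is.null(config$recipe)) {
      say("simulating input (", length(config$recipe$locations), " locations x ",
        length(config$recipe$treatments), " treatments x ",
        config$recipe$biological_reps, " x ", config$recipe$technical_reps, ")")
      sim <- stage("simulate", simulate_experiment(config$recipe, seed = NULL))
      table <- sim$table
      design <- sim$design
      note("input", "simulated")
      for (p in c(
        "n_otus", "depth", "epsilon", "theta", "sigma_treatment",
        "sigma_biological", "sdlog", "artifact_size"
      )) {
        note(paste0("recipe.", p), config$recipe[[p]])
      }
    } else {
      table <- config$table
      design <- config$design
      if (is.character(table)) table <- stage("read_table", read_otu_table(table))
      if (is.character(design)) design <- stage("read_design", read_design(design))
      note("input", "files")
    }
    table <- stage("validate", validate_otu_table(table))
    design <- stage("validate", validate_design(design, table))
    note("n_libraries", ncol(table) - 1L)
    note("seed", if (is.null(config$seed)) NA else config$seed)

    # --- singleton filter (standard order: before resampling) ----------
    filter_singletons <- function(tab) {
      n_before <- nrow(tab)
      tab <- stage(
        "remove_singletons",
        remove_singletons(tab, scope = config$singleton_scope, design = design)
      )
      say("singleton filter removed ", n_before - nrow(tab), " OTUs")
      note("singletons_removed", n_before - nrow(tab))
      note("singleton_scope", config$singleton_scope)
      tab
    }
    note("filter_order", config$filter_order)
    if (config$remove_singletons && config$filter_order == "pre_rarefaction") {
      table <- filter_singletons(table)
    }

    # --- rarefaction ---------------------------------------------------
    depth <- config$rarefaction_depth
    if (identical(depth, "min")) depth <- min_depth(table)
    depth <- as.integer(depth)
    say("rarefying to ", depth, " sequences per library")
    note("rarefaction_depth", depth)
    pre_rarefaction <- table
    table <- stage(
      "rarefy",
      rarefy(table, depth, shallow = config$shallow_libraries)
    )
    if (config$remove_singletons && config$filter_order == "post_rarefaction") {
      table <- filter_singletons(table)
    }
    if (config$remove_unique_otus) {
      n_before <- nrow(table)
      table <- stage(
        "remove_unique_otus",
        remove_unique_otus(table, min_count = config$unique_min_count)
      )
      say("unique-OTU filter removed ", n_before - nrow(table), " OTUs")
      note("unique_otus_removed", n_before - nrow(table))
      note("unique_min_count", config$unique_min_count)
    }
    design <- validate_design(design[design$library %in% library_ids(table), ])

    # --- statistics ----------------------------------------------------
    say("computing overlap statistics")
    overlap <- stage("overlap", overlap_summary(table, design))
    alpha <- stage("alpha_diversity", alpha_diversity(table))
    pairs <- stage(
      "beta_diversity",
      dplyr::bind_rows(lapply(config$metrics, function(met) beta_pairs(table, met)))
    )
    levels <- stage(
      "beta_diversity",
      dplyr::bind_rows(lapply(config$metrics, function(met) {
        dplyr::mutate(
          beta_level_summary(
            pairs[pairs$metric == met, setdiff(names(pairs), "metric")], design
          ),
          metric = met, .before = 1
        )
      }))
    )
    profile <- NULL
    if (config$run_depth_profile) {
      grid <- config$depth_grid
      if (is.null(grid)) {
        grid <- default_depth_grid()
        grid <- grid[grid <= min_depth(pre_rarefaction)]
      }
      say("profiling overlap over ", length(grid), " depths")
      note("depth_grid", grid)
      note("n_resamples", config$n_resamples)
      profile <- stage(
        "depth_profile",
        depth_profile(pre_rarefaction, design,
          depths = grid,
          n_resamples = config$n_resamples
        )
      )
    }
    dispersion <- NULL
    if (config$run_nullmodel) {
      say("running null-model dispersion tests (", config$n_iter, " iterations)")
      note("nullmodel_n_iter", config$n_iter)
      dispersion <- stage(
        "nullmodel",
        permdisp_summary(table, design,
          metrics = config$metrics,
          n_iter = config$n_iter
        )
      )
    }
    report <- structure(
      list(
        table = table, design = design, overlap = overlap, alpha = alpha,
        beta_pairs = pairs, beta_levels = levels, depth_profile = profile,
        dispersion = dispersion, log = dplyr::bind_rows(logs)
      ),
      class = "analysis_report"
    )
    if (!is.null(config$output_dir)) write_report(report, config$output_dir)
    report
  }
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

# run a pipeline stage, prefixing any error with the stage name
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Write an analysis report to tab-delimited files
#'
#' @param report An `analysis_report` from [run_analysis()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- function(x, name) {
    if (!is.null(x)) {
      readr::write_tsv(tibble::as_tibble(x), file.path(dir, paste0(name, ".tsv")),
        progress = FALSE
      )
    }
  }
  out(report$table, "otu_table_rarefied")
  out(report$design, "design")
  out(report$overlap, "overlap_pairs")
  out(attr(report$overlap, "experiment"), "overlap_experiment")
  out(report$alpha, "alpha_diversity")
  out(report$beta_pairs, "beta_pairs")
  out(report$beta_levels, "beta_levels")
  out(report$depth_profile, "depth_profile")
  if (!is.null(report$depth_profile)) {
    out(attr(report$depth_profile, "saturation"), "depth_profile_saturation")
  }
  out(report$dispersion, "dispersion_tests")
  out(report$log, "run_log")
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("repamp analysis report\n")
  cat("  libraries:", ncol(x$table) - 1L, " OTUs:", nrow(x$table), "\n")
  ex <- attr(x$overlap, "experiment")
  ex <- ex[ex$reduction == "per_sample_mean", ]
  for (i in seq_len(nrow(ex))) {
    cat(sprintf(
      "  %s %s overlap: %.1f%% +/- %.1f%%\n", ex$weighting[i],
      ex$statistic[i], 100 * ex$mean[i], 100 * ex$sd[i]
    ))
  }
  if (!is.null(x$dispersion)) {
    cat(
      "  dispersion tests:", nrow(x$dispersion), "(",
      sum(x$dispersion$p <= 0.05), "with p <= 0.05 )\n"
    )
  }
  invisible(x)
}
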