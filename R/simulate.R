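#' Simulate an underlying community profile
#'
#' Draws `n_otus` relative abundances from a log-normal species-abundance
#' distribution (the standard model for microbial communities) and
#' normalizes them to sum to one. The profile plays the role of the
#' underlying community that technical replicates are random sequence
#' samples of.
#'
#' @param n_otus Number of OTUs (S >= 1).
#' @param meanlog,sdlog Mean and sd of log-abundance before normalization.
#'   `meanlog` only sets scale and cancels in the normalization; `sdlog`
#'   controls unevenness (0 gives a perfectly even community).
#' @param seed Optional integer seed; when given the draw is deterministic
#'   and the caller's RNG state is untouched.
#' @return A tibble with columns `otu_id` and `abundance` (sums to 1).
#' @examples
#' simulate_community(5, sdlog = 2, seed = 1)
#' @export
simulate_community <- function(n_otus, meanlog = 0, sdlog = 2, seed = NULL) {
  if (!is.numeric(n_otus) || length(n_otus) != 1L || n_otus < 1) {
    stop("n_otus must be a single count >= 1", call. = FALSE)
  }
  n_otus <- as.integer(n_otus)
  draw <- function() {
    a <- stats::rlnorm(n_otus, meanlog = meanlog, sdlog = sdlog)
    tibble::tibble(
      otu_id = sprintf("otu%0*d", nchar(n_otus), seq_len(n_otus)),
      abundance = a / sum(a)
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Perturb a community profile
#'
#' Shifts each log-abundance by an independent normal draw of sd `sigma`
#' and renormalizes. Used to create location/treatment/biological-replicate
#' differences between communities; `sigma = 0` returns the input unchanged.
#'
#' @param profile A profile tibble (`otu_id`, `abundance`).
#' @param sigma Standard deviation of the log-abundance shift (>= 0).
#' @inheritParams simulate_community
#' @return A profile tibble with the same OTUs.
#' @export
perturb_profile <- function(profile, sigma, seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop("sigma must be a single value >= 0", call. = FALSE)
  }
  profile <- validate_profile(profile)
  if (sigma == 0) {
    return(profile)
  }
  draw <- function() {
    a <- profile$abundance * exp(stats::rnorm(nrow(profile), 0, sigma))
    dplyr::mutate(profile, abundance = a / sum(a))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

validate_profile <- function(profile) {
  profile <- tibble::as_tibble(profile)
  if (!all(c("otu_id", "abundance") %in% names(profile))) {
    stop("a profile needs columns otu_id and abundance", call. = FALSE)
  }
  if (any(profile$abundance < 0)) stop("negative abundance", call. = FALSE)
  s <- sum(profile$abundance)
  if (abs(s - 1) > 1e-12) {
    if (s <= 0) stop("profile abundances sum to zero", call. = FALSE)
    profile$abundance <- profile$abundance / s
  }
  profile
}

#' Simulate technical replicates of one sample
#'
#' Each technical replicate is a random sequence sample of the shared
#' profile: a multinomial draw of `depth` reads (or, with finite `theta`,
#' a draw from a replicate-specific Dirichlet-multinomial with mean
#' `profile` and concentration `theta`, representing extra-multinomial
#' PCR/sequencing dispersion). On top of the true community, each replicate
#' receives `K ~ Poisson(epsilon * depth)` spurious artifact OTUs — novel
#' identifiers unique to that replicate, each with `artifact_size` reads —
#' which replace true-community reads so that every library's depth stays
#' exactly `depth`. This is the mechanism by which error-derived OTUs
#' accumulate with sequencing depth and cap the achievable OTU overlap.
#'
#' @param profile A community profile tibble (`otu_id`, `abundance`).
#' @param depth Reads per replicate (N >= 0).
#' @param n_reps Number of technical replicates (>= 1).
#' @param epsilon Artifact rate: expected spurious OTUs per sequenced read
#'   (0 <= epsilon <= 1).
#' @param theta Dirichlet concentration; `Inf` (default) gives a pure
#'   multinomial, smaller values give stronger replicate-to-replicate
#'   overdispersion.
#' @param artifact_size Reads per artifact OTU (default 1 — replicate-unique
#'   singletons; values >= 2 exercise the unique-OTU filter).
#' @param library_ids Optional character vector of library names.
#' @inheritParams simulate_community
#' @return An OTU table tibble; columns sum exactly to `depth`.
#' @export
simulate_technical_replicates <- function(profile, depth, n_reps = 3,
                                          epsilon = 0, theta = Inf,
                                          artifact_size = 1,
                                          library_ids = NULL, seed = NULL) {
  profile <- validate_profile(profile)
  if (depth < 0) stop("depth must be >= 0", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (epsilon < 0 || epsilon > 1) {
    stop("epsilon must lie in [0, 1]: artifact load cannot exceed depth",
      call. = FALSE
    )
  }
  if (!(theta > 0)) stop("theta must be > 0 (Inf for pure multinomial)", call. = FALSE)
  depth <- as.integer(depth)
  n_reps <- as.integer(n_reps)
  if (is.null(library_ids)) {
    library_ids <- paste0("rep", seq_len(n_reps))
  }
  stopifnot(length(library_ids) == n_reps)

  draw <- function() {
    p <- profile$abundance
    out <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      pr <- if (is.finite(theta)) {
        g <- stats::rgamma(length(p), shape = p * theta, rate = 1)
        if (sum(g) == 0) p else g / sum(g)
      } else {
        p
      }
      counts <- if (depth > 0) {
        as.integer(stats::rmultinom(1, depth, pr))
      } else {
        integer(length(p))
      }
      n_art <- 0L
      art_counts <- integer(0)
      if (epsilon > 0 && depth > 0) {
        k <- stats::rpois(1, epsilon * depth)
        # artifact reads displace true reads; cap the load at the depth
        k <- min(k, depth %/% artifact_size)
        if (k > 0) {
          remove <- depth - k * artifact_size
          # hypergeometric thinning of the true counts down to `remove` reads
          kept <- thin_counts(counts, remove)
          counts <- kept
          n_art <- as.integer(k)
          art_counts <- rep(as.integer(artifact_size), k)
        }
      }
      ids <- profile$otu_id
      if (n_art > 0) {
        ids <- c(ids, sprintf("%s_art%03d", library_ids[r], seq_len(n_art)))
        counts <- c(counts, art_counts)
      }
      out[[r]] <- tibble::tibble(
        otu_id = ids, library = library_ids[r],
        count = counts
      )
    }
    long <- dplyr::bind_rows(out)
    wide <- tidyr::pivot_wider(long,
      names_from = "library", values_from = "count",
      values_fill = 0L
    )
    # restore profile OTU order first, artifacts after
    wide <- wide[order(match(wide$otu_id, profile$otu_id, nomatch = nrow(wide) + 1L)), ]
    validate_otu_table(wide)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# subsample an integer count vector without replacement down to `target` reads
thin_counts <- function(counts, target) {
  total <- sum(counts)
  if (target >= total) {
    return(as.integer(counts))
  }
  if (target <= 0) {
    return(integer(length(counts)))
  }
  drawn <- sample.int(total, target)
  breaks <- cumsum(counts)
  idx <- findInterval(drawn - 1L, c(0L, breaks[-length(breaks)])) # which OTU each read belongs to
  tab <- tabulate(idx, nbins = length(counts))
  as.integer(tab)
}

#' Define a simulation recipe for a full replicated experiment
#'
#' Bundles the parameters of [simulate_experiment()]. The defaults emulate
#' the sampling structure of a replicated soil amplicon study: 3 locations
#' x 2 treatments (planted/unplanted) x 3 field replicates x 3 technical
#' replicates = 54 libraries, each a random sequence sample of its soil
#' community at a depth of 10,000 reads, with a modest artifact load.
#'
#' @param n_otus Richness S of each location's community.
#' @param meanlog,sdlog Log-normal abundance-distribution parameters.
#' @param depth Reads per library.
#' @param epsilon Artifact rate (spurious OTUs per read).
#' @param theta Dirichlet-multinomial concentration (`Inf` = multinomial).
#' @param sigma_treatment,sigma_biological Sd of the log-abundance
#'   perturbation applied per treatment and per field replicate.
#' @param locations,treatments,biological_reps,technical_reps Design
#'   dimensions; `treatments` may be a count (2 -> planted/unplanted) or a
#'   character vector of labels.
#' @param artifact_size Reads per artifact OTU.
#' @param seed Default seed used by [simulate_experiment()].
#' @return A `simulation_recipe` list.
#' @export
simulation_recipe <- function(n_otus = 3000, meanlog = 0, sdlog = 2,
                              depth = 10000, epsilon = 1e-3, theta = Inf,
                              sigma_treatment = 0.6, sigma_biological = 0.3,
                              locations = 3, treatments = 2,
                              biological_reps = 3, technical_reps = 3,
                              artifact_size = 1, seed = NULL) {
  if (is.numeric(treatments)) {
    if (length(treatments) != 1L || treatments < 1) {
      stop("design dimensions must all be >= 1", call. = FALSE)
    }
    treatments <- if (treatments == 2) {
      c("planted", "unplanted")
    } else {
      paste0("T", seq_len(treatments))
    }
  }
  if (is.numeric(locations)) {
    if (length(locations) != 1L || locations < 1) {
      stop("design dimensions must all be >= 1", call. = FALSE)
    }
    locations <- paste0("L", seq_len(locations))
  }
  recipe <- list(
    n_otus = as.integer(n_otus), meanlog = meanlog, sdlog = sdlog,
    depth = as.integer(depth), epsilon = epsilon, theta = theta,
    sigma_treatment = sigma_treatment, sigma_biological = sigma_biological,
    locations = as.character(locations), treatments = as.character(treatments),
    biological_reps = as.integer(biological_reps),
    technical_reps = as.integer(technical_reps),
    artifact_size = as.integer(artifact_size), seed = seed
  )
  with(recipe, {
    if (n_otus < 1) stop("n_otus must be >= 1", call. = FALSE)
    if (depth < 0) stop("depth must be >= 0", call. = FALSE)
    if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]", call. = FALSE)
    if (!(theta > 0)) stop("theta must be > 0", call. = FALSE)
    if (sigma_treatment < 0 || sigma_biological < 0) {
      stop("effect-size sigmas must be >= 0", call. = FALSE)
    }
    if (length(locations) < 1 || length(treatments) < 1 ||
      biological_reps < 1 || technical_reps < 1) {
      stop("design dimensions must all be >= 1", call. = FALSE)
    }
  })
  structure(recipe, class = "simulation_recipe")
}

#' Simulate a full replicated amplicon experiment
#'
#' Builds the nested design the analysis assumes: one independent base
#' community per location, perturbed per treatment (`sigma_treatment`) and
#' then per field replicate (`sigma_biological`); each field replicate's
#' profile is sequenced as `technical_reps` technical replicates via
#' [simulate_technical_replicates()]. All locations share one OTU id pool
#' but draw independent abundances, so between-location communities differ
#' most, mirroring sites hundreds to thousands of kilometres apart.
#'
#' @param recipe A [simulation_recipe()].
#' @param seed Seed; defaults to `recipe$seed`.
#' @return A list with elements `table` (OTU table tibble, one column per
#'   library), `design` (replicate-design tibble) and `profiles` (long
#'   tibble of the ground-truth biological-replicate profiles:
#'   `sample`, `location`, `treatment`, `biological_rep`, `otu_id`,
#'   `abundance`).
#' @examples
#' sim <- simulate_experiment(simulation_recipe(
#'   n_otus = 50, depth = 500,
#'   seed = 1
#' ))
#' dim(sim$table)
#' @export
simulate_experiment <- function(recipe, seed = recipe$seed) {
  stopifnot(inherits(recipe, "simulation_recipe"))
  run <- function() {
    tables <- list()
    designs <- list()
    profiles <- list()
    for (loc in recipe$locations) {
      base <- simulate_community(recipe$n_otus, recipe$meanlog, recipe$sdlog)
      for (trt in recipe$treatments) {
        trt_prof <- perturb_profile(base, recipe$sigma_treatment)
        for (b in seq_len(recipe$biological_reps)) {
          bio_id <- paste0("b", b)
          bio_prof <- perturb_profile(trt_prof, recipe$sigma_biological)
          sample_id <- paste(loc, trt, bio_id, sep = "_")
          lib_ids <- paste0(sample_id, "_t", seq_len(recipe$technical_reps))
          tab <- simulate_technical_replicates(
            bio_prof, recipe$depth, recipe$technical_reps,
            epsilon = recipe$epsilon, theta = recipe$theta,
            artifact_size = recipe$artifact_size, library_ids = lib_ids
          )
          tables[[sample_id]] <- tab
          designs[[sample_id]] <- tibble::tibble(
            library = lib_ids, sample = sample_id,
            technical_rep = seq_len(recipe$technical_reps),
            biological_rep = bio_id, treatment = trt, location = loc
          )
          profiles[[sample_id]] <- dplyr::mutate(bio_prof,
            sample = sample_id, location = loc, treatment = trt,
            biological_rep = bio_id, .before = 1
          )
        }
      }
    }
    long <- dplyr::bind_rows(lapply(tables, function(t) {
      tidyr::pivot_longer(t, -"otu_id", names_to = "library", values_to = "count")
    }))
    table <- tidyr::pivot_wider(long,
      names_from = "library",
      values_from = "count", values_fill = 0L
    )
    table <- table[order(table$otu_id), ]
    design <- validate_design(dplyr::bind_rows(designs), table)
    list(
      table = validate_otu_table(table),
      design = design,
      profiles = dplyr::bind_rows(profiles)
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
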