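#' Simulation experiments validating the dating machinery
#'
#' Each experiment regenerates data from the coalescent generator, runs the
#' corresponding estimator and summarises recovery. Defaults are the study
#' conditions used throughout the package's validation: mutation counts are
#' simulated at the rate of the clock under test (one counted substitution
#' per `years_per_substitution`), so the clock conversion is the identity
#' being checked rather than a built-in scale offset.
#'
#' @param n_rep Number of replicates.
#' @param n_tips Tips per replicate.
#' @param T True expansion time in years.
#' @param clock A [clock_spec()].
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return `experiment_star_recovery`: list with per-replicate tibble and
#'   summary scalars `mean_age`, `rel_error`, `coverage`.
#' @name experiments
NULL

#' @rdname experiments
#' @export
experiment_star_recovery <- function(n_rep = 200L, n_tips = 50L, T = 50000,
                                     clock = clock_whole_molecule(),
                                     seed = 1L) {
  mu <- 1 / (clock$years_per_substitution * 16569)
  rows <- purrr::map(seq_len(n_rep), function(r) {
    tr <- simulate_genealogy(n_tips, dem_star(T), seed = seed + 2L * r)
    tr <- drop_mutations(tr, mu = mu, L = 16569L, seed = seed + 2L * r + 1L)
    age_estimate(tr, clock = clock)
  })
  reps <- dplyr::bind_rows(rows)
  list(
    replicates = reps,
    mean_age = mean(reps$age_years),
    rel_error = abs(mean(reps$age_years) - T) / T,
    coverage = mean(reps$ci_low <= T & T <= reps$ci_high)
  )
}

#' @rdname experiments
#' @param scenario Two-phase founder scenario (see
#'   [dem_two_region_founder()]).
#' @return `experiment_founder_bias`: list with per-replicate ages and
#'   summaries: `p_rho_below_T1`, mean rho/ML shortfalls from `T1`, the
#'   approach-1 and approach-2 mean regional ages for the origin region and
#'   `p_approach2_ge_approach1`.
#' @export
experiment_founder_bias <- function(n_rep = 200L, n_tips = 50L,
                                    scenario = dem_two_region_founder(),
                                    clock = clock_whole_molecule(),
                                    seed = 1L) {
  mu <- 1 / (clock$years_per_substitution * 16569)
  origin <- scenario$origin_region
  rows <- purrr::map(seq_len(n_rep), function(r) {
    tr <- simulate_genealogy(n_tips, scenario, seed = seed + 2L * r)
    tr <- drop_mutations(tr, mu = mu, L = 16569L, seed = seed + 2L * r + 1L)
    cz <- collapse_zero_edges(tr)
    fit <- ml_clock_ages(cz, clock)
    a1 <- regional_age_all_samples(cz, region = origin, clock = clock)
    a2 <- tryCatch(
      regional_age_by_origin(cz, region = origin, clock = clock),
      error = function(e) NULL
    )
    tibble::tibble(
      rho_age = age_estimate(cz, clock = clock)$age_years,
      ml_age = fit$ages$age_years[cz$root],
      approach1 = a1$age_years,
      approach2 = if (is.null(a2)) NA_real_ else a2$age_years
    )
  })
  reps <- dplyr::bind_rows(rows)
  T1 <- scenario$T1
  list(
    replicates = reps,
    T1 = T1,
    p_rho_below_T1 = mean(reps$rho_age < T1),
    mean_rho_shortfall = mean(T1 - reps$rho_age),
    mean_ml_shortfall = mean(T1 - reps$ml_age),
    mean_approach1 = mean(reps$approach1, na.rm = TRUE),
    mean_approach2 = mean(reps$approach2, na.rm = TRUE),
    p_approach2_ge_approach1 = mean(reps$approach2 >= reps$approach1,
                                    na.rm = TRUE)
  )
}

#' @rdname experiments
#' @param N Constant effective size of the clock simulation.
#' @param subs_per_interval Counted substitutions per
#'   `years_per_substitution`; the default 5 keeps per-edge counts in the
#'   moderate regime the chi-square reference assumes.
#' @param lineage_multiplier Rate multiplier applied to one root-to-tip
#'   lineage (1 = null simulation for type-I error).
#' @param alpha Nominal level.
#' @return `experiment_lrt_calibration`: list with per-replicate p values
#'   and `rejection_rate` at `alpha`.
#' @export
experiment_lrt_calibration <- function(n_rep = 500L, n_tips = 20L, N = 1000,
                                       clock = clock_whole_molecule(),
                                       subs_per_interval = 5,
                                       lineage_multiplier = 1,
                                       alpha = 0.05, seed = 1L) {
  y <- clock$years_per_substitution
  mu <- subs_per_interval / (y * 16569)
  p <- vapply(seq_len(n_rep), function(r) {
    tr <- simulate_genealogy(n_tips, dem_constant(N = N),
                             seed = seed + 3L * r)
    tr <- drop_mutations(tr, mu = mu, L = 16569L, seed = seed + 3L * r + 1L)
    if (lineage_multiplier != 1) {
      # rescale the mutation counts of one root-to-tip descent path
      old <- local_rng(seed + 3L * r + 2L)
      path <- integer(); v <- 1L
      while (!is.na(tr$nodes$parent[v])) {
        path <- c(path, v)
        v <- tr$nodes$parent[v]
      }
      for (w in path) {
        dur <- tr$nodes$age[tr$nodes$parent[w]] - tr$nodes$age[w]
        k <- stats::rpois(1L, lineage_multiplier * subs_per_interval *
                            dur / y)
        tr$nodes$edge_muts[[w]] <- if (k > 0L) {
          mutations(sample.int(16569L, k), "A", "G")
        } else empty_mutations()
      }
      restore_rng(old)
    }
    lrt_clock(tr, clock)$p_value
  }, 0)
  list(p_values = p, rejection_rate = mean(p < alpha), alpha = alpha)
}

#' @rdname experiments
#' @param min_tips,max_tips Range of tip counts sampled per replicate.
#' @param mu Per-site per-year rate of the infinite-sites simulation
#'   (elevated so most internal edges are witnessed by a mutation).
#' @return `experiment_topology_recovery`: list with per-replicate RF
#'   distances (reconstruction vs the mutation-witnessed true topology) and
#'   `p_exact` (fraction of exact recoveries).
#' @export
experiment_topology_recovery <- function(n_rep = 100L, min_tips = 8L,
                                         max_tips = 30L,
                                         mu = 8e-4 / 16569, seed = 1L) {
  if (!requireNamespace("phangorn", quietly = TRUE)) {
    stop("experiment_topology_recovery needs the phangorn package",
         call. = FALSE)
  }
  rf <- vapply(seq_len(n_rep), function(r) {
    old <- local_rng(seed + 3L * r)
    n <- sample(seq.int(min_tips, max_tips), 1L)
    restore_rng(old)
    sim <- simulate_genealogy(n, dem_constant(N = 1000),
                              seed = seed + 3L * r + 1L)
    sim <- drop_mutations(sim, mu = mu, L = 16569L,
                          seed = seed + 3L * r + 2L,
                          infinite_sites = TRUE)
    profs <- tibble::tibble(
      sample_id = sim$nodes$label[sim$nodes$type == "sample"],
      mutations = lapply(which(sim$nodes$type == "sample"),
                         function(v) cumulative_profile(sim, v))
    )
    tree <- network_to_tree(reduced_median(profs), profiles = profs)
    suppressMessages(suppressWarnings(phangorn::RF.dist(
      ape::unroot(as_phylo(collapse_zero_edges(sim))),
      ape::unroot(as_phylo(tree))
    )))
  }, 0)
  list(rf_distances = rf, p_exact = mean(rf == 0))
}
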