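#' Demographic scenarios for the coalescent simulator
#'
#' Scenarios describe the effective-size history N(t) (t in years before
#' present) and, for the founder scenarios, the event times: `T1` the clade
#' origin and `T2` the re-expansion from a single surviving lineage. In the
#' founder scenarios the re-expanding lineage is conditioned to carry the
#' unmodified root haplotype (its ancestral path is mutation-free), the
#' mechanism by which a secondary founder effect rejuvenates clade ages.
#'
#' @param N,N0 Effective (female) population size.
#' @param generation_time Years per generation (default 25).
#' @param rate Exponential growth rate per year (looking forward in time).
#' @param T Star expansion time in years.
#' @param T1,T2 Clade origin and re-expansion times in years (`T1 > T2 > 0`).
#' @param burst_fraction Fraction of tips descending from the re-expansion.
#' @param N_large Size during the non-coalescing phases (keeps the burst
#'   star-like and the deep lineages distinct).
#' @param origin_region,founder_region Region labels for the two-region
#'   scenario.
#' @param p_back Fraction of burst tips sampled in the origin region
#'   (back-migration), which is what contaminates naive regional ages.
#' @return A `demography` object.
#' @name demography
NULL

new_demography <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "demography")
}

#' @rdname demography
#' @export
dem_constant <- function(N = 1000, generation_time = 25) {
  stopifnot(N > 0)
  new_demography("constant", N = N, generation_time = generation_time)
}

#' @rdname demography
#' @export
dem_growth <- function(N0 = 10000, rate = 1e-4, generation_time = 25) {
  stopifnot(N0 > 0, rate > 0)
  new_demography("growth", N0 = N0, rate = rate,
                 generation_time = generation_time)
}

#' @rdname demography
#' @export
dem_star <- function(T = 50000, generation_time = 25) {
  stopifnot(T > 0)
  new_demography("star", T = T, generation_time = generation_time)
}

#' @rdname demography
#' @export
dem_founder_reexpansion <- function(T1 = 55000, T2 = 40000,
                                    burst_fraction = 0.8, N_large = 2e5,
                                    generation_time = 25) {
  if (!(T1 > T2 && T2 > 0)) {
    stop("event times must satisfy T1 > T2 > 0", call. = FALSE)
  }
  stopifnot(burst_fraction > 0, burst_fraction < 1)
  new_demography("founder_reexpansion", T1 = T1, T2 = T2,
                 burst_fraction = burst_fraction, N_large = N_large,
                 generation_time = generation_time)
}

#' @rdname demography
#' @export
dem_two_region_founder <- function(T1 = 55000, T2 = 40000,
                                   burst_fraction = 0.8, N_large = 2e5,
                                   origin_region = "west",
                                   founder_region = "east",
                                   p_back = 0.3, generation_time = 25) {
  d <- dem_founder_reexpansion(T1, T2, burst_fraction, N_large,
                               generation_time)
  d$kind <- "two_region_founder"
  d$origin_region <- origin_region
  d$founder_region <- founder_region
  d$p_back <- p_back
  d
}

#' Simulate a rooted genealogy under a demographic scenario
#'
#' Kingman coalescent with piecewise-constant N(t). The founder scenarios
#' build a two-phase genealogy: the burst tips stay distinct until `T2`
#' and coalesce star-like at `T2`; the surviving deep lineages (plus the
#' burst ancestor) coalesce between `T2` and `T1`, closing at `T1`. The
#' path from the clade root to the burst ancestor is flagged `frozen`
#' (mutation-free root-type survival). Deterministic given `seed`.
#'
#' @param n_tips Number of sampled tips (>= 2).
#' @param scenario A `demography` object.
#' @param seed Integer seed.
#' @return A [mutation_tree()] with true node `age`s in years, tips of type
#'   `"sample"` at age 0, and a logical `frozen` column on the nodes.
#' @export
simulate_genealogy <- function(n_tips, scenario = dem_constant(),
                               seed = 1L) {
  stopifnot(n_tips >= 2L)
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  g <- scenario$generation_time
  tree <- switch(
    scenario$kind,
    constant = sim_epochs(n_tips, epochs(0, scenario$N), g),
    growth = {
      t_max <- log(scenario$N0) / scenario$rate
      brk <- seq(0, t_max, length.out = 201L)
      Nv <- pmax(1, scenario$N0 * exp(-scenario$rate * brk))
      sim_epochs(n_tips, epochs(brk, Nv), g)
    },
    star = sim_star(n_tips, scenario$T),
    founder_reexpansion = sim_founder(n_tips, scenario),
    two_region_founder = sim_founder(n_tips, scenario),
    stop("unknown scenario kind: ", scenario$kind, call. = FALSE)
  )
  tree$nodes$label[tree$nodes$type == "sample"] <-
    paste0("s", seq_len(sum(tree$nodes$type == "sample")))
  attr(tree, "scenario") <- scenario
  attr(tree, "seed") <- seed
  tree
}

epochs <- function(start, N) tibble::tibble(start = start, N = N)

# Kingman coalescent of the lineages in `ids` starting at time t0 under
# piecewise-constant N (epochs by start time, years). New internal nodes
# take ids next_id, next_id+1, ...; merge events are recorded into `state`
# (an environment with $parent and $age vectors indexed by node id).
coalesce_into <- function(state, ids, eps, g, t0, next_id) {
  t <- t0
  while (length(ids) > 1L) {
    j <- length(ids)
    repeat {
      e <- max(which(eps$start <= t + 1e-9))
      rate <- j * (j - 1) / 2 / (eps$N[e] * g)
      dt <- stats::rexp(1L, rate)
      nxt <- if (e < nrow(eps)) eps$start[e + 1L] else Inf
      if (t + dt <= nxt) { t <- t + dt; break }
      t <- nxt
    }
    pair <- sample.int(length(ids), 2L)
    state$parent[ids[pair]] <- next_id
    state$age[next_id] <- t
    ids <- c(ids[-pair], next_id)
    next_id <- next_id + 1L
  }
  list(root = ids, next_id = next_id)
}

finish_tree <- function(state, n_tips, regions = NULL, frozen = NULL) {
  n_total <- length(state$age)
  nd <- tibble::tibble(
    node = seq_len(n_total),
    parent = state$parent[seq_len(n_total)],
    type = c(rep("sample", n_tips), rep("haplotype", n_total - n_tips)),
    label = NA_character_,
    age = state$age,
    frozen = if (is.null(frozen)) FALSE else frozen
  )
  if (!is.null(regions)) nd$region <- c(regions,
                                        rep(NA_character_, n_total - n_tips))
  mutation_tree(nd)
}

new_sim_state <- function(n_tips, n_internal) {
  e <- new.env()
  e$parent <- rep(NA_integer_, n_tips + n_internal)
  e$age <- c(rep(0, n_tips), rep(NA_real_, n_internal))
  e
}

sim_epochs <- function(n_tips, eps, g, t0 = 0) {
  st <- new_sim_state(n_tips, n_tips - 1L)
  coalesce_into(st, seq_len(n_tips), eps, g, t0, n_tips + 1L)
  finish_tree(st, n_tips)
}

sim_star <- function(n_tips, T) {
  mutation_tree(tibble::tibble(
    node = seq_len(n_tips + 1L),
    parent = c(rep(n_tips + 1L, n_tips), NA_integer_),
    type = c(rep("sample", n_tips), "haplotype"),
    label = NA_character_,
    age = c(rep(0, n_tips), T),
    frozen = FALSE
  ))
}

sim_founder <- function(n_tips, sc) {
  g <- sc$generation_time
  m <- max(2L, round(sc$burst_fraction * n_tips))
  n_old <- n_tips - m
  if (n_old < 1L) stop("burst_fraction leaves no deep lineage", call. = FALSE)
  N_tiny <- 1e-3  # forces near-immediate closure past an event time
  st <- new_sim_state(n_tips, n_tips - 1L)
  # burst clade (tips 1..m): no coalescence on [0, T2), star closure at T2
  eb <- epochs(c(0, sc$T2), c(sc$N_large, N_tiny))
  res_b <- coalesce_into(st, seq_len(m), eb, g, 0, n_tips + 1L)
  burst_root <- res_b$root
  # deep phase: burst ancestor + old tip lineages stay distinct until the
  # clade origin, where they coalesce (star closure at T1)
  ed <- epochs(c(0, sc$T1), c(sc$N_large, N_tiny))
  deep_ids <- c(burst_root, seq.int(m + 1L, m + n_old))
  coalesce_into(st, deep_ids, ed, g, sc$T2, res_b$next_id)
  # freeze the clade-root -> burst-ancestor path (root-type survival)
  frozen <- rep(FALSE, length(st$age))
  v <- burst_root
  while (!is.na(st$parent[v])) { frozen[v] <- TRUE; v <- st$parent[v] }
  regions <- NULL
  if (identical(sc$kind, "two_region_founder")) {
    in_origin <- c(stats::runif(m) < sc$p_back, rep(TRUE, n_old))
    regions <- ifelse(in_origin, sc$origin_region, sc$founder_region)
  }
  finish_tree(st, n_tips, regions = regions, frozen = frozen)
}

#' Drop mutations onto a simulated genealogy
#'
#' Per edge, the substitution count is Poisson with mean
#' `mu * L * duration`; positions are drawn uniformly without replacement
#' within each edge (finite sites: recurrent hits across edges are possible
#' and produce back mutations along a path), or globally without
#' replacement under `infinite_sites = TRUE`.
#'
#' On the `frozen` path of the founder scenarios (clade root down to the
#' re-expanding ancestor) the Poisson draw is replaced by a fixed total of
#' `founder_mutations` mutations (default 1), placed on the edge directly
#' above the re-expanding node: the surviving near-root type that seeds the
#' re-expansion sits a single defining mutation away from the clade root,
#' which is what rejuvenates the clade's rho age while leaving the burst
#' identifiable as a subclade.
#'
#' @param tree A genealogy from [simulate_genealogy()] (ages in years).
#' @param mu Per-site per-year mutation rate (default the mitogenome
#'   relaxed-clock anchor 2.514e-8).
#' @param L Number of sites (default 16569).
#' @param seed Integer seed (independent of the genealogy seed).
#' @param reference Optional [reference_genome()] supplying ancestral bases
#'   and, when given, synonymous classification of each mutation; without
#'   it the ancestral state is an abstract `"A"` with derived `"G"`.
#' @param infinite_sites Draw every mutation at a fresh site.
#' @param founder_mutations Mutations assigned to the frozen founder path
#'   (default 1).
#' @return The tree with `edge_muts` filled; attributes `mu`, `L`,
#'   `mut_seed` record the draw.
#' @export
drop_mutations <- function(tree, mu = 2.514e-8, L = 16569L, seed = 1L,
                           reference = NULL, infinite_sites = FALSE,
                           founder_mutations = 1L) {
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  nd <- tree$nodes
  if (!"frozen" %in% names(nd)) nd$frozen <- FALSE
  dur <- ifelse(is.na(nd$parent), 0, nd$age[nd$parent] - nd$age)
  if (any(dur < -1e-6, na.rm = TRUE)) {
    stop("negative edge duration: ages must decrease toward the tips",
         call. = FALSE)
  }
  dur <- pmax(dur, 0)
  if (mu * L * sum(dur) > L / 2) {
    warning("expected mutation load exceeds L/2: finite-site saturation")
  }
  counts <- stats::rpois(length(dur), mu * L * dur)
  if (any(nd$frozen)) {
    counts[nd$frozen] <- 0L
    # deepest frozen node = the re-expanding ancestor; its edge carries the
    # founder's defining mutation(s)
    froz <- which(nd$frozen)
    kids_of <- tree_children_list(tree)
    burst <- froz[!vapply(froz, function(v) any(nd$frozen[kids_of[[v]]]),
                          TRUE)][1L]
    counts[burst] <- as.integer(founder_mutations)
  }
  transition <- c(A = "G", G = "A", C = "T", T = "C", N = "A")
  free_sites <- seq_len(L)
  # preorder walk carrying the current state of mutated positions
  kids <- tree_children_list(tree)
  edge_muts <- vector("list", nrow(nd))
  edge_muts[[tree$root]] <- empty_mutations()
  walk <- function(v, state) {
    for (w in kids[[v]]) {
      k <- counts[w]
      st <- state
      if (k > 0L) {
        if (infinite_sites) {
          if (k > length(free_sites)) {
            stop("infinite-sites model exhausted all ", L, " sites",
                 call. = FALSE)
          }
          pos <- sample(free_sites, k)
          free_sites <<- setdiff(free_sites, pos)
        } else {
          pos <- sample.int(L, k)
        }
        anc <- unname(vapply(as.character(pos), function(p) {
          cur <- st[[p]]
          if (!is.null(cur)) cur
          else if (!is.null(reference)) ref_base(reference, as.integer(p))
          else "A"
        }, ""))
        der <- unname(transition[anc])
        for (i in seq_along(pos)) st[[as.character(pos[i])]] <- der[i]
        edge_muts[[w]] <<- mutations(pos, anc, der)
      } else {
        edge_muts[[w]] <<- empty_mutations()
      }
      walk(w, st)
    }
  }
  walk(tree$root, list())
  if (!is.null(reference)) {
    edge_muts <- purrr::map(edge_muts, classify_mutations,
                            reference = reference)
  }
  tree$nodes$edge_muts <- edge_muts
  attr(tree, "mu") <- mu
  attr(tree, "L") <- L
  attr(tree, "mut_seed") <- seed
  tree
}

#' Write a simulated dataset to disk
#'
#' Emits an aligned FASTA (reference row plus one reconstructed sequence
#' per tip), a sample metadata TSV and a truth JSON holding the scenario,
#' true node ages and TMRCA - the inputs every downstream stage consumes.
#'
#' @param tree A mutated genealogy from [drop_mutations()].
#' @param dir Output directory (created if needed).
#' @param reference A [reference_genome()]; when the mutations were dropped
#'   without one, a flat reference of the same length is synthesised so the
#'   FASTA round-trips.
#' @param prefix File name prefix.
#' @return Named character vector of the three file paths, invisibly.
#' @export
emit_dataset <- function(tree, dir, reference = NULL, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- attr(tree, "L") %||% 16569L
  if (is.null(reference)) {
    reference <- reference_genome(
      "flat_reference", strrep("A", L),
      tibble::tibble(name = "all", start = 1L, end = L,
                     strand = "heavy", kind = "control")
    )
  }
  tips <- which(tree$nodes$type == "sample")
  seqs <- vapply(tips, function(v) {
    profile_to_sequence(cumulative_profile(tree, v), reference)
  }, "")
  fasta <- file.path(dir, paste0(prefix, "_aligned.fasta"))
  lines <- c(paste0(">", reference$id), reference$sequence,
             rbind(paste0(">", tree$nodes$label[tips]), seqs))
  writeLines(lines, fasta)
  meta <- file.path(dir, paste0(prefix, "_samples.tsv"))
  readr::write_tsv(tibble::tibble(
    sample_id = tree$nodes$label[tips],
    population = tree$nodes$population[tips],
    region = tree$nodes$region[tips]
  ), meta, progress = FALSE)
  truth <- file.path(dir, paste0(prefix, "_truth.json"))
  sc <- unclass(attr(tree, "scenario"))
  internal <- which(tree$nodes$type != "sample")
  jsonlite::write_json(list(
    scenario = sc[names(sc) != "kind" & !vapply(sc, is.function, TRUE)],
    kind = sc$kind %||% "unknown",
    tmrca = max(tree$nodes$age, na.rm = TRUE),
    seed = attr(tree, "seed"), mut_seed = attr(tree, "mut_seed"),
    mu = attr(tree, "mu"), L = L,
    node_ages = stats::setNames(as.list(tree$nodes$age[internal]),
                                paste0("node", internal)),
    regions = stats::setNames(as.list(tree$nodes$region[tips]),
                              tree$nodes$label[tips])
  ), truth, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(fasta = fasta, metadata = meta, truth = truth))
}

#' True time to the most recent common ancestor of a simulated tree
#' @param tree A simulated genealogy.
#' @return Root age in years.
#' @export
true_tmrca <- function(tree) tree$nodes$age[tree$root]
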