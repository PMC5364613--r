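# Shared fixtures, built in code at test time.

# 90-bp circular toy reference with one 30-codon gene (positions 1-90)
toy_reference <- function() {
  codons <- c("ATG", rep("GCA", 28), "TAA")
  reference_genome(
    "toy90",
    paste(codons, collapse = ""),
    tibble::tibble(name = "G1", start = 1L, end = 90L,
                   strand = "heavy", kind = "protein")
  )
}

# small annotated reference with protein + control region, used for
# classification around the whole syn_status vocabulary
mini_reference <- function() {
  reference_genome(
    "mini",
    paste0("ATGGCATAA", strrep("A", 81)),
    tibble::tibble(name = c("g", "cr"),
                   start = c(1L, 10L), end = c(9L, 90L),
                   strand = "heavy", kind = c("protein", "control"))
  )
}

# deterministic toy motif database: a random rooted tree of `n` haplogroups,
# each non-root node defined by one private mutation at a unique position
toy_motif_db <- function(n = 50L, seed = 42L) {
  set.seed(seed)
  name <- c("ROOT", paste0("H", seq_len(n - 1L)))
  parent <- c(NA_character_,
              vapply(seq_len(n - 1L), function(i) name[sample.int(i, 1L)], ""))
  pos <- sample.int(16000L, n - 1L)
  motif_db(tibble::tibble(
    name = name, parent = parent,
    mutations = c("", paste0("A", pos, "G"))
  ))
}

# random mutation tree with Poisson edge counts (sample tips), for rho /
# sigma property tests
rand_tree <- function(n_leaves, seed, lambda = 2) {
  set.seed(seed)
  tr <- simulate_genealogy(n_leaves, dem_constant(N = 1000),
                           seed = seed)
  nd <- tr$nodes
  pos_pool <- seq_len(16569L)
  nd$edge_muts <- lapply(seq_len(nrow(nd)), function(v) {
    if (is.na(nd$parent[v])) return(empty_mutations())
    k <- stats::rpois(1L, lambda)
    if (k == 0L) return(empty_mutations())
    mutations(sample(pos_pool, k), "A", "G")
  })
  tr$nodes <- nd
  tr
}

# independent per-leaf path counting (test-side oracle for rho)
oracle_rho <- function(tree, node = tree$root) {
  leaves <- sample_leaves(tree, node)
  cnt <- vapply(tree$nodes$edge_muts, nrow, 0L)
  per <- vapply(leaves, function(lf) {
    tot <- 0L; v <- lf
    while (v != node) { tot <- tot + cnt[v]; v <- tree$nodes$parent[v] }
    tot
  }, 0L)
  mean(per)
}

# rate that makes one counted substitution per `y` years on a full molecule
clock_matched_mu <- function(y = 3624, L = 16569L) 1 / (y * L)

profiles_from_sim <- function(sim) {
  tips <- which(sim$nodes$type == "sample")
  tibble::tibble(
    sample_id = sim$nodes$label[tips],
    region = sim$nodes$region[tips],
    population = sim$nodes$population[tips],
    mutations = lapply(tips, function(v) cumulative_profile(sim, v))
  )
}
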