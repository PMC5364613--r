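two_site_profiles <- function() {
  tibble::tibble(
    sample_id = c("a", "b", "c"),
    mutations = list(
      mutations(c(1L, 2L), "A", "G"),
      mutations(c(1L, 3L), "A", "G"),
      mutations(c(2L, 3L), "A", "G")
    )
  )
}

test_that("two haplotypes give a two-node single-link network", {
  profs <- tibble::tibble(
    sample_id = c("a", "b"),
    mutations = list(empty_mutations(), mutations(5L, "A", "G"))
  )
  net <- reduced_median(profs)
  expect_equal(nrow(net$haplotypes), 2L)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(n_reticulations(net), 0L)
})

test_that("the median of three pairwise-conflicting haplotypes is added and
           minimises total length", {
  net <- reduced_median(two_site_profiles())
  expect_equal(sum(net$inferred), 1L)
  med <- net$haplotypes[net$inferred, ]
  expect_equal(unname(med), c(1L, 1L, 1L))
  # brute-force Steiner oracle over all 2^3 vectors: connecting the three
  # inputs through the added median must minimise total link length
  obs <- net$haplotypes[!net$inferred, , drop = FALSE]
  total_via <- function(m) sum(apply(obs, 1L, function(h) sum(h != m)))
  best <- min(apply(as.matrix(expand.grid(0:1, 0:1, 0:1)), 1L, total_via))
  expect_equal(total_via(med), best)
})

test_that("homoplasy-free simulations yield reticulation-free networks", {
  for (i in 1:10) {
    sim <- simulate_genealogy(10, dem_constant(N = 1000), seed = 300 + i)
    sim <- drop_mutations(sim, mu = 5e-4 / 16569, L = 16569L,
                          seed = 400 + i, infinite_sites = TRUE)
    net <- reduced_median(profiles_from_sim(sim))
    expect_equal(n_reticulations(net), 0L)
  }
})

test_that("a tree-shaped network resolves to the same tree", {
  profs <- tibble::tibble(
    sample_id = c("a", "b", "c"),
    mutations = list(
      mutations(1L, "A", "G"),
      mutations(c(1L, 2L), "A", "G"),
      mutations(3L, "A", "G")
    )
  )
  net <- reduced_median(profs)
  expect_equal(n_reticulations(net), 0L)
  tree <- network_to_tree(net, profiles = profs)
  # every sample's cumulative profile is reproduced exactly
  for (i in 1:3) {
    v <- which(tree$nodes$label == profs$sample_id[i])
    cp <- cumulative_profile(tree, v)
    expect_equal(cp$position, profs$mutations[[i]]$position)
    expect_equal(cp$derived, profs$mutations[[i]]$derived)
  }
})

test_that("reticulations duplicate the high-frequency mutation", {
  # 4-cycle: two paths to the double mutant via site 100 (freq 50) or
  # site 200 (freq 2); the tree must reuse (duplicate) the fast site 100
  profs <- tibble::tibble(
    sample_id = c("r", "a", "b", "ab"),
    mutations = list(
      empty_mutations(),
      mutations(100L, "A", "G"),
      mutations(200L, "A", "G"),
      mutations(c(100L, 200L), "A", "G")
    )
  )
  freq <- tibble::tibble(position = c(100L, 200L), frequency = c(50, 2))
  net <- reduced_median(profs, site_weights = freq)
  tree <- network_to_tree(net, profiles = profs, frequency_table = freq)
  tab <- tree_edge_table(tree)
  all_muts <- unlist(strsplit(tab$mutations[nzchar(tab$mutations)], ","))
  n100 <- sum(grepl("^A100G|^G100A", all_muts))
  n200 <- sum(grepl("^A200G|^G200A", all_muts))
  expect_equal(n200, 1L)   # slow site stays unique
  expect_equal(n100, 2L)   # fast site is the recurrent one
})

test_that("simulated data with one fast homoplasic site still recovers the
           genealogy", {
  sim <- simulate_genealogy(12, dem_constant(N = 1000), seed = 99)
  sim <- drop_mutations(sim, mu = 8e-4 / 16569, L = 16569L, seed = 199,
                        infinite_sites = TRUE)
  profs <- profiles_from_sim(sim)
  # inject a recurrent mutation at a known fast site onto two distinct tips
  fast <- 16311L
  profs$mutations[[1L]] <- dplyr::bind_rows(profs$mutations[[1L]],
                                            mutations(fast, "A", "G"))
  profs$mutations[[7L]] <- dplyr::bind_rows(profs$mutations[[7L]],
                                            mutations(fast, "A", "G"))
  net <- reduced_median(profs)
  tree <- network_to_tree(net, profiles = profs)
  truth <- as_phylo(collapse_zero_edges(sim))
  rec <- as_phylo(tree)
  expect_equal(suppressWarnings(
    phangorn::RF.dist(ape::unroot(truth), ape::unroot(rec))), 0)
})

test_that("infinite-sites recovery matches the witnessed true topology", {
  for (i in 1:10) {
    n <- sample(8:20, 1L)
    sim <- simulate_genealogy(n, dem_constant(N = 1000), seed = 500 + i)
    sim <- drop_mutations(sim, mu = 8e-4 / 16569, L = 16569L, seed = 600 + i,
                          infinite_sites = TRUE)
    tree <- network_to_tree(reduced_median(profiles_from_sim(sim)),
                            profiles = profiles_from_sim(sim))
    d <- suppressWarnings(phangorn::RF.dist(
      ape::unroot(as_phylo(collapse_zero_edges(sim))),
      ape::unroot(as_phylo(tree))))
    expect_equal(d, 0)
  }
})

test_that("parsimony sanity: tree length never exceeds star attachment", {
  for (i in 1:5) {
    sim <- simulate_genealogy(10, dem_constant(N = 1000), seed = 700 + i)
    sim <- drop_mutations(sim, mu = 6e-4 / 16569, seed = 800 + i,
                          infinite_sites = TRUE)
    profs <- profiles_from_sim(sim)
    tree <- network_to_tree(reduced_median(profs), profiles = profs)
    tree_len <- sum(vapply(tree$nodes$edge_muts, nrow, 0L))
    star_len <- sum(vapply(profs$mutations, nrow, 0L))
    expect_lte(tree_len, star_len)
  }
})

test_that("leaf profiles are reproduced exactly from the built tree", {
  sim <- simulate_genealogy(15, dem_constant(N = 1000), seed = 901)
  sim <- drop_mutations(sim, mu = 6e-4 / 16569, seed = 902,
                        infinite_sites = TRUE)
  profs <- profiles_from_sim(sim)
  tree <- network_to_tree(reduced_median(profs), profiles = profs)
  for (i in seq_len(nrow(profs))) {
    v <- which(tree$nodes$label == profs$sample_id[i])
    cp <- cumulative_profile(tree, v)
    want <- dplyr::arrange(profs$mutations[[i]], position)
    expect_equal(cp$position, want$position)
    expect_equal(cp$derived, want$derived)
  }
})

test_that("haplogroup labels attach where cumulative sets match motifs", {
  db <- motif_db(tibble::tibble(
    name = c("R", "M", "M2"),
    parent = c(NA, "R", "M"),
    mutations = c("", "A100G A200G", "A300G")
  ))
  profs <- tibble::tibble(
    sample_id = c("x", "y"),
    mutations = list(motif_expected(db, "M"), motif_expected(db, "M2"))
  )
  tree <- network_to_tree(reduced_median(profs), profiles = profs)
  tree <- attach_haplogroup_labels(tree, db)
  labs <- stats::na.omit(tree$nodes$haplogroup)
  expect_setequal(as.character(labs), c("R", "M", "M2"))
  # empty-motif DB (root only) labels at most the root
  db0 <- motif_db(tibble::tibble(name = "R", parent = NA_character_,
                                 mutations = ""))
  t0 <- attach_haplogroup_labels(tree, db0)
  expect_true(all(is.na(t0$nodes$haplogroup) |
                    t0$nodes$haplogroup == "R"))
})

test_that("label nesting violations are dropped with a warning", {
  # two sibling haplogroups whose motifs are nested mutation sets: the
  # deeper tree node then matches a label that is not a DB descendant of
  # its ancestor's label
  db <- motif_db(tibble::tibble(
    name = c("R", "A", "B"),
    parent = c(NA, "R", "R"),
    mutations = c("", "A100G", "A100G A200G")
  ))
  profs <- tibble::tibble(
    sample_id = c("x", "y"),
    mutations = list(mutations(100L, "A", "G"),
                     mutations(c(100L, 200L), "A", "G"))
  )
  tree <- network_to_tree(reduced_median(profs), profiles = profs)
  expect_warning(out <- attach_haplogroup_labels(tree, db), "conflicts")
  expect_false("B" %in% out$nodes$haplogroup)
})
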