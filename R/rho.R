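#' The rho statistic of a clade
#'
#' `rho` is the mean number of counted mutations separating a node from its
#' sampled descendants: averaged over the `n` sample leaves below the node,
#' or equivalently `sum(n_e * l_e) / n` over the edges below it, where `n_e`
#' is the number of sample leaves descending through edge `e` and `l_e` its
#' counted mutations. Both routes are implemented and must agree.
#'
#' @param tree A [mutation_tree()].
#' @param node Node id of the clade root (default: tree root).
#' @param counted_classes,hotspots Counting rules (see [edge_counts()]); pass
#'   a [clock_spec()]'s fields, or a clock via [age_estimate()].
#' @param method `"edge"` (edge-sum, default), `"path"` (leaf path-sum).
#' @return List with `rho` and `n_tips`.
#' @export
rho <- function(tree, node = tree$root, counted_classes = NULL,
                hotspots = default_hotspots(), method = c("edge", "path")) {
  method <- match.arg(method)
  leaves <- sample_leaves(tree, node)
  n <- length(leaves)
  if (n == 0L) stop("node has no sampled descendant leaves", call. = FALSE)
  cnt <- edge_counts(tree, counted_classes, hotspots)
  if (method == "edge") {
    ne <- n_through_edge(tree, node)
    sub <- descendants(tree, node)
    r <- sum(ne[sub] * cnt[sub]) / n
  } else {
    per_leaf <- vapply(leaves, function(lf) {
      tot <- 0
      v <- lf
      while (v != node) { tot <- tot + cnt[v]; v <- tree$nodes$parent[v] }
      tot
    }, 0)
    r <- mean(per_leaf)
  }
  list(rho = r, n_tips = n)
}

# sample leaves descending through the edge above each node (0 outside the
# clade of `node`)
n_through_edge <- function(tree, node = tree$root) {
  ne <- integer(n_nodes(tree))
  for (v in tree_postorder(tree, node)) {
    ne[v] <- if (tree$nodes$type[v] == "sample") 1L else 0L
    kids <- which(tree$nodes$parent == v)
    ne[v] <- ne[v] + sum(ne[kids])
  }
  ne
}

#' Saillard standard error of rho
#'
#' Treating per-edge mutation counts as independent Poisson draws, the
#' variance of rho is `sum((n_e / n)^2 * l_e)` over the edges below the node;
#' the returned sigma is its square root. On a star tree this reduces to
#' `sigma^2 = rho / n`.
#'
#' @inheritParams rho
#' @return List with `sigma`, `rho` and `n_tips`.
#' @export
saillard_sigma <- function(tree, node = tree$root, counted_classes = NULL,
                           hotspots = default_hotspots()) {
  leaves <- sample_leaves(tree, node)
  n <- length(leaves)
  if (n == 0L) stop("node has no sampled descendant leaves", call. = FALSE)
  cnt <- edge_counts(tree, counted_classes, hotspots)
  ne <- n_through_edge(tree, node)
  sub <- descendants(tree, node)
  var_rho <- sum((ne[sub] / n)^2 * cnt[sub])
  list(sigma = sqrt(var_rho), rho = sum(ne[sub] * cnt[sub]) / n, n_tips = n)
}

#' Convert rho and sigma into an age estimate
#'
#' `age = correction(rho * years_per_substitution)`; the 95% interval is
#' `correction((rho +/- 1.96 sigma) * years_per_substitution)`, truncated
#' at zero.
#'
#' @param rho Nonnegative rho value.
#' @param sigma Nonnegative Saillard standard error.
#' @param clock A [clock_spec()].
#' @param n_tips Number of sample leaves behind the estimate.
#' @param node,haplogroup Optional labels carried into the output row.
#' @return One-row tibble of class `age_estimate`: `node`, `haplogroup`,
#'   `method`, `clock`, `rho`, `sigma`, `age_years`, `ci_low`, `ci_high`,
#'   `n_tips`.
#' @export
rho_to_age <- function(rho, sigma, clock, n_tips = NA_integer_,
                       node = NA_character_, haplogroup = NA_character_) {
  if (rho < 0) stop("rho must be nonnegative", call. = FALSE)
  if (sigma < 0) stop("sigma must be nonnegative", call. = FALSE)
  y <- clock$years_per_substitution
  age <- clock$correction(rho * y)
  lo <- clock$correction(max(0, (rho - 1.96 * sigma)) * y)
  hi <- clock$correction(max(0, (rho + 1.96 * sigma)) * y)
  out <- tibble::tibble(
    node = as.character(node), haplogroup = as.character(haplogroup),
    method = "rho", clock = clock$name,
    rho = rho, sigma = sigma, age_years = age,
    ci_low = max(0, lo), ci_high = hi, n_tips = as.integer(n_tips)
  )
  class(out) <- c("age_estimate", class(out))
  out
}

#' Rho age estimate for a tree node under a clock
#'
#' Convenience wrapper: computes rho and the Saillard sigma for `node` with
#' the clock's counting rules and converts to years.
#'
#' @param tree A [mutation_tree()].
#' @param node Node id (default root).
#' @param clock A [clock_spec()].
#' @return An `age_estimate` row (see [rho_to_age()]).
#' @export
age_estimate <- function(tree, node = tree$root, clock = clock_whole_molecule()) {
  s <- saillard_sigma(tree, node, clock$counted_classes, clock$hotspots)
  rho_to_age(s$rho, s$sigma, clock, n_tips = s$n_tips,
             node = tree$nodes$label[node] %||% as.character(node),
             haplogroup = tree$nodes$haplogroup[node])
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Age table for all haplogroup-labelled nodes
#'
#' Mirrors a clade age table: one row per labelled internal node per clock.
#'
#' @param tree A [mutation_tree()].
#' @param clocks List of [clock_spec()] objects.
#' @return Tibble of `age_estimate` rows (ages also given in ka).
#' @export
clade_age_table <- function(tree, clocks = list(clock_whole_molecule(),
                                                clock_synonymous())) {
  nodes <- which(!is.na(tree$nodes$haplogroup))
  rows <- purrr::map(nodes, function(v) {
    purrr::map(clocks, function(ck) age_estimate(tree, v, ck))
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  out$age_ka <- out$age_years / 1000
  out$ci_low_ka <- out$ci_low / 1000
  out$ci_high_ka <- out$ci_high / 1000
  class(out) <- c("age_estimate", class(out))
  out
}
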