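#' Construct a mutation-annotated rooted tree
#'
#' The substrate of all dating in the package: a rooted tree whose edges
#' carry mutation lists. Internal nodes are haplotypes (possibly inferred
#' medians); sampled individuals are leaves of type `"sample"`, attached to
#' their haplotype node by a (possibly empty) edge. Simulated genealogies use
#' the same container with true node ages filled in.
#'
#' @param nodes Tibble with columns `node` (integer id, equal to row number),
#'   `parent` (integer, `NA` for the root), `type` (`"haplotype"` or
#'   `"sample"`), `label`, and optionally `region`, `population`,
#'   `haplogroup`, `age` (years before present) and `edge_muts`
#'   (list-column of mutation tibbles for the edge above each node).
#' @return A `mutation_tree` object.
#' @export
mutation_tree <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  stopifnot(all(c("node", "parent", "type", "label") %in% names(nodes)))
  if (!identical(as.integer(nodes$node), seq_len(nrow(nodes)))) {
    stop("node ids must equal row numbers 1..n", call. = FALSE)
  }
  for (col in c("region", "population", "haplogroup")) {
    if (!col %in% names(nodes)) nodes[[col]] <- NA_character_
  }
  if (!"age" %in% names(nodes)) nodes$age <- NA_real_
  if (!"edge_muts" %in% names(nodes)) {
    nodes$edge_muts <- rep(list(empty_mutations()), nrow(nodes))
  }
  root <- which(is.na(nodes$parent))
  if (length(root) != 1L) {
    stop("tree must have exactly one root, found ", length(root),
         call. = FALSE)
  }
  if (any(nodes$parent[-root] < 1L | nodes$parent[-root] > nrow(nodes),
          na.rm = TRUE)) {
    stop("parent id out of range", call. = FALSE)
  }
  tr <- structure(list(nodes = nodes, root = root), class = "mutation_tree")
  # reachability check doubles as cycle detection
  if (length(tree_preorder(tr)) != nrow(nodes)) {
    stop("tree is not connected (or contains a cycle)", call. = FALSE)
  }
  tr
}

#' @export
print.mutation_tree <- function(x, ...) {
  n_samp <- sum(x$nodes$type == "sample")
  cat("<mutation_tree> ", nrow(x$nodes), " nodes (", n_samp,
      " sample leaves), root = node ", x$root, "\n", sep = "")
  invisible(x)
}

#' Number of nodes in a tree
#' @param tree A [mutation_tree()].
#' @return Integer count.
#' @export
n_nodes <- function(tree) nrow(tree$nodes)

tree_children_list <- function(tree) {
  kids <- vector("list", n_nodes(tree))
  p <- tree$nodes$parent
  for (i in seq_along(p)) {
    if (!is.na(p[i])) kids[[p[i]]] <- c(kids[[p[i]]], i)
  }
  kids
}

tree_preorder <- function(tree, from = tree$root) {
  kids <- tree_children_list(tree)
  out <- integer(0)
  stack <- from
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, rev(kids[[v]]))
  }
  out
}

tree_postorder <- function(tree, from = tree$root) {
  rev(tree_preorder(tree, from))
}

#' Descendant nodes of a tree node
#' @param tree A [mutation_tree()].
#' @param node Node id.
#' @param include_self Include `node` itself?
#' @return Integer vector of node ids.
#' @export
descendants <- function(tree, node, include_self = FALSE) {
  out <- tree_preorder(tree, node)
  if (!include_self) out <- setdiff(out, node)
  out
}

#' Sample leaves below a node
#' @inheritParams descendants
#' @return Integer node ids of `type == "sample"` descendants (including
#'   `node` itself if it is a sample).
#' @export
sample_leaves <- function(tree, node = tree$root) {
  d <- tree_preorder(tree, node)
  d[tree$nodes$type[d] == "sample"]
}

#' Counted mutations on the edge above each node
#'
#' Applies a clock's counting rules: indels are never counted; positions in
#' `hotspots` are excluded; if `counted_classes` is non-NULL only mutations
#' whose `syn_status` is in it are counted.
#'
#' @param tree A [mutation_tree()].
#' @param counted_classes `NULL` (count all substitutions) or a character
#'   vector of `syn_status` values.
#' @param hotspots Integer positions excluded from counting.
#' @return Numeric vector, one count per node (edge above that node; the
#'   root's entry is 0).
#' @export
edge_counts <- function(tree, counted_classes = NULL,
                        hotspots = default_hotspots()) {
  vapply(tree$nodes$edge_muts, function(m) {
    if (is.null(m) || nrow(m) == 0L) return(0)
    keep <- m$class != "indel" & !(m$position %in% hotspots)
    if (!is.null(counted_classes)) {
      keep <- keep & m$syn_status %in% counted_classes
    }
    sum(keep)
  }, 0)
}

#' Cumulative mutations from the root to a node
#'
#' Later mutations at a position supersede earlier ones; a mutation whose
#' derived state equals the reference/ancestral state of an earlier mutation
#' at the same position cancels it (back mutation along the path).
#'
#' @inheritParams descendants
#' @return Mutation tibble.
#' @export
cumulative_profile <- function(tree, node) {
  path <- integer(0)
  v <- node
  while (!is.na(v)) {
    path <- c(v, path)
    v <- tree$nodes$parent[v]
  }
  state <- list()
  for (v in path) {
    m <- tree$nodes$edge_muts[[v]]
    for (i in seq_len(nrow(m))) {
      key <- as.character(m$position[i])
      prev <- state[[key]]
      if (!is.null(prev) && m$derived[i] == prev$ancestral[1L]) {
        state[[key]] <- NULL  # reversion to the pre-existing state
      } else {
        state[[key]] <- m[i, , drop = FALSE]
      }
    }
  }
  if (length(state) == 0L) return(empty_mutations())
  out <- dplyr::bind_rows(state)
  dplyr::arrange(out[, names(empty_mutations())], .data$position)
}

#' Edge table of a mutation tree
#' @param tree A [mutation_tree()].
#' @return Tibble `parent`, `child`, `child_label`, `mutations`
#'   (comma-separated labels), `n_mut`.
#' @export
tree_edge_table <- function(tree) {
  nd <- tree$nodes
  idx <- which(!is.na(nd$parent))
  tibble::tibble(
    parent = nd$parent[idx],
    child = idx,
    child_label = nd$label[idx],
    child_type = nd$type[idx],
    mutations = vapply(nd$edge_muts[idx], function(m) {
      paste(format_mutation_labels(m), collapse = ",")
    }, ""),
    n_mut = vapply(nd$edge_muts[idx], nrow, 0L)
  )
}

#' Write / read a mutation tree as a TSV edge table
#'
#' @param tree A [mutation_tree()].
#' @param path Output TSV path.
#' @return `write_tree_edges` returns `path` invisibly; `read_tree_edges`
#'   returns a [mutation_tree()].
#' @export
write_tree_edges <- function(tree, path) {
  nd <- tree$nodes
  tab <- tibble::tibble(
    node = nd$node,
    parent = ifelse(is.na(nd$parent), 0L, nd$parent),
    type = nd$type, label = nd$label,
    region = nd$region, population = nd$population,
    haplogroup = nd$haplogroup, age = nd$age,
    mutations = vapply(nd$edge_muts, function(m) {
      paste(format_mutation_labels(m), collapse = ",")
    }, "")
  )
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_tree_edges
#' @export
read_tree_edges <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  muts <- purrr::map(tab$mutations, function(s) {
    if (is.na(s) || !nzchar(s)) return(empty_mutations())
    m <- parse_mutation_labels(strsplit(s, ",")[[1L]])
    m$back <- NULL
    m
  })
  mutation_tree(tibble::tibble(
    node = as.integer(tab$node),
    parent = ifelse(tab$parent == 0L, NA_integer_, as.integer(tab$parent)),
    type = tab$type, label = as.character(tab$label),
    region = as.character(tab$region),
    population = as.character(tab$population),
    haplogroup = as.character(tab$haplogroup),
    age = as.numeric(tab$age),
    edge_muts = muts
  ))
}

#' Serialise a mutation tree as annotated newick
#'
#' Edge comments carry the mutation list in BEAST-style bracket annotation,
#' e.g. `label[&muts=A750G,T1438C]:2`. Branch lengths are counted mutations.
#'
#' @param tree A [mutation_tree()].
#' @param path Optional file path; if `NULL` the newick string is returned.
#' @return Newick string (invisibly if written to file).
#' @export
write_tree_newick <- function(tree, path = NULL) {
  kids <- tree_children_list(tree)
  nd <- tree$nodes
  fmt <- function(v) {
    lbl <- nd$label[v]
    lbl <- if (is.na(lbl)) "" else gsub("[,():;\\s]", "_", lbl)
    muts <- format_mutation_labels(nd$edge_muts[[v]])
    ann <- if (length(muts)) paste0("[&muts=", paste(muts, collapse = ","), "]")
           else ""
    sub <- if (length(kids[[v]])) {
      paste0("(", paste(vapply(kids[[v]], fmt, ""), collapse = ","), ")")
    } else ""
    len <- if (is.na(nd$parent[v])) "" else paste0(":", length(muts))
    paste0(sub, lbl, ann, len)
  }
  s <- paste0(fmt(tree$root), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Convert a mutation tree to an ape "phylo" object
#'
#' Sample leaves become tips; haplotype nodes become internal nodes.
#' Degree-2 internal nodes are collapsed (ape convention). Branch lengths are
#' counted mutations unless `use_ages = TRUE`, in which case they are age
#' differences in years.
#'
#' @param x A [mutation_tree()].
#' @param use_ages Use node ages for branch lengths.
#' @param ... Unused.
#' @return An [ape::as.phylo] object.
#' @export
as_phylo <- function(x, use_ages = FALSE, ...) UseMethod("as_phylo")

#' @export
as_phylo.mutation_tree <- function(x, use_ages = FALSE, ...) {
  nd <- x$nodes
  kids <- tree_children_list(x)
  is_tip <- lengths(kids) == 0L
  tip_ids <- which(is_tip)
  int_ids <- c(x$root, setdiff(which(!is_tip), x$root))
  remap <- integer(nrow(nd))
  remap[tip_ids] <- seq_along(tip_ids)
  remap[int_ids] <- length(tip_ids) + seq_along(int_ids)
  idx <- which(!is.na(nd$parent))
  edge <- cbind(remap[nd$parent[idx]], remap[idx])
  len <- if (use_ages) {
    nd$age[nd$parent[idx]] - nd$age[idx]
  } else {
    vapply(nd$edge_muts[idx], nrow, 0L)
  }
  lab <- nd$label[tip_ids]
  lab[is.na(lab)] <- paste0("tip", tip_ids[is.na(lab)])
  phy <- structure(list(edge = edge, tip.label = lab,
                        Nnode = length(int_ids), edge.length = as.numeric(len)),
                   class = "phylo", order = "cladewise")
  ape::collapse.singles(phy)
}

#' Contract internal edges carrying no counted mutations
#'
#' Splits not witnessed by any mutation are unidentifiable from sequence
#' data; this returns the identifiable (possibly multifurcating) topology.
#' Pendant sample edges are always kept.
#'
#' @param tree A [mutation_tree()].
#' @param counted_classes,hotspots Passed to [edge_counts()]; by default all
#'   substitutions count and no hotspot filter is applied.
#' @return A [mutation_tree()].
#' @export
collapse_zero_edges <- function(tree, counted_classes = NULL,
                                hotspots = integer()) {
  cnt <- edge_counts(tree, counted_classes, hotspots)
  kids <- tree_children_list(tree)
  nd <- tree$nodes
  # reassign children of zero-count internal nodes to their parents
  ord <- tree_preorder(tree)
  newpar <- nd$parent
  keep <- rep(TRUE, nrow(nd))
  for (v in ord) {
    p <- newpar[v]
    if (is.na(p)) next
    if (cnt[v] == 0 && nd$type[v] != "sample" && length(kids[[v]]) > 0L) {
      keep[v] <- FALSE
      newpar[kids[[v]]] <- p
      kids[[p]] <- c(setdiff(kids[[p]], v), kids[[v]])
    }
  }
  old_ids <- which(keep)
  remap <- integer(nrow(nd)); remap[old_ids] <- seq_along(old_ids)
  out <- nd[old_ids, , drop = FALSE]
  out$node <- seq_len(nrow(out))
  out$parent <- ifelse(is.na(newpar[old_ids]), NA_integer_,
                       remap[newpar[old_ids]])
  mutation_tree(out)
}
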