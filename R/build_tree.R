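#' Resolve a median network into a rooted mutation tree
#'
#' Reticulations are resolved with the mutation-frequency rule: a minimum-
#' weight spanning tree is taken over the network's links with edge weight
#' equal to the summed site weights (weights are inversely proportional to
#' mutation frequency), so that recurrent placement falls on high-frequency
#' sites and low-frequency mutations stay unique. Residual ties are broken
#' deterministically (site labels, then node keys). The tree is rooted at
#' `root_profile`, sample leaves are attached to their haplotype nodes, and
#' unneeded inferred medians are pruned.
#'
#' @param net A `median_network` from [reduced_median()].
#' @param root_profile Mutation tibble giving the ancestral haplotype
#'   (mutations relative to the reference; sites absent from the network are
#'   ignored - the projection of the root onto the network's site space).
#' @param profiles Optional original profile tibble supplying `region` /
#'   `population` for the sample leaves.
#' @param frequency_table Optional `tibble(position, frequency)` overriding
#'   the site weights carried by the network.
#' @return A [mutation_tree()].
#' @export
network_to_tree <- function(net, root_profile = empty_mutations(),
                            profiles = NULL, frequency_table = NULL) {
  sites <- net$sites
  if (!is.null(frequency_table)) {
    f <- frequency_table$frequency[match(sites$position,
                                         frequency_table$position)]
    f[is.na(f)] <- 1
    sites$weight <- pmax(1, pmin(99, round(99 * min(f) / f)))
  }
  root_vec <- integer(nrow(sites))
  if (nrow(root_profile) > 0L) {
    hit <- match(site_key(root_profile), sites$key)
    root_vec[hit[!is.na(hit)]] <- 1L
  }
  hap <- net$haplotypes
  root_idx <- which(apply(hap, 1L, function(h) all(h == root_vec)))[1L]
  inferred <- net$inferred
  node_samples <- net$node_samples
  if (is.na(root_idx)) {
    hap <- rbind(hap, root_vec)
    inferred <- c(inferred, TRUE)
    node_samples <- c(node_samples, list(character()))
    root_idx <- nrow(hap)
    net2 <- structure(list(haplotypes = hap, sites = sites,
                           node_samples = node_samples, inferred = inferred),
                      class = "median_network")
    net2 <- relink(net2)
  } else {
    net2 <- net
    net2$sites <- sites
  }

  # Kruskal minimum spanning tree; deterministic tie-break by
  # (weight, site labels, node keys)
  ed <- net2$edges
  ed$weight <- vapply(ed$sites, function(s) sum(sites$weight[s]), 0)
  ed$site_lab <- vapply(ed$sites, function(s) {
    paste(sort(sites$key[s]), collapse = ",")
  }, "")
  ed$node_lab <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  ed <- ed[order(ed$weight, ed$site_lab, ed$node_lab), , drop = FALSE]
  n <- nrow(hap)
  comp <- seq_len(n)
  find <- function(v) { while (comp[v] != v) v <- comp[v]; v }
  keep_edge <- logical(nrow(ed))
  for (k in seq_len(nrow(ed))) {
    a <- find(ed$from[k]); b <- find(ed$to[k])
    if (a != b) { comp[a] <- b; keep_edge[k] <- TRUE }
  }
  if (length(unique(vapply(seq_len(n), find, 1L))) != 1L) {
    stop("root not connectable: network is disconnected", call. = FALSE)
  }
  ed <- ed[keep_edge, , drop = FALSE]

  # orient from root
  adj <- vector("list", n)
  for (k in seq_len(nrow(ed))) {
    adj[[ed$from[k]]] <- c(adj[[ed$from[k]]], k)
    adj[[ed$to[k]]] <- c(adj[[ed$to[k]]], k)
  }
  parent <- rep(NA_integer_, n)
  parent_edge <- rep(NA_integer_, n)
  seen <- rep(FALSE, n); seen[root_idx] <- TRUE
  queue <- root_idx
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (k in adj[[v]]) {
      w <- if (ed$from[k] == v) ed$to[k] else ed$from[k]
      if (!seen[w]) {
        seen[w] <- TRUE; parent[w] <- v; parent_edge[w] <- k
        queue <- c(queue, w)
      }
    }
  }

  # prune inferred haplotype nodes with no samples anywhere below
  kids <- vector("list", n)
  for (v in seq_len(n)) if (!is.na(parent[v])) {
    kids[[parent[v]]] <- c(kids[[parent[v]]], v)
  }
  has_sample <- lengths(node_samples) > 0L
  ord <- rev(order_preorder(parent, root_idx, kids))
  needed <- has_sample
  for (v in ord) {
    if (any(needed[kids[[v]]])) needed[v] <- TRUE
  }
  needed[root_idx] <- TRUE

  # emit mutation_tree: haplotype nodes + sample leaves
  keep_nodes <- which(needed)
  remap <- integer(n); remap[keep_nodes] <- seq_along(keep_nodes)
  rows <- list()
  for (v in keep_nodes) {
    muts <- empty_mutations()
    if (!is.na(parent[v])) {
      s <- ed$sites[[parent_edge[v]]]
      gained <- unname(hap[v, s] == 1L)
      muts <- tibble::tibble(
        position = sites$position[s],
        ancestral = ifelse(gained, sites$ancestral[s], sites$derived[s]),
        derived = ifelse(gained, sites$derived[s], sites$ancestral[s]),
        class = mutation_class(ifelse(gained, sites$ancestral[s],
                                      sites$derived[s]),
                               ifelse(gained, sites$derived[s],
                                      sites$ancestral[s])),
        syn_status = "unassigned"
      )
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      node = remap[v],
      parent = if (is.na(parent[v])) NA_integer_ else remap[parent[v]],
      type = "haplotype",
      label = if (v == root_idx) "root" else NA_character_,
      edge_muts = list(muts)
    )
  }
  nd <- dplyr::bind_rows(rows)
  # sample leaves
  meta <- function(id, col) {
    if (is.null(profiles) || !col %in% names(profiles)) return(NA_character_)
    profiles[[col]][match(id, profiles$sample_id)]
  }
  for (v in keep_nodes[lengths(node_samples[keep_nodes]) > 0L]) {
    for (sid in node_samples[[v]]) {
      nd <- dplyr::bind_rows(nd, tibble::tibble(
        node = nrow(nd) + 1L, parent = remap[v], type = "sample",
        label = sid, edge_muts = list(empty_mutations()),
        region = meta(sid, "region"), population = meta(sid, "population")
      ))
    }
  }
  nd$node <- seq_len(nrow(nd))
  mutation_tree(nd)
}

order_preorder <- function(parent, root, kids) {
  out <- integer(0); stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, rev(kids[[v]]))
  }
  out
}

#' Label tree nodes with haplogroups from a motif database
#'
#' An internal node is labelled when its cumulative mutation set (from the
#' tree root) equals the cumulative motif of a database node. Labels must
#' nest consistently with the database's parentage: a label whose motif-DB
#' lineage does not contain the nearest labelled ancestor's label is dropped
#' with a warning.
#'
#' @param tree A [mutation_tree()].
#' @param db A [motif_db()] (may be empty of mutations; unlabelled nodes are
#'   permitted).
#' @return The tree with its `haplogroup` column filled where matched.
#' @export
attach_haplogroup_labels <- function(tree, db) {
  if (nrow(db) == 0L) return(tree)
  motif_key <- vapply(db$name, function(nm) {
    e <- motif_expected(db, nm)
    paste(sort(paste0(e$position, ">", e$derived)), collapse = ";")
  }, "")
  ancestry <- lapply(db$name, function(nm) {
    path <- character(); cur <- nm
    while (!is.na(cur)) { path <- c(path, cur); cur <- db$parent[match(cur, db$name)] }
    path
  })
  names(ancestry) <- db$name
  nd <- tree$nodes
  lab <- rep(NA_character_, nrow(nd))
  for (v in which(nd$type != "sample")) {
    cp <- cumulative_profile(tree, v)
    key <- paste(sort(paste0(cp$position, ">", cp$derived)), collapse = ";")
    hit <- which(motif_key == key)
    if (length(hit)) lab[v] <- db$name[max(hit)]
  }
  # nesting check (preorder, nearest labelled ancestor)
  kids <- tree_children_list(tree)
  nearest <- rep(NA_character_, nrow(nd))
  for (v in tree_preorder(tree)) {
    p <- nd$parent[v]
    inherited <- if (is.na(p)) NA_character_ else nearest[p]
    if (!is.na(lab[v])) {
      if (!is.na(inherited) && !(inherited %in% ancestry[[lab[v]]])) {
        warning("label ", lab[v], " at node ", v,
                " conflicts with ancestor label ", inherited, "; dropped")
        lab[v] <- NA_character_
      }
    }
    nearest[v] <- if (!is.na(lab[v])) lab[v] else inherited
  }
  tree$nodes$haplogroup <- lab
  tree
}
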