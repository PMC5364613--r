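#' Reduced-median network of variant profiles
#'
#' Builds a median network over the binary characters of a profile set:
#' sites are split per derived allele (so multi-allelic positions become
#' independent binary characters), majority (Steiner) medians of haplotype
#' triplets are added iteratively until closure, and a reduction pass with
#' parameter `r` resolves weakly supported parallel paths in favour of
#' duplicating high-weight (low mutation-frequency sites are heavy) edges.
#' Inferred medians not needed to connect observed haplotypes are pruned.
#'
#' Network edges are minimal geodesic links: two nodes are joined when no
#' third node lies strictly between them; whenever an intermediate haplotype
#' exists the link has Hamming length 1.
#'
#' @param profiles Nested profile tibble (see [profile_from_alignment()]).
#' @param r Reduction threshold: a parallel resolution is dropped when the
#'   competing resolution's duplicated-site weight is at least `r` times
#'   smaller (default 2, the conventional reduced-median setting).
#' @param site_weights Optional named numeric vector (names are site keys
#'   `"<ancestral><position><derived>"`) or a frequency table
#'   `tibble(position, frequency)`; defaults to weights inversely
#'   proportional to [default_site_frequencies()], scaled to 1-99.
#' @param max_medians Safety cap on inferred median vectors.
#' @return A `median_network` object: haplotype 0/1 matrix, site table,
#'   per-node sample ids, inferred flags and the minimal-link edge table.
#' @export
reduced_median <- function(profiles, r = 2, site_weights = NULL,
                           max_medians = 5000L) {
  if (nrow(profiles) < 2L) stop("need at least 2 profiles", call. = FALSE)
  sites <- site_table(profiles, site_weights)
  S <- nrow(sites)
  H <- matrix(0L, nrow(profiles), max(S, 1L),
              dimnames = list(profiles$sample_id, sites$key))
  for (i in seq_len(nrow(profiles))) {
    m <- profiles$mutations[[i]]
    m <- m[m$class != "indel", , drop = FALSE]
    H[i, match(site_key(m), sites$key)] <- 1L
  }
  keys <- apply(H, 1L, paste, collapse = "")
  uniq <- !duplicated(keys)
  hap <- H[uniq, , drop = FALSE]
  node_samples <- split(profiles$sample_id, match(keys, keys[uniq]))
  node_samples <- node_samples[order(as.integer(names(node_samples)))]
  inferred <- rep(FALSE, nrow(hap))

  # majority-median closure over triplets
  seen <- new.env(hash = TRUE)
  for (k in apply(hap, 1L, paste, collapse = "")) assign(k, TRUE, seen)
  capped <- FALSE
  repeat {
    n <- nrow(hap)
    added <- FALSE
    for (i in seq_len(max(n - 2L, 0L))) {
      for (j in seq.int(i + 1L, n - 1L)) {
        for (l in seq.int(j + 1L, n)) {
          med <- as.integer(hap[i, ] + hap[j, ] + hap[l, ] >= 2L)
          k <- paste(med, collapse = "")
          if (!exists(k, envir = seen, inherits = FALSE)) {
            assign(k, TRUE, seen)
            hap <- rbind(hap, med)
            inferred <- c(inferred, TRUE)
            node_samples <- c(node_samples, list(character()))
            added <- TRUE
            capped <- nrow(hap) > nrow(profiles) + max_medians
          }
          if (capped) break
        }
        if (capped) break
      }
      if (capped) break
    }
    if (capped) {
      warning("median closure capped at ", max_medians, " inferred vectors")
      break
    }
    if (!added) break
  }
  rownames(hap) <- NULL

  net <- structure(list(haplotypes = hap, sites = sites,
                        node_samples = node_samples, inferred = inferred,
                        edges = NULL),
                   class = "median_network")
  net <- relink(net)
  net <- reduce_network(net, r)
  net <- prune_medians(net)
  net
}

site_key <- function(m) paste0(m$ancestral, m$position, m$derived)

site_table <- function(profiles, site_weights) {
  all_m <- dplyr::bind_rows(profiles$mutations)
  all_m <- all_m[all_m$class != "indel", , drop = FALSE]
  sites <- dplyr::distinct(all_m[, c("position", "ancestral", "derived")])
  sites <- dplyr::arrange(sites, .data$position, .data$derived)
  sites$key <- site_key(sites)
  freq <- NULL
  if (is.null(site_weights)) {
    freq <- default_site_frequencies()
  } else if (is.data.frame(site_weights)) {
    freq <- site_weights
  }
  if (!is.null(freq)) {
    f <- freq$frequency[match(sites$position, freq$position)]
    f[is.na(f)] <- 1
    w <- 99 * min(f) / f
    sites$weight <- pmax(1, pmin(99, round(w)))
  } else {
    w <- unname(site_weights[sites$key])
    w[is.na(w)] <- 1
    sites$weight <- w
  }
  sites
}

#' Default relative mutation-frequency spectrum
#'
#' A coarse site-frequency table for the rCRS coordinate frame: baseline 1
#' everywhere, elevated at well-known hypervariable positions (control-region
#' hotspots and recurrent coding-region sites). Used to derive inverse-
#' frequency site weights for network reduction and reticulation resolution.
#' The values are a stylised spectrum, not an empirical census.
#'
#' @return Tibble `position`, `frequency`.
#' @export
default_site_frequencies <- function() {
  hot <- c(`16093` = 30, `16129` = 25, `16189` = 50, `16223` = 35,
           `16278` = 20, `16311` = 45, `16362` = 30, `16519` = 60,
           `146` = 35, `150` = 30, `152` = 45, `195` = 40, `199` = 15,
           `204` = 12, `207` = 10, `709` = 12, `1438` = 8, `2706` = 8,
           `3010` = 15, `5460` = 12, `8251` = 10, `9055` = 8, `10398` = 25,
           `11914` = 10, `13708` = 15, `15301` = 12, `16172` = 20,
           `16304` = 18, `16356` = 10)
  tibble::tibble(position = as.integer(names(hot)), frequency = unname(hot))
}

hamming <- function(a, b) sum(a != b)

# minimal geodesic links among current nodes
relink <- function(net) {
  hap <- net$haplotypes
  n <- nrow(hap)
  D <- as.matrix(stats::dist(hap, method = "manhattan"))
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- D[i, j]
      if (d == 0) next
      between <- any(D[i, -c(i, j)] + D[-c(i, j), j] == d &
                       D[i, -c(i, j)] > 0 & D[-c(i, j), j] > 0)
      if (!between) { from <- c(from, i); to <- c(to, j) }
    }
  }
  sites_on <- purrr::map2(from, to, function(i, j) which(hap[i, ] != hap[j, ]))
  net$edges <- tibble::tibble(from = from, to = to, sites = sites_on,
                              length = lengths(sites_on))
  net
}

# drop inferred medians supporting only the weakly supported side of a
# 4-cycle: if the duplicated-site weight of one resolution is >= r times the
# other's, the lighter resolution's private median goes
reduce_network <- function(net, r) {
  repeat {
    adj <- network_adjacency(net)
    drop <- NA_integer_
    e <- net$edges[net$edges$length == 1L, , drop = FALSE]
    if (nrow(e) >= 4L) {
      # 4-cycles: nodes u,v with two common unit-distance neighbours a,b
      nbr <- lapply(seq_len(nrow(net$haplotypes)), function(v) {
        c(e$to[e$from == v], e$from[e$to == v])
      })
      n <- nrow(net$haplotypes)
      for (u in seq_len(n - 1L)) {
        for (v in seq.int(u + 1L, n)) {
          common <- intersect(nbr[[u]], nbr[[v]])
          common <- setdiff(common, c(u, v))
          if (length(common) >= 2L) {
            cand <- common[net$inferred[common]]
            if (length(cand) == 0L) next
            w_of <- vapply(common, function(a) {
              s <- which(net$haplotypes[u, ] != net$haplotypes[a, ])
              sum(net$sites$weight[s])
            }, 0)
            heaviest <- max(w_of)
            weakest <- common[which.min(w_of)]
            if (net$inferred[weakest] &&
                heaviest >= r * min(w_of) && heaviest > min(w_of) &&
                still_connected(net, weakest)) {
              drop <- weakest
              break
            }
          }
        }
        if (!is.na(drop)) break
      }
    }
    if (is.na(drop)) break
    net <- drop_node(net, drop)
  }
  net
}

network_adjacency <- function(net) {
  n <- nrow(net$haplotypes)
  adj <- vector("list", n)
  for (k in seq_len(nrow(net$edges))) {
    i <- net$edges$from[k]; j <- net$edges$to[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

still_connected <- function(net, without) {
  n <- nrow(net$haplotypes)
  keep <- setdiff(seq_len(n), without)
  if (length(keep) <= 1L) return(TRUE)
  adj <- network_adjacency(net)
  seen <- rep(FALSE, n); seen[without] <- NA
  stack <- keep[1L]; seen[keep[1L]] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (w in adj[[v]]) {
      if (isFALSE(seen[w])) { seen[w] <- TRUE; stack <- c(stack, w) }
    }
  }
  all(seen[keep])
}

drop_node <- function(net, v) {
  keep <- setdiff(seq_len(nrow(net$haplotypes)), v)
  net$haplotypes <- net$haplotypes[keep, , drop = FALSE]
  net$node_samples <- net$node_samples[keep]
  net$inferred <- net$inferred[keep]
  relink(net)
}

# iteratively remove inferred nodes of degree <= 1
prune_medians <- function(net) {
  repeat {
    deg <- tabulate(c(net$edges$from, net$edges$to),
                    nbins = nrow(net$haplotypes))
    v <- which(net$inferred & deg <= 1L)
    if (length(v) == 0L) break
    net <- drop_node(net, v[1L])
  }
  net
}

#' @export
print.median_network <- function(x, ...) {
  cat("<median_network> ", nrow(x$haplotypes), " nodes (",
      sum(x$inferred), " inferred medians), ", nrow(x$edges), " links, ",
      nrow(x$sites), " binary sites\n", sep = "")
  invisible(x)
}

#' Number of reticulations (independent cycles) in a network
#' @param net A `median_network`.
#' @return Integer cyclomatic number (0 for a tree).
#' @export
n_reticulations <- function(net) {
  nrow(net$edges) - nrow(net$haplotypes) + 1L
}
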