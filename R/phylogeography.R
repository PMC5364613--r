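#' Rho age over a regional leaf subset
#'
#' Approach (1) of regional repartitioning: take all sample leaves of the
#' haplogroup that belong to one region (pruning lineages unsampled in it)
#' and recompute rho, the Saillard sigma and the age from the haplogroup
#' root over that leaf set.
#'
#' @param tree A [mutation_tree()].
#' @param node Haplogroup root node id.
#' @param region Region label to keep.
#' @param clock A [clock_spec()].
#' @return An `age_estimate` row (see [rho_to_age()]).
#' @export
regional_age_all_samples <- function(tree, node = tree$root, region,
                                     clock = clock_whole_molecule()) {
  leaves <- sample_leaves(tree, node)
  keep <- leaves[!is.na(tree$nodes$region[leaves]) &
                   tree$nodes$region[leaves] == region]
  if (length(keep) < 1L) {
    stop("no sampled leaves of region '", region, "' under node ", node,
         call. = FALSE)
  }
  s <- rho_subset(tree, node, keep, clock$counted_classes, clock$hotspots)
  rho_to_age(s$rho, s$sigma, clock, n_tips = s$n_tips,
             node = as.character(node), haplogroup = tree$nodes$haplogroup[node])
}

# rho and Saillard sigma restricted to a chosen leaf subset
rho_subset <- function(tree, node, leaves, counted_classes = NULL,
                       hotspots = default_hotspots()) {
  cnt <- edge_counts(tree, counted_classes, hotspots)
  ne <- integer(n_nodes(tree))
  ne[leaves] <- 1L
  for (v in tree_postorder(tree, node)) {
    kids <- which(tree$nodes$parent == v)
    ne[v] <- ne[v] + sum(ne[kids])
  }
  sub <- descendants(tree, node)
  n <- length(leaves)
  list(rho = sum(ne[sub] * cnt[sub]) / n,
       sigma = sqrt(sum((ne[sub] / n)^2 * cnt[sub])),
       n_tips = n)
}

#' Infer the most probable origin region of a clade
#'
#' Scores each region by three min-max-normalised components: the number of
#' basal branches (children of the clade root) containing samples of the
#' region, the region's rho diversity within the clade, and the proximity
#' of the region to the clade's leaf-weighted centre of gravity. Ties break
#' by raw basal-branch count, then label order.
#'
#' @param tree A [mutation_tree()].
#' @param node Clade root node id.
#' @param weights Length-3 numeric weights for (basal branches, rho
#'   diversity, centre of gravity); default `c(1, 1, 1)`.
#' @param centroids Optional `tibble(region, x, y)` of region centroid
#'   coordinates; by default regions are placed at unit spacing on a line in
#'   label order, which preserves adjacency for ordered regional schemes.
#' @param clock Counting rules for the rho component.
#' @return A one-row tibble of class `origin_call`: `clade`, `node`,
#'   `origin_region`, `score`, plus an `evidence` list-column holding the
#'   per-region component table.
#' @export
infer_origin <- function(tree, node = tree$root, weights = c(1, 1, 1),
                         centroids = NULL,
                         clock = clock_whole_molecule()) {
  kids <- which(tree$nodes$parent == node)
  if (length(kids) < 2L) {
    stop("clade must have at least 2 basal branches", call. = FALSE)
  }
  leaves <- sample_leaves(tree, node)
  reg <- tree$nodes$region[leaves]
  known <- !is.na(reg) & reg != "unknown"
  if (!any(known)) {
    stop("all samples below node ", node, " have unknown region",
         call. = FALSE)
  }
  regions <- sort(unique(reg[known]))
  if (is.null(centroids)) {
    centroids <- tibble::tibble(region = regions,
                                x = seq_along(regions) - 1, y = 0)
  }
  basal <- vapply(regions, function(r) {
    sum(vapply(kids, function(k) {
      lv <- if (tree$nodes$type[k] == "sample") k else sample_leaves(tree, k)
      any(tree$nodes$region[lv] == r, na.rm = TRUE)
    }, TRUE))
  }, 0L)
  basal <- unname(basal)
  rho_div <- vapply(regions, function(r) {
    lv <- leaves[!is.na(tree$nodes$region[leaves]) &
                   tree$nodes$region[leaves] == r]
    if (length(lv) == 0L) return(0)
    rho_subset(tree, node, lv, clock$counted_classes, clock$hotspots)$rho
  }, 0)
  rho_div <- unname(rho_div)
  cx <- centroids$x[match(reg[known], centroids$region)]
  cy <- centroids$y[match(reg[known], centroids$region)]
  cog <- c(mean(cx, na.rm = TRUE), mean(cy, na.rm = TRUE))
  dist <- vapply(regions, function(r) {
    i <- match(r, centroids$region)
    sqrt((centroids$x[i] - cog[1])^2 + (centroids$y[i] - cog[2])^2)
  }, 0)
  dist <- unname(dist)
  norm01 <- function(x) {
    rng <- range(x)
    if (diff(rng) < 1e-12) rep(1, length(x)) else (x - rng[1]) / diff(rng)
  }
  score <- weights[1] * norm01(basal) + weights[2] * norm01(rho_div) +
    weights[3] * (1 - norm01(dist))
  ord <- order(-score, -basal, regions)
  evidence <- tibble::tibble(region = regions, basal_branches = basal,
                             rho_diversity = rho_div, cog_distance = dist,
                             score = score)
  out <- tibble::tibble(
    clade = tree$nodes$haplogroup[node] %||% as.character(node),
    node = node,
    origin_region = regions[ord[1L]],
    score = score[ord[1L]],
    evidence = list(evidence)
  )
  class(out) <- c("origin_call", class(out))
  out
}

#' Regional age using clade origins (approach 2)
#'
#' For target region `R`: keep only the major subclades (children of the
#' haplogroup root meeting `min_samples`) whose inferred origin is `R`,
#' and within each keep its `R`-sampled basal lineages, excluding leaves
#' nested inside a deeper major subclade assigned to a different region.
#' rho/sigma/age are recomputed from the haplogroup root over that leaf
#' set. Minor subclades fall back to the modal region of their leaves.
#'
#' @param tree A [mutation_tree()].
#' @param node Haplogroup root node id.
#' @param region Target region.
#' @param origin_calls Optional precomputed tibble of [infer_origin()] rows
#'   (one per major subclade, keyed by `node`); computed when `NULL`.
#' @param clock A [clock_spec()].
#' @param min_samples Threshold for a subclade to be origin-called by score
#'   (default 5).
#' @return An `age_estimate` row.
#' @export
regional_age_by_origin <- function(tree, node = tree$root, region,
                                   origin_calls = NULL,
                                   clock = clock_whole_molecule(),
                                   min_samples = 5L) {
  kids <- which(tree$nodes$parent == node)
  sub_origin <- function(k) {
    if (!is.null(origin_calls) && k %in% origin_calls$node) {
      return(origin_calls$origin_region[match(k, origin_calls$node)])
    }
    lv <- if (tree$nodes$type[k] == "sample") k else sample_leaves(tree, k)
    regs <- tree$nodes$region[lv]
    regs <- regs[!is.na(regs) & regs != "unknown"]
    if (length(regs) == 0L) return(NA_character_)
    n_basal <- length(which(tree$nodes$parent == k))
    if (length(lv) >= min_samples && n_basal >= 2L) {
      infer_origin(tree, k, clock = clock)$origin_region
    } else {
      names(sort(table(regs), decreasing = TRUE))[1L]  # modal fallback
    }
  }
  excluded <- character()
  # recursively collect region-R leaves, stopping at any nested major
  # subclade whose own origin call is a different region
  collect_r <- function(v) {
    if (tree$nodes$type[v] == "sample") {
      r <- tree$nodes$region[v]
      return(if (!is.na(r) && r == region) v else integer())
    }
    out <- integer()
    for (k in which(tree$nodes$parent == v)) {
      lv <- if (tree$nodes$type[k] == "sample") k else sample_leaves(tree, k)
      if (length(lv) >= min_samples) {
        ok <- sub_origin(k)
        if (!is.na(ok) && ok != region) {
          excluded <<- c(excluded, paste0("node", k, " (origin ", ok, ")"))
          next
        }
      }
      out <- c(out, collect_r(k))
    }
    out
  }
  keep <- integer()
  for (k in kids) {
    o <- sub_origin(k)
    if (is.na(o) || o != region) {
      excluded <- c(excluded, paste0("node", k, " (origin ",
                                     o %||% "unknown", ")"))
      next
    }
    keep <- c(keep, collect_r(k))
  }
  if (length(keep) == 0L) {
    stop("no basal lineages of region '", region, "' remain; excluded: ",
         paste(excluded, collapse = "; "), call. = FALSE)
  }
  s <- rho_subset(tree, node, keep, clock$counted_classes, clock$hotspots)
  rho_to_age(s$rho, s$sigma, clock, n_tips = s$n_tips,
             node = as.character(node),
             haplogroup = tree$nodes$haplogroup[node])
}

#' Default founder arrival time windows
#'
#' Contiguous windows over ages in ka: bronze_age \[0, 4), neolithic
#' \[4, 9), postglacial \[9, 13), late_glacial \[13, 17), LGM \[17, 24) and
#' pre_LGM \[24, Inf). Boundaries bracket the narrative arrival horizons
#' (~21 ka, 16-13 ka, ~12-9 ka, 9-5/4 ka, last 4 ka); exact cutoffs are a
#' configuration choice.
#'
#' @return Tibble `window`, `lower_ka`, `upper_ka` (lower inclusive,
#'   upper exclusive).
#' @export
default_windows <- function() {
  tibble::tibble(
    window = c("bronze_age", "neolithic", "postglacial", "late_glacial",
               "LGM", "pre_LGM"),
    lower_ka = c(0, 4, 9, 13, 17, 24),
    upper_ka = c(4, 9, 13, 17, 24, Inf)
  )
}

validate_windows <- function(w) {
  if (!all(c("window", "lower_ka", "upper_ka") %in% names(w))) {
    stop("window table needs columns window, lower_ka, upper_ka",
         call. = FALSE)
  }
  w <- w[order(w$lower_ka), , drop = FALSE]
  if (w$lower_ka[1L] != 0 || !is.infinite(w$upper_ka[nrow(w)]) ||
      any(w$upper_ka[-nrow(w)] != w$lower_ka[-1L]) ||
      any(w$upper_ka <= w$lower_ka)) {
    stop("windows must be contiguous, non-overlapping and cover [0, Inf)",
         call. = FALSE)
  }
  w
}

#' Assign an age estimate to an arrival time window
#'
#' Returns the window containing the point age; when the 95% CI spans more
#' than one window the call is flagged boundary-ambiguous.
#'
#' @param age An `age_estimate` row (or tibble of them), or a numeric age
#'   in years.
#' @param windows Window table as in [default_windows()].
#' @param ci_low,ci_high Optional CI in years when `age` is numeric.
#' @return Tibble `age_ka`, `window`, `boundary_ambiguous`.
#' @export
assign_window <- function(age, windows = default_windows(),
                          ci_low = NULL, ci_high = NULL) {
  w <- validate_windows(windows)
  if (is.data.frame(age)) {
    ages <- age$age_years; lo <- age$ci_low; hi <- age$ci_high
  } else {
    ages <- age
    lo <- ci_low %||% age
    hi <- ci_high %||% age
  }
  win_of <- function(a_ka) {
    w$window[a_ka >= w$lower_ka & a_ka < w$upper_ka][1L]
  }
  out <- purrr::pmap(list(ages, lo, hi), function(a, l, h) {
    a_ka <- a / 1000
    span <- unique(c(win_of(max(0, l) / 1000), win_of(a_ka),
                     win_of(h / 1000)))
    tibble::tibble(age_ka = a_ka, window = win_of(a_ka),
                   boundary_ambiguous = length(span) > 1L)
  })
  dplyr::bind_rows(out)
}

#' Per-population lineage-origin frequency tables
#'
#' Joins haplogroup calls with an origin annotation (origin class and
#' arrival window per haplogroup) and tabulates, per population and pooled,
#' the fraction of samples per origin class and per window. Haplogroups
#' absent from the annotation are counted as `"unassigned"`.
#'
#' @param samples Tibble `sample_id`, `population`.
#' @param haplogroup_calls Tibble `sample_id`, `haplogroup` (as from
#'   [call_haplogroup()]).
#' @param origin_annotation Tibble `haplogroup`, `origin_class` and
#'   optionally `window`.
#' @return Tibble `population`, `class_type` (`"origin"` / `"window"`),
#'   `class`, `n`, `fraction`; fractions sum to 1 within each population
#'   and class_type. The pooled rows use population `"ALL"`.
#' @export
lineage_frequencies <- function(samples, haplogroup_calls,
                                origin_annotation) {
  df <- dplyr::left_join(tibble::as_tibble(samples),
                         tibble::as_tibble(haplogroup_calls),
                         by = "sample_id")
  if (anyNA(df$haplogroup)) {
    stop("every sample needs a haplogroup call", call. = FALSE)
  }
  ann <- tibble::as_tibble(origin_annotation)
  df$origin_class <- ann$origin_class[match(df$haplogroup, ann$haplogroup)]
  df$origin_class[is.na(df$origin_class)] <- "unassigned"
  has_window <- "window" %in% names(ann)
  if (has_window) {
    df$window <- ann$window[match(df$haplogroup, ann$haplogroup)]
    df$window[is.na(df$window)] <- "unassigned"
  }
  tab <- function(d, pop) {
    per <- function(col, type) {
      counts <- table(d[[col]])
      tibble::tibble(population = pop, class_type = type,
                     class = names(counts), n = as.integer(counts),
                     fraction = as.numeric(counts) / nrow(d))
    }
    out <- per("origin_class", "origin")
    if (has_window) out <- dplyr::bind_rows(out, per("window", "window"))
    out
  }
  pops <- split(df, df$population)
  dplyr::bind_rows(
    dplyr::bind_rows(purrr::imap(pops, tab)),
    tab(df, "ALL")
  )
}
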