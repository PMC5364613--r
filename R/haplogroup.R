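#' Construct a haplogroup motif database
#'
#' A motif database is a rooted tree of haplogroup labels; each node carries
#' the defining mutations gained on the edge from its parent, in PhyloTree
#' notation (suffix `"!"` marks a back mutation, which restores the
#' reference state expectation at that position).
#'
#' @param df Tibble with columns `name`, `parent` (empty/NA for the root) and
#'   `mutations` (space-separated labels, or a list-column of mutation
#'   tibbles).
#' @return A `motif_db` object (tibble with parsed `mutations` list-column).
#' @export
motif_db <- function(df) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("name", "parent") %in% names(df)))
  if (!is.list(df$mutations)) {
    df$mutations <- purrr::map(df$mutations, function(s) {
      if (is.na(s) || !nzchar(trimws(s))) {
        out <- empty_mutations(); out$back <- logical(); out
      } else {
        parse_mutation_labels(strsplit(trimws(s), "\\s+")[[1L]])
      }
    })
  }
  df$parent[is.na(df$parent) | df$parent %in% c("", "root", "-")] <- NA_character_
  if (anyDuplicated(df$name)) stop("duplicate motif names", call. = FALSE)
  roots <- which(is.na(df$parent))
  if (length(roots) != 1L) {
    stop("motif DB must have exactly one root, found ", length(roots),
         call. = FALSE)
  }
  missing_parent <- !is.na(df$parent) & !(df$parent %in% df$name)
  if (any(missing_parent)) {
    stop("unknown parent(s): ", paste(df$parent[missing_parent], collapse = ", "),
         call. = FALSE)
  }
  # check single rooted tree: every node must reach the root
  depth <- motif_depths(df)
  if (anyNA(depth)) stop("motif DB contains a parent cycle", call. = FALSE)
  df$depth <- depth
  class(df) <- c("motif_db", class(df))
  df
}

motif_depths <- function(df) {
  depth <- rep(NA_integer_, nrow(df))
  names(depth) <- df$name
  depth[is.na(df$parent)] <- 0L
  repeat {
    idx <- which(is.na(depth) & !is.na(depth[df$parent]))
    if (length(idx) == 0L) break
    depth[idx] <- depth[df$parent[idx]] + 1L
  }
  unname(depth)
}

#' Read a motif database from TSV
#' @param path TSV with columns `name`, `parent`, `mutations`.
#' @return A [motif_db()] object.
#' @export
read_motif_db <- function(path) {
  motif_db(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = "c")))
}

#' Cumulative expected mutations of a motif node
#'
#' Walks the root-to-node path applying each defining mutation; a back
#' mutation removes the expectation at its position.
#'
#' @param db A [motif_db()].
#' @param name Haplogroup label.
#' @return Mutation tibble (relative to the reference).
#' @export
motif_expected <- function(db, name) {
  path <- character()
  cur <- name
  while (!is.na(cur)) {
    path <- c(cur, path)
    cur <- db$parent[match(cur, db$name)]
    if (length(path) > nrow(db)) stop("cycle in motif DB", call. = FALSE)
  }
  if (!name %in% db$name) stop("unknown haplogroup: ", name, call. = FALSE)
  state <- list()
  for (nm in path) {
    m <- db$mutations[[match(nm, db$name)]]
    for (i in seq_len(nrow(m))) {
      key <- as.character(m$position[i])
      if (isTRUE(m$back[i])) state[[key]] <- NULL
      else state[[key]] <- m[i, c("position", "ancestral", "derived",
                                  "class", "syn_status")]
    }
  }
  if (length(state) == 0L) return(empty_mutations())
  dplyr::arrange(dplyr::bind_rows(state), .data$position)
}

#' Call haplogroups for variant profiles
#'
#' Scores every motif-DB node as
#' `matched expected mutations - penalty * expected-but-absent mutations`
#' against the node's cumulative expectation, and returns the best node.
#' Private mutations (present in the profile but expected nowhere on the
#' path) do not penalise. Ties are broken toward the deeper node, then
#' lexicographically by name.
#'
#' @param profiles Nested profile tibble (as from [profile_from_alignment()]),
#'   or a single mutation tibble.
#' @param db A [motif_db()].
#' @param penalty Penalty per expected-but-absent mutation (default 0.5).
#' @return Tibble `sample_id`, `haplogroup`, `score`, `matched`, `missed`.
#' @export
call_haplogroup <- function(profiles, db, penalty = 0.5) {
  if (!inherits(db, "motif_db")) stop("db must be a motif_db", call. = FALSE)
  if (nrow(db) == 0L) stop("empty motif database", call. = FALSE)
  single <- is.data.frame(profiles) && "position" %in% names(profiles)
  if (single) {
    profiles <- tibble::tibble(sample_id = "sample",
                               mutations = list(profiles))
  }
  expected <- purrr::map(db$name, motif_expected, db = db)
  exp_keys <- purrr::map(expected, function(e) {
    paste(e$position, e$derived, sep = ">")
  })
  # deterministic candidate order: score desc, depth desc, name asc
  ord <- order(-db$depth, db$name)
  res <- purrr::map(profiles$mutations, function(m) {
    have <- paste(m$position, m$derived, sep = ">")
    matched <- vapply(exp_keys, function(k) sum(k %in% have), 0L)
    missed <- lengths(exp_keys) - matched
    score <- matched - penalty * missed
    best <- ord[which.max(score[ord])]
    tibble::tibble(haplogroup = db$name[best], score = score[best],
                   matched = matched[best], missed = missed[best])
  })
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = profiles$sample_id),
    dplyr::bind_rows(res)
  )
  out
}
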