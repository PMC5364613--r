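#' @importFrom rlang .data
NULL

#' An empty mutation table
#'
#' Mutations are plain tibbles with one row per variant: `position` (1-based),
#' `ancestral`, `derived`, `class` (`"transition"`, `"transversion"`,
#' `"indel"`) and `syn_status` (`"synonymous"`, `"nonsynonymous"`, `"rna"`,
#' `"noncoding"`, `"unassigned"`).
#' @return Zero-row mutation tibble.
#' @export
empty_mutations <- function() {
  tibble::tibble(position = integer(), ancestral = character(),
                 derived = character(), class = character(),
                 syn_status = character())
}

#' Build a mutation table from components
#' @param position Integer positions (1-based).
#' @param ancestral,derived Base characters (`"-"` for gaps).
#' @param syn_status Optional status vector; defaults to `"unassigned"`.
#' @return Mutation tibble; `class` is derived from the base pair.
#' @export
mutations <- function(position, ancestral, derived, syn_status = "unassigned") {
  if (length(position) == 0L) return(empty_mutations())
  ancestral <- toupper(ancestral)
  derived <- toupper(derived)
  if (any(ancestral == derived)) {
    stop("ancestral and derived state must differ", call. = FALSE)
  }
  tbl <- tibble::tibble(
    position = as.integer(position), ancestral = ancestral, derived = derived,
    class = mutation_class(ancestral, derived),
    syn_status = rep_len(syn_status, length(position))
  )
  dup <- duplicated(tbl[, c("position", "derived")])
  if (any(dup)) {
    stop("duplicate mutation (same position and derived state) at position ",
         paste(unique(tbl$position[dup]), collapse = ", "), call. = FALSE)
  }
  tbl
}

mutation_class <- function(ancestral, derived) {
  purines <- c("A", "G")
  pyrimidines <- c("C", "T")
  dplyr::case_when(
    ancestral == "-" | derived == "-" ~ "indel",
    (ancestral %in% purines) == (derived %in% purines) ~ "transition",
    TRUE ~ "transversion"
  )
}

#' Parse PhyloTree-style mutation labels
#'
#' Labels such as `"A750G"`, `"C16223T!"` (back mutation) or `"T310-"`
#' (deletion). The trailing `"!"` marks a back mutation (used in motif
#' databases); it is returned in the `back` column.
#'
#' @param x Character vector of labels.
#' @return Mutation tibble with an extra logical `back` column.
#' @export
parse_mutation_labels <- function(x) {
  x <- trimws(x)
  x <- x[nzchar(x)]
  if (length(x) == 0L) {
    out <- empty_mutations()
    out$back <- logical()
    return(out)
  }
  m <- regmatches(x, regexec("^([ACGTN-])(\\d+)([ACGTN-])(!?)$", toupper(x)))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("unparseable mutation label(s): ", paste(x[bad], collapse = ", "),
         call. = FALSE)
  }
  anc <- vapply(m, `[`, "", 2L)
  pos <- as.integer(vapply(m, `[`, "", 3L))
  der <- vapply(m, `[`, "", 4L)
  out <- mutations(pos, anc, der)
  out$back <- vapply(m, `[`, "", 5L) == "!"
  out
}

#' Format mutations as PhyloTree-style labels
#' @param muts Mutation tibble.
#' @return Character vector like `"A750G"`.
#' @export
format_mutation_labels <- function(muts) {
  if (nrow(muts) == 0L) return(character())
  paste0(muts$ancestral, muts$position, muts$derived)
}

#' Default hypermutable-position exclusion list
#'
#' Positions conventionally dropped from substitution clocks: the 16182/16183/
#' 16194 poly-C tract positions, hypervariable 16519, and the length-variant
#' neighbourhoods around 309 and 573.
#' @return Integer vector of positions.
#' @export
default_hotspots <- function() {
  as.integer(c(16182, 16183, 16194, 16519, 303:315, 568:573))
}

#' Derive variant profiles from an alignment against the reference
#'
#' Every aligned record is compared column-by-column with the reference row.
#' Substitutions are recorded with reference coordinates; alignment columns
#' where the reference carries a gap (insertions) are recorded as indels
#' anchored at the preceding reference position; `N`/ambiguity columns are
#' skipped.
#'
#' @param aligned_fasta Path to an aligned FASTA, or a named character vector
#'   of equal-length sequences. Must contain a row whose name matches
#'   `reference$id` (the alignment's reference row) unless the reference is
#'   ungapped and identical in length.
#' @param reference A [reference_genome()].
#' @param metadata Optional tibble `sample_id`, `population`, `region`.
#' @return A nested tibble: one row per sample with columns `sample_id`,
#'   `population`, `region` and a `mutations` list-column.
#' @export
profile_from_alignment <- function(aligned_fasta, reference, metadata = NULL) {
  if (is.character(aligned_fasta) && length(aligned_fasta) == 1L &&
      file.exists(aligned_fasta)) {
    ss <- Biostrings::readDNAStringSet(aligned_fasta)
    seqs <- stats::setNames(as.character(ss), names(ss))
  } else {
    seqs <- aligned_fasta
  }
  seqs <- toupper(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("aligned sequences must be named", call. = FALSE)
  }
  if (reference$id %in% names(seqs)) {
    ref_row <- seqs[[reference$id]]
    seqs <- seqs[names(seqs) != reference$id]
  } else {
    ref_row <- reference$sequence
  }
  widths <- nchar(seqs)
  if (any(widths != nchar(ref_row))) {
    stop("alignment length mismatch: reference row is ", nchar(ref_row),
         " columns but sample(s) ",
         paste(names(seqs)[widths != nchar(ref_row)], collapse = ", "),
         " differ", call. = FALSE)
  }
  ref_chars <- strsplit(ref_row, "")[[1L]]
  # reference coordinate of each alignment column (insertion columns anchor
  # to the preceding reference position)
  ref_pos <- cumsum(ref_chars != "-")
  ref_pos[ref_pos == 0L] <- 1L
  profiles <- purrr::map(seqs, function(s) {
    chars <- strsplit(s, "")[[1L]]
    differ <- chars != ref_chars & chars != "N" & ref_chars != "N"
    idx <- which(differ)
    if (length(idx) == 0L) return(empty_mutations())
    mutations(ref_pos[idx], ref_chars[idx], chars[idx])
  })
  out <- tibble::tibble(
    sample_id = names(seqs),
    population = NA_character_,
    region = NA_character_,
    mutations = unname(profiles)
  )
  if (!is.null(metadata)) {
    metadata <- tibble::as_tibble(metadata)
    out$population <- metadata$population[match(out$sample_id,
                                                metadata$sample_id)]
    if ("region" %in% names(metadata)) {
      out$region <- metadata$region[match(out$sample_id, metadata$sample_id)]
    }
  }
  validate_profiles(out, reference)
  out
}

validate_profiles <- function(profiles, reference = NULL) {
  stopifnot(all(c("sample_id", "mutations") %in% names(profiles)))
  for (i in seq_len(nrow(profiles))) {
    m <- profiles$mutations[[i]]
    if (any(duplicated(m[, c("position", "derived")]))) {
      stop("profile ", profiles$sample_id[i],
           ": duplicate position/derived state", call. = FALSE)
    }
    if (!is.null(reference) &&
        any(m$position < 1L | m$position > reference$length)) {
      stop("profile ", profiles$sample_id[i], ": position outside [1, ",
           reference$length, "]", call. = FALSE)
    }
  }
  invisible(profiles)
}

#' Reconstruct a full sequence from a variant profile
#'
#' Substitution-only inverse of [profile_from_alignment()]; indels are
#' ignored (a warning is emitted if present).
#'
#' @param muts Mutation tibble for one sample.
#' @param reference A [reference_genome()].
#' @return Character scalar sequence of length `reference$length`.
#' @export
profile_to_sequence <- function(muts, reference) {
  chars <- strsplit(reference$sequence, "")[[1L]]
  if (any(muts$class == "indel")) {
    warning("indel mutations ignored in sequence reconstruction")
    muts <- muts[muts$class != "indel", , drop = FALSE]
  }
  mism <- chars[muts$position] != muts$ancestral
  if (any(mism)) {
    stop("ancestral state disagrees with reference at position ",
         paste(muts$position[mism], collapse = ", "), call. = FALSE)
  }
  chars[muts$position] <- muts$derived
  paste(chars, collapse = "")
}
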