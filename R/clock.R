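#' Molecular clock specifications
#'
#' A clock converts counted substitutions into years. Two standard clocks are
#' provided: the synonymous clock (one synonymous substitution per 7884
#' years, counting only synonymous changes) and the whole-molecule mitogenome
#' clock (one substitution per 3624 years, already corrected for purifying
#' selection, counting all substitutions outside the hotspot/indel
#' exclusions). A user-supplied monotone `correction` maps raw ages to
#' corrected ages (identity by default, because the quoted rates are already
#' selection-corrected).
#'
#' @param name Clock label.
#' @param years_per_substitution Positive years per counted substitution.
#' @param counted_classes `NULL` to count every substitution, or a character
#'   vector of `syn_status` values to count.
#' @param correction Monotone function with `correction(0) == 0`.
#' @param hotspots Positions excluded from counting
#'   (default [default_hotspots()]).
#' @return A `clock_spec` object.
#' @export
clock_spec <- function(name, years_per_substitution, counted_classes = NULL,
                       correction = identity, hotspots = default_hotspots()) {
  stopifnot(is.numeric(years_per_substitution),
            years_per_substitution > 0, is.function(correction))
  if (abs(correction(0)) > 1e-9) {
    stop("correction(0) must be 0", call. = FALSE)
  }
  probe <- correction(c(0, 1e3, 1e4, 5e4, 1e5, 1e6))
  if (any(diff(probe) < 0)) {
    stop("correction must be nondecreasing", call. = FALSE)
  }
  structure(list(name = name,
                 years_per_substitution = years_per_substitution,
                 counted_classes = counted_classes,
                 correction = correction, hotspots = hotspots),
            class = "clock_spec")
}

#' @rdname clock_spec
#' @export
clock_synonymous <- function(correction = identity) {
  clock_spec("synonymous", 7884, counted_classes = "synonymous",
             correction = correction)
}

#' @rdname clock_spec
#' @export
clock_whole_molecule <- function(correction = identity) {
  clock_spec("whole_molecule", 3624, counted_classes = NULL,
             correction = correction)
}

#' @export
print.clock_spec <- function(x, ...) {
  cat("<clock_spec> ", x$name, ": 1 substitution / ",
      x$years_per_substitution, " yr; counts ",
      if (is.null(x$counted_classes)) "all substitutions"
      else paste(x$counted_classes, collapse = "+"), "\n", sep = "")
  invisible(x)
}

#' Classify substitutions as synonymous / nonsynonymous / RNA / noncoding
#'
#' Protein-coding positions are evaluated in every overlapping reading frame
#' (light-strand genes are complemented and read in reverse), translated
#' with the vertebrate mitochondrial code; a substitution is synonymous only
#' if the amino acid is unchanged in all overlapping frames. tRNA/rRNA
#' positions are `"rna"`; control-region positions `"noncoding"`. Positions
#' covered by no feature are `"noncoding"` with a warning. Indels keep
#' `"unassigned"`.
#'
#' @param muts Mutation tibble.
#' @param reference A [reference_genome()].
#' @return The mutation tibble with `syn_status` filled.
#' @export
classify_mutations <- function(muts, reference) {
  if (nrow(muts) == 0L) return(muts)
  code <- Biostrings::getGeneticCode("SGC1")  # vertebrate mitochondrial
  refchars <- strsplit(reference$sequence, "")[[1L]]
  status <- muts$syn_status
  orphan <- FALSE
  for (i in seq_len(nrow(muts))) {
    if (muts$class[i] == "indel") next
    pos <- muts$position[i]
    feats <- features_at(reference, pos)
    if (nrow(feats) == 0L) {
      status[i] <- "noncoding"
      orphan <- TRUE
      next
    }
    prot <- feats[feats$kind == "protein", , drop = FALSE]
    if (nrow(prot) > 0L) {
      syn <- TRUE
      informative <- FALSE
      for (j in seq_len(nrow(prot))) {
        aa <- codon_effect(pos, muts$derived[i], prot[j, ], refchars,
                           reference$length, code)
        if (is.null(aa)) next
        informative <- TRUE
        if (aa[1L] != aa[2L]) syn <- FALSE
      }
      status[i] <- if (!informative) "unassigned"
                   else if (syn) "synonymous" else "nonsynonymous"
    } else if (any(feats$kind %in% c("tRNA", "rRNA"))) {
      status[i] <- "rna"
    } else {
      status[i] <- "noncoding"
    }
  }
  if (orphan) {
    warning("position(s) outside all annotated features classified noncoding")
  }
  muts$syn_status <- status
  muts
}

# reference vs mutated amino acid for one position in one protein feature;
# NULL when the codon is incomplete (trailing partial codon)
codon_effect <- function(pos, derived, feat, refchars, L, code) {
  gpos <- if (feat$wraps) c(seq.int(feat$start, L), seq_len(feat$end)) else
    seq.int(feat$start, feat$end)
  if (feat$strand == "light") gpos <- rev(gpos)
  idx <- match(pos, gpos)
  if (is.na(idx)) return(NULL)
  off <- idx - 1L - feat$frame
  if (off < 0L) return(NULL)
  codon_start <- feat$frame + (off %/% 3L) * 3L + 1L
  cpos <- gpos[codon_start:(codon_start + 2L)]
  if (anyNA(cpos)) return(NULL)
  bases <- refchars[cpos]
  mut_bases <- bases
  mut_bases[match(pos, cpos)] <- derived
  if (feat$strand == "light") {
    bases <- dna_complement(bases)
    mut_bases <- dna_complement(mut_bases)
  }
  c(translate_codon(bases, code), translate_codon(mut_bases, code))
}

translate_codon <- function(bases, code) {
  cdn <- paste(bases, collapse = "")
  if (grepl("[^ACGT]", cdn)) return("X")
  unname(code[cdn])
}

#' Classify every edge mutation on a tree
#' @param tree A [mutation_tree()].
#' @param reference A [reference_genome()].
#' @return The tree with `syn_status` filled throughout `edge_muts`.
#' @export
classify_tree <- function(tree, reference) {
  tree$nodes$edge_muts <- purrr::map(tree$nodes$edge_muts,
                                     classify_mutations,
                                     reference = reference)
  tree
}
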