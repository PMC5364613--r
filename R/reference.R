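#' Construct a circular reference genome
#'
#' A reference genome is the coordinate frame for every mutation handled by the
#' package: a single circular nucleotide sequence (rCRS-style, 1-based
#' positions) plus a gene annotation table used to classify substitutions as
#' synonymous, nonsynonymous, RNA or noncoding.
#'
#' @param id Text label for the reference (e.g. `"rCRS"`).
#' @param sequence Character scalar over A/C/G/T/N; its length defines `L`.
#' @param annotation Tibble with columns `name`, `start`, `end`, `strand`
#'   (`"heavy"`/`"light"`), `kind` (`"protein"`, `"tRNA"`, `"rRNA"`,
#'   `"control"`) and optionally `frame` (0-2 reading-frame offset) and
#'   `wraps` (logical, feature spans the circular origin).
#' @return An object of class `reference_genome` with elements `id`,
#'   `sequence`, `length` and `annotation`.
#' @export
reference_genome <- function(id, sequence, annotation) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("reference sequence may contain only A/C/G/T/N", call. = FALSE)
  }
  L <- nchar(sequence)
  annotation <- tibble::as_tibble(annotation)
  required <- c("name", "start", "end", "strand", "kind")
  if (!all(required %in% names(annotation))) {
    stop("annotation must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (!"frame" %in% names(annotation)) annotation$frame <- 0L
  if (!"wraps" %in% names(annotation)) annotation$wraps <- FALSE
  annotation$wraps <- as.logical(annotation$wraps)
  annotation$start <- as.integer(annotation$start)
  annotation$end <- as.integer(annotation$end)
  bad <- annotation$start < 1L | annotation$start > L |
    annotation$end < 1L | annotation$end > L
  if (any(bad)) {
    stop("annotation feature(s) outside [1, ", L, "]: ",
         paste(annotation$name[bad], collapse = ", "), call. = FALSE)
  }
  rev_span <- annotation$end < annotation$start & !annotation$wraps
  if (any(rev_span)) {
    stop("feature(s) with end < start lack a wrap flag: ",
         paste(annotation$name[rev_span], collapse = ", "), call. = FALSE)
  }
  ok_strand <- annotation$strand %in% c("heavy", "light")
  if (!all(ok_strand)) stop("strand must be 'heavy' or 'light'", call. = FALSE)
  ok_kind <- annotation$kind %in% c("protein", "tRNA", "rRNA", "control")
  if (!all(ok_kind)) {
    stop("kind must be protein/tRNA/rRNA/control", call. = FALSE)
  }
  # protein features: span (after wrap) divisible by 3, else flagged
  span <- ifelse(annotation$wraps,
                 L - annotation$start + 1L + annotation$end,
                 annotation$end - annotation$start + 1L)
  annotation$incomplete_codon <- annotation$kind == "protein" & span %% 3L != 0L
  structure(
    list(id = id, sequence = sequence, length = L, annotation = annotation),
    class = "reference_genome"
  )
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("<reference_genome> ", x$id, ": ", x$length, " bp, ",
      nrow(x$annotation), " features\n", sep = "")
  invisible(x)
}

#' Read a reference genome from FASTA plus an annotation table
#'
#' @param fasta_path Path to a single-record FASTA file.
#' @param annotation_path Path to a TSV with columns
#'   `name`, `start`, `end`, `strand`, `kind` and optionally `frame`, `wraps`.
#' @return A [reference_genome()] object.
#' @export
read_reference <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) {
    stop("reference FASTA must contain exactly one record, found ",
         length(seqs), call. = FALSE)
  }
  annotation <- readr::read_tsv(annotation_path, show_col_types = FALSE,
                                progress = FALSE)
  reference_genome(names(seqs)[1L], as.character(seqs[[1L]]), annotation)
}

#' Base at a (1-based, circular) reference position
#' @param reference A [reference_genome()].
#' @param position Integer vector of 1-based positions.
#' @return Character vector of bases.
#' @export
ref_base <- function(reference, position) {
  p <- ((as.integer(position) - 1L) %% reference$length) + 1L
  substring(reference$sequence, p, p)
}

# features overlapping a position, honouring circular wrap
features_at <- function(reference, position) {
  a <- reference$annotation
  hit <- (!a$wraps & position >= a$start & position <= a$end) |
    (a$wraps & (position >= a$start | position <= a$end))
  a[hit, , drop = FALSE]
}

#' A deterministic synthetic full-length mitochondrial reference
#'
#' Builds a 16,569-bp circular reference whose gene layout follows the
#' standard rCRS coordinate frame (control region, the two rRNAs, 22 tRNAs
#' and 13 protein-coding genes at their conventional positions). The
#' nucleotide sequence itself is synthetic (pseudo-random, fixed seed), so
#' base-level values are not those of the real rCRS; the object is intended
#' for coordinate- and annotation-dependent logic, not sequence lookup.
#'
#' Protein-coding spans are filled with valid in-frame codons (no internal
#' stops on the coding strand) so codon-level classification behaves like a
#' real genome.
#'
#' @param seed Integer seed for the sequence fill.
#' @return A [reference_genome()] of length 16,569.
#' @export
synthetic_reference <- function(seed = 1965L) {
  annotation <- rcrs_annotation()
  L <- 16569L
  rng <- local_rng(seed)
  base4 <- c("A", "C", "G", "T")
  seqv <- sample(base4, L, replace = TRUE)
  # fill protein genes with in-frame stop-free codons on the coding strand
  codons <- apply(expand.grid(base4, base4, base4), 1L, paste, collapse = "")
  mito_stops <- c("TAA", "TAG", "AGA", "AGG")
  safe <- setdiff(codons, c(mito_stops, "ATG"))
  prot <- annotation[annotation$kind == "protein", , drop = FALSE]
  for (i in seq_len(nrow(prot))) {
    pos <- seq.int(prot$start[i], prot$end[i])
    n_codon <- length(pos) %/% 3L
    filled <- c("ATG", sample(safe, n_codon - 2L, replace = TRUE), "TAA")
    block <- strsplit(paste(filled, collapse = ""), "")[[1L]]
    # trailing incomplete codon (completed post-transcriptionally in vivo)
    extra <- length(pos) - length(block)
    if (extra > 0L) block <- c(block, rep("A", extra))
    if (prot$strand[i] == "light") block <- rev(dna_complement(block))
    seqv[pos] <- block
  }
  restore_rng(rng)
  reference_genome("synthetic-rCRS-frame", paste(seqv, collapse = ""),
                   annotation)
}

# Standard rCRS gene layout (coordinates per the conventional human mtDNA
# map); the control region wraps the circular origin.
rcrs_annotation <- function() {
  tibble::tribble(
    ~name,      ~start, ~end,  ~strand, ~kind,
    "CR",       16024L, 576L,  "heavy", "control",
    "TF",       577L,   647L,  "heavy", "tRNA",
    "RNR1",     648L,   1601L, "heavy", "rRNA",
    "TV",       1602L,  1670L, "heavy", "tRNA",
    "RNR2",     1671L,  3229L, "heavy", "rRNA",
    "TL1",      3230L,  3304L, "heavy", "tRNA",
    "ND1",      3307L,  4262L, "heavy", "protein",
    "TI",       4263L,  4331L, "heavy", "tRNA",
    "TQ",       4329L,  4400L, "light", "tRNA",
    "TM",       4402L,  4469L, "heavy", "tRNA",
    "ND2",      4470L,  5511L, "heavy", "protein",
    "TW",       5512L,  5579L, "heavy", "tRNA",
    "TA",       5587L,  5655L, "light", "tRNA",
    "TN",       5657L,  5729L, "light", "tRNA",
    "TC",       5761L,  5826L, "light", "tRNA",
    "TY",       5826L,  5891L, "light", "tRNA",
    "CO1",      5904L,  7445L, "heavy", "protein",
    "TS1",      7446L,  7514L, "light", "tRNA",
    "TD",       7518L,  7585L, "heavy", "tRNA",
    "CO2",      7586L,  8269L, "heavy", "protein",
    "TK",       8295L,  8364L, "heavy", "tRNA",
    "ATP8",     8366L,  8572L, "heavy", "protein",
    "ATP6",     8527L,  9207L, "heavy", "protein",
    "CO3",      9207L,  9990L, "heavy", "protein",
    "TG",       9991L,  10058L, "heavy", "tRNA",
    "ND3",      10059L, 10404L, "heavy", "protein",
    "TR",       10405L, 10469L, "heavy", "tRNA",
    "ND4L",     10470L, 10766L, "heavy", "protein",
    "ND4",      10760L, 12137L, "heavy", "protein",
    "TH",       12138L, 12206L, "heavy", "tRNA",
    "TS2",      12207L, 12265L, "heavy", "tRNA",
    "TL2",      12266L, 12336L, "heavy", "tRNA",
    "ND5",      12337L, 14148L, "heavy", "protein",
    "ND6",      14149L, 14673L, "light", "protein",
    "TE",       14674L, 14742L, "light", "tRNA",
    "CYB",      14747L, 15887L, "heavy", "protein",
    "TT",       15888L, 15953L, "heavy", "tRNA",
    "TP",       15956L, 16023L, "light", "tRNA"
  ) |>
    dplyr::mutate(frame = 0L, wraps = .data$end < .data$start)
}

dna_complement <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")[x])
}

# scoped RNG helpers: preserve the caller's RNG state
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
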