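#' Harmonise per-system ancestry fraction tables
#'
#' Aligns mtDNA, Y-chromosome and autosomal ancestry tables onto a common
#' origin-class vocabulary: classes missing from a system are filled with
#' zero, and fractions are renormalised when their per-population sum
#' drifts from 1 by at most `tol` (larger drift is a validation error).
#'
#' @param tables A single long tibble with columns `population`, `system`
#'   (`"mtDNA"`, `"Y"`, `"autosomal"`), `class`, `fraction` and optionally
#'   `n`, or a list of such tibbles (one per system).
#' @param tol Permitted drift of per-population fraction sums (default
#'   1e-3).
#' @return Harmonised long tibble with every population x system x class
#'   combination present and fractions summing to 1 (within 1e-6).
#' @export
harmonize_ancestry <- function(tables, tol = 1e-3) {
  if (is.data.frame(tables)) tbl <- tibble::as_tibble(tables)
  else tbl <- dplyr::bind_rows(purrr::map(tables, tibble::as_tibble))
  req <- c("population", "system", "class", "fraction")
  if (!all(req %in% names(tbl))) {
    stop("need columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  shared <- Reduce(intersect, split(tbl$population, tbl$system))
  if (length(unique(tbl$system)) < 2L || length(shared) < 1L) {
    stop("need >= 2 systems sharing >= 1 population", call. = FALSE)
  }
  sums <- dplyr::summarise(
    dplyr::group_by(tbl, .data$population, .data$system),
    total = sum(.data$fraction), .groups = "drop"
  )
  off <- abs(sums$total - 1) > tol
  if (any(off)) {
    stop("fraction sums off by > ", tol, ": ",
         paste(paste0(sums$population[off], "/", sums$system[off], "=",
                      round(sums$total[off], 4)), collapse = ", "),
         call. = FALSE)
  }
  classes <- sort(unique(tbl$class))
  full <- tidyr::expand_grid(
    dplyr::distinct(tbl[, c("population", "system")]),
    class = classes
  )
  out <- dplyr::left_join(full, tbl,
                          by = c("population", "system", "class"))
  out$fraction[is.na(out$fraction)] <- 0
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$population, .data$system),
    fraction = .data$fraction / sum(.data$fraction)
  )
  dplyr::ungroup(out)
}

#' Sex-bias summary across marker systems
#'
#' For every population x origin class, contrasts the paternal and maternal
#' ancestry fractions: `delta = f_Y - f_mt`, the ratio `f_Y / f_mt`
#' (reported only when `f_mt > 0`) and the gap between the autosomal
#' fraction and the uniparental midpoint, `f_auto - (f_mt + f_Y) / 2`.
#' Classes with `|delta|` above `flag_threshold` are flagged as marked
#' bias. The threshold is a reporting convention of this package, recorded
#' in the output attributes.
#'
#' @param aligned Harmonised table from [harmonize_ancestry()] containing
#'   at least the mtDNA and Y systems.
#' @param flag_threshold Absolute delta above which a class is flagged
#'   (default 0.25).
#' @return Tibble of class `sex_bias_summary`: `population`, `class`,
#'   `f_mt`, `f_y`, `f_auto`, `delta`, `ratio`, `auto_midpoint_gap`,
#'   `marked_bias`.
#' @export
sex_bias_summary <- function(aligned, flag_threshold = 0.25) {
  wide <- tidyr::pivot_wider(aligned[, c("population", "system", "class",
                                         "fraction")],
                             names_from = "system", values_from = "fraction")
  if (!all(c("mtDNA", "Y") %in% names(wide))) {
    stop("need both mtDNA and Y systems", call. = FALSE)
  }
  if (!"autosomal" %in% names(wide)) wide$autosomal <- NA_real_
  out <- tibble::tibble(
    population = wide$population,
    class = wide$class,
    f_mt = wide$mtDNA,
    f_y = wide$Y,
    f_auto = wide$autosomal,
    delta = wide$Y - wide$mtDNA,
    ratio = ifelse(wide$mtDNA > 0, wide$Y / wide$mtDNA, NA_real_),
    auto_midpoint_gap = wide$autosomal - (wide$mtDNA + wide$Y) / 2,
    marked_bias = abs(wide$Y - wide$mtDNA) > flag_threshold
  )
  out <- dplyr::arrange(out, .data$population, .data$class)
  attr(out, "flag_threshold") <- flag_threshold
  class(out) <- c("sex_bias_summary", class(out))
  out
}

#' Stacked comparison table of ancestry by marker system
#'
#' The per-population stacked layout used to compare the ancestry profile
#' of each marker system side by side.
#'
#' @param aligned Harmonised table from [harmonize_ancestry()].
#' @return Wide tibble: one row per population x system, one column per
#'   class.
#' @export
ancestry_comparison_table <- function(aligned) {
  tidyr::pivot_wider(aligned[, c("population", "system", "class",
                                 "fraction")],
                     names_from = "class", values_from = "fraction")
}
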