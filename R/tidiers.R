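#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn ml_clock_ages Tidy node-age table of an ML clock fit.
#' @param x An `ml_clock_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ml_clock_fit <- function(x, ...) {
  out <- x$ages
  out$age_ka <- out$age_years / 1000
  out$n_tips <- vapply(out$node, function(v) {
    length(sample_leaves(x$tree, v))
  }, 0L)
  out
}

#' @describeIn ml_clock_ages One-row model summary of an ML clock fit.
#' @exportS3Method generics::glance
glance.ml_clock_fit <- function(x, ...) {
  tibble::tibble(
    lnL = x$lnL, converged = x$converged,
    clock = x$clock$name,
    years_per_substitution = x$clock$years_per_substitution,
    n_edges = sum(!is.na(x$tree$nodes$parent)),
    root_age_years = x$ages$age_years[x$tree$root]
  )
}

#' @describeIn lrt_clock Tidy one-row test summary.
#' @param x A `clock_lrt`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.clock_lrt <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 lnL_clock = x$lnL_clock, lnL_free = x$lnL_free)
}

#' @describeIn lrt_clock Alias of `tidy()` (the test is already one row).
#' @exportS3Method generics::glance
glance.clock_lrt <- function(x, ...) tidy(x)

#' Plot age estimates with their confidence intervals
#'
#' @param object Tibble of `age_estimate` rows (e.g. [clade_age_table()]).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.age_estimate <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- paste0(ifelse(is.na(df$haplogroup), df$node, df$haplogroup),
                     " [", df$method, "/", df$clock, "]")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_years / 1000,
                                   y = stats::reorder(.data$label,
                                                      .data$age_years))) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low / 1000,
                                          xmax = .data$ci_high / 1000)) +
    ggplot2::labs(x = "age (ka)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Stacked ancestry composition by marker system
#'
#' @param object A harmonised ancestry table ([harmonize_ancestry()]) or a
#'   `sex_bias_summary`.
#' @param ... Unused.
#' @return A ggplot: stacked fractions per population, faceted by system.
#' @exportS3Method ggplot2::autoplot
autoplot.sex_bias_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("population", "class", "f_mt", "f_y",
                                  "f_auto")],
    cols = c("f_mt", "f_y", "f_auto"),
    names_to = "system", values_to = "fraction"
  )
  long$system <- c(f_mt = "mtDNA", f_y = "Y", f_auto = "autosomal")[long$system]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$population,
                                     y = .data$fraction,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~system) +
    ggplot2::labs(y = "ancestry fraction", x = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a mutation tree
#'
#' Thin wrapper over ape's phylogram of [as_phylo()] with branch lengths in
#' counted mutations.
#'
#' @param x A [mutation_tree()].
#' @param ... Passed to [ape::plot.phylo].
#' @export
plot.mutation_tree <- function(x, ...) {
  ape::plot.phylo(as_phylo(x), ...)
}
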