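#' Maximum-likelihood node ages under a Poisson molecular clock
#'
#' Models each edge's counted mutations as
#' `count ~ Poisson((age_parent - age_child) / years_per_substitution)`,
#' with sample leaves fixed at age 0 and the constraint `parent >= child`.
#' The constrained problem is solved deterministically on the log-increment
#' parametrisation `age_v = max(child ages) + exp(z_v)` (constraints
#' implicit) with quasi-Newton (BFGS) ascent initialised at the rho ages,
#' followed by a cyclic coordinate-polish pass over the node ages.
#'
#' @param tree A [mutation_tree()].
#' @param clock A [clock_spec()] supplying the rate and counting rules.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_iter Cap on optimisation iterations; non-convergence warns
#'   and returns the best point found.
#' @return An object of class `ml_clock_fit`: list with `ages` (tibble
#'   `node`, `label`, `age_years`), `lnL`, `converged`, `clock`, `counts`,
#'   and the `tree`.
#' @export
ml_clock_ages <- function(tree, clock = clock_whole_molecule(),
                          tol = 1e-6, max_iter = 1e4) {
  cnt <- edge_counts(tree, clock$counted_classes, clock$hotspots)
  res <- fit_poisson_clock(tree, cnt, clock$years_per_substitution,
                           tol = tol, max_iter = max_iter)
  if (!res$converged) {
    warning("ML clock fit did not converge within ", max_iter,
            " iterations; returning best point")
  }
  ages <- tibble::tibble(node = seq_len(n_nodes(tree)),
                         label = tree$nodes$label,
                         age_years = res$age)
  structure(list(ages = ages, lnL = res$lnL, converged = res$converged,
                 clock = clock, counts = cnt, tree = tree),
            class = "ml_clock_fit")
}

# shared constrained-Poisson-clock engine; `pinned` optionally fixes one
# node's age (used by the profile CI)
fit_poisson_clock <- function(tree, cnt, y, pinned = NULL,
                              tol = 1e-6, max_iter = 1e4) {
  kids <- tree_children_list(tree)
  is_leaf <- lengths(kids) == 0L
  par <- tree$nodes$parent
  pin_node <- if (is.null(pinned)) 0L else as.integer(names(pinned)[1L])
  pin_age <- if (is.null(pinned)) 0 else unname(pinned[1L])
  free <- setdiff(which(!is_leaf), pin_node)
  po <- tree_postorder(tree)
  po_free <- po[po %in% free]
  edges <- which(!is.na(par))

  base_age <- numeric(n_nodes(tree))
  if (pin_node > 0L) base_age[pin_node] <- pin_age

  ages_from_z <- function(z) {
    age <- base_age
    for (j in seq_along(po_free)) {
      v <- po_free[j]
      age[v] <- max(age[kids[[v]]], 0) + exp(z[j])
    }
    age
  }
  lnL_of <- function(age) {
    sum(stats::dpois(cnt[edges], pmax(age[par[edges]] - age[edges], 0) / y,
                     log = TRUE))
  }
  neg <- function(z) {
    val <- -lnL_of(ages_from_z(z))
    if (!is.finite(val)) 1e12 else val
  }

  # rho-age initialisation
  age0 <- numeric(n_nodes(tree))
  sum_paths <- numeric(n_nodes(tree))
  n_below <- numeric(n_nodes(tree))
  for (v in po) {
    if (is_leaf[v]) {
      n_below[v] <- as.numeric(tree$nodes$type[v] == "sample")
      next
    }
    ch <- kids[[v]]
    sum_paths[v] <- sum(sum_paths[ch] + n_below[ch] * cnt[ch])
    n_below[v] <- sum(n_below[ch])
    r <- if (n_below[v] > 0) sum_paths[v] / n_below[v] else 0
    age0[v] <- max(r * y, age0[ch] + y * cnt[ch], y * 1e-3)
    if (v == pin_node) age0[v] <- pin_age
  }
  if (pin_node > 0L) {
    # keep initial descendant ages below the pinned age
    dsc <- descendants(tree, pin_node)
    mx <- max(age0[dsc], 0)
    if (mx > pin_age && mx > 0) age0[dsc] <- age0[dsc] * pin_age * 0.99 / mx
  }
  z0 <- vapply(seq_along(po_free), function(j) {
    v <- po_free[j]
    log(max(age0[v] - max(age0[kids[[v]]], 0), y * 1e-3))
  }, 0)

  if (length(z0) == 0L) {
    age <- ages_from_z(numeric(0))
    return(list(age = age, lnL = lnL_of(age), converged = TRUE))
  }
  opt <- stats::optim(z0, neg, method = "BFGS",
                      control = list(maxit = min(max_iter, 500L),
                                     reltol = 1e-12))
  age <- ages_from_z(opt$par)
  lnL <- -opt$value

  # coordinate polish: exact 1-D maximisation per free node age
  node_lnL <- function(v, a, age) {
    ll <- sum(stats::dpois(cnt[kids[[v]]],
                           pmax(a - age[kids[[v]]], 0) / y, log = TRUE))
    if (!is.na(par[v])) {
      ll <- ll + stats::dpois(cnt[v], pmax(age[par[v]] - a, 0) / y,
                              log = TRUE)
    }
    ll
  }
  stationary <- FALSE
  for (sweep in 1:8) {
    for (v in po_free) {
      lo <- max(age[kids[[v]]], 0)
      hi <- if (!is.na(par[v])) age[par[v]] else {
        lo + y * (sum(cnt[kids[[v]]]) + 1)
      }
      if (hi - lo > 1e-9) {
        o <- stats::optimize(function(a) node_lnL(v, a, age), c(lo, hi),
                             maximum = TRUE)
        cand <- c(lo + (hi - lo) * 1e-9, o$maximum, hi)
        val <- vapply(cand, node_lnL, 0, v = v, age = age)
        cur <- node_lnL(v, age[v], age)
        if (max(val) > cur) age[v] <- cand[which.max(val)]
      }
    }
    lnL_new <- lnL_of(age)
    stationary <- is.finite(lnL_new) && abs(lnL_new - lnL) < tol
    lnL <- lnL_new
    if (stationary) break
  }
  # converged when BFGS reports success or the exact coordinate-wise
  # maximisation finds no further improvement (stationarity)
  list(age = age, lnL = lnL, converged = opt$convergence == 0L || stationary)
}

#' @export
print.ml_clock_fit <- function(x, ...) {
  root <- x$tree$root
  cat("<ml_clock_fit> lnL = ", format(x$lnL, digits = 8),
      ", root age = ", round(x$ages$age_years[root]), " yr",
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' Profile-likelihood confidence interval for one ML node age
#'
#' Bisects on the profile log-likelihood (re-optimising all other node ages
#' with the target age pinned) for the bound where the likelihood-ratio
#' statistic equals the chi-square(1) quantile.
#'
#' @param fit An `ml_clock_fit`.
#' @param node Node id.
#' @param level Coverage (default 0.95).
#' @return Named numeric `c(lower, upper)` in years.
#' @export
ml_age_ci <- function(fit, node, level = 0.95) {
  crit <- stats::qchisq(level, df = 1) / 2
  tree <- fit$tree
  y <- fit$clock$years_per_substitution
  profile_lnL <- function(a0) {
    fit_poisson_clock(tree, fit$counts, y,
                      pinned = stats::setNames(a0, node))$lnL
  }
  hat <- fit$ages$age_years[node]
  lnL_hat <- fit$lnL
  bound <- function(direction) {
    step <- max(hat, y) * 0.5
    a <- hat
    repeat {
      a2 <- a + direction * step
      if (a2 < 0) a2 <- 0
      if (lnL_hat - profile_lnL(a2) >= crit || a2 == 0) break
      a <- a2
      step <- step * 2
      if (step > 1e7) return(if (direction < 0) 0 else Inf)
    }
    lo <- min(a, a2); hi <- max(a, a2)
    for (i in seq_len(30L)) {
      mid <- (lo + hi) / 2
      drop <- lnL_hat - profile_lnL(mid)
      outside <- drop >= crit
      if ((direction > 0 && outside) || (direction < 0 && !outside)) hi <- mid
      else lo <- mid
      if (hi - lo < max(1, hat * 1e-3)) break
    }
    (lo + hi) / 2
  }
  lower <- if (profile_lnL(0) >= lnL_hat - crit) 0 else bound(-1)
  c(lower = max(0, lower), upper = bound(1))
}

#' ML age estimate rows for labelled nodes
#'
#' @param fit An `ml_clock_fit`.
#' @param nodes Node ids (default: haplogroup-labelled internal nodes, or
#'   the root).
#' @param ci Compute profile-likelihood CIs (slower).
#' @return Tibble shaped like [rho_to_age()] output with `method = "ml"`.
#' @export
ml_age_table <- function(fit, nodes = NULL, ci = FALSE) {
  tree <- fit$tree
  if (is.null(nodes)) {
    nodes <- which(!is.na(tree$nodes$haplogroup))
    if (length(nodes) == 0L) nodes <- tree$root
  }
  rows <- purrr::map(nodes, function(v) {
    bounds <- if (ci) ml_age_ci(fit, v) else c(NA_real_, NA_real_)
    tibble::tibble(
      node = tree$nodes$label[v] %||% as.character(v),
      haplogroup = tree$nodes$haplogroup[v],
      method = "ml", clock = fit$clock$name,
      rho = NA_real_, sigma = NA_real_,
      age_years = fit$ages$age_years[v],
      ci_low = bounds[1L], ci_high = bounds[2L],
      n_tips = length(sample_leaves(tree, v))
    )
  })
  dplyr::bind_rows(rows)
}

#' Likelihood-ratio test for clock violation
#'
#' Compares the clock-constrained Poisson model (node ages shared across
#' descendants) with the saturated model in which each edge has its own
#' rate (`lambda_e = observed count`). The statistic
#' `2 (lnL_free - lnL_clock)` is referred to chi-square with
#' `#edges - #internal nodes` degrees of freedom.
#'
#' @param tree A [mutation_tree()].
#' @param clock A [clock_spec()].
#' @param fit Optional pre-computed `ml_clock_fit` for the same tree/clock.
#' @return An object of class `clock_lrt` with `lnL_clock`, `lnL_free`,
#'   `statistic`, `df`, `p_value`.
#' @export
lrt_clock <- function(tree, clock = clock_whole_molecule(), fit = NULL) {
  if (is.null(fit)) fit <- ml_clock_ages(tree, clock)
  cnt <- fit$counts[!is.na(tree$nodes$parent)]
  lnL_free <- sum(stats::dpois(cnt, cnt, log = TRUE))
  stat <- max(0, 2 * (lnL_free - fit$lnL))
  kids <- tree_children_list(tree)
  n_internal <- sum(lengths(kids) > 0L)
  df <- length(cnt) - n_internal
  structure(list(lnL_clock = fit$lnL, lnL_free = lnL_free,
                 statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 fit = fit),
            class = "clock_lrt")
}

#' @export
print.clock_lrt <- function(x, ...) {
  cat("<clock_lrt> 2*dlnL = ", format(x$statistic, digits = 5),
      ", df = ", x$df, ", p = ", format.pval(x$p_value, digits = 4), "\n",
      sep = "")
  invisible(x)
}
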