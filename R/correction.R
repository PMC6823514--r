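## Autosomal-rate correction of X-linked branch lengths, per-group averaging,
## and the standard statistical plumbing (Welch tests and intervals,
## Benjamini-Hochberg correction, Mann-Whitney U).

#' Per-species cumulative branch lengths with replicate distributions
#'
#' @param species character vector of species (or group) labels.
#' @param group group tag per species (`"snake"`, `"agamid"`, ...).
#' @param replicates numeric matrix, one row per species, one column per
#'   bootstrap/simulation replicate.
#' @return object of class `grouped_lengths`; medians and percentile CIs are
#'   computed row-wise.
#' @export
grouped_lengths <- function(species, group, replicates) {
  replicates <- as.matrix(replicates)
  stopifnot(length(species) == nrow(replicates),
            length(group) == length(species))
  if (any(replicates < 0)) stop("negative lengths")
  rownames(replicates) <- species
  structure(list(species = species, group = group, replicates = replicates),
            class = "grouped_lengths")
}

#' @export
print.grouped_lengths <- function(x, ...) {
  med <- apply(x$replicates, 1, stats::median)
  qs <- t(apply(x$replicates, 1, stats::quantile, c(0.025, 0.975)))
  print(data.frame(species = x$species, group = x$group, median = med,
                   ci_low = qs[, 1], ci_high = qs[, 2]), row.names = FALSE)
  invisible(x)
}

#' Correct X-linked lengths by deviations of autosomal lengths
#'
#' Removes lineage rate effects: each focal species' X-linked length is
#' corrected by how much its autosomal length deviates from the mean
#' autosomal length of the focal species set,
#' `corrected_i = x_i - (a_i - mean_j(a_j))`. A fast-evolving lineage (long
#' autosomal branch) is shortened; a slow one is lengthened. Applied
#' replicate-wise, matching replicates by index, so uncertainty propagates.
#' Only species in `focal` groups are corrected; focal species without an
#' autosomal estimate are excluded from the mean and flagged.
#'
#' @param x_lengths,a_lengths [grouped_lengths()] for the X-linked gene set
#'   and the autosomal gene set (same replicate count).
#' @param focal group tags to correct (default: all groups in `x_lengths`).
#' @return corrected [grouped_lengths()] with attribute `missing_autosomal`.
#' @export
autosomal_correction <- function(x_lengths, a_lengths, focal = NULL) {
  if (is.null(focal)) focal <- unique(x_lengths$group)
  fsp <- x_lengths$species[x_lengths$group %in% focal]
  have <- fsp[fsp %in% a_lengths$species]
  miss <- setdiff(fsp, have)
  if (length(miss) > 0)
    warning("no autosomal estimate for: ", paste(miss, collapse = ", "))
  if (length(have) == 0) stop("no focal species with autosomal estimates")
  if (ncol(x_lengths$replicates) != ncol(a_lengths$replicates))
    stop("replicate counts differ between X-linked and autosomal inputs")
  amean <- colMeans(a_lengths$replicates[have, , drop = FALSE])
  out <- x_lengths$replicates
  for (sp in have) {
    dev <- a_lengths$replicates[sp, ] - amean
    out[sp, ] <- pmax(x_lengths$replicates[sp, ] - dev, 0)
  }
  res <- grouped_lengths(x_lengths$species, x_lengths$group, out)
  attr(res, "missing_autosomal") <- miss
  res
}

#' Replicate-wise per-group averages
#'
#' Averages species values within each group, replicate by replicate,
#' yielding one row per group.
#'
#' @param lengths a [grouped_lengths()].
#' @param groups groups to keep (default all).
#' @return a [grouped_lengths()] with one row per group.
#' @export
group_average <- function(lengths, groups = NULL) {
  if (is.null(groups)) groups <- unique(lengths$group)
  reps <- lapply(groups, function(g) {
    rows <- lengths$group == g
    if (!any(rows)) stop("empty group: ", g)
    colMeans(lengths$replicates[rows, , drop = FALSE])
  })
  grouped_lengths(groups, groups, do.call(rbind, reps))
}

#' Welch statistics and multiplicity correction
#'
#' Thin wrappers over the standard R tests, named for how they enter the
#' pipeline: `welch_ci()` is the Welch (t-based) interval for a mean,
#' `welch_test()` the Welch two-sample t-test p-value, `bh_adjust()` the
#' Benjamini-Hochberg step-up adjustment, `mann_whitney()` the two-sided
#' Mann-Whitney U p-value.
#'
#' @param values,a,b numeric samples (>= 2 values each).
#' @param level confidence level.
#' @param pvalues numeric vector of p-values.
#' @return `welch_ci`: named vector `(mean, low, high)`; the tests: a
#'   p-value; `bh_adjust`: adjusted p-values.
#' @export
welch_ci <- function(values, level = 0.95) {
  stopifnot(length(values) >= 2)
  if (stats::sd(values) == 0) {
    # degenerate-variance flag: CI collapses to the point
    return(structure(c(mean = mean(values), low = mean(values),
                       high = mean(values)), degenerate = TRUE))
  }
  tt <- stats::t.test(values, conf.level = level)
  c(mean = unname(tt$estimate), low = tt$conf.int[1], high = tt$conf.int[2])
}

#' @rdname welch_ci
#' @export
welch_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(structure(if (mean(a) == mean(b)) 1 else 0, degenerate = TRUE))
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' @rdname welch_ci
#' @export
bh_adjust <- function(pvalues) stats::p.adjust(pvalues, method = "BH")

#' @rdname welch_ci
#' @export
mann_whitney <- function(a, b) {
  stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE)$p.value
}

#' Rescale simulated values onto the observed scale
#'
#' Simulations run at balanced base composition; real sequences do not. All
#' simulated values are multiplied by the ratio of the observed to the
#' simulated reference-group median, so the reference group (one not
#' differentially affected by the scenarios) matches by construction and
#' within-simulation ratios are preserved exactly.
#'
#' @param x numeric simulated values to rescale.
#' @param sim_reference simulated values of the reference group.
#' @param obs_reference observed values of the reference group.
#' @return rescaled `x`, with the factor as attribute `scale_factor`.
#' @export
rescale_simulated <- function(x, sim_reference, obs_reference) {
  sm <- stats::median(sim_reference)
  if (sm == 0) stop("zero simulated reference median; cannot rescale")
  f <- stats::median(obs_reference) / sm
  structure(x * f, scale_factor = f)
}
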