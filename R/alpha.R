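## Male mutation bias (alpha = male/female mutation rate ratio) from
## chromosomal substitution rates, via Miyata's three equations. The X, Y and
## autosomes spend 1/3, 1 and 1/2 of their time in males, so their relative
## rates are informative about alpha:
##   alpha(Y/X) = 2 / (3X/Y - 1)
##   alpha(Y/A) = 1 / (2A/Y - 1)
##   alpha(X/A) = (4 - 3X/A) / (3X/A - 2)

#' Miyata's alpha from two chromosomal substitution rates
#'
#' Vectorized closed forms. Out-of-domain inputs return `NA` (the pole
#' regime, where the implied alpha diverges); values below 1 are returned
#' as computed (visible out-of-model pathology) rather than clipped.
#'
#' @param X,Y,A substitution rates (> 0) of X-linked, Y-linked and autosomal
#'   sequences.
#' @return numeric alpha estimate(s); `NA` where undefined.
#' @export
alpha_yx <- function(X, Y) {
  den <- 3 * (X / Y) - 1   # ratio first: exactly 1 on equal rates
  ifelse(X > 0 & Y > 0 & den > 0, 2 / den, NA_real_)
}

#' @rdname alpha_yx
#' @export
alpha_ya <- function(Y, A) {
  den <- 2 * (A / Y) - 1
  ifelse(Y > 0 & A > 0 & den > 0, 1 / den, NA_real_)
}

#' @rdname alpha_yx
#' @export
alpha_xa <- function(X, A) {
  r <- 3 * (X / A)
  ifelse(X > 0 & A > 0 & r - 2 > 0, (4 - r) / (r - 2), NA_real_)
}

#' Expected rate ratio implied by an alpha value
#'
#' Inverse of the Miyata equations: the ratio of the first chromosome's rate
#' to the second expected under male mutation bias `alpha`. `XA` gives
#' `2(2+alpha)/(3(1+alpha))`, `YA` gives `2*alpha/(1+alpha)`, `YX` gives
#' `3*alpha/(2+alpha)`.
#'
#' @param comparison `"XA"`, `"YA"` or `"YX"`.
#' @param alpha alpha value(s); a warning is issued below 1.
#' @return expected rate ratio(s).
#' @export
expected_ratio <- function(comparison = c("XA", "YA", "YX"), alpha) {
  comparison <- match.arg(comparison)
  if (any(alpha < 1)) warning("alpha < 1 is outside the male-bias model")
  switch(comparison,
         XA = 2 * (2 + alpha) / (3 * (1 + alpha)),
         YA = 2 * alpha / (1 + alpha),
         YX = 3 * alpha / (2 + alpha))
}

#' Rate triple: X, Y and autosomal rates with bootstrap distributions
#'
#' @param X,Y,A [bootstrap_distribution()]s of the three chromosomal rates.
#' @return object of class `rate_triple`.
#' @export
rate_triple <- function(X, Y, A) {
  stopifnot(inherits(X, "bootstrap_dist"), inherits(Y, "bootstrap_dist"),
            inherits(A, "bootstrap_dist"))
  structure(list(X = X, Y = Y, A = A), class = "rate_triple")
}

#' @export
print.rate_triple <- function(x, ...) {
  cat("Chromosomal substitution rates (median [95% CI])\n")
  for (cl in c("X", "Y", "A")) print(x[[cl]])
  invisible(x)
}

#' Alpha with a replicate-propagated confidence interval
#'
#' The point estimate applies the Miyata equation to the median rates; the
#' interval applies it to the bootstrap replicates matched by replicate index
#' and takes percentile bounds. Undefined replicates (pole regime) are
#' excluded and counted; the estimate is flagged unstable when more than half
#' the replicates are undefined.
#'
#' @param rates a [rate_triple()].
#' @param comparison `"YX"`, `"YA"` or `"XA"`.
#' @param level CI level.
#' @return object of class `alpha_estimate`: `comparison`, `alpha`,
#'   `ci_low`, `ci_high`, `n_replicates`, `n_undefined`, `unstable`.
#' @export
alpha_with_ci <- function(rates, comparison = c("YX", "YA", "XA"),
                          level = 0.95) {
  comparison <- match.arg(comparison)
  f <- switch(comparison,
              YX = function(r) alpha_yx(r$X$values, r$Y$values),
              YA = function(r) alpha_ya(r$Y$values, r$A$values),
              XA = function(r) alpha_xa(r$X$values, r$A$values))
  point <- switch(comparison,
                  YX = alpha_yx(rates$X$median, rates$Y$median),
                  YA = alpha_ya(rates$Y$median, rates$A$median),
                  XA = alpha_xa(rates$X$median, rates$A$median))
  reps <- f(rates)
  ok <- reps[!is.na(reps)]
  n_undef <- sum(is.na(reps))
  unstable <- n_undef > length(reps) / 2
  qs <- if (length(ok) > 0)
    stats::quantile(ok, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  else c(NA_real_, NA_real_)
  structure(list(comparison = comparison, alpha = as.numeric(point),
                 ci_low = qs[1], ci_high = qs[2],
                 n_replicates = length(reps), n_undefined = n_undef,
                 unstable = unstable, replicates = reps),
            class = "alpha_estimate")
}

#' @export
print.alpha_estimate <- function(x, ...) {
  cat("alpha(", x$comparison, ") = ", format(x$alpha), " [",
      format(x$ci_low), ", ", format(x$ci_high), "]",
      if (x$unstable) "  UNSTABLE (>50% replicates undefined)",
      "\n", sep = "")
  invisible(x)
}

#' Estimate male mutation bias from X/Y/A intronic alignments
#'
#' The package's alpha estimator. Intronic pairwise alignments labelled by
#' chromosome class are filtered ([filter_introns()]), each class is
#' summarized by the TN93 distance on its concatenate with an
#' intron-by-site [double_bootstrap()], and Miyata's three equations are
#' applied to the median rates, with percentile intervals propagated
#' replicate-wise.
#'
#' @param introns an [intron_set()] with X, Y and A genes.
#' @param n_boot double-bootstrap replicates per class.
#' @param seed integer seed.
#' @param filter apply [filter_introns()] first.
#' @param min_total gene-level column floor passed to the filter.
#' @param level CI level.
#' @return object of class `alpha_fit` with methods `print`, `summary`,
#'   `coef` and `confint`.
#' @export
estimate_alpha <- function(introns, n_boot = 1000, seed = NULL, filter = TRUE,
                           min_total = 1000, level = 0.95) {
  audit <- NULL
  if (filter) {
    introns <- filter_introns(introns, min_total = min_total)
    audit <- attr(introns, "audit")
  }
  dists <- list()
  for (cl in c("X", "Y", "A")) {
    pool <- pool_introns(introns, cl)
    if (length(pool) < 2)
      stop("fewer than 2 introns in class ", cl, " after filtering")
    bseed <- if (is.null(seed)) NULL else derive_seed(seed, match(cl, c("X", "Y", "A")))
    dists[[cl]] <- double_bootstrap(pool, n = n_boot, seed = bseed,
                                    label = paste0("rate_", cl))
  }
  rates <- rate_triple(dists$X, dists$Y, dists$A)
  ests <- lapply(c("YX", "YA", "XA"), function(cmp)
    alpha_with_ci(rates, cmp, level = level))
  names(ests) <- c("YX", "YA", "XA")
  structure(list(rates = rates, estimates = ests, n_boot = n_boot,
                 seed = seed, level = level, audit = audit,
                 call = match.call()),
            class = "alpha_fit")
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat("Male mutation bias fit (", x$n_boot, " double-bootstrap replicates)\n",
      sep = "")
  for (e in x$estimates) print(e)
  invisible(x)
}

#' @export
summary.alpha_fit <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$estimates, function(e)
    data.frame(comparison = e$comparison, alpha = e$alpha,
               ci_low = e$ci_low, ci_high = e$ci_high,
               n_replicates = e$n_replicates, n_undefined = e$n_undefined)))
  rownames(tab) <- NULL
  structure(list(table = tab, rates = object$rates, n_boot = object$n_boot,
                 audit = object$audit),
            class = "summary.alpha_fit")
}

#' @export
print.summary.alpha_fit <- function(x, ...) {
  print(x$rates)
  cat("\nMiyata alpha estimates:\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$audit))
    cat("\nFilter ledger:", sum(x$audit$retained), "of", nrow(x$audit),
        "genes retained\n")
  invisible(x)
}

#' @export
coef.alpha_fit <- function(object, ...) {
  vapply(object$estimates, function(e) e$alpha, 0)
}

#' @export
confint.alpha_fit <- function(object, parm, level, ...) {
  m <- t(vapply(object$estimates, function(e) c(e$ci_low, e$ci_high),
                numeric(2)))
  colnames(m) <- c("2.5 %", "97.5 %")
  m
}

#' Write an alpha fit as TSV
#'
#' Columns: comparison, alpha, ci_low, ci_high, n_replicates, n_undefined.
#'
#' @param fit an [estimate_alpha()] result.
#' @param file output path.
#' @param ... passed to [write_tsv_report()].
#' @export
write_alpha_tsv <- function(fit, file, ...) {
  tab <- summary(fit)$table
  write_tsv_report(tab, file, ...)
  invisible(tab)
}
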