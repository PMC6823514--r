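## Resampling schemes: the intron-by-site double bootstrap used for the
## two-species X/Y/A rate estimates, and the codon bootstrap of concatenated
## coding alignments with median-consensus trees.

#' Bootstrap distributions
#'
#' @param label statistic label.
#' @param values replicate values (NA allowed for undefined replicates, e.g.
#'   saturated distances; they are excluded from the median and CI and
#'   counted).
#' @param level CI level (percentile bootstrap).
#' @return object of class `bootstrap_dist` with `median`, `ci_low`,
#'   `ci_high`, `values`, `n_undefined`.
#' @export
bootstrap_distribution <- function(label, values, level = 0.95) {
  ok <- values[!is.na(values)]
  if (length(ok) == 0) stop("all replicate values undefined")
  qs <- stats::quantile(ok, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(list(label = label, values = values,
                 median = stats::median(ok),
                 ci_low = qs[1], ci_high = qs[2], level = level,
                 n_undefined = sum(is.na(values))),
            class = "bootstrap_dist")
}

#' @export
print.bootstrap_dist <- function(x, ...) {
  cat(x$label, ": median ", format(x$median), " [",
      format(x$ci_low), ", ", format(x$ci_high), "] (",
      length(x$values), " replicates",
      if (x$n_undefined > 0) paste0(", ", x$n_undefined, " undefined"),
      ")\n", sep = "")
  invisible(x)
}

## Internal: 17-category column counts for a pair alignment (16 ordered base
## pairs + 1 excluded class). Sufficient statistic for TN93 on a concatenate,
## which turns the double bootstrap into cheap multinomial algebra.
pair_counts17 <- function(aln) {
  ia <- match(toupper(aln[1, ]), BASES)
  ib <- match(toupper(aln[2, ]), BASES)
  cat <- ifelse(is.na(ia) | is.na(ib), 17L, (ia - 1L) * 4L + ib)
  tabulate(cat, nbins = 17L)
}

tn93_from_counts17 <- function(c17) {
  counts <- matrix(c17[1:16], 4, byrow = TRUE)
  if (sum(counts) == 0) return(NA_real_)
  as.numeric(tn93_from_counts(counts))
}

#' Double bootstrap of an intron set (introns, then sites)
#'
#' Each replicate resamples introns with replacement to the original intron
#' count, then resamples columns with replacement from the concatenated
#' resample to the original total column count, and computes the statistic.
#' The default statistic is the TN93 distance on the concatenate, for which
#' only column-category counts matter, so both resampling stages reduce to
#' exact multinomial draws on counts; an arbitrary `statistic`
#' (`function(pair_alignment)`) falls back to explicit column resampling.
#'
#' @param introns list of pairwise alignments (2 x L character matrices).
#' @param n number of replicates.
#' @param seed integer seed.
#' @param statistic `NULL` for TN93-on-concatenate, or a function of a 2-row
#'   character matrix returning a scalar.
#' @param label statistic label on the result.
#' @return a [bootstrap_distribution()]; saturated/undefined replicates are
#'   NA and counted.
#' @export
double_bootstrap <- function(introns, n = 1000, seed = NULL, statistic = NULL,
                             label = "tn93_concatenate") {
  stopifnot(length(introns) >= 2)
  if (!is.null(seed)) set.seed(seed)
  k <- length(introns)
  if (is.null(statistic)) {
    cmat <- vapply(introns, pair_counts17, numeric(17))  # 17 x k
    total <- sum(cmat)
    vals <- vapply(seq_len(n), function(i) {
      pick <- sample.int(k, k, replace = TRUE)
      cts <- rowSums(cmat[, pick, drop = FALSE])
      res <- stats::rmultinom(1, total, cts / sum(cts))[, 1]
      tn93_from_counts17(res)
    }, 0)
  } else {
    total <- sum(vapply(introns, ncol, 0L))
    vals <- vapply(seq_len(n), function(i) {
      pick <- sample.int(k, k, replace = TRUE)
      cc <- do.call(cbind, introns[pick])
      cols <- sample.int(ncol(cc), total, replace = TRUE)
      statistic(cc[, cols, drop = FALSE])
    }, 0)
  }
  bootstrap_distribution(label, vals)
}

#' Codon bootstrap of a concatenated coding alignment
#'
#' Resamples codons (aligned triplets, all taxa jointly) with replacement to
#' the original codon count.
#'
#' @param aln character matrix (taxa x sites), columns a multiple of 3.
#' @param n number of resampled alignments.
#' @param seed integer seed.
#' @return list of `n` character matrices, each the size of `aln`.
#' @export
codon_bootstrap <- function(aln, n = 100, seed = NULL) {
  if (ncol(aln) %% 3 != 0) stop("alignment length not divisible by 3")
  if (!is.null(seed)) set.seed(seed)
  nc <- ncol(aln) %/% 3
  lapply(seq_len(n), function(i) {
    cod <- sample.int(nc, nc, replace = TRUE)
    cols <- rep((cod - 1L) * 3L, each = 3L) + rep(1:3, nc)
    aln[, cols, drop = FALSE]
  })
}

#' Median-consensus tree over bootstrap branch-length trees
#'
#' Takes the per-branch median across replicate trees of identical topology;
#' the full per-branch replicate matrix is retained as attribute
#' `edge_replicates` (branches x replicates) so intervals can be propagated.
#'
#' @param trees list of `species_tree`s (same topology, substitutions units).
#' @return a `species_tree` with median branch lengths.
#' @export
consensus_tree <- function(trees) {
  stopifnot(length(trees) >= 1)
  ref <- trees[[1]]
  for (tr in trees[-1]) {
    if (!identical(tr$edge, ref$edge) ||
        !identical(tr$tip.label, ref$tip.label))
      stop("topology mismatch across replicate trees")
  }
  M <- vapply(trees, function(tr) tr$edge.length, numeric(nrow(ref$edge)))
  if (is.null(dim(M))) M <- matrix(M, nrow = 1)
  ref$edge.length <- apply(M, 1, stats::median)
  attr(ref, "edge_replicates") <- M
  ref
}

#' Write bootstrap replicate values as TSV
#'
#' @param dist a [bootstrap_distribution()].
#' @param file output path.
#' @param ... passed to [write_tsv_report()].
#' @export
write_bootstrap_tsv <- function(dist, file, ...) {
  tab <- data.frame(replicate_id = seq_along(dist$values),
                    statistic = dist$label, value = dist$values)
  write_tsv_report(tab, file, ...)
  invisible(tab)
}
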