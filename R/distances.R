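## Substitution rate estimation: closed-form pairwise Tamura-Nei (TN93)
## distances, a synonymous-rate proxy on fourfold degenerate third codon
## positions, and least-squares branch lengths on a fixed topology.

## Internal: 4x4 ordered base-pair counts for an aligned pair, plus the
## number of excluded (non-ACGT in either sequence) columns. This count
## matrix is the sufficient statistic for the TN93 estimator, which is what
## makes the resampling schemes cheap: a bootstrap replicate is a resample
## of counts, never of characters.
pair_counts <- function(seqA, seqB) {
  ia <- match(seqA, BASES)
  ib <- match(seqB, BASES)
  ok <- !is.na(ia) & !is.na(ib)
  counts <- matrix(tabulate((ia[ok] - 1L) * 4L + ib[ok], nbins = 16L),
                   nrow = 4, byrow = TRUE, dimnames = list(BASES, BASES))
  list(counts = counts, excluded = sum(!ok))
}

#' TN93 distance from a 4x4 ordered base-pair count matrix
#'
#' The closed-form Tamura-Nei (1993) estimator: base frequencies are averaged
#' over both sequences, and the two transition classes (A/G and C/T) are
#' corrected separately from transversions. Returns `NA` with attribute
#' `saturated = TRUE` when a logarithm argument is non-positive (distance
#' undefined at saturation).
#'
#' @param counts 4x4 matrix, `counts[a, b]` = columns with base `a` in the
#'   first and `b` in the second sequence (A, C, G, T order).
#' @return numeric distance in expected substitutions per site.
#' @export
tn93_from_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) stop("zero usable sites")
  f <- (rowSums(counts) + colSums(counts)) / (2 * n)  # A C G T
  fA <- f[1]; fC <- f[2]; fG <- f[3]; fT <- f[4]
  gR <- fA + fG; gY <- fC + fT
  P1 <- (counts[1, 3] + counts[3, 1]) / n             # A<->G
  P2 <- (counts[2, 4] + counts[4, 2]) / n             # C<->T
  Q <- (n - sum(diag(counts)) - counts[1, 3] - counts[3, 1] -
          counts[2, 4] - counts[4, 2]) / n
  sat <- FALSE
  d <- 0
  if (fA * fG > 0) {
    w1 <- 1 - gR * P1 / (2 * fA * fG) - Q / (2 * gR)
    if (w1 <= 0) sat <- TRUE else d <- d - (2 * fA * fG / gR) * log(w1)
  } else if (P1 > 0) sat <- TRUE
  if (fC * fT > 0) {
    w2 <- 1 - gY * P2 / (2 * fC * fT) - Q / (2 * gY)
    if (w2 <= 0) sat <- TRUE else d <- d - (2 * fC * fT / gY) * log(w2)
  } else if (P2 > 0) sat <- TRUE
  if (gR * gY > 0) {
    w3 <- 1 - Q / (2 * gR * gY)
    k3 <- 2 * (gR * gY - fA * fG * gY / gR - fC * fT * gR / gY)
    if (w3 <= 0) sat <- TRUE else d <- d - k3 * log(w3)
  } else if (Q > 0) sat <- TRUE
  if (sat) return(structure(NA_real_, saturated = TRUE))
  unname(d)
}

#' Pairwise Tamura-Nei (TN93) distance
#'
#' Columns containing anything other than A, C, G or T in either sequence are
#' excluded (complete deletion per pair) and counted. Saturated pairs (a
#' correction logarithm with non-positive argument) are returned as `NA` with
#' a flag, so downstream medians can exclude rather than truncate them.
#'
#' @param seqA,seqB equal-length aligned sequences (character vectors of
#'   single bases, or single strings).
#' @param method label stored on the result.
#' @return object of class `pairwise_distance`: list with `distance`,
#'   `usable_sites`, `excluded_sites`, `saturated`, `method`.
#' @export
tn93 <- function(seqA, seqB, method = "TN93") {
  if (length(seqA) == 1L && nchar(seqA[1]) > 1L) seqA <- strsplit(seqA, "")[[1]]
  if (length(seqB) == 1L && nchar(seqB[1]) > 1L) seqB <- strsplit(seqB, "")[[1]]
  if (length(seqA) != length(seqB)) stop("sequences must be aligned (equal length)")
  pc <- pair_counts(toupper(seqA), toupper(seqB))
  if (sum(pc$counts) == 0) stop("zero usable sites")
  d <- tn93_from_counts(pc$counts)
  structure(list(distance = as.numeric(d),
                 usable_sites = sum(pc$counts),
                 excluded_sites = pc$excluded,
                 saturated = isTRUE(attr(d, "saturated")),
                 method = method),
            class = "pairwise_distance")
}

#' @export
print.pairwise_distance <- function(x, ...) {
  cat(x$method, "distance:",
      if (x$saturated) "saturated (undefined)" else format(x$distance),
      "over", x$usable_sites, "sites\n")
  invisible(x)
}

#' All pairwise TN93 distances of an alignment
#'
#' @param aln character matrix (taxa x sites).
#' @param warn warn when pairs are saturated.
#' @return square symmetric matrix (NA on saturated pairs).
#' @export
tn93_matrix <- function(aln, warn = TRUE) {
  taxa <- rownames(aln)
  n <- nrow(aln)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  nsat <- 0L
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d <- tn93(aln[i, ], aln[j, ])
    if (d$saturated) nsat <- nsat + 1L
    D[i, j] <- D[j, i] <- d$distance
  }
  if (nsat > 0 && warn)
    warning(nsat, " saturated pair(s) returned as NA")
  D
}

## Codon prefixes whose third position is fourfold degenerate.
FOURFOLD_PREFIXES <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Extract doubly fourfold degenerate third codon positions
#'
#' Returns the third positions of codons whose first two bases are identical
#' in both sequences and belong to a fourfold degenerate family (Leu CTN,
#' Val GTN, Ser TCN, Pro CCN, Thr ACN, Ala GCN, Arg CGN, Gly GGN), so any
#' change at the extracted site is synonymous in both sequences. Codons with
#' gaps or ambiguity are excluded; internal stop codons are excluded and
#' counted separately.
#'
#' @param seqA,seqB aligned in-frame coding sequences (character vectors,
#'   length divisible by 3).
#' @return list: `aln` (2 x k character matrix of third positions),
#'   `n_codons`, `n_fourfold`, `n_stop`.
#' @export
fourfold_sites <- function(seqA, seqB) {
  if (length(seqA) == 1L && nchar(seqA[1]) > 1L) seqA <- strsplit(seqA, "")[[1]]
  if (length(seqB) == 1L && nchar(seqB[1]) > 1L) seqB <- strsplit(seqB, "")[[1]]
  L <- length(seqA)
  if (L != length(seqB)) stop("sequences must be aligned")
  if (L %% 3 != 0) stop("alignment length not divisible by 3")
  seqA <- toupper(seqA); seqB <- toupper(seqB)
  nc <- L %/% 3
  i1 <- seq(1, L, by = 3)
  preA <- paste0(seqA[i1], seqA[i1 + 1])
  preB <- paste0(seqB[i1], seqB[i1 + 1])
  codA <- paste0(preA, seqA[i1 + 2])
  codB <- paste0(preB, seqB[i1 + 2])
  is_stop <- codA %in% STOP_CODONS | codB %in% STOP_CODONS
  ok <- !is_stop & preA == preB & preA %in% FOURFOLD_PREFIXES &
    seqA[i1 + 2] %in% BASES & seqB[i1 + 2] %in% BASES
  sel <- i1[ok] + 2
  list(aln = rbind(seqA[sel], seqB[sel]),
       n_codons = nc, n_fourfold = sum(ok), n_stop = sum(is_stop))
}

#' Synonymous divergence proxy: TN93 on fourfold degenerate sites
#'
#' Applies [tn93()] to the third positions extracted by [fourfold_sites()].
#' Pairs with fewer usable sites than `min_sites` are flagged (`below_floor`)
#' so they can be excluded from concatenate-level medians.
#'
#' @param seqA,seqB aligned in-frame coding sequences.
#' @param min_sites minimum usable fourfold sites.
#' @return a `pairwise_distance` (method `"TN93_4fold"`) with extra fields
#'   `n_codons`, `n_stop`, `below_floor`.
#' @export
ds_proxy <- function(seqA, seqB, min_sites = 50) {
  ff <- fourfold_sites(seqA, seqB)
  if (ff$n_fourfold == 0) stop("no fourfold degenerate sites shared by the pair")
  d <- tn93(ff$aln[1, ], ff$aln[2, ], method = "TN93_4fold")
  d$n_codons <- ff$n_codons
  d$n_stop <- ff$n_stop
  d$below_floor <- d$usable_sites < min_sites
  d
}

## Internal: per-tip edge index sets and the pair design matrix used by the
## OLS fit. Binary roots are unidentifiable from leaf-leaf distances (their
## two edges only ever appear together), so those two columns are merged.
path_design <- function(tree) {
  ntip <- ape::Ntip(tree)
  ne <- nrow(tree$edge)
  tip_edges <- lapply(seq_len(ntip), function(i) path_edges_to_root(tree, i))
  pairs <- utils::combn(ntip, 2)
  A <- matrix(0L, ncol(pairs), ne)
  for (p in seq_len(ncol(pairs))) {
    e1 <- tip_edges[[pairs[1, p]]]
    e2 <- tip_edges[[pairs[2, p]]]
    path <- c(setdiff(e1, e2), setdiff(e2, e1))
    A[p, path] <- 1L
  }
  root <- ntip + 1L
  root_edges <- which(tree$edge[, 1] == root)
  merged <- NULL
  if (length(root_edges) == 2L) {
    ## crossing paths contain both root edges; the merged column is the
    ## indicator of crossing, so its coefficient is the summed root length
    A[, root_edges[1]] <- as.integer(A[, root_edges[1]] + A[, root_edges[2]] > 0)
    A <- A[, -root_edges[2], drop = FALSE]
    merged <- root_edges
  }
  list(A = A, pairs = pairs, merged = merged)
}

#' Least-squares branch lengths on a fixed topology
#'
#' Least squares on the path-indicator design matrix: each pairwise distance
#' is modeled as the sum of the branch lengths on the path joining the pair.
#' Negative estimates are clamped to zero and the remaining branches refit
#' (active-set passes until all estimates are non-negative). With a binary
#' root the two root branches are only identified through their sum; the
#' fitted sum is split between them in proportion to the input tree's
#' lengths (equally if those are zero).
#'
#' `weighting = "ols"` is ordinary least squares; `"fm"` applies
#' Fitch-Margoliash inverse-square weights `1/d^2`, which keeps noisy
#' near-saturated deep pairs (e.g. to distant outgroups) from contaminating
#' shallow branch estimates. Both recover additive matrices exactly.
#'
#' @param topology a `species_tree`; topology is fixed, lengths are ignored
#'   except to apportion a binary root.
#' @param D square symmetric distance matrix over the tree's tips (complete:
#'   no NA).
#' @param weighting `"ols"` (default) or `"fm"`.
#' @return a `species_tree` in `"subs"` units with fitted branch lengths and
#'   attribute `rss` (residual sum of squares).
#' @export
fit_branch_lengths <- function(topology, D, weighting = c("ols", "fm")) {
  weighting <- match.arg(weighting)
  taxa <- topology$tip.label
  if (!all(taxa %in% rownames(D)))
    stop("distance matrix does not cover all tree tips")
  D <- D[taxa, taxa]
  if (any(is.na(D[upper.tri(D)])))
    stop("distance matrix contains NA (saturated pairs?); complete it first")
  des <- path_design(topology)
  y <- D[cbind(des$pairs[1, ], des$pairs[2, ])]
  A <- des$A
  k <- ncol(A)
  if (qr(A)$rank < k)
    stop("singular design: branch lengths not identifiable on this topology")
  w <- if (weighting == "fm") 1 / pmax(y, 1e-4)^2 else rep(1, length(y))
  free <- rep(TRUE, k)
  beta <- rep(0, k)
  for (iter in seq_len(k)) {
    fit <- stats::lm.wfit(A[, free, drop = FALSE], y, w)
    b <- fit$coefficients
    if (all(b >= -1e-12)) { beta[free] <- pmax(b, 0); break }
    neg <- which(free)[b < -1e-12]
    free[neg] <- FALSE
    beta[neg] <- 0
    if (!any(free)) break
  }
  rss <- sum(w * (y - A %*% beta)^2)
  out <- topology
  lens <- numeric(nrow(topology$edge))
  if (!is.null(des$merged)) {
    keep <- seq_len(nrow(topology$edge))[-des$merged[2]]
    lens[keep] <- beta
    tot <- lens[des$merged[1]]
    w <- topology$edge.length[des$merged]
    w <- if (sum(w) > 0) w / sum(w) else c(0.5, 0.5)
    lens[des$merged] <- tot * w
  } else {
    lens <- beta
  }
  out$edge.length <- lens
  attr(out, "units") <- "subs"
  attr(out, "lineages") <- tree_lineages(topology)
  attr(out, "rss") <- rss
  out
}

#' Write a distance matrix as square TSV
#'
#' @param D square matrix with taxa dimnames.
#' @param file output path.
#' @param ... passed to [write_tsv_report()].
#' @export
write_distance_matrix <- function(D, file, ...) {
  tab <- data.frame(taxon = rownames(D), as.data.frame(D), check.names = FALSE)
  write_tsv_report(tab, file, ...)
  invisible(tab)
}
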