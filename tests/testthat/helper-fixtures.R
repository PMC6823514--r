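# Shared fixtures, built in code. Seeds fixed so failures are reproducible.

pair_aln <- function(a, b) {
  rbind(sp1 = strsplit(a, "")[[1]], sp2 = strsplit(b, "")[[1]])
}

ladder_tree <- function() {
  # ((a:1,b:2):3); depths: a = 4, b = 5 from root
  species_tree(ape::read.tree(text = "((a:1,b:2):3,c:6);"), units = "subs")
}

demo_tree <- function() mmbscan:::demo_setup()

# a pair alignment realizing exact substitution-type counts:
# n0 matches per base, m of each of the 12 ordered mismatch types
counted_pair <- function(n0, m) {
  bases <- c("A", "C", "G", "T")
  a <- character(0); b <- character(0)
  for (x in bases) { a <- c(a, rep(x, n0)); b <- c(b, rep(x, n0)) }
  for (x in bases) for (y in setdiff(bases, x)) {
    a <- c(a, rep(x, m)); b <- c(b, rep(y, m))
  }
  rbind(a, b)
}

jc69 <- function(p) -3 / 4 * log(1 - 4 * p / 3)

# brute-force weighted LS branch lengths via normal equations, using an
# independently-built design matrix (ape::nodepath), as an oracle for
# fit_branch_lengths
oracle_branch_lengths <- function(tree, D, w = NULL) {
  nt <- ape::Ntip(tree)
  pairs <- utils::combn(nt, 2)
  ne <- nrow(tree$edge)
  A <- matrix(0, ncol(pairs), ne)
  for (p in seq_len(ncol(pairs))) {
    np <- ape::nodepath(tree, pairs[1, p], pairs[2, p])
    for (k in seq_len(length(np) - 1)) {
      e <- which((tree$edge[, 1] == np[k] & tree$edge[, 2] == np[k + 1]) |
                 (tree$edge[, 2] == np[k] & tree$edge[, 1] == np[k + 1]))
      A[p, e] <- 1
    }
  }
  root <- nt + 1L
  re <- which(tree$edge[, 1] == root)
  if (length(re) == 2L) {  # merge unidentifiable root pair
    A[, re[1]] <- as.integer(A[, re[1]] + A[, re[2]] > 0)
    A <- A[, -re[2], drop = FALSE]
  }
  y <- D[tree$tip.label, tree$tip.label][cbind(pairs[1, ], pairs[2, ])]
  if (is.null(w)) w <- rep(1, length(y))
  solve(t(A) %*% (w * A), t(A) %*% (w * y))[, 1]
}

# drop all attributes except dim/dimnames for content comparisons
bare <- function(x) {
  a <- attributes(x)
  attributes(x) <- a[names(a) %in% c("dim", "dimnames")]
  x
}
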