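## Sequence evolution along a tree: substitution-only, site-independent,
## no indels or rate heterogeneity. Sequences are integer-coded internally
## (1..4 = A,C,G,T) and exposed as character matrices keyed by taxon.

#' Deterministic seed derivation for reproducible substreams
#'
#' Derives a 31-bit seed from a master seed and any number of integer
#' indices (scenario, replicate, ...), so batch runs are reproducible and
#' independent of execution order.
#'
#' @param master integer master seed.
#' @param ... integer indices.
#' @return integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647
  h <- as.double(master %% m)
  for (x in c(...)) {
    h <- (h * 48271 + as.double(x) * 69621 + 1013904223) %% m
  }
  as.integer(h %% (m - 2)) + 1L
}

dna_to_int <- function(x) {
  if (is.matrix(x)) matrix(match(x, BASES), nrow = nrow(x), dimnames = dimnames(x))
  else match(x, BASES)
}

int_to_dna <- function(x) {
  if (is.matrix(x)) matrix(BASES[x], nrow = nrow(x), dimnames = dimnames(x))
  else BASES[x]
}

#' Draw a random root sequence
#'
#' i.i.d. draws from the base frequency vector (default uniform, the
#' "balanced composition" used by the simulation design).
#'
#' @param length sequence length in nt (> 0).
#' @param frequencies base frequencies (A, C, G, T).
#' @param seed optional integer seed.
#' @return character vector of single bases.
#' @export
simulate_root_sequence <- function(length, frequencies = rep(0.25, 4),
                                   seed = NULL) {
  stopifnot(length > 0, length(frequencies) == 4, all(frequencies >= 0))
  if (!is.null(seed)) set.seed(seed)
  BASES[sample.int(4, length, replace = TRUE, prob = frequencies)]
}

## Internal: mutate an integer-coded sequence along one branch.
mutate_seq <- function(parent, P) {
  child <- parent
  u <- stats::runif(length(parent))
  for (b in 1:4) {
    idx <- which(parent == b)
    if (length(idx) == 0L) next
    cp <- cumsum(P[b, ])
    child[idx] <- findInterval(u[idx], cp, left.open = TRUE) + 1L
  }
  child
}

#' Evolve a root sequence along a tree
#'
#' Each branch applies the transition matrix `exp(Q t)` independently at
#' every site; the alignment of leaf sequences is returned keyed by tip
#' label.
#'
#' @param tree a `species_tree` in substitutions units (branch lengths =
#'   expected substitutions per site; all >= 0).
#' @param model a [hky_model()] or [gtr_model()].
#' @param root_sequence character vector of bases (from
#'   [simulate_root_sequence()]), or an integer length to draw one from the
#'   model's equilibrium frequencies.
#' @param seed optional integer seed.
#' @return object of class `sim_alignment`: a character matrix (tips x
#'   sites) with attributes `seed` and `scenario_id` (if the tree carries
#'   one).
#' @export
evolve <- function(tree, model, root_sequence, seed = NULL) {
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (!is.null(seed)) set.seed(seed)
  if (length(root_sequence) == 1L && is.numeric(root_sequence))
    root_sequence <- simulate_root_sequence(root_sequence, model$freq)
  rootint <- dna_to_int(root_sequence)
  if (anyNA(rootint)) stop("root sequence contains non-ACGT symbols")
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  seqs <- vector("list", ntip + nnode)
  seqs[[ntip + 1L]] <- rootint
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    par <- ord$edge[i, 1]; chi <- ord$edge[i, 2]
    t <- ord$edge.length[i]
    seqs[[chi]] <- if (t == 0) seqs[[par]]
                   else mutate_seq(seqs[[par]], transition_matrix(model, t))
  }
  aln <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(aln) <- tree$tip.label
  structure(int_to_dna(aln), class = c("sim_alignment", "matrix"),
            seed = seed, scenario_id = attr(tree, "scenario_id"))
}

#' Simulate replicate alignments for every scenario in a grid
#'
#' For each scenario the (Myr) tree is converted to substitutions, the
#' scenario's shortening is applied, and `n_replicates` independent root
#' sequences are evolved along the transformed tree. Per-replicate seeds are
#' derived deterministically from `(seed, scenario index, replicate index)`,
#' so the output is reproducible and order-independent.
#'
#' @param tree a `species_tree` in Myr units.
#' @param grid list of [lineage_scenario()] (see [scenario_grid()]).
#' @param model a substitution model.
#' @param n_replicates replicates per scenario.
#' @param length sequence length (nt).
#' @param seed master seed.
#' @param calib a [rate_calibration()].
#' @return named list (by scenario id) of lists of `sim_alignment`.
#' @export
run_scenario_batch <- function(tree, grid, model, n_replicates = 100,
                               length = 3000, seed = 1,
                               calib = rate_calibration()) {
  if (length(grid) == 0L) stop("empty scenario grid")
  stree <- myr_to_substitutions(tree, calib)
  out <- vector("list", base::length(grid))
  names(out) <- vapply(grid, function(s) s$scenario_id, "")
  for (si in seq_along(grid)) {
    tr <- apply_scenario(stree, grid[[si]], calib)
    reps <- vector("list", n_replicates)
    for (ri in seq_len(n_replicates)) {
      rs <- derive_seed(seed, si, ri)
      root <- simulate_root_sequence(length, model$freq, seed = rs)
      reps[[ri]] <- evolve(tr, model, root)
      attr(reps[[ri]], "replicate_id") <- ri
      attr(reps[[ri]], "seed") <- rs
    }
    out[[si]] <- reps
  }
  out
}

#' Write an alignment to FASTA
#'
#' @param aln character matrix (taxa x sites).
#' @param file output path.
#' @export
write_alignment_fasta <- function(aln, file) {
  m <- tolower(aln)
  attributes(m) <- list(dim = dim(aln), dimnames = dimnames(aln))
  bin <- ape::as.DNAbin(m)
  ape::write.FASTA(bin, file)
  invisible(file)
}

#' Read a FASTA alignment into a character matrix (taxa x sites)
#'
#' @param file FASTA path.
#' @return uppercase character matrix with taxa as rownames.
#' @export
read_alignment_fasta <- function(file) {
  bin <- ape::read.FASTA(file)
  m <- as.character(ape::as.matrix.DNAbin(bin))
  toupper(m)
}
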