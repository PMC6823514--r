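## Synthetic data with known truth: two-species intronic X/Y/A alignment sets
## evolved under a chosen alpha, and multi-taxon codon gene sets in which
## designated lineages were X-linked for a known retention time. The class
## rates derive from the Miyata inverses ([expected_ratio()]), so estimator
## and generator share only the algebra: recovery is a genuine round trip
## through sequence space.

#' Specifications for the synthetic-data generators
#'
#' `intron_synth_spec()` describes a two-species intronic dataset: `n_genes`
#' genes per chromosome class (X, Y, A), each with several introns. The
#' autosomal pairwise divergence is `2 * divergence_myr * 1e6 * mu`
#' substitutions per site (both lineages accumulate substitutions); X- and
#' Y-linked classes are scaled by the Miyata ratios implied by `alpha`. The
#' default split (15 Myr at mu = 2.22e-9/site/year) places the class
#' distances at 0.05-0.12 substitutions/site, inside the range where the
#' closed-form distance estimator and the column filters are well
#' calibrated; deeper splits are available through `divergence_myr` but the
#' CpG mask then deletes columns conditionally on their substitution
#' history, which measurably distorts the Y-based rate ratios (see the
#' methods vignette). Decoy content exercises the filters: the first intron
#' and the 20-nt exon flanks evolve at `conserved_scale` times the neutral
#' rate, and CpG dinucleotides are injected into the otherwise CpG-depleted
#' root at rate `cpg_rate` (starts per site), optionally hypermutable via
#' `cpg_mult`.
#'
#' `codon_synth_spec()` describes a multi-taxon in-frame gene set whose
#' fourfold degenerate third positions evolve along the scenario-shortened
#' tree (via [apply_scenario()]) while codon prefixes and non-degenerate
#' codons evolve at `constrained_scale` times the branch lengths.
#'
#' @param alpha true male mutation bias.
#' @param n_genes genes per class (intron design) or X-linked gene count
#'   (codon design).
#' @param divergence_myr species split age, Myr (intron design).
#' @param mu substitution rate per site per year.
#' @param introns_per_gene introns per gene (before first-intron removal).
#' @param intron_length range (min, max) of intron alignment lengths, nt.
#' @param flank exon-flank width, nt.
#' @param conserved_scale rate multiplier for first introns and flanks.
#' @param cpg_rate CpG injection rate (CG starts per root site); the root is
#'   otherwise CpG-depleted, as vertebrate introns are.
#' @param cpg_mult rate multiplier at injected CpG sites (hypermutability).
#' @param seed master seed.
#' @return object of class `synth_spec`.
#' @export
intron_synth_spec <- function(alpha = 6, n_genes = 77, divergence_myr = 15,
                              mu = 2.22e-9, introns_per_gene = 4,
                              intron_length = c(500, 1500), flank = 20,
                              conserved_scale = 0.3, cpg_rate = 0.02,
                              cpg_mult = 1, seed = 1) {
  stopifnot(alpha >= 1, n_genes > 0, divergence_myr > 0, introns_per_gene >= 2)
  structure(list(type = "intron", alpha = alpha, n_genes = n_genes,
                 divergence_myr = divergence_myr, mu = mu,
                 introns_per_gene = introns_per_gene,
                 intron_length = intron_length, flank = flank,
                 conserved_scale = conserved_scale, cpg_rate = cpg_rate,
                 cpg_mult = cpg_mult, seed = seed),
            class = "synth_spec")
}

#' @rdname intron_synth_spec
#' @param tree a `species_tree` in Myr units with lineage tags.
#' @param scenario the true [lineage_scenario()] (alpha and retention time
#'   per lineage).
#' @param gene_codons codons per gene.
#' @param fourfold_fraction fraction of codons from fourfold degenerate
#'   families.
#' @param constrained_scale rate multiplier for constrained positions.
#' @param calib a [rate_calibration()].
#' @export
codon_synth_spec <- function(tree, scenario, n_genes = 77, gene_codons = 333,
                             fourfold_fraction = 0.7, constrained_scale = 0.05,
                             mu = 2.22e-9, calib = rate_calibration(mu = mu),
                             seed = 1) {
  stopifnot(inherits(scenario, "lineage_scenario"), n_genes > 0,
            gene_codons > 0)
  if (tree_units(tree) != "myr") stop("tree must be in Myr units")
  structure(list(type = "codon", tree = tree, scenario = scenario,
                 n_genes = n_genes, gene_codons = gene_codons,
                 fourfold_fraction = fourfold_fraction,
                 constrained_scale = constrained_scale, mu = mu,
                 calib = calib, seed = seed),
            class = "synth_spec")
}

## Internal: evolve one pairwise intron with decoy content. The root is
## CpG-depleted (vertebrate introns are; background CG adjacencies are
## rejection-sampled away) and CpG dinucleotides are injected at `cpg_rate`
## starts per site; injected sites may be hypermutable (`cpg_mult` times the
## neutral rate), which is what motivates the CpG filter. Conserved columns
## (flanks, or the whole intron when `conserved` is TRUE) evolve at a reduced
## rate. Returns a 2 x L character matrix.
sim_intron_pair <- function(len, dist, flank, conserved_scale, cpg_rate,
                            cpg_mult = 1, conserved = FALSE,
                            taxa = c("sp1", "sp2")) {
  root <- sample.int(4, len, replace = TRUE)
  repeat {
    bad <- which(root[-len] == 2L & root[-1] == 3L)
    if (!length(bad)) break
    root[bad + 1L] <- sample(c(1L, 2L, 4L), length(bad), replace = TRUE)
  }
  scale_cols <- rep(if (conserved) conserved_scale else 1, len)
  if (!conserved && len > 2 * flank) {
    scale_cols[c(seq_len(flank), seq(len - flank + 1L, len))] <- conserved_scale
  }
  n_inj <- 0L
  if (cpg_rate > 0) {
    starts <- which(stats::runif(len - 1) < cpg_rate)
    if (length(starts)) {
      root[starts] <- 2L; root[starts + 1L] <- 3L
      scale_cols[starts] <- scale_cols[starts] * cpg_mult
      scale_cols[starts + 1L] <- scale_cols[starts + 1L] * cpg_mult
      n_inj <- length(starts)
    }
  }
  aln <- matrix(0L, 2, len)
  model <- hky_model(kappa = 2)
  for (s in unique(scale_cols)) {
    cols <- which(scale_cols == s)
    P <- transition_matrix(model, dist * s / 2)
    aln[1, cols] <- mutate_seq(root[cols], P)
    aln[2, cols] <- mutate_seq(root[cols], P)
  }
  out <- int_to_dna(aln)
  rownames(out) <- taxa
  attr(out, "root_cg") <- sum(root[-len] == 2L & root[-1] == 3L)
  attr(out, "n_injected") <- n_inj
  out
}

#' Generate a two-species intronic X/Y/A dataset with known truth
#'
#' Autosomal introns evolve at the neutral divergence; X- and Y-linked
#' classes at that divergence scaled by `2(2+alpha)/(3(1+alpha))` and
#' `2*alpha/(1+alpha)` respectively. Each gene's first intron and every
#' intron's exon flanks evolve at a reduced rate, and CpG dinucleotides are
#' injected into the roots, so the [filter_introns()] cascade has real work
#' to do before estimation.
#'
#' @param spec an [intron_synth_spec()].
#' @return an [intron_set()] with attribute `truth` (class rates, alpha,
#'   seeds, CpG accounting).
#' @export
gen_intron_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"), spec$type == "intron")
  set.seed(spec$seed)
  d_A <- 2 * spec$divergence_myr * 1e6 * spec$mu
  dists <- c(A = d_A,
             X = d_A * expected_ratio("XA", spec$alpha),
             Y = d_A * expected_ratio("YA", spec$alpha))
  genes <- list()
  cg_injected <- 0L
  root_sites <- 0L
  for (cl in c("X", "Y", "A")) {
    for (g in seq_len(spec$n_genes)) {
      introns <- vector("list", spec$introns_per_gene)
      for (k in seq_len(spec$introns_per_gene)) {
        len <- sample(seq(spec$intron_length[1], spec$intron_length[2]), 1)
        introns[[k]] <- sim_intron_pair(len, dists[[cl]], spec$flank,
                                        spec$conserved_scale, spec$cpg_rate,
                                        cpg_mult = spec$cpg_mult,
                                        conserved = (k == 1L))
        cg_injected <- cg_injected + attr(introns[[k]], "root_cg")
        root_sites <- root_sites + len
      }
      genes[[length(genes) + 1L]] <-
        intron_gene(sprintf("%s_gene%03d", cl, g), cl, introns)
    }
  }
  out <- intron_set(genes)
  attr(out, "truth") <- data.frame(
    class = names(dists), true_distance = unname(dists), alpha = spec$alpha,
    divergence_myr = spec$divergence_myr, mu = spec$mu, seed = spec$seed,
    root_cg_fraction = cg_injected / root_sites)
  out
}

## Non-degenerate codon roots used to pad codon genes (Met, Trp, Lys, Glu,
## Phe, Asn, Asp, Cys families; none fourfold degenerate at position 3).
NONDEG_CODONS <- c("ATG", "TGG", "AAA", "GAA", "TTT", "AAT", "GAT", "TGT")

#' Generate a multi-taxon codon gene set under a retention scenario
#'
#' Builds `n_genes` in-frame alignments along `spec$tree` after applying the
#' true scenario's branch shortening. Third positions of fourfold degenerate
#' codons evolve at the full (shortened) branch lengths; codon prefixes and
#' non-degenerate codons evolve at `constrained_scale` times the branch
#' lengths, preserving amino-acid structure up to rare constrained changes.
#'
#' @param spec a [codon_synth_spec()].
#' @return list with `genes` (list of character matrices), `tree`, and
#'   `truth` (the scenario, per-edge expected lengths, seed).
#' @export
gen_codon_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"), spec$type == "codon")
  stree <- myr_to_substitutions(spec$tree, spec$calib)
  ttree <- apply_scenario(stree, spec$scenario, spec$calib)
  ctree <- ttree
  ctree$edge.length <- ctree$edge.length * spec$constrained_scale
  model <- hky_model(kappa = 2)
  genes <- vector("list", spec$n_genes)
  for (g in seq_len(spec$n_genes)) {
    gs <- derive_seed(spec$seed, 7000, g)
    set.seed(gs)
    nc <- spec$gene_codons
    is4 <- stats::runif(nc) < spec$fourfold_fraction
    pre <- character(nc)
    pre[is4] <- sample(FOURFOLD_PREFIXES, sum(is4), replace = TRUE)
    nd <- sample(NONDEG_CODONS, sum(!is4), replace = TRUE)
    pre[!is4] <- substr(nd, 1, 2)
    third_root <- character(nc)
    third_root[is4] <- BASES[sample.int(4, sum(is4), replace = TRUE)]
    third_root[!is4] <- substr(nd, 3, 3)
    cons_root <- c(rbind(substr(pre, 1, 1), substr(pre, 2, 2), third_root))
    cons_idx <- which(rep(c(TRUE, TRUE, FALSE), nc) |
                        rep(!is4, each = 3) & rep(c(FALSE, FALSE, TRUE), nc))
    neut_idx <- setdiff(seq_len(3 * nc), cons_idx)
    cons_aln <- evolve(ctree, model, cons_root[cons_idx])
    neut_aln <- evolve(ttree, model, cons_root[neut_idx])
    aln <- matrix("", nrow = nrow(cons_aln), ncol = 3 * nc,
                  dimnames = list(rownames(cons_aln), NULL))
    aln[, cons_idx] <- cons_aln
    aln[, neut_idx] <- neut_aln
    genes[[g]] <- aln
  }
  truth <- list(scenario = spec$scenario, seed = spec$seed,
                edge_lengths = data.frame(
                  parent = ttree$edge[, 1], child = ttree$edge[, 2],
                  expected_subs = ttree$edge.length),
                calib = spec$calib)
  list(genes = genes, tree = spec$tree, truth = truth)
}

#' Machine-readable truth record for a synthetic dataset
#'
#' One row per lineage/class with the generating parameters (alpha,
#' retention time, rates, seed), sufficient to score parameter recovery.
#'
#' @param dataset output of [gen_intron_dataset()] or [gen_codon_dataset()].
#' @param file optional TSV path; when given the table is also written.
#' @return data.frame.
#' @export
truth_report <- function(dataset, file = NULL) {
  if (inherits(dataset, "intron_set")) {
    tab <- attr(dataset, "truth")
    if (is.null(tab)) stop("dataset carries no truth record")
  } else if (is.list(dataset) && !is.null(dataset$truth)) {
    sc <- dataset$truth$scenario
    tab <- data.frame(lineage = sc$lineages$lineage,
                      alpha = sc$lineages$alpha,
                      retention_T = sc$lineages$retention_T,
                      system_age = sc$system_age,
                      seed = dataset$truth$seed)
  } else stop("not a synthetic dataset with a truth record")
  if (!is.null(file)) write_tsv_report(tab, file)
  tab
}
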