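## Turnover dating: cumulative synonymous branch lengths observed in the data
## are compared with lengths simulated under a grid of X-linkage retention
## scenarios; the retention times whose simulated interval overlaps the
## observed interval form the inferred retention window, and the loss date is
## the system age minus that window.

## Internal: per-codon TN93 category codes (0 = unusable, 1..16 = ordered
## third-position base pair) for one taxon pair of an in-frame alignment.
## Makes the codon bootstrap a multinomial on counts.
pair_codon_categories <- function(seqA, seqB) {
  L <- length(seqA)
  i1 <- seq(1, L, by = 3)
  preA <- paste0(seqA[i1], seqA[i1 + 1])
  preB <- paste0(seqB[i1], seqB[i1 + 1])
  ia <- match(seqA[i1 + 2], BASES)
  ib <- match(seqB[i1 + 2], BASES)
  codA <- paste0(preA, seqA[i1 + 2])
  codB <- paste0(preB, seqB[i1 + 2])
  ok <- preA == preB & preA %in% FOURFOLD_PREFIXES & !is.na(ia) & !is.na(ib) &
    !(codA %in% STOP_CODONS) & !(codB %in% STOP_CODONS)
  out <- integer(length(i1))
  out[ok] <- (ia[ok] - 1L) * 4L + ib[ok]
  out
}

## Internal: distance matrix over taxa from per-pair category codes and a
## codon index vector (the codon-bootstrap resample).
ds_matrix_from_categories <- function(cats, taxa, idx = NULL) {
  n <- length(taxa)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  p <- 0L
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    p <- p + 1L
    v <- if (is.null(idx)) cats[p, ] else cats[p, idx]
    cts <- tabulate(v, nbins = 16L)
    D[i, j] <- D[j, i] <- tn93_from_counts17(c(cts, 0L))
  }
  D
}

#' Observed cumulative dS lengths with a codon bootstrap
#'
#' Concatenates the gene alignments, and for each codon-bootstrap replicate
#' computes all pairwise synonymous distances ([ds_proxy()] logic on fourfold
#' degenerate third positions), fits branch lengths on the fixed species
#' topology, and accumulates each measured species' branch lengths from the
#' common ancestor of the measured set down to the tip. Replicates in which
#' any pair is saturated are dropped and counted.
#'
#' @param genes list of in-frame codon alignments (character matrices with
#'   identical taxon rownames covering the tree's tips).
#' @param tree a `species_tree` (units irrelevant; topology fixed).
#' @param groups named character vector: names are the measured tip labels,
#'   values their group tags. The focal ancestor is their MRCA.
#' @param n_boot codon-bootstrap replicates.
#' @param seed integer seed.
#' @param weighting passed to [fit_branch_lengths()]; the default
#'   inverse-square weighting protects the measured clade from
#'   near-saturated outgroup pairs.
#' @return a [grouped_lengths()] (species x replicates), with the number of
#'   dropped replicates as attribute `n_dropped`.
#' @export
observed_group_lengths <- function(genes, tree, groups, n_boot = 100,
                                   seed = NULL, weighting = "fm") {
  aln <- do.call(cbind, genes)
  taxa <- rownames(aln)
  if (!all(tree$tip.label %in% taxa))
    stop("alignment missing tree tips: ",
         paste(setdiff(tree$tip.label, taxa), collapse = ", "))
  aln <- aln[tree$tip.label, , drop = FALSE]
  taxa <- tree$tip.label
  if (ncol(aln) %% 3 != 0) stop("concatenate length not divisible by 3")
  if (!is.null(seed)) set.seed(seed)
  nc <- ncol(aln) %/% 3
  npair <- choose(length(taxa), 2)
  cats <- matrix(0L, npair, nc)
  p <- 0L
  for (i in seq_len(length(taxa) - 1)) for (j in seq(i + 1, length(taxa))) {
    p <- p + 1L
    cats[p, ] <- pair_codon_categories(aln[i, ], aln[j, ])
  }
  meas <- names(groups)
  anc <- mrca_node(tree, meas)
  reps <- matrix(NA_real_, length(meas), n_boot, dimnames = list(meas, NULL))
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nc, nc, replace = TRUE)
    D <- ds_matrix_from_categories(cats, taxa, idx)
    if (anyNA(D)) { dropped <- dropped + 1L; next }
    bt <- fit_branch_lengths(tree, D, weighting = weighting)
    reps[, b] <- vapply(meas, function(sp) cumulative_length(bt, sp, anc), 0)
  }
  keep <- colSums(is.na(reps)) == 0
  if (dropped > 0)
    warning(dropped, " bootstrap replicate(s) dropped (saturated pairs)")
  grouped_lengths(meas, unname(groups[meas]), reps[, keep, drop = FALSE])
}

#' Simulated cumulative lengths per scenario
#'
#' For every scenario in the grid, evolves `n_replicates` random sequences
#' along the scenario-shortened tree, estimates a TN93 branch-length tree per
#' replicate, and returns per-replicate group-averaged cumulative lengths
#' from the measured species' common ancestor.
#'
#' @param tree a `species_tree` in Myr units with lineage tags.
#' @param grid list of [lineage_scenario()].
#' @param groups named character vector (measured tips -> group tags).
#' @param model a substitution model.
#' @param n_replicates simulation replicates per scenario.
#' @param length simulated sequence length (nt).
#' @param seed master seed.
#' @param calib a [rate_calibration()].
#' @param weighting passed to [fit_branch_lengths()].
#' @return named list (scenario id) of matrices (groups x replicates).
#' @export
simulate_scenario_lengths <- function(tree, grid, groups, model = hky_model(),
                                      n_replicates = 100, length = 3000,
                                      seed = 1, calib = rate_calibration(),
                                      weighting = "fm") {
  meas <- names(groups)
  anc <- mrca_node(tree, meas)
  gps <- unique(unname(groups))
  stree <- myr_to_substitutions(tree, calib)
  out <- vector("list", base::length(grid))
  names(out) <- vapply(grid, function(s) s$scenario_id, "")
  for (si in seq_along(grid)) {
    tr <- apply_scenario(stree, grid[[si]], calib)
    m <- matrix(NA_real_, base::length(gps), n_replicates,
                dimnames = list(gps, NULL))
    for (ri in seq_len(n_replicates)) {
      rs <- derive_seed(seed, si, ri)
      aln <- evolve(tr, model, length, seed = rs)
      D <- tn93_matrix(aln, warn = FALSE)
      if (anyNA(D)) next
      bt <- fit_branch_lengths(tree, D, weighting = weighting)
      cl <- vapply(meas, function(sp) cumulative_length(bt, sp, anc), 0)
      m[, ri] <- vapply(gps, function(g) mean(cl[groups[meas] == g]), 0)
    }
    out[[si]] <- m[, colSums(is.na(m)) == 0, drop = FALSE]
  }
  out
}

#' Overlap scan: which retention times are compatible with the data
#'
#' For each focal group and each scenario retention time `T`, compares the
#' observed 95% percentile interval (codon bootstrap) with the Welch 95%
#' interval of the simulated replicates, on a common scale anchored to the
#' reference group (one not differentially affected by the scenarios). The
#' retention times whose intervals intersect form the inferred window
#' `[T_min, T_max]`; the loss-date interval is
#' `[system_age - T_max, system_age - T_min]`. Compatibility of the null
#' scenario (`T = 0`) is reported separately: its rejection is the evidence
#' that the lineage once carried the system.
#'
#' Two scale adjustments are available. `"ratio"` (default) divides every
#' focal value by its own side's reference value, replicate by replicate
#' (then multiplies by the observed reference median so units stay
#' interpretable): simulated-vs-observed composition differences cancel by
#' construction and the reference group's sampling noise widens both
#' intervals honestly. `"factor"` reproduces the simpler global adjustment:
#' all simulated values are multiplied by the observed/simulated
#' reference-median ratio ([rescale_simulated()]), the reference being
#' pooled over scenarios.
#'
#' @param observed a [grouped_lengths()] (species rows with group tags).
#' @param simulated named list of group x replicate matrices (from
#'   [simulate_scenario_lengths()]); names parse as `"T<Myr>"`.
#' @param focal focal group tag(s) to scan.
#' @param reference reference group tag for rescaling.
#' @param system_age system age in Ma.
#' @param level interval level.
#' @param scale `"ratio"` or `"factor"` (see Details).
#' @return object of class `turnover_scan`.
#' @export
overlap_scan <- function(observed, simulated, focal, reference, system_age,
                         level = 0.95, scale = c("ratio", "factor")) {
  scale <- match.arg(scale)
  Ts <- as.numeric(sub("^T", "", names(simulated)))
  if (anyNA(Ts)) stop("scenario names must encode retention times as 'T<Myr>'")
  ord <- order(Ts)
  Ts <- Ts[ord]; simulated <- simulated[ord]
  obs_grp <- group_average(observed)
  need <- c(focal, reference)
  if (!all(need %in% obs_grp$species))
    stop("groups missing from observed data: ",
         paste(setdiff(need, obs_grp$species), collapse = ", "))
  if (!all(need %in% rownames(simulated[[1]])))
    stop("groups missing from simulated data")
  obs_ref <- obs_grp$replicates[reference, ]
  ref_med <- stats::median(obs_ref)
  sim_ref_pool <- unlist(lapply(simulated, function(m) m[reference, ]))
  sf <- attr(rescale_simulated(1, sim_ref_pool, obs_ref), "scale_factor")
  a2 <- (1 - level) / 2
  rows <- list()
  for (g in focal) {
    obs <- if (scale == "ratio")
      obs_grp$replicates[g, ] / obs_ref * ref_med
    else obs_grp$replicates[g, ]
    oq <- stats::quantile(obs, c(a2, 1 - a2), names = FALSE)
    for (i in seq_along(Ts)) {
      sims <- if (scale == "ratio")
        simulated[[i]][g, ] / simulated[[i]][reference, ] * ref_med
      else simulated[[i]][g, ] * sf
      wc <- welch_ci(sims, level = level)
      rows[[length(rows) + 1L]] <- data.frame(
        lineage = g, retention_T = Ts[i],
        sim_mean = wc[["mean"]], sim_lo = wc[["low"]], sim_hi = wc[["high"]],
        obs_med = stats::median(obs), obs_lo = oq[1], obs_hi = oq[2],
        overlap = wc[["low"]] <= oq[2] && oq[1] <= wc[["high"]])
    }
  }
  scan <- do.call(rbind, rows)
  intervals <- do.call(rbind, lapply(focal, function(g) {
    sc <- scan[scan$lineage == g, ]
    hit <- sc$retention_T[sc$overlap]
    contiguous <- length(hit) == 0 ||
      all(diff(match(hit, sc$retention_T)) == 1)
    data.frame(lineage = g,
               T_min = if (length(hit)) min(hit) else NA_real_,
               T_max = if (length(hit)) max(hit) else NA_real_,
               loss_min = if (length(hit)) system_age - max(hit) else NA_real_,
               loss_max = if (length(hit)) system_age - min(hit) else NA_real_,
               null_compatible = sc$overlap[sc$retention_T == 0],
               n_compatible = length(hit),
               contiguous = contiguous)
  }))
  if (any(!intervals$contiguous & intervals$n_compatible > 0))
    warning("non-contiguous overlap set for: ",
            paste(intervals$lineage[!intervals$contiguous], collapse = ", "))
  structure(list(scan = scan, intervals = intervals,
                 system_age = system_age, scale_factor = sf,
                 reference = reference, level = level),
            class = "turnover_scan")
}

#' @export
print.turnover_scan <- function(x, ...) {
  cat("Sex chromosome turnover scan (system age ", x$system_age, " Ma, ",
      "reference group '", x$reference, "', scale factor ",
      format(x$scale_factor, digits = 4), ")\n\n", sep = "")
  for (i in seq_len(nrow(x$intervals))) {
    r <- x$intervals[i, ]
    cat(r$lineage, ": ", sep = "")
    if (r$n_compatible == 0) {
      cat("no compatible scenario\n")
    } else {
      cat("retention ", r$T_min, "-", r$T_max, " Myr (loss ",
          r$loss_min, "-", r$loss_max, " Ma); null scenario ",
          if (r$null_compatible) "compatible" else "rejected",
          if (!r$contiguous) "; NON-CONTIGUOUS overlap set", "\n", sep = "")
    }
  }
  invisible(x)
}

#' @export
summary.turnover_scan <- function(object, ...) {
  print(object)
  cat("\nPer-scenario overlap table:\n")
  print(object$scan, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
plot.turnover_scan <- function(x, lineage = x$intervals$lineage[1], ...) {
  sc <- x$scan[x$scan$lineage == lineage, ]
  ylim <- range(sc$sim_lo, sc$sim_hi, sc$obs_lo, sc$obs_hi)
  graphics::plot(sc$retention_T, sc$sim_mean, ylim = ylim, pch = 19,
                 xlab = "retention time (Myr)",
                 ylab = "cumulative length (subs/site)",
                 main = paste("Turnover scan:", lineage), ...)
  graphics::arrows(sc$retention_T, sc$sim_lo, sc$retention_T, sc$sim_hi,
                   angle = 90, code = 3, length = 0.03)
  graphics::rect(graphics::par("usr")[1], sc$obs_lo[1],
                 graphics::par("usr")[2], sc$obs_hi[1],
                 col = grDevices::adjustcolor("darkgreen", 0.2), border = NA)
  graphics::abline(h = sc$obs_med[1], col = "darkgreen", lty = 2)
  invisible(x)
}

#' Fit a turnover scan end to end
#'
#' The package's headline analysis: observed codon alignments are reduced to
#' autosomal-corrected cumulative synonymous lengths per group; a scenario
#' grid is simulated along the same species tree; and [overlap_scan()]
#' intersects the two to date the loss of the sex chromosome system in the
#' focal lineage(s).
#'
#' @param genes list of in-frame codon alignments (the X-linked ortholog
#'   set).
#' @param tree a `species_tree` in Myr units with lineage tags.
#' @param grid list of [lineage_scenario()] (see [scenario_grid()]).
#' @param groups named character vector: measured tips -> group tags.
#' @param focal focal group tag(s) scanned for turnover.
#' @param reference reference group tag (scenario-invariant) for rescaling.
#' @param autosomal_genes optional autosomal ortholog alignments; when given,
#'   observed lengths are corrected with [autosomal_correction()] over the
#'   measured species.
#' @param model substitution model for the simulations.
#' @param n_boot codon-bootstrap replicates (observed side).
#' @param n_sim simulation replicates per scenario.
#' @param sim_length simulated sequence length (nt).
#' @param seed master seed.
#' @param calib a [rate_calibration()].
#' @return a `turnover_scan` object (see [overlap_scan()]) with the observed
#'   and simulated components attached.
#' @export
turnover_scan <- function(genes, tree, grid, groups, focal, reference,
                          autosomal_genes = NULL, model = hky_model(),
                          n_boot = 100, n_sim = 100, sim_length = 3000,
                          seed = 1, calib = rate_calibration()) {
  obs <- observed_group_lengths(genes, tree, groups, n_boot = n_boot,
                                seed = derive_seed(seed, 101))
  if (!is.null(autosomal_genes)) {
    aut <- observed_group_lengths(autosomal_genes, tree, groups,
                                  n_boot = ncol(obs$replicates),
                                  seed = derive_seed(seed, 102))
    nb <- min(ncol(obs$replicates), ncol(aut$replicates))
    obs$replicates <- obs$replicates[, seq_len(nb), drop = FALSE]
    aut$replicates <- aut$replicates[, seq_len(nb), drop = FALSE]
    obs <- autosomal_correction(obs, aut)
  }
  sims <- simulate_scenario_lengths(tree, grid, groups, model = model,
                                    n_replicates = n_sim,
                                    length = sim_length,
                                    seed = derive_seed(seed, 103),
                                    calib = calib)
  res <- overlap_scan(obs, sims, focal = focal, reference = reference,
                      system_age = grid[[1]]$system_age)
  res$observed <- obs
  res$simulated <- sims
  res$seed <- seed
  res
}

#' Write a turnover scan as TSV
#'
#' The per-scenario table plus a `# interval:` comment line per lineage.
#'
#' @param x a `turnover_scan`.
#' @param file output path.
#' @param ... passed to [write_tsv_report()].
#' @export
write_scan_tsv <- function(x, file, ...) {
  extra <- apply(x$intervals, 1, function(r)
    paste0("interval: ", paste(names(x$intervals), r, collapse = " ")))
  write_tsv_report(x$scan, file, extra_header = extra, ...)
  invisible(x$scan)
}
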