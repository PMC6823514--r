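# Construct grouped_lengths / simulated matrices directly so the overlap
# logic can be probed without simulation noise. The reference group is held
# constant so ratio and factor scaling coincide.
mk_obs <- function(focal_vals, ref = 1, n = 40, spread = 0.001) {
  set.seed(1)
  grouped_lengths(c("f", "r"), c("focal", "ref"),
                  rbind(focal_vals + rnorm(n, 0, spread),
                        ref + rnorm(n, 0, spread / 10)))
}
mk_sims <- function(means, ref = 1, n = 20, spread = 0.001) {
  set.seed(2)
  out <- lapply(seq_along(means), function(i)
    rbind(focal = means[i] + rnorm(n, 0, spread),
          ref = ref + rnorm(n, 0, spread / 10)))
  names(out) <- sprintf("T%03d", (seq_along(means) - 1) * 10)
  out
}

test_that("overlap collapses to the matching scenario and flags no-match", {
  sims <- mk_sims(c(0.40, 0.35, 0.30, 0.25))   # T = 0,10,20,30
  sc <- overlap_scan(mk_obs(0.30), sims, focal = "focal", reference = "ref",
                     system_age = 170)
  iv <- sc$intervals
  expect_equal(c(iv$T_min, iv$T_max), c(20, 20))
  expect_equal(c(iv$loss_min, iv$loss_max), c(150, 150))
  expect_false(iv$null_compatible)
  expect_true(iv$contiguous)
  # observed far from every scenario: empty interval, no-compatible flag
  none <- overlap_scan(mk_obs(0.70), sims, "focal", "ref", 170)
  expect_equal(none$intervals$n_compatible, 0)
  expect_true(is.na(none$intervals$T_min))
  expect_output(print(none), "no compatible scenario")
})

test_that("widening the observed interval can only grow the recovered set", {
  sims <- mk_sims(c(0.40, 0.35, 0.30, 0.25, 0.20))
  widths <- c(0.002, 0.01, 0.03, 0.06)
  counts <- vapply(widths, function(w) {
    sc <- overlap_scan(mk_obs(0.30, spread = w), sims, "focal", "ref", 170)
    sc$intervals$n_compatible
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("non-contiguous overlap sets are reported and flagged", {
  sims <- mk_sims(c(0.30, 0.50, 0.30))        # dip at T = 10
  expect_warning(sc <- overlap_scan(mk_obs(0.30), sims, "focal", "ref", 170),
                 "non-contiguous")
  expect_false(sc$intervals$contiguous)
  expect_equal(sc$intervals$n_compatible, 2)
  expect_equal(c(sc$intervals$T_min, sc$intervals$T_max), c(0, 20))
})

test_that("ratio scaling cancels a global scale offset between sides", {
  sims <- mk_sims(c(0.40, 0.35, 0.30, 0.25), ref = 0.8)  # sims on another scale
  obs <- mk_obs(0.30)
  sc <- overlap_scan(obs, sims, "focal", "ref", 170, scale = "ratio")
  # focal/ref = 0.30 observed matches sim focal/ref = 0.30/0.8 at T where
  # sims mean is 0.24 -> no scenario; under ratio scaling the comparison is
  # on ratios, so 0.30/1 matches 0.30/0.8 nowhere; rescale instead by
  # constructing sims whose ratios match
  sims2 <- mk_sims(c(0.40, 0.35, 0.30, 0.25) * 0.8, ref = 0.8)
  sc2 <- overlap_scan(obs, sims2, "focal", "ref", 170, scale = "ratio")
  expect_equal(c(sc2$intervals$T_min, sc2$intervals$T_max), c(20, 20))
  # factor scaling agrees on this fixture
  sc3 <- overlap_scan(obs, sims2, "focal", "ref", 170, scale = "factor")
  expect_equal(c(sc3$intervals$T_min, sc3$intervals$T_max), c(20, 20))
})

test_that("scan inputs are validated", {
  sims <- mk_sims(c(0.4, 0.3))
  expect_error(overlap_scan(mk_obs(0.3), sims, "nope", "ref", 170), "missing")
  bad <- sims; names(bad) <- c("a", "b")
  expect_error(overlap_scan(mk_obs(0.3), bad, "focal", "ref", 170), "encode")
  expect_error(overlap_scan(mk_obs(0.3), list(), "focal", "ref", 170))
})

test_that("observed and simulated pipelines agree on a known tree", {
  setup <- demo_tree()
  truth <- lineage_scenario(rbind(
    data.frame(lineage = "agamid", alpha = 4, retention_T = 60),
    data.frame(lineage = "pleurodont", alpha = 6, retention_T = 170)), 170)
  ds <- gen_codon_dataset(codon_synth_spec(setup$tree, truth, n_genes = 25,
                                           gene_codons = 250, seed = 91))
  obs <- suppressWarnings(observed_group_lengths(ds$genes, setup$tree,
                          setup$groups, n_boot = 25, seed = 13))
  # true cumulative lengths from the measured MRCA, per group
  ttree <- suppressWarnings(apply_scenario(
    myr_to_substitutions(setup$tree), truth))
  anc <- mrca_node(setup$tree, names(setup$groups))
  tru <- vapply(names(setup$groups), function(sp)
    cumulative_length(ttree, sp, anc), 0)
  tru_g <- tapply(tru, setup$groups, mean)
  og <- group_average(obs)
  for (g in c("snake", "agamid")) {
    med <- median(og$replicates[g, ])
    expect_lt(abs(med - tru_g[[g]]) / tru_g[[g]], 0.08)
  }
  expect_s3_class(obs, "grouped_lengths")
  expect_output(print(obs), "species")
})

test_that("turnover_scan recovers truth end to end at desk scale", {
  res <- suppressWarnings(run_demo(true_T = 80, true_alpha = 4, n_genes = 30,
                                   n_boot = 25, n_sim = 10, seed = 14))
  iv <- res$scan$intervals
  expect_false(iv$null_compatible)
  expect_true(iv$T_min <= 80 && 80 <= iv$T_max)
  expect_output(print(res$scan), "retention")
  expect_output(summary(res$scan), "overlap table")
  # plot method draws without error
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(res$scan))
})
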