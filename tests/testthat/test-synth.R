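test_that("intron generator encodes the Miyata structure in its truth record", {
  spec <- intron_synth_spec(alpha = 6, n_genes = 3, seed = 5)
  ds <- gen_intron_dataset(spec)
  tr <- truth_report(ds)
  expect_setequal(tr$class, c("X", "Y", "A"))
  dX <- tr$true_distance[tr$class == "X"]
  dY <- tr$true_distance[tr$class == "Y"]
  dA <- tr$true_distance[tr$class == "A"]
  expect_equal(dY / dX, 9 / 4)                        # (2a/(1+a))/(2(2+a)/(3(1+a)))
  expect_equal(dX / dA, 16 / 21)
  expect_equal(dA, 2 * 15e6 * 2.22e-9)
  # alpha = 1: all classes share one expected rate
  t1 <- truth_report(gen_intron_dataset(intron_synth_spec(alpha = 1,
                                                          n_genes = 2)))
  expect_equal(length(unique(t1$true_distance)), 1)
  # regeneration from the recorded seed is bit-identical
  ds2 <- gen_intron_dataset(spec)
  expect_identical(ds$genes, ds2$genes)
})

test_that("with alpha = 1 the chromosome classes are exchangeable", {
  ds <- gen_intron_dataset(intron_synth_spec(alpha = 1, n_genes = 12,
                                             seed = 71))
  per_gene <- vapply(ds$genes, function(g) {
    cc <- do.call(cbind, g$introns)
    tn93(cc[1, ], cc[2, ])$distance
  }, 0)
  cls <- vapply(ds$genes, function(g) g$class, "")
  obs_spread <- diff(range(tapply(per_gene, cls, median)))
  set.seed(72)
  perm <- replicate(499, {
    p <- sample(cls)
    diff(range(tapply(per_gene, p, median)))
  })
  pval <- (1 + sum(perm >= obs_spread)) / 500
  expect_gt(pval, 0.01)   # class labels carry no signal
})

test_that("the filters find and remove the injected decoy content", {
  # shallow divergence so evolution neither creates nor destroys many CGs and
  # the removal fraction cleanly reflects the injection
  spec <- intron_synth_spec(alpha = 6, n_genes = 15, cpg_rate = 0.03,
                            divergence_myr = 2, seed = 73)
  ds <- gen_intron_dataset(spec)
  filtered <- filter_introns(ds)
  aud <- attr(filtered, "audit")
  expect_true(all(aud$removed_first_intron > 0))
  expect_true(all(aud$removed_flank > 0))
  expect_true(sum(aud$removed_cpg) > 0)
  # CpG recovery: removed fraction tracks the root CG-column fraction
  truth <- truth_report(ds)
  root_cg_cols <- 2 * truth$root_cg_fraction[1]  # two columns per CG start
  post_flank_cols <- sum(aud$columns_in) - sum(aud$removed_first_intron) -
    sum(aud$removed_flank)
  got <- sum(aud$removed_cpg) / post_flank_cols
  expect_lt(abs(got - root_cg_cols) / root_cg_cols, 0.2)
})

test_that("codon generator respects frame, taxa and the scenario monotonics", {
  setup <- demo_tree()
  mk <- function(T) {
    truth <- lineage_scenario(rbind(
      data.frame(lineage = "agamid", alpha = 4, retention_T = T),
      data.frame(lineage = "pleurodont", alpha = 6, retention_T = 170)), 170)
    codon_synth_spec(setup$tree, truth, n_genes = 2, gene_codons = 80,
                     seed = 74)
  }
  ds <- gen_codon_dataset(mk(80))
  expect_length(ds$genes, 2)
  expect_true(all(vapply(ds$genes, ncol, 0L) %% 3 == 0))
  expect_setequal(rownames(ds$genes[[1]]), setup$tree$tip.label)
  expect_identical(ds$genes, gen_codon_dataset(mk(80))$genes)  # seeded
  # expected agamid length decreases in retention time, pinned at the
  # pleurodont value under full retention with pleurodont alpha
  lens <- vapply(c(0, 80, 170), function(T) {
    tt <- suppressWarnings(apply_scenario(myr_to_substitutions(setup$tree),
                                          mk(T)$scenario))
    anc <- mrca_node(setup$tree, names(setup$groups))
    cumulative_length(tt, "agamid1", anc)
  }, 0)
  expect_true(lens[1] > lens[2] && lens[2] > lens[3])
  # full-retention symmetry: same alpha and T give the same expected length
  truth_eq <- lineage_scenario(rbind(
    data.frame(lineage = "agamid", alpha = 6, retention_T = 170),
    data.frame(lineage = "pleurodont", alpha = 6, retention_T = 170)), 170)
  tt <- suppressWarnings(apply_scenario(myr_to_substitutions(setup$tree),
                                        truth_eq))
  anc <- mrca_node(setup$tree, names(setup$groups))
  # agamid and pleurodont tips have equal root paths (ultrametric) and now
  # equal histories; compare against a pleurodont tip
  expect_equal(cumulative_length(tt, "agamid1", anc),
               cumulative_length(tt, "pleuro1", anc), tolerance = 1e-9)
})

test_that("truth reports are complete, unique and joinable", {
  setup <- demo_tree()
  truth <- lineage_scenario(rbind(
    data.frame(lineage = "agamid", alpha = 4, retention_T = 80),
    data.frame(lineage = "pleurodont", alpha = 6, retention_T = 170)), 170)
  ds <- gen_codon_dataset(codon_synth_spec(setup$tree, truth, n_genes = 1,
                                           gene_codons = 30, seed = 75))
  tab <- truth_report(ds)
  expect_equal(anyDuplicated(tab$lineage), 0)
  expect_setequal(tab$lineage, c("agamid", "pleurodont"))
  expect_true(all(c("alpha", "retention_T", "system_age", "seed") %in%
                    names(tab)))
  f <- tempfile(fileext = ".tsv")
  truth_report(ds, f)
  back <- utils::read.delim(f, comment.char = "#")
  expect_equal(back$retention_T, tab$retention_T)
  unlink(f)
  expect_error(truth_report(list(a = 1)), "truth record")
})
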