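test_that("tn93 basics: zero on identity, symmetry, site accounting", {
  a <- "ACGTACGTACGTACGTACGT"
  expect_equal(tn93(a, a)$distance, 0)
  x <- "ACGTACGTAC"; y <- "ACGTACGTAT"
  expect_equal(tn93(x, y)$distance, tn93(y, x)$distance)
  d <- tn93("ACGTNN-A", "ACGTAC-A")
  expect_equal(d$usable_sites, 5)
  expect_equal(d$excluded_sites, 3)
  expect_error(tn93("NNN", "NNN"), "zero usable")
})

test_that("tn93 collapses to JC69 on equal-frequency JC-ratio fixtures", {
  for (m in c(1, 5, 20)) {
    aln <- counted_pair(n0 = 250, m = m)
    p <- 12 * m / (4 * 250 + 12 * m)
    expect_equal(tn93(aln[1, ], aln[2, ])$distance, jc69(p), tolerance = 1e-9)
  }
})

test_that("tn93 agrees with the reference implementation on simulated data", {
  set.seed(5)
  m <- gtr_model(rates = c(1, 3, 0.7, 1.2, 4, 1), freq = c(0.3, 0.2, 0.3, 0.2))
  tr <- species_tree(ape::read.tree(text = "(a:0.1,b:0.15);"), units = "subs")
  for (i in 1:5) {
    aln <- evolve(tr, m, 4000)
    mine <- tn93(aln[1, ], aln[2, ])$distance
    mat <- tolower(unclass(aln))
    ref <- ape::dist.dna(ape::as.DNAbin(mat), model = "TN93",
                         pairwise.deletion = TRUE)[1]
    expect_equal(mine, unname(ref), tolerance = 1e-12)
  }
})

test_that("saturated pairs are flagged, not truncated", {
  # all-mismatch fixture: p = 12m/n -> 1, correction log argument <= 0
  aln <- counted_pair(n0 = 0, m = 20)
  d <- tn93(aln[1, ], aln[2, ])
  expect_true(d$saturated)
  expect_true(is.na(d$distance))
})

test_that("tn93 is monotone in mismatch load at proportional composition", {
  ds <- vapply(c(2, 4, 8, 16, 24), function(m)
    tn93_from_counts(matrix(c(100, m, 2 * m, m,
                              m, 100, m, 2 * m,
                              2 * m, m, 100, m,
                              m, 2 * m, m, 100), 4, byrow = TRUE)), 0)
  expect_true(all(diff(ds) > 0))
})

test_that("fourfold_sites extracts doubly degenerate third positions", {
  # two alanine codons in both sequences -> both third positions usable
  ff <- fourfold_sites("GCAGCG", "GCCGCT")
  expect_equal(ff$n_fourfold, 2)
  expect_equal(ff$aln, rbind(c("A", "G"), c("C", "T")))
  # methionine is not fourfold degenerate
  expect_equal(fourfold_sites("ATGATG", "ATGATG")$n_fourfold, 0)
  # mixed 10-codon fixture, expected count by hand against the genetic code:
  # GCx Ala (yes), GGx Gly (yes), ATG Met (no), TGG Trp (no), CTx Leu (yes),
  # AAA Lys (no), GTx Val (yes), TAA stop (excluded+counted), ACx Thr (yes),
  # prefix mismatch GC/CC (no) -> 5 usable, 1 stop
  a <- paste0("GCA", "GGG", "ATG", "TGG", "CTT", "AAA", "GTC", "TAA", "ACG", "GCT")
  b <- paste0("GCC", "GGA", "ATG", "TGG", "CTA", "AAA", "GTT", "TAA", "ACC", "CCT")
  ff2 <- fourfold_sites(a, b)
  expect_equal(ff2$n_fourfold, 5)
  expect_equal(ff2$n_stop, 1)
  expect_error(fourfold_sites("ACGT", "ACGT"), "divisible by 3")
})

test_that("ds_proxy measures synonymous-only divergence", {
  cds <- paste0(rep(c("GCA", "GCC", "GCG", "GCT"), 15), collapse = "")
  expect_equal(ds_proxy(cds, cds)$distance, 0)
  # mutate a few third positions: amino acids identical, distance positive
  syn <- cds
  substr(syn, 3, 3) <- "G"; substr(syn, 6, 6) <- "T"; substr(syn, 12, 12) <- "A"
  d <- ds_proxy(cds, syn)
  expect_gt(d$distance, 0)
  expect_equal(d$method, "TN93_4fold")
  expect_false(d$below_floor)
  expect_true(ds_proxy(substr(cds, 1, 90), substr(cds, 1, 90))$below_floor)
})

test_that("ds_proxy recovers a known third-position divergence in simulation", {
  m <- hky_model()
  tr <- species_tree(ape::read.tree(text = "(a:0.1,b:0.1);"), units = "subs")
  set.seed(31)
  est <- replicate(40, {
    n <- 500
    pre <- sample(mmbscan:::FOURFOLD_PREFIXES, n, replace = TRUE)
    third <- evolve(tr, m, simulate_root_sequence(n))
    ds_proxy(paste0(pre, third["a", ], collapse = ""),
             paste0(pre, third["b", ], collapse = ""))$distance
  })
  expect_lt(abs(mean(est) - 0.2), 3 * sd(est) / sqrt(40))
})

test_that("fit_branch_lengths recovers additive matrices exactly", {
  st <- species_tree(ape::read.tree(text = "(a:1,b:1,c:1);"), units = "subs")
  D <- matrix(0.2, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(D) <- 0
  expect_equal(fit_branch_lengths(st, D)$edge.length, rep(0.1, 3))
  set.seed(12)
  for (i in 1:5) {
    tr <- species_tree(ape::rtree(6), units = "subs")
    D <- ape::cophenetic.phylo(tr)
    for (w in c("ols", "fm")) {
      ft <- fit_branch_lengths(tr, D, weighting = w)
      expect_equal(ft$edge.length, tr$edge.length, tolerance = 1e-9)
    }
  }
})

test_that("fit_branch_lengths matches a brute-force normal-equations solve", {
  set.seed(13)
  tr <- species_tree(ape::rtree(7), units = "subs")
  D <- ape::cophenetic.phylo(tr)
  D["t1", "t2"] <- D["t2", "t1"] <- D["t1", "t2"] + 0.07  # perturb one entry
  ft <- fit_branch_lengths(tr, D)
  beta <- oracle_branch_lengths(tr, D)
  root <- ape::Ntip(tr) + 1L
  re <- which(tr$edge[, 1] == root)
  keep <- setdiff(seq_len(nrow(tr$edge)), re)
  expect_equal(ft$edge.length[keep], beta[match(keep, setdiff(seq_len(nrow(tr$edge)), re[2]))],
               tolerance = 1e-9)
  expect_equal(sum(ft$edge.length[re]), beta[re[1]], tolerance = 1e-9)
  # weighted fit matches the weighted oracle
  pairs <- utils::combn(ape::Ntip(tr), 2)
  y <- D[tr$tip.label, tr$tip.label][cbind(pairs[1, ], pairs[2, ])]
  fw <- fit_branch_lengths(tr, D, weighting = "fm")
  bw <- oracle_branch_lengths(tr, D, w = 1 / pmax(y, 1e-4)^2)
  expect_equal(sum(fw$edge.length[re]), bw[re[1]], tolerance = 1e-9)
})

test_that("fit_branch_lengths rejects incomplete inputs and clamps negatives", {
  tr <- species_tree(ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);"),
                     units = "subs")
  D <- ape::cophenetic.phylo(tr)
  expect_error(fit_branch_lengths(tr, D[1:3, 1:3]), "cover")
  D2 <- D; D2["a", "b"] <- D2["b", "a"] <- NA
  expect_error(fit_branch_lengths(tr, D2), "NA")
  # force a negative OLS solution: strongly non-additive matrix
  D3 <- D; D3["a", "b"] <- D3["b", "a"] <- 6  # others stay ~2-4
  ft <- fit_branch_lengths(tr, D3)
  expect_true(all(ft$edge.length >= 0))
})
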