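test_that("mmb_shortening reproduces the anchored per-10-Myr constants", {
  cal <- rate_calibration()
  expect_equal(mmb_shortening(6, 10, cal), 0.0227)
  expect_equal(round(mmb_shortening(2.4, 10, cal), 4), 0.0091)
  expect_equal(round(mmb_shortening(4, 10, cal), 4), 0.0151)
  expect_equal(mmb_shortening(4, 180, cal), 0.2724)
  # zero duration is zero shortening in both modes, for any alpha
  mi <- rate_calibration(mode = "miyata")
  for (a in c(1, 1.8, 2.4, 4, 6, 18)) {
    expect_equal(mmb_shortening(a, 0, cal), 0)
    expect_equal(mmb_shortening(a, 0, mi), 0)
  }
  expect_equal(mmb_shortening(1, 50, mi), 0)  # no bias, no deficit
})

test_that("shortening is linear (paper_linear) and increasing in alpha", {
  cal <- rate_calibration()
  mi <- rate_calibration(mode = "miyata")
  alphas <- seq(1, 12, by = 0.5)
  lin <- mmb_shortening(alphas, 10, cal)
  expect_equal(lin, (0.0227 / 6) * alphas, tolerance = 1e-12)
  expect_true(all(diff(lin) > 0))
  expect_true(all(diff(mmb_shortening(alphas, 10, mi)) > 0))
})

test_that("miyata-mode shortening matches the X/A rate-deficit identity", {
  mi <- rate_calibration(mode = "miyata")
  for (a in c(1, 1.8, 2.4, 4, 6, 11)) {
    for (t in c(10, 37, 170)) {
      got <- mmb_shortening(a, t, mi) / (mi$mu * t * 1e6)
      expect_equal(got, 1 - 2 * (2 + a) / (3 * (1 + a)), tolerance = 1e-12)
    }
  }
})

test_that("scenario grids enumerate the null plus one step per retention time", {
  g <- scenario_grid("x", 4, system_age = 20, step = 10)
  expect_length(g, 3)
  expect_equal(vapply(g, function(s) s$lineages$retention_T, 0), c(0, 10, 20))
  expect_length(squamate_design(), 16)
  expect_length(mammal_design(), 18)
  expect_error(scenario_grid("x", 4, system_age = 25, step = 10), "divide")
  expect_error(lineage_scenario(data.frame(lineage = "x", alpha = 0.5,
                                           retention_T = 0), 170), "alpha")
  expect_error(lineage_scenario(data.frame(lineage = "x", alpha = 2,
                                           retention_T = 200), 170),
               "retention_T")
})

test_that("published shortening constants are stored verbatim", {
  k <- published_shortening_constants
  expect_equal(unname(k["squamate_alpha1.8"]), 0.00683)
  expect_equal(unname(k["platypus_alpha2.9"]), 0.0113)
  expect_equal(unname(k[c("placental_alpha1.6_2", "placental_alpha2.9_3.3",
                          "placental_alpha6")]), c(0.122, 0.198, 0.39))
})

test_that("apply_scenario is the identity at T = 0 and local for one branch", {
  phy <- ape::read.tree(text = "((a:50,b:50):100,c:150);")
  tr <- myr_to_substitutions(species_tree(phy, units = "myr"))
  cal <- rate_calibration()
  null_sc <- lineage_scenario(data.frame(lineage = "a", alpha = 4,
                                         retention_T = 0), system_age = 140)
  expect_equal(apply_scenario(tr, null_sc, cal)$edge.length, tr$edge.length)
  # window [100, 140] lies entirely inside the internal (a,b) stem branch
  sc <- lineage_scenario(data.frame(lineage = "a", alpha = 4,
                                    retention_T = 40), system_age = 140)
  out <- apply_scenario(tr, sc, cal)
  delta <- tr$edge.length - out$edge.length
  stem <- which(phy$edge[, 2] == ape::getMRCA(phy, 1:2))
  expect_equal(delta[stem], mmb_shortening(4, 40, cal))
  expect_equal(delta[-stem], rep(0, 3))
  expect_error(apply_scenario(tr, lineage_scenario(
    data.frame(lineage = "zz", alpha = 2, retention_T = 10), 140), cal),
    "zz")
})

test_that("shared branches use the averaged alpha of descendant tips", {
  phy <- ape::read.tree(text = "((a:50,b:50):100,c:150);")
  tr <- myr_to_substitutions(species_tree(phy, units = "myr"))
  cal <- rate_calibration()
  sc <- lineage_scenario(data.frame(lineage = c("a", "b"), alpha = c(2, 4),
                                    retention_T = 40), system_age = 140)
  out <- apply_scenario(tr, sc, cal)
  stem <- which(phy$edge[, 2] == ape::getMRCA(phy, 1:2))
  expect_equal((tr$edge.length - out$edge.length)[stem],
               mmb_shortening(3, 40, cal))
})

test_that("total shortening is conserved for single-tip lineages", {
  setup <- demo_tree()
  tr <- myr_to_substitutions(setup$tree)
  cal <- rate_calibration()
  sc <- lineage_scenario(data.frame(lineage = "agamid1", alpha = 4,
                                    retention_T = 80), system_age = 170)
  out <- apply_scenario(tr, sc, cal)
  expect_equal(sum(tr$edge.length) - sum(out$edge.length),
               mmb_shortening(4, 80, cal))
  expect_equal(nrow(attr(out, "clamp_report")), 0)
})

test_that("over-shortened branches are clamped to the floor and reported", {
  phy <- ape::read.tree(text = "((a:10,b:10):150,c:160);")
  tr <- myr_to_substitutions(species_tree(phy, units = "myr"))
  cal <- rate_calibration()
  # alpha 6 deficit over the 10-Myr pendant window exceeds the pendant length
  sc <- lineage_scenario(data.frame(lineage = "a", alpha = 6,
                                    retention_T = 160), system_age = 160)
  expect_warning(out <- apply_scenario(tr, sc, cal), "clamped")
  expect_true(all(out$edge.length >= cal$clamp_floor))
  expect_gt(nrow(attr(out, "clamp_report")), 0)
})
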