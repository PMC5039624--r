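test_that("combined shift follows the alpha-scaled root-sum-square", {
  expect_equal(combined_shift(0, 0), 0)
  expect_equal(combined_shift(0.10, 0), 0.10)
  # sqrt(0.03^2 + (0.15*0.20)^2) = sqrt(0.0009 + 0.0009)
  expect_equal(combined_shift(0.03, 0.20), sqrt(0.0018), tolerance = 1e-10)
  expect_equal(combined_shift(0.03, 0.20), 0.042426, tolerance = 1e-4)
  expect_error(combined_shift(Inf, 0), class = "cspmap_validation_error")
  expect_error(combined_shift(0.1, 0.1, alpha = 0),
               class = "cspmap_validation_error")
})

test_that("combined shift is sign-symmetric and monotone in |dH|, |dN|", {
  set.seed(11)
  for (i in 1:50) {
    dH <- stats::runif(1, -0.3, 0.3); dN <- stats::runif(1, -2, 2)
    expect_equal(combined_shift(dH, dN), combined_shift(-dH, -dN))
    expect_gte(combined_shift(dH * 1.5, dN), combined_shift(dH, dN))
    expect_gte(combined_shift(dH, dN * 1.5), combined_shift(dH, dN))
  }
})

test_that("csp_profile computes per-point shifts relative to the reference", {
  ref <- make_pl(c("R24", "N13", "G3"), c(8.40, 8.10, 8.00),
                 c(121.0, 118.0, 110.0))
  pt <- make_pl(c("R24", "N13", "G3"), c(8.43, 8.10, 8.00),
                c(121.2, 118.0, 110.0), conc = 60)
  prof <- csp_profile(match_series(ref, list(pt)))
  r24 <- prof[prof$assignment == "R24", ]
  expect_equal(r24$combined, combined_shift(0.03, 0.20), tolerance = 1e-10)
  # unmoved residues give an all-zero profile
  expect_equal(prof$combined[prof$assignment == "N13"], 0)
})

test_that("residues absent at the endpoint are flagged, not dropped", {
  ref <- make_pl(c("R24", "N13", "G3", "K4"), c(8.4, 8.1, 8.0, 7.9),
                 c(121, 118, 110, 115))
  pt <- make_pl(c("N13", "G3", "K4"), c(8.1, 8.0, 7.9), c(118, 110, 115),
                conc = 60)
  prof <- csp_profile(match_series(ref, list(pt)))
  expect_true(prof$missing[prof$assignment == "R24"])
  res <- significance_cutoff(prof)
  expect_equal(res$broadened_out, "R24")
})

test_that("SD cutoff is the population SD with strict exceedance", {
  res <- significance_cutoff(c(a = 0, b = 0, c = 0, d = 1))
  expect_equal(res$cutoff, sqrt(0.1875), tolerance = 1e-12)  # 0.4330
  expect_equal(res$significant, "d")
  # degenerate: equal positive values -> SD 0, all significant
  res2 <- significance_cutoff(c(a = 0.1, b = 0.1, c = 0.1))
  expect_equal(res2$cutoff, 0)
  expect_setequal(res2$significant, c("a", "b", "c"))
  # all zero -> empty significant set
  expect_length(significance_cutoff(c(a = 0, b = 0, c = 0))$significant, 0)
  expect_error(significance_cutoff(c(a = 1, b = 2)),
               class = "cspmap_validation_error")
})

test_that("sidechain peaks are excluded from the backbone SD pool", {
  ref <- make_pl(c("R24", "N13", "G3", "W25"), c(8.4, 8.1, 8.0, 10.1),
                 c(121, 118, 110, 129), atom_group = c("bb", "bb", "bb", "sc"))
  pt <- make_pl(c("R24", "N13", "G3", "W25"), c(8.4, 8.1, 8.0, 10.9),
                c(121, 118, 110, 129), atom_group = c("bb", "bb", "bb", "sc"),
                conc = 60)
  res <- significance_cutoff(csp_profile(match_series(ref, list(pt))))
  expect_false("W25-sc" %in% names(res$endpoint))
  expect_equal(res$cutoff, 0)  # the large sidechain shift never enters
})

test_that("broadening percentages follow the scaled endpoint ratio", {
  ref <- make_pl(c("A1", "B2", "C3", "D4"), c(8, 8.1, 8.2, 8.3),
                 c(110, 111, 112, 113), intensity = c(1e6, 1e6, 1e6, 1e6))
  # endpoint: reference residues A1,B2 unchanged; C3 at 40%; D4 lost
  pt <- make_pl(c("A1", "B2", "C3"), c(8, 8.1, 8.2), c(110, 111, 112),
                intensity = c(1e6, 1e6, 4e5), conc = 60)
  br <- broadening_profile(match_series(ref, list(pt)),
                           reference_set = c("A1", "B2"))
  tab <- br$table
  expect_equal(tab$B[tab$assignment == "C3"], 60)
  expect_equal(tab$B[tab$assignment == "D4"], 100)
  expect_equal(tab$severity[tab$assignment == "D4"], "severe")
  expect_true(tab$B[tab$assignment == "C3"] > 0.5 * br$mean_broadening)
  expect_equal(tab$severity[tab$assignment == "C3"], "significant")
  # all ratios 1 -> zero broadening everywhere
  pt0 <- make_pl(c("A1", "B2", "C3", "D4"), c(8, 8.1, 8.2, 8.3),
                 c(110, 111, 112, 113), intensity = rep(1e6, 4), conc = 60)
  br0 <- broadening_profile(match_series(ref, list(pt0)), c("A1", "B2"))
  expect_true(all(br0$table$B == 0))
  expect_true(all(br0$table$severity == "none"))
})

test_that("broadening is invariant to global intensity rescaling of a point", {
  ref <- make_pl(c("A1", "B2", "C3", "D4"), c(8, 8.1, 8.2, 8.3),
                 c(110, 111, 112, 113), intensity = c(1e6, 9e5, 1e6, 8e5))
  mk <- function(scale) make_pl(c("A1", "B2", "C3", "D4"),
                                c(8, 8.1, 8.2, 8.3), c(110, 111, 112, 113),
                                intensity = scale * c(1e6, 9e5, 3e5, 2e5),
                                conc = 60)
  b1 <- broadening_profile(match_series(ref, list(mk(1))), c("A1", "B2"))
  b2 <- broadening_profile(match_series(ref, list(mk(7.3))), c("A1", "B2"))
  expect_equal(b1$table$B, b2$table$B, tolerance = 1e-12)
  expect_equal(b1$mean_broadening, b2$mean_broadening, tolerance = 1e-12)
})

test_that("broadening requires a usable normalisation reference", {
  ref <- make_pl(c("A1", "B2"), c(8, 8.1), c(110, 111))
  pt <- make_pl("B2", 8.1, 111, conc = 60)
  expect_error(broadening_profile(match_series(ref, list(pt)), "Z9"),
               "absent", class = "cspmap_validation_error")
  expect_error(broadening_profile(match_series(ref, list(pt)), "A1"),
               "lost", class = "cspmap_data_error")
})

test_that("trajectory colinearity is the cosine in (dH, alpha*dN) space", {
  ref <- make_pl(c("A1", "B2", "C3"), c(8, 8.1, 8.2), c(110, 111, 112))
  mk <- function(dH, dN) make_pl(c("A1", "B2", "C3"),
                                 c(8, 8.1, 8.2) + dH, c(110, 111, 112) + dN,
                                 conc = 60)
  sA <- match_series(ref, list(mk(c(0.1, 0.1, 0), c(0, 0.5, 0))))
  sB <- match_series(ref, list(mk(c(0.1, 0.2, 0), c(0, 1.0, 0))))
  tc <- trajectory_colinearity(sA, sB)
  expect_equal(tc$cosine[tc$assignment == "A1"], 1.0, tolerance = 1e-12)
  expect_equal(tc$cosine[tc$assignment == "B2"], 1.0, tolerance = 1e-12)
  expect_true(tc$indeterminate[tc$assignment == "C3"])  # below noise floor
  # orthogonal endpoint vectors
  sC <- match_series(ref, list(mk(c(0, 0.1, 0), c(0.1 / 0.15, 0, 0))))
  tc2 <- trajectory_colinearity(sA, sC)
  expect_equal(tc2$cosine[tc2$assignment == "A1"], 0, tolerance = 1e-12)
})
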