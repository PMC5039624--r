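test_that("evidence maps to the expected active/passive sets", {
  spec <- select_active_passive(example_interface_evidence())
  expect_setequal(spec$partners$A$active, c("R24", "W25"))
  expect_setequal(spec$partners$A$passive, c("K10", "W27", "F34"))
  expect_setequal(spec$partners$B$active, c("E45", "Q49", "E107"))
  expect_setequal(spec$partners$B$passive,
                  c("V43", "Y46", "T47", "L50", "S51", "L55",
                    "F116", "V119", "R123", "I127"))
  expect_true(all(c("G101", "F137", "L148") %in%
                    setdiff(example_interface_evidence()$residue,
                            unlist(spec$partners))))
})

test_that("buried mutagenesis hits are excluded with a warning", {
  ev <- example_interface_evidence()
  ev$surface_exposed[ev$residue == "E45"] <- FALSE
  expect_warning(spec <- select_active_passive(ev), "E45")
  expect_false("E45" %in% spec$partners$B$active)
  expect_equal(spec$excluded, "E45")
})

test_that("empty evidence yields an empty spec and blocks emission", {
  ev <- example_interface_evidence()
  ev$severity <- "none"; ev$csp_significant <- FALSE
  ev$mutagenesis_hit <- FALSE
  spec <- select_active_passive(ev)
  expect_length(spec$partners$A$active, 0)
  expect_error(emit_air_tbl(spec), class = "cspmap_data_error")
})

test_that("AIR statement count equals |active(A)| + |active(B)|", {
  spec <- select_active_passive(example_interface_evidence())
  lines <- emit_air_tbl(spec)
  expect_length(lines, 2 + 3)
  # a single active residue against a 3-residue opposing set: one statement
  # whose selection has exactly three or-joined terms
  mini <- structure(list(partners = list(
    A = list(active = "R24", passive = character()),
    B = list(active = c("E45", "Q49", "E107"), passive = character())),
    excluded = character()), class = "interface_spec")
  one <- emit_air_tbl(mini)[1]
  expect_equal(lengths(regmatches(one, gregexpr(" or ", one))), 2)
  expect_match(one, "^assign \\(segid A and resid 24\\)")
  expect_match(one, "2\\.0 2\\.0 0\\.0$")
})

test_that("AIR emission round-trips byte-identically through the reader", {
  spec <- select_active_passive(example_interface_evidence())
  lines <- emit_air_tbl(spec, distance = 2.0, minus = 2.0, plus = 0.0)
  parsed <- parse_air_tbl(lines)
  expect_equal(nrow(parsed), length(lines))
  rebuilt <- vapply(seq_len(nrow(parsed)), function(i)
    cspmap:::air_record_to_line(parsed[i, ]), character(1))
  expect_identical(rebuilt, lines)
  expect_true(all(parsed$target - parsed$minus >= 0))
})

test_that("sequence-range classification matches its definitions", {
  expect_equal(classify_restraint_range(5, 5), "intraresidue")
  expect_equal(classify_restraint_range(3, 4), "sequential")
  expect_equal(classify_restraint_range(2, 10), "long")
  expect_equal(classify_restraint_range(2, 6), "medium")  # |i-j| = 4
  expect_equal(classify_restraint_range(2, 7), "long")    # |i-j| = 5
  # symmetry
  expect_equal(classify_restraint_range(10, 2), classify_restraint_range(2, 10))
  expect_error(classify_restraint_range(0, 3),
               class = "cspmap_validation_error")
})

test_that("classification agrees with brute-force binning on random pairs", {
  set.seed(99)
  i <- sample.int(150, 1e4, replace = TRUE)
  j <- sample.int(150, 1e4, replace = TRUE)
  got <- classify_restraint_range(i, j)
  oracle <- character(1e4)
  for (k in seq_len(1e4)) {          # independent loop oracle
    d <- abs(i[k] - j[k])
    oracle[k] <- if (d == 0) "intraresidue" else if (d == 1) "sequential"
    else if (d < 5) "medium" else "long"
  }
  expect_identical(got, oracle)
})

test_that("restraint accounting partitions and totals the input", {
  s <- restraint_stats(c(intraresidue = 193, sequential = 206,
                         medium = 116, long = 179))
  expect_equal(s$total, 694)
  empty <- restraint_stats(data.frame(residue_i = integer(),
                                      residue_j = integer()))
  expect_true(all(unlist(empty) == 0))
  set.seed(5)
  rec <- data.frame(residue_i = sample.int(30, 10, TRUE),
                    residue_j = sample.int(30, 10, TRUE))
  s2 <- restraint_stats(rec)
  cls <- classify_restraint_range(rec$residue_i, rec$residue_j)
  for (cc in c("intraresidue", "sequential", "medium", "long"))
    expect_equal(s2[[cc]], sum(cls == cc))
  expect_equal(s2$total, 10)
})

test_that("painting sets B-factors per residue and preserves other bytes", {
  pdb <- pdb_fixture()
  out <- paint_structure(pdb, c("24" = 100))
  atom24 <- grepl("ARG A  24", out)
  expect_true(all(substr(out[atom24], 61, 66) == "100.00"))
  expect_identical(nchar(out[atom24]), nchar(pdb[atom24]))
  # everything except columns 61-66 of painted ATOM records is untouched
  for (k in which(atom24)) {
    expect_identical(substr(out[k], 1, 60), substr(pdb[k], 1, 60))
    expect_identical(substr(out[k], 67, nchar(out[k])),
                     substr(pdb[k], 67, nchar(pdb[k])))
  }
  expect_identical(out[!atom24], pdb[!atom24])
  # empty map: identity
  expect_identical(as.character(paint_structure(pdb, stats::setNames(numeric(0), character(0)))),
                   pdb)
})

test_that("painting then extracting recovers the value map", {
  pdb <- pdb_fixture()
  out <- paint_structure(pdb, c("A:24" = 100, "A:25" = 50))
  b <- extract_bfactors(out)
  expect_equal(b$b[b$resseq == 24], 100)
  expect_equal(b$b[b$resseq == 25], 50)
  # categories encode 0/50/100
  out2 <- paint_structure(pdb, c("24" = "severe", "25" = "passive"))
  b2 <- extract_bfactors(out2)
  expect_equal(b2$b, c(100, 50))
  expect_warning(paint_structure(pdb, c("999" = 1)), "not found")
})
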