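test_that("shipped panel has the full indicator set with printed cut-offs", {
  tab <- MK$table
  expect_equal(nrow(tab), 74)
  expect_equal(sum(tab$kind == "ratio"), 31)
  expect_equal(length(MK$ratios), 31)
  # spot-check printed ranges
  expect_equal(unlist(tab[tab$name == "PHE", c("low", "high")],
                      use.names = FALSE), c(23, 100))
  expect_equal(unlist(tab[tab$name == "C0", c("low", "high")],
                      use.names = FALSE), c(9, 50))
  expect_equal(unlist(tab[tab$name == "C5DC + C6OH", c("low", "high")],
                      use.names = FALSE), c(0.03, 0.25))
  # combined channels are measured, never formulas
  expect_true(all(tab$kind[tab$name %in%
    c("C3DC + C4OH", "C4DC + C5OH", "C5DC + C6OH",
      "LEU + ILE + PRO-OH")] == "combined"))
  expect_false("C3DC+C4OH" %in% names(MK$ratios))
})

test_that("panel configuration round-trips losslessly and rejects duplicates", {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp), add = TRUE)
  write_markers(MK, tmp)
  reloaded <- nbs_markers(tmp)
  expect_equal(reloaded$table, MK$table)
  expect_equal(names(reloaded$ratios), names(MK$ratios))

  dup <- yaml::read_yaml(system.file("extdata", "markers.yaml",
                                     package = "nbscreen"))
  dup$markers[[length(dup$markers) + 1]] <-
    list(name = "C0", kind = "raw", low = 1, high = 2)
  tmp2 <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp2), add = TRUE)
  yaml::write_yaml(dup, tmp2)
  expect_error(nbs_markers(tmp2), "duplicate")
})

test_that("ratio derivation matches printed arithmetic and leaves raw values", {
  rec <- suppressWarnings(compute_derived_markers(c(C3 = 1.0, C2 = 10.0), MK))
  expect_identical(rec[["C3/C2"]], 0.1)
  rec2 <- suppressWarnings(compute_derived_markers(
    c(C0 = 10, C2 = 5, C3 = 1, C16 = 2, "C18:1" = 1, C18 = 1, CIT = 10), MK))
  expect_identical(rec2[["(C0 + C2 + C3 + C16 + C18:1 + C18)/CIT"]], 2.0)
  expect_identical(rec2[["C0"]], 10)
})

test_that("derivation equals the straight-line oracle and is idempotent", {
  set.seed(42)
  for (i in 1:100) {
    raw <- random_measured_panel(wild = FALSE)
    rec <- compute_derived_markers(raw, MK)
    expected <- oracle_ratios(raw)
    expect_equal(rec[names(expected)], expected, tolerance = 1e-12)
    expect_equal(compute_derived_markers(rec, MK), rec, tolerance = 0)
  }
})

test_that("missing operands and zero denominators leave ratios absent", {
  expect_warning(rec <- compute_derived_markers(c(C3 = 1), MK),
                 "missing operand")
  expect_false("C3/C2" %in% names(rec))
  expect_warning(rec2 <- compute_derived_markers(c(C3 = 1, C2 = 0), MK),
                 "zero denominator")
  expect_false("C3/C2" %in% names(rec2))
  # a directly reported ratio survives derivation even without operands
  rec3 <- suppressWarnings(compute_derived_markers(
    c(C5 = 0.45, "(C5DC + C6OH)/(C3DC + C4OH)" = 5.0), MK))
  expect_identical(rec3[["(C5DC + C6OH)/(C3DC + C4OH)"]], 5.0)
})

test_that("reference flagging uses a closed normal interval", {
  fl <- flag_out_of_range(c(PHE = 444.79), MK)
  expect_equal(fl$marker, "PHE")
  expect_equal(fl$direction, "high")
  fl2 <- flag_out_of_range(c(C12 = 0.66), MK)
  expect_equal(fl2$direction, "high")
  # midpoints are normal, and so are values exactly at the bounds
  mp <- midpoint_panel(MK)
  expect_equal(nrow(flag_out_of_range(compute_derived_markers(mp, MK), MK)), 0)
  tab <- MK$table[MK$table$kind != "ratio", ]
  at_low <- stats::setNames(tab$low, tab$name)
  expect_equal(nrow(flag_out_of_range(at_low, MK)), 0)
  at_high <- stats::setNames(tab$high, tab$name)
  expect_equal(nrow(flag_out_of_range(at_high, MK)), 0)
  # unknown markers are skipped with a message, not an error
  expect_message(flag_out_of_range(c(XYZ = 1, PHE = 50), MK), "XYZ")
})
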