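test_that("shipped rule set encodes the printed positive rules", {
  expect_s3_class(RL, "nbs_rules")
  expect_equal(length(RL), 26)
  # primary carnitine deficiency: a strict C0 rule or a milder C0 rule
  # conjoined with the total-esterified-over-citrulline ratio
  pcd <- RL[["PCD"]]
  expect_equal(length(pcd$groups), 2)
  expect_equal(pcd$groups[[1]]$key, "C0")
  expect_equal(pcd$groups[[1]]$cmp, "lt")
  expect_equal(pcd$groups[[1]]$threshold, 8.5)
  expect_equal(pcd$groups[[2]]$threshold, c(9.0, 1.3))
  expect_equal(pcd$groups[[2]]$cmp, c("lt", "le"))
  # hyperphenylalaninemia has three alternative groups
  expect_equal(length(RL[["HPA"]]$groups), 3)
  expect_equal(RL[["HPA"]]$groups[[2]]$threshold, 120)
  # printed comparators preserved exactly
  expect_equal(RL[["HPA"]]$groups[[1]]$cmp, c("gt", "ge"))
  expect_equal(RL[["MCC_HCS"]]$groups[[1]]$cmp, c("gt", "ge"))
})

test_that("a rule referencing an unknown marker is rejected by name", {
  cfg <- list(rules = list(list(
    id = "BAD", name = "bad rule", category = "FAOD",
    groups = list(list("C99 > 1")))))
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp), add = TRUE)
  yaml::write_yaml(cfg, tmp)
  expect_error(nbs_rules(tmp, markers = MK), "BAD.*C99")
})

test_that("record evaluation flags the printed worked cases", {
  mp <- midpoint_panel(MK)
  flag_ids <- function(rec) evaluate_record(rec, RL)$disorder

  low_c0 <- compute_derived_markers(replace(mp, "C0", 5.15), MK)
  expect_true("PCD" %in% flag_ids(low_c0))
  pcd_row <- evaluate_record(low_c0, RL)
  expect_equal(pcd_row$group[pcd_row$disorder == "PCD"], 1L)

  high_phe <- compute_derived_markers(replace(mp, "PHE", 745.62), MK)
  expect_true("HPA" %in% flag_ids(high_phe))

  high_c4 <- compute_derived_markers(replace(mp, "C4", 1.46), MK)
  expect_true("SCADD" %in% flag_ids(high_c4))

  expect_equal(nrow(evaluate_record(compute_derived_markers(mp, MK), RL)), 0)
})

test_that("threshold ties honour the printed comparator strictly", {
  mp <- midpoint_panel(MK)
  at_100 <- compute_derived_markers(replace(mp, "PHE", 100), MK)
  expect_false("HPA" %in% evaluate_record(at_100, RL)$disorder)
  just_over <- compute_derived_markers(replace(mp, "PHE", 120.0001), MK)
  expect_true("HPA" %in% evaluate_record(just_over, RL)$disorder)
  # ">=" is satisfied exactly at the threshold: C5:1 >= 0.01 plus the
  # conjoined hydroxyacylcarnitine elevation
  rec <- compute_derived_markers(
    replace(replace(mp, "C5:1", 0.01), "C4DC + C5OH", 0.45), MK)
  expect_true("BKT" %in% evaluate_record(rec, RL)$disorder)
})

test_that("raising a marker under a 'gt' condition never un-flags", {
  mp <- midpoint_panel(MK)
  cases <- list(c(marker = "PHE", value = 130, rule = "HPA"),
                c(marker = "C8", value = 0.35, rule = "MCADD"),
                c(marker = "C4", value = 0.95, rule = "SCADD"),
                c(marker = "TYR", value = 430, rule = "TYR23"))
  for (cs in cases) {
    rec <- replace(mp, cs[["marker"]], as.numeric(cs[["value"]]))
    for (mult in c(1, 2, 5, 20)) {
      r <- replace(rec, cs[["marker"]],
                   as.numeric(cs[["value"]]) * mult)
      flags <- evaluate_record(compute_derived_markers(r, MK), RL)
      expect_true(cs[["rule"]] %in% flags$disorder,
                  label = paste(cs[["rule"]], "at", mult, "x"))
    }
  }
})

test_that("vectorised screening equals per-record evaluation and the oracle", {
  set.seed(7)
  n <- 100
  tab <- MK$table[MK$table$kind != "ratio", ]
  panels <- matrix(NA_real_, n, nrow(tab), dimnames = list(NULL, tab$name))
  for (i in seq_len(n)) panels[i, ] <- random_measured_panel()
  full <- derive_ratio_columns_test(panels)
  scr <- screen_cohort(full, RL)
  for (i in seq_len(n)) {
    rec <- compute_derived_markers(panels[i, ], MK)
    per_record <- sort(evaluate_record(rec, RL)$disorder)
    oracle <- oracle_flagged(rec, RL)
    vectorised <- sort(colnames(scr$flagged)[scr$flagged[i, ]])
    expect_identical(per_record, oracle)
    expect_identical(vectorised, oracle)
  }
})

test_that("triage applies the k-fold urgency policy", {
  mp <- midpoint_panel(MK)
  none <- evaluate_record(compute_derived_markers(mp, MK), RL)
  expect_identical(triage(none), "negative")
  # C0 = 1.94 is below 8.5 / 2: immediate referral
  severe <- evaluate_record(
    compute_derived_markers(replace(mp, "C0", 1.94), MK), RL)
  expect_identical(triage(severe, k = 2), "clear_aberrant")
  # Phe = 105.43 with tyrosine low enough to co-flag is a mild positive
  rec <- replace(replace(mp, "PHE", 105.43), "TYR", 60)
  mild <- evaluate_record(compute_derived_markers(rec, MK), RL)
  expect_true(nrow(mild) > 0)
  expect_identical(triage(mild, k = 2), "mild_positive")
  expect_error(triage(mild, k = 1), "k > 1")
  expect_error(triage(mild, k = 0.5), "k > 1")
})
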