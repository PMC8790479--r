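# Shared fixtures: load the shipped panel and rules once per test run.
MK <- nbs_markers()
RL <- nbs_rules(markers = MK)

# Independent straight-line re-evaluation of every ratio formula, written out
# by hand (no parsing): the oracle for the ratio-derivation engine.
oracle_ratios <- function(v) {
  g <- function(nm) v[[nm]]
  c(
    "ARG/PHE" = g("ARG") / g("PHE"),
    "(C4DC + C5OH)/C0" = g("C4DC + C5OH") / g("C0"),
    "MET/PHE" = g("MET") / g("PHE"),
    "MET/CIT" = g("MET") / g("CIT"),
    "ORN/CIT" = g("ORN") / g("CIT"),
    "ARG/ORN" = g("ARG") / g("ORN"),
    "ALA/CIT" = g("ALA") / g("CIT"),
    "CIT/PHE" = g("CIT") / g("PHE"),
    "PHE/TYR" = g("PHE") / g("TYR"),
    "SA/PHE" = g("SA") / g("PHE"),
    "TYR/PHE" = g("TYR") / g("PHE"),
    "(LEU + ILE + PRO-OH)/PHE" = g("LEU + ILE + PRO-OH") / g("PHE"),
    "(LEU + ILE + PRO-OH)/TYR" = g("LEU + ILE + PRO-OH") / g("TYR"),
    "C0/(C16 + C18)" = g("C0") / (g("C16") + g("C18")),
    "C3/C0" = g("C3") / g("C0"),
    "C3/C2" = g("C3") / g("C2"),
    "C3/MET" = g("C3") / g("MET"),
    "C4/C2" = g("C4") / g("C2"),
    "C4/C3" = g("C4") / g("C3"),
    "C5/C0" = g("C5") / g("C0"),
    "C8/C2" = g("C8") / g("C2"),
    "C8/C10" = g("C8") / g("C10"),
    "C14:1/C2" = g("C14:1") / g("C2"),
    "C14:1/C16" = g("C14:1") / g("C16"),
    "C16OH/C16" = g("C16OH") / g("C16"),
    "(C16 + C18:1)/C2" = (g("C16") + g("C18:1")) / g("C2"),
    "(C3DC + C4OH)/C10" = g("C3DC + C4OH") / g("C10"),
    "(C5DC + C6OH)/(C3DC + C4OH)" = g("C5DC + C6OH") / g("C3DC + C4OH"),
    "(C5DC + C6OH)/(C4DC + C5OH)" = g("C5DC + C6OH") / g("C4DC + C5OH"),
    "(C0 + C2 + C3 + C16 + C18:1 + C18)/CIT" =
      (g("C0") + g("C2") + g("C3") + g("C16") + g("C18:1") + g("C18")) /
        g("CIT"),
    "(C4DC + C5OH)/C8" = g("C4DC + C5OH") / g("C8")
  )
}

# Brute-force rule oracle: enumerate every (rule, group, condition) directly
# against a named record, with an explicit comparator switch.  Absent or NA
# markers make a condition false.
oracle_flagged <- function(record, rules) {
  keys <- gsub("[[:space:]]+", "", names(record))
  vals <- stats::setNames(as.numeric(record), keys)
  hits <- character()
  for (r in rules) {
    rule_hit <- FALSE
    for (g in r$groups) {
      all_ok <- TRUE
      for (i in seq_len(nrow(g))) {
        v <- if (g$key[i] %in% keys) vals[[g$key[i]]] else NA_real_
        ok <- if (is.na(v)) FALSE else switch(g$cmp[i],
          gt = v > g$threshold[i], ge = v >= g$threshold[i],
          lt = v < g$threshold[i], le = v <= g$threshold[i])
        if (!ok) { all_ok <- FALSE; break }
      }
      if (all_ok) { rule_hit <- TRUE; break }
    }
    if (rule_hit) hits <- c(hits, r$id)
  }
  sort(hits)
}

# A random measured-marker panel: log-normal spread around the cut-off
# midpoints with occasional extreme excursions, so rules actually fire.
random_measured_panel <- function(markers = MK, wild = TRUE) {
  tab <- markers$table[markers$table$kind != "ratio", ]
  mid <- pmax((tab$low + tab$high) / 2, 1e-4)
  v <- mid * exp(stats::rnorm(nrow(tab), 0, 0.6))
  if (wild) {
    k <- sample.int(nrow(tab), 3)
    v[k] <- v[k] * stats::runif(3, 0.05, 20)
  }
  stats::setNames(v, tab$name)
}

# Complete a confirmed case's printed abnormal values with midpoints for all
# unprinted measured markers, derive ratios, then overlay any printed ratio
# values (a reported ratio supersedes the midpoint-derived one).
build_case_record <- function(case_rows, markers = MK) {
  rec <- midpoint_panel(markers)
  keys <- gsub("[[:space:]]+", "", names(rec))
  ratio_rows <- gsub("[[:space:]]+", "", case_rows$marker) %in%
    names(markers$ratios)
  for (i in which(!ratio_rows)) {
    j <- match(gsub("[[:space:]]+", "", case_rows$marker[i]), keys)
    rec[[j]] <- case_rows$value[i]
  }
  rec <- compute_derived_markers(rec, markers)
  keys <- gsub("[[:space:]]+", "", names(rec))
  for (i in which(ratio_rows)) {
    j <- match(gsub("[[:space:]]+", "", case_rows$marker[i]), keys)
    rec[[j]] <- case_rows$value[i]
  }
  rec
}

# Vectorised ratio derivation over a measured-marker matrix (display-name
# columns), through the package's matrix path.
derive_ratio_columns_test <- function(panels) {
  m <- panels
  colnames(m) <- gsub("[[:space:]]+", "", colnames(m))
  nbscreen:::derive_ratio_columns(m, MK)
}

# Fixture rows whose printed marker values cannot satisfy any rule group once
# completed with in-range midpoints (verified by hand against the printed
# thresholds): borderline citrulline/phenylalanine elevations below the
# conjunctive rule thresholds, C5/C3 elevations short of the single-marker
# thresholds, and cases whose printed markers do not appear in their
# disorder's rule.
CASES_NOT_FLAGGABLE <- c("AA03", "AA17", "AA21", "AA22",
                         "OA04", "OA05", "OA07", "FA23", "FA24")
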