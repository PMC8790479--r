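#' Load the disorder positive-rule set
#'
#' Reads a structured rule configuration (YAML).  Each rule screens for one
#' disorder (or a group of disorders sharing a biochemical signature, whose
#' OMIM codes are all carried on the flag) and consists of a *disjunction* of
#' rule groups; the threshold conditions within one group are a
#' *conjunction*.  Printed comparators (`>`, `>=`, `<`, `<=`) are preserved
#' exactly: a value exactly at a strict threshold does not satisfy the
#' condition.
#'
#' @param path path to a rule configuration; defaults to the shipped panel
#'   rule set covering the 41 screened disorders in 26 rule rows.
#' @param markers an `nbs_markers` panel; every marker referenced by a rule
#'   must be defined in it.
#' @return an object of class `nbs_rules`: a list of rules, each with `id`,
#'   `name`, `omim`, `category` (`AAMD`/`OAMD`/`FAOD`) and `groups`, a list
#'   of data frames with columns `marker`, `key`, `cmp`
#'   (`gt`/`ge`/`lt`/`le`) and `threshold`.
#' @examples
#' rules <- nbs_rules()
#' rules[["PCD"]]$groups
#' @export
nbs_rules <- function(path = NULL, markers = nbs_markers()) {
  path <- path %||% nbs_extdata("rules.yaml")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$rules) || !length(cfg$rules)) {
    stop("rule configuration has no 'rules' entries: ", path)
  }
  defined <- markers$table$key
  rules <- lapply(cfg$rules, function(r) {
    for (field in c("id", "name", "category", "groups")) {
      if (is.null(r[[field]])) {
        stop("rule entry is missing field '", field, "'")
      }
    }
    if (!r$category %in% c("AAMD", "OAMD", "FAOD")) {
      stop("rule '", r$id, "': unknown category '", r$category, "'")
    }
    if (!length(r$groups)) stop("rule '", r$id, "' has no groups")
    groups <- lapply(r$groups, function(conds) {
      if (!length(conds)) stop("rule '", r$id, "' has an empty group")
      parsed <- lapply(conds, parse_condition, rule_id = r$id)
      g <- do.call(rbind, parsed)
      bad <- setdiff(g$key, defined)
      if (length(bad)) {
        stop("rule '", r$id, "' references unknown marker(s): ",
             paste(bad, collapse = ", "))
      }
      g
    })
    list(id = r$id, name = r$name,
         omim = as.character(unlist(r$omim %||% character())),
         category = r$category, groups = groups)
  })
  names(rules) <- vapply(rules, `[[`, "", "id")
  if (anyDuplicated(names(rules))) {
    stop("duplicate rule id(s): ",
         paste(unique(names(rules)[duplicated(names(rules))]), collapse = ", "))
  }
  structure(rules, class = "nbs_rules")
}

# "PHE/TYR >= 1.4" -> marker "PHE/TYR", cmp "ge", threshold 1.4.
# The comparator is located from the right so marker names containing '/',
# '+' or '-' parse unambiguously.
parse_condition <- function(text, rule_id = "?") {
  m <- regmatches(text, regexec("^(.*?)\\s*(>=|<=|>|<)\\s*([0-9.]+)\\s*$", text))[[1]]
  if (length(m) != 4L) {
    stop("rule '", rule_id, "': cannot parse condition '", text, "'")
  }
  cmp <- c(">" = "gt", ">=" = "ge", "<" = "lt", "<=" = "le")[[m[3]]]
  thr <- as.numeric(m[4])
  if (!is.finite(thr)) {
    stop("rule '", rule_id, "': non-finite threshold in '", text, "'")
  }
  data.frame(marker = trimws(m[2]), key = norm_key(m[2]), cmp = cmp,
             threshold = thr, stringsAsFactors = FALSE)
}

cmp_fun <- function(cmp) {
  switch(cmp, gt = `>`, ge = `>=`, lt = `<`, le = `<=`,
         stop("unknown comparator '", cmp, "'"))
}

# Exceedance severity of a satisfied condition: how many-fold the value is
# beyond its threshold (value/threshold for upper rules, threshold/value for
# lower rules; a value of 0 under a lower rule is infinitely severe).
condition_severity <- function(value, cmp, threshold) {
  if (cmp %in% c("gt", "ge")) value / threshold
  else if (value == 0) Inf
  else threshold / value
}

#' Evaluate a panel record against the positive rules
#'
#' A disorder is flagged iff at least one of its rule groups has all
#' conditions true.  Conditions on absent (`NA` or missing) markers evaluate
#' to false, so a non-computable ratio can neither satisfy nor clear a group,
#' but single-marker groups on measured channels still fire.
#'
#' @param record named numeric vector with derived markers computed
#'   ([compute_derived_markers()]).
#' @param rules an `nbs_rules` rule set.
#' @return an object of class `nbs_flags`: a data frame sorted by disorder
#'   name with columns `disorder` (rule id), `name`, `category`, `group`
#'   (index of the first satisfied group), `margin` (max over that group's
#'   conditions of `|value - threshold| / threshold`) and `severity` (max
#'   exceedance fold over all satisfied groups, used for triage).
#' @examples
#' rec <- compute_derived_markers(c(midpoint_panel(), PHE = 745.62)[-39])
#' evaluate_record(rec, nbs_rules())
#' @export
evaluate_record <- function(record, rules) {
  stopifnot(inherits(rules, "nbs_rules"))
  vals <- stats::setNames(as.numeric(record), norm_key(names(record)))
  out <- list()
  for (r in rules) {
    first_group <- NA_integer_
    margin <- NA_real_
    severity <- -Inf
    for (gi in seq_along(r$groups)) {
      g <- r$groups[[gi]]
      sat <- TRUE
      g_margin <- 0
      g_sev <- 0
      for (ci in seq_len(nrow(g))) {
        v <- if (g$key[ci] %in% names(vals)) vals[[g$key[ci]]] else NA_real_
        ok <- !is.na(v) && cmp_fun(g$cmp[ci])(v, g$threshold[ci])
        if (!ok) { sat <- FALSE; break }
        g_margin <- max(g_margin, abs(v - g$threshold[ci]) / g$threshold[ci])
        g_sev <- max(g_sev, condition_severity(v, g$cmp[ci], g$threshold[ci]))
      }
      if (sat) {
        if (is.na(first_group)) { first_group <- gi; margin <- g_margin }
        severity <- max(severity, g_sev)
      }
    }
    if (!is.na(first_group)) {
      out[[length(out) + 1L]] <- data.frame(
        disorder = r$id, name = r$name, category = r$category,
        group = first_group, margin = margin, severity = severity,
        stringsAsFactors = FALSE
      )
    }
  }
  flags <- if (length(out)) do.call(rbind, out) else
    data.frame(disorder = character(), name = character(),
               category = character(), group = integer(),
               margin = numeric(), severity = numeric(),
               stringsAsFactors = FALSE)
  flags <- flags[order(flags$name), , drop = FALSE]
  rownames(flags) <- NULL
  class(flags) <- c("nbs_flags", "data.frame")
  flags
}

#' Triage a flagged record
#'
#' Maps a set of screen flags to a triage level.  `negative` if nothing is
#' flagged.  `clear_aberrant` if any satisfied condition's value is beyond
#' `k` times its threshold (value `> k * threshold` for upper rules, value
#' `< threshold / k` for lower rules): such newborns are referred for
#' confirmatory testing immediately, without a recall specimen.  Everything
#' else is `mild_positive` and enters the recall pathway.  The `k`-fold
#' boundary is a configurable operational policy, not a laboratory standard.
#'
#' @param flags an `nbs_flags` object from [evaluate_record()].
#' @param k urgency multiplier, must be `> 1`; default 2.
#' @return one of `"negative"`, `"mild_positive"`, `"clear_aberrant"`.
#' @export
triage <- function(flags, k = 2) {
  if (!is.numeric(k) || length(k) != 1L || k <= 1) {
    stop("triage policy requires an urgency multiplier k > 1")
  }
  if (!nrow(flags)) return("negative")
  if (max(flags$severity) > k) "clear_aberrant" else "mild_positive"
}

#' Screen a whole cohort against the positive rules (vectorised)
#'
#' Equivalent to running [evaluate_record()] and [triage()] on every newborn,
#' but evaluated column-wise for speed on cohorts of hundreds of thousands.
#'
#' @param cohort an `nbs_cohort` from [sample_cohort()], or a numeric matrix
#'   with one row per newborn and marker columns (ratios derived).
#' @param rules an `nbs_rules` rule set.
#' @param k triage urgency multiplier (see [triage()]).
#' @return a list with `suspected` (logical), `clear_aberrant` (logical),
#'   `severity` (numeric, `NA` where not suspected) and `flagged` (logical
#'   matrix newborns x rules).
#' @export
screen_cohort <- function(cohort, rules, k = 2) {
  if (!is.numeric(k) || length(k) != 1L || k <= 1) {
    stop("triage policy requires an urgency multiplier k > 1")
  }
  mat <- if (inherits(cohort, "nbs_cohort")) cohort$panels else cohort
  stopifnot(is.matrix(mat))
  colnames(mat) <- norm_key(colnames(mat))
  n <- nrow(mat)
  flagged <- matrix(FALSE, n, length(rules),
                    dimnames = list(NULL, names(rules)))
  severity <- rep(NA_real_, n)
  for (ri in seq_along(rules)) {
    r <- rules[[ri]]
    for (g in r$groups) {
      sat <- rep(TRUE, n)
      for (ci in seq_len(nrow(g))) {
        key <- g$key[ci]
        v <- if (key %in% colnames(mat)) mat[, key] else rep(NA_real_, n)
        ok <- cmp_fun(g$cmp[ci])(v, g$threshold[ci])
        ok[is.na(ok)] <- FALSE
        sat <- sat & ok
        if (!any(sat)) break
      }
      idx <- which(sat)
      if (!length(idx)) next
      flagged[idx, ri] <- TRUE
      for (ci in seq_len(nrow(g))) {
        v <- mat[idx, g$key[ci]]
        sev <- if (g$cmp[ci] %in% c("gt", "ge")) v / g$threshold[ci] else {
          s <- g$threshold[ci] / v
          s[v == 0] <- Inf
          s
        }
        severity[idx] <- pmax(severity[idx], sev, na.rm = TRUE)
      }
    }
  }
  suspected <- rowSums(flagged) > 0L
  list(
    suspected = suspected,
    clear_aberrant = suspected & !is.na(severity) & severity > k,
    severity = severity,
    flagged = flagged
  )
}

#' @export
print.nbs_rules <- function(x, ...) {
  cat("<nbs_rules> ", length(x), " screening rules (",
      sum(vapply(x, function(r) r$category, "") == "AAMD"), " AAMD, ",
      sum(vapply(x, function(r) r$category, "") == "OAMD"), " OAMD, ",
      sum(vapply(x, function(r) r$category, "") == "FAOD"), " FAOD)\n",
      sep = "")
  invisible(x)
}

#' @export
print.nbs_flags <- function(x, ...) {
  if (!nrow(x)) {
    cat("<nbs_flags> no disorders flagged\n")
  } else {
    cat("<nbs_flags> ", nrow(x), " disorder(s) flagged:\n", sep = "")
    print.data.frame(x)
  }
  invisible(x)
}
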