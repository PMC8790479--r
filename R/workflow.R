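#' Two-tier workflow parameters
#'
#' Operating characteristics of the screen / recall / confirm pathway.
#' Newborns with clear-aberrant first screens are referred for confirmatory
#' testing immediately; mild positives are recalled for a second specimen
#' with probability `recall_prob` (non-recalled newborns are counted as lost
#' and never diagnosed), re-flag with probability `tp_persist` when truly
#' affected and `fp_persist` otherwise, and referred newborns are confirmed
#' with probability `confirm_sens` when truly affected.  Confirmatory
#' testing (urine organic acids, pterin analysis, DHPR activity, gene
#' sequencing) is collapsed into a single Bernoulli step that is perfectly
#' specific: unaffected newborns are never confirmed.
#'
#' @param recall_prob probability a mild positive is successfully recalled;
#'   default 0.8765, the recall fraction the modelled programme reports.
#' @param tp_persist probability a truly affected flagged newborn re-flags
#'   at retest (default 1: a metabolic derangement persists).
#' @param fp_persist probability an unaffected flagged newborn re-flags at
#'   retest (default 0.05, of the order observed for elevated-C3 recalls).
#' @param confirm_sens probability confirmatory testing diagnoses a truly
#'   affected referred newborn.
#' @param k triage urgency multiplier (see [triage()]).
#' @param seed optional integer seed for the workflow's random draws.
#' @return a list of class `nbs_workflow_params`.
#' @export
workflow_params <- function(recall_prob = 0.8765, tp_persist = 1,
                            fp_persist = 0.05, confirm_sens = 1,
                            k = 2, seed = NULL) {
  prob <- c(recall_prob = recall_prob, tp_persist = tp_persist,
            fp_persist = fp_persist, confirm_sens = confirm_sens)
  if (any(prob < 0 | prob > 1)) {
    stop("workflow probabilities must lie in [0, 1]")
  }
  structure(list(recall_prob = recall_prob, tp_persist = tp_persist,
                 fp_persist = fp_persist, confirm_sens = confirm_sens,
                 k = k, seed = seed),
            class = "nbs_workflow_params")
}

#' Run the two-tier screening workflow on a cohort
#'
#' Screens every newborn with the positive rules, triages first-screen
#' results, and simulates recall, retest, referral and confirmation.
#'
#' @param cohort an `nbs_cohort` from [sample_cohort()].
#' @param rules an `nbs_rules` rule set.
#' @param params an [workflow_params()] object.
#' @return an object of class `nbs_workflow`: per-year counts (`screened`,
#'   `suspected`, `recalled`, `retest_positive`, `referred`, `confirmed`),
#'   totals, and the confirmed cases (`disorder`, `year`).
#' @export
run_two_tier <- function(cohort, rules = nbs_rules(),
                         params = workflow_params()) {
  stopifnot(inherits(cohort, "nbs_cohort"),
            inherits(params, "nbs_workflow_params"))
  n <- length(cohort$truth)
  years <- names(cohort$config$year_weights) %||% sort(unique(cohort$year))
  if (n == 0L) {
    warning("empty cohort: returning empty outcome")
    counts <- data.frame(year = character(), screened = integer(),
                         suspected = integer(), recalled = integer(),
                         retest_positive = integer(), referred = integer(),
                         confirmed = integer(), stringsAsFactors = FALSE)
    return(structure(list(by_year = counts,
                          confirmed_cases = data.frame(disorder = character(),
                                                       year = character()),
                          params = params), class = "nbs_workflow"))
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  scr <- screen_cohort(cohort, rules, k = params$k)
  affected <- cohort$truth != "none"

  suspected <- scr$suspected
  clear_ab <- scr$clear_aberrant
  mild <- suspected & !clear_ab
  recalled <- mild & stats::runif(n) < params$recall_prob
  persist_p <- ifelse(affected, params$tp_persist, params$fp_persist)
  retest_pos <- recalled & stats::runif(n) < persist_p
  referred <- retest_pos | clear_ab
  confirmed <- referred & affected & stats::runif(n) < params$confirm_sens

  # structural invariants of the screening funnel
  stopifnot(n >= sum(suspected),
            sum(suspected) >= sum(recalled) + sum(clear_ab),
            sum(recalled) >= sum(retest_pos),
            sum(referred) == sum(retest_pos) + sum(clear_ab),
            all(!recalled | mild),
            all(!retest_pos | recalled),
            all(!confirmed | referred),
            all(!confirmed | affected))

  tab <- function(flag) {
    as.integer(table(factor(cohort$year[flag], levels = years)))
  }
  by_year <- data.frame(
    year = years,
    screened = as.integer(table(factor(cohort$year, levels = years))),
    suspected = tab(suspected),
    recall_eligible = tab(mild),
    recalled = tab(recalled),
    retest_positive = tab(retest_pos),
    referred = tab(referred),
    confirmed = tab(confirmed),
    stringsAsFactors = FALSE
  )
  structure(list(
    by_year = by_year,
    confirmed_cases = data.frame(disorder = cohort$truth[confirmed],
                                 year = cohort$year[confirmed],
                                 stringsAsFactors = FALSE),
    params = params
  ), class = "nbs_workflow")
}

#' Per-year summary of a workflow outcome
#'
#' Tabulates yearly screening volume, suspected positives, recalls, recall
#' rate (percent, 2 dp), confirmed diagnoses and screening frequency
#' ("1:N").  Yearly frequencies follow the yearly-report convention of
#' truncating N down; recall rates are rounded half-up.  The recall rate is
#' an operational quantity: for a simulated workflow outcome it is computed
#' over the recall-eligible newborns (mild positives asked to return a
#' second specimen; clear-aberrant direct referrals are not recallable);
#' for a bare year table without a triage breakdown it falls back to
#' recalled / suspected.  A year with no recallable positives reports an
#' absent (`NA`) recall rate, and a year with no confirmed cases an absent
#' frequency.
#'
#' @param outcome an `nbs_workflow` object, or a data frame with columns
#'   `year`, `screened`, `suspected`, `recalled`, `confirmed` (optionally
#'   `recall_eligible`).
#' @return data frame with one row per year plus a `"Total"` row.
#' @export
summarize_by_year <- function(outcome) {
  tab <- if (inherits(outcome, "nbs_workflow")) outcome$by_year else outcome
  needed <- c("year", "screened", "suspected", "recalled", "confirmed")
  stopifnot(all(needed %in% names(tab)))
  has_elig <- "recall_eligible" %in% names(tab)
  keep <- c(needed, if (has_elig) "recall_eligible")
  tab <- tab[, keep]
  total <- data.frame(year = "Total",
                      screened = sum(tab$screened),
                      suspected = sum(tab$suspected),
                      recalled = sum(tab$recalled),
                      confirmed = sum(tab$confirmed),
                      stringsAsFactors = FALSE)
  if (has_elig) total$recall_eligible <- sum(tab$recall_eligible)
  all_rows <- rbind(tab, total)
  denom <- if (has_elig) all_rows$recall_eligible else all_rows$suspected
  all_rows$recall_rate <- ifelse(
    denom > 0,
    round_half_up(100 * all_rows$recalled / denom, 2),
    NA_real_)
  all_rows$frequency <- ifelse(
    all_rows$confirmed > 0,
    vapply(seq_len(nrow(all_rows)), function(i)
      incidence_ratio(all_rows$screened[i], all_rows$confirmed[i],
                      rounding = "down"), ""),
    NA_character_)
  rownames(all_rows) <- NULL
  all_rows[, c("year", "screened", "suspected", "recalled", "recall_rate",
               "confirmed", "frequency")]
}

#' @export
print.nbs_workflow <- function(x, ...) {
  cat("<nbs_workflow> two-tier screening outcome\n")
  print(summarize_by_year(x))
  invisible(x)
}
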