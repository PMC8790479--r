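#' Screening frequency as a "1:N" string
#'
#' N is the number of screened newborns per confirmed case.  Cumulative
#' reports round N half-up (300,849 screened / 2 cases gives "1:150,425");
#' yearly report tables conventionally truncate (`rounding = "down"`:
#' 59,439 / 20 gives "1:2,971").
#'
#' @param screened number of newborns screened.
#' @param cases number of confirmed cases (must be >= 1).
#' @param rounding `"half_up"` (default) or `"down"`.
#' @return string `"1:N"` with thousands separators.
#' @examples
#' incidence_ratio(300849, 71)
#' incidence_ratio(300849, 2)
#' @export
incidence_ratio <- function(screened, cases, rounding = c("half_up", "down")) {
  rounding <- match.arg(rounding)
  stopifnot(length(screened) == 1L, length(cases) == 1L)
  if (is.na(cases) || cases < 1) {
    stop("incidence is undefined for zero confirmed cases")
  }
  if (screened < cases) {
    stop("screened (", screened, ") must be at least the case count (",
         cases, ")")
  }
  n <- switch(rounding,
              half_up = round_half_up(screened / cases),
              down = floor(screened / cases))
  paste0("1:", fmt_big(n))
}

#' Parse a "1:N" frequency string back to N
#'
#' @param text strings like `"1:4,237"` (whitespace and comma grouping
#'   tolerated).
#' @return integer vector of N.
#' @export
parse_incidence_ratio <- function(text) {
  s <- gsub("[[:space:],]", "", text)
  m <- regmatches(s, regexec("^1:([0-9]+)$", s))
  n <- vapply(m, function(x) {
    if (length(x) != 2L) stop("not a '1:N' frequency string")
    as.integer(x[2])
  }, integer(1))
  n
}

#' Percentage of a total, reported to 2 dp
#'
#' @param cases numerator count.
#' @param total denominator count (must be >= `cases` and > 0).
#' @return `100 * cases / total`, rounded to 2 decimal places half-up.
#' @examples
#' proportion(28, 71)
#' @export
proportion <- function(cases, total) {
  stopifnot(length(cases) == 1L, length(total) == 1L)
  if (total <= 0) stop("proportion is undefined for a zero total")
  if (cases < 0 || cases > total) {
    stop("cases must lie in [0, total]")
  }
  round_half_up(100 * cases / total, 2)
}

#' Disorder and category incidence summary
#'
#' Builds the screening-result summary: one row per confirmed disorder, one
#' roll-up row per category (amino acid, organic acid and fatty acid
#' oxidation disorders), and a grand total.  Frequencies are "1:N" strings
#' (half-up); `percent` is each row's share of all confirmed cases.
#'
#' @param confirmed either a data frame with columns `disorder` and
#'   `category` (one row per confirmed case, or with a `cases` count
#'   column), or a character vector of disorder labels combined with
#'   `category_map`.
#' @param screened total number of newborns screened.
#' @param category_map named character vector disorder -> category, required
#'   when `confirmed` is a character vector or lacks `category`.
#' @return data frame of class `nbs_epi_summary` with columns `label`,
#'   `level` (`disorder`, `category`, `total`), `category`, `cases`,
#'   `frequency`, `percent`.
#' @examples
#' counts <- nbs_confirmed_counts()
#' build_summary(counts[, c("disorder", "category", "cases")], 300849)
#' @export
build_summary <- function(confirmed, screened, category_map = NULL) {
  if (is.character(confirmed)) {
    confirmed <- data.frame(disorder = confirmed, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(confirmed), "disorder" %in% names(confirmed))
  if (!"category" %in% names(confirmed)) {
    if (is.null(category_map)) {
      stop("confirmed cases lack categories and no category_map was given")
    }
    unmapped <- setdiff(unique(confirmed$disorder), names(category_map))
    if (length(unmapped)) {
      stop("disorder(s) without category mapping: ",
           paste(unmapped, collapse = ", "))
    }
    confirmed$category <- unname(category_map[confirmed$disorder])
  }
  if (!"cases" %in% names(confirmed)) confirmed$cases <- 1L
  agg <- stats::aggregate(cases ~ disorder + category, data = confirmed, sum)
  cat_levels <- c("AAMD", "OAMD", "FAOD")
  bad_cat <- setdiff(unique(agg$category), cat_levels)
  if (length(bad_cat)) {
    stop("unknown category label(s): ", paste(bad_cat, collapse = ", "))
  }
  total_cases <- sum(agg$cases)
  rows <- list()
  for (cat in cat_levels) {
    sub <- agg[agg$category == cat, , drop = FALSE]
    if (!nrow(sub)) next
    sub <- sub[order(-sub$cases, sub$disorder), , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      label = cat, level = "category", category = cat,
      cases = sum(sub$cases), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(sub))) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = sub$disorder[i], level = "disorder", category = cat,
        cases = sub$cases[i], stringsAsFactors = FALSE)
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(
    label = "Total", level = "total", category = NA_character_,
    cases = total_cases, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out$frequency <- vapply(out$cases, function(k)
    incidence_ratio(screened, k), "")
  out$percent <- vapply(out$cases, function(k)
    proportion(k, total_cases), numeric(1))
  class(out) <- c("nbs_epi_summary", "data.frame")
  out
}

#' @export
print.nbs_epi_summary <- function(x, ...) {
  cat("<nbs_epi_summary> confirmed IMD cases by disorder and category\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
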