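#' Calibrate log-normal marker distributions to cut-off ranges
#'
#' Concentration markers in reference populations are non-negative and
#' right-skewed, so each measured channel is modelled as log-normal.  The
#' log-scale parameters are solved in closed form so that the distribution's
#' `q_low` and `q_high` quantiles coincide with the marker's cut-off bounds:
#' `sigma = (log(high) - log(low)) / (z_high - z_low)` and
#' `mu = log(low) - z_low * sigma`.  Markers whose lower bound is 0 use
#' `eps = min(high / 1000, 0.001)` in its place.  Ratio markers are never
#' sampled directly — they are always derived from the measured channels.
#'
#' @param markers an `nbs_markers` panel.
#' @param q_low,q_high the quantiles anchored at the cut-off bounds
#'   (defaults 0.005 and 0.995).
#' @return data frame of class `nbs_dists` with columns `marker`, `key`,
#'   `mu`, `sigma` for every measured (raw/combined) marker.
#' @examples
#' d <- calibrate_normal_distributions(nbs_markers())
#' # the log-normal median equals the geometric mean of the bounds
#' exp(d$mu[d$key == "C0"])
#' sqrt(9 * 50)
#' @export
calibrate_normal_distributions <- function(markers, q_low = 0.005,
                                           q_high = 0.995) {
  stopifnot(inherits(markers, "nbs_markers"),
            q_low > 0, q_high < 1, q_low < q_high)
  tab <- markers$table[markers$table$kind != "ratio", ]
  low <- tab$low
  high <- tab$high
  eps <- pmin(high / 1000, 0.001)
  low <- ifelse(low == 0, eps, low)
  bad <- which(low >= high)
  if (length(bad)) {
    stop("cannot calibrate marker(s) with low >= high: ",
         paste(tab$name[bad], collapse = ", "))
  }
  z_low <- stats::qnorm(q_low)
  z_high <- stats::qnorm(q_high)
  sigma <- (log(high) - log(low)) / (z_high - z_low)
  mu <- log(low) - z_low * sigma
  out <- data.frame(marker = tab$name, key = tab$key, mu = mu, sigma = sigma,
                    stringsAsFactors = FALSE)
  class(out) <- c("nbs_dists", "data.frame")
  out
}

#' Build a disease marker profile targeting one rule group
#'
#' A disease profile says how an affected newborn's panel departs from the
#' reference distribution: for every condition in the targeted rule group on
#' a measured channel, the marker is drawn uniformly between the rule
#' threshold and an anchor taken from observed abnormal levels of confirmed
#' cases of that disorder (falling back to 3x the threshold above, or
#' threshold/3 below, when no anchor is available).  Ratio conditions in the
#' group are recorded and enforced after derivation by minimally scaling one
#' operand.  With probability `1 - sensitivity` the affected newborn's panel
#' is left at reference levels (a biochemical screening miss).
#'
#' @param rule a single rule from an `nbs_rules` object.
#' @param group_index which of the rule's groups the profile targets.
#' @param sensitivity probability in (0, 1] that the generated panel
#'   satisfies the target group.
#' @param anchors optional data frame `marker`, `value` of observed abnormal
#'   levels for this disorder (e.g. from [nbs_case_panels()]).
#' @param disorder label carried by generated cases; defaults to the rule id.
#' @param markers an `nbs_markers` panel (to distinguish measured channels
#'   from ratios).
#' @return an object of class `nbs_profile`.
#' @export
make_disease_profile <- function(rule, group_index = 1L, sensitivity = 1,
                                 anchors = NULL, disorder = rule$id,
                                 markers = nbs_markers()) {
  if (group_index < 1L || group_index > length(rule$groups)) {
    stop("rule '", rule$id, "' has no group ", group_index)
  }
  if (!(sensitivity > 0 && sensitivity <= 1)) {
    stop("sensitivity must be in (0, 1]")
  }
  g <- rule$groups[[group_index]]
  measured_keys <- markers$table$key[markers$table$kind != "ratio"]
  is_measured <- g$key %in% measured_keys
  if (!any(is_measured) && !any(g$key %in% names(markers$ratios))) {
    stop("rule '", rule$id, "' group ", group_index,
         " has no condition on a defined marker")
  }
  shift_rows <- g[is_measured, , drop = FALSE]
  shifts <- lapply(seq_len(nrow(shift_rows)), function(i) {
    row <- shift_rows[i, ]
    anchor <- NA_real_
    if (!is.null(anchors)) {
      hit <- norm_key(anchors$marker) == row$key
      if (any(hit)) {
        anchor <- if (row$cmp %in% c("gt", "ge")) max(anchors$value[hit])
                  else min(anchors$value[hit])
      }
    }
    if (row$cmp %in% c("gt", "ge")) {
      hi <- if (!is.na(anchor) && anchor > row$threshold) anchor
            else 3 * row$threshold
      list(key = row$key, cmp = row$cmp, lo = row$threshold, hi = hi)
    } else {
      lo <- if (!is.na(anchor) && anchor < row$threshold) anchor
            else row$threshold / 3
      list(key = row$key, cmp = row$cmp, lo = lo, hi = row$threshold)
    }
  })
  structure(list(
    disorder = disorder, rule_id = rule$id, group_index = group_index,
    sensitivity = sensitivity, shifts = shifts,
    ratio_conditions = g[!is_measured, , drop = FALSE]
  ), class = "nbs_profile")
}

#' Default disease profiles for the confirmed-disorder spectrum
#'
#' One profile per disorder in the shipped confirmed-case table, each
#' targeting the single-marker rule group of its screening rule and anchored
#' to the observed abnormal levels of the confirmed cases.
#'
#' @param rules an `nbs_rules` rule set.
#' @param markers an `nbs_markers` panel.
#' @param sensitivity screening sensitivity applied to every profile.
#' @return named list of `nbs_profile` objects.
#' @export
default_disease_profiles <- function(rules = nbs_rules(),
                                     markers = nbs_markers(),
                                     sensitivity = 1) {
  counts <- nbs_confirmed_counts()
  panels <- nbs_case_panels()
  profiles <- lapply(seq_len(nrow(counts)), function(i) {
    row <- counts[i, ]
    anchors <- panels[panels$diagnosis == row$disorder,
                      c("marker", "value"), drop = FALSE]
    make_disease_profile(rules[[row$rule_id]], group_index = row$target_group,
                         sensitivity = sensitivity, anchors = anchors,
                         disorder = row$disorder, markers = markers)
  })
  stats::setNames(profiles, counts$disorder)
}

#' Cohort generator configuration
#'
#' Defines the study conditions the synthetic cohort emulates.  Defaults
#' reproduce the screening programme the package models: 300,849 newborns
#' over 2016-2020, the confirmed-disorder incidences of that programme,
#' yearly volume weights, and a false-positive layer calibrated so the
#' first-screen suspected-positive fraction is about 1.64%.
#'
#' @param n number of newborns.
#' @param incidence named vector, cases per birth by disorder; defaults to
#'   the shipped confirmed counts over 300,849 births.
#' @param year_weights named vector of per-year screening fractions
#'   (sums to 1).
#' @param fp_rate probability that an unaffected newborn's panel has one
#'   rule-relevant marker displaced just past its threshold (uniform within
#'   20% beyond), emulating pre-analytical and analytical error.
#' @param rho shared log-scale variance fraction: each measured marker loads
#'   on one common per-newborn factor with weight `sqrt(rho) * sigma`, so
#'   marker marginals keep their calibrated quantiles while ratios of
#'   correlated channels have realistically small dispersion.
#' @param q_low,q_high quantiles at which the cut-off bounds anchor the
#'   reference distributions.
#' @param male_fraction probability a newborn is male.
#' @param seed integer seed making the cohort reproducible.
#' @return a list of class `nbs_cohort_config`.
#' @export
cohort_config <- function(n = 300849,
                          incidence = NULL,
                          year_weights = NULL,
                          fp_rate = 0.0139,
                          rho = 0.85,
                          q_low = 0.001, q_high = 0.999,
                          male_fraction = 0.5925,
                          seed = NULL) {
  if (is.null(incidence)) {
    counts <- nbs_confirmed_counts()
    incidence <- stats::setNames(counts$cases / 300849, counts$disorder)
  }
  if (is.null(year_weights)) {
    vol <- nbs_screening_volume()
    year_weights <- stats::setNames(vol$screened / sum(vol$screened),
                                    as.character(vol$year))
  }
  stopifnot(n >= 1, sum(incidence) < 1, fp_rate >= 0, fp_rate <= 1,
            rho >= 0, rho < 1, abs(sum(year_weights) - 1) < 1e-8)
  structure(list(n = as.integer(n), incidence = incidence,
                 year_weights = year_weights, fp_rate = fp_rate, rho = rho,
                 q_low = q_low, q_high = q_high,
                 male_fraction = male_fraction, seed = seed),
            class = "nbs_cohort_config")
}

# Displacement targets for the false-positive layer: every measured channel
# that appears in a rule condition, displaced just past its most lenient
# threshold (smallest upper threshold / largest lower threshold), so the
# displaced panel is borderline — it may or may not flag, and never by a wide
# margin.  One entry per (marker, direction).
fp_repertoire <- function(rules, markers) {
  measured <- markers$table$key[markers$table$kind != "ratio"]
  conds <- do.call(rbind, unlist(lapply(rules, `[[`, "groups"),
                                 recursive = FALSE))
  conds <- conds[conds$key %in% measured, , drop = FALSE]
  conds$dir <- ifelse(conds$cmp %in% c("gt", "ge"), "up", "down")
  pick <- lapply(split(conds, paste(conds$key, conds$dir)), function(d) {
    thr <- if (d$dir[1] == "up") min(d$threshold) else max(d$threshold)
    d[match(thr, d$threshold), , drop = FALSE]
  })
  out <- do.call(rbind, pick)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic newborn screening cohort
#'
#' Draws reference panels from the calibrated log-normal model with a shared
#' per-newborn factor, assigns true disorders at the configured incidences,
#' overwrites affected newborns' rule-relevant markers from their disease
#' profiles, applies the false-positive displacement layer to unaffected
#' newborns, and derives all ratio markers.
#'
#' @param config an [cohort_config()] object.
#' @param dists marker distributions; defaults to
#'   [calibrate_normal_distributions()] at the config's quantile anchors.
#' @param profiles named list of disease profiles, one per disorder with
#'   non-zero incidence; defaults to [default_disease_profiles()].
#' @param rules an `nbs_rules` rule set (used for the false-positive layer
#'   and ratio-condition enforcement).
#' @param markers an `nbs_markers` panel.
#' @return an object of class `nbs_cohort`: list with `panels` (numeric
#'   matrix, newborns x 74 markers), `truth` (disorder label or `"none"`),
#'   `year`, `sex` and the `config`.
#' @examples
#' coh <- sample_cohort(cohort_config(n = 1000, seed = 1))
#' table(coh$truth)
#' @export
sample_cohort <- function(config, dists = NULL, profiles = NULL,
                          rules = nbs_rules(), markers = nbs_markers()) {
  stopifnot(inherits(config, "nbs_cohort_config"))
  dists <- dists %||% calibrate_normal_distributions(
    markers, q_low = config$q_low, q_high = config$q_high)
  profiles <- profiles %||% default_disease_profiles(rules, markers)
  active <- names(config$incidence)[config$incidence > 0]
  missing_prof <- setdiff(active, names(profiles))
  if (length(missing_prof)) {
    stop("no disease profile for disorder(s): ",
         paste(missing_prof, collapse = ", "))
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n

  # true disease labels
  p <- config$incidence[active]
  breaks <- cumsum(c(0, p))
  u <- stats::runif(n)
  truth <- rep("none", n)
  for (i in seq_along(active)) {
    truth[u > breaks[i] & u <= breaks[i + 1]] <- active[i]
  }

  # reference panels: shared factor + marker-specific variation
  z0 <- stats::rnorm(n)
  m <- nrow(dists)
  mat <- matrix(NA_real_, n, m, dimnames = list(NULL, dists$key))
  sr <- sqrt(config$rho)
  ss <- sqrt(1 - config$rho)
  for (j in seq_len(m)) {
    mat[, j] <- exp(dists$mu[j] +
                      dists$sigma[j] * (sr * z0 + ss * stats::rnorm(n)))
  }

  # affected newborns: overwrite rule-relevant measured markers
  for (d in active) {
    idx <- which(truth == d)
    if (!length(idx)) next
    prof <- profiles[[d]]
    expressed <- idx[stats::runif(length(idx)) < prof$sensitivity]
    if (!length(expressed)) next
    for (s in prof$shifts) {
      mat[expressed, s$key] <- stats::runif(length(expressed), s$lo, s$hi)
    }
  }

  # false-positive layer on unaffected newborns
  rep_tab <- fp_repertoire(rules, markers)
  unaffected <- which(truth == "none")
  hit <- unaffected[stats::runif(length(unaffected)) < config$fp_rate]
  if (length(hit) && nrow(rep_tab)) {
    pick <- sample.int(nrow(rep_tab), length(hit), replace = TRUE)
    for (ci in unique(pick)) {
      rows <- hit[pick == ci]
      thr <- rep_tab$threshold[ci]
      if (rep_tab$cmp[ci] %in% c("gt", "ge")) {
        mat[rows, rep_tab$key[ci]] <- stats::runif(length(rows), thr, 1.2 * thr)
      } else {
        mat[rows, rep_tab$key[ci]] <- stats::runif(length(rows), thr / 1.2, thr)
      }
    }
  }

  mat <- derive_ratio_columns(mat, markers)

  # enforce ratio conditions of targeted groups (rarely needed: the shipped
  # profiles target measured-marker groups)
  for (d in active) {
    prof <- profiles[[d]]
    rc <- prof$ratio_conditions
    if (!nrow(rc)) next
    idx <- which(truth == d)
    for (ci in seq_len(nrow(rc))) {
      f <- markers$ratios[[rc$key[ci]]]
      if (is.null(f)) next
      cur <- mat[idx, rc$key[ci]]
      ok <- !is.na(cur) & cmp_fun(rc$cmp[ci])(cur, rc$threshold[ci])
      fix <- idx[!ok & !is.na(cur)]
      if (!length(fix)) next
      target <- if (rc$cmp[ci] %in% c("gt", "ge")) {
        rc$threshold[ci] * stats::runif(length(fix), 1.02, 1.2)
      } else {
        rc$threshold[ci] * stats::runif(length(fix), 0.83, 0.98)
      }
      # rescale every numerator operand jointly so the ratio lands exactly
      # on the sampled target (e.g. all acylcarnitine channels fall together
      # in carnitine deficiency)
      fac <- target / mat[fix, rc$key[ci]]
      for (op in f$num) {
        mat[fix, op] <- mat[fix, op] * fac
      }
    }
    if (length(idx)) {
      mat[idx, , drop = FALSE] -> sub
      sub <- derive_ratio_columns(sub[, dists$key, drop = FALSE], markers)
      mat[idx, colnames(sub)] <- sub
    }
  }

  display <- stats::setNames(markers$table$name, markers$table$key)
  colnames(mat) <- ifelse(colnames(mat) %in% names(display),
                          display[colnames(mat)], colnames(mat))
  years <- names(config$year_weights)
  structure(list(
    panels = mat,
    truth = truth,
    year = sample(years, n, replace = TRUE, prob = config$year_weights),
    sex = ifelse(stats::runif(n) < config$male_fraction, "M", "F"),
    config = config
  ), class = "nbs_cohort")
}

#' @export
print.nbs_cohort <- function(x, ...) {
  cat("<nbs_cohort> ", length(x$truth), " newborns, ",
      sum(x$truth != "none"), " affected (",
      length(unique(x$truth[x$truth != "none"])), " disorders), years ",
      paste(range(x$year), collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.nbs_cohort <- function(x, ...) {
  out <- as.data.frame(x$panels, check.names = FALSE)
  out$truth <- x$truth
  out$year <- x$year
  out$sex <- x$sex
  out
}
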