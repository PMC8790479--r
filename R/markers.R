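#' Load the MS/MS screening marker panel and cut-off ranges
#'
#' Reads a structured marker configuration (YAML) describing the expanded
#' newborn-screening indicator panel: directly measured amino acid and
#' acylcarnitine channels, combined channels reported jointly by
#' non-derivatized kits (e.g. `"C3DC + C4OH"`), and derived ratio markers
#' whose formula is their printed name (numerator and denominator may be
#' parenthesised sums of measured channels).  Each marker carries its
#' laboratory reference ("cut-off") range; concentrations are in umol/L,
#' ratios dimensionless.
#'
#' @param path path to a marker configuration file; defaults to the panel
#'   shipped with the package (74 indicators: 43 measured, 31 ratios).
#' @return an object of class `nbs_markers`: a list with `table` (data frame
#'   of `name`, `key`, `kind`, `low`, `high`) and `ratios` (named list of
#'   parsed formulas with `num` and `den` operand keys).
#' @examples
#' panel <- nbs_markers()
#' nrow(panel$table)
#' subset(panel$table, name == "PHE")
#' @export
nbs_markers <- function(path = NULL) {
  path <- path %||% nbs_extdata("markers.yaml")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$markers) || !length(cfg$markers)) {
    stop("marker configuration has no 'markers' entries: ", path)
  }
  rows <- lapply(seq_along(cfg$markers), function(i) {
    m <- cfg$markers[[i]]
    for (field in c("name", "kind")) {
      if (is.null(m[[field]])) {
        stop("marker entry ", i, " is missing field '", field, "'")
      }
    }
    if (!m$kind %in% c("raw", "combined", "ratio")) {
      stop("marker '", m$name, "': unknown kind '", m$kind, "'")
    }
    low <- m$low %||% NA_real_
    high <- m$high %||% NA_real_
    if (!is.na(low) && !is.na(high) && low > high) {
      stop("marker '", m$name, "': cut-off low ", low, " exceeds high ", high)
    }
    data.frame(
      name = m$name, key = norm_key(m$name), kind = m$kind,
      low = as.numeric(low), high = as.numeric(high),
      stringsAsFactors = FALSE
    )
  })
  table <- do.call(rbind, rows)
  dup <- table$key[duplicated(table$key)]
  if (length(dup)) {
    stop("duplicate marker name(s) in configuration: ",
         paste(unique(dup), collapse = ", "))
  }
  measured <- table$key[table$kind != "ratio"]
  ratios <- list()
  for (i in which(table$kind == "ratio")) {
    f <- parse_ratio_formula(table$name[i], measured)
    bad <- setdiff(c(f$num, f$den), measured)
    if (length(bad)) {
      stop("ratio '", table$name[i], "' references undefined measured marker(s): ",
           paste(bad, collapse = ", "))
    }
    ratios[[table$key[i]]] <- f
  }
  structure(list(table = table, ratios = ratios), class = "nbs_markers")
}

# Parse a printed ratio name, e.g. "(C0 + C2 + C3 + C16 + C18:1 + C18)/CIT",
# into numerator/denominator operand keys.  The "/" is located at parenthesis
# depth zero; each side may be a parenthesised "+"-sum of measured channels.
# Combined channels such as "C4DC + C5OH" are single measured markers, so a
# side is matched against the defined marker keys before being split on "+":
# "(C4DC + C5OH)/C0" divides one combined channel by C0, it does not sum.
parse_ratio_formula <- function(name, measured_keys = character()) {
  s <- norm_key(name)
  chars <- strsplit(s, "")[[1]]
  depth <- 0L
  slash <- NA_integer_
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") depth <- depth - 1L
    else if (chars[i] == "/" && depth == 0L) {
      if (!is.na(slash)) stop("ratio '", name, "': multiple top-level '/'")
      slash <- i
    }
  }
  if (is.na(slash)) stop("ratio '", name, "' has no top-level '/'")
  side <- function(txt) {
    if (grepl("^\\(.*\\)$", txt)) txt <- substr(txt, 2, nchar(txt) - 1)
    if (txt %in% measured_keys) return(txt)
    ops <- strsplit(txt, "+", fixed = TRUE)[[1]]
    ops[nzchar(ops)]
  }
  list(
    num = side(substr(s, 1, slash - 1)),
    den = side(substr(s, slash + 1, nchar(s)))
  )
}

#' Write a marker panel back to configuration
#'
#' Inverse of [nbs_markers()]; the written file reloads to an identical panel.
#'
#' @param markers an `nbs_markers` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path) {
  stopifnot(inherits(markers, "nbs_markers"))
  entries <- lapply(seq_len(nrow(markers$table)), function(i) {
    row <- markers$table[i, ]
    list(name = row$name, kind = row$kind, low = row$low, high = row$high)
  })
  yaml::write_yaml(list(markers = entries), path)
  invisible(path)
}

#' Compute derived ratio markers for a panel record
#'
#' Populates every ratio marker whose operands are present in the record;
#' measured values are never changed.  A ratio with a missing operand or a
#' zero denominator is left absent (`NA`) and reported in a warning: a
#' missing ratio must not silently satisfy or clear a screening rule (the
#' rule engine treats absent operands as condition-not-evaluable).
#'
#' @param record named numeric vector of marker values (names as printed,
#'   whitespace-insensitive).
#' @param markers an `nbs_markers` panel, default the shipped panel.
#' @return the record extended with all computable ratio markers, names in
#'   panel order followed by any extra markers present in the input.
#' @examples
#' compute_derived_markers(c(C3 = 1, C2 = 10))[["C3/C2"]]
#' @export
compute_derived_markers <- function(record, markers = nbs_markers()) {
  stopifnot(is.numeric(record), !is.null(names(record)))
  if (any(record < 0, na.rm = TRUE)) {
    stop("panel values must be non-negative")
  }
  keys <- norm_key(names(record))
  vals <- stats::setNames(as.numeric(record), keys)
  skipped <- character()
  for (rk in names(markers$ratios)) {
    f <- markers$ratios[[rk]]
    ops <- c(f$num, f$den)
    if (!all(ops %in% keys) || anyNA(vals[ops])) {
      # keep a directly reported ratio value if one was supplied
      if (!rk %in% keys) {
        vals[rk] <- NA_real_
        skipped <- c(skipped, paste0(rk, " (missing operand)"))
      }
      next
    }
    den <- sum(vals[f$den])
    if (den == 0) {
      if (!rk %in% keys) {
        vals[rk] <- NA_real_
        skipped <- c(skipped, paste0(rk, " (zero denominator)"))
      }
      next
    }
    vals[rk] <- sum(vals[f$num]) / den
  }
  if (length(skipped)) {
    warning("ratio(s) left absent: ", paste(skipped, collapse = "; "),
            call. = FALSE)
  }
  # report with display names, panel order first
  tab <- markers$table
  out_keys <- c(tab$key[tab$key %in% names(vals)],
                setdiff(names(vals), tab$key))
  display <- stats::setNames(tab$name, tab$key)
  out <- vals[out_keys]
  names(out) <- ifelse(out_keys %in% names(display),
                       display[out_keys], out_keys)
  keys <- norm_key(names(out))
  out[!(keys %in% names(markers$ratios)) | !is.na(out)]
}

# Vectorised ratio derivation for a cohort: `mat` has measured-marker columns
# named by key; returns mat extended with one column per computable ratio.
derive_ratio_columns <- function(mat, markers) {
  for (rk in names(markers$ratios)) {
    f <- markers$ratios[[rk]]
    if (!all(c(f$num, f$den) %in% colnames(mat))) next
    num <- if (length(f$num) == 1L) mat[, f$num] else rowSums(mat[, f$num, drop = FALSE])
    den <- if (length(f$den) == 1L) mat[, f$den] else rowSums(mat[, f$den, drop = FALSE])
    r <- num / den
    r[den == 0] <- NA_real_
    mat <- cbind(mat, r)
    colnames(mat)[ncol(mat)] <- rk
  }
  mat
}

#' Flag markers outside their reference range
#'
#' The closed interval `[low, high]` is "normal": only values strictly below
#' `low` or strictly above `high` are flagged.  Markers in the record that
#' have no configured range are skipped with a message.  This is reference
#' flagging for metabolic interpretation; disorder calls use the positive
#' rules ([evaluate_record()]), whose comparators are defined separately.
#'
#' @param record named numeric vector (derived markers computed).
#' @param markers an `nbs_markers` panel.
#' @return data frame with columns `marker`, `direction` (`"low"`/`"high"`),
#'   `value`, `low`, `high`, in panel order.
#' @examples
#' flag_out_of_range(c(PHE = 444.79))
#' @export
flag_out_of_range <- function(record, markers = nbs_markers()) {
  stopifnot(is.numeric(record), !is.null(names(record)))
  keys <- norm_key(names(record))
  tab <- markers$table
  unknown <- names(record)[!keys %in% tab$key]
  if (length(unknown)) {
    message("marker(s) without configured range ignored: ",
            paste(unknown, collapse = ", "))
  }
  out <- data.frame(marker = character(), direction = character(),
                    value = numeric(), low = numeric(), high = numeric(),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tab))) {
    j <- match(tab$key[i], keys)
    if (is.na(j) || is.na(record[[j]])) next
    v <- record[[j]]
    dir <- if (!is.na(tab$low[i]) && v < tab$low[i]) "low"
           else if (!is.na(tab$high[i]) && v > tab$high[i]) "high"
           else NA_character_
    if (!is.na(dir)) {
      out <- rbind(out, data.frame(marker = tab$name[i], direction = dir,
                                   value = v, low = tab$low[i],
                                   high = tab$high[i],
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Reference panel with every measured marker at its range midpoint
#'
#' Convenience constructor for a metabolically unremarkable record: each
#' measured (raw or combined) marker is set to `(low + high) / 2`.  Useful
#' for completing partially observed case records before rule evaluation.
#'
#' @param markers an `nbs_markers` panel.
#' @return named numeric vector of measured-marker midpoints.
#' @export
midpoint_panel <- function(markers = nbs_markers()) {
  tab <- markers$table[markers$table$kind != "ratio", ]
  stats::setNames((tab$low + tab$high) / 2, tab$name)
}

#' @export
print.nbs_markers <- function(x, ...) {
  tab <- x$table
  cat("<nbs_markers> expanded newborn-screening panel\n")
  cat("  ", nrow(tab), " indicators: ",
      sum(tab$kind == "raw"), " raw, ",
      sum(tab$kind == "combined"), " combined channels, ",
      sum(tab$kind == "ratio"), " derived ratios\n", sep = "")
  invisible(x)
}
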