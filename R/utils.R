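#' @keywords internal
"_PACKAGE"

# Canonical internal key for a marker name: the printed name with all
# whitespace removed, so "C3DC+C4OH", "C3DC + C4OH" and "C3DC +C4OH" match.
norm_key <- function(x) gsub("[[:space:]]+", "", x)

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; screening reports round half up
#' (e.g. 300,849 / 2 = 150,424.5 is reported as 150,425).
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# "12345" -> "12,345"
fmt_big <- function(n) {
  formatC(n, format = "d", big.mark = ",")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nbs_extdata <- function(file) {
  path <- system.file("extdata", file, package = "nbscreen", mustWork = TRUE)
  path
}
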