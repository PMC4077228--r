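# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percentage coverage of a part relative to a total
#'
#' Reports `100 * part / total` rounded to two decimals, the convention used
#' for giant-component node and edge coverage summaries.
#'
#' @param part Numeric count (e.g. nodes in the giant component).
#' @param total Numeric total count; must be positive.
#' @return Numeric percentage rounded to 2 decimal places.
#' @examples
#' coverage_pct(3435, 3450)
#' @export
coverage_pct <- function(part, total) {
  stopifnot(is.numeric(part), is.numeric(total), all(total > 0))
  round(100 * part / total, 2)
}

# canonical unordered edge key for dedup ("a|b" with a <= b lexicographically)
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

abort_io <- function(...) stop(..., call. = FALSE)
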