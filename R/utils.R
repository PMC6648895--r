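# Internal constants and small helpers shared across modules.

# Value substituted for exact zeros on the percent scale so that log10 is
# defined everywhere; the attainable floor of the log-scale data is
# log10(.zero_fill) = -4.
.zero_fill <- 1e-4

# Closed vocabulary of protein group labels, in fixed display order.
# Heat-map rows are blocked in this order.
.group_levels <- c(
  "40S r-protein", "60S r-protein", "ribosome AF", "translation factor",
  "cell division", "histone", "transcription", "other"
)

# Groups counted as ribosomal proteins by rprotein_fraction().
.rprotein_groups <- c("40S r-protein", "60S r-protein")

#' Protein group vocabulary
#'
#' The closed set of group labels used to annotate proteins detected in a
#' purification, in the fixed order used for heat-map blocking: 40S and 60S
#' ribosomal proteins first, then ribosome assembly factors, translation
#' factors, cell-division proteins, histones, transcription-related proteins
#' and a catch-all "other".
#'
#' @return Character vector of the eight group labels.
#' @export
#' @examples
#' protein_groups()
protein_groups <- function() .group_levels

abort_validation <- function(msg, ...) {
  abort(msg, class = c("chaperscreen_validation_error", "chaperscreen_error"), ...)
}

abort_parse <- function(msg, ...) {
  abort(msg, class = c("chaperscreen_parse_error", "chaperscreen_error"), ...)
}

# zero_replaced flag lives as an attribute on relative-intensity tibbles;
# defaults to FALSE when never set.
is_zero_replaced <- function(x) isTRUE(attr(x, "zero_replaced"))

require_columns <- function(x, cols, what) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0L) {
    abort_validation(sprintf(
      "%s must have column(s) %s.", what,
      paste0("'", missing, "'", collapse = ", ")
    ))
  }
  invisible(x)
}

# Fixed decimal format (9 significant digits) used for every numeric column
# written by the run_*() drivers, so reruns are byte-identical.
format_signif <- function(x, digits = 9L) {
  if (!is.numeric(x)) return(x)
  formatC(signif(x, digits), digits = digits, format = "g")
}
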