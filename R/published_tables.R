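#' Published longitudinal screen statistics
#'
#' The two published SCA1 volumetric screen tables (group-by-elapsed-time
#' interactions; within-affected elapsed-time effects), shipped as printed:
#' numeric columns are kept as character strings so the printed precision of
#' each entry is preserved for arithmetic-consistency checks
#' (t = beta/SE, Bonferroni p = min(1, 34 p), p from t).
#'
#' @param which `"group_by_time"` or `"affected_only"`.
#' @return data.frame with columns voi, beta, se, df, t, p, p_bonferroni
#'   (all character except voi is character too; convert with `as.numeric`).
#' @export
published_screen_table <- function(which = c("group_by_time", "affected_only")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0(which, "_screen_published.tsv"),
                   package = "sca1vol", mustWork = TRUE)
  utils::read.delim(f, colClasses = "character")
}

#' Half-ulp tolerance of a printed number
#'
#' For a value printed as, e.g., "-8.54" the rounding tolerance is 0.005; for
#' "1.91e-05" it is half an ulp of the mantissa times the exponent scale.
#' Used to compare recomputed statistics against printed ones at the printed
#' precision.
#'
#' @param s character representation of the printed number.
#' @return numeric tolerance.
#' @export
printed_tolerance <- function(s) {
  vapply(s, function(x) {
    x <- tolower(trimws(x))
    exp10 <- 0
    if (grepl("e", x)) {
      parts <- strsplit(x, "e")[[1]]
      exp10 <- as.numeric(parts[2])
      x <- parts[1]
    }
    dec <- if (grepl("\\.", x)) nchar(strsplit(x, "\\.")[[1]][2]) else 0
    0.5 * 10^(-dec + exp10)
  }, numeric(1), USE.NAMES = FALSE)
}
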