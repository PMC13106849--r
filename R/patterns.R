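#' Canonical mtDNA lineage patterns
#'
#' A honey sample's lineage pattern is the non-empty subset of the three
#' major *Apis mellifera* mtDNA lineages (A, C, M) whose diagnostic
#' fragments amplified from the pooled honey DNA. Patterns are stored as
#' canonical strings with letters sorted alphabetically, so exactly seven
#' values are possible.
#'
#' @return Character vector of the seven canonical patterns.
#' @export
#' @examples
#' pattern_levels()
pattern_levels <- function() {
  c("A", "AC", "ACM", "AM", "C", "CM", "M")
}

#' Binary outcome codings derived from lineage patterns
#'
#' The six codings used throughout the cline analyses: `contains-L` is 1
#' when the pattern includes lineage L (any pattern eligible), `only-L` is 1
#' when the pattern is exactly {L}.
#'
#' @return Character vector of coding names.
#' @export
coding_levels <- function() {
  c("contains-A", "contains-C", "contains-M", "only-A", "only-C", "only-M")
}

#' Parse lineage pattern tokens to canonical form
#'
#' Tokens are case- and order-insensitive strings over the alphabet
#' {A, C, M} ("acm", "CA" and "AC " are all valid). The canonical
#' serialisation sorts the letters alphabetically. Empty tokens, letters
#' outside the alphabet and duplicated letters are parse errors; samples
#' with no amplified lineage are rejected here rather than silently kept.
#'
#' @param token Character vector of raw pattern tokens.
#' @param context Optional character vector (same length) used to name the
#'   offending rows in error messages, e.g. sample ids.
#' @return Character vector of canonical patterns (see [pattern_levels()]).
#' @export
#' @examples
#' parse_pattern(c("acm", "C", "ma"))
parse_pattern <- function(token, context = NULL) {
  if (length(token) == 0L) return(character(0))
  tok <- toupper(gsub("[[:space:]]", "", as.character(token)))
  out <- character(length(tok))
  bad <- character(0)
  for (i in seq_along(tok)) {
    chars <- strsplit(tok[i], "", fixed = TRUE)[[1]]
    ok <- length(chars) > 0 &&
      all(chars %in% c("A", "C", "M")) &&
      !anyDuplicated(chars)
    if (!ok) {
      where <- if (!is.null(context)) context[i] else paste0("row ", i)
      bad <- c(bad, sprintf("%s (token %s)", where, encodeString(token[i], quote = "'")))
      next
    }
    out[i] <- paste(sort(chars), collapse = "")
  }
  if (length(bad) > 0) {
    stop("invalid lineage pattern token(s): ",
         paste(utils::head(bad, 10), collapse = "; "),
         if (length(bad) > 10) sprintf(" ... and %d more", length(bad) - 10) else "",
         call. = FALSE)
  }
  out
}

#' Test whether patterns contain a lineage
#'
#' @param pattern Character vector of canonical patterns.
#' @param lineage One of "A", "C", "M".
#' @return Logical vector.
#' @export
pattern_contains <- function(pattern, lineage) {
  lineage <- match.arg(lineage, c("A", "C", "M"))
  grepl(lineage, pattern, fixed = TRUE)
}

#' Number of distinct lineages in each pattern
#'
#' @param pattern Character vector of canonical patterns.
#' @return Integer vector in 1..3.
#' @export
pattern_diversity <- function(pattern) {
  nchar(pattern)
}

# Evaluate one binary coding on a canonical pattern vector.
# `only-L` means the pattern is exactly {L}; `contains-L` that it includes L.
apply_coding <- function(pattern, coding) {
  coding <- match.arg(coding, coding_levels())
  lineage <- sub("^(contains|only)-", "", coding)
  if (startsWith(coding, "only")) {
    as.integer(pattern == lineage)
  } else {
    as.integer(pattern_contains(pattern, lineage))
  }
}

#' Round half away from zero
#'
#' Percentages are reported with a half-up rule (0.25 -> 0.3 at one
#' decimal), matching the reporting convention used for all frequency
#' tables in this package; base R's `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.25, 0.35), 1)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Reported percentage: one decimal, but two decimals for sub-1% values
# (e.g. 7/4150 -> 0.17).
report_pct <- function(prop) {
  pct <- 100 * prop
  ifelse(pct < 1, round_half_up(pct, 2), round_half_up(pct, 1))
}
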