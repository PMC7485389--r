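#' Validate and normalize ICD-10 codes
#'
#' Discharge records and disease-gene annotations identify diseases by ICD-10
#' codes of the form `letter + two digits`, optionally followed by a dot and a
#' single alphanumeric subcategory character (`"X"` is the conventional
#' placeholder when no subcategory applies, e.g. `"I10.X"` for essential
#' hypertension). `validate_icd10()` uppercases, strips whitespace and checks
#' this syntax; codes that fail carry a rejection reason instead of throwing,
#' so callers can tally discarded codes.
#'
#' @param code Character vector of candidate codes.
#' @return A tibble with one row per input: `input`, `code` (normalized code,
#'   `NA` when rejected), `valid` (logical) and `reason` (`NA` when valid).
#' @examples
#' validate_icd10(c("i49.8", "I10.X", "1234", " n18.9 "))
#' @export
validate_icd10 <- function(code) {
  if (length(code) == 0L) {
    return(tibble(input = character(), code = character(),
                  valid = logical(), reason = character()))
  }
  input <- as.character(code)
  norm <- toupper(gsub("\\s+", "", input))
  reason <- rep(NA_character_, length(norm))
  reason[is.na(input) | norm == ""] <- "empty"
  pat <- "^[A-Z][0-9]{2}(\\.[A-Z0-9])?$"
  bad <- is.na(reason) & !grepl(pat, norm)
  reason[bad & !grepl("^[A-Z]", norm)] <- "no_category_letter"
  reason[bad & grepl("^[A-Z]", norm)] <- "malformed"
  valid <- is.na(reason)
  tibble(input = input,
         code = ifelse(valid, norm, NA_character_),
         valid = valid,
         reason = reason)
}

# Normalized code or NA, without the bookkeeping columns.
icd10_clean <- function(code) {
  validate_icd10(code)$code
}

#' Test ICD-10 codes against a category range
#'
#' Chapter-style disease groups are written as category ranges such as
#' `"Q20-Q28"` (congenital malformations of the circulatory system): a code
#' belongs to the range when its three-character category (letter + two
#' digits) falls lexicographically between the two endpoints, inclusive.
#' Subcategory characters are ignored, so `"Q24.8"` is inside `"Q20-Q28"`.
#'
#' @param code Character vector of (normalized) ICD-10 codes.
#' @param range A single range string `"A00-B99"`; en dashes are accepted.
#' @return Logical vector.
#' @examples
#' code_in_range(c("Q24.8", "I10.X"), "Q20-Q28")
#' @export
code_in_range <- function(code, range) {
  ends <- parse_code_range(range)
  cat3 <- substr(toupper(code), 1L, 3L)
  cat3 >= ends[1] & cat3 <= ends[2]
}

parse_code_range <- function(range) {
  if (!is.character(range) || length(range) != 1L || is.na(range)) {
    abort("A code range must be a single string like \"Q20-Q28\".")
  }
  x <- toupper(gsub("\\s+", "", range))
  x <- gsub("–|—", "-", x)
  parts <- strsplit(x, "-", fixed = TRUE)[[1]]
  ok <- length(parts) == 2L && all(grepl("^[A-Z][0-9]{2}$", parts)) &&
    parts[1] <= parts[2]
  if (!ok) abort(sprintf("Malformed code range: \"%s\".", range))
  parts
}
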