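#' Build a validated record set from long-format diagnosis rows
#'
#' A cohort arrives as one diagnosis per row (`record_id`, `age`, `sex`,
#' `icd10`); `as_record_set()` groups rows into discharge records, applies the
#' inclusion/exclusion rules and returns one row per retained record. The unit
#' of analysis is the discharge record (a "case"), not the unique patient:
#' repeat admissions are kept as distinct records.
#'
#' Exclusion rules, tallied per reason in `attr(, "exclusions")`:
#' * `incomplete` — missing/blank `record_id`, or missing or non-numeric or
#'   negative age (age must agree across a record's rows);
#' * `non_existing_code` — no syntactically valid ICD-10 code remains after
#'   [validate_icd10()] (invalid codes on otherwise valid records are silently
#'   dropped and counted in `attr(, "dropped_codes")`).
#'
#' Sex values are mapped case-insensitively from `F`/`FEMALE` and `M`/`MALE`;
#' anything else (including missing) becomes `"unknown"` and the record is
#' retained, since sex enters only descriptive summaries. Duplicate codes
#' within one record collapse to a set. Records carrying more than
#' `max_codes` distinct codes trigger a warning, not an exclusion: the cap
#' describes the source system (a principal diagnosis plus up to five
#' comorbidities), not a hard schema.
#'
#' @param x Data frame with columns `record_id`, `age`, `sex`, `icd10`.
#' @param max_codes Soft cap on distinct codes per record (default 6).
#' @param provenance Free-text source tag stored on the result.
#' @return A `record_set`: a tibble with columns `record_id`, `age` (integer
#'   years), `sex` (`"female"`/`"male"`/`"unknown"`) and `codes` (list column
#'   of character vectors), plus attributes `exclusions` (named integer
#'   tally), `dropped_codes`, `n_input` and `provenance`.
#' @seealso [read_discharge_records()] to read the same layout from disk.
#' @examples
#' df <- data.frame(
#'   record_id = c("r1", "r1", "r2", "r3"),
#'   age = c(63, 63, 41, NA),
#'   sex = c("F", "F", "M", "F"),
#'   icd10 = c("I10.X", "N18.9", "I25.8", "I50.9")
#' )
#' rs <- as_record_set(df)
#' n_records(rs)
#' attr(rs, "exclusions")
#' @export
as_record_set <- function(x, max_codes = 6L, provenance = "unspecified") {
  required <- c("record_id", "age", "sex", "icd10")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Input is missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(x)[required]
  if (nrow(x) == 0L) abort("Input contains no diagnosis rows.")

  x$record_id <- as.character(x$record_id)
  x$age_num <- suppressWarnings(as.numeric(x$age))
  v <- validate_icd10(x$icd10)
  x$code <- v$code

  per_rec <- x |>
    dplyr::group_by(.data$record_id) |>
    dplyr::summarise(
      bad_id = any(is.na(.data$record_id)) || unique(.data$record_id)[1] == "",
      bad_age = any(is.na(.data$age_num)) ||
        dplyr::n_distinct(.data$age_num) > 1L || .data$age_num[1] < 0,
      age = .data$age_num[1],
      sex = normalize_sex(.data$sex[1]),
      codes = list(sort(unique(.data$code[!is.na(.data$code)]))),
      n_bad_codes = sum(is.na(.data$code)),
      .groups = "drop"
    )

  incomplete <- per_rec$bad_id | per_rec$bad_age
  no_code <- !incomplete & lengths(per_rec$codes) == 0L
  keep <- !incomplete & !no_code

  exclusions <- c(incomplete = sum(incomplete), non_existing_code = sum(no_code))
  out <- per_rec[keep, c("record_id", "age", "sex", "codes")]
  out$age <- as.integer(out$age)

  n_wide <- sum(lengths(out$codes) > max_codes)
  if (n_wide > 0L) {
    warn(sprintf("%d record(s) carry more than %d distinct codes.",
                 n_wide, max_codes))
  }

  new_record_set(out,
                 exclusions = exclusions,
                 dropped_codes = sum(per_rec$n_bad_codes[keep]),
                 n_input = nrow(per_rec),
                 provenance = provenance)
}

new_record_set <- function(df, exclusions, dropped_codes, n_input, provenance) {
  structure(df,
            exclusions = exclusions,
            dropped_codes = dropped_codes,
            n_input = n_input,
            provenance = provenance,
            class = c("record_set", class(tibble())))
}

normalize_sex <- function(x) {
  x <- toupper(trimws(as.character(x)))
  dplyr::case_when(
    x %in% c("F", "FEMALE") ~ "female",
    x %in% c("M", "MALE") ~ "male",
    .default = "unknown"
  )
}

#' Read discharge records from a delimited file
#'
#' Reads a UTF-8 TSV or CSV (by extension; anything not ending in `.csv` is
#' read as tab-separated) with header columns `record_id`, `age`, `sex`,
#' `icd10`, one diagnosis per row, then validates it with [as_record_set()].
#'
#' @inheritParams as_record_set
#' @param path File path.
#' @return A `record_set`; see [as_record_set()].
#' @export
read_discharge_records <- function(path, max_codes = 6L, provenance = path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  df <- reader(path, col_types = readr::cols(.default = readr::col_character()),
               progress = FALSE)
  if (nrow(df) == 0L) abort(sprintf("File contains no diagnosis rows: %s", path))
  as_record_set(df, max_codes = max_codes, provenance = provenance)
}

#' Number of retained records in a record set
#' @param rs A `record_set`.
#' @return Integer cohort size, the `N` used by all co-occurrence statistics.
#' @export
n_records <- function(rs) {
  nrow(rs)
}

#' @export
print.record_set <- function(x, ...) {
  excl <- attr(x, "exclusions")
  cat(sprintf("<record_set> %d records (of %d input; excluded: %s)\n",
              nrow(x), attr(x, "n_input") %||% nrow(x),
              paste(sprintf("%s=%d", names(excl), excl), collapse = ", ")))
  NextMethod()
}

#' Decade age brackets
#'
#' The default stratification uses ten non-overlapping brackets spaced by ten
#' years — `0-10`, `11-20`, ..., `91-100` — with inclusive bounds and an
#' open-ended final bracket, so a 104-year-old falls in `91-100` (91 years
#' and over).
#'
#' @return A tibble with columns `label`, `lo`, `hi` (`hi = Inf` for the last
#'   bracket).
#' @examples
#' default_age_brackets()
#' @export
default_age_brackets <- function() {
  lo <- c(0L, seq(11L, 91L, by = 10L))
  hi <- c(seq(10L, 90L, by = 10L), Inf)
  tibble(label = paste0(lo, "-", pmin(lo + c(10L, rep(9L, 9L)), 100L)),
         lo = lo, hi = hi)
}

check_brackets <- function(brackets) {
  ok <- is.data.frame(brackets) &&
    all(c("label", "lo", "hi") %in% names(brackets)) &&
    nrow(brackets) >= 1L
  if (!ok) abort("`brackets` must be a data frame with columns label, lo, hi.")
  b <- brackets[order(brackets$lo), ]
  if (b$lo[1] != 0) abort("Age brackets must start at 0.")
  if (any(b$lo > b$hi)) abort("Each bracket needs lo <= hi.")
  if (nrow(b) > 1L && any(b$lo[-1] != head(b$hi, -1) + 1)) {
    abort("Age brackets must partition the age axis without gaps or overlap.")
  }
  if (is.finite(b$hi[nrow(b)])) {
    abort("The final age bracket must be open-ended (hi = Inf).")
  }
  b
}

#' Assign each record to its age bracket
#'
#' @param rs A `record_set`.
#' @param brackets Bracket table as from [default_age_brackets()].
#' @return `rs` with an added `age_bracket` factor column (levels in bracket
#'   order); every record lands in exactly one bracket.
#' @export
assign_age_bracket <- function(rs, brackets = default_age_brackets()) {
  b <- check_brackets(brackets)
  idx <- findInterval(rs$age, b$lo)
  rs$age_bracket <- factor(b$label[idx], levels = b$label)
  rs
}

#' Split a record set into one record set per age bracket
#'
#' @inheritParams assign_age_bracket
#' @return Named list of `record_set`s, one per bracket label (empty brackets
#'   yield zero-row record sets); the bracket sizes sum to `n_records(rs)`.
#' @export
stratify_by_age <- function(rs, brackets = default_age_brackets()) {
  tagged <- assign_age_bracket(rs, brackets)
  labs <- levels(tagged$age_bracket)
  out <- lapply(labs, function(lab) {
    sub <- tagged[tagged$age_bracket == lab,
                  c("record_id", "age", "sex", "codes")]
    new_record_set(sub,
                   exclusions = c(incomplete = 0L, non_existing_code = 0L),
                   dropped_codes = 0L,
                   n_input = nrow(sub),
                   provenance = sprintf("%s [%s]",
                                        attr(rs, "provenance") %||% "", lab))
  })
  setNames(out, labs)
}

#' Prevalence of disease groups by sex and age bracket
#'
#' For each sex-by-bracket cell, the percentage of records whose code set
#' intersects each ICD-10 category range (e.g. congenital circulatory
#' malformations `Q20-Q28` peaking in the 0-10 bracket). Cells with no
#' records are omitted; a group absent from a non-empty cell reports 0%.
#'
#' @param rs A `record_set`.
#' @param groups Named character vector of category ranges,
#'   e.g. `c("Congenital circulatory" = "Q20-Q28")`; unnamed ranges are
#'   labelled by the range string.
#' @param brackets Bracket table as from [default_age_brackets()].
#' @return Tibble with columns `sex`, `age_bracket`, `group`, `range`,
#'   `n_cell`, `n_with`, `percent`.
#' @export
prevalence_summary <- function(rs, groups, brackets = default_age_brackets()) {
  if (length(groups) == 0L) abort("`groups` must name at least one code range.")
  labels <- names(groups) %||% unname(groups)
  if (is.null(names(groups))) names(groups) <- unname(groups)
  empty_names <- names(groups) == ""
  names(groups)[empty_names] <- unname(groups)[empty_names]
  lapply(groups, parse_code_range)  # fail fast on malformed ranges

  tagged <- assign_age_bracket(rs, brackets)
  purrr::imap_dfr(groups, function(range, label) {
    tagged |>
      dplyr::mutate(hit = purrr::map_lgl(.data$codes,
                                         ~ any(code_in_range(.x, range)))) |>
      dplyr::group_by(.data$sex, .data$age_bracket) |>
      dplyr::summarise(n_cell = dplyr::n(),
                       n_with = sum(.data$hit), .groups = "drop") |>
      dplyr::mutate(group = label, range = range,
                    percent = 100 * .data$n_with / .data$n_cell)
  }) |>
    dplyr::select("sex", "age_bracket", "group", "range",
                  "n_cell", "n_with", "percent") |>
    dplyr::arrange(.data$group, .data$sex, .data$age_bracket)
}
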