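test_that("rows group into records and duplicate codes collapse", {
  df <- tiny_cohort_df()
  df <- rbind(df, data.frame(record_id = "r1", age = 63, sex = "F",
                             icd10 = "I10.X"))  # duplicate code
  rs <- as_record_set(df)
  expect_equal(n_records(rs), 4L)
  r1 <- rs$codes[[which(rs$record_id == "r1")]]
  expect_equal(r1, c("I10.X", "N18.9"))
})

test_that("incomplete and code-invalid records are excluded with a tally", {
  df <- data.frame(
    record_id = c("a", "b", "c", "d"),
    age = c(10, NA, 30, 40),
    sex = c("F", "M", "F", "M"),
    icd10 = c("I10.X", "I25.8", "bogus", "N18.9")
  )
  rs <- as_record_set(df)
  expect_equal(n_records(rs), 2L)
  excl <- attr(rs, "exclusions")
  expect_equal(unname(excl["incomplete"]), 1L)
  expect_equal(unname(excl["non_existing_code"]), 1L)
  # exclusion accounting: input = retained + sum of tallies
  expect_equal(attr(rs, "n_input"), n_records(rs) + sum(excl))
})

test_that("negative ages are excluded and sex maps to a closed vocabulary", {
  df <- data.frame(record_id = c("a", "b", "c"),
                   age = c(-1, 20, 30),
                   sex = c("F", "x", NA),
                   icd10 = c("I10.X", "I10.X", "I25.8"))
  rs <- as_record_set(df)
  expect_equal(n_records(rs), 2L)
  expect_setequal(rs$sex, "unknown")
})

test_that("missing columns and empty inputs are fatal, wide records warn", {
  expect_error(as_record_set(data.frame(record_id = "a", age = 1, sex = "F")),
               "icd10")
  expect_error(as_record_set(tiny_cohort_df()[0, ]), "no diagnosis rows")
  wide <- data.frame(record_id = "w", age = 50, sex = "M",
                     icd10 = sprintf("I%02d.X", 1:7))
  expect_warning(as_record_set(wide), "more than 6")
})

test_that("round trip through a TSV file preserves the cohort", {
  df <- tiny_cohort_df()
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(df, path)
  rs <- read_discharge_records(path)
  expect_equal(n_records(rs), 4L)
  expect_equal(sort(unlist(rs$codes)),
               sort(validate_icd10(df$icd10)$code))
  expect_error(read_discharge_records(withr::local_tempfile(fileext = ".tsv")),
               "not found")
})

test_that("age brackets partition the cohort with inclusive bounds", {
  b <- default_age_brackets()
  expect_equal(nrow(b), 10L)
  df <- data.frame(record_id = as.character(1:5),
                   age = c(10, 11, 95, 104, 0),
                   sex = "F", icd10 = "I10.X")
  rs <- as_record_set(df)
  tagged <- assign_age_bracket(rs)
  expect_equal(as.character(tagged$age_bracket),
               c("0-10", "11-20", "91-100", "91-100", "0-10"))
  strata <- stratify_by_age(rs)
  expect_equal(sum(vapply(strata, nrow, integer(1))), n_records(rs))
  # disjoint and exhaustive
  ids <- unname(unlist(lapply(strata, function(s) s$record_id)))
  expect_equal(sort(ids), sort(rs$record_id))
})

test_that("prevalence summary counts range intersections per cell", {
  df <- data.frame(record_id = c("a", "b"),
                   age = c(3, 3),
                   sex = c("F", "F"),
                   icd10 = c("Q24.8", "I10.X"))
  rs <- as_record_set(df)
  prev <- prevalence_summary(rs, c(congenital = "Q20-Q28"))
  cell <- prev[prev$age_bracket == "0-10" & prev$sex == "female", ]
  expect_equal(cell$n_cell, 2L)
  expect_equal(cell$percent, 50)
  expect_error(prevalence_summary(rs, c(bad = "Q20")), "Malformed")
})

test_that("planted age-profile prevalence is recovered within binomial error", {
  sim <- generate_cohort(sim_config(n_records = 2000L), seed = 11L)
  rs <- sim$records
  # module 1 (Q codes) concentrates in the 0-10 bracket by construction;
  # direct counting oracle on the generated cohort
  tagged <- assign_age_bracket(rs)
  young <- tagged[tagged$age_bracket == "0-10", ]
  direct <- mean(vapply(young$codes,
                        function(cs) any(code_in_range(cs, "Q00-Q19")),
                        logical(1)))
  prev <- prevalence_summary(rs, c(q = "Q00-Q19"))
  cell <- prev[prev$age_bracket == "0-10", ]
  pooled <- sum(cell$n_with) / sum(cell$n_cell)
  expect_equal(pooled, direct, tolerance = 1e-12)
  # the planted module dominates childhood records
  expect_gt(pooled, 0.75)
})
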