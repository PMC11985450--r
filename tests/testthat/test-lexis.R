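test_that("rate-matrix CSVs parse and round-trip cell-for-cell", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,1992,1993", "30,1,2", "31,3,4"), path)
  rm <- read_rate_matrix(path, "cases")
  expect_equal(unname(rm$values), matrix(c(1, 3, 2, 4), 2))
  expect_equal(rm$ages, c(30, 31))
  expect_equal(rm$periods, c(1992, 1993))
  expect_equal(rm$delta, 1)

  set.seed(71)
  big <- matrix(rpois(55 * 28, 40), 55, 28)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_rate_matrix(big, p2, ages = 30:84, periods = 1992:2019)
  back <- read_rate_matrix(p2, "cases")
  expect_equal(unname(back$values), big)
  expect_equal(back$ages, 30:84)
})

test_that("malformed rate matrices are rejected with informative errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,1992,1993", "30,1,2", "35,3,4", "40,5,6"), p)
  expect_error(read_rate_matrix(p, "cases"), "bin width")
  writeLines(c("age,1992,1993", "30,-1,2", "31,3,4"), p)
  expect_error(read_rate_matrix(p, "cases"), "egative")
  writeLines(c("age,1992,1993", "30,0,2", "31,3,4"), p)
  expect_error(read_rate_matrix(p, "offsets"), "strictly positive")
  writeLines(c("year,1992", "30,1"), p)
  expect_error(read_rate_matrix(p, "cases"), "age")
})

test_that("lexis diagrams enforce shape, positivity and diagonal cohorts", {
  expect_error(lexis_diagram(matrix(1, 3, 4), matrix(1, 4, 3), 30, 1990),
               "identical shape")
  expect_error(lexis_diagram(matrix(1, 3, 3), matrix(0, 3, 3), 30, 1990),
               "strictly positive")
  expect_error(lexis_diagram(matrix(-1, 3, 3), matrix(1, 3, 3), 30, 1990),
               "non-negative")
  lx <- lexis_diagram(matrix(2, 4, 6), matrix(10, 4, 6), 40, 2000)
  expect_length(lx$cohorts, 4 + 6 - 1)
  expect_equal(lx$cohorts[1], 2000 - 43)   # oldest cohort: first period, last age
  expect_equal(observed_rates(lx), matrix(0.2, 4, 6), ignore_attr = TRUE)
})

test_that("tabulate_survivorship counts single subjects correctly", {
  base <- data.frame(age_group_start = 50, age_group_width = 5,
                     diag_year = 2000, exit_time = 2, died = 1)
  sv <- tabulate_survivorship(base, age_starts = 50, periods = 2000:2004,
                              t_max = 5)
  expect_equal(sv$at_risk[1, 1, ], c(1, 1, 1, 0, 0, 0), ignore_attr = TRUE)
  expect_equal(sv$deaths[1, 1, 3], 1, ignore_attr = TRUE)
  expect_equal(sum(sv$deaths), 1)

  cens <- transform(base, died = 0)
  sv2 <- tabulate_survivorship(cens, age_starts = 50, periods = 2000:2004,
                               t_max = 5)
  expect_equal(sv2$at_risk[1, 1, ], c(1, 1, 1, 0, 0, 0), ignore_attr = TRUE)
  expect_equal(sum(sv2$deaths), 0)

  # exit beyond t_max: carried in M through t_max, censored there
  late <- transform(base, exit_time = 9, died = 1)
  sv3 <- tabulate_survivorship(late, age_starts = 50, periods = 2000:2004,
                               t_max = 5)
  expect_equal(sv3$at_risk[1, 1, ], rep(1, 6), ignore_attr = TRUE)
  expect_equal(sum(sv3$deaths), 0)
})

test_that("tabulation conserves subjects per stratum on generated listings", {
  tr <- small_truth(offset = 3e4)
  rec <- generate_case_listing(tr, seed = 42)
  sv <- tabulate_survivorship(rec, age_starts = seq(40, 55, 5),
                              periods = tr$periods, t_max = 10)
  diagnosed <- rowsum(rec$weight,
                      paste(rec$age_group_start, rec$diag_year))
  for (gi in seq_along(sv$age_starts)) for (pj in seq_along(sv$periods)) {
    key <- paste(sv$age_starts[gi], sv$periods[pj])
    n <- if (key %in% rownames(diagnosed)) diagnosed[key, 1] else 0
    # M at t = 0 equals the number diagnosed in the stratum
    expect_identical(unname(sv$at_risk[gi, pj, 1]), as.numeric(n))
    # deaths + censored = diagnosed: censored are at-risk minus deaths,
    # accumulated where follow-up ends
    deaths <- sum(sv$deaths[gi, pj, ])
    expect_lte(deaths, n)
  }
  # global conservation: everyone either dies in-window or is censored
  expect_identical(sum(sv$at_risk[, , 1]), as.numeric(sum(rec$weight)))
})

test_that("records outside the grid are rejected or skipped as configured", {
  rec <- data.frame(age_group_start = c(50, 90), age_group_width = 5,
                    diag_year = 2000, exit_time = 1, died = 0)
  expect_error(tabulate_survivorship(rec, age_starts = 50, periods = 2000,
                                     t_max = 2), "outside")
  expect_message(
    sv <- tabulate_survivorship(rec, age_starts = 50, periods = 2000,
                                t_max = 2, outside = "skip"),
    "skipping 1")
  expect_equal(sum(sv$at_risk[, , 1]), 1)
})

test_that("survivorship arrays round-trip through long-format CSV", {
  tr <- small_truth(offset = 1e4)
  rec <- generate_case_listing(tr, seed = 7)
  sv <- tabulate_survivorship(rec, age_starts = seq(40, 55, 5),
                              periods = tr$periods, t_max = 6)
  p <- withr::local_tempfile(fileext = ".csv")
  write_survivorship(sv, p)
  sv2 <- read_survivorship(p)
  expect_equal(sv2$at_risk, sv$at_risk, ignore_attr = TRUE)
  expect_equal(sv2$deaths, sv$deaths, ignore_attr = TRUE)
  expect_equal(sv2$age_width, 5)
})
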