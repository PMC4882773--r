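test_that("categorizers honor the published cut points at their boundaries", {
  expect_equal(as.character(categorize_age(c(45, 59, 60, 74, 75, 90))),
               c("45-59", "45-59", "60-74", "60-74", "75+", "75+"))
  under <- categorize_age(c(40, 50))
  expect_true(is.na(under[1]))
  expect_equal(attr(under, "excluded"), 1L)

  expect_equal(as.character(categorize_bmi(c(18.4, 18.5, 23.9, 24.0, 27.9, 28.0))),
               c("<18.5", "18.5-23.9", "18.5-23.9", "24.0-27.9", "24.0-27.9",
                 ">=28.0"))
  expect_true(is.na(categorize_bmi(c(-1))[1]))

  # ratio exactly 0.5 is pear; apple is strictly > 0.5
  expect_equal(as.character(categorize_whtr(c(80, 81, 50), c(160, 160, 170))),
               c("pear", "apple", "pear"))
  expect_true(is.na(categorize_whtr(NA, 160)))
})

test_that("stratified prevalence reproduces engineered percentages", {
  rec <- engineered_records(235, 48)
  tab <- suppressWarnings(stratified_prevalence(rec, "age"))
  row <- tab[tab$stratum == "45-59" & tab$gender == "male", ]
  expect_equal(row$cases, 48L)
  expect_equal(row$n, 235L)
  expect_equal(row$percent, 20.43)

  # an all-case stratum is exactly 100.00
  allc <- engineered_records(12, 12)
  t2 <- suppressWarnings(stratified_prevalence(allc, "age"))
  expect_equal(t2$percent[t2$gender == "male"], 100)

  # missing stratum values reduce the denominator rather than erroring
  rec$bmi[1:35] <- NA
  t3 <- suppressWarnings(stratified_prevalence(rec, "bmi"))
  expect_equal(sum(t3$n), 200L)

  expect_error(stratified_prevalence(rec, "shoe_size"), "unknown stratifier")
  expect_error(stratified_prevalence(rec[0, ], "age"), "no subject records")
})

test_that("published stratified counts reproduce the printed headline figures", {
  cc <- zhejiang_strata_counts()
  age <- cc[cc$stratifier == "age", ]
  tab <- prevalence_table(age$stratum, age$gender, age$cases, age$n,
                          stratifier = "age")
  # every cell percentage recomputes exactly at printed 2-decimal precision
  expect_equal(tab$percent[tab$stratum == "45-59" & tab$gender == "male"],
               20.43)
  expect_equal(tab$percent[tab$stratum == "60-74" & tab$gender == "female"],
               45.06)
  tot <- prevalence_totals(tab)
  expect_equal(tot$percent[tot$group == "male"], 30.6)
  expect_equal(tot$percent[tot$group == "female"], 35.5)
  # the age strata cover 1264 subjects; their pooled prevalence is 33.1 %
  expect_equal(tot$n[tot$group == "overall"], 1264L)
  expect_equal(tot$percent[tot$group == "overall"], 33.1)

  # covariate proportions from the category denominators
  whtr <- cc[cc$stratifier == "whtr", ]
  apple_m <- whtr$n[whtr$gender == "male" & whtr$stratum == "apple"] /
    sum(whtr$n[whtr$gender == "male"])
  apple_f <- whtr$n[whtr$gender == "female" & whtr$stratum == "apple"] /
    sum(whtr$n[whtr$gender == "female"])
  expect_equal(round_half_up(100 * apple_m, 1), 63.6)
  expect_equal(round_half_up(100 * apple_f, 1), 82.8)
  bmi <- cc[cc$stratifier == "bmi", ]
  obese_m <- bmi$n[bmi$gender == "male" & bmi$stratum == ">=28.0"] /
    sum(bmi$n[bmi$gender == "male"])
  obese_f <- bmi$n[bmi$gender == "female" & bmi$stratum == ">=28.0"] /
    sum(bmi$n[bmi$gender == "female"])
  expect_equal(round_half_up(100 * obese_m, 1), 6.8)
  expect_equal(round_half_up(100 * obese_f, 1), 11.3)
})

test_that("covariate aggregates compute cell proportions and flag empties", {
  rec <- rbind(engineered_records(10, 3),
               transform(engineered_records(10, 3), age = 62))
  rec$region <- rep(c("A", "B"), each = 10)
  agg <- covariate_aggregates(rec, regions = c("A", "B", "C"))
  expect_equal(agg$elderly[agg$region == "A" & agg$gender == "male"], 0)
  expect_equal(agg$elderly[agg$region == "B" & agg$gender == "male"], 1)
  # region C has no records at all: every covariate flagged missing
  miss <- attr(agg, "missing")
  expect_true(all(c("elderly", "obese", "whtr") %in%
                    miss$covariate[miss$region == "C"]))

  # apple proportion equals the category count ratio
  n <- 50
  rec2 <- engineered_records(n, 10)
  rec2$waist <- c(rep(90, 30), rep(70, 20))   # 30 apple (ratio .545), 20 pear
  rec2$height <- 165
  agg2 <- covariate_aggregates(rec2)
  expect_equal(agg2$whtr[agg2$gender == "male"], 30 / 50)

  # proportions are computed among non-missing only
  rec2$bmi[1:10] <- NA
  rec2$bmi[11:50] <- c(rep(30, 4), rep(22, 36))
  agg3 <- covariate_aggregates(rec2)
  expect_equal(agg3$obese[agg3$gender == "male"], 4 / 40)
})

test_that("subject files round-trip and malformed rows are reported", {
  rec <- engineered_records(8, 2)
  f <- tempfile(fileext = ".tsv")
  write_subjects(rec, f)
  back <- read_subjects(f)
  expect_equal(back$hypertension, rec$hypertension)
  expect_equal(back$bmi, rec$bmi)

  bad <- rec
  bad$gender[3] <- "other"
  write_subjects(bad, f)
  expect_error(read_subjects(f), "line\\(s\\): 3")
  expect_error(read_subjects(tempfile()), "not found")
})
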