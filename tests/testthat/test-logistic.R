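# records with one binary covariate laid out as a 2x2 table
table22_records <- function(a, b, c, d) {
  # a exposed cases, b exposed non-cases, c unexposed cases, d unexposed
  n <- a + b + c + d
  data.frame(region = "A",
             gender = "male",
             age = 50,
             bmi = 22,
             # exposure encoded through WHtR: apple = exposed
             waist = c(rep(90, a + b), rep(70, c + d)),
             height = 160,
             smoking = "never", alcohol = "never", sleep_night = 7, nap = 0,
             hypertension = c(rep(1L, a), rep(0L, b), rep(1L, c), rep(0L, d)),
             stringsAsFactors = FALSE)
}

test_that("single-covariate logistic OR equals the 2x2 closed form", {
  rec <- table22_records(10, 10, 5, 20)
  tab <- fit_multivariable(rec, "whtr", stepwise = FALSE)
  expect_equal(tab$or[!tab$reference], 4.0, tolerance = 1e-6)
  expect_equal(tab$or[tab$reference], 1)
  expect_true(is.na(tab$ci_low[tab$reference]))

  # property: random tables without zero cells, both with and without the
  # stepwise path (a single screened candidate reduces to the direct fit)
  for (s in 1:6) {
    set.seed(s)
    cnt <- sample(5:40, 4, replace = TRUE)
    rec <- table22_records(cnt[1], cnt[2], cnt[3], cnt[4])
    direct <- fit_multivariable(rec, "whtr", stepwise = FALSE)
    closed <- (cnt[1] * cnt[4]) / (cnt[2] * cnt[3])
    expect_equal(direct$or[!direct$reference], closed, tolerance = 1e-5)
    step <- suppressWarnings(fit_multivariable(rec, "whtr", stepwise = TRUE))
    if (nrow(step)) {
      expect_equal(step$or[!step$reference], closed, tolerance = 1e-5)
    }
    # CI endpoints bracket the estimate (log-scale Wald exponentiated)
    i <- which(!direct$reference)
    expect_true(direct$ci_low[i] <= direct$or[i] &&
                  direct$or[i] <= direct$ci_high[i])
  }

  # independence with balanced cells gives OR exactly 1
  null <- fit_multivariable(table22_records(10, 10, 10, 10), "whtr",
                            stepwise = FALSE)
  expect_equal(null$or[!null$reference], 1, tolerance = 1e-8)
})

test_that("univariate screening selects near the nominal rate and flags degeneracies", {
  # covariate identical to the outcome: separation, flagged but retained
  rec <- table22_records(25, 0, 0, 25)
  scr <- univariate_screen(rec, "whtr")
  expect_true(scr$selected)
  expect_equal(scr$flag, "separation")

  # constant covariate: degenerate, never selected
  rec2 <- engineered_records(40, 10)
  expect_warning(scr2 <- univariate_screen(rec2, "whtr"), "constant")
  expect_false(scr2$selected)
  expect_equal(scr2$flag, "degenerate")

  # type-I behaviour at the 0.06 threshold: an independent covariate is
  # selected in about 6 % of replicates
  set.seed(42)
  n <- 2000
  hits <- 0L
  reps <- 500L
  for (r in seq_len(reps)) {
    y <- rbinom(n, 1, 0.3)
    x <- rnorm(n)
    fit <- glm(y ~ x, binomial())
    p <- anova(glm(y ~ 1, binomial()), fit, test = "Chisq")[2, "Pr(>Chi)"]
    hits <- hits + (p < 0.06)
  }
  rate <- hits / reps
  # binomial MC sd at 0.06 over 500 reps is about 0.011
  expect_gt(rate, 0.06 - 3.5 * 0.011)
  expect_lt(rate, 0.06 + 3.5 * 0.011)
})

test_that("VIFs match the auxiliary-regression oracle and flag dependence", {
  set.seed(7)
  n <- 400
  df <- data.frame(hypertension = rbinom(n, 1, 0.4),
                   x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  v <- multicollinearity_check(df, c("x1", "x2", "x3"))
  expect_true(all(v$vif >= 1))
  expect_true(all(v$vif < 1.2))
  expect_false(any(v$flag))

  # near-duplicate: VIF equals 1/(1 - R^2) from the auxiliary regression
  df$x2 <- df$x1 + rnorm(n, 0, 0.05)
  v2 <- multicollinearity_check(df, c("x1", "x2", "x3"))
  r2 <- summary(lm(x1 ~ x2 + x3, df))$r.squared
  expect_equal(v2$vif[v2$term == "x1"], 1 / (1 - r2), tolerance = 1e-8)
  expect_true(all(v2$flag[v2$term %in% c("x1", "x2")]))

  # exact duplication: infinite VIF flag rather than an error
  df$x2 <- df$x1
  expect_warning(v3 <- multicollinearity_check(df, c("x1", "x2", "x3")),
                 "dependence")
  expect_true(all(is.infinite(v3$vif)))
  expect_error(multicollinearity_check(df, "x1"), "at least two")
})

test_that("forward stepwise keeps only covariates that earn entry", {
  set.seed(11)
  n <- 600
  age <- sample(45:85, n, replace = TRUE)
  lp <- -2 + 0.06 * (age - 45)
  rec <- data.frame(region = "A", gender = "male", age = age,
                    bmi = rnorm(n, 23, 2), waist = rnorm(n, 80, 6),
                    height = 165, smoking = sample(c("never", "current"), n, TRUE),
                    alcohol = sample(c("never", "current"), n, TRUE),
                    sleep_night = rnorm(n, 7, 1),
                    hypertension = rbinom(n, 1, plogis(lp)), nap = 0,
                    stringsAsFactors = FALSE)
  tab <- suppressWarnings(
    fit_multivariable(rec, c("age", "smoking", "alcohol", "sleep_night")))
  expect_true("age" %in% attr(tab, "selected"))
  # the pure-noise lifestyle covariates should usually be dropped; at minimum
  # the retained model must include the true signal first
  expect_equal(attr(tab, "selected")[1], "age")
  # reference rows carry OR exactly 1
  expect_true(all(tab$or[tab$reference] == 1))
})
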