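# Traditional comparison arm: univariate screening, forward-stepwise
# multivariable logistic regression, OR/CI tables, collinearity diagnostics.

# model frame with categorized covariates; reference levels are the first
# factor levels (age 45-59, BMI 18.5-23.9 renormalized below, WHtR pear,
# smoking/alcohol never)
logistic_model_frame <- function(records) {
  bmi <- categorize_bmi(records$bmi)
  # normal weight is the clinical reference, not the first band
  bmi <- stats::relevel(bmi, ref = "18.5-23.9")
  data.frame(
    hypertension = as.integer(records$hypertension),
    gender = factor(as.character(records$gender), levels = GENDERS),
    age = categorize_age(records$age),
    bmi = bmi,
    whtr = categorize_whtr(records$waist, records$height),
    smoking = factor(as.character(records$smoking),
                     levels = c("never", "current")),
    alcohol = factor(as.character(records$alcohol),
                     levels = c("never", "current")),
    sleep_night = as.numeric(records$sleep_night))
}

# likelihood-ratio p-value for adding `term` to `base` (character vectors of
# term labels); fits on the supplied (already complete-case) frame
lrt_add_p <- function(frame, base, term) {
  rhs0 <- if (length(base)) paste(base, collapse = " + ") else "1"
  f0 <- glm(as.formula(paste("hypertension ~", rhs0)), binomial(), frame)
  f1 <- glm(as.formula(paste("hypertension ~",
                             paste(c(base, term), collapse = " + "))),
            binomial(), frame)
  a <- anova(f0, f1, test = "Chisq")
  a[2, "Pr(>Chi)"]
}

#' Univariate screening of candidate risk factors
#'
#' Fits one single-covariate logistic model per candidate and tests the whole
#' variable (all dummy levels jointly) against the intercept-only model by
#' likelihood ratio. A candidate enters the multivariable stage when its
#' p-value falls below the threshold, 0.06 by convention so that borderline
#' factors are not discarded prematurely. Candidates with perfect separation
#' are flagged but retained; degenerate (constant) candidates are flagged and
#' never selected.
#'
#' @param records subject-level data frame.
#' @param candidates character vector of covariate names among `age`, `bmi`,
#'   `whtr`, `smoking`, `alcohol`, `sleep_night`.
#' @param p_threshold selection threshold on the LRT p-value (default 0.06).
#' @param gender optional `"male"`/`"female"` to screen within one stratum.
#' @return data frame with columns `candidate`, `p_value`, `selected`, `flag`.
#' @export
univariate_screen <- function(records, candidates, p_threshold = 0.06,
                              gender = NULL) {
  frame <- logistic_model_frame(records)
  if (!is.null(gender)) frame <- frame[frame$gender == gender, ]
  out <- data.frame(candidate = candidates, p_value = NA_real_,
                    selected = FALSE, flag = "", stringsAsFactors = FALSE)
  for (r in seq_along(candidates)) {
    v <- candidates[r]
    if (!v %in% names(frame)) stop("unknown candidate covariate: ", v)
    sub <- frame[!is.na(frame[[v]]), c("hypertension", v)]
    x <- sub[[v]]
    degenerate <- (is.factor(x) && nlevels(droplevels(x)) < 2L) ||
      (!is.factor(x) && (length(unique(x)) < 2L))
    if (degenerate || nrow(sub) == 0L) {
      out$flag[r] <- "degenerate"
      warning("candidate '", v, "' is constant; degenerate fit skipped")
      next
    }
    separated <- FALSE
    fit1 <- withCallingHandlers(
      glm(as.formula(paste("hypertension ~", v)), binomial(), sub),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w)))
          separated <<- TRUE
        invokeRestart("muffleWarning")
      })
    # quasi-separation can converge without the glm warning; catch fitted
    # probabilities pinned at the boundary directly
    if (any(fitted(fit1) < 1e-8) || any(fitted(fit1) > 1 - 1e-8))
      separated <- TRUE
    fit0 <- glm(hypertension ~ 1, binomial(), sub)
    p <- anova(fit0, fit1, test = "Chisq")[2, "Pr(>Chi)"]
    out$p_value[r] <- p
    out$selected[r] <- is.finite(p) && p < p_threshold
    if (separated) {
      out$flag[r] <- "separation"
      out$selected[r] <- TRUE  # retained and reported, never silently dropped
    }
  }
  out
}

# OR table rows from a fitted binomial glm; reference levels carry OR exactly
# 1 with no interval
or_table_from_fit <- function(fit, covariates, conf_level = 0.95) {
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  pv <- 2 * pnorm(-abs(est / se))
  rows <- list()
  frame <- fit$model
  for (v in covariates) {
    x <- frame[[v]]
    if (is.factor(x)) {
      lv <- levels(x)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = lv[1], reference = TRUE, or = 1,
        ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
        stringsAsFactors = FALSE)
      for (l in lv[-1]) {
        term <- paste0(v, l)
        if (!term %in% names(est)) next
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = l, reference = FALSE,
          or = exp(est[term]),
          ci_low = exp(est[term] - z * se[term]),
          ci_high = exp(est[term] + z * se[term]),
          p_value = pv[term], stringsAsFactors = FALSE)
      }
    } else {
      if (!v %in% names(est)) next
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = "(per unit)", reference = FALSE,
        or = exp(est[v]), ci_low = exp(est[v] - z * se[v]),
        ci_high = exp(est[v] + z * se[v]), p_value = pv[v],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("or_table", "data.frame")
  out
}

#' Forward-stepwise multivariable logistic regression
#'
#' Fits the gender-stratified multivariable model by forward selection:
#' starting from the intercept-only model, at each step the candidate with
#' the smallest likelihood-ratio p-value enters if it falls below `enter_p`
#' (0.05), and selection stops when no candidate qualifies. The final model's
#' odds ratios carry Wald 95 percent confidence intervals computed on the
#' log-odds scale and exponentiated. Which covariates survive is
#' data-dependent; nothing is hard-coded.
#'
#' @param records subject-level data frame.
#' @param covariates candidate covariate names (typically the screened set
#'   plus the forced lifestyle candidates).
#' @param gender `"male"` or `"female"`; `NULL` fits on all records.
#' @param enter_p forward-entry threshold (LRT p-value, default 0.05).
#' @param stepwise set `FALSE` to fit all `covariates` directly.
#' @param conf_level confidence level for the Wald intervals.
#' @return an `or_table` data frame (columns `variable`, `level`,
#'   `reference`, `or`, `ci_low`, `ci_high`, `p_value`); attributes `fit`
#'   (the glm) and `selected` (covariates retained).
#' @export
fit_multivariable <- function(records, covariates, gender = NULL,
                              enter_p = 0.05, stepwise = TRUE,
                              conf_level = 0.95) {
  frame <- logistic_model_frame(records)
  if (!is.null(gender)) {
    stopifnot(gender %in% GENDERS)
    frame <- frame[frame$gender == gender, ]
  }
  frame <- frame[, c("hypertension", covariates)]
  frame <- frame[complete.cases(frame), ]
  frame <- droplevels(frame)
  if (!nrow(frame)) stop("no complete-case records available for the model")

  if (stepwise) {
    selected <- character(0)
    pool <- covariates
    while (length(pool)) {
      ps <- vapply(pool, function(v) lrt_add_p(frame, selected, v), 0)
      if (!any(is.finite(ps)) || min(ps, na.rm = TRUE) >= enter_p) break
      best <- pool[which.min(ps)]
      selected <- c(selected, best)
      pool <- setdiff(pool, best)
    }
  } else {
    selected <- covariates
  }
  if (!length(selected)) {
    warning("no covariate met the entry criterion; returning empty table")
    out <- data.frame(variable = character(0), level = character(0),
                      reference = logical(0), or = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      p_value = numeric(0))
    class(out) <- c("or_table", "data.frame")
    return(out)
  }
  fit <- withCallingHandlers(
    glm(as.formula(paste("hypertension ~", paste(selected, collapse = " + "))),
        binomial(), frame),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        warning("possible separation in the final model; profile the fit",
                call. = FALSE)
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged)
    stop("logistic fit did not converge after ", fit$iter, " iterations")
  out <- or_table_from_fit(fit, selected, conf_level)
  attr(out, "fit") <- fit
  attr(out, "selected") <- selected
  out
}

#' Variance inflation factors for the covariate set
#'
#' Classical design-only VIFs (generalized VIFs for factor covariates),
#' computed from a linear model of the numeric outcome on the covariates so
#' that each numeric covariate's VIF equals the auxiliary-regression
#' `1/(1 - R^2)`. Exact linear dependence among covariates is reported as an
#' infinite VIF rather than an error.
#'
#' @param records subject-level data frame (or any data frame holding the
#'   covariates plus `hypertension`).
#' @param covariates covariate names to check (>= 2).
#' @param threshold flag level, conventionally 10.
#' @return data frame with columns `term`, `vif`, `flag` (`TRUE` above the
#'   threshold or for exact dependence).
#' @export
multicollinearity_check <- function(records, covariates, threshold = 10) {
  if (length(covariates) < 2L)
    stop("need at least two covariates to assess collinearity")
  known <- intersect(covariates, names(records))
  if (length(known) == length(covariates)) {
    frame <- records[, c("hypertension", covariates)]
    frame$hypertension <- as.numeric(frame$hypertension)
  } else {
    frame <- logistic_model_frame(records)[, c("hypertension", covariates)]
  }
  frame <- frame[complete.cases(frame), , drop = FALSE]
  fit <- lm(as.formula(paste("hypertension ~",
                             paste(covariates, collapse = " + "))), frame)
  v <- tryCatch(car::vif(fit), error = function(e) e)
  if (inherits(v, "error")) {
    # aliased coefficients: exact linear dependence somewhere in the design
    al <- alias(fit)$Complete
    dep <- if (!is.null(al)) rownames(al) else character(0)
    out <- data.frame(term = covariates, vif = Inf, flag = TRUE,
                      stringsAsFactors = FALSE)
    attr(out, "aliased") <- dep
    warning("exact linear dependence among covariates; VIFs are infinite")
    return(out)
  }
  if (is.matrix(v)) {
    vifs <- v[, "GVIF"]
    terms <- rownames(v)
  } else {
    vifs <- v
    terms <- names(v)
  }
  data.frame(term = terms, vif = as.numeric(vifs),
             flag = as.numeric(vifs) > threshold, stringsAsFactors = FALSE)
}
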