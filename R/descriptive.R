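#' Age bands for the middle-aged and elderly cohort
#'
#' Study inclusion starts at 45 years; bands are middle-aged (45-59), young
#' elderly (60-74) and older (75+). Ages below 45 are not silently dropped:
#' they map to `NA` and their positions are recorded in the `"excluded"`
#' attribute so callers can surface them.
#'
#' @param age integer ages in years.
#' @return factor with levels `"45-59"`, `"60-74"`, `"75+"`; attribute
#'   `excluded` holds indices of under-age records (if any).
#' @export
categorize_age <- function(age) {
  out <- rep(NA_character_, length(age))
  out[!is.na(age) & age >= 45 & age <= 59] <- "45-59"
  out[!is.na(age) & age >= 60 & age <= 74] <- "60-74"
  out[!is.na(age) & age >= 75] <- "75+"
  f <- factor(out, levels = c("45-59", "60-74", "75+"))
  excluded <- which(!is.na(age) & age < 45)
  if (length(excluded)) attr(f, "excluded") <- excluded
  f
}

#' BMI categories (Chinese adult cut points)
#'
#' Cut points 18.5, 24.0 and 28.0 kg/m^2; obesity is defined inclusively as
#' BMI >= 28.0 (the tabulated ">=28.0" convention). Nonpositive or missing
#' values map to `NA`.
#'
#' @param bmi body mass index in kg/m^2.
#' @return factor with levels `"<18.5"`, `"18.5-23.9"`, `"24.0-27.9"`,
#'   `">=28.0"`.
#' @export
categorize_bmi <- function(bmi) {
  out <- rep(NA_character_, length(bmi))
  ok <- !is.na(bmi) & bmi > 0
  out[ok & bmi < 18.5] <- "<18.5"
  out[ok & bmi >= 18.5 & bmi < 24.0] <- "18.5-23.9"
  out[ok & bmi >= 24.0 & bmi < 28.0] <- "24.0-27.9"
  out[ok & bmi >= 28.0] <- ">=28.0"
  factor(out, levels = c("<18.5", "18.5-23.9", "24.0-27.9", ">=28.0"))
}

#' Waist-to-height ratio body shape
#'
#' WHtR > 0.5 is "apple" (abdominal adiposity); WHtR <= 0.5, including exactly
#' 0.5, is "pear". Waist and height must share a length unit.
#'
#' @param waist waist circumference (cm).
#' @param height standing height (cm).
#' @return factor with levels `"pear"`, `"apple"`; `NA` where either input is
#'   missing or nonpositive.
#' @export
categorize_whtr <- function(waist, height) {
  ratio <- ifelse(!is.na(waist) & !is.na(height) & waist > 0 & height > 0,
                  waist / height, NA_real_)
  out <- ifelse(is.na(ratio), NA_character_,
                ifelse(ratio > 0.5, "apple", "pear"))
  factor(out, levels = c("pear", "apple"))
}

# derive a stratum factor for a named stratifier from subject records
stratum_values <- function(records, stratifier) {
  switch(stratifier,
         age = categorize_age(records$age),
         bmi = categorize_bmi(records$bmi),
         whtr = categorize_whtr(records$waist, records$height),
         smoking = factor(as.character(records$smoking),
                          levels = c("never", "current")),
         alcohol = factor(as.character(records$alcohol),
                          levels = c("never", "current")),
         stop("unknown stratifier: '", stratifier, "'"))
}

#' Assemble a prevalence table from stratified counts
#'
#' Validates counts and recomputes percentages (half-up, two decimals) so that
#' every row's percentage is exactly reproducible from its own counts.
#'
#' @param stratum stratum labels.
#' @param gender `"male"`/`"female"` per row.
#' @param cases,n case counts and denominators, `cases <= n`, `n > 0`.
#' @param stratifier optional stratifier name recorded as an attribute.
#' @return data frame of class `prevalence_table` with columns `stratum`,
#'   `gender`, `cases`, `n`, `percent`.
#' @export
prevalence_table <- function(stratum, gender, cases, n,
                             stratifier = NA_character_) {
  stopifnot(length(stratum) == length(gender),
            length(cases) == length(n), length(cases) == length(stratum))
  if (any(n <= 0)) stop("zero or negative denominator in prevalence table")
  if (any(cases > n)) stop("cases exceed denominator in prevalence table")
  if (any(cases < 0)) stop("negative case count")
  out <- data.frame(stratum = as.character(stratum),
                    gender = as.character(gender),
                    cases = as.integer(cases), n = as.integer(n),
                    percent = round_half_up(100 * cases / n, 2),
                    stringsAsFactors = FALSE)
  attr(out, "stratifier") <- stratifier
  class(out) <- c("prevalence_table", "data.frame")
  out
}

#' Stratified prevalence of the outcome by gender
#'
#' One row per (stratum, gender) among records with a non-missing stratum
#' value; missing stratum values reduce the denominator, which is why the
#' per-stratifier denominators of a survey table need not sum to the cohort
#' size. Strata with zero denominator are omitted with a warning.
#'
#' @param records subject-level data frame (see [read_subjects()] for the
#'   schema; needs `gender`, `hypertension` and the stratifier's inputs).
#' @param stratifier one of `"age"`, `"bmi"`, `"whtr"`, `"smoking"`,
#'   `"alcohol"`.
#' @return a [prevalence_table].
#' @export
stratified_prevalence <- function(records, stratifier) {
  stopifnot(is.data.frame(records))
  if (!nrow(records)) stop("no subject records supplied")
  strat <- stratum_values(records, stratifier)
  if (!is.null(attr(strat, "excluded")))
    warning(length(attr(strat, "excluded")),
            " record(s) below the study age of 45 excluded from the age bands")
  gender <- factor(as.character(records$gender), levels = GENDERS)
  hyp <- as.integer(records$hypertension)
  rows <- expand.grid(stratum = levels(strat), gender = GENDERS,
                      stringsAsFactors = FALSE)
  cases <- integer(nrow(rows))
  denom <- integer(nrow(rows))
  for (r in seq_len(nrow(rows))) {
    sel <- !is.na(strat) & strat == rows$stratum[r] &
      !is.na(gender) & gender == rows$gender[r]
    denom[r] <- sum(sel)
    cases[r] <- sum(hyp[sel] == 1L, na.rm = TRUE)
  }
  if (any(denom == 0L)) {
    warning("omitting empty stratum cell(s): ",
            paste(paste(rows$stratum[denom == 0], rows$gender[denom == 0],
                        sep = "/"), collapse = ", "))
    rows <- rows[denom > 0L, ]
    cases <- cases[denom > 0L]
    denom <- denom[denom > 0L]
  }
  prevalence_table(rows$stratum, rows$gender, cases, denom,
                   stratifier = stratifier)
}

#' Headline prevalences from a stratified table
#'
#' Sums the table's counts by gender and overall, then computes prevalence at
#' the printed 1-decimal precision (half-up). For a stratifier that partitions
#' the cohort (e.g. age), these are the cohort's headline figures as far as
#' they are recomputable from the table itself.
#'
#' @param tab a [prevalence_table].
#' @return data frame with rows `male`, `female`, `overall` and columns
#'   `cases`, `n`, `percent`.
#' @export
prevalence_totals <- function(tab) {
  stopifnot(inherits(tab, "prevalence_table"))
  by_g <- lapply(GENDERS, function(g) {
    sel <- tab$gender == g
    c(cases = sum(tab$cases[sel]), n = sum(tab$n[sel]))
  })
  cases <- c(vapply(by_g, `[[`, 0, "cases"), sum(tab$cases))
  n <- c(vapply(by_g, `[[`, 0, "n"), sum(tab$n))
  data.frame(group = c(GENDERS, "overall"), cases = cases, n = n,
             percent = round_half_up(100 * cases / n, 1),
             stringsAsFactors = FALSE)
}

#' Regional covariate aggregates
#'
#' Per (region, gender) proportions of the candidate regional predictors:
#' elderly (aged 60+), obese (BMI >= 28), apple-shaped (WHtR > 0.5), current
#' smoking and current alcohol consumption, each computed among records with
#' the covariate non-missing. A cell with no usable records for a covariate
#' gets `NA` and a missing flag (consumed by [impute_missing()]).
#'
#' @param records subject-level data frame.
#' @param regions region labels to tabulate (default: those present in
#'   `records`); listing extra regions yields all-missing rows for them.
#' @return data frame with columns `region`, `gender`, `n_records`,
#'   `elderly`, `obese`, `whtr`, `smoking`, `alcohol`; attribute `"missing"`
#'   is a data frame of (region, gender, covariate) missing flags.
#' @export
covariate_aggregates <- function(records, regions = NULL) {
  stopifnot(is.data.frame(records))
  if (is.null(regions)) regions <- unique(as.character(records$region))
  vals <- list(
    elderly = ifelse(is.na(records$age), NA, as.numeric(records$age >= 60)),
    obese = ifelse(is.na(records$bmi), NA, as.numeric(records$bmi >= 28)),
    whtr = as.numeric(categorize_whtr(records$waist, records$height)) - 1,
    smoking = ifelse(is.na(records$smoking), NA,
                     as.numeric(records$smoking == "current")),
    alcohol = ifelse(is.na(records$alcohol), NA,
                     as.numeric(records$alcohol == "current")))
  grid <- expand.grid(region = regions, gender = GENDERS,
                      stringsAsFactors = FALSE)
  out <- grid
  out$n_records <- 0L
  for (v in names(vals)) out[[v]] <- NA_real_
  miss <- list()
  for (r in seq_len(nrow(grid))) {
    sel <- as.character(records$region) == grid$region[r] &
      as.character(records$gender) == grid$gender[r]
    out$n_records[r] <- sum(sel)
    for (v in names(vals)) {
      x <- vals[[v]][sel]
      x <- x[!is.na(x)]
      if (length(x)) {
        out[[v]][r] <- mean(x)
      } else {
        miss[[length(miss) + 1L]] <- data.frame(region = grid$region[r],
                                                gender = grid$gender[r],
                                                covariate = v,
                                                stringsAsFactors = FALSE)
      }
    }
  }
  attr(out, "missing") <- if (length(miss)) do.call(rbind, miss) else
    data.frame(region = character(0), gender = character(0),
               covariate = character(0))
  out
}

#' Regional case counts from subject records
#'
#' @param records subject-level data frame.
#' @param regions region labels (default: those present).
#' @return data frame with columns `region`, `gender`, `cases`, `n`.
#' @export
regional_counts <- function(records, regions = NULL) {
  stopifnot(is.data.frame(records))
  if (is.null(regions)) regions <- unique(as.character(records$region))
  grid <- expand.grid(region = regions, gender = GENDERS,
                      stringsAsFactors = FALSE)
  grid$cases <- 0L
  grid$n <- 0L
  for (r in seq_len(nrow(grid))) {
    sel <- as.character(records$region) == grid$region[r] &
      as.character(records$gender) == grid$gender[r]
    grid$n[r] <- sum(sel)
    grid$cases[r] <- sum(as.integer(records$hypertension[sel]) == 1L,
                         na.rm = TRUE)
  }
  grid
}

SUBJECT_COLUMNS <- c("region", "gender", "age", "bmi", "waist", "height",
                     "smoking", "alcohol", "sleep_night", "nap",
                     "hypertension")

#' Read subject-level records from delimited text
#'
#' Tab-delimited, one row per subject, header with the standard field names
#' (`region`, `gender`, `age`, `bmi`, `waist`, `height`, `smoking`,
#' `alcohol`, `sleep_night`, `nap`, `hypertension`); empty fields are
#' missing values. Malformed gender or outcome values are reported with their
#' line numbers.
#'
#' @param path input file path.
#' @return validated data frame of subject records.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop("subject file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!nrow(df)) stop("subject file is empty: ", path)
  missing_cols <- setdiff(c("region", "gender", "hypertension"), names(df))
  if (length(missing_cols))
    stop("subject file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in setdiff(SUBJECT_COLUMNS, names(df))) df[[col]] <- NA
  badg <- which(!df$gender %in% GENDERS)
  if (length(badg))
    stop("invalid gender value at data line(s): ",
         paste(utils::head(badg, 10), collapse = ", "))
  badh <- which(!df$hypertension %in% c(0L, 1L))
  if (length(badh))
    stop("invalid hypertension value at data line(s): ",
         paste(utils::head(badh, 10), collapse = ", "))
  df[SUBJECT_COLUMNS]
}

#' Write subject-level records as delimited text
#'
#' @param records subject data frame.
#' @param path output file path.
#' @export
write_subjects <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Bundled stratified hypertension counts for the Zhejiang cohort
#'
#' Published stratified case counts and denominators (age bands, smoking,
#' alcohol, BMI and WHtR categories, by gender) for the 2012 CHARLS Zhejiang
#' subsample of middle-aged and elderly residents that motivates this
#' package's model. These printed counts are the desk-scale input for the
#' descriptive reproduction checks.
#'
#' @return data frame with columns `stratifier`, `stratum`, `gender`,
#'   `cases`, `n`.
#' @export
zhejiang_strata_counts <- function() {
  read.csv(system.file("extdata", "zhejiang_strata_counts.csv",
                       package = "spscm"),
           stringsAsFactors = FALSE)
}
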