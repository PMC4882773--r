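# Pipeline orchestration: file-in/file-out stages mirroring how the analysis
# is run end to end, each stamped with a run manifest. Outputs are plain
# delimited text so every table diffs cleanly.

#' Read regional count data from delimited text
#'
#' Tab-delimited with columns `region`, `gender`, `cases`, `n`, plus one
#' column per regional covariate (proportions in \[0, 1\]; empty fields are
#' missing). Every (region of the map) x (gender) combination must appear
#' exactly once.
#'
#' @param path input file.
#' @param map a [region_map]; region order follows the map.
#' @param covariates covariate column names (default: every column beyond
#'   the four required ones).
#' @param substituted region labels flagged for count substitution.
#' @return an [scm_data].
#' @export
read_regional <- function(path, map, covariates = NULL,
                          substituted = character(0)) {
  if (!file.exists(path)) stop("regional data file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  req <- c("region", "gender", "cases", "n")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("regional file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  covariates <- covariates %||% setdiff(names(df), req)
  R <- length(map$regions)
  O <- n <- matrix(NA_real_, 2, R)
  x <- array(NA_real_, dim = c(2, R, length(covariates)))
  for (j in 1:2) for (i in seq_len(R)) {
    sel <- df$region == map$regions[i] & df$gender == GENDERS[j]
    if (sum(sel) != 1L)
      stop("expected exactly one row for region '", map$regions[i],
           "', gender '", GENDERS[j], "'; found ", sum(sel))
    O[j, i] <- df$cases[sel]
    n[j, i] <- df$n[sel]
    for (k in seq_along(covariates)) x[j, i, k] <- df[[covariates[k]]][sel]
  }
  scm_data(map, O, n, x, covariates = covariates, substituted = substituted)
}

#' Write regional count data as delimited text
#'
#' @param data an [scm_data].
#' @param path output file.
#' @export
write_regional <- function(data, path) {
  stopifnot(inherits(data, "scm_data"))
  R <- length(data$map$regions)
  df <- data.frame(region = rep(data$map$regions, 2),
                   gender = rep(GENDERS, each = R),
                   cases = c(data$O[1, ], data$O[2, ]),
                   n = c(data$n[1, ], data$n[2, ]),
                   stringsAsFactors = FALSE)
  for (k in seq_along(data$covariates))
    df[[data$covariates[k]]] <- c(data$x[1, , k], data$x[2, , k])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

# run manifest: config snapshot, input digests, seed, version, timings.
# timings go last so the data tables above them stay digest-stable.
write_manifest <- function(dir, stage, config, inputs = character(0),
                           seed = NA, timings = NULL, warnings = character(0)) {
  path <- file.path(dir, paste0(stage, "_manifest.txt"))
  lines <- c(paste0("stage\t", stage),
             paste0("package_version\t", as.character(packageVersion("spscm"))),
             paste0("seed\t", seed))
  for (nm in names(config))
    lines <- c(lines, paste0("config.", nm, "\t",
                             paste(format(config[[nm]]), collapse = ",")))
  for (f in inputs)
    if (file.exists(f))
      lines <- c(lines, paste0("input.", basename(f), ".md5\t",
                               unname(md5sum(f))))
  for (w in warnings) lines <- c(lines, paste0("warning\t", w))
  for (nm in names(timings))
    lines <- c(lines, paste0("elapsed_s.", nm, "\t",
                             round(timings[[nm]], 2)))
  writeLines(lines, path)
  invisible(path)
}

#' Descriptive stage: stratified prevalence tables
#'
#' Runs the full descriptive arm on a subject-level file: one stratified
#' prevalence table per stratifier, exported both in long machine-readable
#' form and as a wide survey-style table, plus the headline totals computed
#' from the age strata.
#'
#' @param input subject-level file (see [read_subjects()]).
#' @param output_dir directory for outputs (created if needed).
#' @return invisibly, the long-format table.
#' @export
run_describe <- function(input, output_dir) {
  t0 <- proc.time()["elapsed"]
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_subjects(input)
  stratifiers <- c("age", "smoking", "alcohol", "bmi", "whtr")
  warns <- character(0)
  long <- list()
  for (s in stratifiers) {
    tab <- withCallingHandlers(stratified_prevalence(records, s),
                               warning = function(w) {
                                 warns <<- c(warns, conditionMessage(w))
                                 invokeRestart("muffleWarning")
                               })
    tab$stratifier <- s
    long[[s]] <- tab
  }
  long_df <- do.call(rbind, lapply(long, as.data.frame))
  long_df <- long_df[, c("stratifier", "stratum", "gender", "cases", "n",
                         "percent")]
  write.table(long_df, file.path(output_dir, "prevalence_long.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  wide <- do.call(rbind, lapply(names(long), function(s) {
    tab <- long[[s]]
    strata <- unique(tab$stratum)
    cell <- function(g, st) {
      r <- tab[tab$gender == g & tab$stratum == st, ]
      if (!nrow(r)) return("")
      sprintf("%.2f (%d/%d)", r$percent, r$cases, r$n)
    }
    data.frame(stratifier = s, stratum = strata,
               male = vapply(strata, cell, "", g = "male"),
               female = vapply(strata, cell, "", g = "female"),
               stringsAsFactors = FALSE)
  }))
  write.table(wide, file.path(output_dir, "prevalence_wide.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  totals <- prevalence_totals(long[["age"]])
  write.table(totals, file.path(output_dir, "prevalence_totals.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(output_dir, "describe", list(stratifiers = stratifiers),
                 inputs = input, warnings = warns,
                 timings = list(describe = proc.time()["elapsed"] - t0))
  invisible(long_df)
}

#' Logistic stage: screened, stepwise OR tables per gender
#'
#' Univariate screening at p < 0.06 over the candidate risk factors, then a
#' forward-stepwise multivariable logistic model per gender over the union of
#' the screened set and the forced lifestyle candidates. Tables carry a
#' significance star at p < 0.05.
#'
#' @param input subject-level file.
#' @param output_dir output directory.
#' @param candidates screening candidates.
#' @param forced lifestyle covariates always offered to the stepwise stage.
#' @param screen_threshold univariate selection threshold.
#' @return invisibly, a list of per-gender OR tables.
#' @export
run_logistic <- function(input, output_dir,
                         candidates = c("age", "bmi", "whtr", "smoking",
                                        "alcohol", "sleep_night"),
                         forced = c("age", "bmi", "whtr", "smoking",
                                    "alcohol", "sleep_night"),
                         screen_threshold = 0.06) {
  t0 <- proc.time()["elapsed"]
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_subjects(input)
  out <- list()
  for (g in GENDERS) {
    scr <- suppressWarnings(
      univariate_screen(records, candidates, screen_threshold, gender = g))
    write.table(scr, file.path(output_dir, paste0("screen_", g, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    offer <- union(scr$candidate[scr$selected], forced)
    tab <- suppressWarnings(fit_multivariable(records, offer, gender = g))
    tab2 <- as.data.frame(tab)
    tab2$sig <- ifelse(!is.na(tab2$p_value) & tab2$p_value < 0.05, "*", "")
    write.table(tab2, file.path(output_dir, paste0("or_", g, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out[[g]] <- tab
  }
  write_manifest(output_dir, "logistic",
                 list(candidates = candidates,
                      screen_threshold = screen_threshold),
                 inputs = input,
                 timings = list(logistic = proc.time()["elapsed"] - t0))
  invisible(out)
}

#' SCM stage: fit, posterior summary, and region-value exports
#'
#' Fits the shared component model to a regional file and exports: the
#' posterior summary table (covariate RRs per gender, shared-variance
#' fractions, delta, component SDs, DIC/pD); and a per-region table of the
#' raw SPR, the model-smoothed RR (posterior-mean fitted counts over
#' internally standardized expected counts) per gender, and the posterior
#' mean of the spatial gender contrast — the tabular equivalents of the
#' disease maps.
#'
#' @param input regional data file ([read_regional()] schema).
#' @param adjacency adjacency edge-list file.
#' @param output_dir output directory.
#' @param priors an [scm_priors].
#' @param control an [mcmc_control].
#' @param model an [scm_control].
#' @param substituted regions whose counts are substituted before fitting.
#' @return invisibly, the fitted `scm_samples`.
#' @export
run_scm <- function(input, adjacency, output_dir, priors = scm_priors(),
                    control = mcmc_control(), model = scm_control(),
                    substituted = character(0)) {
  t0 <- proc.time()["elapsed"]
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  map <- read_adjacency(adjacency)
  data <- read_regional(input, map, substituted = substituted)
  data <- impute_missing(data)
  fit <- run_mcmc(data, priors, control, model)

  pooled <- pooled_draws(fit)
  summ <- summary(fit)
  rr_rows <- do.call(rbind, lapply(GENDERS, function(g)
    do.call(rbind, lapply(data$covariates, function(cv) {
      s <- covariate_rr(fit, cv, g)
      data.frame(parameter = paste0("rr_", g, "_", cv), mean = s["mean"],
                 sd = NA, q2.5 = s["lower"], q50 = NA, q97.5 = s["upper"],
                 rhat = NA, row.names = NULL)
    }))))
  keep <- c("eta_male", "eta_female", "delta", "delta_sq", "sigma_str",
            "sigma_unstr", "sigma_ind_male", "sigma_ind_female",
            "sigma_spat_male", "sigma_spat_female", "log_delta",
            "alpha_male", "alpha_female")
  core <- summ[summ$parameter %in% keep, ]
  names(rr_rows) <- names(core)
  ic <- dic(fit)
  ic_rows <- data.frame(parameter = c("DIC", "pD"),
                        mean = c(ic$DIC, ic$pD), sd = NA, q2.5 = NA,
                        q50 = NA, q97.5 = NA, rhat = NA)
  names(ic_rows) <- names(core)
  out_tab <- rbind(rr_rows, core, ic_rows)
  write.table(out_tab, file.path(output_dir, "posterior_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # region-value exports (map surrogate)
  sc <- expected_counts(data)
  spr_m <- spr(sc)
  pbar <- matrix(colMeans(do.call(rbind, fit$p)), nrow = 2, byrow = TRUE)
  fitted_counts <- pbar * data$n
  rr_sm <- fitted_counts / sc$expected
  gc_mean <- colMeans(pooled[, paste0("gamma_", map$regions), drop = FALSE])
  region_tab <- data.frame(region = map$regions,
                           spr_male = spr_m[1, ], spr_female = spr_m[2, ],
                           rr_smoothed_male = rr_sm[1, ],
                           rr_smoothed_female = rr_sm[2, ],
                           gamma_contrast_mean = gc_mean, row.names = NULL)
  write.table(region_tab, file.path(output_dir, "region_values.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # thinned focus-parameter draws for chain/density plots elsewhere
  focus <- c("log_delta", "eta_male", "eta_female",
             if (length(data$covariates))
               paste0("b_male_", data$covariates[1]))
  dr <- pooled[, focus, drop = FALSE]
  draw_tab <- data.frame(draw = seq_len(nrow(dr)), dr, check.names = FALSE)
  write.table(draw_tab, file.path(output_dir, "focus_draws.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  write_manifest(output_dir, "scm",
                 list(burn_in = control$burn_in,
                      iterations = control$iterations, thin = control$thin,
                      n_chains = control$n_chains,
                      precision_shape = priors$precision_shape,
                      precision_rate = priors$precision_rate,
                      covariate_scale = model$covariate_scale,
                      substituted = substituted),
                 inputs = c(input, adjacency), seed = control$seed,
                 timings = list(scm = proc.time()["elapsed"] - t0))
  invisible(fit)
}

#' Sensitivity stage: prior comparison table and density exports
#'
#' Runs [sensitivity_run()] over a regional file and writes the side-by-side
#' comparison table plus one kernel-density trace per setting for the focus
#' parameter.
#'
#' @inheritParams run_scm
#' @param priors_list named list of prior settings; the default carries the
#'   three conventional precision priors Gamma(1, 1e-4), Gamma(1000, 5e-7)
#'   and Gamma(5, 5e-5).
#' @param exclusions regions each triggering a rerun without that region.
#' @return invisibly, the comparison data frame.
#' @export
run_sensitivity <- function(input, adjacency, output_dir,
                            priors_list = list(
                              priors1 = scm_priors(1, 1e-4),
                              priors2 = scm_priors(1000, 5e-7),
                              priors3 = scm_priors(5, 5e-5)),
                            exclusions = character(0),
                            control = mcmc_control(), model = scm_control(),
                            substituted = character(0)) {
  t0 <- proc.time()["elapsed"]
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  map <- read_adjacency(adjacency)
  data <- read_regional(input, map, substituted = substituted)
  data <- impute_missing(data)
  comp <- sensitivity_run(data, priors_list, control, model, exclusions)
  write.table(as.data.frame(comp),
              file.path(output_dir, "sensitivity_comparison.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  dens <- attr(comp, "densities")
  for (nm in names(dens))
    write.table(data.frame(x = dens[[nm]]$x, y = dens[[nm]]$y),
                file.path(output_dir, paste0("density_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(output_dir, "sensitivity",
                 list(priors = names(priors_list),
                      exclusions = exclusions),
                 inputs = c(input, adjacency), seed = control$seed,
                 timings = list(sensitivity = proc.time()["elapsed"] - t0))
  invisible(comp)
}

#' Simulation stage: synthetic dataset bundle
#'
#' Generates a regional dataset and matching individual-level records from a
#' generating truth and writes the full bundle: regional file, subject file,
#' adjacency edge list, truth record (key-value text) and manifest. Every
#' file parses back through the corresponding pipeline stage.
#'
#' @param output_dir output directory.
#' @param map a [region_map] (default: the bundled 11-prefecture map).
#' @param truth generating [scm_params].
#' @param n_per_cell cell denominators (see [generate_regional()]).
#' @param seed integer seed.
#' @param model an [scm_control].
#' @return invisibly, the generated list (`data`, `truth`).
#' @export
run_simulate <- function(output_dir, map = zhejiang_map(),
                         truth = default_truth(map, model),
                         n_per_cell = c(male = 55, female = 60), seed = 1,
                         model = scm_control()) {
  t0 <- proc.time()["elapsed"]
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_regional(map, truth, n_per_cell, seed, model = model)
  write_regional(gen$data, file.path(output_dir, "regional.tsv"))
  subjects <- generate_individual(gen$data, seed = seed + 1)
  write_subjects(subjects, file.path(output_dir, "subjects.tsv"))
  adj <- file.path(output_dir, "adjacency.adj")
  writeLines(c("# synthetic bundle adjacency",
               paste(map$regions[map$edges[, 1]],
                     map$regions[map$edges[, 2]])), adj)
  tr <- gen$truth$params
  kv <- c(paste0("alpha_male=", tr$alpha[1]),
          paste0("alpha_female=", tr$alpha[2]),
          paste0("log_delta=", tr$log_delta),
          paste0("b_male_", tr$covariates, "=", tr$b[1, ]),
          paste0("b_female_", tr$covariates, "=", tr$b[2, ]),
          paste0(TAU_NAMES, "=", tr$tau),
          paste0("ush_", map$regions, "=", tr$ush),
          paste0("ssh_", map$regions, "=", tr$ssh),
          paste0("bind_male_", map$regions, "=", tr$bind[1, ]),
          paste0("bind_female_", map$regions, "=", tr$bind[2, ]),
          paste0("bspat_male_", map$regions, "=", tr$bspat[1, ]),
          paste0("bspat_female_", map$regions, "=", tr$bspat[2, ]),
          paste0("gamma_", map$regions, "=", tr$gamma_contrast),
          paste0("seed=", seed))
  writeLines(kv, file.path(output_dir, "truth.txt"))
  write_manifest(output_dir, "simulate",
                 list(n_per_cell = n_per_cell,
                      covariate_scale = model$covariate_scale),
                 seed = seed,
                 timings = list(simulate = proc.time()["elapsed"] - t0))
  invisible(gen)
}
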