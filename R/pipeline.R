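#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis: either a simulation
#' design or input paths, spectral parameters, map grid and smoothing,
#' permutation and bootstrap sizes, classifier settings, output directory
#' and the master seed. Every stochastic stage derives its own seed from
#' `seed`, so a configuration reproduces its outputs exactly.
#'
#' @param out_dir Output directory (created if missing).
#' @param design A [cohort_design()] for simulated input, or `NULL` when
#'   reading recorded data.
#' @param eeg_dir Directory of per-subject EEG files (`<subject_id>.edf` or
#'   `<subject_id>.tsv`); ignored when simulating.
#' @param covariates_file Covariate table path; ignored when simulating.
#' @param fs Expected sampling rate (Hz).
#' @param pad_factor Spectral zero-padding factor.
#' @param grid_n Scalp-map grid nodes per side.
#' @param sigma Map smoothing kernel SD (mm).
#' @param n_perm Permutations for the map inference.
#' @param n_boot Bootstrap resamples for effect-size CIs.
#' @param cv_folds,cv_repeats Cross-validation folds and repeats.
#' @param write_eeg Write simulated segments to disk as EDF (default FALSE).
#' @param seed Master seed.
#' @return An object of class `alphashift_config`.
#' @export
pipeline_config <- function(out_dir, design = NULL, eeg_dir = NULL,
                            covariates_file = NULL, fs = 256,
                            pad_factor = 2, grid_n = 32, sigma = 8,
                            n_perm = 10000, n_boot = 5000, cv_folds = 10,
                            cv_repeats = 100, write_eeg = FALSE, seed = 1) {
  if (is.null(design) && (is.null(eeg_dir) || is.null(covariates_file))) {
    stop("either a simulation design or eeg_dir + covariates_file is required")
  }
  structure(list(out_dir = out_dir, design = design, eeg_dir = eeg_dir,
                 covariates_file = covariates_file, fs = fs,
                 pad_factor = pad_factor, grid_n = grid_n, sigma = sigma,
                 n_perm = n_perm, n_boot = n_boot, cv_folds = cv_folds,
                 cv_repeats = cv_repeats, write_eeg = write_eeg, seed = seed),
            class = "alphashift_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override [pipeline_config()] defaults; a `design` block
#' (fields `n_per_group`, `peak_freq`, `bandwidth`, `amplitude`,
#' `anterior_spread` keyed by group, plus noise settings) builds a
#' [cohort_design()].
#'
#' @param path YAML file path.
#' @return An `alphashift_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  design <- NULL
  if (!is.null(raw$design)) {
    d <- raw$design
    npg <- unlist(d$n_per_group)
    oscs <- lapply(names(npg), function(g) {
      o <- d$groups[[g]] %||% list()
      oscillator_spec(o$peak_freq %||% 10.5, o$bandwidth %||% 2,
                      o$amplitude %||% 20, o$anterior_spread %||% 0.2)
    })
    names(oscs) <- names(npg)
    design <- cohort_design(
      n_per_group = npg, group_oscillators = oscs,
      noise = noise_spec(d$one_over_f_exponent %||% 1, d$white_sd %||% 10),
      seed = raw$seed %||% 1)
  }
  args <- raw[setdiff(names(raw), "design")]
  args$design <- design
  do.call(pipeline_config, args)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

# load or simulate the cohort according to the configuration
.acquire_cohort <- function(config) {
  if (!is.null(config$design)) {
    cohort <- generate_cohort(config$design)
    if (isTRUE(config$write_eeg)) {
      eeg_dir <- file.path(config$out_dir, "eeg")
      dir.create(eeg_dir, showWarnings = FALSE, recursive = TRUE)
      for (id in names(cohort$segments)) {
        write_eeg_edf(cohort$segments[[id]], file.path(eeg_dir,
                                                       paste0(id, ".edf")))
      }
    }
    return(cohort)
  }
  table <- read_covariates(config$covariates_file)
  files <- list.files(config$eeg_dir, pattern = "\\.(edf|tsv|txt)$",
                      ignore.case = TRUE, full.names = TRUE)
  ids <- sub("\\.[^.]+$", "", basename(files))
  missing_eeg <- setdiff(table$subject_id, ids)
  if (length(missing_eeg)) {
    stop(sprintf("no EEG file for subject(s): %s",
                 paste(missing_eeg, collapse = ", ")))
  }
  extra_eeg <- setdiff(ids, table$subject_id)
  if (length(extra_eeg)) {
    stop(sprintf("EEG present but no covariates for subject(s): %s",
                 paste(extra_eeg, collapse = ", ")))
  }
  segments <- lapply(table$subject_id, function(id) {
    read_eeg(files[match(id, ids)], fs = config$fs)
  })
  names(segments) <- table$subject_id
  list(table = table, segments = segments)
}

# design matrix + contrast for one pairwise map comparison
.map_contrast_design <- function(table, grp, a, b, with_aed) {
  sel <- grp %in% c(a, b)
  ind <- as.numeric(grp[sel] == a)                 # contrast: a minus b
  X <- cbind(intercept = 1, effect = ind,
             age = table$age[sel],
             gender = as.numeric(factor(table$gender[sel])) - 1)
  if (with_aed) X <- cbind(X, aed = table$aed_load[sel])
  list(sel = sel, X = X, contrast = c(0, 1, rep(0, ncol(X) - 2)),
       vg = droplevels(factor(grp[sel])))
}

#' Run the full alpha-power-shift pipeline
#'
#' Executes simulate-or-load, spectral estimation and alpha shifts, cohort
#' summary statistics, one-way and (when possible) factorial ANCOVA with
#' assumption checks and planned contrasts, scalp-map permutation inference
#' with effect-size maps for the standard pairwise comparisons
#' (patients vs healthy, poor vs good seizure control, focal vs generalized
#' syndrome), and cross-validated LDA classification of seizure control.
#' All outputs are written as delimited text under `config$out_dir` and a
#' JSON manifest records the configuration hash and file list.
#'
#' @param config An `alphashift_config`.
#' @return The manifest, invisibly (a list with `config_hash`, `outputs`,
#'   and the key results).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "alphashift_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  add <- function(p) outputs <<- c(outputs, p)

  cohort <- .acquire_cohort(config)
  table <- cohort$table
  add(.write_tsv(as.data.frame(table), file.path(config$out_dir,
                                                 "covariates.tsv")))

  sh <- cohort_alpha_shifts(cohort$segments, pad_factor = config$pad_factor)
  shifts <- data.frame(subject_id = table$subject_id,
                       global_shift = unname(sh$global[table$subject_id]))
  shifts <- cbind(shifts, sh$per_channel[table$subject_id, , drop = FALSE])
  add(.write_tsv(shifts, file.path(config$out_dir, "shifts.tsv")))

  add(.write_tsv(cohort_table_stats(table),
                 file.path(config$out_dir, "cohort_stats.tsv")))

  grp <- analysis_groups(table)
  y <- shifts$global_shift
  results <- list()

  aov1 <- ancova_oneway(y, grp, table$age, table$gender)
  add(.write_tsv(as.data.frame(aov1), file.path(config$out_dir,
                                                "ancova_oneway.tsv")))
  results$ancova_oneway <- aov1

  lev <- levene_test(y, grp)
  slope_age <- slope_homogeneity(y, grp, table$age)
  slope_gender <- slope_homogeneity(y, grp,
                                    as.numeric(factor(table$gender)) - 1)
  norm <- normality_check(attr(aov1, "fit")$residuals)
  assumptions <- data.frame(
    check = c("levene_equal_variance", "slopes_age", "slopes_gender",
              "shapiro_residuals"),
    statistic = c(lev$W, slope_age$F, slope_gender$F, norm$W),
    p = c(lev$p, slope_age$p, slope_gender$p, norm$p))
  add(.write_tsv(assumptions, file.path(config$out_dir, "assumptions.tsv")))
  results$assumptions <- assumptions

  pat_vs_hs <- factor(ifelse(grp == "HS", "HS", "PAT"), c("PAT", "HS"))
  ph <- pooled_t(y[pat_vs_hs == "PAT"], y[pat_vs_hs == "HS"],
                 n_boot = config$n_boot, seed = child_seed(config$seed, 21))
  contr_rows <- data.frame(contrast = "PAT - HS", t = ph$t, df = ph$df,
                           p = ph$p, g = ph$g, g_lo = ph$g_ci[1],
                           g_hi = ph$g_ci[2])
  if (all(c("GSC", "PSC") %in% grp)) {
    pg <- pooled_t(y[grp == "PSC"], y[grp == "GSC"], n_boot = config$n_boot,
                   seed = child_seed(config$seed, 22))
    contr_rows <- rbind(contr_rows,
                        data.frame(contrast = "PSC - GSC", t = pg$t,
                                   df = pg$df, p = pg$p, g = pg$g,
                                   g_lo = pg$g_ci[1], g_hi = pg$g_ci[2]))
  }
  contr_rows$p_bonferroni <- pmin(1, contr_rows$p * nrow(contr_rows))
  add(.write_tsv(contr_rows, file.path(config$out_dir, "contrasts.tsv")))
  results$contrasts <- contr_rows

  pat <- table$group != "HS"
  if (length(unique(table$syndrome[pat])) == 2 &&
      all(c("GSC", "PSC") %in% table$seizure_control[pat])) {
    aov2 <- try(ancova_factorial(y[pat], table$syndrome[pat],
                                 table$seizure_control[pat], table$age[pat],
                                 table$gender[pat], table$aed_load[pat]),
                silent = TRUE)
    if (!inherits(aov2, "try-error")) {
      add(.write_tsv(as.data.frame(aov2),
                     file.path(config$out_dir, "ancova_factorial.tsv")))
      results$ancova_factorial <- aov2
    }
  }

  # --- scalp-map permutation inference ---------------------------------
  mapper <- scalp_mapper(montage_1020(), grid_n = config$grid_n,
                         sigma = config$sigma)
  Y <- cohort_scalp_maps(sh$per_channel[table$subject_id, , drop = FALSE],
                         mapper)
  comparisons <- list(
    list(name = "PAT_gt_HS", a = "PAT", b = "HS", aed = FALSE,
         grp = as.character(pat_vs_hs)),
    list(name = "PSC_gt_GSC", a = "PSC", b = "GSC", aed = TRUE,
         grp = as.character(grp)),
    list(name = "FE_gt_IGE", a = "FE", b = "IGE", aed = TRUE,
         grp = table$syndrome))
  table2 <- NULL
  for (ci in seq_along(comparisons)) {
    cmp <- comparisons[[ci]]
    if (sum(cmp$grp == cmp$a) < 2 || sum(cmp$grp == cmp$b) < 2) next
    md <- .map_contrast_design(table, cmp$grp, cmp$a, cmp$b, cmp$aed)
    pr <- freedman_lane(Y[md$sel, , drop = FALSE], md$X, md$contrast,
                        n_perm = config$n_perm,
                        seed = child_seed(config$seed, 30 + ci),
                        variance_groups = md$vg, mapper = mapper)
    es <- effect_size_map(Y[md$sel, , drop = FALSE],
                          factor(cmp$grp[md$sel], c(cmp$a, cmp$b)),
                          n_boot = config$n_boot,
                          seed = child_seed(config$seed, 40 + ci))
    for (wh in c("t", "p_uncorrected", "p_fwe")) {
      mp <- perm_result_map(pr, wh)
      add(.write_tsv(as.data.frame(mp$grid),
                     file.path(config$out_dir,
                               sprintf("map_%s_%s.tsv", cmp$name, wh))))
    }
    pk <- pr$peak$node
    table2 <- rbind(table2, data.frame(
      contrast = cmp$name, peak_t = pr$peak$statistic,
      df = pr$peak$df, p_fwe = pr$peak$p_fwe,
      g = es$g[pk], g_lo = es$ci_lo[pk], g_hi = es$ci_hi[pk],
      nearest_electrode = pr$peak$nearest_electrode,
      n_sig_nodes = sum(pr$p_fwe < 0.05)))
    results[[paste0("perm_", cmp$name)]] <- pr
  }
  if (!is.null(table2)) {
    add(.write_tsv(table2, file.path(config$out_dir, "map_peaks.tsv")))
    results$map_peaks <- table2
  }

  # --- classification of seizure control -------------------------------
  if (all(c("GSC", "PSC") %in% grp) &&
      min(table(grp)[c("GSC", "PSC")]) >= config$cv_folds) {
    selp <- grp %in% c("GSC", "PSC")
    feat <- sh$per_channel[table$subject_id, , drop = FALSE][selp, ,
                                                             drop = FALSE]
    lab <- factor(as.character(grp[selp]), c("GSC", "PSC"))
    rep_ <- cross_validate(feat, lab, n_folds = config$cv_folds,
                           n_repeats = config$cv_repeats,
                           seed = child_seed(config$seed, 50))
    zt <- auc_z_test(rep_$oof_scores, lab)
    cls <- rep_$summary
    cls$z_auc <- c(NA, NA, zt$z)
    cls$p_auc <- c(NA, NA, zt$p)
    add(.write_tsv(cls, file.path(config$out_dir, "classification.tsv")))
    results$classification <- rep_
    results$auc_test <- zt
  }

  # --- manifest ---------------------------------------------------------
  cfg_file <- file.path(config$out_dir, "config.yaml")
  cfg_list <- unclass(config)
  cfg_list$out_dir <- NULL      # hash covers the analysis, not its location
  cfg_list$design <- if (is.null(config$design)) NULL else {
    list(n_per_group = as.list(config$design$n_per_group),
         seed = config$design$seed,
         groups = lapply(config$design$group_oscillators, unclass))
  }
  yaml::write_yaml(cfg_list, cfg_file)
  manifest <- list(package = "alphashift",
                   version = tryCatch(
                     as.character(utils::packageVersion("alphashift")),
                     error = function(e) "0.0.0"),
                   config_hash = unname(tools::md5sum(cfg_file)),
                   seed = config$seed,
                   outputs = basename(c(outputs, cfg_file)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$results <- results
  invisible(manifest)
}
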