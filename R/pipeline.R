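# One-call orchestration: generate -> extract -> split -> select -> train
# -> evaluate, with a single master seed fanned out to per-stage seeds and
# every intermediate artifact written to the run directory.

#' Pipeline run configuration
#'
#' @param cohort A [cohort_config()] describing the synthetic cohort (or
#'   `NULL` when `manifest` points at an existing cohort on disk).
#' @param manifest Optional path to a cohort manifest; overrides `cohort`.
#' @param window_side Optional odd integer overriding the spacing-derived
#'   patch side.
#' @param alpha Family-wise error rate for the couple selection.
#' @param rho_max Pairwise correlation threshold.
#' @param train_sizes Training patients per class, `c(ncs, cs)`.
#' @param n_reps,n_folds Repeated-CV structure for the SVM tuning.
#' @param C_grid,gamma_grid Hyperparameter grids.
#' @param n_boot Bootstrap resamples for AUC CIs.
#' @param seed Master seed; per-stage seeds are drawn from it.
#' @param out_dir Run directory for artifacts.
#' @return List of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), manifest = NULL,
                       window_side = NULL, alpha = 0.05, rho_max = 0.15,
                       train_sizes = c(ncs = 18, cs = 30),
                       n_reps = 100, n_folds = 3,
                       C_grid = default_C_grid(),
                       gamma_grid = default_gamma_grid(),
                       n_boot = 2000, seed = 1,
                       out_dir = tempfile("locrad_run_")) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)", "config_error")
  if (rho_max <= 0 || rho_max > 1) abort("rho_max must lie in (0, 1]", "config_error")
  if (!is_count(n_reps) || !is_count(n_folds) || !is_count(n_boot))
    abort("n_reps, n_folds, n_boot must be positive integers", "config_error")
  if (length(train_sizes) != 2L || any(train_sizes < 1))
    abort("train_sizes must be a positive pair", "config_error")
  structure(list(cohort = cohort, manifest = manifest,
                 window_side = window_side, alpha = alpha, rho_max = rho_max,
                 train_sizes = train_sizes, n_reps = n_reps, n_folds = n_folds,
                 C_grid = C_grid, gamma_grid = gamma_grid, n_boot = n_boot,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# One master seed reproduces everything: stage seeds are consecutive draws
# from a generator seeded with the master seed.
stage_seeds <- function(master) {
  set.seed(master)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 4L),
                  c("cohort", "lasso", "folds", "bootstrap"))
}

#' Run the full radiomic pipeline
#'
#' Executes every stage in order and writes the intermediate artifacts
#' (cohort manifest, feature table, selection, model, train/test reports
#' and a provenance log) into `config$out_dir`. A cohort with no
#' Holm-significant feature couple is an expected null outcome: the run
#' stops after selection with `status = "no_significant_couple"` instead
#' of failing.
#'
#' @param config A [run_config()].
#' @return List with `status` (`"ok"` or `"no_significant_couple"`),
#'   the fitted `model`, `selection`, `split`, train/test reports and
#'   artifact `paths`.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stage_seeds(config$seed)
  paths <- list()

  if (!is.null(config$manifest)) {
    manifest <- read_cohort_manifest(config$manifest)
    paths$manifest <- config$manifest
  } else {
    cohort_cfg <- config$cohort
    cohort_cfg$seed <- seeds[["cohort"]]
    patients <- generate_cohort(cohort_cfg)
    paths$manifest <- write_cohort(patients, file.path(config$out_dir, "cohort"))
    manifest <- read_cohort_manifest(paths$manifest)
  }

  table <- extract_cohort_features(manifest, window_side = config$window_side)
  X <- feature_matrix(table)
  y <- table$label

  # Support-vector-candidate split on an all-rows standardization (the
  # split precedes any training set, so there is nothing to leak from).
  norm_all <- normalize_standardize(X)
  plan <- build_training_set(norm_all$X, y, config$train_sizes)
  table$partition <- ifelse(table$patient_id %in% plan$train_ids, "train", "test")
  paths$features <- file.path(config$out_dir, "features.csv")
  write_feature_table(table, paths$features)

  tr <- match(plan$train_ids, rownames(X))
  te <- match(plan$test_ids, rownames(X))
  norm <- normalize_standardize(X, train_idx = tr)
  Xn <- norm$X

  lasso <- lasso_rank(Xn[tr, , drop = FALSE], y[tr], seed = seeds[["lasso"]])
  selection <- tryCatch(
    select_couple(Xn[tr, , drop = FALSE], y[tr], lasso,
                  rho_max = config$rho_max, alpha = config$alpha),
    locrad_selection_error = function(e) e)
  if (inherits(selection, "error")) {
    writeLines(c("status: no_significant_couple",
                 paste0("detail: ", conditionMessage(selection))),
               file.path(config$out_dir, "run_log.txt"))
    return(list(status = "no_significant_couple",
                message = conditionMessage(selection), paths = paths))
  }
  paths$selection <- file.path(config$out_dir, "selection.json")
  jsonlite::write_json(list(selected_couple = selection$selected_couple,
                            selected_pvalue = selection$selected_pvalue,
                            lasso_coefficients = as.list(selection$lasso_coefficients),
                            significant_couples = selection$significant_couples),
                       paths$selection, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  couple <- selection$selected_couple
  X2 <- Xn[, couple, drop = FALSE]
  y_train <- y[tr]
  folds <- make_folds(plan, y_train, n_reps = config$n_reps,
                      n_folds = config$n_folds, seed = seeds[["folds"]])
  candidates <- tune_candidates(X2[tr, , drop = FALSE], y_train, folds,
                                C_grid = config$C_grid,
                                gamma_grid = config$gamma_grid)
  model <- filter_and_select(candidates, couple = couple,
                             normalization = norm$params[
                               norm$params$feature %in% couple, ],
                             seed = config$seed)
  paths$model <- file.path(config$out_dir, "model.json")
  write_model_json(model, paths$model)

  scores_train <- radiomic_score(model, X2[tr, , drop = FALSE])
  scores_test <- radiomic_score(model, X2[te, , drop = FALSE])
  report_train <- evaluate_scores(scores_train, y[tr],
                                  patient_id = plan$train_ids,
                                  n_boot = config$n_boot, seed = seeds[["bootstrap"]])
  report_test <- evaluate_scores(scores_test, y[te],
                                 patient_id = plan$test_ids,
                                 n_boot = config$n_boot, seed = seeds[["bootstrap"]])
  paths$report_train <- file.path(config$out_dir, "report_train.json")
  paths$report_test <- file.path(config$out_dir, "report_test.json")
  render_report(report_train, paths$report_train)
  render_report(report_test, paths$report_test)

  provenance <- list(
    package_version = as.character(utils::packageVersion("locrad")),
    r_version = R.version.string,
    master_seed = config$seed, stage_seeds = as.list(seeds),
    alpha = config$alpha, rho_max = config$rho_max,
    train_sizes = as.list(config$train_sizes),
    n_reps = config$n_reps, n_folds = config$n_folds,
    selected_couple = couple)
  paths$provenance <- file.path(config$out_dir, "provenance.json")
  jsonlite::write_json(provenance, paths$provenance, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  list(status = "ok", model = model, selection = selection, split = plan,
       report_train = report_train, report_test = report_test, paths = paths)
}
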