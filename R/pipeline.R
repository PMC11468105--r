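#' Read a cohort table from a delimited text file
#'
#' Columns `id`, `sex`, `baseline_age`, `baseline_year`, `death_year`
#' (empty = alive at end of study), optionally `end_of_study_year`, plus
#' predictor columns (wave-2 measurements carry the suffix `_w2`).
#'
#' @param path CSV/TSV file path.
#' @return a data frame, validated for the survival columns.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_cohort(df, require_end = FALSE)
}

# cheap deterministic config fingerprint for run logs (not cryptographic)
config_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Configuration of a full analysis run
#'
#' Bundles every input of [run_analysis()]: the life table, the cohort with
#' its predictors, the variable-specification sheet, the analysis mode, the
#' tree control, the cross-validation settings, and the open methodological
#' choices (imputation variant, change representation) that are logged with
#' every run.
#'
#' @param life_table a [life_table()] object or the path of a life-table file.
#' @param cohort a cohort data frame or file path (see [read_cohort()]).
#' @param specs a specification data frame or CSV path
#'   (see [read_variable_specs()]).
#' @param out_dir output directory for the run artifacts.
#' @param mode `"baseline_only"` or `"baseline_plus_changes"`.
#' @param control a [tree_control()].
#' @param cv_k,cv_seed cross-validation settings.
#' @param imputation_variant passed to [compute_cohort_rpd()].
#' @param change_representation passed to [build_feature_table()].
#' @return a list of class `run_config`.
#' @export
run_config <- function(life_table, cohort, specs, out_dir,
                       mode = c("baseline_only", "baseline_plus_changes"),
                       control = tree_control(),
                       cv_k = 10L, cv_seed = 1L,
                       imputation_variant = c("cumulative", "single_year"),
                       change_representation = c("auto", "categorical",
                                                 "difference")) {
  structure(list(life_table = life_table, cohort = cohort, specs = specs,
                 out_dir = out_dir, mode = match.arg(mode),
                 control = control, cv_k = cv_k, cv_seed = cv_seed,
                 imputation_variant = match.arg(imputation_variant),
                 change_representation = match.arg(change_representation)),
            class = "run_config")
}

#' Run the full longevity analysis end to end
#'
#' Reads and validates the inputs, computes RPD/LRPD for every subject,
#' assembles the predictor table for the configured mode, grows the
#' regression tree, computes importance and the cross-validated ASE, and
#' writes the artifacts to `out_dir`: `rpd.csv`, `tree.json`, `tree.dot`,
#' `tree.txt`, `importance.csv`, `cv.csv`, `cv.json` and `run.log`.  Every
#' artifact-producing step is deterministic given the config (the CV seed is
#' part of it), so a rerun reproduces identical outputs.  Any stage error
#' aborts the run naming the stage.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with `rpd` (an `rpd_cohort`), `features`, `tree`,
#'   `importance`, `cv`, and the artifact paths.
#' @export
run_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  lt <- stage("life_table", {
    if (inherits(cfg$life_table, "life_table")) cfg$life_table
    else read_life_table(cfg$life_table)
  })
  cohort <- stage("cohort", {
    if (is.data.frame(cfg$cohort)) validate_cohort(cfg$cohort,
                                                   require_end = FALSE)
    else read_cohort(cfg$cohort)
  })
  specs <- stage("specs", {
    if (is.data.frame(cfg$specs)) cfg$specs
    else read_variable_specs(cfg$specs)
  })
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  rpd <- stage("rpd", compute_cohort_rpd(cohort, lt, cfg$imputation_variant))
  features <- stage("features", {
    wave2 <- NULL
    if (cfg$mode == "baseline_plus_changes") {
      w2cols <- paste0(specs$name[specs$waves == "both_waves"], "_w2")
      have <- w2cols %in% names(cohort)
      wave2 <- cohort[, w2cols[have], drop = FALSE]
      names(wave2) <- sub("_w2$", "", names(wave2))
      # two-wave variables without a wave-2 column are treated as all-missing
      for (v in setdiff(specs$name[specs$waves == "both_waves"],
                        names(wave2))) {
        wave2[[v]] <- NA_real_
      }
    }
    build_feature_table(cohort, wave2, specs, cfg$mode,
                        cfg$change_representation)
  })
  keep <- !is.na(rpd$records$lrpd)
  if (!all(keep)) {
    warning(sum(!keep), " subject(s) with unrepresentable LRPD excluded ",
            "from the tree")
  }
  fit_data <- cbind(lrpd = rpd$records$lrpd[keep],
                    features[keep, , drop = FALSE])
  tree <- stage("tree", rpd_tree(lrpd ~ ., fit_data, cfg$control))
  cv <- stage("cv", kfold_cv_ase(lrpd ~ ., fit_data, cfg$control,
                                 k = cfg$cv_k, seed = cfg$cv_seed))

  paths <- list(rpd = file.path(cfg$out_dir, "rpd.csv"),
                tree_json = file.path(cfg$out_dir, "tree.json"),
                tree_dot = file.path(cfg$out_dir, "tree.dot"),
                tree_txt = file.path(cfg$out_dir, "tree.txt"),
                importance = file.path(cfg$out_dir, "importance.csv"),
                cv_csv = file.path(cfg$out_dir, "cv.csv"),
                cv_json = file.path(cfg$out_dir, "cv.json"),
                log = file.path(cfg$out_dir, "run.log"))
  stage("artifacts", {
    utils::write.csv(rpd$records, paths$rpd, row.names = FALSE)
    export_tree(tree, "json", paths$tree_json)
    export_tree(tree, "dot", paths$tree_dot)
    export_tree(tree, "text", paths$tree_txt)
    utils::write.csv(tree$importance, paths$importance, row.names = FALSE)
    utils::write.csv(cv$fold_ase, paths$cv_csv, row.names = FALSE)
    jsonlite::write_json(list(k = cv$k, seed = cv$seed, pooled_ase = cv$ase,
                              fold_mean_ase = cv$ase_fold_mean),
                         paths$cv_json, auto_unbox = TRUE, digits = NA)
    cfg_desc <- list(mode = cfg$mode,
                     control = unclass(cfg$control),
                     cv_k = cfg$cv_k, cv_seed = cfg$cv_seed,
                     imputation_variant = cfg$imputation_variant,
                     change_representation = cfg$change_representation)
    cfg_json <- as.character(jsonlite::toJSON(cfg_desc, auto_unbox = TRUE,
                                              null = "null"))
    writeLines(c(
      paste0("rpdtree run ", config_hash(cfg_json)),
      paste0("config: ", cfg_json),
      sprintf("subjects: %d (%d imputed RPD, %d excluded from tree)",
              rpd$summary$n, rpd$summary$n_imputed, sum(!keep)),
      sprintf("tree: %d nodes, %d leaves, resub ASE %.6f",
              length(tree$nodes),
              sum(vapply(tree$nodes, is_leaf, logical(1))),
              tree$resub_ase),
      sprintf("cv: pooled ASE %.6f (fold-averaged %.6f)", cv$ase,
              cv$ase_fold_mean)
    ), paths$log)
  })
  invisible(list(rpd = rpd, features = features, tree = tree,
                 importance = tree$importance, cv = cv, paths = paths))
}
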