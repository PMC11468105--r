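#' Predictor variable specifications
#'
#' The tree consumes a typed predictor table: each column is ordinal, nominal
#' or continuous, and directed variables (where higher values are better or
#' worse for the subject) measured at both survey waves can be coded into
#' three-level change variables.  A specification sheet is a data frame with
#' one row per variable.
#'
#' @param name variable (column) name.
#' @param kind one of `"ordinal"`, `"nominal"`, `"continuous"`.
#' @param direction one of `"higher_is_better"`, `"higher_is_worse"`,
#'   `"undirected"`.  Change coding requires a direction; nominal variables
#'   are always `"undirected"` and never change-coded.
#' @param waves `"baseline_only"` or `"both_waves"`.
#' @param min,max allowed range (optional, `NA` = unbounded).
#' @return a one-row data frame; `rbind` rows to build a sheet.
#' @export
variable_spec <- function(name,
                          kind = c("ordinal", "nominal", "continuous"),
                          direction = c("undirected", "higher_is_better",
                                        "higher_is_worse"),
                          waves = c("baseline_only", "both_waves"),
                          min = NA_real_, max = NA_real_) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  waves <- match.arg(waves)
  if (kind == "nominal" && direction != "undirected") {
    stop("nominal variable '", name, "' cannot have a direction")
  }
  if (waves == "both_waves" && direction == "undirected") {
    stop("two-wave variable '", name,
         "' needs a direction for change coding")
  }
  data.frame(name = name, kind = kind, direction = direction, waves = waves,
             min = min, max = max, stringsAsFactors = FALSE)
}

#' Read a variable-specification sheet from CSV
#'
#' Columns: `name`, `kind`, `direction`, `waves`, and optionally `min`, `max`.
#'
#' @param path CSV file path.
#' @return validated specification data frame.
#' @export
read_variable_specs <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("name", "kind", "direction", "waves")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0L) {
    stop("spec sheet is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!("min" %in% names(raw))) raw$min <- NA_real_
  if (!("max" %in% names(raw))) raw$max <- NA_real_
  out <- do.call(rbind, lapply(seq_len(nrow(raw)), function(i) {
    variable_spec(raw$name[i], raw$kind[i], raw$direction[i], raw$waves[i],
                  raw$min[i], raw$max[i])
  }))
  if (anyDuplicated(out$name)) {
    stop("duplicate variable name(s) in spec sheet: ",
         paste(unique(out$name[duplicated(out$name)]), collapse = ", "))
  }
  out
}

#' Three-level change coding of a two-wave measurement
#'
#' Changes between the two survey waves are quantified as *worsened*,
#' *unchanged* or *improved*: the sign of `wave2 - wave1` is mapped through
#' the variable's direction (an increase in a higher-is-better score is an
#' improvement; in a higher-is-worse score, a worsening).  Subjects missing
#' either wave — notably those who died before the second wave — get `NA`.
#'
#' @param spec a one-row [variable_spec()]; must be ordinal or continuous,
#'   directed, and measured at both waves.
#' @param wave1,wave2 numeric values at the two waves (vectorized).
#' @return an ordered factor with levels `worsened < unchanged < improved`.
#' @export
code_change <- function(spec, wave1, wave2) {
  if (spec$kind == "nominal") {
    stop("change coding is undefined for nominal variable '", spec$name, "'")
  }
  if (spec$direction == "undirected") {
    stop("change coding needs a direction for variable '", spec$name, "'")
  }
  s <- sign(wave2 - wave1)
  if (spec$direction == "higher_is_worse") s <- -s
  lv <- c("worsened", "unchanged", "improved")
  factor(lv[s + 2], levels = lv, ordered = TRUE)
}

#' Assemble the predictor table for a tree analysis
#'
#' Two analysis modes mirror the two published data sets: `"baseline_only"`
#' passes the baseline columns through verbatim; `"baseline_plus_changes"`
#' additionally derives one change column per two-wave variable.  The row set
#' is never altered: all baseline subjects are retained, and subjects without
#' a second-wave measurement (usually because they died first) carry missing
#' change values, which the tree routes via surrogates.
#'
#' @param baseline data frame of wave-1 values, one row per subject, columns
#'   named as in `specs`.
#' @param wave2 data frame of wave-2 values with the same rows and the
#'   two-wave columns; required for `"baseline_plus_changes"`.
#' @param specs a specification sheet ([variable_spec()] rows).
#' @param mode `"baseline_only"` or `"baseline_plus_changes"`.
#' @param change_representation how change columns enter the table:
#'   `"categorical"` = ordered three-level factor (worsened < unchanged <
#'   improved); `"difference"` = raw score difference `wave2 - wave1`;
#'   `"auto"` (default) = difference for continuous scales, categorical for
#'   ordinal scales.
#' @return a data frame of predictors; change columns are named
#'   `<variable>_change`.  Nominal columns are coerced to factors.
#' @export
build_feature_table <- function(baseline, wave2 = NULL, specs,
                                mode = c("baseline_only",
                                         "baseline_plus_changes"),
                                change_representation = c("auto",
                                                          "categorical",
                                                          "difference")) {
  mode <- match.arg(mode)
  change_representation <- match.arg(change_representation)
  miss <- setdiff(specs$name, names(baseline))
  if (length(miss) > 0L) {
    stop("baseline table lacks column(s): ", paste(miss, collapse = ", "))
  }
  out <- baseline[, specs$name, drop = FALSE]
  for (i in seq_len(nrow(specs))) {
    if (specs$kind[i] == "nominal" && !is.factor(out[[specs$name[i]]])) {
      out[[specs$name[i]]] <- factor(out[[specs$name[i]]])
    }
  }
  if (mode == "baseline_only") return(out)

  two <- specs[specs$waves == "both_waves", , drop = FALSE]
  if (nrow(two) == 0L) return(out)
  if (is.null(wave2)) {
    stop("mode 'baseline_plus_changes' requires a wave2 table")
  }
  miss <- setdiff(two$name, names(wave2))
  if (length(miss) > 0L) {
    stop("wave2 table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(wave2) != nrow(baseline)) {
    stop("wave2 table must have the same rows as the baseline table")
  }
  for (i in seq_len(nrow(two))) {
    sp <- two[i, , drop = FALSE]
    rep_i <- change_representation
    if (rep_i == "auto") {
      rep_i <- if (sp$kind == "continuous") "difference" else "categorical"
    }
    col <- paste0(sp$name, "_change")
    if (rep_i == "difference") {
      d <- wave2[[sp$name]] - baseline[[sp$name]]
      out[[col]] <- d
    } else {
      out[[col]] <- code_change(sp, baseline[[sp$name]], wave2[[sp$name]])
    }
  }
  out
}
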