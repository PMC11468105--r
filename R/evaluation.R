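#' Cross-validated average squared error of the regression tree
#'
#' Assesses predictive performance by k-fold cross-validation: subjects are
#' randomly partitioned into `k` folds of as-equal-as-possible size (sizes
#' differ by at most one), a tree is grown on each fold's complement, and the
#' held-out subjects are predicted.  The pooled ASE averages the squared
#' held-out errors over *subjects* (well-defined with unequal folds); the
#' fold-averaged ASE (mean of per-fold ASEs) is also reported.
#'
#' @inheritParams rpd_tree
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment; recorded in the result.
#' @return an object of class `rpd_cv`: list with `k`, `seed`, `fold`
#'   (assignment per subject), `fold_ase` (data frame `fold`, `n`, `ase`),
#'   `ase` (pooled), `ase_fold_mean`, and `predictions` (held-out prediction
#'   per subject).
#' @export
kfold_cv_ase <- function(formula, data, control = tree_control(), k = 10L,
                         seed = 1L) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  n <- length(y)
  if (n < k) stop("need at least k = ", k, " subjects, got ", n)
  # seeded balanced random assignment: fold sizes differ by at most one
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))

  pred <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    hold <- fold == f
    fit <- rpd_tree(formula, data[!hold, , drop = FALSE], control)
    pred[hold] <- predict(fit, data[hold, , drop = FALSE])
  }
  sq <- (y - pred)^2
  fold_ase <- data.frame(fold = seq_len(k),
                         n = as.integer(tabulate(fold, k)),
                         ase = vapply(seq_len(k),
                                      function(f) mean(sq[fold == f]),
                                      numeric(1)))
  structure(list(k = k, seed = seed, fold = fold, fold_ase = fold_ase,
                 ase = mean(sq), ase_fold_mean = mean(fold_ase$ase),
                 predictions = pred),
            class = "rpd_cv")
}

#' @export
print.rpd_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$k, x$seed))
  cat(sprintf("  pooled ASE       : %.4f\n", x$ase))
  cat(sprintf("  fold-averaged ASE: %.4f\n", x$ase_fold_mean))
  invisible(x)
}

#' Resubstitution average squared error
#'
#' Mean squared training error of a fitted tree; algebraically equal to the
#' sum of leaf SSEs divided by the number of subjects.
#'
#' @param tree an [rpd_tree()] fit.
#' @return a non-negative number.
#' @export
resubstitution_ase <- function(tree) {
  stopifnot(inherits(tree, "rpd_tree"))
  tree$resub_ase
}

#' Hyperparameter sensitivity scan
#'
#' Refits the tree under each control preset and reports, per preset, the
#' structure summary (root split variable, depth, leaf count), the importance
#' table and the cross-validated ASE, plus a structural diff of the split
#' variables used by each pair of presets.
#'
#' @inheritParams kfold_cv_ase
#' @param presets a named list of [tree_control()] objects (at least 2).
#' @return an object of class `rpd_sensitivity`.
#' @export
sensitivity_scan <- function(formula, data,
                             presets = list(
                               default = tree_control(preset = "default"),
                               sensitivity = tree_control(preset = "sensitivity")
                             ),
                             k = 10L, seed = 1L) {
  if (length(presets) < 2L) stop("need at least 2 presets to compare")
  if (is.null(names(presets))) {
    names(presets) <- paste0("preset", seq_along(presets))
  }
  runs <- lapply(presets, function(ctrl) {
    fit <- rpd_tree(formula, data, ctrl)
    root <- fit$nodes[["1"]]
    cv <- kfold_cv_ase(formula, data, ctrl, k = k, seed = seed)
    list(control = ctrl,
         root_variable = if (is_leaf(root)) NA_character_ else root$rule$var,
         depth = max(vapply(fit$nodes, `[[`, integer(1), "depth")),
         n_leaves = sum(vapply(fit$nodes, is_leaf, logical(1))),
         importance = fit$importance,
         resub_ase = fit$resub_ase,
         cv_ase = cv$ase,
         split_variables = unique(fit$importance$variable))
  })
  nm <- names(presets)
  pairs <- utils::combn(nm, 2L, simplify = FALSE)
  diffs <- lapply(pairs, function(p) {
    a <- runs[[p[1L]]]$split_variables
    b <- runs[[p[2L]]]$split_variables
    list(presets = p, only_in_first = setdiff(a, b),
         only_in_second = setdiff(b, a), shared = intersect(a, b))
  })
  structure(list(runs = runs, diffs = diffs, k = k, seed = seed),
            class = "rpd_sensitivity")
}

#' @export
print.rpd_sensitivity <- function(x, ...) {
  cat("Hyperparameter sensitivity scan\n")
  for (nm in names(x$runs)) {
    r <- x$runs[[nm]]
    cat(sprintf(
      "  %-12s root=%s depth=%d leaves=%d resub ASE=%.4f CV ASE=%.4f\n",
      nm, r$root_variable, r$depth, r$n_leaves, r$resub_ase, r$cv_ase))
  }
  for (d in x$diffs) {
    cat(sprintf("  %s vs %s: shared {%s}", d$presets[1L], d$presets[2L],
                paste(d$shared, collapse = ",")))
    if (length(d$only_in_first) + length(d$only_in_second) == 0L) {
      cat("  (no structural differences)\n")
    } else {
      cat(sprintf("  only-first {%s} only-second {%s}\n",
                  paste(d$only_in_first, collapse = ","),
                  paste(d$only_in_second, collapse = ",")))
    }
  }
  invisible(x)
}
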