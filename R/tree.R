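#' Control parameters for growing a regression tree
#'
#' Stopping rules for [rpd_tree()].  The two named presets mirror common
#' defaults for interval-target recursive partitioning: `"default"` grows to
#' depth 5 with no leaf-size floor and an essentially-zero variance floor;
#' `"sensitivity"` allows depth 10 but requires at least 10 subjects per leaf
#' and a within-node response variance of at least 0.01 for a further split.
#'
#' @param maxdepth maximum number of split levels below the root (`>= 1`).
#' @param minleafsize minimum number of subjects in each child (`>= 1`).
#' @param minvariance minimum within-node variance of the response
#'   (`SSE / n`) for the node to be split further.
#' @param max_surrogates maximum number of surrogate rules stored per split.
#' @param preset `"default"` or `"sensitivity"`; when given, the three
#'   stopping parameters are taken from the preset and the explicit arguments
#'   are ignored.
#' @return a list of class `tree_control`.
#' @export
tree_control <- function(maxdepth = 5L, minleafsize = 1L, minvariance = 1e-8,
                         max_surrogates = 5L, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("default", "sensitivity"))
    if (preset == "default") {
      maxdepth <- 5L; minleafsize <- 1L; minvariance <- 1e-8
    } else {
      maxdepth <- 10L; minleafsize <- 10L; minvariance <- 0.01
    }
  }
  stopifnot(maxdepth >= 1, minleafsize >= 1, minvariance >= 0)
  structure(list(maxdepth = as.integer(maxdepth),
                 minleafsize = as.integer(minleafsize),
                 minvariance = as.numeric(minvariance),
                 max_surrogates = as.integer(max_surrogates),
                 preset = preset),
            class = "tree_control")
}

# Convert a model-frame-style predictor data.frame into the internal
# representation: numeric columns stay numeric, ordered factors become their
# level codes, unordered factors/characters become character.  Level sets are
# recorded so prediction data is coded identically.
prepare_x <- function(data, var_names, xlevels = NULL) {
  values <- vector("list", length(var_names))
  kinds <- character(length(var_names))
  lv <- if (is.null(xlevels)) list() else xlevels
  for (j in seq_along(var_names)) {
    v <- var_names[j]
    if (!(v %in% names(data))) stop("predictor '", v, "' not found in data")
    x <- data[[v]]
    if (is.ordered(x)) {
      if (!is.null(xlevels) && v %in% names(xlevels)) {
        values[[j]] <- as.numeric(match(as.character(x), xlevels[[v]]))
      } else {
        lv[[v]] <- levels(x)
        values[[j]] <- as.numeric(unclass(x))
      }
      kinds[j] <- "ordered"
    } else if (is.factor(x) || is.character(x)) {
      values[[j]] <- as.character(x)
      kinds[j] <- "nominal"
      if (is.null(xlevels)) lv[[v]] <- sort(unique(as.character(x)))
    } else if (is.logical(x)) {
      values[[j]] <- as.numeric(x)
      kinds[j] <- "numeric"
    } else if (is.numeric(x)) {
      values[[j]] <- as.numeric(x)
      kinds[j] <- "numeric"
    } else {
      stop("predictor '", v, "' has unsupported type ", class(x)[1L])
    }
  }
  names(values) <- var_names
  list(values = values, kinds = kinds, xlevels = lv)
}

# Route the given rows through one internal node: primary rule when observed,
# else surrogates in agreement order, else the majority branch.
# Returns a logical vector (TRUE = left).
route_rows <- function(node, xp, rows) {
  n <- length(rows)
  left <- rep(NA, n)
  apply_rule <- function(rule, pending) {
    x <- xp$values[[rule$var]][rows[pending]]
    if (rule$kind == "threshold") {
      r <- x < rule$threshold
      if (!is.null(rule$left_if_less) && !rule$left_if_less) r <- !r
    } else {
      r <- ifelse(is.na(x), NA, as.character(x) %in% rule$left_set)
    }
    r[is.na(x)] <- NA
    r
  }
  pending <- seq_len(n)
  for (rule in c(list(node$rule), node$surrogates)) {
    if (length(pending) == 0L) break
    if (!(rule$var %in% names(xp$values))) next
    r <- apply_rule(rule, pending)
    left[pending[!is.na(r)]] <- r[!is.na(r)]
    pending <- pending[is.na(r)]
  }
  left[pending] <- node$majority == "left"
  left
}

#' Fit a variance-reduction regression tree for LRPD
#'
#' Grows a binary regression tree by recursive partitioning.  At every node
#' the predictor and cut maximizing the reduction in the response sum of
#' squared errors is chosen: ordered predictors (numeric, integer, ordered
#' factors) are cut at midpoints between consecutive distinct observed values
#' (`value < c` goes left), nominal predictors are partitioned by the exact
#' mean-ordering scan.  Growth stops at a node when its depth reaches
#' `maxdepth`, its response variance falls below `minvariance`, or no
#' admissible split (both children `>= minleafsize`) reduces the SSE.
#'
#' Missing predictor values never participate in split selection.  Each split
#' stores surrogate rules — splits on other variables ranked by how well they
#' agree with the primary left/right assignment — and subjects missing the
#' primary variable are routed by the first observed surrogate, falling back
#' to the majority branch.  Ties between candidate splits are broken toward
#' the lowest predictor column index, then the smallest threshold, making the
#' fit fully deterministic.
#'
#' @param formula a model formula, e.g. `lrpd ~ .`; the response must be a
#'   complete numeric vector (typically LRPD from [compute_cohort_rpd()]).
#' @param data a data frame holding the response and predictors; predictor
#'   missingness is allowed and handled by surrogate routing.
#' @param control a [tree_control()] object.
#' @return an object of class `rpd_tree` with components `nodes` (list of
#'   node records: `id`, `depth`, `n`, `mean`, `sse`, and for internal nodes
#'   `rule`, `sse_reduction`, `surrogates`, `majority`, `children`),
#'   `importance`, `fitted`, `resub_ase`, `control`, `var_names`, `var_kinds`,
#'   `xlevels`, `terms`, `call`.  Children of node `i` are numbered `2i` and
#'   `2i + 1`.
#'
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(200))
#' d$y <- ifelse(d$x < 0, -1, 1) + rnorm(200, sd = 0.1)
#' fit <- rpd_tree(y ~ x, d, tree_control(maxdepth = 1))
#' print(fit)
#' @export
rpd_tree <- function(formula, data, control = tree_control()) {
  stopifnot(inherits(control, "tree_control"))
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- unname(stats::model.response(mf))
  if (!is.numeric(y)) stop("the response must be numeric (LRPD)")
  if (anyNA(y)) {
    stop(sum(is.na(y)), " subject(s) with missing response; the tree ",
         "requires a complete outcome (drop or recompute those rows)")
  }
  n <- length(y)
  if (n < 1L) stop("no subjects to fit on")
  var_names <- attr(stats::terms(mf), "term.labels")
  if (length(var_names) == 0L) stop("no predictors in the formula")
  xp <- prepare_x(mf, var_names)

  nodes <- list()
  grow <- function(rows, id, depth) {
    yn <- y[rows]
    nn <- length(rows)
    mu <- mean(yn)
    sse <- sum((yn - mu)^2)
    node <- list(id = id, depth = depth, n = nn, mean = mu, sse = sse)
    splittable <- depth < control$maxdepth &&
      nn >= 2L * control$minleafsize &&
      sse / nn >= control$minvariance
    best <- if (splittable) {
      best_split_any(xp, rows, yn, control$minleafsize)
    }
    if (is.null(best)) {
      nodes[[as.character(id)]] <<- node
      return(invisible(NULL))
    }
    xprim <- xp$values[[best$var]][rows]
    primary_obs <- !is.na(xprim)
    primary_left <- rep(NA, nn)
    if (best$kind == "threshold") {
      primary_left[primary_obs] <- xprim[primary_obs] < best$threshold
    } else {
      primary_left[primary_obs] <-
        as.character(xprim[primary_obs]) %in% best$left_set
    }
    n_left_obs <- sum(primary_left[primary_obs])
    majority <- if (n_left_obs >= sum(primary_obs) - n_left_obs) "left"
                else "right"
    node$rule <- list(var = best$var, kind = best$kind,
                      threshold = best$threshold, left_set = best$left_set)
    node$sse_reduction <- best$sse_reduction
    node$surrogates <- find_surrogates(xp, rows, primary_left, primary_obs,
                                       best$var_index,
                                       control$max_surrogates)
    node$majority <- majority
    node$children <- c(2L * id, 2L * id + 1L)
    left <- route_rows(node, xp, rows)
    nodes[[as.character(id)]] <<- node
    grow(rows[left], 2L * id, depth + 1L)
    grow(rows[!left], 2L * id + 1L, depth + 1L)
  }
  grow(seq_len(n), 1L, 0L)
  ids <- as.integer(names(nodes))
  nodes <- nodes[order(ids)]

  fit <- structure(
    list(nodes = nodes, control = control, var_names = var_names,
         var_kinds = xp$kinds, xlevels = xp$xlevels,
         terms = stats::terms(mf), call = match.call(), n = n),
    class = "rpd_tree"
  )
  fit$importance <- compute_importance(fit)
  fit$fitted <- predict_rows(fit, xp, n)
  fit$y <- y
  fit$resub_ase <- mean((y - fit$fitted)^2)
  fit
}

is_leaf <- function(node) is.null(node$children)

# Route all rows of a prepared predictor table down the tree.
predict_rows <- function(tree, xp, n, type = "mean") {
  out <- numeric(n)
  walk <- function(rows, id) {
    node <- tree$nodes[[as.character(id)]]
    if (is_leaf(node)) {
      out[rows] <<- if (type == "leaf") node$id else node$mean
      return(invisible(NULL))
    }
    left <- route_rows(node, xp, rows)
    if (any(left)) walk(rows[left], node$children[1L])
    if (any(!left)) walk(rows[!left], node$children[2L])
  }
  if (n > 0L) walk(seq_len(n), 1L)
  if (type == "leaf") out <- as.integer(out)
  out
}

#' Predict LRPD from a fitted regression tree
#'
#' Each subject is routed from the root to a leaf — primary split rule when
#' the subject's value is observed, otherwise surrogates, otherwise the
#' majority branch — and receives that leaf's mean LRPD.  The routing is a
#' total function: every subject, however incomplete, reaches a leaf.
#'
#' @param object an [rpd_tree()] fit.
#' @param newdata data frame of predictors; omitted = training data fits.
#' @param type `"mean"` (default) returns the leaf mean LRPD; `"leaf"`
#'   returns the id of the leaf each subject lands in.
#' @param ... unused.
#' @return numeric vector of predicted LRPD, or integer leaf ids.
#' @export
predict.rpd_tree <- function(object, newdata = NULL,
                             type = c("mean", "leaf"), ...) {
  type <- match.arg(type)
  if (is.null(newdata) && type == "mean") return(object$fitted)
  if (is.null(newdata)) {
    stop("type = 'leaf' requires newdata (training data is not stored)")
  }
  xp <- prepare_x(newdata, object$var_names, object$xlevels)
  xp$kinds <- object$var_kinds
  predict_rows(object, xp, nrow(newdata), type)
}

#' @export
residuals.rpd_tree <- function(object, ...) object$y - object$fitted

#' @export
fitted.rpd_tree <- function(object, ...) object$fitted

compute_importance <- function(tree) {
  internal <- Filter(Negate(is_leaf), tree$nodes)
  if (length(internal) == 0L) {
    return(data.frame(variable = character(), importance = numeric(),
                      count = integer()))
  }
  vars <- vapply(internal, function(nd) nd$rule$var, character(1))
  red <- vapply(internal, function(nd) nd$sse_reduction, numeric(1))
  raw <- rowsum(red, vars, reorder = TRUE)[, 1L]
  cnt <- table(vars)[names(raw)]
  out <- data.frame(variable = names(raw),
                    importance = 100 * raw / sum(raw),
                    count = as.integer(cnt))
  out <- out[order(-out$importance, out$variable), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variable importance of a fitted tree
#'
#' A variable's raw importance is the total SSE reduction over all primary
#' splits made on it; shares are scaled so they sum to 100 across the
#' variables appearing in the tree.  `count` is the number of primary splits
#' on the variable.  Variables never split on are omitted; a single-leaf tree
#' yields an empty table.  Surrogate rules do not contribute.
#'
#' @param tree an [rpd_tree()] fit.
#' @return data frame with columns `variable`, `importance`, `count`, sorted
#'   by decreasing importance.
#' @export
variable_importance <- function(tree) {
  stopifnot(inherits(tree, "rpd_tree"))
  tree$importance
}

rule_label <- function(node, xlevels = NULL) {
  r <- node$rule
  if (r$kind == "threshold") {
    lv <- xlevels[[r$var]]
    if (!is.null(lv)) {
      # ordered factor: show the level boundary rather than the code midpoint
      below <- lv[seq_len(floor(r$threshold))]
      sprintf("%s <= %s", r$var, below[length(below)])
    } else {
      sprintf("%s < %s", r$var, format(r$threshold, digits = 6))
    }
  } else {
    sprintf("%s in {%s}", r$var, paste(r$left_set, collapse = ","))
  }
}

#' @export
print.rpd_tree <- function(x, ...) {
  cat("Regression tree for LRPD (variance-reduction splits)\n")
  cat(sprintf("  n = %d, %d node(s), %d leaves, resubstitution ASE = %.4f\n",
              x$n, length(x$nodes),
              sum(vapply(x$nodes, is_leaf, logical(1))), x$resub_ase))
  walk <- function(id, prefix) {
    node <- x$nodes[[as.character(id)]]
    cat(sprintf("%s[%d] n=%d mean=%.3f", prefix, node$id, node$n, node$mean))
    if (!is_leaf(node)) {
      cat(sprintf("  split: %s (dSSE=%.3f)\n", rule_label(node, x$xlevels),
                  node$sse_reduction))
      walk(node$children[1L], paste0(prefix, "  "))
      walk(node$children[2L], paste0(prefix, "  "))
    } else {
      cat("  *\n")
    }
  }
  walk(1L, "  ")
  invisible(x)
}

#' @export
summary.rpd_tree <- function(object, ...) {
  leaves <- Filter(is_leaf, object$nodes)
  structure(
    list(n = object$n,
         n_nodes = length(object$nodes),
         n_leaves = length(leaves),
         depth = max(vapply(object$nodes, `[[`, integer(1), "depth")),
         resub_ase = object$resub_ase,
         control = object$control,
         importance = object$importance,
         leaf_table = data.frame(
           id = vapply(leaves, `[[`, integer(1), "id"),
           n = vapply(leaves, `[[`, integer(1), "n"),
           mean_lrpd = vapply(leaves, `[[`, numeric(1), "mean"))),
    class = "summary.rpd_tree")
}

#' @export
print.summary.rpd_tree <- function(x, ...) {
  cat(sprintf(
    "rpd_tree: n = %d, %d nodes (%d leaves), depth %d, resub ASE %.4f\n",
    x$n, x$n_nodes, x$n_leaves, x$depth, x$resub_ase))
  cat(sprintf("control: maxdepth %d, minleafsize %d, minvariance %g\n",
              x$control$maxdepth, x$control$minleafsize,
              x$control$minvariance))
  if (nrow(x$importance) > 0L) {
    cat("\nVariable importance (scaled to 100):\n")
    print(x$importance, row.names = FALSE)
  }
  cat("\nLeaves (predicted LRPD = leaf mean; negative = longer life):\n")
  print(x$leaf_table[order(x$leaf_table$mean_lrpd), ], row.names = FALSE)
  invisible(x)
}

#' Plot a fitted regression tree
#'
#' Draws the tree with base graphics: internal nodes show their split rule,
#' leaves show mean LRPD and size.  Darker leaves indicate higher mean LRPD
#' (shorter life relative to age/sex peers).
#'
#' @param x an [rpd_tree()] fit.
#' @param ... unused.
#' @export
plot.rpd_tree <- function(x, ...) {
  leaves <- Filter(is_leaf, x$nodes)
  pos <- new.env()
  xc <- 0
  assign_x <- function(id) {
    node <- x$nodes[[as.character(id)]]
    if (is_leaf(node)) {
      xc <<- xc + 1
      assign(as.character(id), xc, envir = pos)
      return(xc)
    }
    xl <- assign_x(node$children[1L])
    xr <- assign_x(node$children[2L])
    mid <- (xl + xr) / 2
    assign(as.character(id), mid, envir = pos)
    mid
  }
  assign_x(1L)
  maxd <- max(vapply(x$nodes, `[[`, integer(1), "depth"))
  graphics::plot(NULL, xlim = c(0.5, length(leaves) + 0.5),
                 ylim = c(-maxd - 0.5, 0.5), axes = FALSE, xlab = "",
                 ylab = "", main = "Regression tree for LRPD")
  mrange <- range(vapply(leaves, `[[`, numeric(1), "mean"))
  for (node in x$nodes) {
    px <- get(as.character(node$id), envir = pos)
    py <- -node$depth
    if (!is_leaf(node)) {
      for (ch in node$children) {
        cx <- get(as.character(ch), envir = pos)
        graphics::segments(px, py, cx, py - 1, col = "grey50")
      }
      graphics::text(px, py, rule_label(node, x$xlevels), cex = 0.7)
    } else {
      shade <- if (diff(mrange) > 0) {
        (node$mean - mrange[1L]) / diff(mrange)
      } else 0.5
      graphics::points(px, py, pch = 21, cex = 3,
                       bg = grDevices::grey(1 - 0.6 * shade))
      graphics::text(px, py - 0.35,
                     sprintf("%.2f\nn=%d", node$mean, node$n), cex = 0.6)
    }
  }
  invisible(x)
}
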