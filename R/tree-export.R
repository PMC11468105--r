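#' Serialize a fitted regression tree
#'
#' `"json"` produces a lossless structural serialization (node statistics,
#' split rules, surrogates, control parameters) that [import_tree()] restores;
#' `"dot"` produces Graphviz source for rendering the tree; `"text"` produces
#' the indented rule listing also shown by `print()`.
#'
#' @param tree an [rpd_tree()] fit.
#' @param format one of `"json"`, `"dot"`, `"text"`.
#' @param file optional path; when given the serialization is also written
#'   there.
#' @return the serialized tree as a single character string, invisibly when
#'   `file` is given.
#' @export
export_tree <- function(tree, format = c("json", "dot", "text"), file = NULL) {
  stopifnot(inherits(tree, "rpd_tree"))
  format <- match.arg(format)
  out <- switch(format,
                json = tree_to_json(tree),
                dot = tree_to_dot(tree),
                text = paste(utils::capture.output(print(tree)),
                             collapse = "\n"))
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

serialize_rule <- function(rule) {
  if (is.null(rule)) return(NULL)
  out <- list(var = rule$var, kind = rule$kind)
  if (rule$kind == "threshold") {
    out$threshold <- rule$threshold
    if (!is.null(rule$left_if_less)) out$left_if_less <- rule$left_if_less
  } else {
    out$left_set <- as.list(rule$left_set)
  }
  if (!is.null(rule$agreement)) out$agreement <- rule$agreement
  out
}

tree_to_json <- function(tree) {
  nodes <- lapply(tree$nodes, function(nd) {
    out <- list(id = nd$id, depth = nd$depth, n = nd$n,
                mean = nd$mean, sse = nd$sse)
    if (!is_leaf(nd)) {
      out$rule <- serialize_rule(nd$rule)
      out$sse_reduction <- nd$sse_reduction
      out$surrogates <- lapply(nd$surrogates, serialize_rule)
      out$majority <- nd$majority
      out$children <- nd$children
    }
    out
  })
  obj <- list(
    format = "rpd_tree",
    control = list(maxdepth = tree$control$maxdepth,
                   minleafsize = tree$control$minleafsize,
                   minvariance = tree$control$minvariance,
                   max_surrogates = tree$control$max_surrogates),
    n = tree$n,
    resub_ase = tree$resub_ase,
    var_names = as.list(tree$var_names),
    var_kinds = as.list(tree$var_kinds),
    xlevels = lapply(tree$xlevels, as.list),
    nodes = unname(nodes)
  )
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE))
}

deserialize_rule <- function(r) {
  if (is.null(r)) return(NULL)
  out <- list(var = r$var, kind = r$kind)
  if (r$kind == "threshold") {
    out$threshold <- as.numeric(r$threshold)
    if (!is.null(r$left_if_less)) out$left_if_less <- isTRUE(r$left_if_less)
  } else {
    out$left_set <- vapply(r$left_set, as.character, character(1))
  }
  if (!is.null(r$agreement)) out$agreement <- as.numeric(r$agreement)
  out
}

#' Restore a regression tree from its JSON serialization
#'
#' The inverse of `export_tree(tree, "json")`: structure, node statistics,
#' split and surrogate rules, and control parameters round-trip exactly, so
#' the restored tree predicts identically.  Training data (`y`, `fitted`) is
#' not part of the serialization.
#'
#' @param json a JSON string, or the path of a file containing one.
#' @return an object of class `rpd_tree`.
#' @export
import_tree <- function(json) {
  if (length(json) == 1L && !grepl("{", json, fixed = TRUE) &&
      file.exists(json)) {
    json <- paste(readLines(json), collapse = "\n")
  }
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (is.null(obj$format) || obj$format != "rpd_tree") {
    stop("not an rpd_tree JSON serialization")
  }
  nodes <- lapply(obj$nodes, function(nd) {
    out <- list(id = as.integer(nd$id), depth = as.integer(nd$depth),
                n = as.integer(nd$n), mean = as.numeric(nd$mean),
                sse = as.numeric(nd$sse))
    if (!is.null(nd$rule)) {
      out$rule <- deserialize_rule(nd$rule)
      out$sse_reduction <- as.numeric(nd$sse_reduction)
      out$surrogates <- lapply(nd$surrogates, deserialize_rule)
      out$majority <- nd$majority
      out$children <- vapply(nd$children, as.integer, integer(1))
    }
    out
  })
  names(nodes) <- vapply(nodes, function(nd) as.character(nd$id), character(1))
  ctrl <- tree_control(maxdepth = obj$control$maxdepth,
                       minleafsize = obj$control$minleafsize,
                       minvariance = obj$control$minvariance,
                       max_surrogates = obj$control$max_surrogates)
  fit <- structure(
    list(nodes = nodes, control = ctrl,
         var_names = vapply(obj$var_names, as.character, character(1)),
         var_kinds = vapply(obj$var_kinds, as.character, character(1)),
         xlevels = lapply(obj$xlevels,
                          function(l) vapply(l, as.character, character(1))),
         terms = NULL, call = NULL,
         n = as.integer(obj$n)),
    class = "rpd_tree")
  fit$resub_ase <- as.numeric(obj$resub_ase)
  fit$importance <- compute_importance(fit)
  fit
}

tree_to_dot <- function(tree) {
  esc <- function(s) gsub("\"", "\\\"", s, fixed = TRUE)
  lines <- c("digraph rpd_tree {",
             "  node [shape=box, fontsize=10];")
  for (nd in tree$nodes) {
    label <- if (is_leaf(nd)) {
      sprintf("mean LRPD = %.2f\\nn = %d", nd$mean, nd$n)
    } else {
      sprintf("%s\\nmean = %.2f, n = %d", esc(rule_label(nd, tree$xlevels)),
              nd$mean, nd$n)
    }
    shape <- if (is_leaf(nd)) ", shape=oval" else ""
    lines <- c(lines, sprintf("  n%d [label=\"%s\"%s];", nd$id, label, shape))
    if (!is_leaf(nd)) {
      lines <- c(lines,
                 sprintf("  n%d -> n%d [label=\"yes\"];", nd$id,
                         nd$children[1L]),
                 sprintf("  n%d -> n%d [label=\"no\"];", nd$id,
                         nd$children[2L]))
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}
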