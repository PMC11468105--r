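# Split search for the variance-reduction regression tree.
#
# All split evaluation is done on subjects with the candidate variable
# observed; missing values never participate in choosing a split and are
# routed afterwards through surrogates (see route_rows in tree.R).

#' Best threshold split of an ordered predictor
#'
#' Scans every midpoint between consecutive distinct observed values of `x`
#' and returns the cut maximizing the reduction in the sum of squared errors
#' of `y`, `SSE(parent) - SSE(left) - SSE(right)`, subject to both children
#' holding at least `minleafsize` observations.  The rule orientation is
#' `value < threshold` goes left.  Ties are broken toward the smallest
#' threshold.
#'
#' @param x numeric (or ordered-codes) predictor; `NA`s are excluded.
#' @param y numeric response, same length as `x`.
#' @param minleafsize minimum child size (counted over observed `x`).
#' @return `NULL` when no admissible cut improves the SSE, otherwise a list
#'   with `threshold`, `sse_reduction`, `n_left`, `n_right`.
#' @export
best_threshold_split <- function(x, y, minleafsize = 1L) {
  obs <- !is.na(x) & !is.na(y)
  x <- unname(x[obs]); y <- unname(y[obs])
  n <- length(x)
  if (n < 2L * minleafsize || n < 2L) return(NULL)
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  k <- seq_len(n - 1L)
  ok <- (xs[k] != xs[k + 1L]) & (k >= minleafsize) & (n - k >= minleafsize)
  if (!any(ok)) return(NULL)
  cy <- cumsum(ys); cy2 <- cumsum(ys * ys)
  tot <- cy[n]; tot2 <- cy2[n]
  sse_parent <- tot2 - tot * tot / n
  sse_left <- cy2[k] - cy[k]^2 / k
  sse_right <- (tot2 - cy2[k]) - (tot - cy[k])^2 / (n - k)
  red <- sse_parent - sse_left - sse_right
  red[!ok] <- -Inf
  best <- which.max(red) # first max = smallest threshold
  if (!(red[best] > 0)) return(NULL)
  list(threshold = (xs[best] + xs[best + 1L]) / 2,
       sse_reduction = red[best],
       n_left = best, n_right = n - best)
}

#' Best binary subset split of a nominal predictor
#'
#' Orders the observed categories by their within-category mean of `y` and
#' scans that ordering as if it were an ordered variable — for a squared-error
#' criterion the optimal binary partition is always a split of this ordering,
#' so the scan is exact without enumerating all `2^(k-1) - 1` subsets.
#'
#' @param x factor or character predictor; `NA`s are excluded.
#' @inheritParams best_threshold_split
#' @return `NULL` when no admissible split improves the SSE, otherwise a list
#'   with `left_set` (character vector of categories routed left),
#'   `sse_reduction`, `n_left`, `n_right`.
#' @export
best_subset_split <- function(x, y, minleafsize = 1L) {
  obs <- !is.na(x) & !is.na(y)
  x <- as.character(x)[obs]; y <- unname(y[obs])
  n <- length(x)
  if (n < 2L * minleafsize || n < 2L) return(NULL)
  lev <- sort(unique(x))
  if (length(lev) < 2L) return(NULL)
  g <- match(x, lev)
  cnt <- tabulate(g, length(lev))
  sums <- unname(rowsum(y, g, reorder = TRUE)[, 1L])
  means <- sums / cnt
  ord <- order(means, seq_along(lev)) # ties: original (lexicographic) order
  lev <- lev[ord]; cnt <- cnt[ord]; sums <- sums[ord]
  k <- seq_len(length(lev) - 1L)
  cn <- cumsum(cnt); cs <- cumsum(sums)
  tot_n <- cn[length(lev)]; tot_s <- cs[length(lev)]
  ok <- (cn[k] >= minleafsize) & (tot_n - cn[k] >= minleafsize)
  if (!any(ok)) return(NULL)
  # SSE reduction only depends on group sums/counts: the within-category SSE
  # cancels between parent and children.
  red <- cs[k]^2 / cn[k] + (tot_s - cs[k])^2 / (tot_n - cn[k]) -
    tot_s^2 / tot_n
  red[!ok] <- -Inf
  best <- which.max(red)
  if (!(red[best] > 0)) return(NULL)
  list(left_set = lev[seq_len(best)],
       sse_reduction = red[best],
       n_left = cn[best], n_right = tot_n - cn[best])
}

# Best split across all columns of a prepared predictor table.
# xp: list with $values (list of numeric/character columns) and $kinds.
# Returns NULL or list(var, kind, threshold|left_set, sse_reduction).
best_split_any <- function(xp, rows, y, minleafsize) {
  best <- NULL
  for (j in seq_along(xp$values)) {
    xj <- xp$values[[j]][rows]
    cand <- if (xp$kinds[j] == "nominal") {
      best_subset_split(xj, y, minleafsize)
    } else {
      best_threshold_split(xj, y, minleafsize)
    }
    if (is.null(cand)) next
    # strict > : ties go to the lowest column index (and within a column the
    # scan already prefers the smallest threshold / smallest left-set)
    if (is.null(best) || cand$sse_reduction > best$sse_reduction) {
      best <- c(list(var = names(xp$values)[j],
                     var_index = j,
                     kind = if (xp$kinds[j] == "nominal") "subset"
                            else "threshold"),
                cand)
    }
  }
  best
}

# Surrogate rules for a node: for each non-primary variable, the split that
# best agrees with the primary left/right assignment, evaluated on subjects
# with both variables observed.  Only surrogates beating the majority-branch
# baseline are kept, ordered by decreasing agreement.
find_surrogates <- function(xp, rows, primary_left, primary_obs, primary_index,
                            max_surrogates = 5L) {
  dirs <- primary_left[primary_obs] # logical: TRUE = left
  out <- list()
  for (j in seq_along(xp$values)) {
    if (j == primary_index) next
    w <- xp$values[[j]][rows][primary_obs]
    both <- !is.na(w)
    m <- sum(both)
    if (m < 2L) next
    d <- dirs[both]
    nl <- sum(d)
    baseline <- max(nl, m - nl) / m
    wb <- w[both]
    if (xp$kinds[j] == "nominal") {
      lev <- sort(unique(as.character(wb)))
      if (length(lev) < 2L) next
      g <- match(as.character(wb), lev)
      left_cnt <- rowsum(as.numeric(d), g, reorder = TRUE)[, 1L]
      tot_cnt <- tabulate(g, length(lev))
      to_left <- left_cnt * 2 >= tot_cnt # ties -> left
      matches <- sum(ifelse(to_left, left_cnt, tot_cnt - left_cnt))
      agree <- matches / m
      if (agree <= baseline) next
      out[[length(out) + 1L]] <- list(var = names(xp$values)[j],
                                      var_index = j, kind = "subset",
                                      left_set = lev[to_left],
                                      agreement = agree)
    } else {
      o <- order(wb)
      ws <- wb[o]; ds <- d[o]
      k <- seq_len(m - 1L)
      okc <- ws[k] != ws[k + 1L]
      if (!any(okc)) next
      cl <- cumsum(ds)
      # matches when rule is "w < c -> left"
      match_lt <- cl[k] + (m - nl) - (k - cl[k])
      match_ge <- m - match_lt # reversed orientation
      score <- pmax(match_lt, match_ge)
      score[!okc] <- -Inf
      b <- which.max(score)
      agree <- score[b] / m
      if (agree <= baseline) next
      out[[length(out) + 1L]] <- list(var = names(xp$values)[j],
                                      var_index = j, kind = "threshold",
                                      threshold = (ws[b] + ws[b + 1L]) / 2,
                                      left_if_less = match_lt[b] >= match_ge[b],
                                      agreement = agree)
    }
  }
  if (length(out) == 0L) return(out)
  ord <- order(-vapply(out, `[[`, numeric(1), "agreement"),
               vapply(out, `[[`, integer(1), "var_index"))
  out[ord[seq_len(min(length(ord), max_surrogates))]]
}
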