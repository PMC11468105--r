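# Independent brute-force oracles.  These deliberately avoid the package's
# cumulative-sum and mean-ordering shortcuts: SSE is recomputed from scratch
# for every candidate partition.

oracle_sse <- function(v) if (length(v) == 0L) 0 else sum((v - mean(v))^2)

# Best achievable SSE reduction for one predictor column, scanning every
# threshold (ordered values) or every binary subset (nominal values).
oracle_best_column <- function(x, y, minleafsize = 1L) {
  obs <- !is.na(x) & !is.na(y)
  y <- y[obs]
  best <- -Inf
  if (is.factor(x) && !is.ordered(x) || is.character(x)) {
    x <- as.character(x)[obs]
    lev <- sort(unique(x))
    k <- length(lev)
    if (k < 2L) return(best)
    # enumerate each binary partition once: subsets containing lev[1]
    for (mask in seq_len(2^(k - 1L)) - 1L) {
      left_set <- lev[c(TRUE, as.logical(bitwAnd(mask, 2^(seq_len(k - 1L) - 1L))))]
      if (length(left_set) == k) next
      L <- x %in% left_set
      if (sum(L) < minleafsize || sum(!L) < minleafsize) next
      red <- oracle_sse(y) - oracle_sse(y[L]) - oracle_sse(y[!L])
      best <- max(best, red)
    }
  } else {
    if (is.ordered(x)) x <- as.numeric(unclass(x))
    x <- x[obs]
    ux <- sort(unique(x))
    if (length(ux) < 2L) return(best)
    cuts <- (ux[-1] + ux[-length(ux)]) / 2
    for (cc in cuts) {
      L <- x < cc
      if (sum(L) < minleafsize || sum(!L) < minleafsize) next
      red <- oracle_sse(y) - oracle_sse(y[L]) - oracle_sse(y[!L])
      best <- max(best, red)
    }
  }
  best
}

# Maximum SSE reduction over all columns of X at the given rows.
oracle_best_split <- function(X, y, minleafsize = 1L) {
  max(vapply(X, oracle_best_column, numeric(1), y = y,
             minleafsize = minleafsize), -Inf)
}

# Per-node membership of every training row, recovered from assigned leaf
# ids: node k is an ancestor of leaf L iff repeated halving of L reaches k.
node_rows <- function(tree, data) {
  leaf <- predict(tree, data, type = "leaf")
  ids <- as.integer(names(tree$nodes))
  out <- lapply(ids, function(k) {
    anc <- vapply(leaf, function(l) {
      while (l > k) l <- l %/% 2L
      l == k
    }, logical(1))
    which(anc)
  })
  names(out) <- as.character(ids)
  out
}

# Year-at-a-time RPD oracle: multiply death_prob calls one by one.
oracle_rpd <- function(lt, sex, baseline_age, baseline_year, death_year) {
  p <- 1
  for (yr in seq.int(baseline_year, death_year)) {
    age <- baseline_age + (yr - baseline_year)
    q <- death_prob(lt, sex, age, if (lt$period_only) NULL else yr)
    p <- p * (1 - q)
  }
  p
}
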