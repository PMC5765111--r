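# Parsimony scoring via the Sankoff dynamic program, vectorized across
# character columns. Unordered (Fitch-equivalent) scores use the unit
# cost matrix; ordinal characters use the linear cost |i - j| (ordered /
# Wagner parsimony). Multifurcating nodes are handled exactly. Missing
# tip values contribute zero cost to every state.

.BIG <- 1e7

.postorder_nodes <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  children <- split(po$edge[, 2L], po$edge[, 1L])
  ord <- unique(po$edge[, 1L])   # postorder: children listed before parents
  list(ntip = ntip, order = ord, children = children,
       root = ord[length(ord)])
}

# Cost matrices are stored characters-by-states (C x K) so every state
# update is one contiguous column operation.
.state_mins <- function(m) {
  out <- m[, 1L]
  for (i in seq_len(ncol(m))[-1L]) out <- pmin(out, m[, i])
  out
}

# child cost matrix (C x K) -> contribution to the parent per parent state
.child_contrib <- function(cc, cost) {
  K <- ncol(cc)
  if (cost == "unit") {
    mins <- .state_mins(cc) + 1
    return(pmin(cc, mins))   # the vector recycles down each column
  }
  f <- cc
  for (i in seq_len(K)[-1L]) f[, i] <- pmin(cc[, i], f[, i - 1L] + 1)
  b <- cc
  for (i in rev(seq_len(K))[-1L]) b[, i] <- pmin(cc[, i], b[, i + 1L] + 1)
  pmin(f, b)
}

# leaf cost matrices (C x K) for each row of a 0-based state matrix
.leaf_costs <- function(states, K) {
  C <- ncol(states)
  lapply(seq_len(nrow(states)), function(tip) {
    m <- matrix(.BIG, C, K)
    s <- states[tip, ]
    obs <- which(!is.na(s))
    if (length(obs)) m[cbind(obs, s[obs] + 1L)] <- 0
    if (length(obs) < C) m[which(is.na(s)), ] <- 0
    m
  })
}

# leaves: list of C x K leaf cost matrices indexed by tip number
.sankoff_engine <- function(topo, leaves, cost) {
  costm <- vector("list", topo$ntip + length(topo$order))
  costm[seq_len(topo$ntip)] <- leaves
  for (nd in topo$order) {
    kids <- topo$children[[as.character(nd)]]
    acc <- .child_contrib(costm[[kids[1L]]], cost)
    for (ch in kids[-1L])
      acc <- acc + .child_contrib(costm[[ch]], cost)
    costm[[nd]] <- acc
  }
  .state_mins(costm[[topo$root]])
}

# states: ntip x C matrix of 0-based states (NA = missing), rows in tip order
.sankoff_scores <- function(topo, states, K, cost = c("unit", "linear")) {
  cost <- match.arg(cost)
  .sankoff_engine(topo, .leaf_costs(states, K), cost)
}

#' Parsimony score of a character on a tree
#'
#' Binary (and unordered) characters are scored as the minimum number of
#' state changes (the Fitch count); ordinal characters use ordered
#' parsimony with cost `|i - j|` per change. Missing values are free.
#' Continuous characters must be discretized first (see [discretize()]).
#'
#' @param tree a `phylo` tree.
#' @param values numeric vector of states named by the tree's tips.
#' @param kind `"binary"` or `"ordinal(K)"`.
#' @return Integer parsimony score.
#' @export
parsimony_score <- function(tree, values, kind = "binary") {
  stopifnot(inherits(tree, "phylo"))
  if (!all(tree$tip.label %in% names(values)))
    stop("missing character value for tip: ",
         setdiff(tree$tip.label, names(values))[1L])
  k <- .parse_kind(kind)
  if (k$kind == "continuous")
    stop("continuous characters must be discretized before scoring")
  v <- values[tree$tip.label]
  topo <- .postorder_nodes(tree)
  sc <- .sankoff_scores(topo, matrix(v, ncol = 1L), K = k$K,
                        cost = if (k$kind == "binary") "unit" else "linear")
  as.integer(round(sc))
}

#' Discretize a continuous character into ordinal states
#'
#' Equal-width bins over the observed range map values to states
#' `0..K-1`; the maximum maps to `K-1` and a constant column maps wholly
#' to state 0. With `method = "quantile"` bin edges are the empirical
#' quantiles instead. Missing values stay missing.
#'
#' @param values numeric vector (may contain `NA`).
#' @param K number of states (default 10).
#' @param method `"width"` (default) or `"quantile"`.
#' @return Integer vector of states in `0..K-1`, `NA` preserved.
#' @export
discretize <- function(values, K = 10L, method = c("width", "quantile")) {
  method <- match.arg(method)
  obs <- values[!is.na(values)]
  if (length(obs) == 0L) stop("no observed values to discretize")
  if (any(!is.finite(obs))) stop("non-finite value in continuous character")
  if (K < 2L) stop("K must be at least 2")
  rng <- range(obs)
  out <- rep(NA_integer_, length(values))
  if (rng[1L] == rng[2L]) {
    out[!is.na(values)] <- 0L
    return(out)
  }
  if (method == "width") {
    st <- floor((values - rng[1L]) / (rng[2L] - rng[1L]) * K)
  } else {
    qs <- stats::quantile(obs, probs = seq(0, 1, length.out = K + 1L),
                          names = FALSE, type = 7)
    st <- findInterval(values, qs, rightmost.closed = TRUE,
                       left.open = FALSE) - 1L
  }
  st[which(st >= K)] <- K - 1L
  st[which(st < 0)] <- 0L
  out[!is.na(values)] <- as.integer(st[!is.na(values)])
  out
}
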