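# Independent brute-force oracles used across the test files. These are
# deliberately naive (exhaustive enumeration, O(n^3) scans) and share no
# code with the package internals they check.

# --- all unrooted binary topologies on a label set ------------------------
# Trees are grown by inserting each new taxon on every edge of every
# smaller tree, giving the (2n-5)!! distinct labelled topologies.
# Representation during growth: an edge matrix over node ids; tips get
# ids 1..n, internal nodes n+1, n+2, ...
all_topologies <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 3L)
  base <- list(list(edges = rbind(c(n + 1L, 1L), c(n + 1L, 2L),
                                  c(n + 1L, 3L)),
                    nextnode = n + 2L))
  trees <- base
  for (tip in seq_len(n)[-(1:3)]) {
    grown <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edges))) {
        ed <- tr$edges
        u <- ed[e, 1L]; v <- ed[e, 2L]
        w <- tr$nextnode
        ed <- rbind(ed[-e, , drop = FALSE],
                    c(u, w), c(w, v), c(w, tip))
        grown[[length(grown) + 1L]] <- list(edges = ed,
                                            nextnode = w + 1L)
      }
    }
    trees <- grown
  }
  lapply(trees, function(tr) {
    nwk <- edges_to_newick(tr$edges, n, labels)
    ape::read.tree(text = nwk)
  })
}

edges_to_newick <- function(edges, ntip, labels) {
  adj <- split(c(edges[, 2L], edges[, 1L]), c(edges[, 1L], edges[, 2L]))
  build <- function(node, parent) {
    nbrs <- setdiff(adj[[as.character(node)]], parent)
    if (!length(nbrs)) return(labels[node])
    paste0("(", paste(vapply(nbrs, build, character(1L), parent = node),
                      collapse = ","), ")")
  }
  paste0(build(ntip + 1L, NA), ";")
}

# --- exhaustive parsimony over internal-state assignments -----------------
# cost_fun(i, j) with 0-based states; tip_states named by tip label.
brute_parsimony <- function(tree, tip_states, K, cost_fun) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  states <- 0:(K - 1L)
  grid <- do.call(expand.grid, rep(list(states), nint))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    assign_int <- as.integer(grid[r, ])
    total <- 0
    for (e in seq_len(nrow(tree$edge))) {
      u <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
      su <- assign_int[u - ntip]
      sv <- if (v <= ntip) tip_states[[tree$tip.label[v]]]
            else assign_int[v - ntip]
      total <- total + cost_fun(su, sv)
    }
    if (total < best) best <- total
  }
  best
}

# --- exhaustive ungapped local alignment (Smith-Waterman, no gaps) --------
# Returns the best-scoring contiguous diagonal segment.
brute_ungapped_best <- function(s1, s2, sm) {
  c1 <- strsplit(s1, "")[[1L]]; c2 <- strsplit(s2, "")[[1L]]
  n1 <- length(c1); n2 <- length(c2)
  best <- list(score = -Inf)
  for (d in (-(n2 - 1L)):(n1 - 1L)) {
    q0 <- max(0L, d); q1 <- min(n1, n2 + d)
    if (q1 - q0 < 1L) next
    qpos <- (q0 + 1L):q1
    v <- sm[cbind(match(c1[qpos], rownames(sm)),
                  match(c2[qpos - d], colnames(sm)))]
    # best contiguous segment by exhaustive start/end scan
    cum <- c(0, cumsum(v))
    for (i in seq_along(v)) for (j in i:length(v)) {
      sc <- cum[j + 1L] - cum[i]
      if (sc > best$score) {
        best <- list(score = sc,
                     qs = q0 + i - 1L, qe = q0 + j,
                     ss = q0 + i - 1L - d, se = q0 + j - d,
                     nid = sum(c1[qpos[i:j]] != c2[qpos[i:j] - d]))
      }
    }
  }
  best
}

# --- misc helpers ---------------------------------------------------------
random_protein <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
          "S","T","V","W","Y")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

mutate_protein <- function(s, positions, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
          "S","T","V","W","Y")
  ch <- strsplit(s, "")[[1L]]
  for (p in positions) ch[p] <- sample(setdiff(aa, ch[p]), 1L)
  paste(ch, collapse = "")
}

# random binary tree with positive branch lengths and its additive matrix
random_additive_case <- function(ntip, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntip, rooted = FALSE,
                   br = function(n) stats::runif(n, 0.5, 2))
  tr$tip.label <- paste0("t", seq_len(ntip))
  D <- ape::cophenetic.phylo(tr)
  D <- (D + t(D)) / 2
  list(tree = tr, D = D[order(rownames(D)), order(rownames(D))])
}
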