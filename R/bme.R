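# Balanced minimum evolution: criterion and NNI hill climbing.
#
# The balanced tree-length of a topology given distances D follows
# Pauplin's weighting: L(T) = sum_{i<j} 2^(1 - p_ij) D_ij, with p_ij the
# number of edges on the tip-to-tip path. FastME's published search
# strategy (BME criterion + nearest-neighbor interchanges) is implemented
# directly; the FastME binary is not wrapped.

#' Balanced minimum evolution length of a tree
#'
#' @param tree a `phylo` object (unrooted or trifurcating-rooted).
#' @param D labelled distance matrix covering the tree's tips.
#' @return The balanced tree length (a scalar).
#' @export
bme_length <- function(tree, D) {
  tree <- ape::unroot(tree)
  labs <- tree$tip.label
  if (!all(labs %in% rownames(D)))
    stop("distance matrix is missing tree tips")
  topo <- tree
  topo$edge.length <- rep(1, nrow(topo$edge))
  p <- ape::dist.nodes(topo)[seq_along(labs), seq_along(labs)]
  Dm <- D[labs, labs]
  w <- 2 ^ (1 - p)
  diag(w) <- 0
  sum(w * Dm) / 2
}

# the two NNI neighbors around internal edge (u, v); returns list of trees
.nni_neighbors <- function(tree, u, v) {
  kids_v <- tree$edge[tree$edge[, 1L] == v, 2L]
  kids_u <- setdiff(tree$edge[tree$edge[, 1L] == u, 2L], v)
  if (length(kids_v) < 2L || length(kids_u) < 1L) return(list())
  w <- kids_u[1L]
  lapply(kids_v[1:2], function(ch) {
    tr <- tree
    tr$edge[tr$edge[, 2L] == ch, 1L] <- u
    tr$edge[tr$edge[, 2L] == w, 1L] <- v
    ape::read.tree(text = ape::write.tree(tr))  # renormalize structure
  })
}

#' Refine a tree topology under balanced minimum evolution
#'
#' Nearest-neighbor-interchange hill climbing on the balanced tree
#' length: internal edges are visited in a fixed order, the first swap
#' that strictly lowers the criterion is accepted, and sweeps repeat
#' until a local optimum. When the topology changed, branch lengths are
#' re-estimated by least squares on `D`.
#'
#' @param tree starting `phylo` tree (typically from [nj_tree()]).
#' @param D labelled distance matrix with exactly the tree's tips.
#' @return A `phylo` tree whose balanced length is less than or equal to
#'   the input's; the input object itself when no swap improves it.
#' @export
bme_refine <- function(tree, D) {
  stopifnot(inherits(tree, "phylo"))
  if (!setequal(tree$tip.label, rownames(D)))
    stop("tree tips and distance-matrix labels differ")
  cur <- ape::unroot(tree)
  cur_len <- bme_length(cur, D)
  changed <- FALSE
  repeat {
    improved <- FALSE
    ntip <- length(cur$tip.label)
    internal_edges <- which(cur$edge[, 2L] > ntip)
    for (e in internal_edges) {
      u <- cur$edge[e, 1L]; v <- cur$edge[e, 2L]
      for (nb in .nni_neighbors(cur, u, v)) {
        len <- bme_length(nb, D)
        if (len < cur_len - 1e-12) {
          cur <- nb; cur_len <- len
          improved <- TRUE; changed <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  if (!changed) return(tree)
  fitted <- phangorn::nnls.tree(as.dist(D[cur$tip.label, cur$tip.label]),
                                cur, method = "unrooted")
  fitted$edge.length[fitted$edge.length < 0] <- 0
  fitted
}

#' Annotate a tree with pseudo-bootstrap support values
#'
#' Each internal edge of the main tree receives `100 *` the fraction of
#' replicate trees containing the same (unrooted) bipartition, rounded to
#' the nearest integer and stored as the internal node label.
#'
#' @param main the tree to annotate.
#' @param replicates list of replicate trees over the same tip set.
#' @return `main` with integer supports as `node.label`.
#' @export
support_values <- function(main, replicates) {
  stopifnot(inherits(main, "phylo"))
  main <- ape::unroot(main)
  for (r in replicates)
    if (!setequal(r$tip.label, main$tip.label))
      stop("replicate tree has a different tip set")
  rep_splits <- lapply(replicates, function(t) .split_strings(t)$split)
  ms <- .split_strings(main)
  labs <- character(main$Nnode)
  B <- length(replicates)
  if (B == 0L) stop("no replicate trees given")
  for (i in seq_len(nrow(ms))) {
    hits <- sum(vapply(rep_splits, function(s) ms$split[i] %in% s,
                       logical(1L)))
    labs[ms$node[i] - length(main$tip.label)] <-
      as.character(round(100 * hits / B))
  }
  main$node.label <- labs
  main
}

# canonical informative bipartitions of a tree, one per internal edge;
# the stored block is the one NOT containing the alphabetically smallest tip
.split_strings <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  anchor <- min(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  rows <- list(); ri <- 0L
  sup <- tree_supports(tree)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2L]
    if (ch <= ntip) next
    blk <- below[[ch]]
    if (length(blk) < 2L || length(blk) > ntip - 2L) next
    if (anchor %in% blk) blk <- setdiff(tree$tip.label, blk)
    s <- sup[ch - ntip]
    ri <- ri + 1L
    rows[[ri]] <- data.frame(
      node = ch,
      split = paste(sort(blk), collapse = "\r"),
      size = length(blk),
      support = if (is.na(s)) 100 else s,
      stringsAsFactors = FALSE)
  }
  if (ri == 0L)
    return(data.frame(node = integer(0), split = character(0),
                      size = integer(0), support = numeric(0)))
  do.call(rbind, rows)
}
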