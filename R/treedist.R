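#' Informative bipartitions of a tree
#'
#' One bipartition per internal edge of the unrooted tree, in canonical
#' form: the reported block is the one not containing the alphabetically
#' smallest tip, so the representation is independent of Newick rotation
#' and rooting. Supports are taken from numeric internal node labels
#' (0-1 scales are rescaled to 0-100) and default to 100 when absent.
#'
#' @param tree a `phylo` object.
#' @return Data frame with columns `split` (tip labels joined by `"\r"`),
#'   `size` (block size) and `support`. Trees with fewer than 4 tips, and
#'   star trees, yield zero rows.
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 4L)
    return(data.frame(split = character(0), size = integer(0),
                      support = numeric(0)))
  s <- .split_strings(tree)
  s[, c("split", "size", "support")]
}

#' Robinson-Foulds distance between two trees
#'
#' Modes: `plain` is the symmetric-difference count of bipartitions;
#' `relative` divides by the total number of bipartitions in both trees
#' (range 0-1); `weighted_relative` weights every bipartition by its
#' support, i.e. the summed supports of splits unique to either tree over
#' the summed supports of all splits in both. With uniform supports the
#' weighted variant equals the relative one. Two star trees are at
#' distance 0 in the normalized modes. Input trees are unrooted before
#' comparison.
#'
#' @param t1,t2 `phylo` trees over the same tip set.
#' @param mode `"plain"`, `"relative"` or `"weighted_relative"`.
#' @return A single non-negative number.
#' @export
rf_distance <- function(t1, t2,
                        mode = c("plain", "relative", "weighted_relative")) {
  mode <- match.arg(mode)
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different tip sets")
  b1 <- bipartitions(t1)
  b2 <- bipartitions(t2)
  uniq1 <- !(b1$split %in% b2$split)
  uniq2 <- !(b2$split %in% b1$split)
  if (mode == "plain") return(sum(uniq1) + sum(uniq2))
  denom <- switch(mode,
                  relative = nrow(b1) + nrow(b2),
                  weighted_relative = sum(b1$support) + sum(b2$support))
  num <- switch(mode,
                relative = sum(uniq1) + sum(uniq2),
                weighted_relative = sum(b1$support[uniq1]) +
                  sum(b2$support[uniq2]))
  if (denom == 0) return(0)   # two star trees
  num / denom
}

#' Pairwise topological distances among a set of trees
#'
#' Tips absent from any tree are pruned from all (with a message naming
#' them) so the comparison runs on the common tip set.
#'
#' @param trees named list of `phylo` trees.
#' @param mode passed to [rf_distance()].
#' @return Labelled symmetric matrix of tree-to-tree distances.
#' @export
tree_distance_matrix <- function(trees, mode = "relative") {
  if (length(trees) < 2L) stop("need at least two trees")
  if (is.null(names(trees)) || any(names(trees) == ""))
    stop("trees must be named")
  common <- Reduce(intersect, lapply(trees, `[[`, "tip.label"))
  if (length(common) < 4L)
    stop("fewer than 4 tips shared by all trees")
  all_tips <- unique(unlist(lapply(trees, `[[`, "tip.label")))
  dropped <- setdiff(all_tips, common)
  if (length(dropped))
    message("pruning tips absent from some trees: ",
            paste(dropped, collapse = ", "))
  trees <- lapply(trees, function(t)
    if (length(t$tip.label) > length(common))
      ape::keep.tip(t, common) else t)
  n <- length(trees)
  m <- matrix(0, n, n, dimnames = list(names(trees), names(trees)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    m[i, j] <- m[j, i] <- rf_distance(trees[[i]], trees[[j]], mode = mode)
  m
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: the squared-distance matrix is double
#' centered, eigendecomposed, and coordinates are eigenvectors scaled by
#' the square root of their (non-negative) eigenvalues. Negative
#' eigenvalues, which arise for non-Euclidean distances, are reported but
#' excluded from the coordinates.
#'
#' @param D labelled symmetric distance matrix with zero diagonal.
#' @param n_axes number of axes to return (default 2).
#' @return List with `coords` (objects x axes matrix) and `eigenvalues`
#'   (all `n` eigenvalues, descending).
#' @export
pcoa <- function(D, n_axes = 2L) {
  m <- as.matrix(D)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop("pcoa needs a square symmetric matrix")
  n <- nrow(m)
  fit <- stats::cmdscale(m, k = min(n_axes, n - 1L), eig = TRUE)
  coords <- fit$points
  if (ncol(coords) < n_axes) {
    pad <- matrix(0, n, n_axes - ncol(coords))
    coords <- cbind(coords, pad)
  }
  rownames(coords) <- rownames(m)
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  list(coords = coords, eigenvalues = fit$eig)
}

#' Scatter plot of the first two principal coordinates
#'
#' @param fit result of [pcoa()].
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `fit`.
#' @export
plot_pcoa <- function(fit, ...) {
  ev <- fit$eigenvalues
  pct <- round(100 * pmax(ev, 0) / sum(pmax(ev, 0)), 1)
  graphics::plot(fit$coords[, 1L], fit$coords[, 2L],
                 xlab = sprintf("PCo1 (%.1f%%)", pct[1L]),
                 ylab = sprintf("PCo2 (%.1f%%)", pct[2L]),
                 pch = 19, ...)
  graphics::text(fit$coords[, 1L], fit$coords[, 2L],
                 labels = rownames(fit$coords), pos = 3, cex = 0.8)
  invisible(fit)
}
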