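#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining under the Q-criterion. Tie-breaking is
#' deterministic: among pairs minimizing Q, the pair whose (sorted) label
#' pair is lexicographically smallest is joined, where a merged node
#' carries the smallest label of its members. Negative branch-length
#' estimates are clamped to zero. On an exactly additive matrix the
#' generating topology and branch lengths are recovered.
#'
#' @param D labelled symmetric distance matrix, `n >= 3`, finite entries.
#' @return Unrooted `phylo` tree (stored with a trifurcating root).
#' @export
nj_tree <- function(D) {
  .check_dist_matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labs <- rownames(D)
  frag <- labs                 # newick fragment per active node
  minlab <- labs               # tie-break key per active node
  Dw <- D
  fmt <- function(x) sprintf("%.12g", max(0, x))
  while (n > 3L) {
    r <- rowSums(Dw)
    Q <- (n - 2) * Dw - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      p <- sort(c(minlab[ij[1L]], minlab[ij[2L]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    bi <- Dw[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- Dw[i, j] - bi
    newfrag <- paste0("(", frag[i], ":", fmt(bi), ",",
                      frag[j], ":", fmt(bj), ")")
    newmin <- min(minlab[i], minlab[j])
    dnew <- (Dw[i, ] + Dw[j, ] - Dw[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    Dw <- rbind(cbind(Dw[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    minlab <- c(minlab[keep], newmin)
    n <- n - 1L
  }
  x <- (Dw[1, 2] + Dw[1, 3] - Dw[2, 3]) / 2
  y <- (Dw[1, 2] + Dw[2, 3] - Dw[1, 3]) / 2
  z <- (Dw[1, 3] + Dw[2, 3] - Dw[1, 2]) / 2
  nwk <- paste0("(", frag[1], ":", fmt(x), ",", frag[2], ":", fmt(y), ",",
                frag[3], ":", fmt(z), ");")
  ape::read.tree(text = nwk)
}
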