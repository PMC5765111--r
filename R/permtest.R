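#' Tip-permutation test of phylogenetic conservation
#'
#' Each character is parsimony-scored on the tree under its original
#' tip-to-value arrangement; the tip labels are then permuted `M - 1`
#' times (uniformly at random, the identity arrangement counting as the
#' M-th permutation) and rescored. The one-sided p-value is the fraction
#' of the `M` arrangements whose score is as low or lower than the
#' original, so the smallest attainable p is `1/M`. The same permutation
#' stream is shared across characters for reproducibility. Continuous
#' characters are discretized to ordinal states first and scored under
#' linear costs; binary characters use the Fitch count.
#'
#' @param tree a `phylo` tree.
#' @param table a [character_table] whose tips equal the tree's tips.
#' @param M number of arrangements including the identity (default 10000).
#' @param seed RNG seed (required).
#' @param k_bins states used when discretizing continuous characters.
#' @param binning `"width"` or `"quantile"` (see [discretize()]).
#' @param bh also report Benjamini-Hochberg adjusted p-values (default
#'   `FALSE`; raw p-values against fixed alpha lines are the primary
#'   report).
#' @return Data frame with one row per character: `character`, `kind`,
#'   `panel`, `score` (original parsimony score), `M`, `count_le`,
#'   `p_value` (and `p_adjusted` when `bh`).
#' @export
tip_permutation_test <- function(tree, table, M = 10000L, seed,
                                 k_bins = 10L, binning = "width",
                                 bh = FALSE) {
  stopifnot(inherits(tree, "phylo"), inherits(table, "character_table"))
  if (missing(seed)) stop("seed is required")
  if (M < 2L) stop("M must be at least 2")
  if (!setequal(tree$tip.label, rownames(table)))
    stop("character table tips and tree tips differ")
  tab <- table[tree$tip.label, , drop = FALSE]
  kinds <- attr(table, "kinds")
  panels <- attr(table, "panels")
  if (is.null(panels)) panels <- rep("all", ncol(tab))
  n <- nrow(tab)
  nc <- ncol(tab)

  # encode every character as 0-based ordinal states + a cost model
  states <- matrix(NA_integer_, n, nc)
  Kvec <- integer(nc)
  costvec <- character(nc)
  for (j in seq_len(nc)) {
    k <- .parse_kind(kinds[j])
    if (k$kind == "binary") {
      states[, j] <- as.integer(tab[, j]); Kvec[j] <- 2L
      costvec[j] <- "unit"
    } else if (k$kind == "ordinal") {
      states[, j] <- as.integer(tab[, j]); Kvec[j] <- k$K
      costvec[j] <- "linear"
    } else {
      states[, j] <- discretize(tab[, j], K = k_bins, method = binning)
      Kvec[j] <- as.integer(k_bins)
      costvec[j] <- "linear"
    }
  }

  topo <- .postorder_nodes(tree)
  grp_key <- paste(Kvec, costvec)
  groups <- split(seq_len(nc), grp_key)
  # leaf cost matrices are fixed per character group; a tip permutation
  # only reassigns them to tips
  grp_leaves <- lapply(groups, function(g)
    .leaf_costs(states[, g, drop = FALSE], Kvec[g[1L]]))

  score_all <- function(perm) {
    out <- numeric(nc)
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      out[g] <- .sankoff_engine(topo, grp_leaves[[gi]][perm],
                                cost = costvec[g[1L]])
    }
    out
  }

  orig <- score_all(seq_len(n))
  count_le <- rep(1L, nc)          # the identity arrangement always counts
  set.seed(seed)
  for (b in seq_len(M - 1L)) {
    perm <- sample.int(n)
    count_le <- count_le + (score_all(perm) <= orig)
  }
  out <- data.frame(character = colnames(tab), kind = kinds,
                    panel = panels, score = orig, M = as.integer(M),
                    count_le = count_le, p_value = count_le / M,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (bh) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Summarize permutation-test results at alpha levels
#'
#' @param results data frame from [tip_permutation_test()].
#' @param alphas significance levels (default 0.01, 0.05, 0.10).
#' @return Data frame with one row per (panel, alpha): the number of
#'   characters with `p <= alpha` and their names.
#' @export
summarize_alpha <- function(results, alphas = c(0.01, 0.05, 0.10)) {
  if (is.null(results) || nrow(results) == 0L) stop("no results to summarize")
  rows <- list(); ri <- 0L
  for (pan in unique(results$panel)) {
    sub <- results[results$panel == pan, ]
    for (a in alphas) {
      sig <- sub$character[sub$p_value <= a]
      ri <- ri + 1L
      rows[[ri]] <- data.frame(panel = pan, alpha = a,
                               n_tested = nrow(sub),
                               n_significant = length(sig),
                               characters = paste(sig, collapse = ","),
                               stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Strip plot of per-character permutation p-values by panel
#'
#' Characters are arranged by panel along the x axis with their p-values
#' on the y axis; dotted lines mark the alpha levels.
#'
#' @param results data frame from [tip_permutation_test()].
#' @param alphas alpha levels to draw (default 0.01, 0.05, 0.10).
#' @return Invisibly, `results`.
#' @export
plot_conservation <- function(results, alphas = c(0.01, 0.05, 0.10)) {
  pans <- unique(results$panel)
  x <- match(results$panel, pans) +
    stats::runif(nrow(results), -0.25, 0.25)
  graphics::plot(x, results$p_value, xaxt = "n", xlab = "",
                 ylab = "permutation p-value", ylim = c(0, 1), pch = 19,
                 cex = 0.7)
  graphics::axis(1, at = seq_along(pans), labels = pans, las = 2,
                 cex.axis = 0.8)
  graphics::abline(h = alphas, lty = 3)
  invisible(results)
}
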