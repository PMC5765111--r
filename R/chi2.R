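#' Chi-squared test of association between two binary features
#'
#' Pearson's chi-squared on the 2x2 contingency table, after pairwise
#' deletion of missing values. No continuity correction is applied by
#' default; set `correct = TRUE` for the Yates-corrected statistic. A
#' table with a zero row or column margin is flagged degenerate and gets
#' no p-value.
#'
#' @param x,y binary vectors (0/1, `NA` allowed) of equal length.
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return A list: `table` (2x2 counts), `statistic`, `df`, `p_value`,
#'   `sign` (+1 positive association, -1 negative, 0 none), `n` (pairs
#'   used), `degenerate` flag.
#' @export
chi2_pair <- function(x, y, correct = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) stop("fewer than 2 complete observations")
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1)))
    stop("features must be binary 0/1")
  tab <- matrix(c(sum(x == 0 & y == 0), sum(x == 0 & y == 1),
                  sum(x == 1 & y == 0), sum(x == 1 & y == 1)),
                2L, 2L, byrow = TRUE,
                dimnames = list(x = c("0", "1"), y = c("0", "1")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(table = tab, statistic = NA_real_, df = 1L,
                p_value = NA_real_, sign = 0L, n = length(x),
                degenerate = TRUE))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(table = tab, statistic = unname(ct$statistic), df = 1L,
       p_value = ct$p.value,
       sign = sign(tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1]),
       n = length(x), degenerate = FALSE)
}

#' Chi-squared screen over all binary character pairs
#'
#' Tests every unordered pair of binary characters in the table and sorts
#' the results by p-value (degenerate pairs last). Optionally flags
#' discoveries under Benjamini-Hochberg control.
#'
#' @param table a [character_table] with at least two binary characters.
#' @param alpha significance level for flagging (default 0.05).
#' @param correct continuity correction, passed to [chi2_pair()].
#' @param bh also compute BH-adjusted p-values (default `FALSE`).
#' @return Data frame: `feature_a`, `feature_b`, counts `n00 .. n11`,
#'   `statistic`, `p_value`, `sign`, `degenerate`, `significant` (and
#'   `p_adjusted` when `bh`).
#' @export
chi2_screen <- function(table, alpha = 0.05, correct = FALSE, bh = FALSE) {
  stopifnot(inherits(table, "character_table"))
  bin <- which(attr(table, "kinds") == "binary")
  if (length(bin) < 2L) stop("need at least 2 binary characters")
  rows <- list(); ri <- 0L
  for (a in seq_along(bin)[-length(bin)])
    for (b in (a + 1L):length(bin)) {
      ja <- bin[a]; jb <- bin[b]
      res <- chi2_pair(table[, ja], table[, jb], correct = correct)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        feature_a = colnames(table)[ja], feature_b = colnames(table)[jb],
        n00 = res$table[1, 1], n01 = res$table[1, 2],
        n10 = res$table[2, 1], n11 = res$table[2, 2],
        statistic = res$statistic, p_value = res$p_value,
        sign = res$sign, degenerate = res$degenerate,
        stringsAsFactors = FALSE)
    }
  out <- do.call(rbind, rows)
  out <- out[order(out$degenerate, out$p_value), ]
  rownames(out) <- NULL
  if (bh) {
    out$p_adjusted <- NA_real_
    ok <- !out$degenerate
    out$p_adjusted[ok] <- stats::p.adjust(out$p_value[ok], method = "BH")
    out$significant <- !out$degenerate & out$p_adjusted <= alpha
  } else {
    out$significant <- !out$degenerate & out$p_value <= alpha
  }
  out
}
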