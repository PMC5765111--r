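#' GBDP intergenomic distance from a trimmed hit set
#'
#' With `N` the total number of non-identical residues within the hits and
#' `L` the overall length of the hits, the distance is the log-transformed
#' mismatch ratio `d = -ln(1 - N/L)`: zero for identical genomes and
#' increasing with divergence. With no hits (`L = 0`) or all columns
#' mismatched (`N = L`) the distance is undefined and flagged; callers
#' substitute a configured ceiling (see [distance_matrix()]).
#'
#' @param hitset a trimmed `hit_set` (see [trim_hits()]).
#' @return A list: `d` (distance, `NA` when undefined), `ratio` (`N/L`),
#'   `N`, `L`, `undefined` flag.
#' @export
gbdp_distance <- function(hitset) {
  stopifnot(inherits(hitset, "hit_set"))
  if (!isTRUE(hitset$trimmed))
    stop("gbdp_distance requires a trimmed hit_set; call trim_hits() first")
  N <- sum(hitset$hits$nid)
  L <- sum(hitset$hits$length)
  if (L == 0L || N == L)
    return(list(d = NA_real_, ratio = if (L) N / L else NA_real_,
                N = N, L = L, undefined = TRUE))
  list(d = -log(1 - N / L), ratio = N / L, N = N, L = L, undefined = FALSE)
}

#' Pairwise GBDP distance matrix over a set of genomes
#'
#' Runs [find_hits()], [trim_hits()] and [gbdp_distance()] for every
#' unordered pair. Undefined pairs (no surviving hits) receive the `d_max`
#' ceiling with a warning, or raise an error when `d_max` is `NULL`.
#'
#' @param genomes list of [seq_set] objects with unique strain ids and a
#'   common alphabet.
#' @param k,x_drop,min_len,min_score passed to [find_hits()].
#' @param d_max substitute distance for undefined pairs (default 5.0);
#'   `NULL` to make an undefined pair an error.
#' @return Symmetric labelled distance matrix, zero diagonal. Attributes:
#'   `hitsets` (named list of trimmed hit sets, keys `"A|B"`) and
#'   `details` (data frame of per-pair `d`, `ratio`, `N`, `L`,
#'   `undefined`).
#' @export
distance_matrix <- function(genomes, k = NULL, x_drop = 20, min_len = 10L,
                            min_score = 30, d_max = 5.0) {
  if (length(genomes) < 2L) stop("need at least two genomes")
  stopifnot(all(vapply(genomes, inherits, logical(1L), "seq_set")))
  ids <- vapply(genomes, `[[`, character(1L), "strain_id")
  if (anyDuplicated(ids)) stop("duplicate strain id: ",
                               ids[duplicated(ids)][1L])
  n <- length(genomes)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  alph <- unique(vapply(genomes, `[[`, character(1L), "alphabet"))
  if (length(alph) > 1L) stop("genomes mix alphabets")
  if (is.null(k)) k <- if (alph == "protein") 6L else 11L
  sm <- .subst_matrix(alph)
  idx <- lapply(genomes, .kmer_index, k = k, sm = sm)
  hitsets <- list()
  det <- list(); di <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    hs <- trim_hits(.find_hits_idx(genomes[[i]], genomes[[j]],
                                   idx[[i]], idx[[j]], sm,
                                   x_drop = x_drop, min_len = min_len,
                                   min_score = min_score))
    res <- gbdp_distance(hs)
    d <- res$d
    if (res$undefined) {
      if (is.null(d_max))
        stop("undefined distance for pair ", ids[i], " / ", ids[j])
      warning("undefined distance for pair ", ids[i], " / ", ids[j],
              "; substituting d_max = ", d_max)
      d <- d_max
    }
    m[i, j] <- m[j, i] <- d
    hitsets[[paste(ids[i], ids[j], sep = "|")]] <- hs
    di <- di + 1L
    det[[di]] <- data.frame(a = ids[i], b = ids[j], d = d, ratio = res$ratio,
                            N = res$N, L = res$L, undefined = res$undefined,
                            stringsAsFactors = FALSE)
  }
  attr(m, "hitsets") <- hitsets
  attr(m, "details") <- do.call(rbind, det)
  m
}

#' Pseudo-bootstrap replicate distance matrices
#'
#' For each replicate and each genome pair, the pair's trimmed hits are
#' resampled with replacement (keeping the hit count) and the distance is
#' recomputed from the resampled totals. Pairs without hits inherit the
#' `d_max` ceiling in every replicate.
#'
#' @param dm a distance matrix from [distance_matrix()] (carrying stored
#'   hit sets), or a named list of trimmed hit sets with keys `"A|B"`.
#' @param B number of replicates (default 100).
#' @param seed RNG seed (required).
#' @param d_max ceiling for undefined replicate distances.
#' @return List of `B` symmetric distance matrices.
#' @export
pseudo_bootstrap <- function(dm, B = 100L, seed, d_max = 5.0) {
  if (missing(seed)) stop("seed is required")
  hitsets <- if (is.matrix(dm)) attr(dm, "hitsets") else dm
  if (is.null(hitsets) || !length(hitsets))
    stop("no stored hit sets; run distance_matrix() first")
  pairs <- strsplit(names(hitsets), "|", fixed = TRUE)
  ids <- unique(unlist(pairs))
  n <- length(ids)
  set.seed(seed)
  reps <- vector("list", B)
  # per pair, precompute hit columns
  for (b in seq_len(B)) {
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    for (p in seq_along(hitsets)) {
      h <- hitsets[[p]]$hits
      if (nrow(h) == 0L) {
        d <- d_max
      } else {
        idx <- sample.int(nrow(h), nrow(h), replace = TRUE)
        N <- sum(h$nid[idx]); L <- sum(h$length[idx])
        d <- if (L == 0L || N == L) d_max else -log(1 - N / L)
      }
      i <- pairs[[p]][1L]; j <- pairs[[p]][2L]
      m[i, j] <- m[j, i] <- d
    }
    reps[[b]] <- m
  }
  reps
}

#' Digital DDH estimate from a GBDP distance
#'
#' The default mapping is an exponential decay anchored so that identical
#' genomes map to 100% and the species-boundary distance `d70` maps to
#' exactly the recommended 70% cut-off: `ddh(d) = 100 * exp(lambda * d)`
#' with `lambda = ln(0.70) / d70`. The screening rule that motivates the
#' default anchor is that pairs with distance below 0.09 are close enough
#' to warrant a DDH comparison. Any other mapping (for example a published
#' regression of wet-lab DDH on distance) can be plugged in as a function.
#'
#' @param d distance value, vector or matrix (non-negative).
#' @param d70 distance mapped to 70% (default 0.09).
#' @param mapping `"expdecay"` or a function `d -> percentage`.
#' @return dDDH percentage(s) in (0, 100].
#' @export
ddh_estimate <- function(d, d70 = 0.09, mapping = "expdecay") {
  if (any(d < 0, na.rm = TRUE)) stop("distances must be non-negative")
  if (is.function(mapping)) return(mapping(d))
  if (!identical(mapping, "expdecay")) stop("unknown mapping: ", mapping)
  100 * exp(log(0.70) / d70 * d)
}

#' Delineate genomic species from a dDDH matrix
#'
#' Two strains belong to the same genomic species when their dDDH is at
#' or above the threshold (default 70%); species are the connected
#' components of the resulting graph, so membership is transitive.
#'
#' @param ddh_matrix symmetric matrix of dDDH percentages in \[0, 100\].
#' @param threshold species boundary (default 70).
#' @return Named integer vector: species index per strain. Components are
#'   numbered by the alphabetical order of their first member, so the
#'   partition does not depend on input strain order.
#' @export
delineate_species <- function(ddh_matrix, threshold = 70) {
  m <- as.matrix(ddh_matrix)
  if (is.null(rownames(m))) stop("ddh matrix must be labelled")
  if (any(m < 0 | m > 100, na.rm = TRUE))
    stop("dDDH values must lie in [0, 100]")
  n <- nrow(m)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (!is.na(m[i, j]) && m[i, j] >= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  roots <- vapply(seq_len(n), find, integer(1L))
  labs <- rownames(m)
  # canonical numbering: order components by their alphabetically first member
  first_member <- vapply(unique(roots), function(r)
    min(labs[roots == r]), character(1L))
  comp_order <- unique(roots)[order(first_member)]
  out <- match(roots, comp_order)
  names(out) <- labs
  out
}
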