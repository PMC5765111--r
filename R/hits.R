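# Ungapped local-alignment hits between two sequence sets.
#
# Hits are found by exact k-mer seeding followed by ungapped X-drop
# extension under a substitution matrix (BLOSUM62 for protein, +1/-2 for
# DNA), the deterministic desk-scale counterpart of a BLASTP/BLASTN HSP
# search. Coordinates are 0-based, half-open, and hits are strictly
# diagonal: q_end - q_start == s_end - s_start == length.

.subst_matrix <- function(alphabet) {
  if (alphabet == "protein") {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    return(e$BLOSUM62)
  }
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(-2, 5L, 5L, dimnames = list(letters, letters))
  diag(m) <- 1
  m["N", ] <- -2; m[, "N"] <- -2   # ambiguous base never counts as a match
  m
}

# per-genome search index: k-mer occurrences plus integer-coded residues
.kmer_index <- function(x, k, sm = .subst_matrix(x$alphabet)) {
  recs <- integer(0); offs <- integer(0); kmers <- character(0)
  codes <- vector("list", length(x$sequences))
  ab <- rownames(sm)
  for (i in seq_along(x$sequences)) {
    s <- x$sequences[[i]]
    n <- nchar(s)
    codes[[i]] <- match(strsplit(s, "", fixed = TRUE)[[1L]], ab)
    if (n < k) next
    st <- seq_len(n - k + 1L)
    kmers <- c(kmers, substring(s, st, st + k - 1L))
    recs <- c(recs, rep.int(i, length(st)))
    offs <- c(offs, st - 1L)
  }
  map <- split(seq_along(kmers), kmers)
  list(rec = recs, off = offs, kmer = kmers, map = map, codes = codes,
       k = k)
}

#' Find ungapped local-alignment hits between two sequence sets
#'
#' Exact `k`-mer seed matches are extended without gaps in both directions
#' under X-drop termination; extension from a seed stops once the running
#' score falls more than `x_drop` below the best score seen, and the hit
#' is the maximal-scoring stretch. Hits shorter than `min_len` or scoring
#' below `min_score` are discarded; seeds falling inside an already
#' accepted hit on the same diagonal are skipped, so duplicate hits with
#' identical coordinates are merged.
#'
#' @param a,b [seq_set] objects sharing an alphabet.
#' @param k seed length (default 6 for protein, 11 for DNA).
#' @param x_drop X-drop termination threshold in score units.
#' @param min_len minimum hit length retained.
#' @param min_score minimum hit score retained.
#' @return An object of class `hit_set`: strain ids, a data frame of hits
#'   (`qrec`, `srec`, record ids; `qs`, `qe`, `ss`, `se` 0-based half-open
#'   coordinates; `length`; `nid` non-identical columns; `score`), and the
#'   encoded sequences needed to recount columns after trimming.
#' @export
find_hits <- function(a, b, k = NULL, x_drop = 20, min_len = 10L,
                      min_score = 30) {
  stopifnot(inherits(a, "seq_set"), inherits(b, "seq_set"))
  if (a$alphabet != b$alphabet)
    stop("alphabet mismatch: ", a$alphabet, " vs ", b$alphabet)
  if (is.null(k)) k <- if (a$alphabet == "protein") 6L else 11L
  sm <- .subst_matrix(a$alphabet)
  .find_hits_idx(a, b, .kmer_index(a, k, sm), .kmer_index(b, k, sm),
                 sm, x_drop, min_len, min_score)
}

.find_hits_idx <- function(a, b, ia, ib, sm, x_drop, min_len, min_score) {
  k <- ia$k
  rows <- list(); nrows <- 0L
  if (length(ia$kmer) && length(ib$kmer)) {
    amap <- ia$map
    bmap <- ib$map
    shared <- intersect(names(amap), names(bmap))
    if (length(shared)) {
      al <- amap[match(shared, names(amap))]   # positional, O(1) access
      bl <- bmap[match(shared, names(bmap))]
      na <- lengths(al); nb <- lengths(bl)
      ai <- unlist(mapply(function(x, times) rep(x, each = times),
                          al, nb, SIMPLIFY = FALSE), use.names = FALSE)
      bi <- unlist(mapply(function(x, times) rep.int(x, times),
                          bl, na, SIMPLIFY = FALSE), use.names = FALSE)
      arec <- ia$rec[ai]; brec <- ib$rec[bi]
      adiag <- ia$off[ai] - ib$off[bi]
      key <- paste(arec, brec, adiag)
      groups <- split(seq_along(key), key)
      for (g in groups) {
        h <- .extend_diagonal(
          qrec = arec[g[1L]], srec = brec[g[1L]], diag = adiag[g[1L]],
          seed_q = sort(unique(ia$off[ai[g]])),
          ca_full = ia$codes[[arec[g[1L]]]],
          cb_full = ib$codes[[brec[g[1L]]]],
          k = k, sm = sm, x_drop = x_drop)
        if (length(h)) { nrows <- nrows + 1L; rows[[nrows]] <- h }
      }
    }
  }
  hits <- .assemble_hits(rows, a, b, min_len, min_score)
  structure(list(genome_a = a$strain_id, genome_b = b$strain_id,
                 hits = hits, alphabet = a$alphabet,
                 codes_a = ia$codes, codes_b = ib$codes, sm = sm,
                 rec_names_a = names(a$sequences),
                 rec_names_b = names(b$sequences),
                 params = list(k = k, x_drop = x_drop, min_len = min_len,
                               min_score = min_score),
                 trimmed = FALSE),
            class = "hit_set")
}

.assemble_hits <- function(rows, a, b, min_len, min_score) {
  if (!length(rows)) return(.empty_hits())
  m <- do.call(rbind, rows)
  keep <- m[, "length"] >= min_len & m[, "score"] >= min_score
  m <- m[keep, , drop = FALSE]
  if (!nrow(m)) return(.empty_hits())
  m <- m[!duplicated(m[, c("qrec", "srec", "qs", "ss"), drop = FALSE]), ,
         drop = FALSE]
  h <- data.frame(qrec = names(a$sequences)[m[, "qrec"]],
                  srec = names(b$sequences)[m[, "srec"]],
                  qs = as.integer(m[, "qs"]), qe = as.integer(m[, "qe"]),
                  ss = as.integer(m[, "ss"]), se = as.integer(m[, "se"]),
                  length = as.integer(m[, "length"]),
                  nid = as.integer(m[, "nid"]), score = m[, "score"],
                  stringsAsFactors = FALSE)
  h <- h[order(h$qrec, h$srec, h$qs, h$ss), , drop = FALSE]
  rownames(h) <- NULL
  h
}

.empty_hits <- function() {
  data.frame(qrec = character(0), srec = character(0),
             qs = integer(0), qe = integer(0),
             ss = integer(0), se = integer(0),
             length = integer(0), nid = integer(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

# Extend every seed on one (query record, subject record) diagonal.
# seed_q: sorted 0-based query offsets of the seeds. Returns a numeric
# matrix with one row per accepted hit.
.extend_diagonal <- function(qrec, srec, diag, seed_q, ca_full, cb_full,
                             k, sm, x_drop) {
  la <- length(ca_full); lb <- length(cb_full)
  q0 <- max(0L, diag)            # first aligned query position (0-based)
  q1 <- min(la, lb + diag)       # one past the last aligned query position
  ca <- ca_full[(q0 + 1L):q1]
  cb <- cb_full[(q0 - diag + 1L):(q1 - diag)]
  v <- sm[cbind(ca, cb)]
  ident <- ca == cb
  n <- length(v)
  out <- matrix(0, length(seed_q), 9L)
  colnames(out) <- c("qrec", "srec", "qs", "qe", "ss", "se",
                     "length", "nid", "score")
  ri <- 0L
  last_end <- -1L
  for (sq in seed_q) {
    i0 <- sq - q0 + 1L           # seed start, 1-based within the diagonal
    i1 <- i0 + k - 1L
    if (i0 <= last_end) next
    r_end <- i1
    if (i1 < n) {
      cum <- cumsum(v[(i1 + 1L):n])
      run_max <- cummax(cum)
      stop_at <- which(run_max - cum > x_drop)
      lim <- if (length(stop_at)) stop_at[1L] - 1L else length(cum)
      if (lim > 0L) {
        wb <- which.max(cum[seq_len(lim)])
        if (cum[wb] > 0) r_end <- i1 + wb
      }
    }
    l_start <- i0
    if (i0 > 1L) {
      cum <- cumsum(v[(i0 - 1L):1L])
      run_max <- cummax(cum)
      stop_at <- which(run_max - cum > x_drop)
      lim <- if (length(stop_at)) stop_at[1L] - 1L else length(cum)
      if (lim > 0L) {
        wb <- which.max(cum[seq_len(lim)])
        if (cum[wb] > 0) l_start <- i0 - wb
      }
    }
    ri <- ri + 1L
    qs <- q0 + l_start - 1L
    qe <- q0 + r_end
    out[ri, ] <- c(qrec, srec, qs, qe, qs - diag, qe - diag,
                   r_end - l_start + 1L,
                   sum(!ident[l_start:r_end]),
                   sum(v[l_start:r_end]))
    last_end <- r_end
  }
  if (ri == 0L) return(numeric(0))
  out[seq_len(ri), , drop = FALSE]
}

#' @export
print.hit_set <- function(x, ...) {
  cat(sprintf("<hit_set> %s vs %s: %d hit(s)%s\n", x$genome_a, x$genome_b,
              nrow(x$hits), if (x$trimmed) " (trimmed)" else ""))
  invisible(x)
}

#' Resolve overlapping hits by greedy trimming
#'
#' Hits are processed in descending score (ties broken by descending
#' length, then lexicographic coordinates). Each accepted hit claims its
#' query and subject intervals; later hits lose any column whose query or
#' subject position is already claimed. Surviving runs of columns shorter
#' than `min_len` are dropped; the non-identical count and score of a
#' trimmed hit are recomputed over its surviving columns. The result
#' satisfies the GBDP non-overlap requirement: no two hits share a query
#' or subject position.
#'
#' @param hitset a `hit_set` from [find_hits()].
#' @param min_len minimum surviving fragment length (defaults to the
#'   value used when finding hits).
#' @return A trimmed `hit_set`.
#' @export
trim_hits <- function(hitset, min_len = NULL) {
  stopifnot(inherits(hitset, "hit_set"))
  if (is.null(min_len)) min_len <- hitset$params$min_len
  h <- hitset$hits
  out <- hitset
  if (nrow(h) == 0L) { out$trimmed <- TRUE; return(out) }
  sm <- hitset$sm
  ord <- order(-h$score, -h$length, h$qrec, h$srec, h$qs, h$ss)
  h <- h[ord, , drop = FALSE]
  qcov <- lapply(hitset$codes_a, function(s) logical(length(s)))
  scov <- lapply(hitset$codes_b, function(s) logical(length(s)))
  names(qcov) <- hitset$rec_names_a
  names(scov) <- hitset$rec_names_b
  kept <- list(); ki <- 0L
  for (i in seq_len(nrow(h))) {
    qr <- h$qrec[i]; sr <- h$srec[i]
    qidx <- (h$qs[i] + 1L):h$qe[i]       # 1-based positions
    sidx <- (h$ss[i] + 1L):h$se[i]
    free <- !qcov[[qr]][qidx] & !scov[[sr]][sidx]
    if (!any(free)) next
    runs <- rle(free)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (j in which(runs$values)) {
      len <- runs$lengths[j]
      if (len < min_len) next
      cols <- starts[j]:ends[j]
      qa <- qidx[cols]; sb <- sidx[cols]
      ca <- hitset$codes_a[[match(qr, hitset$rec_names_a)]][qa]
      cb <- hitset$codes_b[[match(sr, hitset$rec_names_b)]][sb]
      vv <- sm[cbind(ca, cb)]
      ki <- ki + 1L
      kept[[ki]] <- data.frame(
        qrec = qr, srec = sr,
        qs = qa[1L] - 1L, qe = qa[len], ss = sb[1L] - 1L, se = sb[len],
        length = len, nid = sum(ca != cb), score = sum(vv),
        stringsAsFactors = FALSE)
      qcov[[qr]][qa] <- TRUE
      scov[[sr]][sb] <- TRUE
    }
  }
  res <- if (ki) do.call(rbind, kept) else .empty_hits()
  res <- res[order(res$qrec, res$srec, res$qs, res$ss), , drop = FALSE]
  rownames(res) <- NULL
  out$hits <- res
  out$trimmed <- TRUE
  out
}
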