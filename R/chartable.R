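#' Character tables
#'
#' A `character_table` is a tips-by-characters numeric matrix with a
#' declared kind per character: `"binary"` (states 0/1), `"ordinal(K)"`
#' (integer states 0..K-1, ordered) or `"continuous"`. Missing values
#' (`NA`) are allowed; every character needs at least one observation.
#'
#' @param values numeric matrix or data frame, rows = tips (rownames
#'   required), columns = characters (colnames required).
#' @param kinds character vector of kind tokens, one per column.
#' @param panels optional character vector assigning each character to a
#'   display panel (e.g. "fatty acids", "COGs").
#' @return An object of class `character_table`: the numeric matrix with
#'   attributes `kinds` and `panels`.
#' @export
character_table <- function(values, kinds, panels = NULL) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("values must carry tip rownames and character colnames")
  if (anyDuplicated(rownames(m))) stop("duplicate tip labels")
  if (anyDuplicated(colnames(m))) stop("duplicate character labels")
  if (length(kinds) != ncol(m))
    stop("need one kind per character column")
  parsed <- lapply(kinds, .parse_kind)
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    obs <- v[!is.na(v)]
    if (length(obs) == 0L)
      stop("character '", colnames(m)[j], "' has no observed values")
    k <- parsed[[j]]
    if (k$kind == "binary" && !all(obs %in% c(0, 1)))
      stop("character '", colnames(m)[j], "' declared binary but contains ",
           obs[!obs %in% c(0, 1)][1L])
    if (k$kind == "ordinal" &&
        (!all(obs == round(obs)) || any(obs < 0) || any(obs > k$K - 1)))
      stop("character '", colnames(m)[j], "' declared ordinal(", k$K,
           ") but contains a value outside 0..", k$K - 1)
    if (k$kind == "continuous" && any(!is.finite(obs)))
      stop("character '", colnames(m)[j], "' contains non-finite values")
  }
  if (!is.null(panels) && length(panels) != ncol(m))
    stop("need one panel label per character")
  structure(m, kinds = as.character(kinds), panels = panels,
            class = c("character_table", "matrix", "array"))
}

.parse_kind <- function(tok) {
  if (tok == "binary") return(list(kind = "binary", K = 2L))
  if (tok == "continuous") return(list(kind = "continuous", K = NA_integer_))
  mm <- regmatches(tok, regexec("^ordinal\\(([0-9]+)\\)$", tok))[[1L]]
  if (length(mm) == 2L) {
    K <- as.integer(mm[2L])
    if (K < 2L) stop("ordinal kind needs K >= 2")
    return(list(kind = "ordinal", K = K))
  }
  stop("unknown character kind token: '", tok, "'")
}

#' @export
print.character_table <- function(x, ...) {
  cat(sprintf("<character_table> %d tips x %d characters (%s)\n",
              nrow(x), ncol(x),
              paste(names(table(attr(x, "kinds"))), collapse = ", ")))
  invisible(x)
}

#' Read / write a character table as TSV
#'
#' The file has two header rows: the first names the characters (first
#' cell is the tip-column header, conventionally `tip`), the second
#' declares their kinds (`binary`, `ordinal(K)` or `continuous`; first
#' cell is ignored, conventionally `kind`). An optional third header row
#' starting with `panel` assigns display panels. Data rows are tip label
#' plus values; missing values are written `NA`.
#'
#' @param path input file.
#' @return A [character_table].
#' @export
read_character_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3L) stop("character table needs 2 header rows and data")
  split_row <- function(s) strsplit(s, "\t", fixed = TRUE)[[1L]]
  header <- split_row(lines[1L])
  kinds <- split_row(lines[2L])[-1L]
  chars <- header[-1L]
  body_start <- 3L
  panels <- NULL
  third <- split_row(lines[3L])
  if (identical(third[1L], "panel")) {
    panels <- third[-1L]
    body_start <- 4L
  }
  rows <- lapply(lines[body_start:length(lines)], split_row)
  tips <- vapply(rows, `[`, character(1L), 1L)
  vals <- t(vapply(rows, function(r) {
    v <- r[-1L]
    if (length(v) != length(chars))
      stop("row '", r[1L], "': expected ", length(chars), " values")
    suppressWarnings(ifelse(v == "NA", NA_real_, as.numeric(v)))
  }, numeric(length(chars))))
  if (length(chars) == 1L) vals <- matrix(vals, ncol = 1L)
  dimnames(vals) <- list(tips, chars)
  character_table(vals, kinds, panels = panels)
}

#' @rdname read_character_table
#' @param x a [character_table].
#' @return `path`, invisibly.
#' @export
write_character_table <- function(x, path) {
  stopifnot(inherits(x, "character_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("tip", colnames(x)), collapse = "\t"), con)
  writeLines(paste(c("kind", attr(x, "kinds")), collapse = "\t"), con)
  if (!is.null(attr(x, "panels")))
    writeLines(paste(c("panel", attr(x, "panels")), collapse = "\t"), con)
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]
    txt <- ifelse(is.na(v), "NA", formatC(v, digits = 10, format = "g"))
    writeLines(paste(c(rownames(x)[i], txt), collapse = "\t"), con)
  }
  invisible(path)
}
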