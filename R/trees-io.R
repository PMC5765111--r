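#' Read a Newick tree
#'
#' Trees are handled throughout the package as \pkg{ape} `phylo` objects.
#' Numeric internal node labels are interpreted as branch support values
#' (the FastME/RAxML convention), accessible via [tree_supports()].
#'
#' @param x a Newick string (containing `(` and terminated by `;`) or the
#'   path of a file holding one.
#' @return A `phylo` object.
#' @export
read_newick <- function(x) {
  is_text <- grepl("\\(", x) && grepl(";", x)
  tr <- tryCatch(
    if (is_text) ape::read.tree(text = x) else ape::read.tree(file = x),
    error = function(e) stop("malformed Newick: ", conditionMessage(e)),
    warning = function(w) stop("malformed Newick: ", conditionMessage(w)))
  if (is.null(tr)) stop("malformed Newick input")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip label: ", tr$tip.label[duplicated(tr$tip.label)][1L])
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch length in tree")
  tr
}

#' Write a tree as Newick
#'
#' Support values present as internal node labels are preserved.
#'
#' @param tree a `phylo` object.
#' @param path optional output file; when `NULL` the Newick string is
#'   returned instead.
#' @return The Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Per-internal-node support values of a tree
#'
#' Internal node labels that parse as numbers are returned as supports;
#' non-numeric or absent labels yield `NA`. Supports on a 0-1 scale are
#' rescaled to 0-100 (detected when every numeric label is <= 1).
#'
#' @param tree a `phylo` object.
#' @param rescale rescale 0-1 supports to 0-100 (default `TRUE`).
#' @return Numeric vector of length `tree$Nnode`.
#' @export
tree_supports <- function(tree, rescale = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  sup <- suppressWarnings(as.numeric(tree$node.label))
  if (rescale && any(!is.na(sup)) && all(sup[!is.na(sup)] <= 1))
    sup <- sup * 100
  sup
}

#' Root a tree for display
#'
#' Trees are inferred and compared unrooted; rooting is a display choice.
#' `"midpoint"` roots at the midpoint of the longest tip-to-tip path,
#' `"outgroup"` on the branch leading to the named tip(s), `"none"`
#' returns the tree unchanged.
#'
#' @param tree a `phylo` object.
#' @param method `"none"`, `"midpoint"` or `"outgroup"`.
#' @param outgroup tip label(s), required for `method = "outgroup"`.
#' @return A `phylo` tree.
#' @export
root_tree <- function(tree, method = c("none", "midpoint", "outgroup"),
                      outgroup = NULL) {
  method <- match.arg(method)
  switch(method,
         none = tree,
         midpoint = phangorn::midpoint(tree),
         outgroup = {
           if (is.null(outgroup)) stop("outgroup labels required")
           if (!all(outgroup %in% tree$tip.label))
             stop("outgroup tip not in tree: ",
                  setdiff(outgroup, tree$tip.label)[1L])
           ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
         })
}

#' Read / write a square PHYLIP distance matrix
#'
#' The format is a count line followed by one row per label: the label and
#' its full row of distances. The matrix must be square, symmetric within
#' `1e-6`, and have a zero diagonal; it is exactly symmetrized on read.
#'
#' @param path input file.
#' @return A labelled symmetric numeric matrix.
#' @export
read_phylip_distances <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) stop("first line must be the taxon count")
  if (length(lines) != n + 1L)
    stop("expected ", n, " matrix rows, found ", length(lines) - 1L)
  labs <- character(n)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1L]]
    if (length(tok) != n + 1L)
      stop("row ", i, ": expected label plus ", n, " values")
    labs[i] <- tok[1L]
    m[i, ] <- as.numeric(tok[-1L])
  }
  if (anyNA(m)) stop("non-numeric distance entry")
  if (anyDuplicated(labs)) stop("duplicate labels in distance matrix")
  if (any(abs(diag(m)) > 0)) stop("nonzero diagonal in distance matrix")
  if (max(abs(m - t(m))) > 1e-6)
    stop("matrix asymmetric beyond 1e-6")
  m <- (m + t(m)) / 2
  dimnames(m) <- list(labs, labs)
  m
}

#' @rdname read_phylip_distances
#' @param m labelled symmetric matrix.
#' @param digits printed precision.
#' @return `path`, invisibly.
#' @export
write_phylip_distances <- function(m, path, digits = 9L) {
  .check_dist_matrix(m)
  labs <- rownames(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(labs[i], formatC(m[i, ], digits = digits,
                                        format = "g")), collapse = " "), con)
  invisible(path)
}

.check_dist_matrix <- function(m, tol = 1e-12) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("distance matrix must be square")
  if (is.null(rownames(m))) stop("distance matrix must be labelled")
  if (any(!is.finite(m))) stop("non-finite distance entries")
  if (max(abs(m - t(m))) > tol) stop("distance matrix must be symmetric")
  if (any(diag(m) != 0)) stop("distance matrix diagonal must be zero")
  if (any(m < 0)) stop("negative distances")
  invisible(TRUE)
}
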