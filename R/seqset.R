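#' Sequence sets
#'
#' A `seq_set` holds the residue sequences of one strain (its proteome or
#' genome assembly): a named character vector of uppercase sequences, a
#' strain identifier, and a declared alphabet. All pairwise-distance
#' machinery in the package consumes this type.
#'
#' @param sequences named character vector of residue strings.
#' @param strain_id single string identifying the strain.
#' @param alphabet `"protein"` or `"dna"`.
#' @return An object of class `seq_set`.
#' @export
seq_set <- function(sequences, strain_id, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (length(sequences) == 0L) stop("seq_set must contain at least one sequence")
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("every sequence needs a record id")
  if (anyDuplicated(names(sequences)))
    stop("duplicate record id: ", names(sequences)[duplicated(names(sequences))][1L])
  sequences <- toupper(sequences)
  if (any(nchar(sequences) == 0L))
    stop("empty sequence for record ", names(sequences)[nchar(sequences) == 0L][1L])
  .check_alphabet(sequences, alphabet)
  structure(list(strain_id = as.character(strain_id),
                 sequences = sequences,
                 alphabet = alphabet),
            class = "seq_set")
}

.legal_chars <- list(
  protein = c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
              "S","T","V","W","Y","X"),
  dna = c("A","C","G","T","N"))

.check_alphabet <- function(sequences, alphabet) {
  legal <- .legal_chars[[alphabet]]
  for (id in names(sequences)) {
    ch <- strsplit(sequences[[id]], "", fixed = TRUE)[[1L]]
    bad <- which(!(ch %in% legal))
    if (length(bad))
      stop(sprintf("illegal %s residue '%s' in record '%s' at position %d",
                   alphabet, ch[bad[1L]], id, bad[1L]))
  }
  invisible(TRUE)
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("<seq_set> strain '%s': %d %s sequence(s), %d residues total\n",
              x$strain_id, length(x$sequences), x$alphabet,
              sum(nchar(x$sequences))))
  invisible(x)
}

#' Read a multi-FASTA file into a sequence set
#'
#' Record ids are the first whitespace-delimited token of each header;
#' residues are uppercased and validated against the declared alphabet
#' (ambiguity codes `X` for protein, `N` for DNA are accepted).
#'
#' @param path path to a FASTA file.
#' @param alphabet `"protein"` or `"dna"`.
#' @param strain_id strain label; defaults to the file name without extension.
#' @return A [seq_set].
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna"), strain_id = NULL) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  ids <- vapply(strsplit(names(ss), "[ \t]"), `[`, character(1L), 1L)
  seqs <- as.character(ss)
  names(seqs) <- ids
  if (is.null(strain_id))
    strain_id <- sub("\\.[^.]*$", "", basename(path))
  seq_set(seqs, strain_id = strain_id, alphabet = alphabet)
}

#' Write a sequence set as multi-FASTA
#'
#' @param x a [seq_set].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "seq_set"))
  ss <- Biostrings::BStringSet(x$sequences)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Genome size and G+C content
#'
#' Size is the total residue count over all records. For DNA input the
#' G+C content is `100 * (G + C) / (A + C + G + T)` with ambiguous bases
#' (`N`) excluded from numerator and denominator, rounded to one decimal
#' as customary in taxonomic descriptions.
#'
#' @param x a [seq_set].
#' @return A list with `size` (residues) and, for DNA, `gc_percent`.
#' @export
genome_stats <- function(x) {
  stopifnot(inherits(x, "seq_set"))
  size <- sum(nchar(x$sequences))
  if (x$alphabet != "dna")
    return(list(size = size, gc_percent = NULL))
  counts <- rowSums(vapply(
    x$sequences,
    function(s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1L]]
      c(A = sum(ch == "A"), C = sum(ch == "C"),
        G = sum(ch == "G"), T = sum(ch == "T"))
    }, numeric(4L)))
  acgt <- sum(counts)
  if (acgt == 0L) stop("no unambiguous bases; G+C content undefined")
  list(size = size,
       gc_percent = round(100 * (counts[["G"]] + counts[["C"]]) / acgt, 1L))
}
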