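#' Read DNA sequences from a FASTA file
#'
#' Reads a multi-FASTA file into a named character vector of upper-case DNA
#' sequences (a "sequence set"). Record ids are the first whitespace-separated
#' token of each header and must be unique. Sequences may contain IUPAC
#' ambiguity codes (including \code{N}); these are retained but reported with
#' a warning, because ambiguous positions cannot take part in match counting
#' and are skipped by the k-mer filters downstream.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgtACGT", ">b", "GGGGCCCC"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ",
                                           path, " (", conditionMessage(e), ")"))
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  bad <- vapply(seqs, function(s)
    any(!strsplit(s, "")[[1]] %in% IUPAC_CODES), logical(1))
  if (any(bad))
    stop("non-nucleotide characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  if (any(nchar(seqs) < 1L))
    stop("empty sequence in record(s): ",
         paste(ids[nchar(seqs) < 1L], collapse = ", "))
  ambig <- vapply(seqs, function(s)
    any(!strsplit(s, "")[[1]] %in% DNA_BASES), logical(1))
  if (any(ambig))
    warning("ambiguity codes present in record(s): ",
            paste(ids[ambig], collapse = ", "),
            "; affected k-mers will be excluded from the graph")
  seqs
}

#' Write a sequence set to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Nucleotide composition of a DNA string
#'
#' Returns the relative frequency of each of A, C, G, T in `text`. This is
#' the distribution \eqn{\{p(b)\}} entering the sum-of-squared-distance (SSD)
#' comparison between a candidate site and its background.
#'
#' @param text A DNA string over \{A,C,G,T\} of length >= 1.
#' @return Named numeric vector of length 4 (A, C, G, T) summing to 1.
#' @examples
#' base_frequencies("ACGTACGT")
#' base_frequencies("AACG")
#' @export
base_frequencies <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nchar(text) >= 1L)
  chars <- strsplit(text, "")[[1]]
  idx <- match(chars, DNA_BASES)
  if (anyNA(idx))
    stop("base_frequencies: non-ACGT character(s): ",
         paste(unique(chars[is.na(idx)]), collapse = ", "))
  counts <- tabulate(idx, nbins = 4L)
  setNames(counts / length(chars), DNA_BASES)
}

# Pooled A/C/G/T composition of a sequence set, ignoring ambiguity codes.
pooled_base_frequencies <- function(seqs) {
  chars <- strsplit(paste(seqs, collapse = ""), "")[[1]]
  idx <- match(chars, DNA_BASES)
  counts <- tabulate(idx[!is.na(idx)], nbins = 4L)
  if (sum(counts) == 0L) stop("no unambiguous bases in input sequences")
  setNames(counts / sum(counts), DNA_BASES)
}

# Reverse complement of character DNA sequences.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
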