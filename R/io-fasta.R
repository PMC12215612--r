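#' Read a FASTA file as a named character vector
#'
#' Sequences are upper-cased. Duplicate record ids and empty sequences are
#' errors.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector id -> sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("cannot read FASTA file: %s", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stopf("duplicate FASTA id: %s", ids[duplicated(ids)][1L])
  }
  seqs <- toupper(as.character(ss))
  empty <- !nzchar(seqs)
  if (any(empty)) stopf("empty sequence for FASTA record '%s'", ids[empty][1L])
  setNames(seqs, ids)
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector id -> sequence.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- names(seqs)
  write_atomic(function(tmp) Biostrings::writeXStringSet(ss, tmp, width = width), path)
}

#' Write a data.frame as a tab-separated file
#'
#' Header row, tab-separated, newline-terminated; never quoted.
#'
#' @param table A data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(table, path) {
  stopifnot(is.data.frame(table))
  write_atomic(function(tmp) {
    write.table(table, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
  }, path)
}

#' Read a tab-separated file written by [write_tsv()]
#'
#' @param path Input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, quote = "",
             comment.char = "", stringsAsFactors = FALSE)
}

## strict reverse complement for ACGTN character strings
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
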