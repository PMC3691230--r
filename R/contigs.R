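# Contig sets are plain named character vectors: names are FASTA ids (first
# whitespace-delimited token of the header), values are upper-case DNA.

#' Read a contig set from a multi-record FASTA file
#'
#' @param path Path to a FASTA file of assembled contigs.
#' @return Named character vector of upper-case DNA sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_contigs <- function(path) {
  if (!file.exists(path)) {
    stop("contig FASTA not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  contigs <- toupper(as.character(set))
  names(contigs) <- ids
  validate_contigs(contigs)
  contigs
}

# Invariant checks shared by read_contigs() and the fixture generator.
validate_contigs <- function(contigs) {
  ids <- names(contigs)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids))) {
    stop("every contig must have a non-empty id", call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate contig id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  empty <- ids[!nzchar(contigs)]
  if (length(empty)) {
    stop("empty sequence for contig(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_along(contigs)) {
    check_dna(contigs[[i]], what = sprintf("contig '%s'", ids[i]))
  }
  invisible(contigs)
}
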