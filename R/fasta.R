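# FASTA emission. Reading goes through Biostrings (read_contigs); writing
# is pinned here so output bytes never change between runs or versions:
# 70-column wrap, no blank lines, trailing newline.

#' Render sequences as FASTA text
#'
#' @param records Named character vector of DNA sequences; names become the
#'   FASTA ids and must be unique and non-empty.
#' @param width Line-wrap width in columns (default 70).
#' @return FASTA text as a single string with trailing newline.
#' @export
render_fasta <- function(records, width = 70L) {
  ids <- names(records)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids))) {
    stop("every FASTA record needs a non-empty id", call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(records))) {
    stop("empty sequence in FASTA record set", call. = FALSE)
  }
  chunks <- vapply(seq_along(records), function(i) {
    s <- records[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    paste0(">", ids[i], "\n",
           paste(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
                 collapse = "\n"),
           "\n")
  }, character(1))
  paste(chunks, collapse = "")
}
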