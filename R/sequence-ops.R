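# Low-level DNA string operations shared by assembly and lift-over.

# IUPAC nucleotide alphabet accepted throughout the package, and the
# complement of each code in the same position.
IUPAC_CODES <- "ACGTNRYSWKMBDHV"
IUPAC_COMPLEMENT <- "TGCANYRSWMKVHDB"

#' Reverse complement of a DNA sequence
#'
#' Computes the Watson-Crick reverse complement of a single DNA string.
#' IUPAC ambiguity codes are complemented to their partners (R<->Y, K<->M,
#' B<->V, D<->H; S, W and N are self-complementary). Input is
#' case-insensitive; the result is upper case.
#'
#' @param seq A single character string over the IUPAC DNA alphabet.
#' @return The reverse-complemented string, same length as the input.
#' @examples
#' reverse_complement("AACCG") # "CGGTT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  s <- toupper(seq)
  bad <- regexpr(sprintf("[^%s]", IUPAC_CODES), s)
  if (bad != -1L) {
    stop(sprintf("unknown nucleotide '%s' at position %d",
                 substr(s, bad, bad), as.integer(bad)), call. = FALSE)
  }
  if (!nzchar(s)) return(s)
  intToUtf8(rev(utf8ToInt(chartr(IUPAC_CODES, IUPAC_COMPLEMENT, s))))
}

# Validate a DNA string, returning it upper-cased; `what` names the sequence
# in error messages.
check_dna <- function(seq, what = "sequence") {
  s <- toupper(seq)
  bad <- regexpr(sprintf("[^%s]", IUPAC_CODES), s)
  if (bad != -1L) {
    stop(sprintf("%s contains unknown nucleotide '%s' at position %d",
                 what, substr(s, bad, bad), as.integer(bad)), call. = FALSE)
  }
  s
}

#' Apply patch inserts to a host contig
#'
#' Replaces each `[open, close]` span of the host sequence (1-based,
#' inclusive, host coordinates) with the full sequence of the named patch
#' contig, e.g. a PCR product spanning a former assembly gap. Spans must not
#' overlap. Replacements are applied from the highest `open` downwards so
#' that earlier host coordinates remain valid while splicing.
#'
#' @param host A single DNA string.
#' @param inserts A list of inserts as returned by [contig_insert()].
#' @param contigs Named character vector of contig sequences supplying the
#'   patch sequences.
#' @return A list with elements `seq` (the post-insert sequence) and
#'   `offset_map`, an integer vector of length `nchar(host)` giving, for each
#'   original host position, its 1-based position in the post-insert
#'   sequence, or `NA` for positions inside a replaced span.
#' @export
apply_inserts <- function(host, inserts, contigs) {
  n <- nchar(host)
  if (length(inserts) == 0L) {
    return(list(seq = host, offset_map = seq_len(n)))
  }
  opens <- vapply(inserts, function(x) x$open, integer(1))
  closes <- vapply(inserts, function(x) x$close, integer(1))
  sources <- vapply(inserts, function(x) x$source, character(1))
  if (any(opens < 1L) || any(closes < opens) || any(closes > n)) {
    stop("insert coordinates out of host range [1, ", n, "]", call. = FALSE)
  }
  missing <- setdiff(sources, names(contigs))
  if (length(missing)) {
    stop("insert source(s) not in contig set: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ord <- order(opens)
  if (any(opens[ord][-1L] <= closes[ord][-length(ord)])) {
    stop("inserts overlap on the host contig", call. = FALSE)
  }

  patches <- unname(contigs[sources])
  # splice ascending: host[..open-1] + patch + host[close+1..]
  pieces <- character(0)
  prev <- 0L
  for (i in ord) {
    pieces <- c(pieces, substr(host, prev + 1L, opens[i] - 1L), patches[i])
    prev <- closes[i]
  }
  pieces <- c(pieces, substr(host, prev + 1L, n))

  shift <- integer(n)
  dead <- logical(n)
  for (i in seq_along(inserts)) {
    delta <- nchar(patches[i]) - (closes[i] - opens[i] + 1L)
    dead[opens[i]:closes[i]] <- TRUE
    if (closes[i] < n) {
      idx <- (closes[i] + 1L):n
      shift[idx] <- shift[idx] + delta
    }
  }
  offset_map <- seq_len(n) + shift
  offset_map[dead] <- NA_integer_

  list(seq = paste(pieces, collapse = ""), offset_map = offset_map)
}

#' Render the sequence contributed by one scaffold entry
#'
#' Applies the entry's processing pipeline in the fixed order inserts ->
#' trim -> orientation: patch inserts are spliced into the host contig
#' first, the `start`/`stop` trim is then taken in post-insert coordinates,
#' and finally the slice is reverse-complemented if the entry is reversed.
#'
#' @param entry A sequence entry from a [scaffold()].
#' @param contigs Named character vector of contig sequences.
#' @return The rendered DNA string.
#' @export
entry_sequence <- function(entry, contigs) {
  if (!identical(entry$kind, "sequence")) {
    stop("entry_sequence() requires a sequence entry", call. = FALSE)
  }
  if (!entry$source %in% names(contigs)) {
    stop("unknown contig '", entry$source, "'", call. = FALSE)
  }
  post <- apply_inserts(contigs[[entry$source]], entry$inserts, contigs)$seq
  stop_ <- if (is.na(entry$stop)) nchar(post) else entry$stop
  if (entry$start < 1L || stop_ < entry$start || stop_ > nchar(post)) {
    stop(sprintf(
      "trim [%d, %d] outside post-insert bounds [1, %d] of contig '%s'",
      entry$start, stop_, nchar(post), entry$source), call. = FALSE)
  }
  s <- substr(post, entry$start, stop_)
  if (entry$reverse) reverse_complement(s) else s
}
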