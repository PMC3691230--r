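# GFF3 in and out. Annotations live in a plain data frame with one
# list-column of ordered attribute key/value pairs, so coordinate arithmetic
# stays simple and attribute order survives to the output.

#' Build an annotation table
#'
#' @param seqid Sequence id(s) the features live on (contig ids before
#'   lift-over, the scaffold id after).
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"`, `"-"` or `"."`.
#' @param type Feature type, e.g. `"gene"`.
#' @param source GFF3 source column.
#' @param score Numeric score or `NA`.
#' @param phase CDS phase (0/1/2) or `NA`.
#' @param attributes List of named character vectors (ordered key/value
#'   attribute maps), recycled if a single one is given.
#' @return A data frame with class `c("gff_annotations", "data.frame")`.
#' @export
make_annotations <- function(seqid, start, end, strand = ".",
                             type = "gene", source = "scaffoldsmith",
                             score = NA_real_, phase = NA_integer_,
                             attributes = list(character(0))) {
  n <- length(seqid)
  if (length(attributes) == 1L && n > 1L) {
    attributes <- rep(attributes, n)
  }
  df <- data.frame(
    seqid = as.character(seqid),
    source = rep_len(as.character(source), n),
    type = rep_len(as.character(type), n),
    start = as.integer(start),
    end = as.integer(end),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    phase = rep_len(as.integer(phase), n),
    stringsAsFactors = FALSE)
  df$attributes <- attributes
  bad <- which(df$start < 1L | df$start > df$end)
  if (length(bad)) {
    stop("malformed annotation(s) at row(s) ",
         paste(bad, collapse = ", "), ": need 1 <= start <= end",
         call. = FALSE)
  }
  if (any(!df$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  }
  class(df) <- c("gff_annotations", "data.frame")
  df
}

empty_annotations <- function() {
  make_annotations(character(0), integer(0), integer(0), character(0),
                   type = character(0), source = character(0),
                   attributes = list())
}

# Pull one attribute value per row out of the attributes list-column.
ann_attr <- function(annotations, key) {
  vapply(annotations$attributes, function(a) {
    if (key %in% names(a)) unname(a[[key]]) else NA_character_
  }, character(1))
}

#' Read GFF3 annotations
#'
#' Parses a GFF3 file (via `rtracklayer`) into the package's annotation
#' table. Multi-valued attributes are collapsed with commas.
#'
#' @param path Path to a GFF3 file.
#' @return A [make_annotations()] data frame.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) {
    stop("GFF3 file not found: ", path, call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- as.data.frame(S4Vectors::mcols(gr), stringsAsFactors = FALSE)
  n <- length(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  attr_cols <- setdiff(names(mc), c("source", "type", "score", "phase"))
  attributes <- lapply(seq_len(n), function(i) {
    out <- character(0)
    for (col in attr_cols) {
      v <- mc[[col]][[i]]
      v <- as.character(unlist(v))
      v <- v[!is.na(v)]
      if (length(v)) {
        out[[col]] <- paste(v, collapse = ",")
      }
    }
    out
  })
  make_annotations(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = strand,
    type = if (n) as.character(mc$type) else character(0),
    source = if (n) as.character(mc$source) else character(0),
    score = if (!is.null(mc$score) && n) as.numeric(mc$score) else NA_real_,
    phase = if (!is.null(mc$phase) && n) as.integer(mc$phase) else NA_integer_,
    attributes = if (n) attributes else list())
}

# GFF3 attribute escaping: percent-encode the structural characters.
gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  gsub("\n", "%0A", x, fixed = TRUE)
}

#' Render annotations as GFF3 text
#'
#' Emits the `##gff-version 3` directive, one `##sequence-region` directive
#' per entry of `seq_lengths`, and the nine tab-separated columns per
#' feature, with attribute values percent-escaped. Output is byte-stable for
#' identical input.
#'
#' @param annotations A [make_annotations()] data frame.
#' @param seq_lengths Named integer vector of sequence lengths to declare as
#'   `##sequence-region` directives.
#' @return GFF3 text as a single string with trailing newline.
#' @export
write_gff3 <- function(annotations, seq_lengths = integer(0)) {
  header <- "##gff-version 3"
  if (length(seq_lengths)) {
    header <- c(header, sprintf("##sequence-region %s 1 %d",
                                names(seq_lengths),
                                as.integer(seq_lengths)))
  }
  body <- vapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations$attributes[[i]]
    attr_str <- if (length(a)) {
      paste(paste0(gff3_escape(names(a)), "=", gff3_escape(unname(a))),
            collapse = ";")
    } else "."
    paste(
      annotations$seqid[i],
      annotations$source[i],
      annotations$type[i],
      annotations$start[i],
      annotations$end[i],
      if (is.na(annotations$score[i])) "." else
        format(annotations$score[i], scientific = FALSE, trim = TRUE),
      annotations$strand[i],
      if (is.na(annotations$phase[i])) "." else annotations$phase[i],
      attr_str,
      sep = "\t")
  }, character(1))
  paste0(paste(c(header, body), collapse = "\n"), "\n")
}
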