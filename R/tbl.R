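# NCBI 5-column feature table generation: gene rows, derived CDS rows,
# locus_tag renumbering. Minus strand is encoded as start > stop, per the
# .tbl convention.

#' Construct a feature-table row
#'
#' @param start,stop Scaffold coordinates as written to the table; for a
#'   minus-strand feature `start > stop`.
#' @param key Feature key (`"gene"`, `"CDS"`, ...).
#' @param qualifiers Named character vector of qualifiers in output order;
#'   duplicate names are allowed.
#' @export
tbl_feature <- function(start, stop, key, qualifiers = character(0)) {
  stopifnot(is.character(key), length(key) == 1L, nzchar(key))
  list(start = as.integer(start), stop = as.integer(stop), key = key,
       qualifiers = qualifiers)
}

#' Derive the gene + CDS feature pair from a gene annotation
#'
#' Under the single-interval gene model (no intron/exon structure), every
#' gene-type annotation yields a gene feature and a CDS feature spanning the
#' identical interval. Minus-strand genes emit `start > stop` in both rows.
#' The gene feature carries the `gene` name (when a `Name` attribute is
#' present) and the `locus_tag`; the CDS carries the `product` (defaulting
#' to `"hypothetical protein"`) and the same `locus_tag`.
#'
#' @param gene A single-row gene annotation in scaffold coordinates.
#' @return List of two [tbl_feature()] objects: the gene, then its CDS.
#' @export
derive_cds <- function(gene) {
  stopifnot(nrow(gene) == 1L)
  if (!identical(gene$type, "gene")) {
    stop("derive_cds() requires a gene-type feature, got '", gene$type,
         "'", call. = FALSE)
  }
  attrs <- gene$attributes[[1L]]
  locus <- if ("locus_tag" %in% names(attrs)) attrs[["locus_tag"]] else NA
  name <- if ("Name" %in% names(attrs)) attrs[["Name"]] else NA
  product <- if ("product" %in% names(attrs)) attrs[["product"]] else
    "hypothetical protein"
  minus <- identical(gene$strand, "-")
  s <- if (minus) gene$end else gene$start
  e <- if (minus) gene$start else gene$end
  gene_q <- character(0)
  if (!is.na(name)) gene_q <- c(gene_q, gene = name)
  if (!is.na(locus)) gene_q <- c(gene_q, locus_tag = locus)
  cds_q <- c(product = product)
  if (!is.na(locus)) cds_q <- c(cds_q, locus_tag = locus)
  list(tbl_feature(s, e, "gene", gene_q),
       tbl_feature(s, e, "CDS", cds_q))
}

#' Renumber locus tags from the scaffold origin
#'
#' Replaces every annotation's `locus_tag` with `<prefix>_<n>`, where `n`
#' starts at 00010 and increments by 10 in scaffold order (zero-padded to 5
#' digits) — the prokaryotic-submission convention, leaving room for later
#' insertions.
#'
#' @param annotations Annotation data frame sorted by scaffold start (as
#'   the `lifted` table of [lift_all()] is).
#' @param prefix Non-empty locus_tag prefix registered for the submission.
#' @return The annotations with locus tags reassigned.
#' @export
renumber_locus_tags <- function(annotations, prefix) {
  if (!is.character(prefix) || length(prefix) != 1L || !nzchar(prefix)) {
    stop("locus_tag prefix must be a non-empty string", call. = FALSE)
  }
  n <- nrow(annotations)
  if (n > 1L && is.unsorted(annotations$start)) {
    stop("annotations must be sorted by scaffold start before renumbering",
         call. = FALSE)
  }
  tags <- sprintf("%s_%05d", prefix, 10L * seq_len(n))
  annotations$attributes <- lapply(seq_len(n), function(i) {
    a <- annotations$attributes[[i]]
    if ("locus_tag" %in% names(a)) {
      a[["locus_tag"]] <- tags[i]
    } else {
      a <- c(a, locus_tag = tags[i])
    }
    a
  })
  annotations
}

#' Render features as an NCBI 5-column feature table
#'
#' First line is `>Feature <identifier>`; each feature contributes a
#' `start<TAB>stop<TAB>key` line followed by one
#' `<TAB><TAB><TAB>qualifier<TAB>value` line per qualifier, in stored
#' order — the exact layout consumed by tbl2asn/sequin.
#'
#' @param identifier Scaffold sequence id.
#' @param features List of [tbl_feature()] rows in scaffold order.
#' @param seq_length Optional scaffold length; when given, every coordinate
#'   is checked to lie in `[1, seq_length]`.
#' @return Feature-table text as a single string with trailing newline.
#' @export
render_tbl <- function(identifier, features, seq_length = NULL) {
  lines <- paste0(">Feature ", identifier)
  for (f in features) {
    if (!is.null(seq_length) &&
        (f$start < 1L || f$stop < 1L ||
         f$start > seq_length || f$stop > seq_length)) {
      stop(sprintf(
        "feature coordinates [%d, %d] outside scaffold [1, %d]",
        f$start, f$stop, seq_length), call. = FALSE)
    }
    lines <- c(lines, paste(f$start, f$stop, f$key, sep = "\t"))
    if (length(f$qualifiers)) {
      lines <- c(lines, paste0("\t\t\t", names(f$qualifiers), "\t",
                               unname(f$qualifiers)))
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Expand gene annotations into interleaved gene/CDS table features
#'
#' @param annotations Gene annotations in scaffold order.
#' @return List of [tbl_feature()] rows, gene then CDS per input gene.
#' @export
tbl_features_from_genes <- function(annotations) {
  out <- list()
  for (i in seq_len(nrow(annotations))) {
    out <- c(out, derive_cds(annotations[i, ]))
  }
  out
}
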