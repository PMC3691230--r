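# AGP 2.0: the "golden path" description of how components and gaps tile
# the scaffold, plus the reconstruction routine used to verify it.

#' Render an assembly's layout as AGP 2.0 text
#'
#' One row per layout segment. Contig segments become `W` rows referencing
#' the placed component sequences of [scaffold_components()] (so
#' `component_beg` is 1 and `component_end` the component length), with
#' orientation `+`/`-`. Gap segments become `N` rows with gap type
#' `scaffold`, linkage `yes` and linkage evidence `unspecified`.
#'
#' @param assembled An [assemble()] result.
#' @return AGP text as a single string with trailing newline, starting with
#'   the `##agp-version 2.0` comment header.
#' @export
render_agp <- function(assembled) {
  stopifnot(inherits(assembled, "assembled_scaffold"))
  layout <- assembled$layout
  comp_ids <- component_ids(assembled)
  ci <- 0L
  rows <- vapply(seq_len(nrow(layout)), function(i) {
    seg <- layout[i, ]
    if (seg$kind == "contig") {
      ci <<- ci + 1L
      len <- seg$scaffold_stop - seg$scaffold_start + 1L
      paste(assembled$identifier, seg$scaffold_start, seg$scaffold_stop,
            i, "W", comp_ids[ci], 1L, len,
            if (seg$reversed) "-" else "+", sep = "\t")
    } else {
      len <- seg$scaffold_stop - seg$scaffold_start + 1L
      paste(assembled$identifier, seg$scaffold_start, seg$scaffold_stop,
            i, "N", len, "scaffold", "yes", "unspecified", sep = "\t")
    }
  }, character(1))
  paste0(paste(c("##agp-version 2.0", rows), collapse = "\n"), "\n")
}

# Parse AGP text into a data frame of rows (comments skipped). Internal to
# reconstruction; field validation happens during reconstruction.
parse_agp <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("AGP contains no rows", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    stop("AGP row(s) without 9 tab-separated columns: line(s) ",
         paste(which(nf != 9L), collapse = ", "), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  data.frame(
    object = m[, 1], object_beg = as.integer(m[, 2]),
    object_end = as.integer(m[, 3]), part_number = as.integer(m[, 4]),
    component_type = m[, 5], f6 = m[, 6], f7 = m[, 7], f8 = m[, 8],
    f9 = m[, 9], stringsAsFactors = FALSE)
}

#' Rebuild the scaffold sequence from AGP and its component sequences
#'
#' Splices the component slices referenced by `W` rows
#' (reverse-complementing `-` orientations) and `N`/`U` gap runs back into
#' the object sequence, verifying that the rows tile the object without
#' holes or overlaps. This is the package's own check that an emitted AGP
#' plus the emitted contig FASTA reproduce the assembled genome exactly.
#'
#' @param agp AGP text (as from [render_agp()]).
#' @param components Named character vector of component sequences (as from
#'   [scaffold_components()], or a parsed contig FASTA).
#' @return The reconstructed DNA string.
#' @export
reconstruct_from_agp <- function(agp, components) {
  rows <- parse_agp(agp)
  if (length(unique(rows$object)) != 1L) {
    stop("expected a single AGP object, found: ",
         paste(unique(rows$object), collapse = ", "), call. = FALSE)
  }
  if (!identical(rows$part_number, seq_len(nrow(rows)))) {
    stop("AGP part_number must run sequentially from 1", call. = FALSE)
  }
  pos <- 0L
  pieces <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    if (r$object_beg != pos + 1L) {
      stop(sprintf(
        "AGP tiling violation at part %d: object_beg %d, expected %d",
        r$part_number, r$object_beg, pos + 1L), call. = FALSE)
    }
    span <- r$object_end - r$object_beg + 1L
    if (span < 1L) {
      stop(sprintf("AGP part %d: object_end < object_beg", r$part_number),
           call. = FALSE)
    }
    if (r$component_type == "W") {
      comp_id <- r$f6
      if (!comp_id %in% names(components)) {
        stop("AGP references unknown component '", comp_id, "'",
             call. = FALSE)
      }
      comp <- components[[comp_id]]
      cbeg <- as.integer(r$f7)
      cend <- as.integer(r$f8)
      if (is.na(cbeg) || is.na(cend) || cbeg < 1L || cend < cbeg ||
          cend > nchar(comp)) {
        stop(sprintf(
          "AGP part %d: component span [%s, %s] outside '%s' [1, %d]",
          r$part_number, r$f7, r$f8, comp_id, nchar(comp)), call. = FALSE)
      }
      if (cend - cbeg + 1L != span) {
        stop(sprintf(
          "AGP part %d: object span (%d) != component span (%d)",
          r$part_number, span, cend - cbeg + 1L), call. = FALSE)
      }
      slice <- substr(comp, cbeg, cend)
      if (!r$f9 %in% c("+", "-")) {
        stop(sprintf("AGP part %d: orientation must be '+' or '-'",
                     r$part_number), call. = FALSE)
      }
      pieces[i] <- if (r$f9 == "-") reverse_complement(slice) else slice
    } else if (r$component_type %in% c("N", "U")) {
      gap_len <- as.integer(r$f6)
      if (is.na(gap_len) || gap_len != span) {
        stop(sprintf(
          "AGP part %d: gap_length (%s) != object span (%d)",
          r$part_number, r$f6, span), call. = FALSE)
      }
      pieces[i] <- strrep("N", gap_len)
    } else {
      stop(sprintf("AGP part %d: unsupported component_type '%s'",
                   r$part_number, r$component_type), call. = FALSE)
    }
    pos <- pos + span
  }
  paste(pieces, collapse = "")
}
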