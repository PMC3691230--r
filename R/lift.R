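# Coordinate lift-over: contig-space annotations onto the assembled
# scaffold. The core rule: an annotation survives only if its interval
# passes through insert replacement and trimming intact within exactly one
# placed entry; anything else is dropped with a reason, never truncated.

DROP_REASONS <- c("contig-not-placed", "overlaps-trimmed-region",
                  "overlaps-insert-region", "ambiguous-multiple-placements")

#' Lift one annotation onto scaffold coordinates
#'
#' Translates a single contig-space interval into scaffold space. On a
#' reversed placement the interval is mirrored within the placed slice and
#' the strand flips (`+` <-> `-`; `.` is left alone). An annotation whose
#' interval overlaps an insert-replaced span, overlaps a trimmed-off region,
#' sits on an unplaced contig, or sits on a contig placed more than once is
#' dropped with the corresponding reason.
#'
#' @param annotation A single-row annotation (as from [make_annotations()]).
#' @param assembled An [assemble()] result.
#' @return A list: either `list(status = "lifted", annotation = <row>)` with
#'   scaffold coordinates and `seqid` set to the scaffold identifier, or
#'   `list(status = "dropped", reason = <string>)`.
#' @export
lift_annotation <- function(annotation, assembled) {
  stopifnot(inherits(assembled, "assembled_scaffold"),
            nrow(annotation) == 1L)
  start <- annotation$start
  stop_ <- annotation$end
  if (is.na(start) || is.na(stop_) || start > stop_) {
    stop("malformed annotation: start > stop", call. = FALSE)
  }
  layout <- assembled$layout
  hits <- which(layout$kind == "contig" &
                  layout$source_id == annotation$seqid)
  if (length(hits) == 0L) {
    return(list(status = "dropped", reason = "contig-not-placed"))
  }
  if (length(hits) > 1L) {
    return(list(status = "dropped",
                reason = "ambiguous-multiple-placements"))
  }
  seg <- layout[hits, ]
  om <- assembled$offset_maps[[seg$entry_index]]
  if (stop_ > length(om)) {
    stop(sprintf(
      "annotation [%d, %d] extends beyond contig '%s' (%d bp)",
      start, stop_, annotation$seqid, length(om)), call. = FALSE)
  }
  mapped <- om[start:stop_]
  if (anyNA(mapped)) {
    return(list(status = "dropped", reason = "overlaps-insert-region"))
  }
  m1 <- mapped[1L]
  m2 <- mapped[length(mapped)]
  if (m1 < seg$source_start || m2 > seg$source_stop) {
    return(list(status = "dropped", reason = "overlaps-trimmed-region"))
  }
  if (!seg$reversed) {
    new_start <- seg$scaffold_start + (m1 - seg$source_start)
    new_stop <- seg$scaffold_start + (m2 - seg$source_start)
    new_strand <- annotation$strand
  } else {
    new_start <- seg$scaffold_start + (seg$source_stop - m2)
    new_stop <- seg$scaffold_start + (seg$source_stop - m1)
    new_strand <- switch(annotation$strand,
                         "+" = "-", "-" = "+", annotation$strand)
  }
  out <- annotation
  out$seqid <- assembled$identifier
  out$start <- new_start
  out$end <- new_stop
  out$strand <- new_strand
  list(status = "lifted", annotation = out)
}

#' Lift all annotations onto the assembled scaffold
#'
#' Applies [lift_annotation()] to every feature and partitions the input
#' into lifted features (scaffold coordinates, sorted by start, then end,
#' then `ID` attribute) and dropped features with their reasons. Every input
#' feature lands in exactly one of the two tables.
#'
#' @param annotations A [make_annotations()] data frame in contig
#'   coordinates.
#' @param assembled An [assemble()] result.
#' @return An object of class `"lift_report"`: list with `lifted` (an
#'   annotation data frame) and `dropped` (the original rows plus a
#'   `reason` column).
#' @export
lift_all <- function(annotations, assembled) {
  n <- nrow(annotations)
  lifted_rows <- vector("list", n)
  dropped_rows <- vector("list", n)
  for (i in seq_len(n)) {
    res <- lift_annotation(annotations[i, ], assembled)
    if (res$status == "lifted") {
      lifted_rows[[i]] <- res$annotation
    } else {
      row <- annotations[i, ]
      row$reason <- res$reason
      dropped_rows[[i]] <- row
    }
  }
  lifted <- do.call(rbind, lifted_rows[!vapply(lifted_rows, is.null,
                                               logical(1))])
  dropped <- do.call(rbind, dropped_rows[!vapply(dropped_rows, is.null,
                                                 logical(1))])
  if (is.null(lifted)) {
    lifted <- empty_annotations()
  } else {
    ids <- ann_attr(lifted, "ID")
    ord <- order(lifted$start, lifted$end, ids, method = "radix")
    lifted <- lifted[ord, ]
    rownames(lifted) <- NULL
  }
  if (is.null(dropped)) {
    dropped <- empty_annotations()
    dropped$reason <- character(0)
  } else {
    rownames(dropped) <- NULL
  }
  structure(list(lifted = lifted, dropped = dropped),
            class = "lift_report")
}

#' @export
print.lift_report <- function(x, ...) {
  cat(sprintf("<lift_report> %d lifted, %d dropped\n",
              nrow(x$lifted), nrow(x$dropped)))
  if (nrow(x$dropped)) {
    tab <- table(x$dropped$reason)
    for (r in names(tab)) {
      cat(sprintf("  dropped (%s): %d\n", r, tab[[r]]))
    }
  }
  invisible(x)
}
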