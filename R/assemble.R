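# Render the scaffold plan into the draft genome sequence plus the
# coordinate layout that every downstream artifact (AGP, lift-over) reads.

#' Assemble a scaffold plan into the draft genome sequence
#'
#' Renders each entry (inserts, then trim, then orientation; `N` runs for
#' gaps), concatenates them, and records a coordinate layout mapping every
#' entry onto its scaffold span. Assembly is fully deterministic: the same
#' plan and contig set always yield byte-identical output.
#'
#' @param scaffold A [scaffold()] plan; must validate cleanly against
#'   `contigs` (see [validate_scaffold()]).
#' @param contigs Named character vector of contig sequences.
#' @param identifier Output sequence id for the assembled scaffold.
#' @return An object of class `"assembled_scaffold"`: a list with
#'   \describe{
#'     \item{identifier}{the output sequence id}
#'     \item{seq}{the assembled DNA string}
#'     \item{layout}{data frame with one row per entry: `entry_index`,
#'       `kind` (`"contig"`/`"gap"`), `scaffold_start`, `scaffold_stop`,
#'       `source_id`, `source_start`, `source_stop` (post-insert host
#'       coordinates of the placed slice) and `reversed`}
#'     \item{entry_sequences}{per-entry rendered strings (post-orientation)}
#'     \item{forward_sequences}{per-entry placed slices before
#'       reverse-complementing; the AGP component sequences}
#'     \item{offset_maps}{per-entry host-to-post-insert coordinate maps}
#'     \item{scaffold}{the input plan}
#'   }
#' @export
assemble <- function(scaffold, contigs, identifier = "scaffold") {
  stopifnot(is.character(identifier), length(identifier) == 1L,
            nzchar(identifier))
  errs <- validate_scaffold(scaffold, contigs)
  if (length(errs)) {
    stop("invalid scaffold:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  n <- length(scaffold$entries)
  entry_seqs <- vector("list", n)
  fwd_seqs <- vector("list", n)
  offset_maps <- vector("list", n)
  rows <- vector("list", n)
  pos <- 0L
  for (i in seq_len(n)) {
    e <- scaffold$entries[[i]]
    if (e$kind == "unresolved") {
      entry_seqs[[i]] <- strrep("N", e$length)
      rows[[i]] <- data.frame(
        entry_index = i, kind = "gap",
        scaffold_start = pos + 1L, scaffold_stop = pos + e$length,
        source_id = NA_character_, source_start = NA_integer_,
        source_stop = NA_integer_, reversed = FALSE,
        stringsAsFactors = FALSE)
      pos <- pos + e$length
      next
    }
    post <- apply_inserts(contigs[[e$source]], e$inserts, contigs)
    offset_maps[[i]] <- post$offset_map
    stop_ <- if (is.na(e$stop)) nchar(post$seq) else e$stop
    fwd <- substr(post$seq, e$start, stop_)
    entry_seqs[[i]] <- if (e$reverse) reverse_complement(fwd) else fwd
    fwd_seqs[[i]] <- fwd
    len <- stop_ - e$start + 1L
    rows[[i]] <- data.frame(
      entry_index = i, kind = "contig",
      scaffold_start = pos + 1L, scaffold_stop = pos + len,
      source_id = e$source, source_start = e$start, source_stop = stop_,
      reversed = e$reverse, stringsAsFactors = FALSE)
    pos <- pos + len
  }
  structure(list(
    identifier = identifier,
    seq = paste(unlist(entry_seqs), collapse = ""),
    layout = do.call(rbind, rows),
    entry_sequences = entry_seqs,
    forward_sequences = fwd_seqs,
    offset_maps = offset_maps,
    scaffold = scaffold
  ), class = "assembled_scaffold")
}

#' @export
print.assembled_scaffold <- function(x, ...) {
  ncontig <- sum(x$layout$kind == "contig")
  ngap <- sum(x$layout$kind == "gap")
  cat(sprintf("<assembled_scaffold> %s: %d bp, %d contig segment(s), %d gap(s)\n",
              x$identifier, nchar(x$seq), ncontig, ngap))
  invisible(x)
}

#' Unique component ids for the placed contig slices
#'
#' A contig placed once keeps its id; further placements of the same contig
#' get `.2`, `.3`, ... suffixes so the component FASTA and AGP stay
#' consistent and ids stay unique.
#'
#' @param assembled An [assemble()] result.
#' @return Character vector, one id per contig segment of the layout (in
#'   layout order).
#' @export
component_ids <- function(assembled) {
  ids <- assembled$layout$source_id[assembled$layout$kind == "contig"]
  out <- ids
  for (id in unique(ids)) {
    k <- which(ids == id)
    if (length(k) > 1L) {
      out[k[-1L]] <- paste0(id, ".", seq_along(k)[-1L])
    }
  }
  out
}

#' Placed component sequences of an assembly
#'
#' The forward-orientation (pre-reverse-complement) post-insert, trimmed
#' slice of every placed contig, named by [component_ids()]. These are the
#' sequences emitted in the contig FASTA submission file and referenced by
#' the AGP `W` rows.
#'
#' @param assembled An [assemble()] result.
#' @return Named character vector of component sequences.
#' @export
scaffold_components <- function(assembled) {
  idx <- which(assembled$layout$kind == "contig")
  seqs <- vapply(assembled$layout$entry_index[idx],
                 function(i) assembled$forward_sequences[[i]], character(1))
  names(seqs) <- component_ids(assembled)
  seqs
}
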