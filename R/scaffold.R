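# The scaffold plan: an ordered list of contig placements and unresolved
# gaps, read from and written to a plain-text YAML file.

#' Construct a patch insert
#'
#' An insert replaces the host-contig span `[open, close]` (1-based,
#' inclusive) with the full sequence of the contig named `source`, typically
#' a PCR product used to close an assembly gap.
#'
#' @param source Contig-set id of the patch sequence.
#' @param open,close 1-based inclusive host-contig coordinates of the span
#'   to replace.
#' @export
contig_insert <- function(source, open, close) {
  stopifnot(is.character(source), length(source) == 1L, nzchar(source))
  list(source = source, open = as.integer(open), close = as.integer(close))
}

#' Construct a contig placement entry
#'
#' @param source Contig id to place.
#' @param start,stop Optional 1-based inclusive trim, interpreted in
#'   post-insert coordinates (inserts are applied before trimming).
#'   `stop = NA` means "to the end".
#' @param reverse Place the reverse complement?
#' @param inserts List of [contig_insert()] patches.
#' @export
seq_entry <- function(source, start = 1L, stop = NA_integer_,
                      reverse = FALSE, inserts = list()) {
  stopifnot(is.character(source), length(source) == 1L, nzchar(source))
  list(kind = "sequence", source = source, start = as.integer(start),
       stop = as.integer(stop), reverse = isTRUE(reverse),
       inserts = inserts)
}

#' Construct an unresolved-gap entry
#'
#' @param length Number of `N` bases the gap renders to (>= 1).
#' @export
gap_entry <- function(length) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) {
    stop("gap length must be ≥ 1", call. = FALSE)
  }
  list(kind = "unresolved", length = length)
}

#' Construct a scaffold plan from entries
#'
#' @param entries List of [seq_entry()] / [gap_entry()] objects, in scaffold
#'   order.
#' @return An object of class `"scaffold"`.
#' @export
scaffold <- function(entries) {
  structure(list(entries = entries), class = "scaffold")
}

#' @export
print.scaffold <- function(x, ...) {
  cat("<scaffold>", length(x$entries), "entries\n")
  for (i in seq_along(x$entries)) {
    e <- x$entries[[i]]
    if (e$kind == "unresolved") {
      cat(sprintf("  %2d. gap %d bp\n", i, e$length))
    } else {
      cat(sprintf("  %2d. %s%s%s%s\n", i, e$source,
                  if (e$reverse) " (reversed)" else "",
                  if (e$start != 1L || !is.na(e$stop))
                    sprintf(" [%s..%s]", e$start,
                            if (is.na(e$stop)) "end" else e$stop) else "",
                  if (length(e$inserts))
                    sprintf(" +%d insert(s)", length(e$inserts)) else ""))
    }
  }
  invisible(x)
}

scalar_int <- function(x, what, where) {
  if (length(x) != 1L || is.na(suppressWarnings(as.integer(x))) ||
      (is.numeric(x) && x != as.integer(x))) {
    stop(sprintf("%s: %s must be a single integer", where, what),
         call. = FALSE)
  }
  as.integer(x)
}

parse_insert_block <- function(x, where) {
  if (!is.list(x) || is.null(names(x))) {
    stop(where, ": malformed insert block (expected a map with keys ",
         "source, open, close)", call. = FALSE)
  }
  unknown <- setdiff(names(x), c("source", "open", "close"))
  if (length(unknown)) {
    stop(where, ": unknown insert key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  need <- setdiff(c("source", "open", "close"), names(x))
  if (length(need)) {
    stop(where, ": malformed insert block, missing key(s): ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!is.character(x$source) || length(x$source) != 1L || !nzchar(x$source)) {
    stop(where, ": insert source must be a non-empty string", call. = FALSE)
  }
  open <- scalar_int(x$open, "insert open", where)
  close <- scalar_int(x$close, "insert close", where)
  if (open < 1L) stop(where, ": insert open must be ≥ 1", call. = FALSE)
  if (close < 1L) stop(where, ": insert close must be ≥ 1", call. = FALSE)
  contig_insert(x$source, open, close)
}

parse_entry <- function(x, i) {
  where <- sprintf("scaffold entry %d", i)
  if (!is.list(x) || length(x) != 1L || is.null(names(x))) {
    stop(where, ": each entry must be a single-key map ",
         "('sequence' or 'unresolved')", call. = FALSE)
  }
  key <- names(x)
  body <- x[[1L]]
  if (key == "unresolved") {
    if (!is.list(body) || is.null(names(body))) {
      stop(where, ": 'unresolved' must carry a map with key 'length'",
           call. = FALSE)
    }
    unknown <- setdiff(names(body), "length")
    if (length(unknown)) {
      stop(where, ": unknown key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (is.null(body$length)) {
      stop(where, ": 'unresolved' requires a 'length'", call. = FALSE)
    }
    len <- scalar_int(body$length, "length", where)
    if (len < 1L) stop(where, ": gap length must be ≥ 1", call. = FALSE)
    return(gap_entry(len))
  }
  if (key == "sequence") {
    if (!is.list(body) || is.null(names(body))) {
      stop(where, ": 'sequence' must carry a map with at least 'source'",
           call. = FALSE)
    }
    unknown <- setdiff(names(body),
                       c("source", "start", "stop", "reverse", "inserts"))
    if (length(unknown)) {
      stop(where, ": unknown key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (!is.character(body$source) || length(body$source) != 1L ||
        !nzchar(body$source)) {
      stop(where, ": 'sequence' requires a non-empty 'source'",
           call. = FALSE)
    }
    start <- if (is.null(body$start)) 1L else
      scalar_int(body$start, "start", where)
    if (start < 1L) stop(where, ": start must be ≥ 1", call. = FALSE)
    stop_ <- if (is.null(body$stop)) NA_integer_ else
      scalar_int(body$stop, "stop", where)
    if (!is.na(stop_) && stop_ < 1L) {
      stop(where, ": stop must be ≥ 1", call. = FALSE)
    }
    reverse <- if (is.null(body$reverse)) FALSE else body$reverse
    if (!is.logical(reverse) || length(reverse) != 1L || is.na(reverse)) {
      stop(where, ": reverse must be true or false", call. = FALSE)
    }
    inserts <- if (is.null(body$inserts)) list() else body$inserts
    if (!is.list(inserts)) {
      stop(where, ": inserts must be a list", call. = FALSE)
    }
    inserts <- lapply(inserts, parse_insert_block, where = where)
    return(seq_entry(body$source, start, stop_, reverse, inserts))
  }
  stop(where, ": unknown entry key '", key, "'", call. = FALSE)
}

#' Parse a scaffold description file
#'
#' The scaffold file is a YAML list of single-key maps. A `sequence` entry
#' places a contig and may carry `start`, `stop` (1-based inclusive trim in
#' post-insert coordinates), `reverse`, and `inserts` (each with `source`,
#' `open`, `close`). An `unresolved` entry carries the `length` of a run of
#' `N` bases. Unknown keys are a hard error so that typos in a hand-edited
#' file fail loudly.
#'
#' @param text Scaffold file contents as a single string (or a vector of
#'   lines).
#' @return A [scaffold()] object with defaults filled in
#'   (`start = 1`, `stop = NA` meaning end, `reverse = FALSE`,
#'   `inserts = list()`).
#' @seealso [write_scaffold()], [validate_scaffold()], [read_scaffold()]
#' @export
parse_scaffold <- function(text) {
  text <- paste(text, collapse = "\n")
  doc <- tryCatch(
    yaml::yaml.load(text),
    error = function(e) {
      stop("scaffold syntax error: ", conditionMessage(e), call. = FALSE)
    })
  if (is.null(doc)) stop("scaffold file is empty", call. = FALSE)
  if (!is.list(doc) || !is.null(names(doc))) {
    stop("scaffold file must be a YAML list of entries", call. = FALSE)
  }
  entries <- lapply(seq_along(doc), function(i) parse_entry(doc[[i]], i))
  scaffold(entries)
}

#' Read a scaffold description file from disk
#'
#' @param path Path to the scaffold YAML file.
#' @return A [scaffold()] object.
#' @export
read_scaffold <- function(path) {
  if (!file.exists(path)) {
    stop("scaffold file not found: ", path, call. = FALSE)
  }
  parse_scaffold(readLines(path, warn = FALSE))
}

#' Write a scaffold plan back to scaffold-file text
#'
#' Inverse of [parse_scaffold()]: `parse_scaffold(write_scaffold(s))` is
#' structurally identical to `s`. Keys holding their default values
#' (`start = 1`, `stop` = end, `reverse = FALSE`, empty `inserts`) are
#' omitted to keep the file minimal and hand-editable.
#'
#' @param scaffold A [scaffold()] object.
#' @return Scaffold-file text (single string, trailing newline).
#' @export
write_scaffold <- function(scaffold) {
  stopifnot(inherits(scaffold, "scaffold"))
  doc <- lapply(scaffold$entries, function(e) {
    if (e$kind == "unresolved") {
      return(list(unresolved = list(length = e$length)))
    }
    body <- list(source = e$source)
    if (e$start != 1L) body$start <- e$start
    if (!is.na(e$stop)) body$stop <- e$stop
    if (e$reverse) body$reverse <- TRUE
    if (length(e$inserts)) {
      body$inserts <- lapply(e$inserts, function(x) {
        list(source = x$source, open = x$open, close = x$close)
      })
    }
    list(sequence = body)
  })
  yaml::as.yaml(doc)
}

#' Validate a scaffold plan against a contig set
#'
#' Checks referential integrity and coordinate invariants: every `source`
#' resolves to a contig, insert spans lie within their host and do not
#' overlap, trims lie within post-insert bounds, the plan contains at least
#' one contig placement, and it neither starts nor ends with a gap.
#'
#' @param scaffold A [scaffold()] object.
#' @param contigs Named character vector of contig sequences.
#' @return Character vector of human-readable problems; empty when the plan
#'   is fully consistent.
#' @export
validate_scaffold <- function(scaffold, contigs) {
  stopifnot(inherits(scaffold, "scaffold"))
  errs <- character(0)
  kinds <- vapply(scaffold$entries, function(e) e$kind, character(1))
  if (!any(kinds == "sequence")) {
    errs <- c(errs, "scaffold must contain at least one sequence entry")
  }
  if (length(kinds) && kinds[1L] == "unresolved") {
    errs <- c(errs, "scaffold must not begin with an unresolved gap")
  }
  if (length(kinds) && kinds[length(kinds)] == "unresolved") {
    errs <- c(errs, "scaffold must not end with an unresolved gap")
  }
  for (i in seq_along(scaffold$entries)) {
    e <- scaffold$entries[[i]]
    where <- sprintf("entry %d", i)
    if (e$kind == "unresolved") next
    if (!e$source %in% names(contigs)) {
      errs <- c(errs, sprintf("%s: unknown contig '%s'", where, e$source))
      next
    }
    host_len <- nchar(contigs[[e$source]])
    ins_ok <- TRUE
    spans <- matrix(integer(0), ncol = 2)
    for (j in seq_along(e$inserts)) {
      ins <- e$inserts[[j]]
      iw <- sprintf("%s insert %d", where, j)
      if (!ins$source %in% names(contigs)) {
        errs <- c(errs, sprintf("%s: unknown contig '%s'", iw, ins$source))
        ins_ok <- FALSE
        next
      }
      if (ins$close < ins$open) {
        errs <- c(errs, sprintf("%s: close < open (%d < %d)",
                                iw, ins$close, ins$open))
        ins_ok <- FALSE
        next
      }
      if (ins$open < 1L || ins$close > host_len) {
        errs <- c(errs, sprintf(
          "%s: span [%d, %d] outside host contig '%s' [1, %d]",
          iw, ins$open, ins$close, e$source, host_len))
        ins_ok <- FALSE
        next
      }
      spans <- rbind(spans, c(ins$open, ins$close))
    }
    if (nrow(spans) > 1L) {
      ord <- order(spans[, 1L])
      if (any(spans[ord, 1L][-1L] <= spans[ord, 2L][-nrow(spans)])) {
        errs <- c(errs, sprintf("%s: inserts overlap", where))
        ins_ok <- FALSE
      }
    }
    if (!ins_ok) next
    post_len <- host_len +
      sum(vapply(e$inserts, function(ins) {
        nchar(contigs[[ins$source]]) - (ins$close - ins$open + 1L)
      }, integer(1)))
    stop_ <- if (is.na(e$stop)) post_len else e$stop
    if (e$start > stop_) {
      errs <- c(errs, sprintf("%s: start > stop (%d > %d)",
                              where, e$start, stop_))
    } else if (stop_ > post_len) {
      errs <- c(errs, sprintf(
        "%s: stop %d beyond post-insert length %d of contig '%s'",
        where, stop_, post_len, e$source))
    }
  }
  errs
}
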