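# Independent oracles used to cross-check the implementation. These are
# deliberately written as naive, position-by-position computations that
# share no code with the package internals.

# Biostrings as the reverse-complement reference.
oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Brute-force splice: walk the host one position at a time, emitting patch
# sequences at insert openings. Returns the spliced string and the
# post-insert position of every surviving host position.
oracle_splice <- function(host, inserts, contigs) {
  chars <- strsplit(host, "")[[1]]
  open_at <- integer(0)
  close_of <- integer(0)
  patch_of <- character(0)
  for (ins in inserts) {
    open_at <- c(open_at, ins$open)
    close_of <- c(close_of, ins$close)
    patch_of <- c(patch_of, contigs[[ins$source]])
  }
  out <- character(0)
  map <- rep(NA_integer_, length(chars))
  i <- 1L
  while (i <= length(chars)) {
    hit <- which(open_at == i)
    if (length(hit) == 1L) {
      out <- c(out, strsplit(patch_of[hit], "")[[1]])
      i <- close_of[hit] + 1L
    } else {
      out <- c(out, chars[i])
      map[i] <- length(out)
      i <- i + 1L
    }
  }
  list(seq = paste(out, collapse = ""), offset_map = map)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Random scaffold plan for round-trip property tests (no contig set needed).
random_scaffold <- function() {
  n_seq <- sample.int(4L, 1L)
  entries <- list()
  for (i in seq_len(n_seq)) {
    ins <- list()
    if (runif(1) < 0.4) {
      n_ins <- sample.int(2L, 1L)
      open <- 1L
      for (j in seq_len(n_ins)) {
        open <- open + sample.int(50L, 1L)
        close <- open + sample.int(30L, 1L)
        ins[[j]] <- contig_insert(sprintf("patch%d_%d", i, j), open, close)
        open <- close
      }
    }
    entries[[length(entries) + 1L]] <- seq_entry(
      source = sprintf("ctg%d", i),
      start = if (runif(1) < 0.5) 1L else sample.int(20L, 1L),
      stop = if (runif(1) < 0.5) NA_integer_ else 500L + sample.int(500L, 1L),
      reverse = runif(1) < 0.5,
      inserts = ins)
    if (i < n_seq && runif(1) < 0.6) {
      entries[[length(entries) + 1L]] <- gap_entry(sample.int(200L, 1L))
    }
  }
  scaffold(entries)
}

# Independent AGP 2.0 structural validator: column counts, coordinate
# arithmetic, part numbering, gap fields, tiling. Returns a character
# vector of violations (empty when conformant).
validate_agp_text <- function(text) {
  problems <- character(0)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (!any(grepl("^##agp-version\\s+2\\.0", lines))) {
    problems <- c(problems, "missing ##agp-version 2.0 header")
  }
  rows <- lines[nzchar(lines) & !grepl("^#", lines)]
  expect_pos <- 1L
  for (k in seq_along(rows)) {
    f <- strsplit(rows[k], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) {
      problems <- c(problems, sprintf("row %d: %d columns", k, length(f)))
      next
    }
    ob <- suppressWarnings(as.integer(f[2]))
    oe <- suppressWarnings(as.integer(f[3]))
    pn <- suppressWarnings(as.integer(f[4]))
    if (is.na(ob) || is.na(oe) || ob > oe) {
      problems <- c(problems, sprintf("row %d: bad object span", k))
      next
    }
    if (is.na(pn) || pn != k) {
      problems <- c(problems, sprintf("row %d: part_number %s", k, f[4]))
    }
    if (ob != expect_pos) {
      problems <- c(problems, sprintf("row %d: tiling hole/overlap", k))
    }
    expect_pos <- oe + 1L
    if (f[5] == "W") {
      cb <- suppressWarnings(as.integer(f[7]))
      ce <- suppressWarnings(as.integer(f[8]))
      if (is.na(cb) || is.na(ce) || cb < 1L ||
          (oe - ob) != (ce - cb)) {
        problems <- c(problems,
                      sprintf("row %d: object/component span mismatch", k))
      }
      if (!f[9] %in% c("+", "-")) {
        problems <- c(problems, sprintf("row %d: bad orientation", k))
      }
    } else if (f[5] %in% c("N", "U")) {
      gl <- suppressWarnings(as.integer(f[6]))
      if (is.na(gl) || gl != (oe - ob + 1L)) {
        problems <- c(problems, sprintf("row %d: gap length mismatch", k))
      }
      if (!f[8] %in% c("yes", "no")) {
        problems <- c(problems, sprintf("row %d: bad linkage", k))
      }
    } else {
      problems <- c(problems, sprintf("row %d: component_type %s", k, f[5]))
    }
  }
  problems
}

# Check one assembly's layout and sequence invariants; returns violations.
check_assembly_invariants <- function(asm, contigs) {
  problems <- character(0)
  lay <- asm$layout
  if (lay$scaffold_start[1L] != 1L) {
    problems <- c(problems, "layout does not start at 1")
  }
  if (nrow(lay) > 1L &&
      any(lay$scaffold_start[-1L] != lay$scaffold_stop[-nrow(lay)] + 1L)) {
    problems <- c(problems, "layout segments do not tile contiguously")
  }
  if (lay$scaffold_stop[nrow(lay)] != nchar(asm$seq)) {
    problems <- c(problems, "layout does not end at sequence length")
  }
  lens <- lay$scaffold_stop - lay$scaffold_start + 1L
  if (sum(lens) != nchar(asm$seq)) {
    problems <- c(problems, "segment lengths do not sum to sequence length")
  }
  for (i in seq_len(nrow(lay))) {
    slice <- substr(asm$seq, lay$scaffold_start[i], lay$scaffold_stop[i])
    if (lay$kind[i] == "gap") {
      if (!grepl("^N+$", slice)) {
        problems <- c(problems, sprintf("gap segment %d not all N", i))
      }
    } else {
      if (!identical(slice, asm$entry_sequences[[lay$entry_index[i]]])) {
        problems <- c(problems,
                      sprintf("segment %d slice != rendered entry", i))
      }
    }
  }
  problems
}

# Sequence-identity check for a lift report: every lifted feature's
# scaffold slice must equal the original contig slice when its contig was
# placed forward, and the reverse complement when placed reversed (with the
# strand flipped accordingly). Returns violations.
check_lift_identity <- function(report, asm, contigs, original) {
  problems <- character(0)
  orig_ids <- vapply(original$attributes,
                     function(a) unname(a[["ID"]]), character(1))
  lay <- asm$layout
  for (i in seq_len(nrow(report$lifted))) {
    lf <- report$lifted[i, ]
    id <- lf$attributes[[1L]][["ID"]]
    og <- original[orig_ids == id, ]
    placed <- which(lay$kind == "contig" & lay$source_id == og$seqid)
    if (length(placed) != 1L) {
      problems <- c(problems, sprintf("%s: contig not placed exactly once", id))
      next
    }
    reversed <- lay$reversed[placed]
    got <- substr(asm$seq, lf$start, lf$end)
    src <- substr(contigs[[og$seqid]], og$start, og$end)
    want <- if (reversed) oracle_revcomp(src) else src
    if (!identical(got, want)) {
      problems <- c(problems, sprintf("%s: slice mismatch", id))
    }
    want_strand <- if (!reversed || og$strand == ".") og$strand else
      if (og$strand == "+") "-" else "+"
    if (!identical(lf$strand, want_strand)) {
      problems <- c(problems, sprintf("%s: wrong strand", id))
    }
    if (lf$end - lf$start != og$end - og$start) {
      problems <- c(problems, sprintf("%s: length not preserved", id))
    }
  }
  problems
}
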