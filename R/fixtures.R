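# Synthetic fixture generation: random contig sets, gene annotations and
# scaffold plans with a ground-truth map of where every gene must land.
# The ground truth is computed by a straight-line calculation that never
# calls the lift-over code, so comparing the two is a genuine
# two-implementation cross-check.

# Uniform integer in [lo, hi]; avoids sample()'s length-1 surprise.
rint <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  stopifnot(lo <= hi)
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

rdna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

as_range <- function(x, what) {
  x <- as.integer(x)
  if (length(x) == 1L) x <- c(x, x)
  if (length(x) != 2L || any(is.na(x)) || x[1L] > x[2L]) {
    stop(what, " must be a single integer or a (min, max) range",
         call. = FALSE)
  }
  x
}

#' Describe a synthetic fixture
#'
#' The defaults are the package's reference study conditions: 2–6 contigs
#' of 1–10 kbp carrying 0–5 genes each, gaps of 100–500 bp, and placement
#' probabilities 0.5 / 0.3 / 0.3 for reversal, trimming and a single patch
#' insert.
#'
#' @param n_contigs Number of placed contigs; scalar or (min, max) range.
#' @param contig_length Contig length range in bp.
#' @param genes_per_contig Genes per contig; scalar or (min, max) range.
#' @param gap_length Unresolved-gap length range in bp.
#' @param p_reverse,p_trim,p_insert Per-placement probabilities of reverse
#'   orientation, trimming, and carrying one patch insert.
#' @param seed Integer seed; the same seed always yields the same fixture.
#' @export
fixture_spec <- function(n_contigs = c(2L, 6L),
                         contig_length = c(1000L, 10000L),
                         genes_per_contig = c(0L, 5L),
                         gap_length = c(100L, 500L),
                         p_reverse = 0.5, p_trim = 0.3, p_insert = 0.3,
                         seed = 1L) {
  spec <- list(
    n_contigs = as_range(n_contigs, "n_contigs"),
    contig_length = as_range(contig_length, "contig_length"),
    genes_per_contig = as_range(genes_per_contig, "genes_per_contig"),
    gap_length = as_range(gap_length, "gap_length"),
    p_reverse = p_reverse, p_trim = p_trim, p_insert = p_insert,
    seed = as.integer(seed))
  if (spec$n_contigs[1L] < 1L) stop("need at least one contig",
                                    call. = FALSE)
  if (spec$contig_length[1L] < 1L || spec$gap_length[1L] < 1L) {
    stop("length ranges must start at 1", call. = FALSE)
  }
  if (spec$genes_per_contig[1L] < 0L) {
    stop("genes_per_contig must be >= 0", call. = FALSE)
  }
  for (p in c(spec$p_reverse, spec$p_trim, spec$p_insert)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      stop("probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  if (is.na(spec$seed)) stop("seed must be an integer", call. = FALSE)
  class(spec) <- "fixture_spec"
  spec
}

#' Generate a synthetic finishing project with known ground truth
#'
#' Draws random contigs (uniform A/C/G/T), non-overlapping gene intervals,
#' and a scaffold plan placing every contig once (in shuffled order, with
#' optional reversal, trim, single patch insert, and gaps between
#' placements). Alongside, a ground-truth table records where each gene
#' must land on the scaffold — or why it must be dropped — computed
#' independently of the lift-over module.
#'
#' @param spec A [fixture_spec()].
#' @return List with `contigs` (named character vector, patches included),
#'   `annotations` (contig-space gene table), `scaffold` (the plan),
#'   `truth` (data frame: `id`, `status` `"retained"`/`"clipped"`,
#'   `reason`, `exp_start`, `exp_stop`, `exp_strand`) and `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(spec$seed)

  n <- rint(spec$n_contigs[1L], spec$n_contigs[2L])
  contig_ids <- sprintf("contig%02d", seq_len(n))
  lens <- integer(n)
  contigs <- character(0)
  ann <- list()
  for (i in seq_len(n)) {
    lens[i] <- rint(spec$contig_length[1L], spec$contig_length[2L])
    contigs[[contig_ids[i]]] <- rdna(lens[i])
    k <- rint(spec$genes_per_contig[1L], spec$genes_per_contig[2L])
    if (k == 0L) next
    # one gene per equal-width block keeps intervals non-overlapping
    bw <- lens[i] %/% k
    if (bw < 25L) {
      stop(sprintf("cannot fit %d genes on a %d bp contig", k, lens[i]),
           call. = FALSE)
    }
    for (j in seq_len(k)) {
      b1 <- (j - 1L) * bw + 1L
      glen <- rint(20L, min(300L, bw - 4L))
      gstart <- b1 + rint(0L, bw - glen - 1L)
      gid <- sprintf("gene_%02d_%02d", i, j)
      ann[[gid]] <- make_annotations(
        seqid = contig_ids[i], start = gstart, end = gstart + glen - 1L,
        strand = if (runif(1) < 0.5) "+" else "-",
        attributes = list(c(
          ID = gid,
          Name = sprintf("gn%02d%02d", i, j),
          locus_tag = sprintf("TMP_%02d%02d", i, j),
          product = sample(c("hypothetical protein",
                             "DNA polymerase III subunit alpha",
                             "ABC transporter permease",
                             "50S ribosomal protein L3"), 1L))))
    }
  }
  annotations <- do.call(rbind, unname(ann))
  if (is.null(annotations)) annotations <- empty_annotations()

  order_idx <- sample.int(n)
  entries <- list()
  placements <- list()
  patch_n <- 0L
  for (pos in seq_along(order_idx)) {
    i <- order_idx[pos]
    host_len <- lens[i]
    ins <- list()
    ins_meta <- NULL
    if (runif(1) < spec$p_insert && host_len >= 200L) {
      span <- rint(40L, 120L)
      open <- rint(1L, host_len - span + 1L)
      close <- open + span - 1L
      patch_n <- patch_n + 1L
      patch_id <- sprintf("patch%02d", patch_n)
      patch_len <- rint(20L, 140L)
      contigs[[patch_id]] <- rdna(patch_len)
      ins <- list(contig_insert(patch_id, open, close))
      ins_meta <- list(open = open, close = close, patch_len = patch_len)
    }
    post_len <- host_len +
      if (is.null(ins_meta)) 0L else
        ins_meta$patch_len - (ins_meta$close - ins_meta$open + 1L)
    t_start <- 1L
    t_stop <- NA_integer_
    if (runif(1) < spec$p_trim && post_len >= 40L) {
      t_start <- rint(1L, max(1L, post_len %/% 10L))
      t_stop <- rint(post_len - post_len %/% 10L, post_len)
    }
    reverse <- runif(1) < spec$p_reverse
    entries[[length(entries) + 1L]] <-
      seq_entry(contig_ids[i], t_start, t_stop, reverse, ins)
    placements[[contig_ids[i]]] <- list(
      insert = ins_meta, t_start = t_start,
      t_stop = if (is.na(t_stop)) post_len else t_stop,
      reverse = reverse, post_len = post_len)
    if (pos < length(order_idx) && runif(1) < 0.7) {
      entries[[length(entries) + 1L]] <-
        gap_entry(rint(spec$gap_length[1L], spec$gap_length[2L]))
    }
  }
  plan <- scaffold(entries)

  # --- independent ground truth -----------------------------------------
  # scaffold offset of each entry, from entry lengths alone
  offsets <- integer(length(entries))
  cum <- 0L
  for (e in seq_along(entries)) {
    offsets[e] <- cum
    ent <- entries[[e]]
    cum <- cum + if (ent$kind == "unresolved") ent$length else {
      pl <- placements[[ent$source]]
      pl$t_stop - pl$t_start + 1L
    }
  }
  entry_of <- vapply(entries, function(ent) {
    if (ent$kind == "sequence") ent$source else NA_character_
  }, character(1))

  truth <- data.frame(id = character(0), status = character(0),
                      reason = character(0), exp_start = integer(0),
                      exp_stop = integer(0), exp_strand = character(0),
                      stringsAsFactors = FALSE)
  for (r in seq_len(nrow(annotations))) {
    g <- annotations[r, ]
    gid <- g$attributes[[1L]][["ID"]]
    pl <- placements[[g$seqid]]
    e <- which(entry_of == g$seqid)
    off <- offsets[e]
    row <- list(id = gid, status = "retained", reason = NA_character_,
                exp_start = NA_integer_, exp_stop = NA_integer_,
                exp_strand = NA_character_)
    im <- pl$insert
    if (!is.null(im) && g$start <= im$close && g$end >= im$open) {
      row$status <- "clipped"
      row$reason <- "overlaps-insert-region"
    } else {
      shift <- if (!is.null(im) && g$start > im$close) {
        im$patch_len - (im$close - im$open + 1L)
      } else 0L
      m1 <- g$start + shift
      m2 <- g$end + shift
      if (m1 < pl$t_start || m2 > pl$t_stop) {
        row$status <- "clipped"
        row$reason <- "overlaps-trimmed-region"
      } else if (!pl$reverse) {
        row$exp_start <- off + (m1 - pl$t_start) + 1L
        row$exp_stop <- off + (m2 - pl$t_start) + 1L
        row$exp_strand <- g$strand
      } else {
        row$exp_start <- off + (pl$t_stop - m2) + 1L
        row$exp_stop <- off + (pl$t_stop - m1) + 1L
        row$exp_strand <- if (g$strand == "+") "-" else
          if (g$strand == "-") "+" else g$strand
      }
    }
    truth <- rbind(truth, as.data.frame(row, stringsAsFactors = FALSE))
  }

  list(contigs = contigs, annotations = annotations, scaffold = plan,
       truth = truth, spec = spec)
}

#' Write a fixture to disk as a three-file finishing project
#'
#' Writes `contigs.fasta`, `annotations.gff3` and `scaffold.yml` into a
#' directory, ready for [cmd_view()] / the command-line tool.
#'
#' @param fixture A [generate_fixture()] result (or any list with
#'   `contigs`, `annotations`, `scaffold`).
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fixture_dir <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(sub("\n$", "", render_fasta(fixture$contigs)),
             file.path(dir, "contigs.fasta"))
  lens <- nchar(fixture$contigs)
  writeLines(sub("\n$", "", write_gff3(fixture$annotations, lens)),
             file.path(dir, "annotations.gff3"))
  writeLines(sub("\n$", "", write_scaffold(fixture$scaffold)),
             file.path(dir, "scaffold.yml"))
  invisible(dir)
}
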