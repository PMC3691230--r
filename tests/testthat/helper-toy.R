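# A small fully hand-checkable finishing project used by the submission
# and CLI tests. Layout (135 bp scaffold):
#   contig1 forward, untouched          -> scaffold [1, 60]
#   gap 10                              -> [61, 70]
#   contig2 reversed                    -> [71, 110]
#   gap 5                               -> [111, 115]
#   contig3 trimmed to [5, 24]          -> [116, 135]
# Genes: g1 contig1 [11, 40] + (dnaE); g2 contig2 [5, 16] +;
#        g3 contig3 [1, 8] + (clipped by the trim).
toy_project <- function() {
  contigs <- c(
    contig1 = paste0("ACGTACGTAC", "GATTACAGAT", "TACAGATTAC",
                     "AGGCCGGCCG", "TTTTAAAACC", "CCGGGGTTAA"),
    contig2 = paste0("TTGACATTGA", "CATTGACATT", "GACAGGGGCC", "CCAATTGGAA"),
    contig3 = paste0("AAACCCGGGT", "TTACGTACGT", "ACGTAAACCC"))
  annotations <- rbind(
    make_annotations("contig1", 11L, 40L, "+",
                     attributes = list(c(ID = "g1", Name = "dnaE",
                                         locus_tag = "TMP_0001",
                                         product = "DNA polymerase III"))),
    make_annotations("contig2", 5L, 16L, "+",
                     attributes = list(c(ID = "g2",
                                         locus_tag = "TMP_0002"))),
    make_annotations("contig3", 1L, 8L, "+",
                     attributes = list(c(ID = "g3",
                                         locus_tag = "TMP_0003"))))
  plan <- scaffold(list(
    seq_entry("contig1"),
    gap_entry(10L),
    seq_entry("contig2", reverse = TRUE),
    gap_entry(5L),
    seq_entry("contig3", start = 5L, stop = 24L)))
  list(contigs = contigs, annotations = annotations, scaffold = plan)
}

# Write the toy project into a temp directory; caller owns cleanup via
# withr deferral.
toy_dir <- function(env = parent.frame()) {
  d <- withr::local_tempdir(.local_envir = env)
  write_fixture_dir(toy_project(), d)
  d
}

# Run the CLI in-process, capturing stdout/stderr separately.
run_cli <- function(args) {
  out_buf <- character(0)
  err_buf <- character(0)
  out_c <- textConnection("out_buf", "w", local = TRUE)
  err_c <- textConnection("err_buf", "w", local = TRUE)
  status <- ssmith_main(args, out = out_c, err = err_c)
  close(out_c)
  close(err_c)
  list(status = status,
       out = if (length(out_buf)) {
         paste0(paste(out_buf, collapse = "\n"), "\n")
       } else "",
       err = err_buf)
}
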