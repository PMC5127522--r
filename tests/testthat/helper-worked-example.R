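# The 4-taxon, 5-site alignment used throughout the documentation: Tax2
# duplicates Tax1, sites 2 and 4 share a split, site 1 is invariant.
worked_alignment <- function() {
  alignment(c(Tax1 = "abaca", Tax2 = "abaca", Tax3 = "aaaac",
              Tax4 = "aacad"), alphabet_kind = "categorical")
}

worked_fasta <- function() {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">Tax1", "abaca", ">Tax2", "abaca",
               ">Tax3", "aaaac", ">Tax4", "aacad"), fa)
  fa
}

# Config matching the worked example: singleton states included.
cfg1 <- function(...) metric_config(min_state_count = 1, ...)
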