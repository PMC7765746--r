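# Small in-code fixtures shared across test files.

# Record with two H-strand PCGs and one L-strand PCG on a 400 bp genome,
# built by the generator so every declared column is self-consistent.
tinyRecord <- function(seed = 11L) {
  ft <- data.frame(
    locus = c("GENE1", "GENE2", "GENE3"),
    category = "PCG",
    strand = c("H", "H", "L"),
    start = c(10L, 120L, 240L),
    stop = c(108L, 219L, 338L),
    start_codon = c("ATG", "GTG", "ATG"),
    stop_codon = c("TAA", "T-", "TAG"),
    stringsAsFactors = FALSE)
  generateGenome(genomeSpec(ft, genomeLength = 400L, seed = seed,
                            taxon = paste0("synth", seed)))
}

# Per-site classification oracle for transition/transversion proportions.
bruteForcePQ <- function(a, b) {
  pur <- c("A", "G")
  usable <- 0L; ts <- 0L; tv <- 0L
  for (k in seq_along(a)) {
    if (!a[k] %in% c("A", "C", "G", "T") || !b[k] %in% c("A", "C", "G", "T"))
      next
    usable <- usable + 1L
    if (a[k] == b[k]) next
    if ((a[k] %in% pur) == (b[k] %in% pur)) ts <- ts + 1L else tv <- tv + 1L
  }
  list(P = ts / usable, Q = tv / usable, usable = usable)
}

# The start/stop codon row the cross-species matrix prints for the
# reference taxon (13 canonical PCGs, ASCII stop labels).
referenceStartStopRow <- function() {
  c(ND1 = "ATG/TAA", ND2 = "ATG/T-", COI = "GTG/TAA", COII = "ATG/T-",
    ATP8 = "ATG/TAG", ATP6 = "GTG/TA-", COIII = "ATG/TA-", ND3 = "ATG/T-",
    ND4L = "ATG/TAA", ND4 = "ATG/T-", ND5 = "ATG/TAA", ND6 = "ATG/TAG",
    Cytb = "ATG/T-")
}
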