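LOCUS_SYNONYMS <- c(
  "COX1" = "COI", "CO1" = "COI", "COXI" = "COI",
  "COX2" = "COII", "CO2" = "COII", "COXII" = "COII",
  "COX3" = "COIII", "CO3" = "COIII", "COXIII" = "COIII",
  "CYTB" = "Cytb", "COB" = "Cytb", "CYT B" = "Cytb", "CYB" = "Cytb",
  "ATPASE6" = "ATP6", "ATPASE8" = "ATP8", "ATP 6" = "ATP6", "ATP 8" = "ATP8",
  "NAD1" = "ND1", "NAD2" = "ND2", "NAD3" = "ND3", "NAD4" = "ND4",
  "NAD4L" = "ND4L", "NAD5" = "ND5", "NAD6" = "ND6",
  "12S" = "12S-rRNA", "RRNS" = "12S-rRNA", "12S RRNA" = "12S-rRNA",
  "12S RIBOSOMAL RNA" = "12S-rRNA", "S-RRNA" = "12S-rRNA",
  "16S" = "16S-rRNA", "RRNL" = "16S-rRNA", "16S RRNA" = "16S-rRNA",
  "16S RIBOSOMAL RNA" = "16S-rRNA", "L-RRNA" = "16S-rRNA",
  "D-LOOP" = "D-loop", "CONTROL REGION" = "D-loop")

#' Harmonize gene locus names
#'
#' Maps common spelling variants of mitochondrial gene names (COX1/COI,
#' CYTB/Cytb, NAD1/ND1, rrnS/12S-rRNA, ...) onto the canonical names used
#' throughout the package. Unrecognized names pass through verbatim with a
#' warning; canonical names (and tRNA-* names) are silently kept.
#'
#' @param loci character vector of locus names.
#' @param warn warn on unrecognized non-canonical names.
#' @return character vector of harmonized names.
#' @export
harmonizeLoci <- function(loci, warn = FALSE) {
  canonical <- c(CANONICAL_PCGS, "12S-rRNA", "16S-rRNA", "D-loop")
  key <- toupper(loci)
  out <- loci
  hit <- key %in% names(LOCUS_SYNONYMS)
  out[hit] <- unname(LOCUS_SYNONYMS[key[hit]])
  # case-insensitive match against canonical names
  canon_hit <- !hit & key %in% toupper(canonical)
  out[canon_hit] <- canonical[match(key[canon_hit], toupper(canonical))]
  if (warn) {
    unknown <- !hit & !canon_hit & !startsWith(out, "tRNA")
    if (any(unknown))
      warning("unrecognized locus name(s) kept verbatim: ",
              paste(unique(out[unknown]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Start/stop codon matrix across genomes
#'
#' One row per record, one column per canonical protein-coding gene, each
#' cell a "START/STOP" label pair (e.g. "ATG/T-"); locus names are
#' harmonized before matching. An accompanying difference report lists,
#' per gene, the taxa whose label pair deviates from the column's majority.
#'
#' @param records list of \code{\linkS4class{MitoRecord}} with distinct
#'   taxon labels.
#' @param loci columns to report (default the 13 canonical PCGs).
#' @return list: \code{matrix} (data.frame, rownames = taxa, plus an
#'   \code{accession} column), \code{differences} (data.frame gene/taxon/
#'   label/majority).
#' @export
startStopMatrix <- function(records, loci = CANONICAL_PCGS) {
  taxa <- vapply(records, taxonName, character(1))
  if (anyDuplicated(taxa))
    stop("duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  cells <- matrix("", nrow = length(records), ncol = length(loci),
                  dimnames = list(taxa, loci))
  for (r in seq_along(records)) {
    rep <- pcgCodonReport(records[[r]])
    ss <- rep$startStop
    ss$locus <- harmonizeLoci(ss$locus)
    hit <- match(loci, ss$locus)
    missing <- is.na(hit)
    if (any(missing))
      warning(sprintf("%s: missing gene(s) %s", taxa[r],
                      paste(loci[missing], collapse = ", ")), call. = FALSE)
    cells[r, !missing] <- paste0(ss$start_codon[hit[!missing]], "/",
                                 ss$stop_codon[hit[!missing]])
  }
  diffs <- list()
  for (j in seq_along(loci)) {
    col <- cells[, j]
    col <- col[nzchar(col)]
    if (length(col) < 2L) next
    tab <- sort(table(col), decreasing = TRUE)
    majority <- names(tab)[1L]
    dev <- names(col)[col != majority]
    for (taxon in dev)
      diffs[[length(diffs) + 1L]] <- data.frame(
        gene = loci[j], taxon = taxon, label = col[[taxon]],
        majority = majority, stringsAsFactors = FALSE)
  }
  mat <- as.data.frame(cells, stringsAsFactors = FALSE)
  mat$accession <- vapply(records, accessionOf, character(1))
  list(matrix = mat,
       differences = if (length(diffs)) do.call(rbind, diffs)
       else data.frame(gene = character(0), taxon = character(0),
                       label = character(0), majority = character(0),
                       stringsAsFactors = FALSE))
}

#' Genome-level length/composition/skew summary across records
#'
#' @param records list of \code{\linkS4class{MitoRecord}}.
#' @return data.frame sorted by taxon: \code{taxon}, \code{accession},
#'   \code{length_bp}, \code{AT_pct}, \code{at_skew}, \code{gc_skew}.
#' @export
genomeSummary <- function(records) {
  rows <- lapply(records, function(rec) {
    comp <- baseComposition(genomeSequence(rec), "genome")
    data.frame(taxon = taxonName(rec), accession = accessionOf(rec),
               length_bp = comp$length, AT_pct = comp$AT_pct,
               at_skew = comp$at_skew, gc_skew = comp$gc_skew,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}
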