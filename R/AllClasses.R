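#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

FEATURE_CATEGORIES <- c("PCG", "tRNA", "rRNA", "control")

FEATURE_COLUMNS <- c("locus", "category", "strand", "start", "stop",
                     "size", "start_codon", "stop_codon", "anticodon",
                     "intergenic")

#' GeneTable: ordered annotation of a circular mitochondrial genome
#'
#' Holds the gene map of one mitogenome: one row per feature (protein-coding
#' gene, tRNA, rRNA or control region) with 1-based fully inclusive
#' coordinates on the deposited (H) strand. A feature whose \code{start}
#' exceeds its \code{stop} wraps across the origin of a circular genome.
#' Declared columns (\code{size}, \code{start_codon}, \code{stop_codon},
#' \code{anticodon}, \code{intergenic}) are stored verbatim as annotated and
#' never recomputed in place; discrepancies against coordinate-derived
#' values are surfaced by \code{\link{validateTable}}.
#'
#' @slot features data.frame with columns \code{locus}, \code{category}
#'   (PCG/tRNA/rRNA/control), \code{strand} (H/L), \code{start}, \code{stop}
#'   plus the declared columns above (NA where not annotated), ordered by
#'   ascending \code{start}.
#' @slot genomeLength integer genome length in bp.
#' @slot circular logical, circular topology flag.
#' @slot taxon character label of the organism.
#' @slot accession character, sequence database accession ("" if none).
#'
#' @seealso \code{\link{geneTable}}, \code{\link{junctionGaps}},
#'   \code{\link{validateTable}}, \code{\link{table1Fixture}}
#' @exportClass GeneTable
setClass("GeneTable",
  representation(
    features = "data.frame",
    genomeLength = "integer",
    circular = "logical",
    taxon = "character",
    accession = "character"
  )
)

setValidity("GeneTable", function(object) {
  ft <- object@features
  msgs <- character(0)
  missing_cols <- setdiff(c("locus", "category", "strand", "start", "stop"),
                          colnames(ft))
  if (length(missing_cols))
    return(paste("features missing column(s):",
                 paste(missing_cols, collapse = ", ")))
  L <- object@genomeLength
  if (length(L) != 1L || is.na(L) || L < 1L)
    msgs <- c(msgs, "genomeLength must be a single positive integer")
  bad_cat <- setdiff(unique(ft$category), FEATURE_CATEGORIES)
  if (length(bad_cat))
    msgs <- c(msgs, paste("unknown category:", paste(bad_cat, collapse = ", ")))
  bad_strand <- setdiff(unique(ft$strand), c("H", "L"))
  if (length(bad_strand))
    msgs <- c(msgs, paste("strand must be H or L, got:",
                          paste(bad_strand, collapse = ", ")))
  if (nrow(ft) && length(msgs) == 0L) {
    out <- ft$start < 1L | ft$start > L | ft$stop < 1L | ft$stop > L
    if (any(out))
      msgs <- c(msgs, paste0("coordinates outside [1, ", L, "] for: ",
                             paste(ft$locus[out], collapse = ", ")))
    wraps <- ft$start > ft$stop
    if (any(wraps) && !object@circular)
      msgs <- c(msgs, paste0("wrapping feature on a linear genome: ",
                             paste(ft$locus[wraps], collapse = ", ")))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a GeneTable
#'
#' @param features data.frame of features; required columns \code{locus},
#'   \code{category}, \code{strand}, \code{start}, \code{stop}. Optional
#'   declared columns \code{size}, \code{start_codon}, \code{stop_codon},
#'   \code{anticodon}, \code{intergenic} are kept verbatim; absent ones are
#'   filled with NA.
#' @param genomeLength genome length in bp.
#' @param circular logical; circular topology (default TRUE).
#' @param taxon,accession organism label and database accession.
#' @return A \code{\linkS4class{GeneTable}}.
#' @examples
#' gt <- geneTable(
#'   data.frame(locus = c("g1", "g2"), category = c("PCG", "tRNA"),
#'              strand = c("H", "H"), start = c(1, 100), stop = c(90, 170)),
#'   genomeLength = 200)
#' nFeatures(gt)
#' @export
geneTable <- function(features, genomeLength, circular = TRUE,
                      taxon = "", accession = "") {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  for (col in setdiff(FEATURE_COLUMNS, colnames(features)))
    features[[col]] <- if (col %in% c("size", "intergenic")) NA_integer_
                       else NA_character_
  features$start <- as.integer(features$start)
  features$stop <- as.integer(features$stop)
  features$size <- as.integer(features$size)
  features$intergenic <- as.integer(features$intergenic)
  for (col in c("locus", "category", "strand", "start_codon",
                "stop_codon", "anticodon"))
    features[[col]] <- as.character(features[[col]])
  features <- features[FEATURE_COLUMNS]
  rownames(features) <- NULL
  new("GeneTable", features = features,
      genomeLength = as.integer(genomeLength),
      circular = isTRUE(circular), taxon = as.character(taxon),
      accession = as.character(accession))
}

#' MitoRecord: an annotated mitochondrial genome
#'
#' Couples a genome sequence (deposited/H strand) with its
#' \code{\linkS4class{GeneTable}}, the unit consumed by the composition,
#' codon-usage and comparative analyses.
#'
#' @slot sequence \code{DNAString}, the H-strand sequence (A/C/G/T/N).
#' @slot geneTable the annotation (\code{\linkS4class{GeneTable}}).
#' @slot source character provenance note (file path or generator tag).
#'
#' @seealso \code{\link{mitoRecord}}, \code{\link{readGenBank}},
#'   \code{\link{generateGenome}}
#' @exportClass MitoRecord
setClass("MitoRecord",
  representation(
    sequence = "DNAString",
    geneTable = "GeneTable",
    source = "character"
  )
)

setValidity("MitoRecord", function(object) {
  if (length(object@sequence) != object@geneTable@genomeLength)
    return(sprintf("sequence length (%d) != geneTable genomeLength (%d)",
                   length(object@sequence), object@geneTable@genomeLength))
  TRUE
})

#' Construct a MitoRecord
#'
#' @param sequence a \code{DNAString} or single character string (upper-cased,
#'   U converted to T).
#' @param geneTable a \code{\linkS4class{GeneTable}} whose
#'   \code{genomeLength} equals the sequence length.
#' @param source provenance note.
#' @return A \code{\linkS4class{MitoRecord}}.
#' @export
mitoRecord <- function(sequence, geneTable, source = "") {
  if (is.character(sequence))
    sequence <- Biostrings::DNAString(normalizeResidues(sequence))
  new("MitoRecord", sequence = sequence, geneTable = geneTable,
      source = as.character(source))
}

# Uppercase, U->T, map ambiguity codes beyond N to N (with a warning).
normalizeResidues <- function(x, allowGap = FALSE) {
  x <- chartr("U", "T", toupper(x))
  ok <- c("A", "C", "G", "T", "N", if (allowGap) "-")
  chars <- strsplit(x, "", fixed = TRUE)
  fixed <- vapply(chars, function(ch) {
    bad <- !(ch %in% ok)
    if (any(bad)) {
      warning(sprintf("%d ambiguity character(s) mapped to N", sum(bad)),
              call. = FALSE)
      ch[bad] <- "N"
    }
    paste(ch, collapse = "")
  }, character(1))
  unname(fixed)
}

#' JunctionReport: gaps and overlaps between consecutive features
#'
#' Result of \code{\link{junctionGaps}}. For each consecutive feature pair
#' the signed gap in bp (negative = overlap, positive = intergenic spacer,
#' zero = contiguous), with overlap/spacer totals and extremes.
#'
#' @slot junctions data.frame with columns \code{upstream}, \code{downstream},
#'   \code{gap}.
#' @slot overlapBp,overlapJunctionCount total overlapping bp and number of
#'   overlapping junctions.
#' @slot spacerBp,spacerRegionCount total spacer bp and number of spacer
#'   regions.
#' @slot largestSpacer,largestOverlap lists with \code{bp} and \code{pairs}
#'   (character vector "upstream/downstream", all pairs attaining the
#'   extreme).
#' @exportClass JunctionReport
setClass("JunctionReport",
  representation(
    junctions = "data.frame",
    overlapBp = "integer",
    overlapJunctionCount = "integer",
    spacerBp = "integer",
    spacerRegionCount = "integer",
    largestSpacer = "list",
    largestOverlap = "list"
  )
)

#' @describeIn GeneTable-accessors number of features
#' @export
nFeatures <- function(x) nrow(x@features)

#' Accessors for GeneTable and MitoRecord
#'
#' @param x a \code{GeneTable} or \code{MitoRecord}.
#' @name GeneTable-accessors
#' @aliases features genomeLength isCircular taxonName accessionOf
NULL

#' @describeIn GeneTable-accessors the feature data.frame
#' @export
features <- function(x) {
  if (is(x, "MitoRecord")) x <- x@geneTable
  x@features
}

#' @describeIn GeneTable-accessors genome length in bp
#' @export
genomeLength <- function(x) {
  if (is(x, "MitoRecord")) x <- x@geneTable
  x@genomeLength
}

#' @describeIn GeneTable-accessors circular topology flag
#' @export
isCircular <- function(x) {
  if (is(x, "MitoRecord")) x <- x@geneTable
  x@circular
}

#' @describeIn GeneTable-accessors taxon label
#' @export
taxonName <- function(x) {
  if (is(x, "MitoRecord")) x <- x@geneTable
  x@taxon
}

#' @describeIn GeneTable-accessors accession ("" if none)
#' @export
accessionOf <- function(x) {
  if (is(x, "MitoRecord")) x <- x@geneTable
  x@accession
}

#' @describeIn GeneTable-accessors genome sequence of a MitoRecord
#' @export
genomeSequence <- function(x) x@sequence

setMethod("show", "GeneTable", function(object) {
  ft <- object@features
  cat(sprintf("GeneTable: %d feature(s) on a %s %d bp genome\n",
              nrow(ft), if (object@circular) "circular" else "linear",
              object@genomeLength))
  if (nzchar(object@taxon))
    cat("  taxon:", object@taxon,
        if (nzchar(object@accession)) paste0("(", object@accession, ")"),
        "\n")
  tab <- table(factor(ft$category, levels = FEATURE_CATEGORIES))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "MitoRecord", function(object) {
  cat(sprintf("MitoRecord: %d bp %s genome\n", length(object@sequence),
              if (object@geneTable@circular) "circular" else "linear"))
  show(object@geneTable)
})

setMethod("show", "JunctionReport", function(object) {
  cat(sprintf(
    "JunctionReport: %d junction(s)\n  overlaps: %d bp over %d junction(s)\n",
    nrow(object@junctions), object@overlapBp, object@overlapJunctionCount))
  cat(sprintf("  spacers: %d bp over %d region(s)\n",
              object@spacerBp, object@spacerRegionCount))
  if (length(object@largestOverlap$pairs))
    cat(sprintf("  largest overlap: %d bp (%s)\n", object@largestOverlap$bp,
                paste(object@largestOverlap$pairs, collapse = "; ")))
  if (length(object@largestSpacer$pairs))
    cat(sprintf("  largest spacer: %d bp (%s)\n", object@largestSpacer$bp,
                paste(object@largestSpacer$pairs, collapse = "; ")))
})
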