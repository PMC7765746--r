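#' Feature length on a (possibly circular) genome
#'
#' Length in bp of a feature with 1-based fully inclusive coordinates.
#' On a circular genome a feature with \code{start > stop} wraps across the
#' origin and its length is \code{(genomeLength - start + 1) + stop}.
#'
#' @param start,stop 1-based inclusive coordinates (vectorized).
#' @param genomeLength genome length in bp.
#' @param circular logical; whether wrapping is permitted.
#' @param locus optional label(s) used in error messages.
#' @return integer vector of lengths (always >= 1).
#' @examples
#' featureLength(4052, 5096, 16598)   # 1045
#' featureLength(16590, 10, 16598)    # 19, wraps the origin
#' @export
featureLength <- function(start, stop, genomeLength, circular = TRUE,
                          locus = NULL) {
  start <- as.integer(start); stop <- as.integer(stop)
  genomeLength <- as.integer(genomeLength)
  bad <- start < 1L | start > genomeLength | stop < 1L | stop > genomeLength
  if (any(bad)) {
    who <- if (is.null(locus)) which(bad) else locus[bad]
    stop(sprintf("coordinate outside [1, %d] for feature(s): %s",
                 genomeLength, paste(who, collapse = ", ")))
  }
  wraps <- start > stop
  if (any(wraps) && !circular) {
    who <- if (is.null(locus)) which(wraps) else locus[wraps]
    stop(sprintf("start > stop on a linear genome for feature(s): %s",
                 paste(who, collapse = ", ")))
  }
  ifelse(wraps, (genomeLength - start + 1L) + stop, stop - start + 1L)
}

#' Lengths of all features in a GeneTable
#'
#' @param table a \code{\linkS4class{GeneTable}} or \code{MitoRecord}.
#' @return named integer vector (names = loci).
#' @export
featureLengths <- function(table) {
  ft <- features(table)
  stats::setNames(
    featureLength(ft$start, ft$stop, genomeLength(table),
                  isCircular(table), ft$locus),
    ft$locus)
}

#' Junction gaps, overlaps and spacers between consecutive features
#'
#' For each consecutive pair of features in ascending-start order the signed
#' gap \code{start(downstream) - stop(upstream) - 1} is computed; negative
#' gaps are overlaps of \code{|gap|} bp, positive gaps are intergenic
#' spacers, zero gaps are contiguous junctions counted as neither. Junctions
#' pair consecutive rows regardless of strand, the convention in which
#' mitogenome gene tables print their intergenic column.
#'
#' The junction between the last and the first feature (across the circular
#' origin) is excluded by default, matching printed tables that do not
#' report it; set \code{includeOriginJunction = TRUE} to append it with gap
#' \code{start(first) + genomeLength - stop(last) - 1}.
#'
#' @param table a \code{\linkS4class{GeneTable}} (or \code{MitoRecord}) with
#'   >= 2 features in ascending-start order.
#' @param includeOriginJunction include the origin-spanning junction
#'   (circular genomes only).
#' @return A \code{\linkS4class{JunctionReport}}.
#' @examples
#' gt <- table1Fixture()
#' jr <- junctionGaps(gt)
#' overlapTotals(jr)   # 22 bp over 6 junctions
#' @export
junctionGaps <- function(table, includeOriginJunction = FALSE) {
  ft <- features(table)
  if (nrow(ft) < 2L)
    stop("junctionGaps needs at least 2 features")
  if (is.unsorted(ft$start))
    stop("features are not in ascending-start order; sort the table first")
  up <- ft[-nrow(ft), , drop = FALSE]
  down <- ft[-1L, , drop = FALSE]
  jx <- data.frame(upstream = up$locus, downstream = down$locus,
                   gap = down$start - up$stop - 1L,
                   stringsAsFactors = FALSE)
  if (includeOriginJunction) {
    if (!isCircular(table))
      stop("origin junction requested on a linear genome")
    jx <- rbind(jx, data.frame(
      upstream = ft$locus[nrow(ft)], downstream = ft$locus[1L],
      gap = ft$start[1L] + genomeLength(table) - ft$stop[nrow(ft)] - 1L))
  }
  ov <- jx$gap < 0L
  sp <- jx$gap > 0L
  pair <- paste(jx$upstream, jx$downstream, sep = "/")
  largestOverlap <- if (any(ov)) {
    m <- max(-jx$gap[ov])
    list(bp = m, pairs = pair[ov & -jx$gap == m])
  } else list(bp = 0L, pairs = character(0))
  largestSpacer <- if (any(sp)) {
    m <- max(jx$gap[sp])
    list(bp = m, pairs = pair[sp & jx$gap == m])
  } else list(bp = 0L, pairs = character(0))
  new("JunctionReport", junctions = jx,
      overlapBp = as.integer(sum(-jx$gap[ov])),
      overlapJunctionCount = as.integer(sum(ov)),
      spacerBp = as.integer(sum(jx$gap[sp])),
      spacerRegionCount = as.integer(sum(sp)),
      largestSpacer = largestSpacer, largestOverlap = largestOverlap)
}

#' @rdname junctionGaps
#' @param report a \code{JunctionReport}.
#' @export
overlapTotals <- function(report)
  c(overlap_bp = report@overlapBp,
    overlap_junctions = report@overlapJunctionCount)

#' @rdname junctionGaps
#' @export
spacerTotals <- function(report)
  c(spacer_bp = report@spacerBp,
    spacer_regions = report@spacerRegionCount)

#' @rdname junctionGaps
#' @export
junctions <- function(report) report@junctions

#' @rdname junctionGaps
#' @export
largestOverlap <- function(report) report@largestOverlap

#' @rdname junctionGaps
#' @export
largestSpacer <- function(report) report@largestSpacer

CANONICAL_PCGS <- c("ND1", "ND2", "COI", "COII", "ATP8", "ATP6", "COIII",
                    "ND3", "ND4L", "ND4", "ND5", "ND6", "Cytb")

#' Cross-check declared annotation columns against recomputed values
#'
#' Compares the declared (verbatim) columns of a gene table against values
#' recomputed from its coordinates and, when a sequence is supplied, from
#' the sequence itself. Printed mitogenome tables are not always internally
#' consistent; this surfaces the discrepancies as findings without ever
#' modifying the table.
#'
#' Checks: declared \code{size} vs coordinate-derived length; declared
#' \code{intergenic} vs recomputed junction gap; declared start/stop codon
#' labels vs sequence-derived codons (sequence needed); presence of the
#' canonical vertebrate complement (13 PCGs, 22 tRNAs, 2 rRNAs, 1 control
#' region).
#'
#' @param table a \code{\linkS4class{GeneTable}} or \code{MitoRecord}.
#' @param sequence optional \code{DNAString}/character genome sequence
#'   (taken from the record when \code{table} is a \code{MitoRecord}).
#' @return data.frame of findings with columns \code{locus}, \code{check},
#'   \code{declared}, \code{derived}, \code{message}; zero rows when the
#'   table is self-consistent.
#' @examples
#' v <- validateTable(table1Fixture())
#' subset(v, check == "intergenic")  # printed 4 vs coordinate-derived 5
#' @export
validateTable <- function(table, sequence = NULL) {
  if (is(table, "MitoRecord")) {
    if (is.null(sequence)) sequence <- genomeSequence(table)
    table <- table@geneTable
  }
  ft <- features(table)
  finding <- function(locus, check, declared, derived, message)
    data.frame(locus = locus, check = check,
               declared = as.character(declared),
               derived = as.character(derived),
               message = message, stringsAsFactors = FALSE)
  out <- list()

  lens <- featureLength(ft$start, ft$stop, genomeLength(table),
                        isCircular(table), ft$locus)
  has_size <- !is.na(ft$size)
  bad <- has_size & ft$size != lens
  for (i in which(bad))
    out[[length(out) + 1L]] <- finding(
      ft$locus[i], "size", ft$size[i], lens[i],
      sprintf("declared size %d differs from coordinate-derived length %d",
              ft$size[i], lens[i]))

  # declared intergenic column: attached to the downstream feature of each
  # junction (first row's declared value, if any, refers to the origin
  # junction and is not checked)
  if (nrow(ft) >= 2L && any(!is.na(ft$intergenic))) {
    gaps <- ft$start[-1L] - ft$stop[-nrow(ft)] - 1L
    decl <- ft$intergenic[-1L]
    bad <- !is.na(decl) & decl != gaps
    for (k in which(bad))
      out[[length(out) + 1L]] <- finding(
        ft$locus[k + 1L], "intergenic", decl[k], gaps[k],
        sprintf("declared intergenic %d differs from %s->%s gap %d",
                decl[k], ft$locus[k], ft$locus[k + 1L], gaps[k]))
  }

  if (!is.null(sequence)) {
    rec <- mitoRecord(sequence, table)
    for (i in which(ft$category == "PCG")) {
      ex <- tryCatch(extractCodons(rec, ft$locus[i], featureIndex = i),
                     error = function(e) NULL)
      if (is.null(ex)) next
      if (!is.na(ft$start_codon[i]) && nzchar(ft$start_codon[i]) &&
          ft$start_codon[i] != ex$start_label)
        out[[length(out) + 1L]] <- finding(
          ft$locus[i], "start_codon", ft$start_codon[i], ex$start_label,
          sprintf("declared start codon %s differs from sequence-derived %s",
                  ft$start_codon[i], ex$start_label))
      if (!is.na(ft$stop_codon[i]) && nzchar(ft$stop_codon[i]) &&
          ft$stop_codon[i] != ex$stop_label)
        out[[length(out) + 1L]] <- finding(
          ft$locus[i], "stop_codon", ft$stop_codon[i], ex$stop_label,
          sprintf("declared stop codon %s differs from sequence-derived %s",
                  ft$stop_codon[i], ex$stop_label))
      for (w in ex$findings)
        out[[length(out) + 1L]] <- finding(ft$locus[i], "internal_stop",
                                           NA, NA, w)
    }
  }

  counts <- table(factor(ft$category, levels = FEATURE_CATEGORIES))
  expected <- c(PCG = 13L, tRNA = 22L, rRNA = 2L, control = 1L)
  for (cat in names(expected))
    if (counts[[cat]] != expected[[cat]])
      out[[length(out) + 1L]] <- finding(
        NA_character_, "gene_complement", expected[[cat]], counts[[cat]],
        sprintf("expected %d %s feature(s) in a standard vertebrate mitogenome, found %d",
                expected[[cat]], cat, counts[[cat]]))
  missing <- setdiff(CANONICAL_PCGS, harmonizeLoci(ft$locus[ft$category == "PCG"]))
  for (m in missing)
    out[[length(out) + 1L]] <- finding(
      m, "missing_gene", NA, NA, sprintf("canonical PCG %s not annotated", m))

  if (length(out)) do.call(rbind, out)
  else data.frame(locus = character(0), check = character(0),
                  declared = character(0), derived = character(0),
                  message = character(0), stringsAsFactors = FALSE)
}

#' Canonical gene-order string
#'
#' Comma-separated locus list in table order with L-strand loci prefixed
#' "-", suitable for string-equality comparison of gene order and strand
#' layout between genomes.
#'
#' @param table a \code{\linkS4class{GeneTable}} or \code{MitoRecord}.
#' @return a single character string.
#' @examples
#' substr(geneOrderString(table1Fixture()), 1, 40)
#' @export
geneOrderString <- function(table) {
  ft <- features(table)
  paste(ifelse(ft$strand == "L", paste0("-", ft$locus), ft$locus),
        collapse = ",")
}

#' Read / write a gene table as TSV
#'
#' Tab-separated gene tables with header \code{locus category strand start
#' stop size start_codon stop_codon anticodon intergenic}; empty cells mark
#' inapplicable fields. The genome length defaults to the maximum stop
#' coordinate (the last feature of a full mitogenome table ends at the
#' genome's final position).
#'
#' @param path file path.
#' @param genomeLength genome length; default \code{max(stop)}.
#' @param circular circular topology flag.
#' @param taxon,accession labels stored on the table.
#' @return \code{readGeneTable}: a \code{\linkS4class{GeneTable}};
#'   \code{writeGeneTable}: the path, invisibly.
#' @export
readGeneTable <- function(path, genomeLength = NULL, circular = TRUE,
                          taxon = "", accession = "") {
  ft <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          check.names = FALSE)
  missing_cols <- setdiff(c("locus", "category", "strand", "start", "stop"),
                          colnames(ft))
  if (length(missing_cols))
    stop("gene-table TSV missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("start", "stop", "size", "intergenic"))
    if (col %in% colnames(ft))
      ft[[col]] <- suppressWarnings(as.integer(ft[[col]]))
  for (col in c("start_codon", "stop_codon", "anticodon"))
    if (col %in% colnames(ft))
      ft[[col]][!nzchar(ft[[col]])] <- NA_character_
  if (is.null(genomeLength)) genomeLength <- max(ft$stop, ft$start)
  geneTable(ft, genomeLength = genomeLength, circular = circular,
            taxon = taxon, accession = accession)
}

#' @rdname readGeneTable
#' @param table a \code{\linkS4class{GeneTable}}.
#' @export
writeGeneTable <- function(table, path) {
  ft <- features(table)
  out <- ft
  for (col in colnames(out)) {
    v <- as.character(out[[col]])
    v[is.na(v)] <- ""
    out[[col]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Genome positions covered by feature row i, in H-strand order
# (wrapping resolved on circular genomes).
featurePositions <- function(ft_row, genomeLength) {
  if (ft_row$start <= ft_row$stop) seq.int(ft_row$start, ft_row$stop)
  else c(seq.int(ft_row$start, genomeLength), seq.int(1L, ft_row$stop))
}

#' Coding-sense sequence of one feature
#'
#' Extracts the sequence of a feature from its record, resolving circular
#' wrap and reverse-complementing L-strand features so the result reads in
#' coding (functional) sense.
#'
#' @param record a \code{\linkS4class{MitoRecord}}.
#' @param locus feature locus name (first match used), or give
#'   \code{featureIndex} directly when loci are duplicated.
#' @param featureIndex row index into \code{features(record)}.
#' @return a \code{DNAString}.
#' @export
featureSequence <- function(record, locus = NULL, featureIndex = NULL) {
  ft <- features(record)
  if (is.null(featureIndex)) {
    featureIndex <- which(ft$locus == locus)
    if (!length(featureIndex))
      stop("no feature named ", locus)
    featureIndex <- featureIndex[1L]
  }
  pos <- featurePositions(ft[featureIndex, ], genomeLength(record))
  s <- genomeSequence(record)[pos]
  if (ft$strand[featureIndex] == "L") Biostrings::reverseComplement(s) else s
}
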