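#' AT and GC strand skews from base counts
#'
#' AT-skew = (A - T)/(A + T), GC-skew = (G - C)/(G + C). Positive skews
#' mark an excess of A (respectively G) on the strand counted; in
#' vertebrate mitogenomes the two strands show opposite, mirror-image
#' skews. A zero denominator yields NA (undefined), never an error, and
#' both skews are scale-invariant in the counts.
#'
#' @param counts named numeric vector with elements \code{A}, \code{C},
#'   \code{G}, \code{T} (counts or percentages; the ratios are
#'   scale-free).
#' @return list with numeric \code{at_skew} and \code{gc_skew} (NA when
#'   the respective denominator is zero).
#' @examples
#' skews(c(A = 31.3, T = 24.0, G = 16.2, C = 28.6))  # 0.132, -0.277
#' @export
skews <- function(counts) {
  counts <- counts[c("A", "C", "G", "T")]
  if (anyNA(counts))
    stop("counts must carry named elements A, C, G, T")
  if (any(counts < 0))
    stop("counts must be non-negative")
  at <- unname(counts["A"] + counts["T"])
  gc <- unname(counts["G"] + counts["C"])
  list(
    at_skew = if (at > 0) unname((counts["A"] - counts["T"]) / at) else NA_real_,
    gc_skew = if (gc > 0) unname((counts["G"] - counts["C"]) / gc) else NA_real_
  )
}

compositionRow <- function(chars, partition) {
  counts <- c(A = sum(chars == "A"), C = sum(chars == "C"),
              G = sum(chars == "G"), T = sum(chars == "T"))
  acgt <- sum(counts)
  if (acgt == 0L)
    stop(sprintf("partition '%s' contains no unambiguous bases; composition undefined",
                 partition))
  pct <- 100 * counts / acgt
  sk <- skews(counts)
  data.frame(partition = partition, length = length(chars),
             T_pct = pct[["T"]], C_pct = pct[["C"]],
             A_pct = pct[["A"]], G_pct = pct[["G"]],
             AT_pct = pct[["A"]] + pct[["T"]],
             at_skew = sk$at_skew, gc_skew = sk$gc_skew,
             stringsAsFactors = FALSE)
}

#' Base composition of a sequence
#'
#' Counts A/C/G/T over the sequence; N (and gap) characters count toward
#' \code{length} but are excluded from both the numerators and the
#' denominator of the percentages. Percentages are returned at full
#' precision; round to 1 decimal (skews to 3) for table-style reporting.
#'
#' @param seq a \code{DNAString}, character string, or character vector of
#'   single residues.
#' @param partition label for the output row.
#' @return one-row data.frame: \code{partition}, \code{length},
#'   \code{T_pct}, \code{C_pct}, \code{A_pct}, \code{G_pct}, \code{AT_pct},
#'   \code{at_skew}, \code{gc_skew}.
#' @examples
#' baseComposition("AATT")$at_skew  # 0
#' @export
baseComposition <- function(seq, partition = "custom") {
  chars <- sequenceChars(seq)
  compositionRow(chars, partition)
}

sequenceChars <- function(seq) {
  if (is(seq, "XString")) strsplit(as.character(seq), "")[[1L]]
  else if (is.character(seq) && length(seq) == 1L) strsplit(seq, "")[[1L]]
  else as.character(seq)
}

#' Partitioned composition of an annotated mitogenome
#'
#' Reproduces the classic mitogenome composition table: one row each for
#' the whole genome, the concatenated protein-coding genes (PCGs), the
#' three codon positions of that concatenation, the rRNAs, the tRNAs and
#' the control region (D-loop). Gene-functional partitions (PCG, tRNA,
#' rRNA) are strand-corrected: L-strand members are reverse-complemented
#' to coding sense before counting; the genome row uses the deposited
#' H strand. Codon positions are assigned 1,2,3 cyclically from each PCG's
#' annotated start, restarting at each gene, so a gene ending in an
#' incomplete stop codon contributes its trailing 1-2 nucleotides to
#' positions 1 (and 2) only.
#'
#' @param record a \code{\linkS4class{MitoRecord}}.
#' @return data.frame with one row per non-empty partition (empty
#'   partitions are dropped with a warning), columns as in
#'   \code{\link{baseComposition}}.
#' @export
partitionComposition <- function(record) {
  ft <- features(record)
  rows <- list(compositionRow(sequenceChars(genomeSequence(record)), "genome"))

  pcg_idx <- which(ft$category == "PCG")
  if (length(pcg_idx)) {
    per_gene <- lapply(pcg_idx, function(i)
      sequenceChars(featureSequence(record, featureIndex = i)))
    pcg_chars <- unlist(per_gene, use.names = FALSE)
    rows[[length(rows) + 1L]] <- compositionRow(pcg_chars, "PCGs")
    # codon positions restart at 1 within each gene
    pos_labels <- unlist(lapply(per_gene, function(ch)
      rep_len(1:3, length(ch))), use.names = FALSE)
    for (p in 1:3)
      rows[[length(rows) + 1L]] <-
        compositionRow(pcg_chars[pos_labels == p], paste0("codon_pos", p))
  } else warning("no PCG features; PCG and codon-position partitions omitted")

  for (part in list(c("rRNA", "rRNA"), c("tRNA", "tRNA"),
                    c("control", "D-loop"))) {
    idx <- which(ft$category == part[1L])
    if (length(idx)) {
      chars <- unlist(lapply(idx, function(i)
        sequenceChars(featureSequence(record, featureIndex = i))),
        use.names = FALSE)
      rows[[length(rows) + 1L]] <- compositionRow(chars, part[2L])
    } else warning(sprintf("no %s features; partition omitted", part[1L]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format a composition table at reporting precision
#'
#' Rounds percentages to 1 decimal and skews to 3 decimals, the precision
#' at which mitogenome composition tables are conventionally printed.
#'
#' @param comp data.frame from \code{\link{partitionComposition}} or
#'   \code{\link{baseComposition}}.
#' @return data.frame with rounded columns.
#' @export
formatComposition <- function(comp) {
  for (col in grep("_pct$", colnames(comp), value = TRUE))
    comp[[col]] <- round(comp[[col]], 1)
  for (col in c("at_skew", "gc_skew"))
    comp[[col]] <- round(comp[[col]], 3)
  comp
}
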