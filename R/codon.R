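#' Vertebrate mitochondrial genetic code
#'
#' NCBI translation table 2: TGA codes Trp, ATA codes Met, and AGA/AGG are
#' stop codons; alternative initiators include GTG and ATA/ATT/ATC in
#' addition to the canonical ATG.
#'
#' @return list with \code{id}, \code{code} (named character vector, 64
#'   codons to one-letter amino acids, "*" for stops), \code{starts}
#'   (initiator codons), \code{stops}.
#' @export
mitoGeneticCode <- function() {
  code <- Biostrings::getGeneticCode("2")
  alt <- attr(code, "alt_init_codons")
  list(id = 2L, code = code,
       starts = unique(c("ATG", "ATA", alt)),
       stops = names(code)[code == "*"])
}

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val")

#' Synonymous codon families of the mitochondrial code
#'
#' Non-stop codons grouped by amino acid, with serine split into its two
#' unrelated codon boxes, Ser (TCN) and Ser2 (AGY), the convention of
#' mitogenome codon-usage plots. Under translation table 2 AGA/AGG are
#' stops, so Ser2 holds AGT/AGC only.
#'
#' @param code a genetic code from \code{\link{mitoGeneticCode}}.
#' @return named character vector mapping each sense codon to its family
#'   label (three-letter amino-acid name, "Ser2" for AGY).
#' @export
codonFamilies <- function(code = mitoGeneticCode()) {
  sense <- code$code[code$code != "*"]
  fam <- unname(AA3[sense])
  names(fam) <- names(sense)
  fam[names(fam) %in% c("AGT", "AGC")] <- "Ser2"
  fam
}

#' Extract codons of one protein-coding gene
#'
#' Obtains the coding-sense CDS (L-strand features reverse-complemented,
#' circular wrap resolved), reads complete triplets in frame from position
#' 1, and classifies the start and stop. Genes whose length is not a
#' multiple of 3 end in an incomplete stop codon — a trailing T or TA
#' completed to TAA by post-transcriptional polyadenylation — labelled
#' "T-" (1-nt tail) or "TA-" (2-nt tail). Internal stop codons are
#' reported as findings, not errors, so misannotated inputs remain
#' analyzable.
#'
#' @param record a \code{\linkS4class{MitoRecord}}.
#' @param gene PCG locus name.
#' @param featureIndex optional explicit row index (for duplicated loci).
#' @param code genetic code (default vertebrate mitochondrial).
#' @return list of class \code{CodonExtraction}: \code{gene},
#'   \code{complete_codons} (character vector of triplets),
#'   \code{incomplete_tail} ("" / "T" / "TA"-class remainder),
#'   \code{start_label} (observed first triplet), \code{stop_label}
#'   (terminal stop codon, or "T-"/"TA-"), \code{cds_length},
#'   \code{findings} (character vector of warnings).
#' @examples
#' rec <- generateGenome(minimalGenomeSpec())
#' extractCodons(rec, "GENE1")$start_label
#' @export
extractCodons <- function(record, gene, featureIndex = NULL,
                          code = mitoGeneticCode()) {
  ft <- features(record)
  if (is.null(featureIndex)) {
    featureIndex <- which(ft$locus == gene & ft$category == "PCG")
    if (!length(featureIndex))
      stop("no PCG feature named ", gene)
    featureIndex <- featureIndex[1L]
  }
  cds <- as.character(featureSequence(record, featureIndex = featureIndex))
  n <- nchar(cds)
  if (n < 6L)
    stop(sprintf("malformed CDS for %s: only %d nt", gene, n))
  ncod <- n %/% 3L
  tail_len <- n %% 3L
  codons <- substring(cds, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
  tail <- if (tail_len) substring(cds, 3L * ncod + 1L, n) else ""
  stop_label <- if (tail_len == 1L) "T-"
                else if (tail_len == 2L) "TA-"
                else codons[ncod]
  findings <- character(0)
  internal <- codons[-c(1L, if (tail_len == 0L) ncod)] %in% code$stops
  if (any(internal))
    findings <- sprintf("internal stop codon(s) at codon position(s) %s of %s",
                        paste(which(internal) + 1L, collapse = ","),
                        ft$locus[featureIndex])
  if (tail_len == 0L && !(codons[ncod] %in% code$stops))
    findings <- c(findings,
                  sprintf("terminal codon %s of %s is not a stop codon",
                          codons[ncod], ft$locus[featureIndex]))
  structure(list(gene = ft$locus[featureIndex],
                 complete_codons = codons, incomplete_tail = tail,
                 start_label = codons[1L], stop_label = stop_label,
                 cds_length = n, findings = findings),
            class = "CodonExtraction")
}

#' Classify a start codon under the mitochondrial code
#'
#' @param start_label observed initiator triplet, or a
#'   \code{CodonExtraction}.
#' @param code genetic code list.
#' @return "canonical" (ATG), "alternative" (other table-2 initiators such
#'   as GTG), or "invalid".
#' @export
classifyStart <- function(start_label, code = mitoGeneticCode()) {
  if (inherits(start_label, "CodonExtraction"))
    start_label <- start_label$start_label
  if (start_label == "ATG") "canonical"
  else if (start_label %in% code$starts) "alternative"
  else "invalid"
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its count divided by the mean count over its
#' synonymous family; 1 marks unbiased usage. Stop codons are excluded;
#' a family with zero total usage yields RSCU 0 for all its members. For
#' every family with nonzero usage the family mean of RSCU is exactly 1.
#'
#' @param counts named numeric vector of per-codon counts (sense codons;
#'   missing codons count 0).
#' @param code genetic code list.
#' @return data.frame: \code{codon}, \code{family}, \code{count},
#'   \code{rscu}, ordered by family then codon.
#' @examples
#' rscu(c(AAA = 3, AAG = 1))[, c("codon", "rscu")]  # 1.5 and 0.5
#' @export
rscu <- function(counts, code = mitoGeneticCode()) {
  fam <- codonFamilies(code)
  full <- stats::setNames(numeric(length(fam)), names(fam))
  counts <- counts[names(counts) %in% names(fam)]
  if (any(counts < 0)) stop("codon counts must be non-negative")
  full[names(counts)] <- counts
  fam_mean <- tapply(full, fam, mean)
  denom <- fam_mean[fam]
  vals <- ifelse(denom > 0, full / denom, 0)
  out <- data.frame(codon = names(fam), family = unname(fam),
                    count = unname(full), rscu = unname(vals),
                    stringsAsFactors = FALSE)
  out[order(out$family, out$codon), ]
}

#' Codons per thousand codons by amino-acid family
#'
#' CDpT(family) = 1000 * family count / total codon count, families as in
#' \code{\link{codonFamilies}} (Ser split into Ser/Ser2). Family values
#' sum to 1000 up to rounding.
#'
#' @param counts named numeric vector of per-codon counts.
#' @param code genetic code list.
#' @return named numeric vector of CDpT per family.
#' @export
cdpt <- function(counts, code = mitoGeneticCode()) {
  fam <- codonFamilies(code)
  counts <- counts[names(counts) %in% names(fam)]
  total <- sum(counts)
  if (total <= 0) stop("total codon count is zero; CDpT undefined")
  fam_tot <- tapply(counts, fam[names(counts)], sum)
  all_fam <- sort(unique(unname(fam)))
  out <- stats::setNames(numeric(length(all_fam)), all_fam)
  out[names(fam_tot)] <- 1000 * fam_tot / total
  out
}

#' Codon-usage report over all protein-coding genes
#'
#' Extracts all PCGs of a record, tabulates codon usage, and computes RSCU
#' and CDpT. Two codon totals are reported: \code{totalCodons}, the
#' concatenated PCG length divided by 3 (floor) — the convention of
#' printed mitogenome summaries — and \code{completeCodons}, the sum of
#' per-gene complete triplets, which excludes incomplete terminal tails.
#' Usage counts exclude terminal stop codons and incomplete tails; the
#' initiator triplet is counted literally (a GTG start counts under Val)
#' unless \code{initiatorAsMet = TRUE} recodes initiators to ATG.
#'
#' @param record a \code{\linkS4class{MitoRecord}} with >= 1 PCG.
#' @param initiatorAsMet count alternative initiators as Met (default
#'   FALSE: literal counting).
#' @param code genetic code list.
#' @return list: \code{usage} (data.frame codon/family/count/rscu/
#'   cdpt_family), \code{cdpt} (per-family vector), \code{totalCodons},
#'   \code{completeCodons}, \code{extractions} (named list of
#'   \code{CodonExtraction}), \code{startStop} (data.frame locus/
#'   start_codon/stop_codon/start_class), \code{findings}.
#' @export
pcgCodonReport <- function(record, initiatorAsMet = FALSE,
                           code = mitoGeneticCode()) {
  ft <- features(record)
  idx <- which(ft$category == "PCG")
  if (!length(idx)) stop("record contains no PCG features")
  ex <- lapply(idx, function(i) extractCodons(record, featureIndex = i,
                                              code = code))
  names(ex) <- ft$locus[idx]
  codons <- unlist(lapply(ex, function(e) {
    cc <- e$complete_codons
    # drop a complete terminal stop; tails are already excluded
    if (e$incomplete_tail == "" && cc[length(cc)] %in% code$stops)
      cc <- cc[-length(cc)]
    if (initiatorAsMet && cc[1L] %in% code$starts) cc[1L] <- "ATG"
    cc
  }), use.names = FALSE)
  counts <- table(factor(codons, levels = names(code$code)))
  counts <- stats::setNames(as.numeric(counts), names(counts))
  usage <- rscu(counts, code)
  fam_cdpt <- cdpt(counts, code)
  usage$cdpt_family <- unname(fam_cdpt[usage$family])
  total_len <- sum(vapply(ex, function(e) e$cds_length, numeric(1)))
  startStop <- data.frame(
    locus = names(ex),
    start_codon = vapply(ex, function(e) e$start_label, character(1)),
    stop_codon = vapply(ex, function(e) e$stop_label, character(1)),
    stringsAsFactors = FALSE)
  startStop$start_class <- vapply(startStop$start_codon, classifyStart,
                                  character(1), code = code)
  rownames(startStop) <- NULL
  list(usage = usage, cdpt = fam_cdpt,
       totalCodons = total_len %/% 3L,
       completeCodons = sum(vapply(ex, function(e)
         length(e$complete_codons), numeric(1))),
       extractions = ex, startStop = startStop,
       findings = unlist(lapply(ex, function(e) e$findings),
                         use.names = FALSE))
}
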