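COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Default base-composition target: the whole-genome composition typical of
# cyprinid mitogenomes (A 31.3%, C 28.6%, T 24.0%, G 16.2%).
DEFAULT_BASE_FREQS <- c(A = 0.313, C = 0.286, G = 0.162, T = 0.240)

#' Specification for a synthetic annotated mitogenome
#'
#' Describes the genome a generator run will plant: explicit feature
#' coordinates (features may overlap, as real mitochondrial genes do),
#' desired start/stop codon labels for PCGs, base-composition targets for
#' unconstrained positions, and a seed. Feasibility is checked up front:
#' a complete stop label requires a gene length divisible by 3, "T-"
#' length mod 3 = 1, "TA-" length mod 3 = 2.
#'
#' @param features data.frame with columns \code{locus}, \code{category},
#'   \code{strand}, \code{start}, \code{stop} and, for PCGs,
#'   \code{start_codon} and \code{stop_codon}; optional \code{anticodon}.
#' @param genomeLength genome length in bp.
#' @param baseFreqs named A/C/G/T fractions for random fill (normalized).
#' @param seed RNG seed for reproducible generation.
#' @param taxon,accession labels for the generated record.
#' @param circular topology flag.
#' @return list of class \code{GenomeSpec}.
#' @seealso \code{\link{generateGenome}}, \code{\link{table1GenomeSpec}}
#' @export
genomeSpec <- function(features, genomeLength,
                       baseFreqs = DEFAULT_BASE_FREQS, seed = 1L,
                       taxon = "synthetic", accession = "", circular = TRUE) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  gt <- geneTable(features, genomeLength, circular = circular)  # validates
  ft <- features(gt)
  code <- mitoGeneticCode()
  lens <- featureLength(ft$start, ft$stop, genomeLength, circular, ft$locus)
  for (i in which(ft$category == "PCG")) {
    sc <- ft$start_codon[i]; pc <- ft$stop_codon[i]
    if (is.na(sc) || nchar(sc) != 3L)
      stop(sprintf("infeasible spec: PCG %s needs a 3-nt start codon",
                   ft$locus[i]))
    need <- if (is.na(pc)) NA_integer_
            else if (pc %in% code$stops) 0L
            else if (pc == "T-") 1L
            else if (pc == "TA-") 2L
            else stop(sprintf("infeasible spec: unknown stop label %s for %s",
                              pc, ft$locus[i]))
    if (!is.na(need) && lens[i] %% 3L != need)
      stop(sprintf(
        "infeasible spec: %s stop label %s requires length mod 3 = %d, but length %d mod 3 = %d",
        ft$locus[i], pc, need, lens[i], lens[i] %% 3L))
  }
  bf <- baseFreqs[c("A", "C", "G", "T")]
  if (anyNA(bf) || any(bf < 0) || sum(bf) <= 0)
    stop("baseFreqs must carry non-negative A, C, G, T fractions")
  structure(list(features = ft, genomeLength = as.integer(genomeLength),
                 baseFreqs = bf / sum(bf), seed = as.integer(seed),
                 taxon = taxon, accession = accession, circular = circular),
            class = "GenomeSpec")
}

#' A minimal one-gene genome specification
#'
#' One 99-nt PCG (ATG ... TAA) on a 200-bp circular genome; the smallest
#' spec that exercises codon extraction end to end.
#'
#' @param seed RNG seed.
#' @return a \code{GenomeSpec}.
#' @export
minimalGenomeSpec <- function(seed = 1L) {
  genomeSpec(
    data.frame(locus = "GENE1", category = "PCG", strand = "H",
               start = 10L, stop = 108L,
               start_codon = "ATG", stop_codon = "TAA",
               stringsAsFactors = FALSE),
    genomeLength = 200L, seed = seed)
}

#' Generate a self-consistent synthetic annotated mitogenome
#'
#' Plants every specified feature on a circular sequence: PCGs begin with
#' the requested start triplet, end with the requested stop (a literal T
#' or TA tail for incomplete stops) and contain no internal stop codons
#' (rejection sampling per codon); L-strand features are inserted as
#' reverse complements; positions constrained by overlapping genes are
#' written once and respected by later genes; remaining positions are
#' filled from the base-composition targets. Fully reproducible from the
#' spec's seed. The output passes \code{\link{validateTable}} with zero
#' findings by construction (declared size and intergenic columns are
#' filled with the coordinate-derived values).
#'
#' @param spec a \code{\link{genomeSpec}}.
#' @return a \code{\linkS4class{MitoRecord}}.
#' @export
generateGenome <- function(spec) {
  stopifnot(inherits(spec, "GenomeSpec"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)

  L <- spec$genomeLength
  ft <- spec$features
  code <- mitoGeneticCode()
  bases <- c("A", "C", "G", "T")
  genome <- rep(NA_character_, L)

  # coding index k of feature i -> genome position
  codingMap <- function(i) {
    pos <- featurePositions(ft[i, ], L)
    if (ft$strand[i] == "L") rev(pos) else pos
  }
  writeCoding <- function(i, ks, chars, gmap) {
    gpos <- gmap[ks]
    gchar <- if (ft$strand[i] == "L") unname(COMPLEMENT[chars]) else chars
    clash <- !is.na(genome[gpos]) & genome[gpos] != gchar
    if (any(clash))
      stop(sprintf(
        "infeasible spec: %s conflicts with overlapping feature at genome position(s) %s",
        ft$locus[i], paste(gpos[clash], collapse = ",")))
    genome[gpos] <<- gchar
  }
  readCoding <- function(i, ks, gmap) {
    g <- genome[gmap[ks]]
    if (ft$strand[i] == "L") unname(COMPLEMENT[g]) else g
  }

  pcg <- which(ft$category == "PCG")
  lens <- featureLength(ft$start, ft$stop, L, spec$circular, ft$locus)
  # phase 1: plant all fixed positions (starts, stops, tails) first so
  # overlapping genes constrain each other before random fill
  for (i in pcg) {
    gmap <- codingMap(i)
    len <- lens[i]
    writeCoding(i, 1:3, strsplit(ft$start_codon[i], "")[[1L]], gmap)
    pc <- ft$stop_codon[i]
    if (!is.na(pc)) {
      if (pc %in% code$stops)
        writeCoding(i, (len - 2L):len, strsplit(pc, "")[[1L]], gmap)
      else if (pc == "T-")
        writeCoding(i, len, "T", gmap)
      else if (pc == "TA-")
        writeCoding(i, (len - 1L):len, c("T", "A"), gmap)
    }
  }
  # phase 2: fill codons, avoiding internal stops, honoring fixed positions
  for (i in pcg) {
    gmap <- codingMap(i)
    ncod <- lens[i] %/% 3L
    for (cj in seq_len(ncod)) {
      ks <- (3L * cj - 2L):(3L * cj)
      cur <- readCoding(i, ks, gmap)
      free <- is.na(cur)
      if (!any(free)) next  # fully constrained (start, stop, or overlap)
      terminal <- cj == ncod && lens[i] %% 3L == 0L
      for (try in 1:200) {
        cand <- cur
        cand[free] <- sample(bases, sum(free), replace = TRUE,
                             prob = spec$baseFreqs)
        codon <- paste(cand, collapse = "")
        ok <- if (terminal) codon %in% code$stops
              else !(codon %in% code$stops)
        if (ok) break
      }
      if (!ok) warning(sprintf("could not avoid internal stop in %s codon %d",
                               ft$locus[i], cj), call. = FALSE)
      writeCoding(i, ks[free], cand[free], gmap)
    }
  }
  # phase 3: everything else (tRNA/rRNA/control interiors, spacers)
  nfree <- sum(is.na(genome))
  genome[is.na(genome)] <- sample(bases, nfree, replace = TRUE,
                                  prob = spec$baseFreqs)

  # self-consistent declared columns
  out_ft <- ft
  out_ft$size <- as.integer(lens)
  out_ft$intergenic <- c(NA_integer_,
                         out_ft$start[-1L] - out_ft$stop[-nrow(out_ft)] - 1L)
  gt <- geneTable(out_ft, L, circular = spec$circular,
                  taxon = spec$taxon, accession = spec$accession)
  mitoRecord(paste(genome, collapse = ""), gt,
             source = sprintf("generateGenome(seed=%d)", spec$seed))
}

#' The packaged reference gene table
#'
#' Verbatim transcription of the printed gene-organization table of the
#' Onychostoma lepturum mitogenome (GenBank MT258556): all 38 features
#' (13 PCGs, 22 tRNAs, 2 rRNAs, control region) with their coordinates,
#' declared sizes, codon labels, anticodons, intergenic column and
#' strands, on a 16,598 bp circular genome. Declared columns are stored
#' exactly as printed — including the internal inconsistencies the source
#' table carries (see \code{\link{validateTable}}).
#'
#' @return a \code{\linkS4class{GeneTable}}.
#' @examples
#' gt <- table1Fixture()
#' table(features(gt)$category)
#' @export
table1Fixture <- function() {
  path <- system.file("extdata", "table1_onychostoma_lepturum.tsv",
                      package = "mitochar", mustWork = TRUE)
  readGeneTable(path, genomeLength = 16598L, circular = TRUE,
                taxon = "Onychostoma lepturum", accession = "MT258556")
}

#' Self-consistent genome spec derived from the reference table
#'
#' The reference layout with the two internal inconsistencies of the
#' printed table resolved so that a generated genome validates clean:
#' COIII's stop label becomes "TA-" (its 785 bp length is not divisible
#' by 3, and the cross-species codon matrix prints TA- for COIII), and
#' the intergenic column is recomputed from the coordinates (the printed
#' value 4 at the ND1/tRNA-Ile junction is coordinate-derived 5).
#'
#' @param seed RNG seed for the generator.
#' @return a \code{GenomeSpec}.
#' @export
table1GenomeSpec <- function(seed = 101L) {
  gt <- table1Fixture()
  ft <- features(gt)
  ft$stop_codon[ft$locus == "COIII"] <- "TA-"
  ft$intergenic <- NA_integer_
  genomeSpec(ft, genomeLength = genomeLength(gt), seed = seed,
             taxon = taxonName(gt), accession = accessionOf(gt))
}

#' Specification for simulating an alignment down a tree
#'
#' Sequences evolve along the tree under the two-rate (Kimura
#' transition/transversion) continuous-time substitution model with
#' uniform stationary base frequencies; branch lengths are expected
#' substitutions per site.
#'
#' @param tree a \code{phylo}-structured tree or a Newick string.
#' @param length alignment length in sites.
#' @param alpha,beta instantaneous transition and (per-target)
#'   transversion rates; only their ratio matters since branch lengths
#'   are rescaled to substitutions per site. Default kappa = alpha/beta
#'   of 4.
#' @param seed RNG seed.
#' @return list of class \code{SimSpec}.
#' @export
simSpec <- function(tree, length = 1000L, alpha = 4, beta = 1, seed = 1L) {
  if (is.character(tree)) tree <- readNewick(tree)
  if (alpha <= 0 || beta <= 0) stop("rates must be > 0")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  structure(list(tree = tree, length = as.integer(length),
                 alpha = alpha, beta = beta, seed = as.integer(seed)),
            class = "SimSpec")
}

#' Simulate an alignment under the two-rate substitution model
#'
#' Draws a root sequence from the uniform stationary distribution and
#' evolves it down the spec's tree: per branch of length t (expected
#' substitutions per site) the K80 transition probabilities are applied
#' site-wise. Reproducible from the seed.
#'
#' @param spec a \code{\link{simSpec}}.
#' @return named character vector of leaf sequences (an alignment).
#' @export
simulateAlignment <- function(spec) {
  stopifnot(inherits(spec, "SimSpec"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)

  tree <- spec$tree
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  len <- spec$length
  # base coding 1=A 2=C 3=G 4=T; transitions 1<->3, 2<->4
  partner <- c(3L, 4L, 1L, 2L)
  tv1 <- c(2L, 1L, 2L, 1L)
  tv2 <- c(4L, 3L, 4L, 3L)
  rate <- spec$alpha + 2 * spec$beta

  seqs <- vector("list", nnode)
  root <- ntip + 1L
  seqs[[root]] <- sample.int(4L, len, replace = TRUE)
  # process edges parent-first
  pending <- seq_len(nrow(tree$edge))
  done <- rep(FALSE, nnode)
  done[root] <- TRUE
  while (length(pending)) {
    ready <- pending[done[tree$edge[pending, 1L]]]
    if (!length(ready)) stop("tree edges are not connected to the root")
    for (e in ready) {
      par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
      tau <- tree$edge.length[e] / rate
      e1 <- exp(-4 * spec$beta * tau)
      e2 <- exp(-2 * (spec$alpha + spec$beta) * tau)
      pSame <- 0.25 + 0.25 * e1 + 0.5 * e2
      pTs <- 0.25 + 0.25 * e1 - 0.5 * e2
      p <- seqs[[par]]
      u <- stats::runif(len)
      coin <- stats::runif(len) < 0.5
      child_seq <- ifelse(u < pSame, p,
                   ifelse(u < pSame + pTs, partner[p],
                   ifelse(coin, tv1[p], tv2[p])))
      seqs[[child]] <- child_seq
      done[child] <- TRUE
    }
    pending <- setdiff(pending, ready)
  }
  bases <- c("A", "C", "G", "T")
  stats::setNames(
    vapply(seq_len(ntip), function(i)
      paste(bases[seqs[[i]]], collapse = ""), character(1)),
    tree$tip.label)
}

#' Random unrooted binary tree
#'
#' Uniformly partitions the taxa into three groups at the basal
#' trifurcation and recursively into two within each group, with branch
#' lengths drawn uniformly from \code{blRange}. Used for property tests
#' of additive-distance recovery.
#'
#' @param labels taxon labels (>= 3).
#' @param blRange branch-length range (uniform draw).
#' @param seed RNG seed (NULL to use the current RNG state).
#' @return a \code{phylo}-structured unrooted tree.
#' @export
randomUnrootedTree <- function(labels, blRange = c(0.05, 1), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(labels) < 3L) stop("need >= 3 taxa")
  bl <- function() stats::runif(1, blRange[1L], blRange[2L])
  grow <- function(taxa) {
    if (length(taxa) == 1L)
      return(list(children = list(), label = taxa, length = bl()))
    k <- sample(seq_len(length(taxa) - 1L), 1L)
    sel <- sample(taxa, k)
    list(children = list(grow(sel), grow(setdiff(taxa, sel))),
         label = "", length = bl())
  }
  k1 <- if (length(labels) == 3L) 1L else sample(seq_len(length(labels) - 2L), 1L)
  g1 <- sample(labels, k1)
  rest <- setdiff(labels, g1)
  k2 <- if (length(rest) == 2L) 1L else sample(seq_len(length(rest) - 1L), 1L)
  g2 <- sample(rest, k2)
  g3 <- setdiff(rest, g2)
  root <- list(children = list(grow(g1), grow(g2), grow(g3)),
               label = "", length = NA_real_)
  nestedToPhylo(root)
}
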