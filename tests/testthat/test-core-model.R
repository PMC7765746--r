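test_that("feature lengths follow the inclusive-coordinate and wrap conventions", {
  expect_identical(featureLength(4052, 5096, 16598), 1045L)   # ND2
  expect_identical(featureLength(15664, 16598, 16598), 935L)  # D-loop
  expect_identical(featureLength(16590, 10, 16598), 19L)      # wraps origin
  expect_identical(featureLength(5, 5, 100), 1L)
  expect_error(featureLength(0, 10, 100), "outside")
  expect_error(featureLength(5, 101, 100, locus = "geneX"), "geneX")
  expect_error(featureLength(50, 10, 100, circular = FALSE), "linear")
})

test_that("junction gaps classify spacers, overlaps and contiguity", {
  gt <- geneTable(
    data.frame(locus = c("a", "b", "c", "d"), category = "tRNA",
               strand = "H",
               start = c(1, 101, 137, 150), stop = c(100, 136, 149, 200)),
    genomeLength = 220)
  jr <- junctionGaps(gt)
  expect_equal(junctions(jr)$gap, c(0L, 0L, 0L))
  gt2 <- geneTable(
    data.frame(locus = c("tRNA-Asn", "tRNA-Cys", "ATP8", "ATP6"),
               category = c("tRNA", "tRNA", "PCG", "PCG"),
               strand = "H",
               start = c(5241, 5349, 7965, 8123),
               stop = c(5313, 5415, 8129, 8805)),
    genomeLength = 16598)
  g <- junctions(junctionGaps(gt2))$gap
  expect_equal(g[1], 35L)   # Asn -> Cys spacer
  expect_equal(g[3], -7L)   # ATP8/ATP6 overlap
})

test_that("reference gene map reproduces the printed junction totals", {
  jr <- junctionGaps(table1Fixture())
  expect_equal(unname(overlapTotals(jr)), c(22L, 6L))
  expect_setequal(largestOverlap(jr)$pairs, c("ATP8/ATP6", "ND4L/ND4"))
  expect_equal(largestOverlap(jr)$bp, 7L)
  expect_equal(largestSpacer(jr)$bp, 35L)
  expect_equal(largestSpacer(jr)$pairs, "tRNA-Asn/tRNA-Cys")
})

test_that("junction totals are invariant under origin rotation that splits no feature", {
  gt <- table1Fixture()
  ft <- features(gt)
  L <- genomeLength(gt)
  jr0 <- junctionGaps(gt, includeOriginJunction = TRUE)
  # rotate so that the k-th feature becomes the first (cut in the junction
  # before it); totals including the origin junction must not change
  for (k in c(5L, 20L, 38L)) {
    shift <- ft$start[k] - 1L
    rot <- ft
    rot$start <- ((ft$start - 1L - shift) %% L) + 1L
    rot$stop <- ((ft$stop - 1L - shift) %% L) + 1L
    rot <- rot[order(rot$start), ]
    jr <- junctionGaps(geneTable(rot, L), includeOriginJunction = TRUE)
    expect_equal(overlapTotals(jr), overlapTotals(jr0))
    expect_equal(spacerTotals(jr), spacerTotals(jr0))
  }
})

test_that("origin junction is excluded by default and included on request", {
  gt <- geneTable(
    data.frame(locus = c("a", "b"), category = "tRNA", strand = "H",
               start = c(10, 60), stop = c(50, 90)),
    genomeLength = 100)
  expect_equal(nrow(junctions(junctionGaps(gt))), 1L)
  jr <- junctionGaps(gt, includeOriginJunction = TRUE)
  expect_equal(nrow(junctions(jr)), 2L)
  expect_equal(junctions(jr)$gap[2], 19L)  # start(a) + L - stop(b) - 1
  lin <- geneTable(features(gt), 100, circular = FALSE)
  expect_error(junctionGaps(lin, includeOriginJunction = TRUE), "linear")
})

test_that("unsorted tables are rejected", {
  gt <- geneTable(
    data.frame(locus = c("a", "b"), category = "tRNA", strand = "H",
               start = c(60, 10), stop = c(90, 50)),
    genomeLength = 100)
  expect_error(junctionGaps(gt), "order")
})

test_that("validateTable surfaces the printed table's internal inconsistencies", {
  v <- validateTable(table1Fixture())
  expect_equal(nrow(v), 1L)
  expect_equal(v$check, "intergenic")
  expect_equal(v$locus, "tRNA-Ile")
  expect_equal(as.integer(v$declared), 4L)
  expect_equal(as.integer(v$derived), 5L)
})

test_that("validateTable is silent on self-consistent tables and genomes", {
  rec <- generateGenome(table1GenomeSpec(seed = 42L))
  expect_identical(nrow(validateTable(rec)), 0L)
  # tamper with a declared size -> exactly one size finding appears
  ft <- features(rec)
  ft$size[ft$locus == "ND2"] <- 1000L
  bad <- geneTable(ft, genomeLength(rec))
  v <- validateTable(bad)
  expect_true(any(v$check == "size" & v$locus == "ND2"))
})

test_that("validateTable flags codon labels contradicted by the sequence", {
  rec <- tinyRecord()
  ft <- features(rec)
  ft$start_codon[1] <- "GTG"   # sequence actually begins ATG
  tampered <- mitoRecord(genomeSequence(rec), geneTable(ft, genomeLength(rec)))
  v <- validateTable(tampered)
  expect_true(any(v$check == "start_codon" & v$locus == "GENE1"))
})

test_that("gene order strings capture layout and strand", {
  gt <- table1Fixture()
  s <- geneOrderString(gt)
  expect_true(startsWith(
    s, "tRNA-Phe,12S-rRNA,tRNA-Val,16S-rRNA,tRNA-Leu,ND1,tRNA-Ile,-tRNA-Gln"))
  expect_identical(s, geneOrderString(table1Fixture()))
  ft <- features(gt)
  ft$strand[ft$locus == "ND6"] <- "H"
  s2 <- geneOrderString(geneTable(ft, genomeLength(gt)))
  tok <- strsplit(s, ",")[[1]]; tok2 <- strsplit(s2, ",")[[1]]
  expect_equal(sum(tok != tok2), 1L)
  expect_equal(tok[tok != tok2], "-ND6")
})

test_that("GeneTable validity rejects bad coordinates and categories", {
  expect_error(geneTable(
    data.frame(locus = "x", category = "PCG", strand = "H",
               start = 1, stop = 300), genomeLength = 200), "outside")
  expect_error(geneTable(
    data.frame(locus = "x", category = "exon", strand = "H",
               start = 1, stop = 50), genomeLength = 200), "category")
  expect_error(geneTable(
    data.frame(locus = "x", category = "PCG", strand = "H",
               start = 150, stop = 50), genomeLength = 200,
    circular = FALSE), "linear")
})
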