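test_that("the vertebrate mitochondrial code has its known reassignments", {
  code <- mitoGeneticCode()
  expect_length(code$code, 64)
  expect_identical(unname(code$code[["TGA"]]), "W")
  expect_identical(unname(code$code[["ATA"]]), "M")
  expect_setequal(code$stops, c("TAA", "TAG", "AGA", "AGG"))
  expect_true(all(c("ATG", "GTG") %in% code$starts))
})

test_that("codon extraction reads frame, tails and labels", {
  ft <- data.frame(locus = "G", category = "PCG", strand = "H",
                   start = 11, stop = 19, start_codon = "ATG",
                   stop_codon = "TAA")
  rec <- generateGenome(genomeSpec(ft, genomeLength = 60, seed = 2L))
  # overwrite gene with the worked example ATG AAA TAA
  s <- strsplit(as.character(genomeSequence(rec)), "")[[1]]
  s[11:19] <- strsplit("ATGAAATAA", "")[[1]]
  rec <- mitoRecord(paste(s, collapse = ""), rec@geneTable)
  ex <- extractCodons(rec, "G")
  expect_equal(ex$complete_codons, c("ATG", "AAA", "TAA"))
  expect_equal(ex$incomplete_tail, "")
  expect_equal(ex$start_label, "ATG")
  expect_equal(ex$stop_label, "TAA")
  expect_length(ex$findings, 0)
})

test_that("incomplete stop codons are classified by tail length", {
  rec <- generateGenome(table1GenomeSpec(seed = 19L))
  nd2 <- extractCodons(rec, "ND2")
  expect_equal(nd2$cds_length, 1045L)
  expect_equal(nd2$stop_label, "T-")
  expect_equal(nd2$incomplete_tail, "T")
  atp6 <- extractCodons(rec, "ATP6")
  expect_equal(atp6$cds_length, 683L)
  expect_equal(atp6$stop_label, "TA-")
  expect_equal(atp6$incomplete_tail, "TA")
  # conservation: 3 * complete + tail = CDS length, for every PCG
  for (g in features(rec)$locus[features(rec)$category == "PCG"]) {
    ex <- extractCodons(rec, g)
    expect_equal(3 * length(ex$complete_codons) + nchar(ex$incomplete_tail),
                 ex$cds_length)
  }
})

test_that("malformed and misannotated CDSs are handled as specified", {
  rec <- tinyRecord()
  ft <- features(rec)
  ft$stop[1] <- ft$start[1] + 3L  # 4 nt "CDS"
  short <- mitoRecord(genomeSequence(rec), geneTable(ft, genomeLength(rec)))
  expect_error(extractCodons(short, "GENE1"), "malformed")
  # plant an internal stop -> finding, not error
  s <- strsplit(as.character(genomeSequence(rec)), "")[[1]]
  st <- features(rec)$start[1]
  s[(st + 9):(st + 11)] <- c("T", "A", "A")
  withstop <- mitoRecord(paste(s, collapse = ""), rec@geneTable)
  ex <- extractCodons(withstop, "GENE1")
  expect_match(ex$findings, "internal stop", all = FALSE)
})

test_that("RSCU normalizes within synonymous families", {
  r <- rscu(c(GCA = 2, GCC = 2, GCG = 2, GCT = 2))
  expect_equal(r$rscu[r$family == "Ala"], rep(1, 4))
  r <- rscu(c(AAA = 3, AAG = 1))
  expect_equal(sort(r$rscu[r$family == "Lys"]), c(0.5, 1.5))
  # family mean is 1 for every nonzero family, random counts
  set.seed(8)
  for (rep in 1:20) {
    counts <- setNames(rpois(64, 5), names(mitoGeneticCode()$code))
    rr <- rscu(counts)
    for (f in unique(rr$family)) {
      sub <- rr[rr$family == f, ]
      if (sum(sub$count) > 0) expect_equal(mean(sub$rscu), 1)
      else expect_equal(sub$rscu, rep(0, nrow(sub)))
    }
    # stop codons never appear
    expect_false(any(rr$codon %in% mitoGeneticCode()$stops))
  }
})

test_that("CDpT is proportional and sums to 1000", {
  counts <- setNames(rep(0, 64), names(mitoGeneticCode()$code))
  counts[c("TGA", "TGG")] <- c(30, 20)   # all codons in the Trp family
  expect_equal(unname(cdpt(counts)[["Trp"]]), 1000)
  counts[["GCA"]] <- 450
  expect_equal(unname(cdpt(counts)[["Trp"]]), 100)  # Trp is 10% of total
  set.seed(12)
  for (r in 1:10) {
    counts <- setNames(rpois(64, 4), names(mitoGeneticCode()$code))
    counts[mitoGeneticCode()$stops] <- 0
    v <- cdpt(counts + 1e-9)
    expect_equal(sum(v), 1000, tolerance = 1e-9)
    fam <- codonFamilies()
    oracle <- 1000 * sum(counts[names(fam)[fam == "Leu"]]) /
      sum(counts[names(fam)])
    expect_equal(unname(v[["Leu"]]), oracle, tolerance = 1e-6)
  }
  expect_error(cdpt(setNames(rep(0, 64), names(mitoGeneticCode()$code))),
               "undefined|zero")
})

test_that("serine's two codon boxes are kept separate", {
  fam <- codonFamilies()
  expect_setequal(names(fam)[fam == "Ser"], c("TCA", "TCC", "TCG", "TCT"))
  expect_setequal(names(fam)[fam == "Ser2"], c("AGT", "AGC"))
})

test_that("the aggregated codon report reproduces planted labels and totals", {
  rec <- generateGenome(table1GenomeSpec(seed = 23L))
  rep <- pcgCodonReport(rec)
  got <- setNames(paste0(rep$startStop$start_codon, "/",
                         rep$startStop$stop_codon),
                  rep$startStop$locus)
  want <- referenceStartStopRow()
  expect_identical(got[names(want)], want)
  expect_equal(rep$totalCodons, 3803L)
  expect_equal(rep$completeCodons, 3800L)
  expect_equal(sum(rep$usage$count %% 1), 0)
  expect_equal(sum(rep$cdpt), 1000, tolerance = 1e-9)
  # GTG initiators are counted literally under Val unless recoded to Met
  lit <- rep$usage
  met <- pcgCodonReport(rec, initiatorAsMet = TRUE)$usage
  expect_equal(met$count[met$codon == "GTG"] + 2,
               lit$count[lit$codon == "GTG"])
  expect_equal(met$count[met$codon == "ATG"] - 2,
               lit$count[lit$codon == "ATG"])
})

test_that("start codons classify as canonical, alternative or invalid", {
  expect_identical(classifyStart("ATG"), "canonical")
  expect_identical(classifyStart("GTG"), "alternative")
  expect_identical(classifyStart("CCC"), "invalid")
  rec <- tinyRecord()
  expect_identical(classifyStart(extractCodons(rec, "GENE2")), "alternative")
})
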