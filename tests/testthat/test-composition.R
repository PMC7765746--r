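test_that("skews apply the strand-asymmetry formulas", {
  # the printed whole-genome composition gives the published skews
  s <- skews(c(A = 31.3, T = 24.0, G = 16.2, C = 28.6))
  expect_equal(round(s$at_skew, 3), 0.132)
  expect_equal(round(s$gc_skew, 3), -0.277)
  expect_equal(skews(c(A = 5, T = 5, G = 3, C = 3)),
               list(at_skew = 0, gc_skew = 0))
  s <- skews(c(A = 4, T = 0, G = 0, C = 0))
  expect_equal(s$at_skew, 1)
  expect_true(is.na(s$gc_skew))
  expect_error(skews(c(A = 1, C = -1, G = 0, T = 0)), "non-negative")
})

test_that("skews are scale-invariant in the counts", {
  set.seed(3)
  for (r in 1:20) {
    counts <- setNames(sample(0:500, 4, TRUE) + c(1, 1, 0, 0),
                       c("A", "T", "G", "C"))
    s1 <- skews(counts)
    k <- runif(1, 0.1, 50)
    s2 <- skews(counts * k)
    expect_equal(s2$at_skew, s1$at_skew)
    expect_equal(s2$gc_skew, s1$gc_skew)
  }
})

test_that("base composition counts match an independent per-character tally", {
  expect_equal(baseComposition("AATT")$A_pct, 50)
  expect_equal(baseComposition("AATT")$at_skew, 0)
  expect_equal(baseComposition("AATT")$AT_pct, 100)
  set.seed(9)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 1000, TRUE,
                    prob = c(.3, .3, .15, .2, .05)), collapse = "")
  comp <- baseComposition(s)
  # oracle: regex occurrence counts
  cnt <- vapply(c("A", "C", "G", "T"), function(b)
    nchar(gsub(sprintf("[^%s]", b), "", s)), numeric(1))
  expect_equal(comp$length, 1000L)
  expect_equal(comp$A_pct, 100 * cnt[["A"]] / sum(cnt))
  expect_equal(comp$G_pct, 100 * cnt[["G"]] / sum(cnt))
  expect_equal(comp$at_skew,
               (cnt[["A"]] - cnt[["T"]]) / (cnt[["A"]] + cnt[["T"]]))
  expect_error(baseComposition("NNNN"), "undefined")
})

test_that("reverse complement negates both skews", {
  set.seed(21)
  for (r in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE,
                      prob = runif(4, 0.1, 1)), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    f <- baseComposition(s); b <- baseComposition(rc)
    expect_equal(b$at_skew, -f$at_skew)
    expect_equal(b$gc_skew, -f$gc_skew)
  }
})

test_that("partition lengths conserve feature-length sums and codon-position splits", {
  rec <- generateGenome(table1GenomeSpec(seed = 13L))
  comp <- partitionComposition(rec)
  lens <- setNames(comp$length, comp$partition)
  fl <- featureLengths(rec)
  cat_of <- features(rec)$category
  expect_equal(lens[["genome"]], 16598L)
  expect_equal(lens[["PCGs"]], sum(fl[cat_of == "PCG"]))
  expect_equal(lens[["rRNA"]], sum(fl[cat_of == "rRNA"]))
  expect_equal(lens[["tRNA"]], sum(fl[cat_of == "tRNA"]))
  expect_equal(lens[["D-loop"]], sum(fl[cat_of == "control"]))
  # codon positions partition the PCG concatenation; per-gene cyclic
  # assignment puts incomplete-tail nucleotides in positions 1 (and 2)
  expect_equal(lens[["codon_pos1"]] + lens[["codon_pos2"]] +
                 lens[["codon_pos3"]], lens[["PCGs"]])
  expect_true(max(lens[paste0("codon_pos", 1:3)]) -
                min(lens[paste0("codon_pos", 1:3)]) <= 13)
})

test_that("mutating one gene leaves unrelated partitions untouched", {
  rec <- generateGenome(table1GenomeSpec(seed = 17L))
  ft <- features(rec)
  nd6 <- ft[ft$locus == "ND6", ]
  s <- strsplit(as.character(genomeSequence(rec)), "")[[1]]
  mid <- nd6$start + 60L  # inside ND6, away from planted ends and ND5
  s[mid] <- setdiff(c("A", "C", "G", "T"), s[mid])[1]
  rec2 <- mitoRecord(paste(s, collapse = ""), rec@geneTable)
  c1 <- partitionComposition(rec)
  suppressWarnings(c2 <- partitionComposition(rec2))
  pick <- function(cc, p) cc[cc$partition == p, -1]
  expect_false(isTRUE(all.equal(pick(c1, "PCGs"), pick(c2, "PCGs"))))
  expect_equal(pick(c1, "D-loop"), pick(c2, "D-loop"))
  expect_equal(pick(c1, "tRNA"), pick(c2, "tRNA"))
  expect_equal(pick(c1, "rRNA"), pick(c2, "rRNA"))
})

test_that("L-strand genes are counted in coding sense", {
  rec <- tinyRecord()
  ft <- features(rec)
  i <- which(ft$locus == "GENE3")  # L strand
  cds <- featureSequence(rec, featureIndex = i)
  expect_identical(substr(as.character(cds), 1, 3), "ATG")
  # only PCGs annotated here; the empty-partition warnings are expected
  comp <- suppressWarnings(partitionComposition(rec))
  pcg_chars <- unlist(lapply(which(ft$category == "PCG"), function(k)
    strsplit(as.character(featureSequence(rec, featureIndex = k)), "")[[1]]))
  oracle <- sum(pcg_chars == "A")
  got <- comp$A_pct[comp$partition == "PCGs"] / 100 *
    comp$length[comp$partition == "PCGs"]
  expect_equal(got, oracle)
})

test_that("reporting precision rounds percentages to 1 and skews to 3 decimals", {
  comp <- formatComposition(baseComposition("AACCCGGGGT"))
  expect_equal(comp$A_pct, 20)
  expect_equal(comp$gc_skew, round((4 - 3) / 7, 3))
})
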