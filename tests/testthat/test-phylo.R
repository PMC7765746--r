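test_that("transition/transversion proportions match per-site classification", {
  expect_equal(pqProportions(rep("A", 4), rep("A", 4)),
               list(P = 0, Q = 0, usable_sites = 4L))
  expect_equal(pqProportions(c("A", "G"), c("G", "A")),
               list(P = 1, Q = 0, usable_sites = 2L))
  expect_equal(pqProportions(c("A", "C"), c("C", "A"))$Q, 1)
  # pairwise deletion: N and gaps drop sites from both sides
  pq <- pqProportions(c("A", "N", "G", "-"), c("A", "A", "A", "A"))
  expect_equal(pq$usable_sites, 2L)
  expect_equal(pq$P, 0.5)
  expect_error(pqProportions(c("N", "-"), c("A", "A")), "comparable")
  expect_error(pqProportions(c("A"), c("A", "A")), "length")
  set.seed(14)
  for (r in 1:10) {
    a <- sample(c("A", "C", "G", "T", "N", "-"), 200, TRUE)
    b <- sample(c("A", "C", "G", "T", "N", "-"), 200, TRUE)
    oracle <- bruteForcePQ(a, b)
    got <- pqProportions(a, b)
    expect_equal(got$P, oracle$P)
    expect_equal(got$Q, oracle$Q)
    expect_equal(got$usable_sites, oracle$usable)
  }
})

test_that("K2P distance evaluates its closed form and respects its domain", {
  expect_equal(k2pDistance(0, 0), 0)
  # frozen from independent arithmetic:
  # -0.5 * log((1 - 0.2 - 0.05) * sqrt(1 - 0.1)) = 0.1701812
  expect_equal(k2pDistance(0.1, 0.05), 0.1701812, tolerance = 1e-5)
  # small-divergence limit: d = P + Q + O((P+Q)^2)
  expect_lt(abs(k2pDistance(0.001, 0.002) - 0.003), 2e-5)
  expect_error(k2pDistance(0.5, 0.2), "saturation")
  expect_error(k2pDistance(0.1, 0.5), "saturation")
  expect_error(k2pDistance(0.4, 0.21, pair = "x/y"), "x/y")
})

test_that("K2P distance is monotone in P and Q on the valid domain", {
  grid <- seq(0.01, 0.2, by = 0.02)
  d_p <- vapply(grid, k2pDistance, numeric(1), Q = 0.05)
  d_q <- vapply(grid, function(q) k2pDistance(0.05, q), numeric(1))
  expect_true(all(diff(d_p) > 0))
  expect_true(all(diff(d_q) > 0))
})

test_that("K2P matrix agrees with an independent implementation", {
  skip_if_not_installed("ape")
  aln <- simulateAlignment(simSpec(
    "((A:0.15,B:0.1):0.06,(C:0.12,D:0.08):0.06);", length = 3000, seed = 4))
  dm <- k2pMatrix(aln)
  m <- alignmentMatrix(aln)
  oracle <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(m)),
                                    model = "K80", pairwise.deletion = TRUE))
  expect_equal(dm, oracle[rownames(dm), colnames(dm)], tolerance = 1e-12)
  expect_equal(dm, t(dm))
  expect_equal(unname(diag(dm)), rep(0, 4))
})

test_that("neighbor-joining recovers a 4-taxon additive tree exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)) -> path distances
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- njTree(D)
  expect_equal(treeDistances(tr)[rownames(D), colnames(D)], D)
  expect_identical(unname(treeSplits(tr)), "C|D")
  # branch lengths: tips 1,2,3,4 and internal edge 1
  tip_edges <- tr$edge[, 2] <= 4
  tip_len <- setNames(tr$edge.length[tip_edges],
                      tr$tip.label[tr$edge[tip_edges, 2]])
  expect_equal(tip_len[c("A", "B", "C", "D")],
               c(A = 1, B = 2, C = 3, D = 4))
  expect_equal(tr$edge.length[!tip_edges], 1)
})

test_that("three taxa resolve by the closed three-point formulas", {
  D <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(D)
  expect_equal(tr$Nnode, 1L)
  len <- setNames(tr$edge.length[order(tr$edge[, 2])][1:3], tr$tip.label)
  expect_equal(len, c(A = 1, B = 1, C = 2))
})

test_that("neighbor-joining is exact on random additive matrices (4-8 taxa)", {
  set.seed(15)
  for (r in 1:40) {
    ntax <- sample(4:8, 1)
    tr <- randomUnrootedTree(paste0("t", seq_len(ntax)))
    D <- treeDistances(tr)
    nj <- njTree(D)
    expect_setequal(unname(treeSplits(nj)), unname(treeSplits(tr)))
    expect_equal(treeDistances(nj)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("neighbor-joining is deterministic and validates its input", {
  D <- matrix(runif(25), 5, 5); D <- D + t(D); diag(D) <- 0
  dimnames(D) <- list(letters[1:5], letters[1:5])
  expect_identical(writeNewick(njTree(D)), writeNewick(njTree(D)))
  bad <- D; bad[1, 2] <- bad[1, 2] + 1
  expect_error(njTree(bad), "symmetric")
  expect_error(njTree(D[1:2, 1:2]), ">= 3")
})

test_that("negative branch estimates are clamped unless explicitly allowed", {
  # triangle-inequality violation forces a negative three-point estimate:
  # v(B) = (d(AB) + d(BC) - d(AC)) / 2 = (1 + 2 - 5) / 2 = -1
  D <- matrix(c(0, 1, 5,
                1, 0, 2,
                5, 2, 0), 3, 3,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  tr <- njTree(D)
  expect_true(all(tr$edge.length >= 0))
  tr2 <- njTree(D, allowNegative = TRUE)
  expect_equal(sort(tr2$edge.length), c(-1, 2, 3))
})

test_that("bootstrap supports are reproducible and strong for clear signal", {
  aln <- simulateAlignment(simSpec(
    "((A:0.15,B:0.15):0.08,(C:0.15,D:0.15):0.08);", length = 4000, seed = 6))
  t1 <- bootstrapSupport(aln, replicates = 100, seed = 9)
  t2 <- bootstrapSupport(aln, replicates = 100, seed = 9)
  expect_identical(writeNewick(t1), writeNewick(t2))
  sup <- suppressWarnings(as.integer(t1$node.label))
  expect_gte(max(sup, na.rm = TRUE), 95)
  expect_equal(attr(t1, "completedReplicates"), 100L)
})

test_that("identical sequences give zero distances and a degenerate-tree warning", {
  aln <- setNames(rep(strrep("ACGT", 100), 3), c("A", "B", "C"))
  expect_warning(tr <- bootstrapSupport(aln, replicates = 5, seed = 1),
                 "degenerate")
  expect_equal(sum(tr$edge.length), 0)
})

test_that("outgroup rooting preserves tips and path lengths", {
  set.seed(33)
  tr <- randomUnrootedTree(paste0("t", 1:5))
  rooted <- rootAtOutgroup(tr, "t3")
  expect_setequal(rooted$tip.label, tr$tip.label)
  d1 <- treeDistances(tr); d2 <- treeDistances(rooted)
  expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-8)
})
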