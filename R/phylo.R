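#' Coerce an alignment to a character matrix
#'
#' Accepts a named character vector of equal-length sequences, a
#' \code{DNAStringSet}, or a character matrix (rows = taxa). Sequences may
#' contain A/C/G/T/N/-.
#'
#' @param aln the alignment in any accepted form.
#' @return character matrix with one row per taxon, rownames = labels.
#' @export
alignmentMatrix <- function(aln) {
  if (is.matrix(aln)) {
    m <- aln
  } else {
    if (is(aln, "XStringSet"))
      aln <- stats::setNames(as.character(aln), names(aln))
    if (!is.character(aln)) stop("unsupported alignment representation")
    lens <- nchar(aln)
    if (length(unique(lens)) != 1L)
      stop("alignment rows differ in length")
    m <- do.call(rbind, strsplit(unname(aln), "", fixed = TRUE))
    rownames(m) <- names(aln)
  }
  if (is.null(rownames(m)))
    rownames(m) <- paste0("seq", seq_len(nrow(m)))
  m
}

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Transition and transversion proportions of a sequence pair
#'
#' The sufficient statistics of the Kimura 2-parameter model: P, the
#' proportion of sites differing by a transition (purine-purine A<->G or
#' pyrimidine-pyrimidine C<->T), and Q, the proportion differing by a
#' transversion. Sites where either sequence carries N or a gap are
#' excluded from numerator and denominator (pairwise deletion, the MEGA
#' default for K2P distances).
#'
#' @param rowA,rowB character vectors of single residues (equal length).
#' @return list: \code{P}, \code{Q}, \code{usable_sites}.
#' @examples
#' pqProportions(c("A","G"), c("G","A"))  # P = 1, Q = 0
#' @export
pqProportions <- function(rowA, rowB) {
  if (length(rowA) != length(rowB))
    stop("rows differ in length")
  use <- rowA %in% c(PURINES, PYRIMIDINES) & rowB %in% c(PURINES, PYRIMIDINES)
  usable <- sum(use)
  if (usable == 0L)
    stop("no comparable sites between the two rows (all gapped/ambiguous)")
  a <- rowA[use]; b <- rowB[use]
  diff <- a != b
  ts <- diff & ((a %in% PURINES) == (b %in% PURINES))
  list(P = sum(ts) / usable, Q = sum(diff & !ts) / usable,
       usable_sites = usable)
}

#' Kimura 2-parameter distance
#'
#' d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q)), in substitutions per site.
#' Defined only while 1 - 2P - Q > 0 and 1 - 2Q > 0; beyond that the
#' sequences are saturated under the model and an error naming the pair is
#' raised.
#'
#' @param P,Q transition and transversion proportions.
#' @param pair optional label used in the saturation error message.
#' @return distance in substitutions per site.
#' @examples
#' k2pDistance(0.1, 0.05)  # 0.17018
#' @export
k2pDistance <- function(P, Q, pair = NULL) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop(sprintf("K2P distance undefined (saturation)%s: P=%.4f, Q=%.4f",
                 if (is.null(pair)) "" else paste0(" for pair ", pair), P, Q))
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise K2P distance matrix of an alignment
#'
#' @param aln alignment (see \code{\link{alignmentMatrix}}) with >= 2 taxa.
#' @return symmetric numeric matrix with zero diagonal, dimnames = taxa.
#' @export
k2pMatrix <- function(aln) {
  m <- alignmentMatrix(aln)
  ntax <- nrow(m)
  d <- matrix(0, ntax, ntax, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(ntax - 1L))
    for (j in (i + 1L):ntax) {
      pq <- pqProportions(m[i, ], m[j, ])
      d[i, j] <- d[j, i] <- k2pDistance(
        pq$P, pq$Q, pair = paste(rownames(m)[i], rownames(m)[j], sep = "/"))
    }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomeration with the standard rate-corrected criterion
#' Q(i,j) = (n-2) d(i,j) - r(i) - r(j). Deterministic: ties in Q are
#' broken toward the lexicographically smallest pair of cluster labels
#' (a cluster is labelled by its alphabetically first member). Exact on
#' additive distances: it recovers the generating topology and branch
#' lengths. Negative branch-length estimates are clamped to 0 with the
#' deficit shifted to the sister branch (the MEGA-compatible convention)
#' unless \code{allowNegative = TRUE}.
#'
#' @param dm symmetric distance matrix with dimnames (>= 3 taxa).
#' @param allowNegative keep negative branch-length estimates.
#' @return an unrooted \code{phylo}-structured tree (edge matrix, edge
#'   lengths, tip labels; internal nodes of degree 3).
#' @export
njTree <- function(dm, allowNegative = FALSE) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || max(abs(dm - t(dm))) > 1e-8)
    stop("distance matrix must be symmetric")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(dm)))
  ntax <- length(labels)
  if (ntax < 3L) stop("neighbor-joining needs >= 3 taxa")

  # node registry: tips 1..ntax; internal nodes appended as created.
  # `active`, `cluster_label` and the rows of D stay positionally aligned.
  children <- vector("list", ntax)
  active <- seq_len(ntax)
  cluster_label <- labels
  D <- unname(dm)
  node_count <- ntax

  addNode <- function(child_ids, child_lens) {
    node_count <<- node_count + 1L
    children[[node_count]] <<- list(ids = child_ids, lens = child_lens)
    node_count
  }
  clamp <- function(v) {
    # v = c(len_i, len_j); shift any deficit to the sister branch
    if (!allowNegative) {
      if (v[1L] < 0) { v[2L] <- v[2L] + v[1L]; v[1L] <- 0 }
      if (v[2L] < 0) { v[1L] <- max(0, v[1L] + v[2L]); v[2L] <- 0 }
    }
    v
  }

  while (length(active) > 3L) {
    n <- length(active)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij)
      paste(sort(cluster_label[ij]), collapse = "\r"))
    pick <- cand[order(keys)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    u <- addNode(c(active[i], active[j]), clamp(c(vi, vj)))
    newd <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    cluster_label <- c(cluster_label[keep], min(cluster_label[c(i, j)]))
    active <- c(active[keep], u)
  }
  # final three clusters join at the central node (three-point formulas)
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- c(va, vb, vc)
  if (!allowNegative) v <- pmax(v, 0)
  center <- addNode(active, v)

  # flatten the registry into a phylo edge matrix (preorder from center)
  id_map <- integer(node_count)
  next_id <- ntax + 1L
  edges <- list()
  emit <- function(node) {
    id_map[node] <<- next_id
    next_id <<- next_id + 1L
    ch <- children[[node]]
    for (k in seq_along(ch$ids)) {
      cid <- ch$ids[k]
      if (cid <= ntax) {
        edges[[length(edges) + 1L]] <<- c(id_map[node], cid, ch$lens[k])
      } else {
        pos <- length(edges) + 1L
        edges[[pos]] <<- c(id_map[node], NA, ch$lens[k])
        emit(cid)
        edges[[pos]][2L] <<- id_map[cid]
      }
    }
  }
  emit(center)
  em <- do.call(rbind, edges)
  tree <- list(edge = matrix(as.integer(em[, 1:2]), ncol = 2L),
               edge.length = em[, 3L], tip.label = labels,
               Nnode = node_count - ntax)
  class(tree) <- "phylo"
  tree
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' One bipartition (split) per internal edge, canonicalized as the sorted
#' tip-label set on the side not containing the alphabetically smallest
#' taxon, joined with "|". Used for topology comparison and bootstrap
#' counting.
#'
#' @param tree a \code{phylo}-structured tree.
#' @return character vector of split keys, named by the child node id of
#'   the internal edge defining each split.
#' @export
treeSplits <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  tipsUnder <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tipsUnder), use.names = FALSE)
  }
  anchor <- min(tree$tip.label)
  internal_children <- tree$edge[tree$edge[, 2L] > ntip, 2L]
  out <- character(0)
  for (node in internal_children) {
    side <- tipsUnder(node)
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    if (anchor %in% side)
      side <- setdiff(tree$tip.label, side)
    out[as.character(node)] <- paste(sort(side), collapse = "|")
  }
  out
}

#' Path-length distances between the tips of a tree
#'
#' Sums branch lengths along the unique tip-to-tip paths; the independent
#' additive-distance oracle for neighbor-joining.
#'
#' @param tree a \code{phylo}-structured tree with edge lengths.
#' @return symmetric matrix of tip-to-tip distances.
#' @export
treeDistances <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  adj <- vector("list", nnode)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  d <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (s in seq_len(ntip)) {
    dist <- rep(NA_real_, nnode)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (k in seq_len(NROW(adj[[v]]))) {
        nb <- adj[[v]][k, 1L]; w <- adj[[v]][k, 2L]
        if (is.na(dist[nb])) {
          dist[nb] <- dist[v] + w
          queue <- c(queue, nb)
        }
      }
    }
    d[s, ] <- dist[seq_len(ntip)]
  }
  d
}

#' Bootstrap supports for a K2P + neighbor-joining tree
#'
#' Builds the tree from the full alignment, then resamples alignment
#' columns with replacement \code{replicates} times, rebuilding the
#' K2P/NJ tree each time; the support of each internal bipartition of the
#' original tree is the percentage of completed replicates containing it.
#' Replicates in which a distance is incomputable (saturation, no
#' comparable sites) are skipped with a warning and supports are
#' normalized by the completed count. Reproducible given \code{seed}.
#'
#' @param aln alignment (>= 3 taxa).
#' @param replicates bootstrap replicate count (>= 1).
#' @param seed RNG seed.
#' @param allowNegative passed to \code{\link{njTree}}.
#' @return the original tree with integer supports in \code{node.label}
#'   ("" at the basal node) and attribute \code{completedReplicates}.
#' @export
bootstrapSupport <- function(aln, replicates = 1000, seed = NULL,
                             allowNegative = FALSE) {
  if (replicates < 1L) stop("replicates must be >= 1")
  m <- alignmentMatrix(aln)
  if (!is.null(seed)) set.seed(seed)
  dm <- k2pMatrix(m)
  if (all(dm == 0))
    warning("all pairwise distances are zero; tree is degenerate",
            call. = FALSE)
  tree <- njTree(dm, allowNegative = allowNegative)
  orig <- treeSplits(tree)
  counts <- stats::setNames(rep(0L, length(orig)), orig)
  completed <- 0L
  nsites <- ncol(m)
  for (b in seq_len(replicates)) {
    cols <- sample.int(nsites, nsites, replace = TRUE)
    rep_tree <- tryCatch(njTree(k2pMatrix(m[, cols, drop = FALSE]),
                                allowNegative = allowNegative),
                         error = function(e) {
                           warning(sprintf("replicate %d skipped: %s", b,
                                           conditionMessage(e)),
                                   call. = FALSE)
                           NULL
                         })
    if (is.null(rep_tree)) next
    completed <- completed + 1L
    hit <- orig %in% treeSplits(rep_tree)
    counts[hit] <- counts[hit] + 1L
  }
  if (completed == 0L) stop("no bootstrap replicate completed")
  ntip <- length(tree$tip.label)
  node_label <- rep("", tree$Nnode)
  support <- round(100 * counts / completed)
  for (k in seq_along(orig)) {
    node <- as.integer(names(orig)[k])
    node_label[node - ntip] <- as.character(support[k])
  }
  tree$node.label <- node_label
  attr(tree, "completedReplicates") <- completed
  tree
}

#' Root a tree on an outgroup for display
#'
#' The NJ tree is unrooted; for figure-style display it can be rooted on
#' an outgroup taxon by inserting a root in the middle of the outgroup's
#' pendant edge.
#'
#' @param tree a \code{phylo}-structured unrooted tree.
#' @param outgroup tip label.
#' @return a rooted \code{phylo}-structured tree.
#' @export
rootAtOutgroup <- function(tree, outgroup) {
  ntip <- length(tree$tip.label)
  tipn <- match(outgroup, tree$tip.label)
  if (is.na(tipn)) stop("outgroup not in tree: ", outgroup)
  e <- which(tree$edge[, 2L] == tipn)
  # re-hang the tree from a new root placed on the outgroup's pendant edge
  half <- tree$edge.length[e] / 2
  adj <- vector("list", ntip + tree$Nnode)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1L]; b <- tree$edge[k, 2L]
    if (k == e) next
    adj[[a]] <- rbind(adj[[a]], c(b, tree$edge.length[k]))
    adj[[b]] <- rbind(adj[[b]], c(a, tree$edge.length[k]))
  }
  inner <- tree$edge[e, 1L]
  nested_from <- function(node, parent) {
    nb <- adj[[node]]
    ch <- list()
    if (NROW(nb)) for (k in seq_len(nrow(nb)))
      if (nb[k, 1L] != parent) {
        sub <- nested_from(nb[k, 1L], node)
        sub$length <- nb[k, 2L]
        ch[[length(ch) + 1L]] <- sub
      }
    if (node <= ntip && !length(ch))
      list(children = list(), label = tree$tip.label[node], length = NA_real_)
    else {
      lab <- if (!is.null(tree$node.label)) tree$node.label[node - ntip] else ""
      list(children = ch, label = lab, length = NA_real_)
    }
  }
  root <- list(children = list(
    list(children = list(), label = tree$tip.label[tipn], length = half),
    {
      sub <- nested_from(inner, -1L)
      sub$length <- half
      sub
    }), label = "", length = NA_real_)
  nestedToPhylo(root)
}
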