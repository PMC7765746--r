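#' Read a GenBank flat file into a MitoRecord
#'
#' Minimal GenBank dialect for single-record mitogenome flat files: the
#' LOCUS line supplies length and circular/linear topology, ACCESSION the
#' accession, the source feature's /organism the taxon, and the feature
#' keys gene/CDS/tRNA/rRNA/D_loop/misc_feature become
#' \code{GeneFeature} rows (CDS -> PCG, D_loop/misc_feature -> control).
#' \code{complement(...)} locations map to strand L and
#' \code{join(a..L,1..b)} to an origin-wrapping feature. The ORIGIN block
#' yields the sequence. Qualifiers /gene, /product, /anticodon and the
#' /note block written by \code{\link{writeGenBank}} (declared size,
#' codon labels, intergenic value) are parsed when present.
#'
#' @param path file path.
#' @return a \code{\linkS4class{MitoRecord}}.
#' @seealso \code{\link{writeGenBank}}
#' @export
readGenBank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_line <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus_line)) stop("not a GenBank flat file: no LOCUS line")
  toks <- strsplit(trimws(locus_line[1L]), "\\s+")[[1L]]
  len <- as.integer(toks[which(toks == "bp") - 1L])
  circular <- any(grepl("circular", locus_line[1L], ignore.case = TRUE))
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  accession <- if (length(acc_line)) {
    a <- trimws(sub("^ACCESSION", "", acc_line[1L]))
    if (nzchar(a)) strsplit(a, "\\s+")[[1L]][1L] else ""
  } else ""

  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stop("malformed GenBank file: no ORIGIN block")
  fstart <- grep("^FEATURES", lines)
  fend <- ostart[1L] - 1L
  feat_lines <- if (length(fstart)) lines[(fstart[1L] + 1L):fend] else character(0)

  seq_lines <- lines[(ostart[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq_txt <- toupper(gsub("[ 0-9]", "", paste(seq_lines, collapse = "")))
  if (!is.na(len) && nchar(seq_txt) != len)
    warning(sprintf("LOCUS length %d != ORIGIN length %d", len,
                    nchar(seq_txt)), call. = FALSE)

  # split feature block into (key, location+qualifier) chunks
  is_key <- grepl("^ {5}\\S", feat_lines)
  idx <- which(is_key)
  taxon <- ""
  rows <- list()
  for (k in seq_along(idx)) {
    from <- idx[k]
    to <- if (k < length(idx)) idx[k + 1L] - 1L else length(feat_lines)
    chunk <- feat_lines[from:to]
    head_toks <- strsplit(trimws(chunk[1L]), "\\s+")[[1L]]
    key <- head_toks[1L]
    loc <- paste0(head_toks[-1L], collapse = "")
    # location may continue on non-qualifier lines
    cont <- chunk[-1L]
    qual_start <- grep("^\\s+/", cont)
    loc_extra <- if (length(qual_start)) cont[seq_len(qual_start[1L] - 1L)]
                 else cont
    loc <- paste0(loc, paste0(trimws(loc_extra), collapse = ""))
    quals <- paste(trimws(cont), collapse = " ")
    getq <- function(name) {
      m <- regmatches(quals, regexpr(sprintf('/%s="[^"]*"', name), quals))
      if (length(m)) sub(sprintf('^/%s="', name), "",
                         sub('"$', "", m)) else NA_character_
    }
    if (key == "source") {
      org <- getq("organism")
      if (!is.na(org)) taxon <- org
      next
    }
    if (!key %in% c("gene", "CDS", "tRNA", "rRNA", "D_loop", "misc_feature"))
      next
    strand <- if (grepl("complement", loc)) "L" else "H"
    nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1L]])
    if (length(nums) < 2L) stop("unparseable feature location: ", loc)
    if (grepl("join", loc)) {
      start <- nums[1L]; stop_ <- nums[length(nums)]
    } else {
      start <- nums[1L]; stop_ <- nums[2L]
    }
    if (any(c(start, stop_) < 1L) || any(c(start, stop_) > len))
      stop(sprintf("feature location %s outside sequence [1, %d]", loc, len))
    anticodon <- getq("anticodon")
    if (!is.na(anticodon) && grepl("seq:", anticodon))
      anticodon <- toupper(sub(".*seq:([A-Za-z]+).*", "\\1", anticodon))
    note <- getq("note")
    size <- sc <- pc <- ig <- NA
    if (!is.na(note) && grepl("mitochar:", note)) {
      kv <- strsplit(sub(".*mitochar:", "", note), ";")[[1L]]
      kvl <- strsplit(kv, "=")
      vals <- stats::setNames(vapply(kvl, `[`, "", 2L),
                              vapply(kvl, `[`, "", 1L))
      size <- suppressWarnings(as.integer(vals["size"]))
      sc <- unname(vals["start_codon"]); pc <- unname(vals["stop_codon"])
      ig <- suppressWarnings(as.integer(vals["intergenic"]))
    }
    locus <- getq("gene")
    if (is.na(locus)) locus <- getq("product")
    if (is.na(locus)) locus <- key
    rows[[length(rows) + 1L]] <- data.frame(
      locus = locus,
      category = switch(key, CDS = "PCG", gene = "PCG", tRNA = "tRNA",
                        rRNA = "rRNA", "control"),
      strand = strand, start = start, stop = stop_,
      size = size, start_codon = sc, stop_codon = pc,
      anticodon = if (is.na(anticodon)) NA_character_ else anticodon,
      intergenic = ig, key = key, stringsAsFactors = FALSE)
  }
  ft <- do.call(rbind, rows)
  # drop bare "gene" features duplicating a typed feature at the same locus
  if (!is.null(ft) && any(ft$key == "gene")) {
    dup <- ft$key == "gene" &
      paste(ft$locus, ft$start) %in%
        paste(ft$locus[ft$key != "gene"], ft$start[ft$key != "gene"])
    ft <- ft[!dup, , drop = FALSE]
  }
  if (is.null(ft)) stop("no recognized features in GenBank file")
  ft$key <- NULL
  ft <- ft[order(ft$start), , drop = FALSE]
  gt <- geneTable(ft, genomeLength = nchar(seq_txt), circular = circular,
                  taxon = taxon, accession = accession)
  mitoRecord(seq_txt, gt, source = path)
}

#' Write a MitoRecord as a minimal GenBank flat file
#'
#' Emits LOCUS (length + topology), ACCESSION, a source feature with the
#' taxon, one feature per gene-table row (PCG -> CDS, control -> D_loop;
#' L strand as \code{complement(...)}, origin wrap as \code{join}), and a
#' 60-column ORIGIN block. Declared columns are carried in a /note
#' qualifier so that \code{\link{readGenBank}} round-trips every field.
#'
#' @param record a \code{\linkS4class{MitoRecord}}.
#' @param path output path.
#' @param name LOCUS name (default accession or "genome").
#' @return the path, invisibly.
#' @export
writeGenBank <- function(record, path, name = NULL) {
  gt <- record@geneTable
  L <- genomeLength(record)
  if (is.null(name))
    name <- if (nzchar(accessionOf(record))) accessionOf(record) else "genome"
  out <- c(sprintf("LOCUS       %-16s %d bp    DNA     %s VRT 01-JAN-2000",
                   name, L, if (isCircular(record)) "circular" else "linear"))
  if (nzchar(accessionOf(record)))
    out <- c(out, paste0("ACCESSION   ", accessionOf(record)))
  out <- c(out, "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", L))
  if (nzchar(taxonName(record)))
    out <- c(out, sprintf('                     /organism="%s"',
                          taxonName(record)))
  ft <- features(record)
  for (i in seq_len(nrow(ft))) {
    key <- switch(ft$category[i], PCG = "CDS", tRNA = "tRNA",
                  rRNA = "rRNA", control = "D_loop")
    loc <- if (ft$start[i] <= ft$stop[i])
      sprintf("%d..%d", ft$start[i], ft$stop[i])
    else sprintf("join(%d..%d,1..%d)", ft$start[i], L, ft$stop[i])
    if (ft$strand[i] == "L") loc <- sprintf("complement(%s)", loc)
    out <- c(out, sprintf("     %-15s %s", key, loc),
             sprintf('                     /gene="%s"', ft$locus[i]))
    if (!is.na(ft$anticodon[i]))
      out <- c(out, sprintf('                     /anticodon="%s"',
                            ft$anticodon[i]))
    kv <- character(0)
    if (!is.na(ft$size[i])) kv <- c(kv, paste0("size=", ft$size[i]))
    if (!is.na(ft$start_codon[i]))
      kv <- c(kv, paste0("start_codon=", ft$start_codon[i]))
    if (!is.na(ft$stop_codon[i]))
      kv <- c(kv, paste0("stop_codon=", ft$stop_codon[i]))
    if (!is.na(ft$intergenic[i]))
      kv <- c(kv, paste0("intergenic=", ft$intergenic[i]))
    if (length(kv))
      out <- c(out, sprintf('                     /note="mitochar:%s"',
                            paste(kv, collapse = ";")))
  }
  out <- c(out, "ORIGIN")
  s <- tolower(as.character(genomeSequence(record)))
  starts <- seq(1L, nchar(s), by = 60L)
  for (st in starts) {
    block <- substr(s, st, min(st + 59L, nchar(s)))
    tens <- substring(block, seq(1L, nchar(block), 10L),
                      pmin(seq(10L, nchar(block) + 9L, 10L), nchar(block)))
    out <- c(out, sprintf("%9d %s", st, paste(tens, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Read / write DNA FASTA
#'
#' Standard multi-FASTA. On reading, residues are upper-cased, U is
#' normalized to T, and ambiguity codes beyond N are mapped to N with a
#' warning; alignment gaps ("-") are preserved, so aligned FASTA reads
#' through the same function. Writing wraps at 60 columns and preserves
#' IDs verbatim.
#'
#' @param path file path.
#' @return \code{readFastaDNA}: a named character vector of sequences;
#'   \code{writeFastaDNA}: the path, invisibly.
#' @export
readFastaDNA <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !startsWith(lines[1L], ">"))
    stop("not a FASTA file (empty or missing '>' header): ", path)
  hdr <- startsWith(lines, ">")
  ids <- sub("^>", "", lines[hdr])
  if (anyDuplicated(ids))
    warning("duplicate FASTA IDs: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "),
            call. = FALSE)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 paste, character(1), collapse = "")
  stats::setNames(normalizeResidues(unname(seqs), allowGap = TRUE), ids)
}

#' @rdname readFastaDNA
#' @param seqs named character vector, \code{DNAStringSet}, or list of
#'   sequences.
#' @export
writeFastaDNA <- function(seqs, path) {
  if (is(seqs, "XStringSet"))
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    writeLines(substring(s, seq(1L, nchar(s), 60L),
                         pmin(seq(60L, nchar(s) + 59L, 60L), nchar(s))), con)
  }
  invisible(path)
}

quoteNewickLabel <- function(x) {
  reserved <- grepl("[][(){},:;'\" \t]", x)
  x[reserved] <- paste0("'", gsub("'", "''", x[reserved]), "'")
  x
}

#' Write a tree in Newick format
#'
#' Branch lengths are printed to 6 decimals and integer bootstrap supports
#' (the tree's internal \code{node.label}s) as internal-node labels; taxon
#' labels containing Newick-reserved characters are quoted. The string
#' terminates with ";".
#'
#' @param tree a \code{phylo}-structured tree (as returned by
#'   \code{\link{njTree}} / \code{\link{bootstrapSupport}}).
#' @param path output path, or NULL to return the string only.
#' @param digits decimals for branch lengths.
#' @return the Newick string, invisibly when \code{path} is given.
#' @export
writeNewick <- function(tree, path = NULL, digits = 6) {
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt <- paste0("%.", digits, "f")
  rec <- function(node, edge_idx) {
    if (node <= ntip) {
      lab <- quoteNewickLabel(tree$tip.label[node])
    } else {
      ch <- kids[[as.character(node)]]
      inner <- vapply(ch, function(e) rec(tree$edge[e, 2L], e), character(1))
      nl <- if (!is.null(tree$node.label)) tree$node.label[node - ntip] else ""
      if (is.na(nl)) nl <- ""
      lab <- paste0("(", paste(inner, collapse = ","), ")", nl)
    }
    if (!is.null(edge_idx) && !is.null(tree$edge.length))
      lab <- paste0(lab, ":", sprintf(fmt, tree$edge.length[edge_idx]))
    lab
  }
  root <- ntip + 1L
  txt <- paste0(rec(root, NULL), ";")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a Newick tree
#'
#' Minimal Newick parser handling branch lengths, internal-node labels and
#' quoted taxon labels; returns the same \code{phylo}-structured list the
#' tree builders produce (edge matrix, edge lengths, tip and node labels).
#'
#' @param text Newick string, or NULL to read from \code{path}.
#' @param path file to read when \code{text} is NULL.
#' @return a \code{phylo}-structured tree.
#' @export
readNewick <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "")
  text <- trimws(text)
  text <- sub(";\\s*$", "", text)
  pos <- 1L
  n <- nchar(text)
  peek <- function() if (pos <= n) substr(text, pos, pos) else ""
  advance <- function() pos <<- pos + 1L
  readLabel <- function() {
    if (peek() == "'") {
      advance()
      out <- character(0)
      repeat {
        ch <- peek(); advance()
        if (ch == "'") {
          if (peek() == "'") { out <- c(out, "'"); advance() } else break
        } else out <- c(out, ch)
      }
      return(paste(out, collapse = ""))
    }
    start <- pos
    while (pos <= n && !substr(text, pos, pos) %in% c("(", ")", ",", ":"))
      advance()
    substr(text, start, pos - 1L)
  }
  parseNode <- function() {
    node <- list(children = list(), label = "", length = NA_real_)
    if (peek() == "(") {
      advance()
      repeat {
        node$children[[length(node$children) + 1L]] <- parseNode()
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        stop("malformed Newick near position ", pos)
      }
      node$label <- readLabel()
    } else {
      node$label <- readLabel()
    }
    if (peek() == ":") {
      advance()
      node$length <- as.numeric(readLabel())
    }
    node
  }
  root <- parseNode()
  nestedToPhylo(root)
}

# Convert a nested (children/label/length) structure to phylo form.
nestedToPhylo <- function(root) {
  tips <- character(0)
  countTips <- function(nd) {
    if (!length(nd$children)) tips <<- c(tips, nd$label)
    else for (ch in nd$children) countTips(ch)
  }
  countTips(root)
  ntip <- length(tips)
  edge <- matrix(0L, 0L, 2L)
  edge_len <- numeric(0)
  node_label <- character(0)
  next_internal <- ntip + 1L
  tip_i <- 0L
  assign_ids <- function(nd) {
    if (!length(nd$children)) {
      tip_i <<- tip_i + 1L
      return(tip_i)
    }
    my_id <- next_internal
    next_internal <<- next_internal + 1L
    node_label[my_id - ntip] <<- nd$label
    for (ch in nd$children) {
      ch_id <- assign_ids(ch)
      edge <<- rbind(edge, c(my_id, ch_id))
      edge_len <<- c(edge_len, if (is.na(ch$length)) 0 else ch$length)
    }
    my_id
  }
  assign_ids(root)
  tree <- list(edge = edge, edge.length = edge_len, tip.label = tips,
               Nnode = next_internal - ntip - 1L)
  if (any(nzchar(node_label))) tree$node.label <- node_label
  class(tree) <- "phylo"
  tree
}
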