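#' @importFrom stats optim optimize sd setNames rbinom rexp runif rgamma quantile
#' @importFrom utils write.table read.table head combn
NULL

# IUPAC nucleotide alphabet used throughout.  Ambiguity codes are the
# degenerate (heterozygous/uncertain) states; '-' is a gap, '?' missing.
.DNA_BASES <- c("A", "C", "G", "T")
.DNA_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
.DNA_OTHER <- c("-", "?")
.DNA_ALPHABET <- c(.DNA_BASES, .DNA_AMBIG, .DNA_OTHER)

clade_key <- function(members) paste(sort(as.character(members)), collapse = "\r")

#' Construct a support-annotated phylogenetic tree
#'
#' Wraps an `ape` \code{phylo} object together with per-internal-node dual
#' support annotations: maximum-likelihood bootstrap proportion (`mlbp`,
#' percentage in \[0, 100\]) and Bayesian posterior probability (`bipp`,
#' probability in \[0, 1\]).  Either value may be `NA` (unannotated node).
#'
#' @param phy an object of class \code{phylo} (rooted).
#' @param support data frame with columns `node`, `mlbp`, `bipp`, one row per
#'   internal node of `phy` (missing rows are filled with `NA`).
#' @return an object of class \code{c("annotated_phylo", "phylo")}.
#' @export
annotated_tree <- function(phy, support = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge) || is.null(phy$tip.label))
    stop("invalid phylo object")
  if (anyDuplicated(phy$tip.label))
    stop("tip labels must be unique within a tree")
  if (!is.null(phy$edge.length) && any(phy$edge.length < -1e-12))
    stop("branch lengths must be >= 0")
  ntip <- length(phy$tip.label)
  nodes <- seq.int(ntip + 1L, ntip + phy$Nnode)
  sup <- data.frame(node = nodes, mlbp = NA_real_, bipp = NA_real_)
  if (!is.null(support)) {
    support <- as.data.frame(support)
    if (!all(c("node", "mlbp", "bipp") %in% names(support)))
      stop("support must have columns node, mlbp, bipp")
    idx <- match(support$node, nodes)
    if (anyNA(idx)) stop("support rows refer to non-internal nodes")
    sup$mlbp[idx] <- support$mlbp
    sup$bipp[idx] <- support$bipp
  }
  .validate_support_values(sup$mlbp, sup$bipp)
  phy$support <- sup
  class(phy) <- unique(c("annotated_phylo", class(phy)))
  phy
}

.validate_support_values <- function(mlbp, bipp) {
  bad <- !is.na(mlbp) & (mlbp < 0 | mlbp > 100)
  if (any(bad))
    stop("ML bootstrap support out of range [0, 100]: ", paste(mlbp[bad], collapse = ", "))
  bad <- !is.na(bipp) & (bipp < 0 | bipp > 1)
  if (any(bad))
    stop("Bayesian posterior out of range [0, 1]: ", paste(bipp[bad], collapse = ", "))
  invisible(TRUE)
}

.parse_support_label <- function(labels, dialect) {
  labels[is.na(labels) | labels == "" | labels == "-" | labels == "–"] <- NA_character_
  n <- length(labels)
  mlbp <- rep(NA_real_, n)
  bipp <- rep(NA_real_, n)
  one <- function(x) {
    if (x %in% c("-", "")) NA_real_ else suppressWarnings(as.numeric(x))
  }
  for (i in seq_len(n)) {
    lab <- labels[i]
    if (is.na(lab)) next
    if (dialect == "mlbp/bipp") {
      parts <- strsplit(lab, "/", fixed = TRUE)[[1]]
      if (length(parts) != 2L)
        stop("node label '", lab, "' is not of the form 'mlbp/bipp'")
      mlbp[i] <- one(parts[1])
      bipp[i] <- one(parts[2])
      if ((!is.na(parts[1]) && parts[1] != "-" && is.na(mlbp[i])) ||
          (!is.na(parts[2]) && parts[2] != "-" && is.na(bipp[i])))
        stop("non-numeric support in node label '", lab, "'")
    } else if (dialect == "mlbp") {
      mlbp[i] <- one(lab)
    } else if (dialect == "bipp") {
      bipp[i] <- one(lab)
    } else stop("unknown annotation dialect: ", dialect)
  }
  list(mlbp = mlbp, bipp = bipp)
}

#' Parse a newick or NEXUS tree with support annotations
#'
#' Internal-node labels are interpreted according to `dialect`:
#' `"mlbp/bipp"` reads the common `"x/y"` convention (ML bootstrap percentage
#' before the slash, Bayesian posterior after; `"-"` or an empty field means
#' missing), `"mlbp"` reads a single bootstrap percentage, and `"bipp"` a
#' single posterior probability.  To merge supports carried on two separate
#' trees (one per analysis) see [merge_supports()].
#'
#' @param text a newick string or the contents of a NEXUS file with a TREES
#'   block (a single tree is read).
#' @param dialect annotation dialect, see Details.
#' @return an [annotated_tree()].
#' @export
parse_tree <- function(text, dialect = c("mlbp/bipp", "mlbp", "bipp")) {
  dialect <- match.arg(dialect)
  stopifnot(is.character(text), length(text) == 1L)
  is_nexus <- grepl("^\\s*#NEXUS", text, ignore.case = TRUE)
  if (!is_nexus) .check_newick_syntax(text)
  phy <- if (is_nexus) {
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf), add = TRUE)
    writeLines(text, tf)
    tr <- ape::read.nexus(tf)
    if (inherits(tr, "multiPhylo")) tr[[1]] else tr
  } else {
    tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
    if (is.null(tr)) stop("failed to parse newick string")
    tr
  }
  ntip <- length(phy$tip.label)
  nodes <- seq.int(ntip + 1L, ntip + phy$Nnode)
  sup <- if (is.null(phy$node.label)) {
    list(mlbp = rep(NA_real_, phy$Nnode), bipp = rep(NA_real_, phy$Nnode))
  } else {
    .parse_support_label(phy$node.label, dialect)
  }
  phy$node.label <- NULL
  annotated_tree(phy, data.frame(node = nodes, mlbp = sup$mlbp, bipp = sup$bipp))
}

# Cheap syntactic pre-check so parse errors can name a character offset.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed newick: unbalanced ')' at character offset ", i)
    }
  }
  if (in_quote) stop("malformed newick: unterminated quote at character offset ",
                     length(chars))
  if (depth != 0L)
    stop("malformed newick: ", depth, " unclosed '(' at end of string")
  invisible(TRUE)
}

#' Merge ML and Bayesian supports carried on two copies of one topology
#'
#' The "two-file" annotation dialect: one tree annotated with ML bootstrap
#' values, a second (same taxa, possibly different resolution) with posterior
#' probabilities.  Supports are matched by descendant tip set; clades of
#' `ml_tree` absent from `bi_tree` keep a missing posterior.
#'
#' @param ml_tree tree parsed with `dialect = "mlbp"` (topology carrier).
#' @param bi_tree tree parsed with `dialect = "bipp"`.
#' @return `ml_tree` with `bipp` filled in where clades match.
#' @export
merge_supports <- function(ml_tree, bi_tree) {
  stopifnot(inherits(ml_tree, "annotated_phylo"), inherits(bi_tree, "annotated_phylo"))
  if (!setequal(ml_tree$tip.label, bi_tree$tip.label))
    stop("the two trees must share a taxon universe")
  cl_ml <- node_clades(ml_tree)
  cl_bi <- node_clades(bi_tree)
  bi_keys <- vapply(cl_bi, clade_key, "")
  bi_nodes <- as.integer(names(cl_bi))
  for (i in seq_len(nrow(ml_tree$support))) {
    node <- ml_tree$support$node[i]
    key <- clade_key(cl_ml[[as.character(node)]])
    j <- match(key, bi_keys)
    if (!is.na(j)) {
      k <- match(bi_nodes[j], bi_tree$support$node)
      ml_tree$support$bipp[i] <- bi_tree$support$bipp[k]
    }
  }
  ml_tree
}

#' Serialise an annotated tree to newick
#'
#' Internal-node supports are written in the `"x/y"` dialect (`"-"` for a
#' missing half; no label when both are missing), so
#' `parse_tree(write_tree(x))` round-trips bipartitions, supports and branch
#' lengths.
#'
#' @param tree an [annotated_tree()].
#' @return a single newick string.
#' @export
write_tree <- function(tree) {
  stopifnot(inherits(tree, "annotated_phylo"))
  phy <- tree
  fmt <- function(x, d) ifelse(is.na(x), "-", sprintf("%.12g", x))
  lab <- character(phy$Nnode)
  for (i in seq_len(nrow(phy$support))) {
    m <- phy$support$mlbp[i]; b <- phy$support$bipp[i]
    lab[i] <- if (is.na(m) && is.na(b)) "" else paste0(fmt(m), "/", fmt(b))
  }
  phy$node.label <- lab
  phy$support <- NULL
  class(phy) <- "phylo"
  ape::write.tree(phy, digits = 12)
}

#' Descendant tip sets of every internal node
#'
#' @param tree a \code{phylo} (or annotated) tree.
#' @return a named list (names = internal node numbers) of character vectors
#'   of tip labels.
#' @export
node_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1]; c <- ord$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[c]])
  }
  out <- desc[(ntip + 1L):nn]
  names(out) <- as.character((ntip + 1L):nn)
  out
}

#' Table of clades with their supports
#'
#' One row per internal node: node number, clade size, `mlbp`, `bipp` and a
#' canonical clade key.  The list of member labels is attached as the
#' `"members"` attribute.
#'
#' @param tree an [annotated_tree()].
#' @return data frame, see Description.
#' @export
clade_table <- function(tree) {
  stopifnot(inherits(tree, "annotated_phylo"))
  cl <- node_clades(tree)
  nodes <- as.integer(names(cl))
  sup <- tree$support[match(nodes, tree$support$node), ]
  out <- data.frame(
    node = nodes,
    size = lengths(cl),
    mlbp = sup$mlbp,
    bipp = sup$bipp,
    key = vapply(cl, clade_key, ""),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "members") <- cl
  out
}

#' Test whether a set of tips forms a clade
#'
#' A clade (descendant tip set) test on a rooted tree: `TRUE` iff some node's
#' descendant tip set equals `clade` exactly.  If `universe` is supplied the
#' tree is first restricted to the taxa shared with that universe, so a clade
#' stated on a smaller taxon set can be tested against a larger tree.
#'
#' @param tree a rooted tree (\code{phylo} or annotated).
#' @param clade character vector of tip labels (the candidate clade).
#' @param universe optional taxon universe of the clade.
#' @return list with `monophyletic` (logical) and `node` (witness internal
#'   node number, or `NA`).
#' @export
is_monophyletic <- function(tree, clade, universe = NULL) {
  clade <- unique(as.character(clade))
  unknown <- setdiff(clade, tree$tip.label)
  if (length(unknown))
    stop("clade contains labels not in the tree: ", paste(unknown, collapse = ", "))
  if (!is.null(universe)) {
    keep <- intersect(tree$tip.label, universe)
    if (!setequal(keep, tree$tip.label)) {
      phy <- ape::keep.tip(.as_plain_phylo(tree), keep)
      return(is_monophyletic(phy, clade))
    }
  }
  ntip <- length(tree$tip.label)
  if (length(clade) == 1L)
    return(list(monophyletic = TRUE, node = match(clade, tree$tip.label)))
  if (length(clade) == ntip)
    return(list(monophyletic = TRUE, node = ntip + 1L))
  key <- clade_key(clade)
  cl <- node_clades(tree)
  keys <- vapply(cl, clade_key, "")
  j <- match(key, keys)
  if (is.na(j)) list(monophyletic = FALSE, node = NA_integer_)
  else list(monophyletic = TRUE, node = as.integer(names(cl)[j]))
}

.as_plain_phylo <- function(tree) {
  tree$support <- NULL
  class(tree) <- "phylo"
  tree
}

#' Restrict trees to a common taxon set, preserving supports
#'
#' Drops tips outside `keep` from every tree, suppresses the resulting unary
#' nodes, and carries over the support annotation of each retained clade
#' (matched by restricted descendant tip set; where a chain of nested
#' original clades collapses onto one restricted clade, the most tip-ward
#' original node's supports are kept).
#'
#' @param trees list of [annotated_tree()] objects.
#' @param keep character vector of tip labels; must be a subset of every
#'   tree's taxa.
#' @return list of annotated trees on exactly the `keep` taxa.
#' @export
restrict_to_common_taxa <- function(trees, keep) {
  keep <- unique(as.character(keep))
  if (!length(keep)) stop("empty taxon intersection: nothing to keep")
  lapply(trees, function(tree) {
    stopifnot(inherits(tree, "annotated_phylo"))
    miss <- setdiff(keep, tree$tip.label)
    if (length(miss))
      stop("taxa absent from a tree: ", paste(miss, collapse = ", "))
    if (setequal(keep, tree$tip.label)) return(tree)
    orig_cl <- node_clades(tree)
    orig_nodes <- as.integer(names(orig_cl))
    orig_sizes <- lengths(orig_cl)
    restricted <- lapply(orig_cl, function(m) sort(intersect(m, keep)))
    restricted_keys <- vapply(restricted, function(m) paste(m, collapse = "\r"), "")
    phy <- ape::keep.tip(.as_plain_phylo(tree), keep)
    new_cl <- node_clades(phy)
    new_nodes <- as.integer(names(new_cl))
    sup <- data.frame(node = new_nodes, mlbp = NA_real_, bipp = NA_real_)
    for (i in seq_along(new_cl)) {
      key <- clade_key(new_cl[[i]])
      cand <- which(restricted_keys == key)
      if (length(cand)) {
        best <- cand[which.min(orig_sizes[cand])]
        k <- match(orig_nodes[best], tree$support$node)
        sup$mlbp[i] <- tree$support$mlbp[k]
        sup$bipp[i] <- tree$support$bipp[k]
      }
    }
    annotated_tree(phy, sup)
  })
}

#' Read a nucleotide alignment
#'
#' Reads FASTA, relaxed PHYLIP (sequential or interleaved) or NEXUS DATA
#' matrices into an upper-case character matrix (rows = sequences, columns =
#' sites) and validates shape and alphabet: IUPAC nucleotide codes plus gap
#' `'-'` and missing `'?'`.
#'
#' @param path file path.
#' @param format one of `"fasta"`, `"phylip"`, `"nexus"`.
#' @return character matrix with sequence labels as row names.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file does not exist: ", path)
  recs <- switch(format,
    fasta = .read_fasta_chars(path),
    phylip = {
      x <- ape::read.dna(path, format = "sequential", as.character = TRUE)
      setNames(lapply(seq_len(nrow(x)), function(i) unname(x[i, ])), rownames(x))
    },
    nexus = {
      x <- ape::read.nexus.data(path)
      lapply(x, identity)
    })
  labels <- names(recs)
  if (is.null(labels) || any(labels == ""))
    stop("alignment records must all carry labels")
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L) {
    off <- labels[which(lens != lens[1])[1]]
    stop("ragged alignment: row '", off, "' has length ", lens[match(off, labels)],
         " but '", labels[1], "' has length ", lens[1])
  }
  aln <- do.call(rbind, lapply(recs, toupper))
  rownames(aln) <- labels
  validate_alignment(aln)
  aln
}

# seqinr would also do this, but plain-text FASTA must preserve '?' exactly,
# which DNAbin round-trips do not guarantee; the format is trivial.
.read_fasta_chars <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  labels <- sub("^>\\s*", "", lines[hdr])
  labels <- sub("\\s.*$", "", labels)
  starts <- hdr + 1L
  ends <- c(hdr[-1] - 1L, length(lines))
  recs <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    seq <- paste(lines[seq.int(starts[i], ends[i])][
      !grepl("^>", lines[seq.int(starts[i], ends[i])])], collapse = "")
    seq <- gsub("\\s", "", seq)
    recs[[i]] <- strsplit(seq, "")[[1]]
  }
  names(recs) <- labels
  recs
}

#' Validate an alignment matrix
#'
#' @param aln character matrix of residues.
#' @return the matrix, invisibly; errors name the offending label/position.
#' @export
validate_alignment <- function(aln) {
  stopifnot(is.matrix(aln), is.character(aln))
  bad <- matrix(!(aln %in% .DNA_ALPHABET), nrow(aln))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("illegal character '", aln[idx[1], idx[2]], "' in sequence '",
         rownames(aln)[idx[1]], "' at site ", idx[2])
  }
  invisible(aln)
}

#' Write an alignment as FASTA
#' @param aln character matrix (rows = sequences).
#' @param path output file path.
#' @export
write_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    writeLines(paste(aln[i, ], collapse = ""), con)
  }
  invisible(path)
}

#' Sequence-label to sample map
#'
#' Maps every sequence label to exactly one sample (a sample may own several
#' cloned sequence copies), with an optional a-priori group per sample.
#'
#' @param label character vector of sequence labels (unique).
#' @param sample character vector of sample ids, same length.
#' @param group optional a-priori group label per sequence's sample.
#' @return data frame of class `"taxon_map"`.
#' @export
taxon_map <- function(label, sample, group = NA_character_) {
  stopifnot(length(label) == length(sample))
  if (anyDuplicated(label))
    stop("every sequence label must map to exactly one sample")
  out <- data.frame(label = as.character(label), sample = as.character(sample),
                    group = rep_len(as.character(group), length(label)),
                    stringsAsFactors = FALSE)
  class(out) <- c("taxon_map", "data.frame")
  out
}

# Map a vector of sequence labels to sample ids (case-sensitive, exact).
labels_to_samples <- function(labels, map) {
  i <- match(labels, map$label)
  if (anyNA(i))
    stop("labels missing from taxon map: ",
         paste(labels[is.na(i)], collapse = ", "))
  map$sample[i]
}
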