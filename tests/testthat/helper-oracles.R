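# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational paths: the DEC oracle integrates the CTMC by
# dense RK4 time-stepping (no matrix exponentials), the rate matrices are
# rebuilt from the model definition by explicit loops, and set/partition
# oracles are plain double loops.

# Explicit DEC rate-matrix construction (independent of build_rate_matrix).
oracle_dec_Q <- function(states, d, e, m) {
  keys <- vapply(states, function(s) paste(sort(s), collapse = ""), "")
  ns <- length(states)
  Q <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    R <- states[[i]]
    if (!length(R)) next
    for (a in setdiff(colnames(m), R)) {
      tgt <- paste(sort(c(R, a)), collapse = "")
      j <- match(tgt, keys)
      if (!is.na(j)) {
        rate <- 0
        for (b in R) rate <- rate + d * m[b, a]
        Q[i, j] <- Q[i, j] + rate
      }
    }
    for (a in R) {
      tgt <- paste(sort(setdiff(R, a)), collapse = "")
      j <- match(tgt, keys)
      if (!is.na(j)) Q[i, j] <- Q[i, j] + e
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# All legal states (null first), independent enumeration.
oracle_dec_states <- function(areas, max_size, excluded = character()) {
  states <- list(character(0))
  for (size in seq_len(max_size)) {
    for (s in utils::combn(sort(areas), size, simplify = FALSE)) {
      if (!(paste(s, collapse = "") %in% excluded))
        states[[length(states) + 1L]] <- s
    }
  }
  states
}

# DEC cladogenetic scenario list for ancestor state index i.
oracle_dec_scenarios <- function(states, i) {
  keys <- vapply(states, function(s) paste(sort(s), collapse = ""), "")
  S <- states[[i]]
  if (!length(S)) return(NULL)
  if (length(S) == 1L) return(matrix(c(i, i), 1, 2))
  pairs <- NULL
  for (a in S) {
    ia <- match(a, keys)
    ir <- match(paste(sort(setdiff(S, a)), collapse = ""), keys)
    if (!is.na(ia) && !is.na(ir)) pairs <- rbind(pairs, c(ia, ir), c(ir, ia))
    if (!is.na(ia)) pairs <- rbind(pairs, c(ia, i), c(i, ia))
  }
  pairs
}

# Dense RK4 integration of the pruning recursion: conditional likelihoods are
# propagated along each branch by solving dL/dt = Q L with the epoch's Q.
oracle_dec_loglik <- function(tr, tips, geo, d, e, h = 0.005) {
  states <- oracle_dec_states(geo$areas, geo$max_range_size,
                              vapply(geo$excluded_ranges, paste, "",
                                     collapse = ""))
  keys <- vapply(states, function(s) paste(sort(s), collapse = ""), "")
  Qs <- lapply(geo$epochs, function(ep) oracle_dec_Q(states, d, e, ep$m))
  eps <- vapply(geo$epochs, function(x) x$start, 0)
  epe <- vapply(geo$epochs, function(x) x$end, 0)
  depths <- ape::node.depth.edgelength(tr)
  ages <- max(depths) - depths
  ntip <- length(tr$tip.label)
  kids <- vector("list", ntip + tr$Nnode)
  for (k in seq_len(nrow(tr$edge)))
    kids[[tr$edge[k, 1]]] <- c(kids[[tr$edge[k, 1]]], tr$edge[k, 2])
  prop <- function(L, a0, a1) {
    a <- a0
    while (a < a1 - 1e-12) {
      e_idx <- which(eps - 1e-9 <= a & a < epe - 1e-9)[1]
      if (is.na(e_idx)) e_idx <- length(Qs)
      step <- min(h, a1 - a, epe[e_idx] - a)
      Q <- Qs[[e_idx]]
      k1 <- Q %*% L
      k2 <- Q %*% (L + step / 2 * k1)
      k3 <- Q %*% (L + step / 2 * k2)
      k4 <- Q %*% (L + step * k3)
      L <- L + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      a <- a + step
    }
    L
  }
  below <- function(v) {
    if (v <= ntip) {
      L <- numeric(length(states))
      L[match(tips[tr$tip.label[v]], keys)] <- 1
      return(L)
    }
    kk <- kids[[v]]
    L1 <- prop(below(kk[1]), ages[kk[1]], ages[v])
    L2 <- prop(below(kk[2]), ages[kk[2]], ages[v])
    out <- numeric(length(states))
    for (s in seq_along(states)) {
      pr <- oracle_dec_scenarios(states, s)
      if (!is.null(pr)) out[s] <- sum(L1[pr[, 1]] * L2[pr[, 2]]) / nrow(pr)
    }
    out
  }
  Lr <- below(ntip + 1L)
  prior <- numeric(length(states))
  prior[lengths(states) > 0] <- 1
  prior <- prior / sum(prior)
  log(sum(prior * Lr))
}

# Brute-force monophyly: recursive descendant-set scan over every node.
oracle_monophyletic <- function(tr, clade) {
  ntip <- length(tr$tip.label)
  kids <- vector("list", ntip + tr$Nnode)
  for (k in seq_len(nrow(tr$edge)))
    kids[[tr$edge[k, 1]]] <- c(kids[[tr$edge[k, 1]]], tr$edge[k, 2])
  found <- FALSE
  desc <- function(v) {
    if (v <= ntip) return(tr$tip.label[v])
    out <- unlist(lapply(kids[[v]], desc))
    if (setequal(out, clade)) found <<- TRUE
    out
  }
  desc(ntip + 1L)
  found
}

# Brute-force group mean distances: explicit double loops.
oracle_group_means <- function(D, groups) {
  gs <- sort(unique(groups))
  within <- setNames(rep(NA_real_, length(gs)), gs)
  for (g in gs) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    tot <- 0; n <- 0
    for (i in idx) for (j in idx) if (i < j) { tot <- tot + D[i, j]; n <- n + 1 }
    within[g] <- tot / n
  }
  between <- list()
  for (gi in seq_along(gs)) for (gj in seq_along(gs)) {
    if (gi >= gj) next
    a <- which(groups == gs[gi]); b <- which(groups == gs[gj])
    tot <- 0; n <- 0
    for (i in a) for (j in b) { tot <- tot + D[i, j]; n <- n + 1 }
    between[[paste(gs[gi], gs[gj], sep = "|")]] <- tot / n
  }
  list(within = within, between = unlist(between))
}

# Brute-force inclusion-minimal filter over a family of sets.
oracle_minimal_sets <- function(sets) {
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i != j && length(sets[[j]]) < length(sets[[i]]) &&
        all(sets[[j]] %in% sets[[i]]))
      keep[i] <- FALSE
  }
  sets[keep]
}

# Independent per-column site tally (vector-free loops).
oracle_site_stats <- function(aln) {
  bases <- c("A", "C", "G", "T")
  ambig <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
  poly <- 0; degen <- 0
  for (j in seq_len(ncol(aln))) {
    seen <- character()
    has_amb <- FALSE
    for (i in seq_len(nrow(aln))) {
      ch <- aln[i, j]
      if (ch %in% bases) seen <- union(seen, ch)
      if (ch %in% ambig) has_amb <- TRUE
    }
    if (length(seen) >= 2) poly <- poly + 1
    if (has_amb) degen <- degen + 1
  }
  c(poly = poly, degen = degen)
}

# Random support-annotated tree (some supports missing).
rand_annotated_tree <- function(n, with_lengths = TRUE) {
  tr <- ape::rtree(n)
  if (!with_lengths) tr$edge.length <- NULL
  ntip <- length(tr$tip.label)
  nodes <- seq.int(ntip + 1L, ntip + tr$Nnode)
  mlbp <- round(stats::runif(tr$Nnode, 0, 100), 1)
  bipp <- round(stats::runif(tr$Nnode, 0, 1), 3)
  mlbp[stats::runif(tr$Nnode) < 0.2] <- NA
  bipp[stats::runif(tr$Nnode) < 0.2] <- NA
  annotated_tree(tr, data.frame(node = nodes, mlbp = mlbp, bipp = bipp))
}

# Map of clade-key -> c(mlbp, bipp) for comparing annotated trees.
support_map <- function(tree) {
  ct <- clade_table(tree)
  setNames(lapply(seq_len(nrow(ct)), function(i) c(ct$mlbp[i], ct$bipp[i])),
           ct$key)
}
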