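#' Geography: areas, range constraints and epoch-stratified dispersal
#'
#' Defines the area universe for a Dispersal-Extinction-Cladogenesis (DEC)
#' analysis: which area subsets are legal ranges (maximum range size,
#' explicitly excluded subsets) and how dispersal rates between areas are
#' scaled through time (an ordered list of epochs, each with a non-negative
#' multiplier matrix `m` where `m[b, a]` scales the rate of range gain into
#' area `a` from a lineage occupying area `b`).
#'
#' @param areas character vector of single-letter area labels.
#' @param max_range_size maximum number of areas in a range (>= 1).
#' @param excluded_ranges list of character vectors: area subsets that are
#'   never legal ranges (e.g. two areas that were never adjacent).
#' @param epochs list of `list(start, end, m)` with `start < end` in Ma
#'   before present, youngest first, tiling `[0, Inf)` (the last epoch may
#'   end at `Inf`).  Default: a single epoch with all multipliers 1.
#' @return object of class `"dec_geography"`.
#' @export
geography <- function(areas, max_range_size = length(areas),
                      excluded_ranges = list(), epochs = NULL) {
  areas <- as.character(areas)
  stopifnot(length(areas) >= 1L, !anyDuplicated(areas), max_range_size >= 1L)
  if (is.null(epochs)) {
    m <- matrix(1, length(areas), length(areas), dimnames = list(areas, areas))
    epochs <- list(list(start = 0, end = Inf, m = m))
  }
  prev_end <- 0
  for (ep in epochs) {
    stopifnot(is.numeric(ep$start), is.numeric(ep$end), ep$start < ep$end)
    if (abs(ep$start - prev_end) > 1e-9)
      stop("epochs must tile time without gaps or overlap (expected start ",
           prev_end, ", got ", ep$start, ")")
    prev_end <- ep$end
    if (!is.matrix(ep$m) || any(dim(ep$m) != length(areas)))
      stop("epoch multiplier matrix must be areas x areas")
    if (any(ep$m < 0)) stop("negative dispersal multiplier")
    if (is.null(dimnames(ep$m))) dimnames(ep$m) <- list(areas, areas)
  }
  structure(list(areas = areas, max_range_size = as.integer(max_range_size),
                 excluded_ranges = lapply(excluded_ranges, function(x)
                   sort(as.character(x))),
                 epochs = epochs),
            class = "dec_geography")
}

#' A three-area geography with a recent trans-Pacific dispersal shutoff
#'
#' Convenience constructor for the configuration used throughout the test
#' fixtures: areas A (Australasia), B (mainland + SE Asia), C (North +
#' Central America); ranges of at most two areas; the disjunct range AC
#' excluded; and, in the youngest epoch (0-5 Ma), dispersal between B and C
#' shut off in both directions.  Older-epoch multipliers default to 1.
#'
#' @param shutoff_end age (Ma) at which the B-C dispersal shutoff ends.
#' @return a [geography()].
#' @export
three_area_geography <- function(shutoff_end = 5) {
  areas <- c("A", "B", "C")
  m1 <- matrix(1, 3, 3, dimnames = list(areas, areas))
  m1["B", "C"] <- 0
  m1["C", "B"] <- 0
  m2 <- matrix(1, 3, 3, dimnames = list(areas, areas))
  geography(areas, max_range_size = 2,
            excluded_ranges = list(c("A", "C")),
            epochs = list(list(start = 0, end = shutoff_end, m = m1),
                          list(start = shutoff_end, end = Inf, m = m2)))
}

range_key <- function(range) paste(sort(range), collapse = "")

#' Enumerate the legal range states
#'
#' All subsets of the areas of size `<= max_range_size`, minus the excluded
#' ranges, plus the null (empty, absorbing) range as state 1.  Ordering is
#' deterministic: null, then by size, then lexicographic.
#'
#' @param geo a [geography()].
#' @return object of class `"range_states"`: list of character vectors, with
#'   a `"keys"` attribute of range strings (`""` for null).
#' @export
build_state_space <- function(geo) {
  n <- length(geo$areas)
  states <- list(character(0))
  excl <- vapply(geo$excluded_ranges, paste, "", collapse = "")
  for (size in seq_len(min(geo$max_range_size, n))) {
    combos <- utils::combn(sort(geo$areas), size, simplify = FALSE)
    for (s in combos) if (!(paste(s, collapse = "") %in% excl))
      states[[length(states) + 1L]] <- s
  }
  if (length(states) < 2L)
    stop("all non-null range states are excluded")
  attr(states, "keys") <- vapply(states, range_key, "")
  class(states) <- "range_states"
  states
}

.state_index <- function(states, range) {
  match(range_key(range), attr(states, "keys"))
}

#' Anagenetic DEC rate matrix for one epoch
#'
#' Range gain `R -> R + {a}` occurs at rate `d * sum(m[b, a])` over occupied
#' areas `b` (zero if the target state is illegal); range loss `R -> R - {a}`
#' at rate `e` per occupied area (a single-area range decays into the
#' absorbing null range).  Rows sum to zero.
#'
#' @param states a [build_state_space()] result.
#' @param params list/vector with dispersal rate `d` and extinction rate `e`
#'   (events/Ma, both >= 0).
#' @param m epoch dispersal multiplier matrix (areas x areas, non-negative).
#' @return square rate matrix over the states.
#' @export
build_rate_matrix <- function(states, params, m) {
  d <- params[["d"]]; e <- params[["e"]]
  stopifnot(d >= 0, e >= 0)
  if (any(m < 0)) stop("negative dispersal multiplier")
  ns <- length(states)
  keys <- attr(states, "keys")
  Q <- matrix(0, ns, ns, dimnames = list(keys, keys))
  for (i in seq_len(ns)) {
    R <- states[[i]]
    if (!length(R)) next                      # null range is absorbing
    for (a in setdiff(colnames(m), R)) {
      j <- .state_index(states, c(R, a))
      if (!is.na(j)) Q[i, j] <- Q[i, j] + d * sum(m[R, a])
    }
    for (a in R) {
      target <- setdiff(R, a)
      j <- if (!length(target)) 1L else .state_index(states, target)
      if (!is.na(j)) Q[i, j] <- Q[i, j] + e
    }
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

# Cladogenetic scenario table: for each ancestral state, the ordered
# (daughter1, daughter2) state-index pairs of the canonical DEC scenario set
# (identical inheritance for single-area ancestors; vicariance and subset
# sympatry, each with one single-area daughter, for widespread ancestors),
# each enumerated outcome weighted equally within a node.
.clado_table <- function(states) {
  lapply(seq_along(states), function(i) {
    S <- states[[i]]
    if (!length(S)) return(matrix(integer(0), 0, 2))
    if (length(S) == 1L) return(matrix(c(i, i), 1, 2))
    pairs <- NULL
    for (a in S) {
      ia <- .state_index(states, a)
      rest <- setdiff(S, a)
      ir <- .state_index(states, rest)
      if (!is.na(ia) && !is.na(ir))
        pairs <- rbind(pairs, c(ia, ir), c(ir, ia))      # vicariance
      if (!is.na(ia))
        pairs <- rbind(pairs, c(ia, i), c(i, ia))        # subset sympatry
    }
    if (is.null(pairs)) matrix(integer(0), 0, 2) else pairs
  })
}

# Matrix exponential factory: spectral when Q is cleanly diagonalisable,
# otherwise Matrix::expm.  Results are cached per (epoch, duration).
.expm_factory <- function(Q) {
  ev <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eigen <- FALSE
  if (!is.null(ev)) {
    Vi <- tryCatch(solve(ev$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      err <- max(Mod(ev$vectors %*% (ev$values * Vi) - Q))
      use_eigen <- is.finite(err) && err < 1e-9 * max(1, max(abs(Q)))
    }
  }
  if (use_eigen) {
    V <- ev$vectors; lam <- ev$values
    function(t) {
      P <- Re(V %*% (exp(lam * t) * Vi))
      P[P < 0] <- 0
      P
    }
  } else {
    function(t) {
      P <- as.matrix(Matrix::expm(Q * t))
      P[P < 0] <- 0
      P
    }
  }
}

.node_ages <- function(phy, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(phy)
  root_age <- max(depths)
  ages <- root_age - depths
  ntip <- length(phy$tip.label)
  if (any(abs(ages[seq_len(ntip)]) > tol * max(1, root_age)))
    stop("chronogram is not ultrametric (tip ages differ from 0)")
  ages[seq_len(ntip)] <- 0
  ages
}

# Precompute everything about (tree, geography) that does not depend on the
# rates: state space, cladogenesis table, per-branch epoch segments.
.dec_plan <- function(chrono, tip_ranges, geo) {
  phy <- .as_plain_phylo(chrono)
  if (!ape::is.binary(phy)) stop("DEC requires a binary chronogram")
  if (is.null(phy$edge.length)) stop("chronogram must have branch lengths")
  ages <- .node_ages(phy)
  states <- build_state_space(geo)
  keys <- attr(states, "keys")
  ntip <- length(phy$tip.label)
  if (is.list(tip_ranges)) tip_ranges <- vapply(tip_ranges, range_key, "")
  miss <- setdiff(phy$tip.label, names(tip_ranges))
  if (length(miss)) stop("tips without a range: ", paste(miss, collapse = ", "))
  tip_idx <- vapply(phy$tip.label, function(tp) {
    r <- strsplit(tip_ranges[[tp]], "")[[1]]
    j <- .state_index(states, r)
    if (is.na(j) || !length(r))
      stop("illegal observed range '", tip_ranges[[tp]], "' at tip ", tp)
    j
  }, 0L)
  ep_start <- vapply(geo$epochs, `[[`, 0, "start")
  ep_end <- vapply(geo$epochs, `[[`, 0, "end")
  root_age <- max(ages)
  if (ep_end[length(ep_end)] < root_age - 1e-9)
    stop("epochs do not cover the root age (", signif(root_age, 6), " Ma)")
  segments <- vector("list", nrow(phy$edge))
  for (k in seq_len(nrow(phy$edge))) {
    a_child <- ages[phy$edge[k, 2]]
    a_parent <- ages[phy$edge[k, 1]]
    segs <- NULL
    for (e in seq_along(geo$epochs)) {
      lo <- max(a_child, ep_start[e]); hi <- min(a_parent, ep_end[e])
      if (hi - lo > 1e-12) segs <- rbind(segs, c(epoch = e, len = hi - lo,
                                                 old = hi))
    }
    if (is.null(segs)) segs <- matrix(c(1, 0, a_parent), 1, 3,
                                      dimnames = list(NULL, c("epoch", "len", "old")))
    segs <- segs[order(-segs[, "old"]), , drop = FALSE]
    attr(segs, "keys") <- paste0(segs[, "epoch"], "_",
                                 format(segs[, "len"], digits = 15))
    segments[[k]] <- segs
  }
  edge_post <- ape::reorder.phylo(phy, "postorder")$edge
  children <- .node_children(phy)
  list(phy = phy, ages = ages, states = states, keys = keys,
       nstates = length(states), tip_idx = tip_idx,
       clado = .clado_table(states), segments = segments,
       edge = phy$edge, edge_post = edge_post, children = children,
       root = ntip + 1L, ntip = ntip, geo = geo)
}

.root_prior <- function(plan, root_prior) {
  p <- numeric(plan$nstates)
  sizes <- lengths(plan$states)
  legal <- sizes > 0
  p[legal] <- if (root_prior == "range_size") 1 / sizes[legal] else 1
  p / sum(p)
}

# Conditional-likelihood down-pass.  Returns per-node bottom vectors, per-edge
# top vectors and transition matrices, and the log-likelihood.
.dec_downpass <- function(plan, params, root_prior = "uniform") {
  ns <- plan$nstates
  efacs <- lapply(plan$geo$epochs, function(ep)
    .expm_factory(build_rate_matrix(plan$states, params, ep$m)))
  cache <- new.env(parent = emptyenv())
  Pseg <- function(key, epoch, len) {
    got <- cache[[key]]
    if (is.null(got)) {
      got <- efacs[[epoch]](len)
      cache[[key]] <- got
    }
    got
  }
  nn <- plan$ntip + plan$phy$Nnode
  Lbot <- matrix(0, nn, ns)
  Ltop <- matrix(0, nn, ns)     # row = child node of the branch
  Pmat <- vector("list", nn)
  for (i in seq_len(plan$ntip)) Lbot[i, plan$tip_idx[i]] <- 1
  # postorder over edges: after both children of a node are propagated,
  # combine them through the cladogenesis table
  edge <- plan$edge_post
  edge_of_child <- integer(nn)
  for (k in seq_len(nrow(plan$edge))) edge_of_child[plan$edge[k, 2]] <- k
  done_children <- integer(nn)
  for (k in seq_len(nrow(edge))) {
    child <- edge[k, 2]; parent <- edge[k, 1]
    if (child > plan$ntip) {
      kids <- plan$children[[child]]
      Lbot[child, ] <- .clado_combine(plan, Ltop[kids[1], ], Ltop[kids[2], ])
    }
    segs <- plan$segments[[edge_of_child[child]]]
    keys <- attr(segs, "keys")
    P <- Pseg(keys[1], segs[1, "epoch"], segs[1, "len"])
    if (nrow(segs) > 1L) for (s in seq.int(2L, nrow(segs)))
      P <- P %*% Pseg(keys[s], segs[s, "epoch"], segs[s, "len"])
    Pmat[[child]] <- P
    Ltop[child, ] <- as.vector(P %*% Lbot[child, ])
    done_children[parent] <- done_children[parent] + 1L
  }
  kids <- plan$children[[plan$root]]
  Lbot[plan$root, ] <- .clado_combine(plan, Ltop[kids[1], ], Ltop[kids[2], ])
  prior <- .root_prior(plan, root_prior)
  lik <- sum(prior * Lbot[plan$root, ])
  list(Lbot = Lbot, Ltop = Ltop, Pmat = Pmat, prior = prior,
       loglik = if (lik > 0) log(lik) else -Inf)
}

.clado_combine <- function(plan, L1, L2) {
  out <- numeric(plan$nstates)
  for (s in seq_len(plan$nstates)) {
    pr <- plan$clado[[s]]
    if (!nrow(pr)) next
    out[s] <- sum(L1[pr[, 1]] * L2[pr[, 2]]) / nrow(pr)
  }
  out
}

#' DEC log-likelihood on a chronogram
#'
#' Felsenstein pruning over the range-state CTMC: branch transition matrices
#' are matrix exponentials of the epoch rate matrices, sliced at epoch
#' boundaries crossing the branch (integrated in age order from the older
#' node to the younger); internal nodes combine daughters over the DEC
#' cladogenetic scenario set with equal weights per enumerated scenario; the
#' root is integrated under the root prior.  The null range is absorbing and
#' unobservable at tips.
#'
#' @param chrono ultrametric tree with branch lengths in Ma.
#' @param tip_ranges named character vector of observed ranges (area-letter
#'   strings, e.g. `"AB"`), one per tip.
#' @param geo a [geography()].
#' @param params list/vector with rates `d` and `e`.
#' @param root_prior `"uniform"` over legal non-null ranges (default) or
#'   `"range_size"` (weight inversely proportional to range size).
#' @return log-likelihood (scalar).
#' @export
dec_loglik <- function(chrono, tip_ranges, geo, params,
                       root_prior = c("uniform", "range_size")) {
  root_prior <- match.arg(root_prior)
  plan <- .dec_plan(chrono, tip_ranges, geo)
  .dec_downpass(plan, params, root_prior)$loglik
}

#' Maximum-likelihood estimation of the DEC rates
#'
#' Bounded multi-start local optimisation of [dec_loglik()] over `(d, e)` on
#' the log scale; deterministic under fixed starts.
#'
#' @inheritParams dec_loglik
#' @param bounds length-2 lower/upper bounds applied to both rates.
#' @param starts matrix/data.frame of starting values (columns `d`, `e`);
#'   default: a fixed 2x2 grid.
#' @return list with `d`, `e`, `loglik`, the per-start `diagnostics` table
#'   and the winning start index.
#' @export
fit_dec <- function(chrono, tip_ranges, geo, bounds = c(1e-6, 10),
                    starts = NULL, root_prior = c("uniform", "range_size")) {
  root_prior <- match.arg(root_prior)
  plan <- .dec_plan(chrono, tip_ranges, geo)
  if (plan$ntip < 3L) stop("need at least three tips to fit DEC rates")
  if (is.null(starts))
    starts <- expand.grid(d = c(0.01, 0.1), e = c(0.005, 0.05))
  starts <- as.matrix(starts)
  neg <- function(lp) {
    val <- .dec_downpass(plan, list(d = exp(lp[1]), e = exp(lp[2])),
                         root_prior)$loglik
    if (!is.finite(val)) 1e10 else -val
  }
  diag_rows <- list()
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(log(pmin(pmax(starts[s, ], bounds[1]), bounds[2])), neg,
                   method = "L-BFGS-B",
                   lower = log(bounds[1]), upper = log(bounds[2]),
                   control = list(factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit)) next
    diag_rows[[s]] <- data.frame(start = s, d0 = starts[s, 1], e0 = starts[s, 2],
                                 d = exp(fit$par[1]), e = exp(fit$par[2]),
                                 loglik = -fit$value,
                                 convergence = fit$convergence)
    if (is.null(best) || -fit$value > best$loglik)
      best <- list(d = unname(exp(fit$par[1])), e = unname(exp(fit$par[2])),
                   loglik = -fit$value, start = s)
  }
  if (is.null(best) || !is.finite(best$loglik) || best$loglik <= -1e9)
    stop("DEC likelihood non-finite at every start")
  c(best, list(diagnostics = do.call(rbind, diag_rows)))
}

#' LAGRANGE-style ancestral split tables
#'
#' For every internal node, the relative probability of each cladogenetic
#' split — the fraction of the global likelihood flowing through each
#' (ancestral range, left daughter range, right daughter range) combination —
#' normalised to 1 within the node and ranked descending.  A per-node
#' marginal table over ancestral ranges (summing splits by ancestral range)
#' is returned alongside.
#'
#' @inheritParams dec_loglik
#' @return object of class `"node_split_table"`: data frames `splits`
#'   (`node`, `anc`, `left`, `right`, `prob`) and `ranges` (`node`, `range`,
#'   `prob`).
#' @export
ancestral_splits <- function(chrono, tip_ranges, geo, params,
                             root_prior = c("uniform", "range_size")) {
  root_prior <- match.arg(root_prior)
  plan <- .dec_plan(chrono, tip_ranges, geo)
  dp <- .dec_downpass(plan, params, root_prior)
  if (!is.finite(dp$loglik)) stop("non-finite DEC likelihood")
  ns <- plan$nstates
  nn <- plan$ntip + plan$phy$Nnode
  O <- matrix(0, nn, ns)
  O[plan$root, ] <- dp$prior
  # preorder up-pass: cladewise edge order lists every internal node as a
  # parent only after its own parent, so O[v, ] is ready when v is reached
  internal <- unique(ape::reorder.phylo(plan$phy, "cladewise")$edge[, 1])
  for (v in internal) {
    kids <- plan$children[[v]]
    for (ci in 1:2) {
      child <- kids[ci]; sib <- kids[3 - ci]
      Otop <- numeric(ns)
      for (s in seq_len(ns)) {
        pr <- plan$clado[[s]]
        if (!nrow(pr) || O[v, s] == 0) next
        w <- O[v, s] / nrow(pr)
        if (ci == 1L) {
          contrib <- w * dp$Ltop[sib, pr[, 2]]
          for (r in seq_len(nrow(pr)))
            Otop[pr[r, 1]] <- Otop[pr[r, 1]] + contrib[r]
        } else {
          contrib <- w * dp$Ltop[sib, pr[, 1]]
          for (r in seq_len(nrow(pr)))
            Otop[pr[r, 2]] <- Otop[pr[r, 2]] + contrib[r]
        }
      }
      O[child, ] <- as.vector(crossprod(dp$Pmat[[child]], Otop))
    }
  }
  lik <- exp(dp$loglik)
  splits <- list()
  ranges <- list()
  for (v in sort(internal)) {
    kids <- plan$children[[v]]
    rows <- list()
    for (s in seq_len(ns)) {
      pr <- plan$clado[[s]]
      if (!nrow(pr) || O[v, s] == 0) next
      w <- O[v, s] / nrow(pr)
      val <- w * dp$Ltop[kids[1], pr[, 1]] * dp$Ltop[kids[2], pr[, 2]]
      keep <- val > 0
      if (any(keep))
        rows[[length(rows) + 1L]] <- data.frame(
          node = v, anc = plan$keys[s],
          left = plan$keys[pr[keep, 1]], right = plan$keys[pr[keep, 2]],
          weight = val[keep])
    }
    tab <- do.call(rbind, rows)
    if (is.null(tab)) next
    tab <- stats::aggregate(weight ~ node + anc + left + right, tab, sum)
    tab$prob <- tab$weight / sum(tab$weight)
    tab <- tab[order(-tab$prob), c("node", "anc", "left", "right", "prob")]
    splits[[length(splits) + 1L]] <- tab
    rmarg <- stats::aggregate(prob ~ anc, tab, sum)
    ranges[[length(ranges) + 1L]] <- data.frame(node = v, range = rmarg$anc,
                                                prob = rmarg$prob)
  }
  structure(list(splits = do.call(rbind, splits),
                 ranges = do.call(rbind, ranges),
                 loglik = dp$loglik, params = params),
            class = "node_split_table")
}

#' @export
print.node_split_table <- function(x, ...) {
  cat("DEC ancestral split table;", length(unique(x$splits$node)),
      "internal nodes; loglik", sprintf("%.4f", x$loglik), "\n")
  invisible(x)
}

#' Export a node split table
#'
#' `write_split_table()` writes the ranked per-node splits as TSV;
#' `annotate_tree_with_splits()` returns a newick string whose internal-node
#' labels carry the best split (`left|right`).
#'
#' @param nst a [ancestral_splits()] result.
#' @param path output path.
#' @export
write_split_table <- function(nst, path) {
  utils::write.table(nst$splits, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_split_table
#' @param chrono the chronogram the table was computed on.
#' @export
annotate_tree_with_splits <- function(nst, chrono) {
  phy <- .as_plain_phylo(chrono)
  best <- nst$splits[!duplicated(nst$splits$node), ]
  lab <- character(phy$Nnode)
  ntip <- length(phy$tip.label)
  for (k in seq_len(nrow(best)))
    lab[best$node[k] - ntip] <- paste0(best$left[k], "|", best$right[k])
  phy$node.label <- lab
  ape::write.tree(phy)
}
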