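#' Distance model configuration
#'
#' @param model substitution model: `"p"` (proportion of differing sites),
#'   `"TN93"` (Tamura-Nei 1993, per-pair base frequencies), or `"MCL-TN93"`
#'   (composite-likelihood TN93: exchange parameters and base frequencies
#'   estimated once over all pairs by maximising the summed pairwise
#'   log-likelihood, then per-pair distances under the shared parameters).
#' @param gamma_shape shape of the gamma distribution of rates among sites
#'   (> 0), or `NA` for equal rates.  Default 1.  Ignored by `"p"`.
#' @param deletion gap treatment; only `"pairwise"` deletion is implemented
#'   (per pair, sites with a gap, `?` or an ambiguity code in either sequence
#'   are excluded).
#' @param lineage_pattern_mode accepted for interface compatibility with
#'   distance software offering a "different patterns among lineages" option;
#'   the composite-likelihood model here always shares one parameter set
#'   across lineages, so the flag is recorded and has no further effect.
#' @param gamma_ncat number of discrete gamma rate categories (mean
#'   categories) used by the likelihood-based models.
#' @return a list of class `"dist_config"`.
#' @export
dist_config <- function(model = c("p", "TN93", "MCL-TN93"),
                        gamma_shape = 1,
                        deletion = "pairwise",
                        lineage_pattern_mode = FALSE,
                        gamma_ncat = 4L) {
  model <- match.arg(model)
  if (!identical(deletion, "pairwise"))
    stop("only pairwise deletion is implemented")
  if (!is.na(gamma_shape) && gamma_shape <= 0)
    stop("gamma_shape must be positive (or NA for equal rates)")
  structure(list(model = model, gamma_shape = gamma_shape,
                 deletion = deletion,
                 lineage_pattern_mode = isTRUE(lineage_pattern_mode),
                 gamma_ncat = as.integer(gamma_ncat)),
            class = "dist_config")
}

# Sites comparable under pairwise deletion: unambiguous base in both rows.
.comparable <- function(a, b) a %in% .DNA_BASES & b %in% .DNA_BASES

# Mean rates of the discrete gamma categories (Yang-style mean categories,
# shape = rate = a so the overall mean rate is 1).
.gamma_rates <- function(shape, ncat) {
  if (is.na(shape)) return(1)
  b <- stats::qgamma(seq_len(ncat - 1L) / ncat, shape = shape, rate = shape)
  b <- c(0, b, Inf)
  ncat * (stats::pgamma(b[-1], shape + 1, shape) -
            stats::pgamma(b[-(ncat + 1L)], shape + 1, shape))
}

# Closed-form TN93 (+ gamma) distance from mismatch proportions.
# P1: A<->G, P2: C<->T, Q: transversions; pi: base frequencies ACGT.
.tn93_formula <- function(P1, P2, Q, pi, gamma_shape) {
  piR <- pi["A"] + pi["G"]; piY <- pi["C"] + pi["T"]
  if (piR <= 0 || piY <= 0) return(NA_real_)
  k1 <- 2 * pi["A"] * pi["G"] / piR
  k2 <- 2 * pi["C"] * pi["T"] / piY
  k3 <- 2 * (piR * piY - pi["A"] * pi["G"] * piY / piR -
               pi["C"] * pi["T"] * piR / piY)
  w1 <- if (k1 > 0) 1 - P1 / k1 - Q / (2 * piR) else 1
  w2 <- if (k2 > 0) 1 - P2 / k2 - Q / (2 * piY) else 1
  w3 <- 1 - Q / (2 * piR * piY)
  if ((k1 > 0 && w1 <= 0) || (k2 > 0 && w2 <= 0) || w3 <= 0)
    return(NA_real_)  # saturated: inestimable
  if ((k1 == 0 && P1 > 0) || (k2 == 0 && P2 > 0)) return(NA_real_)
  if (is.na(gamma_shape)) {
    d <- -(k1 * log(w1) + k2 * log(w2) + k3 * log(w3))
  } else {
    a <- gamma_shape
    d <- a * (k1 * w1^(-1 / a) + k2 * w2^(-1 / a) + k3 * w3^(-1 / a) -
                (k1 + k2 + k3))
  }
  unname(max(d, 0))
}

#' Pairwise genetic distance between two sequences
#'
#' Applies pairwise deletion (sites where either residue is a gap, `?` or an
#' IUPAC ambiguity code are excluded), then the configured model on the
#' remaining sites.  The `"MCL-TN93"` model needs whole-alignment parameter
#' sharing and falls back to per-pair TN93 here; use [distance_matrix()] for
#' the composite-likelihood estimate.
#'
#' @param a,b character vectors of residues, equal length.
#' @param cfg a [dist_config()].
#' @return list with `distance` (substitutions/site; `NA` with
#'   `inestimable = TRUE` when saturated or no sites are comparable) and
#'   `sites` (effective comparable site count).
#' @export
pairwise_distance <- function(a, b, cfg = dist_config()) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (length(a) != length(b)) stop("sequences must have equal length")
  ok <- .comparable(a, b)
  n <- sum(ok)
  if (n == 0L)
    return(list(distance = NA_real_, sites = 0L, inestimable = TRUE))
  a <- a[ok]; b <- b[ok]
  d <- switch(cfg$model,
    p = mean(a != b),
    {
      transition1 <- mean((a == "A" & b == "G") | (a == "G" & b == "A"))
      transition2 <- mean((a == "C" & b == "T") | (a == "T" & b == "C"))
      transv <- mean(a != b) - transition1 - transition2
      pi <- table(factor(c(a, b), levels = .DNA_BASES)) / (2 * n)
      pi <- setNames(as.numeric(pi), .DNA_BASES)
      .tn93_formula(transition1, transition2, transv, pi, cfg$gamma_shape)
    })
  list(distance = d, sites = n, inestimable = is.na(d))
}

# --- composite-likelihood TN93 machinery ------------------------------------

# Normalised TN93 rate matrix: k1 purine transitions, k2 pyrimidine
# transitions relative to transversions; mean rate scaled to 1.
.tn93_Q <- function(k1, k2, pi) {
  Q <- matrix(0, 4, 4, dimnames = list(.DNA_BASES, .DNA_BASES))
  for (i in .DNA_BASES) for (j in .DNA_BASES) {
    if (i == j) next
    r <- if ((i == "A" && j == "G") || (i == "G" && j == "A")) k1
         else if ((i == "C" && j == "T") || (i == "T" && j == "C")) k2
         else 1
    Q[i, j] <- r * pi[j]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# Spectral decomposition of a reversible Q via its symmetrised form, giving a
# cheap, real P(t) = exp(Qt).
.rev_eig <- function(Q, pi) {
  s <- sqrt(pi)
  B <- (s %o% (1 / s)) * Q
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(U = e$vectors, lam = e$values, s = s)
}

.rev_expm <- function(eig, t) {
  E <- eig$U %*% (exp(eig$lam * t) * t(eig$U))
  P <- ((1 / eig$s) %o% eig$s) * E
  P[P < 0] <- 0
  P
}

# Pairwise log-likelihood of a 4x4 divergence count matrix at divergence t
# under shared (eig, pi, gamma rates).
.pair_loglik <- function(N, t, eig, pi, rates) {
  P <- 0
  for (r in rates) P <- P + .rev_expm(eig, r * t)
  P <- P / length(rates)
  M <- pi * P          # joint probability pi_i * P_ij
  M[M < 1e-300] <- 1e-300
  sum(N * log(M))
}

.pair_mle_t <- function(N, eig, pi, rates, upper = 30) {
  if (sum(N) == 0) return(list(t = NA_real_, ll = 0))
  f <- function(t) -.pair_loglik(N, t, eig, pi, rates)
  # identical sequences: likelihood maximised at t -> 0
  opt <- stats::optimize(f, c(1e-9, upper), tol = 1e-9)
  list(t = opt$minimum, ll = -opt$objective)
}

# 4x4 divergence count matrices for all pairs (pairwise deletion).
.pair_counts <- function(aln) {
  n <- nrow(aln)
  idx <- lapply(seq_len(n), function(i) match(aln[i, ], .DNA_BASES))
  pairs <- utils::combn(n, 2)
  counts <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ok <- !is.na(idx[[i]]) & !is.na(idx[[j]])
    N <- matrix(0, 4, 4, dimnames = list(.DNA_BASES, .DNA_BASES))
    if (any(ok)) {
      tab <- table(factor(idx[[i]][ok], levels = 1:4),
                   factor(idx[[j]][ok], levels = 1:4))
      N[] <- as.numeric(tab)
    }
    counts[[k]] <- N
  }
  list(pairs = pairs, counts = counts)
}

.mcl_fit <- function(aln, cfg) {
  pc <- .pair_counts(aln)
  base_tab <- table(factor(aln[aln %in% .DNA_BASES], levels = .DNA_BASES))
  pi <- as.numeric(base_tab) / sum(base_tab)
  names(pi) <- .DNA_BASES
  if (any(pi == 0)) pi <- (pi + 1e-6) / sum(pi + 1e-6)
  rates <- .gamma_rates(cfg$gamma_shape, cfg$gamma_ncat)
  neg_comp <- function(logk) {
    k1 <- exp(logk[1]); k2 <- exp(logk[2])
    if (!is.finite(k1) || !is.finite(k2) || k1 > 1e4 || k2 > 1e4) return(1e12)
    eig <- .rev_eig(.tn93_Q(k1, k2, pi), pi)
    ll <- 0
    for (N in pc$counts) ll <- ll + .pair_mle_t(N, eig, pi, rates)$ll
    -ll
  }
  fit <- stats::optim(log(c(4, 4)), neg_comp, method = "Nelder-Mead",
                      control = list(reltol = 1e-8, maxit = 300))
  k <- exp(fit$par)
  eig <- .rev_eig(.tn93_Q(k[1], k[2], pi), pi)
  list(k1 = k[1], k2 = k[2], pi = pi, eig = eig, rates = rates,
       pairs = pc$pairs, counts = pc$counts,
       composite_loglik = -fit$value)
}

#' All-pairs distance matrix
#'
#' For `"p"` and `"TN93"` each pair is computed independently via
#' [pairwise_distance()].  For `"MCL-TN93"` the TN93 exchange parameters and
#' base frequencies are estimated once by maximising the summed pairwise
#' (composite) log-likelihood over all pairs, then per-pair maximum-likelihood
#' divergences are computed under the shared parameters.
#'
#' @param aln character matrix alignment (rows = sequences, >= 2).
#' @param cfg a [dist_config()].
#' @return object of class `"gene_dist"`: list with `d` (symmetric distance
#'   matrix, `NA` = inestimable), `sites` (per-cell effective comparable site
#'   counts), `labels`, `model`, and for the composite-likelihood model the
#'   shared parameter estimates in `params`.
#' @export
distance_matrix <- function(aln, cfg = dist_config()) {
  validate_alignment(aln)
  n <- nrow(aln)
  if (n < 2L) stop("need at least two sequences")
  labels <- rownames(aln)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  sites <- matrix(ncol(aln), n, n, dimnames = list(labels, labels))
  params <- NULL
  if (cfg$model == "MCL-TN93") {
    fit <- .mcl_fit(aln, cfg)
    params <- fit[c("k1", "k2", "pi", "composite_loglik")]
    for (kk in seq_len(ncol(fit$pairs))) {
      i <- fit$pairs[1, kk]; j <- fit$pairs[2, kk]
      N <- fit$counts[[kk]]
      ns <- sum(N)
      est <- if (ns == 0) NA_real_ else
        .pair_mle_t(N, fit$eig, fit$pi, fit$rates)$t
      d[i, j] <- d[j, i] <- est
      sites[i, j] <- sites[j, i] <- ns
    }
  } else {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      pd <- pairwise_distance(aln[i, ], aln[j, ], cfg)
      d[i, j] <- d[j, i] <- pd$distance
      sites[i, j] <- sites[j, i] <- pd$sites
    }
  }
  structure(list(d = d, sites = sites, labels = labels,
                 model = cfg$model, config = cfg, params = params),
            class = "gene_dist")
}

#' @export
print.gene_dist <- function(x, ...) {
  cat("Genetic distance matrix (", x$model, "), ", length(x$labels),
      " sequences\n", sep = "")
  if (any(is.na(x$d[upper.tri(x$d)])))
    cat("  contains inestimable (saturated) cells\n")
  invisible(x)
}

# Resolve a grouping argument into a named group vector over dm labels.
.resolve_groups <- function(dm, groups, map = NULL) {
  if (inherits(groups, "species_partition")) {
    assignment <- groups$assignment
    if (!is.null(map)) {
      samples <- labels_to_samples(dm$labels, map)
      g <- assignment[samples]
    } else {
      g <- assignment[dm$labels]
    }
    names(g) <- dm$labels
    groups <- g
  }
  if (is.null(names(groups))) stop("groups must be a named vector or partition")
  miss <- setdiff(dm$labels, names(groups))
  if (length(miss))
    stop("labels without a group assignment: ", paste(miss, collapse = ", "))
  groups[dm$labels]
}

#' Within- and between-group mean distances
#'
#' Within-group mean = average over unordered within-group pairs (undefined,
#' reported `NA`, for singleton groups — never 0).  Between-group mean =
#' average over all cross pairs.  All cloned sequence copies of a sample
#' participate as separate rows.  Inestimable cells are dropped from the
#' averages with a warning.
#'
#' @param dm a [distance_matrix()] result.
#' @param groups named character vector (sequence label -> group), or a
#'   `species_partition` (then `map` translates labels to samples).
#' @param map optional [taxon_map()] when `groups` is a partition.
#' @return object of class `"group_dist_summary"`: data frames `within`
#'   (group, mean, n_pairs) and `between` (g1, g2, mean, n_pairs).
#' @export
group_mean_distances <- function(dm, groups, map = NULL) {
  groups <- .resolve_groups(dm, groups, map)
  if (!length(groups)) stop("empty partition")
  gs <- sort(unique(groups))
  if (anyNA(dm$d[upper.tri(dm$d)]))
    warning("inestimable distances excluded from group means")
  within <- data.frame(group = gs, mean = NA_real_, n_pairs = 0L)
  for (k in seq_along(gs)) {
    members <- which(groups == gs[k])
    if (length(members) >= 2L) {
      v <- dm$d[members, members][upper.tri(diag(length(members)))]
      within$mean[k] <- mean(v, na.rm = TRUE)
      within$n_pairs[k] <- sum(!is.na(v))
      if (within$n_pairs[k] == 0L) within$mean[k] <- NA_real_
    }
  }
  pairs <- utils::combn(gs, 2)
  between <- data.frame(g1 = pairs[1, ], g2 = pairs[2, ],
                        mean = NA_real_, n_pairs = 0L)
  for (k in seq_len(ncol(pairs))) {
    a <- which(groups == pairs[1, k]); b <- which(groups == pairs[2, k])
    v <- as.vector(dm$d[a, b, drop = FALSE])
    between$mean[k] <- mean(v, na.rm = TRUE)
    between$n_pairs[k] <- sum(!is.na(v))
    if (between$n_pairs[k] == 0L) between$mean[k] <- NA_real_
  }
  structure(list(within = within, between = between, groups = groups),
            class = "group_dist_summary")
}

#' Bootstrap standard errors for group mean distances
#'
#' Alignment columns are resampled with replacement `n_reps` times; distances
#' and group means are recomputed per replicate; the standard error of each
#' statistic is its standard deviation across replicates.  Reproducible under
#' a fixed seed (the seed is recorded in the result).
#'
#' @param aln alignment matrix.
#' @param groups named group vector over the alignment's rows.
#' @param cfg a [dist_config()].
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @return a `"group_dist_summary"` with `se` columns added to `within` and
#'   `between`, plus `n_reps` and `seed`.
#' @export
bootstrap_se <- function(aln, groups, cfg = dist_config(), n_reps = 1000L,
                         seed = 1L) {
  stopifnot(n_reps >= 1L)
  validate_alignment(aln)
  point <- group_mean_distances(distance_matrix(aln, cfg), groups)
  L <- ncol(aln)
  nw <- nrow(point$within); nb <- nrow(point$between)
  reps <- matrix(NA_real_, n_reps, nw + nb)
  .with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      gm <- suppressWarnings(
        group_mean_distances(distance_matrix(aln[, cols, drop = FALSE], cfg),
                             groups))
      reps[r, ] <- c(gm$within$mean, gm$between$mean)
    }
  })
  ses <- apply(reps, 2, stats::sd, na.rm = TRUE)
  point$within$se <- ses[seq_len(nw)]
  point$within$se[is.na(point$within$mean)] <- NA_real_
  point$between$se <- ses[nw + seq_len(nb)]
  point$n_reps <- n_reps
  point$seed <- seed
  point
}

#' Alignment site statistics
#'
#' Classifies each column over the selected rows: polymorphic means at least
#' two distinct unambiguous bases (ambiguity codes never count toward
#' polymorphism); degenerate means at least one IUPAC ambiguity code.  A site
#' can be both.
#'
#' @param aln alignment matrix.
#' @param rows character vector of row labels to include (default: all).
#' @return object of class `"site_stats"`: `n_sites`, `n_polymorphic`,
#'   `n_degenerate`, and a per-site logical data frame `classification`
#'   (1-based `site`, `polymorphic`, `degenerate`).
#' @export
site_stats <- function(aln, rows = NULL) {
  validate_alignment(aln)
  if (is.null(rows)) rows <- rownames(aln)
  unknown <- setdiff(rows, rownames(aln))
  if (length(unknown))
    stop("unknown row labels: ", paste(unknown, collapse = ", "))
  sub <- aln[rows, , drop = FALSE]
  poly <- apply(sub, 2, function(col) {
    length(unique(col[col %in% .DNA_BASES])) >= 2L
  })
  degen <- apply(sub, 2, function(col) any(col %in% .DNA_AMBIG))
  structure(list(
    n_sites = ncol(sub),
    n_polymorphic = sum(poly),
    n_degenerate = sum(degen),
    classification = data.frame(site = seq_len(ncol(sub)),
                                polymorphic = poly, degenerate = degen)
  ), class = "site_stats")
}

#' @export
print.site_stats <- function(x, ...) {
  cat("Sites:", x$n_sites, "| polymorphic:", x$n_polymorphic,
      "| degenerate:", x$n_degenerate, "\n")
  invisible(x)
}

#' Export a distance matrix
#'
#' `write_distance_csv()` writes a labelled square CSV;
#' `write_distance_phylip()` writes square PHYLIP distance format.
#' @param dm a `"gene_dist"` object.
#' @param path output path.
#' @export
write_distance_csv <- function(dm, path) {
  utils::write.table(cbind(label = dm$labels, as.data.frame(dm$d)),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
write_distance_phylip <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(dm$labels)), con)
  for (i in seq_along(dm$labels)) {
    writeLines(paste(c(sprintf("%-12s", dm$labels[i]),
                       sprintf("%.8f", dm$d[i, ])), collapse = " "), con)
  }
  invisible(path)
}

#' Export site statistics as TSV (1-based site indices)
#' @param ss a `"site_stats"` object.
#' @param path output path.
#' @export
write_site_stats <- function(ss, path) {
  utils::write.table(ss$classification, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
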