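#' Simulation specification
#'
#' Collects every knob of the synthetic-data generator with documented
#' defaults: a birth-death species tree, per-locus gene trees with NNI
#' discordance and a two-regime support noise model, TN93+gamma sequence
#' evolution, and a forward DEC range history.
#'
#' @param seed mandatory integer seed (single pseudo-random stream per run).
#' @param n_species number of species-tree tips.
#' @param samples_per_species samples attached per species (scalar or vector).
#' @param birth,death birth-death rates per Ma of the species tree.
#' @param p_nni probability that each internal species-tree edge is perturbed
#'   by a nearest-neighbour interchange in a given locus.
#' @param n_loci number of loci.
#' @param clock_rate substitutions/site/Ma used to scale gene trees before
#'   sequence simulation.
#' @param locus_model a [locus_model()] (shared across loci by default).
#' @param support_high,support_low ranges (`list(mlbp = c(lo, hi),
#'   bipp = c(lo, hi))`) from which supports are drawn for clades concordant
#'   (resp. discordant) with the species tree.
#' @param dec_params list with DEC truth rates `d` and `e` (events/Ma).
#' @param geo a [geography()] for the range simulation.
#' @return list of class `"sim_spec"`.
#' @export
sim_spec <- function(seed,
                     n_species = 12L,
                     samples_per_species = 2L,
                     birth = 0.15, death = 0.05,
                     p_nni = 0.1,
                     n_loci = 3L,
                     clock_rate = 0.005,
                     locus_model = NULL,
                     support_high = list(mlbp = c(85, 100), bipp = c(0.96, 1)),
                     support_low = list(mlbp = c(20, 65), bipp = c(0.2, 0.9)),
                     dec_params = list(d = 0.05, e = 0.02),
                     geo = three_area_geography()) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_species >= 2L, birth >= 0, death >= 0,
            p_nni >= 0, p_nni <= 1, clock_rate > 0)
  if (is.null(locus_model)) locus_model <- locus_model()
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 samples_per_species = samples_per_species,
                 birth = birth, death = death, p_nni = p_nni,
                 n_loci = as.integer(n_loci), clock_rate = clock_rate,
                 locus_model = locus_model,
                 support_high = support_high, support_low = support_low,
                 dec_params = dec_params, geo = geo),
            class = "sim_spec")
}

#' Per-locus substitution model for sequence simulation
#'
#' @param length alignment length (sites).
#' @param pi stationary base frequencies (ACGT).
#' @param k1,k2 purine/pyrimidine transition rates relative to transversions.
#' @param gamma_shape gamma shape for among-site rate variation (`NA` = equal
#'   rates).
#' @param gamma_ncat discrete gamma categories.
#' @param ambiguity_rate per-site, per-sequence probability of replacing a
#'   base with a two-base IUPAC ambiguity code containing it (emulating
#'   unphased heterozygous positions).
#' @return list of class `"locus_model"`.
#' @export
locus_model <- function(length = 1000L,
                        pi = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                        k1 = 4, k2 = 4, gamma_shape = 1, gamma_ncat = 4L,
                        ambiguity_rate = 0) {
  stopifnot(length >= 1L, all(pi > 0), abs(sum(pi) - 1) < 1e-8,
            k1 > 0, k2 > 0, ambiguity_rate >= 0, ambiguity_rate <= 1)
  names(pi) <- .DNA_BASES
  structure(list(length = as.integer(length), pi = pi, k1 = k1, k2 = k2,
                 gamma_shape = gamma_shape, gamma_ncat = as.integer(gamma_ncat),
                 ambiguity_rate = ambiguity_rate),
            class = "locus_model")
}

#' Simulate an ultrametric birth-death chronogram
#'
#' A birth-death tree conditioned on `n_species` extant tips (ages in Ma),
#' reproducible under `seed`.
#'
#' @param n_species number of tips (>= 2).
#' @param birth,death rates per Ma.
#' @param seed integer seed.
#' @param max_tries internal resampling cap for degenerate draws.
#' @return a \code{phylo} chronogram with tip labels `sp01, sp02, ...`.
#' @export
sim_chronogram <- function(n_species, birth = 0.15, death = 0.05, seed = 1L,
                           max_tries = 100L) {
  stopifnot(n_species >= 2L, birth > 0, death >= 0)
  .with_seed(seed, {
    res <- NULL
    for (i in seq_len(max_tries)) {
      phy <- tryCatch(ape::rphylo(n_species, birth = birth, death = death),
                      error = function(e) NULL)
      if (!is.null(phy) && length(phy$tip.label) == n_species) {
        phy$tip.label <- sprintf("sp%02d", seq_len(n_species))
        res <- phy
        break
      }
    }
    if (is.null(res))
      stop("failed to simulate a ", n_species, "-tip birth-death tree after ",
           max_tries, " tries")
    res
  })
}

# One rooted nearest-neighbour interchange across a random internal edge:
# swap a child of the edge's lower node with the lower node's sibling.
.rooted_nni <- function(phy) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  cand <- which(phy$edge[, 2] > ntip & phy$edge[, 1] != 0)
  cand <- cand[phy$edge[cand, 1] >= root]         # child is internal
  if (!length(cand)) return(phy)
  k <- cand[sample.int(length(cand), 1L)]
  u <- phy$edge[k, 1]; v <- phy$edge[k, 2]
  kc <- which(phy$edge[, 1] == v)                 # edges v -> children
  ks <- which(phy$edge[, 1] == u & phy$edge[, 2] != v)  # edge u -> sibling
  if (!length(kc) || !length(ks)) return(phy)
  kc <- kc[sample.int(length(kc), 1L)]
  ks <- ks[1]
  c_node <- phy$edge[kc, 2]; s_node <- phy$edge[ks, 2]
  phy$edge[kc, 2] <- s_node
  phy$edge[ks, 2] <- c_node
  tmp <- phy$edge.length[kc]
  phy$edge.length[kc] <- phy$edge.length[ks]
  phy$edge.length[ks] <- tmp
  phy
}

.draw_support <- function(n, range) {
  list(mlbp = stats::runif(n, range$mlbp[1], range$mlbp[2]),
       bipp = stats::runif(n, range$bipp[1], range$bipp[2]))
}

# Attach sample subtrees (scaled coalescent shapes) to every species tip.
.attach_samples <- function(phy, samples_by_species, depth_frac = 0.15) {
  for (sp in names(samples_by_species)) {
    samples <- samples_by_species[[sp]]
    tipk <- match(sp, phy$tip.label)
    if (is.na(tipk)) stop("species tip not found: ", sp)
    if (length(samples) == 1L) {
      phy$tip.label[tipk] <- samples
      next
    }
    len <- phy$edge.length[phy$edge[, 2] == tipk]
    h <- depth_frac * len
    sub <- ape::rcoal(length(samples), tip.label = samples)
    sub$edge.length <- sub$edge.length * (h / max(ape::node.depth.edgelength(sub)))
    sub$root.edge <- 0
    phy <- ape::bind.tree(phy, sub, where = tipk, position = h)
    phy <- ape::drop.tip(phy, sp)
  }
  phy
}

#' Simulate support-annotated gene trees under partial discordance
#'
#' Each locus tree is the species tree with every internal edge perturbed by
#' a nearest-neighbour interchange with probability `p_nni`; samples are then
#' attached per species as shallow clades (locus-specific shapes).  Clades
#' concordant with the species tree (species-level clades present in it, and
#' within-species clades) draw supports from the high range, all others from
#' the low range.
#'
#' @param species_tree a \code{phylo} species tree (tips = species).
#' @param spec a [sim_spec()].
#' @param samples_by_species named list (species tip -> sample labels);
#'   default `spec$samples_per_species` samples named `<species>_1`, ...
#' @return list of [annotated_tree()]s, one per locus, with the sample-level
#'   species map in attribute `"sample_species"`.
#' @export
sim_gene_trees <- function(species_tree, spec, samples_by_species = NULL) {
  if (is.null(samples_by_species)) {
    m <- rep_len(spec$samples_per_species, length(species_tree$tip.label))
    samples_by_species <- setNames(lapply(seq_along(species_tree$tip.label),
      function(i) if (m[i] == 1L) species_tree$tip.label[i] else
        paste0(species_tree$tip.label[i], "_", seq_len(m[i]))),
      species_tree$tip.label)
  }
  sample_species <- setNames(
    rep(names(samples_by_species), lengths(samples_by_species)),
    unlist(samples_by_species))
  species_clades <- c(lapply(node_clades(species_tree), sort),
                      as.list(species_tree$tip.label))
  species_keys <- vapply(species_clades, clade_key, "")
  n_int_edges <- sum(species_tree$edge[, 2] > length(species_tree$tip.label))
  out <- .with_seed(spec$seed, {
    lapply(seq_len(spec$n_loci), function(locus) {
      gt <- species_tree
      k <- stats::rbinom(1L, n_int_edges, spec$p_nni)
      for (i in seq_len(k)) gt <- .rooted_nni(gt)
      gt <- .attach_samples(gt, samples_by_species)
      cl <- node_clades(gt)
      concordant <- vapply(cl, function(members) {
        sps <- unique(sample_species[members])
        # only complete species-level clades count; partial within-species
        # clades are shallow locus-specific arrangements and draw low support
        complete <- all(unlist(samples_by_species[sps]) %in% members)
        complete && clade_key(sps) %in% species_keys
      }, TRUE)
      hi <- .draw_support(sum(concordant), spec$support_high)
      lo <- .draw_support(sum(!concordant), spec$support_low)
      mlbp <- bipp <- numeric(length(cl))
      mlbp[concordant] <- hi$mlbp; bipp[concordant] <- hi$bipp
      mlbp[!concordant] <- lo$mlbp; bipp[!concordant] <- lo$bipp
      annotated_tree(gt, data.frame(node = as.integer(names(cl)),
                                    mlbp = round(mlbp), bipp = round(bipp, 2)))
    })
  })
  attr(out, "sample_species") <- sample_species
  out
}

#' Simulate a nucleotide alignment along a tree
#'
#' TN93 substitution with discrete-gamma among-site rate variation: the root
#' sequence is drawn from the stationary frequencies and evolved down every
#' branch (lengths in substitutions/site).  Optionally, bases are replaced at
#' a fixed per-site rate by two-base IUPAC ambiguity codes containing them.
#'
#' @param tree \code{phylo} with branch lengths in substitutions/site.
#' @param model a [locus_model()].
#' @param seed integer seed.
#' @return character matrix alignment (rows = tips).
#' @export
sim_alignment <- function(tree, model = locus_model(), seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  L <- model$length
  Q <- .tn93_Q(model$k1, model$k2, model$pi)
  eig <- .rev_eig(Q, model$pi)
  rates <- .gamma_rates(model$gamma_shape, model$gamma_ncat)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  .with_seed(seed, {
    site_cat <- sample.int(length(rates), L, replace = TRUE)
    states <- matrix(0L, nn, L)
    states[ntip + 1L, ] <- sample.int(4L, L, replace = TRUE, prob = model$pi)
    edges <- ape::reorder.phylo(tree, "cladewise")$edge
    lens <- tree$edge.length[match(paste(edges[, 1], edges[, 2]),
                                   paste(tree$edge[, 1], tree$edge[, 2]))]
    for (k in seq_len(nrow(edges))) {
      parent <- edges[k, 1]; child <- edges[k, 2]
      Ps <- lapply(rates, function(r) {
        P <- .rev_expm(eig, r * lens[k])
        P / rowSums(P)
      })
      cs <- integer(L)
      for (cat in seq_along(rates)) for (b in 1:4) {
        sel <- which(site_cat == cat & states[parent, ] == b)
        if (length(sel))
          cs[sel] <- sample.int(4L, length(sel), replace = TRUE,
                                prob = Ps[[cat]][b, ])
      }
      states[child, ] <- cs
    }
    aln <- matrix(.DNA_BASES[states[seq_len(ntip), , drop = FALSE]],
                  ntip, L, dimnames = list(tree$tip.label, NULL))
    if (model$ambiguity_rate > 0) {
      amb_of <- matrix(c("M", "R", "W", "M", "S", "Y", "R", "S", "K",
                         "W", "Y", "K"), 4, 3, byrow = TRUE)
      # row = true base (ACGT); columns = code with one of the other bases
      hits <- which(matrix(stats::runif(ntip * L) < model$ambiguity_rate,
                           ntip, L), arr.ind = TRUE)
      for (r in seq_len(nrow(hits))) {
        b <- match(aln[hits[r, 1], hits[r, 2]], .DNA_BASES)
        aln[hits[r, 1], hits[r, 2]] <- amb_of[b, sample.int(3L, 1L)]
      }
    }
    aln
  })
}

#' Forward simulation of range evolution under DEC
#'
#' Anagenetic dispersal/extinction events are simulated by competing
#' exponential waiting times within epochs (rates switching at epoch
#' boundaries); at every speciation a cladogenetic scenario is drawn
#' uniformly from the DEC scenario set of the current range.  A lineage that
#' hits the absorbing null range cannot be observed at a tip, so that
#' branch's history is redrawn (up to `max_tries` per branch), conditioning
#' every surviving branch on non-extinction.
#'
#' @param chrono ultrametric \code{phylo} in Ma.
#' @param geo a [geography()].
#' @param params list with rates `d` and `e`.
#' @param seed integer seed.
#' @param root_range optional fixed root range (area letters); default: drawn
#'   uniformly from the legal non-null states.
#' @param max_tries per-branch redraw cap before giving up (error advises
#'   lowering `e`).
#' @return list with `tip_ranges` (named area strings), `node_states` (true
#'   range at every node), `splits` (true cladogenetic outcomes), `n_events`
#'   (anagenetic event count), `n_redraws` (branch histories discarded for
#'   hitting the null range) and `events` (age/from/to log of the surviving
#'   anagenetic events).
#' @export
sim_ranges <- function(chrono, geo, params, seed = 1L, root_range = NULL,
                       max_tries = 100L) {
  phy <- .as_plain_phylo(chrono)
  states <- build_state_space(geo)
  keys <- attr(states, "keys")
  clado <- .clado_table(states)
  Qs <- lapply(geo$epochs, function(ep)
    build_rate_matrix(states, params, ep$m))
  ep_start <- vapply(geo$epochs, `[[`, 0, "start")
  ep_end <- vapply(geo$epochs, `[[`, 0, "end")
  ages <- .node_ages(phy)
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  children <- .node_children(phy)
  epoch_at <- function(age) {
    e <- which(ep_start - 1e-12 <= age & age <= ep_end + 1e-12)
    e[1]          # a boundary age resolves to the younger epoch being entered
  }
  .with_seed(seed, {
    if (is.null(root_range)) {
      legal <- which(lengths(states) > 0)
    } else {
      legal <- .state_index(states, strsplit(root_range, "")[[1]])
      if (is.na(legal)) stop("illegal root range")
    }
    node_state <- integer(ntip + phy$Nnode)
    node_state[root] <- if (length(legal) > 1L)
      legal[sample.int(length(legal), 1L)] else legal
    splits <- NULL
    n_events <- 0L
    n_redraws <- 0L
    event_log <- list()
    # One pass down one branch; returns the end state (1 = hit null) and the
    # (age, from, to) event log.
    run_branch <- function(s, from_age, to_age) {
      a <- from_age
      ev <- list()
      while (a > to_age + 1e-12) {
        e <- epoch_at(a)
        boundary <- max(ep_start[e], to_age)
        rate <- -Qs[[e]][s, s]
        if (rate <= 0) { a <- boundary; if (a <= to_age + 1e-12) break; next }
        w <- stats::rexp(1L, rate)
        if (a - w < boundary) { a <- boundary
          if (a <= to_age + 1e-12) break else next }
        a <- a - w
        p <- Qs[[e]][s, ]; p[s] <- 0
        to <- sample.int(length(keys), 1L, prob = p)
        ev[[length(ev) + 1L]] <- data.frame(age = a, from = keys[s],
                                            to = keys[to])
        s <- to
        if (s == 1L) break               # null range: lineage extinct
      }
      list(s = s, ev = ev)
    }
    # Lineages hitting the absorbing null range cannot be observed at tips:
    # such a branch history is redrawn (up to max_tries per branch),
    # conditioning each surviving branch on non-extinction.
    simulate_branch <- function(s, from_age, to_age) {
      for (try in seq_len(max_tries)) {
        res <- run_branch(s, from_age, to_age)
        if (res$s != 1L) {
          n_events <<- n_events + length(res$ev)
          if (length(res$ev))
            event_log[[length(event_log) + 1L]] <<- do.call(rbind, res$ev)
          if (try > 1L) n_redraws <<- n_redraws + (try - 1L)
          return(res$s)
        }
      }
      stop("a lineage hit the null range in every redraw; ",
           "lower the extinction rate e")
    }
    edges <- ape::reorder.phylo(phy, "cladewise")$edge
    for (v in c(root, edges[edges[, 2] > ntip, 2])) {
      s <- node_state[v]
      pr <- clado[[s]]
      pick <- pr[sample.int(nrow(pr), 1L), ]
      kids <- children[[v]]
      splits <- rbind(splits, data.frame(node = v, anc = keys[s],
                                         left = keys[pick[1]],
                                         right = keys[pick[2]]))
      for (ci in 1:2)
        node_state[kids[ci]] <- simulate_branch(pick[ci], ages[v],
                                                ages[kids[ci]])
    }
    list(
      tip_ranges = setNames(keys[node_state[seq_len(ntip)]], phy$tip.label),
      node_states = setNames(keys[node_state], c(phy$tip.label,
        paste0("node", seq.int(root, ntip + phy$Nnode)))),
      splits = splits, n_events = n_events, n_redraws = n_redraws,
      events = if (length(event_log)) do.call(rbind, event_log) else
        data.frame(age = numeric(), from = character(), to = character()))
  })
}

# ---------------------------------------------------------------------------
# Desk-scale study fixture
# ---------------------------------------------------------------------------

# Gene-tree scaffolds for the fixture.  Species-level topology is identical
# (concordant) across loci; within-species sample arrangements differ per
# locus so that sub-species clades appear in at most one genealogy.
.fixture_scaffold <- function(locus) {
  sub <- list(
    F  = c("(((f1:1,f2:1):1,f3:2):1,f4:3)",
           "(((f1:1,f2:1):1,f3:2):1,f4:3)",
           "(((f1:1,f3:1):1,f2:2):1,f4:3)")[locus],
    P  = c("((p1:1,(p2:0.7,p3:0.7):0.3):2,((p4:1,p5:1):1,p6:2):1)",
           "((((p1:0.6,p2:0.6):0.4,p3:1):1,p4:2):0.5,(p5:0.8,p6:0.8):1.7)",
           "(((p1:0.9,p3:0.9):1.1,(p4:1.2,p6:1.2):0.8):1,(p2:1.5,p5:1.5):1.5)")[locus],
    Ppend = c("6", "6.5", "6")[locus],
    N2 = "((n2a:0.8,n2b:0.8):1.2,m1:2)",
    N3 = "(w1:4,w2:4)",
    N1 = "(n1a:0.8,n1b:0.8)",
    N4 = "(n4a:0.6,n4b:0.6)", N5 = "(n5a:0.7,n5b:0.7)",
    N6 = "(n6a:0.5,n6b:0.5)", N7 = "(n7a:0.5,n7b:0.5)")
  paste0("((", sub$F, ":11,(", sub$P, ":", sub$Ppend, ",(", sub$N4, ":5.4,",
         sub$N5, ":5.3):3):5):11,((", sub$N1, ":7.2,a1:8):10,((", sub$N2,
         ":5,", sub$N3, ":3):5,(", sub$N6, ":4.5,", sub$N7,
         ":4.5):7):6):7);")
}

.fixture_sample_species <- function() {
  c(f1 = "F", f2 = "F", f3 = "F", f4 = "F",
    p1 = "P", p2 = "P", p3 = "P", p4 = "P", p5 = "P", p6 = "P",
    n1a = "N1", n1b = "N1", n2a = "N2", n2b = "N2", m1 = "N2",
    w1 = "N3", w2 = "N3",
    n4a = "N4", n4b = "N4", n5a = "N5", n5b = "N5",
    n6a = "N6", n6b = "N6", n7a = "N7", n7b = "N7", a1 = "A")
}

# Assign fixture supports: species-concordant clades get the high default,
# within/scrambled clades the low default, specific clades the stated
# overrides (mirroring the heterogeneous support pattern of real multilocus
# datasets: one lineage concordant-but-weak, one supported in one locus only).
.fixture_supports <- function(gt, species_tree, overrides,
                              high = c(97, 1), low = c(45, 0.6)) {
  sample_species <- .fixture_sample_species()
  species_keys <- vapply(c(lapply(node_clades(species_tree), sort),
                           as.list(species_tree$tip.label)), clade_key, "")
  cl <- node_clades(gt)
  sup <- data.frame(node = as.integer(names(cl)), mlbp = NA_real_,
                    bipp = NA_real_)
  for (i in seq_along(cl)) {
    members <- cl[[i]]
    key <- clade_key(members)
    ov <- overrides[[key]]
    if (!is.null(ov)) {
      sup$mlbp[i] <- ov[1]; sup$bipp[i] <- ov[2]
      next
    }
    sps <- unique(sample_species[members])
    concordant <-
      all(names(sample_species)[sample_species %in% sps] %in% members) &&
        clade_key(sps) %in% species_keys
    vals <- if (concordant) high else low
    sup$mlbp[i] <- vals[1]; sup$bipp[i] <- vals[2]
  }
  annotated_tree(gt, sup)
}

.ov <- function(...) {
  args <- list(...)
  out <- lapply(args, `[[`, 2)
  names(out) <- vapply(args, function(a) clade_key(a[[1]]), "")
  out
}

#' Build the desk-scale multi-locus study fixture
#'
#' A deterministic analogue of a three-locus fungal species-delimitation
#' study: 12 true species over three areas; three per-locus gene trees on 26
#' common samples with heterogeneous supports (one lineage concordant across
#' two loci but weakly supported, one visible in a single locus only, two
#' stray samples recoverable by exhaustive subdivision); a combined tree;
#' simulated alignments per locus plus an ITS-style alignment carrying an
#' extra locus-restricted sample (`x1`) and two cloned sequence copies of one
#' sample (`p1`); two declared 3-locus singletons — `a1` (distant: should
#' split) and `m1` (close to N2: should merge) — and DEC-evolved tip ranges
#' on the species chronogram.  Everything is reproducible byte-for-byte from
#' `seed`.
#'
#' @param seed integer seed (drives alignment and range simulation; the tree
#'   topologies and supports are fixed by design).
#' @param aln_length sites simulated per locus.
#' @param its_length sites in the ITS-style alignment.
#' @param clock_rate substitutions/site/Ma.
#' @return list of class `"study_fixture"`; see Details.
#' @export
make_study_fixture <- function(seed = 1L, aln_length = 800L,
                               its_length = 900L, clock_rate = 0.005) {
  species_newick <- paste0(
    "((F:14,(P:9,(N4:6,N5:6):3):5):11,",
    "((N1:8,A:8):10,((N2:7,N3:7):5,(N6:5,N7:5):7):6):7);")
  chronogram <- ape::read.tree(text = species_newick)
  sp_for_gcpsr <- ape::drop.tip(chronogram, "A")   # A is the split singleton

  ov1 <- .ov(list(c("f1", "f2"), c(67, 0.73)),
             list(c("f1", "f2", "f3"), c(55, 0.80)),
             list(c("p1", "p2", "p3"), c(96, 0.78)),
             list(c("p4", "p5", "p6"), c(95, 0.99)),
             list(c("n2a", "n2b"), c(98, 1.00)),
             list(c("n2a", "n2b", "m1"), c(60, 0.90)))
  ov2 <- .ov(list(c("f1", "f2"), c(64, 0.93)),
             list(c("f1", "f2", "f3"), c(50, 0.75)),
             list(c("p1", "p2", "p3"), c(95, 0.99)),
             list(c("n2a", "n2b"), c(97, 1.00)),
             list(c("n2a", "n2b", "m1"), c(62, 0.91)))
  ov3 <- .ov(list(c("n2a", "n2b"), c(99, 1.00)),
             list(c("n2a", "n2b", "m1"), c(58, 0.88)))
  ovc <- .ov(list(c("f1", "f2"), c(71, 1.00)),
             list(c("p1", "p2", "p3"), c(100, 1.00)),
             list(c("n2a", "n2b"), c(98, 1.00)),
             list(c("n2a", "n2b", "m1"), c(65, 0.92)))
  overrides <- list(ov1, ov2, ov3)

  gene_trees <- lapply(1:3, function(locus) {
    gt <- ape::read.tree(text = .fixture_scaffold(locus))
    .fixture_supports(gt, sp_for_gcpsr, overrides[[locus]])
  })
  combined_tree <- .fixture_supports(
    ape::read.tree(text = .fixture_scaffold(1)), sp_for_gcpsr, ovc)

  alignments <- lapply(1:3, function(locus) {
    gt <- .as_plain_phylo(gene_trees[[locus]])
    gt$edge.length <- gt$edge.length * clock_rate
    sim_alignment(gt, locus_model(length = aln_length,
                                  ambiguity_rate = if (locus == 3L) 0.01 else 0),
                  seed = seed + locus)
  })
  combined_aln <- do.call(cbind, alignments)

  # ITS-style tree: locus-1 topology, plus the ITS-only sample x1 on the
  # stem of the P clade and two cloned sequence copies of p1
  its_newick <- .fixture_scaffold(1)
  its_newick <- sub("((p1:1", "(((p1:1", its_newick, fixed = TRUE)
  its_newick <- sub("):6,(", "):5,x1:8):1,(", its_newick, fixed = TRUE)
  its_newick <- sub("p1:1", "(p1_c1:0.05,p1_c2:0.05):0.95", its_newick,
                    fixed = TRUE)
  its_tree <- ape::read.tree(text = its_newick)
  its_scaled <- its_tree
  its_scaled$edge.length <- its_scaled$edge.length * clock_rate
  its_alignment <- sim_alignment(its_scaled,
                                 locus_model(length = its_length),
                                 seed = seed + 4L)
  its_labels <- its_tree$tip.label
  its_map <- taxon_map(its_labels,
                       ifelse(its_labels %in% c("p1_c1", "p1_c2"), "p1",
                              its_labels))

  geo <- three_area_geography()
  dec_params <- list(d = 0.05, e = 0.02)
  ranges <- sim_ranges(chronogram, geo, dec_params, seed = seed + 5L)

  truth <- c(f1 = "F", f2 = "F", f3 = "F", f4 = "F",
             p1 = "P1", p2 = "P1", p3 = "P1",
             p4 = "P2", p5 = "P2", p6 = "P2",
             n1a = "N1", n1b = "N1", n2a = "N2", n2b = "N2", m1 = "N2",
             w1 = "N3", w2 = "N3", n4a = "N4", n4b = "N4",
             n5a = "N5", n5b = "N5", n6a = "N6", n6b = "N6",
             n7a = "N7", n7b = "N7", a1 = "A", x1 = "X")

  structure(list(
    seed = seed,
    chronogram = chronogram,
    gene_trees = gene_trees,
    combined_tree = combined_tree,
    alignments = alignments,
    combined_alignment = combined_aln,
    its_tree = its_tree,
    its_alignment = its_alignment,
    its_map = its_map,
    singletons = c(split = "a1", merge = "m1"),
    its_singleton = "x1",
    geo = geo,
    dec_params = dec_params,
    tip_ranges = ranges$tip_ranges,
    range_truth = ranges,
    truth = truth,
    n_true_species = length(unique(truth)),
    n_expected_lineages = 10L
  ), class = "study_fixture")
}

#' @export
print.study_fixture <- function(x, ...) {
  cat("Study fixture (seed ", x$seed, "): ", x$n_true_species,
      " true species, 3 loci, ", length(x$truth), " samples\n", sep = "")
  invisible(x)
}

#' Write a fixture bundle to a directory
#'
#' Trees as newick, alignments as FASTA, tip ranges as TSV, truth labels and
#' the generating configuration as JSON.
#'
#' @param fx a [make_study_fixture()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(fx$gene_trees))
    writeLines(write_tree(fx$gene_trees[[i]]),
               file.path(dir, sprintf("locus%d.nwk", i)))
  writeLines(write_tree(fx$combined_tree), file.path(dir, "combined.nwk"))
  writeLines(ape::write.tree(fx$chronogram), file.path(dir, "chronogram.nwk"))
  for (i in seq_along(fx$alignments))
    write_alignment(fx$alignments[[i]],
                    file.path(dir, sprintf("locus%d.fasta", i)))
  write_alignment(fx$its_alignment, file.path(dir, "its.fasta"))
  utils::write.table(
    data.frame(tip = names(fx$tip_ranges), range = unname(fx$tip_ranges)),
    file.path(dir, "tip_ranges.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  jsonlite::write_json(
    list(seed = fx$seed, truth = as.list(fx$truth),
         singletons = as.list(fx$singletons),
         its_singleton = fx$its_singleton,
         dec_params = fx$dec_params),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
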