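#' Dual support thresholds for clade significance
#'
#' A clade counts as "highly supported" only when both its maximum-likelihood
#' bootstrap proportion and its Bayesian posterior probability meet the
#' thresholds (missing support never qualifies).
#'
#' @param mlbp_min minimum ML bootstrap percentage (default 70).
#' @param bipp_min minimum Bayesian posterior probability (default 0.95).
#' @return list of class `"support_thresholds"`.
#' @export
support_thresholds <- function(mlbp_min = 70, bipp_min = 0.95) {
  stopifnot(mlbp_min > 0, mlbp_min <= 100, bipp_min > 0, bipp_min <= 1)
  structure(list(mlbp_min = mlbp_min, bipp_min = bipp_min),
            class = "support_thresholds")
}

# Clade table rows that pass both thresholds (candidate "supported" clades).
# Root/universe-sized clades and trivial clades are excluded.
.supported_clades <- function(tree, thr) {
  ct <- clade_table(tree)
  ntip <- length(tree$tip.label)
  keep <- ct$size >= 2L & ct$size < ntip &
    !is.na(ct$mlbp) & !is.na(ct$bipp) &
    ct$mlbp >= thr$mlbp_min & ct$bipp >= thr$bipp_min
  out <- ct[keep, , drop = FALSE]
  attr(out, "members") <- attr(ct, "members")[keep]
  out
}

.check_common_taxa <- function(trees) {
  if (length(trees) < 2L) stop("need at least two gene trees")
  u <- lapply(trees, function(t) sort(t$tip.label))
  for (i in seq_along(u)[-1]) {
    if (!identical(u[[1]], u[[i]]))
      stop("gene trees must be restricted to a common taxon set ",
           "(see restrict_to_common_taxa)")
  }
  u[[1]]
}

# Two clades contradict when they overlap but neither contains the other.
.contradicts <- function(x, y) {
  ix <- length(intersect(x, y))
  ix > 0L && ix < length(x) && ix < length(y)
}

#' Detect significant phylogenetic conflict between loci
#'
#' A conflict is recorded for every pair of clades, in different loci, that
#' contradict one another (overlapping, neither containing the other) while
#' both meet the dual support thresholds.  An empty result means the loci are
#' combinable under this criterion.
#'
#' @param trees list of [annotated_tree()] per locus, restricted to a common
#'   taxon set.
#' @param thresholds a [support_thresholds()].
#' @return data frame of class `"conflict_records"` with one row per
#'   conflicting clade pair: locus indices, supports, and the two member sets
#'   in list columns `taxa_a`, `taxa_b`.
#' @export
detect_conflicts <- function(trees, thresholds = support_thresholds()) {
  .check_common_taxa(trees)
  sup <- lapply(trees, .supported_clades, thr = thresholds)
  rec <- list()
  for (i in seq_along(trees)[-length(trees)]) {
    for (j in seq.int(i + 1L, length(trees))) {
      mi <- attr(sup[[i]], "members"); mj <- attr(sup[[j]], "members")
      for (a in seq_along(mi)) for (b in seq_along(mj)) {
        if (.contradicts(mi[[a]], mj[[b]])) {
          rec[[length(rec) + 1L]] <- data.frame(
            locus_a = i, locus_b = j,
            mlbp_a = sup[[i]]$mlbp[a], bipp_a = sup[[i]]$bipp[a],
            mlbp_b = sup[[j]]$mlbp[b], bipp_b = sup[[j]]$bipp[b],
            key_a = sup[[i]]$key[a], key_b = sup[[j]]$key[b])
          rec[[length(rec)]]$taxa_a <- I(list(mi[[a]]))
          rec[[length(rec)]]$taxa_b <- I(list(mj[[b]]))
        }
      }
    }
  }
  out <- if (length(rec)) do.call(rbind, rec) else
    data.frame(locus_a = integer(), locus_b = integer(),
               mlbp_a = numeric(), bipp_a = numeric(),
               mlbp_b = numeric(), bipp_b = numeric(),
               key_a = character(), key_b = character(),
               taxa_a = I(list()), taxa_b = I(list()))
  class(out) <- c("conflict_records", "data.frame")
  out
}

#' Genealogical concordance candidates (criterion i)
#'
#' Clades (2 <= size < number of taxa) monophyletic in at least `min_trees`
#' of the maximum-likelihood genealogies, regardless of support level.
#'
#' @param ml_trees list of trees on a common taxon set.
#' @param min_trees minimum number of genealogies exhibiting the clade
#'   (default 2).
#' @return named list of clades (character vectors of tip labels); names are
#'   canonical clade keys; the presence count is in attribute `"count"`.
#' @export
criterion_a_lineages <- function(ml_trees, min_trees = 2L) {
  .check_common_taxa(ml_trees)
  ntip <- length(ml_trees[[1]]$tip.label)
  seen <- new.env(parent = emptyenv())
  members <- list()
  for (tr in ml_trees) {
    ct <- clade_table(tr)
    mem <- attr(ct, "members")
    ok <- ct$size >= 2L & ct$size < ntip
    for (k in which(ok)) {
      key <- ct$key[k]
      cnt <- if (is.null(seen[[key]])) 0L else seen[[key]]
      seen[[key]] <- cnt + 1L
      if (is.null(members[[key]])) members[[key]] <- sort(mem[[k]])
    }
  }
  keys <- names(members)
  counts <- vapply(keys, function(k) seen[[k]], 0L)
  keep <- counts >= min_trees
  out <- members[keep]
  attr(out, "count") <- counts[keep]
  out
}

#' Genealogical non-discordance candidates (criterion ii)
#'
#' Clades highly supported (both thresholds) in at least one genealogy and
#' not contradicted at the same level of support in any other genealogy,
#' operationalised as absence from every conflict record.
#'
#' @param trees list of support-annotated trees on a common taxon set.
#' @param thresholds a [support_thresholds()].
#' @param conflicts optional pre-computed [detect_conflicts()] result.
#' @return named list of clades (canonical keys as names).
#' @export
criterion_b_lineages <- function(trees, thresholds = support_thresholds(),
                                 conflicts = NULL) {
  .check_common_taxa(trees)
  if (is.null(conflicts)) conflicts <- detect_conflicts(trees, thresholds)
  conflicted <- unique(c(conflicts$key_a, conflicts$key_b))
  members <- list()
  for (tr in trees) {
    sup <- .supported_clades(tr, thresholds)
    mem <- attr(sup, "members")
    for (k in seq_along(mem)) {
      key <- sup$key[k]
      if (key %in% conflicted) next
      if (is.null(members[[key]])) members[[key]] <- sort(mem[[k]])
    }
  }
  members
}

#' Select terminal (inclusion-minimal) independent lineages
#'
#' Keeps the inclusion-minimal clades among the criterion-i/ii candidates (no
#' qualifying proper sub-clade), attaches criterion labels, and verifies that
#' the survivors are pairwise disjoint.
#'
#' @param a_candidates clades from [criterion_a_lineages()] (may be empty).
#' @param b_candidates clades from [criterion_b_lineages()] (may be empty).
#' @return object of class `"lineage_set"`: data frame with `id`, `size`,
#'   `criterion` (`"a"`, `"b"` or `"a and b"`); member sets in attribute
#'   `"members"`.
#' @export
terminal_lineages <- function(a_candidates = list(), b_candidates = list()) {
  keys <- union(names(a_candidates), names(b_candidates))
  if (!length(keys)) stop("no candidate lineages")
  members <- lapply(keys, function(k) {
    if (!is.null(a_candidates[[k]])) a_candidates[[k]] else b_candidates[[k]]
  })
  names(members) <- keys
  criterion <- vapply(keys, function(k) {
    a <- k %in% names(a_candidates); b <- k %in% names(b_candidates)
    if (a && b) "a and b" else if (a) "a" else "b"
  }, "")
  # inclusion-minimal: drop any candidate with a qualifying proper subset
  sizes <- lengths(members)
  minimal <- rep(TRUE, length(members))
  for (i in seq_along(members)) {
    for (j in seq_along(members)) {
      if (i == j) next
      if (sizes[j] < sizes[i] && all(members[[j]] %in% members[[i]])) {
        minimal[i] <- FALSE
        break
      }
    }
  }
  members <- members[minimal]
  criterion <- criterion[minimal]
  # survivors must be pairwise disjoint
  if (length(members) >= 2L) {
    for (i in seq_len(length(members) - 1L)) {
      for (j in seq.int(i + 1L, length(members))) {
        if (length(intersect(members[[i]], members[[j]])))
          stop("overlapping non-nested lineages survive minimal selection: {",
               paste(members[[i]], collapse = ","), "} vs {",
               paste(members[[j]], collapse = ","),
               "} - upstream conflict between loci")
      }
    }
  }
  ord <- order(vapply(members, function(m) min(m), ""))
  members <- members[ord]
  criterion <- criterion[ord]
  out <- data.frame(id = paste0("L", seq_along(members)),
                    size = lengths(members),
                    criterion = unname(criterion),
                    stringsAsFactors = FALSE)
  attr(out, "members") <- setNames(members, out$id)
  class(out) <- c("lineage_set", "data.frame")
  out
}

.node_children <- function(tree) {
  kids <- vector("list", length(tree$tip.label) + tree$Nnode)
  for (k in seq_len(nrow(tree$edge)))
    kids[[tree$edge[k, 1]]] <- c(kids[[tree$edge[k, 1]]], tree$edge[k, 2])
  kids
}

.node_parent <- function(tree) {
  par <- integer(length(tree$tip.label) + tree$Nnode)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

#' Exhaustive subdivision on the combined tree
#'
#' Every tip not covered by a terminal lineage is merged by walking rootward
#' in the combined (concatenated-data) tree to the smallest proper ancestor
#' whose descendant tips consist only of whole recognised lineages and/or
#' unassigned tips; all tips under that node become one species.  Lineages
#' are atomic: a walk that would bisect one is disallowed (the walk continues
#' rootward instead; an impossible configuration errors).  Merges are applied
#' in order of increasing merge-node height, rechecking after each merge.
#'
#' @param combined_tree the combined tree (its taxa must cover all lineage
#'   members).
#' @param lineages a [terminal_lineages()] result.
#' @param exclude tips to withhold from subdivision (e.g. samples to be
#'   resolved by the singleton distance rule instead).
#' @return a `"species_partition"`: named assignment tip label -> species id
#'   plus a provenance table.
#' @export
exhaustive_subdivision <- function(combined_tree, lineages,
                                   exclude = character()) {
  members <- attr(lineages, "members")
  tips_all <- combined_tree$tip.label
  miss <- setdiff(unlist(members), tips_all)
  if (length(miss))
    stop("combined tree lacks lineage members: ", paste(miss, collapse = ", "))
  universe <- setdiff(tips_all, exclude)
  phy <- if (length(exclude)) ape::keep.tip(.as_plain_phylo(combined_tree), universe)
         else .as_plain_phylo(combined_tree)
  groups <- members            # evolving atomic groups, lineage ids as names
  provenance <- setNames(rep("lineage", length(groups)), names(groups))
  repeat {
    assigned <- unlist(groups, use.names = FALSE)
    strays <- setdiff(phy$tip.label, assigned)
    if (!length(strays)) break
    cl <- node_clades(phy)
    parent <- .node_parent(phy)
    ntip <- length(phy$tip.label)
    node_height <- .node_heights(phy)
    # candidate merge node per stray: nearest proper ancestor containing no
    # partially-included group
    best <- lapply(strays, function(s) {
      v <- parent[match(s, phy$tip.label)]
      repeat {
        tipset <- cl[[as.character(v)]]
        partial <- any(vapply(groups, function(g) {
          ix <- length(intersect(g, tipset))
          ix > 0L && ix < length(g)
        }, TRUE))
        if (!partial) return(list(stray = s, node = v,
                                  height = node_height[v]))
        if (v == ntip + 1L)
          stop("exhaustive subdivision cannot proceed without splitting a ",
               "lineage (tip ", s, ")")
        v <- parent[v]
      }
    })
    heights <- vapply(best, `[[`, 0, "height")
    pick <- best[[which.min(heights)]]
    tipset <- cl[[as.character(pick$node)]]
    absorbed <- names(groups)[vapply(groups, function(g)
      all(g %in% tipset), TRUE)]
    newgroup <- sort(tipset)
    groups <- groups[setdiff(names(groups), absorbed)]
    gid <- paste0("M", length(provenance) + 1L)
    groups[[gid]] <- newgroup
    provenance[gid] <- "subdivision"
  }
  .partition_from_groups(groups, provenance)
}

# Node heights (max edge count from any descendant tip).
.node_heights <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  h <- numeric(nn)
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1]; c <- ord$edge[k, 2]
    h[p] <- max(h[p], h[c] + 1)
  }
  h
}

.partition_from_groups <- function(groups, provenance) {
  ord <- order(vapply(groups, min, ""))
  groups <- groups[ord]
  ids <- sprintf("sp%02d", seq_along(groups))
  assignment <- character()
  prov <- data.frame(sample = character(), species = character(),
                     how = character(), stringsAsFactors = FALSE)
  for (k in seq_along(groups)) {
    assignment[groups[[k]]] <- ids[k]
    prov <- rbind(prov, data.frame(sample = groups[[k]], species = ids[k],
                                   how = unname(provenance[names(groups)[k]])))
  }
  structure(list(assignment = assignment, provenance = prov,
                 members = setNames(groups, ids)),
            class = "species_partition")
}

#' @export
print.species_partition <- function(x, ...) {
  cat("Species partition:", length(unique(x$assignment)), "species,",
      length(x$assignment), "samples\n")
  invisible(x)
}

#' Resolve singleton samples by the genetic-distance rule
#'
#' For each singleton: compute its between-group mean distance to every
#' recognised species and compare the minimum with the maximum within-species
#' mean distance.  Strictly greater means the singleton is a distinct
#' species; otherwise it is merged into the species attaining the minimum
#' (ties merge, since a strict inequality is required to split).  Each
#' singleton is judged against the incoming partition.
#'
#' @param partition a `"species_partition"` (must contain at least one
#'   multi-member species so a within mean exists).
#' @param dm a [distance_matrix()] covering the singletons and the species
#'   members (possibly with several cloned sequence rows per sample).
#' @param singletons labels of the singleton samples (not in the partition).
#' @param map optional [taxon_map()] translating `dm` sequence labels to
#'   sample ids.
#' @return list with the updated `partition` and a `report` data frame
#'   (`singleton`, `min_between`, `nearest`, `max_within`, `decision`).
#' @export
assign_singletons <- function(partition, dm, singletons, map = NULL) {
  stopifnot(inherits(partition, "species_partition"))
  if (any(singletons %in% names(partition$assignment)))
    stop("singletons must not already be in the partition")
  seq_samples <- if (is.null(map)) setNames(dm$labels, dm$labels)
                 else setNames(labels_to_samples(dm$labels, map), dm$labels)
  base_groups <- partition$assignment[seq_samples]
  names(base_groups) <- dm$labels
  report <- data.frame(singleton = character(), min_between = numeric(),
                       nearest = character(), max_within = numeric(),
                       decision = character(), stringsAsFactors = FALSE)
  groups0 <- base_groups
  for (s in singletons) groups0[seq_samples == s] <- paste0(".single.", s)
  known <- groups0[!is.na(groups0)]
  if (!length(known)) stop("distance matrix covers no partition members")
  gm <- suppressWarnings(
    group_mean_distances(.subset_dm(dm, names(known)), known))
  species_ids <- unique(partition$assignment[seq_samples[names(known)]])
  species_ids <- species_ids[!is.na(species_ids)]
  max_within <- suppressWarnings(
    max(gm$within$mean[gm$within$group %in% species_ids], na.rm = TRUE))
  if (!is.finite(max_within))
    stop("no multi-member species with an estimable within-group mean; ",
         "the singleton rule needs at least one")
  newgroups <- list()
  for (s in singletons) {
    sg <- paste0(".single.", s)
    if (!sg %in% known)
      stop("singleton ", s, " absent from the distance matrix")
    bt <- gm$between[(gm$between$g1 == sg & gm$between$g2 %in% species_ids) |
                     (gm$between$g2 == sg & gm$between$g1 %in% species_ids), ]
    if (!nrow(bt) || all(is.na(bt$mean)))
      stop("no estimable between-group distance for singleton ", s)
    k <- which.min(bt$mean)
    min_between <- bt$mean[k]
    nearest <- if (bt$g1[k] == sg) bt$g2[k] else bt$g1[k]
    split <- min_between > max_within
    report <- rbind(report, data.frame(
      singleton = s, min_between = min_between, nearest = nearest,
      max_within = max_within,
      decision = if (split) "split" else "merge"))
    newgroups[[s]] <- if (split) NA_character_ else nearest
  }
  members <- partition$members
  prov <- partition$provenance
  for (s in singletons) {
    target <- newgroups[[s]]
    if (is.na(target)) {
      sid <- paste0("sp_", s)
      members[[sid]] <- s
      prov <- rbind(prov, data.frame(sample = s, species = sid,
                                     how = "singleton split"))
    } else {
      members[[target]] <- sort(c(members[[target]], s))
      prov <- rbind(prov, data.frame(sample = s, species = target,
                                     how = "singleton merge"))
    }
  }
  assignment <- character()
  for (k in seq_along(members)) assignment[members[[k]]] <- names(members)[k]
  out <- structure(list(assignment = assignment, provenance = prov,
                        members = members),
                   class = "species_partition")
  list(partition = out, report = report)
}

.subset_dm <- function(dm, labels) {
  keep <- match(labels, dm$labels)
  structure(list(d = dm$d[keep, keep, drop = FALSE],
                 sites = dm$sites[keep, keep, drop = FALSE],
                 labels = dm$labels[keep], model = dm$model,
                 config = dm$config, params = dm$params),
            class = "gene_dist")
}

#' Full GCPSR species delimitation
#'
#' Runs the whole engine: genealogical concordance (criterion i) and
#' non-discordance (criterion ii) candidate recognition on the per-locus
#' trees, terminal (inclusion-minimal) lineage selection, exhaustive
#' subdivision on the combined tree, and the distance rule for declared
#' singleton samples.  Emits a criterion table (species x per-locus supports
#' x criterion) mirroring the usual report shape.
#'
#' @param trees list of per-locus [annotated_tree()]s restricted to a common
#'   taxon set.
#' @param combined_tree the combined-data tree (its taxa = the common set
#'   plus any declared singletons present in all loci).
#' @param dm optional distance matrix for singleton resolution.
#' @param thresholds a [support_thresholds()].
#' @param singletons labels to withhold from subdivision and resolve by the
#'   distance rule (requires `dm`); singletons absent from `dm` are left
#'   unassigned with a note in the report.
#' @param map optional [taxon_map()] for cloned sequence copies in `dm`.
#' @return object of class `"delimitation"`: `partition`, `lineages`,
#'   `conflicts`, `criterion_table`, `singleton_report`.
#' @export
delimit <- function(trees, combined_tree, dm = NULL,
                    thresholds = support_thresholds(),
                    singletons = character(), map = NULL) {
  .check_common_taxa(trees)
  conflicts <- detect_conflicts(trees, thresholds)
  cand_a <- criterion_a_lineages(trees)
  cand_b <- criterion_b_lineages(trees, thresholds, conflicts = conflicts)
  lineages <- terminal_lineages(cand_a, cand_b)
  partition <- exhaustive_subdivision(combined_tree, lineages,
                                      exclude = singletons)
  singleton_report <- NULL
  resolvable <- character()
  if (length(singletons) && !is.null(dm)) {
    seq_samples <- if (is.null(map)) dm$labels
                   else labels_to_samples(dm$labels, map)
    resolvable <- intersect(singletons, seq_samples)
    if (length(resolvable)) {
      res <- assign_singletons(partition, dm, resolvable, map)
      partition <- res$partition
      singleton_report <- res$report
    }
  }
  ct <- .criterion_table(partition, lineages, trees, combined_tree)
  structure(list(partition = partition, lineages = lineages,
                 conflicts = conflicts, criterion_table = ct,
                 singleton_report = singleton_report,
                 unresolved_singletons = setdiff(singletons, resolvable)),
            class = "delimitation")
}

.support_string <- function(tree, members) {
  members <- intersect(members, tree$tip.label)
  if (length(members) < 1L) return("-/-")
  res <- is_monophyletic(tree, members)
  if (!res$monophyletic) return("-/-")
  if (length(members) < 2L) return("-/-")
  i <- match(res$node, tree$support$node)
  if (is.na(i)) return("-/-")
  m <- tree$support$mlbp[i]; b <- tree$support$bipp[i]
  paste0(ifelse(is.na(m), "-", sprintf("%g", m)), "/",
         ifelse(is.na(b), "-", sprintf("%g", b)))
}

.criterion_table <- function(partition, lineages, trees, combined_tree) {
  lin_members <- attr(lineages, "members")
  rows <- lapply(names(partition$members), function(sid) {
    mem <- partition$members[[sid]]
    crit <- unique(lineages$criterion[vapply(lineages$id, function(lid)
      all(lin_members[[lid]] %in% mem), TRUE)])
    crit_label <- if (!length(crit)) {
      how <- partition$provenance$how[match(mem[1], partition$provenance$sample)]
      if (grepl("singleton", how)) "distance" else "subdivision"
    } else if (any(crit == "a and b") || (any(crit == "a") && any(crit == "b")))
      "a and b" else crit[1]
    sup <- vapply(trees, .support_string, "", members = mem)
    comb <- .support_string(combined_tree, mem)
    c(species = sid, setNames(sup, paste0("locus", seq_along(trees))),
      combined = comb, criterion = crit_label,
      n_samples = as.character(length(mem)))
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.delimitation <- function(x, ...) {
  cat("GCPSR delimitation:", nrow(x$lineages), "terminal lineages ->",
      length(x$partition$members), "species\n")
  if (nrow(x$conflicts))
    cat("  ", nrow(x$conflicts), "inter-locus conflict record(s)\n")
  print(x$criterion_table)
  invisible(x)
}

#' Export a criterion table as TSV
#' @param delim a `"delimitation"` object.
#' @param path output path.
#' @export
write_criterion_table <- function(delim, path) {
  utils::write.table(delim$criterion_table, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
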