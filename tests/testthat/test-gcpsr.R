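test_that("the dual-threshold conflict rule flags only supported contradictions", {
  t1 <- parse_tree("((A,B)95/1.00,(C,D));")
  t2 <- parse_tree("((A,C)96/1.00,(B,D));")
  cf <- detect_conflicts(list(t1, t2))
  expect_equal(nrow(cf), 1L)
  expect_setequal(cf$taxa_a[[1]], c("A", "B"))
  expect_setequal(cf$taxa_b[[1]], c("A", "C"))
  # symmetric in the locus pair
  cf2 <- detect_conflicts(list(t2, t1))
  expect_equal(nrow(cf2), 1L)
  expect_setequal(cf2$taxa_a[[1]], c("A", "C"))
  # the AND of both thresholds: dropping either support kills the record
  expect_equal(nrow(detect_conflicts(list(
    t1, parse_tree("((A,C)96/0.90,(B,D));")))), 0L)
  expect_equal(nrow(detect_conflicts(list(
    t1, parse_tree("((A,C)65/1.00,(B,D));")))), 0L)
  # fully concordant loci are combinable
  t3 <- parse_tree("((A,B)99/1.00,(C,D)98/1.00);")
  expect_equal(nrow(detect_conflicts(list(t3, t3))), 0L)
  expect_error(detect_conflicts(list(t1)), "two")
})

test_that("criterion i counts presence in >= 2 genealogies regardless of support", {
  # weakly supported clade present in two of three genealogies qualifies
  t1 <- parse_tree("(((A,B)30/0.40,C),D);")
  t2 <- parse_tree("(((A,B)20/0.30,C),D);")
  t3 <- parse_tree("(((A,C),B),D);")
  cand <- criterion_a_lineages(list(t1, t2, t3))
  expect_true(clade_key(c("A", "B")) %in% names(cand))
  # present in exactly one genealogy: excluded
  expect_false(clade_key(c("A", "C")) %in% names(cand))

  set.seed(31)
  for (rep in 1:20) {
    trees <- lapply(1:3, function(i) annotated_tree(ape::rtree(6)))
    cand <- criterion_a_lineages(trees)
    # exhaustive subset oracle
    labs <- trees[[1]]$tip.label
    for (size in 2:5) {
      for (sub in utils::combn(labs, size, simplify = FALSE)) {
        n_mono <- sum(vapply(trees, function(tr)
          oracle_monophyletic(tr, sub), TRUE))
        expect_equal(clade_key(sub) %in% names(cand), n_mono >= 2,
                     info = paste(sub, collapse = ","))
      }
    }
  }
})

test_that("criterion ii needs one strong genealogy and no strong contradiction", {
  # supported in one locus, unresolved elsewhere: qualifies
  t1 <- parse_tree("(((A,B)95/0.99,C),D);")
  t2 <- parse_tree("((A,B,C),D);")     # polytomy: no contradiction
  cand <- criterion_b_lineages(list(t1, t2))
  expect_true(clade_key(c("A", "B")) %in% names(cand))
  # contradicted at full support elsewhere: excluded
  t3 <- parse_tree("(((A,C)98/1.00,B),D);")
  cand2 <- criterion_b_lineages(list(t1, t3))
  expect_false(clade_key(c("A", "B")) %in% names(cand2))

  # monotonicity: stricter thresholds can only shrink the candidate set
  set.seed(5)
  sp <- sim_chronogram(8, 0.3, 0.05, seed = 77)
  spec <- sim_spec(seed = 78, n_species = 8, samples_per_species = 1,
                   p_nni = 0.3)
  for (rep in 1:10) {
    spec$seed <- 78 + rep
    trees <- sim_gene_trees(sp, spec)
    loose <- criterion_b_lineages(trees, support_thresholds(70, 0.95))
    strict <- criterion_b_lineages(trees, support_thresholds(95, 0.99))
    expect_true(all(names(strict) %in% names(loose)))
  }
})

test_that("terminal lineage selection keeps inclusion-minimal disjoint clades", {
  a <- list(); b <- list()
  a[[clade_key(c("A", "B"))]] <- c("A", "B")
  a[[clade_key(c("A", "B", "C", "D"))]] <- c("A", "B", "C", "D")
  b[[clade_key(c("A", "B"))]] <- c("A", "B")
  b[[clade_key(c("E", "F"))]] <- c("E", "F")
  lin <- terminal_lineages(a, b)
  mem <- attr(lin, "members")
  expect_equal(length(mem), 2L)
  expect_setequal(unlist(lapply(mem, paste, collapse = "")), c("AB", "EF"))
  expect_equal(lin$criterion[vapply(mem, setequal, TRUE, y = c("A", "B"))],
               "a and b")
  expect_equal(lin$criterion[vapply(mem, setequal, TRUE, y = c("E", "F"))],
               "b")

  # overlapping non-nested survivors signal upstream conflict
  bad <- list()
  bad[[clade_key(c("A", "B"))]] <- c("A", "B")
  bad[[clade_key(c("B", "C"))]] <- c("B", "C")
  expect_error(terminal_lineages(bad, list()), "overlapping")

  # poset oracle on laminar families drawn from random trees
  set.seed(19)
  for (rep in 1:25) {
    phy <- ape::rtree(10)
    fam <- Filter(function(x) length(x) >= 2 && length(x) < 10,
                  lapply(node_clades(phy), sort))
    fam <- fam[sample(length(fam), max(2, length(fam) - 3))]
    cand <- setNames(fam, vapply(fam, clade_key, ""))
    cand <- cand[!duplicated(names(cand))]
    lin <- terminal_lineages(cand, list())
    keys_pkg <- sort(vapply(attr(lin, "members"), clade_key, ""))
    keys_orc <- sort(vapply(oracle_minimal_sets(unname(cand)), clade_key, ""))
    expect_equal(unname(keys_pkg), keys_orc)
  }
})

mk_lineages <- function(...) {
  sets <- list(...)
  cand <- setNames(sets, vapply(sets, clade_key, ""))
  terminal_lineages(cand, list())
}

test_that("exhaustive subdivision walks strays rootward into whole lineages", {
  # two strays outside a recognised pair merge stepwise into one species
  comb <- parse_tree("((((a:1,b:1)90/1:1,c:2)50/0.6:1,d:3)40/0.5:1,(e:2,f:2)95/1:2);")
  lin <- mk_lineages(c("a", "b"), c("e", "f"))
  part <- exhaustive_subdivision(comb, lin)
  expect_equal(length(part$members), 2L)
  expect_setequal(part$members[[which(vapply(part$members, function(m)
    "a" %in% m, TRUE))]], c("a", "b", "c", "d"))

  # no strays: partition equals the lineages
  comb2 <- parse_tree("((a,b)90/1,(e,f)95/1);")
  part2 <- exhaustive_subdivision(comb2, mk_lineages(c("a", "b"), c("e", "f")))
  expect_equal(length(part2$members), 2L)
  expect_true(all(part2$provenance$how == "lineage"))

  # star tree: the only available ancestor is the root
  star <- annotated_tree(ape::read.tree(text = "(a,b,x);"))
  part3 <- exhaustive_subdivision(star, mk_lineages(c("a", "b")))
  expect_equal(length(part3$members), 1L)
  expect_setequal(part3$members[[1]], c("a", "b", "x"))

  # withheld singletons are excluded from the walk
  part4 <- exhaustive_subdivision(comb, lin, exclude = c("c", "d"))
  expect_setequal(names(part4$assignment), c("a", "b", "e", "f"))
})

mk_dm <- function(D, labels) {
  dimnames(D) <- list(labels, labels)
  structure(list(d = D, sites = D * 0 + 100, labels = labels, model = "p",
                 config = dist_config("p"), params = NULL),
            class = "gene_dist")
}

test_that("the singleton distance rule splits on strict inequality only", {
  labels <- c("a1", "a2", "b1", "b2", "s")
  D <- matrix(0, 5, 5)
  D[1, 2] <- D[2, 1] <- 0.004          # within A
  D[3, 4] <- D[4, 3] <- 0.006          # within B (the max within)
  D[1:2, 3:4] <- D[3:4, 1:2] <- 0.05
  D[5, 1:4] <- D[1:4, 5] <- c(0.03, 0.03, 0.05, 0.05)
  part <- exhaustive_subdivision(
    parse_tree("(((a1,a2)99/1,(b1,b2)99/1),o);"),
    mk_lineages(c("a1", "a2"), c("b1", "b2")), exclude = c("s", "o"))
  part$members[["spO"]] <- "o"; part$assignment["o"] <- "spO"
  res <- assign_singletons(part, mk_dm(D, labels), "s")
  expect_equal(res$report$decision, "split")
  expect_equal(res$report$min_between, 0.03)
  expect_equal(res$report$max_within, 0.006)

  # min between equal to max within: merge (strictly-bigger rule)
  D2 <- D
  D2[5, 1:2] <- D2[1:2, 5] <- 0.006
  res2 <- assign_singletons(part, mk_dm(D2, labels), "s")
  expect_equal(res2$report$decision, "merge")
  expect_true("s" %in% res2$partition$members[[res2$report$nearest]])

  # demands at least one estimable within mean
  Dall <- matrix(0.1, 3, 3); diag(Dall) <- 0
  p1 <- exhaustive_subdivision(parse_tree("((x,y)99/1,z);"),
                               mk_lineages(c("x", "y")), exclude = "s")
  p1$members <- list(spx = "x", spy = "y")
  p1$assignment <- c(x = "spx", y = "spy")
  expect_error(assign_singletons(p1, mk_dm(Dall, c("x", "y", "s")), "s"),
               "within")
})

test_that("delimitation is invariant to locus order and handles a single cherry", {
  fx <- make_study_fixture(seed = 5)
  dm <- distance_matrix(fx$combined_alignment, dist_config("p"))
  base <- delimit(fx$gene_trees, fx$combined_tree, dm = dm,
                  singletons = unname(fx$singletons))
  for (perm in list(c(2, 1, 3), c(3, 2, 1))) {
    alt <- delimit(fx$gene_trees[perm], fx$combined_tree, dm = dm,
                   singletons = unname(fx$singletons))
    expect_equal(alt$partition$assignment[names(base$partition$assignment)],
                 base$partition$assignment)
  }
  # two loci, one fully supported cherry -> a single lineage
  t1 <- parse_tree("((A,B)100/1.00,C);")
  lin <- terminal_lineages(criterion_a_lineages(list(t1, t1)),
                           criterion_b_lineages(list(t1, t1)))
  expect_equal(nrow(lin), 1L)
})
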