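chars <- function(s) strsplit(s, "")[[1]]

test_that("pairwise distances apply the pairwise-deletion rule", {
  expect_equal(pairwise_distance(chars("ACGT"), chars("ACGT"),
                                 dist_config("p"))$distance, 0)
  pd <- pairwise_distance(chars("ACGT"), chars("ACGA"), dist_config("p"))
  expect_equal(pd$distance, 0.25)
  expect_equal(pd$sites, 4L)
  pd <- pairwise_distance(chars("AC-T"), chars("ACGT"), dist_config("p"))
  expect_equal(pd$distance, 0)
  expect_equal(pd$sites, 3L)
  # ambiguity codes excluded like gaps
  pd <- pairwise_distance(chars("ACRT"), chars("ACGT"), dist_config("p"))
  expect_equal(pd$sites, 3L)
  # zero comparable sites flag, never 0
  pd <- pairwise_distance(chars("??--"), chars("ACGT"), dist_config("p"))
  expect_true(pd$inestimable)
  expect_true(is.na(pd$distance))
})

test_that("distance matrices are symmetric with zero diagonal; corrections exceed p", {
  tr <- ape::read.tree(text = "((a:0.05,b:0.05):0.03,(c:0.06,d:0.06):0.02);")
  aln <- sim_alignment(tr, locus_model(length = 1500), seed = 5)
  for (model in c("p", "TN93")) {
    dm <- distance_matrix(aln, dist_config(model, gamma_shape = NA))
    expect_equal(dm$d, t(dm$d))
    expect_equal(unname(diag(dm$d)), rep(0, 4))
    if (model == "p") expect_true(all(dm$d <= 1))
  }
  dp <- distance_matrix(aln, dist_config("p"))
  dt <- distance_matrix(aln, dist_config("TN93", gamma_shape = NA))
  off <- upper.tri(dp$d)
  expect_true(all(dt$d[off] >= dp$d[off] - 1e-12))
})

test_that("TN93 distances agree with an independent implementation", {
  tr <- ape::read.tree(text = "((a:0.06,b:0.06):0.02,(c:0.05,d:0.05):0.03);")
  aln <- sim_alignment(tr, locus_model(length = 3000, k1 = 6, k2 = 3,
                                       pi = c(A = .3, C = .2, G = .2, T = .3),
                                       gamma_shape = NA), seed = 9)
  bin <- ape::as.DNAbin(aln)
  dm <- distance_matrix(aln, dist_config("TN93", gamma_shape = NA))
  ref <- as.matrix(ape::dist.dna(bin, model = "TN93", pairwise.deletion = TRUE))
  expect_lt(max(abs(dm$d[rownames(ref), colnames(ref)] - ref)), 1e-4)
  dmg <- distance_matrix(aln, dist_config("TN93", gamma_shape = 0.5))
  refg <- as.matrix(ape::dist.dna(bin, model = "TN93", gamma = 0.5,
                                  pairwise.deletion = TRUE))
  # base-frequency conventions differ slightly between implementations and
  # the gamma correction amplifies them
  expect_lt(max(abs(dmg$d[rownames(refg), colnames(refg)] - refg)), 2e-3)
})

test_that("composite-likelihood TN93 recovers true path lengths", {
  # 10 sequences on a fixed tree; mean relative error of the estimated
  # pairwise distances against the true patristic distances stays under 10%
  set.seed(21)
  tr <- ape::rcoal(10)
  tr$edge.length <- tr$edge.length * (0.15 / max(ape::node.depth.edgelength(tr)))
  truth <- ape::cophenetic.phylo(tr)
  est_sum <- truth * 0
  n_rep <- 15
  for (r in seq_len(n_rep)) {
    aln <- sim_alignment(tr, locus_model(length = 2000, k1 = 5, k2 = 2.5,
                                         pi = c(A = .3, C = .2, G = .2, T = .3),
                                         gamma_shape = 1),
                         seed = 7000 + r)
    dm <- distance_matrix(aln, dist_config("MCL-TN93", gamma_shape = 1))
    est_sum <- est_sum + dm$d[rownames(truth), colnames(truth)]
  }
  est <- est_sum / n_rep
  # relative error of the replicate-averaged estimates; the shallowest pairs
  # are excluded because relative error is undefined in the noise regime
  off <- upper.tri(truth) & truth >= 0.03
  rel <- (est[off] - truth[off]) / truth[off]
  expect_lt(max(abs(rel)), 0.1)
})

test_that("corrected distances track p at low divergence", {
  tr <- ape::read.tree(text = "(a:0.008,b:0.008);")
  for (s in 1:5) {
    aln <- sim_alignment(tr, locus_model(length = 4000), seed = 100 + s)
    p <- distance_matrix(aln, dist_config("p"))$d[1, 2]
    if (p == 0 || p > 0.02) next
    tn <- distance_matrix(aln, dist_config("TN93", gamma_shape = 1))$d[1, 2]
    expect_gte(tn, p)
    expect_lte(tn, 1.2 * p)
  }
})

test_that("group mean distances equal an explicit double loop", {
  mk_dm <- function(D, labels) {
    dimnames(D) <- list(labels, labels)
    structure(list(d = D, sites = D * 0 + 100, labels = labels,
                   model = "p", config = dist_config("p"), params = NULL),
              class = "gene_dist")
  }
  # two singleton groups
  D <- matrix(c(0, .1, .1, 0), 2)
  gm <- group_mean_distances(mk_dm(D, c("x", "y")),
                             c(x = "g1", y = "g2"))
  expect_equal(gm$between$mean, 0.1)
  expect_true(all(is.na(gm$within$mean)))

  set.seed(13)
  for (rep in 1:15) {
    n <- 15
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- runif(n * (n - 1) / 2)
    D <- D + t(D)
    labels <- paste0("t", seq_len(n))
    groups <- setNames(sample(c("a", "b", "c"), n, replace = TRUE), labels)
    gm <- group_mean_distances(mk_dm(D, labels), groups)
    or <- oracle_group_means(D, unname(groups))
    for (g in names(or$within))
      expect_equal(gm$within$mean[gm$within$group == g], unname(or$within[g]))
    for (k in seq_len(nrow(gm$between))) {
      key <- paste(gm$between$g1[k], gm$between$g2[k], sep = "|")
      expect_equal(gm$between$mean[k], unname(or$between[key]))
    }
    # invariance under group relabeling and row order
    perm <- sample(n)
    gm2 <- group_mean_distances(mk_dm(D[perm, perm], labels[perm]),
                                groups[labels[perm]])
    expect_equal(sort(gm2$within$mean), sort(gm$within$mean))
    expect_equal(sort(gm2$between$mean), sort(gm$between$mean))
  }
})

test_that("bootstrap SEs are reproducible and vanish for invariant data", {
  aln <- matrix("A", 4, 60, dimnames = list(paste0("s", 1:4), NULL))
  groups <- setNames(c("g1", "g1", "g2", "g2"), rownames(aln))
  bs <- bootstrap_se(aln, groups, dist_config("p"), n_reps = 25, seed = 3)
  expect_equal(bs$within$se[!is.na(bs$within$se)], c(0, 0))
  expect_equal(bs$between$se, 0)

  tr <- ape::read.tree(text = "((a:0.03,b:0.03):0.02,(c:0.04,d:0.04):0.01);")
  aln <- sim_alignment(tr, locus_model(length = 600), seed = 8)
  groups <- setNames(c("g1", "g1", "g2", "g2"), rownames(aln))
  b1 <- bootstrap_se(aln, groups, dist_config("p"), n_reps = 40, seed = 17)
  b2 <- bootstrap_se(aln, groups, dist_config("p"), n_reps = 40, seed = 17)
  expect_identical(b1$between$se, b2$between$se)
  expect_equal(b1$seed, 17)
})

test_that("site statistics match an independent tally", {
  aln <- matrix("A", 3, 10, dimnames = list(c("a", "b", "c"), NULL))
  ss <- site_stats(aln)
  expect_equal(ss$n_polymorphic, 0L)
  expect_equal(ss$n_degenerate, 0L)

  aln2 <- rbind(a = c("A", "A"), b = c("R", "G"), c = c("A", "A"))
  ss2 <- site_stats(aln2)
  expect_equal(unname(ss2$classification$polymorphic), c(FALSE, TRUE))
  expect_equal(unname(ss2$classification$degenerate), c(TRUE, FALSE))

  set.seed(29)
  for (rep in 1:10) {
    pool <- c("A", "C", "G", "T", "R", "Y", "N", "-", "?")
    aln <- matrix(sample(pool, 6 * 40, replace = TRUE,
                         prob = c(rep(0.2, 4), rep(0.04, 5))), 6, 40,
                  dimnames = list(paste0("s", 1:6), NULL))
    ss <- site_stats(aln)
    or <- oracle_site_stats(aln)
    expect_equal(ss$n_polymorphic, unname(or["poly"]))
    expect_equal(ss$n_degenerate, unname(or["degen"]))
  }
  expect_error(site_stats(aln, rows = "nope"), "nope")
})
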