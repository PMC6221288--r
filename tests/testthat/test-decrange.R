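test_that("range state spaces enumerate constrained subsets deterministically", {
  geo <- three_area_geography()
  st <- build_state_space(geo)
  keys <- attr(st, "keys")
  expect_equal(keys, c("", "A", "B", "C", "AB", "BC"))   # null + 5 observable

  st1 <- build_state_space(geography("A"))
  expect_equal(attr(st1, "keys"), c("", "A"))

  st_all <- build_state_space(geography(c("A", "B", "C")))
  expect_equal(length(st_all), 2^3)                      # power set + null

  expect_error(build_state_space(
    geography("A", excluded_ranges = list("A"))), "excluded")
})

test_that("the anagenetic rate matrix follows the DEC gain/loss rules", {
  geo <- three_area_geography()
  st <- build_state_space(geo)
  # d = 0: only extinction transitions remain
  Q <- build_rate_matrix(st, list(d = 0, e = 0.1), geo$epochs[[1]]$m)
  off <- Q; diag(off) <- 0
  gains <- 0
  for (i in seq_along(st)) for (j in seq_along(st))
    if (length(st[[j]]) > length(st[[i]]) && off[i, j] > 0) gains <- gains + 1
  expect_equal(gains, 0)
  expect_equal(unname(Q["A", 1]), 0.1)   # single area decays to null
  expect_equal(Q["AB", "A"], 0.1)

  # the young-epoch Asia-America shutoff zeroes the B <-> C gains
  Q1 <- build_rate_matrix(st, list(d = 0.2, e = 0.05), geo$epochs[[1]]$m)
  expect_equal(Q1["B", "BC"], 0)
  expect_equal(Q1["C", "BC"], 0)
  Q2 <- build_rate_matrix(st, list(d = 0.2, e = 0.05), geo$epochs[[2]]$m)
  expect_equal(Q2["B", "BC"], 0.2)

  # gain rate sums multipliers over occupied source areas
  m <- geo$epochs[[2]]$m
  expect_false("ABC" %in% colnames(Q2))           # max range size 2
  expect_equal(Q2["A", "AB"], 0.2 * m["A", "B"])

  set.seed(3)
  for (rep in 1:10) {
    m <- matrix(runif(9), 3, 3, dimnames = list(c("A","B","C"), c("A","B","C")))
    Q <- build_rate_matrix(st, list(d = runif(1), e = runif(1)), m)
    expect_true(all(abs(rowSums(Q)) < 1e-12))
    expect_true(all(Q - diag(diag(Q)) >= 0))
  }
  expect_error(build_rate_matrix(st, list(d = 1, e = 1), -m), "negative")
})

test_that("the DEC likelihood matches closed forms and is invariant to branch slicing", {
  g1 <- geography("A")
  tr <- ape::read.tree(text = "(t1:3,t2:3);")
  expect_equal(dec_loglik(tr, c(t1 = "A", t2 = "A"), g1,
                          list(d = 0.7, e = 0.11)), -2 * 0.11 * 3,
               tolerance = 1e-10)

  # inserting an epoch boundary with identical multipliers changes nothing
  areas <- c("A", "B", "C")
  m <- matrix(1, 3, 3, dimnames = list(areas, areas))
  geo_plain <- geography(areas, max_range_size = 2,
                         excluded_ranges = list(c("A", "C")))
  geo_cut <- geography(areas, max_range_size = 2,
                       excluded_ranges = list(c("A", "C")),
                       epochs = list(list(start = 0, end = 2.3, m = m),
                                     list(start = 2.3, end = Inf, m = m)))
  tr4 <- ape::read.tree(text = "((t1:2,t2:2):5,(t3:4,t4:4):3);")
  tips <- c(t1 = "A", t2 = "AB", t3 = "B", t4 = "BC")
  p <- list(d = 0.07, e = 0.03)
  expect_equal(dec_loglik(tr4, tips, geo_plain, p),
               dec_loglik(tr4, tips, geo_cut, p), tolerance = 1e-10)

  # invariance under consistent area relabeling
  perm <- c(A = "B", B = "C", C = "A")
  geo_perm <- geography(areas, max_range_size = 2,
                        excluded_ranges = list(sort(perm[c("A", "C")])))
  tips_perm <- vapply(tips, function(r)
    paste(sort(perm[strsplit(r, "")[[1]]]), collapse = ""), "")
  expect_equal(dec_loglik(tr4, tips, geo_plain, p),
               dec_loglik(tr4, tips_perm, geo_perm, p), tolerance = 1e-10)

  # illegal tip range and non-ultrametric input are rejected
  expect_error(dec_loglik(tr4, c(t1 = "AC", t2 = "A", t3 = "B", t4 = "C"),
                          geo_plain, p), "illegal")
  bad <- tr4; bad$edge.length[1] <- 9
  expect_error(dec_loglik(bad, tips, geo_plain, p), "ultrametric")
})

test_that("the likelihood agrees with a dense RK4 integration of the CTMC", {
  geo <- three_area_geography()
  tr4 <- ape::read.tree(text = "((t1:2,t2:2):5,(t3:4,t4:4):3);")
  tips <- c(t1 = "A", t2 = "AB", t3 = "B", t4 = "BC")
  p <- list(d = 0.07, e = 0.03)
  expect_equal(dec_loglik(tr4, tips, geo, p),
               oracle_dec_loglik(tr4, tips, geo, p$d, p$e, h = 0.002),
               tolerance = 1e-7)
})

test_that("ancestral split tables normalise and match brute-force enumeration", {
  g1 <- geography("A")
  tr <- ape::read.tree(text = "((t1:1,t2:1):1.5,(t3:2,t4:2):0.5);")
  nst <- ancestral_splits(tr, c(t1 = "A", t2 = "A", t3 = "A", t4 = "A"),
                          g1, list(d = 0.1, e = 0.05))
  expect_true(all(nst$splits$anc == "A" & nst$splits$prob == 1))

  geo <- three_area_geography()
  tips <- c(t1 = "A", t2 = "AB", t3 = "B", t4 = "BC")
  p <- list(d = 0.07, e = 0.03)
  nst <- ancestral_splits(tr, tips, geo, p)
  sums <- tapply(nst$splits$prob, nst$splits$node, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  sums_r <- tapply(nst$ranges$prob, nst$ranges$node, sum)
  expect_true(all(abs(sums_r - 1) < 1e-9))

  # brute force: enumerate every (node state, split) combination, weighting
  # by exact path probabilities from independently computed P matrices
  st <- oracle_dec_states(geo$areas, 2, "AC")
  keys <- vapply(st, function(s) paste(sort(s), collapse = ""), "")
  # piecewise P per branch (branch segments may cross the 5 Ma boundary)
  Pbranch <- function(a_child, a_parent) {
    P <- diag(length(st))
    segs <- rbind(c(max(a_child, 5), a_parent), c(a_child, min(a_parent, 5)))
    for (r in 1:2) {
      lo <- segs[r, 1]; hi <- segs[r, 2]
      if (hi - lo <= 0) next
      Qe <- oracle_dec_Q(st, p$d, p$e,
                         if (lo >= 5) geo$epochs[[2]]$m else geo$epochs[[1]]$m)
      P <- P %*% as.matrix(Matrix::expm(Qe * (hi - lo)))
    }
    P
  }
  dep <- ape::node.depth.edgelength(tr)
  age <- max(dep) - dep
  ntip <- 4
  kids <- phylodelim:::.node_children(tr)
  root <- ntip + 1L
  tipidx <- vapply(tr$tip.label, function(x) match(tips[x], keys), 0L)
  prior <- ifelse(lengths(st) > 0, 1, 0); prior <- prior / sum(prior)
  total <- 0
  node_split_mass <- list()
  v1 <- kids[[root]][1]; v2 <- kids[[root]][2]
  P_rv1 <- Pbranch(age[v1], age[root]); P_rv2 <- Pbranch(age[v2], age[root])
  P_t <- lapply(1:4, function(t) {
    par <- tr$edge[tr$edge[, 2] == t, 1]
    Pbranch(0, age[par])
  })
  add_mass <- function(node, s, x, y, w) {
    key <- paste(node, keys[s], keys[x], keys[y])
    node_split_mass[[key]] <<- (if (is.null(node_split_mass[[key]])) 0
                                else node_split_mass[[key]]) + w
  }
  for (s0 in seq_along(st)) {
    pr0 <- oracle_dec_scenarios(st, s0)
    if (is.null(pr0) || prior[s0] == 0) next
    for (r0 in seq_len(nrow(pr0))) {
      x0 <- pr0[r0, 1]; y0 <- pr0[r0, 2]
      for (s1 in seq_along(st)) {
        pr1 <- oracle_dec_scenarios(st, s1)
        if (is.null(pr1)) next
        for (r1 in seq_len(nrow(pr1))) {
          for (s2 in seq_along(st)) {
            pr2 <- oracle_dec_scenarios(st, s2)
            if (is.null(pr2)) next
            for (r2 in seq_len(nrow(pr2))) {
              k1 <- kids[[v1]]; k2 <- kids[[v2]]
              w <- prior[s0] / nrow(pr0) *
                P_rv1[x0, s1] * P_rv2[y0, s2] *
                (1 / nrow(pr1)) * (1 / nrow(pr2)) *
                P_t[[k1[1]]][pr1[r1, 1], tipidx[k1[1]]] *
                P_t[[k1[2]]][pr1[r1, 2], tipidx[k1[2]]] *
                P_t[[k2[1]]][pr2[r2, 1], tipidx[k2[1]]] *
                P_t[[k2[2]]][pr2[r2, 2], tipidx[k2[2]]]
              if (w > 0) {
                total <- total + w
                add_mass(root, s0, x0, y0, w)
                add_mass(v1, s1, pr1[r1, 1], pr1[r1, 2], w)
                add_mass(v2, s2, pr2[r2, 1], pr2[r2, 2], w)
              }
            }
          }
        }
      }
    }
  }
  expect_equal(log(total), dec_loglik(tr, tips, geo, p), tolerance = 1e-8)
  for (k in seq_len(nrow(nst$splits))) {
    row <- nst$splits[k, ]
    key <- paste(row$node, row$anc, row$left, row$right)
    expect_equal(row$prob, node_split_mass[[key]] / total, tolerance = 1e-8,
                 info = key)
  }
})

test_that("rate fitting matches a grid search and respects constraints", {
  geo <- three_area_geography()
  chr <- sim_chronogram(12, 0.25, 0.05, seed = 61)
  sr <- sim_ranges(chr, geo, list(d = 0.08, e = 0.01), seed = 62)
  fit <- fit_dec(chr, sr$tip_ranges, geo)
  expect_true(is.finite(fit$loglik))
  expect_true(all(c("d", "e", "loglik") %in% names(fit)))
  # a coarse grid never beats the optimiser materially
  grid <- expand.grid(d = exp(seq(log(1e-3), log(1), length.out = 12)),
                      e = exp(seq(log(1e-4), log(0.5), length.out = 12)))
  best_grid <- max(apply(grid, 1, function(g)
    dec_loglik(chr, sr$tip_ranges, geo, list(d = g[1], e = g[2]))))
  expect_lte(best_grid, fit$loglik + 1e-3)

  # degenerate geometry: one area, all tips observed there
  g1 <- geography("A")
  tr <- ape::read.tree(text = "((t1:1,t2:1):1,t3:2);")
  f1 <- fit_dec(tr, c(t1 = "A", t2 = "A", t3 = "A"), g1, bounds = c(1e-6, 10))
  expect_equal(f1$e, 1e-6, tolerance = 1e-6)
  expect_equal(f1$loglik, -1e-6 * sum(tr$edge.length), tolerance = 1e-4)

  # the reported optimum is locally maximal in both rates
  for (fac in c(0.8, 1.25)) {
    expect_lte(dec_loglik(chr, sr$tip_ranges, geo,
                          list(d = fit$d * fac, e = max(fit$e, 1e-5))),
               fit$loglik + 1e-6)
  }
})

test_that("with no extinction and strong dispersal the root prefers widespread ranges", {
  geo <- geography(c("A", "B"))
  tr <- ape::read.tree(text = "(t1:4,t2:4);")
  nst <- ancestral_splits(tr, c(t1 = "A", t2 = "B"), geo,
                          list(d = 1.5, e = 0))
  root_ranges <- nst$ranges[nst$ranges$node == 3, ]
  expect_equal(root_ranges$range[which.max(root_ranges$prob)], "AB")
})
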