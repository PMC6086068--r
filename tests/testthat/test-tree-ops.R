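sim_tree <- function(seed, la = 1.16, chi = 0.5, mu = 0.6, Tm = 6) {
  g <- simulate_genealogy(pbd_params(la, chi, mu, duration = Tm), seed = seed)
  sample_species_tree(g)
}

test_that("Newick round trips preserve topology and branch lengths", {
  tr <- read_newick("(A:1,B:1):0;")
  expect_equal(length(tr$tip.label), 2L)
  expect_equal(branching_times(tr), 1)
  tr3 <- read_newick("((A:1,B:1):1,C:2):0;")
  expect_equal(length(tr3$tip.label), 3L)
  expect_equal(branching_times(tr3), c(2, 1))
  suppressWarnings(
    expect_error(read_newick("((A:1,B:1):1,C:2"), "malformed|parenthe"))
  expect_error(read_newick("((A,B),C);"), "branch lengths")
  # property: read(write(t)) == t for simulated trees
  for (s in 1:5) {
    tr <- sim_tree(400 + s)
    back <- read_newick(write_newick(tr))
    expect_equal(sort(back$tip.label), sort(tr$tip.label))
    d1 <- ape::cophenetic.phylo(tr); d2 <- ape::cophenetic.phylo(back)
    expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-9)
  }
})

test_that("branching times equal brute-force root-to-node path sums", {
  tr <- read_newick("((A:1,B:1):2,(C:1,D:1):2):0;")
  expect_equal(branching_times(tr), c(3, 1, 1))
  for (s in 1:5) {
    tr <- sim_tree(500 + s)
    if (length(tr$tip.label) < 2) next
    depth <- brute_node_depths(tr)
    nt <- length(tr$tip.label)
    ages <- max(depth[1:nt]) - depth[(nt + 1):(nt + tr$Nnode)]
    expect_equal(branching_times(tr), sort(ages, decreasing = TRUE),
                 tolerance = 1e-9)
  }
  expect_error(branching_times(read_newick("((A:1,B:1):1,C:1):0;")),
               "ultrametric")
})

test_that("sister pairs are exactly the two-tip monophyletic groups", {
  bal <- read_newick("((A:1,B:1):2,(C:1,D:1):2):0;")
  expect_equal(nrow(sister_pairs(bal)), 2L)
  cat4 <- read_newick("(((A:1,B:1):1,C:2):1,D:3):0;")
  expect_equal(nrow(sister_pairs(cat4)), 1L)
  expect_equal(sort(as.vector(sister_pairs(cat4))), c("A", "B"))
  for (s in 1:4) {
    tr <- sim_tree(600 + s)
    if (length(tr$tip.label) < 2) next
    got <- sister_pairs(tr)
    got <- t(apply(got, 1, sort))
    got <- got[order(got[, 1]), , drop = FALSE]
    expected <- brute_sister_pairs(tr)
    expected <- t(apply(expected, 1, sort))
    expected <- expected[order(expected[, 1]), , drop = FALSE]
    expect_equal(unname(got), unname(expected))
    # invariance to tip-label permutation
    perm <- tr
    set.seed(s)
    relab <- sample(perm$tip.label)
    names(relab) <- perm$tip.label
    perm$tip.label <- unname(relab[perm$tip.label])
    got_perm <- t(apply(sister_pairs(perm), 1, sort))
    expect_equal(nrow(got_perm), nrow(got))
    expect_setequal(apply(got_perm, 1, paste, collapse = "|"),
                    apply(t(apply(matrix(relab[got], ncol = 2), 1, sort)),
                          1, paste, collapse = "|"))
  }
})

test_that("cophenetic distances match an independent traversal and are a
          metric", {
  tr3 <- read_newick("((A:1,B:1):1,C:2):0;")
  expect_equal(cophenetic_distance(tr3, "A", "C"), 4)
  expect_equal(cophenetic_distance(tr3, "A", "B"), 2)
  expect_error(cophenetic_distance(tr3, "A", "Z"), "unknown")
  two <- read_newick("(A:3.5,B:3.5):0;")
  expect_equal(cophenetic_distance(two, "A", "B"), 7)
  tr <- sim_tree(701)
  d <- ape::cophenetic.phylo(tr)
  expect_equal(d, brute_cophenetic(tr), tolerance = 1e-9)
  # metric axioms
  expect_true(all(abs(d - t(d)) < 1e-12))
  expect_true(all(diag(d) == 0))
  minplus <- Reduce(pmin, lapply(seq_len(nrow(d)), function(k)
    outer(d[, k], d[k, ], "+")))
  expect_true(all(d <= minplus + 1e-9))
  # sister distance is exactly twice the cherry age
  sd_ <- sister_distances(tr)
  bt <- branching_times(tr)
  for (r in seq_len(nrow(sd_))) {
    m <- ape::getMRCA(tr, c(sd_$tip1[r], sd_$tip2[r]))
    age <- max(brute_node_depths(tr)[seq_along(tr$tip.label)]) -
      brute_node_depths(tr)[m]
    expect_equal(sd_$distance[r], 2 * age, tolerance = 1e-9)
  }
})

test_that("random-representative pruning induces the correct subtree", {
  # the induced species tree must reproduce, pairwise, the divergence times
  # read directly off the genealogy event records for the chosen
  # representative lineages
  for (s in 1:5) {
    g <- simulate_genealogy(pbd_params(1.13, 0.15, 0.3, duration = 6),
                            seed = 800 + s)
    tr <- sample_species_tree(g, seed = s)
    reps <- attr(tr, "representatives")
    if (length(reps) < 2) next
    d <- ape::cophenetic.phylo(tr)
    Tm <- g$params$duration
    for (i in seq_along(reps)[-length(reps)]) {
      for (j in seq(i + 1, length(reps))) {
        t_split <- genealogy_divergence(g, reps[[i]], reps[[j]])
        expect_equal(d[names(reps)[i], names(reps)[j]], 2 * (Tm - t_split),
                     tolerance = 1e-9)
      }
    }
    # ultrametric by construction
    dep <- brute_node_depths(tr)[seq_along(tr$tip.label)]
    expect_lt(max(dep) - min(dep), 1e-9)
  }
  # single-species genealogy -> one-tip tree
  g1 <- simulate_genealogy(pbd_params(0.4, 0, 0.1, duration = 3), seed = 5,
                           start = "crown_incipient")
  tr1 <- sample_species_tree(g1)
  expect_equal(length(tr1$tip.label), 1L)
  # Fig-1c style fixture: three species, multi-population species included
  tr3 <- sample_species_tree(fixture_three_species(), seed = 1)
  expect_equal(sort(tr3$tip.label), c("s1", "s2", "s3"))
  expect_equal(branching_times(tr3)[1], 6)
})

test_that("Welch's t-test reproduces the hand-computed example", {
  res <- welch_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$statistic, -sqrt(3 / 2), tolerance = 1e-9)
  expect_equal(res$df, 4)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # equal variance, equal n: Satterthwaite df reduces to 2n - 2
  x <- c(1, 2, 3, 4); y <- c(10, 11, 12, 13)
  expect_equal(welch_t(x, y)$df, 6)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})
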