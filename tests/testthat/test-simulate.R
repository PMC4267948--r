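test_that("branching-process trees are ultrametric, sized and seeded", {
  tr <- simulate_yule_tree(20, 1e-3, seed = 1)
  expect_equal(ape::Ntip(tr), 20L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-10))
  expect_identical(write_newick(simulate_yule_tree(20, 1e-3, seed = 1)),
                   write_newick(tr))
  expect_false(identical(write_newick(simulate_yule_tree(20, 1e-3,
                                                         seed = 2)),
                         write_newick(tr)))
  expect_error(simulate_yule_tree(1, 1e-3), "at least 2")
  expect_error(simulate_yule_tree(5, 0), "positive")
})

test_that("the rootmost branching interval has expected length t/2", {
  # for 3-tip trees the interval between the root split and the next split
  # is the root height minus the internal node height
  t_par <- 1e-3
  n <- 4000
  set.seed(123)
  iv <- vapply(seq_len(n), function(i) {
    tr <- simulate_yule_tree(3, t_par)
    h <- phyloerr:::node_heights(ape::reorder.phylo(tr, "postorder"))
    h[4] - h[5]  # root is node 4, the single internal split node 5
  }, numeric(1))
  se <- sd(iv) / sqrt(n)
  expect_lt(abs(mean(iv) - t_par / 2), 3 * se)
})

test_that("mean total tree length approaches (n-1) * t", {
  # each inter-split interval contributes t to the expected total length
  n <- 3000
  set.seed(321)
  tot <- vapply(seq_len(n), function(i) {
    total_length(simulate_yule_tree(10, 1e-3))
  }, numeric(1))
  se <- sd(tot) / sqrt(n)
  expect_lt(abs(mean(tot) - 9e-3), 3 * se)
})

test_that("sequence evolution follows the transition matrix", {
  m <- k2p_model(2)
  # zero-length tree: all tips identical
  star <- parse_newick("(A:0,B:0,C:0);")
  a0 <- evolve_alignment(star, m, 500, seed = 4)
  expect_true(all(a0[1, ] == a0[2, ]) && all(a0[1, ] == a0[3, ]))
  # one branch: empirical substitution frequencies match P(b)
  b <- 0.5
  t2 <- parse_newick(sprintf("(A:%g,B:0);", b))
  aln <- evolve_alignment(t2, m, 200000, seed = 5)
  P <- transition_matrix(m, b)
  for (from in c("A", "C", "G", "T")) {
    sel <- aln["B", ] == from
    for (to in c("A", "C", "G", "T")) {
      phat <- mean(aln["A", sel] == to)
      se <- sqrt(P[from, to] * (1 - P[from, to]) / sum(sel))
      expect_lt(abs(phat - P[from, to]), 4 * se)
    }
  }
  # transition:transversion counts on a short branch reflect R = 2
  t3 <- parse_newick("(A:0.02,B:0);")
  aln3 <- evolve_alignment(t3, m, 500000, seed = 6)
  diffs <- aln3["A", ] != aln3["B", ]
  ts_pairs <- c("AG", "GA", "CT", "TC")
  is_ts <- paste0(aln3["A", diffs], aln3["B", diffs]) %in% ts_pairs
  ratio <- sum(is_ts) / sum(!is_ts)
  expect_lt(abs(ratio - 2), 0.15)
})

test_that("error injection hits cells at the declared rate", {
  clean <- bernoulli_snp_alignment(20, 10000, 0, seed = 7)
  expect_identical(unclass(inject_errors(clean, 0, seed = 8)),
                   unclass(clean))
  noisy <- inject_errors(clean, 0.1, seed = 8)
  frac <- mean(unclass(noisy) != unclass(clean))
  expect_lt(abs(frac - 0.1), 4 * sqrt(0.1 * 0.9 / length(clean)))
  # segregating fraction of a constant alignment: 1 - (1-eps)^n
  seg <- snp_density(noisy) / 1000
  want <- 1 - 0.9^20
  expect_lt(abs(seg - want), 4 * sqrt(want * (1 - want) / 10000))
  # per-taxon rates hit only their taxon
  spec <- error_spec(0, per_taxon = c(t1 = 0.5))
  noisy2 <- inject_errors(clean, spec, seed = 9)
  expect_true(all(unclass(noisy2)[-1, ] == unclass(clean)[-1, ]))
  expect_gt(mean(unclass(noisy2)[1, ] != unclass(clean)[1, ]), 0.4)
  expect_error(inject_errors(alignment(c(a = "AN", b = "AC")), 0.1),
               "resolved bases")
  # determinism per seed
  expect_identical(unclass(inject_errors(clean, 0.1, seed = 8)),
                   unclass(noisy))
})

test_that("Bernoulli SNP fixtures hit their target polymorphism density", {
  expect_equal(snp_density(bernoulli_snp_alignment(10, 500, 0, seed = 1)), 0)
  expect_equal(snp_density(bernoulli_snp_alignment(10, 500, 1, seed = 1)),
               1000)
  a <- bernoulli_snp_alignment(20, 100000, 0.0472, seed = 2)
  expect_lt(abs(snp_density(a) - 47.2),
            4 * 1000 * sqrt(0.0472 * (1 - 0.0472) / 100000))
  expect_identical(
    unclass(bernoulli_snp_alignment(5, 100, 0.3, seed = 3)),
    unclass(bernoulli_snp_alignment(5, 100, 0.3, seed = 3)))
})

test_that("error injection composes with mutation density as expected", {
  # P(segregating) = 1 - (1-m)(1-eps)^n, up to rare error-reversal events
  n <- 20; m <- 0.05; eps <- 0.01; L <- 50000
  aln <- bernoulli_snp_alignment(n, L, m, seed = 10)
  obs <- inject_errors(aln, eps, seed = 11)
  want <- 1 - (1 - m) * (1 - eps)^n
  got <- snp_density(obs) / 1000
  expect_lt(abs(got - want), 4 * sqrt(want * (1 - want) / L) + m * eps)
})
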