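test_that("pairwise ML distance reduces to the closed-form K2P distance", {
  # 200 sites with exactly P = 0.1 transitions, Q = 0.05 transversions
  s1 <- rep("A", 200)
  s2 <- c(rep("G", 20), rep("C", 5), rep("T", 5), rep("A", 170))
  d <- ml_pairwise_distance(s1, s2)
  want <- -0.5 * log(1 - 2 * 0.1 - 0.05) - 0.25 * log(1 - 2 * 0.05)
  expect_equal(d, want, tolerance = 1e-6)
  expect_equal(round(want, 5), 0.17018)
  expect_equal(ml_pairwise_distance(rep("A", 50), rep("A", 50)), 0)
})

test_that("a matched declared error rate absorbs pure-miscall divergence", {
  set.seed(61)
  base <- alignment(matrix("C", 2, 4000,
                           dimnames = list(c("s1", "s2"), NULL)))
  noisy <- inject_errors(base, error_spec(0, per_taxon = c(s2 = 0.1)),
                         seed = 5)
  d <- ml_pairwise_distance(noisy["s1", ], noisy["s2", ], epsilon = 0.1)
  expect_lte(d, 1e-7)
  # undeclared, the same divergence is read as real distance
  d0 <- ml_pairwise_distance(noisy["s1", ], noisy["s2", ], epsilon = 0)
  expect_gt(d0, 0.05)
})

test_that("branch-length optimization recovers truth on abundant data", {
  true <- parse_newick("((A:0.05,B:0.07):0.2,(C:0.04,D:0.09):0.1);")
  aln <- evolve_alignment(true, k2p_model(2), 100000, seed = 71)
  fit <- optimize_branch_lengths(ape::unroot(true), aln)
  expect_lt(rfl_distance(fit$tree, true) / total_length(true), 0.05)
  # per-branch agreement via matched splits
  b_true <- bipartitions(true, include_trivial = TRUE)
  b_fit <- bipartitions(fit$tree, include_trivial = TRUE)
  for (k in seq_len(nrow(b_true))) {
    est <- b_fit$length[b_fit$split == b_true$split[k]]
    expect_lt(abs(est - b_true$length[k]), 0.05 * b_true$length[k] + 0.002)
  }
})

test_that("two-taxon optimization equals the pairwise path length", {
  aln <- alignment(c(A = paste(rep(c("A", "C", "G", "T"), 100),
                               collapse = ""),
                     B = paste(c(rep("G", 30), rep(c("A", "C", "G", "T"),
                                                   100)[-(1:30)]),
                               collapse = "")))
  t2 <- parse_newick("(A:0.05,B:0.05);")
  fit <- optimize_branch_lengths(t2, aln)
  # compare against a 1-D scan of the same fixed-ratio likelihood
  f <- function(d) log_likelihood(parse_newick(
    sprintf("(A:%.12f,B:0);", d)), aln, k2p_model(2), 0)
  dstar <- optimize(f, c(1e-6, 2), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(total_length(fit$tree), dstar, tolerance = 1e-5)
})

test_that("all-identical sequences drive every branch to the minimum", {
  aln <- alignment(c(A = "AAAA", B = "AAAA", C = "AAAA", D = "AAAA"))
  cfg <- inference_config()
  fit <- optimize_branch_lengths(parse_newick(
    "((A:0.1,B:0.1):0.1,C:0.1,D:0.1);"), aln, config = cfg)
  expect_true(all(fit$tree$edge.length <= cfg$bl_min * 10))
})

test_that("clock optimization yields ultrametric trees and true heights", {
  # 2-taxon symmetry: root height is half the optimal path length
  aln <- alignment(c(A = paste(rep(c("A", "C", "G", "T"), 100),
                               collapse = ""),
                     B = paste(c(rep("G", 30), rep(c("A", "C", "G", "T"),
                                                   100)[-(1:30)]),
                               collapse = "")))
  t2 <- parse_newick("(A:0.01,B:0.01);")
  nc <- optimize_branch_lengths(t2, aln)
  cl <- optimize_clock_heights(t2, aln)
  expect_equal(cl$tree$edge.length[1], total_length(nc$tree) / 2,
               tolerance = 1e-4)
  expect_equal(cl$tree$edge.length[1], cl$tree$edge.length[2])
  # 4-taxon clocklike data: heights recovered within 5%
  true <- parse_newick("((A:0.05,B:0.05):0.1,(C:0.08,D:0.08):0.07);")
  aln4 <- evolve_alignment(true, k2p_model(2), 100000, seed = 81)
  fit <- optimize_clock_heights(true, aln4)
  expect_true(ape::is.ultrametric(fit$tree, tol = 1e-8))
  h_true <- phyloerr:::node_heights(ape::reorder.phylo(true, "postorder"))
  h_fit <- phyloerr:::node_heights(fit$tree)
  internal <- (ape::Ntip(true) + 1):(ape::Ntip(true) + true$Nnode)
  expect_lt(max(abs(h_fit[internal] - h_true[internal]) / h_true[internal]),
            0.05)
  # random inputs still come back ultrametric
  set.seed(91)
  rt <- ape::rcoal(6)
  rt$tip.label <- paste0("t", 1:6)
  ra <- random_alignment(6, 200)
  rfit <- optimize_clock_heights(rt, ra)
  expect_true(ape::is.ultrametric(rfit$tree, tol = 1e-8))
})

test_that("tree search recovers a strong 4-taxon signal and is seeded", {
  true <- parse_newick("((A:0.05,B:0.05):0.2,(C:0.05,D:0.05):0.2);")
  aln <- evolve_alignment(true, k2p_model(2), 5000, seed = 13)
  r1 <- infer_tree(aln, inference_config(seed = 5))
  expect_equal(rf_distance(r1$tree, true), 0)
  r2 <- infer_tree(aln, inference_config(seed = 5))
  expect_identical(write_newick(r1$tree), write_newick(r2$tree))
  expect_identical(r1$loglik, r2$loglik)
  expect_error(infer_tree(aln[1:2, ], inference_config()), "at least 3")
  # clock-mode search on the same (clocklike) data
  rc <- infer_tree(aln, inference_config(clock = TRUE, seed = 5))
  expect_equal(rf_distance(rc$tree, true), 0)
  expect_true(ape::is.ultrametric(rc$tree, tol = 1e-8))
})

test_that("declaring the error on pure-noise data collapses the tree", {
  clean <- alignment(matrix("G", 5, 10000,
                            dimnames = list(paste0("t", 1:5), NULL)))
  noisy <- inject_errors(clean, 0.2, seed = 3)
  fit <- infer_tree(noisy, inference_config(declared_error = 0.2, seed = 2))
  # essentially all variable sites read as error: tiny residual lengths
  expect_lt(total_length(fit$tree), 0.02)
  # without the correction the same data support a long tree
  fit0 <- infer_tree(noisy, inference_config(declared_error = 0, seed = 2))
  expect_gt(total_length(fit0$tree), 0.5)
})

test_that("inferred tree length is non-increasing in the declared error", {
  tr <- simulate_yule_tree(6, 1e-3, seed = 19)
  aln <- evolve_alignment(tr, k2p_model(2), 1500, seed = 20)
  obs <- inject_errors(aln, 0.05, seed = 21)
  lens <- vapply(c(0, 0.02, 0.05, 0.1), function(e) {
    total_length(infer_tree(obs, inference_config(declared_error = e,
                                                  seed = 7))$tree)
  }, numeric(1))
  expect_true(all(diff(lens) < 1e-8))
})
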