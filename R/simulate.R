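# Simulation laboratory: clocklike branching-process trees, K2P sequence
# evolution, miscall-error injection, and Bernoulli SNP fixtures.
#
# All simulators are deterministic given their seed. Tree shape, sequence
# evolution and error injection take independent seeds so the same base
# data set can be re-used with different error realizations.

.seed_rng <- function(seed) {
  if (!is.null(seed)) {
    if (length(seed) != 1L || is.na(seed)) stop("seed must be a single integer")
    set.seed(as.integer(seed))
  }
}

#' Simulation settings
#'
#' @param n_taxa Number of tips per simulated tree.
#' @param t Tree-size scaling parameter: each lineage splits at rate `1/t`,
#'   so the interval between the rootward and next split has expected
#'   length `t/2`. Larger `t` means longer branches and more mutational
#'   signal.
#' @param seq_length Sites simulated per taxon.
#' @param true_error An `error_spec`: the miscall rate actually injected.
#' @param n_replicates Replicate data sets per condition.
#' @param seed Master seed.
#' @param ts_tv K2P transition/transversion ratio used for evolution.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_taxa = 20L, t = 1e-3, seq_length = 20000L,
                              true_error = error_spec(0),
                              n_replicates = 100L, seed = 1L, ts_tv = 2) {
  true_error <- as_error_spec(true_error)
  if (n_taxa < 3L) stop("n_taxa must be at least 3")
  if (!(t > 0)) stop("t must be positive")
  if (seq_length < 1L) stop("seq_length must be at least 1")
  if (n_replicates < 1L) stop("n_replicates must be at least 1")
  structure(list(n_taxa = as.integer(n_taxa), t = t,
                 seq_length = as.integer(seq_length),
                 true_error = true_error,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), ts_tv = ts_tv),
            class = "simulation_config")
}

#' Simulate a clocklike branching-process (Yule) tree
#'
#' Pure birth process with per-lineage split rate `1/t`: the process starts
#' with two lineages at the root; while fewer than `n_taxa` lineages exist
#' it waits an exponential time with rate `k/t` (k = current lineage count)
#' and splits a uniformly chosen lineage; after reaching `n_taxa` lineages
#' a final exponential interval with rate `n_taxa/t` is appended and all
#' lineages are cut, so every tip lies at the same time (ultrametric) and
#' terminal branches are non-degenerate.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param t Tree-size scaling parameter (> 0).
#' @param seed Optional seed.
#' @return A rooted ultrametric `ape::phylo` tree with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n_taxa, t, seed = NULL) {
  if (n_taxa < 2L) stop("n_taxa must be at least 2")
  if (!(t > 0)) stop("t must be positive")
  .seed_rng(seed)
  # lineage bookkeeping: each lineage is an edge from its parent split
  # node; node 1 is the root split at time 0
  parent_node <- c(1L, 1L)   # per active lineage
  start_time <- c(0, 0)
  next_node <- 2L
  edges <- list()            # (parent, child, length)
  now <- 0
  k <- 2L
  while (k < n_taxa) {
    now <- now + stats::rexp(1L, rate = k / t)
    i <- sample.int(k, 1L)
    node <- next_node; next_node <- next_node + 1L
    edges[[length(edges) + 1L]] <- c(parent_node[i], node, now - start_time[i])
    parent_node[i] <- node; start_time[i] <- now
    parent_node <- append(parent_node, node, after = i)
    start_time <- append(start_time, now, after = i)
    k <- k + 1L
  }
  now <- now + stats::rexp(1L, rate = n_taxa / t)
  tip_ids <- next_node + seq_len(n_taxa) - 1L
  for (i in seq_len(n_taxa)) {
    edges[[length(edges) + 1L]] <- c(parent_node[i], tip_ids[i],
                                     now - start_time[i])
  }
  em <- do.call(rbind, edges)
  labels <- stats::setNames(paste0("t", seq_len(n_taxa)), tip_ids)
  build_phylo(as.integer(em[, 1L]), as.integer(em[, 2L]), em[, 3L], labels)
}

#' Evolve sequences along a tree under K2P
#'
#' The root sequence is drawn uniformly over A,C,G,T per site; along each
#' branch every site mutates independently according to the K2P transition
#' matrix for that branch length. Only resolved bases are produced.
#'
#' @param tree A tree with finite branch lengths.
#' @param model A `k2p_model`.
#' @param seq_length Number of sites.
#' @param seed Optional seed.
#' @return An alignment with one row per tip.
#' @export
evolve_alignment <- function(tree, model = k2p_model(), seq_length,
                             seed = NULL) {
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and non-negative")
  }
  .seed_rng(seed)
  bases <- c("A", "C", "G", "T")
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  ntot <- ape::Ntip(tr) + tr$Nnode
  seqs <- matrix(0L, ntot, seq_length)
  root <- tr$edge[1L, 1L]
  seqs[root, ] <- sample.int(4L, seq_length, replace = TRUE)
  for (e in seq_len(nrow(tr$edge))) {
    P <- transition_matrix(model, tr$edge.length[e])
    cum <- t(apply(P, 1L, cumsum))
    par <- seqs[tr$edge[e, 1L], ]
    r <- stats::runif(seq_length)
    seqs[tr$edge[e, 2L], ] <- 1L + (r > cum[cbind(par, 1L)]) +
      (r > cum[cbind(par, 2L)]) + (r > cum[cbind(par, 3L)])
  }
  m <- matrix(bases[seqs[seq_len(ape::Ntip(tr)), ]], nrow = ape::Ntip(tr))
  rownames(m) <- tr$tip.label
  alignment(m)
}

#' Inject miscall errors into a resolved-base alignment
#'
#' Each base is independently replaced, with its taxon's epsilon, by one of
#' the three other bases chosen uniformly. Error injection precedes any
#' ambiguity coding, so the input must contain resolved bases only.
#'
#' @param aln An alignment of A,C,G,T only.
#' @param spec An `error_spec` (or bare epsilon): the true error rate(s).
#' @param seed Optional seed.
#' @return The alignment with errors applied.
#' @export
inject_errors <- function(aln, spec, seed = NULL) {
  aln <- as_alignment(aln)
  spec <- as_error_spec(spec)
  if (any(!(aln %in% c("A", "C", "G", "T")))) {
    stop("error injection requires resolved bases only (A, C, G, T)")
  }
  extra <- setdiff(names(spec$per_taxon), rownames(aln))
  if (length(extra)) {
    stop("per-taxon epsilon given for unknown taxon '", extra[1L], "'")
  }
  .seed_rng(seed)
  eps <- vapply(rownames(aln), function(tx) effective_epsilon(spec, tx),
                numeric(1L))
  bases <- c("A", "C", "G", "T")
  code <- matrix(match(aln, bases), nrow = nrow(aln))
  hit <- matrix(stats::runif(length(code)) < eps[row(code)],
                nrow = nrow(code))
  nhit <- sum(hit)
  if (nhit > 0L) {
    shift <- sample.int(3L, nhit, replace = TRUE)
    code[hit] <- ((code[hit] - 1L + shift) %% 4L) + 1L
  }
  out <- matrix(bases[code], nrow = nrow(aln),
                dimnames = list(rownames(aln), NULL))
  alignment(out)
}

#' Bernoulli single-SNP alignment fixture
#'
#' Each site independently: with probability `m` the site is polymorphic --
#' one uniformly chosen taxon carries a uniformly chosen base different
#' from the uniformly chosen base shared by all other taxa; otherwise all
#' taxa are identical at the site. A direct generator for alignments of a
#' given mutation-polymorphism density (segregating sites per site).
#'
#' @param n_taxa Number of taxa.
#' @param seq_length Number of sites.
#' @param m Per-site polymorphism probability in `[0, 1]`.
#' @param seed Optional seed.
#' @return An alignment with taxa `t1..tn`.
#' @export
bernoulli_snp_alignment <- function(n_taxa, seq_length, m, seed = NULL) {
  if (m < 0 || m > 1) stop("m must lie in [0, 1]")
  .seed_rng(seed)
  bases <- c("A", "C", "G", "T")
  shared <- sample.int(4L, seq_length, replace = TRUE)
  code <- matrix(rep(shared, each = n_taxa), nrow = n_taxa)
  poly <- which(stats::runif(seq_length) < m)
  if (length(poly)) {
    carrier <- sample.int(n_taxa, length(poly), replace = TRUE)
    shift <- sample.int(3L, length(poly), replace = TRUE)
    code[cbind(carrier, poly)] <-
      ((shared[poly] - 1L + shift) %% 4L) + 1L
  }
  out <- matrix(bases[code], nrow = n_taxa,
                dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
  alignment(out)
}
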