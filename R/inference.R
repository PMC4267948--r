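# Maximum likelihood inference: branch-length optimization and topology
# search, with (Dnamlk-style) or without (Dnaml-style) a molecular clock.
#
# Each branch (or node height) is optimized by bounded one-dimensional
# Brent search on the pruning log-likelihood, swept until the gain per
# sweep drops below `tol_lnl`. Branch lengths are searched on a log scale,
# which keeps resolution uniform across the orders of magnitude between
# `bl_min` and `bl_max` and is robust where the error model flattens the
# likelihood surface near zero length. Topology search is seeded
# random-order stepwise addition followed by nearest-neighbor-interchange
# sweeps; the log-likelihood never decreases along the trajectory because
# every move is accepted only on improvement.

#' Inference settings
#'
#' @param clock Assume a molecular clock (rooted, ultrametric output)?
#' @param declared_error An `error_spec` (or bare epsilon): the error rate
#'   assumed during inference. It is a fixed input, never estimated.
#' @param ts_tv K2P transition/transversion ratio.
#' @param seed Integer seed driving the taxon addition order.
#' @param bl_min,bl_max Branch length search bounds.
#' @param tol_lnl Convergence threshold on the log-likelihood gain per sweep.
#' @param max_passes Maximum optimization sweeps.
#' @return An `inference_config` object.
#' @export
inference_config <- function(clock = FALSE, declared_error = error_spec(0),
                             ts_tv = 2, seed = 1L, bl_min = 1e-8,
                             bl_max = 100, tol_lnl = 1e-6,
                             max_passes = 20L) {
  declared_error <- as_error_spec(declared_error)
  if (!(bl_min > 0 && bl_min < bl_max)) stop("need 0 < bl_min < bl_max")
  if (!(tol_lnl > 0)) stop("tol_lnl must be positive")
  if (length(seed) != 1L || is.na(seed)) stop("seed must be a single integer")
  structure(list(clock = clock, declared_error = declared_error,
                 ts_tv = ts_tv, seed = as.integer(seed), bl_min = bl_min,
                 bl_max = bl_max, tol_lnl = tol_lnl,
                 max_passes = as.integer(max_passes)),
            class = "inference_config")
}

# Maximize f over branch length b in [bl_min, bl_max] on a log scale.
# Returns list(b, value). `f` takes the branch length.
maximize_branch <- function(f, bl_min, bl_max, rel_tol = 1e-5) {
  opt <- stats::optimize(function(u) f(exp(u)),
                         c(log(bl_min), log(bl_max)),
                         maximum = TRUE, tol = rel_tol)
  list(b = exp(opt$maximum), value = opt$objective)
}

#' Two-taxon maximum likelihood distance
#'
#' Maximizes the two-sequence likelihood over the total path length
#' separating the sequences, profiling the transition/transversion ratio
#' (the two K2P rates are free, as in the classical two-parameter distance
#' estimator). With `epsilon = 0` this equals the closed-form K2P distance
#' `-log(1-2P-Q)/2 - log(1-2Q)/4` for observed transition and transversion
#' proportions P and Q. Saturated data (no finite optimum) return `bl_max`
#' with a warning.
#'
#' @param seq1,seq2 Equal-length sequences (strings or symbol vectors).
#' @param model A `k2p_model`; its ratio seeds the profile search.
#' @param epsilon Declared error rate applied to both sequences.
#' @param bl_max Upper search bound.
#' @return Estimated distance in expected substitutions per site.
#' @export
ml_pairwise_distance <- function(seq1, seq2, model = k2p_model(),
                                 epsilon = 0, bl_max = 100) {
  aln <- alignment(c(s1 = paste(if (length(seq1) > 1) seq1 else
                                  strsplit(seq1, "")[[1L]], collapse = ""),
                     s2 = paste(if (length(seq2) > 1) seq2 else
                                  strsplit(seq2, "")[[1L]], collapse = "")))
  pat <- compress_patterns(aln)
  spec <- as_error_spec(epsilon)
  v1 <- tip_partials(pat$patterns["s1", ], "s1", spec)
  v2 <- tip_partials(pat$patterns["s2", ], "s2", spec)
  w <- pat$weights
  lnl <- function(d, ratio) {
    P <- .k2p_pmat_cpp(ratio / (ratio + 1), 1 / (2 * (ratio + 1)), d)
    sum(w * log(0.25 * colSums(v1 * (P %*% v2))))
  }
  f <- function(d) {  # profile out the ts/tv ratio
    if (d == 0) return(lnl(0, model$ts_tv))
    stats::optimize(function(u) lnl(d, exp(u)), c(log(1e-4), log(1e4)),
                    maximum = TRUE, tol = 1e-9)$objective
  }
  opt <- maximize_branch(f, 1e-12, bl_max, rel_tol = 1e-9)
  at0 <- f(0)
  if (at0 >= opt$value) return(0)
  if (opt$b > bl_max * (1 - 1e-6)) {
    warning("saturated sequence pair: distance capped at bl_max")
    return(bl_max)
  }
  opt$b
}

# One sweep-style optimizer over selected edges of a pruning context.
# Per edge, the above/below partial caches make the 1-D objective O(npat)
# per evaluation. Returns updated lengths and the (non-decreasing)
# log-likelihood.
sweep_branches <- function(ctx, elen, config, edges = seq_along(elen),
                           passes = config$max_passes, rel_tol = 1e-5) {
  cur <- ctx_loglik(ctx, elen)
  for (p in seq_len(passes)) {
    prev <- cur
    for (i in edges) {
      prep <- .edge_partials_cpp(ctx$edge, elen, ctx$ntip, ctx$nnode,
                                 ctx$tipp, ctx$alpha, ctx$beta, i)
      opt <- maximize_branch(function(b) {
        .edge_loglik_cpp(prep$A, prep$D, prep$scale, ctx$w,
                         ctx$alpha, ctx$beta, b)
      }, config$bl_min, config$bl_max, rel_tol)
      if (opt$value > cur) {
        elen[i] <- opt$b
        cur <- opt$value
      }
    }
    if (cur - prev < config$tol_lnl) break
  }
  list(elen = elen, loglik = cur)
}

#' Optimize all branch lengths of a fixed topology (no clock)
#'
#' Iterates bounded one-dimensional likelihood maximization per branch in
#' sweeps until the log-likelihood gain per sweep falls below
#' `config$tol_lnl` or `config$max_passes` is reached. The log-likelihood
#' is non-decreasing across the whole procedure.
#'
#' @param tree Tree with the taxa of `x` at its tips.
#' @param x An alignment or `site_patterns`.
#' @param model A `k2p_model`.
#' @param spec An `error_spec` (declared error).
#' @param config An `inference_config`.
#' @return `list(tree = <tree with updated lengths>, loglik = <lnL>)`.
#' @export
optimize_branch_lengths <- function(tree, x, model = k2p_model(),
                                    spec = error_spec(0),
                                    config = inference_config()) {
  patterns <- as_site_patterns(x)
  spec <- as_error_spec(spec)
  ctx <- pruning_context(tree, patterns, model, spec)
  res <- sweep_branches(ctx, pmax(ctx$elen, config$bl_min), config)
  out <- ctx$tree
  out$edge.length <- res$elen
  list(tree = out, loglik = res$loglik)
}

# ---- clock (ultrametric) machinery -------------------------------------

# Node heights above the tips, computed bottom-up (exact for ultrametric
# trees; for others, the smallest heights consistent with the edges).
node_heights <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  h <- numeric(ape::Ntip(tr) + tr$Nnode)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    h[p] <- max(h[p], h[ch] + tr$edge.length[e])
  }
  h[seq_len(ape::Ntip(tr))] <- 0
  h
}

heights_to_lengths <- function(edge, h) h[edge[, 1L]] - h[edge[, 2L]]

# Sweep node-height optimization on a fixed rooted topology.
sweep_heights <- function(ctx, h, config, nodes = NULL,
                          passes = config$max_passes) {
  edge <- ctx$edge
  parent_of <- integer(ctx$nnode)
  parent_of[edge[, 2L]] <- edge[, 1L]
  root <- edge[nrow(edge), 1L]
  if (is.null(nodes)) {
    nodes <- unique(edge[, 1L])  # postorder: children before parents
  }
  cur <- ctx_loglik(ctx, heights_to_lengths(edge, h))
  for (p in seq_len(passes)) {
    prev <- cur
    for (u in nodes) {
      lo <- max(h[edge[edge[, 1L] == u, 2L]])
      hi <- if (u == root) lo + config$bl_max else h[parent_of[u]]
      if (hi - lo < 1e-12) next
      f <- function(hu) {
        hh <- h; hh[u] <- hu
        tryCatch(ctx_loglik(ctx, heights_to_lengths(edge, hh)),
                 error = function(e) -Inf)
      }
      # search the offset above the highest child on a log scale: height
      # optima are often tiny relative to the (bl_max-wide) root interval
      opt <- stats::optimize(function(u_) f(lo + exp(u_)),
                             c(log(1e-12), log(hi - lo)),
                             maximum = TRUE, tol = 1e-6)
      cand_h <- lo + exp(opt$maximum)
      cand <- opt$objective
      at_lo <- f(lo)
      if (at_lo > cand) {
        cand_h <- lo
        cand <- at_lo
      }
      if (cand > cur) {
        h[u] <- cand_h
        cur <- cand
      }
    }
    if (cur - prev < config$tol_lnl) break
  }
  list(h = h, loglik = cur)
}

#' Optimize node heights of a fixed rooted topology under a clock
#'
#' Each internal node height is optimized by bounded one-dimensional search
#' between its highest child and its parent (the root upward bound is
#' `bl_max` above its children), swept until convergence. The output tree
#' is ultrametric: tips at height 0, branch length = parent height minus
#' child height.
#'
#' @inheritParams optimize_branch_lengths
#' @return `list(tree = <ultrametric tree>, loglik = <lnL>)`.
#' @export
optimize_clock_heights <- function(tree, x, model = k2p_model(),
                                   spec = error_spec(0),
                                   config = inference_config(clock = TRUE)) {
  if (!ape::is.rooted(tree)) stop("clock optimization requires a rooted tree")
  patterns <- as_site_patterns(x)
  spec <- as_error_spec(spec)
  ctx <- pruning_context(tree, patterns, model, spec)
  h <- node_heights(ctx$tree)
  res <- sweep_heights(ctx, h, config)
  out <- ctx$tree
  out$edge.length <- heights_to_lengths(ctx$edge, res$h)
  list(tree = out, loglik = res$loglik)
}

# ---- topology search ---------------------------------------------------

# Pairwise ML distance matrix used to initialize branch lengths.
pairwise_distances <- function(aln, model, spec, bl_max) {
  n <- nrow(aln)
  D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      eps <- max(effective_epsilon(spec, rownames(aln)[i]),
                 effective_epsilon(spec, rownames(aln)[j]))
      d <- suppressWarnings(
        ml_pairwise_distance(aln[i, ], aln[j, ], model, eps, bl_max))
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

# Rows of the (postorder) context tree touching the tip named `label`:
# its pendant edge plus the two halves of the bisected edge.
edges_touching_tip <- function(tr, label) {
  tipid <- match(label, tr$tip.label)
  pend <- which(tr$edge[, 2L] == tipid)
  w <- tr$edge[pend, 1L]
  sort(unique(c(pend, which(tr$edge[, 1L] == w | tr$edge[, 2L] == w))))
}

infer_nonclock <- function(aln, patterns, model, spec, config) {
  labels <- sample(rownames(aln))
  partials <- taxon_partials(patterns, spec)
  D <- pairwise_distances(aln, model, spec, config$bl_max)
  sub_patterns <- function(labs) {
    list(taxa = labs, patterns = patterns$patterns[labs, , drop = FALSE],
         weights = patterns$weights, n_sites = patterns$n_sites)
  }
  # starting 3-taxon star with additive initial lengths
  l3 <- labels[1:3]
  d3 <- vapply(1:3, function(i) {
    j <- l3[-i]
    max(config$bl_min,
        (D[l3[i], j[1]] + D[l3[i], j[2]] - D[j[1], j[2]]) / 2)
  }, numeric(1))
  tree <- build_phylo(parent = c(4L, 4L, 4L), child = 1:3, len = d3,
                      tip_labels = stats::setNames(l3, 1:3))
  fit <- function(tr, labs, passes = config$max_passes, edges = NULL) {
    ctx <- pruning_context(tr, sub_patterns(labs), model, spec, partials)
    if (is.null(edges)) edges <- seq_along(ctx$elen)
    res <- sweep_branches(ctx, pmax(ctx$elen, config$bl_min), config,
                          edges = edges, passes = passes)
    out <- ctx$tree
    out$edge.length <- res$elen
    list(tree = out, loglik = res$loglik)
  }
  cur <- fit(tree, l3)
  in_tree <- l3
  for (tx in labels[-(1:3)]) {
    pend0 <- max(config$bl_min, min(D[tx, in_tree]) / 2)
    in_tree <- c(in_tree, tx)
    best <- NULL
    for (e in seq_len(nrow(cur$tree$edge))) {
      cand <- attach_tip(cur$tree, e, tx, pend0)
      loc <- fit(cand, in_tree, passes = 1L,
                 edges = edges_touching_tip(
                   ape::reorder.phylo(cand, "postorder"), tx))
      if (is.null(best) || loc$loglik > best$loglik) best <- loc
    }
    cur <- fit(best$tree, in_tree, passes = 3L)
  }
  # NNI sweeps until no rearrangement improves lnL by more than tol_lnl
  for (round in seq_len(10L)) {
    improved <- FALSE
    internal <- which(cur$tree$edge[, 2L] > ape::Ntip(cur$tree))
    for (e in internal) {
      for (nb in nni_neighbors(cur$tree, e)) {
        u <- cur$tree$edge[e, 1L]; v <- cur$tree$edge[e, 2L]
        nbp <- ape::reorder.phylo(nb, "postorder")
        central <- which(nbp$edge[, 1L] == u & nbp$edge[, 2L] == v)
        loc <- fit(nb, in_tree, passes = 1L, edges = central)
        if (loc$loglik > cur$loglik + config$tol_lnl) {
          full <- fit(loc$tree, in_tree, passes = 3L)
          if (full$loglik > cur$loglik + config$tol_lnl) {
            cur <- full
            improved <- TRUE
            break
          }
        }
      }
    }
    if (!improved) break
  }
  fit(cur$tree, in_tree)
}

# Attach a tip above the current root of a rooted tree: new root at height
# `new_h`, old root and the new tip as its children.
attach_root_tip <- function(tree, label, new_h) {
  h <- node_heights(tree)
  ntot <- ape::Ntip(tree) + tree$Nnode
  root <- ape::Ntip(tree) + 1L
  newroot <- ntot + 1L
  newtip <- ntot + 2L
  parent <- c(tree$edge[, 1L], newroot, newroot)
  child <- c(tree$edge[, 2L], root, newtip)
  len <- c(tree$edge.length, new_h - h[root], new_h)
  tips <- stats::setNames(c(tree$tip.label, label),
                          c(seq_len(ape::Ntip(tree)), newtip))
  build_phylo(parent, child, len, tips)
}

# Clock attachment on an edge: new node w at height hw on edge (p -> c),
# pendant from w down to the new tip at height 0.
attach_clock_tip <- function(tree, edge_idx, label, hw) {
  h <- node_heights(tree)
  ntot <- ape::Ntip(tree) + tree$Nnode
  w <- ntot + 1L
  newtip <- ntot + 2L
  p <- tree$edge[edge_idx, 1L]
  ch <- tree$edge[edge_idx, 2L]
  parent <- c(tree$edge[-edge_idx, 1L], p, w, w)
  child <- c(tree$edge[-edge_idx, 2L], w, ch, newtip)
  len <- c(tree$edge.length[-edge_idx], h[p] - hw, hw - h[ch], hw)
  tips <- stats::setNames(c(tree$tip.label, label),
                          c(seq_len(ape::Ntip(tree)), newtip))
  build_phylo(parent, child, len, tips)
}

# Raise internal node heights minimally so every parent is at least as
# high as its children (needed after a rooted NNI swap).
repair_heights <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  h <- numeric(ape::Ntip(tr) + tr$Nnode)
  hs <- node_heights(tr)
  # keep each internal node's height, but never below its children
  depth_first <- unique(tr$edge[, 1L])
  h <- hs
  for (u in depth_first) {
    kids <- tr$edge[tr$edge[, 1L] == u, 2L]
    h[u] <- max(h[u], max(h[kids]) + 0)
  }
  tr$edge.length <- heights_to_lengths(tr$edge, h)
  tr
}

infer_clock <- function(aln, patterns, model, spec, config) {
  labels <- sample(rownames(aln))
  partials <- taxon_partials(patterns, spec)
  D <- pairwise_distances(aln, model, spec, config$bl_max)
  sub_patterns <- function(labs) {
    list(taxa = labs, patterns = patterns$patterns[labs, , drop = FALSE],
         weights = patterns$weights, n_sites = patterns$n_sites)
  }
  fit <- function(tr, labs, passes = config$max_passes) {
    ctx <- pruning_context(tr, sub_patterns(labs), model, spec, partials)
    res <- sweep_heights(ctx, node_heights(ctx$tree), config,
                         passes = passes)
    out <- ctx$tree
    out$edge.length <- heights_to_lengths(ctx$edge, res$h)
    list(tree = out, loglik = res$loglik)
  }
  l2 <- labels[1:2]
  h0 <- max(config$bl_min, D[l2[1], l2[2]] / 2)
  tree <- build_phylo(parent = c(3L, 3L), child = 1:2, len = c(h0, h0),
                      tip_labels = stats::setNames(l2, 1:2))
  cur <- fit(tree, l2)
  in_tree <- l2
  for (tx in labels[-(1:2)]) {
    in_tree <- c(in_tree, tx)
    best <- NULL
    h <- node_heights(cur$tree)
    for (e in seq_len(nrow(cur$tree$edge))) {
      p <- cur$tree$edge[e, 1L]; ch <- cur$tree$edge[e, 2L]
      hw <- (h[p] + h[ch]) / 2
      if (hw <= 0) hw <- h[p] / 2
      if (hw <= 0) next
      cand <- attach_clock_tip(cur$tree, e, tx, hw)
      loc <- fit(cand, in_tree, passes = 1L)
      if (is.null(best) || loc$loglik > best$loglik) best <- loc
    }
    root_h <- h[ape::Ntip(cur$tree) + 1L]
    cand <- attach_root_tip(cur$tree, tx,
                            max(root_h * 1.5, root_h + config$bl_min * 10,
                                D[tx, in_tree[1]] / 2))
    loc <- fit(cand, in_tree, passes = 1L)
    if (is.null(best) || loc$loglik > best$loglik) best <- loc
    cur <- fit(best$tree, in_tree, passes = 3L)
  }
  for (round in seq_len(10L)) {
    improved <- FALSE
    internal <- which(cur$tree$edge[, 2L] > ape::Ntip(cur$tree))
    for (e in internal) {
      for (nb in nni_neighbors(cur$tree, e)) {
        loc <- fit(repair_heights(nb), in_tree, passes = 1L)
        if (loc$loglik > cur$loglik + config$tol_lnl) {
          full <- fit(loc$tree, in_tree, passes = 3L)
          if (full$loglik > cur$loglik + config$tol_lnl) {
            cur <- full
            improved <- TRUE
            break
          }
        }
      }
    }
    if (!improved) break
  }
  fit(cur$tree, in_tree)
}

#' Infer a maximum likelihood tree
#'
#' Seeded random-order stepwise addition (each added taxon is tried on
#' every branch, the best placement kept) followed by
#' nearest-neighbor-interchange sweeps over all internal edges until no
#' rearrangement improves the log-likelihood by more than `tol_lnl`.
#' Deterministic for a fixed `config$seed`. With `config$clock = TRUE` the
#' search works on rooted ultrametric trees and optimizes node heights;
#' otherwise on unrooted trees with free branch lengths.
#'
#' @param aln An alignment of at least 3 taxa.
#' @param config An `inference_config`.
#' @return `list(tree = <phylo>, loglik = <lnL>)`.
#' @export
infer_tree <- function(aln, config = inference_config()) {
  aln <- as_alignment(aln)
  if (nrow(aln) < 3L) stop("tree inference requires at least 3 taxa")
  patterns <- compress_patterns(aln)
  model <- k2p_model(config$ts_tv)
  spec <- config$declared_error
  set.seed(config$seed)
  if (config$clock) {
    infer_clock(aln, patterns, model, spec, config)
  } else {
    infer_nonclock(aln, patterns, model, spec, config)
  }
}
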