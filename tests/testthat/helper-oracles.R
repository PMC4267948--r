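# Independent oracles used across the suite. These deliberately avoid the
# package's own pruning/closed-form code paths: transition probabilities
# come from a matrix exponential, likelihoods from exhaustive enumeration
# of internal-node states, and splits from graph components.

# K2P rate matrix (A,C,G,T), normalized to one expected substitution per
# unit branch length, exponentiated with Matrix::expm.
expm_k2p <- function(ts_tv, b) {
  a <- ts_tv / (ts_tv + 1)
  be <- 1 / (2 * (ts_tv + 1))
  Q <- matrix(be, 4, 4)
  Q[1, 3] <- Q[3, 1] <- Q[2, 4] <- Q[4, 2] <- a
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  as.matrix(Matrix::expm(Q * b))
}

# Tip observation probabilities straight from the error model's defining
# rule (set membership), without the package's lookup table.
oracle_tip_vec <- function(symbol, eps) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"), `-` = c("A", "C", "G", "T"),
               `?` = c("A", "C", "G", "T"))
  S <- sets[[symbol]]
  k <- length(S)
  vapply(c("A", "C", "G", "T"), function(x) {
    if (x %in% S) 1 - eps + (k - 1) * eps / 3 else k * eps / 3
  }, numeric(1))
}

# Exhaustive log-likelihood: sum over all assignments of states to the
# internal nodes, products of matrix-exponential transition probabilities
# along edges, uniform 1/4 root frequencies. Feasible for <= 6 taxa.
brute_force_loglik <- function(tree, aln, ts_tv, eps) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  internal <- sort(unique(tr$edge[, 1L]))
  Ps <- lapply(seq_len(nrow(tr$edge)),
               function(e) expm_k2p(ts_tv, tr$edge.length[e]))
  nint <- length(internal)
  states <- as.matrix(expand.grid(rep(list(1:4), nint)))
  lnl <- 0
  for (site in seq_len(ncol(aln))) {
    tipv <- lapply(seq_len(ntip), function(i) {
      oracle_tip_vec(aln[tr$tip.label[i], site], eps)
    })
    tot <- 0
    for (a in seq_len(nrow(states))) {
      st <- integer(ntip + tr$Nnode)
      st[internal] <- states[a, ]
      p <- 0.25
      for (e in seq_len(nrow(tr$edge))) {
        par <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
        if (ch <= ntip) {
          p <- p * sum(Ps[[e]][st[par], ] * tipv[[ch]])
        } else {
          p <- p * Ps[[e]][st[par], st[ch]]
        }
      }
      tot <- tot + p
    }
    lnl <- lnl + log(tot)
  }
  lnl
}

# All splits of a tree by deleting each edge of the unrooted tree and
# reading off the tip component, via graph traversal (igraph).
oracle_splits <- function(tree) {
  tr <- phyloerr:::unroot_safely(tree)
  g <- igraph::graph_from_edgelist(apply(tr$edge, 2L, as.character),
                                   directed = FALSE)
  ntip <- ape::Ntip(tr)
  labels <- tr$tip.label
  res <- list()
  for (e in seq_len(nrow(tr$edge))) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(
      g, as.character(tr$edge[e, ])))
    comp <- igraph::components(g2)$membership
    side <- as.integer(names(comp)[comp == comp[as.character(tr$edge[e, 2L])]])
    side_tips <- sort(labels[side[side <= ntip]])
    other <- sort(setdiff(labels, side_tips))
    key <- if (labels[order(labels)[1L]] %in% side_tips) {
      paste(side_tips, collapse = "|")
    } else {
      paste(other, collapse = "|")
    }
    res[[e]] <- list(key = key, length = tr$edge.length[e],
                     trivial = length(side_tips) %in% c(1L, ntip - 1L))
  }
  res
}

oracle_rf <- function(t1, t2) {
  s1 <- vapply(Filter(function(x) !x$trivial, oracle_splits(t1)),
               `[[`, character(1), "key")
  s2 <- vapply(Filter(function(x) !x$trivial, oracle_splits(t2)),
               `[[`, character(1), "key")
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

oracle_rfl <- function(t1, t2) {
  f <- function(t) {
    sp <- oracle_splits(t)
    stats::setNames(vapply(sp, `[[`, numeric(1), "length"),
                    vapply(sp, `[[`, character(1), "key"))
  }
  l1 <- f(t1); l2 <- f(t2)
  keys <- union(names(l1), names(l2))
  g1 <- ifelse(keys %in% names(l1), l1[keys], 0)
  g2 <- ifelse(keys %in% names(l2), l2[keys], 0)
  sum(abs(g1 - g2))
}

# Random binary tree with exponential branch lengths, for property tests.
random_tree <- function(ntip, mean_bl = 0.1) {
  tr <- ape::rtree(ntip, br = function(n) stats::rexp(n, 1 / mean_bl))
  tr$tip.label <- paste0("t", seq_len(ntip))
  tr
}

random_alignment <- function(ntip, nsites,
                             symbols = c("A", "C", "G", "T")) {
  m <- matrix(sample(symbols, ntip * nsites, replace = TRUE), nrow = ntip,
              dimnames = list(paste0("t", seq_len(ntip)), NULL))
  alignment(m)
}
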