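# Pruning (peeling) log-likelihood with error-adjusted tips.
#
# Conditional likelihood 4-vectors propagate from the tips to the root; the
# tip vectors are the error model's observation probabilities, the root is
# closed with the K2P stationary frequencies (1/4 each). The inner loop
# lives in C++ (src/pruning.cpp); this file builds the inputs and caches
# everything that does not change while branch lengths are being optimized.

# Per-taxon tip partial matrices (4 x npat each), named list.
taxon_partials <- function(patterns, spec) {
  spec <- as_error_spec(spec)
  if (!is.null(spec$per_taxon)) {
    extra <- setdiff(names(spec$per_taxon), patterns$taxa)
    if (length(extra)) {
      stop("per-taxon epsilon given for unknown taxon '", extra[1L], "'")
    }
  }
  out <- lapply(patterns$taxa, function(tx) {
    tip_partials(patterns$patterns[tx, ], tx, spec)
  })
  names(out) <- patterns$taxa
  out
}

# Everything the C++ pruning needs for one topology; branch lengths are
# supplied separately so 1-D optimization re-uses the context.
pruning_context <- function(tree, patterns, model, spec,
                            partials = NULL) {
  if (!setequal(tree$tip.label, patterns$taxa)) {
    stop("tree tips and alignment taxa differ")
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  if (is.null(partials)) partials <- taxon_partials(patterns, spec)
  tipp <- do.call(rbind, partials[tr$tip.label])
  list(edge = tr$edge,
       elen = tr$edge.length,
       ntip = ntip,
       nnode = ntip + tr$Nnode,
       tipp = tipp,
       w = as.numeric(patterns$weights),
       alpha = model$alpha,
       beta = model$beta,
       tree = tr)
}

ctx_loglik <- function(ctx, elen = ctx$elen) {
  .pruning_loglik_cpp(ctx$edge, elen, ctx$ntip, ctx$nnode, ctx$tipp,
                      ctx$w, ctx$alpha, ctx$beta)
}

#' Log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning under the K2P model with error-adjusted tip vectors:
#' for each site pattern, `L = sum_x pi_x L_root(x)` with `pi = 1/4` and
#' `L_u(x) = prod_children sum_y P_xy(b_c) L_c(y)`; the returned value is
#' the weighted sum of pattern log-likelihoods (natural log). Per-node
#' rescaling keeps the computation stable for large trees and alignments.
#'
#' @param tree An `ape::phylo` tree whose tips exactly match the taxa.
#' @param x An alignment or a `site_patterns` object.
#' @param model A `k2p_model`.
#' @param spec An `error_spec` (or bare epsilon) giving the declared error
#'   rate(s).
#' @return The natural-log likelihood (a single number).
#' @examples
#' aln <- alignment(c(A = "ACGT", B = "ACGA", C = "ACTT"))
#' tr <- parse_newick("(A:0.1,B:0.1,C:0.1);")
#' log_likelihood(tr, aln, k2p_model(2), error_spec(0.01))
#' @export
log_likelihood <- function(tree, x, model = k2p_model(),
                           spec = error_spec(0)) {
  patterns <- as_site_patterns(x)
  spec <- as_error_spec(spec)
  ctx <- pruning_context(tree, patterns, model, spec)
  ctx_loglik(ctx)
}
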