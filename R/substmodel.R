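# Kimura 2-parameter substitution model.
#
# Rates are normalized so that one unit of branch length equals one expected
# substitution per site: alpha + 2*beta = 1, where alpha is the rate of the
# single transition from each base (A<->G, C<->T) and beta the rate to each
# of the two transversion targets. The transition/transversion ratio
# R = alpha / (2*beta) is the ratio of total transition to total
# transversion rate; R = 0.5 recovers Jukes-Cantor.

#' Build a Kimura 2-parameter model
#'
#' @param ts_tv Transition/transversion ratio R (total transition rate over
#'   total transversion rate), positive. Default 2.
#' @return A `k2p_model` with fields `ts_tv`, `alpha` = R/(R+1) and
#'   `beta` = 1/(2(R+1)).
#' @examples
#' k2p_model(2)   # alpha = 2/3, beta = 1/6
#' @export
k2p_model <- function(ts_tv = 2) {
  if (!is.numeric(ts_tv) || length(ts_tv) != 1L || !is.finite(ts_tv) ||
      ts_tv <= 0) {
    stop("ts_tv ratio must be a positive finite number")
  }
  structure(list(ts_tv = ts_tv,
                 alpha = ts_tv / (ts_tv + 1),
                 beta  = 1 / (2 * (ts_tv + 1))),
            class = "k2p_model")
}

#' @export
print.k2p_model <- function(x, ...) {
  cat(sprintf("K2P model: ts/tv ratio %g (alpha = %.6g, beta = %.6g)\n",
              x$ts_tv, x$alpha, x$beta))
  invisible(x)
}

#' K2P transition probability matrix
#'
#' Closed form for the probability of ending in base `y` given start base
#' `x` after a branch of length `b` expected substitutions per site:
#' the transition pair has probability
#' `1/4 + exp(-4 beta b)/4 - exp(-2 (alpha+beta) b)/2`, each transversion
#' `1/4 - exp(-4 beta b)/4`, and the diagonal the complement.
#'
#' @param model A `k2p_model`.
#' @param b Branch length, finite and >= 0.
#' @return 4x4 row-stochastic matrix with rows/columns ordered A, C, G, T.
#' @export
transition_matrix <- function(model, b) {
  stopifnot(inherits(model, "k2p_model"))
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b < 0) {
    stop("branch length must be finite and non-negative")
  }
  P <- .k2p_pmat_cpp(model$alpha, model$beta, b)
  dimnames(P) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  P
}
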