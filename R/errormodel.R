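# Sequencing-error model for tip likelihoods.
#
# A true base is miscalled as each of the three other bases with probability
# epsilon/3 (total miscall probability epsilon), independently across sites
# and sequences. Ambiguity codes are assumed to be produced *after* the
# error process from specific (possibly wrong) base calls, so the
# probability of observing a code with resolution set S given true base x is
# the probability that the called base fell in S.

.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"), `-` = c("A", "C", "G", "T"),
  `?` = c("A", "C", "G", "T"))

#' Resolution set of an IUPAC symbol
#'
#' @param symbol A single IUPAC nucleotide code (case-insensitive); `N`,
#'   `-` and `?` all resolve to all four bases.
#' @return Character vector, a subset of `c("A","C","G","T")`.
#' @examples
#' ambiguity_set("M")  # A or C
#' @export
ambiguity_set <- function(symbol) {
  s <- toupper(symbol)
  if (s == "U") s <- "T"
  set <- .iupac_sets[[s]]
  if (is.null(set)) stop("unknown nucleotide symbol: '", symbol, "'")
  set
}

#' Declared or true sequencing-error rates
#'
#' @param epsilon Global per-base miscall probability, in `[0, 0.75)`.
#'   At 0.75 a call would be uniformly random and the model carries no
#'   information, so the domain is capped below it.
#' @param per_taxon Optional named numeric vector of per-taxon miscall rates
#'   overriding the global value.
#' @return An `error_spec` object.
#' @export
error_spec <- function(epsilon = 0, per_taxon = NULL) {
  check_eps <- function(e, what) {
    if (!is.numeric(e) || anyNA(e) || any(e < 0) || any(e >= 0.75)) {
      stop(what, " must lie in [0, 0.75)")
    }
  }
  check_eps(epsilon, "epsilon")
  if (length(epsilon) != 1L) stop("epsilon must be a single value")
  if (!is.null(per_taxon)) {
    if (is.null(names(per_taxon)) || any(!nzchar(names(per_taxon)))) {
      stop("per_taxon rates must be named by taxon")
    }
    check_eps(per_taxon, "per-taxon epsilon")
  }
  structure(list(epsilon = epsilon, per_taxon = per_taxon),
            class = "error_spec")
}

#' @export
print.error_spec <- function(x, ...) {
  cat(sprintf("Error spec: global epsilon = %g", x$epsilon))
  if (!is.null(x$per_taxon)) {
    cat(";", length(x$per_taxon), "per-taxon override(s)")
  }
  cat("\n")
  invisible(x)
}

as_error_spec <- function(x) {
  if (inherits(x, "error_spec")) x else error_spec(x)
}

# Effective epsilon for one taxon under a spec.
effective_epsilon <- function(spec, taxon) {
  if (!is.null(spec$per_taxon) && taxon %in% names(spec$per_taxon)) {
    unname(spec$per_taxon[[taxon]])
  } else {
    spec$epsilon
  }
}

#' Error-adjusted tip likelihood vector for one observed symbol
#'
#' For a symbol with resolution set S of size k, the probability of the
#' observation given true base x is `1 - epsilon + (k-1) epsilon/3` when x
#' is in S (a correct call, or a miscall landing elsewhere in S) and
#' `k epsilon/3` otherwise (a miscall into S). These are probabilities of
#' the observation, not of the underlying base, and need not sum to 1;
#' missing data gives `(1,1,1,1)` for any epsilon.
#'
#' @param symbol A single IUPAC code.
#' @param epsilon Miscall probability in `[0, 0.75)`.
#' @return Numeric 4-vector named A, C, G, T.
#' @examples
#' tip_vector("A", 0.01)  # (1-eps, eps/3, eps/3, eps/3)
#' tip_vector("M", 0.01)  # (1-2eps/3, 1-2eps/3, 2eps/3, 2eps/3)
#' @export
tip_vector <- function(symbol, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
      epsilon < 0 || epsilon >= 0.75) {
    stop("epsilon must lie in [0, 0.75)")
  }
  S <- ambiguity_set(symbol)
  k <- length(S)
  v <- rep(k * epsilon / 3, 4L)
  names(v) <- c("A", "C", "G", "T")
  v[S] <- 1 - epsilon + (k - 1) * epsilon / 3
  v
}

# 4 x n_symbols lookup of tip vectors for one epsilon, columns named by
# symbol. Used to build per-taxon partials quickly.
tip_vector_table <- function(epsilon) {
  vapply(names(.iupac_sets), tip_vector, numeric(4L), epsilon = epsilon)
}

#' Per-site tip likelihood vectors for a whole sequence
#'
#' @param sequence Character vector of symbols or a single sequence string.
#' @param taxon Taxon name, used to resolve a per-taxon epsilon.
#' @param spec An `error_spec` (or a bare epsilon).
#' @return 4 x n_sites numeric matrix; column i is `tip_vector` of site i
#'   under the taxon's effective epsilon.
#' @export
tip_partials <- function(sequence, taxon, spec) {
  spec <- as_error_spec(spec)
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  }
  sequence <- toupper(sequence)
  sequence[sequence == "U"] <- "T"
  idx <- match(sequence, names(.iupac_sets))
  if (anyNA(idx)) {
    stop("unknown symbol '", sequence[which(is.na(idx))[1L]],
         "' in sequence for taxon '", taxon, "'")
  }
  tab <- tip_vector_table(effective_epsilon(spec, taxon))
  m <- tab[, idx, drop = FALSE]
  dimnames(m) <- list(c("A", "C", "G", "T"), NULL)
  m
}
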