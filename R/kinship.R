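#' Generate a synthetic strain kinship matrix
#'
#' Emulates a strain-level additive genetic relationship matrix of the kind
#' derived from founder haplotype probabilities in multiparental panels:
#' strains share random founder-like loadings, giving off-diagonal
#' relatedness, and the matrix is rescaled so its mean diagonal equals 1.
#' The result is symmetric positive semi-definite and deterministic given
#' the seed.
#'
#' @param n_strains number of strains (>= 2).
#' @param seed integer seed.
#' @param n_founders number of latent founder loadings (default 8).
#' @return A symmetric PSD matrix with strain labels `CC01`, `CC02`, ... and
#'   mean diagonal exactly 1.
#' @export
#' @examples
#' K <- generate_kinship(10, seed = 1)
#' mean(diag(K))
generate_kinship <- function(n_strains, seed = 1L, n_founders = 8L) {
  if (n_strains < 2) stop("invalid design: need at least 2 strains")
  set.seed(as.integer(seed))
  ## founder-dosage-like loadings; rows sum to 1 as haplotype proportions do
  B <- matrix(rexp(n_strains * n_founders), n_strains, n_founders)
  B <- B / rowSums(B)
  K <- tcrossprod(B)
  ## inbred strains are fully related to themselves: inflate the diagonal
  diag(K) <- diag(K) + 0.5
  K <- (K + t(K)) / 2
  K <- K / mean(diag(K))
  dimnames(K) <- rep(list(sprintf("CC%02d", seq_len(n_strains))), 2)
  K
}

#' Subset and rescale a kinship matrix
#'
#' Extracts the rows/columns for a strain subset and divides by the mean of
#' the resulting diagonal so that the mean diagonal equals 1, the
#' normalization under which the genetic variance scale parameter is
#' comparable with the residual variance.
#'
#' @param K square symmetric relatedness matrix with strain dimnames.
#' @param subset character vector of strain labels (default: all).
#' @return The rescaled submatrix.
#' @export
rescale_kinship <- function(K, subset = rownames(K)) {
  if (is.null(rownames(K))) stop("kinship matrix must have strain labels")
  missing_lab <- setdiff(subset, rownames(K))
  if (length(missing_lab))
    stop("unknown strain label(s): ", paste(missing_lab, collapse = ", "))
  Ks <- K[subset, subset, drop = FALSE]
  md <- mean(diag(Ks))
  if (md <= 0) stop("degenerate kinship matrix: mean diagonal is not positive")
  Ks / md
}

## lower-triangular factor L with K = L L', tolerant of a PSD (singular) K
kinship_factor <- function(K, tol = 1e-10) {
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -tol * max(abs(eg$values)))
    stop("kinship matrix is not positive semi-definite")
  vals <- pmax(eg$values, 0)
  L <- eg$vectors %*% diag(sqrt(vals), length(vals))
  rownames(L) <- rownames(K)
  L
}
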