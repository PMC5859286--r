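#' Regularized weighted amino-acid frequencies
#'
#' Computes single-site frequencies from a weighted alignment:
#' \deqn{f_i^a = (1-\lambda)\,\frac{\sum_s w_s \, 1(s_i = a)}{M'} + \lambda q^a}
#' Gaps (and `X`) contribute no amino-acid count, so at gapped columns the 20
#' frequencies sum to less than one. The pseudocount `lambda` mixes toward
#' the background and keeps every frequency strictly inside (0, 1), which the
#' conservation weight `phi` requires.
#'
#' @param paln A `processed_alignment`.
#' @param bg Background frequencies (named, 20 letters).
#' @param lambda Pseudocount fraction in \[0, 1).
#' @return L x 20 matrix of frequencies (rows = positions).
#' @export
site_frequencies <- function(paln, bg = background_frequencies(),
                             lambda = 0.03) {
  if (lambda < 0 || lambda >= 1) {
    stop("configuration error: lambda must lie in [0, 1)", call. = FALSE)
  }
  bg <- check_background(bg)
  enc <- encode_alignment(paln$seqs)
  X <- one_hot(enc)                      # M x 20L
  counts <- crossprod(X, paln$weights)   # 20L x 1
  L <- ncol(paln$seqs)
  f <- matrix(counts / paln$m_eff, nrow = L, ncol = 20, byrow = TRUE)
  f <- (1 - lambda) * f +
    lambda * matrix(bg, nrow = L, ncol = 20, byrow = TRUE)
  colnames(f) <- aa_alphabet()
  f
}

#' Regularized weighted pairwise frequencies
#'
#' Joint frequencies of amino-acid pairs across all position pairs,
#' \deqn{f_{ij}^{ab} = (1-\lambda)\,\frac{\sum_s w_s\,1(s_i=a)\,1(s_j=b)}{M'}
#'   + \lambda\, q^a q^b,}
#' returned as a `(20L) x (20L)` symmetric matrix in which the block
#' `(i, j)` holds the 20 x 20 table for positions `i` and `j` (position `i`
#' occupies rows `(i-1)*20 + 1:20`). At `lambda = 0` the pair table
#' marginalizes exactly to the single-site frequencies on gap-free columns.
#'
#' @inheritParams site_frequencies
#' @return `(20L) x (20L)` numeric matrix.
#' @export
pair_frequencies <- function(paln, bg = background_frequencies(),
                             lambda = 0.03) {
  if (lambda < 0 || lambda >= 1) {
    stop("configuration error: lambda must lie in [0, 1)", call. = FALSE)
  }
  bg <- check_background(bg)
  enc <- encode_alignment(paln$seqs)
  X <- one_hot(enc)
  Xw <- X * paln$weights
  F2 <- crossprod(Xw, X) / paln$m_eff
  F2 <- (F2 + t(F2)) / 2               # exact symmetry
  L <- ncol(paln$seqs)
  qq <- tcrossprod(rep(bg, L))
  (1 - lambda) * F2 + lambda * qq
}

#' Frequency model for an alignment
#'
#' Bundles the single-site and pairwise regularized frequencies, the raw
#' (unregularized) single-site frequencies used for centering in the
#' sequence-space projection, the background and the pseudocount.
#'
#' @inheritParams site_frequencies
#' @param pairs Compute the pairwise table (set `FALSE` to save memory when
#'   only conservation is needed).
#' @return Object of class `frequency_model` with elements `f1` (L x 20),
#'   `f2` (`20L x 20L` or `NULL`), `f1_raw`, `bg`, `lambda`, `L`.
#' @export
frequency_model <- function(paln, bg = background_frequencies(),
                            lambda = 0.03, pairs = TRUE) {
  bg <- check_background(bg)
  f1 <- site_frequencies(paln, bg, lambda)
  f1_raw <- if (lambda == 0) f1 else site_frequencies(paln, bg, 0)
  f2 <- if (pairs) pair_frequencies(paln, bg, lambda) else NULL
  structure(list(f1 = f1, f2 = f2, f1_raw = f1_raw, bg = bg,
                 lambda = lambda, L = ncol(paln$seqs)),
            class = "frequency_model")
}

#' @export
print.frequency_model <- function(x, ...) {
  cat("<frequency_model> L = ", x$L, ", lambda = ", x$lambda,
      if (is.null(x$f2)) ", singles only" else ", singles + pairs",
      "\n", sep = "")
  invisible(x)
}
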