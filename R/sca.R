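#' Conservation-weighted covariance tensor
#'
#' The elementwise conservation-weighted covariance of amino-acid occurrence,
#' \deqn{\tilde C_{ij}^{ab} = \phi_i^a\,\phi_j^b\,(f_{ij}^{ab} - f_i^a f_j^b),}
#' stored as a `(20L) x (20L)` symmetric matrix of 20 x 20 blocks (block
#' `(i, j)` holds amino-acid pairs for positions `i`, `j`). It vanishes
#' identically whenever the joint frequencies factorize.
#'
#' @param freq A `frequency_model` with pairs computed.
#' @param phi Conservation weights from [phi_weight()]; computed from `freq`
#'   when omitted.
#' @return `(20L) x (20L)` matrix of class `sca_tensor`.
#' @export
build_tensor <- function(freq, phi = NULL) {
  if (is.null(freq$f2)) stop("internal error: pair frequencies missing", call. = FALSE)
  if (is.null(phi)) phi <- phi_weight(freq)
  L <- freq$L
  if (!all(dim(phi) == c(L, 20))) {
    stop("internal error: phi dimensions do not match frequency model",
         call. = FALSE)
  }
  f1v <- as.vector(t(freq$f1))   # 20L, position-major blocks of 20
  phiv <- as.vector(t(phi))
  cov <- freq$f2 - tcrossprod(f1v)
  tens <- cov * tcrossprod(phiv)
  tens <- (tens + t(tens)) / 2
  structure(tens, class = c("sca_tensor", "matrix"), L = L)
}

#' Reduce the SCA tensor to the positional SCA matrix
#'
#' Frobenius norm over the amino-acid indices of each positional block:
#' \deqn{\tilde C_{ij} = \sqrt{\sum_{a,b} (\tilde C_{ij}^{ab})^2}.}
#'
#' @param tens An `sca_tensor`.
#' @return L x L nonnegative symmetric matrix of class `sca_matrix`.
#' @export
frobenius_reduce <- function(tens) {
  L <- attr(tens, "L")
  if (is.null(L)) L <- nrow(tens) / 20L
  grp <- rep(seq_len(L), each = 20L)
  S <- unclass(tens)^2
  S1 <- rowsum(S, grp)                 # L x 20L
  S2 <- t(rowsum(t(S1), grp))          # L x L
  m <- sqrt(S2)
  m <- (m + t(m)) / 2
  structure(m, class = c("sca_matrix", "matrix"))
}

#' Compute the SCA matrix for a processed alignment
#'
#' Convenience wrapper: frequencies, conservation weights, Eq.-style tensor
#' and its Frobenius reduction in one call.
#'
#' @param paln A `processed_alignment`.
#' @param bg Background frequencies.
#' @param lambda Pseudocount.
#' @return A list with `matrix` (`sca_matrix`), `tensor` (`sca_tensor`),
#'   `freq` (`frequency_model`), `phi`.
#' @export
sca_matrix <- function(paln, bg = background_frequencies(), lambda = 0.03) {
  freq <- frequency_model(paln, bg, lambda, pairs = TRUE)
  phi <- phi_weight(freq)
  tens <- build_tensor(freq, phi)
  list(matrix = frobenius_reduce(tens), tensor = tens, freq = freq, phi = phi)
}

#' Spectral decomposition of a symmetric matrix
#'
#' Eigendecomposition with deterministic conventions: eigenvalues in
#' descending order and each eigenvector oriented so that its
#' largest-magnitude loading is positive (ties broken by first index). The
#' input must be symmetric to tolerance.
#'
#' @param m Symmetric numeric matrix.
#' @param k Number of top modes to keep (default: all).
#' @param tol Symmetry tolerance relative to the largest entry.
#' @return Object of class `spectral_result`: `values` (descending),
#'   `vectors` (columns = modes, oriented), `k`, `dim`.
#' @export
eigendecompose <- function(m, k = ncol(m), tol = 1e-8) {
  m <- unclass(m)
  asym <- max(abs(m - t(m)))
  if (asym > tol * max(1, max(abs(m)))) {
    stop("validation error: matrix is not symmetric (max asymmetry ",
         signif(asym, 3), ")", call. = FALSE)
  }
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  k <- min(k, ncol(m))
  vals <- e$values[seq_len(k)]
  vecs <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vecs[, j]))     # first index on ties
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(list(values = vals, vectors = vecs, k = k, dim = ncol(m)),
            class = "spectral_result")
}

#' @export
print.spectral_result <- function(x, ...) {
  cat("<spectral_result> top ", x$k, " of ", x$dim, " modes; eigenvalues: ",
      paste(signif(utils::head(x$values, 5), 4), collapse = ", "),
      if (x$k > 5) ", ...", "\n", sep = "")
  invisible(x)
}

#' Sector definition along a top eigenmode
#'
#' A sector is the set of positions whose loading on the chosen eigenmode
#' (after orientation) exceeds the threshold strictly — the `EV1 > 0.03`
#' rule.
#'
#' @param spec A `spectral_result` from the SCA matrix.
#' @param threshold Loading threshold (strict inequality).
#' @param mode Eigenmode index (default 1).
#' @param paln Optional `processed_alignment` for original-column and
#'   reference-residue coordinates.
#' @return Object of class `sector_definition`: `members` (columns),
#'   `loadings` (full vector), `threshold`, `mode`, and a tibble `table`
#'   with `column`, `original_column`, `ref_residue`, `loading`,
#'   `in_sector`.
#' @export
define_sector <- function(spec, threshold = 0.03, mode = 1, paln = NULL) {
  if (mode > spec$k) stop("mode index out of range", call. = FALSE)
  ld <- spec$vectors[, mode]
  members <- which(ld > threshold)
  tab <- tibble::tibble(
    column = seq_along(ld),
    original_column = if (!is.null(paln)) paln$column_map[seq_along(ld)] else
      seq_along(ld),
    ref_residue = if (!is.null(paln)) paln$ref_residue[seq_along(ld)] else
      NA_integer_,
    loading = ld,
    in_sector = ld > threshold
  )
  structure(list(members = members, loadings = ld, threshold = threshold,
                 mode = mode, table = tab),
            class = "sector_definition")
}

#' @export
print.sector_definition <- function(x, ...) {
  cat("<sector_definition> ", length(x$members), " positions with mode-",
      x$mode, " loading > ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Per-position sector loadings as a tibble
#'
#' @param x A `sector_definition`.
#' @param ... Unused.
#' @return The loading table (tibble).
#' @method tidy sector_definition
#' @export
tidy.sector_definition <- function(x, ...) x$table

#' @method glance sector_definition
#' @export
glance.sector_definition <- function(x, ...) {
  tibble::tibble(n_sector = length(x$members), threshold = x$threshold,
                 mode = x$mode, n_positions = length(x$loadings))
}

#' Eigenvalue summary of a spectral result
#'
#' @param x A `spectral_result`.
#' @param ... Unused.
#' @return Tibble with `mode`, `eigenvalue`, `fraction` of total (over the
#'   kept modes).
#' @method tidy spectral_result
#' @export
tidy.spectral_result <- function(x, ...) {
  tibble::tibble(mode = seq_len(x$k), eigenvalue = x$values,
                 fraction = x$values / sum(abs(x$values)))
}
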