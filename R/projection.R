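#' Reduce the alignment over its amino-acid axis
#'
#' Projects the three-dimensional binarized alignment (sequence x position x
#' amino acid) down to sequence x position by weighting each position's
#' amino-acid indicators with the conservation weight phi and centering them
#' at the empirical (weighted, unregularized) frequencies:
#' \deqn{r_{si} = \sum_a \phi_i^a\,(x_{sia} - \hat f_i^a).}
#' The projection vector at each position is phi itself (no further
#' per-position normalization); the reduction is linear in the indicators
#' and fully reproducible from the alignment, frequency model and phi. A
#' column where every sequence carries the same letter reduces to exact
#' zeros.
#'
#' @param paln A `processed_alignment`.
#' @param freq A `frequency_model` on the same alignment.
#' @param phi Conservation weights; computed from `freq` when omitted.
#' @return M x L numeric matrix (rows named by sequence id).
#' @export
reduce_alignment <- function(paln, freq, phi = NULL) {
  if (is.null(phi)) phi <- phi_weight(freq)
  L <- ncol(paln$seqs)
  if (freq$L != L || !all(dim(phi) == c(L, 20))) {
    stop("internal error: frequency model does not match alignment",
         call. = FALSE)
  }
  enc <- encode_alignment(paln$seqs)
  X <- one_hot(enc)                          # M x 20L
  phiv <- as.vector(t(phi))                  # 20L
  f1v <- as.vector(t(freq$f1_raw))
  # sum_a phi (x - f) = (X %*% diag(phi)) summed per block  - sum_a phi f
  Xp <- X * rep(phiv, each = nrow(X))
  grp <- rep(seq_len(L), each = 20L)
  R <- t(rowsum(t(Xp), grp))                 # M x L
  offset <- rowsum(phiv * f1v, grp)[, 1]
  R <- sweep(R, 2L, offset, "-")
  rownames(R) <- paln$ids
  R
}

#' Spectral decomposition of the reduced alignment's positional correlation
#'
#' Builds the weight-aware positional correlation of the reduced alignment,
#' \deqn{P = R^\top \mathrm{diag}(w) R / M',}
#' and eigendecomposes it. By singular-value duality, projecting sequences
#' onto these eigenvectors (see [project_sequences()]) reproduces the left
#' singular vectors of `R` exactly (up to sign) when all weights are one.
#' `P` is invariant to duplicating every sequence, so sequence coordinates
#' are too.
#'
#' @param reduced M x L matrix from [reduce_alignment()].
#' @param paln The `processed_alignment` providing weights and `m_eff`.
#' @param k Number of modes.
#' @return A `spectral_result`.
#' @export
sequence_space_spectral <- function(reduced, paln, k = min(6, ncol(reduced))) {
  P <- crossprod(reduced * paln$weights, reduced) / paln$m_eff
  eigendecompose((P + t(P)) / 2, k = k)
}

#' Project sequences into the space of positional correlations
#'
#' The coordinate of sequence `s` along mode `m` is the inner product of its
#' reduced-alignment row with eigenvector `m`, scaled by
#' \eqn{(M' \lambda_m)^{-1/2}} so coordinates are comparable across modes.
#' Modes with nonpositive eigenvalues are excluded. Sequences that diverge at
#' the positions loading on a mode separate along that coordinate.
#'
#' @param reduced M x L matrix from [reduce_alignment()].
#' @param spec A `spectral_result`; by default computed from the reduced
#'   alignment itself via [sequence_space_spectral()] (the SVD-dual route).
#' @param paln The `processed_alignment` (for weights / `m_eff` and ids).
#' @param modes Integer vector of mode indices to report.
#' @return Tibble with `id` and one `mode<k>` column per requested mode.
#' @export
project_sequences <- function(reduced, paln, spec = NULL,
                              modes = NULL) {
  if (is.null(spec)) spec <- sequence_space_spectral(reduced, paln)
  if (is.null(modes)) modes <- seq_len(spec$k)
  if (any(modes > spec$k)) stop("mode index out of range", call. = FALSE)
  keep <- modes[spec$values[modes] > 0]
  scal <- 1 / sqrt(paln$m_eff * spec$values[keep])
  coords <- (reduced %*% spec$vectors[, keep, drop = FALSE]) %*% diag(scal,
    nrow = length(keep))
  colnames(coords) <- paste0("mode", keep)
  dplyr::bind_cols(tibble::tibble(id = paln$ids),
                   tibble::as_tibble(coords))
}

#' Attach annotation labels to sequence coordinates
#'
#' Joins a per-sequence label table onto the coordinates and summarises each
#' label group (centroid and dispersion along each mode). Sequences without
#' a label are marked `"unlabeled"`.
#'
#' @param coords Tibble from [project_sequences()].
#' @param annotation Tibble with columns `id`, `label`.
#' @return A list with `coordinates` (labeled tibble) and `summary`
#'   (per-label centroids/sd per mode, long format: `label`, `mode`,
#'   `n`, `centroid`, `dispersion`).
#' @export
annotate_projection <- function(coords, annotation) {
  stopifnot(all(c("id", "label") %in% names(annotation)))
  lab <- dplyr::left_join(coords, annotation[, c("id", "label")], by = "id")
  lab$label[is.na(lab$label)] <- "unlabeled"
  long <- tidyr::pivot_longer(lab, dplyr::starts_with("mode"),
                              names_to = "mode", values_to = "coord")
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$label, .data$mode),
    n = dplyr::n(),
    centroid = mean(.data$coord),
    dispersion = stats::sd(.data$coord),
    .groups = "drop"
  )
  list(coordinates = lab, summary = summ)
}

#' Separation of two labeled groups along a mode
#'
#' Area under the ROC curve for discriminating two labels by their
#' coordinate along one mode: 0.5 means no separation, 1 means perfect.
#' Computed by the rank-sum (Mann-Whitney) identity; reported as
#' `max(AUC, 1 - AUC)` when `symmetric = TRUE` since a mode's sign carries
#' no meaning.
#'
#' @param coords Labeled coordinates (must contain `label` and the mode
#'   column).
#' @param mode Mode column name (default `"mode1"`).
#' @param labels Optional length-2 label pair; defaults to the two most
#'   frequent labels.
#' @param symmetric Fold AUC about 0.5.
#' @return AUC in \[0, 1\] (or \[0.5, 1\] when symmetric).
#' @export
mode_separation_auc <- function(coords, mode = "mode1", labels = NULL,
                                symmetric = TRUE) {
  stopifnot("label" %in% names(coords), mode %in% names(coords))
  if (is.null(labels)) {
    labels <- names(sort(table(coords$label), decreasing = TRUE))[1:2]
  }
  x <- coords[[mode]][coords$label == labels[1]]
  y <- coords[[mode]][coords$label == labels[2]]
  r <- rank(c(x, y))
  auc <- (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
    (length(x) * length(y))
  if (symmetric) max(auc, 1 - auc) else auc
}
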