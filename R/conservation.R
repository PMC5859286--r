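#' Positional conservation as Kullback-Leibler relative entropy
#'
#' For each alignment position the divergence of the observed amino-acid
#' frequencies from the background,
#' \deqn{D_i = \sum_a f_i^a \ln\frac{f_i^a}{q^a},}
#' summed over amino acids with positive frequency (gaps carry no mass, so a
#' fully gapped column scores 0). Values are in nats: 0 means the column
#' looks like random draws from the background; values above ~3 indicate
#' near-total conservation. Also returns the per-amino-acid binarized
#' entropies
#' \deqn{D_i^a = f\ln\frac{f}{q} + (1-f)\ln\frac{1-f}{1-q}}
#' whose frequency-derivative is the conservation weight [phi_weight()].
#'
#' @param freq A `frequency_model` (or an L x 20 frequency matrix).
#' @param bg Background frequencies; taken from the model when omitted.
#' @return Tibble with columns `column`, `conservation` (`D_i`), and
#'   `max_binarized` (max over letters of `D_i^a`), plus attribute
#'   `binarized` (L x 20 matrix of `D_i^a`).
#' @export
kl_conservation <- function(freq, bg = NULL) {
  f1 <- if (inherits(freq, "frequency_model")) freq$f1 else freq
  if (is.null(bg)) bg <- if (inherits(freq, "frequency_model")) freq$bg else
    background_frequencies()
  bg <- check_background(bg)
  qmat <- matrix(bg, nrow(f1), 20, byrow = TRUE)
  term <- ifelse(f1 > 0, f1 * log(f1 / qmat), 0)
  d <- rowSums(term)
  dbin <- binarized_kl(f1, qmat)
  out <- tibble::tibble(column = seq_len(nrow(f1)),
                        conservation = d,
                        max_binarized = apply(dbin, 1, max))
  attr(out, "binarized") <- dbin
  out
}

binarized_kl <- function(f, q) {
  t1 <- ifelse(f > 0, f * log(f / q), 0)
  t2 <- ifelse(f < 1, (1 - f) * log((1 - f) / (1 - q)), 0)
  t1 + t2
}

#' Conservation weight phi
#'
#' The derivative of the binarized per-amino-acid KL entropy with respect to
#' frequency,
#' \deqn{\phi_i^a = \frac{\partial D_i^a}{\partial f_i^a}
#'   = \ln\frac{f_i^a (1 - q^a)}{q^a (1 - f_i^a)},}
#' the weighting factor of the conservation-weighted covariance tensor. It is
#' zero exactly when the observed frequency equals background and strictly
#' increasing in `f`. Frequencies of exactly 0 or 1 make it infinite, which
#' the pseudocount regularization precludes.
#'
#' @inheritParams kl_conservation
#' @return L x 20 matrix of weights.
#' @export
phi_weight <- function(freq, bg = NULL) {
  f1 <- if (inherits(freq, "frequency_model")) freq$f1 else freq
  if (is.null(bg)) bg <- if (inherits(freq, "frequency_model")) freq$bg else
    background_frequencies()
  bg <- check_background(bg)
  if (any(f1 <= 0) || any(f1 >= 1)) {
    stop("regularization error: frequencies must lie strictly in (0, 1); ",
         "use a pseudocount lambda > 0", call. = FALSE)
  }
  qmat <- matrix(bg, nrow(f1), 20, byrow = TRUE)
  log(f1 * (1 - qmat) / (qmat * (1 - f1)))
}

#' Identity level corresponding to a binarized conservation value
#'
#' Solves `D^a(f) = d` for `f > q` per background letter: the fractional
#' identity at which a column's binarized conservation reaches `d` nats.
#' Reported for documentation (the identity is background-dependent).
#'
#' @param d Conservation value in nats (default 3).
#' @param bg Background frequencies.
#' @return Tibble with `letter`, `q`, `identity_at_d`.
#' @export
identity_for_conservation <- function(d = 3, bg = background_frequencies()) {
  bg <- check_background(bg)
  solve_one <- function(q) {
    fn <- function(f) f * log(f / q) + (1 - f) * log((1 - f) / (1 - q)) - d
    hi <- 1 - 1e-12
    if (fn(hi) < 0) return(NA_real_)
    stats::uniroot(fn, lower = q, upper = hi, tol = 1e-10)$root
  }
  tibble::tibble(letter = names(bg), q = unname(bg),
                 identity_at_d = vapply(bg, solve_one, numeric(1)))
}

#' Weighted per-subfamily frequency tables
#'
#' Restricts the weighted single-site frequency computation to the sequences
#' carrying each annotation label (e.g. CRY vs PHL), producing one L x 20
#' table per label — the input to sequence-logo rendering.
#'
#' @param paln A `processed_alignment`.
#' @param annotation Tibble/data frame with columns `id` and `label` covering
#'   the sequences of interest.
#' @param positions Optional integer vector of alignment columns to keep.
#' @param lambda Pseudocount (default 0: raw per-label frequencies).
#' @param bg Background frequencies (used only when `lambda > 0`).
#' @return Named list of L x 20 matrices, one per label.
#' @export
subfamily_frequency_table <- function(paln, annotation, positions = NULL,
                                      lambda = 0, bg = background_frequencies()) {
  stopifnot(all(c("id", "label") %in% names(annotation)))
  unknown <- setdiff(annotation$id, paln$ids)
  if (length(unknown) > 0) {
    stop("annotation error: unknown sequence ids: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  labels <- unique(annotation$label)
  out <- lapply(labels, function(lb) {
    ids <- annotation$id[annotation$label == lb]
    sub <- paln
    keep <- which(paln$ids %in% ids)
    sub$ids <- paln$ids[keep]
    sub$seqs <- paln$seqs[keep, , drop = FALSE]
    sub$weights <- paln$weights[keep]
    sub$m_eff <- sum(sub$weights)
    f <- site_frequencies(sub, bg, lambda)
    if (!is.null(positions)) f <- f[positions, , drop = FALSE]
    f
  })
  stats::setNames(out, labels)
}

#' Conservation profile as a tidy table
#'
#' Joins per-column conservation with the original-column and
#' reference-residue maps of a processed alignment.
#'
#' @param paln A `processed_alignment`.
#' @param freq A `frequency_model` for the same alignment.
#' @return Tibble with `column`, `original_column`, `ref_residue`,
#'   `conservation`, `max_binarized`.
#' @export
conservation_profile <- function(paln, freq) {
  kl <- kl_conservation(freq)
  tibble::tibble(column = kl$column,
                 original_column = paln$column_map[kl$column],
                 ref_residue = paln$ref_residue[kl$column],
                 conservation = kl$conservation,
                 max_binarized = kl$max_binarized)
}
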