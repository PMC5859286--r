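#' Preprocessing configuration
#'
#' Collects the alignment-preprocessing thresholds. Defaults follow the CPF
#' analysis: sequences with ungapped length outside \[400, 800\] residues are
#' removed (bounds inclusive, since only strictly smaller/larger sequences
#' are discarded), positions with more than 40% gaps and then sequences with
#' more than 20% gaps over the kept positions are removed, sequences whose
#' fractional identity to the reference falls outside \[0.2, 0.8\] are
#' removed, and sequence weights use an 80% identity threshold.
#'
#' @param min_length,max_length Ungapped sequence-length bounds (residues),
#'   inclusive.
#' @param max_gap_pos Maximum gap fraction per position.
#' @param max_gap_seq Maximum gap fraction per sequence (over kept columns).
#' @param ref_identity_range Length-2 keep-interval of fractional identity to
#'   the reference sequence (inclusive).
#' @param weight_identity Identity threshold for redundancy weighting;
#'   neighbors are sequences with identity strictly above this value.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(min_length = 400, max_length = 800,
                              max_gap_pos = 0.4, max_gap_seq = 0.2,
                              ref_identity_range = c(0.2, 0.8),
                              weight_identity = 0.8) {
  stopifnot(min_length <= max_length,
            max_gap_pos >= 0, max_gap_pos <= 1,
            max_gap_seq >= 0, max_gap_seq <= 1,
            length(ref_identity_range) == 2,
            ref_identity_range[1] <= ref_identity_range[2],
            all(ref_identity_range >= 0), all(ref_identity_range <= 1),
            weight_identity >= 0, weight_identity <= 1)
  structure(list(min_length = min_length, max_length = max_length,
                 max_gap_pos = max_gap_pos, max_gap_seq = max_gap_seq,
                 ref_identity_range = ref_identity_range,
                 weight_identity = weight_identity),
            class = "preprocess_config")
}

subset_alignment <- function(aln, rows = NULL, cols = NULL) {
  mat <- aln$seqs
  if (!is.null(rows)) mat <- mat[rows, , drop = FALSE]
  if (!is.null(cols)) mat <- mat[, cols, drop = FALSE]
  raw_alignment(mat, ids = rownames(mat), ref_id =
                  if (!is.null(aln$ref_id) && aln$ref_id %in% rownames(mat))
                    aln$ref_id else NULL)
}

#' Filter sequences by ungapped length
#'
#' Keeps sequences whose number of non-gap residues lies in
#' `[min_length, max_length]` (inclusive).
#'
#' @param aln A `raw_alignment`.
#' @param cfg A [preprocess_config()].
#' @return Filtered `raw_alignment`.
#' @export
filter_by_length <- function(aln, cfg = preprocess_config()) {
  len <- ungapped_length(aln$seqs)
  keep <- len >= cfg$min_length & len <= cfg$max_length
  if (!any(keep)) stop("empty-result error: all sequences removed by length filter",
                       call. = FALSE)
  subset_alignment(aln, rows = which(keep))
}

#' Remove highly gapped positions
#'
#' Drops alignment columns whose gap frequency exceeds `max_gap_pos`
#' (strictly). Returns the filtered alignment together with the map from
#' kept columns to original column indices.
#'
#' @inheritParams filter_by_length
#' @return A list with `alignment` (filtered `raw_alignment`) and
#'   `column_map` (integer vector: kept column -> original index).
#' @export
filter_gapped_positions <- function(aln, cfg = preprocess_config()) {
  gf <- gap_fraction_cols(aln$seqs)
  keep <- which(gf <= cfg$max_gap_pos)
  list(alignment = subset_alignment(aln, cols = keep),
       column_map = keep)
}

#' Remove highly gapped sequences
#'
#' Drops sequences whose gap fraction over the (already position-filtered)
#' columns exceeds `max_gap_seq` (strictly).
#'
#' @inheritParams filter_by_length
#' @return Filtered `raw_alignment`.
#' @export
filter_gapped_sequences <- function(aln, cfg = preprocess_config()) {
  gf <- gap_fraction_rows(aln$seqs)
  keep <- which(gf <= cfg$max_gap_seq)
  if (length(keep) == 0) {
    stop("empty-result error: all sequences removed by gap filter", call. = FALSE)
  }
  subset_alignment(aln, rows = keep)
}

#' Filter sequences by identity to the reference
#'
#' Keeps sequences whose fractional identity to the reference sequence lies
#' in the keep-interval (inclusive). The reference itself is always kept.
#'
#' @inheritParams filter_by_length
#' @param ref_id Reference sequence id; defaults to the alignment's.
#' @return Filtered `raw_alignment`.
#' @export
filter_reference_identity <- function(aln, ref_id = aln$ref_id,
                                      cfg = preprocess_config()) {
  if (is.null(ref_id) || !(ref_id %in% aln$ids)) {
    stop("configuration error: reference sequence not present", call. = FALSE)
  }
  ids <- pairwise_identity(aln$seqs)[, ref_id]
  lo <- cfg$ref_identity_range[1]; hi <- cfg$ref_identity_range[2]
  keep <- which(ids >= lo & ids <= hi | aln$ids == ref_id)
  out <- subset_alignment(aln, rows = keep)
  out$ref_id <- ref_id
  out
}

#' Redundancy-correcting sequence weights
#'
#' Each sequence receives weight `1 / n_s`, where `n_s` counts the sequences
#' (including itself) with fractional identity strictly above the threshold.
#' The effective number of sequences is the sum of the weights: duplicating
#' every sequence leaves it unchanged.
#'
#' @inheritParams filter_by_length
#' @return A list with `weights` (named numeric, each in (0, 1\]) and
#'   `m_eff` (effective number of sequences).
#' @export
compute_weights <- function(aln, cfg = preprocess_config()) {
  id <- pairwise_identity(aln$seqs)
  n_s <- rowSums(id > cfg$weight_identity)
  w <- 1 / n_s
  list(weights = stats::setNames(w, aln$ids), m_eff = sum(w))
}

#' Full alignment preprocessing
#'
#' Applies the preprocessing stages in fixed order: length filter, gapped
#' positions, gapped sequences, reference-identity filter (when a reference
#' is available), then sequence weighting. Returns a processed alignment
#' carrying the filtered matrix, per-sequence weights, effective sequence
#' count and the column maps back to the original alignment and to the
#' reference sequence's residue numbering.
#'
#' @param aln A `raw_alignment`.
#' @param cfg A [preprocess_config()].
#' @param ref_id Reference id; defaults to the alignment's. If `NULL`, the
#'   reference-identity filter is skipped and no reference-residue map is
#'   produced.
#' @param apply_length_filter Apply the 400-800 residue filter (disable for
#'   short synthetic alignments).
#' @return An object of class `processed_alignment`: `ids`, `seqs` (M x L),
#'   `weights`, `m_eff`, `column_map` (kept column -> original column),
#'   `ref_residue` (kept column -> reference residue ordinal, NA at
#'   reference gaps), `ref_id`, `cfg`.
#' @export
preprocess_alignment <- function(aln, cfg = preprocess_config(),
                                 ref_id = aln$ref_id,
                                 apply_length_filter = TRUE) {
  force(ref_id)   # resolve against the input alignment, not a filtered one
  n0 <- nrow(aln$seqs); l0 <- ncol(aln$seqs)
  if (apply_length_filter) aln <- filter_by_length(aln, cfg)
  fp <- filter_gapped_positions(aln, cfg)
  aln <- fp$alignment
  column_map <- fp$column_map
  if (ncol(aln$seqs) == 0) stop("empty-result error: no positions survive gap filter",
                                call. = FALSE)
  aln <- filter_gapped_sequences(aln, cfg)
  if (!is.null(ref_id)) {
    if (!(ref_id %in% aln$ids)) {
      stop("configuration error: reference sequence removed by filters",
           call. = FALSE)
    }
    aln$ref_id <- ref_id
    aln <- filter_reference_identity(aln, ref_id, cfg)
  }
  wres <- compute_weights(aln, cfg)
  ref_residue <- rep(NA_integer_, ncol(aln$seqs))
  if (!is.null(ref_id)) {
    refrow <- aln$seqs[ref_id, ]
    nong <- refrow != GAP_CHAR
    ref_residue[nong] <- cumsum(nong)[nong]
  }
  structure(list(ids = aln$ids, seqs = aln$seqs,
                 weights = wres$weights, m_eff = wres$m_eff,
                 column_map = column_map, ref_residue = ref_residue,
                 ref_id = ref_id, cfg = cfg,
                 n_input = n0, l_input = l0),
            class = "processed_alignment")
}

#' Wrap an already-clean alignment as processed
#'
#' Skips all filters; computes weights only. Convenient for synthetic
#' alignments generated gap-poor and non-redundant.
#'
#' @inheritParams preprocess_alignment
#' @return A `processed_alignment`.
#' @export
as_processed_alignment <- function(aln, cfg = preprocess_config()) {
  wres <- compute_weights(aln, cfg)
  ref_residue <- rep(NA_integer_, ncol(aln$seqs))
  if (!is.null(aln$ref_id)) {
    refrow <- aln$seqs[aln$ref_id, ]
    nong <- refrow != GAP_CHAR
    ref_residue[nong] <- cumsum(nong)[nong]
  }
  structure(list(ids = aln$ids, seqs = aln$seqs,
                 weights = wres$weights, m_eff = wres$m_eff,
                 column_map = seq_len(ncol(aln$seqs)),
                 ref_residue = ref_residue,
                 ref_id = aln$ref_id, cfg = cfg,
                 n_input = nrow(aln$seqs), l_input = ncol(aln$seqs)),
            class = "processed_alignment")
}

#' @export
print.processed_alignment <- function(x, ...) {
  cat("<processed_alignment> ", nrow(x$seqs), " sequences (M' = ",
      signif(x$m_eff, 6), ") x ", ncol(x$seqs), " positions\n", sep = "")
  invisible(x)
}

#' @export
dim.processed_alignment <- function(x) dim(x$seqs)

#' Summarise a processed alignment
#'
#' @param x A `processed_alignment`.
#' @param ... Unused.
#' @return One-row tibble with M, L, effective sequences and input sizes.
#' @method glance processed_alignment
#' @export
glance.processed_alignment <- function(x, ...) {
  tibble::tibble(n_sequences = nrow(x$seqs), n_positions = ncol(x$seqs),
                 m_eff = x$m_eff, n_input = x$n_input, l_input = x$l_input)
}

#' Per-sequence weights as a tibble
#'
#' @param x A `processed_alignment`.
#' @param ... Unused.
#' @return Tibble with `id`, `weight`.
#' @method tidy processed_alignment
#' @export
tidy.processed_alignment <- function(x, ...) {
  tibble::tibble(id = x$ids, weight = unname(x$weights))
}
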