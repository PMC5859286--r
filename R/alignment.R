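#' Construct a raw alignment object
#'
#' A raw alignment is the package's container for an aligned set of protein
#' sequences before preprocessing: a character matrix (rows = sequences,
#' columns = alignment positions) over the 20 amino acids, `-` (gap) and `X`
#' (unknown), with unique sequence ids and an optional reference id.
#'
#' @param seqs Character vector of aligned sequences (equal length), or a
#'   character matrix of single letters.
#' @param ids Character vector of unique sequence identifiers.
#' @param ref_id Optional id of the reference sequence.
#' @return An object of class `raw_alignment` with elements `ids`, `seqs`
#'   (M x L character matrix), `ref_id`.
#' @export
raw_alignment <- function(seqs, ids = NULL, ref_id = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (length(seqs) == 0) stop("empty alignment", call. = FALSE)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1) {
      stop("alignment-format error: sequences have unequal lengths (",
           paste(sort(unique(lens)), collapse = ", "), ")", call. = FALSE)
    }
    mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  }
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(mat)))
  if (anyDuplicated(ids)) stop("sequence ids must be unique", call. = FALSE)
  mat <- toupper(mat)
  # map '.' gaps and anything outside the alphabet
  mat[mat == "."] <- GAP_CHAR
  known <- c(aa_alphabet(), GAP_CHAR, UNK_CHAR)
  mat[!(mat %in% known)] <- UNK_CHAR
  rownames(mat) <- ids
  if (!is.null(ref_id) && !(ref_id %in% ids)) {
    stop("reference id '", ref_id, "' not present in alignment", call. = FALSE)
  }
  structure(list(ids = ids, seqs = mat, ref_id = ref_id),
            class = "raw_alignment")
}

#' @export
print.raw_alignment <- function(x, ...) {
  cat("<raw_alignment> ", nrow(x$seqs), " sequences x ", ncol(x$seqs),
      " positions", if (!is.null(x$ref_id)) paste0(", reference ", x$ref_id),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.raw_alignment <- function(x) dim(x$seqs)

#' Read an aligned FASTA file
#'
#' Parses an aligned FASTA file into a [raw_alignment()]. Letters are
#' uppercased, `.` gaps become `-`, and unknown letters become `X`. Record
#' order is preserved.
#'
#' @param path Path to an aligned FASTA file.
#' @param ref_id Optional reference sequence id (must be present).
#' @return A `raw_alignment`.
#' @export
read_alignment <- function(path, ref_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty-input error: no FASTA records in ", path,
                            call. = FALSE)
  ids <- sub("\\s.*$", "", names(ss))
  lens <- Biostrings::width(ss)
  if (length(unique(lens)) != 1) {
    stop("alignment-format error: records have unequal lengths", call. = FALSE)
  }
  raw_alignment(as.character(ss), ids = ids, ref_id = ref_id)
}

#' Write an alignment to FASTA
#'
#' @param aln A `raw_alignment` or `processed_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  mat <- if (inherits(aln, "processed_alignment")) aln$seqs else aln$seqs
  seqs <- apply(mat, 1L, paste, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- rownames(mat)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Tidy an alignment into a long tibble
#'
#' @param x A `raw_alignment`.
#' @param ... Unused.
#' @return A tibble with columns `id`, `column`, `letter`.
#' @method tidy raw_alignment
#' @export
tidy.raw_alignment <- function(x, ...) {
  tibble::tibble(
    id = rep(x$ids, times = ncol(x$seqs)),
    column = rep(seq_len(ncol(x$seqs)), each = nrow(x$seqs)),
    letter = as.vector(x$seqs)
  )
}

ungapped_length <- function(mat) rowSums(mat != GAP_CHAR)

gap_fraction_cols <- function(mat) colMeans(mat == GAP_CHAR)

gap_fraction_rows <- function(mat) rowMeans(mat == GAP_CHAR)

#' Pairwise fractional identity between aligned sequences
#'
#' Identity between two aligned rows is the number of columns where both
#' carry the same non-gap letter, divided by the number of columns where at
#' least one of the pair is non-gap. Column pairs that are gap in both
#' sequences do not count toward the denominator. `X` counts as an ordinary
#' (22nd) letter in the numerator only when both rows carry `X`.
#'
#' @param mat Character matrix of aligned sequences.
#' @return M x M numeric matrix of identities in `[0, 1]`.
#' @export
pairwise_identity <- function(mat) {
  enc <- encode_alignment(mat)
  M <- nrow(enc); L <- ncol(enc)
  # indicator over the 21 non-gap states (20 aa + X)
  X <- matrix(0, M, 21L * L)
  state <- ifelse(enc == 22L, 21L, enc) # X -> state 21
  idx <- which(enc != 21L, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    cols <- (idx[, 2] - 1L) * 21L + state[idx]
    X[cbind(idx[, 1], cols)] <- 1
  }
  matches <- tcrossprod(X)
  G <- (enc == 21L) * 1
  both_gap <- tcrossprod(G)
  denom <- L - both_gap
  id <- ifelse(denom > 0, matches / denom, 1)
  dimnames(id) <- list(rownames(mat), rownames(mat))
  id
}
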