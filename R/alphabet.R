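#' Amino-acid alphabet used throughout the package
#'
#' Twenty standard amino acids in the fixed order used for all frequency
#' vectors and tensors. Gaps are represented by `"-"` and unknown or
#' non-standard letters by `"X"`; neither carries amino-acid probability
#' mass.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

GAP_CHAR <- "-"
UNK_CHAR <- "X"

#' Background amino-acid frequencies
#'
#' Default background distribution q over the 20 amino acids, taken from a
#' large nonredundant protein database; this is the reference against which
#' positional conservation (Kullback-Leibler relative entropy) is measured.
#' The table sums to one exactly. Any strictly positive vector named by the
#' 20 letters can be supplied in its place throughout the package.
#'
#' @param uniform If `TRUE`, return the uniform distribution (each letter
#'   1/20) instead of the database table. Useful for closed-form checks.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
background_frequencies <- function(uniform = FALSE) {
  aa <- aa_alphabet()
  if (uniform) {
    q <- rep(1 / 20, 20)
  } else {
    q <- c(0.073, 0.025, 0.050, 0.061, 0.042, 0.072, 0.023, 0.053, 0.064,
           0.089, 0.023, 0.043, 0.052, 0.040, 0.052, 0.073, 0.056, 0.063,
           0.013, 0.033)
  }
  stats::setNames(q, aa)
}

check_background <- function(q) {
  aa <- aa_alphabet()
  if (is.null(names(q))) names(q) <- aa
  if (!setequal(names(q), aa)) {
    stop("background frequencies must be named by the 20 amino acids",
         call. = FALSE)
  }
  q <- q[aa]
  if (any(q <= 0)) stop("background frequencies must be positive", call. = FALSE)
  q / sum(q)
}

# Integer encoding: 1..20 amino acids, 21 gap, 22 unknown (X).
encode_alignment <- function(seq_matrix) {
  lut <- stats::setNames(seq_len(22),
                         c(aa_alphabet(), GAP_CHAR, UNK_CHAR))
  enc <- lut[seq_matrix]
  enc[is.na(enc)] <- 22L
  dim(enc) <- dim(seq_matrix)
  dimnames(enc) <- dimnames(seq_matrix)
  storage.mode(enc) <- "integer"
  enc
}

# One-hot indicator over the 20 amino acids: M x (20*L), column-major in
# positions (position i occupies columns (i-1)*20 + 1:20). Gaps and X rows
# are all-zero at that position.
one_hot <- function(enc) {
  M <- nrow(enc); L <- ncol(enc)
  X <- matrix(0, M, 20L * L)
  idx <- which(enc <= 20L, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    cols <- (idx[, 2] - 1L) * 20L + enc[idx]
    X[cbind(idx[, 1], cols)] <- 1
  }
  X
}
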