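# Shared fixtures: tiny alignments built in code, plus loop-based oracles
# kept deliberately independent of the package's vectorized implementations.

tiny_alignment <- function(seqs, ids = NULL, ref_id = NULL) {
  raw_alignment(seqs, ids = ids, ref_id = ref_id)
}

random_alignment <- function(m, l, gap_rate = 0.1, seed = 1) {
  set.seed(seed)
  letters20 <- aa_alphabet()
  mat <- matrix(sample(letters20, m * l, replace = TRUE), m, l)
  mat[matrix(stats::runif(m * l) < gap_rate, m, l)] <- "-"
  rownames(mat) <- sprintf("s%03d", seq_len(m))
  raw_alignment(mat, ids = rownames(mat))
}

# Brute-force identity between two aligned character vectors
oracle_identity <- function(a, b) {
  nongap <- a != "-" | b != "-"
  if (!any(nongap)) return(1)
  sum(a == b & a != "-" & nongap) / sum(nongap)
}

# Loop-based single-site weighted frequencies (no regularization)
oracle_site_freq <- function(mat, w, m_eff) {
  aa <- aa_alphabet()
  f <- matrix(0, ncol(mat), 20, dimnames = list(NULL, aa))
  for (i in seq_len(ncol(mat))) {
    for (a in seq_along(aa)) {
      f[i, a] <- sum(w[mat[, i] == aa[a]]) / m_eff
    }
  }
  f
}

# Term-by-term KL sum
oracle_kl <- function(fvec, q) {
  s <- 0
  for (a in seq_along(fvec)) {
    if (fvec[a] > 0) s <- s + as.numeric(fvec[a] * log(fvec[a] / q[a]))
  }
  s
}

# Loop-based conservation-weighted covariance tensor (dense 4D array)
oracle_tensor <- function(mat, w, m_eff, bg, lambda) {
  aa <- aa_alphabet()
  L <- ncol(mat)
  f1 <- matrix(0, L, 20)
  for (i in seq_len(L)) for (a in 1:20) {
    f1[i, a] <- (1 - lambda) * sum(w[mat[, i] == aa[a]]) / m_eff +
      lambda * bg[a]
  }
  phi <- log(f1 * (1 - matrix(bg, L, 20, byrow = TRUE)) /
               (matrix(bg, L, 20, byrow = TRUE) * (1 - f1)))
  tens <- array(0, c(L, L, 20, 20))
  for (i in seq_len(L)) for (j in seq_len(L)) for (a in 1:20) for (b in 1:20) {
    f2 <- (1 - lambda) * sum(w[mat[, i] == aa[a] & mat[, j] == aa[b]]) / m_eff +
      lambda * bg[a] * bg[b]
    tens[i, j, a, b] <- phi[i, a] * phi[j, b] * (f2 - f1[i, a] * f1[j, b])
  }
  list(tensor = tens, phi = phi, f1 = f1)
}

# Extract the (i, j) 20x20 block of the package's flattened tensor
tensor_block <- function(tens, i, j) {
  unclass(tens)[(i - 1) * 20 + 1:20, (j - 1) * 20 + 1:20]
}

make_paln <- function(seqs, ids = NULL, ref_id = NULL) {
  as_processed_alignment(tiny_alignment(seqs, ids, ref_id))
}
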