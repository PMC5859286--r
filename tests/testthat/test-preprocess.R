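make_len_seq <- function(n_res, width = 900) {
  paste0(strrep("A", n_res), strrep("-", width - n_res))
}

test_that("length filter keeps the inclusive [min, max] band", {
  aln <- tiny_alignment(vapply(c(350, 400, 800, 801, 399, 401), make_len_seq,
                               character(1)),
                        ids = paste0("s", c(350, 400, 800, 801, 399, 401)))
  kept <- filter_by_length(aln, preprocess_config())
  expect_setequal(kept$ids, c("s400", "s800", "s401"))
  # identity when everything is in range
  aln2 <- tiny_alignment(vapply(c(500, 600), make_len_seq, character(1)))
  expect_identical(filter_by_length(aln2)$seqs, aln2$seqs)
  expect_error(filter_by_length(tiny_alignment(make_len_seq(100))),
               "empty-result")
})

test_that("gapped-position filter matches a brute-force recount", {
  mat <- rbind(c("A", "-", "C", "-"),
               c("A", "-", "C", "A"),
               c("A", "-", "-", "A"),
               c("A", "G", "-", "A"))
  aln <- raw_alignment(mat)
  res <- filter_gapped_positions(aln, preprocess_config(max_gap_pos = 0.4))
  expect_equal(res$column_map, c(1L, 4L))   # cols 2 (3/4) and 3 (1/2) dropped
  # gap-free alignment is untouched
  aln0 <- random_alignment(5, 8, gap_rate = 0, seed = 2)
  expect_equal(filter_gapped_positions(aln0)$column_map, 1:8)
  # random fixture vs per-column recount
  aln <- random_alignment(20, 30, gap_rate = 0.35, seed = 7)
  res <- filter_gapped_positions(aln, preprocess_config(max_gap_pos = 0.4))
  brute <- which(vapply(seq_len(30), function(j)
    mean(aln$seqs[, j] == "-") <= 0.4, logical(1)))
  expect_equal(res$column_map, brute)
})

test_that("gapped-sequence filter matches a brute-force recount", {
  mat <- rbind(a = c("A", "C", "-", "-", "-", "E", "F", "G", "H", "I"),
               b = c("A", "C", "D", "E", "D", "E", "F", "G", "H", "I"))
  aln <- raw_alignment(mat, ids = c("a", "b"))
  expect_equal(filter_gapped_sequences(aln, preprocess_config())$ids, "b")
  aln <- random_alignment(25, 20, gap_rate = 0.2, seed = 11)
  kept <- filter_gapped_sequences(aln, preprocess_config(max_gap_seq = 0.2))$ids
  brute <- aln$ids[vapply(seq_len(25), function(i)
    mean(aln$seqs[i, ] == "-") <= 0.2, logical(1))]
  expect_equal(kept, brute)
})

test_that("reference-identity filter keeps the interval and the reference", {
  base <- strsplit(strrep("ACDEFGHIKLMNPQRSTVWY", 5), "")[[1]]
  vary <- function(n_diff) {
    s <- base
    s[seq_len(n_diff)] <- "W"
    paste(s, collapse = "")
  }
  seqs <- c(ref = paste(base, collapse = ""),
            hi = vary(5),    # identity 0.96 (pos 1 already W? no: base[1]='A')
            mid = vary(50),  # identity 0.5 + share of replaced W matches
            lo = vary(95))
  aln <- raw_alignment(seqs, ids = names(seqs), ref_id = "ref")
  id <- pairwise_identity(aln$seqs)[, "ref"]
  kept <- filter_reference_identity(aln, "ref", preprocess_config())$ids
  manual <- names(id)[(id >= 0.2 & id <= 0.8) | names(id) == "ref"]
  expect_setequal(kept, manual)
  expect_true("ref" %in% kept)
  expect_false("hi" %in% kept)
  expect_error(filter_reference_identity(aln, "nope"), "configuration error")
})

test_that("weights are reciprocal neighbor counts and sum to M'", {
  # 3 near-identical + 2 singletons -> weights {1/3,1/3,1/3,1,1}, M' = 3
  s <- strrep("ACDEFGHIKL", 3)
  mut <- function(s, pos, to) {
    v <- strsplit(s, "")[[1]]; v[pos] <- to; paste(v, collapse = "")
  }
  seqs <- c(a1 = s, a2 = mut(s, 1, "W"), a3 = mut(s, 2, "W"),
            b = strrep("WYWYWYWYWY", 3), c = strrep("MNPQRSTVKL", 3))
  aln <- tiny_alignment(seqs, ids = names(seqs))
  w <- compute_weights(aln, preprocess_config())
  expect_equal(unname(w$weights), c(1/3, 1/3, 1/3, 1, 1))
  expect_equal(w$m_eff, 3)
  expect_equal(sum(w$weights), w$m_eff)
  # all identical -> M' = 1; all dissimilar -> M' = M
  same <- tiny_alignment(rep(s, 6), ids = paste0("d", 1:6))
  expect_equal(compute_weights(same)$m_eff, 1)
  dis <- random_alignment(10, 50, gap_rate = 0, seed = 5)
  expect_equal(compute_weights(dis)$m_eff, 10)
})

test_that("duplication leaves M' unchanged and scales weights by 1/d", {
  aln <- random_alignment(12, 30, gap_rate = 0.05, seed = 9)
  w1 <- compute_weights(aln)
  for (d in c(2, 5)) {
    mat <- aln$seqs[rep(seq_len(12), each = d), ]
    rownames(mat) <- paste0("r", seq_len(12 * d))
    wd <- compute_weights(raw_alignment(mat))
    expect_equal(wd$m_eff, w1$m_eff, tolerance = 1e-12)
    expect_equal(unname(wd$weights), rep(unname(w1$weights) / d, each = d),
                 tolerance = 1e-12)
  }
})

test_that("filters are idempotent and column maps compose", {
  aln <- random_alignment(30, 40, gap_rate = 0.3, seed = 13)
  cfg <- preprocess_config(max_gap_pos = 0.35, max_gap_seq = 0.35)
  p1 <- filter_gapped_positions(aln, cfg)
  p2 <- filter_gapped_positions(p1$alignment, cfg)
  expect_identical(p2$alignment$seqs, p1$alignment$seqs)
  expect_equal(p2$column_map, seq_along(p1$column_map))
  s1 <- filter_gapped_sequences(p1$alignment, cfg)
  expect_identical(filter_gapped_sequences(s1, cfg)$seqs, s1$seqs)
  # composed map recovers original columns
  paln <- preprocess_alignment(aln, cfg, apply_length_filter = FALSE)
  for (k in seq_along(paln$column_map)) {
    expect_identical(paln$seqs[paln$ids[1], k],
                     aln$seqs[paln$ids[1], paln$column_map[k]])
  }
})

test_that("full preprocessing records reference residue numbering", {
  mat <- rbind(ref = c("A", "-", "C", "D", "-", "E"),
               o1  = c("A", "G", "C", "D", "H", "E"),
               o2  = c("A", "G", "C", "-", "H", "E"))
  aln <- raw_alignment(mat, ids = rownames(mat), ref_id = "ref")
  paln <- preprocess_alignment(aln,
                               preprocess_config(max_gap_pos = 0.5,
                                                 max_gap_seq = 0.4),
                               apply_length_filter = FALSE)
  # reference letters at columns 1,3,4,6 are residues 1,2,3,4
  expect_equal(paln$ref_residue[paln$column_map %in% c(1, 3, 4, 6)],
               1:4)
  expect_true(all(diff(paln$column_map) > 0))
})
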