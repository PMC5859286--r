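toy_pdb <- function(..., file = withr::local_tempfile(fileext = ".pdb",
                                                      .local_envir =
                                                        parent.frame())) {
  generate_toy_structure(..., path = file)
  file
}

test_that("toy PDB parses to the constructed residues and ligand", {
  f <- toy_pdb(n_residues = 3, pocket_residues = 2)
  s <- parse_structure(f, "A", "FAD")
  expect_equal(length(s$resno), 3)
  expect_equal(names(s$ligands), "FAD")
  expect_equal(nrow(s$ligands$FAD), 2)
  expect_error(parse_structure(f, "A", "XYZ"), "ligand-not-found")
})

test_that("alternate locations resolve to the highest occupancy atom", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.60  0.00           C",
    "HETATM    3  C1  FAD A   2       5.500   0.000   0.000  1.00  0.00           C",
    "END"), f)
  s <- parse_structure(f, "A", "FAD")
  ca <- s$residues[s$residues$elety == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 5.0)  # altloc B carried the higher occupancy
})

test_that("pocket membership is an inclusive 4-angstrom rule", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       3.900   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       4.100   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  SER A   3       4.000   0.000   0.000  1.00  0.00           C",
    "HETATM    4  C1  FAD A   9       0.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  s <- parse_structure(f, "A", "FAD")
  p <- define_pocket(s, "FAD", 4.0)
  expect_true(1 %in% p$members)    # 3.9 A
  expect_false(2 %in% p$members)   # 4.1 A
  expect_true(3 %in% p$members)    # exactly 4.0 A, inclusive
})

test_that("pocket matches brute-force distances, rigid motion, monotone cutoffs", {
  f <- toy_pdb(n_residues = 12, pocket_residues = c(3, 7, 11))
  s <- parse_structure(f, "A", "FAD")
  p <- define_pocket(s, "FAD", 4.0)
  expect_equal(p$members, c(3L, 7L, 11L))
  # all-pairs distance oracle
  lg <- as.matrix(s$ligands$FAD[, c("x", "y", "z")])
  brute <- integer(0)
  for (rn in s$resno) {
    pa <- as.matrix(s$residues[s$residues$resno == rn, c("x", "y", "z")])
    mind <- Inf
    for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(lg))) {
      mind <- min(mind, sqrt(sum((pa[i, ] - lg[j, ])^2)))
    }
    if (mind <= 4.0) brute <- c(brute, rn)
  }
  expect_equal(p$members, brute)
  # rigid-body transformation leaves membership unchanged
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  s2 <- s
  xyz <- as.matrix(s$residues[, c("x", "y", "z")]) %*% rot
  s2$residues$x <- xyz[, 1] + 10; s2$residues$y <- xyz[, 2] - 4
  s2$residues$z <- xyz[, 3] + 2
  lxyz <- as.matrix(s$ligands$FAD[, c("x", "y", "z")]) %*% rot
  s2$ligands$FAD$x <- lxyz[, 1] + 10; s2$ligands$FAD$y <- lxyz[, 2] - 4
  s2$ligands$FAD$z <- lxyz[, 3] + 2
  expect_equal(define_pocket(s2, "FAD", 4.0)$members, p$members)
  # cutoff monotonicity
  m3 <- define_pocket(s, "FAD", 3)$members
  m4 <- define_pocket(s, "FAD", 4)$members
  m5 <- define_pocket(s, "FAD", 5)$members
  expect_true(all(m3 %in% m4) && all(m4 %in% m5))
})

test_that("column-residue mapping honors numbering offsets and missing ends", {
  f <- toy_pdb(n_residues = 10, pocket_residues = 2, resno_offset = 100)
  s <- parse_structure(f, "A", "FAD")
  refseq <- paste(s$sequence, collapse = "")
  aln <- raw_alignment(c(ref = refseq, o = refseq),
                       ids = c("ref", "o"), ref_id = "ref")
  paln <- as_processed_alignment(aln)
  mp <- map_columns_to_residues(paln, s)
  expect_equal(mp$table$resno, 101:110)
  expect_equal(mp$identity, 1)
  # structure missing its 5 N-terminal residues: first 5 columns unmapped
  f2 <- withr::local_tempfile(fileext = ".pdb")
  generate_toy_structure(n_residues = 10, pocket_residues = 2,
                         path = f2)
  s2 <- parse_structure(f2, "A", "FAD")
  s2$residues <- s2$residues[s2$residues$resno > 5, ]
  s2$sequence <- s2$sequence[6:10]; s2$resno <- s2$resno[6:10]
  mp2 <- map_columns_to_residues(paln, s2)
  expect_false(any(1:5 %in% mp2$table$column))
  expect_equal(mp2$table$resno, 6:10)
  # round trip: mapped residue letter equals the alignment reference letter
  for (k in seq_len(nrow(mp$table))) {
    col <- mp$table$column[k]
    expect_equal(unname(paln$seqs["ref", col]),
                 s$sequence[match(mp$table$resno[k], s$resno)])
  }
})

test_that("a gapped, indel-perturbed reference still maps correctly", {
  f <- toy_pdb(n_residues = 12, pocket_residues = 3)
  s <- parse_structure(f, "A", "FAD")
  # reference lacks structure residues 5-6 and the alignment has a gap column
  letters_ref <- s$sequence[-c(5, 6)]
  refrow <- append(letters_ref, "-", after = 3)
  other <- append(s$sequence[-c(5, 6)], "A", after = 3)
  aln <- raw_alignment(rbind(ref = refrow, o = other),
                       ids = c("ref", "o"), ref_id = "ref")
  paln <- as_processed_alignment(aln)
  mp <- map_columns_to_residues(paln, s)
  # hand-constructed expectation: columns 1:3 -> residues 1:3, column 4 is a
  # reference gap (unmapped), columns 5:11 -> residues 4, 7:12
  expect_false(4 %in% mp$table$column)
  expect_equal(mp$table$resno[mp$table$column %in% c(1, 2, 3)], 1:3)
  expect_equal(mp$table$resno[mp$table$column == 5], 4)
  expect_equal(mp$table$resno[mp$table$column %in% 6:11], 7:12)
})

test_that("sector-pocket overlap counts and enrichment behave", {
  f <- toy_pdb(n_residues = 20, pocket_residues = c(2, 5, 9))
  s <- parse_structure(f, "A", "FAD")
  p <- define_pocket(s, "FAD", 4.0)
  refseq <- paste(s$sequence, collapse = "")
  aln <- raw_alignment(c(ref = refseq, o = refseq), ids = c("ref", "o"),
                       ref_id = "ref")
  paln <- as_processed_alignment(aln)
  mp <- map_columns_to_residues(paln, s)
  mk_sector <- function(cols) {
    structure(list(members = cols, loadings = rep(0, 20), threshold = 0.03,
                   mode = 1, table = NULL), class = "sector_definition")
  }
  # sector = pocket
  ov <- sector_pocket_overlap(mk_sector(c(2L, 5L, 9L)), p, mp)
  expect_equal(ov$n_overlap, 3)
  expect_equal(ov$p_enrichment, 1 / choose(20, 3), tolerance = 1e-12)
  # disjoint
  ov0 <- sector_pocket_overlap(mk_sector(c(1L, 3L, 4L)), p, mp)
  expect_equal(ov0$n_overlap, 0)
  # random sectors give roughly uniform enrichment p-values
  set.seed(91)
  ps <- replicate(400, {
    sector_pocket_overlap(mk_sector(sort(sample(20L, 5))), p, mp)$p_enrichment
  })
  expect_gt(mean(ps > 0.5), 0.25)   # not concentrated at small p
  expect_gt(min(ps), 0)
})
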