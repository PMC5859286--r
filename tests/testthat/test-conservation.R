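test_that("site frequencies count weighted non-gap letters", {
  paln <- make_paln(c("A", "A", "C", "A"), ids = paste0("s", 1:4))
  paln$weights[] <- 1; paln$m_eff <- 4      # unit weights for the raw count
  f <- site_frequencies(paln, lambda = 0)
  expect_equal(unname(f[1, "A"]), 0.75)
  expect_equal(unname(f[1, "C"]), 0.25)
  expect_equal(sum(f[1, ]), 1)
  # explicit weights (0.5, 0.5, 1, 1): f^A = 2/3, f^C = 1/3
  paln$weights[] <- c(0.5, 0.5, 1, 1)
  paln$m_eff <- 3
  f <- site_frequencies(paln, lambda = 0)
  expect_equal(unname(f[1, "A"]), 2 / 3)
  expect_equal(unname(f[1, "C"]), 1 / 3)
  # gaps carry no mass
  paln2 <- make_paln(c("A", "A", "-", "-"))
  paln2$weights[] <- 1; paln2$m_eff <- 4
  f2 <- site_frequencies(paln2, lambda = 0)
  expect_equal(sum(f2[1, ]), 0.5)
  # lambda mixes linearly toward the background
  bg <- background_frequencies()
  f3 <- site_frequencies(paln2, bg, lambda = 0.5)
  expect_equal(unname(f3[1, "A"]), 0.5 * 0.5 + 0.5 * bg[["A"]])
  expect_error(site_frequencies(paln2, lambda = 1), "configuration error")
  # oracle recount on a random weighted alignment
  aln <- random_alignment(15, 6, gap_rate = 0.15, seed = 21)
  paln <- as_processed_alignment(aln)
  expect_equal(unname(site_frequencies(paln, lambda = 0)),
               unname(oracle_site_freq(paln$seqs, paln$weights, paln$m_eff)),
               tolerance = 1e-12)
})

test_that("pair frequencies hold joint counts and marginalize to singles", {
  paln <- make_paln(c("AD", "CE", "AD", "CE"))
  f2 <- pair_frequencies(paln, lambda = 0)
  blk <- f2[1:20, 21:40]  # positions (1, 2); letters in aa_alphabet() order
  a <- match(c("A", "C", "D", "E"), aa_alphabet())
  expect_equal(blk[a[1], a[3]], 0.5)   # f^{AD}
  expect_equal(blk[a[2], a[4]], 0.5)   # f^{CE}
  expect_equal(sum(blk), 1)
  expect_equal(sum(blk != 0), 2)
  # symmetry under (i,a) <-> (j,b)
  expect_identical(f2, t(f2))
  # marginalization at lambda = 0 on a gap-free alignment
  aln <- random_alignment(12, 5, gap_rate = 0, seed = 31)
  paln <- as_processed_alignment(aln)
  f1 <- site_frequencies(paln, lambda = 0)
  f2 <- pair_frequencies(paln, lambda = 0)
  for (i in 1:5) for (j in 1:5) {
    marg <- rowSums(f2[(i - 1) * 20 + 1:20, (j - 1) * 20 + 1:20])
    expect_equal(unname(marg), unname(f1[i, ]), tolerance = 1e-12)
  }
})

test_that("KL conservation matches closed forms and a summation oracle", {
  bg <- background_frequencies()
  # f = q -> D = 0
  f1 <- matrix(bg, 3, 20, byrow = TRUE, dimnames = list(NULL, names(bg)))
  expect_equal(kl_conservation(f1, bg)$conservation, rep(0, 3))
  # fully conserved letter under uniform background -> ln 20
  u <- background_frequencies(uniform = TRUE)
  fc <- matrix(0, 1, 20, dimnames = list(NULL, names(u)))
  fc[1, "A"] <- 1
  expect_equal(kl_conservation(fc, u)$conservation, log(20))
  # random 8-sequence column vs term-by-term oracle
  paln <- as_processed_alignment(random_alignment(8, 4, gap_rate = 0.1,
                                                  seed = 41))
  f <- site_frequencies(paln, bg, lambda = 0.03)
  d <- kl_conservation(f, bg)$conservation
  for (i in 1:4) expect_equal(d[i], oracle_kl(f[i, ], bg), tolerance = 1e-12)
})

test_that("phi weight is the binarized-KL derivative", {
  bg <- background_frequencies()
  # phi = 0 at f = q
  f1 <- matrix(bg, 1, 20, byrow = TRUE, dimnames = list(NULL, names(bg)))
  expect_equal(unname(phi_weight(f1, bg)[1, ]), rep(0, 20), tolerance = 1e-12)
  # closed form: f = 0.9, q = 0.05 -> ln 171
  f2 <- f1
  f2[1, "A"] <- 0.9
  q <- stats::setNames(rep(0.05, 20), names(bg))
  expect_equal(unname(phi_weight(f2, q)[1, "A"]), log(171),
               tolerance = 1e-12)
  # strictly increasing in f; numerically equals d(binarized KL)/df
  fs <- seq(0.1, 0.9, by = 0.1)
  phis <- vapply(fs, function(f) {
    m <- f1; m[1, "W"] <- f
    phi_weight(m, bg)[1, "W"]
  }, numeric(1))
  expect_true(all(diff(phis) > 0))
  q_w <- bg[["W"]]; eps <- 1e-7
  dbin <- function(f) f * log(f / q_w) + (1 - f) * log((1 - f) / (1 - q_w))
  m <- f1; m[1, "W"] <- 0.5
  expect_equal(unname(phi_weight(m, bg)[1, "W"]),
               (dbin(0.5 + eps) - dbin(0.5 - eps)) / (2 * eps),
               tolerance = 1e-6)
  # exact 0/1 frequencies are a regularization error
  z <- matrix(1e-12, 1, 20, dimnames = list(NULL, names(bg)))
  z[1, "A"] <- 1
  expect_error(phi_weight(z, bg), "regularization error")
})

test_that("conservation is invariant to joint relabeling of letters", {
  bg <- background_frequencies()
  paln <- as_processed_alignment(random_alignment(10, 3, seed = 51))
  d0 <- kl_conservation(site_frequencies(paln, bg, 0), bg)$conservation
  # swap A <-> W everywhere, and in the background
  perm <- aa_alphabet()
  perm[perm == "A"] <- "."; perm[perm == "W"] <- "A"; perm[perm == "."] <- "W"
  mat <- paln$seqs
  mat[mat == "A"] <- "."; mat[mat == "W"] <- "A"; mat[mat == "."] <- "W"
  paln2 <- as_processed_alignment(raw_alignment(mat, ids = paln$ids))
  bg2 <- bg
  bg2[c("A", "W")] <- bg[c("W", "A")]
  d1 <- kl_conservation(site_frequencies(paln2, bg2, 0), bg2)$conservation
  expect_equal(d1, d0, tolerance = 1e-12)
})

test_that("identity level for D = 3 is background-dependent and near 0.8-0.9", {
  tab <- identity_for_conservation(3)
  # common letters cannot reach D = 3 even at full conservation (NA);
  # where reachable, the identity sits in the near-total-conservation band
  reach <- tab$identity_at_d[!is.na(tab$identity_at_d)]
  expect_gt(length(reach), 5)
  expect_true(all(reach > 0.6 & reach < 1))
  expect_true(is.na(tab$identity_at_d[tab$letter == "L"]))
  # more common letters need higher identity to reach the same divergence
  expect_gt(tab$identity_at_d[tab$letter == "C"],
            tab$identity_at_d[tab$letter == "W"])
})

test_that("subfamily frequency tables match per-label recounts", {
  aln <- random_alignment(12, 6, gap_rate = 0.05, seed = 61)
  paln <- as_processed_alignment(aln)
  set.seed(62)
  ann <- tibble::tibble(id = paln$ids,
                        label = sample(c("CRY", "PHL"), 12, replace = TRUE))
  tabs <- subfamily_frequency_table(paln, ann, lambda = 0)
  for (lb in c("CRY", "PHL")) {
    keep <- which(paln$ids %in% ann$id[ann$label == lb])
    w <- paln$weights[keep]
    expect_equal(unname(tabs[[lb]]),
                 unname(oracle_site_freq(paln$seqs[keep, , drop = FALSE],
                                         w, sum(w))),
                 tolerance = 1e-12)
  }
  # single label reproduces global frequencies
  one <- subfamily_frequency_table(
    paln, tibble::tibble(id = paln$ids, label = "ALL"), lambda = 0)
  expect_equal(one$ALL, site_frequencies(paln, lambda = 0), tolerance = 1e-12)
  expect_error(subfamily_frequency_table(paln,
    tibble::tibble(id = "missing", label = "A")), "annotation error")
})
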