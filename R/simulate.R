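#' Generate a synthetic alignment with a planted sector
#'
#' Emulates the statistical structure that statistical coupling analysis
#' assumes: a group of "sector" columns co-varies through a latent
#' per-sequence state (each state prefers one low-background letter with the
#' given coupling probability), other columns are independent background
#' draws, some columns are independently conserved toward a consensus
#' letter, gaps are injected at a low rate, and optional near-duplicate
#' clusters exercise the redundancy weighting. The latent state can define
#' subfamily labels (CRY/PHL style) to exercise sequence-space separation.
#' Ground truth (states, sector columns, labels) is returned alongside the
#' alignment.
#'
#' Defaults define the benchmark conditions used throughout the package's
#' tests: 500 sequences, 100 positions, a 15-column sector with coupling
#' 0.9 and two equally likely states.
#'
#' @param n_seq Number of sequences.
#' @param n_pos Number of alignment columns.
#' @param n_sector Number of planted sector columns (ignored when
#'   `sector_columns` given).
#' @param sector_columns Explicit sector column indices.
#' @param coupling Probability that a sector column carries its state's
#'   letter (background draw otherwise).
#' @param n_states Number of latent states (2 by default).
#' @param state_props State proportions (uniform by default).
#' @param sector_letters One letter per state. Defaults alternate
#'   rare-background and common-background letters (W, L, C, ...): rarity
#'   makes the conservation weighting amplify the planted coupling, while
#'   the contrast in background frequency between the states' letters is
#'   what lets the one-dimensional conservation-weighted sequence
#'   projection tell the states apart (two equally rare letters produce a
#'   nearly state-symmetric reduction and no sequence-space separation).
#' @param n_conserved Number of independently conserved (non-sector)
#'   columns.
#' @param conserved_freq Consensus frequency at conserved columns.
#' @param bg Background frequencies for independent draws.
#' @param gap_rate Per-cell gap injection probability.
#' @param n_dup_clusters,dup_cluster_size,dup_mutation_rate Near-duplicate
#'   clusters: number of founder sequences to replicate, total copies per
#'   founder, and per-position mutation rate of the copies.
#' @param subfamily_rule `"by_state"` labels sequences by latent state
#'   (state 1 = CRY, others PHL...), `"random"` assigns labels independently
#'   of state, `"none"` returns no labels.
#' @param seed Integer seed; identical configuration and seed give an
#'   identical alignment.
#' @return A list with `alignment` (a `raw_alignment`) and `truth` (list:
#'   `states`, `sector_columns`, `conserved_columns`, `labels` tibble or
#'   `NULL`, `sector_letters`).
#' @export
generate_msa <- function(n_seq = 500, n_pos = 100,
                         n_sector = 15, sector_columns = NULL,
                         coupling = 0.9,
                         n_states = 2, state_props = NULL,
                         sector_letters = NULL,
                         n_conserved = 10, conserved_freq = 0.9,
                         bg = background_frequencies(),
                         gap_rate = 0.01,
                         n_dup_clusters = 0, dup_cluster_size = 3,
                         dup_mutation_rate = 0.05,
                         subfamily_rule = c("by_state", "random", "none"),
                         seed = 1) {
  subfamily_rule <- match.arg(subfamily_rule)
  bg <- check_background(bg)
  aa <- aa_alphabet()
  stopifnot(coupling >= 0, coupling <= 1, gap_rate >= 0, gap_rate < 1)
  if (is.null(state_props)) state_props <- rep(1 / n_states, n_states)
  stopifnot(length(state_props) == n_states, all(state_props >= 0))
  state_props <- state_props / sum(state_props)
  if (is.null(sector_letters)) {
    pool <- c("W", "L", "C", "S", "H", "E")
    if (n_states > length(pool)) pool <- c(pool, setdiff(aa, pool))
    sector_letters <- pool[seq_len(n_states)]
  }
  set.seed(seed)
  if (is.null(sector_columns)) {
    sector_columns <- sort(sample.int(n_pos, n_sector))
  } else {
    sector_columns <- sort(unique(as.integer(sector_columns)))
    n_sector <- length(sector_columns)
  }
  if (n_sector > n_pos || max(sector_columns, 0) > n_pos) {
    stop("config error: sector exceeds alignment width", call. = FALSE)
  }
  conserved_columns <- sort(sample(setdiff(seq_len(n_pos), sector_columns),
                                   min(n_conserved,
                                       n_pos - n_sector)))
  n_extra <- if (n_dup_clusters > 0) n_dup_clusters * (dup_cluster_size - 1) else 0
  n_base <- n_seq - n_extra
  if (n_base < 1) stop("config error: duplicate clusters exceed n_seq", call. = FALSE)

  states <- sample.int(n_states, n_base, replace = TRUE, prob = state_props)
  mat <- matrix(sample(aa, n_base * n_pos, replace = TRUE, prob = bg),
                n_base, n_pos)
  for (j in sector_columns) {
    hit <- stats::runif(n_base) < coupling
    mat[hit, j] <- sector_letters[states[hit]]
  }
  cons_letters <- sample(aa, length(conserved_columns), replace = TRUE)
  for (k in seq_along(conserved_columns)) {
    j <- conserved_columns[k]
    hit <- stats::runif(n_base) < conserved_freq
    mat[hit, j] <- cons_letters[k]
  }
  if (n_dup_clusters > 0) {
    founders <- sample.int(n_base, n_dup_clusters)
    copies <- matrix("", n_extra, n_pos)
    copy_states <- integer(n_extra)
    r <- 0L
    for (f in founders) {
      for (c in seq_len(dup_cluster_size - 1)) {
        r <- r + 1L
        row <- mat[f, ]
        mut <- stats::runif(n_pos) < dup_mutation_rate
        row[mut] <- sample(aa, sum(mut), replace = TRUE, prob = bg)
        copies[r, ] <- row
        copy_states[r] <- states[f]
      }
    }
    mat <- rbind(mat, copies)
    states <- c(states, copy_states)
  }
  if (gap_rate > 0) {
    mat[stats::runif(length(mat)) < gap_rate] <- GAP_CHAR
  }
  ids <- sprintf("seq%04d", seq_len(nrow(mat)))
  rownames(mat) <- ids
  labels <- switch(subfamily_rule,
    by_state = tibble::tibble(id = ids,
                              label = ifelse(states == 1, "CRY", "PHL")),
    random = tibble::tibble(id = ids,
                            label = sample(c("CRY", "PHL"), nrow(mat),
                                           replace = TRUE)),
    none = NULL)
  list(alignment = raw_alignment(mat, ids = ids),
       truth = list(states = states, sector_columns = sector_columns,
                    conserved_columns = conserved_columns,
                    labels = labels, sector_letters = sector_letters))
}

#' Write a toy protein structure in PDB format
#'
#' Emits a minimal, valid single-chain PDB with `n_residues` two-atom
#' residues and one ligand; the designated pocket residues are placed within
#' 4 angstroms of the ligand and all other residues beyond 6, so the
#' constructed pocket is known exactly. Used as a packaged stand-in for real
#' crystal structures in tests (synthetic by construction).
#'
#' @param n_residues Number of protein residues.
#' @param pocket_residues Residue numbers (1-based) to place inside the
#'   pocket.
#' @param ligand_name Three-letter ligand residue name.
#' @param chain Chain id.
#' @param sequence Optional one-letter sequence of length `n_residues`;
#'   defaults to a fixed repeating pattern.
#' @param path Output file path; when `NULL` the PDB text is returned as a
#'   character vector of lines.
#' @param resno_offset Added to residue numbers (to emulate structures that
#'   do not start at 1).
#' @return `path` (invisibly) or the PDB lines.
#' @export
generate_toy_structure <- function(n_residues = 10,
                                   pocket_residues = integer(),
                                   ligand_name = "FAD", chain = "A",
                                   sequence = NULL, path = NULL,
                                   resno_offset = 0) {
  stopifnot(all(pocket_residues >= 1), all(pocket_residues <= n_residues))
  aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
           H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
           P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
           W = "TRP", Y = "TYR")
  if (is.null(sequence)) {
    sequence <- rep(c("A", "G", "S", "L", "K", "D", "F", "W", "T", "V"),
                    length.out = n_residues)
  }
  stopifnot(length(sequence) == n_residues)
  lines <- character(0)
  serial <- 0L
  emit <- function(record, elety, resid, resno, x, y, z, element) {
    serial <<- serial + 1L
    sprintf("%-6s%5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, serial, elety, resid, chain, resno, x, y, z, 1.00, 0.00,
            element)
  }
  n_pocket <- length(pocket_residues)
  pocket_angle <- if (n_pocket > 0) 2 * pi * (seq_len(n_pocket) - 1) / n_pocket
    else numeric(0)
  far_i <- 0L
  for (i in seq_len(n_residues)) {
    resid <- aa3[[sequence[i]]]
    resno <- i + resno_offset
    if (i %in% pocket_residues) {
      k <- match(i, pocket_residues)
      cx <- 3.5 * cos(pocket_angle[k]); cy <- 3.5 * sin(pocket_angle[k]); cz <- 0
    } else {
      far_i <- far_i + 1L
      cx <- 12; cy <- 0; cz <- 4 * far_i
    }
    lines <- c(lines,
               emit("ATOM", "N", resid, resno, cx, cy, cz + 1.2, "N"),
               emit("ATOM", "CA", resid, resno, cx, cy, cz, "C"))
  }
  lines <- c(lines,
             emit("HETATM", "C1", ligand_name, n_residues + resno_offset + 1,
                  0, 0, 0, "C"),
             emit("HETATM", "N1", ligand_name, n_residues + resno_offset + 1,
                  0.8, 0, 0, "N"),
             "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

#' Generate a synthetic luminescence trace
#'
#' A damped sinusoid sampled every `dt_h` hours with optional constant
#' baseline, linear drift and Gaussian noise — the shape of a circadian
#' rescue recording. Ground-truth parameters are attached as the `truth`
#' attribute.
#'
#' @param period_h Oscillation period (hours).
#' @param amplitude Initial oscillation amplitude (counts).
#' @param damping_per_h Exponential damping rate (1/h).
#' @param phase_rad Phase (radians).
#' @param baseline Constant offset (counts).
#' @param drift_per_h Linear drift slope (counts/h).
#' @param noise_sd Gaussian noise standard deviation (counts).
#' @param duration_h Recording length (hours); must cover at least two
#'   periods for fitting.
#' @param dt_h Sampling interval (hours; default 10 minutes).
#' @param seed Integer seed for the noise.
#' @return A `luminescence_trace` with attribute `truth`.
#' @export
generate_trace <- function(period_h = 24, amplitude = 100,
                           damping_per_h = 0.01, phase_rad = 0,
                           baseline = 200, drift_per_h = 0, noise_sd = 0,
                           duration_h = 70, dt_h = 1 / 6, seed = 1) {
  stopifnot(period_h > 0)
  t <- seq(0, duration_h, by = dt_h)
  set.seed(seed)
  y <- baseline + drift_per_h * t +
    amplitude * exp(-damping_per_h * t) * sin(2 * pi * t / period_h + phase_rad)
  if (noise_sd > 0) y <- y + stats::rnorm(length(t), sd = noise_sd)
  tr <- luminescence_trace(t, y, id = sprintf("sim_T%.1f", period_h))
  attr(tr, "truth") <- list(period_h = period_h, amplitude = amplitude,
                            damping_per_h = damping_per_h,
                            phase_rad = phase_rad, baseline = baseline,
                            drift_per_h = drift_per_h, noise_sd = noise_sd)
  tr
}

#' Generate a synthetic exponential-decay trace
#'
#' Single-exponential decay toward a plateau, the shape of a
#' cycloheximide-chase degradation recording.
#'
#' @param half_life_h Half-life in hours (rate `k = ln 2 / half_life_h`).
#' @param y0 Initial value.
#' @param plateau Asymptote.
#' @param noise_sd Gaussian noise sd.
#' @param duration_h,dt_h Sampling window and interval (hours).
#' @param seed Integer seed.
#' @return A `luminescence_trace` with attribute `truth`.
#' @export
generate_decay_trace <- function(half_life_h = 10, y0 = 1, plateau = 0,
                                 noise_sd = 0, duration_h = 24, dt_h = 1 / 6,
                                 seed = 1) {
  stopifnot(half_life_h > 0)
  k <- log(2) / half_life_h
  t <- seq(0, duration_h, by = dt_h)
  set.seed(seed)
  y <- (y0 - plateau) * exp(-k * t) + plateau
  if (noise_sd > 0) y <- y + stats::rnorm(length(t), sd = noise_sd)
  tr <- luminescence_trace(t, y, id = sprintf("sim_hl%.1f", half_life_h))
  attr(tr, "truth") <- list(half_life_h = half_life_h, rate_per_h = k,
                            y0 = y0, plateau = plateau, noise_sd = noise_sd)
  tr
}

#' Set-overlap recovery metrics
#'
#' Precision, recall and F1 of a predicted position set against a truth set
#' over the same index space. An empty prediction against a nonempty truth
#' scores precision 0 (convention) and recall 0; two empty sets score 1.
#'
#' @param predicted Integer vector of predicted positions.
#' @param truth Integer vector of true positions.
#' @return One-row tibble: `n_predicted`, `n_truth`, `n_overlap`,
#'   `precision`, `recall`, `f1`.
#' @export
sector_recovery_metrics <- function(predicted, truth) {
  predicted <- unique(predicted); truth <- unique(truth)
  ov <- length(intersect(predicted, truth))
  if (length(predicted) == 0 && length(truth) == 0) {
    prec <- rec <- f1 <- 1
  } else {
    prec <- if (length(predicted) > 0) ov / length(predicted) else 0
    rec <- if (length(truth) > 0) ov / length(truth) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  tibble::tibble(n_predicted = length(predicted), n_truth = length(truth),
                 n_overlap = ov, precision = prec, recall = rec, f1 = f1)
}
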