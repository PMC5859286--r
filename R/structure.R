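#' Parse a protein structure from a PDB file
#'
#' Reads one chain's protein residues and the named ligand(s) from a PDB
#' file. Waters are ignored; alternate-location atoms are resolved by
#' keeping the highest-occupancy record (ties: first altloc code). Hydrogens
#' are retained when present.
#'
#' @param path PDB file path.
#' @param chain Chain identifier for the protein residues.
#' @param ligands Character vector of ligand residue names (e.g. `"FAD"`).
#' @return Object of class `structure_model`: `chain`; `residues` tibble
#'   (`resno`, `resid`, `elety`, `x`, `y`, `z`); `ligands` named list of
#'   atom tibbles; `sequence` (one-letter, in residue order); `resno`
#'   (residue numbers matching `sequence`).
#' @export
parse_structure <- function(path, chain, ligands = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- tibble::as_tibble(pdb$atom)
  at <- at[at$resid != "HOH", ]
  at <- resolve_altloc(at)
  prot <- at[at$type == "ATOM" & at$chain == chain, ]
  if (nrow(prot) == 0) stop("chain '", chain, "' has no protein atoms",
                            call. = FALSE)
  lig_list <- list()
  for (lg in ligands) {
    la <- at[at$resid == lg & at$chain == chain, ]
    if (nrow(la) == 0) la <- at[at$resid == lg, ]   # ligand on another chain id
    if (nrow(la) == 0) {
      stop("ligand-not-found error: no atoms for ligand '", lg, "'",
           call. = FALSE)
    }
    lig_list[[lg]] <- la[, c("resno", "resid", "elety", "x", "y", "z")]
  }
  ord <- order(prot$resno, prot$insert, na.last = TRUE)
  prot <- prot[ord, ]
  resno <- unique(prot$resno)
  res1 <- vapply(resno, function(rn) {
    aa3 <- prot$resid[prot$resno == rn][1]
    one <- bio3d::aa321(aa3)
    if (is.na(one) || !nzchar(one)) "X" else one
  }, character(1))
  structure(list(chain = chain,
                 residues = prot[, c("resno", "resid", "elety", "x", "y", "z")],
                 ligands = lig_list,
                 sequence = res1, resno = resno),
            class = "structure_model")
}

resolve_altloc <- function(at) {
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(at)
  key <- paste(at$type, at$chain, at$resno, at$resid, at$elety,
               ifelse(is.na(at$insert), "", at$insert))
  occ <- at$o
  occ[is.na(occ)] <- 1
  ord <- order(key, -occ, alt)
  at2 <- at[ord, ]
  key2 <- key[ord]
  at2[!duplicated(key2), ]
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model> chain ", x$chain, ": ", length(x$resno),
      " residues, ligands: ",
      if (length(x$ligands)) paste(names(x$ligands), collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}

#' Define a ligand-binding pocket by a distance cutoff
#'
#' The pocket is the set of residues with at least one atom within `cutoff`
#' angstroms (Euclidean, inclusive) of any atom of the ligand — the rule
#' used to delineate the primary FAD pocket and the secondary antenna
#' pocket.
#'
#' @param s A `structure_model`.
#' @param ligand Ligand name (must be present in `s`).
#' @param cutoff Distance cutoff in angstroms (default 4.0).
#' @return Object of class `pocket_definition`: `ligand`, `cutoff`,
#'   `members` (residue numbers), `table` tibble (`resno`, `resid`,
#'   `min_distance`, `in_pocket`).
#' @export
define_pocket <- function(s, ligand, cutoff = 4.0) {
  if (!(ligand %in% names(s$ligands))) {
    stop("ligand-not-found error: '", ligand, "' not parsed", call. = FALSE)
  }
  lg <- as.matrix(s$ligands[[ligand]][, c("x", "y", "z")])
  res <- s$residues
  dmin <- vapply(split(seq_len(nrow(res)), res$resno), function(ix) {
    pa <- as.matrix(res[ix, c("x", "y", "z")])
    d2 <- outer(rowSums(pa^2), rowSums(lg^2), "+") - 2 * tcrossprod(pa, lg)
    sqrt(max(0, min(d2)))
  }, numeric(1))
  resno <- as.integer(names(dmin))
  resid3 <- vapply(resno, function(rn) res$resid[res$resno == rn][1],
                   character(1))
  tab <- tibble::tibble(resno = resno, resid = resid3,
                        min_distance = unname(dmin),
                        in_pocket = unname(dmin) <= cutoff)
  tab <- tab[order(tab$resno), ]
  structure(list(ligand = ligand, cutoff = cutoff,
                 members = tab$resno[tab$in_pocket], table = tab),
            class = "pocket_definition")
}

#' @export
print.pocket_definition <- function(x, ...) {
  cat("<pocket_definition> ", length(x$members), " residues within ",
      x$cutoff, " A of ", x$ligand, "\n", sep = "")
  invisible(x)
}

#' @method tidy pocket_definition
#' @export
tidy.pocket_definition <- function(x, ...) x$table

#' Map alignment columns to structure residue numbers
#'
#' Globally aligns the (ungapped) reference sequence of the processed
#' alignment against the structure-derived sequence (BLOSUM62, affine gaps)
#' and records matched, non-gap pairs. Alignment columns then map to
#' structure residue numbers through the reference-residue map.
#'
#' @param paln A `processed_alignment` with a retained reference sequence.
#' @param s A `structure_model`.
#' @param min_identity Warn (and optionally return an empty map) below this
#'   alignment identity.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @param empty_on_low_identity Return an empty map instead of a low-identity
#'   one.
#' @return Object of class `column_residue_map`: `table` tibble (`column`,
#'   `ref_residue`, `resno`), `identity`, `params`.
#' @export
map_columns_to_residues <- function(paln, s, min_identity = 0.3,
                                    gap_opening = 10, gap_extension = 0.5,
                                    empty_on_low_identity = FALSE) {
  if (is.null(paln$ref_id)) {
    stop("configuration error: processed alignment has no reference sequence",
         call. = FALSE)
  }
  refrow <- paln$seqs[paln$ref_id, ]
  refseq <- paste(refrow[refrow != GAP_CHAR], collapse = "")
  strseq <- paste(s$sequence, collapse = "")
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  pa <- Biostrings::pairwiseAlignment(
    refseq, strseq, type = "global",
    substitutionMatrix = data_env$BLOSUM62,
    gapOpening = gap_opening, gapExtension = gap_extension)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ri <- 0L; si <- 0L
  pairs <- matrix(NA_integer_, 0, 2)
  n_match <- 0L; n_aligned <- 0L
  for (k in seq_along(ap)) {
    pg <- ap[k] == "-"; sg <- as_[k] == "-"
    if (!pg) ri <- ri + 1L
    if (!sg) si <- si + 1L
    if (!pg && !sg) {
      pairs <- rbind(pairs, c(ri, si))
      n_aligned <- n_aligned + 1L
      if (ap[k] == as_[k]) n_match <- n_match + 1L
    }
  }
  identity <- if (n_aligned > 0) n_match / n_aligned else 0
  if (identity < min_identity) {
    warning("reference-structure alignment identity ", signif(identity, 3),
            " below ", min_identity, call. = FALSE)
    if (empty_on_low_identity) pairs <- pairs[0, , drop = FALSE]
  }
  ref2res <- stats::setNames(s$resno[pairs[, 2]], pairs[, 1])
  cols <- which(!is.na(paln$ref_residue))
  rr <- paln$ref_residue[cols]
  resno <- unname(ref2res[as.character(rr)])
  tab <- tibble::tibble(column = cols, ref_residue = rr, resno = resno)
  tab <- tab[!is.na(tab$resno), ]
  structure(list(table = tab, identity = identity,
                 params = list(substitution = "BLOSUM62",
                               gap_opening = gap_opening,
                               gap_extension = gap_extension)),
            class = "column_residue_map")
}

#' @export
print.column_residue_map <- function(x, ...) {
  cat("<column_residue_map> ", nrow(x$table), " columns mapped (identity ",
      signif(x$identity, 3), ")\n", sep = "")
  invisible(x)
}

#' @method tidy column_residue_map
#' @export
tidy.column_residue_map <- function(x, ...) x$table

#' Overlap between a sector and structural pockets
#'
#' Counts sector positions falling in each pocket (through the
#' column-to-residue map) and scores the enrichment with a hypergeometric
#' tail test over the mapped positions.
#'
#' @param sector A `sector_definition`.
#' @param pockets A `pocket_definition` or list thereof.
#' @param map A `column_residue_map`.
#' @return Tibble with one row per pocket: `pocket`, `n_pocket_mapped`,
#'   `n_sector_mapped`, `n_overlap`, `p_enrichment`, and a list-column
#'   `overlap_resno`.
#' @export
sector_pocket_overlap <- function(sector, pockets, map) {
  if (inherits(pockets, "pocket_definition")) pockets <- list(pockets)
  if (is.null(names(pockets)) || any(!nzchar(names(pockets)))) {
    names(pockets) <- vapply(pockets, function(p) p$ligand, character(1))
  }
  mapped <- map$table
  n_univ <- nrow(mapped)
  sector_resno <- mapped$resno[mapped$column %in% sector$members]
  purrr::map_dfr(names(pockets), function(nm) {
    p <- pockets[[nm]]
    pocket_resno <- intersect(p$members, mapped$resno)
    ov <- intersect(sector_resno, pocket_resno)
    pval <- stats::phyper(length(ov) - 1, length(pocket_resno),
                          n_univ - length(pocket_resno),
                          length(sector_resno), lower.tail = FALSE)
    tibble::tibble(pocket = nm,
                   n_pocket_mapped = length(pocket_resno),
                   n_sector_mapped = length(sector_resno),
                   n_overlap = length(ov),
                   p_enrichment = pval,
                   overlap_resno = list(sort(ov)))
  })
}
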