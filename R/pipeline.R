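#' Default pipeline configuration
#'
#' Returns the full configuration list with every default the pipeline
#' applies, mirroring the YAML schema accepted by [run_pipeline()]. All
#' thresholds of the CPF analysis appear as named defaults: 400/800 residue
#' length bounds, 80% weighting identity, pseudocount 0.03, sector threshold
#' EV1 > 0.03, 4 angstrom pocket cutoff.
#'
#' @return Nested named list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1,
    output_dir = NULL,
    alignment = list(fasta = NULL, reference_id = NULL,
                     annotation_tsv = NULL, simulate = NULL),
    preprocess = list(min_length = 400, max_length = 800,
                      max_gap_pos = 0.4, max_gap_seq = 0.2,
                      ref_identity_min = 0.2, ref_identity_max = 0.8,
                      weight_identity = 0.8,
                      apply_length_filter = TRUE),
    conservation = list(lambda = 0.03, uniform_background = FALSE),
    sca = list(n_modes = 6, sector_threshold = 0.03),
    projection = list(modes = 2),
    structure = list(pdb = NULL, chain = "A", ligands = list("FAD"),
                     cutoff = 4.0)
  )
}

merge_config <- function(defaults, user, path = "", log = NULL) {
  for (nm in names(defaults)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]],
                                     if (is.null(user[[nm]])) list() else user[[nm]],
                                     paste0(path, nm, "."), log)
    } else if (!is.null(user[[nm]])) {
      defaults[[nm]] <- user[[nm]]
    } else if (!is.null(log)) {
      log(paste0("default applied: ", path, nm, " = ",
                 paste(format(defaults[[nm]]), collapse = ",")))
    }
  }
  extra <- setdiff(names(user), names(defaults))
  if (length(extra) > 0) {
    stop("config schema error: unknown key(s) ",
         paste0(path, extra, collapse = ", "), call. = FALSE)
  }
  defaults
}

#' Run the full sector-analysis pipeline
#'
#' Executes preprocess -> conservation -> SCA -> sector -> sequence
#' projection (-> structure overlap when a PDB is configured) as one
#' reproducible run. Inputs come from a YAML config (or equivalent list);
#' all stage outputs are written under the run directory (`inputs/`,
#' `tables/`, `matrices/`, `report.json`, `log.txt`) and the returned
#' manifest summarises every stage. Identical config and seed reproduce
#' byte-identical outputs.
#'
#' @param config Path to a YAML config file, or a nested list with the same
#'   schema (see [default_pipeline_config()]).
#' @param output_dir Overrides `output_dir` from the config.
#' @return The run manifest (list), invisibly; also written as
#'   `report.json`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  log_lines <- character(0)
  logf <- function(msg) log_lines <<- c(log_lines, msg)
  cfg <- merge_config(default_pipeline_config(), config, log = logf)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  if (is.null(cfg$output_dir)) {
    stop("config schema error: output_dir is required", call. = FALSE)
  }
  has_fasta <- !is.null(cfg$alignment$fasta)
  has_sim <- !is.null(cfg$alignment$simulate)
  if (!has_fasta && !has_sim) {
    stop("config schema error: alignment.fasta or alignment.simulate required",
         call. = FALSE)
  }
  dir.create(file.path(cfg$output_dir, "inputs"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(cfg$output_dir, "tables"), showWarnings = FALSE)
  dir.create(file.path(cfg$output_dir, "matrices"), showWarnings = FALSE)
  cfg_snapshot <- cfg
  cfg_snapshot$output_dir <- NULL   # keep report byte-identical across run dirs
  manifest <- list(config = cfg_snapshot, seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("cpfsca")),
                   stages = list())
  set.seed(cfg$seed)

  # --- stage: input alignment -------------------------------------------
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  truth <- NULL
  aln <- stage("input", {
    if (has_sim) {
      sim_args <- cfg$alignment$simulate
      sim_args$seed <- if (is.null(sim_args$seed)) cfg$seed else sim_args$seed
      sim <- do.call(generate_msa, sim_args)
      truth <- sim$truth
      write_alignment(sim$alignment,
                      file.path(cfg$output_dir, "inputs", "alignment.fasta"))
      if (!is.null(truth$labels)) {
        readr::write_tsv(truth$labels,
                         file.path(cfg$output_dir, "inputs", "annotation.tsv"))
      }
      sim$alignment
    } else {
      if (!file.exists(cfg$alignment$fasta)) {
        stop("alignment file not found: ", cfg$alignment$fasta, call. = FALSE)
      }
      read_alignment(cfg$alignment$fasta, ref_id = cfg$alignment$reference_id)
    }
  })
  input_files <- if (has_fasta) cfg$alignment$fasta else
    file.path(cfg$output_dir, "inputs", "alignment.fasta")
  checks <- tools::md5sum(input_files)
  names(checks) <- basename(names(checks))
  manifest$input_checksums <- as.list(checks)
  annotation <- NULL
  if (!is.null(cfg$alignment$annotation_tsv)) {
    annotation <- readr::read_tsv(cfg$alignment$annotation_tsv,
                                  show_col_types = FALSE)
  } else if (has_sim && !is.null(truth$labels)) {
    annotation <- truth$labels
  }

  # --- stage: preprocess -------------------------------------------------
  pc <- cfg$preprocess
  pcfg <- preprocess_config(min_length = pc$min_length,
                            max_length = pc$max_length,
                            max_gap_pos = pc$max_gap_pos,
                            max_gap_seq = pc$max_gap_seq,
                            ref_identity_range = c(pc$ref_identity_min,
                                                   pc$ref_identity_max),
                            weight_identity = pc$weight_identity)
  paln <- stage("preprocess",
                preprocess_alignment(aln, pcfg,
                                     ref_id = cfg$alignment$reference_id,
                                     apply_length_filter = pc$apply_length_filter))
  write_alignment(paln, file.path(cfg$output_dir, "inputs",
                                  "alignment_filtered.fasta"))
  readr::write_tsv(tidy.processed_alignment(paln),
                   file.path(cfg$output_dir, "tables", "weights.tsv"))
  manifest$stages$preprocess <- as.list(glance.processed_alignment(paln))

  # --- stage: conservation ----------------------------------------------
  bg <- background_frequencies(uniform = cfg$conservation$uniform_background)
  freq <- stage("conservation",
                frequency_model(paln, bg, cfg$conservation$lambda))
  phi <- phi_weight(freq)
  cons <- conservation_profile(paln, freq)
  readr::write_tsv(cons, file.path(cfg$output_dir, "tables",
                                   "conservation.tsv"))
  manifest$stages$conservation <- list(lambda = cfg$conservation$lambda,
                                       mean_conservation = mean(cons$conservation),
                                       max_conservation = max(cons$conservation))

  # --- stage: sca --------------------------------------------------------
  sca <- stage("sca", {
    tens <- build_tensor(freq, phi)
    list(tensor = tens, matrix = frobenius_reduce(tens))
  })
  spec <- eigendecompose(sca$matrix, k = min(cfg$sca$n_modes,
                                             ncol(sca$matrix)))
  sector <- define_sector(spec, threshold = cfg$sca$sector_threshold,
                          paln = paln)
  utils::write.table(format(unclass(sca$matrix), digits = 12, trim = TRUE),
                     file.path(cfg$output_dir, "matrices", "sca_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(format(spec$vectors, digits = 12, trim = TRUE),
                     file.path(cfg$output_dir, "matrices", "eigenvectors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  readr::write_tsv(sector$table,
                   file.path(cfg$output_dir, "tables", "sector.tsv"))
  manifest$stages$sca <- list(eigenvalues = spec$values,
                              sector_size = length(sector$members),
                              sector_threshold = cfg$sca$sector_threshold)
  if (has_sim) {
    rec <- sector_recovery_metrics(sector$members, truth$sector_columns)
    manifest$stages$sca$recovery <- as.list(rec[, c("precision", "recall",
                                                    "f1")])
  }

  # --- stage: projection -------------------------------------------------
  reduced <- stage("projection", reduce_alignment(paln, freq, phi))
  seq_spec <- sequence_space_spectral(reduced, paln,
                                      k = max(2, cfg$projection$modes))
  coords <- project_sequences(reduced, paln, seq_spec,
                              modes = seq_len(cfg$projection$modes))
  if (!is.null(annotation)) {
    ann <- annotate_projection(coords, annotation)
    coords_out <- ann$coordinates
    manifest$stages$projection <- list(
      group_summary = lapply(split(ann$summary, ann$summary$label),
                             function(d) as.list(d[, -1])))
  } else {
    coords_out <- coords
    manifest$stages$projection <- list(group_summary = NULL)
  }
  readr::write_tsv(coords_out,
                   file.path(cfg$output_dir, "tables", "coordinates.tsv"))

  # --- stage: structure --------------------------------------------------
  if (!is.null(cfg$structure$pdb)) {
    ov <- stage("structure", {
      s <- parse_structure(cfg$structure$pdb, cfg$structure$chain,
                           unlist(cfg$structure$ligands))
      pockets <- lapply(unlist(cfg$structure$ligands), function(lg)
        define_pocket(s, lg, cfg$structure$cutoff))
      names(pockets) <- unlist(cfg$structure$ligands)
      map <- map_columns_to_residues(paln, s)
      for (nm in names(pockets)) {
        readr::write_tsv(pockets[[nm]]$table,
                         file.path(cfg$output_dir, "tables",
                                   paste0("pocket_", nm, ".tsv")))
      }
      sector_pocket_overlap(sector, pockets, map)
    })
    manifest$stages$structure <- lapply(seq_len(nrow(ov)), function(i)
      list(pocket = ov$pocket[i], n_pocket_mapped = ov$n_pocket_mapped[i],
           n_sector_mapped = ov$n_sector_mapped[i],
           n_overlap = ov$n_overlap[i], p_enrichment = ov$p_enrichment[i]))
    readr::write_tsv(ov[, setdiff(names(ov), "overlap_resno")],
                     file.path(cfg$output_dir, "tables", "overlap.tsv"))
  }

  jsonlite::write_json(manifest, file.path(cfg$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(log_lines, file.path(cfg$output_dir, "log.txt"))
  invisible(manifest)
}
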