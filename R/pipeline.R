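# End-to-end driver: generate synthetic inputs, write them to disk in
# standard formats, read them back, run every analysis stage, and write
# the result tables. Everything is a pure function of the configuration,
# so two runs with the same config produce byte-identical files.

RISK_POSE_SHAPES <- list(
  risk = list(PBG = c(B = 1L, F = 9L), Top3 = c(B = 1L, F = 7L, O = 2L)),
  possible_risk = list(PBG = c(F = 10L), Top3 = c(B = 6L, O = 4L)),
  control = list(PBG = c(B = 8L, F = 2L), Top3 = c(B = 7L, F = 3L)))

#' Simulate a complete synthetic study
#'
#' Generates every input the pipeline consumes: the groove structure,
#' per allele x drug x search-space pose sets (risk alleles
#' predominantly in the F pocket, controls in the B pocket, mirroring
#' the docking pattern under study), the allele panel (alignment,
#' frequency table, PSSMs) and the planted truth.
#'
#' @param config A [sim_config()].
#' @param ligands Named logical vector: ligand code -> carries a
#'   thiocarbonyl group. Defaults to methimazole-like (`MMZ`, with C=S)
#'   and a non-thioamide comparator (`DMI`, without).
#' @return List with `groove`, `pose_sets` (named
#'   `<allele>_<ligand>_<space>`, each with planted labels), `panel`,
#'   and `config`.
#' @export
simulate_study <- function(config = sim_config(),
                           ligands = c(MMZ = TRUE, DMI = FALSE)) {
  groove <- make_groove(config)
  panel <- make_allele_panel(config)
  rows <- panel$alignment$rows
  keep <- rows$status %in% c("risk", "possible_risk", "control")
  pose_sets <- list()
  for (i in which(keep)) {
    shapes <- RISK_POSE_SHAPES[[rows$status[i]]]
    for (lig in names(ligands)) {
      for (space in names(shapes)) {
        key <- paste(rows$allele[i], lig, space, sep = "_")
        pose_sets[[key]] <- make_pose_set(
          config, n_per_pocket = shapes[[space]], ligand_id = lig,
          thiocarbonyl = ligands[[lig]], search_space = space,
          salt = string_salt(key))
      }
    }
  }
  list(groove = groove, pose_sets = pose_sets, panel = panel,
       config = config)
}

#' Write a simulated study to disk as standard formats
#'
#' Emits PDB (groove), multi-model PDB pose sets with embedded scores,
#' aligned FASTA plus a status-label CSV, the frequency CSV, plain-text
#' PSSM files, and a JSON truth sidecar (planted labels are only ever in
#' the sidecar, never in the analysis-facing files).
#'
#' @param study From [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "poses"), showWarnings = FALSE)
  dir.create(file.path(dir, "pssm"), showWarnings = FALSE)
  write_structure(study$groove, file.path(dir, "groove.pdb"))
  planted <- list()
  for (key in names(study$pose_sets)) {
    write_pose_set(study$pose_sets[[key]],
                   file.path(dir, "poses", paste0(key, ".pdb")))
    planted[[key]] <- attr(study$pose_sets[[key]], "planted")
  }
  write_alignment(study$panel$alignment, file.path(dir, "alignment.fasta"),
                  file.path(dir, "labels.csv"))
  utils::write.csv(study$panel$frequency_table,
                   file.path(dir, "frequencies.csv"),
                   row.names = FALSE, quote = FALSE)
  for (nm in names(study$panel$pssms)) {
    write_pssm(study$panel$pssms[[nm]],
               file.path(dir, "pssm", paste0(nm, ".pssm")))
  }
  truth <- study$panel$truth
  truth$pose_labels <- planted
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the full analysis pipeline on a directory of study inputs
#'
#' Reads the inputs written by [write_study()] (or real data laid out the
#' same way), runs every stage -- pocket assignment, pose summaries,
#' Thr80 interaction tabulation, risk-unique residue scan, control
#' selection, motif distances and UPGMA tree -- and writes the result
#' tables to `outdir`. Fully deterministic for a fixed input directory
#' and seed.
#'
#' @param indir Input directory (layout of [write_study()]).
#' @param outdir Output directory (created if needed).
#' @param seed Seed forwarded to the (deterministic) clustering.
#' @param groove_radius Outside-groove threshold in Angstrom.
#' @return Invisible list of the in-memory results.
#' @export
run_pipeline <- function(indir, outdir, seed = 1L, groove_radius = 12) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  groove <- read_structure(file.path(indir, "groove.pdb"))
  model <- build_pocket_model(groove, groove_radius = groove_radius)

  pose_files <- sort(list.files(file.path(indir, "poses"),
                                full.names = TRUE))
  assignments <- list()
  for (pf in pose_files) {
    key <- sub("\\.pdb$", "", basename(pf))
    parts <- strsplit(key, "_")[[1L]]
    n <- length(parts)
    allele <- paste(parts[seq_len(n - 2L)], collapse = "_")
    lig <- parts[n - 1L]
    space <- parts[n]
    poses <- read_pose_set(pf, search_space = space, ligand_id = lig)
    a <- assign_pockets(groove, poses, k = 2L, seed = seed,
                        groove_radius = groove_radius)
    a$allele <- allele
    a$ligand_id <- lig
    assignments[[key]] <- list(table = a, poses = poses)
  }
  assign_tab <- do.call(rbind, lapply(assignments, `[[`, "table"))
  rownames(assign_tab) <- NULL
  utils::write.table(assign_tab, file.path(outdir, "pocket_assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary_tab <- summarize_poses(assign_tab)
  labels <- utils::read.csv(file.path(indir, "labels.csv"),
                            stringsAsFactors = FALSE)
  alignment <- read_alignment(file.path(indir, "alignment.fasta"),
                              labels = labels,
                              reference = labels$allele[
                                labels$status == "control"][1L])
  annotations <- data.frame(
    allele = labels$allele,
    status = labels$status,
    mutation = vapply(labels$allele, function(a) {
      tryCatch(mutation_label(alignment, a, 80L, "N"),
               error = function(e) "")
    }, character(1L)),
    stringsAsFactors = FALSE)
  write_pose_summary(summary_tab, file.path(outdir, "pose_summary.tsv"),
                     annotations = annotations, include_O = TRUE)

  # Thr80 interaction taxonomy over the groove-search pose sets of the
  # risk alleles
  thr80 <- list()
  risk_alleles <- labels$allele[labels$status == "risk"]
  for (key in names(assignments)) {
    a <- assignments[[key]]$table
    if (!(a$allele[1L] %in% risk_alleles) || a$search_space[1L] != "PBG") next
    poses <- assignments[[key]]$poses
    classes <- vapply(poses, function(p) {
      classify_thr80(detect_contacts(groove, p), p, groove, position = 80L)
    }, character(1L))
    row <- tabulate_thr80(classes, vapply(poses, `[[`, numeric(1L), "score"))
    thr80[[key]] <- c(list(allele = a$allele[1L], ligand = a$ligand_id[1L]),
                      as.list(row))
  }
  jsonlite::write_json(thr80, file.path(outdir, "thr80_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  positions <- scan_unique_residues(alignment)
  utils::write.table(positions, file.path(outdir, "unique_positions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  freq <- read_frequency_table(file.path(indir, "frequencies.csv"))
  controls <- select_controls(freq, details = TRUE)
  utils::write.csv(controls, file.path(outdir, "selected_controls.csv"),
                   row.names = FALSE, quote = FALSE)

  pssm_files <- sort(list.files(file.path(indir, "pssm"),
                                full.names = TRUE))
  pssms <- lapply(pssm_files, read_pssm)
  names(pssms) <- vapply(pssms, attr, character(1L), "allele")
  dmat <- motif_distance_matrix(pssms)
  utils::write.csv(round(dmat, 6L), file.path(outdir, "motif_distances.csv"),
                   quote = FALSE)
  tree <- build_tree(dmat, file = file.path(outdir, "motif_tree.nwk"))

  invisible(list(assignments = assign_tab, summary = summary_tab,
                 thr80 = thr80, positions = positions, controls = controls,
                 distances = dmat, tree = tree))
}
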