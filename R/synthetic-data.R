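# Synthetic study inputs with planted ground truth: a pseudo-groove
# structure, docking pose clouds, allele sequence panels, case/control
# frequency tables and clustered PSSM sets. A single root seed drives
# independent per-stream substreams so adding one generator call never
# perturbs another stream's output.

#' Simulation configuration
#'
#' Bundles the parameters of every synthetic-data stream. The defaults
#' emulate the study conditions of the docking analysis: two groove
#' pockets 15 Angstrom apart with 1.5 Angstrom pose spread, 10 poses per
#' search space, docking scores of a few kcal/mol favouring the F pocket
#' for risk alleles, allele panels sharing planted residues at mature
#' positions 67 and 80 (with one possible-risk allele differing from a
#' risk allele only by Thr80Ile), frequency tables with tens of cases and
#' hundreds to thousands of controls, and two-cluster PSSM panels with a
#' near-duplicate allele pair.
#'
#' @param seed Root seed; identical configurations are bit-reproducible.
#' @param pocket_separation Distance between B and F pocket centres
#'   (Angstrom).
#' @param pocket_spread Gaussian sigma of pose reference atoms around
#'   their pocket centre (Angstrom).
#' @param score_mean,score_sd Named per-pocket docking score parameters
#'   (kcal/mol, lower = more favourable).
#' @param n_poses Poses per allele per drug per search space.
#' @param n_risk,n_possible,n_control,n_common Allele panel sizes.
#' @param seq_length Mature-protein sequence length of the panel.
#' @param planted_positions Named character vector: mature position ->
#'   residue shared by all risk alleles.
#' @param control_residues Named character vector: mature position ->
#'   residue carried by controls at the planted positions.
#' @param planted_or Odds ratio planted for enriched (risk) alleles in
#'   the frequency table; 1 for null alleles.
#' @param case_n,control_n Cohort sizes (individuals).
#' @param n_healthy_pops,healthy_pop_n Number of healthy reference
#'   populations in the table and individuals per population.
#' @param healthy_spread Range of the per-population multiplicative
#'   factor on the background allele frequency, emulating the large
#'   cross-population spread seen in population frequency databases.
#' @param pssm_clusters,pssm_per_cluster,pssm_noise PSSM panel shape:
#'   number of cluster prototypes, members per cluster, and noise
#'   standard deviation as a fraction of the prototype signal range.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       pocket_separation = 15,
                       pocket_spread = 1.5,
                       score_mean = c(B = -3.4, F = -4.2, O = -3.6),
                       score_sd = c(B = 0.3, F = 0.3, O = 0.3),
                       n_poses = 10L,
                       n_risk = 2L, n_possible = 1L,
                       n_control = 5L, n_common = 4L,
                       seq_length = 120L,
                       planted_positions = c("67" = "C", "80" = "T"),
                       control_residues = c("67" = "Y", "80" = "N"),
                       planted_or = 7,
                       case_n = 50L, control_n = 1000L,
                       n_healthy_pops = 6L, healthy_pop_n = 1000L,
                       healthy_spread = c(0.6, 1.9),
                       pssm_clusters = 2L, pssm_per_cluster = 4L,
                       pssm_noise = 0.05) {
  stopifnot(pocket_spread > 0, planted_or >= 1, seq_length >= 1L)
  if (any(as.integer(names(planted_positions)) > seq_length)) {
    stop("planted position beyond sequence length ", seq_length)
  }
  cfg <- list(seed = as.integer(seed),
              pocket_separation = pocket_separation,
              pocket_spread = pocket_spread,
              score_mean = score_mean, score_sd = score_sd,
              n_poses = as.integer(n_poses),
              n_risk = n_risk, n_possible = n_possible,
              n_control = n_control, n_common = n_common,
              seq_length = as.integer(seq_length),
              planted_positions = planted_positions,
              control_residues = control_residues,
              planted_or = planted_or,
              case_n = as.integer(case_n), control_n = as.integer(control_n),
              n_healthy_pops = as.integer(n_healthy_pops),
              healthy_pop_n = as.integer(healthy_pop_n),
              healthy_spread = healthy_spread,
              pssm_clusters = pssm_clusters,
              pssm_per_cluster = pssm_per_cluster,
              pssm_noise = pssm_noise)
  class(cfg) <- "sim_config"
  cfg
}

# Independent substream seed per generator stream (kept below 2^31).
stream_seed <- function(config, stream, salt = 0L) {
  offsets <- c(groove = 11L, poses = 23L, sequences = 37L,
               frequencies = 41L, pssms = 53L)
  if (!stream %in% names(offsets)) stop("unknown stream: ", stream)
  base <- (as.numeric(config$seed) * 7919 + offsets[[stream]] * 104729 +
             as.numeric(salt) * 131) %% 2147483647
  as.integer(base)
}

# stable small integer from a string, for per-pose-set salts
string_salt <- function(x) {
  sum(utf8ToInt(x) * seq_along(utf8ToInt(x))) %% 10000L
}

# pocket centres used by the generator: B at the origin, F along +x,
# an outside-groove site well away from both
pocket_centers <- function(config) {
  sep <- config$pocket_separation
  list(B = c(0, 0, 0), F = c(sep, 0, 0), O = c(sep / 2, 2 * sep, 0))
}

#' Generate a synthetic groove structure
#'
#' A pseudo-protein carrying side-chain atoms for every configured B- and
#' F-pocket residue position, placed around two centres separated by the
#' configured distance, in mature 1-based numbering. Residue 80 is built
#' as THR (with an OG1 side-chain oxygen) and residue 67 as CYS (with an
#' SG), so contact detection and the Thr80 taxonomy behave as on real
#' structures; all other residues are ALA stand-ins.
#'
#' @param config A [sim_config()].
#' @param definitions Pocket residue sets (default
#'   [default_pocket_definitions()]).
#' @return A `structure3d`; centre-proximity warnings, if any, are
#'   recorded in `attr(, "metadata")`.
#' @export
make_groove <- function(config, definitions = default_pocket_definitions()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config, "groove"))
  centers <- pocket_centers(config)
  meta <- character()
  if (sqrt(sum((centers$B - centers$F)^2)) < 2 * config$pocket_spread) {
    meta <- c(meta, "pocket centres closer than 2 sigma")
  }
  rows <- list()
  serial <- 0L
  add_atom <- function(name, element, resname, resno, xyz) {
    serial <<- serial + 1L
    data.frame(serial = serial, name = name, element = element,
               resname = resname, resno = resno, chain = "A",
               x = xyz[1L], y = xyz[2L], z = xyz[3L],
               stringsAsFactors = FALSE)
  }
  for (pocket in intersect(names(definitions), c("B", "F"))) {
    center <- centers[[pocket]]
    for (resno in definitions[[pocket]]) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      r <- stats::runif(1, 2.5, 4.5)
      cb <- center + u * r
      ca <- center + u * (r + 1.5)
      resname <- if (resno == 80L) "THR" else if (resno == 67L) "CYS" else "ALA"
      rows[[length(rows) + 1L]] <- add_atom("CA", "C", resname, resno, ca)
      rows[[length(rows) + 1L]] <- add_atom("CB", "C", resname, resno, cb)
      if (resno == 80L) {
        rows[[length(rows) + 1L]] <- add_atom("OG1", "O", resname, resno,
                                              center + u * (r - 1.4))
      }
      if (resno == 67L) {
        rows[[length(rows) + 1L]] <- add_atom("SG", "S", resname, resno,
                                              center + u * (r - 1.8))
      }
    }
  }
  atoms <- do.call(rbind, rows)
  out <- new_structure3d(atoms, "synthetic_groove")
  attr(out, "metadata") <- meta
  out
}

# Deterministic minimal ligand: five-membered C/N ring (imidazole-like)
# with the reference atom C1 at `center`; when thiocarbonyl = TRUE a
# sulfur sits at the canonical C=S length (1.68 A) radially beyond C1
# along `direction`.
synthetic_ligand_atoms <- function(center, direction = c(1, 0, 0),
                                   perp = NULL, thiocarbonyl = TRUE,
                                   serial_start = 9001L) {
  u <- direction / sqrt(sum(direction^2))
  if (is.null(perp)) {
    perp <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  }
  w <- perp - sum(perp * u) * u
  w <- w / sqrt(sum(w^2))
  ring_r <- 1.19                       # pentagon side ~1.40 A
  rc <- center - ring_r * u
  names_ring <- c("C1", "N2", "C3", "C4", "N5")
  elem_ring <- c("C", "N", "C", "C", "N")
  ang <- 2 * pi * (0:4) / 5
  pos <- lapply(seq_len(5L), function(k) {
    rc + ring_r * (cos(ang[k]) * u + sin(ang[k]) * w)
  })
  nm <- names_ring
  el <- elem_ring
  if (thiocarbonyl) {
    pos <- c(pos, list(center + 1.68 * u))
    nm <- c(nm, "S1")
    el <- c(el, "S")
  }
  data.frame(serial = serial_start + seq_along(nm) - 1L,
             name = nm, element = el, resname = "LIG",
             resno = 1L, chain = "L",
             x = vapply(pos, `[`, numeric(1L), 1L),
             y = vapply(pos, `[`, numeric(1L), 2L),
             z = vapply(pos, `[`, numeric(1L), 3L),
             stringsAsFactors = FALSE)
}

#' Construct a single synthetic ligand pose
#'
#' Deterministic helper for placing one ligand with its reference atom
#' `C1` at a chosen point and, optionally, its thiocarbonyl sulfur
#' extending along a chosen direction -- useful for geometric tests
#' (e.g. planting the sulfur within contact range of residue 80).
#'
#' @param center 3-vector: position of the reference atom `C1`.
#' @param direction 3-vector: direction from the ring towards the
#'   thiocarbonyl sulfur.
#' @param thiocarbonyl Include the C=S sulfur (`S1`)?
#' @param score,run_id,search_space,ligand_id Pose metadata.
#' @return A `ligand_pose`.
#' @export
synthetic_ligand_pose <- function(center, direction = c(1, 0, 0),
                                  thiocarbonyl = TRUE, score = -4,
                                  run_id = 1L, search_space = "PBG",
                                  ligand_id = "MMZ") {
  atoms <- synthetic_ligand_atoms(center, direction,
                                  thiocarbonyl = thiocarbonyl)
  new_ligand_pose(atoms, score = score, run_id = run_id,
                  search_space = search_space, ligand_id = ligand_id)
}

#' Generate a synthetic docking pose set with planted pocket labels
#'
#' Reference atoms are drawn from a Gaussian around each planted
#' pocket's centre; scores from the pocket's score distribution. The
#' planted labels travel as `attr(, "planted")`, never inside the
#' pose records themselves.
#'
#' @param config A [sim_config()].
#' @param n_per_pocket Named integer vector of planted pose counts, e.g.
#'   `c(B = 1, F = 9)`; an `O` entry places poses far outside the
#'   groove.
#' @param ligand_id Ligand code (e.g. `"MMZ"`, `"PTU"`, `"DMI"`).
#' @param thiocarbonyl Does the ligand carry the C=S group? (The
#'   non-thioamide comparators do not.)
#' @param search_space Search-space tag for the whole set.
#' @param score_shift Constant added to all score means (drug-level
#'   offset).
#' @param salt Extra substream salt so that sets for different
#'   allele/drug/space combinations are independent; defaults to a hash
#'   of `ligand_id` and `search_space`.
#' @return List of `ligand_pose` with attribute `planted` (character
#'   labels).
#' @export
make_pose_set <- function(config, n_per_pocket = c(B = 1L, F = 9L),
                          ligand_id = "MMZ", thiocarbonyl = TRUE,
                          search_space = "PBG", score_shift = 0,
                          salt = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(salt)) {
    salt <- string_salt(paste(ligand_id, search_space))
  }
  set.seed(stream_seed(config, "poses", salt))
  centers <- pocket_centers(config)
  labels <- rep(names(n_per_pocket), times = n_per_pocket)
  n <- length(labels)
  poses <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- labels[i]
    c1 <- centers[[lab]] + stats::rnorm(3, 0, config$pocket_spread)
    u <- stats::rnorm(3)
    perp <- stats::rnorm(3)
    score <- stats::rnorm(1, config$score_mean[[lab]] + score_shift,
                          config$score_sd[[lab]])
    atoms <- synthetic_ligand_atoms(c1, direction = u, perp = perp,
                                    thiocarbonyl = thiocarbonyl)
    poses[[i]] <- new_ligand_pose(atoms, score = round(score, 4L),
                                  run_id = i, search_space = search_space,
                                  ligand_id = ligand_id)
  }
  attr(poses, "planted") <- labels
  poses
}

#' Generate a synthetic allele panel with planted ground truth
#'
#' Builds three linked inputs: (1) an allele alignment in which all risk
#' alleles share the planted residues (default Cys at 67, Thr at 80),
#' exactly one possible-risk allele equals the second risk allele except
#' for a single Thr80Ile difference, and control/common alleles carry
#' other residues at the planted positions plus scattered private
#' variation; (2) a case/control/healthy frequency table in which risk
#' alleles are enriched at the configured odds ratio and control alleles
#' are null, realised by binomial sampling at the configured cohort
#' sizes; (3) a PSSM set drawn from cluster prototypes plus noise, with
#' one near-duplicate pair (the Thr80Ile analog pair) inside the first
#' cluster.
#'
#' Allele names are synthetic (`R01`, `R02` risk; `P01` possible risk;
#' `C01`.. controls; `M01`.. common).
#'
#' @param config A [sim_config()].
#' @return List with elements `alignment` (an `allele_alignment`,
#'   reference row `C01`), `frequency_table`, `pssms` (named list), and
#'   `truth` (planted positions, per-allele odds ratios, PSSM cluster
#'   membership and the near-duplicate pair).
#' @export
make_allele_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config, "sequences"))
  L <- config$seq_length
  planted_pos <- as.integer(names(config$planted_positions))
  planted_res <- unname(config$planted_positions)
  ctrl_res <- unname(config$control_residues[names(config$planted_positions)])

  consensus <- sample(AA_LETTERS, L, replace = TRUE)
  consensus[planted_pos] <- ctrl_res

  risk_names <- sprintf("R%02d", seq_len(config$n_risk))
  poss_names <- if (config$n_possible > 0L) {
    sprintf("P%02d", seq_len(config$n_possible))
  } else character()
  ctrl_names <- sprintf("C%02d", seq_len(config$n_control))
  common_names <- if (config$n_common > 0L) {
    sprintf("M%02d", seq_len(config$n_common))
  } else character()

  seqs <- list()
  for (nm in risk_names) {
    s <- consensus
    s[planted_pos] <- planted_res
    seqs[[nm]] <- s
  }
  # one possible-risk allele: copy of the last risk allele differing at
  # exactly one planted position (the Thr80Ile analog)
  if (length(poss_names) > 0L) {
    anchor <- seqs[[risk_names[length(risk_names)]]]
    flip_at <- planted_pos[length(planted_pos)]
    s <- anchor
    s[flip_at] <- "I"
    seqs[[poss_names[1L]]] <- s
    for (nm in poss_names[-1L]) seqs[[nm]] <- s
  }
  for (nm in c(ctrl_names, common_names)) seqs[[nm]] <- consensus
  # scattered private variation away from the planted positions; only
  # ever one row per column, so no column becomes discriminating
  free_pos <- setdiff(seq_len(L), planted_pos)
  var_pos <- sample(free_pos, min(6L, length(free_pos)))
  var_rows <- sample(c(ctrl_names, common_names), length(var_pos),
                     replace = TRUE)
  for (i in seq_along(var_pos)) {
    p <- var_pos[i]
    old <- seqs[[var_rows[i]]][p]
    seqs[[var_rows[i]]][p] <- sample(setdiff(AA_LETTERS, old), 1L)
  }
  # one control mirrors the Ile-at-80 polymorphism seen among controls
  if (length(ctrl_names) >= 4L && "80" %in% names(config$planted_positions)) {
    seqs[[ctrl_names[4L]]][80L] <- "I"
  }

  alleles <- c(risk_names, poss_names, ctrl_names, common_names)
  statuses <- c(rep("risk", length(risk_names)),
                rep("possible_risk", length(poss_names)),
                rep("control", length(ctrl_names)),
                rep("common", length(common_names)))
  alignment <- allele_alignment(
    alleles, statuses,
    vapply(seqs[alleles], paste, character(1L), collapse = ""),
    numbering_offset = 0L, reference = ctrl_names[1L])

  freq <- make_frequency_table(config, risk_names, poss_names, ctrl_names)

  pssm_set <- make_pssm_panel(config, alleles = c(risk_names, poss_names,
                                                  ctrl_names))

  list(alignment = alignment,
       frequency_table = freq$table,
       pssms = pssm_set$pssms,
       truth = list(planted_positions = stats::setNames(planted_res,
                                                        planted_pos),
                    possible_risk_pair = if (length(poss_names) > 0L) {
                      c(risk_names[length(risk_names)], poss_names[1L])
                    },
                    planted_or = freq$planted_or,
                    pssm_clusters = pssm_set$clusters,
                    near_duplicate_pair = pssm_set$near_duplicate_pair))
}

# Frequency table with planted enrichment: risk (+possible-risk) alleles
# get the configured odds ratio, controls are null; case and control
# frequencies realised by binomial sampling on chromosomes (2n).
make_frequency_table <- function(config, risk_names, poss_names,
                                 ctrl_names) {
  set.seed(stream_seed(config, "frequencies"))
  alleles <- c(risk_names, poss_names, ctrl_names, "X01", "X02")
  or <- stats::setNames(rep(1, length(alleles)), alleles)
  or[c(risk_names, poss_names)] <- config$planted_or
  p_ctrl <- stats::runif(length(alleles), 0.04, 0.12)
  names(p_ctrl) <- alleles
  p_ctrl[c("X01", "X02")] <- stats::runif(2L, 0.002, 0.02)  # fail the screen
  p_case <- or * p_ctrl / (1 + (or - 1) * p_ctrl)
  case_chr <- 2L * config$case_n
  ctrl_chr <- 2L * config$control_n
  tab <- data.frame(
    allele = alleles,
    case_freq = stats::rbinom(length(alleles), case_chr, p_case) / case_chr,
    study_control_freq = stats::rbinom(length(alleles), ctrl_chr,
                                       p_ctrl) / ctrl_chr,
    case_n = config$case_n,
    control_n = config$control_n,
    stringsAsFactors = FALSE)
  # healthy-population frequencies: population databases show large
  # cross-population spread for HLA-B alleles (factors of 2-10 between
  # populations), emulated as a per-population multiplicative factor on
  # the background frequency; healthy cohorts are never enriched.
  pops <- sprintf("pop%02d", seq_len(config$n_healthy_pops))
  pop_chr <- 2L * config$healthy_pop_n
  for (pop in pops) {
    spread <- stats::runif(length(alleles), config$healthy_spread[1L],
                           config$healthy_spread[2L])
    p_pop <- pmin(p_ctrl * spread, 0.5)
    tab[[pop]] <- stats::rbinom(length(alleles), pop_chr, p_pop) / pop_chr
  }
  list(table = validate_frequency_table(tab), planted_or = or)
}

# Two-cluster PSSM panel + near-duplicate pair inside cluster 1
make_pssm_panel <- function(config, alleles) {
  set.seed(stream_seed(config, "pssms"))
  k <- config$pssm_clusters
  n <- length(alleles)
  protos <- lapply(seq_len(k), function(i) matrix(stats::rnorm(180), 9L, 20L))
  per <- ceiling(n / k)
  cluster <- rep(seq_len(k), each = per)[seq_len(n)]
  names(cluster) <- alleles
  pssms <- vector("list", n)
  names(pssms) <- alleles
  near_pair <- NULL
  for (i in seq_len(n)) {
    proto <- protos[[cluster[i]]]
    noise_sd <- config$pssm_noise * diff(range(proto))
    pssms[[i]] <- pssm(proto + matrix(stats::rnorm(180, 0, noise_sd), 9L, 20L),
                       allele = alleles[i])
  }
  # near-duplicate pair: second and third allele of cluster 1 share one
  # realisation up to a tiny jitter (the Thr80Ile analog pair)
  in1 <- alleles[cluster == 1L]
  if (length(in1) >= 3L) {
    near_pair <- in1[2:3]
    base <- unclass(pssms[[near_pair[1L]]])
    tiny <- 0.002 * diff(range(base))
    pssms[[near_pair[2L]]] <- pssm(base + matrix(stats::rnorm(180, 0, tiny),
                                                 9L, 20L),
                                   allele = near_pair[2L])
  }
  list(pssms = pssms, clusters = cluster, near_duplicate_pair = near_pair)
}
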