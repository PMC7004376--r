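# Ligand-residue interaction detection (LigPlot-style hydrophobic
# contacts and heavy-atom hydrogen bonds) and the Thr80/thiocarbonyl pose
# taxonomy.

#' Interaction detection cutoffs
#'
#' Heavy-atom distance windows for contact detection. Defaults follow
#' common LigPlot-style conventions: hydrophobic contacts between
#' nonpolar (C, S) atoms within 2.9-3.9 Angstrom, hydrogen bonds between
#' N/O/S donor-acceptor pairs within 3.35 Angstrom, no explicit
#' hydrogens and no angle term.
#'
#' @param hphob_min,hphob_max Hydrophobic contact window (Angstrom).
#' @param hbond_max Donor-acceptor heavy-atom maximum (Angstrom).
#' @return List of cutoffs.
#' @export
contact_params <- function(hphob_min = 2.9, hphob_max = 3.9,
                           hbond_max = 3.35) {
  stopifnot(hphob_min > 0, hphob_max >= hphob_min, hbond_max > 0)
  list(hphob_min = hphob_min, hphob_max = hphob_max, hbond_max = hbond_max)
}

NONPOLAR_ELEMENTS <- c("C", "S")
POLAR_ELEMENTS <- c("N", "O", "S")

#' Locate a thiocarbonyl sulfur in a ligand
#'
#' Finds a sulfur in the C=S pattern shared by the anti-thyroid drugs:
#' a terminal sulfur (exactly one heavy-atom neighbour within
#' `thio_bond_max`) bonded to a carbon that itself has at least two other
#' heavy neighbours (a ring or chain carbon). Thioether sulfurs (C-S-C)
#' have two neighbours and are rejected. Absence is a valid outcome:
#' ligands without the thiocarbonyl group return `NA`.
#'
#' @param pose A `ligand_pose`.
#' @param thio_bond_max C=S bond-length cutoff (Angstrom); the canonical
#'   thiocarbonyl bond is about 1.68 Angstrom.
#' @param bond_max Generic heavy-atom bond cutoff used to count the
#'   carbon's other neighbours.
#' @return The sulfur atom's name, or `NA_character_` when no
#'   thiocarbonyl is present.
#' @export
find_thiocarbonyl_sulfur <- function(pose, thio_bond_max = 1.85,
                                     bond_max = 1.75) {
  stopifnot(inherits(pose, "ligand_pose"))
  atoms <- pose$atoms
  heavy <- atoms[atoms$element != "H", , drop = FALSE]
  xyz <- as.matrix(heavy[c("x", "y", "z")])
  s_rows <- which(heavy$element == "S")
  for (i in s_rows) {
    d <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    nbr <- which(d > 0 & d <= thio_bond_max)
    if (length(nbr) != 1L) next           # terminal sulfur only (not C-S-C)
    j <- nbr[1L]
    if (heavy$element[j] != "C") next
    dj <- sqrt(rowSums(sweep(xyz, 2, xyz[j, ])^2))
    others <- which(dj > 0 & dj <= bond_max)
    others <- setdiff(others, i)
    if (length(others) >= 2L) {
      return(heavy$name[i])
    }
  }
  NA_character_
}

# Hydrogen-bond capability templates for standard residues; atoms not
# covered default to both roles so simplified synthetic residues keep
# working. Returns c(donor, acceptor).
protein_hbond_capability <- function(resname, atom_name) {
  if (atom_name == "N") return(c(TRUE, FALSE))     # backbone amide
  if (atom_name %in% c("O", "OXT")) return(c(FALSE, TRUE))
  key <- paste(resname, atom_name)
  templates <- list(
    "SER OG"  = c(TRUE, TRUE),  "THR OG1" = c(TRUE, TRUE),
    "TYR OH"  = c(TRUE, TRUE),  "CYS SG"  = c(TRUE, TRUE),
    "ASN OD1" = c(FALSE, TRUE), "ASN ND2" = c(TRUE, FALSE),
    "GLN OE1" = c(FALSE, TRUE), "GLN NE2" = c(TRUE, FALSE),
    "ASP OD1" = c(FALSE, TRUE), "ASP OD2" = c(FALSE, TRUE),
    "GLU OE1" = c(FALSE, TRUE), "GLU OE2" = c(FALSE, TRUE),
    "LYS NZ"  = c(TRUE, FALSE), "ARG NE"  = c(TRUE, FALSE),
    "ARG NH1" = c(TRUE, FALSE), "ARG NH2" = c(TRUE, FALSE),
    "HIS ND1" = c(TRUE, TRUE),  "HIS NE2" = c(TRUE, TRUE),
    "TRP NE1" = c(TRUE, FALSE), "HOH O"   = c(TRUE, TRUE))
  if (!is.null(templates[[key]])) return(templates[[key]])
  c(TRUE, TRUE)
}

#' Detect ligand-residue contacts
#'
#' All-pairs heavy-atom scan between a protein structure and one docked
#' pose. A hydrophobic record is produced for every (protein C/S, ligand
#' C/S) pair whose distance falls inside the hydrophobic window; a
#' hydrogen-bond record for every N/O/S pair within the hydrogen-bond
#' cutoff where one side can donate and the other accept (residue
#' templates on the protein side; per-ligand donor/acceptor annotations
#' in `pose$donors`/`pose$acceptors`, defaulting to all polar atoms in
#' both roles). Records are sorted by distance.
#'
#' @param structure Protein `structure3d` (mature numbering assumed).
#' @param pose A `ligand_pose`.
#' @param params Cutoffs from [contact_params()].
#' @return Data frame of interaction records: `residue_position`,
#'   `residue_name`, `protein_atom`, `ligand_atom`, `kind`
#'   (`"hydrophobic"` or `"hbond"`), `distance`.
#' @export
detect_contacts <- function(structure, pose, params = contact_params()) {
  stopifnot(inherits(structure, "structure3d"), inherits(pose, "ligand_pose"))
  if (length(intersect(structure$atoms$serial, pose$atoms$serial)) > 0L) {
    stop("structure and pose share atom serial numbers; renumber one of them")
  }
  prot <- structure$atoms[structure$atoms$element != "H", , drop = FALSE]
  lig <- pose$atoms[pose$atoms$element != "H", , drop = FALSE]
  if (nrow(prot) == 0L || nrow(lig) == 0L) return(empty_interactions())
  P <- as.matrix(prot[c("x", "y", "z")])
  L <- as.matrix(lig[c("x", "y", "z")])
  d2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L)
  d <- sqrt(pmax(d2, 0))

  recs <- list()
  # hydrophobic: nonpolar-nonpolar within the window
  hp <- which(outer(prot$element %in% NONPOLAR_ELEMENTS,
                    lig$element %in% NONPOLAR_ELEMENTS, "&") &
                d >= params$hphob_min & d <= params$hphob_max,
              arr.ind = TRUE)
  if (nrow(hp) > 0L) {
    recs$hp <- data.frame(residue_position = prot$resno[hp[, 1L]],
                          residue_name = prot$resname[hp[, 1L]],
                          protein_atom = prot$name[hp[, 1L]],
                          ligand_atom = lig$name[hp[, 2L]],
                          kind = "hydrophobic",
                          distance = d[hp],
                          stringsAsFactors = FALSE)
  }
  # hydrogen bonds: polar-polar pairs with complementary roles
  cap <- t(mapply(protein_hbond_capability, prot$resname, prot$name))
  prot_donor <- prot$element %in% POLAR_ELEMENTS & cap[, 1L]
  prot_accept <- prot$element %in% POLAR_ELEMENTS & cap[, 2L]
  lig_polar <- lig$element %in% POLAR_ELEMENTS
  lig_donor <- lig_polar & (if (is.null(pose$donors)) TRUE
                            else lig$name %in% pose$donors)
  lig_accept <- lig_polar & (if (is.null(pose$acceptors)) TRUE
                             else lig$name %in% pose$acceptors)
  compat <- outer(prot_donor, lig_accept, "&") |
    outer(prot_accept, lig_donor, "&")
  hb <- which(compat & d <= params$hbond_max & d > 0, arr.ind = TRUE)
  if (nrow(hb) > 0L) {
    recs$hb <- data.frame(residue_position = prot$resno[hb[, 1L]],
                          residue_name = prot$resname[hb[, 1L]],
                          protein_atom = prot$name[hb[, 1L]],
                          ligand_atom = lig$name[hb[, 2L]],
                          kind = "hbond",
                          distance = d[hb],
                          stringsAsFactors = FALSE)
  }
  out <- if (length(recs) == 0L) empty_interactions() else do.call(rbind, recs)
  out <- out[order(out$distance, out$residue_position, out$protein_atom,
                   out$ligand_atom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_interactions <- function() {
  data.frame(residue_position = integer(), residue_name = character(),
             protein_atom = character(), ligand_atom = character(),
             kind = character(), distance = numeric(),
             stringsAsFactors = FALSE)
}

THR80_CLASSES <- c("NoThr80", "Thr80_S", "OtherThr80")

#' Classify a pose by its Thr80 interactions
#'
#' Three-way taxonomy of a docked pose with respect to the residue at a
#' given mature position (default 80, the Thr80 of the risk alleles):
#' `Thr80_S` when any interaction record at that position involves the
#' ligand's thiocarbonyl sulfur; `OtherThr80` when records at the
#' position exist but none involve that sulfur; `NoThr80` otherwise.
#'
#' @param records Interaction records from [detect_contacts()] for this
#'   pose.
#' @param pose The `ligand_pose` the records were computed for.
#' @param structure Protein `structure3d` (used to check the position
#'   exists).
#' @param position Mature residue position, default 80.
#' @return One of `"NoThr80"`, `"Thr80_S"`, `"OtherThr80"`.
#' @export
classify_thr80 <- function(records, pose, structure, position = 80L) {
  stopifnot(inherits(pose, "ligand_pose"), inherits(structure, "structure3d"))
  if (!position %in% structure$atoms$resno) {
    stop("position ", position, " absent from structure '",
         structure$label, "'")
  }
  at_pos <- records[records$residue_position == position, , drop = FALSE]
  if (nrow(at_pos) == 0L) return("NoThr80")
  thio <- find_thiocarbonyl_sulfur(pose)
  if (!is.na(thio) && any(at_pos$ligand_atom == thio)) return("Thr80_S")
  "OtherThr80"
}

#' Tabulate Thr80 classes across a pose set
#'
#' Produces the per-drug-allele summary row: counts of poses in each
#' Thr80 class plus the class of the most favourable (minimum-score)
#' pose, ties on score broken by the lowest pose index.
#'
#' @param classes Character vector of per-pose Thr80 classes.
#' @param scores Numeric vector of per-pose docking scores (kcal/mol).
#' @return One-row data frame: `no_thr80`, `thr80_s`, `other_thr80`,
#'   `most_favourable`.
#' @export
tabulate_thr80 <- function(classes, scores) {
  if (length(classes) == 0L) stop("empty pose set")
  stopifnot(length(classes) == length(scores))
  bad <- setdiff(unique(classes), THR80_CLASSES)
  if (length(bad) > 0L) stop("unknown Thr80 class: ", bad[1L])
  counts <- vapply(THR80_CLASSES, function(cl) sum(classes == cl), integer(1L))
  best <- which(scores == min(scores))[1L]
  data.frame(no_thr80 = counts[["NoThr80"]],
             thr80_s = counts[["Thr80_S"]],
             other_thr80 = counts[["OtherThr80"]],
             most_favourable = classes[best],
             stringsAsFactors = FALSE)
}

#' Render a Thr80 summary row with report labels
#'
#' Converts the internal class codes to the labels used in the printed
#' summary tables (`No Thr80`, `Thr80-S`, `Other Thr80`).
#'
#' @param row One-row data frame from [tabulate_thr80()].
#' @return Character string `"<no> <s> <other> <label>"`.
#' @export
format_thr80_row <- function(row) {
  labels <- c(NoThr80 = "No Thr80", Thr80_S = "Thr80-S",
              OtherThr80 = "Other Thr80")
  paste(row$no_thr80, row$thr80_s, row$other_thr80,
        labels[[row$most_favourable]])
}
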