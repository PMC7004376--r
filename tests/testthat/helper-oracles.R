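# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (double loops, direct set logic) so they cannot
# share a defect with the implementation paths they check.

# all-pairs contact scan with explicit double loop
oracle_contacts <- function(structure, pose, params = contact_params()) {
  prot <- structure$atoms[structure$atoms$element != "H", ]
  lig <- pose$atoms[pose$atoms$element != "H", ]
  recs <- list()
  for (i in seq_len(nrow(prot))) {
    for (j in seq_len(nrow(lig))) {
      d <- sqrt((prot$x[i] - lig$x[j])^2 + (prot$y[i] - lig$y[j])^2 +
                  (prot$z[i] - lig$z[j])^2)
      if (prot$element[i] %in% c("C", "S") && lig$element[j] %in% c("C", "S") &&
          d >= params$hphob_min && d <= params$hphob_max) {
        recs[[length(recs) + 1L]] <- data.frame(
          residue_position = prot$resno[i], protein_atom = prot$name[i],
          ligand_atom = lig$name[j], kind = "hydrophobic", distance = d,
          stringsAsFactors = FALSE)
      }
      if (prot$element[i] %in% c("N", "O", "S") &&
          lig$element[j] %in% c("N", "O", "S") && d <= params$hbond_max &&
          d > 0) {
        cap <- hlagroove:::protein_hbond_capability(prot$resname[i],
                                                    prot$name[i])
        if (cap[1L] || cap[2L]) {  # ligand side defaults to both roles
          recs[[length(recs) + 1L]] <- data.frame(
            residue_position = prot$resno[i], protein_atom = prot$name[i],
            ligand_atom = lig$name[j], kind = "hbond", distance = d,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(recs) == 0L) {
    return(data.frame(residue_position = integer(), protein_atom = character(),
                      ligand_atom = character(), kind = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, recs)
}

# per-column set-intersection scan of an alignment matrix
oracle_unique_positions <- function(mat, risk_rows, ctrl_rows) {
  hits <- integer()
  for (col in seq_len(ncol(mat))) {
    rr <- unique(mat[risk_rows, col])
    if (length(rr) != 1L || rr == "-") next
    if (rr %in% mat[ctrl_rows, col]) next
    hits <- c(hits, col)
  }
  hits
}

# direct tally + median per group for pose summaries
oracle_summary <- function(df) {
  out <- list()
  for (al in unique(df$allele)) {
    for (lg in unique(df$ligand_id[df$allele == al])) {
      for (sp in unique(df$search_space[df$allele == al &
                                        df$ligand_id == lg])) {
        g <- df[df$allele == al & df$ligand_id == lg &
                  df$search_space == sp, ]
        med <- function(lab) {
          s <- g$score[g$label == lab]
          if (length(s) == 0L) NA_real_ else median(s)
        }
        imin <- which(g$score == min(g$score))
        imin <- imin[which.min(g$pose_index[imin])]
        out[[paste(al, lg, sp)]] <- list(
          allele = al, ligand_id = lg, search_space = sp,
          lowest = g$label[imin],
          count_B = sum(g$label == "B"), count_F = sum(g$label == "F"),
          count_O = sum(g$label == "O"),
          median_B = med("B"), median_F = med("F"), median_O = med("O"))
      }
    }
  }
  out
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3L, 3L))
  Q <- qr.Q(qr_dec)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# apply a rigid motion to an atom table
transform_atoms <- function(atoms, R, t) {
  xyz <- as.matrix(atoms[c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1L] + t[1L]
  atoms$y <- xyz[, 2L] + t[2L]
  atoms$z <- xyz[, 3L] + t[3L]
  atoms
}

transform_structure <- function(s, R, t) {
  s$atoms <- transform_atoms(s$atoms, R, t)
  s
}

transform_pose <- function(p, R, t) {
  p$atoms <- transform_atoms(p$atoms, R, t)
  p
}

# tiny structure from a coordinate matrix
toy_structure <- function(xyz, label = "toy", element = "C", name = NULL) {
  n <- nrow(xyz)
  if (is.null(name)) name <- paste0("C", seq_len(n))
  hlagroove:::new_structure3d(data.frame(
    serial = seq_len(n), name = name, element = rep_len(element, n),
    resname = "ALA", resno = seq_len(n), chain = "A",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    stringsAsFactors = FALSE), label)
}

# bipartition of a rooted phylo tree at its root, as a list of two
# sorted tip-label sets
root_bipartition <- function(tree) {
  root <- length(tree$tip.label) + 1L
  kids <- tree$edge[tree$edge[, 1L] == root, 2L]
  tips_under <- function(node) {
    if (node <= length(tree$tip.label)) return(tree$tip.label[node])
    out <- character()
    for (child in tree$edge[tree$edge[, 1L] == node, 2L]) {
      out <- c(out, tips_under(child))
    }
    out
  }
  lapply(kids, function(k) sort(tips_under(k)))
}
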