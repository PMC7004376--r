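# Structure and pose input/output: fixed-width PDB records, the AutoDock
# PDBQT dialect, multi-MODEL pose sets with docking scores, and rigid-body
# superposition.

#' Read a protein or ligand structure from PDB or PDBQT
#'
#' Parses `ATOM` and `HETATM` records into an atom table. The PDBQT dialect
#' (AutoDock) is read as fixed-width PDB for identity and coordinates; the
#' trailing partial-charge and AutoDock atom-type columns are consumed only
#' to recover the element symbol, and otherwise ignored.
#'
#' @param path Path to a PDB or PDBQT file.
#' @param format `"auto"` (by file extension), `"pdb"` or `"pdbqt"`.
#' @param label Free-text identifier for the structure; defaults to the
#'   file name without extension. Conventionally allele name plus a
#'   `_S` (crystal) or `_M` (homology model) suffix.
#' @return A `structure3d` object: a list with `atoms` (data frame with
#'   columns `serial`, `name`, `element`, `resname`, `resno`, `chain`,
#'   `x`, `y`, `z`) and `label`. Residue numbers are taken verbatim from
#'   the file (author numbering); mapping to mature HLA numbering is a
#'   separate explicit step (see [map_numbering()]).
#' @seealso [write_structure()], [read_pose_set()], [superpose_rmsd()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "pdbqt"),
                           label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  if (format == "auto") {
    format <- if (grepl("\\.pdbqt$", path, ignore.case = TRUE)) "pdbqt" else "pdb"
  }
  lines <- readLines(path, warn = FALSE)
  atoms <- parse_atom_records(lines, format = format, file = path)
  if (nrow(atoms) == 0L) {
    stop("no ATOM/HETATM records in ", path)
  }
  if (is.null(label)) {
    label <- sub("\\.[^.]*$", "", basename(path))
  }
  new_structure3d(atoms, label)
}

new_structure3d <- function(atoms, label) {
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue_number, atom name) in structure '",
         label, "': ", key[duplicated(key)][1L])
  }
  structure(list(atoms = atoms, label = label), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat("<structure3d> ", x$label, ": ", nrow(x$atoms), " atoms, ",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), " residues\n",
      sep = "")
  invisible(x)
}

# Fixed-width ATOM/HETATM parser shared by the PDB and PDBQT dialects.
# PDBQT keeps the PDB coordinate columns; its record tail is
# occupancy, tempFactor, partial charge, AutoDock atom type.
parse_atom_records <- function(lines, format, file = "<text>") {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(is_atom)
  if (length(idx) == 0L) {
    return(empty_atom_table())
  }
  rec <- lines[idx]
  sub_field <- function(start, stop) {
    trimws(substr(rec, start, stop))
  }
  num_field <- function(start, stop, what) {
    txt <- sub_field(start, stop)
    out <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.finite(out))
    if (length(bad) > 0L) {
      stop("malformed ", what, " field at line ", idx[bad[1L]],
           " of ", file, ": '", txt[bad[1L]], "'")
    }
    out
  }
  serial <- as.integer(num_field(7, 11, "atom serial"))
  name <- sub_field(13, 16)
  resname <- sub_field(18, 20)
  chain <- substr(rec, 22, 22)
  resno <- as.integer(num_field(23, 26, "residue number"))
  x <- num_field(31, 38, "x coordinate")
  y <- num_field(39, 46, "y coordinate")
  z <- num_field(47, 54, "z coordinate")
  element <- if (format == "pdbqt") {
    # AutoDock atom type is the last whitespace-separated token
    type <- vapply(strsplit(trimws(rec), "[ \t]+"), function(tok) {
      tok[length(tok)]
    }, character(1L))
    element_from_autodock_type(type, name)
  } else {
    el <- toupper(sub_field(77, 78))
    miss <- !nzchar(el)
    el[miss] <- element_from_name(name[miss])
    el
  }
  if (any(!nzchar(element))) {
    stop("could not determine element for atom serial ",
         serial[which(!nzchar(element))[1L]], " in ", file)
  }
  data.frame(serial = serial, name = name, element = element,
             resname = resname, resno = resno, chain = chain,
             x = x, y = y, z = z, stringsAsFactors = FALSE)
}

empty_atom_table <- function() {
  data.frame(serial = integer(), name = character(), element = character(),
             resname = character(), resno = integer(), chain = character(),
             x = numeric(), y = numeric(), z = numeric(),
             stringsAsFactors = FALSE)
}

# AutoDock atom types: aromatic carbon is "A"; polar variants carry
# suffixes (NA, OA, SA, HD, ...). Fall back to the leading letters.
element_from_autodock_type <- function(type, name) {
  type <- toupper(type)
  out <- character(length(type))
  out[type %in% c("C", "A")] <- "C"
  out[type %in% c("N", "NA", "NS")] <- "N"
  out[type %in% c("O", "OA", "OS")] <- "O"
  out[type %in% c("S", "SA")] <- "S"
  out[type %in% c("H", "HD", "HS")] <- "H"
  out[type %in% c("CL", "BR", "F", "I", "P", "FE", "ZN", "MG", "MN", "CA")] <-
    type[type %in% c("CL", "BR", "F", "I", "P", "FE", "ZN", "MG", "MN", "CA")]
  miss <- !nzchar(out)
  out[miss] <- element_from_name(name[miss])
  out
}

element_from_name <- function(name) {
  # strip leading digits (e.g. "1HB"), take the first letter; two-letter
  # halogens/metals appear rarely in this package's inputs
  core <- sub("^[0-9]+", "", toupper(name))
  two <- substr(core, 1, 2)
  el <- substr(core, 1, 1)
  known2 <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE")
  el[two %in% known2 & !(two %in% c("NA"))] <- two[two %in% known2 & !(two %in% c("NA"))]
  el
}

#' Write a structure as a PDB file
#'
#' Emits standard-conformant `ATOM` records (element symbol in columns
#' 77-78) and a terminal `END`. Coordinates are written at PDB precision
#' (3 decimals), which bounds round-trip accuracy.
#'
#' @param x A `structure3d` object.
#' @param path Output file path.
#' @param record Record name, `"ATOM"` for protein, `"HETATM"` for ligands.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, record = "ATOM") {
  stopifnot(inherits(x, "structure3d"))
  writeLines(c(format_atom_records(x$atoms, record), "END"), path)
  invisible(path)
}

format_atom_records <- function(atoms, record = "ATOM") {
  record <- formatC(record, width = -6)
  # atom-name column convention: 1-3 character names start in column 14
  nm <- ifelse(nchar(atoms$name) < 4L,
               formatC(paste0(" ", atoms$name), width = -4),
               formatC(atoms$name, width = -4))
  sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, atoms$serial, nm, atoms$resname, atoms$chain,
          atoms$resno, atoms$x, atoms$y, atoms$z, 1, 0, atoms$element)
}

#' Read a multi-model docking pose set
#'
#' Reads an AutoDock-style pose file (`MODEL`/`ENDMDL` blocks in PDB or
#' PDBQT dialect) into a list of ligand poses. Docking scores (kcal/mol,
#' lower is more favourable) come from an embedded
#' `REMARK ... SCORE <value>` line inside each model when present, else
#' from a sidecar table keyed by `run_id`; if both are present for a pose
#' they must agree.
#'
#' @param path Path to the pose file.
#' @param scores Optional sidecar: a data frame (or CSV path) with columns
#'   `run_id`, `score`, and optionally `search_space`.
#' @param search_space Search-space tag for the poses, `"PBG"` (peptide
#'   binding groove) or `"Top3"` (three largest pockets); recycled across
#'   poses. Ignored for poses whose sidecar row carries its own tag.
#' @param ligand_id Short ligand code (e.g. `"MMZ"`, `"PTU"`).
#' @param format Passed to the atom parser; `"auto"` uses the extension.
#' @param reference_atom Name of the designated reference atom used for
#'   pose clustering (default `"C1"`).
#' @return A list of `ligand_pose` objects, each with `atoms`, `score`,
#'   `run_id`, `search_space`, `ligand_id` and `reference_atom`.
#' @export
read_pose_set <- function(path, scores = NULL,
                          search_space = "PBG", ligand_id = "LIG",
                          format = c("auto", "pdb", "pdbqt"),
                          reference_atom = "C1") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdbqt$", path, ignore.case = TRUE)) "pdbqt" else "pdb"
  }
  lines <- readLines(path, warn = FALSE)
  if (is.character(scores) && length(scores) == 1L) {
    scores <- utils::read.csv(scores, stringsAsFactors = FALSE)
  }
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0L) {
    starts <- 1L
    ends <- length(lines)
    run_ids <- 1L
  } else {
    if (length(starts) != length(ends)) {
      stop("unbalanced MODEL/ENDMDL records in ", path)
    }
    run_ids <- as.integer(sub("^MODEL\\s+", "", lines[starts]))
  }
  if (anyDuplicated(run_ids)) {
    stop("duplicate run_id ", run_ids[duplicated(run_ids)][1L], " in ", path)
  }
  n <- length(starts)
  search_space <- rep_len(search_space, n)
  poses <- vector("list", n)
  for (i in seq_len(n)) {
    block <- lines[starts[i]:ends[i]]
    atoms <- parse_atom_records(block, format = format, file = path)
    if (nrow(atoms) == 0L) {
      stop("model ", run_ids[i], " in ", path, " has no atoms")
    }
    embedded <- extract_remark_score(block)
    sc <- resolve_pose_score(embedded, scores, run_ids[i], path)
    ss <- search_space[i]
    if (!is.null(scores) && "search_space" %in% names(scores)) {
      row <- match(run_ids[i], scores$run_id)
      if (!is.na(row)) ss <- scores$search_space[row]
    }
    poses[[i]] <- new_ligand_pose(atoms, score = sc, run_id = run_ids[i],
                                  search_space = ss, ligand_id = ligand_id,
                                  reference_atom = reference_atom)
  }
  poses
}

extract_remark_score <- function(block) {
  hits <- grep("^(REMARK|USER).*SCORE", block, ignore.case = TRUE, value = TRUE)
  if (length(hits) == 0L) {
    return(NULL)
  }
  val <- regmatches(hits[1L],
                    regexpr("-?[0-9]+\\.?[0-9]*([eE]-?[0-9]+)?$",
                            trimws(hits[1L])))
  if (length(val) == 0L) {
    m <- regexpr("SCORE[ :=]+(-?[0-9]+\\.?[0-9]*)", hits[1L], ignore.case = TRUE)
    if (m < 0) return(NULL)
    val <- sub("(?i)SCORE[ :=]+", "", regmatches(hits[1L], m), perl = TRUE)
  }
  as.numeric(val)
}

resolve_pose_score <- function(embedded, sidecar, run_id, path) {
  from_sidecar <- NULL
  if (!is.null(sidecar)) {
    stopifnot(all(c("run_id", "score") %in% names(sidecar)))
    row <- match(run_id, sidecar$run_id)
    if (!is.na(row)) from_sidecar <- sidecar$score[row]
  }
  if (!is.null(embedded) && !is.null(from_sidecar)) {
    if (abs(embedded - from_sidecar) > 1e-6) {
      stop("embedded score (", embedded, ") and sidecar score (",
           from_sidecar, ") disagree for run_id ", run_id, " in ", path)
    }
    return(embedded)
  }
  sc <- if (!is.null(embedded)) embedded else from_sidecar
  if (is.null(sc) || !is.finite(sc)) {
    stop("no resolvable score for run_id ", run_id, " in ", path)
  }
  sc
}

new_ligand_pose <- function(atoms, score, run_id, search_space, ligand_id,
                            reference_atom = "C1") {
  if (!is.finite(score)) stop("pose score must be finite")
  if (!search_space %in% c("PBG", "Top3")) {
    stop("search_space must be 'PBG' or 'Top3', got '", search_space, "'")
  }
  structure(list(atoms = atoms, score = score, run_id = as.integer(run_id),
                 search_space = search_space, ligand_id = ligand_id,
                 reference_atom = reference_atom),
            class = "ligand_pose")
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat("<ligand_pose> ", x$ligand_id, " run ", x$run_id, " [", x$search_space,
      "] score ", sprintf("%.2f", x$score), " kcal/mol, ", nrow(x$atoms),
      " atoms\n", sep = "")
  invisible(x)
}

#' Write a pose set as a multi-model PDB file
#'
#' Each pose becomes a `MODEL`/`ENDMDL` block with its docking score on a
#' `REMARK SCORE` line, so a written set re-reads without a sidecar.
#'
#' @param poses List of `ligand_pose` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pose_set <- function(poses, path) {
  out <- unlist(lapply(poses, function(p) {
    c(sprintf("MODEL %8d", p$run_id),
      sprintf("REMARK SCORE %.4f", p$score),
      format_atom_records(p$atoms, "HETATM"),
      "ENDMDL")
  }))
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Designated reference atom of a pose
#'
#' Docking poses of dissimilar ligands are clustered on the coordinates of
#' a single designated atom (default `C1`), so ligands with differing atom
#' counts can share one clustering.
#'
#' @param pose A `ligand_pose`.
#' @param name Reference atom name; defaults to the pose's configured
#'   `reference_atom`.
#' @return One-row atom data frame.
#' @export
get_reference_atom <- function(pose, name = NULL) {
  stopifnot(inherits(pose, "ligand_pose"))
  if (is.null(name)) name <- pose$reference_atom
  hit <- which(pose$atoms$name == name)
  if (length(hit) == 0L) {
    stop("pose has no atom named '", name, "'; available: ",
         paste(unique(pose$atoms$name), collapse = ", "))
  }
  pose$atoms[hit[1L], , drop = FALSE]
}

# n x 3 matrix of reference-atom coordinates for a pose list
pose_reference_coords <- function(poses, name = NULL) {
  coords <- t(vapply(poses, function(p) {
    a <- get_reference_atom(p, name)
    c(a$x, a$y, a$z)
  }, numeric(3L)))
  colnames(coords) <- c("x", "y", "z")
  coords
}

#' Superposition RMSD between two structures
#'
#' Matches atoms by (chain, residue number, atom name) and returns the
#' RMSD in Angstrom, by default after optimal rigid superposition via
#' the Kabsch algorithm. `fit = FALSE` skips the fitting step and
#' measures the coordinates as given, which is the appropriate mode when
#' comparing models already built in a common frame (e.g. homology
#' models from the same template). Symmetric in its arguments.
#'
#' @param a,b `structure3d` objects.
#' @param selection Which atoms enter the match: `"all"`, `"backbone"`
#'   (N, CA, C, O) or `"calpha"`.
#' @param fit Optimally superpose before measuring (default `TRUE`).
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(a, b, selection = c("all", "backbone", "calpha"),
                           fit = TRUE) {
  stopifnot(inherits(a, "structure3d"), inherits(b, "structure3d"))
  selection <- match.arg(selection)
  keep <- switch(selection,
                 all = function(df) df,
                 backbone = function(df) df[df$name %in% c("N", "CA", "C", "O"), ],
                 calpha = function(df) df[df$name == "CA", ])
  aa <- keep(a$atoms)
  bb <- keep(b$atoms)
  key_a <- paste(aa$chain, aa$resno, aa$name)
  key_b <- paste(bb$chain, bb$resno, bb$name)
  common <- intersect(key_a, key_b)
  if (length(common) == 0L) {
    stop("no matched atoms between '", a$label, "' and '", b$label, "'")
  }
  P <- as.matrix(aa[match(common, key_a), c("x", "y", "z")])
  Q <- as.matrix(bb[match(common, key_b), c("x", "y", "z")])
  if (nrow(P) != nrow(Q)) {
    stop("unequal matched atom lists")
  }
  if (fit) kabsch_rmsd(P, Q) else sqrt(sum((P - Q)^2) / nrow(P))
}

# Least-squares RMSD after optimal rotation (Kabsch, via SVD with
# reflection correction).
kabsch_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  diff <- Pc %*% R - Qc
  sqrt(sum(diff^2) / nrow(P))
}
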