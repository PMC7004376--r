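# Multiple-sequence-alignment analysis: residues unique to risk alleles
# and mutation labels against a reference residue.

ALLELE_STATUSES <- c("risk", "possible_risk", "control", "common")

#' Construct an allele alignment
#'
#' Holds aligned allele protein sequences together with a risk-status
#' label per allele and the bookkeeping needed to translate alignment
#' columns into mature-protein residue numbers.
#'
#' @param alleles Character vector of allele names (unique).
#' @param statuses One of `"risk"`, `"possible_risk"`, `"control"`,
#'   `"common"` per allele.
#' @param sequences Aligned residue strings, all the same length; `-` is
#'   the gap character.
#' @param numbering_offset Integer added when mapping ungapped reference
#'   positions to mature-protein numbers (0 for pre-trimmed mature
#'   sequences).
#' @param reference Allele name whose row anchors the numbering; defaults
#'   to the first row.
#' @return An `allele_alignment` object.
#' @export
allele_alignment <- function(alleles, statuses, sequences,
                             numbering_offset = 0L, reference = NULL) {
  stopifnot(length(alleles) == length(statuses),
            length(alleles) == length(sequences))
  if (anyDuplicated(alleles)) {
    stop("duplicate allele names: ",
         paste(unique(alleles[duplicated(alleles)]), collapse = ", "))
  }
  bad <- setdiff(unique(statuses), ALLELE_STATUSES)
  if (length(bad) > 0L) {
    stop("unknown status values: ", paste(bad, collapse = ", "),
         " (expected ", paste(ALLELE_STATUSES, collapse = "/"), ")")
  }
  widths <- nchar(sequences)
  if (length(unique(widths)) > 1L) {
    stop("ragged alignment: sequence lengths ",
         paste(unique(widths), collapse = ", "))
  }
  if (is.null(reference)) reference <- alleles[1L]
  if (!reference %in% alleles) {
    stop("reference allele '", reference, "' not present in alignment")
  }
  structure(list(rows = data.frame(allele = alleles,
                                   status = statuses,
                                   seq = toupper(sequences),
                                   stringsAsFactors = FALSE),
                 numbering_offset = as.integer(numbering_offset),
                 reference = reference),
            class = "allele_alignment")
}

#' @export
print.allele_alignment <- function(x, ...) {
  cat("<allele_alignment> ", nrow(x$rows), " alleles x ",
      nchar(x$rows$seq[1L]), " columns (",
      paste(sprintf("%s:%d", names(table(x$rows$status)),
                    as.integer(table(x$rows$status))), collapse = ", "),
      "); reference ", x$reference, "\n", sep = "")
  invisible(x)
}

#' Read an aligned FASTA plus status labels into an allele alignment
#'
#' @param path Aligned FASTA file (equal record widths).
#' @param labels Data frame with columns `allele`, `status`, or a CSV path
#'   to one. Alleles absent from the table default to status `"common"`.
#' @param numbering_offset,reference Passed to [allele_alignment()].
#' @return An `allele_alignment`.
#' @export
read_alignment <- function(path, labels = NULL, numbering_offset = 0L,
                           reference = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in ", path)
  alleles <- sub("\\s.*$", "", names(seqs))
  widths <- Biostrings::width(seqs)
  if (length(unique(widths)) > 1L) {
    stop("ragged alignment in ", path, ": widths ",
         paste(unique(widths), collapse = ", "))
  }
  statuses <- rep("common", length(alleles))
  if (!is.null(labels)) {
    if (is.character(labels) && length(labels) == 1L) {
      labels <- utils::read.csv(labels, stringsAsFactors = FALSE)
    }
    stopifnot(all(c("allele", "status") %in% names(labels)))
    hit <- match(alleles, labels$allele)
    statuses[!is.na(hit)] <- labels$status[hit[!is.na(hit)]]
  }
  allele_alignment(alleles, statuses, as.character(seqs),
                   numbering_offset = numbering_offset,
                   reference = reference)
}

#' Write an allele alignment as FASTA plus a label table
#'
#' @param alignment An `allele_alignment`.
#' @param fasta_path Output FASTA path.
#' @param labels_path Optional CSV path for the `allele,status` table.
#' @return `fasta_path`, invisibly.
#' @export
write_alignment <- function(alignment, fasta_path, labels_path = NULL) {
  stopifnot(inherits(alignment, "allele_alignment"))
  set <- Biostrings::AAStringSet(alignment$rows$seq)
  names(set) <- alignment$rows$allele
  Biostrings::writeXStringSet(set, fasta_path)
  if (!is.null(labels_path)) {
    utils::write.csv(alignment$rows[c("allele", "status")], labels_path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(fasta_path)
}

#' Map an alignment column to a mature-protein position
#'
#' The mature-protein position is the ungapped 1-based index of the
#' reference row at that column, plus the alignment's numbering offset.
#' Positions such as 67 and 80 in HLA-B refer to this mature numbering
#' (signal peptide removed).
#'
#' @param alignment An `allele_alignment`.
#' @param column 1-based alignment column index.
#' @return Integer mature position.
#' @export
map_numbering <- function(alignment, column) {
  stopifnot(inherits(alignment, "allele_alignment"))
  ref <- alignment_chars(alignment, alignment$reference)
  if (column < 1L || column > length(ref)) {
    stop("column ", column, " outside alignment width ", length(ref))
  }
  if (ref[column] == "-") {
    stop("column ", column, " is a gap in reference row '",
         alignment$reference, "'")
  }
  sum(ref[seq_len(column)] != "-") + alignment$numbering_offset
}

# inverse of map_numbering: alignment column of a mature position
column_for_position <- function(alignment, position) {
  ref <- alignment_chars(alignment, alignment$reference)
  ungapped <- cumsum(ref != "-")
  target <- position - alignment$numbering_offset
  hit <- which(ungapped == target & ref != "-")
  if (length(hit) == 0L) {
    stop("mature position ", position, " not resolvable in reference row '",
         alignment$reference, "'")
  }
  hit[1L]
}

alignment_chars <- function(alignment, allele) {
  row <- match(allele, alignment$rows$allele)
  if (is.na(row)) stop("allele '", allele, "' not in alignment")
  strsplit(alignment$rows$seq[row], "")[[1L]]
}

alignment_matrix <- function(alignment) {
  do.call(rbind, strsplit(alignment$rows$seq, ""))
}

#' Scan for residues unique to risk alleles
#'
#' Reports every alignment position where all risk-group rows share one
#' residue and no control-group row carries that residue -- the pattern
#' that singles out positions such as Cys67 and Thr80 as candidates for a
#' shared adverse-reaction mechanism. Gaps never match a residue, and
#' columns with any gap in the risk group are skipped. Alleles whose
#' status is in neither group (e.g. `possible_risk` by default, mirroring
#' an unconfirmed allele) are ignored.
#'
#' @param alignment An `allele_alignment`.
#' @param risk_statuses Statuses forming the risk group (default
#'   `"risk"`).
#' @param control_statuses Statuses forming the control group (default
#'   `"control"` and `"common"`).
#' @return Data frame with columns `position` (mature numbering),
#'   `risk_residue` and `control_residues` (comma-joined set).
#' @export
scan_unique_residues <- function(alignment, risk_statuses = "risk",
                                 control_statuses = c("control", "common")) {
  stopifnot(inherits(alignment, "allele_alignment"))
  mat <- alignment_matrix(alignment)
  risk_rows <- alignment$rows$status %in% risk_statuses
  ctrl_rows <- alignment$rows$status %in% control_statuses
  if (!any(risk_rows)) stop("no rows with risk statuses ",
                            paste(risk_statuses, collapse = "/"))
  if (!any(ctrl_rows)) stop("no rows with control statuses ",
                            paste(control_statuses, collapse = "/"))
  out <- list()
  for (col in seq_len(ncol(mat))) {
    risk_res <- unique(mat[risk_rows, col])
    if (length(risk_res) != 1L || risk_res == "-") next
    ctrl_res <- mat[ctrl_rows, col]
    if (risk_res %in% ctrl_res) next
    ref_char <- alignment_chars(alignment, alignment$reference)[col]
    if (ref_char == "-") {
      warning("discriminating column ", col,
              " falls on a reference gap; skipped")
      next
    }
    ctrl_set <- sort(unique(ctrl_res[ctrl_res != "-"]))
    out[[length(out) + 1L]] <- data.frame(
      position = map_numbering(alignment, col),
      risk_residue = risk_res,
      control_residues = paste(ctrl_set, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(position = integer(), risk_residue = character(),
                      control_residues = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Mutation label for an allele at a mature position
#'
#' Formats the residue observed in one allele against a reference
#' residue, in the `N80T` convention: `<ref><position><observed>` when
#' the residues differ, `<ref><position>` when they agree.
#'
#' @param alignment An `allele_alignment`.
#' @param allele Allele name.
#' @param position Mature-protein position.
#' @param reference_residue 1-letter reference residue (e.g. `"N"` at
#'   position 80 of the HLA-B consensus).
#' @return Label string such as `"N80T"`, `"N80I"` or `"N80"`.
#' @export
mutation_label <- function(alignment, allele, position, reference_residue) {
  col <- column_for_position(alignment, position)
  obs <- alignment_chars(alignment, allele)[col]
  if (obs == "-") {
    stop("allele '", allele, "' has a gap at mature position ", position)
  }
  if (obs == toupper(reference_residue)) {
    paste0(toupper(reference_residue), position)
  } else {
    paste0(toupper(reference_residue), position, obs)
  }
}
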