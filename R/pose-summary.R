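# Per allele x drug x search-space pose summaries (the docking summary
# table row shape) and boxplot-ready multi-run score distributions.

#' Summarise pocket assignments per allele, drug and search space
#'
#' One row per (allele, ligand, search space) group: the pocket of the
#' lowest-scoring pose, per-pocket pose counts and per-pocket median
#' scores. Ties on the minimum score are broken by the lowest pose
#' index; a pocket with no poses has an undefined median (rendered
#' `"N/A"` in reports). Median of an even count is the mean of the two
#' central values.
#'
#' @param assignments Data frame with one row per pose: columns `allele`,
#'   `ligand_id`, `search_space`, `score`, `label` (B/F/O), and
#'   optionally `pose_index` (defaults to row order within each group).
#' @return A data frame of class `pose_summary` with columns `allele`,
#'   `ligand_id`, `search_space`, `lowest_pocket`, `count_B`, `count_F`,
#'   `count_O`, `median_B`, `median_F`, `median_O` (NA when the pocket is
#'   empty).
#' @export
summarize_poses <- function(assignments) {
  needed <- c("allele", "ligand_id", "search_space", "score", "label")
  missing <- setdiff(needed, names(assignments))
  if (length(missing) > 0L) {
    stop("assignments lack columns: ", paste(missing, collapse = ", "))
  }
  if (!all(assignments$label %in% c("B", "F", "O"))) {
    stop("labels must be B, F or O")
  }
  if (is.null(assignments$pose_index)) {
    assignments$pose_index <- stats::ave(seq_len(nrow(assignments)),
                                         assignments$allele,
                                         assignments$ligand_id,
                                         assignments$search_space,
                                         FUN = seq_along)
  }
  key <- interaction(assignments$allele, assignments$ligand_id,
                     assignments$search_space, drop = TRUE, lex.order = TRUE)
  groups <- split(assignments, key)
  rows <- lapply(groups, function(g) {
    med <- function(lab) {
      s <- g$score[g$label == lab]
      if (length(s) == 0L) NA_real_ else stats::median(s)
    }
    best <- order(g$score, g$pose_index)[1L]
    data.frame(allele = g$allele[1L],
               ligand_id = g$ligand_id[1L],
               search_space = g$search_space[1L],
               lowest_pocket = g$label[best],
               count_B = sum(g$label == "B"),
               count_F = sum(g$label == "F"),
               count_O = sum(g$label == "O"),
               median_B = med("B"),
               median_F = med("F"),
               median_O = med("O"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pose_summary", "data.frame")
  out
}

#' Render a pose summary row as printed in the docking tables
#'
#' Formats `lowest_pocket`, then count and median per pocket, scores to
#' two decimals with `"N/A"` for empty pockets -- e.g.
#' `"F 1 -3.10 9 -4.39"` for a group with one B pose at -3.10 and nine F
#' poses with median -4.39 whose best pose sits in F.
#'
#' @param row One row of a [summarize_poses()] result.
#' @param include_O Include the O-pocket count/median pair (used for the
#'   extended search space); default `FALSE`.
#' @return Character string.
#' @export
format_summary_row <- function(row, include_O = FALSE) {
  fmt <- function(x) if (is.na(x)) "N/A" else sprintf("%.2f", x)
  parts <- c(row$lowest_pocket,
             row$count_B, fmt(row$median_B),
             row$count_F, fmt(row$median_F))
  if (include_O) {
    parts <- c(parts, row$count_O, fmt(row$median_O))
  }
  paste(parts, collapse = " ")
}

#' Write a pose summary table as TSV
#'
#' Emits the printed-table column order (`Status`, `Allele`, `Mutation`,
#' `Lowest`, `B`, `Median`, `F`, `Median`, and for the extended search
#' space `O`, `Median`), with scores to two decimals and `N/A` for empty
#' pockets. `status` and `mutation` columns are optional annotations
#' joined by allele.
#'
#' @param summary A [summarize_poses()] result.
#' @param path Output TSV path.
#' @param annotations Optional data frame with columns `allele`,
#'   `status`, `mutation`.
#' @param include_O Include O-pocket columns.
#' @return `path`, invisibly.
#' @export
write_pose_summary <- function(summary, path, annotations = NULL,
                               include_O = FALSE) {
  fmt <- function(x) ifelse(is.na(x), "N/A", sprintf("%.2f", x))
  status <- mutation <- rep("", nrow(summary))
  if (!is.null(annotations)) {
    hit <- match(summary$allele, annotations$allele)
    status <- ifelse(is.na(hit), "", annotations$status[hit])
    mutation <- ifelse(is.na(hit), "", annotations$mutation[hit])
  }
  out <- data.frame(Status = status, Allele = summary$allele,
                    Mutation = mutation, Lowest = summary$lowest_pocket,
                    B = summary$count_B, Median = fmt(summary$median_B),
                    F = summary$count_F, Median.1 = fmt(summary$median_F),
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (include_O) {
    out$O <- summary$count_O
    out$Median.2 <- fmt(summary$median_O)
  }
  names(out) <- sub("\\.[0-9]+$", "", names(out))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Five-number score summaries per allele and drug
#'
#' Boxplot-ready summaries (minimum, lower quartile, median, upper
#' quartile, maximum) of docking scores grouped by allele and ligand, as
#' used for multi-run (e.g. 100-run) analyses. Quartiles use linear
#' interpolation between closest ranks (`stats::quantile` type 7), fixed
#' so outputs are deterministic.
#'
#' @param scores Data frame with columns `allele`, `ligand_id`, `score`.
#' @return Data frame with one row per group: `allele`, `ligand_id`,
#'   `n`, `min`, `q1`, `median`, `q3`, `max`. Group order follows first
#'   appearance in the input.
#' @export
score_distribution <- function(scores) {
  needed <- c("allele", "ligand_id", "score")
  missing <- setdiff(needed, names(scores))
  if (length(missing) > 0L) {
    stop("scores lack columns: ", paste(missing, collapse = ", "))
  }
  key <- paste(scores$allele, scores$ligand_id, sep = "\r")
  groups <- split(scores, factor(key, levels = unique(key)))
  rows <- lapply(groups, function(g) {
    q <- stats::quantile(g$score, probs = c(0, 0.25, 0.5, 0.75, 1),
                         type = 7, names = FALSE)
    data.frame(allele = g$allele[1L], ligand_id = g$ligand_id[1L],
               n = nrow(g), min = q[1L], q1 = q[2L], median = q[3L],
               q3 = q[4L], max = q[5L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
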