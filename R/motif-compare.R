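# Peptide-binding motif comparison: correlation distances between
# per-allele position-specific score matrices (PSSMs) and UPGMA trees.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a 9x20 peptide-binding score matrix
#'
#' A PSSM summarises an allele's peptide-binding motif: one row per
#' 9-mer peptide position, one column per amino acid, real-valued
#' preference scores.
#'
#' @param scores 9x20 numeric matrix (finite entries). Columns are
#'   reordered to the standard amino-acid alphabet if named.
#' @param allele Allele name.
#' @return A `pssm` object (matrix with `allele` attribute).
#' @export
pssm <- function(scores, allele) {
  scores <- as.matrix(scores)
  if (!all(dim(scores) == c(9L, 20L))) {
    stop("PSSM must be 9 positions x 20 amino acids, got ",
         nrow(scores), "x", ncol(scores))
  }
  if (!all(is.finite(scores))) stop("PSSM entries must be finite")
  if (!is.null(colnames(scores))) {
    if (!setequal(colnames(scores), AA_LETTERS)) {
      stop("PSSM column names must be the 20 amino-acid letters")
    }
    scores <- scores[, AA_LETTERS, drop = FALSE]
  } else {
    colnames(scores) <- AA_LETTERS
  }
  rownames(scores) <- as.character(seq_len(9L))
  structure(scores, allele = allele, class = c("pssm", "matrix", "array"))
}

#' Read a PSSM from a plain-text matrix file
#'
#' Whitespace-delimited 9-row by 20-column matrix with a header row of
#' amino-acid letters; an optional leading position column is accepted.
#'
#' @param path File path.
#' @param allele Allele name; defaults to the file name without
#'   extension.
#' @return A `pssm` object.
#' @export
read_pssm <- function(path, allele = NULL) {
  if (is.null(allele)) allele <- sub("\\.[^.]*$", "", basename(path))
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE)
  if (ncol(tab) == 21L) tab <- tab[, -1L, drop = FALSE]
  pssm(as.matrix(tab), allele)
}

#' Write a PSSM to a plain-text matrix file
#'
#' @param x A `pssm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(x, path) {
  stopifnot(inherits(x, "pssm"))
  m <- format(unclass(x), digits = 8, trim = TRUE, scientific = FALSE)
  lines <- c(paste(AA_LETTERS, collapse = " "),
             apply(m, 1L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Distance between two peptide-binding motifs
#'
#' Correlation distance `(1 - r) / 2` between the flattened score
#' matrices, mapping perfectly correlated motifs to 0 and perfectly
#' anti-correlated motifs to 1 -- the red(0)/white(1) scale of motif
#' similarity heat maps. Symmetric, zero for identical matrices; the
#' triangle inequality is not guaranteed.
#'
#' @param a,b `pssm` objects of equal dimensions.
#' @return Distance in `[0, 1]`.
#' @export
motif_distance <- function(a, b) {
  va <- as.vector(unclass(a))
  vb <- as.vector(unclass(b))
  if (length(va) != length(vb)) stop("PSSM dimensions differ")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("correlation undefined for a zero-variance score matrix")
  }
  r <- stats::cor(va, vb)
  d <- (1 - r) / 2
  min(max(d, 0), 1)
}

#' Pairwise motif distance matrix for a set of alleles
#'
#' @param pssms Named list of `pssm` objects (names are allele labels;
#'   unnamed lists use each PSSM's `allele` attribute).
#' @return Symmetric numeric matrix with zero diagonal, entries in
#'   `[0, 1]`, dimnames = allele names.
#' @export
motif_distance_matrix <- function(pssms) {
  n <- length(pssms)
  if (n < 1L) stop("no PSSMs supplied")
  nm <- names(pssms)
  if (is.null(nm) || any(!nzchar(nm))) {
    nm <- vapply(pssms, attr, character(1L), "allele")
  }
  if (anyDuplicated(nm)) stop("duplicate allele names in PSSM set")
  m <- matrix(0, n, n, dimnames = list(nm, nm))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        m[i, j] <- m[j, i] <- motif_distance(pssms[[i]], pssms[[j]])
      }
    }
  }
  m
}

#' UPGMA tree from a motif distance matrix
#'
#' Average-linkage (UPGMA) hierarchical clustering of the allele motif
#' distances, returned as a rooted ultrametric `phylo` tree. Labels are
#' sorted lexicographically before clustering so equal-distance merges
#' resolve deterministically.
#'
#' @param m Symmetric distance matrix with allele dimnames (n >= 2).
#' @param method Clustering method; only `"upgma"` is supported.
#' @param file Optional path; when given the tree is also written as
#'   Newick text.
#' @return An [ape::phylo] object (use [ape::write.tree] for Newick).
#' @export
build_tree <- function(m, method = "upgma", file = NULL) {
  method <- match.arg(method, "upgma")
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("m must be a square matrix")
  if (nrow(m) < 2L) stop("need at least 2 alleles to build a tree")
  if (max(abs(m - t(m))) > 1e-9) stop("distance matrix must be symmetric")
  ord <- order(rownames(m))
  m <- m[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  tree <- ape::as.phylo(hc)
  if (!is.null(file)) ape::write.tree(tree, file)
  tree
}
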