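simple_alignment <- function(seqs, statuses, reference = names(seqs)[1],
                             offset = 0L) {
  allele_alignment(names(seqs), statuses, unname(unlist(seqs)),
                   numbering_offset = offset, reference = reference)
}

test_that("column-to-mature-position mapping handles offsets and gaps", {
  aln <- simple_alignment(list(ref = "ACDEFGHIKL", x = "ACDEFGHIKL"),
                          c("control", "risk"))
  expect_equal(map_numbering(aln, 5L), 5L)
  aln10 <- simple_alignment(list(ref = "ACDEFGHIKL", x = "ACDEFGHIKL"),
                            c("control", "risk"), offset = 24L)
  expect_equal(map_numbering(aln10, 1L), 25L)
  gapped <- simple_alignment(list(ref = "--CDEFGHIK", x = "AACDEFGHIK"),
                             c("control", "risk"))
  expect_equal(map_numbering(gapped, 3L), 1L)
  expect_error(map_numbering(gapped, 1L), "gap in reference")
  expect_error(map_numbering(gapped, 99L), "outside alignment width")
})

test_that("risk-unique scan recovers planted positions and honours controls", {
  # planted: risk share C at col 4 and T at col 8; controls differ there
  aln <- simple_alignment(
    list(R1 = "AAAC AAT A" , R2 = "AAAC AAT A",
         C1 = "AAAY AAN A", C2 = "AAAY AAI A") |>
      lapply(gsub, pattern = " ", replacement = "G"),
    c("risk", "risk", "control", "control"), reference = "C1")
  hits <- scan_unique_residues(aln)
  expect_equal(hits$position, c(4L, 8L))
  expect_equal(hits$risk_residue, c("C", "T"))
  expect_equal(hits$control_residues, c("Y", "I,N"))

  # a control sharing the risk residue kills the column
  aln2 <- simple_alignment(
    list(R1 = "AAACAAATGA", R2 = "AAACAAATGA",
         C1 = "AAAYAAATGA", C2 = "AAAYAAAIGA"),
    c("risk", "risk", "control", "control"), reference = "C1")
  expect_equal(scan_unique_residues(aln2)$position, 4L)

  # risk rows disagreeing everywhere yield nothing
  aln3 <- simple_alignment(
    list(R1 = "AAAA", R2 = "CCCC", C1 = "DDDD"),
    c("risk", "risk", "control"), reference = "C1")
  expect_equal(nrow(scan_unique_residues(aln3)), 0L)

  expect_error(scan_unique_residues(
    simple_alignment(list(R1 = "AAAA"), "risk")), "no rows with control")
})

test_that("scan matches the brute-force set-intersection oracle", {
  set.seed(2024)
  for (rep in 1:100) {
    n_risk <- sample(2:4, 1)
    n_ctrl <- sample(2:6, 1)
    width <- sample(20:200, 1)
    mat <- matrix(sample(c(hlagroove:::AA_LETTERS, "-"),
                         (n_risk + n_ctrl) * width,
                         replace = TRUE,
                         prob = c(rep(1, 20), 0.5)),
                  nrow = n_risk + n_ctrl)
    # make some columns low-diversity so hits actually occur
    for (col in sample(width, width %/% 4)) {
      mat[, col] <- sample(c("A", "C"), nrow(mat), replace = TRUE)
    }
    # gap-free reference row so column == mature position
    mat[n_risk + 1, ] <- ifelse(mat[n_risk + 1, ] == "-", "A",
                                mat[n_risk + 1, ])
    statuses <- c(rep("risk", n_risk), rep("control", n_ctrl))
    alleles <- sprintf("AL%02d", seq_len(nrow(mat)))
    aln <- allele_alignment(alleles, statuses,
                            apply(mat, 1, paste, collapse = ""),
                            reference = alleles[n_risk + 1])
    got <- scan_unique_residues(aln)$position
    want <- oracle_unique_positions(mat, seq_len(n_risk),
                                    n_risk + seq_len(n_ctrl))
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("adding a control copying a risk row removes all hits", {
  for (s in 1:10) {
    panel <- make_allele_panel(sim_config(seed = 400 + s))
    aln <- panel$alignment
    expect_gt(nrow(scan_unique_residues(aln)), 0L)
    risk_row <- which(aln$rows$status == "risk")[1]
    aug <- allele_alignment(c(aln$rows$allele, "COPY"),
                            c(aln$rows$status, "control"),
                            c(aln$rows$seq, aln$rows$seq[risk_row]),
                            reference = aln$reference)
    expect_equal(nrow(scan_unique_residues(aug)), 0L)
  }
})

test_that("possible-risk pair differs at exactly one column", {
  panel <- make_allele_panel(sim_config(seed = 9))
  pair <- panel$truth$possible_risk_pair
  s1 <- strsplit(panel$alignment$rows$seq[
    panel$alignment$rows$allele == pair[1]], "")[[1]]
  s2 <- strsplit(panel$alignment$rows$seq[
    panel$alignment$rows$allele == pair[2]], "")[[1]]
  expect_equal(sum(s1 != s2), 1L)
  expect_equal(which(s1 != s2), 80L)
})

test_that("mutation labels follow the <ref><pos><obs> convention", {
  aln <- simple_alignment(
    list(C1 = paste(rep("N", 80), collapse = ""),
         R1 = paste0(paste(rep("N", 79), collapse = ""), "T"),
         P1 = paste0(paste(rep("N", 79), collapse = ""), "I")),
    c("control", "risk", "possible_risk"), reference = "C1")
  expect_equal(mutation_label(aln, "R1", 80L, "N"), "N80T")
  expect_equal(mutation_label(aln, "P1", 80L, "N"), "N80I")
  expect_equal(mutation_label(aln, "C1", 80L, "N"), "N80")
})
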