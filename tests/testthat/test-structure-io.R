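pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     element, record = "ATOM") {
  sprintf("%-6s%5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, name, resname, chain, resno, x, y, z, element)
}

test_that("single ATOM records parse with verbatim fields", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(7, "CA", "THR", "A", 80, 1.5, -2.25, 3.125, "C"),
               "END"), f)
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$serial, 7L)
  expect_equal(s$atoms$name, "CA")
  expect_equal(s$atoms$resname, "THR")
  expect_equal(s$atoms$resno, 80L)
  expect_equal(c(s$atoms$x, s$atoms$y, s$atoms$z), c(1.5, -2.25, 3.125))
  expect_equal(s$atoms$element, "C")
})

test_that("PDBQT dialect yields the same atoms as the equivalent PDB", {
  fq <- withr::local_tempfile(fileext = ".pdbqt")
  fp <- withr::local_tempfile(fileext = ".pdb")
  # PDBQT tail: occupancy, temp factor, partial charge, AutoDock type
  writeLines(c(
    "ATOM      1  C1  LIG L   1       1.000   2.000   3.000  1.00  0.00    0.123 A ",
    "ATOM      2  N2  LIG L   1       2.000   2.500   3.000  1.00  0.00   -0.350 NA",
    "ATOM      3  S1  LIG L   1       0.000   1.000   3.000  1.00  0.00   -0.200 SA"),
    fq)
  writeLines(c(pdb_line(1, "C1", "LIG", "L", 1, 1, 2, 3, "C"),
               pdb_line(2, "N2", "LIG", "L", 1, 2, 2.5, 3, "N"),
               pdb_line(3, "S1", "LIG", "L", 1, 0, 1, 3, "S")), fp)
  sq <- read_structure(fq)
  sp <- read_structure(fp)
  expect_equal(sq$atoms[, names(sq$atoms) != "serial"],
               sp$atoms[, names(sp$atoms) != "serial"])
  expect_equal(sq$atoms$element, c("C", "N", "S"))
})

test_that("files without atoms and malformed coordinates are rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER junk", "END"), f)
  expect_error(read_structure(f), "no ATOM/HETATM")
  bad <- sub("   3.000", "  3.0.00",
             pdb_line(1, "CA", "ALA", "A", 1, 1, 2, 3, "C"))
  writeLines(bad, f)
  expect_error(read_structure(f), "line 1")
})

test_that("structure round-trips through PDB at 3-decimal precision", {
  cfg <- sim_config(seed = 11)
  g <- make_groove(cfg)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(g, f)
  g2 <- read_structure(f)
  expect_equal(nrow(g2$atoms), nrow(g$atoms))
  expect_equal(g2$atoms$name, g$atoms$name)
  expect_equal(g2$atoms$resno, g$atoms$resno)
  expect_equal(g2$atoms$x, round(g$atoms$x, 3), tolerance = 1e-9)
  expect_equal(g2$atoms$z, round(g$atoms$z, 3), tolerance = 1e-9)
})

test_that("plain-PDB parsing agrees with bio3d on a generated structure", {
  skip_if_not_installed("bio3d")
  g <- make_groove(sim_config(seed = 5))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(g, f)
  ours <- read_structure(f)
  ref <- bio3d::read.pdb(f)
  expect_equal(nrow(ours$atoms), nrow(ref$atom))
  expect_equal(ours$atoms$x, ref$atom$x)
  expect_equal(ours$atoms$resno, ref$atom$resno)
  expect_equal(trimws(ours$atoms$name), trimws(ref$atom$elety))
})

test_that("pose sets resolve scores from sidecar, REMARK, or fail loudly", {
  cfg <- sim_config(seed = 3)
  poses <- make_pose_set(cfg, c(B = 5L, F = 5L), search_space = "PBG")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pose_set(poses, f)

  # embedded REMARK scores
  back <- read_pose_set(f, search_space = "PBG", ligand_id = "MMZ")
  expect_length(back, 10L)
  expect_equal(vapply(back, `[[`, numeric(1), "score"),
               vapply(poses, `[[`, numeric(1), "score"))

  # agreeing sidecar is accepted; disagreeing sidecar is an error
  side <- data.frame(run_id = 1:10,
                     score = vapply(poses, `[[`, numeric(1), "score"))
  expect_length(read_pose_set(f, scores = side), 10L)
  side$score[7] <- side$score[7] + 1
  expect_error(read_pose_set(f, scores = side), "disagree.*run_id 7")

  # sidecar-only file: complete sidecar works, missing row is an error
  lines <- readLines(f)
  writeLines(grep("^REMARK", lines, invert = TRUE, value = TRUE), f)
  expect_length(read_pose_set(f, scores = side), 10L)
  expect_error(read_pose_set(f, scores = side[-7, ]),
               "no resolvable score for run_id 7")
})

test_that("pose cardinality and tags follow the file", {
  cfg <- sim_config(seed = 8)
  pbg <- make_pose_set(cfg, c(B = 5L, F = 5L), search_space = "PBG")
  top <- make_pose_set(cfg, c(B = 5L, F = 5L), search_space = "Top3")
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pose_set(pbg, f1)
  write_pose_set(top, f2)
  all20 <- c(read_pose_set(f1, search_space = "PBG"),
             read_pose_set(f2, search_space = "Top3"))
  tags <- vapply(all20, `[[`, character(1), "search_space")
  expect_equal(unname(table(tags)[c("PBG", "Top3")]), c(10L, 10L),
               ignore_attr = TRUE)
})

test_that("duplicate run ids are rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL 1", "REMARK SCORE -3.0",
               pdb_line(1, "C1", "LIG", "L", 1, 0, 0, 0, "C"), "ENDMDL",
               "MODEL 1", "REMARK SCORE -3.5",
               pdb_line(1, "C1", "LIG", "L", 1, 1, 0, 0, "C"), "ENDMDL"), f)
  expect_error(read_pose_set(f), "duplicate run_id")
})

test_that("reference atom lookup honours configuration and errors helpfully", {
  p <- synthetic_ligand_pose(c(1, 2, 3))
  ref <- get_reference_atom(p)
  expect_equal(ref$name, "C1")
  expect_equal(c(ref$x, ref$y, ref$z), c(1, 2, 3), tolerance = 1e-12)
  expect_equal(get_reference_atom(p, "C3")$name, "C3")
  expect_error(get_reference_atom(p, "C9"), "no atom named 'C9'.*C1")
})

test_that("superposition RMSD: identity, rigid invariance, symmetry", {
  g <- make_groove(sim_config(seed = 21))
  expect_equal(superpose_rmsd(g, g), 0, tolerance = 1e-9)
  set.seed(99)
  for (i in 1:100) {
    moved <- transform_structure(g, random_rotation(), rnorm(3, 0, 20))
    expect_lt(superpose_rmsd(g, moved), 1e-6)
  }
  set.seed(100)
  jit <- g
  jit$atoms$x <- jit$atoms$x + rnorm(nrow(jit$atoms), 0, 0.4)
  expect_equal(superpose_rmsd(g, jit), superpose_rmsd(jit, g),
               tolerance = 1e-9)
})

test_that("3-atom displacement: unfitted closed form and fitted rotation-grid bound", {
  # one atom of three displaced by 1 A: without fitting the RMSD is
  # exactly sqrt(1/3); with optimal superposition it is smaller, and a
  # random rotation/translation search can never beat the Kabsch fit
  a <- toy_structure(matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0), 3, byrow = TRUE),
                     name = c("A1", "A2", "A3"))
  b <- a
  b$atoms$z[1] <- 1
  expect_equal(superpose_rmsd(a, b, fit = FALSE), sqrt(1 / 3),
               tolerance = 1e-12)
  r_fit <- superpose_rmsd(a, b)
  expect_lt(r_fit, sqrt(1 / 3))
  # independent numeric optimisation over Euler angles + centroid shift
  P <- as.matrix(a$atoms[c("x", "y", "z")])
  Q <- as.matrix(b$atoms[c("x", "y", "z")])
  euler <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    matrix(c(cy * cz, cy * sz, -sy,
             sx * sy * cz - cx * sz, sx * sy * sz + cx * cz, sx * cy,
             cx * sy * cz + sx * sz, cx * sy * sz - sx * cz, cx * cy),
           3, 3, byrow = TRUE)
  }
  obj <- function(ang) {
    PR <- P %*% t(euler(ang))
    PR <- sweep(PR, 2, colMeans(PR) - colMeans(Q))
    sqrt(sum((PR - Q)^2) / 3)
  }
  opt <- optim(c(0, 0, 0), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  expect_lte(r_fit, opt$value + 1e-6)
  expect_equal(r_fit, opt$value, tolerance = 1e-3)
})

test_that("superposition agrees with bio3d's Kabsch fit", {
  skip_if_not_installed("bio3d")
  g <- make_groove(sim_config(seed = 31))
  set.seed(7)
  jit <- transform_structure(g, random_rotation(), rnorm(3, 0, 5))
  jit$atoms$x <- jit$atoms$x + rnorm(nrow(jit$atoms), 0, 0.3)
  jit$atoms$y <- jit$atoms$y + rnorm(nrow(jit$atoms), 0, 0.3)
  xyz_a <- as.vector(t(as.matrix(g$atoms[c("x", "y", "z")])))
  xyz_b <- as.vector(t(as.matrix(jit$atoms[c("x", "y", "z")])))
  idx <- seq_along(xyz_a)
  fitted <- bio3d::fit.xyz(fixed = xyz_a, mobile = xyz_b,
                           fixed.inds = idx, mobile.inds = idx)
  ref <- bio3d::rmsd(xyz_a, fitted)
  expect_equal(superpose_rmsd(g, jit), ref, tolerance = 1e-4)
})

test_that("alignment reading enforces shape and carries status labels", {
  f <- withr::local_tempfile(fileext = ".fasta")
  seqs <- replicate(8, paste(sample(c("A", "C", "G", "T", "N", "Y"), 100,
                                    replace = TRUE), collapse = ""))
  writeLines(as.vector(rbind(paste0(">AL", 1:8), seqs)), f)
  labels <- data.frame(allele = paste0("AL", 1:8),
                       status = c("risk", "risk", "possible_risk",
                                  rep("control", 5)))
  aln <- read_alignment(f, labels)
  expect_equal(nrow(aln$rows), 8L)
  expect_equal(aln$rows$status[3], "possible_risk")
  expect_equal(sum(aln$rows$status == "control"), 5L)

  writeLines(c(">A", "ACDEF", ">B", "ACD"), f)
  expect_error(read_alignment(f), "ragged")
  writeLines(c(">A", "ACDEF", ">A", "ACDEF"), f)
  expect_error(read_alignment(f), "duplicate")
})
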