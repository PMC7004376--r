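protein_atom <- function(serial, name, element, resname, resno, xyz) {
  data.frame(serial = serial, name = name, element = element,
             resname = resname, resno = resno, chain = "A",
             x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
}

test_that("thiocarbonyl sulfur detection: C=S found, thioether and no-S rejected", {
  p <- synthetic_ligand_pose(c(0, 0, 0), thiocarbonyl = TRUE)
  expect_equal(find_thiocarbonyl_sulfur(p), "S1")
  # canonical C=S bond length in the template
  s1 <- p$atoms[p$atoms$name == "S1", ]
  c1 <- p$atoms[p$atoms$name == "C1", ]
  expect_equal(sqrt((s1$x - c1$x)^2 + (s1$y - c1$y)^2 + (s1$z - c1$z)^2),
               1.68, tolerance = 1e-6)

  expect_true(is.na(find_thiocarbonyl_sulfur(
    synthetic_ligand_pose(c(0, 0, 0), thiocarbonyl = FALSE))))

  # thioether: C-S-C with both bonds ~1.81 A fails the carbonyl pattern
  thioether <- hlagroove:::new_ligand_pose(
    rbind(protein_atom(9001, "C1", "C", "LIG", 1, c(-1.81, 0, 0)),
          protein_atom(9002, "S1", "S", "LIG", 1, c(0, 0, 0)),
          protein_atom(9003, "C2", "C", "LIG", 1, c(1.81, 0, 0)),
          protein_atom(9004, "C3", "C", "LIG", 1, c(-2.5, 1.2, 0)),
          protein_atom(9005, "C4", "C", "LIG", 1, c(-2.5, -1.2, 0))),
    score = -3, run_id = 1, search_space = "PBG", ligand_id = "THE")
  expect_true(is.na(find_thiocarbonyl_sulfur(thioether)))
})

test_that("contact windows behave at the default cutoffs", {
  prot <- hlagroove:::new_structure3d(
    rbind(protein_atom(1, "CB", "C", "ALA", 10, c(0, 0, 0)),
          protein_atom(2, "O", "O", "ALA", 11, c(10, 0, 0))), "toy")
  lig_at <- function(xyz, name = "C9", element = "C") {
    hlagroove:::new_ligand_pose(
      protein_atom(9001, name, element, "LIG", 1, xyz),
      score = -1, run_id = 1, search_space = "PBG", ligand_id = "L")
  }
  # carbon 3.5 A from a side-chain carbon: one hydrophobic record
  rec <- detect_contacts(prot, lig_at(c(3.5, 0, 0)))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$kind, "hydrophobic")
  expect_equal(rec$distance, 3.5, tolerance = 1e-9)
  expect_equal(rec$residue_position, 10L)
  # ligand N donor 2.9 A from a backbone O: one hydrogen bond
  rec2 <- detect_contacts(prot, lig_at(c(12.9, 0, 0), "N9", "N"))
  expect_equal(nrow(rec2), 1L)
  expect_equal(rec2$kind, "hbond")
  # far atom: nothing
  expect_equal(nrow(detect_contacts(prot, lig_at(c(50, 0, 0)))), 0L)
  # overlapping serial numbers are rejected
  clash <- lig_at(c(3.5, 0, 0))
  clash$atoms$serial <- 1L
  expect_error(detect_contacts(prot, clash), "serial")
})

test_that("contact detection equals the all-pairs brute-force oracle", {
  set.seed(321)
  for (rep in 1:50) {
    n_prot <- sample(20:60, 1)
    elements <- sample(c("C", "N", "O", "S"), n_prot, replace = TRUE)
    prot_atoms <- do.call(rbind, lapply(seq_len(n_prot), function(i) {
      protein_atom(i, paste0(elements[i], i), elements[i],
                   sample(c("ALA", "THR", "SER", "ASN", "LYS"), 1),
                   i, runif(3, -8, 8))
    }))
    prot <- hlagroove:::new_structure3d(prot_atoms, paste0("rand", rep))
    pose <- synthetic_ligand_pose(runif(3, -8, 8),
                                  direction = rnorm(3),
                                  thiocarbonyl = rep %% 2 == 0)
    got <- detect_contacts(prot, pose)
    want <- oracle_contacts(prot, pose)
    expect_equal(nrow(got), nrow(want))
    key <- function(df) sort(paste(df$residue_position, df$protein_atom,
                                   df$ligand_atom, df$kind,
                                   round(df$distance, 9)))
    expect_equal(key(got), key(want))
  }
})

test_that("hydrophobic records shrink monotonically with hphob_max", {
  cfg <- sim_config(seed = 53)
  g <- make_groove(cfg)
  pose <- synthetic_ligand_pose(unname(
    hlagroove:::pocket_centers(cfg)$F))
  maxes <- c(3.9, 3.6, 3.3, 3.0)
  counts <- vapply(maxes, function(m) {
    sum(detect_contacts(g, pose, contact_params(hphob_max = m))$kind ==
          "hydrophobic")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("Thr80 taxonomy distinguishes thiocarbonyl, other, and absent contacts", {
  # hand-built residue 80 with a THR side chain at a known spot
  prot <- hlagroove:::new_structure3d(
    rbind(protein_atom(1, "CB", "C", "THR", 80, c(0, 0, 0)),
          protein_atom(2, "OG1", "O", "THR", 80, c(0, 1.4, 0)),
          protein_atom(3, "CB", "C", "ALA", 45, c(20, 0, 0))), "thr80")

  # thiocarbonyl S placed 3.4 A from the THR CB -> Thr80_S
  p1 <- synthetic_ligand_pose(c(-5.08, 0, 0), direction = c(1, 0, 0))
  s1 <- p1$atoms[p1$atoms$name == "S1", ]
  expect_equal(sqrt(sum(c(s1$x, s1$y, s1$z)^2)), 3.4, tolerance = 1e-6)
  r1 <- detect_contacts(prot, p1)
  expect_equal(classify_thr80(r1, p1, prot), "Thr80_S")

  # same geometry without the sulfur: ring atoms contact 80 -> OtherThr80
  p2 <- synthetic_ligand_pose(c(-3.4, 0, 0), direction = c(-1, 0, 0),
                              thiocarbonyl = FALSE)
  r2 <- detect_contacts(prot, p2)
  expect_gt(sum(r2$residue_position == 80), 0)
  expect_equal(classify_thr80(r2, p2, prot), "OtherThr80")

  # no contacts at 80 at all -> NoThr80
  p3 <- synthetic_ligand_pose(c(100, 0, 0))
  expect_equal(classify_thr80(detect_contacts(prot, p3), p3, prot),
               "NoThr80")
  expect_error(classify_thr80(r1, p1, prot, position = 999L), "absent")
})

test_that("pose with no atom near the protein always classifies NoThr80", {
  cfg <- sim_config(seed = 61)
  g <- make_groove(cfg)
  set.seed(15)
  for (i in 1:20) {
    far <- synthetic_ligand_pose(c(200, 200, 200) + rnorm(3),
                                 direction = rnorm(3))
    recs <- detect_contacts(g, far)
    expect_equal(nrow(recs), 0L)
    expect_equal(classify_thr80(recs, far, g), "NoThr80")
  }
})

test_that("Thr80 tabulation counts match a brute-force tally and sum to n", {
  set.seed(654)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    classes <- sample(c("NoThr80", "Thr80_S", "OtherThr80"), n,
                      replace = TRUE)
    scores <- round(runif(n, -7, -2), 2)
    row <- tabulate_thr80(classes, scores)
    expect_equal(row$no_thr80, sum(classes == "NoThr80"))
    expect_equal(row$thr80_s, sum(classes == "Thr80_S"))
    expect_equal(row$other_thr80, sum(classes == "OtherThr80"))
    expect_equal(row$no_thr80 + row$thr80_s + row$other_thr80, n)
    best <- which(scores == min(scores))[1]
    expect_equal(row$most_favourable, classes[best])
  }
  expect_equal(tabulate_thr80("NoThr80", -3)$most_favourable, "NoThr80")
  expect_error(tabulate_thr80(character(), numeric()), "empty")
})

test_that("summary rows render with the printed class labels", {
  row <- tabulate_thr80(c(rep("NoThr80", 5), rep("Thr80_S", 4), "OtherThr80"),
                        c(-3, -3.1, -3.2, -3.3, -3.4,
                          -5.1, -4.2, -4.3, -4.4, -3.9))
  expect_equal(format_thr80_row(row), "5 4 1 Thr80-S")
})
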