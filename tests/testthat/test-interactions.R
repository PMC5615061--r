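# Hydrogen-bond geometry, contact fingerprints, key-residue triage and
# the pairwise energy decomposition.

# one receptor N/O "residue" and a ligand hydroxyl at a chosen
# distance/angle
toy_pair <- function(da_dist, dha_angle, with_h = TRUE) {
  receptor <- tibble::tibble(
    chain = "A", resno = 842L, insert = "", resname = "LYS",
    atom_name = "NZ", element = "N",
    x = da_dist, y = 0, z = 0, occupancy = 1, alt = "", het = FALSE)
  th <- dha_angle * pi / 180
  sinA <- sin(th) / da_dist
  angA <- asin(min(1, sinA))
  angD <- pi - th - angA
  H <- c(cos(angD), sin(angD), 0)
  pose <- tibble::tibble(
    atom = c("O1", "H1"), element = c("O", "H"),
    x = c(0, H[1]), y = c(0, H[2]), z = c(0, H[3]))
  if (!with_h) pose <- pose[1, ]
  list(pose = pose, receptor = receptor)
}

test_that("hydrogen bonds require both distance and angle", {
  ok <- toy_pair(2.8, 170)
  hb <- detect_hbonds(ok$pose, ok$receptor)
  expect_true(any(hb$donor_side == "ligand" & hb$angle_checked))
  expect_equal(hb$distance[1], 2.8, tolerance = 1e-9)
  expect_equal(hb$angle[hb$donor_side == "ligand"], 170, tolerance = 1e-6)

  far <- toy_pair(5.0, 170)
  expect_equal(nrow(detect_hbonds(far$pose, far$receptor)), 0)

  bent <- toy_pair(2.8, 90)
  hb_bent <- detect_hbonds(bent$pose, bent$receptor)
  expect_false(any(hb_bent$donor_side == "ligand"))
})

test_that("donors without resolved hydrogens fall back to distance-only", {
  noh <- toy_pair(2.8, 170, with_h = FALSE)
  hb <- detect_hbonds(noh$pose, noh$receptor)
  expect_true(nrow(hb) >= 1)
  expect_true(all(!hb$angle_checked))
  expect_true(all(is.na(hb$angle)))
})

test_that("apolar poses give empty hydrogen-bond sets, not errors", {
  apolar <- tibble::tibble(atom = "C1", element = "C", x = 0, y = 0, z = 0)
  rec <- toy_pair(2.8, 170)$receptor
  expect_equal(nrow(detect_hbonds(apolar, rec)), 0)
})

test_that("hydrogen-bond detection matches the brute-force scan", {
  set.seed(41)
  for (k in 1:25) {
    nl <- sample(3:8, 1); nr <- sample(4:10, 1)
    pose <- tibble::tibble(
      atom = sprintf("a%d", 1:nl),
      element = sample(c("C", "N", "O", "H"), nl, replace = TRUE),
      x = runif(nl, -4, 4), y = runif(nl, -4, 4), z = runif(nl, -4, 4))
    receptor <- tibble::tibble(
      chain = "A", resno = rep(1:2, length.out = nr), insert = "",
      resname = "GLY",
      atom_name = sprintf("r%d", 1:nr),
      element = sample(c("C", "N", "O", "H"), nr, replace = TRUE),
      x = runif(nr, -4, 4), y = runif(nr, -4, 4), z = runif(nr, -4, 4),
      occupancy = 1, alt = "", het = FALSE)
    hb <- detect_hbonds(pose, receptor)
    got <- sort(paste(hb$donor_side, hb$donor_index, hb$acceptor_index))
    expect_equal(got, brute_hbond_pairs(pose, receptor))
  }
})

test_that("fingerprints mark planted contacts and imply polar from hbond", {
  tc <- gen_toy_complex(generator_spec(seed = 2))
  fp <- contact_fingerprint(tc$pose, tc$receptor)
  expect_true(all(fp$has_polar[fp$has_hbond]))
  expect_equal(sort(fp$resno[fp$has_hbond]), sort(tc$truth$contact_resno))
  expect_true(all(!fp$has_hbond[!fp$resno %in% tc$truth$contact_resno]))
  # repeated bonds to one residue keep a single idempotent record
  expect_equal(nrow(fp), 5)
})

test_that("triage applies any/all semantics and errors on absent residues", {
  tc <- gen_toy_complex(generator_spec(seed = 2)) # contact with Lys842 only
  fp <- contact_fingerprint(tc$pose, tc$receptor)
  any_rule <- triage_key_residues(fp, triage_rule(mode = "any"))
  expect_true(any_rule$pass)
  expect_equal(any_rule$matched, 842L)
  all_rule <- triage_key_residues(fp, triage_rule(mode = "all"))
  expect_false(all_rule$pass)
  none <- triage_key_residues(fp, triage_rule(residues = c(557), mode = "any"))
  expect_false(none$pass)
  expect_error(triage_key_residues(fp, triage_rule(residues = 999)), "999")
})

test_that("Coulomb and Lennard-Jones terms follow their closed forms", {
  rec <- tibble::tibble(chain = "A", resno = 1L, insert = "",
                        resname = "GLY", atom_name = "N", element = "N",
                        x = 3.32, y = 0, z = 0, occupancy = 1, alt = "",
                        het = FALSE, charge = -0.5)
  pose <- tibble::tibble(atom = "O1", element = "O", x = 0, y = 0, z = 0,
                         charge = 0.5)
  no_lj <- lj_params(tibble::tibble(element = c("N", "O"),
                                    rmin_half = c(1, 1), epsilon = c(0, 0)))
  en <- per_residue_energy(pose, rec, params = no_lj, cutoff = 10)
  expect_equal(en$energy_kcal_mol, 332.0636 * (-0.25) / 3.32,
               tolerance = 1e-9)
  expect_equal(en$energy_kcal_mol, -25.0, tolerance = 0.001)

  # at r = rmin with zero charges the LJ well depth is exactly -epsilon
  rec0 <- dplyr::mutate(rec, charge = 0, x = 2 * 1.7)
  pose0 <- dplyr::mutate(pose, charge = 0)
  pl <- lj_params(tibble::tibble(element = c("N", "O"),
                                 rmin_half = c(1.7, 1.7),
                                 epsilon = c(0.2, 0.2)))
  en0 <- per_residue_energy(pose0, rec0, params = pl, cutoff = 10)
  expect_equal(en0$energy_kcal_mol, -0.2, tolerance = 1e-12)

  # beyond the cutoff everything is zero
  en_cut <- per_residue_energy(pose, rec, cutoff = 2)
  expect_equal(en_cut$energy_kcal_mol, 0)
  expect_equal(attr(en_cut, "total"), 0)

  expect_error(per_residue_energy(dplyr::select(pose, -charge), rec),
               "charge")
})

test_that("per-residue energies conserve the brute-force pairwise total", {
  set.seed(53)
  params <- lj_params()
  for (k in 1:20) {
    tc <- gen_toy_complex(generator_spec(seed = k))
    en <- per_residue_energy(tc$pose, tc$receptor, params = params,
                             cutoff = 8)
    brute <- brute_total_energy(tc$pose, tc$receptor, params, cutoff = 8)
    expect_equal(attr(en, "total"), brute, tolerance = 1e-9)
  }
})

test_that("energies and hydrogen bonds are rigid-motion invariant", {
  set.seed(59)
  tc <- gen_toy_complex(generator_spec(seed = 6))
  en0 <- per_residue_energy(tc$pose, tc$receptor, cutoff = 8)
  hb0 <- detect_hbonds(tc$pose, tc$receptor)
  for (k in 1:5) {
    tr <- random_rigid()
    en1 <- per_residue_energy(apply_rigid(tc$pose, tr),
                              apply_rigid(tc$receptor, tr), cutoff = 8)
    expect_equal(en1$energy_kcal_mol, en0$energy_kcal_mol, tolerance = 1e-9)
    hb1 <- detect_hbonds(apply_rigid(tc$pose, tr),
                         apply_rigid(tc$receptor, tr))
    expect_equal(nrow(hb1), nrow(hb0))
    expect_equal(sort(hb1$distance), sort(hb0$distance), tolerance = 1e-9)
  }
})
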