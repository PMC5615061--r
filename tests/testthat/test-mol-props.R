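# Molecular parsing, the four screened descriptors, and the filter
# cascade.

AMENTOFLAVONE <-
  "O=c1cc(-c2ccc(O)c(-c3c(O)cc(O)c4c(=O)cc(-c5ccc(O)cc5)oc34)c2)oc2cc(O)cc(O)c12"

test_that("SMILES parsing reproduces format-defined graphs", {
  b <- parse_molecule("c1ccccc1")
  expect_equal(nrow(b$atoms), 6)
  expect_equal(nrow(b$bonds), 6)
  expect_true(all(b$atoms$aromatic))
  expect_true(all(b$atoms$implicit_h == 1))
  expect_true(all(b$bonds$order == "a"))

  e <- parse_molecule("CCO")
  expect_equal(nrow(e$atoms), 3)
  expect_equal(nrow(e$bonds), 2)
  expect_true(all(e$bonds$order == "1"))
  expect_equal(e$atoms$implicit_h, c(3L, 2L, 1L))

  g <- parse_smiles("[NH3+]CC([O-])=O")
  expect_equal(g$atoms$charge, c(1L, 0L, 0L, -1L, 0L))
  expect_equal(g$atoms$implicit_h[1], 3L)
})

test_that("malformed SMILES raise errors naming the token position", {
  expect_error(parse_smiles("C1CC"), "position 2.*never closed")
  expect_error(parse_smiles("C[Xx]C"), "unknown element")
  expect_error(parse_smiles("C[NH"), "unclosed bracket")
  expect_error(parse_smiles("CC)C"), "unmatched")
})

test_that("molecular weight sums average atomic masses incl. implicit H", {
  expect_equal(molecular_weight(parse_smiles("O")), 18.02, tolerance = 0.001)
  expect_equal(molecular_weight(parse_smiles("c1ccccc1")), 78.11,
               tolerance = 1e-4)
  # hexahydroxy biflavone, C30H18O10
  expect_equal(molecular_weight(parse_smiles(AMENTOFLAVONE)), 538.46,
               tolerance = 1e-4)
})

test_that("ring systems merge fused/spiro rings and split linked ones", {
  expect_equal(count_ring_systems(parse_smiles("c1ccccc1")), 1)
  expect_equal(count_ring_systems(parse_smiles("c1ccc2ccccc2c1")), 1) # fused
  expect_equal(count_ring_systems(parse_smiles("C1CCC2(CC1)CCCCC2")), 1) # spiro
  expect_equal(count_ring_systems(parse_smiles("c1ccccc1-c1ccccc1")), 2)
  expect_equal(count_ring_systems(parse_smiles("CCCC")), 0)
  expect_equal(count_ring_systems(parse_smiles(AMENTOFLAVONE)), 4)
})

test_that("ring-system count is invariant under atom reordering", {
  variants <- c("c1ccccc1-c1ccccc1CC", "CCc1ccccc1-c1ccccc1",
                "c1cc(-c2ccccc2CC)ccc1")
  counts <- vapply(variants, function(s) count_ring_systems(parse_smiles(s)),
                   numeric(1))
  expect_true(all(counts == 2))
})

test_that("Lipinski-style donor/acceptor counts follow the convention", {
  expect_equal(count_hb_donors_acceptors(parse_smiles("c1ccccc1")),
               list(hbd = 0L, hba = 0L))
  expect_equal(count_hb_donors_acceptors(parse_smiles("CCO")),
               list(hbd = 1L, hba = 1L))
  am <- count_hb_donors_acceptors(parse_smiles(AMENTOFLAVONE))
  expect_equal(am$hbd, 6L) # six phenolic hydroxyls
  expect_equal(am$hba, 10L) # all ten oxygens
  # pyrrole-type exclusion drops the aromatic N-H from the acceptors
  pyrrole <- parse_smiles("c1cc[nH]c1")
  expect_equal(count_hb_donors_acceptors(pyrrole)$hba, 1L)
  expect_equal(count_hb_donors_acceptors(pyrrole, exclude_pyrrole_n = TRUE)$hba,
               0L)
})

test_that("ionization takes charges as drawn", {
  expect_equal(classify_ionization(parse_smiles("C")),
               list(net_charge = 0L, is_zwitterion = FALSE))
  expect_equal(classify_ionization(parse_smiles("CC([O-])=O")),
               list(net_charge = -1L, is_zwitterion = FALSE))
  expect_equal(classify_ionization(parse_smiles("[NH3+]CC([O-])=O")),
               list(net_charge = 0L, is_zwitterion = TRUE))
})

test_that("the filter cascade evaluates every rule independently", {
  am <- apply_filter_cascade(parse_smiles(AMENTOFLAVONE, id = "amento"))
  expect_true(am$pass_overall)
  expect_equal(am$n_ring_systems, 4)

  bz <- apply_filter_cascade(parse_smiles("c1ccccc1", id = "benzene"))
  expect_false(bz$pass_overall)
  expect_false(bz$pass_mw) # 78 Da below the window
  expect_false(bz$pass_hbonds) # no donors/acceptors
  expect_true(bz$pass_charge)

  vacuous <- filter_rules(mw_min = 0, mw_max = Inf,
                          require_neutral_non_zwitterion = FALSE,
                          ring_systems_min = 0, ring_systems_max = Inf,
                          hba_min = 0, hbd_min = 0)
  expect_true(apply_filter_cascade(parse_smiles("c1ccccc1"),
                                   vacuous)$pass_overall)
  expect_true(apply_filter_cascade(parse_smiles("[NH3+]CC([O-])=O"),
                                   vacuous)$pass_overall)
})

test_that("overall_pass is the conjunction of the four flags", {
  gl <- gen_library(generator_spec(seed = 42, library = list(n = 80)))
  rep <- filter_library(gl$molecules)
  expect_equal(rep$pass_overall,
               rep$pass_mw & rep$pass_charge & rep$pass_rings &
                 rep$pass_hbonds)
})

test_that("widening the rules never loses passing molecules", {
  gl <- gen_library(generator_spec(seed = 9, library = list(n = 100)))
  narrow <- filter_library(gl$molecules, filter_rules())
  wide <- filter_library(gl$molecules,
                         filter_rules(mw_min = 100, mw_max = 900,
                                      ring_systems_min = 0,
                                      ring_systems_max = 8, hbd_min = 0))
  expect_true(all(wide$pass_overall[narrow$pass_overall]))
  expect_gte(sum(wide$pass_overall), sum(narrow$pass_overall))
})

test_that("SDF blocks parse with charges, aromatic bonds and $$$$ records", {
  sdf <- paste(
    "acetate", "  synthetic", "",
    " 4  3  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    1.5000    0.0000    0.0000 C   0  0",
    "    2.1000    1.1000    0.0000 O   0  0",
    "    2.1000   -1.1000    0.0000 O   0  0",
    "  1  2  1  0", "  2  3  2  0", "  2  4  1  0",
    "M  CHG  1   4  -1",
    "M  END",
    sep = "\n")
  m <- parse_molecule(sdf)
  expect_equal(m$id, "acetate")
  expect_equal(nrow(m$atoms), 4)
  expect_equal(m$atoms$charge, c(0L, 0L, 0L, -1L))
  expect_equal(classify_ionization(m)$net_charge, -1L)
  # methyl keeps 3 implicit H; the charged oxygen none
  expect_equal(m$atoms$implicit_h, c(3L, 0L, 0L, 0L))
  expect_equal(molecular_weight(m), 59.04, tolerance = 0.01)

  tmp <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(strsplit(sdf, "\n")[[1]], "$$$$",
               strsplit(sdf, "\n")[[1]], "$$$$"), tmp)
  mols <- read_library(tmp)
  expect_length(mols, 2)
})

test_that("unparsable library entries are skipped with a warning", {
  tmp <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ok1", "C1CC broken", "c1ccccc1 ok2"), tmp)
  expect_warning(mols <- read_library(tmp), "skipping")
  expect_equal(vapply(mols, function(m) m$id, character(1)), c("ok1", "ok2"))
})

test_that("generated molecules round-trip through the SDF writer", {
  gl <- gen_library(generator_spec(seed = 15, library = list(n = 15)))
  tmp <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(gl$molecules, tmp)
  back <- read_library(tmp)
  expect_length(back, 15)
  rep <- filter_library(back)
  expect_equal(rep$id, gl$truth$id)
  expect_equal(rep$mw, gl$truth$mw, tolerance = 1e-6)
  expect_equal(rep$hbd, gl$truth$hbd)
  expect_equal(rep$net_charge, gl$truth$net_charge)
  expect_equal(rep$n_ring_systems, gl$truth$n_ring_systems)
})

test_that("generated SMILES round-trip through the writer", {
  gl <- gen_library(generator_spec(seed = 3, library = list(n = 10)))
  tmp <- withr::local_tempfile(fileext = ".smi")
  write_smiles(gl$molecules, tmp)
  back <- read_library(tmp)
  expect_equal(vapply(back, function(m) m$id, character(1)),
               gl$truth$id)
  expect_equal(filter_library(back)$mw, gl$truth$mw, tolerance = 1e-6)
})
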