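# PDB parsing, Kabsch superposition, in-place pose RMSD and pose
# clustering.

test_that("PDB records parse with keep-first altloc policy", {
  lines <- c(
    "ATOM      1  CA  PRO A 559      10.000  20.000  30.000  1.00  0.00           C",
    "ATOM      2  CA APRO A 560       1.000   2.000   3.000  0.50  0.00           C",
    "ATOM      3  CA BPRO A 560       9.000   9.000   9.000  0.50  0.00           C",
    "HETATM    4  O1  LIG A 900       0.000   0.000   0.000  1.00  0.00           O")
  s <- parse_pdb(lines)
  expect_equal(nrow(s), 3) # altloc B dropped
  expect_equal(s$x[s$resno == 559], 10)
  expect_equal(s$x[s$resno == 560], 1) # first altloc kept
  expect_true(s$het[s$resname == "LIG"])
  expect_error(parse_pdb("REMARK nothing here"), "no ATOM/HETATM")
})

test_that("Kabsch recovers identity, known rotations and proper reflections", {
  P <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, byrow = TRUE)
  sp0 <- kabsch_superpose(P, P)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(sp0$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-12)

  th <- pi / 2
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  sp <- kabsch_superpose(P, P %*% t(Rz))
  expect_equal(sp$rotation, Rz, tolerance = 1e-8)
  expect_equal(sp$rmsd, 0, tolerance = 1e-8)

  # mirror image: no proper rotation achieves zero, determinant stays +1
  set.seed(5)
  Q <- matrix(rnorm(15), 5)
  M <- Q; M[, 1] <- -M[, 1]
  spm <- kabsch_superpose(M, Q)
  expect_equal(det(spm$rotation), 1, tolerance = 1e-9)
  expect_gt(spm$rmsd, 0.1)

  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), "at least 3")
  line <- cbind(1:4, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("Kabsch RMSD agrees with the quaternion oracle on random pairs", {
  set.seed(11)
  for (k in 1:200) {
    n <- sample(3:50, 1)
    P <- matrix(rnorm(3 * n), n)
    Q <- matrix(rnorm(3 * n), n)
    expect_equal(kabsch_superpose(P, Q)$rmsd, quaternion_rmsd(P, Q),
                 tolerance = 1e-10)
  }
})

test_that("A-onto-B and B-onto-A superpositions are mutually inverse", {
  set.seed(13)
  for (k in 1:20) {
    A <- matrix(rnorm(30), 10)
    B <- matrix(rnorm(30), 10)
    f <- kabsch_superpose(A, B)
    g <- kabsch_superpose(B, A)
    comp <- f$rotation %*% g$rotation
    expect_equal(comp, diag(3), tolerance = 1e-6)
    roundtrip <- apply_superposition(f, apply_superposition(g, A))
    expect_equal(roundtrip, A, tolerance = 1e-6)
  }
})

test_that("CA-core superposition brings a rotated copy home", {
  set.seed(21)
  n <- 12
  ref <- tibble::tibble(
    chain = "A", resno = seq_len(n), insert = "",
    resname = "GLY", atom_name = "CA", element = "C",
    x = rnorm(n, sd = 5), y = rnorm(n, sd = 5), z = rnorm(n, sd = 5),
    occupancy = 1, alt = "", het = FALSE)
  tr <- random_rigid()
  mob <- apply_rigid(ref, tr)
  out <- superpose_structures(mob, ref)
  expect_lt(out$superposition$rmsd, 1e-8)
  expect_equal(out$atoms$x, ref$x, tolerance = 1e-8)
})

test_that("in-place pose RMSD follows its closed forms", {
  set.seed(3)
  a <- matrix(rnorm(12), 4)
  expect_equal(pose_rmsd(a, a), 0)
  b <- sweep(a, 2, c(3, 4, 0), `+`)
  expect_equal(pose_rmsd(a, b), 5)
  expect_equal(pose_rmsd(matrix(c(0, 0, 0), 1), matrix(c(2, 0, 0), 1)), 2)
  expect_error(pose_rmsd(a, a[1:3, ]), "differ")
})

test_that("pose RMSD is a metric on fixed-ordering poses", {
  set.seed(17)
  for (k in 1:50) {
    a <- matrix(rnorm(15), 5); b <- matrix(rnorm(15), 5)
    c_ <- matrix(rnorm(15), 5)
    expect_equal(pose_rmsd(a, b), pose_rmsd(b, a))
    expect_lte(pose_rmsd(a, c_), pose_rmsd(a, b) + pose_rmsd(b, c_) + 1e-12)
  }
})

test_that("pose clustering finds the biggest cluster and its representative", {
  set.seed(31)
  base <- matrix(rnorm(30), 10)
  near <- lapply(1:3, function(k) base + matrix(rnorm(30, sd = 0.2), 10))
  far <- list(base + 10)
  poses <- c(near, far)
  names(poses) <- sprintf("p%d", 1:4)
  cl <- cluster_poses(poses, threshold = 2)
  expect_equal(max(cl$assignments$cluster_size), 3)
  expect_true(cl$assignments$is_biggest[1])
  expect_false(cl$assignments$is_biggest[4])

  same <- cluster_poses(list(a = base, b = base, c = base), threshold = 1)
  expect_equal(unique(same$assignments$cluster), 1L)
  expect_equal(unique(same$assignments$cluster_size), 3L)

  # all singletons: biggest-cluster tie broken by best affinity
  spread <- list(x = base, y = base + 20, z = base + 40)
  cl2 <- cluster_poses(spread, threshold = 0.5,
                       affinities = c(x = -6, y = -9, z = -7))
  expect_equal(cl2$representative, "y")
  expect_true(all(cl2$assignments$cluster_size == 1))
})

test_that("pose clustering is invariant under input order", {
  set.seed(33)
  base <- matrix(rnorm(24), 8)
  poses <- list(a = base, b = base + 0.1, c = base + 12,
                d = base + 12.05, e = base + 0.2)
  aff <- c(a = -7, b = -8, c = -6, d = -5, e = -7.5)
  cl1 <- cluster_poses(poses, 2, aff)
  perm <- c("c", "e", "a", "d", "b")
  cl2 <- cluster_poses(poses[perm], 2, aff[perm])
  for (id in names(poses)) {
    m1 <- cl1$assignments[cl1$assignments$pose_id == id, ]
    m2 <- cl2$assignments[cl2$assignments$pose_id == id, ]
    expect_equal(m1$cluster_size, m2$cluster_size)
    expect_equal(m1$is_biggest, m2$is_biggest)
    expect_equal(m1$is_representative, m2$is_representative)
  }
  expect_equal(cl1$representative, cl2$representative)
})
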