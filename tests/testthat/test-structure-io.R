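test_that("read_pdb parses ATOM records, drops hydrogens/altlocs/HETATM", {
  pdb <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
    "ATOM      6  HA  ALA A   1       1.800  -0.500   0.900  1.00  0.00           H",
    "ATOM      7  N  AGLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      8  N  BGLY A   2       3.400   1.600   0.100  1.00  0.00           N",
    "ATOM      9  CA  GLY A   2       4.000   2.800   0.000  1.00  0.00           C",
    "HETATM   10  O   HOH A 100      9.000   9.000   9.000  1.00  0.00           O",
    "END")
  f <- withr::local_tempfile(lines = pdb, fileext = ".pdb")
  s <- read_pdb(f, domain_map = list(core = c(1, 2)))
  expect_s3_class(s, "sbm_structure")
  # 5 heavy atoms res 1 + altloc-A N + CA of res 2; H and HETATM dropped
  expect_equal(n_atoms(s), 7)
  expect_false("H" %in% s$element)
  expect_equal(sum(s$resid == 2), 2)
  expect_equal(s$xyz[2, ], c(1.458, 0, 0))
  expect_equal(unique(s$domain), "core")
})

test_that("read_pdb error contracts: HETATM-only, insertion codes, coverage", {
  het <- c("HETATM    1  O   HOH A   1       0.0     0.0     0.0  1.00  0.00           O",
           "END")
  f <- withr::local_tempfile(lines = het, fileext = ".pdb")
  expect_error(read_pdb(f, list(core = c(1, 1))), "no ATOM records")

  ins <- c("ATOM      1  CA  ALA A   1A      0.000   0.000   0.000  1.00  0.00           C",
           "END")
  f2 <- withr::local_tempfile(lines = ins, fileext = ".pdb")
  expect_error(read_pdb(f2, list(core = c(1, 1))), "insertion")

  ok <- c("ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
          "ATOM      2  CA  ALA A   5       3.800   0.000   0.000  1.00  0.00           C",
          "END")
  f3 <- withr::local_tempfile(lines = ok, fileext = ".pdb")
  s <- read_pdb(f3, list(core = c(1, 1)))
  expect_equal(s$domain, c("core", "linker"))
  expect_error(read_pdb(f3, list(core = c(1, 1)), linker_label = NULL),
               "not covered")
})

test_that("radius_of_gyration matches its definition and symmetry cases", {
  # two identical-mass atoms 2 A apart
  s2 <- place_atoms(rbind(c(0, 0, 0), c(2, 0, 0)), resid = 1:2)
  expect_equal(radius_of_gyration(s2), 1.0)
  # single atom
  s1 <- place_atoms(matrix(c(1, 2, 3), 1), resid = 1)
  expect_equal(radius_of_gyration(s1), 0)
  # 100 random carbons vs direct evaluation of the mass-weighted formula
  set.seed(1)
  xyz <- matrix(rnorm(300), 100, 3) * 10
  m <- rep(12.011, 100)
  cm <- colSums(xyz * m) / sum(m)
  expected <- sqrt(sum(m * rowSums(sweep(xyz, 2, cm)^2)) / sum(m))
  s <- place_atoms(xyz, resid = rep(1:25, each = 4))
  expect_equal(radius_of_gyration(s), expected, tolerance = 1e-12)
  # mixed elements: mass weighting matters and matches the definition
  ele <- rep(c("C", "N", "O", "S"), 25)
  s$element <- ele
  mm <- atomic_mass(ele)
  cmm <- colSums(xyz * mm) / sum(mm)
  expect_equal(radius_of_gyration(s),
               sqrt(sum(mm * rowSums(sweep(xyz, 2, cmm)^2)) / sum(mm)),
               tolerance = 1e-12)
})

test_that("Rg is invariant under rigid motions", {
  set.seed(2)
  xyz <- matrix(rnorm(150), 50, 3) * 5
  s <- place_atoms(xyz, resid = rep(1:10, each = 5))
  rg0 <- radius_of_gyration(s)
  for (k in 1:5) {
    s$xyz <- random_rigid(xyz)
    expect_equal(radius_of_gyration(s), rg0, tolerance = 1e-9)
  }
})

test_that("rmsd_superposed removes rigid motion and matches bio3d", {
  set.seed(3)
  xyz <- matrix(rnorm(60), 20, 3) * 4
  a <- place_atoms(xyz, resid = rep(1:5, each = 4))
  expect_equal(rmsd_superposed(a, a), 0, tolerance = 1e-9)
  b <- a
  b$xyz <- random_rigid(xyz)
  expect_equal(rmsd_superposed(a, b), 0, tolerance = 1e-7)
  # symmetric, and equal to the bio3d fitted-RMSD oracle on deformed pairs
  for (k in 1:5) {
    b$xyz <- random_rigid(xyz + matrix(rnorm(60, 0, 0.8), 20, 3))
    r_ab <- rmsd_superposed(a, b)
    r_ba <- rmsd_superposed(b, a)
    expect_equal(r_ab, r_ba, tolerance = 1e-9)
    oracle <- bio3d::rmsd(as.vector(t(a$xyz)), as.vector(t(b$xyz)),
                          fit = TRUE)
    expect_equal(r_ab, oracle, tolerance = 1e-3)
  }
  expect_error(rmsd_superposed(a, place_atoms(xyz[1:5, ], resid = 1:5)),
               "atom count")
})

test_that("curve files round-trip at full precision and honour the dialect", {
  c3 <- saxs_curve(c(0.01, 0.02, 0.03), c(10, 9, 8), sigma = c(1, 1, 1))
  f <- withr::local_tempfile(fileext = ".dat")
  write_curve(c3, f, header = "synthetic test curve")
  back <- read_curve(f)
  expect_equal(back$q, c3$q)
  expect_equal(back$I, c3$I)
  expect_equal(back$sigma, c3$sigma)
  # comment lines are skipped
  expect_true(any(startsWith(readLines(f), "#")))
  # 100-point round trip to 1e-12 relative
  set.seed(4)
  q <- default_qgrid()
  I <- exp(-q^2 * 900 / 3) * 1e5 * (1 + rnorm(100, 0, 0.01))
  cv <- saxs_curve(q, I, sigma = abs(I) * 0.01)
  write_curve(cv, f)
  rt <- read_curve(f)
  expect_equal(rt$I, cv$I, tolerance = 1e-12)
  expect_equal(rt$sigma, cv$sigma, tolerance = 1e-12)
})

test_that("curve validation rejects malformed input", {
  expect_error(saxs_curve(c(0.2, 0.1), c(1, 2)), "strictly increasing")
  expect_error(saxs_curve(c(0.1, 0.2), c(1, 2), sigma = c(1, 0)),
               "sigma")
  f <- withr::local_tempfile(lines = c("0.1 1.0 0.1", "0.05 2.0 0.1"))
  expect_error(read_curve(f), "strictly increasing")
})

test_that("multi-model PDB round-trips a conformation set", {
  toy <- toy_multidomain(2, atoms_per_domain = 10, linker_length = 3,
                         seed = 5)
  cs <- conformer_family(toy, 4, mode = "hinge", seed = 6)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(cs, f)
  dmap <- list(D1 = range(toy$resid[toy$domain == "D1"]),
               D2 = range(toy$resid[toy$domain == "D2"]))
  back <- read_models(f, dmap)
  expect_equal(length(back), 4)
  expect_equal(n_atoms(back$template), n_atoms(toy))
  for (k in 1:4) # PDB stores 3 decimals
    expect_equal(back$frames[[k]], cs$frames[[k]], tolerance = 1e-3)
})
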