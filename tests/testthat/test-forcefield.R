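test_that("shadow rules: distance, sequence separation, occlusion", {
  p <- ff_params()
  # pair at 5.0 A, residue separation 5, nothing in between -> contact
  s <- place_atoms(rbind(c(0, 0, 0), c(5, 0, 0)), resid = c(1, 6))
  expect_equal(nrow(shadow_contacts(s, p)), 1)
  # same geometry, residue separation 3 -> rejected
  s3 <- place_atoms(rbind(c(0, 0, 0), c(5, 0, 0)), resid = c(1, 4))
  expect_equal(nrow(shadow_contacts(s3, p)), 0)
  # collinear blocker on the segment -> rejected
  sb <- place_atoms(rbind(c(0, 0, 0), c(5, 0, 0), c(2.5, 0, 0)),
                    resid = c(1, 6, 12))
  cm <- shadow_contacts(sb, p)
  expect_false(any(cm[, "i"] == 1 & cm[, "j"] == 2))
  # blocker just outside the shadow radius does not screen
  so <- place_atoms(rbind(c(0, 0, 0), c(5, 0, 0), c(2.5, 1.05, 0)),
                    resid = c(1, 6, 12))
  cmo <- shadow_contacts(so, p)
  expect_true(any(cmo[, "i"] == 1 & cmo[, "j"] == 2))
  # pairs on different chains qualify regardless of residue numbering
  sc <- place_atoms(rbind(c(0, 0, 0), c(5, 0, 0)), resid = c(1, 2),
                    chain = c("A", "B"))
  expect_equal(nrow(shadow_contacts(sc, p)), 1)
})

test_that("shadow map equals the literal brute-force oracle", {
  set.seed(10)
  for (rep in 1:20) {
    xyz <- matrix(rnorm(90), 30, 3) * 3.5
    s <- place_atoms(xyz, resid = sort(sample(1:12, 30, TRUE)))
    got <- shadow_contacts(s)[, 1:2, drop = FALSE]
    want <- brute_shadow(s)
    expect_equal(unname(got[order(got[, 1], got[, 2]), , drop = FALSE]),
                 unname(want[order(want[, 1], want[, 2]), , drop = FALSE]))
  }
})

test_that("shadow map is invariant under atom reordering", {
  set.seed(11)
  xyz <- matrix(rnorm(90), 30, 3) * 3.5
  s <- place_atoms(xyz, resid = sort(sample(1:12, 30, TRUE)))
  cm <- shadow_contacts(s)
  key <- function(m) sort(paste(pmin(m[, 1], m[, 2]),
                                pmax(m[, 1], m[, 2])))
  perm <- sample(30)
  sp <- s # bypass the sortedness check: permuted labelling on purpose
  sp$xyz <- xyz[perm, , drop = FALSE]
  sp$resid <- s$resid[perm]
  cmp <- shadow_contacts(sp)
  # map permuted indices back to the original labelling
  back <- cbind(perm[cmp[, 1]], perm[cmp[, 2]])
  expect_equal(key(back), key(cm[, 1:2, drop = FALSE]))
})

test_that("build_topology removes every inter-label contact", {
  toy <- toy_multidomain(2, atoms_per_domain = 25, linker_length = 5,
                         seed = 12)
  p <- ff_params()
  full <- shadow_contacts(toy, p)
  topo <- build_topology(toy, p)
  lab <- toy$domain
  inter <- lab[full[, 1]] != lab[full[, 2]]
  expect_equal(nrow(topo$contacts), sum(!inter))
  expect_true(all(lab[topo$contacts[, 1]] == lab[topo$contacts[, 2]]))
  # single-domain structure: nothing removed
  one <- toy_multidomain(1, atoms_per_domain = 25, seed = 13)
  topo1 <- build_topology(one, p)
  expect_equal(nrow(topo1$contacts), nrow(shadow_contacts(one, p)))
})

test_that("bonded terms of a linear chain match hand enumeration", {
  # 5 atoms in a bent chain, 1.5 A spacing: 4 bonds, 3 angles,
  # 2 proper dihedrals (one per interior bond), no impropers
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.3, 1.3, 0),
               c(3.8, 1.4, 0.3), c(4.4, 2.6, 1.0))
  s <- place_atoms(xyz, resid = 1:5)
  topo <- build_topology(s)
  expect_equal(nrow(topo$bonds), 4)
  expect_equal(nrow(topo$angles), 3)
  expect_equal(nrow(topo$dihedrals), 2)
  expect_equal(nrow(topo$impropers), 0)
  # native reference values equal the geometry they were read from
  d12 <- sqrt(sum((xyz[1, ] - xyz[2, ])^2))
  expect_equal(unname(topo$bonds[topo$bonds[, 1] == 1, "r0"]), d12)
})

test_that("energy-weight normalization follows the 2:1 convention", {
  # 100 atoms, 30 contacts, 40 weighted dihedrals
  topo <- make_topo(100)
  topo$dihedrals <- matrix(rep(c(1, 2, 3, 4, 0, 1, 0), 40), ncol = 7,
                           byrow = TRUE,
                           dimnames = list(NULL, c("i", "j", "k", "l",
                                                   "phi0", "weight",
                                                   "rigid")))
  topo$contacts <- matrix(rep(c(1, 50, 5, 1), 30), ncol = 4, byrow = TRUE,
                          dimnames = list(NULL, c("i", "j", "r0", "eps")))
  topo <- assign_energy_weights(topo)
  expect_equal(sum(topo$contacts[, "eps"]), 200 / 3, tolerance = 1e-12)
  expect_equal(sum(topo$dihedrals[, "weight"]), 100 / 3,
               tolerance = 1e-12)
  expect_equal(length(unique(topo$contacts[, "eps"])), 1)
  # doubling the atom count doubles every weight
  topo2 <- topo
  topo2$n_atoms <- 200
  topo2 <- assign_energy_weights(topo2)
  expect_equal(topo2$contacts[, "eps"], 2 * topo$contacts[, "eps"])
  # no contacts: the whole budget goes to dihedrals
  topo0 <- topo
  topo0$contacts <- topo0$contacts[0, , drop = FALSE]
  topo0 <- assign_energy_weights(topo0)
  expect_equal(sum(topo0$dihedrals[, "weight"]), 100, tolerance = 1e-12)
})

test_that("linker-spanning non-rigid dihedrals carry zero weight", {
  toy <- toy_multidomain(2, atoms_per_domain = 20, linker_length = 6,
                         seed = 14)
  topo <- build_topology(toy)
  dih <- topo$dihedrals
  lab <- toy$domain
  for (r in seq_len(nrow(dih))) {
    labs <- lab[dih[r, 1:4]]
    if (dih[r, "rigid"] == 0 && length(unique(labs)) > 1)
      expect_equal(unname(dih[r, "weight"]), 0)
  }
  # and there are free linker dihedrals to begin with
  expect_true(any(dih[, "weight"] == 0))
  expect_true(any(dih[, "weight"] > 0))
})

test_that("topology serialization round-trips", {
  toy <- toy_multidomain(2, atoms_per_domain = 15, linker_length = 4,
                         seed = 15)
  topo <- build_topology(toy)
  f <- withr::local_tempfile(fileext = ".top")
  write_topology(topo, f)
  back <- read_topology(f)
  expect_equal(back$n_atoms, topo$n_atoms)
  expect_equal(back$element, topo$element)
  expect_equal(back$domain, topo$domain)
  for (part in c("bonds", "angles", "impropers", "dihedrals", "contacts",
                 "exclusions"))
    expect_equal(unname(back[[part]]), unname(topo[[part]]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unclass(back$params), unclass(topo$params))
})

test_that("a user-supplied contact list overrides the shadow map", {
  toy <- toy_multidomain(1, atoms_per_domain = 20, seed = 16)
  cl <- rbind(c(1, 10), c(2, 15))
  topo <- build_topology(toy, contacts = cl)
  expect_equal(nrow(topo$contacts), 2)
  d <- sqrt(sum((toy$xyz[1, ] - toy$xyz[10, ])^2))
  expect_equal(unname(topo$contacts[1, "r0"]), d)
})
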