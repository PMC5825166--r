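two_domain_fixture <- function(seed = 31) {
  mm <- make_multidomain(synthetic_spec(seed = seed))
  mm
}

test_that("amputation keeps exactly the common domain, coordinates untouched", {
  mm <- two_domain_fixture()
  ad <- amputate(mm$md, mm$common)
  expect_equal(n_residues(ad), 60)
  expect_equal(ca_coords(ad), ca_coords(mm$md)[1:60, ],
               ignore_attr = "resindex")

  # amputated construct maps to the isolated member at identity level
  m <- map_common_domain(ad, mm$id)
  expect_equal(m$identity, 1.0)

  # amputating with the whole structure as the domain is the identity
  s <- make_domain(30, "coil", seed = 1)
  whole <- domain_def("w", data.frame(chain = "A", start = 1, end = 30))
  expect_equal(ca_coords(amputate(s, whole)), ca_coords(s),
               ignore_attr = "resindex")
})

test_that("amputated and isolated members have identical fluctuation profiles
           when their conformations are identical", {
  mm <- make_multidomain(synthetic_spec(noise_sd = 0, seed = 33))
  ad <- amputate(mm$md, mm$common)
  run <- function(s) {
    m <- build_anm(ca_coords(s))
    square_fluctuations(m, select_modes_80(m))
  }
  expect_equal(run(ad), run(mm$id), tolerance = 1e-8)
})

test_that("domain swap is idempotent for identical conformations and grafts rigidly", {
  mm <- make_multidomain(synthetic_spec(noise_sd = 0, seed = 35))
  md_common <- extract_domain(mm$md, mm$common)
  m <- map_common_domain(md_common, mm$id)

  # noiseless generator: ID == MD common domain, swap reproduces MD
  sw <- swap_common_domain(mm$md, mm$id, m, mm$common)
  expect_equal(n_residues(sw), n_residues(mm$md))
  expect_equal(ca_coords(sw), ca_coords(mm$md), tolerance = 1e-8,
               ignore_attr = "resindex")

  # with noise, the grafted domain is a rigid copy of the ID (RMSD 0)
  mm2 <- two_domain_fixture(36)
  m2 <- map_common_domain(extract_domain(mm2$md, mm2$common), mm2$id)
  sw2 <- swap_common_domain(mm2$md, mm2$id, m2, mm2$common)
  grafted <- extract_domain(sw2, mm2$common)
  sup <- kabsch_superpose(ca_coords(grafted), ca_coords(mm2$id))
  expect_equal(sup$rmsd, 0, tolerance = 1e-8)

  # swap then amputation of the grafted part returns the transformed ID
  back <- amputate(sw2, mm2$common)
  expect_equal(structure_sequence(back), structure_sequence(mm2$id))
})

test_that("self-graft chimera needs no trimming and is deterministic", {
  s <- make_domain(40, "coil", seed = 40)
  dom <- domain_def("self", data.frame(chain = "A", start = 1, end = 40))
  mp <- map_common_domain(s, s, mode = "homolog")
  ch <- build_chimera(s, s, list(domain = dom, mapping = mp))
  expect_equal(sum(ch$record$junction_trims), 0)
  expect_equal(n_residues(ch$structure), 40)
  expect_equal(ca_coords(ch$structure), ca_coords(s), tolerance = 1e-8,
               ignore_attr = "resindex")

  ch2 <- build_chimera(s, s, list(domain = dom, mapping = mp))
  expect_identical(ch$structure$atoms, ch2$structure$atoms)
  expect_identical(ch$record$junction_trims, ch2$record$junction_trims)
})

test_that("an engineered junction clash is relieved by trimming", {
  mm <- two_domain_fixture(44)
  dom <- mm$common
  md_common <- extract_domain(mm$md, dom)
  mp <- map_common_domain(md_common, md_common, mode = "homolog")
  # graft the common domain back into its own scaffold: geometry identical,
  # so the junction clash is fully controlled by where we plant an atom
  single <- md_common
  # plant a clashing pseudo-atom on the tether side right at the junction:
  # 1.0 A from the grafted domain's last CA
  junction_ca <- ca_coords(md_common)[60, ]
  clash_atom <- data.frame(chain = "A", resno = 61, ins = "",
                           resname = "GLY", atom = "CA", element = "C",
                           x = junction_ca[1] + 1.0, y = junction_ca[2],
                           z = junction_ca[3], occ = 1)
  multi_at <- rbind(md_common$atoms[, names(clash_atom)], clash_atom,
                    mm$md$atoms[mm$md$atoms$resindex > 61,
                                names(clash_atom)])
  multi <- protstruct(multi_at, id = "clashy")
  mp2 <- map_common_domain(single, extract_domain(multi, dom),
                           mode = "homolog")
  ch <- build_chimera(single, multi, list(domain = dom, mapping = mp2))
  expect_gte(sum(ch$record$junction_trims), 1)
  # all inter-parent contacts now clear the clash threshold
  prov <- ch$record$provenance
  own <- ch$structure$atoms$resindex %in% prov$resno[prov$parent == single$id]
  xi <- as.matrix(ch$structure$atoms[own, c("x", "y", "z")])
  xj <- as.matrix(ch$structure$atoms[!own, c("x", "y", "z")])
  d2 <- outer(rowSums(xi^2), rowSums(xj^2), "+") - 2 * xi %*% t(xj)
  expect_gte(sqrt(min(d2)), 2.0)
})

test_that("double graft into duplicated domains records trims per junction", {
  # a scaffold with two copies of the same fold, hexokinase-style
  s <- make_domain(30, "coil", seed = 46)
  x <- ca_coords(s)
  shifted <- sweep(x, 2, c(max(x[, 1]) - min(x[, 1]) + 12, 0, 0), "+")
  nm <- s$residues$resname
  multi <- protstruct(data.frame(
    chain = "A", resno = 1:60, ins = "", resname = c(nm, nm), atom = "CA",
    element = "C", x = c(x[, 1], shifted[, 1]), y = c(x[, 2], shifted[, 2]),
    z = c(x[, 3], shifted[, 3]), occ = 1), id = "repeat2")
  d1 <- domain_def("rep1", data.frame(chain = "A", start = 1, end = 30))
  d2 <- domain_def("rep2", data.frame(chain = "A", start = 31, end = 60))
  mp1 <- map_common_domain(s, extract_domain(multi, d1), mode = "homolog")
  mp2 <- map_common_domain(s, extract_domain(multi, d2), mode = "homolog")
  ch <- build_chimera(s, multi, list(
    list(domain = d1, mapping = mp1), list(domain = d2, mapping = mp2)))
  expect_equal(n_residues(ch$structure), 60)
  # both halves of the chimera are the single-domain parent
  expect_true(all(ch$record$provenance$parent == s$id))
  expect_equal(structure_sequence(ch$structure), rep(structure_sequence(s), 2))
})
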