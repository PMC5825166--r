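test_that("contact list excludes bonded neighbours and is inclusive at 5 A", {
  # extended chain, CA spacing 3.8 A: all |i-j| >= 2 distances exceed 5 A
  ext <- protstruct(data.frame(
    chain = "A", resno = 1:10, ins = "", resname = "GLY", atom = "CA",
    element = "C", x = 3.8 * (0:9), y = 0, z = 0, occ = 1))
  expect_equal(nrow(contact_list(ext)), 0)

  # pair at exactly 5.0 A with sequence separation 2: contact (inclusive)
  tri <- protstruct(data.frame(
    chain = "A", resno = 1:3, ins = "", resname = "ALA", atom = "CA",
    element = "C", x = c(0, 3.8, 5), y = c(0, 2, 0), z = 0, occ = 1))
  cl <- contact_list(tri)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$i, 1); expect_equal(cl$j, 3)
  expect_equal(cl$dist, 5.0)

  # empty structure
  empty <- protstruct(data.frame(chain = character(0), resno = integer(0),
                                 ins = character(0), resname = character(0),
                                 atom = character(0), element = character(0),
                                 x = numeric(0), y = numeric(0),
                                 z = numeric(0), occ = numeric(0)))
  expect_equal(nrow(contact_list(empty)), 0)
})

test_that("frustration index is the stated decoy Z-score", {
  set.seed(1)
  decoys <- rnorm(200)
  decoys <- (decoys - mean(decoys)) / sd(decoys)   # mean 0, sd 1 exactly
  expect_equal(frustration_index(-2, decoys), 2, tolerance = 1e-12)
  expect_equal(frustration_index(0, decoys), 0, tolerance = 1e-12)
  expect_equal(frustration_index(1.5, decoys), -1.5, tolerance = 1e-12)
  expect_error(frustration_index(1, rep(3, 10)), "undefined-index")
  expect_error(frustration_index(1, 2), "undefined-index")
})

test_that("classification boundaries are strict as stated", {
  expect_equal(classify_frustration(0.9), "minimal")
  expect_equal(classify_frustration(0.78), "neutral")
  expect_equal(classify_frustration(-1.0), "neutral")
  expect_equal(classify_frustration(-1.2), "high")
  expect_equal(classify_frustration(c(2, 0, -3)),
               c("minimal", "neutral", "high"))
})

test_that("mutational decoys enumerate all 400 pairs and are seed-stable", {
  pot <- contact_potential()
  co <- list(aa_i = "A", aa_j = "L", dist = 4.5)
  d <- decoys_mutational(co, pot)
  expect_length(d, 400)
  # the native pair's energy appears exactly as often as the table
  # predicts (ordered enumeration: a symmetric table yields the unordered
  # native pair twice, a homo-pair once)
  e_nat <- pot["A", "L"] * (4 / 4.5)^2
  expect_equal(sum(abs(d - e_nat) < 1e-12),
               sum(abs(pot - pot["A", "L"]) < 1e-12))
  dww <- decoys_mutational(list(aa_i = "W", aa_j = "W", dist = 4.5), pot)
  expect_equal(sum(abs(dww - pot["W", "W"] * (4 / 4.5)^2) < 1e-12),
               sum(abs(pot - pot["W", "W"]) < 1e-12))

  # sampling mode is reproducible under the seed
  d1 <- decoys_mutational(co, pot, n = 50, seed = 7)
  d2 <- decoys_mutational(co, pot, n = 50, seed = 7)
  expect_identical(d1, d2)
  expect_length(d1, 50)

  # uniform potential: all decoys equal, index undefined downstream
  flat <- matrix(-1, 20, 20, dimnames = dimnames(pot))
  expect_error(frustration_index(-1, decoys_mutational(co, flat)),
               "undefined-index")
})

test_that("configurational decoys are seeded and track the empirical contexts", {
  s <- make_domain(40, "coil", seed = 50)
  pot <- contact_potential()
  co <- list(aa_i = "A", aa_j = "V")
  d1 <- decoys_configurational(co, s, pot, n = 200, seed = 3)
  d2 <- decoys_configurational(co, s, pot, n = 200, seed = 3)
  expect_identical(d1, d2)

  small <- make_domain(12, "helix", seed = 1)
  few <- extract_domain(small, domain_def("f", data.frame(
    chain = "A", start = 1, end = 9)))
  expect_error(decoys_configurational(co, few, pot, n = 10, seed = 1),
               "resample error")

  # resampled distances follow the empirical contact-distance distribution
  cl <- contact_list(s)
  ctx <- tetherscope:::resample_contexts(s, 1e4, seed = 11)
  emp <- table(factor(cl$dist, levels = sort(unique(cl$dist))))
  obs <- table(factor(ctx$dist, levels = sort(unique(cl$dist))))
  expect_true(all(ctx$dist %in% cl$dist))
  p <- suppressWarnings(stats::chisq.test(
    as.numeric(obs), p = as.numeric(emp) / sum(emp))$p.value)
  expect_gt(p, 0.001)
})

test_that("SRLF matches a hand-computed Z-score on a 3-residue system", {
  # residues 1 and 3 in contact (|i-j| = 2, d = 5); residue 2 off to the
  # side so no other contact forms
  s <- protstruct(data.frame(
    chain = "A", resno = 1:3, ins = "", resname = c("ILE", "GLY", "VAL"),
    atom = "CA", element = "C", x = c(0, 3.8, 5), y = c(0, 20, 0), z = 0,
    occ = 1))
  pot <- contact_potential()
  w <- (4 / 5)^2
  e_all <- pot[, "V"] * w          # residue 1 mutated through all 20
  e_nat <- unname(e_all["I"])
  e_dec <- unname(e_all[setdiff(rownames(pot), "I")])
  expected <- (mean(e_dec) - e_nat) / sd(e_dec)
  expect_equal(srlf(1, s, pot), expected, tolerance = 1e-12)

  # isolated residue: undefined
  expect_error(srlf(2, s, pot), "no contacts")
})

test_that("indices are invariant to potential scaling and decoy order", {
  s <- make_domain(30, "coil", seed = 52)
  pot <- contact_potential()
  r <- which(tabulate(c(contact_list(s)$i, contact_list(s)$j), 30) > 0)[1]
  expect_equal(srlf(r, s, pot), srlf(r, s, 5 * pot), tolerance = 1e-10)

  co <- list(aa_i = "F", aa_j = "K", dist = 4.2)
  d <- decoys_mutational(co, pot)
  e_nat <- pot["F", "K"] * (4 / 4.2)^2
  expect_equal(frustration_index(e_nat, d),
               frustration_index(e_nat, rev(d)), tolerance = 1e-12)
})

test_that("profile classes partition all items and self-pairs never change class", {
  s <- make_domain(35, "coil", seed = 54)
  fp <- frustration_profile(s, n_decoys = 200, seed = 9)
  expect_equal(nrow(fp$residues), 35)
  expect_true(all(fp$residues$class %in%
                    c("minimal", "neutral", "high", "undefined")))
  expect_true(all(fp$contacts$mfi_class %in%
                    c("minimal", "neutral", "high", "undefined")))
  expect_true(all(fp$contacts$cfi_class %in%
                    c("minimal", "neutral", "high", "undefined")))

  # identical coordinates and potential: zero class changes
  fp2 <- frustration_profile(s, n_decoys = 200, seed = 9)
  expect_identical(fp$residues$class, fp2$residues$class)
  expect_identical(fp$contacts$cfi, fp2$contacts$cfi)
})
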