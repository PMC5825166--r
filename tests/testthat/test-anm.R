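test_that("dimer ANM has one non-zero mode of stiffness 2*gamma(d)", {
  dimer <- rbind(c(0, 0, 0), c(10, 0, 0))
  md <- build_anm(dimer, cutoff = 15)
  nz <- setdiff(seq_along(md$values), md$zero_modes)
  expect_length(nz, 1)
  expect_equal(md$values[nz], 2 * (1 / 10^2), tolerance = 1e-10)
  # the stretch eigenvector lies along the bond (x) axis
  v <- md$vectors[, nz]
  expect_equal(abs(v[c(2, 3, 5, 6)]), rep(0, 4), tolerance = 1e-8)
  expect_equal(abs(v[1]), abs(v[4]), tolerance = 1e-8)

  # every Hessian superblock row sums to zero (translation invariance)
  xyz <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 12, 0))
  m <- suppressWarnings(build_anm(xyz, cutoff = 15))
  n <- nrow(xyz)
  for (i in seq_len(n)) {
    rows <- (3 * i - 2):(3 * i)
    blocksum <- matrix(0, 3, 3)
    for (j in seq_len(n))
      blocksum <- blocksum + m$hessian[rows, (3 * j - 2):(3 * j)]
    expect_equal(blocksum, matrix(0, 3, 3), tolerance = 1e-12)
  }
})

test_that("4-bead systems have the zero-mode counts the ENM energy dictates", {
  # non-planar tetrahedron: the generic 6 rigid-body zero modes
  tet <- rbind(c(0, 0, 0), c(8, 0, 0), c(4, 7, 0), c(4, 3.5, 6.5))
  m <- build_anm(tet, cutoff = 15)
  expect_length(m$zero_modes, 6)
  expect_true(all(m$values[-m$zero_modes] > 0))
  expect_equal(m$hessian, oracle_numeric_hessian(tet, cutoff = 15),
               tolerance = 1e-5)

  # a flat square adds one zero mode per out-of-plane degree of freedom
  # beyond the rigid set (pairwise-distance energies have no first-order
  # transverse stiffness): 4 + 3 = 7, confirmed by the numeric oracle
  sq <- rbind(c(0, 0, 0), c(8, 0, 0), c(8, 8, 0), c(0, 8, 0))
  ms <- suppressWarnings(build_anm(sq, cutoff = 15))
  expect_length(ms$zero_modes, 7)
  Hnum <- oracle_numeric_hessian(sq, cutoff = 15)
  expect_equal(ms$hessian, Hnum, tolerance = 1e-5)
})

test_that("ANM Hessian matches numeric second derivatives of the ENM energy", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(5:10, 1)
    xyz <- matrix(rnorm(3 * n, sd = 6), ncol = 3)
    m <- suppressWarnings(build_anm(xyz, cutoff = 15))
    Hnum <- oracle_numeric_hessian(xyz, cutoff = 15)
    expect_equal(m$hessian, Hnum, tolerance = 1e-5)
  }
})

test_that("degenerate geometries are rejected", {
  expect_error(build_anm(matrix(0, 1, 3)), "degeneracy")
  expect_error(build_anm(cbind(1:5, 0, 0)), "degeneracy")
  expect_warning(build_anm(rbind(c(0, 0, 0), c(4, 0, 0), c(3, 3, 0),
                                 c(100, 0, 0), c(104, 0, 0),
                                 c(103, 3, 0))), "disconnected")
})

test_that("80%-variance mode selection follows 1/lambda fractions", {
  fake <- structure(list(values = c(0, 0, 0, 0, 0, 0, 1, 1, 8),
                         zero_modes = 1:6), class = "anm")
  # fractions {0.4706, 0.4706, 0.0588}: first two modes selected
  expect_equal(select_modes_80(fake), c(7L, 8L))

  # a dominant first mode alone reaches 80%
  fake2 <- structure(list(values = c(rep(0, 6), 1, 100, 100),
                          zero_modes = 1:6), class = "anm")
  expect_equal(select_modes_80(fake2), 7L)

  # single non-zero mode: that mode alone
  fake3 <- structure(list(values = c(rep(0, 6), 3), zero_modes = 1:6),
                     class = "anm")
  expect_equal(select_modes_80(fake3), 7L)
})

test_that("fluctuations are non-negative, symmetric for the dimer, equal on a ring", {
  dimer <- build_anm(rbind(c(0, 0, 0), c(10, 0, 0)), cutoff = 15)
  stretch <- setdiff(seq_along(dimer$values), dimer$zero_modes)
  fl <- square_fluctuations(dimer, stretch)
  expect_true(all(fl >= 0))
  expect_equal(fl[1], fl[2], tolerance = 1e-10)  # dimer symmetry

  # uniform ring of beads: symmetry forces equal fluctuations
  t8 <- 2 * pi * (0:7) / 8
  ring <- cbind(10 * cos(t8), 10 * sin(t8), 0)
  mr <- suppressWarnings(build_anm(ring, cutoff = 15))
  flr <- square_fluctuations(mr, setdiff(seq_along(mr$values),
                                         mr$zero_modes))
  expect_equal(max(flr) - min(flr), 0, tolerance = 1e-8 * max(flr))
})

test_that("fluctuation trimming drops 5+5 residues and z-scores the rest", {
  f <- rexp(20)
  nf <- normalize_fluctuations(f, trim = 5)
  expect_length(nf$normalized, 10)
  expect_equal(nf$kept, 6:15)
  expect_equal(mean(nf$normalized), 0, tolerance = 1e-12)
  expect_equal(sd(nf$normalized), 1, tolerance = 1e-12)

  expect_warning(z <- normalize_fluctuations(rep(2, 20))$normalized,
                 "constant")
  expect_equal(z, rep(0, 10))
  expect_error(normalize_fluctuations(rexp(10), trim = 5), "trim error")
})

test_that("cross-correlation has unit diagonal, [-1,1] range, dimer anti-correlation", {
  s <- make_domain(30, "coil", seed = 21)
  m <- build_anm(ca_coords(s))
  C <- cross_correlation(m)
  expect_equal(diag(C), rep(1, 30))
  expect_true(all(C >= -1 & C <= 1))
  expect_equal(C, t(C))

  # dimer stretch mode: perfectly anti-correlated beads
  md <- build_anm(rbind(c(0, 0, 0), c(10, 0, 0)), cutoff = 15)
  stretch <- setdiff(seq_along(md$values), md$zero_modes)
  Cd <- cross_correlation(md, modes = stretch)
  expect_equal(Cd[1, 2], -1, tolerance = 1e-8)
})

test_that("dynamics are invariant under rigid motion of the input", {
  s <- make_domain(25, "coil", seed = 22)
  x <- ca_coords(s)
  ang <- 0.9
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
             c(0, 0, 1))
  xr <- sweep(x %*% R, 2, c(3, -7, 11), "+")
  m1 <- build_anm(x); m2 <- build_anm(xr)
  k1 <- select_modes_80(m1); k2 <- select_modes_80(m2)
  expect_equal(m1$values, m2$values, tolerance = 1e-8)
  expect_equal(square_fluctuations(m1, k1), square_fluctuations(m2, k2),
               tolerance = 1e-6)
  expect_equal(cross_correlation(m1, k1), cross_correlation(m2, k2),
               tolerance = 1e-6)
})

test_that("Rv coefficient definition and invariances", {
  A <- diag(2); B <- matrix(1, 2, 2)
  expect_equal(rv_coefficient(A, B), 2 / sqrt(2 * 4))

  set.seed(3)
  M <- crossprod(matrix(rnorm(25), 5))
  expect_equal(rv_coefficient(M, M), 1)
  expect_equal(rv_coefficient(M, 3.7 * M), 1)
  expect_equal(rv_coefficient(M, B = diag(5)),
               rv_coefficient(diag(5), M))
  expect_error(rv_coefficient(diag(2), diag(3)), "shape")
  expect_error(rv_coefficient(matrix(0, 2, 2), diag(2)), "undefined")
})

test_that("coupling fraction counts |cc| >= 0.7 inclusively", {
  expect_equal(coupling_fraction(diag(4)), 0)
  allc <- matrix(0.7, 3, 3); diag(allc) <- 1
  expect_equal(coupling_fraction(allc), 1)       # inclusive at 0.7
  neg <- matrix(c(1, -1, -1, 1), 2)
  expect_equal(coupling_fraction(neg), 1)        # absolute value
  just_below <- matrix(0.6999, 3, 3); diag(just_below) <- 1
  expect_equal(coupling_fraction(just_below), 0)
})
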