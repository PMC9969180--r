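# Jones/Mueller calculus: constructors, transforms, decomposition, retrieval.

test_that("Jones rotator matches the plane-rotation basis-change oracle", {
  expect_equal(m4(jones_rotator(0)), diag(2) + 0i, tolerance = 1e-14)
  # gamma = pi rotates linear polarization by 180 deg: -identity up to phase
  expect_equal(abs(m4(jones_rotator(pi))), abs(-diag(2)) + 0,
               tolerance = 1e-12)
  expect_equal(Re(m4(jones_rotator(pi))), -diag(2), tolerance = 1e-12)
  # Cartesian form is the plane rotation by gamma
  expect_equal(Re(m4(jones_rotator(0.2))), plane_rotation(0.2),
               tolerance = 1e-12)
  expect_lt(max(abs(Im(m4(jones_rotator(0.2))))), 1e-12)
  expect_error(jones_rotator(Inf), class = "mp_invalid_argument")
})

test_that("circular diattenuator is Hermitian and commutes with the rotator", {
  J <- m4(jones_circular_diattenuator(0.02))
  expect_equal(J, Conj(t(J)), tolerance = 1e-14)
  JR <- m4(jones_rotator(0.3))
  expect_lt(max(abs(JR %*% J - J %*% JR)), 1e-14)
  expect_equal(m4(jones_circular_diattenuator(0)), diag(2) + 0i,
               tolerance = 1e-14)
  expect_error(jones_circular_diattenuator(NaN), class = "mp_invalid_argument")
})

test_that("Jones-to-Mueller transformation reproduces direct evaluations", {
  expect_equal(m4(jones_to_mueller(diag(2) + 0i)), diag(4),
               tolerance = 1e-12)
  # Cartesian half-wave plate diag(1, -1) -> diag(1, 1, -1, -1)
  expect_equal(m4(jones_to_mueller(diag(c(1, -1)) + 0i)),
               diag(c(1, 1, -1, -1)), tolerance = 1e-12)
})

test_that("closed-form Mueller constructors agree with the Jones route", {
  set.seed(42)
  for (i in 1:100) {
    g <- stats::runif(1, -pi, pi)
    expect_equal(m4(jones_to_mueller(jones_rotator(g))),
                 m4(mueller_rotator(g)), tolerance = 1e-12)
    gp <- stats::runif(1, -0.2, 0.2)
    J <- m4(jones_rotator(g)) %*% m4(jones_circular_diattenuator(gp))
    expect_equal(m4(jones_to_mueller(J)),
                 m4(mueller_chiral(chiro_state(g, gp))),
                 tolerance = 1e-10)
  }
})

test_that("Mueller rotator has the documented form and group property", {
  expect_equal(m4(mueller_rotator(0)), diag(4))
  M <- mueller_rotator(pi / 4)
  expect_equal(M[2, 2], 0, tolerance = 1e-15)
  expect_equal(M[3, 3], 0, tolerance = 1e-15)
  expect_equal(M[2, 3], 1)
  expect_equal(M[3, 2], -1)
  # dextrorotatory sign convention at a measured-scale angle
  M <- mueller_rotator(-0.38)
  expect_equal(M[2, 2], cos(-0.76), tolerance = 1e-12)
  expect_equal(M[2, 3], sin(-0.76), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:20) {
    a <- stats::runif(1, -2, 2); b <- stats::runif(1, -2, 2)
    expect_equal(m4(mueller_rotator(a) %*% mueller_rotator(b)),
                 m4(mueller_rotator(a + b)), tolerance = 1e-12)
  }
})

test_that("forward-constructed matrices are passive and non-depolarizing", {
  set.seed(11)
  for (i in 1:25) {
    g <- stats::runif(1, -pi, pi); gp <- stats::runif(1, -0.3, 0.3)
    M <- mueller_chiral(chiro_state(g, gp))
    expect_lte(max(abs(M)), 1 + 1e-12)
    expect_lt(abs(muellerpol:::gil_bernabeu_deviation(m4(M))), 1e-6)
    if (abs(gp) < 1e-12) {
      expect_equal(det(m4(M)), 1, tolerance = 1e-12)
    }
  }
})

test_that("chiral matrix reduces to the rotator and has first-order CD entries", {
  g <- 0.7
  expect_equal(m4(mueller_chiral(chiro_state(g, 0))),
               m4(mueller_rotator(g)), tolerance = 1e-15)
  M <- mueller_chiral(chiro_state(0, 0.01))
  expect_lt(abs(M[1, 4] - 0.01), 1e-6)
  expect_lt(abs(M[4, 1] - 0.01), 1e-6)
})

test_that("differential decomposition isolates CB for rotators", {
  d0 <- differential_decompose(diag(4))
  expect_equal(max(abs(d0$log_matrix)), 0, tolerance = 1e-12)
  g <- 10 * pi / 180
  d <- differential_decompose(m4(mueller_rotator(g)))
  expect_equal(unname(d$measures["CB"]), 2 * g, tolerance = 1e-10)
  others <- d$measures[setdiff(names(d$measures), "CB")]
  expect_lt(max(abs(others)), 1e-10)
  # CD measure proportional to gamma_prime for the chiral matrix
  dm <- differential_decompose(m4(mueller_chiral(chiro_state(0.3, 0.02))))
  expect_equal(unname(dm$measures["CB"]), 0.6, tolerance = 1e-8)
  expect_equal(unname(dm$measures["CD"]), 0.02, tolerance = 1e-8)
})

test_that("decomposition flags the pi-branch and rejects bad input", {
  expect_error(differential_decompose(m4(mueller_rotator(pi / 2))),
               class = "mp_branch_ambiguity")
  expect_error(differential_decompose(2 * diag(4)),
               class = "mp_invalid_argument")
})

test_that("cuvette stress appears in the linear-birefringence log positions", {
  # forward-simulate an LB-CB product and decompose it
  M <- m4(mueller_linear_retarder(0.025, 0)) %*%
    m4(mueller_rotator(0.2)) %*%
    m4(mueller_linear_retarder(0.025, 0))
  d <- differential_decompose(M, tol = 1e-3)
  L <- d$log_matrix
  expect_gt(abs(L[3, 4]), 1e-3)   # m34 / m43: LB on the 0/90 axes
  expect_gt(abs(L[4, 3]), 1e-3)
  # the sandwich is only approximately commuting at this rotation size
  expect_equal(unname(d$measures["LB"]), 0.05, tolerance = 0.02)
  expect_equal(unname(d$measures["CB"]), 0.4, tolerance = 0.02)
  expect_lt(abs(L[1, 2]), 1e-8)   # no dichroism anywhere
  expect_lt(abs(L[1, 4]), 1e-8)
})

test_that("extract_state inverts the rotator on the principal branch", {
  for (g in seq(-1.5, 1.5, by = 0.25)) {
    expect_equal(extract_state(m4(mueller_rotator(g)))$gamma, g,
                 tolerance = 1e-12)
  }
  # pi-periodicity: only the principal value is recoverable from one matrix
  s <- extract_state(m4(mueller_rotator(0.3 + pi)))
  expect_equal(s$gamma, 0.3, tolerance = 1e-12)
  expect_identical(s$branch_index, 0L)
  # CD retrieval
  sc <- extract_state(m4(mueller_chiral(chiro_state(0.4, 0.015))))
  expect_equal(sc$gamma_prime, 0.015, tolerance = 1e-10)
  expect_error(extract_state(diag(c(1, 0, 0, 1))),
               class = "mp_degenerate_input")
})

test_that("retardation retrieval under element noise stays below the floor", {
  set.seed(123)
  truth <- 0.3
  M0 <- m4(mueller_rotator(truth))
  err <- replicate(1000, {
    M <- M0 + matrix(stats::rnorm(16, 0, 0.001), 4, 4)
    M[1, 1] <- 1
    abs(extract_state(M)$gamma - truth)
  })
  expect_lt(mean(err), 0.001)
})
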