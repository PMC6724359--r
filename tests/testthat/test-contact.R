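test_that("single- and double-layer bending stiffness match closed forms", {
  one <- laminate_stack(data.frame(name = "a", thickness = 2e-4,
                                   modulus = 1e6))
  expect_equal(effective_bending_stiffness(one), 1e6 * (2e-4)^3 / 12,
               tolerance = 1e-12)
  two <- laminate_stack(data.frame(name = c("a", "b"),
                                   thickness = c(2e-4, 2e-4),
                                   modulus = c(1e6, 1e6)))
  expect_equal(effective_bending_stiffness(two), 1e6 * (4e-4)^3 / 12,
               tolerance = 1e-12)
  expect_error(laminate_stack(data.frame(name = "a", thickness = 0,
                                         modulus = 1e6)), "thickness")
})

test_that("composite stiffness matches brute-force neutral-axis integration", {
  # independent oracle: neutral axis from the modulus-weighted first moment,
  # then direct piecewise integration of E(z) (z - z_na)^2 dz, i.e.
  # E [(top - z_na)^3 - (bot - z_na)^3] / 3 per layer — a different algebraic
  # route than the parallel-axis decomposition in the implementation
  brute_EI <- function(stack) {
    t <- stack$layers$thickness; E <- stack$layers$modulus
    top <- cumsum(t); bot <- top - t
    z_na <- sum(E * (top^2 - bot^2) / 2) / sum(E * t)
    sum(E * ((top - z_na)^3 - (bot - z_na)^3) / 3)
  }
  st <- default_stack(e_elastomer = 32.23e3)
  expect_equal(effective_bending_stiffness(st), brute_EI(st),
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:5) {
    st <- laminate_stack(data.frame(
      name = paste0("l", 1:4),
      thickness = runif(4, 1e-7, 5e-4),
      modulus = 10^runif(4, 4, 11)))
    expect_equal(effective_bending_stiffness(st), brute_EI(st),
                 tolerance = 1e-12)
  }
})

test_that("sag amplitude obeys its limits and midpoint identity", {
  skin <- skin_model(E_skin = 130e3, lambda_rough = 140e-6, h_rough = 50e-6)
  expect_identical(sag_amplitude(0, skin), skin$h_rough)
  expect_identical(sag_amplitude(1e6, skin_model(h_rough = 0)), 0)
  expect_lt(sag_amplitude(1e3, skin), 1e-9)
  # EI chosen so the two stiffness terms balance -> h = h_rough / 2
  EI_star <- skin$E_skin * skin$lambda_rough^3 / (16 * pi^3)
  expect_equal(sag_amplitude(EI_star, skin), skin$h_rough / 2,
               tolerance = 1e-12)
  # monotone decreasing in EI, bounded by [0, h_rough]
  h <- vapply(10^seq(-12, -2, length.out = 30), sag_amplitude, 0, skin = skin)
  expect_true(all(diff(h) < 0))
  expect_true(all(h >= 0 & h <= skin$h_rough))
})

test_that("sag amplitude minimizes the bending-plus-skin energy", {
  # independent oracle: numerical minimization of the energy functional
  skin <- skin_model()
  for (EI in c(1e-9, 1e-7, 1e-5)) {
    u <- function(h) pi^4 * EI * h^2 / skin$lambda_rough^4 +
      pi * skin$E_skin * (skin$h_rough - h)^2 / (16 * skin$lambda_rough)
    opt <- optimize(u, c(0, skin$h_rough), tol = 1e-16)
    expect_equal(sag_amplitude(EI, skin), opt$minimum, tolerance = 1e-6)
  }
})

test_that("critical adhesion vanishes on smooth skin and scales with alpha", {
  st <- default_stack()
  smooth <- skin_model(h_rough = 0)
  expect_identical(critical_adhesion(st, smooth)$gamma_crit, 0)

  skin <- skin_model()
  st0 <- default_stack(alpha = 0)
  st5 <- default_stack(alpha = 0.5)
  g0 <- critical_adhesion(st0, skin)$gamma_crit
  g5 <- critical_adhesion(st5, skin)$gamma_crit
  expect_equal(g5 / g0, 2, tolerance = 1e-12)

  # independent re-derivation of the full expression
  EI <- effective_bending_stiffness(st0)
  lam <- skin$lambda_rough
  h <- skin$E_skin * skin$h_rough / (16 * pi^3 * EI / lam^3 + skin$E_skin)
  ref <- pi^4 * EI * h^2 / lam^4 +
    pi * skin$E_skin * (skin$h_rough - h)^2 / (16 * lam) *
      (1 + pi^2 * h^2 / (4 * lam^2))
  expect_equal(g0, ref, tolerance = 1e-12)
  expect_error(laminate_stack(default_stack()$layers, alpha = 1), "alpha")
})

test_that("gamma_crit is non-decreasing in roughness amplitude", {
  st <- default_stack()
  g <- vapply(seq(0, 100e-6, length.out = 20), function(hr)
    critical_adhesion(st, skin_model(h_rough = hr))$gamma_crit, 0)
  expect_true(all(diff(g) >= 0))
})

test_that("elastomer candidates rank by margin; boundary case is strict", {
  skin <- skin_model()
  # the five candidate moduli, softest to stiffest, with adhesion values
  # increasing with softness (tackier gels adhere more)
  cand <- data.frame(
    name = c("PDMS", "Solaris", "Ecoflex0030", "Ecoflex1:1", "Ecoflex1:2"),
    E = c(1131.04e3, 251.53e3, 32.23e3, 11.17e3, 7.85e3),
    gamma = c(0.1, 0.3, 1.0, 2.5, 3.5))
  tab <- classify_elastomers(cand, default_stack(), skin)
  # margin ordering follows softness/adhesion ordering
  expect_identical(tab$name,
                   c("Ecoflex1:2", "Ecoflex1:1", "Ecoflex0030", "Solaris",
                     "PDMS"))
  expect_true(all(diff(tab$margin) < 0))

  # a candidate exactly on the boundary is non-conformal (strict >)
  gc <- critical_adhesion(default_stack(e_elastomer = 50e3), skin)$gamma_crit
  onb <- classify_elastomers(
    data.frame(name = "boundary", E = 50e3, gamma = gc),
    default_stack(), skin)
  expect_false(onb$conformal)

  # any candidate on smooth skin is conformal
  sm <- classify_elastomers(
    data.frame(name = "x", E = 1e6, gamma = 1e-12),
    default_stack(), skin_model(h_rough = 0))
  expect_true(sm$conformal)

  expect_warning(
    out <- classify_elastomers(
      data.frame(name = c("a", "b"), E = c(1e5, 1e5), gamma = c(NA, 1)),
      default_stack(), skin),
    "skipped")
  expect_identical(nrow(out), 1L)
})

test_that("work-of-adhesion intercept is exact on a noiseless line", {
  pts <- data.frame(speed = c(0.1, 0.2, 0.5, 1, 2),
                    delta_gamma = 2 + 3 * c(0.1, 0.2, 0.5, 1, 2))
  fit <- suppressWarnings(work_of_adhesion_intercept(pts))  # perfect fit
  expect_equal(fit$gamma_0, 2, tolerance = 1e-10)
  expect_error(work_of_adhesion_intercept(
    data.frame(speed = c(1, 1), delta_gamma = c(2, 3))), "distinct")
})

test_that("intercept standard error has near-nominal coverage", {
  set.seed(99)
  hits <- vapply(1:100, function(i) {
    v <- runif(40, 0.05, 2)
    pts <- data.frame(speed = v, delta_gamma = 2 + 3 * v + rnorm(40, 0, 0.5))
    f <- work_of_adhesion_intercept(pts)
    abs(f$gamma_0 - 2) <= 2 * f$se
  }, TRUE)
  expect_gte(sum(hits), 93)
})

test_that("peel energy integrates force-displacement curves exactly", {
  tri <- data.frame(displacement = c(0, 0.005, 0.010),
                    force = c(0, 1, 0))
  expect_equal(peel_energy(tri), 0.005, tolerance = 1e-12)   # 5 mJ
  flat <- data.frame(displacement = seq(0, 0.01, by = 1e-3),
                     force = rep(0, 11))
  expect_identical(peel_energy(flat), 0)
  # dense sine bump against the closed-form integral
  d <- seq(0, 0.01, length.out = 20001)
  bump <- data.frame(displacement = d, force = sin(pi * d / 0.01))
  expect_equal(peel_energy(bump), 2 * 0.01 / pi, tolerance = 1e-6)
  expect_error(peel_energy(data.frame(displacement = c(0, 2e-3, 1e-3),
                                      force = c(0, 1, 1))), "increasing")
})
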