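test_that("jacobian has the expected structure and entries", {
  p <- default_params()
  # wavenumber-free limit is lower-triangular
  expect_equal(jacobian_at_k(p, 6e7, 0),
               matrix(c(0, 0, -p$k_c, -p$f), 2, byrow = TRUE))
  # hand-substitution oracle at W_eq = 6e7, k = 1e4
  O_eq <- p$O_am - p$k_c * 6e7 / p$f
  V <- p$curve$a * O_eq^2 + p$curve$b * O_eq + p$curve$c
  dV <- 2 * p$curve$a * O_eq + p$curve$b
  D_W <- V^2 / (2 * p$curve$tau)
  beta <- V * dV / (2 * p$curve$tau)
  expect_equal(jacobian_at_k(p, 6e7, 1e4),
               matrix(c(-D_W * 1e8, -beta * 6e7 * 1e8,
                        -p$k_c, -p$D_O * 1e8 - p$f), 2, byrow = TRUE))
  # diagonal entries are never positive
  for (rep in 1:20) {
    set.seed(rep)
    pr <- random_params()
    J <- jacobian_at_k(pr, random_feasible_density(pr), 10^runif(1, 0, 5))
    expect_lte(J[1, 1], 0)
    expect_lte(J[2, 2], 0)
  }
})

test_that("closed-form eigenvalues match numeric eigendecomposition", {
  p <- default_params()
  d0 <- dispersion_relation(p, 6e7, 0)
  expect_equal(sort(Re(c(d0$lambda_plus, d0$lambda_minus))), c(-p$f, 0))
  set.seed(42)
  for (rep in 1:200) {
    pr <- random_params()
    W <- random_feasible_density(pr)
    k <- 10^runif(1, 1, 4.5)
    dr <- dispersion_relation(pr, W, k)
    ev <- eigen(jacobian_at_k(pr, W, k), only.values = TRUE)$values
    got <- sort(Re(c(dr$lambda_plus, dr$lambda_minus)))
    ref <- sort(Re(ev))
    scale <- max(abs(ref), .Machine$double.eps)
    expect_lt(max(abs(got - ref)) / scale, 1e-10)
    # trace identity: eigenvalue sum equals -(D_W k^2 + D_O k^2 + f)
    J <- jacobian_at_k(pr, W, k)
    expect_equal(Re(dr$lambda_plus + dr$lambda_minus), sum(diag(J)),
                 tolerance = 1e-12)
  }
})

test_that("instability criterion matches the sign of the maximal growth rate", {
  set.seed(7)
  for (rep in 1:100) {
    pr <- random_params()
    W <- random_feasible_density(pr)
    crit <- instability_criterion(pr, W)
    ks <- 10^seq(0, 5, length.out = 400)
    gmax <- max(dispersion_relation(pr, W, ks)$growth)
    expect_identical(unname(crit), gmax > 1e-15)
  }
})

test_that("instability is re-entrant in density at atmospheric oxygen", {
  p <- default_params()
  expect_false(instability_criterion(p, 1e7))
  expect_true(instability_criterion(p, 6e7))
  expect_false(instability_criterion(p, 9e7))
})

test_that("unstable band edge is positive iff unstable and scales as 1/D_O", {
  p <- default_params()
  expect_identical(unstable_band(p, 1e7), 0)
  b6 <- unstable_band(p, 6e7)
  expect_equal(b6, 4.1e8, tolerance = 0.02)
  # shortest unstable wavelength ~ 0.3 mm
  expect_equal(2 * pi / sqrt(b6), 3.1e-4, tolerance = 0.02)
  p2 <- model_params(p$curve, D_O = 2 * p$D_O, f = p$f, k_c = p$k_c,
                     O_am = p$O_am, L = p$L)
  expect_equal(unstable_band(p2, 6e7), b6 / 2)
  # growth rate crosses zero exactly at the band edge and decays beyond
  dr <- dispersion_relation(p, 6e7, sqrt(b6))
  expect_equal(dr$growth, 0, tolerance = 1e-8)
  expect_lt(dispersion_relation(p, 6e7, 3 * sqrt(b6))$growth, 0)
})

test_that("fastest-growing mode agrees with a dense brute-force scan", {
  p <- default_params()
  m <- fastest_growing_mode(p, 6e7)
  expect_true(m$unstable)
  expect_gt(m$k_star^2, 0)
  expect_lt(m$k_star^2, m$k_sq_max)
  ks <- seq(sqrt(m$k_sq_max) / 1e5, sqrt(m$k_sq_max), length.out = 1e5)
  g <- dispersion_relation(p, 6e7, ks)$growth
  expect_rel_equal(m$growth_max, max(g), 1e-3)
  expect_rel_equal(m$k_star, ks[which.max(g)], 1e-3)
  # stable configuration
  s <- fastest_growing_mode(p, 1e7)
  expect_false(s$unstable)
  expect_identical(s$k_star, 0)
  expect_lte(s$growth_max, 0)
})

test_that("critical densities bracket the instability zone (re-entrant)", {
  p <- default_params()
  cd <- critical_densities(p)
  expect_identical(cd$root, c("W_lower", "W_upper"))
  expect_gt(cd$W_per_mm2[1], 30); expect_lt(cd$W_per_mm2[1], 40)
  expect_gt(cd$W_per_mm2[2], 80); expect_lt(cd$W_per_mm2[2], 90)
  # criterion true strictly between the roots, false outside
  eps <- 1e4
  expect_false(instability_criterion(p, cd$W[1] - eps))
  expect_true(instability_criterion(p, cd$W[1] + eps))
  expect_true(instability_criterion(p, cd$W[2] - eps))
  expect_false(instability_criterion(p, cd$W[2] + eps))
  # ambient oxygen below the velocity minimum: beta <= 0 everywhere, no zone
  o_vertex <- -p$curve$b / (2 * p$curve$a)
  cd_low <- critical_densities(p, O_am = o_vertex * 0.9)
  expect_identical(nrow(cd_low), 0L)
})

test_that("phase diagram reproduces the pointwise criterion and band structure", {
  p <- default_params()
  one <- phase_diagram(p, 6e7, 0.21)
  expect_identical(one$unstable, instability_criterion(p, 6e7))
  pd <- phase_diagram(p, seq(1e6, 9e7, length.out = 12),
                      c(0.08, 0.12, 0.21), compute_modes = FALSE)
  # at 21% the unstable densities form one contiguous interior run
  slice <- dplyr::filter(pd, O_am == 0.21)
  runs <- rle(slice$unstable)
  expect_identical(runs$values, c(FALSE, TRUE, FALSE))
  # the unstable interval shrinks as ambient oxygen decreases
  # (cells infeasible at low O_am count as not unstable)
  n_unstable <- vapply(split(pd$unstable, pd$O_am),
                       function(u) sum(u, na.rm = TRUE), numeric(1))
  expect_true(all(diff(n_unstable) >= 0))
  # infeasible cells are labelled, not errors
  pd2 <- phase_diagram(p, max_feasible_density(p) * 2, 0.21)
  expect_false(pd2$feasible)
  expect_true(is.na(pd2$unstable))
})
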