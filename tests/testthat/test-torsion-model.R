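test_that("wrapped deviations behave on and across the periodic boundary", {
  expect_equal(wrap_deviation(104, 90), 14)
  expect_equal(wrap_deviation(350, 10), -20)
  expect_equal(wrap_deviation(123.4, 123.4), 0)
  # vectorized, identity for arbitrary angles, range (-180, 180]
  x <- seq(-720, 720, by = 7.3)
  expect_true(all(wrap_deviation(x, x) == 0))
  d <- wrap_deviation(x, rev(x))
  expect_true(all(d > -180 & d <= 180))
  expect_true(all(abs((x - rev(x) - d) %% 360) < 1e-9))
})

test_that("molecule_spec enforces a disjoint covering group partition", {
  dofs <- data.frame(label = "r1", category = "bond_length")
  expect_error(molecule_spec(c("a", "b"), list(1), dofs, "A1"),
               "partition")
  expect_error(molecule_spec(c("a", "b"), list(1, c(1, 2)), dofs, "A1"),
               "partition")
  expect_error(molecule_spec(c("a", "b"), list(1:2, integer(0)), dofs, "A1"),
               "non-empty")
  expect_error(molecule_spec("a", list(1),
                             data.frame(label = character(),
                                        category = character()), "A1"))
  m <- molecule_spec(c("a", "b"), list(2, 1), dofs, "A1")
  expect_s3_class(m, "molecule_spec")
  expect_equal(unname(molecule_dims(m)[["groups"]]), 2)
})

test_that("constrained minimization returns the closed-form reduced energy", {
  # quadratic bowl: energy above the bowl floor at +10 degrees is 50 * c
  c0 <- 0.005
  m <- one_bowl_model(center = 120, curvature = c0)
  rec <- minimize_at(m, 130)
  floor_rec <- minimize_at(m, 120)
  expect_equal(rec$energy - floor_rec$energy, 50 * c0, tolerance = 1e-12)

  # dependent DoFs sit exactly on their torsion-dependent equilibria
  fx <- fixture_paraben(epsilon = 0.4)
  th <- c(33, 211, 147)
  rec <- minimize_at(fx$model, th)
  bm <- fx$params$beta_map
  arg <- (bm$mult * matrix(th, nrow(bm$amp), 3, byrow = TRUE) + bm$phase) *
    pi / 180
  expect_equal(rec$beta, bm$base + rowSums(bm$amp * sin(arg)),
               tolerance = 1e-12)

  # invariant to 360-degree shifts of any input torsion
  rec2 <- minimize_at(fx$model, th + c(360, -360, 720))
  expect_equal(rec$energy, rec2$energy, tolerance = 1e-12)
  expect_equal(rec$beta, rec2$beta, tolerance = 1e-12)
  expect_equal(rec$hess_energy, rec2$hess_energy, tolerance = 1e-12)
})

test_that("analytic derivative blocks match finite differences", {
  fx <- fixture_paraben(epsilon = 0.35)
  set.seed(11)
  for (i in 1:10) {
    th <- runif(3, 0, 360)
    rec <- minimize_at(fx$model, th)
    expect_lt(max(abs(rec$grad_energy - fd_gradient(fx$model, th))), 1e-6)
    fdH <- fd_hessian(fx$model, th)
    expect_lt(max(abs(rec$hess_energy - fdH)) / max(abs(fdH)), 1e-4)
    expect_equal(rec$hess_energy, t(rec$hess_energy))
  }
})

test_that("total charge is conserved at every conformation", {
  fx <- fixture_xx(epsilon = 0.3)
  set.seed(5)
  total0 <- sum(minimize_at(fx$model, runif(8, 0, 360))$charges)
  for (i in 1:20) {
    rec <- minimize_at(fx$model, runif(8, 0, 360))
    expect_equal(sum(rec$charges), total0, tolerance = 1e-12)
    expect_lt(max(abs(colSums(rec$jac_charges))), 1e-12)
  }
  # construction refuses charge maps that leak charge
  mol <- one_torsion_molecule()
  expect_error(synthetic_params(
    mol,
    torsion_terms = list(list(type = "cosine",
                              terms = data.frame(amplitude = 1,
                                                 multiplicity = 1,
                                                 phase = 0))),
    beta_map = list(type = "sinusoidal", base = 1.4, amp = matrix(0.01),
                    mult = matrix(1), phase = matrix(0)),
    charge_map = list(type = "sinusoidal", base = c(0.1, -0.1),
                      weight = matrix(c(0.02, 0.01), 2, 1),
                      mult = 1, phase = 0)),
    "conservation")
})

test_that("zero cross-coupling makes the energy exactly group-additive", {
  fx <- fixture_paraben(epsilon = 0)
  vac <- minimize_vacuo(fx$model, fx$starts)
  set.seed(21)
  for (i in 1:100) {
    th <- runif(3, 0, 360)
    u_full <- minimize_at(fx$model, th)$energy - vac$U_vac
    u_sum <- 0
    for (g in fx$molecule$groups) {
      tg <- vac$theta_vac
      tg[g] <- th[g]
      u_sum <- u_sum + minimize_at(fx$model, tg)$energy - vac$U_vac
    }
    expect_lt(abs(u_full - u_sum), 1e-9)
  }
})

test_that("parameter generation is deterministic given the seed", {
  fx <- fixture_paraben()
  p1 <- random_synthetic_params(fx$molecule, seed = 77,
                                cross_coupling_epsilon = 0.2)
  p2 <- random_synthetic_params(fx$molecule, seed = 77,
                                cross_coupling_epsilon = 0.2)
  expect_identical(p1, p2)
  p3 <- random_synthetic_params(fx$molecule, seed = 78,
                                cross_coupling_epsilon = 0.2)
  expect_false(identical(p1$torsion_terms, p3$torsion_terms))
  # randomized models satisfy the analytic-derivative contract too
  m <- make_synthetic_model(p1)
  th <- c(100, 220, 340)
  expect_lt(max(abs(minimize_at(m, th)$grad_energy - fd_gradient(m, th))),
            1e-6)
})

test_that("parameter validation rejects unphysical inputs", {
  mol <- one_torsion_molecule()
  bmap <- list(type = "sinusoidal", base = 1.4, amp = matrix(0.01),
               mult = matrix(1), phase = matrix(0))
  qmap <- list(type = "sinusoidal", base = c(0.1, -0.1),
               weight = matrix(c(0.01, -0.01), 2, 1), mult = 1, phase = 0)
  expect_error(synthetic_params(
    mol, list(list(type = "cosine",
                   terms = data.frame(amplitude = 1, multiplicity = 0.5,
                                      phase = 0))),
    beta_map = bmap, charge_map = qmap), "multiplicity")
  expect_error(synthetic_params(
    mol, list(list(type = "bowl", center = 0, curvature = -1)),
    beta_map = bmap, charge_map = qmap), "curvature")
  expect_error(synthetic_params(
    mol, list(list(type = "cosine",
                   terms = data.frame(amplitude = 1, multiplicity = 1,
                                      phase = 0))),
    beta_map = bmap, charge_map = qmap, stiffness = -5), "stiffness")
})

test_that("in vacuo search finds the per-group brute-force minimum", {
  # independent oracle: dense 1-degree scan of each group's potential
  fx <- fixture_paraben(epsilon = 0)
  vac <- minimize_vacuo(fx$model, fx$starts)
  scan <- seq(0, 359.5, by = 1)
  for (g in fx$molecule$groups) {
    for (t in g) {
      e <- vapply(scan, function(x) {
        th <- vac$theta_vac
        th[t] <- x
        minimize_at(fx$model, th)$energy
      }, 0)
      # vacuo is a per-coordinate global minimum (wells may be degenerate,
      # so compare energies, not positions)
      expect_lte(vac$U_vac, min(e) + 1e-6)
    }
  }
})

test_that("multi-start minimization returns the lower of two wells", {
  m <- two_well_model()
  # analytic layout: wells of the two-fold term at 0 and 180; the weak
  # one-fold term (phase 180) penalizes the 0-degree well by +2 kJ/mol
  scan <- seq(0, 359.9, by = 0.1)
  e <- vapply(scan, function(x) minimize_at(m, x)$energy, 0)
  global <- scan[which.min(e)]
  expect_lt(abs(wrap_deviation(global, 180)), 5)
  for (starts in list(rbind(10, 350, 170), rbind(170, 10, 350))) {
    vac <- minimize_vacuo(m, starts)
    expect_lt(abs(wrap_deviation(vac$theta_vac, global)), 0.5)
    expect_lte(vac$U_vac, min(e) + 1e-6)
  }
})

test_that("finite-difference oracle adapter reproduces analytic blocks", {
  fx <- fixture_paraben(epsilon = 0.3)
  om <- oracle_model(fx$molecule, function(th) {
    r <- minimize_at(fx$model, th)
    list(energy = r$energy, beta = r$beta, charges = r$charges)
  }, fd_step = 0.01)
  th <- c(10, 200, 111)
  ra <- minimize_at(fx$model, th)
  rf <- minimize_at(om, th)
  expect_equal(rf$energy, ra$energy, tolerance = 1e-12)
  expect_lt(max(abs(ra$grad_energy - rf$grad_energy)), 1e-6)
  expect_lt(max(abs(ra$hess_energy - rf$hess_energy)), 1e-6)
  expect_lt(max(abs(ra$jac_beta - rf$jac_beta)), 1e-6)
  expect_lt(max(abs(ra$jac_charges - rf$jac_charges)), 1e-6)
})
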