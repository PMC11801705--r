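# Small model builders shared across test files. All are deterministic.

# one-torsion molecule with a minimal dependent-DoF/charge schema
one_torsion_molecule <- function() {
  molecule_spec("t1", list(1),
                data.frame(label = "r1", category = "bond_length"),
                c("A1", "A2"))
}

# single cosine-series torsional potential, tiny smooth property maps
one_cosine_model <- function(amplitude = 9, multiplicity = 2, phase = 30) {
  mol <- one_torsion_molecule()
  p <- synthetic_params(
    mol,
    torsion_terms = list(list(
      type = "cosine",
      terms = data.frame(amplitude = amplitude,
                         multiplicity = multiplicity, phase = phase))),
    beta_map = list(type = "sinusoidal", base = 1.4, amp = matrix(0.01),
                    mult = matrix(1), phase = matrix(0)),
    charge_map = list(type = "sinusoidal", base = c(0.1, -0.1),
                      weight = matrix(c(0.01, -0.01), 2, 1),
                      mult = 1, phase = 0))
  make_synthetic_model(p)
}

# single quadratic bowl; LAMs reproduce it exactly on its smooth branch
one_bowl_model <- function(center = 180, curvature = 0.005) {
  mol <- one_torsion_molecule()
  p <- synthetic_params(
    mol,
    torsion_terms = list(list(type = "bowl", center = center,
                              curvature = curvature)),
    beta_map = list(type = "affine", base = 1.4, coef = matrix(1e-4)),
    charge_map = list(type = "affine", base = c(0.1, -0.1),
                      weight = NULL, coef = matrix(c(1e-4, -1e-4), 2, 1)))
  make_synthetic_model(p)
}

# two unequal wells: a two-fold cosine split by a weak one-fold term;
# the deeper well sits at 180 degrees
two_well_model <- function() {
  mol <- one_torsion_molecule()
  p <- synthetic_params(
    mol,
    torsion_terms = list(list(
      type = "cosine",
      terms = data.frame(amplitude = c(6, 1), multiplicity = c(2, 1),
                         phase = c(0, 180)))),
    beta_map = list(type = "sinusoidal", base = 1.4, amp = matrix(0.01),
                    mult = matrix(1), phase = matrix(0)),
    charge_map = list(type = "sinusoidal", base = c(0.1, -0.1),
                      weight = matrix(c(0.01, -0.01), 2, 1),
                      mult = 1, phase = 0))
  make_synthetic_model(p)
}

# reduced-energy finite differences, independent of the analytic path
fd_gradient <- function(model, theta, h = 0.01) {
  vapply(seq_along(theta), function(t) {
    tp <- theta; tp[t] <- tp[t] + h
    tm <- theta; tm[t] <- tm[t] - h
    (minimize_at(model, tp)$energy - minimize_at(model, tm)$energy) / (2 * h)
  }, 0)
}

fd_hessian <- function(model, theta, h = 0.05) {
  l <- length(theta)
  H <- matrix(0, l, l)
  e0 <- minimize_at(model, theta)$energy
  for (t in seq_len(l)) {
    tp <- theta; tp[t] <- tp[t] + h
    tm <- theta; tm[t] <- tm[t] - h
    H[t, t] <- (minimize_at(model, tp)$energy - 2 * e0 +
                minimize_at(model, tm)$energy) / h^2
  }
  if (l > 1) for (t in 1:(l - 1)) for (u in (t + 1):l) {
    sh <- function(st, su) {
      x <- theta; x[t] <- x[t] + st * h; x[u] <- x[u] + su * h; x
    }
    H[t, u] <- H[u, t] <-
      (minimize_at(model, sh(1, 1))$energy -
       minimize_at(model, sh(1, -1))$energy -
       minimize_at(model, sh(-1, 1))$energy +
       minimize_at(model, sh(-1, -1))$energy) / (4 * h^2)
  }
  H
}

# oracle intramolecular energy difference at a full conformation
oracle_delta_u <- function(model, db, theta) {
  minimize_at(model, theta)$energy - db$vacuo$U_vac
}
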