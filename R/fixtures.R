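#' @title Ready-made fixture molecules
#' @description Synthetic molecules that reproduce the geometries of the
#'   standard worked examples of the method: a trivial two-torsion
#'   molecule with one torsion per group, a three-torsion paraben-like
#'   molecule (hydroxyl torsion in its own group, two coupled ester
#'   torsions in the other), a paracetamol-like molecule with narrow
#'   bounded grids, an eight-torsion molecule-XX-like compound in both
#'   full-range and restricted-range variants, and a quadratic/affine
#'   molecule on which the LAM representation is exact.
#' @name fixtures
NULL

cosine_term <- function(amplitude, multiplicity, phase) {
  list(type = "cosine",
       terms = data.frame(amplitude = amplitude,
                          multiplicity = multiplicity, phase = phase))
}

# deterministic smooth sinusoidal dependent-DoF map (no RNG)
det_beta_map <- function(molecule) {
  m <- nrow(molecule$dependent_dofs)
  l <- length(molecule$torsion_names)
  cat <- molecule$dependent_dofs$category
  base <- ifelse(cat == "bond_length", 1.40 + 0.01 * seq_len(m),
          ifelse(cat == "bond_angle", 108 + seq_len(m),
                 wrap_angle(47 * seq_len(m))))
  scale <- ifelse(cat == "bond_length", 0.015, 4)
  amp <- sin(outer(seq_len(m), seq_len(l), `*`)) * scale
  list(type = "sinusoidal", base = base, amp = amp,
       mult = matrix(1 + (outer(seq_len(m), seq_len(l), `+`) %% 2), m, l),
       phase = matrix(wrap_angle(31 * outer(seq_len(m), seq_len(l), `+`)),
                      m, l))
}

# deterministic charge map with exact total-charge conservation
det_charge_map <- function(molecule) {
  a <- length(molecule$charge_atoms)
  l <- length(molecule$torsion_names)
  w <- 0.02 * sin(outer(seq_len(a), seq_len(l), `*`) + 0.5)
  w <- sweep(w, 2, colMeans(w))
  q0 <- 0.3 * sin(seq_len(a))
  q0 <- q0 - mean(q0)
  list(type = "sinusoidal", base = q0, weight = w,
       mult = rep_len(c(1, 2), l), phase = wrap_angle(45 * seq_len(l)))
}

new_fixture <- function(name, molecule, params, grids, grids_full, starts) {
  structure(list(name = name, molecule = molecule, params = params,
                 model = make_synthetic_model(params),
                 grids = grids, grids_full = grids_full, starts = starts),
            class = "lam_fixture")
}

#' @export
print.lam_fixture <- function(x, ...) {
  cat("Fixture molecule:", x$name, "\n")
  print(x$molecule)
  cat("  cross-group coupling epsilon:",
      x$params$cross_coupling_epsilon, "\n")
  invisible(x)
}

#' Two-torsion worked-example molecule
#'
#' Two independent torsions trivially separated into two one-torsion
#' groups, with the in vacuo minimum at (243, 126) degrees and six
#' reference points per group on a 60-degree wraparound grid with first
#' point at 30 degrees. Building the partitioned database therefore costs
#' 13 oracle minimizations (12 reference fits plus the in vacuo one), and
#' a query at (104, 235) selects the references at 90 and 210 degrees.
#'
#' @param epsilon cross-group coupling strength (default 0, making the
#'   group-additive representation structurally exact).
#' @return A `lam_fixture`: molecule, synthetic-model parameters, built
#'   model, per-group grids, per-torsion full grids and in vacuo start
#'   points.
#' @export
fixture_fig1 <- function(epsilon = 0) {
  molecule <- molecule_spec(
    torsion_names = c("theta1", "theta2"),
    groups = list(1, 2),
    dependent_dofs = data.frame(
      label = c("r_C1O", "a_C1C2O", "t_ring"),
      category = c("bond_length", "bond_angle", "torsion")),
    charge_atoms = c("C1", "C2", "O1", "H1"))
  params <- synthetic_params(
    molecule,
    torsion_terms = list(cosine_term(8, 1, 243), cosine_term(6, 1, 126)),
    coupling = data.frame(i = 1, j = 2, amplitude = 2, phase = 40),
    beta_map = det_beta_map(molecule),
    charge_map = det_charge_map(molecule),
    cross_coupling_epsilon = epsilon)
  w60 <- grid_wraparound(60, 30)
  new_fixture("fig1-two-torsion", molecule, params,
              grids = list(list(w60), list(w60)),
              grids_full = list(w60, w60),
              starts = rbind(c(243, 126), c(60, 300)))
}

#' Paraben-like three-torsion molecule
#'
#' A hydroxyl-like torsion in its own group and two ester-like torsions,
#' directly coupled to each other, in a second group; the two groups sit
#' on opposite sides of an aromatic ring, so their mutual coupling is
#' weak (scaled by `epsilon`). With 60-degree wraparound grids (first
#' point at 30 degrees) the partitioned build costs 6 + 36 + 1 = 43
#' oracle calls against 217 for the non-partitioned one.
#'
#' @param epsilon cross-group coupling strength.
#' @param intra_amplitude coupling amplitude (kJ/mol) between the two
#'   torsions sharing a group.
#' @return A `lam_fixture`.
#' @export
fixture_paraben <- function(epsilon = 0.25, intra_amplitude = 3) {
  molecule <- molecule_spec(
    torsion_names = c("theta1", "theta2", "theta3"),
    groups = list(1, c(2, 3)),
    dependent_dofs = data.frame(
      label = c("r_CO_h", "r_CO_e", "r_CC", "a_COH", "a_OCO", "a_CCO",
                "t_ring1", "t_ring2"),
      category = c(rep("bond_length", 3), rep("bond_angle", 3),
                   rep("torsion", 2))),
    charge_atoms = paste0("A", 1:10))
  params <- synthetic_params(
    molecule,
    torsion_terms = list(cosine_term(6, 2, 0),
                         cosine_term(7, 2, 90),
                         cosine_term(4, 3, 20)),
    coupling = data.frame(
      i = c(2, 1, 1), j = c(3, 2, 3),
      amplitude = c(intra_amplitude, 1.5, 1),
      phase = c(15, 70, 200)),
    beta_map = det_beta_map(molecule),
    charge_map = det_charge_map(molecule),
    cross_coupling_epsilon = epsilon)
  w60 <- grid_wraparound(60, 30)
  new_fixture("paraben-like", molecule, params,
              grids = list(list(w60), list(w60, w60)),
              grids_full = list(w60, w60, w60),
              starts = as.matrix(expand.grid(c(0, 180), c(90, 270),
                                             c(20, 140, 260))))
}

#' Paracetamol-like three-torsion molecule with narrow bounded grids
#'
#' Same two-group topology as the paraben-like fixture, but with bounded
#' grids covering a narrow range around the preferred conformation:
#' 3 points on `[-30, 30]` for the lone torsion and 5 points on
#' `[120, 240]` for each of the coupled pair (30-degree increments).
#' Partitioned build: 3 + 25 + 1 = 29 calls; full build:
#' 3 x 5 x 5 + 1 = 76 calls, a 62 percent reduction.
#'
#' @param epsilon cross-group coupling strength.
#' @return A `lam_fixture`.
#' @export
fixture_paracetamol <- function(epsilon = 0.2) {
  molecule <- molecule_spec(
    torsion_names = c("theta1", "theta2", "theta3"),
    groups = list(1, c(2, 3)),
    dependent_dofs = data.frame(
      label = c("r_CN", "r_CO", "a_CNC", "a_CCO", "t_amide"),
      category = c("bond_length", "bond_length", "bond_angle",
                   "bond_angle", "torsion")),
    charge_atoms = paste0("A", 1:8))
  params <- synthetic_params(
    molecule,
    torsion_terms = list(cosine_term(9, 1, 0),
                         cosine_term(8, 1, 180),
                         cosine_term(7, 1, 180)),
    coupling = data.frame(
      i = c(2, 1), j = c(3, 2),
      amplitude = c(2.5, 1.2), phase = c(10, 60)),
    beta_map = det_beta_map(molecule),
    charge_map = det_charge_map(molecule),
    cross_coupling_epsilon = epsilon)
  g1 <- list(grid_bounded(-30, 30, 30))
  g23 <- list(grid_bounded(120, 30, 240), grid_bounded(120, 30, 240))
  new_fixture("paracetamol-like", molecule, params,
              grids = list(g1, g23),
              grids_full = c(g1, g23),
              starts = rbind(c(0, 180, 180)))
}

#' Molecule-XX-like eight-torsion molecule
#'
#' Eight independent torsions split across a central ring into groups
#' `{1, 2, 3}` and `{4, ..., 8}`. The full-range variant carries the
#' bounded initial grids of the adaptive study (27 and 162 reference
#' points); the restricted variant covers a narrow range around the
#' preferred conformation with two points per torsion 15 degrees either
#' side of the grid midpoint, except the sixth torsion which varies only
#' slightly around 180 and gets a single point -- hence 2^7 = 128
#' references (129 calls) non-partitioned versus 8 + 16 + 1 = 25
#' partitioned.
#'
#' @param restricted use the narrow-range grids (default `FALSE`).
#' @param epsilon cross-group coupling strength.
#' @return A `lam_fixture`.
#' @export
fixture_xx <- function(restricted = FALSE, epsilon = 0.15) {
  molecule <- molecule_spec(
    torsion_names = paste0("theta", 1:8),
    groups = list(1:3, 4:8),
    dependent_dofs = data.frame(
      label = c(paste0("r", 1:4), paste0("a", 1:4), paste0("t", 1:3)),
      category = c(rep("bond_length", 4), rep("bond_angle", 4),
                   rep("torsion", 3))),
    charge_atoms = paste0("A", 1:12))
  centers <- c(110, 90, 180, 0, 180, 180, 270, 270)
  amps <- c(6, 6, 7, 5, 5, 15, 6, 6)
  params <- synthetic_params(
    molecule,
    torsion_terms = lapply(1:8, function(t)
      cosine_term(amps[t], if (t == 5) 2 else 1, centers[t])),
    coupling = data.frame(
      i = c(1, 2, 4, 5, 6, 7, 3, 2),
      j = c(2, 3, 5, 6, 7, 8, 4, 7),
      amplitude = c(2, 2, 2, 2, 2, 2, 1, 1),
      phase = c(20, 110, 65, 155, 245, 335, 10, 95)),
    beta_map = det_beta_map(molecule),
    charge_map = det_charge_map(molecule),
    cross_coupling_epsilon = epsilon)

  if (restricted) {
    per_torsion <- lapply(1:8, function(t)
      if (t == 6) grid_points(180)
      else grid_points(c(centers[t] - 15, centers[t] + 15)))
  } else {
    per_torsion <- list(
      grid_bounded(60, 120, 300),    # theta1
      grid_bounded(-30, 120, 210),   # theta2
      grid_bounded(60, 120, 300),    # theta3
      grid_bounded(-120, 120, 120),  # theta4
      grid_bounded(0, 180, 180),     # theta5
      grid_bounded(60, 120, 300),    # theta6
      grid_bounded(30, 120, 270),    # theta7
      grid_bounded(-30, 120, 210))   # theta8
  }
  new_fixture(if (restricted) "xx-like-restricted" else "xx-like",
              molecule, params,
              grids = list(per_torsion[1:3], per_torsion[4:8]),
              grids_full = per_torsion,
              starts = rbind(centers))
}

#' Quadratic/affine molecule on which LAMs are exact
#'
#' Per-torsion quadratic bowls centred at 180 degrees, affine dependent-
#' DoF and charge maps, and no coupling of any kind: the second-order
#' energy expansion and first-order property expansions reproduce the
#' oracle exactly at every conformation (up to round-off), for any grid
#' whose reference points keep the wrapped deviations on the bowls'
#' smooth branch -- the default 60-degree wraparound grid with first
#' point at 30 degrees does.
#'
#' @param l number of torsions (default 3).
#' @param groups group partition (default `{1}, {2..l}` for `l > 1`).
#' @return A `lam_fixture`.
#' @export
fixture_quadratic <- function(l = 3, groups = NULL) {
  if (is.null(groups)) groups <- if (l > 1) list(1, 2:l) else list(1)
  molecule <- molecule_spec(
    torsion_names = paste0("theta", seq_len(l)),
    groups = groups,
    dependent_dofs = data.frame(
      label = c("r1", "a1", "t1"),
      category = c("bond_length", "bond_angle", "torsion")),
    charge_atoms = paste0("A", 1:5))
  curv <- 0.003 + 0.001 * seq_len(l)
  beta_coef <- matrix(c(1e-4, 5e-3, 8e-3), 3, l) *
    matrix(rep(seq_len(l), each = 3), 3, l)
  q_coef <- matrix(1e-4 * sin(outer(1:5, seq_len(l))), 5, l)
  q_coef <- sweep(q_coef, 2, colMeans(q_coef))
  params <- synthetic_params(
    molecule,
    torsion_terms = lapply(seq_len(l), function(t)
      list(type = "bowl", center = 180, curvature = curv[t])),
    beta_map = list(type = "affine", base = c(1.4, 110, 120),
                    coef = beta_coef),
    charge_map = list(type = "affine",
                      base = c(0.2, -0.1, 0.3, -0.25, -0.15),
                      coef = q_coef))
  w60 <- grid_wraparound(60, 30)
  new_fixture("quadratic-affine", molecule, params,
              grids = lapply(groups, function(g) rep(list(w60), length(g))),
              grids_full = rep(list(w60), l),
              starts = rbind(rep(180, l)))
}

#' Look up a fixture by name
#' @param name one of `"fig1"`, `"paraben"`, `"paracetamol"`, `"xx"`,
#'   `"xx_restricted"`, `"quadratic"`.
#' @param ... passed to the fixture constructor.
#' @return A `lam_fixture`.
#' @export
fixture <- function(name = c("fig1", "paraben", "paracetamol", "xx",
                             "xx_restricted", "quadratic"), ...) {
  name <- match.arg(name)
  switch(name,
         fig1 = fixture_fig1(...),
         paraben = fixture_paraben(...),
         paracetamol = fixture_paracetamol(...),
         xx = fixture_xx(restricted = FALSE, ...),
         xx_restricted = fixture_xx(restricted = TRUE, ...),
         quadratic = fixture_quadratic(...))
}
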