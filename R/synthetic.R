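#' Synthetic conformational model
#'
#' `make_synthetic_model()` builds a fully analytic stand-in for the
#' quantum-mechanical engine that a crystal structure prediction pipeline
#' would call for constrained conformational energy minimizations. The
#' model has the structure the torsional-group method assumes:
#'
#' * a smooth periodic torsional energy, composed of per-torsion potentials
#'   (cosine series or quadratic bowls), pairwise couplings *within*
#'   torsional groups, and pairwise couplings *between* groups whose
#'   strength is scaled by a single knob `cross_coupling_epsilon`;
#' * dependent degrees of freedom (bond lengths, bond angles, non-flexible
#'   torsions) bound by harmonic restraints to torsion-dependent
#'   equilibrium values, so that at the constrained minimum they equal
#'   those equilibria exactly and contribute no energy;
#' * per-atom point charges varying smoothly with the torsions under a
#'   total-charge-conservation constraint.
#'
#' Because the dependent DoFs relax exactly onto their equilibria, the
#' reduced (dependent-DoF-relaxed) energy, its gradient and Hessian, and
#' the Jacobians of the dependent DoFs and charges are all available in
#' closed form. With `cross_coupling_epsilon = 0` the reduced energy is
#' exactly a sum of per-group functions, which makes the group-additivity
#' approximation exact and gives the test suite a ground truth.
#'
#' @param params a [synthetic_params()] object.
#' @return An object of classes `synthetic_model`, `conformational_model`.
#' @seealso [synthetic_params()], [random_synthetic_params()],
#'   [minimize_at()], [minimize_vacuo()]
#' @export
make_synthetic_model <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  molecule <- params$molecule
  l <- length(molecule$torsion_names)

  # classify pairwise couplings: cross-group terms are scaled by epsilon
  coup <- params$coupling
  if (!is.null(coup) && nrow(coup) > 0L) {
    grp_of <- integer(l)
    for (g in seq_along(molecule$groups)) grp_of[molecule$groups[[g]]] <- g
    coup$cross <- grp_of[coup$i] != grp_of[coup$j]
    coup$scale <- ifelse(coup$cross, params$cross_coupling_epsilon, 1)
  }

  structure(
    list(molecule = molecule, params = params, coupling = coup),
    class = c("synthetic_model", "conformational_model"))
}

#' Parameters of the synthetic conformational model
#'
#' @param molecule a [molecule_spec()].
#' @param torsion_terms list with one entry per torsion; each entry is
#'   either `list(type = "cosine", terms = data.frame(amplitude,
#'   multiplicity, phase))` giving a potential
#'   \eqn{\sum_k a_k (1 - \cos(n_k (\theta - \phi_k)))} (kJ/mol, phases in
#'   degrees), or `list(type = "bowl", center, curvature)` giving a
#'   quadratic bowl \eqn{\tfrac12 c\, w(\theta - \theta_0)^2} in the
#'   wrapped deviation (curvature in kJ/mol/deg^2).
#' @param coupling optional data frame with columns `i`, `j`, `amplitude`,
#'   `phase` adding pairwise terms \eqn{a \cos(\theta_i - \theta_j + \phi)};
#'   terms whose torsions lie in different groups are multiplied by
#'   `cross_coupling_epsilon`.
#' @param beta_map map from torsions to dependent-DoF equilibria: either
#'   `list(type = "sinusoidal", base, amp, mult, phase)` with M-vector
#'   `base` and M x l matrices, giving
#'   \eqn{\beta_m = base_m + \sum_t amp_{mt} \sin((mult_{mt}\theta_t + phase_{mt}) \pi/180)},
#'   or `list(type = "affine", base, coef)` with \eqn{\beta = base + coef\,\theta}
#'   on the raw domain `[0, 360)`.
#' @param charge_map analogous map for the atomic charges; sinusoidal form
#'   `list(type = "sinusoidal", base, weight, mult, phase)` shares one
#'   multiplicity/phase per torsion across atoms and requires the columns
#'   of `weight` to sum to zero, so total charge is conserved at every
#'   conformation; affine form requires zero column sums of `coef`.
#' @param stiffness positive harmonic constants (one per dependent DoF)
#'   binding the raw dependent DoFs to their equilibria. They do not enter
#'   the reduced energy (the restraints are exactly relaxed) but are kept
#'   as part of the model definition.
#' @param cross_coupling_epsilon dimensionless scale of the inter-group
#'   coupling terms; 0 makes the reduced energy exactly group-additive.
#' @param energy_offset absolute energy offset U0 (kJ/mol); all reported
#'   energies are absolute, energy differences are taken against the
#'   in vacuo minimum.
#' @param seed optional integer recording how randomized parameters were
#'   drawn (see [random_synthetic_params()]).
#'
#' @return An object of class `synthetic_params`.
#' @export
synthetic_params <- function(molecule, torsion_terms, coupling = NULL,
                             beta_map, charge_map, stiffness = NULL,
                             cross_coupling_epsilon = 0,
                             energy_offset = 0, seed = NULL) {
  stopifnot(inherits(molecule, "molecule_spec"))
  l <- length(molecule$torsion_names)
  m <- nrow(molecule$dependent_dofs)
  a <- length(molecule$charge_atoms)

  if (!is.list(torsion_terms) || length(torsion_terms) != l)
    stop("'torsion_terms' must have one entry per torsion")
  for (t in seq_len(l)) {
    tt <- torsion_terms[[t]]
    if (identical(tt$type, "cosine")) {
      tm <- tt$terms
      if (!all(c("amplitude", "multiplicity", "phase") %in% names(tm)))
        stop("cosine terms need amplitude, multiplicity, phase")
      if (any(tm$multiplicity < 1) || any(tm$multiplicity != round(tm$multiplicity)))
        stop("invalid multiplicity: must be a positive integer")
    } else if (identical(tt$type, "bowl")) {
      if (!is.numeric(tt$curvature) || tt$curvature <= 0)
        stop("bowl curvature must be positive")
    } else stop("torsion term type must be 'cosine' or 'bowl'")
  }

  if (!is.null(coupling)) {
    coupling <- as.data.frame(coupling)
    stopifnot(all(c("i", "j", "amplitude", "phase") %in% names(coupling)),
              all(coupling$i %in% seq_len(l)), all(coupling$j %in% seq_len(l)),
              all(coupling$i != coupling$j))
  }

  beta_map <- check_dof_map(beta_map, m, l, conserve = FALSE, what = "beta_map")
  charge_map <- check_dof_map(charge_map, a, l, conserve = TRUE,
                              what = "charge_map")

  if (is.null(stiffness)) stiffness <- rep(100, m)
  if (length(stiffness) == 1L) stiffness <- rep(stiffness, m)
  if (length(stiffness) != m || any(stiffness <= 0))
    stop("stiffness must be positive, one constant per dependent DoF")

  stopifnot(is.numeric(cross_coupling_epsilon),
            length(cross_coupling_epsilon) == 1L,
            cross_coupling_epsilon >= 0)

  structure(
    list(molecule = molecule, torsion_terms = torsion_terms,
         coupling = coupling, beta_map = beta_map, charge_map = charge_map,
         stiffness = stiffness,
         cross_coupling_epsilon = cross_coupling_epsilon,
         energy_offset = energy_offset, seed = seed),
    class = "synthetic_params")
}

check_dof_map <- function(map, nrow_out, l, conserve, what) {
  if (identical(map$type, "sinusoidal")) {
    map$base <- as.numeric(map$base)
    stopifnot(length(map$base) == nrow_out)
    if (!is.null(map$weight)) {
      # charge form: one multiplicity/phase per torsion shared across atoms,
      # so zero column sums of the weights conserve total charge at every theta
      map$weight <- matrix(as.numeric(map$weight), nrow_out, l)
      map$mult <- rep(as.numeric(map$mult), length.out = l)
      map$phase <- rep(as.numeric(map$phase), length.out = l)
      if (any(map$mult < 1) || any(map$mult != round(map$mult)))
        stop(what, ": invalid multiplicity")
      if (conserve && max(abs(colSums(map$weight))) > 1e-10)
        stop(what, ": sinusoidal weights must sum to zero across atoms ",
             "(total-charge conservation)")
    } else {
      for (fld in c("amp", "mult", "phase"))
        map[[fld]] <- matrix(as.numeric(map[[fld]]), nrow_out, l)
      if (any(map$mult < 1) || any(map$mult != round(map$mult)))
        stop(what, ": invalid multiplicity")
    }
  } else if (identical(map$type, "affine")) {
    map$base <- as.numeric(map$base)
    map$coef <- matrix(as.numeric(map$coef), nrow_out, l)
    stopifnot(length(map$base) == nrow_out)
    if (conserve && max(abs(colSums(map$coef))) > 1e-10)
      stop(what, ": affine coefficients must sum to zero across atoms ",
           "(total-charge conservation)")
  } else stop(what, ": type must be 'sinusoidal' or 'affine'")
  map
}

#' Draw randomized synthetic-model parameters
#'
#' Convenience generator for test and benchmark models: random cosine
#' potentials per torsion, optional pairwise couplings within and between
#' groups, and sinusoidal dependent-DoF/charge maps. Deterministic given
#' `seed`; the caller's RNG state is left untouched.
#'
#' @inheritParams synthetic_params
#' @param seed integer seed.
#' @param amplitude typical torsional barrier height (kJ/mol).
#' @param intra_amplitude amplitude of couplings between torsions of the
#'   same group (kJ/mol); 0 omits them.
#' @param cross_amplitude amplitude of inter-group couplings before the
#'   `cross_coupling_epsilon` scaling (kJ/mol).
#' @param beta_amplitude typical modulation of dependent DoFs around their
#'   base values (schema units).
#' @param charge_amplitude typical charge modulation (e).
#' @return A `synthetic_params` object.
#' @export
random_synthetic_params <- function(molecule, seed,
                                    cross_coupling_epsilon = 0,
                                    amplitude = 8,
                                    intra_amplitude = 0,
                                    cross_amplitude = 2,
                                    beta_amplitude = 0.5,
                                    charge_amplitude = 0.02) {
  stopifnot(inherits(molecule, "molecule_spec"))
  l <- length(molecule$torsion_names)
  m <- nrow(molecule$dependent_dofs)
  a <- length(molecule$charge_atoms)

  with_seed(seed, {
    torsion_terms <- lapply(seq_len(l), function(t) {
      k <- sample(1:2, 1)
      list(type = "cosine",
           terms = data.frame(
             amplitude = stats::runif(k, 0.4, 1) * amplitude / k,
             multiplicity = sample(1:3, k, replace = TRUE),
             phase = stats::runif(k, 0, 360)))
    })

    coupling <- NULL
    pairs <- utils::combn(l, 2)
    grp_of <- integer(l)
    for (g in seq_along(molecule$groups)) grp_of[molecule$groups[[g]]] <- g
    rows <- list()
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      same <- grp_of[i] == grp_of[j]
      amp <- if (same) intra_amplitude else cross_amplitude
      if (amp <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        i = i, j = j,
        amplitude = amp * stats::runif(1, 0.6, 1),
        phase = stats::runif(1, 0, 360))
    }
    if (length(rows)) coupling <- do.call(rbind, rows)

    # bond lengths ~1.4 A, bond angles ~112 deg, dependent torsions ~180 deg
    base <- ifelse(molecule$dependent_dofs$category == "bond_length",
                   stats::runif(m, 1.2, 1.6),
            ifelse(molecule$dependent_dofs$category == "bond_angle",
                   stats::runif(m, 105, 120), stats::runif(m, 0, 360)))
    scale <- ifelse(molecule$dependent_dofs$category == "bond_length",
                    0.02, beta_amplitude * 10)
    beta_map <- list(
      type = "sinusoidal", base = base,
      amp = matrix(stats::runif(m * l, -1, 1), m, l) * scale,
      mult = matrix(sample(1:2, m * l, replace = TRUE), m, l),
      phase = matrix(stats::runif(m * l, 0, 360), m, l))

    w <- matrix(stats::runif(a * l, -1, 1), a, l) * charge_amplitude
    w <- sweep(w, 2, colMeans(w))    # zero column sums: charge conservation
    q0 <- stats::runif(a, -0.4, 0.4)
    q0 <- q0 - mean(q0)              # neutral molecule
    charge_map <- list(type = "sinusoidal", base = q0, weight = w,
                       mult = sample(1:2, l, replace = TRUE),
                       phase = stats::runif(l, 0, 360))

    synthetic_params(molecule, torsion_terms, coupling, beta_map, charge_map,
                     stiffness = stats::runif(m, 50, 200),
                     cross_coupling_epsilon = cross_coupling_epsilon,
                     seed = seed)
  })
}

# --- closed-form reduced energy -------------------------------------------

# value, gradient and Hessian of the reduced (dependent-DoF-relaxed)
# energy of a synthetic model, all in one pass; angles in degrees,
# derivatives per degree
reduced_energy <- function(model, theta, derivatives = TRUE) {
  theta <- wrap_angle(theta)
  l <- length(theta)
  U <- model$params$energy_offset
  g <- numeric(l)
  H <- matrix(0, l, l)

  for (t in seq_len(l)) {
    tt <- model$params$torsion_terms[[t]]
    if (tt$type == "cosine") {
      tm <- tt$terms
      arg <- tm$multiplicity * (theta[t] - tm$phase) * D2R
      U <- U + sum(tm$amplitude * (1 - cos(arg)))
      if (derivatives) {
        g[t] <- g[t] + sum(tm$amplitude * tm$multiplicity * D2R * sin(arg))
        H[t, t] <- H[t, t] +
          sum(tm$amplitude * (tm$multiplicity * D2R)^2 * cos(arg))
      }
    } else {
      u <- wrap_deviation(theta[t], tt$center)
      U <- U + 0.5 * tt$curvature * u^2
      if (derivatives) {
        g[t] <- g[t] + tt$curvature * u
        H[t, t] <- H[t, t] + tt$curvature
      }
    }
  }

  coup <- model$coupling
  if (!is.null(coup) && nrow(coup) > 0L) {
    for (r in seq_len(nrow(coup))) {
      s <- coup$scale[r]
      if (s == 0) next
      i <- coup$i[r]; j <- coup$j[r]
      u <- (theta[i] - theta[j] + coup$phase[r]) * D2R
      A <- s * coup$amplitude[r]
      U <- U + A * cos(u)
      if (derivatives) {
        g[i] <- g[i] - A * D2R * sin(u)
        g[j] <- g[j] + A * D2R * sin(u)
        H[i, i] <- H[i, i] - A * D2R^2 * cos(u)
        H[j, j] <- H[j, j] - A * D2R^2 * cos(u)
        H[i, j] <- H[i, j] + A * D2R^2 * cos(u)
        H[j, i] <- H[j, i] + A * D2R^2 * cos(u)
      }
    }
  }

  if (!derivatives) return(list(U = U))
  list(U = U, grad = g, hess = H)
}

# torsion-dependent equilibria of the dependent DoFs and their Jacobian
eval_dof_map <- function(map, theta) {
  l <- length(theta)
  if (map$type == "affine") {
    return(list(value = map$base + drop(map$coef %*% theta),
                jac = map$coef))
  }
  if (!is.null(map$weight)) {           # charge form: shared mult/phase
    arg <- (map$mult * theta + map$phase) * D2R
    value <- map$base + drop(map$weight %*% sin(arg))
    jac <- sweep(map$weight, 2, map$mult * D2R * cos(arg), `*`)
    return(list(value = value, jac = jac))
  }
  th <- matrix(theta, nrow(map$amp), l, byrow = TRUE)
  arg <- (map$mult * th + map$phase) * D2R
  list(value = map$base + rowSums(map$amp * sin(arg)),
       jac = map$amp * map$mult * D2R * cos(arg))
}

# --- oracle contract -------------------------------------------------------

#' Constrained conformational energy minimization at fixed torsions
#'
#' The central oracle call of the method: minimize the molecule's energy
#' over the dependent degrees of freedom while holding the independent
#' torsions fixed at `theta`. In a production pipeline this is an
#' isolated-molecule QM minimization; here it is answered either in closed
#' form by the synthetic model or by a user-supplied adapter (see
#' [oracle_model()]).
#'
#' @param model a `conformational_model` (from [make_synthetic_model()] or
#'   [oracle_model()]).
#' @param theta numeric vector of independent torsion values (degrees),
#'   one per torsion; wrapped into `[0, 360)`.
#' @param ... passed to methods.
#'
#' @return An object of class `constrained_minimum` with fields `theta`
#'   (wrapped), `energy` (kJ/mol), `beta` (dependent-DoF values), `charges`
#'   (e), `grad_energy` (kJ/mol/deg), `hess_energy` (kJ/mol/deg^2,
#'   symmetric), `jac_beta` and `jac_charges` (per-degree Jacobians).
#' @export
minimize_at <- function(model, theta, ...) UseMethod("minimize_at")

#' @export
minimize_at.synthetic_model <- function(model, theta, ...) {
  check_theta(model$molecule, theta)
  theta <- wrap_angle(theta)
  en <- reduced_energy(model, theta)
  if (!is.finite(en$U)) stop("oracle returned a non-finite energy")
  bt <- eval_dof_map(model$params$beta_map, theta)
  qv <- eval_dof_map(model$params$charge_map, theta)
  new_constrained_minimum(theta, en$U, bt$value, qv$value,
                          en$grad, en$hess, bt$jac, qv$jac)
}

new_constrained_minimum <- function(theta, energy, beta, charges,
                                    grad, hess, jac_beta, jac_charges) {
  hess <- (hess + t(hess)) / 2   # enforce exact symmetry
  structure(
    list(theta = theta, energy = energy, beta = beta, charges = charges,
         grad_energy = grad, hess_energy = hess,
         jac_beta = jac_beta, jac_charges = jac_charges),
    class = "constrained_minimum")
}

#' Wrap an external conformational oracle
#'
#' Adapts any function performing a constrained minimization at fixed
#' independent torsions to the `conformational_model` contract. The
#' function must return `list(energy, beta, charges)`; derivative blocks
#' are filled in by wrap-aware central finite differences.
#'
#' @param molecule a [molecule_spec()].
#' @param fn `function(theta) -> list(energy, beta, charges)`.
#' @param fd_step finite-difference step in degrees (default 1, small
#'   against typical 60-120 degree reference spacings).
#' @return An object of classes `oracle_model`, `conformational_model`.
#' @export
oracle_model <- function(molecule, fn, fd_step = 1) {
  stopifnot(inherits(molecule, "molecule_spec"), is.function(fn),
            is.numeric(fd_step), fd_step > 0)
  structure(list(molecule = molecule, fn = fn, fd_step = fd_step),
            class = c("oracle_model", "conformational_model"))
}

#' @export
minimize_at.oracle_model <- function(model, theta, ...) {
  check_theta(model$molecule, theta)
  theta <- wrap_angle(theta)
  h <- model$fd_step
  l <- length(theta)
  call_fn <- function(th) {
    r <- model$fn(wrap_angle(th))
    if (!is.finite(r$energy)) stop("oracle returned a non-finite energy")
    r
  }
  r0 <- call_fn(theta)
  m <- length(r0$beta); a <- length(r0$charges)
  if (m != nrow(model$molecule$dependent_dofs) ||
      a != length(model$molecule$charge_atoms))
    stop("oracle output dimensions do not match the molecule schemas")

  shift <- function(t, dh) { th <- theta; th[t] <- th[t] + dh; th }
  plus <- lapply(seq_len(l), function(t) call_fn(shift(t, +h)))
  minus <- lapply(seq_len(l), function(t) call_fn(shift(t, -h)))

  grad <- vapply(seq_len(l),
                 function(t) (plus[[t]]$energy - minus[[t]]$energy) / (2 * h),
                 0)
  hess <- matrix(0, l, l)
  for (t in seq_len(l))
    hess[t, t] <- (plus[[t]]$energy - 2 * r0$energy + minus[[t]]$energy) / h^2
  if (l > 1) for (t in seq_len(l - 1)) for (u in (t + 1):l) {
    th <- function(st, su) { x <- theta; x[t] <- x[t] + st * h
                             x[u] <- x[u] + su * h; x }
    v <- (call_fn(th(1, 1))$energy - call_fn(th(1, -1))$energy -
          call_fn(th(-1, 1))$energy + call_fn(th(-1, -1))$energy) / (4 * h^2)
    hess[t, u] <- hess[u, t] <- v
  }
  jac_beta <- vapply(seq_len(l),
                     function(t) (plus[[t]]$beta - minus[[t]]$beta) / (2 * h),
                     numeric(m))
  jac_charges <- vapply(seq_len(l),
                        function(t) (plus[[t]]$charges - minus[[t]]$charges) / (2 * h),
                        numeric(a))
  new_constrained_minimum(theta, r0$energy, r0$beta, r0$charges,
                          grad, hess,
                          matrix(jac_beta, m, l), matrix(jac_charges, a, l))
}

#' @export
print.constrained_minimum <- function(x, ...) {
  cat("Constrained conformational minimum\n")
  cat("  theta (deg):", paste(sprintf("%.2f", x$theta), collapse = ", "), "\n")
  cat("  energy:", format(x$energy), "kJ/mol\n")
  cat(sprintf("  %d dependent DoFs, %d charges, derivative blocks attached\n",
              length(x$beta), length(x$charges)))
  invisible(x)
}

# --- in vacuo minimum ------------------------------------------------------

#' Locate the in vacuo (unconstrained) conformational minimum
#'
#' Runs gradient-based local minimizations of the reduced energy over the
#' independent torsions from each supplied start point (dependent DoFs
#' relax implicitly through the constrained-minimization oracle) and
#' returns the lowest minimum found. The in vacuo conformation anchors all
#' intramolecular energy differences.
#'
#' @param model a `conformational_model`.
#' @param starts matrix of start points (one per row, degrees), a single
#'   numeric vector, or a list of vectors.
#' @return An object of class `vacuo_record`: `theta_vac` (degrees,
#'   wrapped), `beta_vac`, `q_vac`, `U_vac` (kJ/mol).
#' @export
minimize_vacuo <- function(model, starts) {
  molecule <- model$molecule
  l <- length(molecule$torsion_names)
  if (is.numeric(starts) && is.null(dim(starts))) starts <- rbind(starts)
  if (is.list(starts)) starts <- do.call(rbind, starts)
  starts <- as.matrix(starts)
  if (nrow(starts) < 1L || ncol(starts) != l)
    stop("'starts' must supply at least one torsion vector of length ", l)

  analytic <- inherits(model, "synthetic_model")
  fn <- if (analytic) function(th) reduced_energy(model, th, FALSE)$U
        else function(th) model$fn(wrap_angle(th))$energy
  gr <- if (analytic) function(th) reduced_energy(model, th)$grad else NULL

  best <- NULL
  failures <- 0L
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[s, ], fn, gr, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) { failures <- failures + 1L; next }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("in vacuo minimization failed from every start point")

  rec <- minimize_at(model, wrap_angle(best$par))
  structure(
    list(theta_vac = rec$theta, beta_vac = rec$beta, q_vac = rec$charges,
         U_vac = rec$energy, n_starts = nrow(starts), n_failed = failures),
    class = "vacuo_record")
}

#' @export
print.vacuo_record <- function(x, ...) {
  cat("In vacuo conformational minimum\n")
  cat("  theta_vac (deg):",
      paste(sprintf("%.2f", x$theta_vac), collapse = ", "), "\n")
  cat("  U_vac:", format(x$U_vac), "kJ/mol\n")
  invisible(x)
}
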