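#' @title Local Approximate Models: reference fitting and evaluation
#' @description Core of the method: each reference point carries a
#'   second-order Taylor model of the intramolecular energy and first-order
#'   models of the dependent degrees of freedom and charges in its group's
#'   torsions; a query conformation is answered by picking the nearest
#'   reference in each torsional group and summing the per-group
#'   deviations from the in vacuo values (the additivity principle).
#' @name lam-core
NULL

#' Fit a Local Approximate Model at a reference point
#'
#' Assembles the full torsion vector with group `group_id` fixed at
#' `theta_ref_g` and all other groups at their in vacuo values, performs
#' the constrained minimization through the oracle, and extracts the
#' group-subblock derivative matrices: the energy gradient `b` and Hessian
#' `H` in the group's torsions, the dependent-DoF Jacobian `K` and the
#' charge Jacobian `A`.
#'
#' @param model a `conformational_model`.
#' @param molecule a [molecule_spec()].
#' @param group_id index of the torsional group.
#' @param theta_ref_g torsion values of the reference point (degrees), one
#'   per group member.
#' @param vacuo a `vacuo_record` from [minimize_vacuo()].
#' @return An object of class `reference_record`.
#' @export
fit_reference <- function(model, molecule, group_id, theta_ref_g, vacuo) {
  stopifnot(inherits(molecule, "molecule_spec"),
            inherits(vacuo, "vacuo_record"))
  members <- molecule$groups[[group_id]]
  if (length(theta_ref_g) != length(members))
    stop("reference point has ", length(theta_ref_g),
         " torsions but group ", group_id, " has ", length(members))
  theta <- vacuo$theta_vac
  theta[members] <- theta_ref_g
  rec <- minimize_at(model, theta)
  structure(
    list(group_id = group_id,
         theta_ref = wrap_angle(as.numeric(theta_ref_g)),
         U_ref = rec$energy,
         beta_ref = rec$beta,
         q_ref = rec$charges,
         b = rec$grad_energy[members],
         H = rec$hess_energy[members, members, drop = FALSE],
         K = rec$jac_beta[, members, drop = FALSE],
         A = rec$jac_charges[, members, drop = FALSE]),
    class = "reference_record")
}

new_group_database <- function(group_id, members, records, provenance = list()) {
  if (length(records) == 0L)
    stop("a group database must contain at least one reference record")
  dims <- vapply(records, function(r) length(r$theta_ref), 0L)
  if (any(dims != length(members)))
    stop("record dimensionality does not match the group's torsion count")
  th <- do.call(rbind, lapply(records, `[[`, "theta_ref"))
  if (nrow(th) > 1L) {
    for (r in 2:nrow(th)) for (s in 1:(r - 1))
      if (max(abs(wrap_deviation(th[r, ], th[s, ]))) < 1e-6)
        stop("duplicate reference point in group ", group_id,
             " (records ", s, " and ", r, ")")
  }
  structure(
    list(group_id = as.integer(group_id), members = as.integer(members),
         records = records, provenance = provenance),
    class = "lam_group_db")
}

new_lam_database <- function(molecule, vacuo, group_dbs, ledger) {
  stopifnot(inherits(molecule, "molecule_spec"),
            inherits(vacuo, "vacuo_record"))
  covered <- sort(unlist(lapply(group_dbs, `[[`, "members")))
  if (!identical(covered, seq_along(molecule$torsion_names)))
    stop("group databases do not cover the molecule's torsion set")
  structure(
    list(molecule = molecule, vacuo = vacuo, group_dbs = group_dbs,
         ledger = ledger),
    class = "lam_database")
}

#' Nearest reference point of a group
#'
#' Returns the index of the record whose reference point minimizes the
#' Euclidean norm of the wrapped per-torsion deviations from `theta_g`.
#' Ties are broken toward the lowest record index.
#'
#' @param group_db a group database (component of a LAM database).
#' @param theta_g torsion values of the group (degrees).
#' @return integer record index.
#' @export
nearest_reference <- function(group_db, theta_g) {
  stopifnot(inherits(group_db, "lam_group_db"))
  if (length(theta_g) != length(group_db$members))
    stop("query has ", length(theta_g), " torsions but the group has ",
         length(group_db$members))
  d2 <- vapply(group_db$records, function(r)
    sum(wrap_deviation(theta_g, r$theta_ref)^2), 0)
  which.min(d2)   # which.min returns the first (lowest-index) minimum
}

#' Evaluate one group's LAM at a group conformation
#'
#' With \eqn{d} the wrapped deviation of `theta_g` from the record's
#' reference point, returns the second-order energy deviation
#' \eqn{\Delta U_g = (U_{ref} - U_{vac}) + b^T d + \tfrac12 d^T H d} and
#' the first-order dependent-DoF and charge deviations
#' \eqn{\Delta\beta_g = (\beta_{ref} - \beta_{vac}) + K d},
#' \eqn{\Delta q_g = (q_{ref} - q_{vac}) + A d}.
#'
#' @param record a `reference_record`.
#' @param theta_g group torsion values (degrees).
#' @param vacuo the owning database's `vacuo_record`.
#' @return `list(delta_U, delta_beta, delta_q, deviation)`.
#' @export
evaluate_group <- function(record, theta_g, vacuo) {
  stopifnot(inherits(record, "reference_record"),
            inherits(vacuo, "vacuo_record"))
  if (length(theta_g) != length(record$theta_ref))
    stop("dimension mismatch between query and reference record")
  d <- wrap_deviation(theta_g, record$theta_ref)
  list(delta_U = (record$U_ref - vacuo$U_vac) +
         sum(record$b * d) + 0.5 * drop(crossprod(d, record$H %*% d)),
       delta_beta = (record$beta_ref - vacuo$beta_vac) +
         drop(record$K %*% d),
       delta_q = (record$q_ref - vacuo$q_vac) + drop(record$A %*% d),
       deviation = d)
}

#' Evaluate a LAM database at a query conformation
#'
#' For each torsional group, selects the nearest reference point and
#' evaluates its Taylor model; the additivity principle then combines the
#' per-group deviations:
#' \eqn{U = U_{vac} + \sum_g \Delta U_g},
#' \eqn{\beta = \beta_{vac} + \sum_g \Delta\beta_g},
#' \eqn{q = q_{vac} + \sum_g \Delta q_g}.
#' A negative total \eqn{\Delta U} marks a conformation apparently below
#' the current in vacuo minimum (`below_vacuo` flag); confirm and absorb
#' it with [rebase_vacuo()].
#'
#' @param db a `lam_database`.
#' @param theta full torsion vector (degrees).
#' @return An object of class `lam_evaluation`: `delta_U` (kJ/mol), `U`,
#'   `beta`, `charges`, `below_vacuo`, and a `per_group` data frame with
#'   the chosen reference index and energy contribution of each group.
#' @export
lam_evaluate <- function(db, theta) {
  stopifnot(inherits(db, "lam_database"))
  check_theta(db$molecule, theta)
  theta <- wrap_angle(theta)

  delta_U <- 0
  beta <- db$vacuo$beta_vac
  charges <- db$vacuo$q_vac
  pg <- vector("list", length(db$group_dbs))
  for (k in seq_along(db$group_dbs)) {
    gdb <- db$group_dbs[[k]]
    theta_g <- theta[gdb$members]
    i <- nearest_reference(gdb, theta_g)
    ev <- evaluate_group(gdb$records[[i]], theta_g, db$vacuo)
    delta_U <- delta_U + ev$delta_U
    beta <- beta + ev$delta_beta
    charges <- charges + ev$delta_q
    pg[[k]] <- data.frame(group_id = gdb$group_id, ref_index = i,
                          delta_U = ev$delta_U)
  }
  structure(
    list(delta_U = delta_U, U = db$vacuo$U_vac + delta_U,
         beta = beta, charges = charges,
         per_group = do.call(rbind, pg),
         below_vacuo = delta_U < 0),
    class = "lam_evaluation")
}

#' @export
print.lam_evaluation <- function(x, ...) {
  cat("LAM evaluation\n")
  cat("  delta_U:", format(x$delta_U), "kJ/mol",
      if (x$below_vacuo) "(below current in vacuo minimum!)" else "", "\n")
  cat("  per-group contributions:\n")
  print(x$per_group, row.names = FALSE)
  invisible(x)
}

#' @export
print.lam_database <- function(x, ...) {
  cat("LAM database\n")
  print(x$molecule)
  cat("  U_vac:", format(x$vacuo$U_vac), "kJ/mol at (",
      paste(sprintf("%.1f", x$vacuo$theta_vac), collapse = ", "), ")\n")
  for (gdb in x$group_dbs)
    cat(sprintf("  group %d: %d reference points (%s)\n", gdb$group_id,
                length(gdb$records),
                if (is.null(gdb$provenance$type)) "manual"
                else gdb$provenance$type))
  cat("  oracle calls:", ledger_total(x$ledger), "\n")
  invisible(x)
}

#' Rebase a LAM database on a newly found lower in vacuo minimum
#'
#' When evaluation (or an oracle call) indicates a conformation below the
#' current in vacuo energy, the database must be re-anchored: the
#' candidate is re-minimized without constraints, and if a lower minimum
#' is confirmed the in vacuo record is replaced and every reference record
#' is refitted with the other groups pinned to the new in vacuo torsions.
#' All incurred oracle calls are logged in the ledger (one per refitted
#' reference, plus one for the new in vacuo minimization).
#'
#' @param db a `lam_database`.
#' @param model the `conformational_model` the database was built from.
#' @param theta_new torsion vector at which a lower energy was indicated.
#' @param tol minimum confirmed energy decrease (kJ/mol) to trigger the
#'   rebase.
#' @return The updated (or, with a warning, unchanged) `lam_database`.
#' @export
rebase_vacuo <- function(db, model, theta_new, tol = 1e-9) {
  stopifnot(inherits(db, "lam_database"))
  check_theta(db$molecule, theta_new)
  cand <- minimize_vacuo(model, rbind(theta_new))
  if (cand$U_vac >= db$vacuo$U_vac - tol) {
    warning("candidate does not yield a lower in vacuo minimum ",
            "(confirmed ", format(cand$U_vac), " vs current ",
            format(db$vacuo$U_vac), " kJ/mol); database unchanged")
    return(db)
  }
  ledger <- ledger_add(db$ledger, "vacuo", NA_integer_, 1L)
  group_dbs <- db$group_dbs
  for (k in seq_along(group_dbs)) {
    gdb <- group_dbs[[k]]
    gdb$records <- lapply(gdb$records, function(r)
      fit_reference(model, db$molecule, gdb$group_id, r$theta_ref, cand))
    ledger <- ledger_add(ledger, "rebase_refit", gdb$group_id,
                         length(gdb$records))
    group_dbs[[k]] <- gdb
  }
  new_lam_database(db$molecule, cand, group_dbs, ledger)
}
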