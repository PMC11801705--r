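#' Declare a molecule's flexible-torsion model
#'
#' A `molecule_spec` names the flexible (independent) torsions of a
#' molecule, partitions them into torsional groups assumed to contribute
#' additively to conformational deviations, and declares the schemas of the
#' dependent degrees of freedom (bond lengths, bond angles and non-flexible
#' torsions that relax at fixed independent torsions) and of the atomic
#' point charges.
#'
#' @param torsion_names character vector naming the `l` independent
#'   torsions, in order.
#' @param groups list of integer vectors partitioning `seq_along(torsion_names)`
#'   into disjoint, covering, non-empty torsional groups.
#' @param dependent_dofs data frame with columns `label` and `category`
#'   (one of `"bond_length"`, `"bond_angle"`, `"torsion"`) describing the
#'   dependent degrees of freedom. Units are Angstrom for bond lengths and
#'   degrees for angles/torsions.
#' @param charge_atoms character vector of atom labels, each carrying one
#'   scalar point charge (e).
#'
#' @return An object of class `molecule_spec`.
#' @export
molecule_spec <- function(torsion_names, groups, dependent_dofs, charge_atoms) {
  stopifnot(is.character(torsion_names), length(torsion_names) >= 1L,
            !anyDuplicated(torsion_names))
  l <- length(torsion_names)

  if (!is.list(groups) || length(groups) < 1L)
    stop("'groups' must be a non-empty list of index vectors")
  groups <- lapply(groups, function(g) as.integer(g))
  if (any(lengths(groups) == 0L)) stop("torsional groups must be non-empty")
  idx <- sort(unlist(groups))
  if (!identical(idx, seq_len(l)))
    stop("'groups' must partition the torsion indices 1..", l,
         " with each index in exactly one group")

  dependent_dofs <- as.data.frame(dependent_dofs, stringsAsFactors = FALSE)
  if (!all(c("label", "category") %in% names(dependent_dofs)))
    stop("'dependent_dofs' needs columns 'label' and 'category'")
  if (nrow(dependent_dofs) == 0L) stop("dependent-DoF schema must be non-empty")
  if (anyDuplicated(dependent_dofs$label)) stop("duplicate dependent-DoF labels")
  ok <- dependent_dofs$category %in% c("bond_length", "bond_angle", "torsion")
  if (!all(ok))
    stop("unknown dependent-DoF category: ",
         paste(unique(dependent_dofs$category[!ok]), collapse = ", "))
  dependent_dofs$unit <- ifelse(dependent_dofs$category == "bond_length",
                                "angstrom", "degrees")

  stopifnot(is.character(charge_atoms), length(charge_atoms) >= 1L,
            !anyDuplicated(charge_atoms))

  structure(
    list(torsion_names = torsion_names,
         groups = groups,
         dependent_dofs = dependent_dofs,
         charge_atoms = charge_atoms),
    class = "molecule_spec")
}

#' Number of independent torsions, groups, dependent DoFs and charges
#' @param molecule a [molecule_spec()].
#' @return named integer vector with elements `torsions`, `groups`,
#'   `dependent_dofs`, `charges`.
#' @export
molecule_dims <- function(molecule) {
  stopifnot(inherits(molecule, "molecule_spec"))
  c(torsions = length(molecule$torsion_names),
    groups = length(molecule$groups),
    dependent_dofs = nrow(molecule$dependent_dofs),
    charges = length(molecule$charge_atoms))
}

#' @export
print.molecule_spec <- function(x, ...) {
  d <- molecule_dims(x)
  cat("Molecule torsion model\n")
  cat("  independent torsions:", d[["torsions"]],
      paste0("(", paste(x$torsion_names, collapse = ", "), ")"), "\n")
  cat("  torsional groups:    ", d[["groups"]], "\n")
  for (g in seq_along(x$groups))
    cat(sprintf("    group %d: {%s}\n", g,
                paste(x$torsion_names[x$groups[[g]]], collapse = ", ")))
  cat("  dependent DoFs:      ", d[["dependent_dofs"]],
      sprintf("(%d bond lengths, %d bond angles, %d torsions)\n",
              sum(x$dependent_dofs$category == "bond_length"),
              sum(x$dependent_dofs$category == "bond_angle"),
              sum(x$dependent_dofs$category == "torsion")))
  cat("  point charges:       ", d[["charges"]], "atoms\n")
  invisible(x)
}

# Return a copy of `molecule` with all torsions merged into a single group,
# used when building a non-partitioned database.
merge_groups <- function(molecule) {
  molecule$groups <- list(seq_along(molecule$torsion_names))
  molecule
}

# Check that `theta` is a valid full torsion vector for `molecule`.
check_theta <- function(molecule, theta) {
  l <- length(molecule$torsion_names)
  if (!is.numeric(theta) || length(theta) != l)
    stop("theta must be numeric of length ", l, " (one value per torsion)")
  if (!all(is.finite(theta))) stop("theta contains non-finite values")
  invisible(TRUE)
}
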