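#' @title Database archives and configuration I/O
#' @name cli-io
#' @description A LAM database built from thousands of oracle calls is an
#'   asset; it is serialized to a single-file archive with an explicit
#'   format version, validated on load, and flagged when its records
#'   predate an in vacuo rebase. Molecule specifications travel as YAML.
NULL

LAM_ARCHIVE_VERSION <- 1L

#' Save / load a LAM database archive
#'
#' `save_lam_database()` writes the complete database -- molecule
#' specification, in vacuo record, every reference record with its
#' derivative blocks, the oracle-call ledger and all provenance -- to a
#' single archive file (RDS container). The round trip is lossless: every
#' numeric field is reproduced bit-exactly. `load_lam_database()` checks
#' the format version, re-validates the structural invariants, optionally
#' checks the archive against an expected molecule specification, and
#' flags databases whose reference energies fall below the stored in
#' vacuo energy (stale, pre-rebase records).
#'
#' @param db a `lam_database`.
#' @param path archive file path.
#' @param molecule optional `molecule_spec` the archive must match.
#' @return `save_lam_database()`: `path`, invisibly.
#'   `load_lam_database()`: the `lam_database`; attribute `"stale"` is
#'   `TRUE` (with a warning) if any reference lies below the in vacuo
#'   energy.
#' @export
save_lam_database <- function(db, path) {
  stopifnot(inherits(db, "lam_database"))
  archive <- list(format_version = LAM_ARCHIVE_VERSION,
                  package_version = as.character(utils::packageVersion("lampart")),
                  database = db)
  saveRDS(archive, path)
  invisible(path)
}

#' @rdname save_lam_database
#' @export
load_lam_database <- function(path, molecule = NULL) {
  archive <- tryCatch(readRDS(path),
                      error = function(e) stop("corrupted or unreadable archive: ",
                                               conditionMessage(e)))
  if (!is.list(archive) || is.null(archive$format_version))
    stop("not a LAM database archive: ", path)
  if (archive$format_version != LAM_ARCHIVE_VERSION)
    stop("archive format version ", archive$format_version,
         " is not supported (expected ", LAM_ARCHIVE_VERSION, ")")
  db <- archive$database
  if (!inherits(db, "lam_database")) stop("archive payload is not a LAM database")

  # re-validate structural invariants
  db <- new_lam_database(db$molecule, db$vacuo, db$group_dbs, db$ledger)

  if (!is.null(molecule)) {
    stopifnot(inherits(molecule, "molecule_spec"))
    same <- identical(molecule$torsion_names, db$molecule$torsion_names) &&
      identical(molecule$dependent_dofs$label, db$molecule$dependent_dofs$label) &&
      identical(molecule$charge_atoms, db$molecule$charge_atoms)
    if (!same)
      stop("archive molecule specification does not match the expected schema")
  }

  u_min <- min(vapply(db$group_dbs, function(g)
    min(vapply(g$records, `[[`, 0, "U_ref")), 0))
  if (u_min < db$vacuo$U_vac - 1e-9) {
    warning("database contains references below the stored in vacuo energy; ",
            "flagged stale -- rebase with rebase_vacuo()")
    attr(db, "stale") <- TRUE
  } else attr(db, "stale") <- FALSE
  db
}

#' Export the oracle-call ledger as TSV
#' @param ledger a `call_ledger`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ledger_tsv <- function(ledger, path) {
  stopifnot(inherits(ledger, "call_ledger"))
  utils::write.table(as.data.frame(ledger), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a molecule specification as YAML
#'
#' The YAML document carries the torsion names, the group partition, the
#' dependent-DoF schema with categories (units are implied: Angstrom for
#' bond lengths, degrees otherwise) and the charge-carrying atom labels.
#'
#' @param molecule a [molecule_spec()].
#' @param path YAML file path.
#' @return `write_molecule_yaml()`: `path`, invisibly;
#'   `read_molecule_yaml()`: a `molecule_spec`.
#' @export
write_molecule_yaml <- function(molecule, path) {
  stopifnot(inherits(molecule, "molecule_spec"))
  doc <- list(
    torsions = as.list(molecule$torsion_names),
    groups = lapply(molecule$groups, as.list),
    dependent_dofs = lapply(seq_len(nrow(molecule$dependent_dofs)),
                            function(i) list(
                              label = molecule$dependent_dofs$label[i],
                              category = molecule$dependent_dofs$category[i])),
    charge_atoms = as.list(molecule$charge_atoms))
  writeLines(yaml::as.yaml(doc), path)
  invisible(path)
}

#' @rdname write_molecule_yaml
#' @export
read_molecule_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  req <- c("torsions", "groups", "dependent_dofs", "charge_atoms")
  if (!all(req %in% names(doc)))
    stop("molecule YAML must define: ", paste(req, collapse = ", "))
  molecule_spec(
    torsion_names = unlist(doc$torsions),
    groups = lapply(doc$groups, unlist),
    dependent_dofs = data.frame(
      label = vapply(doc$dependent_dofs, `[[`, "", "label"),
      category = vapply(doc$dependent_dofs, `[[`, "", "category")),
    charge_atoms = unlist(doc$charge_atoms))
}
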