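#' @title Accuracy-assessment protocol
#' @description Implements the standard protocol for judging a LAM
#'   database against its oracle: draw conformations uniformly over
#'   torsion space, discard those outside the crystallographically
#'   relevant energy region (above a 20 kJ/mol ceiling by default), then
#'   compare LAM and oracle predictions point by point, aggregating
#'   average absolute deviations per property category, the maximum
#'   energy error, and the parity R-squared.
#' @name accuracy
NULL

#' Sample conformations uniformly over torsion space
#'
#' @param molecule a [molecule_spec()].
#' @param n number of conformations (2000 is the conventional choice for
#'   the assessment protocol).
#' @param seed integer seed; the caller's RNG state is untouched.
#' @return numeric matrix `n x l`, components i.i.d. uniform on `[0, 360)`.
#' @export
sample_uniform <- function(molecule, n, seed) {
  stopifnot(inherits(molecule, "molecule_spec"), n >= 1)
  l <- length(molecule$torsion_names)
  with_seed(seed, matrix(stats::runif(n * l, 0, 360), nrow = n))
}

#' Filter samples to the crystallographically relevant region
#'
#' Performs the oracle minimization at each sampled conformation and
#' retains those with energy at most `cutoff` above the in vacuo minimum.
#' The oracle records are cached for reuse by [assess_accuracy()], so the
#' assessment costs one oracle call per sample in total.
#'
#' @param model a `conformational_model`.
#' @param vacuo the `vacuo_record` anchoring energy differences.
#' @param samples matrix of conformations (one per row, degrees).
#' @param cutoff relevance ceiling (kJ/mol, default 20).
#' @return `list(samples, records, delta_U, n_sampled, n_retained, cutoff)`
#'   where `samples` are the retained rows and `records` the matching
#'   oracle records.
#' @export
filter_relevant <- function(model, vacuo, samples, cutoff = 20) {
  stopifnot(inherits(vacuo, "vacuo_record"), is.numeric(cutoff), cutoff > 0)
  samples <- as.matrix(samples)
  records <- lapply(seq_len(nrow(samples)), function(r)
    minimize_at(model, samples[r, ]))
  du <- vapply(records, function(rec) rec$energy - vacuo$U_vac, 0)
  keep <- du <= cutoff
  list(samples = samples[keep, , drop = FALSE],
       records = records[keep],
       delta_U = du[keep],
       n_sampled = nrow(samples),
       n_retained = sum(keep),
       cutoff = cutoff)
}

#' Compare LAM predictions with the oracle over retained samples
#'
#' For each retained conformation the LAM database and the oracle are
#' both evaluated; errors are aggregated as average absolute deviations
#' (AAD) per property category -- intramolecular energy (kJ/mol), bond
#' lengths (Angstrom), bond angles (degrees), dependent torsions
#' (degrees, wrapped), charges (e) -- together with the maximum absolute
#' energy error and the squared Pearson correlation of the energy parity
#' scatter. Angular errors are wrapped into `(-180, 180]` before taking
#' magnitudes, so no angle error can exceed 180 degrees. The dependent
#' (non-flexible) torsions are the ones compared: the independent
#' torsions are inputs, fixed per sample by construction.
#'
#' @param db a `lam_database`.
#' @param model the oracle the database approximates.
#' @param retained output of [filter_relevant()], or a plain matrix of
#'   conformations (oracle records are then computed here).
#' @param seed optional seed to record in the report (provenance only).
#' @return An object of class `accuracy_report`.
#' @export
assess_accuracy <- function(db, model, retained, seed = NULL) {
  stopifnot(inherits(db, "lam_database"))
  if (is.matrix(retained) || is.data.frame(retained))
    retained <- list(samples = as.matrix(retained),
                     records = lapply(seq_len(nrow(as.matrix(retained))),
                                      function(r) minimize_at(model, as.matrix(retained)[r, ])),
                     n_sampled = nrow(as.matrix(retained)),
                     n_retained = nrow(as.matrix(retained)),
                     cutoff = Inf)
  n <- nrow(retained$samples)
  if (n == 0L) stop("no retained samples to assess")

  cat_of <- db$molecule$dependent_dofs$category
  is_angle <- cat_of %in% c("bond_angle", "torsion")

  du_lam <- numeric(n); du_or <- numeric(n)
  err_beta <- matrix(0, n, length(cat_of))
  err_q <- numeric(n)
  for (r in seq_len(n)) {
    ev <- lam_evaluate(db, retained$samples[r, ])
    rec <- retained$records[[r]]
    du_lam[r] <- ev$delta_U
    du_or[r] <- rec$energy - db$vacuo$U_vac
    e <- ev$beta - rec$beta
    e[is_angle] <- wrap_deviation(ev$beta[is_angle], rec$beta[is_angle])
    err_beta[r, ] <- abs(e)
    err_q[r] <- mean(abs(ev$charges - rec$charges))
  }

  aad_cat <- function(category) {
    sel <- cat_of == category
    if (!any(sel)) return(NA_real_)
    mean(err_beta[, sel, drop = FALSE])
  }
  r2 <- if (isTRUE(all.equal(du_lam, du_or, tolerance = 1e-12))) 1
        else if (stats::sd(du_lam) == 0 || stats::sd(du_or) == 0) NA_real_
        else stats::cor(du_lam, du_or)^2

  structure(
    list(n_sampled = retained$n_sampled,
         n_retained = n,
         cutoff = retained$cutoff,
         aad = c(energy = mean(abs(du_lam - du_or)),
                 bond_length = aad_cat("bond_length"),
                 bond_angle = aad_cat("bond_angle"),
                 torsion = aad_cat("torsion"),
                 charge = mean(err_q)),
         max_energy_error = max(abs(du_lam - du_or)),
         r_squared = r2,
         parity = data.frame(oracle = du_or, lam = du_lam),
         seed = seed),
    class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("LAM accuracy report\n")
  cat(sprintf("  %d of %d sampled conformations within %s kJ/mol of vacuo\n",
              x$n_retained, x$n_sampled, format(x$cutoff)))
  cat("  average absolute deviations:\n")
  cat(sprintf("    energy        %.4g kJ/mol\n", x$aad[["energy"]]))
  if (!is.na(x$aad[["bond_length"]]))
    cat(sprintf("    bond lengths  %.4g A\n", x$aad[["bond_length"]]))
  if (!is.na(x$aad[["bond_angle"]]))
    cat(sprintf("    bond angles   %.4g deg\n", x$aad[["bond_angle"]]))
  if (!is.na(x$aad[["torsion"]]))
    cat(sprintf("    torsions      %.4g deg\n", x$aad[["torsion"]]))
  cat(sprintf("    charges       %.4g e\n", x$aad[["charge"]]))
  cat(sprintf("  max |energy error|: %.4g kJ/mol\n", x$max_energy_error))
  cat(sprintf("  parity R^2: %.6f\n", x$r_squared))
  invisible(x)
}

#' Export an accuracy report
#'
#' Writes the aggregate statistics as TSV or JSON, and optionally the
#' parity scatter (oracle vs LAM energy differences) as CSV for plotting.
#'
#' @param report an `accuracy_report`.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @param parity_path optional CSV path for the parity scatter.
#' @return `path`, invisibly.
#' @export
write_accuracy_report <- function(report, path, format = c("tsv", "json"),
                                  parity_path = NULL) {
  stopifnot(inherits(report, "accuracy_report"))
  format <- match.arg(format)
  stats <- list(n_sampled = report$n_sampled,
                n_retained = report$n_retained,
                cutoff_kj_mol = report$cutoff,
                aad_energy_kj_mol = report$aad[["energy"]],
                aad_bond_length_angstrom = report$aad[["bond_length"]],
                aad_bond_angle_deg = report$aad[["bond_angle"]],
                aad_torsion_deg = report$aad[["torsion"]],
                aad_charge_e = report$aad[["charge"]],
                max_energy_error_kj_mol = report$max_energy_error,
                r_squared = report$r_squared,
                seed = if (is.null(report$seed)) NA else report$seed)
  if (format == "tsv") {
    df <- data.frame(statistic = names(stats),
                     value = vapply(stats, function(v)
                       if (is.na(v)) NA_real_ else as.numeric(v), 0))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(stats, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(parity_path))
    utils::write.csv(report$parity, parity_path, row.names = FALSE)
  invisible(path)
}
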