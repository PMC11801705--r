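#' @title Reference grids, database construction and call accounting
#' @description Uniform reference grids in the two dialects used in
#'   practice (bounded `[lower, increment, upper]` ranges, and wraparound
#'   spacings over the full circle), Cartesian-product grid generation,
#'   partitioned and non-partitioned database builders with an oracle-call
#'   ledger, pure combinatorial call-count projections, and the adaptive
#'   refinement variant.
#' @name grids
NULL

# --- call ledger -----------------------------------------------------------

#' Oracle-call ledger
#'
#' Tracks the number of constrained-minimization oracle calls by purpose:
#' `"vacuo"` (in vacuo minimizations, counted once per established
#' minimum), `"reference_fit"` (uniform-grid reference fits, per group),
#' `"adaptive_fit"` (references added by adaptive refinement),
#' `"adaptive_probe"` (adaptive candidates probed but not added) and
#' `"rebase_refit"` (refits after an in vacuo rebase). The total never
#' decreases.
#'
#' @param ledger a `call_ledger`.
#' @param purpose,group_id,n entry to add.
#' @param purposes optional subset of purposes to total over.
#' @return `ledger_new()` an empty ledger; `ledger_add()` the updated
#'   ledger; `ledger_total()` the integer call total.
#' @export
ledger_new <- function() {
  structure(
    data.frame(purpose = character(), group_id = integer(),
               count = integer()),
    class = c("call_ledger", "data.frame"))
}

#' @rdname ledger_new
#' @export
ledger_add <- function(ledger, purpose, group_id = NA_integer_, n = 1L) {
  stopifnot(inherits(ledger, "call_ledger"), n >= 0)
  if (n == 0L) return(ledger)
  out <- rbind(as.data.frame(ledger),
               data.frame(purpose = purpose,
                          group_id = as.integer(group_id),
                          count = as.integer(n)))
  structure(out, class = c("call_ledger", "data.frame"))
}

#' @rdname ledger_new
#' @export
ledger_total <- function(ledger, purposes = NULL) {
  stopifnot(inherits(ledger, "call_ledger"))
  x <- as.data.frame(ledger)
  if (!is.null(purposes)) x <- x[x$purpose %in% purposes, , drop = FALSE]
  sum(x$count)
}

#' @export
print.call_ledger <- function(x, ...) {
  cat("Oracle-call ledger (total", ledger_total(x), "minimizations)\n")
  if (nrow(x)) {
    agg <- stats::aggregate(count ~ purpose, data = as.data.frame(x), sum)
    print(agg, row.names = FALSE)
  }
  invisible(x)
}

# --- grid specifications ---------------------------------------------------

#' Per-torsion reference-grid specifications
#'
#' Two dialects are supported. `grid_bounded(lower, increment, upper)`
#' spans a closed range with inclusive endpoints, e.g.
#' `grid_bounded(60, 120, 300)` gives `{60, 180, 300}`;
#' `grid_wraparound(increment, offset)` spans the full circle, e.g. a 60
#' degree spacing with the first point at 30 degrees gives
#' `{30, 90, 150, 210, 270, 330}`. `grid_points()` takes an explicit point
#' list. Generated points are stored wrapped into `[0, 360)`.
#'
#' @param lower,increment,upper bounded-range parameters (degrees);
#'   `upper - lower` must be divisible by `increment`.
#' @param offset first grid point of a wraparound grid (degrees); 360 must
#'   be divisible by `increment`.
#' @param points explicit point list (degrees).
#' @return An object of class `grid_spec`.
#' @export
grid_bounded <- function(lower, increment, upper) {
  stopifnot(is.numeric(lower), is.numeric(increment), is.numeric(upper),
            increment > 0, upper >= lower)
  if (abs((upper - lower) / increment -
          round((upper - lower) / increment)) > 1e-9)
    stop("(upper - lower) must be divisible by the increment")
  structure(list(dialect = "bounded", lower = lower, increment = increment,
                 upper = upper),
            class = "grid_spec")
}

#' @rdname grid_bounded
#' @export
grid_wraparound <- function(increment, offset = 0) {
  stopifnot(is.numeric(increment), increment > 0)
  if (abs(360 / increment - round(360 / increment)) > 1e-9)
    stop("360 must be divisible by the increment for a wraparound grid")
  structure(list(dialect = "wraparound", increment = increment,
                 offset = offset),
            class = "grid_spec")
}

#' @rdname grid_bounded
#' @export
grid_points <- function(points) {
  stopifnot(is.numeric(points), length(points) >= 1L)
  structure(list(dialect = "explicit", points = as.numeric(points)),
            class = "grid_spec")
}

#' Materialize the point list of a grid spec
#' @param spec a `grid_spec`.
#' @return numeric vector of grid points, wrapped into `[0, 360)`.
#' @export
grid_values <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  pts <- switch(spec$dialect,
    bounded = seq(spec$lower, spec$upper, by = spec$increment),
    wraparound = seq(spec$offset, spec$offset + 360 - spec$increment,
                     by = spec$increment),
    explicit = spec$points)
  wrap_angle(pts)
}

#' Cartesian-product grid for a torsional group
#'
#' Combines the per-torsion point lists of a group into the full set of
#' group reference points, in deterministic lexicographic order (first
#' torsion most significant).
#'
#' @param specs list of `grid_spec` objects, one per group member, or a
#'   single `grid_spec` recycled over all members.
#' @param members integer indices of the group's torsions (only the count
#'   is used).
#' @return numeric matrix, one reference point per row.
#' @export
build_uniform_grid <- function(specs, members) {
  k <- length(members)
  if (inherits(specs, "grid_spec")) specs <- rep(list(specs), k)
  stopifnot(length(specs) == k)
  pts <- lapply(specs, grid_values)
  if (any(lengths(pts) == 0L)) stop("empty per-torsion grid")
  g <- do.call(expand.grid, rev(pts))          # last torsion varies fastest
  m <- as.matrix(g[, rev(seq_len(k)), drop = FALSE])
  dimnames(m) <- NULL
  m
}

# normalize a group grid argument into a matrix of reference points
as_grid_matrix <- function(grid, members) {
  if (is.matrix(grid)) {
    stopifnot(ncol(grid) == length(members))
    return(grid)
  }
  if (inherits(grid, "grid_spec")) return(build_uniform_grid(grid, members))
  if (is.list(grid)) return(build_uniform_grid(grid, members))
  if (is.numeric(grid) && length(members) == 1L)
    return(matrix(grid, ncol = 1L))
  stop("cannot interpret grid specification")
}

# --- database builders -----------------------------------------------------

#' Build the reference set of one torsional group
#'
#' Performs one constrained-minimization fit per grid point, with all
#' other groups held at their in vacuo torsions.
#'
#' @param model a `conformational_model`.
#' @param molecule a [molecule_spec()].
#' @param group_id group index.
#' @param grid per-torsion `grid_spec` list, a single spec, or an explicit
#'   matrix of reference points (one per row).
#' @param vacuo a `vacuo_record`.
#' @return A group database whose `"calls"` attribute holds the number of
#'   oracle fits performed.
#' @export
build_group_database <- function(model, molecule, group_id, grid, vacuo) {
  members <- molecule$groups[[group_id]]
  pts <- as_grid_matrix(grid, members)
  if (nrow(pts) == 0L) stop("empty grid for group ", group_id)
  records <- lapply(seq_len(nrow(pts)), function(r)
    fit_reference(model, molecule, group_id, pts[r, ], vacuo))
  gdb <- new_group_database(group_id, members, records,
                            provenance = list(type = "uniform",
                                              grid = grid))
  attr(gdb, "calls") <- nrow(pts)
  gdb
}

#' Build a partitioned or non-partitioned LAM database
#'
#' `build_partitioned_database()` minimizes the in vacuo conformation and
#' then fits each torsional group's references independently, with all
#' other groups pinned at the in vacuo torsions; the oracle-call total is
#' the sum of per-group grid sizes plus one. `build_full_database()`
#' instead merges all torsions into a single group, so the grid is the
#' Cartesian product over every torsion and the call total is the product
#' of the per-torsion counts plus one.
#'
#' @param model a `conformational_model`.
#' @param molecule a [molecule_spec()].
#' @param grids for the partitioned build, a list with one entry per group
#'   (each a per-torsion `grid_spec` list, single spec, or point matrix);
#'   for the full build, a per-torsion `grid_spec` list (or nested
#'   per-group lists, which are flattened in torsion order).
#' @param vacuo optional precomputed `vacuo_record`; when absent it is
#'   computed from `starts`.
#' @param starts start points for the in vacuo search (default: every
#'   torsion at 180 degrees). However found, the in vacuo minimization is
#'   accounted as one oracle call.
#' @return A `lam_database` with a populated call ledger.
#' @export
build_partitioned_database <- function(model, molecule, grids,
                                       vacuo = NULL, starts = NULL) {
  stopifnot(inherits(molecule, "molecule_spec"))
  n_g <- length(molecule$groups)
  if (length(grids) != n_g)
    stop("'grids' must supply one grid per torsional group (", n_g, ")")
  if (is.null(vacuo)) {
    if (is.null(starts))
      starts <- rbind(rep(180, length(molecule$torsion_names)))
    vacuo <- minimize_vacuo(model, starts)
  }
  ledger <- ledger_add(ledger_new(), "vacuo", NA_integer_, 1L)
  group_dbs <- vector("list", n_g)
  for (g in seq_len(n_g)) {
    gdb <- build_group_database(model, molecule, g, grids[[g]], vacuo)
    ledger <- ledger_add(ledger, "reference_fit", g, attr(gdb, "calls"))
    group_dbs[[g]] <- gdb
  }
  new_lam_database(molecule, vacuo, group_dbs, ledger)
}

#' @rdname build_partitioned_database
#' @export
build_full_database <- function(model, molecule, grids,
                                vacuo = NULL, starts = NULL) {
  stopifnot(inherits(molecule, "molecule_spec"))
  l <- length(molecule$torsion_names)
  specs <- flatten_grid_specs(grids, l)
  mol_full <- merge_groups(molecule)
  build_partitioned_database(model, mol_full, list(specs),
                             vacuo = vacuo, starts = starts)
}

flatten_grid_specs <- function(grids, l) {
  if (inherits(grids, "grid_spec")) return(rep(list(grids), l))
  flat <- list()
  for (g in grids) {
    if (inherits(g, "grid_spec")) flat <- c(flat, list(g))
    else flat <- c(flat, g)
  }
  if (length(flat) != l)
    stop("expected ", l, " per-torsion grid specs, got ", length(flat))
  flat
}

# --- projections and reductions -------------------------------------------

#' Project oracle-call counts without performing any calls
#'
#' Pure combinatorics of the two construction schemes. Given per-group
#' grids (or plain per-group record counts, as produced by adaptive
#' refinement), reports the per-group reference counts, the partitioned
#' call total (sum + 1 for the in vacuo minimization), the full
#' (non-partitioned) call total when per-torsion grids are available
#' (product + 1), and the full-equivalent database size for adaptive
#' databases (the product of per-group record counts).
#'
#' @param grids list with one entry per group: per-torsion `grid_spec`
#'   list, a single spec with a `members` count... or simply a single
#'   number of records in that group.
#' @param members optional list of group member indices (needed only when
#'   a single `grid_spec` is to be recycled over a group's torsions).
#' @return `list(per_group, partitioned_total, full_total, full_equivalent)`;
#'   `full_total` is `NA` when only per-group record counts were given.
#' @export
projected_call_counts <- function(grids, members = NULL) {
  per_torsion <- list()
  per_group <- numeric(length(grids))
  have_torsion_counts <- TRUE
  for (g in seq_along(grids)) {
    gr <- grids[[g]]
    if (is.numeric(gr) && length(gr) == 1L && !inherits(gr, "grid_spec")) {
      per_group[g] <- gr
      have_torsion_counts <- FALSE
    } else {
      if (inherits(gr, "grid_spec")) {
        k <- if (is.null(members)) 1L else length(members[[g]])
        gr <- rep(list(gr), k)
      }
      counts <- vapply(gr, function(s) length(grid_values(s)), 0L)
      per_torsion <- c(per_torsion, list(counts))
      per_group[g] <- prod(counts)
    }
  }
  list(per_group = per_group,
       partitioned_total = sum(per_group) + 1,
       full_total = if (have_torsion_counts)
         prod(unlist(per_torsion)) + 1 else NA_real_,
       full_equivalent = prod(per_group))
}

#' Percent reduction in oracle calls achieved by partitioning
#' @param n_full call count of the non-partitioned scheme.
#' @param n_partitioned call count of the partitioned scheme.
#' @return percentage, `100 * (n_full - n_partitioned) / n_full`.
#' @export
percent_reduction <- function(n_full, n_partitioned) {
  stopifnot(n_full > 0)
  100 * (n_full - n_partitioned) / n_full
}

# --- adaptive refinement ---------------------------------------------------

# Halton low-discrepancy sequence (radical-inverse in the first k primes),
# with a seeded Cranley-Patterson rotation so runs are deterministic given
# the seed yet distinct across seeds.
halton_points <- function(n, dim, start_index = 1L, shift = NULL) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37)
  if (dim > length(primes)) stop("Halton sequence limited to ",
                                 length(primes), " dimensions")
  radical_inverse <- function(i, base) {
    f <- 1 / base; r <- 0
    while (i > 0) { r <- r + f * (i %% base); i <- i %/% base; f <- f / base }
    r
  }
  idx <- seq.int(start_index, length.out = n)
  m <- vapply(seq_len(dim), function(d)
    vapply(idx, radical_inverse, 0, base = primes[d]), numeric(n))
  m <- matrix(m, nrow = n)
  if (!is.null(shift)) m <- sweep(m, 2, shift, `+`) %% 1
  m
}

#' Adaptively refine a group's reference set
#'
#' Refinement variant for non-uniform reference sets: candidate
#' conformations of the group are drawn from a seeded low-discrepancy
#' (Halton) sequence over the group's domain, with all other groups held
#' at their in vacuo torsions. Candidates whose oracle energy exceeds the
#' crystallographic-relevance cutoff `delta_star_star` are skipped; a new
#' reference is inserted wherever the current LAM's energy error exceeds
#' the tolerance `delta_star`. The sweep loop stops when a full sweep adds
#' no points (converged) or the candidate budget is exhausted (flagged
#' non-converged). Runs are deterministic given `seed`.
#'
#' @param model a `conformational_model`.
#' @param molecule a [molecule_spec()].
#' @param db a `lam_database` already holding an initial grid for the
#'   group.
#' @param group_id group to refine.
#' @param delta_star LAM energy-error tolerance (kJ/mol; default 5).
#' @param delta_star_star crystallographic-relevance cutoff on the oracle
#'   energy above the in vacuo minimum (kJ/mol; default 20).
#' @param candidate_budget maximum number of candidates to probe.
#' @param sweep_size candidates per convergence sweep.
#' @param domain optional 2-column matrix of per-torsion `[lower, upper]`
#'   bounds (degrees); default is the full circle per torsion.
#' @param seed integer seed for the candidate sequence.
#' @return The updated `lam_database`; the refined group's provenance
#'   records type `"adaptive"`, the per-sweep history, the seed and a
#'   `converged` flag, and the ledger gains `"adaptive_probe"` /
#'   `"adaptive_fit"` entries.
#' @export
adaptive_refine <- function(model, molecule, db, group_id,
                            delta_star = 5, delta_star_star = 20,
                            candidate_budget = 400, sweep_size = 50,
                            domain = NULL, seed = 1) {
  stopifnot(inherits(db, "lam_database"))
  k <- which(vapply(db$group_dbs, `[[`, 0L, "group_id") == group_id)
  if (length(k) != 1L) stop("group ", group_id, " not found in database")
  gdb <- db$group_dbs[[k]]
  dim_g <- length(gdb$members)
  if (is.null(domain)) domain <- cbind(rep(0, dim_g), rep(360, dim_g))
  stopifnot(is.matrix(domain), nrow(domain) == dim_g, ncol(domain) == 2L)

  shift <- with_seed(seed, stats::runif(dim_g))
  ledger <- db$ledger
  history <- list()
  probes <- 0L; added <- 0L; pos <- 1L
  converged <- FALSE

  while (probes < candidate_budget) {
    n_sweep <- min(sweep_size, candidate_budget - probes)
    u <- halton_points(n_sweep, dim_g, start_index = pos, shift = shift)
    pos <- pos + n_sweep
    cand <- sweep(sweep(u, 2, domain[, 2] - domain[, 1], `*`),
                  2, domain[, 1], `+`)
    added_this_sweep <- 0L
    max_err_seen <- 0
    for (r in seq_len(nrow(cand))) {
      theta_g <- wrap_angle(cand[r, ])
      theta <- db$vacuo$theta_vac
      theta[gdb$members] <- theta_g
      rec <- minimize_at(model, theta)
      probes <- probes + 1L
      du_oracle <- rec$energy - db$vacuo$U_vac
      if (du_oracle > delta_star_star) {
        ledger <- ledger_add(ledger, "adaptive_probe", group_id, 1L)
        next
      }
      i <- nearest_reference(gdb, theta_g)
      du_lam <- evaluate_group(gdb$records[[i]], theta_g, db$vacuo)$delta_U
      err <- abs(du_lam - du_oracle)
      max_err_seen <- max(max_err_seen, err)
      if (err > delta_star) {
        new_rec <- structure(
          list(group_id = group_id, theta_ref = theta_g,
               U_ref = rec$energy, beta_ref = rec$beta, q_ref = rec$charges,
               b = rec$grad_energy[gdb$members],
               H = rec$hess_energy[gdb$members, gdb$members, drop = FALSE],
               K = rec$jac_beta[, gdb$members, drop = FALSE],
               A = rec$jac_charges[, gdb$members, drop = FALSE]),
          class = "reference_record")
        gdb$records <- c(gdb$records, list(new_rec))
        added <- added + 1L
        added_this_sweep <- added_this_sweep + 1L
        ledger <- ledger_add(ledger, "adaptive_fit", group_id, 1L)
      } else {
        ledger <- ledger_add(ledger, "adaptive_probe", group_id, 1L)
      }
    }
    history[[length(history) + 1L]] <-
      data.frame(sweep = length(history) + 1L, probed = n_sweep,
                 added = added_this_sweep, max_err_relevant = max_err_seen)
    if (added_this_sweep == 0L) { converged <- TRUE; break }
  }
  if (!converged)
    warning("adaptive refinement of group ", group_id,
            " exhausted its candidate budget without a clean sweep")

  gdb$provenance <- list(type = "adaptive",
                         initial = gdb$provenance,
                         history = do.call(rbind, history),
                         delta_star = delta_star,
                         delta_star_star = delta_star_star,
                         seed = seed, converged = converged)
  db$group_dbs[[k]] <- gdb
  db$ledger <- ledger
  db
}

#' Dense validation scan of a group's LAM error
#'
#' Scans the group's domain on a regular grid (1 degree by default for
#' one-dimensional groups), evaluates the LAM and the oracle at each scan
#' point (other groups at in vacuo), and returns the maximum absolute
#' energy error over the crystallographically relevant points.
#'
#' @inheritParams adaptive_refine
#' @param step scan step (degrees).
#' @param cutoff relevance cutoff (kJ/mol); scan points whose oracle
#'   energy above in vacuo exceeds it are ignored.
#' @return `list(max_error, n_scanned, n_relevant)`.
#' @export
validation_scan <- function(model, db, group_id, step = 1,
                            cutoff = 20, domain = NULL) {
  k <- which(vapply(db$group_dbs, `[[`, 0L, "group_id") == group_id)
  if (length(k) != 1L) stop("group ", group_id, " not found in database")
  gdb <- db$group_dbs[[k]]
  dim_g <- length(gdb$members)
  if (is.null(domain)) domain <- cbind(rep(0, dim_g), rep(360, dim_g))
  axes <- lapply(seq_len(dim_g), function(d)
    seq(domain[d, 1], domain[d, 2] - step, by = step))
  pts <- as.matrix(do.call(expand.grid, axes))
  max_err <- 0; n_rel <- 0L
  for (r in seq_len(nrow(pts))) {
    theta_g <- wrap_angle(pts[r, ])
    theta <- db$vacuo$theta_vac
    theta[gdb$members] <- theta_g
    du_oracle <- minimize_at(model, theta)$energy - db$vacuo$U_vac
    if (du_oracle > cutoff) next
    n_rel <- n_rel + 1L
    i <- nearest_reference(gdb, theta_g)
    du_lam <- evaluate_group(gdb$records[[i]], theta_g, db$vacuo)$delta_U
    max_err <- max(max_err, abs(du_lam - du_oracle))
  }
  list(max_error = max_err, n_scanned = nrow(pts), n_relevant = n_rel)
}
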