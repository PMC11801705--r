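test_that("both grid dialects generate the documented point sets", {
  expect_equal(grid_values(grid_wraparound(60, 30)),
               c(30, 90, 150, 210, 270, 330))
  expect_equal(grid_values(grid_bounded(0, 180, 180)), c(0, 180))
  expect_equal(grid_values(grid_bounded(60, 120, 300)), c(60, 180, 300))
  # negative bounds wrap into [0, 360)
  expect_equal(grid_values(grid_bounded(-30, 120, 210)), c(330, 90, 210))
  expect_error(grid_bounded(0, 50, 120), "divisible")
  expect_error(grid_wraparound(50), "divisible")
  # a bounded spec covering [offset, 360 - inc + offset] equals wraparound
  expect_equal(sort(grid_values(grid_bounded(30, 60, 330))),
               sort(grid_values(grid_wraparound(60, 30))))
})

test_that("Cartesian grids are lexicographic with the stated sizes", {
  g <- build_uniform_grid(list(grid_bounded(60, 120, 300),
                               grid_bounded(0, 180, 180)), 1:2)
  expect_equal(nrow(g), 6)
  expect_equal(g[, 1], rep(c(60, 180, 300), each = 2))
  expect_equal(g[, 2], rep(c(0, 180), times = 3))
  g3 <- build_uniform_grid(grid_bounded(60, 120, 300), 1:3)
  expect_equal(nrow(g3), 27)
  expect_error(build_group_database(NULL, fixture_fig1()$molecule, 1,
                                    matrix(numeric(0), 0, 1), NULL),
               "empty")
})

test_that("worked-example call totals are reproduced by actual builds", {
  # two one-torsion groups, six points each: 12 fits + 1 vacuo
  fx <- fixture_fig1()
  db <- build_partitioned_database(fx$model, fx$molecule, fx$grids,
                                   starts = fx$starts)
  expect_equal(ledger_total(db$ledger), 13)

  # paraben-like: 6 + 36 + 1 partitioned, 216 + 1 full, ~80% saved
  fx <- fixture_paraben()
  vac <- minimize_vacuo(fx$model, fx$starts)
  dbp <- build_partitioned_database(fx$model, fx$molecule, fx$grids,
                                    vacuo = vac)
  expect_equal(ledger_total(dbp$ledger), 43)
  dbf <- build_full_database(fx$model, fx$molecule, fx$grids_full,
                             vacuo = vac)
  expect_equal(length(dbf$group_dbs[[1]]$records), 216)
  expect_equal(ledger_total(dbf$ledger), 217)
  expect_equal(round(percent_reduction(217, 43)), 80)

  # paracetamol-like bounded grids: 29 vs 76, a 62% decrease
  fx <- fixture_paracetamol()
  vac <- minimize_vacuo(fx$model, fx$starts)
  dbp <- build_partitioned_database(fx$model, fx$molecule, fx$grids,
                                    vacuo = vac)
  dbf <- build_full_database(fx$model, fx$molecule, fx$grids_full,
                             vacuo = vac)
  expect_equal(ledger_total(dbp$ledger), 29)
  expect_equal(ledger_total(dbf$ledger), 76)
  expect_equal(round(percent_reduction(76, 29)), 62)
})

test_that("restricted eight-torsion grids give 25 vs 129 calls", {
  fx <- fixture_xx(restricted = TRUE)
  vac <- minimize_vacuo(fx$model, fx$starts)
  dbp <- build_partitioned_database(fx$model, fx$molecule, fx$grids,
                                    vacuo = vac)
  expect_equal(vapply(dbp$group_dbs, function(g) length(g$records), 0L),
               c(8L, 16L))
  expect_equal(ledger_total(dbp$ledger), 25)
  proj <- projected_call_counts(fx$grids)
  expect_equal(proj$partitioned_total, 25)
  expect_equal(proj$full_total, 129)
})

test_that("projected counts cover adaptive sizes and single-group cases", {
  # adaptive per-group record counts for the eight-torsion compound
  proj <- projected_call_counts(list(334, 8461))
  expect_equal(proj$partitioned_total, 8796)
  expect_true(is.na(proj$full_total))
  expect_equal(proj$full_equivalent, 334 * 8461)
  expect_gt(proj$full_equivalent, 2.8e6)

  # seven-torsion two-group sizes: full-equivalent ~4.73 million
  proj <- projected_call_counts(list(1148, 4121))
  expect_equal(proj$full_equivalent, 4730908)

  # single group: partitioned and full projections coincide
  proj <- projected_call_counts(list(list(grid_wraparound(60, 30),
                                          grid_wraparound(60, 30))))
  expect_equal(proj$partitioned_total, proj$full_total)

  expect_equal(percent_reduction(10, 10), 0)
})

test_that("ledger arithmetic holds for random grid shapes", {
  set.seed(101)
  incs <- c(180, 120, 90, 60)
  for (rep in 1:20) {
    n_g <- sample(1:3, 1)
    sizes_per_group <- lapply(seq_len(n_g), function(g)
      360 / sample(incs, sample(1:2, 1), replace = TRUE))
    grids <- lapply(sizes_per_group, function(s)
      lapply(360 / s, grid_wraparound))
    proj <- projected_call_counts(grids)
    expect_equal(proj$partitioned_total,
                 sum(vapply(sizes_per_group, prod, 0)) + 1)
    expect_equal(proj$full_total,
                 prod(unlist(sizes_per_group)) + 1)
  }
  # the ledger total never decreases under additions
  led <- ledger_new()
  tot <- 0
  for (i in 1:10) {
    led <- ledger_add(led, sample(c("vacuo", "reference_fit"), 1), 1L,
                      sample(0:5, 1))
    expect_gte(ledger_total(led), tot)
    tot <- ledger_total(led)
  }
})

test_that("adaptive refinement converges immediately on an exact model", {
  m <- one_bowl_model(center = 180, curvature = 0.004)
  db <- build_partitioned_database(m, m$molecule,
                                   list(list(grid_wraparound(120, 60))),
                                   starts = rbind(180))
  db2 <- adaptive_refine(m, m$molecule, db, 1, seed = 5)
  prov <- db2$group_dbs[[1]]$provenance
  expect_true(prov$converged)
  expect_equal(length(db2$group_dbs[[1]]$records), 3)   # nothing added
  expect_equal(sum(prov$history$added), 0)
})

test_that("adaptive refinement drives the relevant-region error below the
           tolerance on a coarse cosine grid", {
  m <- one_cosine_model(amplitude = 9, multiplicity = 2, phase = 30)
  db <- build_partitioned_database(m, m$molecule,
                                   list(list(grid_wraparound(120, 30))),
                                   starts = rbind(30))
  pre <- validation_scan(m, db, 1, step = 1, cutoff = 20)
  expect_gt(pre$max_error, 5)
  db2 <- adaptive_refine(m, m$molecule, db, 1,
                         delta_star = 5, delta_star_star = 20, seed = 3)
  expect_true(db2$group_dbs[[1]]$provenance$converged)
  post <- validation_scan(m, db2, 1, step = 1, cutoff = 20)
  expect_lte(post$max_error, 5)
  expect_gt(length(db2$group_dbs[[1]]$records), 3)
  # refinement only ever adds points; the initial grid survives
  first3 <- vapply(db2$group_dbs[[1]]$records[1:3],
                   function(r) r$theta_ref, 0)
  expect_equal(first3, grid_values(grid_wraparound(120, 30)))

  # same seed, same result; different seed may differ
  db2b <- adaptive_refine(m, m$molecule, db, 1,
                          delta_star = 5, delta_star_star = 20, seed = 3)
  expect_identical(db2$group_dbs[[1]]$records, db2b$group_dbs[[1]]$records)
})

test_that("candidates above the relevance cutoff are never added", {
  # barrier 2a = 30 kJ/mol: the region above 20 is irrelevant and stays
  # unrefined no matter how bad the LAM is there
  m <- one_cosine_model(amplitude = 15, multiplicity = 1, phase = 180)
  db <- build_partitioned_database(m, m$molecule,
                                   list(list(grid_wraparound(120, 60))),
                                   starts = rbind(180))
  db2 <- adaptive_refine(m, m$molecule, db, 1, seed = 11)
  recs <- db2$group_dbs[[1]]$records
  # initial grid survives untouched; anything beyond it was added adaptively
  expect_equal(vapply(recs[1:3], function(r) r$theta_ref, 0),
               grid_values(grid_wraparound(120, 60)))
  for (rec in recs[-(1:3)])
    expect_lte(rec$U_ref - db2$vacuo$U_vac, 20)
})
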