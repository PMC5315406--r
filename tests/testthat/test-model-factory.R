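test_that("generate_models emits one model per design row, atomically", {
  base <- build_th17_model()
  rg <- th17_receptor_ranges()
  d <- lhs_sample(rg, 20, seed = 2)
  out <- generate_models(base, d)
  expect_length(out$models, 20)
  expect_equal(nrow(out$manifest), 20)
  expect_equal(names(out$manifest), c("filename", d$targets))
  for (i in c(1, 20)) {
    m <- out$models[[i]]
    expect_equal(m$parameters$value[match(d$targets, m$parameters$id)],
                 unname(d$values[i, ]))
  }
  # on-disk emission
  dir <- file.path(tempdir(), "gen20")
  generate_models(base, d, output_dir = dir)
  expect_length(list.files(dir, pattern = "\\.xml$"), 20)
  expect_true(file.exists(file.path(dir, "manifest.csv")))

  # unresolvable column: error before anything is produced
  bad <- d
  bad$targets[1] <- "zz"
  colnames(bad$values)[1] <- "zz"
  dir2 <- file.path(tempdir(), "gen-bad")
  expect_error(generate_models(base, bad, output_dir = dir2), "zz")
  expect_false(dir.exists(dir2))

  # empty design
  empty <- lhs_sample(rg, 2, seed = 1)
  empty$values <- empty$values[0, , drop = FALSE]
  out0 <- generate_models(base, empty)
  expect_length(out0$models, 0)
  expect_equal(nrow(out0$manifest), 0)
})

test_that("snapshot takes the requested or final time point", {
  doc <- make_reversible_model()
  tr <- solve_model(doc, 10, 0.5)
  snap <- snapshot_from_trajectory(doc, tr, "auto")
  expect_equal(snap$annotations$snapshot_time, 10)
  expect_equal(snap$species$initial,
               unname(tr$values[nrow(tr$values), c("A", "B")]))
  snap5 <- snapshot_from_trajectory(doc, tr, 5)
  expect_equal(snap5$species$initial,
               unname(tr$values[tr$times == 5, c("A", "B")]))
  expect_error(snapshot_from_trajectory(doc, tr, 144), "outside")
  tr_missing <- trajectory(tr$times,
                           tr$values[, "A", drop = FALSE])
  expect_error(snapshot_from_trajectory(doc, tr_missing, "auto"), "B")
})

test_that("snapshot + re-solve continues the uninterrupted trajectory", {
  doc <- make_random_toy_model(1)
  full <- solve_model(doc, 10, 0.5)
  half <- solve_model(doc, 5, 0.5)
  snap <- snapshot_from_trajectory(doc, half, "auto")
  cont <- solve_model(snap, 5, 0.5)
  tail_rows <- full$values[full$times >= 5, ]
  expect_equal(cont$values, tail_rows, tolerance = 1e-6)
})

test_that("interventions change exactly the targeted fields", {
  doc <- make_reversible_model()
  tr <- solve_model(doc, 10, 0.5)
  snap <- snapshot_from_trajectory(doc, tr, "auto")
  final <- tr$values[nrow(tr$values), ]

  set_iv <- intervention("A", "species_initial", "SET", 100)
  out <- apply_interventions(snap, list(set_iv))
  expect_equal(out$species$initial[out$species$id == "A"], 100)
  expect_equal(out$species$initial[out$species$id == "B"],
               snap$species$initial[snap$species$id == "B"])
  expect_equal(out$parameters, snap$parameters)
  expect_equal(out$annotations$interventions[[1]], set_iv)
  # serialised diff touches only the A element and the annotation
  d <- setdiff(strsplit(write_model(out), "\n")[[1]],
               strsplit(write_model(snap), "\n")[[1]])
  expect_true(all(grepl("\"A\"|intervention", d)))

  # SCALE semantics
  sc <- apply_interventions(
    snap, list(intervention("B", "species_initial", "SCALE", 2)),
    final_state = final)
  expect_equal(sc$species$initial[sc$species$id == "B"],
               2 * final[["B"]])
  id1 <- apply_interventions(
    snap, list(intervention("B", "species_initial", "SCALE", 1)),
    final_state = final)
  expect_equal(id1$species, snap$species, tolerance = 1e-12)
  expect_error(
    apply_interventions(snap,
                        list(intervention("kf", "parameter", "SCALE", 2)),
                        final_state = final),
    "absent from final state")
})

test_that("intervention sweeps produce exactly one model per value", {
  doc <- build_th17_model()
  tr <- solve_model(doc, 5, 1)
  snap <- snapshot_from_trajectory(doc, tr, "auto")
  vals <- 10^seq(1, 4, length.out = 10)
  models <- intervention_sweep(snap, "CX", vals)
  expect_length(models, 10)
  got <- vapply(models, function(m) m$species$initial[m$species$id == "CX"],
                numeric(1))
  expect_identical(got, vals)
  expect_length(intervention_sweep(snap, "CX", 100), 1)
  expect_error(intervention_sweep(snap, "CX", numeric(0)), "non-empty")
})
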