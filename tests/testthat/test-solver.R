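test_that("exponential decay matches its closed form", {
  tr <- solve_model(make_decay_model(k = 1, s0 = 1), t_end = 1, step = 0.1)
  expect_equal(length(tr$times), 11) # floor(t_end/step) + 1
  expect_equal(unname(tr$values[11, "S"]), exp(-1), tolerance = 1e-6)
  expect_equal(tr$values[, "S"], exp(-tr$times), tolerance = 1e-6)
})

test_that("reversible mass action conserves mass and matches closed form", {
  kf <- 0.7; kr <- 0.3
  tr <- solve_model(make_reversible_model(kf, kr), t_end = 10, step = 0.25)
  expect_true(all(abs(tr$values[, "A"] + tr$values[, "B"] - 1) < 1e-8))
  # A(t) = eq + (1 - eq) * exp(-(kf+kr) t)
  eq <- kr / (kf + kr)
  expect_equal(tr$values[, "A"], eq + (1 - eq) * exp(-(kf + kr) * tr$times),
               tolerance = 1e-6)
})

test_that("output grid is sampling, not integration", {
  doc <- make_random_toy_model(4)
  coarse <- solve_model(doc, 8, 1)
  fine <- solve_model(doc, 8, 0.5)
  shared <- match(coarse$times, fine$times)
  expect_equal(fine$values[shared, ], coarse$values, tolerance = 1e-7)
  expect_equal(length(solve_model(doc, 1, 0.12)$times),
               floor(1 / 0.12) + 1)
})

test_that("boundary species stay fixed and feed the kinetics", {
  doc <- model_document(
    "bnd",
    species = data.frame(id = c("E", "P"), compartment = "cell",
                         initial = c(2, 0), boundary = c(TRUE, FALSE)),
    parameters = data.frame(id = "kcat", value = 0.5, constant = TRUE),
    reactions = list(list(
      id = "make",
      reactants = data.frame(species = character(), stoich = numeric()),
      products = data.frame(species = "P", stoich = 1),
      kinetic_law = quote(kcat * E))))
  tr <- solve_model(doc, 2, 0.5)
  expect_true(all(tr$values[, "E"] == 2))
  expect_equal(tr$values[, "P"], 1 * tr$times, tolerance = 1e-7)
})

test_that("integration failure is loud, with a time stamp", {
  doc <- model_document(
    "blow",
    species = data.frame(id = "S", compartment = "cell", initial = 1,
                         boundary = FALSE),
    parameters = data.frame(id = "g", value = 3, constant = TRUE),
    reactions = list(list(
      id = "explode",
      reactants = data.frame(species = character(), stoich = numeric()),
      products = data.frame(species = "S", stoich = 1),
      kinetic_law = quote(g * S^2))))
  expect_error(solve_model(doc, 10, 0.5), "integration failure")
})

test_that("steady-state detection follows the windowed sup-norm rule", {
  # constant trajectory: detected at t = 0
  tt <- seq(0, 10, 0.5)
  flat <- trajectory(tt, matrix(2, length(tt), 1,
                                dimnames = list(NULL, "S")))
  expect_equal(detect_steady_state(flat, window = 2, rel_tol = 1e-3), 0)

  # pure exponential decay: |x(t) - x(t*)| <= rel_tol * x(t*) over a window
  # of w requires exp(-t*) - exp(-(t*+w)) <= rel_tol * exp(-t*),
  # i.e. any t* once 1 - exp(-w) <= rel_tol; for larger rel_tol the
  # absolute-floor branch admits earlier times, so t* decreases in rel_tol
  tt <- seq(0, 40, 0.1)
  dec <- trajectory(tt, matrix(exp(-tt), length(tt), 1,
                               dimnames = list(NULL, "S")))
  t_tight <- detect_steady_state(dec, window = 5, rel_tol = 1e-3)
  t_loose <- detect_steady_state(dec, window = 5, rel_tol = 1e-1)
  expect_false(is.na(t_tight))
  expect_lt(t_loose, t_tight)
  # analytic oracle: earliest grid point where the floor admits the window,
  # exp(-t) - exp(-(t+w)) <= rel_tol * max(exp(-t), 1e-9)
  ok <- vapply(tt[tt <= 35], function(t0) {
    win <- tt[tt >= t0 & tt <= t0 + 5]
    all(abs(exp(-win) - exp(-t0)) <= 1e-3 * max(exp(-t0), 1e-9))
  }, logical(1))
  expect_equal(t_tight, tt[which(ok)[1]])

  # diverging trajectory: no steady state
  div <- trajectory(tt, matrix(exp(tt / 10), length(tt), 1,
                               dimnames = list(NULL, "S")))
  expect_true(is.na(detect_steady_state(div, window = 5, rel_tol = 1e-3)))
  expect_error(detect_steady_state(flat, window = 20), "span")
})

test_that("trajectory CSV round trips through the documented dialect", {
  tr <- solve_model(make_reversible_model(), 5, 0.5)
  path <- file.path(tempdir(), "traj.csv")
  write_trajectory(tr, path)
  first <- readLines(path, n = 1)
  expect_equal(first, "time,A,B")
  back <- read_trajectory(path)
  expect_equal(back$times, tr$times)
  expect_equal(back$values, tr$values, tolerance = 1e-12)
})
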