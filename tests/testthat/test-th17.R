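baselines_of <- function(doc) {
  c(doc$species$initial[doc$species$id == "T"],
    doc$species$initial[doc$species$id == "R"])
}

test_that("the cytokine-free model sits at its basal fixed point", {
  doc <- build_th17_model()
  tr <- solve_model(doc, 144, 0.12)
  rel <- abs(tr$values[nrow(tr$values), ] - tr$values[1, ]) /
    pmax(abs(tr$values[1, ]), 1e-9)
  expect_lt(max(rel), 1e-6)
  cl <- classify_phenotype(tr, baselines_of(doc), eval_time = "end")
  expect_equal(cl$label, "UNPOLARISED")
})

test_that("C17 polarises to a stable Th17 state; C1 cannot undo it", {
  doc <- build_th17_model()
  b <- baselines_of(doc)
  tr0 <- solve_model(doc, 144, 0.12)
  snap <- snapshot_from_trajectory(doc, tr0, "auto")
  stim <- apply_interventions(
    snap, list(intervention("C17", "species_initial", "SET", 100)))
  tr17 <- solve_model(stim, 144, 0.12)
  cl17 <- classify_phenotype(tr17, b, eval_time = "end")
  expect_equal(cl17$label, "TH17")
  expect_gt(cl17$R_level, 2 * b[2])
  expect_lte(cl17$T_level, 2 * b[1])
  # C17 decays away: polarisation is maintained by autoactivation
  expect_lt(tr17$values[nrow(tr17$values), "C17"], 1)

  # hysteresis: C1 restimulation of the polarised cell
  snap17 <- snapshot_from_trajectory(stim, tr17, "auto")
  stim1 <- apply_interventions(
    snap17, list(intervention("C1", "species_initial", "SET", 100)))
  tr1 <- solve_model(stim1, 144, 0.12)
  cl1 <- classify_phenotype(tr1, b, history = "TH17", eval_time = "end")
  expect_equal(cl1$label, "TH17")
})

test_that("naive cells polarise to Th1 under C1 (lineage symmetry)", {
  doc <- build_th17_model()
  b <- baselines_of(doc)
  tr0 <- solve_model(doc, 144, 0.12)
  snap <- snapshot_from_trajectory(doc, tr0, "auto")
  stim <- apply_interventions(
    snap, list(intervention("C1", "species_initial", "SET", 100)))
  tr <- solve_model(stim, 144, 0.12)
  expect_equal(classify_phenotype(tr, b, eval_time = "end")$label, "TH1")
})

test_that("classification rule covers all label combinations", {
  mk <- function(T, R) {
    tt <- c(0, 1)
    trajectory(tt, matrix(c(T, T, R, R), 2, 2,
                          dimnames = list(NULL, c("T", "R"))))
  }
  b <- c(1, 1)
  expect_equal(classify_phenotype(mk(1, 1), b, eval_time = "end")$label,
               "UNPOLARISED")
  expect_equal(classify_phenotype(mk(1, 10), b, eval_time = "end")$label,
               "TH17")
  expect_equal(classify_phenotype(mk(10, 1), b, eval_time = "end")$label,
               "TH1")
  expect_equal(classify_phenotype(mk(10, 10), b, eval_time = "end")$label,
               "DOUBLE_POSITIVE")
  expect_equal(classify_phenotype(mk(10, 1), b, history = "TH17",
                                  eval_time = "end")$label, "EX_TH17")
  # scale invariance: common factor on levels and baselines
  expect_equal(classify_phenotype(mk(50, 5), 5 * b, eval_time = "end")$label,
               "TH1")
  expect_error(classify_phenotype(mk(1, 1), c(0, 1)), "positive")
})

test_that("ex-Th17 history is recognised within a single trajectory", {
  # R high then collapses while T rises: the final (T above, R below)
  # state must read EX_TH17 because the trajectory passed through Th17
  tt <- 0:10
  T <- c(rep(1, 6), 2, 4, 8, 10, 10)
  R <- c(rep(10, 6), 8, 4, 2, 1, 1)
  tr <- trajectory(tt, cbind(T = T, R = R))
  expect_equal(classify_phenotype(tr, c(1, 1), eval_time = "end")$label,
               "EX_TH17")
})

test_that("switching experiment report has sound structure (smoke, n = 4)", {
  rep <- run_switching_experiment(4, variant = "PROMOTE_TBET", seed = 11)
  expect_s3_class(rep, "switch_report")
  expect_equal(nrow(rep), 4)
  expect_true(all(rep$error == ""))
  expect_true(all(rep$th17_established))
  expect_equal(attr(rep, "n_switched") + attr(rep, "n_not_switched"), 4)
  expect_true(all(is.na(rep$time_to_switch) |
                    (rep$time_to_switch > 0 & rep$time_to_switch <= 144)))
  # empty report
  rep0 <- run_switching_experiment(0, variant = "PROMOTE_TBET")
  expect_equal(nrow(rep0), 0)
  expect_equal(attr(rep0, "n_switched"), 0L)
  # determinism under seed
  rep2 <- run_switching_experiment(4, variant = "PROMOTE_TBET", seed = 11)
  expect_equal(rep2$switched, rep$switched)
})

test_that("default parameter set switches under promotion, not inhibition", {
  p <- th17_default_params()
  pl_p <- sbmlsens:::th17_pipeline(p, "PROMOTE_TBET")
  expect_equal(pl_p$call17$label, "TH17")
  expect_equal(pl_p$callx$label, "EX_TH17")
  pl_i <- sbmlsens:::th17_pipeline(p, "INHIBIT_RORGT")
  expect_equal(pl_i$callx$label, "TH17")
  # inhibition causes a transient RORgammat dip, not a switch
  expect_lt(min(pl_i$trajx$values[, "R"]), pl_i$trajx$values[1, "R"])
  expect_gt(pl_i$callx$R_level, 2 * pl_i$baselines[2])
})

test_that("build_th17_model validates parameters", {
  p <- th17_default_params()
  p$a5 <- -1
  expect_error(build_th17_model(p), "positive")
  p$a5 <- NULL
  expect_error(build_th17_model(p), "missing parameter")
})
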