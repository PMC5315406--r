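#!/usr/bin/env Rscript
# Verification (and, if ever needed, re-tuning) of the shipped default
# parameter set for the Th17/Th1 switching model.
#
# The defaults in th17_default_params() were chosen analytically from the
# bistability conditions of the autoactivation + mutual-inhibition core
# (see the methods vignette: a low fixed point requires
# mu^2 >= 4 * beta * a / k^2 even with the competing factor absent) and
# then confirmed, not fitted, by this script. Run it after any change to
# the model structure; every check must print TRUE.

suppressMessages(library(sbmlsens))

p <- th17_default_params()
doc <- build_th17_model(p)
b <- c(doc$species$initial[doc$species$id == "T"],
       doc$species$initial[doc$species$id == "R"])
check <- function(what, ok) cat(sprintf("%-55s %s\n", what, ok))

# 1. basal fixed point: nothing moves without cytokines
tr0 <- solve_model(doc, 144, 0.12)
drift <- max(abs(tr0$values[nrow(tr0$values), ] - tr0$values[1, ]) /
               pmax(abs(tr0$values[1, ]), 1e-9))
check("no-cytokine drift < 1e-6", drift < 1e-6)

# 2. C17 pulse -> stable Th17
snap0 <- snapshot_from_trajectory(doc, tr0, "auto")
stim17 <- apply_interventions(
  snap0, list(intervention("C17", "species_initial", "SET", 100)))
tr17 <- solve_model(stim17, 144, 0.12)
check("C17 pulse polarises to TH17",
      classify_phenotype(tr17, b, eval_time = "end")$label == "TH17")

# 3. subsequent C1 pulse cannot destabilise Th17
snap17 <- snapshot_from_trajectory(stim17, tr17, "auto")
stim1 <- apply_interventions(
  snap17, list(intervention("C1", "species_initial", "SET", 100)))
tr1 <- solve_model(stim1, 144, 0.12)
check("Th17 stable under C1 restimulation",
      classify_phenotype(tr1, b, history = "TH17",
                         eval_time = "end")$label == "TH17")

# 4. mechanism asymmetry for the default set
stimx <- apply_interventions(
  snap17, list(intervention("CX", "species_initial", "SET", 100)))
for (v in c("PROMOTE_TBET", "INHIBIT_RORGT")) {
  docv <- build_th17_model(p, v)
  trv0 <- solve_model(docv, 144, 0.12)
  sv <- snapshot_from_trajectory(docv, trv0, "auto")
  sv <- apply_interventions(
    sv, list(intervention("C17", "species_initial", "SET", 100)))
  trv17 <- solve_model(sv, 144, 0.12)
  sv17 <- snapshot_from_trajectory(sv, trv17, "auto")
  sv17 <- apply_interventions(
    sv17, list(intervention("CX", "species_initial", "SET", 100)))
  trvx <- solve_model(sv17, 144, 0.12)
  lab <- classify_phenotype(trvx, b, history = "TH17",
                            eval_time = "end")$label
  if (v == "PROMOTE_TBET") {
    check("CX under T-bet promotion switches to EX_TH17", lab == "EX_TH17")
  } else {
    check("CX under RORgammat inhibition stays TH17", lab == "TH17")
  }
}

# 5. ensemble asymmetry on a small seeded ensemble
rp <- run_switching_experiment(10, variant = "PROMOTE_TBET", seed = 1)
ri <- run_switching_experiment(10, variant = "INHIBIT_RORGT", seed = 1)
check("promotion ensemble has switchers (n=10)",
      attr(rp, "n_switched") > 0)
check("inhibition ensemble has none (n=10)",
      attr(ri, "n_switched") == 0)
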