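test_that("count simulation is a pure function of parameters and seed", {
  dsn <- pipelineDesign(n_rep = 2)
  a <- simulateCounts(dsn, n_genes = 60, seed = 42)
  b <- simulateCounts(dsn, n_genes = 60, seed = 42)
  expect_identical(doseCounts(a$experiment), doseCounts(b$experiment))
  expect_identical(a$truth$group_means, b$truth$group_means)
  c <- simulateCounts(dsn, n_genes = 60, seed = 43)
  expect_false(identical(doseCounts(a$experiment), doseCounts(c$experiment)))
})

test_that("Poisson-limit group sample means track the planted means", {
  ## phi = 0, large means: law of large numbers over 6 replicates
  sim <- simulateCounts(pipelineDesign(), n_genes = 60, phi = 0,
                        base_mean_range = c(1e4, 5e4), n_per_archetype = 10,
                        lib_size_sdlog = 0, seed = 7)
  cnt <- doseCounts(sim$experiment)
  grp <- sampleGroups(sim$experiment)
  for (g in levels(grp)) {
    obs <- rowMeans(cnt[, grp == g, drop = FALSE])
    expect_lt(max(abs(obs / sim$truth$group_means[, g] - 1)), 0.05)
  }
})

test_that("archetype trajectories interpolate between the L0 and N0 means", {
  sim <- simulateCounts(pipelineDesign(n_rep = 2), n_genes = 60,
                        n_per_archetype = 10, effect_fold = 2, seed = 3)
  mu <- sim$truth$group_means
  arch <- sim$truth$profile_archetype
  inc <- names(arch)[arch == "increased_dose_effect"]
  expect_equal(mu[inc, "L4"], (mu[inc, "L0"] + mu[inc, "N0"]) / 2)
  expect_equal(mu[inc, "L8"], mu[inc, "N0"])
  sen <- names(arch)[arch == "sensitive_dose"]
  expect_equal(mu[sen, "L4"], mu[sen, "N0"])
  ctr <- names(arch)[arch == "counter_effect"]
  expect_true(all(abs(mu[ctr, "L8"] - mu[ctr, "N0"]) >=
                  abs(mu[ctr, "L0"] - mu[ctr, "N0"])))
  nul <- names(arch)[arch == "null"]
  expect_true(all(mu[nul, ] == mu[nul, "L0"]))
  expect_true(all(mu > 0))
})

test_that("an effect that would drive a mean negative is rejected", {
  expect_error(simulateCounts(pipelineDesign(n_rep = 2), n_genes = 60,
                              effect_fold = 0, seed = 1), "effect_fold")
})

test_that("event simulation honours the binomial PSI model", {
  dsn <- pipelineDesign(n_rep = 2)
  expect_error(simulateEvents(dsn, n_events = 5, coverage = 0), "coverage")

  ## true PSI 1 -> all inclusion, PSI estimate exactly 1
  sim <- simulateEvents(dsn, n_events = 20, coverage = 100, n_diff = 0, seed = 2)
  psi_true <- sim$truth$psi
  one <- simulateEvents(dsn, n_events = 5, coverage = 50, n_diff = 0, seed = 2)
  inc <- inclusionCounts(one$events)
  ## force the degenerate case by direct construction
  ev <- makeEvents(matrix(50L, 3, 8), matrix(0L, 3, 8))
  expect_true(all(computePsi(ev) == 1))

  ## planted |dPSI| 0.4 at coverage 100: empirical mean within 0.05 over 100 events
  sim2 <- simulateEvents(pipelineDesign(), n_events = 100, coverage = 100,
                         n_diff = 100, dpsi = 0.4, seed = 11)
  psi <- computePsi(sim2$events)
  dsn6 <- pipelineDesign()
  grp <- as.character(dsn6$group)
  d_obs <- rowMeans(psi[, grp == "N0"]) - rowMeans(psi[, grp == "L0"])
  expect_lt(abs(mean(abs(d_obs)) - 0.4), 0.05)

  ## determinism
  s1 <- simulateEvents(dsn, n_events = 10, coverage = 30, seed = 9, n_diff = 3)
  s2 <- simulateEvents(dsn, n_events = 10, coverage = 30, seed = 9, n_diff = 3)
  expect_identical(inclusionCounts(s1$events), inclusionCounts(s2$events))
})

test_that("motif planting hits every differential body at p_diff = 1, p_bg = 0", {
  dsn <- pipelineDesign(n_rep = 2)
  sim <- simulateEvents(dsn, n_events = 40, coverage = 20, n_diff = 15, seed = 21)
  motif <- iupacMotif("SRSF1", "m1", "GGAGGA")
  gen <- simulateGenomeWithMotifs(sim$events, motif, sim$truth$diff_events,
                                  p_diff = 1, p_bg = 0, seed = 22)
  expect_setequal(gen$truth$planted_events, sim$truth$diff_events)
  regions <- buildBindingRegions(sim$events, gen$genome)
  seqs <- regionSequences(regions, gen$genome)
  ev_of <- S4Vectors::mcols(regions)$event_id
  diff_regions <- names(regions)[ev_of %in% sim$truth$diff_events]
  ## every differential event has >= 1 region containing an exact hit
  hit_events <- unique(ev_of[vapply(names(regions), function(nm) {
    length(scanMotif(seqs[[nm]], motif)) > 0
  }, logical(1))])
  expect_true(all(sim$truth$diff_events %in% hit_events))

  ## background hit rate compatible with the random-match expectation
  bg_regions <- names(regions)[!ev_of %in% sim$truth$diff_events]
  bg_hit <- mean(vapply(bg_regions, function(nm) {
    length(scanMotif(seqs[[nm]], motif)) > 0
  }, logical(1)))
  ## ~580 scanned positions x 4^-6 per position: expect under ~35%
  expect_lt(bg_hit, 0.35)

  ## determinism
  gen2 <- simulateGenomeWithMotifs(sim$events, motif, sim$truth$diff_events,
                                   p_diff = 1, p_bg = 0, seed = 22)
  expect_identical(as.character(gen$genome), as.character(gen2$genome))
})

test_that("trait simulation couples TG to the hub gene as specified", {
  dsn <- pipelineDesign()
  hub_tpm <- setNames(rep(c(10, 20, 30, 40), each = 6), dsn$sample_id)

  tr0 <- simulateTrait(dsn, hub_tpm, slope = -2, noise_sd = 0, seed = 1)
  tg_grp <- tapply(tr0$tg_mg_dl, dsn$group, mean)
  tpm_grp <- tapply(hub_tpm, dsn$group, mean)
  expect_equal(unname(cor(tg_grp, tpm_grp)), -1)

  trp <- simulateTrait(dsn, hub_tpm, slope = 3, noise_sd = 0, seed = 1)
  expect_equal(unname(cor(tapply(trp$tg_mg_dl, dsn$group, mean), tpm_grp)), 1)

  ## slope 0: |r| rarely extreme over 200 seeds
  rs <- vapply(1:200, function(s) {
    tr <- simulateTrait(dsn, hub_tpm, slope = 0, noise_sd = 5, seed = s)
    abs(cor(tapply(tr$tg_mg_dl, dsn$group, mean), tpm_grp))
  }, numeric(1))
  expect_lt(mean(rs), 0.9)
})

test_that("ortholog simulation plants exact identities", {
  sim <- simulateOrthologs(pig_length = 1000,
                           species_identities = c(human = 1.0, mouse = 0.8),
                           seed = 4)
  expect_identical(as.character(sim$sequences[["human"]]),
                   as.character(sim$sequences[["sus_scrofa"]]))
  id_mouse <- pairwiseIdentity(sim$sequences[["sus_scrofa"]],
                               sim$sequences[["mouse"]])$identity
  expect_lt(abs(id_mouse - 80), 1)

  sim7 <- simulateOrthologs(pig_length = 1000, seed = 5)
  cons <- conservationFromOrthologs(sim7$sequences)
  expect_lt(abs(cons$gene_score - 80), 1)
})
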