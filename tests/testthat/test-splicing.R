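test_that("PSI formula evaluates exactly and handles degeneracies", {
  expect_equal(computePsi(5, 5), 0.5)
  expect_equal(computePsi(0, 7), 0)
  expect_equal(computePsi(3, 1), 0.75)
  expect_error(computePsi(-1, 2), "non-negative")
  expect_warning(psi <- computePsi(0, 0), "zero coverage")
  expect_true(is.na(psi))
})

test_that("PSI estimator is unbiased under binomial sampling", {
  set.seed(99)
  for (true_psi in c(0.2, 0.5, 0.8)) {
    inc <- rbinom(1000, 100, true_psi)
    est <- computePsi(inc, 100L - inc)
    expect_lt(abs(mean(est) - true_psi), 0.01)
  }
})

test_that("identical pooled counts give p = 1 and no differential call", {
  inc <- matrix(10L, 3, 8)
  exc <- matrix(10L, 3, 8)
  ev <- makeEvents(inc, exc)
  res <- differentialEvents(ev, pipelineDesign(n_rep = 2), comparison = "N0")
  expect_true(all(res$p == 1))
  expect_false(any(res$is_differential))
  expect_true(all(res$delta_psi == 0))
})

test_that("a strong PSI flip is flagged with the exact hypergeometric p", {
  ## group sums (90,10) vs (10,90): L0 samples carry (45,5), N0 (5,45)
  dsn <- pipelineDesign(n_rep = 2)
  inc <- matrix(20L, 2, 8); exc <- matrix(20L, 2, 8)
  grp <- as.character(dsn$group)
  inc[1, grp == "L0"] <- 45L; exc[1, grp == "L0"] <- 5L
  inc[1, grp == "N0"] <- 5L;  exc[1, grp == "N0"] <- 45L
  ev <- makeEvents(inc, exc)
  res <- differentialEvents(ev, dsn, comparison = "N0")
  r1 <- res[res$event_id == "ev01", ]
  expect_true(r1$is_differential)
  ## two-sided Fisher p by exhaustive enumeration of the margin-fixed tables
  p_enum <- local({
    r1tot <- 100; r2tot <- 100; c1 <- 100; n <- 200
    probs <- vapply(max(0, c1 - r2tot):min(r1tot, c1), function(x) {
      exp(lchoose(r1tot, x) + lchoose(r2tot, c1 - x) - lchoose(n, c1))
    }, numeric(1))
    obs <- probs[[90 - max(0, c1 - r2tot) + 1]]
    sum(probs[probs <= obs * (1 + 1e-7)])
  })
  expect_equal(r1$p, p_enum, tolerance = 1e-10)
})

test_that("the conjunction rule vetoes tiny delta-PSI at any significance", {
  ## delta PSI 0.04 with enormous counts: p is tiny but the effect is small
  dsn <- pipelineDesign(n_rep = 2)
  inc <- matrix(0L, 1, 8); exc <- matrix(0L, 1, 8)
  grp <- as.character(dsn$group)
  inc[1, grp == "L0"] <- 5000L; exc[1, grp == "L0"] <- 5000L
  inc[1, grp == "N0"] <- 5400L; exc[1, grp == "N0"] <- 4600L
  inc[1, grp %in% c("L4", "L8")] <- 5000L; exc[1, grp %in% c("L4", "L8")] <- 5000L
  ev <- makeEvents(inc, exc)
  res <- differentialEvents(ev, dsn, comparison = "N0")
  expect_lt(res$p[1], 1e-6)
  expect_equal(res$delta_psi[1], 0.04)
  expect_false(res$is_differential[1])
})

test_that("flagged set equals an independent filter re-implementation", {
  dsn <- pipelineDesign(n_rep = 2)
  sim <- simulateEvents(dsn, n_events = 40, coverage = 80, n_diff = 12,
                        dpsi = 0.35, seed = 31)
  res <- differentialEvents(sim$events, dsn, comparison = "N0")
  ## independent route: per-event fisher.test + p.adjust + conjunction
  inc <- inclusionCounts(sim$events); exc <- exclusionCounts(sim$events)
  grp <- as.character(dsn$group)
  p2 <- vapply(seq_len(nrow(inc)), function(i) {
    tab <- matrix(c(sum(inc[i, grp == "L0"]), sum(exc[i, grp == "L0"]),
                    sum(inc[i, grp == "N0"]), sum(exc[i, grp == "N0"])),
                  2, 2, byrow = TRUE)
    fisher.test(tab)$p.value
  }, numeric(1))
  psi <- computePsi(sim$events)
  dp <- rowMeans(psi[, grp == "N0"]) - rowMeans(psi[, grp == "L0"])
  want <- rownames(inc)[p.adjust(p2, "BH") < 0.1 & abs(dp) >= 0.05]
  expect_setequal(res$event_id[res$is_differential], want)
  expect_equal(res$p, unname(p2), tolerance = 1e-12)
})

test_that("per-replicate t-test method is available and sane", {
  dsn <- pipelineDesign()
  sim <- simulateEvents(dsn, n_events = 30, coverage = 100, n_diff = 10,
                        dpsi = 0.4, seed = 41)
  res <- differentialEvents(sim$events, dsn, comparison = "N0",
                            method = "ttest")
  flagged <- res$event_id[res$is_differential]
  expect_gt(length(intersect(flagged, sim$truth$diff_events)), 5)
})

test_that("event tallies count flagged events by type and conserve totals", {
  res <- S4Vectors::DataFrame(
    event_id = sprintf("e%d", 1:6),
    type = c("SE", "SE", "SE", "RI", "A5SS", "MXE"),
    is_differential = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )
  tal <- tallyEventTypes(res)
  expect_equal(unname(tal["SE"]), 3L)
  expect_equal(unname(tal["RI"]), 1L)
  expect_equal(unname(tal["A5SS"]), 0L)
  expect_equal(sum(tal), sum(res$is_differential))
  ## empty input -> all zeros
  expect_true(all(tallyEventTypes(res[res$is_differential == FALSE & FALSE, ]) == 0))
})

test_that("null splicing simulation keeps the raw positive rate near nominal", {
  dsn <- pipelineDesign()
  sim <- simulateEvents(dsn, n_events = 400, coverage = 50, n_diff = 0, seed = 51)
  res <- differentialEvents(sim$events, dsn, comparison = "N0")
  ## exact test at coverage 50 is conservative: rate at or below ~0.07
  expect_lte(mean(res$p < 0.05), 0.07)
  expect_false(any(res$is_differential))
})
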