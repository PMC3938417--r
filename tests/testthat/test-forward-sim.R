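test_that("demographic model validates its parameters", {
  expect_error(demographic_model("L", i0 = 0), "i0")
  expect_error(demographic_model("L", i0 = 1.2), "i0")
  expect_error(demographic_model("M", t1 = 450, t2 = 420), "t1 < t2")
  expect_error(demographic_model("M", Nei = 20000), "Nei")
  expect_error(demographic_model("R", p_R0 = 1.5), "p_R0")
  m <- demographic_model("R")
  expect_output(print(m), "bottleneck")
  expect_error(simulate_model(m, replicates = 0), "replicates")
})

test_that("census trajectories encode the three control scenarios", {
  L <- mtpopgen:::census_trajectory(demographic_model("L"))
  expect_true(all(L == 10000))
  M <- mtpopgen:::census_trajectory(demographic_model("M", Nei = 100))
  expect_equal(unique(M[1:400]), 10000)
  expect_equal(unique(M[401:500]), 100)
  R <- mtpopgen:::census_trajectory(demographic_model("R", Nei = 100))
  expect_equal(unique(R[401:420]), 100)     # suppressed while resistance establishes
  expect_equal(R[440], 10000)               # recovered 20 generations later
  expect_true(all(diff(R[421:440]) >= 0))
})

test_that("a fixed focal haplotype stays fixed", {
  for (sc in c("L", "M", "R")) {
    sim <- simulate_model(demographic_model(sc, i0 = 1, Nei = 100),
                          replicates = 30, seed = 1)
    expect_true(all(sim$final_focal_freqs == 1))
  }
})

test_that("counts are conserved every generation", {
  m <- demographic_model("R", Ne0 = 500, Nei = 50, generations = 60,
                         t1 = 30, t2 = 40, n_haplotypes = 5, i0 = 0.3)
  sim <- simulate_model(m, replicates = 50, seed = 3, check = TRUE)
  expect_equal(unname(rowSums(sim$final_counts)),
               rep(mtpopgen:::mt_copies(500, "half"), 50))
  expect_true(all(sim$final_focal_freqs >= 0 & sim$final_focal_freqs <= 1))
})

test_that("neutral drift is unbiased: mean final frequency equals i0", {
  sL <- simulate_model(demographic_model("L", Ne0 = 2000, generations = 200,
                                         t1 = 150, t2 = 160, i0 = 0.3),
                       replicates = 2000, seed = 4, focal_only = TRUE)
  se <- sd(sL$final_focal_freqs) / sqrt(2000)
  expect_lt(abs(mean(sL$final_focal_freqs) - 0.3), 4 * se)
  sM <- simulate_model(demographic_model("M", Ne0 = 2000, Nei = 200,
                                         generations = 200, t1 = 150,
                                         t2 = 160, i0 = 0.3),
                       replicates = 2000, seed = 5, focal_only = TRUE)
  seM <- sd(sM$final_focal_freqs) / sqrt(2000)
  expect_lt(abs(mean(sM$final_focal_freqs) - 0.3), 4 * seM)
})

test_that("a bottleneck at the founding size is indistinguishable from L", {
  args <- list(Ne0 = 1000, generations = 120, t1 = 80, t2 = 100,
               n_haplotypes = 10, i0 = 0.4)
  sL <- simulate_model(do.call(demographic_model, c(list("L"), args)),
                       replicates = 800, seed = 6)
  sM <- simulate_model(do.call(demographic_model,
                               c(list("M", Nei = 1000), args)),
                       replicates = 800, seed = 7)
  ks <- suppressWarnings(
    stats::ks.test(sL$final_focal_freqs, sM$final_focal_freqs))
  expect_gt(ks$p.value, 0.01)
})

test_that("the resistance machinery embeds the neutral case", {
  # no selection, no resistance copies, no size change: scenario R's
  # joint haplotype x genotype bookkeeping must reproduce scenario M
  args <- list(Ne0 = 1000, Nei = 1000, generations = 120, t1 = 80,
               t2 = 100, n_haplotypes = 10, i0 = 0.4)
  sM <- simulate_model(do.call(demographic_model, c(list("M"), args)),
                       replicates = 800, seed = 8)
  sR <- simulate_model(do.call(demographic_model,
                               c(list("R", s = 0, p_R0 = 0), args)),
                       replicates = 800, seed = 9)
  ks <- suppressWarnings(
    stats::ks.test(sM$final_focal_freqs, sR$final_focal_freqs))
  expect_gt(ks$p.value, 0.01)
})

test_that("lumping non-focal haplotypes preserves the focal law", {
  m <- demographic_model("R", Ne0 = 1000, Nei = 100, generations = 120,
                         t1 = 80, t2 = 90, i0 = 0.2)
  full <- simulate_model(m, replicates = 800, seed = 10)
  lump <- simulate_model(m, replicates = 800, seed = 11, focal_only = TRUE)
  ks <- suppressWarnings(
    stats::ks.test(full$final_focal_freqs, lump$final_focal_freqs))
  expect_gt(ks$p.value, 0.01)
})

test_that("final-frequency variance follows the diffusion prediction", {
  # constant size, i0 = 0.4, 500 generations, 5000 transmitting copies:
  # Var = p(1-p)(1 - exp(-t/N))
  sim <- simulate_model(demographic_model("L", i0 = 0.4),
                        replicates = 5000, seed = 12, focal_only = TRUE)
  v <- var(sim$final_focal_freqs)
  vth <- 0.4 * 0.6 * (1 - exp(-500 / 5000))
  expect_lt(abs(v / vth - 1), 0.15)
})

test_that("held extreme bottlenecks drive exceedance toward fixation", {
  # after 100 generations at 50 transmitting copies drift is near
  # absorption, so P(final >= 0.72) approaches P(fixation) ~ i0
  probs <- vapply(c(0.05, 0.07, 0.1), function(i0) {
    sim <- simulate_model(demographic_model("M", Nei = 100, i0 = i0),
                          replicates = 1500, seed = round(1000 * i0),
                          focal_only = TRUE)
    prob_exceed(sim, 0.72)
  }, numeric(1))
  expect_true(all(abs(probs - c(0.05, 0.07, 0.1)) < 0.05))
  expect_true(all(diff(probs) > 0))
})

test_that("exceedance probability is a simple replicate fraction", {
  sim <- structure(list(final_focal_freqs = c(0.8, 0.5, 0.9, 0.7)),
                   class = "drift_sim")
  expect_equal(prob_exceed(sim, 0.72), 0.5)
  expect_equal(prob_exceed(sim, 0), 1)
  expect_equal(prob_exceed(sim, 1.01), 0)
})

test_that("threshold sweep finds the crossing and flags unattainable targets", {
  m <- demographic_model("M", Ne0 = 1000, Nei = 100, generations = 120,
                         t1 = 80, t2 = 100, n_haplotypes = 10)
  sw <- threshold_initial_frequency(m, target = 0.72, alpha = 0.05,
                                    grid_step = 0.05, replicates = 300,
                                    seed = 13)
  expect_true(sw$attained)
  expect_true(sw$threshold > 0 && sw$threshold < 1)
  expect_true(all(diff(sw$prob_smooth) >= 0))
  # an impossible target is reported as not attained, with the maximum
  sw2 <- threshold_initial_frequency(m, target = 1.5, alpha = 0.05,
                                     grid_step = 0.2, replicates = 50,
                                     seed = 14)
  expect_false(sw2$attained)
  expect_true(is.na(sw2$threshold))
  expect_equal(sw2$max_prob, 0)
})
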