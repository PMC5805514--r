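# Synthetic-data generator: scenarios, the neutral 1/f tail, the
# observation model, and whole-case simulation.

test_that("scenario defaults encode each mode's fraction structure", {
  sc <- build_scenario("E", seed = 1)
  n <- sc$n_shared + sc$n_polyp_private + sc$n_cancer_private
  expect_equal(sc$n_shared / n, 0.85)
  expect_equal(sc$n_polyp_private / n, 0.12)
  expect_equal(sc$n_cancer_private / n, 0.03)
  expect_identical(sc$aneuploidy_timing, "polyp")

  scn <- build_scenario("N", seed = 1)
  nn <- scn$n_shared + scn$n_polyp_private + scn$n_cancer_private
  expect_lt(scn$n_polyp_private / nn, 0.05)
  expect_lt(scn$n_cancer_private / nn, 0.05)
  expect_identical(scn$aneuploidy_timing, "random")
  expect_identical(build_scenario("S", seed = 1)$aneuploidy_timing, "cancer")
})

test_that("scenario validation rejects bad inputs but allows overrides", {
  expect_error(build_scenario("X"), "unknown moe_label")
  expect_error(build_scenario("S", list(purity_polyp = 0)), "purity")
  expect_error(build_scenario("S", list(neutral_fmin = 0.6)), "neutral_fmin")
  # A degenerate override is accepted; the classifier simply will not
  # vote stepwise on the resulting case.
  sc <- build_scenario("S", list(n_shared = 0L), seed = 1)
  expect_identical(sc$n_shared, 0L)
  b <- simulate_case(sc)
  part <- partition_snvs(b$snvs, "villous", "cancer")
  expect_false("S" %in% rule1_fractions(part)$votes)
})

test_that("neutral subclonal draws follow the closed-form 1/f^2 law", {
  f <- sample_neutral_subclonal_afs(10000, 0.05, 0.25, seed = 7)
  expect_true(all(f >= 0.05 & f <= 0.25))
  grid <- seq(0.05, 0.25, length.out = 400)
  cdf <- (1 / 0.05 - 1 / grid) / (1 / 0.05 - 1 / 0.25)
  ks <- max(abs(ecdf(f)(grid) - cdf))
  expect_lt(ks, 0.02)
  # Cumulative count M(f) is linear in 1/f.
  expect_gte(neutral_tail_fit(f, 0.05, 0.25, n_grid = 20L)$r_squared, 0.98)
  # Determinism and support edge cases.
  expect_identical(f, sample_neutral_subclonal_afs(10000, 0.05, 0.25,
                                                   seed = 7))
  f1 <- sample_neutral_subclonal_afs(1, 0.1, 0.3, seed = 1)
  expect_true(f1 >= 0.1 && f1 <= 0.3)
  expect_error(sample_neutral_subclonal_afs(10, 0.3, 0.1), "f_min")
})

test_that("observation model recovers expected AFs and detection loss", {
  # Clonal heterozygous limit.
  expect_equal(apply_observation_model(1, 1, 1e6, seed = 1)$af, 0.5,
               tolerance = 0.005)
  # Purity scales the expected AF: 0.6 * 1 / 2 = 0.30.
  expect_equal(apply_observation_model(1, 0.6, 1e6, seed = 2)$af, 0.30,
               tolerance = 0.01)
  # Deep subclonal variants frequently fall below the detection limit;
  # the Monte-Carlo undetected fraction matches the binomial tail
  # marginalized over the truncated-Poisson depth.
  obs <- apply_observation_model(rep(0.05, 20000), 1, 60,
                                 detection_limit = 0.05, seed = 3)
  d <- 1:250
  pd <- dpois(d, 60)
  pd <- pd / sum(pd) # depth distribution truncated at >= 1 read
  p_undetected <- sum(pd * pbinom(ceiling(0.05 * d) - 1, d, 0.025))
  expect_gt(p_undetected, 0.5) # "frequently undetected"
  expect_equal(mean(!obs$detected), p_undetected, tolerance = 0.02)
})

test_that("case simulation is deterministic under a fixed seed", {
  sc <- build_scenario("P", seed = 42)
  b1 <- simulate_case(sc)
  b2 <- simulate_case(sc)
  expect_identical(b1$snvs, b2$snvs)
  expect_identical(b1$cna$cancer$segments, b2$cna$cancer$segments)
})

test_that("simulated partitions track the scenario fractions", {
  # At depth >= 100 and purities >= 0.6 the observed fractions sit
  # within 0.05 of the scenario targets.
  for (lab in c("S", "P", "N", "E")) {
    sc <- build_scenario(lab, list(depth = 120), seed = 5)
    b <- simulate_case(sc)
    part <- partition_snvs(b$snvs, "villous", "cancer")
    n <- sc$n_shared + sc$n_polyp_private + sc$n_cancer_private
    expect_lt(abs(part$f_shared - sc$n_shared / n), 0.05)
    expect_lt(abs(part$f_polyp - sc$n_polyp_private / n), 0.05)
    expect_lt(abs(part$f_cancer - sc$n_cancer_private / n), 0.05)
  }
  # Neutral cases are almost entirely shared.
  bn <- simulate_case(build_scenario("N", seed = 3))
  expect_gte(partition_snvs(bn$snvs, "villous", "cancer")$f_shared, 0.95)
})

test_that("aneuploidy timing controls where simulated events appear", {
  p0 <- simulate_cna_profiles("none", 4, seed = 1)
  expect_identical(nrow(p0$polyp$segments), 0L)
  expect_identical(nrow(p0$cancer$segments), 0L)

  pp <- simulate_cna_profiles("polyp", 4, seed = 5)
  # Identical profiles: each event-bearing chromosome scores 1, so M
  # equals the number of distinct chromosomes with events.
  expect_equal(genome_similarity(pp$polyp, pp$cancer),
               length(unique(pp$cancer$segments$chrom)))
  expect_identical(pp$polyp$segments, pp$cancer$segments)

  pc <- simulate_cna_profiles("cancer", 4, seed = 2)
  expect_identical(pc$polyp$autosomal_altered_fraction, 0)
  expect_gt(pc$cancer$autosomal_altered_fraction, 0)

  # Bundle-level timing defaults: eruptive polyps carry events,
  # stepwise polyps do not.
  be <- simulate_case(build_scenario("E", seed = 3))
  expect_gte(nrow(be$cna$villous$segments), 1)
  bs <- simulate_case(build_scenario("S", seed = 3))
  expect_identical(nrow(bs$cna$villous$segments), 0L)
})

test_that("simulated SNVs carry valid trinucleotide contexts", {
  b <- simulate_case(build_scenario("N", seed = 8))
  expect_true(all(substr(b$snvs$context, 2, 2) == b$snvs$ref))
  expect_true(all(b$snvs$ref != b$snvs$alt))
  # Contexts map onto the 96 channels without error.
  idx <- channel_of(b$snvs$ref, b$snvs$alt, b$snvs$context)
  expect_true(all(idx >= 1 & idx <= 96))
})
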