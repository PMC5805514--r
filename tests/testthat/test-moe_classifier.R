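# The five rules, the majority vote, and end-to-end classification.

test_that("rule 1 votes every mode whose fraction condition holds", {
  expect_identical(rule1_fractions(make_partition(0.45, 0.25, 0.30))$votes,
                   "S")
  expect_identical(rule1_fractions(make_partition(0.96, 0.02, 0.02))$votes,
                   "N")
  # Overlapping conditions are possible by construction.
  expect_identical(rule1_fractions(make_partition(0.40, 0.50, 0.10))$votes,
                   c("S", "P"))
  expect_identical(rule1_fractions(make_partition(0.85, 0.12, 0.03))$votes,
                   "E")
  v <- rule1_fractions(make_partition(0.70, 0.08, 0.22))
  expect_length(v$votes, 0)
  expect_match(v$note, "no MOE")
})

test_that("rule 2 maps the gap pattern to modes under both conventions", {
  expect_identical(rule2_gaps(TRUE, TRUE)$votes, c("S", "P"))
  expect_identical(rule2_gaps(FALSE, FALSE)$votes, "N")
  expect_identical(rule2_gaps(FALSE, TRUE)$votes, "E")
  polyp_only <- rule2_gaps(TRUE, FALSE)
  expect_length(polyp_only$votes, 0)
  expect_true(polyp_only$applicable)
  expect_match(polyp_only$note, "matches no MOE")
  # The narrative convention swaps the one-sided directions.
  expect_identical(rule2_gaps(TRUE, FALSE, convention = "narrative")$votes,
                   "E")
  expect_length(rule2_gaps(FALSE, TRUE, convention = "narrative")$votes, 0)
  expect_false(rule2_gaps(NA, TRUE)$applicable)
})

test_that("rule 3 votes on private cluster positions", {
  expect_identical(rule3_positions("lower", "lower")$votes, c("S", "E"))
  expect_identical(rule3_positions("equal", "equal")$votes, "P")
  expect_identical(rule3_positions("none", "none")$votes, "N")
  expect_identical(rule3_positions("lower", "equal")$votes, "S")
  up <- rule3_positions("lower", "higher")
  expect_identical(up$votes, "S")
  expect_match(up$note, "polyclonal")
})

test_that("rule 4 asks whether shared SNVs form one cluster in both", {
  set.seed(5)
  uni_p <- rnorm(300, 0.35, 0.02)
  uni_c <- rnorm(300, 0.40, 0.02)
  expect_identical(rule4_shared_structure(uni_p, uni_c)$votes, c("N", "E"))
  bi_c <- c(rnorm(150, 0.2, 0.02), rnorm(150, 0.45, 0.02))
  expect_identical(rule4_shared_structure(uni_p, bi_c)$votes, c("S", "P"))
  expect_false(rule4_shared_structure(rnorm(5, 0.4, 0.01), uni_c)$applicable)
})

test_that("rule 5 reads aneuploidy timing off the altered fractions", {
  expect_identical(rule5_aneuploidy_timing(profile_with_fraction("p", 0.2),
                                           profile_with_fraction("c", 0.4))$votes,
                   c("N", "E"))
  expect_identical(rule5_aneuploidy_timing(profile_with_fraction("p", 0),
                                           profile_with_fraction("c", 0.3))$votes,
                   c("S", "P", "N"))
  none <- rule5_aneuploidy_timing(profile_with_fraction("p", 0),
                                  profile_with_fraction("c", 0))
  expect_false(none$applicable)
  marginal <- rule5_aneuploidy_timing(profile_with_fraction("p", 0.09),
                                      profile_with_fraction("c", 0.4))
  expect_false(marginal$applicable)
  expect_match(marginal$note, "n,e or s,p,n")
})

test_that("majority vote reproduces the published tally arithmetic", {
  a09 <- list(rule_vote(1, "E"), rule_vote(2, "E"),
              rule_vote(3, c("S", "E")), rule_vote(4, c("N", "E")),
              rule_vote(5, c("N", "E")))
  call <- majority_vote(a09)
  expect_identical(call$final, "E")
  expect_identical(unname(call$tally[c("E", "N", "S")]), c(5L, 2L, 1L))

  a02 <- list(rule_vote(1, "S"), rule_vote(2, c("S", "P")),
              rule_vote(3, "P"), rule_vote(4, c("S", "P")),
              rule_vote(5, c("S", "P", "N")))
  expect_identical(majority_vote(a02)$final, c("S", "P"))

  a13 <- list(rule_vote(1, "P"), rule_vote(2, applicable = FALSE),
              rule_vote(3, applicable = FALSE),
              rule_vote(4, applicable = FALSE),
              rule_vote(5, applicable = FALSE, note = "n,e or s,p,n"))
  call13 <- majority_vote(a13, restrict_to_rules = c(1, 5))
  expect_identical(call13$final, "P")
  expect_identical(call13$confidence, "low")

  expect_identical(
    majority_vote(list(rule_vote(1, applicable = FALSE)))$final,
    "unclassifiable")
})

test_that("removing a rule never adds tally mass to any mode", {
  set.seed(6)
  for (i in 1:20) {
    votes <- lapply(1:5, function(r)
      rule_vote(r, sample(c("S", "P", "N", "E"), sample(0:3, 1))))
    full <- majority_vote(votes)$tally
    sub <- majority_vote(votes, restrict_to_rules = sample(1:5, 3))$tally
    expect_true(all(sub <= full))
  }
})

test_that("the independent-origin flag restricts voting and lowers confidence", {
  b <- simulate_case(build_scenario("S", seed = 7))
  # Force the flagged pattern onto the simulated drivers: clonal in the
  # polyp, collapsed in the cancer.
  drv <- which(b$snvs$is_driver)
  b$snvs$af_villous[drv] <- 0.45
  b$snvs$af_cancer[drv] <- 0.05
  call <- classify_case(b)
  expect_true(call$independent_origin)
  expect_identical(call$confidence, "low")
  expect_true(all(vapply(call$rule_votes, function(v)
    v$rule_id %in% c(1L, 5L), logical(1))))
  expect_gte(nrow(call$features$independent_origin_evidence), 1)
})

test_that("classification recovers each simulated archetype", {
  expect_true("S" %in% classify_case(
    simulate_case(build_scenario("S", seed = 11)))$final)
  for (lab in c("P", "N", "E")) {
    call <- classify_case(simulate_case(build_scenario(lab, seed = 11)))
    expect_identical(call$final, lab)
  }
  # Noiseless settings give the exact single label, stepwise included.
  for (lab in c("S", "P", "N", "E")) {
    sc <- build_scenario(lab, list(purity_polyp = 1, purity_cancer = 1,
                                   depth = 1e6), seed = 21)
    expect_identical(classify_case(simulate_case(sc))$final, lab)
  }
})

test_that("cases without CNA data fall back to a four-rule vote", {
  b <- simulate_case(build_scenario("N", seed = 13))
  b$cna <- list()
  call <- classify_case(b)
  expect_length(call$rule_votes, 4L)
  expect_identical(call$final, "N")
  # A neutral case with no aneuploidies keeps rule 5 but inapplicable.
  b2 <- simulate_case(build_scenario("N", list(aneuploidy_timing = "none"),
                                     seed = 13))
  call2 <- classify_case(b2)
  r5 <- call2$rule_votes[[5]]
  expect_false(r5$applicable)
  expect_identical(call2$final, "N")
})
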