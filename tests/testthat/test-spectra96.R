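# Trinucleotide spectra: channel mapping, spectrum construction,
# correlation, clustering, signature matching.

test_that("channel mapping follows the pyrimidine-reference convention", {
  expect_identical(unname(channel_of("C", "A", "ACA")), 1L)
  expect_identical(names(channel_of("C", "A", "ACA")), "A[C>A]A")
  # Reverse complement maps to the same channel.
  expect_identical(unname(channel_of("G", "T", "TGT")), 1L)
  # A>G complements to T>C with reverse-complemented context.
  expect_identical(names(channel_of("A", "G", "CAG")), "C[T>C]G")
  expect_error(channel_of("C", "C", "ACA"), "differ")
  expect_error(channel_of("C", "A", "AGA"), "middle base")
  expect_error(channel_of("C", "A", "AC"), "3-mer")
})

test_that("all 192 raw combinations map with exact strand symmetry", {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n_seen <- integer(96)
  for (ref in bases) for (alt in setdiff(bases, ref))
    for (f in bases) for (t in bases) {
      ctx <- paste0(f, ref, t)
      idx <- channel_of(ref, alt, ctx)
      rc_ctx <- paste0(comp[t], comp[ref], comp[f])
      rc <- channel_of(comp[ref], comp[alt], rc_ctx)
      expect_identical(unname(idx), unname(rc))
      n_seen[idx] <- n_seen[idx] + 1L
    }
  # Each of the 96 channels is hit by exactly its two strand
  # representations over the 192 raw (ref, alt, context) triples.
  expect_true(all(n_seen == 2L))
})

test_that("spectra are normalized counts over the selected SNVs", {
  snvs <- data.frame(chrom = "1", pos = 1:100, ref = "C", alt = "T",
                     context = "ACG", af_cancer = 0.4)
  s <- mutation_spectrum(snvs, "cancer")
  expect_s3_class(s, "spectrum96")
  expect_equal(sum(s), 1, tolerance = 1e-12)
  expect_equal(unname(s[channel_of("C", "T", "ACG")]), 1)
  expect_true(all(s >= 0))
  # Input order does not matter; a merged set is the count-weighted
  # average of the parts.
  b <- simulate_case(build_scenario("N", seed = 17))
  sv <- b$snvs
  s_all <- mutation_spectrum(sv, "cancer")
  s_perm <- mutation_spectrum(sv[sample.int(nrow(sv)), ], "cancer")
  expect_equal(as.numeric(s_all), as.numeric(s_perm))
  split <- seq_len(nrow(sv)) <= nrow(sv) / 2
  sub1 <- sv[split, ]; sub2 <- sv[!split, ]
  s1 <- mutation_spectrum(sub1, "cancer")
  s2 <- mutation_spectrum(sub2, "cancer")
  n1 <- attr(s1, "n_snvs"); n2 <- attr(s2, "n_snvs")
  expect_equal(as.numeric(s_all),
               (n1 * as.numeric(s1) + n2 * as.numeric(s2)) / (n1 + n2),
               tolerance = 1e-12)
})

test_that("the simulator's deamination-like mixture is C>T dominated", {
  sc <- build_scenario("N", list(signature_weights =
                                   c(flat = 0, deamination = 1, mmr = 0)),
                       seed = 18)
  s <- mutation_spectrum(simulate_case(sc)$snvs, "cancer")
  ct <- grepl("\\[C>T\\]", names(s))
  expect_gt(sum(s[ct]), 0.5)
  npg <- grepl("^\\w\\[C>T\\]G$", names(s))
  expect_gt(sum(s[npg]), 0.5)
})

test_that("too few compartment-specific SNVs triggers the flagged fallback", {
  set.seed(19)
  n <- 200L
  snvs <- data.frame(chrom = "1", pos = 1:n, ref = "C", alt = "T",
                     context = sample(c("ACA", "ACG", "TCT"), n, TRUE),
                     af_villous = c(rep(0.4, 170), rep(0, 30)),
                     af_cancer = 0.4)
  s <- mutation_spectrum(snvs, "cancer", subtract_sample = "villous")
  expect_true(attr(s, "fallback"))
  expect_identical(attr(s, "n_snvs"), n)
  # With enough specific SNVs no fallback happens.
  s2 <- mutation_spectrum(snvs, "cancer", subtract_sample = "villous",
                          min_snvs = 20)
  expect_false(attr(s2, "fallback"))
  expect_identical(attr(s2, "n_snvs"), 30L)
})

test_that("spectrum correlation is Pearson with its closed forms", {
  u <- numeric(96); u[1] <- 1
  v <- numeric(96); v[50] <- 1
  expect_equal(spectrum_correlation(u, u), 1)
  # Two disjoint single-channel indicators: r = -1/95.
  expect_equal(spectrum_correlation(u, v), -1 / 95, tolerance = 1e-12)
  expect_equal(spectrum_correlation(u, v), spectrum_correlation(v, u))
  # Scale invariance: counts and proportions give identical r.
  set.seed(20)
  for (i in 1:10) {
    a <- rpois(96, 5); b <- rpois(96, 5)
    expect_equal(spectrum_correlation(a, b),
                 spectrum_correlation(a / sum(a), b / sum(b)),
                 tolerance = 1e-12)
  }
  expect_warning(r <- spectrum_correlation(rep(1, 96), u), "zero-variance")
  expect_true(is.na(r))
})

test_that("spectrum clustering groups identical spectra first", {
  u <- numeric(96); u[1] <- 1
  v <- numeric(96); v[50] <- 1
  hc <- cluster_spectra(list(a = u, b = u, c = v))
  expect_equal(hc$height[1], 0)
  expect_setequal(abs(hc$merge[1, ]), c(1, 2))
  # Simulated cohort with two signature mixtures separates cleanly.
  mk <- function(lab, w, seed) mutation_spectrum(
    simulate_case(build_scenario(lab, list(signature_weights = w),
                                 seed = seed))$snvs, "cancer")
  deam <- c(flat = 0, deamination = 1, mmr = 0)
  mmr <- c(flat = 0, deamination = 0, mmr = 1)
  spectra <- list(d1 = mk("N", deam, 1), d2 = mk("N", deam, 2),
                  m1 = mk("N", mmr, 3), m2 = mk("N", mmr, 4))
  hc2 <- cluster_spectra(spectra)
  groups <- cutree(hc2, k = 2)
  expect_identical(groups[["d1"]], groups[["d2"]])
  expect_identical(groups[["m1"]], groups[["m2"]])
  expect_false(groups[["d1"]] == groups[["m1"]])
})

test_that("signature matching ranks cosine similarity", {
  sig <- matrix(0, 96, 2, dimnames = list(channel_labels(), c("sigA", "sigB")))
  sig[1:10, 1] <- 1 / 10
  sig[11:20, 2] <- 1 / 10
  hit <- match_signatures(sig[, 1], sig)
  expect_equal(unname(hit$cosine["sigA"]), 1)
  expect_identical(hit$best, "sigA")
  ortho <- numeric(96); ortho[30:40] <- 1 / 11
  expect_true(all(match_signatures(ortho, sig)$cosine == 0))
  mix <- 0.8 * sig[, 1] + 0.2 * sig[, 2]
  ranks <- match_signatures(mix, sig)$cosine
  expect_identical(names(sort(ranks, decreasing = TRUE))[1], "sigA")
  expect_error(match_signatures(numeric(95), sig), "length 96")
})
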