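# Simulation scenarios: the parameter sets that define each archetypal
# mode of evolution for the synthetic-data generator.

#' Build a simulation scenario for one mode of evolution
#'
#' Returns the parameter set from which [simulate_case()] generates a
#' synthetic polyp/cancer case. Defaults are chosen per mode so that the
#' resulting shared/private SNV structure satisfies the rule-1 condition
#' of its own mode (e.g. the eruptive defaults give shared/polyp/cancer
#' fractions 0.85/0.12/0.03) and the aneuploidy timing matches the mode's
#' expectation (stepwise and parallel: cancer; eruptive: polyp; neutral:
#' random). Any field can be overridden.
#'
#' @param moe_label one of `"S"` (stepwise), `"P"` (parallel), `"N"`
#'   (neutral), `"E"` (eruptive).
#' @param overrides named list of scenario fields replacing the defaults.
#' @param seed integer RNG seed stored in the scenario; [simulate_case()]
#'   is deterministic given the scenario.
#' @return A list of class `sim_scenario` with fields `moe_label`,
#'   `n_shared`, `n_polyp_private`, `n_cancer_private`, `purity_polyp`,
#'   `purity_cancer`, `depth`, `detection_limit`, `selection_shift`,
#'   `neutral_fmin`, `neutral_fmax`, `neutral_tail_weight`,
#'   `aneuploidy_timing`, `n_cna_events`, `signature_weights`, `stages`,
#'   `seed`.
#' @export
#' @examples
#' sc <- build_scenario("E", seed = 1)
#' sc$n_shared / (sc$n_shared + sc$n_polyp_private + sc$n_cancer_private)
build_scenario <- function(moe_label, overrides = list(), seed = 1L) {
  if (!is.character(moe_label) || length(moe_label) != 1L ||
      !moe_label %in% MOE_LEVELS)
    stop("unknown moe_label '", paste(moe_label, collapse = ","),
         "': must be one of S, P, N, E")
  base <- list(
    moe_label = moe_label,
    purity_polyp = 0.7,
    purity_cancer = 0.8,
    depth = 60,
    detection_limit = 0.05,
    selection_shift = 0.6,
    neutral_fmin = 0.15,
    neutral_fmax = 0.5,
    neutral_tail_weight = 0.7,
    n_cna_events = 4L,
    signature_weights = c(flat = 0.1, deamination = 0.7, mmr = 0.2),
    stages = c("villous", "cancer"),
    seed = as.integer(seed)
  )
  per_moe <- switch(moe_label,
    S = list(n_shared = 1100L, n_polyp_private = 400L,
             n_cancer_private = 500L, aneuploidy_timing = "cancer"),
    P = list(n_shared = 400L, n_polyp_private = 550L,
             n_cancer_private = 1050L, aneuploidy_timing = "cancer"),
    N = list(n_shared = 2000L, n_polyp_private = 15L,
             n_cancer_private = 15L, aneuploidy_timing = "random"),
    E = list(n_shared = 1700L, n_polyp_private = 240L,
             n_cancer_private = 60L, aneuploidy_timing = "polyp")
  )
  sc <- utils::modifyList(c(base, per_moe), as.list(overrides))
  validate_scenario(sc)
  structure(sc, class = "sim_scenario")
}

validate_scenario <- function(sc) {
  counts <- c(sc$n_shared, sc$n_polyp_private, sc$n_cancer_private,
              sc$n_cna_events)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("all counts must be non-negative")
  for (nm in c("purity_polyp", "purity_cancer")) {
    if (sc[[nm]] <= 0 || sc[[nm]] > 1)
      stop(nm, " must be in (0, 1]")
  }
  if (sc$detection_limit <= 0 || sc$detection_limit >= 1)
    stop("detection_limit must be in (0, 1)")
  if (!(sc$neutral_fmin > 0 && sc$neutral_fmin < sc$neutral_fmax &&
        sc$neutral_fmax <= 0.5))
    stop("need 0 < neutral_fmin < neutral_fmax <= 0.5")
  if (!sc$aneuploidy_timing %in% c("none", "polyp", "cancer", "random"))
    stop("aneuploidy_timing must be none, polyp, cancer or random")
  if (!"cancer" %in% sc$stages ||
      !length(intersect(sc$stages, c("tubular", "villous"))))
    stop("stages must contain 'cancer' and at least one polyp stage")
  invisible(sc)
}

#' @export
print.sim_scenario <- function(x, ...) {
  n <- x$n_shared + x$n_polyp_private + x$n_cancer_private
  cat(sprintf(
    "Simulation scenario: MOE %s, %d SNVs (%.2f/%.2f/%.2f shared/polyp/cancer)\n",
    x$moe_label, n, x$n_shared / n, x$n_polyp_private / n,
    x$n_cancer_private / n))
  cat(sprintf(
    "  purity %.2f/%.2f, depth %g, detection limit %.2f, aneuploidy: %s (%d events), seed %d\n",
    x$purity_polyp, x$purity_cancer, x$depth, x$detection_limit,
    x$aneuploidy_timing, x$n_cna_events, x$seed))
  invisible(x)
}

#' Sample subclonal frequencies from the neutral 1/f model
#'
#' Draws i.i.d. frequencies with density proportional to 1/f^2 on
#' \[`f_min`, `f_max`\] by inverting the closed-form CDF
#' `F(f) = (1/f_min - 1/f) / (1/f_min - 1/f_max)`. Under neutral growth
#' the cumulative number of subclonal mutations above frequency f grows
#' linearly in 1/f; these draws are the "true" pre-noise frequencies on
#' the half scale where a clonal heterozygous variant sits at 0.5
#' (cancer-cell fraction = 2f).
#'
#' @param n number of draws (>= 1).
#' @param f_min,f_max support bounds, 0 < f_min < f_max <= 0.5.
#' @param seed optional seed for a self-contained deterministic draw.
#' @return Numeric vector of length `n` inside \[`f_min`, `f_max`\].
#' @export
#' @examples
#' f <- sample_neutral_subclonal_afs(1000, 0.05, 0.25, seed = 7)
#' range(f)
sample_neutral_subclonal_afs <- function(n, f_min, f_max, seed = NULL) {
  if (!is.finite(n) || n < 1) stop("n must be >= 1")
  if (!(f_min > 0 && f_min < f_max && f_max <= 0.5))
    stop("need 0 < f_min < f_max <= 0.5")
  with_seed(seed, {
    u <- runif(n)
    1 / (1 / f_min - u * (1 / f_min - 1 / f_max))
  })
}

#' Sequencing observation model for a true cell fraction
#'
#' Converts true cancer-cell fractions into observed allele fractions
#' under the heterozygous-diploid assumption: expected AF =
#' `purity * ccf / 2`. Site depth is Poisson around `depth` (truncated at
#' >= 1 read) and the variant read count is binomial, so the observed AF
#' is k/d. An SNV is undetected in the sample when its observed AF falls
#' below `detection_limit`; the raw observed AF is still reported, mirroring
#' re-quantification of known variant sites below the calling limit.
#'
#' @param ccf numeric vector of cancer-cell fractions in \[0, 1\] (0 =
#'   variant absent from the sample).
#' @param purity fraction of neoplastic cells in the sample, (0, 1\].
#' @param depth mean sequencing depth.
#' @param detection_limit minimum observable AF (default 0.05).
#' @param seed optional seed for a self-contained deterministic draw.
#' @return `data.frame` with columns `af` (observed k/d), `depth` (site
#'   depth d) and `detected` (logical, `af >= detection_limit`).
#' @export
#' @examples
#' apply_observation_model(1, purity = 0.6, depth = 1e6, seed = 1)$af
apply_observation_model <- function(ccf, purity, depth,
                                    detection_limit = 0.05, seed = NULL) {
  stopifnot(all(ccf >= 0 & ccf <= 1), purity > 0, purity <= 1, depth > 0)
  with_seed(seed, {
    n <- length(ccf)
    # Poisson truncated at >= 1 via inverse CDF conditioning.
    d <- qpois(runif(n, min = ppois(0, depth), max = 1), depth)
    p <- pmin(purity * ccf * 0.5, 1)
    k <- rbinom(n, d, p)
    af <- k / d
    data.frame(af = af, depth = d,
               detected = af >= detection_limit)
  })
}

#' Fit the neutral 1/f model to subclonal frequencies
#'
#' Regresses the cumulative mutation count `M(f)` (number of mutations
#' with frequency >= f) against `1/f` over a grid spanning the subclonal
#' range, the standard linearity check for neutral evolution.
#'
#' @param f numeric vector of subclonal frequencies.
#' @param f_min,f_max grid bounds (defaults: observed range).
#' @param n_grid number of grid points (default 20).
#' @return List with `r_squared`, `slope`, `intercept` and the `grid`
#'   data.frame (`f`, `inv_f`, `M`).
#' @export
neutral_tail_fit <- function(f, f_min = min(f), f_max = max(f),
                             n_grid = 20L) {
  if (length(f) < n_grid) stop("too few frequencies for the grid")
  grid <- seq(f_min, f_max, length.out = n_grid)
  M <- vapply(grid, function(g) sum(f >= g), numeric(1))
  fit <- lm(M ~ I(1 / grid))
  list(r_squared = summary(fit)$r.squared,
       slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       grid = data.frame(f = grid, inv_f = 1 / grid, M = M))
}
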