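# Synthetic case generation: archetypal clonal structures per mode of
# evolution, pushed through the sequencing observation model.

# Cancer-cell-fraction layouts per mode. Each returns a data.frame with
# columns class (shared / polyp_private / cancer_private), ccf_polyp and
# ccf_cancer. These archetypes are frozen design choices mirroring the
# four schematic modes: the numbers are documented in the methods
# vignette.
moe_ccf_layout <- function(sc) {
  lab <- sc$moe_label
  shift <- sc$selection_shift
  layer <- function(class, ccf_polyp, ccf_cancer) {
    n <- max(length(ccf_polyp), length(ccf_cancer))
    data.frame(class = rep_len(class, n),
               ccf_polyp = rep_len(ccf_polyp, n),
               ccf_cancer = rep_len(ccf_cancer, n))[seq_len(n), ,
                                                    drop = FALSE]
  }
  if (lab == "S") {
    n_clonal <- round(0.7 * sc$n_shared)
    n_sweep <- sc$n_shared - n_clonal
    shared <- layer("shared",
                    c(rep(1, n_clonal), rep(0.25, n_sweep)),
                    rep(1, sc$n_shared))
    pp <- c(polyp = 0.25, cancer = 0)
    cp <- c(polyp = 0, cancer = min(1, 0.25 + shift))
  } else if (lab == "P") {
    shared <- layer("shared", rep(1, sc$n_shared), rep(1, sc$n_shared))
    pp <- c(polyp = 1, cancer = 0)
    cp <- c(polyp = 0, cancer = 1)
  } else if (lab == "N") {
    n_tail <- round(sc$neutral_tail_weight * sc$n_shared)
    n_clonal <- sc$n_shared - n_tail
    f <- sample_neutral_subclonal_afs(n_tail, sc$neutral_fmin,
                                      sc$neutral_fmax)
    shared <- layer("shared", c(rep(1, n_clonal), 2 * f),
                    c(rep(1, n_clonal), 2 * f))
    pp <- c(polyp = 0.3, cancer = 0)
    cp <- c(polyp = 0, cancer = 0.3)
  } else { # E
    n_clonal <- round(0.4 * sc$n_shared)
    n_fam <- round((sc$n_shared - n_clonal) / 3)
    n_fam3 <- max(0, sc$n_shared - n_clonal - 2 * n_fam)
    shared <- layer("shared",
                    c(rep(1, n_clonal), rep(0.75, n_fam), rep(0.55, n_fam),
                      rep(0.40, n_fam3)),
                    c(rep(1, n_clonal), rep(0.90, n_fam), rep(0.80, n_fam),
                      rep(0.70, n_fam3)))
    pp <- c(polyp = 0.25, cancer = 0)
    cp <- c(polyp = 0, cancer = 0.25)
  }
  rbind(
    shared,
    layer("polyp_private", rep(pp[["polyp"]], sc$n_polyp_private),
          rep(pp[["cancer"]], sc$n_polyp_private)),
    layer("cancer_private", rep(cp[["polyp"]], sc$n_cancer_private),
          rep(cp[["cancer"]], sc$n_cancer_private))
  )
}

#' Simulate paired copy-number profiles with a given aneuploidy timing
#'
#' Generates whole-chromosome or arm-scale deletion/duplication events on
#' the autosomes. With `timing = "polyp"` every event is present in both
#' profiles (aneuploidies started before the polyp stage and persisted);
#' with `"cancer"` events appear only in the cancer profile; with
#' `"random"` each event is independently assigned to start in the polyp
#' (and persist) or in the cancer.
#'
#' @param timing one of `"none"`, `"polyp"`, `"cancer"`, `"random"`.
#' @param n_events number of events (0..22; chromosomes are drawn without
#'   replacement).
#' @param seed optional seed for a self-contained deterministic draw.
#' @param sample_ids ids for the two returned profiles.
#' @return Named list of two [cna_profile] objects (`polyp`, `cancer`).
#' @export
simulate_cna_profiles <- function(timing, n_events, seed = NULL,
                                  sample_ids = c("polyp", "cancer")) {
  if (!timing %in% c("none", "polyp", "cancer", "random"))
    stop("timing must be none, polyp, cancer or random")
  if (n_events > 22L) stop("at most 22 events (one per autosome)")
  with_seed(seed, {
    empty <- data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), state = character(0))
    if (timing == "none" || n_events == 0L) {
      return(list(
        polyp = cna_profile(sample_ids[1L], empty),
        cancer = cna_profile(sample_ids[2L], empty)))
    }
    chroms <- sample(names(AUTOSOME_LENGTHS), n_events)
    len <- AUTOSOME_LENGTHS[chroms]
    whole <- runif(n_events) < 0.5
    p_arm <- runif(n_events) < 0.5
    # Arm-scale proxy: the proximal 40% of the chromosome stands in for
    # the short arm, the rest for the long arm.
    start <- ifelse(whole, 0, ifelse(p_arm, 0, round(0.4 * len)))
    end <- ifelse(whole, len, ifelse(p_arm, round(0.4 * len), len))
    state <- sample(c("del", "dup"), n_events, replace = TRUE)
    in_polyp <- switch(timing,
                       polyp = rep(TRUE, n_events),
                       cancer = rep(FALSE, n_events),
                       random = runif(n_events) < 0.5)
    ev <- data.frame(chrom = chroms, start = start, end = end,
                     state = state)
    list(polyp = cna_profile(sample_ids[1L], ev[in_polyp, , drop = FALSE]),
         cancer = cna_profile(sample_ids[2L], ev))
  })
}

#' Simulate a complete polyp/cancer case
#'
#' Generates a [case_bundle] whose SNV allele-frequency structure and
#' copy-number profiles follow the scenario's mode-of-evolution archetype:
#'
#' * stepwise: a clonal shared cluster, a shared lineage that is subclonal
#'   in the polyp and swept to clonality in the cancer, a low-frequency
#'   polyp-private cluster, and a cancer-private cluster swept toward the
#'   clonal mode by `selection_shift`; aneuploidies cancer-only.
#' * parallel: a minority clonal trunk; polyp- and cancer-private clusters
#'   clonal within their own compartment; aneuploidies cancer-only.
#' * neutral: almost everything shared -- a clonal cluster plus a 1/f
#'   subclonal tail present in both compartments; negligible privates;
#'   aneuploidy timing random.
#' * eruptive: a large shared fraction made of a clonal cluster plus early
#'   subclonal families at several cell fractions in both compartments, a
#'   polyp-private cluster, under 5% cancer-private; aneuploidies starting
#'   in the polyp.
#'
#' Each SNV carries a trinucleotide context drawn from the scenario's
#' signature mixture. The generator is deterministic given the scenario
#' (including its seed).
#'
#' @param scenario a [build_scenario()] object.
#' @param case_id case identifier (default `"sim_<label><seed>"`).
#' @return A [case_bundle]. The SNV table carries truth columns `class`
#'   (shared / polyp_private / cancer_private), `ccf_polyp`, `ccf_cancer`
#'   alongside the observed per-sample `af_*` columns.
#' @export
#' @examples
#' bundle <- simulate_case(build_scenario("N", seed = 3))
#' partition_snvs(bundle$snvs, "villous", "cancer")$f_shared
simulate_case <- function(scenario,
                          case_id = paste0("sim_", scenario$moe_label,
                                           scenario$seed)) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  truth <- moe_ccf_layout(scenario)
  n <- nrow(truth)

  chrom <- sample(names(AUTOSOME_LENGTHS), n, replace = TRUE,
                  prob = AUTOSOME_LENGTHS / sum(AUTOSOME_LENGTHS))
  pos <- floor(runif(n, 1, AUTOSOME_LENGTHS[chrom])) # 1-based positions
  ctx <- sample_contexts(n, scenario$signature_weights)

  snvs <- data.frame(chrom = chrom, pos = pos, ref = ctx$ref,
                     alt = ctx$alt, context = ctx$context,
                     gene = NA_character_, is_driver = FALSE,
                     class = truth$class, ccf_polyp = truth$ccf_polyp,
                     ccf_cancer = truth$ccf_cancer,
                     stringsAsFactors = FALSE)
  # Driver annotation: a few clonal trunk mutations, as in the classical
  # adenoma-carcinoma sequence.
  clonal <- which(truth$class == "shared" & truth$ccf_polyp == 1 &
                    truth$ccf_cancer == 1)
  drivers <- utils::head(clonal, 3L)
  snvs$gene[drivers] <- c("APC", "KRAS", "TP53")[seq_along(drivers)]
  snvs$is_driver[drivers] <- TRUE

  stages <- scenario$stages
  purity <- vapply(stages, function(st) switch(
    st,
    cancer = scenario$purity_cancer,
    villous = scenario$purity_polyp,
    # A tubular stage, when requested, is modeled as an earlier, less
    # pure snapshot of the same polyp compartment.
    tubular = max(0.3, scenario$purity_polyp - 0.15)), numeric(1))
  for (st in stages) {
    ccf <- if (st == "cancer") truth$ccf_cancer else truth$ccf_polyp
    obs <- apply_observation_model(ccf, purity[[st]], scenario$depth,
                                   scenario$detection_limit)
    snvs[[af_col(st)]] <- obs$af
  }

  prof <- simulate_cna_profiles(scenario$aneuploidy_timing,
                                scenario$n_cna_events)
  cna <- list()
  for (st in setdiff(stages, "cancer"))
    cna[[st]] <- cna_profile(st, prof$polyp$segments)
  cna$cancer <- cna_profile("cancer", prof$cancer$segments)

  samples <- data.frame(id = stages, tissue = stages,
                        purity = unname(purity),
                        stringsAsFactors = FALSE)
  case_bundle(case_id, samples, snvs, cna, scenario = scenario)
}

#' Construct a case bundle
#'
#' A case bundle holds everything known about one patient case: the
#' ordered tissue samples (polyp stage(s) and cancer), the somatic SNV
#' table with one AF column per sample, and optional per-sample CNA
#' profiles.
#'
#' @param case_id case identifier.
#' @param samples `data.frame` with columns `id` and `tissue` (tissue in
#'   normal / tubular / villous / cancer); exactly one cancer sample and
#'   at least one polyp-stage sample.
#' @param snvs SNV table: `chrom`, `pos`, `ref`, `alt`, optional
#'   `context`, `gene`, `is_driver`, and `af_<sample id>` columns.
#' @param cna named list of [cna_profile] objects keyed by sample id
#'   (optional).
#' @param scenario optional provenance ([build_scenario()] object for
#'   simulated cases).
#' @return A list of class `case_bundle`.
#' @export
case_bundle <- function(case_id, samples, snvs, cna = list(),
                        scenario = NULL) {
  stopifnot(is.data.frame(samples), all(c("id", "tissue") %in% names(samples)),
            is.data.frame(snvs))
  if (sum(samples$tissue == "cancer") != 1L)
    stop("a case bundle needs exactly one cancer sample")
  if (!any(samples$tissue %in% c("tubular", "villous")))
    stop("a case bundle needs at least one polyp-stage sample")
  missing_af <- setdiff(af_col(samples$id), names(snvs))
  if (length(missing_af))
    stop("SNV table lacks AF column(s): ", paste(missing_af, collapse = ", "))
  if (length(cna) && is.null(names(cna)))
    stop("cna must be a named list keyed by sample id")
  structure(list(case_id = case_id, samples = samples, snvs = snvs,
                 cna = cna, scenario = scenario),
            class = "case_bundle")
}

#' @export
print.case_bundle <- function(x, ...) {
  cat(sprintf("Case bundle '%s': %d SNVs, samples: %s\n", x$case_id,
              nrow(x$snvs),
              paste(sprintf("%s (%s)", x$samples$id, x$samples$tissue),
                    collapse = ", ")))
  if (length(x$cna))
    cat("  CNA profiles:", paste(names(x$cna), collapse = ", "), "\n")
  invisible(x)
}

# The designated polyp sample for two-sample rules: the most advanced
# polyp stage present (villous over tubular).
polyp_sample_id <- function(bundle) {
  ids <- bundle$samples$id[bundle$samples$tissue %in% c("villous", "tubular")]
  tissues <- bundle$samples$tissue[match(ids, bundle$samples$id)]
  if ("villous" %in% tissues) ids[tissues == "villous"][1L] else ids[1L]
}

cancer_sample_id <- function(bundle) {
  bundle$samples$id[bundle$samples$tissue == "cancer"][1L]
}
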