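# The five classification rules and the majority vote.
#
# Each rule returns the set of modes of evolution (S, P, N, E) compatible
# with its feature; the final call is the argmax set of the per-mode
# tally over the applicable rules.

#' Construct a rule vote
#'
#' @param rule_id integer rule number (1..5).
#' @param votes character subset of `c("S","P","N","E")`; empty with
#'   `applicable = TRUE` means the feature matches no mode.
#' @param applicable whether the rule could be evaluated.
#' @param note free-text annotation (e.g. why a rule abstained).
#' @return A list of class `rule_vote`.
#' @export
rule_vote <- function(rule_id, votes = character(0), applicable = TRUE,
                      note = "") {
  votes <- unique(as.character(votes))
  stopifnot(all(votes %in% MOE_LEVELS))
  structure(list(rule_id = as.integer(rule_id),
                 votes = votes[order(match(votes, MOE_LEVELS))],
                 applicable = isTRUE(applicable), note = note),
            class = "rule_vote")
}

#' @export
print.rule_vote <- function(x, ...) {
  cat(sprintf("rule #%d: %s%s\n", x$rule_id,
              if (!x$applicable) "inapplicable"
              else if (!length(x$votes)) "matches no MOE"
              else paste(x$votes, collapse = ","),
              if (nzchar(x$note)) paste0(" (", x$note, ")") else ""))
  invisible(x)
}

#' Rule 1: fraction of private relative to shared SNVs
#'
#' Stepwise needs sizable private fractions in both compartments on top
#' of a large shared core (cancer-private >= 10%, polyp-private >= 10%,
#' shared >= 40%); parallel needs a private majority (>= 50% on either
#' side); neutral has almost no privates (< 5% each); eruptive combines
#' near-absent cancer-privates (< 5%) with >= 10% polyp-private and
#' >= 80% shared. Conditions are tested independently, so a fraction
#' vector can legitimately vote for several modes.
#'
#' @param partition an [partition_snvs()] result.
#' @return A [rule_vote] for rule 1.
#' @export
rule1_fractions <- function(partition) {
  stopifnot(inherits(partition, "af_partition"))
  fs <- partition$f_shared; fp <- partition$f_polyp
  fc <- partition$f_cancer
  votes <- character(0)
  if (fc >= 0.10 && fp >= 0.10 && fs >= 0.40) votes <- c(votes, "S")
  if (fc >= 0.50 || fp >= 0.50) votes <- c(votes, "P")
  if (fc < 0.05 && fp < 0.05) votes <- c(votes, "N")
  if (fc < 0.05 && fp >= 0.10 && fs >= 0.80) votes <- c(votes, "E")
  rule_vote(1L, votes,
            note = if (!length(votes)) "fractions match no MOE" else "")
}

#' Rule 2: gap in the SNV AF distribution in polyp and in cancer
#'
#' Gap in both compartments: stepwise or parallel. Gap in neither:
#' neutral. Under the default `"table"` convention a cancer-only gap
#' votes eruptive and a polyp-only gap matches no mode (the pattern of
#' the two suspected independent-origin cases); `"narrative"` swaps the
#' two directions.
#'
#' @param polyp_has_gap,cancer_has_gap logical gap flags from
#'   [cluster_afs()] (`NA` = not assessable, rule abstains).
#' @param convention `"table"` (default) or `"narrative"`.
#' @return A [rule_vote] for rule 2.
#' @export
rule2_gaps <- function(polyp_has_gap, cancer_has_gap,
                       convention = c("table", "narrative")) {
  convention <- match.arg(convention)
  if (is.na(polyp_has_gap) || is.na(cancer_has_gap))
    return(rule_vote(2L, applicable = FALSE,
                     note = "gap not assessable"))
  if (polyp_has_gap && cancer_has_gap) return(rule_vote(2L, c("S", "P")))
  if (!polyp_has_gap && !cancer_has_gap) return(rule_vote(2L, "N"))
  eruptive_pattern <- if (convention == "table") {
    !polyp_has_gap && cancer_has_gap
  } else {
    polyp_has_gap && !cancer_has_gap
  }
  if (eruptive_pattern) rule_vote(2L, "E")
  else rule_vote(2L, character(0), note = "matches no MOE")
}

#' Rule 3: position of private clusters relative to the shared cluster
#'
#' No private clusters on either side is the neutral pattern. A
#' polyp-private cluster below the shared cluster votes stepwise; both
#' sides below votes eruptive as well; both sides at the shared position
#' votes parallel. A private cluster above the shared cluster matches no
#' mode and raises a polyclonal-suspicion note (the independent-origin
#' pattern).
#'
#' @param polyp_private_pos,cancer_private_pos positions from
#'   [relative_position()].
#' @return A [rule_vote] for rule 3.
#' @export
rule3_positions <- function(polyp_private_pos, cancer_private_pos) {
  ok <- c("lower", "equal", "higher", "none")
  stopifnot(polyp_private_pos %in% ok, cancer_private_pos %in% ok)
  votes <- character(0)
  note <- ""
  if (polyp_private_pos == "none" && cancer_private_pos == "none") {
    votes <- "N"
  } else {
    if (polyp_private_pos == "lower") votes <- c(votes, "S")
    if (polyp_private_pos == "lower" && cancer_private_pos == "lower")
      votes <- c(votes, "E")
    if (polyp_private_pos == "equal" && cancer_private_pos == "equal")
      votes <- c(votes, "P")
    if (polyp_private_pos == "higher" || cancer_private_pos == "higher")
      note <- "private cluster above shared: polyclonal origin suspected"
  }
  if (!length(votes) && !nzchar(note)) note <- "positions match no MOE"
  rule_vote(3L, votes, note = note)
}

#' Rule 4: are early shared and later shared SNVs indistinguishable?
#'
#' Shared SNVs forming a single AF cluster in both compartments mean the
#' early clonal mutations cannot be told apart from later shared ones --
#' the neutral/eruptive pattern. A multi-cluster shared distribution in
#' either compartment votes stepwise/parallel.
#'
#' @param shared_afs_polyp,shared_afs_cancer AFs of the shared SNVs in
#'   each sample.
#' @param config a [moe_config()] supplying the clustering parameters.
#' @return A [rule_vote] for rule 4 (inapplicable when either side has
#'   fewer than `config$min_afs` values).
#' @export
rule4_shared_structure <- function(shared_afs_polyp, shared_afs_cancer,
                                   config = moe_config()) {
  cl <- function(afs) cluster_afs(
    afs, bandwidth = config$bandwidth,
    min_cluster_weight = config$min_cluster_weight,
    min_gap_width = config$min_gap_width,
    density_ratio = config$density_ratio,
    lower = config$detection_limit, min_n = config$min_afs)
  cp <- cl(shared_afs_polyp)
  cc <- cl(shared_afs_cancer)
  if (!cp$assessable || !cc$assessable)
    return(rule_vote(4L, applicable = FALSE,
                     note = "too few shared SNVs"))
  if (nrow(cp$clusters) == 1L && nrow(cc$clusters) == 1L)
    rule_vote(4L, c("N", "E"))
  else rule_vote(4L, c("S", "P"))
}

#' Rule 5: in which compartment do numerous aneuploidies start?
#'
#' A sample is aneuploid when more than `threshold` of its autosomal
#' genome is copy-number altered. Aneuploidies already present in the
#' polyp vote neutral/eruptive (neutral because drift can fix
#' aneuploidies at any time, so every aneuploid case keeps the neutral
#' assignment); aneuploidies confined to the cancer vote
#' stepwise/parallel/neutral. Without significant aneuploidies the rule
#' abstains, as it does when the polyp fraction falls within `margin` of
#' the threshold (ambiguous timing).
#'
#' @param polyp_profile,cancer_profile [cna_profile] objects.
#' @param threshold altered-genome-fraction cutoff (default 0.10).
#' @param margin ambiguity half-width around the threshold (default
#'   0.02).
#' @return A [rule_vote] for rule 5.
#' @export
rule5_aneuploidy_timing <- function(polyp_profile, cancer_profile,
                                    threshold = 0.10, margin = 0.02) {
  stopifnot(inherits(polyp_profile, "cna_profile"),
            inherits(cancer_profile, "cna_profile"))
  fp <- polyp_profile$autosomal_altered_fraction
  fc <- cancer_profile$autosomal_altered_fraction
  if (abs(fp - threshold) <= margin)
    return(rule_vote(5L, applicable = FALSE, note = "n,e or s,p,n"))
  if (fp > threshold) return(rule_vote(5L, c("N", "E")))
  if (fc > threshold) return(rule_vote(5L, c("S", "P", "N")))
  rule_vote(5L, applicable = FALSE, note = "no significant aneuploidies")
}

#' Combine rule votes by majority
#'
#' Tallies, for each mode, the number of applicable rules whose vote set
#' contains it; the final call is the set of modes attaining the maximum
#' tally (ties are reported as sets, e.g. stepwise/parallel). Confidence
#' is low when the independent-origin flag is set or fewer than three
#' rules were applicable. When the flag is set and no explicit
#' restriction is given, only rules 1 and 5 are consulted, since the AF
#' distribution shape rules presuppose a common clonal origin.
#'
#' @param rule_votes list of [rule_vote] objects.
#' @param restrict_to_rules optional integer vector of rule ids to use.
#' @param independent_origin logical flag from
#'   [flag_independent_origin()].
#' @param case_id case identifier carried into the call.
#' @return A list of class `moe_call`: `case_id`, `tally` (named integer),
#'   `final` (character subset of S/P/N/E, or `"unclassifiable"`),
#'   `confidence` (`"normal"`/`"low"`), `independent_origin`,
#'   `n_applicable`, `rule_votes`.
#' @export
#' @examples
#' v <- list(rule_vote(1, "E"), rule_vote(2, "E"), rule_vote(3, c("S", "E")),
#'           rule_vote(4, c("N", "E")), rule_vote(5, c("N", "E")))
#' majority_vote(v)$final
majority_vote <- function(rule_votes, restrict_to_rules = NULL,
                          independent_origin = FALSE, case_id = NA) {
  stopifnot(all(vapply(rule_votes, inherits, logical(1), "rule_vote")))
  if (independent_origin && is.null(restrict_to_rules))
    restrict_to_rules <- c(1L, 5L)
  if (!is.null(restrict_to_rules)) {
    rule_votes <- Filter(function(v) v$rule_id %in% restrict_to_rules,
                         rule_votes)
  }
  applicable <- Filter(function(v) v$applicable, rule_votes)
  tally <- setNames(integer(length(MOE_LEVELS)), MOE_LEVELS)
  for (v in applicable) tally[v$votes] <- tally[v$votes] + 1L
  final <- if (length(applicable) == 0L || max(tally) == 0L)
    "unclassifiable"
  else MOE_LEVELS[tally == max(tally)]
  confidence <- if (independent_origin || length(applicable) < 3L)
    "low" else "normal"
  structure(list(case_id = case_id, tally = tally, final = final,
                 confidence = confidence,
                 independent_origin = independent_origin,
                 n_applicable = length(applicable),
                 rule_votes = rule_votes),
            class = "moe_call")
}

#' @export
print.moe_call <- function(x, ...) {
  cat(sprintf("MOE call%s: %s (confidence %s)\n",
              if (!is.na(x$case_id)) paste0(" for ", x$case_id) else "",
              paste(x$final, collapse = ","), x$confidence))
  cat("  tally:", paste(sprintf("%s=%d", names(x$tally), x$tally),
                        collapse = " "),
      sprintf(" (%d applicable rule(s))\n", x$n_applicable))
  if (x$independent_origin)
    cat("  independent polyp/cancer origin suspected; rules restricted\n")
  for (v in x$rule_votes) {
    cat("  "); print(v)
  }
  invisible(x)
}

#' Classify a case's mode of evolution
#'
#' Runs the full pipeline on a case bundle: shared/private partition,
#' per-axis AF clustering and gap detection, relative cluster positions,
#' shared-structure clustering, aneuploidy timing, the
#' independent-origin check, and the majority vote over rules 1-5.
#'
#' For rule 2, each compartment's gap is assessed on the AF values of the
#' full SNV union on that compartment's axis (SNVs private to the other
#' compartment contribute their re-quantified, typically near-zero, AF),
#' because the gap patterns of the four modes are defined on the joint
#' distribution of all somatic SNVs of the case. Rules 3 and 4 and the
#' purity estimate use detected-only AFs. A private side with fewer than
#' `config$min_afs` detected SNVs has no assessable cluster and counts
#' as "no private mutations" for rule 3. Cases without CNA profiles are
#' classified by the four AF rules alone.
#'
#' @param bundle a [case_bundle].
#' @param config a [moe_config()].
#' @return A `moe_call` (see [majority_vote()]) with a `features` element
#'   recording the partition fractions, gap flags, cluster positions and
#'   purity estimates that fed the rules.
#' @export
#' @examples
#' call <- classify_case(simulate_case(build_scenario("S", seed = 11)))
#' call$final
classify_case <- function(bundle, config = moe_config()) {
  stopifnot(inherits(bundle, "case_bundle"))
  ps <- polyp_sample_id(bundle)
  cs <- cancer_sample_id(bundle)
  snvs <- bundle$snvs
  lim <- config$detection_limit

  part <- partition_snvs(snvs, ps, cs, detection_limit = lim)
  cl <- function(afs, lower) cluster_afs(
    afs, bandwidth = config$bandwidth,
    min_cluster_weight = config$min_cluster_weight,
    min_gap_width = config$min_gap_width,
    density_ratio = config$density_ratio, lower = lower,
    min_n = config$min_afs)

  # Union axes for gap detection: every SNV detected in at least one
  # compartment contributes its AF on both axes (0 when absent).
  det_u <- is_detected(snv_af(snvs, ps), lim) |
    is_detected(snv_af(snvs, cs), lim)
  axis_af <- function(sample) {
    af <- snv_af(snvs, sample)[det_u]
    af[is.na(af)] <- 0
    af
  }
  axis_p <- cl(axis_af(ps), lower = 0)
  axis_c <- cl(axis_af(cs), lower = 0)

  shared_p <- snv_af(part$shared, ps)
  shared_c <- snv_af(part$shared, cs)
  shared_cl_p <- cl(shared_p, lower = lim)
  shared_cl_c <- cl(shared_c, lower = lim)
  pos_p <- relative_position(cl(snv_af(part$polyp_private, ps), lower = lim),
                             shared_cl_p, delta = config$delta)
  pos_c <- relative_position(cl(snv_af(part$cancer_private, cs), lower = lim),
                             shared_cl_c, delta = config$delta)

  votes <- list(
    rule1_fractions(part),
    rule2_gaps(axis_p$has_gap, axis_c$has_gap,
               convention = config$rule2_convention),
    rule3_positions(pos_p, pos_c),
    rule4_shared_structure(shared_p, shared_c, config = config)
  )
  if (!is.null(bundle$cna[[ps]]) && !is.null(bundle$cna[[cs]])) {
    votes <- c(votes, list(rule5_aneuploidy_timing(
      bundle$cna[[ps]], bundle$cna[[cs]],
      threshold = config$aneuploidy_threshold,
      margin = config$aneuploidy_margin)))
  }

  indep <- flag_independent_origin(
    snvs, ps, cs, kappa = config$kappa, detection_limit = lim,
    driver_af_min = config$driver_af_min,
    driver_genes = config$driver_genes)

  call <- majority_vote(votes, independent_origin = indep$flag,
                        case_id = bundle$case_id)
  call$features <- list(
    polyp_sample = ps, cancer_sample = cs,
    fractions = c(shared = part$f_shared, polyp = part$f_polyp,
                  cancer = part$f_cancer),
    n_union = part$n_union,
    polyp_has_gap = axis_p$has_gap, cancer_has_gap = axis_c$has_gap,
    polyp_axis_clusters = axis_p, cancer_axis_clusters = axis_c,
    polyp_private_position = pos_p, cancer_private_position = pos_c,
    purity = c(polyp = estimate_purity(shared_p, config),
               cancer = estimate_purity(shared_c, config)),
    independent_origin_evidence = indep$evidence
  )
  call
}
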