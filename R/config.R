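#' Analysis configuration
#'
#' Bundles every tunable threshold of the MOE classification pipeline into
#' one list so that a run is fully described by its configuration. The
#' defaults encode the published rule thresholds (the rule-1 percentages,
#' the 10% aneuploid-genome cutoff) and the package's own
#' operationalization choices for quantities the rules leave qualitative
#' (kernel bandwidth, gap width, cluster-position tolerance).
#'
#' @param detection_limit minimum allele fraction at which an SNV counts as
#'   detected in a sample (default 0.05).
#' @param consensus_min_callers minimum number of variant callers that must
#'   report an SNV for it to be kept by [consensus_merge()] (default 3).
#' @param bandwidth Gaussian kernel bandwidth, on the AF scale, used by
#'   [cluster_afs()] (default 0.03).
#' @param density_ratio fraction of the global density maximum below which
#'   the AF density is considered empty (default 0.10).
#' @param min_cluster_weight minimum fraction of SNVs a density region must
#'   hold to count as a cluster (default 0.05).
#' @param min_gap_width minimum width, in AF units, of an inter-cluster
#'   interval reported as a gap (default 0.08).
#' @param min_afs minimum number of AF values required before clustering or
#'   purity estimation is attempted (default 20); below this the feature is
#'   "not assessable".
#' @param delta tolerance, in AF units, for calling a private cluster
#'   position equal to the shared cluster (default 0.10).
#' @param kappa independent-origin trigger: a driver whose cancer AF falls
#'   below `kappa` times its polyp AF raises the flag (default 0.5).
#' @param driver_af_min minimum polyp AF for a driver SNV to be considered
#'   by the independent-origin check (default 0.25).
#' @param driver_genes genes treated as drivers when the SNV table carries
#'   no `is_driver` annotation (default APC, KRAS, TP53).
#' @param aneuploidy_threshold fraction of the autosomal genome that must
#'   be copy-number altered for a sample to count as aneuploid for rule 5
#'   (default 0.10).
#' @param aneuploidy_margin half-width of the band around
#'   `aneuploidy_threshold` in which the polyp aneuploidy status is judged
#'   ambiguous and rule 5 abstains (default 0.02).
#' @param rule2_convention `"table"` (default) maps a cancer-only AF gap to
#'   the eruptive mode and flags a polyp-only gap as matching no mode;
#'   `"narrative"` swaps the two directions.
#' @param min_spectrum_snvs minimum number of compartment-specific SNVs for
#'   a mutation spectrum before [mutation_spectrum()] falls back to all
#'   SNVs of the sample (default 50).
#'
#' @return A named list of class `moe_config`.
#' @seealso [read_config()], [write_config()]
#' @export
#' @examples
#' cfg <- moe_config(bandwidth = 0.02)
#' cfg$bandwidth
moe_config <- function(detection_limit = 0.05,
                       consensus_min_callers = 3,
                       bandwidth = 0.03,
                       density_ratio = 0.10,
                       min_cluster_weight = 0.05,
                       min_gap_width = 0.08,
                       min_afs = 20,
                       delta = 0.10,
                       kappa = 0.5,
                       driver_af_min = 0.25,
                       driver_genes = c("APC", "KRAS", "TP53"),
                       aneuploidy_threshold = 0.10,
                       aneuploidy_margin = 0.02,
                       rule2_convention = c("table", "narrative"),
                       min_spectrum_snvs = 50) {
  rule2_convention <- match.arg(rule2_convention)
  cfg <- list(
    detection_limit = detection_limit,
    consensus_min_callers = consensus_min_callers,
    bandwidth = bandwidth,
    density_ratio = density_ratio,
    min_cluster_weight = min_cluster_weight,
    min_gap_width = min_gap_width,
    min_afs = min_afs,
    delta = delta,
    kappa = kappa,
    driver_af_min = driver_af_min,
    driver_genes = driver_genes,
    aneuploidy_threshold = aneuploidy_threshold,
    aneuploidy_margin = aneuploidy_margin,
    rule2_convention = rule2_convention,
    min_spectrum_snvs = min_spectrum_snvs
  )
  for (nm in c("detection_limit", "bandwidth", "density_ratio",
               "min_cluster_weight", "min_gap_width", "delta", "kappa",
               "driver_af_min", "aneuploidy_threshold",
               "aneuploidy_margin")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("config field '%s' must be a single value in [0, 1]", nm))
  }
  structure(cfg, class = "moe_config")
}

#' Read / write a configuration as YAML
#'
#' @param path file path of a YAML file whose keys are [moe_config()]
#'   arguments; missing keys take their defaults.
#' @return `read_config()` returns a `moe_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(moe_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(moe_config, vals)
}

#' @rdname read_config
#' @param config a `moe_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "moe_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.moe_config <- function(x, ...) {
  cat("MOE analysis configuration\n")
  for (nm in names(x))
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}
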