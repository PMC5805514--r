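# Allele-frequency feature extraction: the quantities the five
# classification rules consume.

#' Partition SNVs into shared and private sets
#'
#' An SNV is detected in a sample when its AF there is at or above the
#' detection limit. SNVs detected in both compartments are shared;
#' otherwise they are private to the compartment where they are detected.
#' Fractions are taken over the union of detected SNVs.
#'
#' @param snvs SNV table with `af_<sample>` columns.
#' @param polyp_sample,cancer_sample sample ids of the two compartments.
#' @param detection_limit AF detection threshold (default 0.05).
#' @return List of class `af_partition`: `shared`, `polyp_private`,
#'   `cancer_private` (row subsets of `snvs`), fractions `f_shared`,
#'   `f_polyp`, `f_cancer`, and `n_union`.
#' @export
#' @examples
#' b <- simulate_case(build_scenario("E", seed = 3))
#' partition_snvs(b$snvs, "villous", "cancer")$f_cancer
partition_snvs <- function(snvs, polyp_sample, cancer_sample,
                           detection_limit = 0.05) {
  det_p <- is_detected(snv_af(snvs, polyp_sample), detection_limit)
  det_c <- is_detected(snv_af(snvs, cancer_sample), detection_limit)
  union <- det_p | det_c
  n <- sum(union)
  if (n == 0L) stop("no SNV is detected in either sample")
  shared <- union & det_p & det_c
  polyp_only <- det_p & !det_c
  cancer_only <- det_c & !det_p
  structure(list(
    shared = snvs[shared, , drop = FALSE],
    polyp_private = snvs[polyp_only, , drop = FALSE],
    cancer_private = snvs[cancer_only, , drop = FALSE],
    f_shared = sum(shared) / n,
    f_polyp = sum(polyp_only) / n,
    f_cancer = sum(cancer_only) / n,
    n_union = n,
    polyp_sample = polyp_sample,
    cancer_sample = cancer_sample
  ), class = "af_partition")
}

#' @export
print.af_partition <- function(x, ...) {
  cat(sprintf(
    "AF partition (%d SNVs): shared %.3f, polyp-private %.3f, cancer-private %.3f\n",
    x$n_union, x$f_shared, x$f_polyp, x$f_cancer))
  invisible(x)
}

#' Cluster a 1D allele-frequency distribution and locate gaps
#'
#' Kernel-density based clustering of an AF vector. The density (Gaussian
#' kernel, fixed bandwidth) is evaluated on \[`lower`, 1\]; clusters are
#' maximal regions where it reaches at least `density_ratio` times its
#' global maximum. Candidate regions separated by less than
#' `min_gap_width` are merged, and regions holding less than
#' `min_cluster_weight` of the SNVs are discarded, so every reported gap
#' is an inter-cluster interval of width at least `min_gap_width` and
#' `has_gap` is simply "two or more clusters".
#'
#' With fewer than `min_n` values the distribution is judged not
#' assessable: `has_gap` is `NA` and no clusters are reported.
#'
#' @param afs numeric vector of allele fractions.
#' @param bandwidth kernel bandwidth on the AF scale (default 0.03).
#' @param min_cluster_weight minimum SNV fraction per cluster (default
#'   0.05).
#' @param min_gap_width minimum gap width in AF units (default 0.08).
#' @param density_ratio density threshold relative to the maximum
#'   (default 0.10).
#' @param lower lower edge of the density support: the detection limit
#'   for detected-only AF vectors, or 0 when the vector includes
#'   re-quantified sub-limit AFs of SNVs private to the other compartment.
#' @param min_n assessability threshold (default 20).
#' @return List of class `af_clusters`: `clusters` (data.frame `mode`,
#'   `weight`, `lo`, `hi`, ordered and disjoint), `gaps` (data.frame `lo`,
#'   `hi`), `has_gap` (logical, `NA` when not assessable), `assessable`,
#'   `n`.
#' @export
#' @examples
#' af <- c(rnorm(250, 0.25, 0.02), rnorm(250, 0.5, 0.02))
#' cluster_afs(af)$has_gap
cluster_afs <- function(afs, bandwidth = 0.03, min_cluster_weight = 0.05,
                        min_gap_width = 0.08, density_ratio = 0.10,
                        lower = 0.05, min_n = 20L) {
  afs <- afs[is.finite(afs)]
  afs <- pmin(pmax(afs, 0), 1)
  empty_clusters <- data.frame(mode = numeric(0), weight = numeric(0),
                               lo = numeric(0), hi = numeric(0))
  empty_gaps <- data.frame(lo = numeric(0), hi = numeric(0))
  if (length(afs) < min_n) {
    return(structure(list(clusters = empty_clusters, gaps = empty_gaps,
                          has_gap = NA, assessable = FALSE,
                          n = length(afs)),
                     class = "af_clusters"))
  }
  dens <- density(afs, bw = bandwidth, from = lower, to = 1, n = 512L)
  thr <- density_ratio * max(dens$y)
  above <- dens$y >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(lo = dens$x[starts[r$values]],
                     hi = dens$x[ends[r$values]])
  # Merge candidate regions whose separation is below the minimum gap
  # width: a narrower dip is not a gap, so the regions form one cluster.
  if (nrow(runs) > 1L) {
    merged <- runs[1L, , drop = FALSE]
    for (i in 2L:nrow(runs)) {
      if (runs$lo[i] - merged$hi[nrow(merged)] < min_gap_width) {
        merged$hi[nrow(merged)] <- runs$hi[i]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
    runs <- merged
  }
  if (nrow(runs)) {
    runs$weight <- vapply(seq_len(nrow(runs)), function(i)
      mean(afs >= runs$lo[i] & afs <= runs$hi[i]), numeric(1))
    runs$mode <- vapply(seq_len(nrow(runs)), function(i) {
      inside <- dens$x >= runs$lo[i] & dens$x <= runs$hi[i]
      dens$x[inside][which.max(dens$y[inside])]
    }, numeric(1))
    runs <- runs[runs$weight >= min_cluster_weight, , drop = FALSE]
  }
  clusters <- if (nrow(runs))
    data.frame(mode = runs$mode, weight = runs$weight, lo = runs$lo,
               hi = runs$hi)
  else empty_clusters
  gaps <- if (nrow(clusters) > 1L)
    data.frame(lo = clusters$hi[-nrow(clusters)], hi = clusters$lo[-1L])
  else empty_gaps
  structure(list(clusters = clusters, gaps = gaps,
                 has_gap = nrow(clusters) >= 2L, assessable = TRUE,
                 n = length(afs)),
            class = "af_clusters")
}

#' @export
print.af_clusters <- function(x, ...) {
  if (!x$assessable) {
    cat(sprintf("AF clustering: not assessable (%d values)\n", x$n))
    return(invisible(x))
  }
  cat(sprintf("AF clustering of %d values: %d cluster(s), has_gap = %s\n",
              x$n, nrow(x$clusters), x$has_gap))
  if (nrow(x$clusters))
    print(format(x$clusters, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Position of the private SNV cluster relative to the shared cluster
#'
#' Compares the weight-dominant modal AF of the private clusters with the
#' weight-dominant modal AF of the shared clusters on the same sample
#' axis. Because sample purity rescales both modes together, the relative
#' position is purity invariant.
#'
#' @param private_clusters,shared_clusters [cluster_afs()] results for
#'   the private and shared SNV AFs of one sample.
#' @param delta tolerance in AF units for "equal" (default 0.10).
#' @return One of `"lower"`, `"equal"`, `"higher"`, `"none"` (`"none"`
#'   when either side has no assessable cluster).
#' @export
relative_position <- function(private_clusters, shared_clusters,
                              delta = 0.10) {
  dominant_mode <- function(cl) {
    if (!inherits(cl, "af_clusters") || !cl$assessable ||
        nrow(cl$clusters) == 0L)
      return(NA_real_)
    cl$clusters$mode[which.max(cl$clusters$weight)]
  }
  m_p <- dominant_mode(private_clusters)
  m_s <- dominant_mode(shared_clusters)
  if (is.na(m_p) || is.na(m_s)) return("none")
  if (m_s - m_p > delta) "lower"
  else if (m_p - m_s > delta) "higher"
  else "equal"
}

#' Estimate sample purity from shared clonal allele fractions
#'
#' The clonal heterozygous cluster of a pure diploid sample sits at AF
#' 0.5; impurity scales it down proportionally, so purity is estimated as
#' twice the modal AF of the highest-AF shared cluster (capped at 1).
#'
#' @param shared_afs AFs, in one sample, of SNVs shared between the
#'   compartments (>= 20 values).
#' @param config a [moe_config()] supplying the clustering parameters.
#' @return Purity in (0, 1\], or `NA` when not assessable.
#' @export
estimate_purity <- function(shared_afs, config = moe_config()) {
  cl <- cluster_afs(shared_afs, bandwidth = config$bandwidth,
                    min_cluster_weight = config$min_cluster_weight,
                    min_gap_width = config$min_gap_width,
                    density_ratio = config$density_ratio,
                    lower = config$detection_limit,
                    min_n = config$min_afs)
  if (!cl$assessable || nrow(cl$clusters) == 0L) return(NA_real_)
  min(1, 2 * max(cl$clusters$mode))
}

#' Flag a possible independent origin of polyp and cancer
#'
#' If the cancer grew out of the sampled polyp, driver mutations that are
#' clonal in the polyp should persist at comparable or higher AF in the
#' cancer. A driver with polyp AF at or above `driver_af_min` whose
#' cancer AF drops below `kappa` times its polyp AF -- or that is
#' undetected in the cancer altogether -- suggests instead that cancer
#' and polyp arose from different clones independently.
#'
#' @param snvs SNV table; drivers are rows with `is_driver = TRUE`, or,
#'   when that column is absent, rows whose `gene` is in `driver_genes`.
#' @param polyp_sample,cancer_sample sample ids.
#' @param kappa relative-drop trigger (default 0.5).
#' @param detection_limit AF detection threshold (default 0.05).
#' @param driver_af_min minimum polyp AF for a driver to be considered
#'   (default 0.25).
#' @param driver_genes fallback driver gene symbols.
#' @return List with `flag` (logical) and `evidence` (data.frame of the
#'   triggering SNVs with both AFs).
#' @export
#' @examples
#' snvs <- data.frame(chrom = "17", pos = 1, ref = "C", alt = "T",
#'                    gene = "TP53", is_driver = TRUE,
#'                    af_villous = 0.471, af_cancer = 0.167)
#' flag_independent_origin(snvs, "villous", "cancer")$flag
flag_independent_origin <- function(snvs, polyp_sample, cancer_sample,
                                    kappa = 0.5, detection_limit = 0.05,
                                    driver_af_min = 0.25,
                                    driver_genes = c("APC", "KRAS", "TP53")) {
  is_driver <- if ("is_driver" %in% names(snvs)) {
    !is.na(snvs$is_driver) & snvs$is_driver
  } else if ("gene" %in% names(snvs)) {
    !is.na(snvs$gene) & snvs$gene %in% driver_genes
  } else rep(FALSE, nrow(snvs))
  drv <- snvs[is_driver, , drop = FALSE]
  empty <- list(flag = FALSE,
                evidence = data.frame(gene = character(0),
                                      af_polyp = numeric(0),
                                      af_cancer = numeric(0)))
  if (nrow(drv) == 0L) return(empty)
  af_p <- snv_af(drv, polyp_sample)
  af_c <- snv_af(drv, cancer_sample)
  in_polyp <- !is.na(af_p) & af_p >= driver_af_min
  undetected_cancer <- is.na(af_c) | af_c < detection_limit
  dropped <- !is.na(af_c) & !is.na(af_p) & af_c < kappa * af_p
  trigger <- in_polyp & (undetected_cancer | dropped)
  if (!any(trigger)) return(empty)
  ev <- data.frame(
    gene = if ("gene" %in% names(drv)) drv$gene[trigger] else NA_character_,
    chrom = drv$chrom[trigger], pos = drv$pos[trigger],
    af_polyp = af_p[trigger], af_cancer = af_c[trigger])
  list(flag = TRUE, evidence = ev)
}
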