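# Copy-number aberration metrics: genotype filtering, the per-chromosome
# Jaccard similarity and its genome-wide sum M, chromosome recurrence
# testing, and UPGMA clustering.

#' Construct a CNA profile
#'
#' A profile stores the deletion and duplication intervals of one sample
#' as 0-based half-open bp coordinates, merged per chromosome and state,
#' plus the fraction of the autosomal genome altered.
#'
#' @param sample_id sample identifier.
#' @param segments `data.frame` with columns `chrom`, `start`, `end`,
#'   `state` (`"del"`/`"dup"`); coordinates 0-based half-open.
#' @param genome named vector of chromosome lengths (default GRCh37
#'   autosomes).
#' @return A list of class `cna_profile` with `sample_id`, `segments`
#'   (merged) and `autosomal_altered_fraction`.
#' @export
cna_profile <- function(sample_id, segments,
                        genome = autosome_lengths()) {
  stopifnot(is.data.frame(segments),
            all(c("chrom", "start", "end", "state") %in% names(segments) |
                  nrow(segments) == 0L))
  if (nrow(segments)) {
    segments$chrom <- norm_chrom(segments$chrom)
    stopifnot(all(segments$state %in% c("del", "dup")),
              all(segments$start < segments$end))
    segments <- segments[segments$chrom %in% names(genome), , drop = FALSE]
    merged <- list()
    for (chrom in unique(segments$chrom)) for (st in c("del", "dup")) {
      rows <- segments[segments$chrom == chrom & segments$state == st, ]
      if (!nrow(rows)) next
      ir <- IRanges::reduce(IRanges::IRanges(start = rows$start + 1,
                                             end = rows$end))
      merged[[length(merged) + 1L]] <- data.frame(
        chrom = chrom, start = BiocGenerics::start(ir) - 1,
        end = BiocGenerics::end(ir), state = st)
    }
    segments <- if (length(merged)) do.call(rbind, merged)
    else segments[0, c("chrom", "start", "end", "state")]
    segments <- segments[order(match(segments$chrom, names(genome)),
                               segments$start), , drop = FALSE]
    rownames(segments) <- NULL
  } else {
    segments <- data.frame(chrom = character(0), start = numeric(0),
                           end = numeric(0), state = character(0))
  }
  altered <- 0
  if (nrow(segments)) {
    for (chrom in unique(segments$chrom)) {
      rows <- segments[segments$chrom == chrom, ]
      ir <- IRanges::reduce(IRanges::IRanges(start = rows$start + 1,
                                             end = rows$end))
      altered <- altered + sum(BiocGenerics::width(ir))
    }
  }
  structure(list(sample_id = sample_id, segments = segments,
                 genome = genome,
                 autosomal_altered_fraction = altered / sum(genome)),
            class = "cna_profile")
}

#' @export
print.cna_profile <- function(x, ...) {
  cat(sprintf("CNA profile '%s': %d segment(s), %.1f%% of autosomes altered\n",
              x$sample_id, nrow(x$segments),
              100 * x$autosomal_altered_fraction))
  invisible(x)
}

#' Genotype-filter raw CNA segments into a profile
#'
#' Keeps only segments whose matched-normal copy number lies strictly
#' within (1.75, 2.25) and whose tumor-normal copy-number difference
#' exceeds 0.2; the retained segments become duplications (tumor above
#' normal) or deletions (below). Chromosomes X and Y are excluded so the
#' metric is comparable across genders. Rows with malformed coordinates
#' or missing copy numbers are dropped with a message.
#'
#' @param segments `data.frame` with columns `chrom`, `start`, `end`,
#'   `tumor_cn`, `normal_cn`.
#' @param sample_id sample identifier for the resulting profile.
#' @param one_based set `TRUE` when `start` is 1-based inclusive; it is
#'   converted to the 0-based half-open convention at this boundary.
#' @param normal_band allowed normal copy-number interval (open).
#' @param min_diff minimum |tumor - normal| difference.
#' @param genome chromosome lengths (default GRCh37 autosomes).
#' @return A [cna_profile].
#' @export
#' @examples
#' seg <- data.frame(chrom = "7", start = 0, end = 1e6,
#'                   tumor_cn = 3.1, normal_cn = 2.0)
#' genotype_filter(seg, "s1")$segments$state
genotype_filter <- function(segments, sample_id = "sample",
                            one_based = FALSE,
                            normal_band = c(1.75, 2.25), min_diff = 0.2,
                            genome = autosome_lengths()) {
  need <- c("chrom", "start", "end", "tumor_cn", "normal_cn")
  if (!all(need %in% names(segments)))
    stop("segments must have columns: ", paste(need, collapse = ", "))
  segments$chrom <- norm_chrom(segments$chrom)
  if (one_based) segments$start <- segments$start - 1
  bad <- !is.finite(segments$start) | !is.finite(segments$end) |
    segments$start >= segments$end | !is.finite(segments$tumor_cn) |
    !is.finite(segments$normal_cn)
  if (any(bad)) {
    message(sum(bad), " malformed segment row(s) dropped")
    segments <- segments[!bad, , drop = FALSE]
  }
  keep <- segments$normal_cn > normal_band[1] &
    segments$normal_cn < normal_band[2] &
    abs(segments$tumor_cn - segments$normal_cn) > min_diff &
    segments$chrom %in% names(genome)
  segments <- segments[keep, , drop = FALSE]
  segments$state <- ifelse(segments$tumor_cn > segments$normal_cn,
                           "dup", "del")
  cna_profile(sample_id, segments[, c("chrom", "start", "end", "state")],
              genome = genome)
}

# Intersection and union lengths (bp) of the per-state interval sets of
# two profiles on one chromosome, via IRanges.
state_ranges <- function(profile, chrom, state) {
  rows <- profile$segments[profile$segments$chrom == chrom &
                             profile$segments$state == state, ]
  IRanges::IRanges(start = rows$start + 1, end = rows$end)
}

#' Per-chromosome CNA similarity
#'
#' Jaccard-style score of two profiles on one chromosome: the summed
#' length of duplications common to both plus deletions common to both,
#' over the length of the union of all duplicated and deleted regions of
#' either sample (cross-state overlap counts toward the denominator
#' only). Defined as 0 when neither sample has an event on the
#' chromosome.
#'
#' @param profile1,profile2 [cna_profile] objects.
#' @param chrom chromosome name.
#' @return Score in \[0, 1\].
#' @export
chromosome_similarity <- function(profile1, profile2, chrom) {
  chrom <- norm_chrom(chrom)
  num <- 0
  total <- 0
  for (st in c("del", "dup")) {
    r1 <- state_ranges(profile1, chrom, st)
    r2 <- state_ranges(profile2, chrom, st)
    num <- num + sum(BiocGenerics::width(IRanges::intersect(r1, r2)))
    total <- total + sum(BiocGenerics::width(r1)) +
      sum(BiocGenerics::width(r2))
  }
  denom <- total - num
  if (denom == 0) 0 else num / denom
}

#' Genome-wide CNA similarity metric M
#'
#' The sum of [chromosome_similarity()] over autosomes 1-22, so M ranges
#' from 0 (no common aberration) to 22 (identical per-state aberrations
#' on every autosome).
#'
#' @param profile1,profile2 [cna_profile] objects.
#' @return M in \[0, 22\].
#' @export
#' @examples
#' p <- simulate_cna_profiles("polyp", 4, seed = 5)
#' genome_similarity(p$polyp, p$cancer)
genome_similarity <- function(profile1, profile2) {
  sum(vapply(names(AUTOSOME_LENGTHS), function(chrom)
    chromosome_similarity(profile1, profile2, chrom), numeric(1)))
}

#' Pairwise CNA similarity matrix
#'
#' @param profiles named list of [cna_profile] objects.
#' @return List of class `similarity_matrix`: `M` (symmetric matrix of
#'   genome scores) and `per_chromosome` (array samples x samples x 22).
#' @export
similarity_matrix <- function(profiles) {
  if (is.null(names(profiles)))
    names(profiles) <- vapply(profiles, `[[`, character(1), "sample_id")
  n <- length(profiles)
  chroms <- names(AUTOSOME_LENGTHS)
  per <- array(0, dim = c(n, n, length(chroms)),
               dimnames = list(names(profiles), names(profiles), chroms))
  for (i in seq_len(n)) for (j in i:n) for (k in seq_along(chroms)) {
    s <- chromosome_similarity(profiles[[i]], profiles[[j]], chroms[k])
    per[i, j, k] <- per[j, i, k] <- s
  }
  M <- apply(per, c(1, 2), sum)
  structure(list(M = M, per_chromosome = per, samples = names(profiles)),
            class = "similarity_matrix")
}

#' Test chromosomes for recurrent aneuploidies across a cohort
#'
#' For each autosome, compares its aberration concordance against the
#' other autosomes with a one-sided Wilcoxon signed-rank test. With the
#' default `unit = "pair"`, the paired observation for chromosome c is,
#' over all sample pairs, the per-chromosome similarity score on c minus
#' the mean score over the remaining autosomes; with `unit = "sample"`
#' it is each sample's altered fraction of c minus its mean altered
#' fraction of the other autosomes. Raw p-values are primary;
#' Benjamini-Hochberg adjusted values are reported alongside.
#'
#' @param profiles list of at least 5 [cna_profile] objects from one
#'   tissue type.
#' @param unit paired observation unit, `"pair"` (default) or
#'   `"sample"`.
#' @return `data.frame` with columns `chrom`, `statistic` (signed-rank
#'   V), `p_value`, `p_adjusted`, `note`.
#' @export
recurrence_test <- function(profiles, unit = c("pair", "sample")) {
  unit <- match.arg(unit)
  if (length(profiles) < 5L)
    stop("need at least 5 profiles for the recurrence test")
  chroms <- names(AUTOSOME_LENGTHS)
  scores <- if (unit == "pair") {
    idx <- combn(length(profiles), 2L)
    t(apply(idx, 2L, function(ij) vapply(chroms, function(chrom)
      chromosome_similarity(profiles[[ij[1]]], profiles[[ij[2]]], chrom),
      numeric(1))))
  } else {
    t(vapply(profiles, function(p) vapply(chroms, function(chrom) {
      rows <- p$segments[p$segments$chrom == chrom, ]
      if (!nrow(rows)) return(0)
      ir <- IRanges::reduce(IRanges::IRanges(start = rows$start + 1,
                                             end = rows$end))
      sum(BiocGenerics::width(ir)) / p$genome[[chrom]]
    }, numeric(1)), numeric(length(chroms))))
  }
  res <- lapply(seq_along(chroms), function(k) {
    diffs <- scores[, k] - rowMeans(scores[, -k, drop = FALSE])
    if (all(diffs == 0)) {
      return(data.frame(chrom = chroms[k], statistic = NA_real_,
                        p_value = 1, note = "all paired differences zero"))
    }
    wt <- suppressWarnings(
      wilcox.test(diffs, mu = 0, alternative = "greater", exact = FALSE))
    data.frame(chrom = chroms[k], statistic = unname(wt$statistic),
               p_value = wt$p.value, note = "")
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out[, c("chrom", "statistic", "p_value", "p_adjusted", "note")]
}

#' UPGMA (average-linkage) hierarchical clustering
#'
#' Clusters samples from a symmetric distance or similarity matrix using
#' unweighted pair-group average linkage. Similarities are converted to
#' distances by `d = max(s) - s`, a monotone, parameter-free mapping.
#' Merging is deterministic; equal-distance ties follow the stable
#' lowest-index order of [stats::hclust()].
#'
#' @param m symmetric numeric matrix.
#' @param type `"distance"` or `"similarity"`.
#' @return An object of class `hclust` (merge matrix plus heights).
#' @export
upgma_cluster <- function(m, type = c("distance", "similarity")) {
  type <- match.arg(type)
  m <- as.matrix(m)
  if (!isSymmetric(unname(m), tol = 1e-8))
    stop("input matrix must be symmetric")
  if (type == "similarity") {
    m <- max(m) - m
    diag(m) <- 0
  }
  hclust(as.dist(m), method = "average")
}

#' Export a CNA profile as a binned heatmap table
#'
#' Bins the genome into fixed-width windows and writes one row per bin
#' with -1 for deletion, 1 for duplication, 0 otherwise, ready for
#' heatmap plotting.
#'
#' @param profile a [cna_profile].
#' @param path output TSV path.
#' @param bin_size bin width in bp (default 50 kb).
#' @return `path`, invisibly.
#' @export
export_cna_bins <- function(profile, path, bin_size = 5e4) {
  rows <- list()
  for (chrom in names(profile$genome)) {
    starts <- seq(0, profile$genome[[chrom]] - 1, by = bin_size)
    val <- numeric(length(starts))
    seg <- profile$segments[profile$segments$chrom == chrom, ]
    for (i in seq_len(nrow(seg))) {
      hit <- starts < seg$end[i] & (starts + bin_size) > seg$start[i]
      val[hit] <- if (seg$state[i] == "dup") 1 else -1
    }
    rows[[chrom]] <- data.frame(chrom = chrom, start = starts,
                                end = pmin(starts + bin_size,
                                           profile$genome[[chrom]]),
                                value = val)
  }
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
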