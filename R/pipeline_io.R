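# Readers, writers and consensus merging.
#
# Coordinate conventions: VCF positions are 1-based inclusive and stay so
# in the SNV table; segment tables are 0-based half-open (BED-like), with
# 1-based input converted at the reader boundary.

#' Merge per-caller variant sets by consensus
#'
#' Variants are keyed by (chrom, pos, ref, alt); a key is kept when at
#' least `min_callers` of the input sets contain it. Non-key columns
#' (AFs, annotations) are taken from the first set listing the key (the
#' designated primary source); keys whose AF differs across callers by
#' more than `af_tol` are recorded in the `discordant` attribute.
#'
#' @param caller_sets list of SNV `data.frame`s, one per caller, each
#'   with `chrom`, `pos`, `ref`, `alt` columns.
#' @param min_callers consensus threshold (default 3).
#' @param af_tol AF discordance tolerance for logging (default 0.05).
#' @return The merged SNV `data.frame`, with attributes `n_callers`
#'   (integer support per kept variant) and `discordant` (keys with
#'   conflicting AFs).
#' @export
#' @examples
#' a <- data.frame(chrom = "1", pos = 1:3, ref = "C", alt = "T")
#' b <- a[1:2, ]; c <- a[c(1, 3), ]
#' nrow(consensus_merge(list(a, b, c), min_callers = 2))
consensus_merge <- function(caller_sets, min_callers = 3, af_tol = 0.05) {
  if (min_callers > length(caller_sets))
    stop("min_callers exceeds the number of caller sets")
  key_of <- function(df) paste(norm_chrom(df$chrom), df$pos, df$ref,
                               df$alt, sep = ":")
  keys <- lapply(caller_sets, key_of)
  support <- table(unlist(lapply(keys, unique)))
  kept <- names(support)[support >= min_callers]
  first_rows <- list()
  for (i in seq_along(caller_sets)) {
    new <- setdiff(intersect(keys[[i]], kept), names(first_rows))
    rows <- caller_sets[[i]][match(new, keys[[i]]), , drop = FALSE]
    first_rows[new] <- split(rows, seq_len(nrow(rows)))
  }
  merged <- do.call(rbind, first_rows[kept])
  rownames(merged) <- NULL
  af_cols <- grep("^af_", names(merged), value = TRUE)
  discordant <- character(0)
  if (length(af_cols)) {
    for (k in kept) {
      vals <- unlist(lapply(seq_along(caller_sets), function(i) {
        j <- match(k, keys[[i]])
        if (is.na(j)) return(NULL)
        unlist(caller_sets[[i]][j, intersect(af_cols,
                                             names(caller_sets[[i]]))])
      }))
      vals <- vals[!is.na(vals)]
      if (length(vals) > 1L && diff(range(vals)) > af_tol)
        discordant <- c(discordant, k)
    }
  }
  structure(merged,
            n_callers = as.integer(support[kept]),
            discordant = discordant)
}

#' Read / write the merged SNV table
#'
#' The package's TSV dialect: columns `chrom`, `pos`, `ref`, `alt`,
#' optional `context`, `gene`, `is_driver`, truth columns for simulated
#' cases, and one `af_<sample>` column per sample. Writing preserves full
#' AF precision so that a write/read cycle is an identity.
#'
#' @param snvs SNV `data.frame`.
#' @param path file path.
#' @return `read_snv_table()` returns the SNV `data.frame`;
#'   `write_snv_table()` returns `path` invisibly.
#' @export
write_snv_table <- function(snvs, path) {
  out <- snvs
  num_cols <- names(out)[vapply(out, is.double, logical(1))]
  for (col in num_cols)
    out[[col]] <- ifelse(is.na(out[[col]]), NA,
                         sprintf("%.17g", out[[col]]))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_snv_table
#' @export
read_snv_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(chrom = "character"))
  need <- c("chrom", "pos", "ref", "alt")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("SNV table lacks column(s): ", paste(missing, collapse = ", "))
  df
}

#' Read somatic SNVs and allele fractions from a VCF
#'
#' Uses vcfR to parse the file and derives each variant's allele
#' fraction from, in order of preference, the `AF` FORMAT field or
#' `AD`/`DP`. Only biallelic single-base substitutions are kept;
#' positions remain 1-based.
#'
#' @param path VCF path (uncompressed or gzipped).
#' @param sample sample id for the resulting AF column; defaults to the
#'   first genotype column in the file.
#' @return SNV `data.frame` with `chrom`, `pos`, `ref`, `alt` and
#'   `af_<sample>`.
#' @export
read_vcf_snvs <- function(path, sample = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCFs requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT)
  gt_samples <- colnames(v@gt)[-1L]
  if (is.null(sample)) sample <- gt_samples[1L]
  if (!sample %in% gt_samples)
    stop("VCF has no genotype column for sample '", sample, "'")
  af <- rep(NA_real_, nrow(fix))
  fmt_af <- try(suppressWarnings(
    vcfR::extract.gt(v, element = "AF", as.numeric = TRUE)[, sample]),
    silent = TRUE)
  if (!inherits(fmt_af, "try-error") && any(!is.na(fmt_af))) {
    af <- as.numeric(fmt_af)
  } else {
    ad <- try(suppressWarnings(
      vcfR::extract.gt(v, element = "AD")[, sample]), silent = TRUE)
    dp <- try(suppressWarnings(
      vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[, sample]),
      silent = TRUE)
    if (!inherits(ad, "try-error") && !inherits(dp, "try-error")) {
      alt_reads <- vapply(strsplit(as.character(ad), ","), function(x)
        suppressWarnings(as.numeric(x[2L])), numeric(1))
      af <- alt_reads / as.numeric(dp)
    }
  }
  out <- data.frame(chrom = norm_chrom(fix$CHROM),
                    pos = as.integer(fix$POS), ref = fix$REF,
                    alt = fix$ALT, stringsAsFactors = FALSE)[snv, ]
  out[[af_col(sample)]] <- af[snv]
  rownames(out) <- NULL
  out
}

#' Write one sample's detected SNVs as a VCF
#'
#' Emits a minimal VCF 4.2 with the allele fraction in the `AF` FORMAT
#' field and the site depth, when available, in `DP`. Only SNVs detected
#' in the sample (AF at or above `detection_limit`) are written.
#'
#' @param snvs SNV table.
#' @param sample sample id (selects the `af_<sample>` column and names
#'   the genotype column).
#' @param path output path.
#' @param detection_limit detection threshold (default 0.05).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(snvs, sample, path, detection_limit = 0.05) {
  af <- snv_af(snvs, sample)
  keep <- is_detected(af, detection_limit)
  rows <- snvs[keep, , drop = FALSE]
  af <- af[keep]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=moeinfer",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AF\t0/1:%.6g",
                  rows$chrom, as.integer(rows$pos), rows$ref, rows$alt,
                  af)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write CNA segment tables
#'
#' BED-like TSV with columns `chrom`, `start`, `end`, `tumor_cn`,
#' `normal_cn` (0-based half-open coordinates). The reader feeds
#' [genotype_filter()].
#'
#' @param segments segment `data.frame`.
#' @param path file path.
#' @return `read_segment_table()` returns the segment `data.frame`;
#'   `write_segment_table()` returns `path` invisibly.
#' @export
write_segment_table <- function(segments, path) {
  write.table(segments, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_segment_table
#' @export
read_segment_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(chrom = "character"))
}

# Segment-table representation of a simulated profile: synthetic tumor
# and normal copy numbers consistent with the genotype filter (normal
# diploid, del = 1 copy, dup = 3 copies).
profile_to_segments <- function(profile) {
  seg <- profile$segments
  data.frame(chrom = seg$chrom, start = seg$start, end = seg$end,
             tumor_cn = ifelse(seg$state == "dup", 3, 1),
             normal_cn = 2)
}

#' Write a simulated case to disk
#'
#' One VCF per sample (AF in the FORMAT field), one segment table per
#' sample with a CNA profile, and the merged SNV TSV.
#'
#' @param bundle a [case_bundle].
#' @param dir output directory (created if needed).
#' @param detection_limit detection threshold for the per-sample VCFs.
#' @return Character vector of the written paths, invisibly.
#' @export
write_case <- function(bundle, dir, detection_limit = 0.05) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, paste0(bundle$case_id, "_snvs.tsv"))
  write_snv_table(bundle$snvs, p)
  paths <- c(paths, p)
  for (id in bundle$samples$id) {
    p <- file.path(dir, paste0(bundle$case_id, "_", id, ".vcf"))
    write_vcf(bundle$snvs, id, p, detection_limit)
    paths <- c(paths, p)
    if (!is.null(bundle$cna[[id]])) {
      p <- file.path(dir, paste0(bundle$case_id, "_", id, "_cna.tsv"))
      write_segment_table(profile_to_segments(bundle$cna[[id]]), p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
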