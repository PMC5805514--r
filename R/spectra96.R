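# 96-channel trinucleotide substitution spectra.
#
# Channels are ordered lexicographically by (substitution class, 5' base,
# 3' base) with the six pyrimidine-reference classes C>A, C>G, C>T, T>A,
# T>C, T>G and flanking bases in A, C, G, T order, i.e. channel 1 is
# A[C>A]A and channel 96 is T[T>G]T. Purine-reference variants are mapped
# to their reverse complement before lookup.

SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
DNA_BASES <- c("A", "C", "G", "T")

comp_base <- function(b) {
  chartr("ACGT", "TGCA", b)
}

revcomp3 <- function(context) {
  vapply(strsplit(chartr("ACGT", "TGCA", context), ""), function(x)
    paste(rev(x), collapse = ""), character(1))
}

#' Trinucleotide channel labels
#'
#' @return Character vector of the 96 channel labels in package order,
#'   e.g. `"A[C>A]A"`.
#' @export
channel_labels <- function() {
  out <- character(96)
  k <- 1L
  for (s in SUB_CLASSES) {
    refalt <- strsplit(s, ">")[[1]]
    for (f in DNA_BASES) for (t in DNA_BASES) {
      out[k] <- sprintf("%s[%s]%s", f, s, t)
      k <- k + 1L
    }
  }
  out
}

#' Map a substitution in context to its trinucleotide channel
#'
#' Assigns each single-base substitution, given its reference-strand 3-mer
#' context, to one of the 96 pyrimidine-reference trinucleotide channels.
#' Purine-reference substitutions are complemented and their context
#' reverse-complemented, so for example G>T in `TGT` maps to the same
#' channel as C>A in `ACA`.
#'
#' @param ref,alt single reference and alternate bases (vectorized).
#' @param context reference-strand 3-mer centered on the variant; its
#'   middle base must equal `ref`.
#' @return Integer vector of channel indices in 1..96, named by channel
#'   label.
#' @export
#' @examples
#' channel_of("C", "A", "ACA")   # 1, A[C>A]A
#' channel_of("G", "T", "TGT")   # same channel by reverse complement
channel_of <- function(ref, alt, context) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  context <- toupper(as.character(context))
  n <- max(length(ref), length(alt), length(context))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  context <- rep_len(context, n)
  if (!all(ref %in% DNA_BASES) || !all(alt %in% DNA_BASES))
    stop("ref and alt must be single bases in {A, C, G, T}")
  if (any(ref == alt)) stop("ref and alt must differ")
  if (any(nchar(context) != 3L) || !all(grepl("^[ACGT]{3}$", context)))
    stop("context must be a 3-mer over {A, C, G, T}")
  if (any(substr(context, 2L, 2L) != ref))
    stop("middle base of context must equal ref")
  purine <- ref %in% c("A", "G")
  ref[purine] <- comp_base(ref[purine])
  alt[purine] <- comp_base(alt[purine])
  context[purine] <- revcomp3(context[purine])
  sub_idx <- match(paste0(ref, ">", alt), SUB_CLASSES)
  f_idx <- match(substr(context, 1L, 1L), DNA_BASES)
  t_idx <- match(substr(context, 3L, 3L), DNA_BASES)
  idx <- (sub_idx - 1L) * 16L + (f_idx - 1L) * 4L + t_idx
  names(idx) <- channel_labels()[idx]
  idx
}

#' Build a 96-channel mutation spectrum for a sample
#'
#' Counts the SNVs detected in `sample` per trinucleotide channel and
#' normalizes the counts to sum to one. When `subtract_sample` is given
#' (typically the polyp compartment while building a cancer spectrum),
#' SNVs also detected there are excluded first, so the spectrum describes
#' compartment-specific mutations. If fewer than `min_snvs` SNVs remain
#' and `fallback = TRUE`, the spectrum is instead computed over all SNVs
#' detected in `sample` and flagged via the `fallback` attribute (the
#' convention used to mark samples with too few cancer-specific
#' mutations).
#'
#' @param snvs SNV table with `ref`, `alt`, `context` and per-sample AF
#'   columns (see [simulate_case()] / [read_snv_table()]).
#' @param sample sample id whose spectrum is built.
#' @param subtract_sample optional sample id whose detected SNVs are
#'   excluded.
#' @param min_snvs minimum compartment-specific SNV count before the
#'   fallback applies (default 50).
#' @param fallback use all SNVs of `sample` when too few specific SNVs
#'   remain (default TRUE).
#' @param detection_limit AF detection threshold (default 0.05).
#' @return Numeric vector of length 96 (class `spectrum96`) summing to 1,
#'   with attributes `n_snvs`, `fallback` and `sample`.
#' @export
mutation_spectrum <- function(snvs, sample, subtract_sample = NULL,
                              min_snvs = 50, fallback = TRUE,
                              detection_limit = 0.05) {
  if (!all(c("ref", "alt", "context") %in% names(snvs)))
    stop("SNV table must carry ref, alt and context columns")
  det <- is_detected(snv_af(snvs, sample), detection_limit)
  keep <- det
  used_fallback <- FALSE
  if (!is.null(subtract_sample)) {
    other <- is_detected(snv_af(snvs, subtract_sample), detection_limit)
    specific <- det & !other
    if (sum(specific) >= min_snvs || !fallback) {
      keep <- specific
    } else {
      used_fallback <- TRUE
    }
  }
  sel <- snvs[keep & !is.na(snvs$context), , drop = FALSE]
  if (nrow(sel) == 0L) stop("no usable SNVs for sample '", sample, "'")
  idx <- channel_of(sel$ref, sel$alt, sel$context)
  counts <- tabulate(idx, nbins = 96L)
  spec <- counts / sum(counts)
  names(spec) <- channel_labels()
  structure(spec, class = "spectrum96", n_snvs = nrow(sel),
            fallback = used_fallback, sample = sample)
}

#' Pearson correlation between two spectra
#'
#' @param s1,s2 numeric vectors of length 96 (counts or proportions;
#'   Pearson correlation is scale invariant, so both give identical
#'   values).
#' @return Pearson r in \[-1, 1\], or `NA` with a warning when either
#'   vector has zero variance.
#' @export
spectrum_correlation <- function(s1, s2) {
  s1 <- as.numeric(s1); s2 <- as.numeric(s2)
  if (length(s1) != 96L || length(s2) != 96L)
    stop("spectra must have length 96")
  if (stats::sd(s1) == 0 || stats::sd(s2) == 0) {
    warning("zero-variance spectrum: correlation undefined")
    return(NA_real_)
  }
  stats::cor(s1, s2, method = "pearson")
}

#' UPGMA clustering of mutation spectra
#'
#' Computes all pairwise Pearson correlations, converts them to distances
#' `d = 1 - r`, and clusters by average linkage via [upgma_cluster()].
#'
#' @param spectra named list of `spectrum96` vectors (>= 2).
#' @return An object of class `hclust`.
#' @export
cluster_spectra <- function(spectra) {
  if (length(spectra) < 2L) stop("need at least 2 spectra")
  if (is.null(names(spectra)))
    names(spectra) <- paste0("sample", seq_along(spectra))
  n <- length(spectra)
  r <- diag(1, n)
  dimnames(r) <- list(names(spectra), names(spectra))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r[i, j] <- r[j, i] <- spectrum_correlation(spectra[[i]], spectra[[j]])
  }
  upgma_cluster(1 - r, type = "distance")
}

#' Match a spectrum against signature vectors
#'
#' Cosine similarity between a spectrum and each column of a user-supplied
#' signature matrix (e.g. COSMIC signatures; none are bundled).
#'
#' @param spectrum numeric vector of length 96.
#' @param signature_matrix numeric matrix with 96 rows, one column per
#'   signature.
#' @return List with `cosine` (named numeric vector) and `best` (name or
#'   index of the top-scoring signature).
#' @export
match_signatures <- function(spectrum, signature_matrix) {
  spectrum <- as.numeric(spectrum)
  signature_matrix <- as.matrix(signature_matrix)
  if (length(spectrum) != 96L || nrow(signature_matrix) != 96L)
    stop("spectrum and signature columns must have length 96")
  cosine <- apply(signature_matrix, 2L, function(sig) {
    den <- sqrt(sum(spectrum^2)) * sqrt(sum(sig^2))
    if (den == 0) return(NA_real_)
    sum(spectrum * sig) / den
  })
  list(cosine = cosine, best = if (all(is.na(cosine))) NA else
    names(cosine)[which.max(cosine)] %||% which.max(cosine))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.spectrum96 <- function(x, ...) {
  cat(sprintf("96-channel mutation spectrum for sample '%s' (%d SNVs%s)\n",
              attr(x, "sample"), attr(x, "n_snvs"),
              if (isTRUE(attr(x, "fallback"))) ", fallback to all SNVs" else ""))
  top <- sort(unclass(x), decreasing = TRUE)[1:5]
  cat("top channels:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = " "), "\n")
  invisible(x)
}

# Built-in toy signature-like spectra for the simulator. These are simple
# invented stand-ins (flat; C>T-at-NpCpG-enriched "deamination-like";
# C>T/C>A-mixed "MMR-like"), not COSMIC signatures.
toy_signatures <- function() {
  labels <- channel_labels()
  flat <- rep(1 / 96, 96)
  deam <- rep(0.2 / 92, 96)
  npg <- grepl("^\\w\\[C>T\\]G$", labels)
  deam[npg] <- 0.8 / sum(npg)
  mmr <- rep(0.2 / 64, 96)
  ct <- grepl("\\[C>T\\]", labels)
  ca <- grepl("\\[C>A\\]", labels)
  mmr[ct] <- 0.5 / sum(ct)
  mmr[ca] <- 0.3 / sum(ca)
  m <- cbind(flat = flat, deamination = deam, mmr = mmr)
  rownames(m) <- labels
  m
}

# Draw (ref, alt, context) triples from a mixture of the toy spectra;
# strands are flipped at random so both pyrimidine- and purine-reference
# representations occur in the output.
sample_contexts <- function(n, signature_weights) {
  sigs <- toy_signatures()
  w <- signature_weights[colnames(sigs)]
  w[is.na(w)] <- 0
  if (sum(w) <= 0) stop("signature_weights must give positive total weight")
  mix <- as.numeric(sigs %*% (w / sum(w)))
  ch <- sample.int(96L, n, replace = TRUE, prob = mix)
  sub_idx <- (ch - 1L) %/% 16L + 1L
  f_idx <- ((ch - 1L) %% 16L) %/% 4L + 1L
  t_idx <- (ch - 1L) %% 4L + 1L
  refalt <- do.call(rbind, strsplit(SUB_CLASSES[sub_idx], ">"))
  ref <- refalt[, 1L]; alt <- refalt[, 2L]
  context <- paste0(DNA_BASES[f_idx], ref, DNA_BASES[t_idx])
  flip <- runif(n) < 0.5
  if (any(flip)) {
    ref[flip] <- comp_base(ref[flip])
    alt[flip] <- comp_base(alt[flip])
    context[flip] <- revcomp3(context[flip])
  }
  data.frame(ref = ref, alt = alt, context = context,
             stringsAsFactors = FALSE)
}

#' Export spectra as a TSV heatmap table
#'
#' Writes one row per trinucleotide channel and one column per sample,
#' with substitution class and flanking bases as leading columns (the
#' 6-class-by-16-context panel layout), plus a trailing comment line with
#' the per-sample SNV counts.
#'
#' @param spectra named list of `spectrum96` vectors.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_spectra <- function(spectra, path) {
  labels <- channel_labels()
  df <- data.frame(
    channel = labels,
    class = sub("^.\\[(.*)\\].$", "\\1", labels),
    context = paste0(substr(labels, 1, 1), substr(labels, 3, 3),
                     substr(labels, 7, 7)),
    stringsAsFactors = FALSE
  )
  for (nm in names(spectra)) df[[nm]] <- as.numeric(spectra[[nm]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- vapply(spectra, function(s) attr(s, "n_snvs") %||% NA_integer_,
                   numeric(1))
  cat(sprintf("# n_snvs\t%s\n",
              paste(sprintf("%s=%s", names(counts), counts), collapse = "\t")),
      file = path, append = TRUE)
  invisible(path)
}
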