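# Independent oracles and fixture builders shared across the test files.

# Per-bin bitmap Jaccard oracle for the genome similarity metric. Exact
# (not approximate) whenever all segment boundaries are multiples of
# `unit`, because bin counts are then proportional to bp lengths.
bitmap_genome_similarity <- function(p1, p2, unit = 1e5) {
  g <- autosome_lengths()
  total <- 0
  for (chrom in names(g)) {
    n_bins <- ceiling(g[[chrom]] / unit)
    mask <- function(p, st) {
      m <- logical(n_bins)
      seg <- p$segments[p$segments$chrom == chrom & p$segments$state == st, ,
                        drop = FALSE]
      for (i in seq_len(nrow(seg))) {
        lo <- floor(seg$start[i] / unit) + 1L
        hi <- ceiling(seg$end[i] / unit)
        m[lo:hi] <- TRUE
      }
      m
    }
    num <- den <- 0
    for (st in c("del", "dup")) {
      m1 <- mask(p1, st)
      m2 <- mask(p2, st)
      num <- num + sum(m1 & m2)
      den <- den + sum(m1) + sum(m2)
    }
    den <- den - num
    if (den > 0) total <- total + num / den
  }
  total
}

# Random CNA profile whose segment boundaries are aligned to `unit`, so
# the bitmap oracle is exact on it.
random_cna_profile <- function(id, n_seg = 6, unit = 1e5) {
  g <- autosome_lengths()
  chroms <- sample(names(g), n_seg, replace = TRUE)
  start <- floor(runif(n_seg, 0, g[chroms] / unit - 10)) * unit
  width <- pmax(1, floor(runif(n_seg, 1, 200))) * unit
  end <- pmin(start + width, floor(g[chroms] / unit) * unit)
  cna_profile(id, data.frame(
    chrom = chroms, start = start, end = end,
    state = sample(c("del", "dup"), n_seg, replace = TRUE)))
}

# Brute-force UPGMA: returns the sorted merge heights of average-linkage
# agglomeration on a distance matrix, maintained by direct size-weighted
# averaging of cluster distances.
upgma_oracle_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  size <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a >= b) next
      dd <- d[active[a], active[b]]
      if (dd < best_d) {
        best_d <- dd
        best <- c(active[a], active[b])
      }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, best_d)
    for (k in setdiff(active, best)) {
      d[i, k] <- d[k, i] <-
        (size[i] * d[i, k] + size[j] * d[j, k]) / (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  sort(heights)
}

# Minimal AF partition carrying just the fractions rule 1 consumes.
make_partition <- function(fs, fp, fc, n = 1000) {
  structure(list(f_shared = fs, f_polyp = fp, f_cancer = fc, n_union = n),
            class = "af_partition")
}

# CNA profile covering a prescribed fraction of the autosomal genome,
# filled chromosome by chromosome from chr1.
profile_with_fraction <- function(id, frac, state = "dup") {
  g <- autosome_lengths()
  target <- frac * sum(g)
  segs <- list()
  got <- 0
  i <- 1L
  while (got < target - 0.5 && i <= length(g)) {
    take <- min(g[[i]], target - got)
    if (take >= 1)
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = names(g)[i], start = 0, end = take, state = state)
    got <- got + take
    i <- i + 1L
  }
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), state = character(0))
  cna_profile(id, if (length(segs)) do.call(rbind, segs) else empty)
}
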