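# Shared internal helpers and genome constants.

# GRCh37 autosome lengths in bp; used for simulated CNA coordinates and
# for the altered-genome-fraction denominator. Chromosomes X and Y are
# excluded throughout the CNA analysis to keep the metric comparable
# across genders.
AUTOSOME_LENGTHS <- c(
  "1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
  "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
  "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
  "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
  "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
  "21" = 48129895, "22" = 51304566
)

#' Autosome lengths used by the package
#'
#' @return Named numeric vector of GRCh37 autosome lengths in bp
#'   (chromosomes 1-22).
#' @export
autosome_lengths <- function() AUTOSOME_LENGTHS

MOE_LEVELS <- c("S", "P", "N", "E")

# Strip an optional "chr" prefix and return chromosome names as character.
norm_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

# AF column name for a sample id within an SNV table.
af_col <- function(sample) paste0("af_", sample)

# AF vector of `sample` from an SNV table; errors if the column is absent.
snv_af <- function(snvs, sample) {
  col <- af_col(sample)
  if (!col %in% names(snvs))
    stop("SNV table has no AF column for sample '", sample, "'")
  snvs[[col]]
}

# Detection indicator: quantified and at or above the detection limit.
is_detected <- function(af, detection_limit) {
  !is.na(af) & af >= detection_limit
}

# Run `expr` with a locally seeded RNG when `seed` is given, restoring the
# caller's RNG state afterwards so that seeded helpers do not perturb an
# enclosing simulation stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
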