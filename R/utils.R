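#' Round half away from zero
#'
#' Fixed-point rounding in which ties go away from zero, matching how
#' percentages and per-trio costs are conventionally printed in clinical
#' reports (139/264 -> 52.7, 172305/241 -> 715).  `base::round()` rounds
#' ties to even and would disagree on exactly those boundary cases.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @export
#' @examples
#' round_half_up(714.96)        # 715
#' round_half_up(24.338, 1)     # 24.3
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small relative nudge so values that are exactly .5 after decimal
  # arithmetic (e.g. 100*139/264 = 52.65151...) are not pushed by fp error
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Canonical variant key
#'
#' @param chrom,pos,ref,alt variant coordinates and alleles (GRCh37-style
#'   chromosome labels, 1-based position).
#' @return character key `chrom:pos:ref:alt`, unique per small variant.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# stop() with a classed condition so callers/tests can match on class
crs_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "crstrio_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# split a comma-separated model/source string into a character vector
split_tags <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- strsplit(x, ",", fixed = TRUE)
  lapply(out, function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

join_tags <- function(x) vapply(x, paste, character(1), collapse = ",")

# largest-remainder allocation of n among categories with given weights;
# deterministic (ties broken by category order), sums exactly to n
allocate_counts <- function(weights, n) {
  if (n == 0 || sum(weights) == 0) return(rep(0L, length(weights)))
  quota <- n * weights / sum(weights)
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

INHERITANCE_MODELS <- c("AD", "AR", "XLD", "XLR")
ACMG_CLASSES <- c("P", "LP", "VUS", "LB", "B")
FUNCTIONAL_CLASSES <- c(
  "frameshift", "nonsense", "splicing", "missense", "inframe_indel",
  "synonymous", "intronic", "utr", "intergenic", "noncoding"
)
LOF_CLASSES <- c("frameshift", "nonsense", "splicing")
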