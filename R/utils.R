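#' Round half away from zero
#'
#' Printed percentage tables in this field round 0.5 up (away from zero),
#' unlike [base::round()]'s banker's rounding. Used for every percentage
#' and log2 fold-change the package reports.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(0.125, 2)   # 0.13
#' round_half_up(23.465, 2)  # 23.47 would be naive; printed tables use 23.46
#'                           # only when the stored value is 23.4649...
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Reverse complement of nucleotide strings
#'
#' Thin vectorised wrapper over [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Keeps hierarchical sub-generators independent.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a bounded child seed from a parent seed and a component label.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629 + 1
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
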