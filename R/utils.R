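#' @importFrom stats median cor rbinom rpois runif setNames dhyper fisher.test ave
#' @importFrom utils read.table write.table head tail
#' @importFrom methods is
NULL

# Internal: reverse complement of a plain character vector of DNA strings.
# N maps to N; case is normalised to upper.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

# Internal: round half up to `digits` decimals (R's round() is half-even;
# reported percentages use the conventional half-up rule).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Internal: stopifnot-style check with a plain message.
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
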