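`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Random uniform DNA sequence
#'
#' @param n length in bases.
#' @return A character scalar over A/C/G/T.
#' @keywords internal
rand_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Round half away from zero at a fixed number of decimals
#'
#' Base \code{round()} rounds half to even; printed summary tables in this
#' package use the conventional half-up rule.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## most frequent value of an integer vector (ties: smallest)
modal_int <- function(x) {
  tb <- table(x)
  as.integer(names(tb)[which.max(tb)])
}

## do [s1,e1] and [s2,e2] overlap (closed intervals)?
ivl_overlaps <- function(s1, e1, s2, e2) s1 <= e2 & e1 >= s2

## any overlap of [s,e] with rows of data.frame df(start,end), optionally same chrom
ivl_hits_df <- function(df, chrom, s, e) {
  if (is.null(df) || nrow(df) == 0) return(FALSE)
  sub <- df[df$chrom == chrom, , drop = FALSE]
  if (nrow(sub) == 0) return(FALSE)
  any(ivl_overlaps(sub$start, sub$end, s, e))
}

## hamming distance between two equal-length strings
str_hamming <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  sum(av != bv)
}

stop_input <- function(...) stop(..., call. = FALSE)

## sample() without the length-1 surprise
sample1 <- function(x) if (length(x) == 1) x else sample(x, 1L)
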