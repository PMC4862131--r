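#' @importFrom stats rbinom rpois runif setNames aov anova t.test chisq.test
#'   wilcox.test cor complete.cases
#' @importFrom utils read.delim write.table head
NULL

BASES <- c("A", "C", "G", "T")
PYRIMIDINES <- c("C", "T")
PURINES <- c("A", "G")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character strings (A/C/G/T/N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    paste(rev(unname(COMPLEMENT[chars])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(x) unname(COMPLEMENT[x])

is_pyrimidine <- function(b) b %in% PYRIMIDINES

#' Extract a subsequence of a reference chromosome
#'
#' 1-based inclusive coordinates; returns NA if the window extends beyond the
#' chromosome (contig-edge contexts are treated as unassignable downstream).
#' @param seq single chromosome sequence (character scalar).
#' @param start,end 1-based inclusive bounds (vectorised).
#' @return character vector; NA where out of bounds.
#' @export
ref_window <- function(seq, start, end) {
  n <- nchar(seq)
  out <- substring(seq, pmax(start, 1L), pmin(end, n))
  out[start < 1L | end > n] <- NA_character_
  out
}

## normalise reference input: named character vector, DNAStringSet, or a
## single unnamed string
as_reference <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    out <- as.character(reference)
    names(out) <- names(reference)
    return(toupper(out))
  }
  if (!is.character(reference)) {
    stop("reference must be a named character vector or DNAStringSet")
  }
  if (is.null(names(reference))) {
    if (length(reference) == 1L) names(reference) <- "chr1"
    else stop("multi-sequence reference must be named by chromosome")
  }
  toupper(reference)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single number", name))
  }
}
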