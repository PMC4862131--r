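#' Construct a table of mutations
#'
#' Canonical in-memory representation of called or implanted mutations: one
#' row per event with the originating sample, 1-based position, and explicit
#' alleles. For insertions `pos` is the base immediately 5' of the inserted
#' sequence and `ref_allele` is empty; for deletions `pos` is the first
#' deleted base and `alt_allele` is empty.
#'
#' @param sample_id character vector of sample identifiers.
#' @param chrom chromosome names.
#' @param pos 1-based positions.
#' @param ref_allele reference alleles ("" for insertions).
#' @param alt_allele alternate alleles ("" for deletions).
#' @param mut_class one of "SNV", "INS", "DEL", "DNV"; inferred from the
#'   alleles when missing.
#' @return a `data.frame` with columns `sample_id, chrom, pos, ref_allele,
#'   alt_allele, mut_class`, validated against the class invariants.
#' @export
mutations <- function(sample_id, chrom, pos, ref_allele, alt_allele,
                      mut_class = NULL) {
  n <- max(length(sample_id), length(chrom), length(pos),
           length(ref_allele), length(alt_allele))
  ref_allele <- toupper(ref_allele)
  alt_allele <- toupper(alt_allele)
  if (is.null(mut_class)) {
    mut_class <- infer_mut_class(ref_allele, alt_allele)
  }
  df <- data.frame(
    sample_id = rep_len(as.character(sample_id), n),
    chrom = rep_len(as.character(chrom), n),
    pos = rep_len(as.integer(pos), n),
    ref_allele = rep_len(ref_allele, n),
    alt_allele = rep_len(alt_allele, n),
    mut_class = rep_len(mut_class, n),
    stringsAsFactors = FALSE
  )
  validate_mutations(df)
  df
}

infer_mut_class <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  cls <- rep(NA_character_, length(ref))
  cls[nr == 1 & na == 1] <- "SNV"
  cls[nr == 2 & na == 2] <- "DNV"
  cls[nr == 0 & na >= 1] <- "INS"
  cls[nr >= 1 & na == 0] <- "DEL"
  if (anyNA(cls)) stop("allele lengths do not match any mutation class")
  cls
}

#' Validate a mutation table
#'
#' Checks the structural invariants: allele lengths per class, ACGT-only
#' alleles, ref != alt, positive positions.
#'
#' @param df data.frame as produced by [mutations()].
#' @return the input, invisibly, if valid; otherwise an error.
#' @export
validate_mutations <- function(df) {
  need <- c("sample_id", "chrom", "pos", "ref_allele", "alt_allele",
            "mut_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("mutation table missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$pos < 1L)) stop("positions must be >= 1")
  ok_chars <- function(x) grepl("^[ACGT]*$", x)
  if (!all(ok_chars(df$ref_allele)) || !all(ok_chars(df$alt_allele))) {
    stop("alleles must contain only A/C/G/T")
  }
  if (any(df$ref_allele == df$alt_allele)) {
    stop("ref_allele must differ from alt_allele")
  }
  nr <- nchar(df$ref_allele); na <- nchar(df$alt_allele)
  bad <-
    (df$mut_class == "SNV" & !(nr == 1 & na == 1)) |
    (df$mut_class == "DNV" & !(nr == 2 & na == 2)) |
    (df$mut_class == "INS" & !(nr == 0 & na >= 1)) |
    (df$mut_class == "DEL" & !(nr >= 1 & na == 0))
  if (any(bad)) {
    stop("allele lengths inconsistent with mut_class at row(s) ",
         paste(head(which(bad)), collapse = ", "))
  }
  invisible(df)
}

empty_mutations <- function() {
  data.frame(sample_id = character(), chrom = character(), pos = integer(),
             ref_allele = character(), alt_allele = character(),
             mut_class = character(), stringsAsFactors = FALSE)
}

sort_mutations <- function(df) {
  df[order(df$chrom, df$pos, df$sample_id), , drop = FALSE]
}
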