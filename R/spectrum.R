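## 96-channel trinucleotide spectrum machinery.
##
## Channel order contract: substitution classes C>A, C>G, C>T, T>A, T>C, T>G,
## each with the 16 flanking contexts in alphabetical order of the 5' then the
## 3' base, labelled "A[C>A]A" ... "T[T>G]T".

SNV_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Canonical 96-channel labels
#'
#' @return character vector of length 96 in canonical order.
#' @export
channel_labels <- function() {
  unlist(lapply(SNV_CLASSES, function(cl) {
    ref <- substr(cl, 1, 1)
    as.vector(t(outer(BASES, BASES, function(f, t3)
      paste0(f, "[", cl, "]", t3))))
  }))
}

#' The 32 strand-folded (pyrimidine-centred) triplets
#' @return character vector of length 32, alphabetical.
#' @export
pyrimidine_triplets <- function() {
  sort(as.vector(outer(BASES, as.vector(outer(PYRIMIDINES, BASES, paste0)),
                       function(f, ct) paste0(f, ct))))
}

## context triplet (5' + pyrimidine ref + 3') of each of the 96 channels
channel_context_triplet <- function() {
  lab <- channel_labels()
  paste0(substr(lab, 1, 1), substr(lab, 3, 3), substr(lab, 7, 7))
}

#' Construct a 96-channel spectrum
#'
#' @param values numeric vector of length 96 (canonical channel order), or a
#'   named vector using `"A[C>A]A"`-style labels.
#' @param type `"counts"` or `"rates"`.
#' @return a `spectrum96` object (named numeric vector).
#' @export
spectrum96 <- function(values = numeric(96), type = c("counts", "rates")) {
  type <- match.arg(type)
  lab <- channel_labels()
  if (!is.null(names(values))) {
    if (!setequal(names(values), lab)) stop("unknown channel labels")
    values <- values[lab]
  }
  if (length(values) != 96L) stop("a spectrum has exactly 96 channels")
  if (any(values < 0)) stop("spectrum values must be non-negative")
  structure(setNames(as.numeric(values), lab), class = "spectrum96",
            type = type)
}

#' @export
print.spectrum96 <- function(x, ...) {
  cat(sprintf("96-channel mutation spectrum (%s), total %.4g\n",
              attr(x, "type"), sum(x)))
  m <- six_class_marginal(x)
  for (cl in SNV_CLASSES) cat(sprintf("  %s: %.4g\n", cl, m[[cl]]))
  invisible(x)
}

#' @export
plot.spectrum96 <- function(x, main = "Mutation spectrum", ...) {
  cols <- rep(c("#03BCEE", "#010101", "#E32926", "#CAC9C9", "#A1CE63",
                "#EBC6C4"), each = 16)
  graphics::barplot(unclass(x), col = cols, border = NA, las = 2,
                    cex.names = 0.4, main = main, ...)
  invisible(x)
}

#' Six-class marginal of a 96-channel spectrum
#'
#' @param spectrum a [spectrum96()] object or plain 96-vector.
#' @return named numeric vector over C>A, C>G, C>T, T>A, T>C, T>G.
#' @export
six_class_marginal <- function(spectrum) {
  if (length(spectrum) != 96L) stop("expected 96 channels")
  setNames(vapply(seq_along(SNV_CLASSES), function(i)
    sum(spectrum[((i - 1) * 16 + 1):(i * 16)]), numeric(1)), SNV_CLASSES)
}

#' Classify an SNV into its 96-channel index
#'
#' Purine-reference substitutions are folded to the reverse complement so
#' every SNV is represented pyrimidine-centred. SNVs whose immediate flanks
#' are unavailable (contig edge) or non-ACGT are unassignable (NA).
#'
#' @param reference named character vector of chromosome sequences (or
#'   DNAStringSet).
#' @param snvs mutation table (SNV rows are classified; others rejected).
#' @return integer vector of channel indices (1-96), NA for unassignable.
#' @export
classify_snv <- function(reference, snvs) {
  reference <- as_reference(reference)
  if (nrow(snvs) == 0L) return(integer(0))
  if (any(snvs$mut_class != "SNV")) stop("classify_snv expects SNVs only")
  out <- rep(NA_integer_, nrow(snvs))
  for (chrom in unique(snvs$chrom)) {
    if (!chrom %in% names(reference)) {
      stop("chromosome absent from reference: ", chrom)
    }
    seq <- reference[[chrom]]
    i <- which(snvs$chrom == chrom)
    ctx <- ref_window(seq, snvs$pos[i] - 1L, snvs$pos[i] + 1L)
    ref <- snvs$ref_allele[i]
    alt <- snvs$alt_allele[i]
    ok <- !is.na(ctx) & grepl("^[ACGT]{3}$", ctx)
    ok[ok] <- substr(ctx[ok], 2, 2) == ref[ok]
    if (any(!is.na(ctx) & grepl("^[ACGT]{3}$", ctx) &
            substr(ctx, 2, 2) != ref)) {
      stop("SNV reference allele disagrees with reference sequence on ",
           chrom)
    }
    fold <- ok & ref %in% PURINES
    ctx[fold] <- revcomp(ctx[fold])
    alt[fold] <- complement_base(alt[fold])
    ref[fold] <- complement_base(ref[fold])
    idx <- rep(NA_integer_, length(i))
    cls <- match(paste0(ref[ok], ">", alt[ok]), SNV_CLASSES)
    f5 <- match(substr(ctx[ok], 1, 1), BASES)
    f3 <- match(substr(ctx[ok], 3, 3), BASES)
    idx[ok] <- (cls - 1L) * 16L + (f5 - 1L) * 4L + f3
    out[i] <- idx
  }
  out
}

#' Count the 96-channel and 6-class spectra of a set of SNVs
#'
#' @inheritParams classify_snv
#' @return list with `spectrum96` (counts), `six_class` (named counts),
#'   `n_unassignable`.
#' @export
count_spectrum <- function(snvs, reference) {
  idx <- classify_snv(reference, snvs)
  counts <- tabulate(idx, nbins = 96L)
  sp <- spectrum96(counts, type = "counts")
  list(spectrum96 = sp, six_class = six_class_marginal(sp),
       n_unassignable = sum(is.na(idx)))
}

#' Strand-folded triplet occurrence counts of a genome
#'
#' Counts all overlapping triplets, folding purine-centred triplets onto their
#' reverse complement so the table has the 32 pyrimidine-centred keys.
#' Windows containing non-ACGT bases are skipped.
#'
#' @param reference named character vector or DNAStringSet.
#' @return named numeric vector of length 32 (a triplet frequency table).
#' @export
triplet_occurrences <- function(reference) {
  reference <- as_reference(reference)
  if (length(reference) == 0L || all(nchar(reference) == 0L)) {
    stop("empty genome")
  }
  dna <- Biostrings::DNAStringSet(unname(reference))
  tf <- colSums(Biostrings::trinucleotideFrequency(dna))
  keys <- pyrimidine_triplets()
  out <- setNames(numeric(32), keys)
  for (trip in names(tf)) {
    centre <- substr(trip, 2, 2)
    key <- if (centre %in% PYRIMIDINES) trip else revcomp(trip)
    if (key %in% keys) out[key] <- out[key] + tf[[trip]]
  }
  if (all(out == 0)) stop("degenerate genome: no pyrimidine-centred triplets")
  out
}

#' Normalise channel counts by triplet occurrence
#'
#' rate[channel] = count[channel] / occurrences[context triplet of channel].
#'
#' @param counts a count [spectrum96()].
#' @param occurrences triplet frequency table ([triplet_occurrences()]).
#' @return a rate `spectrum96`.
#' @export
normalize_rates <- function(counts, occurrences) {
  trip <- channel_context_triplet()
  miss <- setdiff(trip, names(occurrences))
  if (length(miss)) stop("occurrence table missing triplets: ",
                         paste(unique(miss), collapse = ", "))
  occ <- occurrences[trip]
  if (any(occ == 0 & counts > 0)) {
    stop("non-zero count at a triplet with zero genomic occurrence")
  }
  rates <- ifelse(occ > 0, unclass(counts) / occ, 0)
  spectrum96(as.numeric(rates), type = "rates")
}

#' Fold enrichment of a channel subset
#'
#' Mean rate over the subset divided by the mean rate over all 96 channels.
#'
#' @param rates a rate `spectrum96`.
#' @param channel_subset integer indices or channel labels.
#' @return single numeric ratio.
#' @export
fold_enrichment <- function(rates, channel_subset) {
  if (is.character(channel_subset)) {
    channel_subset <- match(channel_subset, channel_labels())
    if (anyNA(channel_subset)) stop("unknown channel label in subset")
  }
  overall <- mean(rates)
  if (overall == 0) stop("zero overall mean rate")
  mean(rates[channel_subset]) / overall
}

#' Adjust a spectrum to a different genome's triplet composition
#'
#' Each channel is multiplied by the ratio of the target to the source triplet
#' frequency (both tables internally normalised to sum 1), then the spectrum
#' is renormalised to unit sum.
#'
#' @param spectrum a `spectrum96`.
#' @param source,target triplet frequency tables (32 pyrimidine-centred keys).
#' @return adjusted `spectrum96` summing to 1 (type "rates").
#' @export
adjust_to_species <- function(spectrum, source, target) {
  trip <- channel_context_triplet()
  for (tab in list(source, target)) {
    miss <- setdiff(unique(trip), names(tab))
    if (length(miss)) stop("triplet table missing keys: ",
                           paste(miss, collapse = ", "))
    if (any(tab[unique(trip)] <= 0)) stop("triplet tables must be positive")
  }
  src <- source / sum(source)
  tgt <- target / sum(target)
  w <- unclass(spectrum) * as.numeric(tgt[trip] / src[trip])
  s <- sum(w)
  if (s == 0) return(spectrum96(w, type = "rates"))
  spectrum96(w / s, type = "rates")
}

#' Compare a spectrum against a signature catalogue
#'
#' @param spectrum a `spectrum96` (any scale; Pearson and cosine are
#'   scale-free in the relevant sense).
#' @param signatures a signature matrix as read by [read_signature_matrix()]:
#'   96 rows (canonical channel order) x K signature columns.
#' @return data.frame with `signature`, `pearson`, `cosine`; Pearson is NA
#'   with a warning for zero-variance vectors.
#' @export
compare_signatures <- function(spectrum, signatures) {
  x <- as.numeric(spectrum)
  if (nrow(signatures) != 96L) stop("signature matrix must have 96 rows")
  cosine <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(NA_real_)
    sum(a * b) / (na * nb)
  }
  pear <- function(a, b) {
    if (stats::var(a) == 0 || stats::var(b) == 0) {
      warning("zero-variance vector: Pearson correlation undefined")
      return(NA_real_)
    }
    cor(a, b)
  }
  data.frame(
    signature = colnames(signatures),
    pearson = apply(signatures, 2, pear, a = x),
    cosine = apply(signatures, 2, cosine, a = x),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Mutation rate per base per cell division
#'
#' @param n_mutations observed mutation count.
#' @param diploid_genome_bp diploid genome size in bp.
#' @param generations number of cell divisions spanned by the assay.
#' @return list of class `rate_result` with the rate and its inputs.
#' @export
mutation_rate <- function(n_mutations, diploid_genome_bp, generations) {
  stop_if_not_scalar_number(n_mutations, "n_mutations")
  stop_if_not_scalar_number(diploid_genome_bp, "diploid_genome_bp")
  stop_if_not_scalar_number(generations, "generations")
  if (diploid_genome_bp <= 0) stop("genome size must be positive")
  if (generations <= 0) stop("generations must be positive")
  if (n_mutations < 0) stop("mutation count must be non-negative")
  structure(list(
    per_base_per_division = n_mutations / (diploid_genome_bp * generations),
    n_mutations = n_mutations, diploid_genome_bp = diploid_genome_bp,
    generations = generations
  ), class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf(
    "%g mutations / (%.3g bp diploid genome x %g divisions) = %.2g per base per cell division\n",
    x$n_mutations, x$diploid_genome_bp, x$generations,
    signif(x$per_base_per_division, 2)))
  invisible(x)
}

#' Mutation density per megabase
#'
#' @param n_mutations mutation count.
#' @param haploid_genome_bp haploid genome size in bp.
#' @return mutations per Mb (numeric scalar).
#' @export
per_mb_density <- function(n_mutations, haploid_genome_bp) {
  if (haploid_genome_bp <= 0) stop("genome size must be positive")
  n_mutations / (haploid_genome_bp / 1e6)
}

#' Group comparisons of per-clone mutation counts
#'
#' One-way ANOVA across all treatment groups plus unpaired two-sided Student
#' t-tests of each group against the reference (mock) group.
#'
#' @param counts named list of numeric vectors: per-clone mutation counts per
#'   treatment group.
#' @param mock name of the reference group (default "mock").
#' @return list with `anova_p`, `anova_F`, and data.frame `t_tests`
#'   (group, t, p) for every non-reference group.
#' @export
group_tests <- function(counts, mock = "mock") {
  if (length(counts) < 2L) stop("need at least 2 groups")
  if (any(lengths(counts) < 2L)) stop("each group needs >= 2 replicates")
  if (!mock %in% names(counts)) stop("reference group '", mock, "' absent")
  df <- data.frame(
    y = unlist(counts, use.names = FALSE),
    g = factor(rep(names(counts), lengths(counts)))
  )
  fit <- anova(aov(y ~ g, data = df))
  others <- setdiff(names(counts), mock)
  tt <- lapply(others, function(grp) {
    r <- t.test(counts[[grp]], counts[[mock]], var.equal = TRUE)
    data.frame(group = grp, t = unname(r$statistic), p = r$p.value,
               stringsAsFactors = FALSE)
  })
  list(anova_F = fit$`F value`[1], anova_p = fit$`Pr(>F)`[1],
       t_tests = do.call(rbind, tt))
}
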