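## Genic/intergenic mutation density, expression-stratified mutation
## distribution, and transcriptional strand bias.

#' Genic vs intergenic assignment of mutations
#'
#' Overlapping gene intervals are merged (strand ignored) before computing
#' the genic genome fraction; every mutation is assigned genic iff it falls
#' inside a merged interval. A 1-df chi-square test compares the observed
#' genic/intergenic counts against the genome-fraction expectation, and
#' density enrichment ratios (observed fraction / genome fraction) are
#' reported for both regions. Mutations on chromosomes without annotation or
#' length information are excluded with a count.
#'
#' @param muts mutation table.
#' @param annotation GRanges of gene intervals carrying seqlengths (see
#'   [read_annotation()]).
#' @return list of class `region_tally`.
#' @export
assign_regions <- function(muts, annotation) {
  sl <- GenomeInfoDb::seqlengths(annotation)
  if (all(is.na(sl))) stop("annotation carries no chromosome lengths")
  sl <- sl[!is.na(sl)]
  merged <- GenomicRanges::reduce(annotation, ignore.strand = TRUE)
  merged <- merged[as.character(GenomicRanges::seqnames(merged)) %in%
                     names(sl)]
  genic_bp <- sum(GenomicRanges::width(merged))
  genome_bp <- sum(as.numeric(sl))
  genic_frac <- genic_bp / genome_bp
  usable <- muts$chrom %in% names(sl)
  n_excluded <- sum(!usable)
  m <- muts[usable, , drop = FALSE]
  if (nrow(m)) {
    gr <- GenomicRanges::GRanges(
      m$chrom, IRanges::IRanges(m$pos, m$pos))
    genic <- GenomicRanges::countOverlaps(gr, merged,
                                          ignore.strand = TRUE) > 0
  } else {
    genic <- logical(0)
  }
  n_genic <- sum(genic); n_inter <- sum(!genic); n <- n_genic + n_inter
  chisq <- NULL
  if (n > 0) {
    chisq <- suppressWarnings(
      chisq.test(c(n_genic, n_inter), p = c(genic_frac, 1 - genic_frac)))
  }
  structure(list(
    genome_fraction_genic = genic_frac,
    genome_fraction_intergenic = 1 - genic_frac,
    n_genic = n_genic, n_intergenic = n_inter, n_excluded = n_excluded,
    observed_fraction_genic = if (n) n_genic / n else NA_real_,
    observed_fraction_intergenic = if (n) n_inter / n else NA_real_,
    genic_enrichment = if (n) (n_genic / n) / genic_frac else NA_real_,
    intergenic_enrichment =
      if (n) (n_inter / n) / (1 - genic_frac) else NA_real_,
    chisq_statistic = if (!is.null(chisq)) unname(chisq$statistic) else NA,
    p_value = if (!is.null(chisq)) chisq$p.value else NA,
    genic_index = genic
  ), class = "region_tally")
}

#' @export
print.region_tally <- function(x, ...) {
  cat(sprintf(
    "genic %.1f%% of genome; %d/%d mutations genic (%.1f%%); intergenic enrichment %.2f; chi-sq %.3g (p = %.3g)\n",
    100 * x$genome_fraction_genic, x$n_genic, x$n_genic + x$n_intergenic,
    100 * x$observed_fraction_genic, x$intergenic_enrichment,
    x$chisq_statistic, x$p_value))
  invisible(x)
}

#' Intergenic/genic density enrichment from printed fractions
#'
#' Density ratio of each region relative to a uniform genomic distribution:
#' intergenic enrichment = (1 - observed genic fraction) / (1 - genome genic
#' fraction); genic ratio = observed / genome genic fraction.
#'
#' @param genome_genic_frac fraction of the genome that is genic.
#' @param observed_genic_frac fraction of mutations falling in genes.
#' @return list `intergenic_enrichment`, `genic_ratio`, `genic_depletion`.
#' @export
region_enrichment <- function(genome_genic_frac, observed_genic_frac) {
  list(
    intergenic_enrichment =
      (1 - observed_genic_frac) / (1 - genome_genic_frac),
    genic_ratio = observed_genic_frac / genome_genic_frac,
    genic_depletion = 1 - observed_genic_frac / genome_genic_frac
  )
}

#' Expression distribution of mutated genes
#'
#' Compares the expression (log10 FPKM) of genes carrying mutations against
#' all genes, with a one-sided Mann-Whitney test for a skew toward low
#' expression. Zero FPKM values get a pseudo-count (display only; the rank
#' test is unaffected by the monotone transform).
#'
#' @param mutated_gene_ids character vector of gene ids containing mutations.
#' @param fpkm named numeric vector of FPKM per gene.
#' @param pseudo pseudo-count added before log10 (default 1e-3).
#' @return list with `all_log10`, `mutated_log10`, `p_value`
#'   (one-sided, mutated < all), `n_missing`.
#' @export
expression_distribution <- function(mutated_gene_ids, fpkm, pseudo = 1e-3) {
  if (length(mutated_gene_ids) == 0L) stop("empty mutated gene set")
  present <- mutated_gene_ids %in% names(fpkm)
  n_missing <- sum(!present)
  if (n_missing) warning(n_missing, " mutated gene(s) absent from FPKM table")
  mut <- fpkm[mutated_gene_ids[present]]
  if (!length(mut)) stop("no mutated genes found in FPKM table")
  wt <- suppressWarnings(wilcox.test(mut, fpkm, alternative = "less"))
  list(all_log10 = log10(fpkm + pseudo),
       mutated_log10 = log10(mut + pseudo),
       p_value = wt$p.value, n_missing = n_missing)
}

#' Transcriptional strand bias of genic SNVs
#'
#' For every genic SNV of the given class (pyrimidine notation), the strand
#' carrying the mutated pyrimidine is compared with the gene's template
#' (transcribed) strand: for a gene on "+", the template is "-". SNVs inside
#' overlapping genes of opposite strand are excluded with a count. A 1-df
#' chi-square tests the transcribed/non-transcribed counts against 50:50.
#'
#' @param snvs mutation table of SNVs.
#' @param annotation stranded GRanges of gene intervals.
#' @param mutation_class class in pyrimidine notation, e.g. "C>A".
#' @return list of class `strand_bias` with `n_transcribed` (pyrimidine on
#'   template strand), `n_untranscribed`, `chisq_statistic`, `p_value`,
#'   `n_excluded`.
#' @export
strand_bias <- function(snvs, annotation, mutation_class) {
  ref <- snvs$ref_allele; alt <- snvs$alt_allele
  flip <- ref %in% PURINES
  ref[flip] <- complement_base(ref[flip])
  alt[flip] <- complement_base(alt[flip])
  sel <- snvs$mut_class == "SNV" & paste0(ref, ">", alt) == mutation_class
  m <- snvs[sel, , drop = FALSE]
  pyr_strand <- ifelse(flip[sel], "-", "+")
  if (!nrow(m)) {
    return(structure(list(n_transcribed = 0L, n_untranscribed = 0L,
                          chisq_statistic = NA_real_, p_value = NA_real_,
                          n_excluded = 0L), class = "strand_bias"))
  }
  gr <- GenomicRanges::GRanges(m$chrom, IRanges::IRanges(m$pos, m$pos))
  hits <- GenomicRanges::findOverlaps(gr, annotation, ignore.strand = TRUE)
  gene_strand <- as.character(GenomicRanges::strand(annotation))
  byq <- split(gene_strand[S4Vectors::subjectHits(hits)],
               S4Vectors::queryHits(hits))
  n_t <- 0L; n_u <- 0L; n_excl <- 0L
  for (q in names(byq)) {
    strands <- unique(byq[[q]])
    strands <- strands[strands %in% c("+", "-")]
    if (length(strands) != 1L) { n_excl <- n_excl + 1L; next }
    template <- if (strands == "+") "-" else "+"
    if (pyr_strand[as.integer(q)] == template) n_t <- n_t + 1L
    else n_u <- n_u + 1L
  }
  cs <- if (n_t + n_u > 0) {
    suppressWarnings(chisq.test(c(n_t, n_u), p = c(0.5, 0.5)))
  } else NULL
  structure(list(
    n_transcribed = n_t, n_untranscribed = n_u,
    chisq_statistic = if (!is.null(cs)) unname(cs$statistic) else NA_real_,
    p_value = if (!is.null(cs)) cs$p.value else NA_real_,
    n_excluded = n_excl
  ), class = "strand_bias")
}

#' @export
print.strand_bias <- function(x, ...) {
  cat(sprintf(
    "strand bias: %d transcribed vs %d non-transcribed (chi-sq %.3g, p = %.3g; %d excluded)\n",
    x$n_transcribed, x$n_untranscribed, x$chisq_statistic, x$p_value,
    x$n_excluded))
  invisible(x)
}
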