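## Dinucleotide mutations, rainfall distances, and indel sequence-context
## classification with strand folding.

#' Intermutation distances (rainfall data)
#'
#' For each SNV, the distance to the previous SNV on the same chromosome of
#' the same sample. The first SNV of each chromosome has no distance and is
#' omitted. A distance of 1 flags dinucleotide-mutation candidacy.
#'
#' @param snvs mutation table of SNVs (computed per sample_id and chromosome).
#' @return data.frame `sample_id, chrom, pos, distance`.
#' @export
intermutation_distances <- function(snvs) {
  empty <- data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), distance = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(snvs) == 0L) return(empty)
  o <- order(snvs$sample_id, snvs$chrom, snvs$pos)
  if (!identical(o, seq_len(nrow(snvs)))) {
    warning("input not sorted by sample/chrom/pos; sorting internally")
    snvs <- snvs[o, , drop = FALSE]
  }
  res <- lapply(split(seq_len(nrow(snvs)),
                      list(snvs$sample_id, snvs$chrom), drop = TRUE),
                function(i) {
    if (length(i) < 2L) return(NULL)
    data.frame(sample_id = snvs$sample_id[i[-1]], chrom = snvs$chrom[i[-1]],
               pos = snvs$pos[i[-1]], distance = diff(snvs$pos[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Fold a dinucleotide substitution onto its canonical strand
#'
#' Equivalent events on the two strands are merged; the canonical
#' representation is the strand whose reference dinucleotide carries more
#' pyrimidines (so GG>TT is reported as CC>AA), with alphabetical tie-breaks
#' on the reference then the alternate dinucleotide.
#'
#' @param ref,alt length-2 reference/alternate dinucleotides (vectorised).
#' @return data.frame `ref, alt, flipped`.
#' @export
fold_dinucleotide <- function(ref, alt) {
  rref <- revcomp(ref); ralt <- revcomp(alt)
  n_pyr <- function(x) {
    vapply(strsplit(x, ""), function(ch) sum(ch %in% PYRIMIDINES),
           integer(1))
  }
  keep <- n_pyr(ref) > n_pyr(rref) |
    (n_pyr(ref) == n_pyr(rref) &
       (ref < rref | (ref == rref & alt <= ralt)))
  data.frame(ref = ifelse(keep, ref, rref),
             alt = ifelse(keep, alt, ralt),
             flipped = !keep, stringsAsFactors = FALSE)
}

#' Detect dinucleotide mutations among called SNVs
#'
#' Maximal runs of adjacent mutated positions (per sample and chromosome) of
#' length 2 are merged into dinucleotide mutations and folded onto the
#' canonical strand; runs of three or more are reported separately as
#' multi-nucleotide events; remaining SNVs are returned as isolated.
#'
#' @param snvs mutation table of SNVs.
#' @return list with `dinucleotides`, `multi_runs`, `isolated`.
#' @export
detect_dinucleotides <- function(snvs) {
  dn <- list(); runs <- list()
  snvs <- snvs[order(snvs$sample_id, snvs$chrom, snvs$pos), , drop = FALSE]
  iso <- logical(nrow(snvs))
  for (i in split(seq_len(nrow(snvs)),
                  list(snvs$sample_id, snvs$chrom), drop = TRUE)) {
    pos <- snvs$pos[i]
    run_id <- cumsum(c(1L, diff(pos) != 1L))
    for (r in split(seq_along(i), run_id)) {
      if (length(r) == 1L) {
        iso[i[r]] <- TRUE
      } else if (length(r) == 2L) {
        a <- i[r[1]]; b <- i[r[2]]
        ref2 <- paste0(snvs$ref_allele[a], snvs$ref_allele[b])
        alt2 <- paste0(snvs$alt_allele[a], snvs$alt_allele[b])
        f <- fold_dinucleotide(ref2, alt2)
        dn[[length(dn) + 1L]] <- data.frame(
          sample_id = snvs$sample_id[a], chrom = snvs$chrom[a],
          pos = snvs$pos[a], ref_dinuc = ref2, alt_dinuc = alt2,
          folded_ref = f$ref, folded_alt = f$alt,
          folded_label = paste0(f$ref, ">", f$alt),
          stringsAsFactors = FALSE)
      } else {
        runs[[length(runs) + 1L]] <- data.frame(
          sample_id = snvs$sample_id[i[r[1]]], chrom = snvs$chrom[i[r[1]]],
          pos = snvs$pos[i[r[1]]], length = length(r),
          stringsAsFactors = FALSE)
      }
    }
  }
  empty_dn <- data.frame(sample_id = character(), chrom = character(),
                         pos = integer(), ref_dinuc = character(),
                         alt_dinuc = character(), folded_ref = character(),
                         folded_alt = character(), folded_label = character(),
                         stringsAsFactors = FALSE)
  list(
    dinucleotides = if (length(dn)) do.call(rbind, dn) else empty_dn,
    multi_runs = if (length(runs)) do.call(rbind, runs) else
      data.frame(sample_id = character(), chrom = character(),
                 pos = integer(), length = integer(),
                 stringsAsFactors = FALSE),
    isolated = snvs[iso, , drop = FALSE]
  )
}

#' Classify one-base insertions by sequence context
#'
#' Insertions of A or G are analysed on the opposite strand — realigned to
#' the right first, so complementary events share one representation — and
#' reported as T or C insertions. Returns the two preceding and two following
#' bases around the insertion point on the folded strand.
#'
#' @param reference named character vector.
#' @param ins mutation table of 1-base insertions.
#' @return data.frame `preceding_2, inserted, following_2, strand_folded`;
#'   NA context where the flanks run off the contig.
#' @export
classify_insertion <- function(reference, ins) {
  reference <- as_reference(reference)
  if (nrow(ins) && any(ins$mut_class != "INS" | nchar(ins$alt_allele) != 1L)) {
    stop("classify_insertion expects 1-base insertions")
  }
  out <- data.frame(preceding_2 = rep(NA_character_, nrow(ins)),
                    inserted = NA_character_, following_2 = NA_character_,
                    strand_folded = NA, stringsAsFactors = FALSE)
  if (nrow(ins) == 0L) return(out)
  la <- left_align_indel(reference, ins)
  for (k in seq_len(nrow(ins))) {
    seq <- reference[[la$chrom[k]]]
    base <- la$alt_allele[k]
    if (base %in% PYRIMIDINES) {
      p <- la$pos[k]
      pre <- ref_window(seq, p - 1L, p)
      fol <- ref_window(seq, p + 1L, p + 2L)
      if (is.na(pre) || is.na(fol)) next
      out$preceding_2[k] <- pre; out$inserted[k] <- base
      out$following_2[k] <- fol; out$strand_folded[k] <- FALSE
    } else {
      ra <- realign_right(reference, la[k, , drop = FALSE])
      q <- ra$pos[1]
      pre <- ref_window(seq, q + 1L, q + 2L)   # opposite-strand preceding
      fol <- ref_window(seq, q - 1L, q)        # opposite-strand following
      if (is.na(pre) || is.na(fol)) next
      out$preceding_2[k] <- revcomp(pre)
      out$inserted[k] <- complement_base(ra$alt_allele[1])
      out$following_2[k] <- revcomp(fol)
      out$strand_folded[k] <- TRUE
    }
  }
  out
}

#' Classify one-base deletions by sequence context
#'
#' Deletions of A or G are analysed on the opposite strand (right-realigned
#' first) and reported as T or C deletions; returns the preceding base, the
#' deleted base and the following base on the folded strand. Events are
#' left-aligned before classification so homopolymer deletions have a single
#' canonical context.
#'
#' @param reference named character vector.
#' @param del mutation table of 1-base deletions.
#' @return data.frame `preceding, deleted, following, strand_folded`.
#' @export
classify_deletion <- function(reference, del) {
  reference <- as_reference(reference)
  if (nrow(del) && any(del$mut_class != "DEL" | nchar(del$ref_allele) != 1L)) {
    stop("classify_deletion expects 1-base deletions")
  }
  out <- data.frame(preceding = rep(NA_character_, nrow(del)),
                    deleted = NA_character_, following = NA_character_,
                    strand_folded = NA, stringsAsFactors = FALSE)
  if (nrow(del) == 0L) return(out)
  la <- left_align_indel(reference, del)
  for (k in seq_len(nrow(del))) {
    seq <- reference[[la$chrom[k]]]
    base <- la$ref_allele[k]
    if (base %in% PYRIMIDINES) {
      p <- la$pos[k]
      pre <- ref_window(seq, p - 1L, p - 1L)
      fol <- ref_window(seq, p + 1L, p + 1L)
      if (is.na(pre) || is.na(fol)) next
      out$preceding[k] <- pre; out$deleted[k] <- base
      out$following[k] <- fol; out$strand_folded[k] <- FALSE
    } else {
      ra <- realign_right(reference, la[k, , drop = FALSE])
      q <- ra$pos[1]
      pre <- ref_window(seq, q + 1L, q + 1L)
      fol <- ref_window(seq, q - 1L, q - 1L)
      if (is.na(pre) || is.na(fol)) next
      out$preceding[k] <- complement_base(pre)
      out$deleted[k] <- complement_base(ra$ref_allele[1])
      out$following[k] <- complement_base(fol)
      out$strand_folded[k] <- TRUE
    }
  }
  out
}

#' Fraction of two-base deletions removing a putative crosslink motif
#'
#' Counts two-base deletions whose deleted dinucleotide coincides exactly
#' (either strand reading) with an AG or GG dinucleotide — the putative
#' intrastrand crosslink motifs — i.e. deleted pair in {AG, GG, CT, CC}.
#'
#' @param reference named character vector (used to verify alleles).
#' @param del mutation table of 2-base deletions.
#' @return list `n_total`, `n_motif`, `fraction`.
#' @export
motif_overlap_two_base_deletions <- function(reference, del) {
  if (nrow(del) && any(del$mut_class != "DEL" | nchar(del$ref_allele) != 2L)) {
    stop("expects 2-base deletions")
  }
  motifs <- c("AG", "GG", "CT", "CC")
  hit <- del$ref_allele %in% motifs
  list(n_total = nrow(del), n_motif = sum(hit),
       fraction = if (nrow(del)) sum(hit) / nrow(del) else NA_real_)
}

#' Catalogue flanking sequences around SNVs of a given class
#'
#' Generic flanking-window tally used, e.g., to break the TC>AC events into
#' TCC/TCT/... classes or to isolate GCG>GAG candidates. The class is given
#' in pyrimidine notation; SNVs with a purine reference are folded before
#' matching, and their flanks are read from the folded strand.
#'
#' @param reference named character vector.
#' @param snvs mutation table of SNVs.
#' @param class substitution class, e.g. "C>A".
#' @param five_prime,three_prime optional required context base(s) immediately
#'   5'/3' of the mutated base (on the folded strand); NULL = no constraint.
#' @param flank_up,flank_down how many bases up/downstream (folded strand) to
#'   include in the tallied window (the mutated base is marked with ".").
#' @return list with `tally` (named counts of flank windows), `n_matching`,
#'   `n_skipped` (flank beyond contig).
#' @export
context_catalogue <- function(reference, snvs, class, five_prime = NULL,
                              three_prime = NULL, flank_up = 1L,
                              flank_down = 1L) {
  reference <- as_reference(reference)
  if (nrow(snvs) == 0L) {
    return(list(tally = integer(0), n_matching = 0L, n_skipped = 0L))
  }
  ref <- snvs$ref_allele; alt <- snvs$alt_allele
  flip <- ref %in% PURINES
  ref[flip] <- complement_base(ref[flip])
  alt[flip] <- complement_base(alt[flip])
  match_class <- paste0(ref, ">", alt) == class
  windows <- character(0); skipped <- 0L
  for (k in which(match_class)) {
    seq <- reference[[snvs$chrom[k]]]
    p <- snvs$pos[k]
    up <- ref_window(seq, p - flank_up, p - 1L)
    dn <- ref_window(seq, p + 1L, p + flank_down)
    if (flank_up == 0L) up <- ""
    if (flank_down == 0L) dn <- ""
    if (is.na(up) || is.na(dn)) { skipped <- skipped + 1L; next }
    if (flip[k]) {
      tmp <- revcomp(dn); dn <- revcomp(up); up <- tmp
    }
    ## context constraints apply to the immediate neighbours (folded strand)
    if (!is.null(five_prime) &&
        substr(up, nchar(up), nchar(up)) != five_prime) next
    if (!is.null(three_prime) && substr(dn, 1, 1) != three_prime) next
    windows <- c(windows, paste0(up, ".", dn))
  }
  tally <- if (length(windows)) table(windows) else integer(0)
  list(tally = c(tally), n_matching = length(windows), n_skipped = skipped)
}

#' Cross-clone mutation clustering
#'
#' For each pair of clones, counts positions of one clone lying within
#' `window_bp` of a mutation of the other clone, and compares the total
#' against the expectation under uniform independent placement
#' (approximately n1*n2*2w/L per ordered pair).
#'
#' @param snv_sets named list of per-clone position data.frames
#'   (`chrom`, `pos`).
#' @param window_bp window size in bp.
#' @param genome_length total genome length (for the expectation).
#' @return list with `pairs` (data.frame clone_a, clone_b, n_pairs,
#'   expected), `total`, `expected_total`.
#' @export
cross_clone_clustering <- function(snv_sets, window_bp, genome_length) {
  if (length(snv_sets) < 2L) stop("need at least 2 clones")
  ids <- names(snv_sets)
  res <- list()
  for (a in seq_along(ids)) {
    for (b in seq_along(ids)) {
      if (b <= a) next
      A <- snv_sets[[a]]; B <- snv_sets[[b]]
      n <- 0L
      for (chrom in intersect(unique(A$chrom), unique(B$chrom))) {
        pa <- sort(A$pos[A$chrom == chrom])
        pb <- sort(B$pos[B$chrom == chrom])
        ## count pairs within the window via sorted interval counting
        lo <- findInterval(pa - window_bp - 0.5, pb)
        hi <- findInterval(pa + window_bp + 0.5, pb)
        n <- n + sum(hi - lo)
      }
      expected <- nrow(A) * nrow(B) * (2 * window_bp + 1) / genome_length
      res[[length(res) + 1L]] <- data.frame(
        clone_a = ids[a], clone_b = ids[b], n_pairs = n,
        expected = expected, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, res)
  list(pairs = pairs, total = sum(pairs$n_pairs),
       expected_total = sum(pairs$expected))
}
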