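#' Caller filter parameters
#'
#' The published filter set for unique-mutation detection in isogenic clone
#' cohorts: a candidate is accepted when, in exactly one sample, the mutated
#' allele frequency and coverage pass their thresholds while every other
#' sample looks reference-like.
#'
#' @param min_mut_af minimum mutated allele frequency in the mutated sample
#'   (default 0.33).
#' @param min_cov_mutated minimum coverage of the mutated sample (default 10).
#' @param min_other_ref_af minimum reference allele frequency in every other
#'   sample (default 0.9).
#' @param min_base_quality Phred base-quality filter applied at pileup
#'   construction (default 30; recorded here, enforced by [read_mpileup()]).
#' @return list of class `caller_params`.
#' @export
caller_params <- function(min_mut_af = 0.33, min_cov_mutated = 10,
                          min_other_ref_af = 0.9, min_base_quality = 30) {
  if (!(min_mut_af > 0 && min_mut_af <= 1)) stop("min_mut_af must be in (0,1]")
  if (!(min_other_ref_af > 0 && min_other_ref_af <= 1)) {
    stop("min_other_ref_af must be in (0,1]")
  }
  if (min_cov_mutated < 1) stop("min_cov_mutated must be >= 1")
  structure(list(min_mut_af = min_mut_af,
                 min_cov_mutated = min_cov_mutated,
                 min_other_ref_af = min_other_ref_af,
                 min_base_quality = min_base_quality),
            class = "caller_params")
}

#' Call mutations unique to one sample of an isogenic cohort
#'
#' At every pileup position a candidate allele (the most supported
#' non-reference base, ties broken alphabetically; or the most supported
#' inserted sequence / deletion length) is evaluated per sample. A call is
#' emitted iff (i) in exactly one sample the candidate allele fraction is at
#' least `min_mut_af` with coverage at least `min_cov_mutated`, and (ii) the
#' reference allele fraction in every other sample is at least
#' `min_other_ref_af`. Samples with zero coverage fail the other-sample
#' filter, suppressing the call. Positions with a non-ACGT reference base are
#' skipped. Emitted indels are left-aligned.
#'
#' For indels the allele fraction denominator is the spanning-read coverage at
#' the anchor position, and an other sample's reference fraction is the
#' fraction of its reads not supporting any indel there.
#'
#' @param pu a [pileup()] covering the whole cohort.
#' @param params a [caller_params()].
#' @param reference named character vector of chromosome sequences; required
#'   when the pileup carries indel evidence (deleted sequences are read from
#'   it and emitted indels left-aligned against it).
#' @param cohort sample ids expected in the pileup; defaults to the pileup's
#'   own samples. A mismatch is an error.
#' @return mutation table with extra columns `mut_af` and `cov`.
#' @export
call_unique_mutations <- function(pu, params = caller_params(),
                                  reference = NULL, cohort = NULL) {
  if (!inherits(pu, "pileup")) stop("expected a pileup object")
  if (is.null(cohort)) cohort <- pu$samples
  if (!setequal(cohort, pu$samples)) {
    stop("pileup samples do not match the declared cohort")
  }
  if (length(pu$samples) < 2L) stop("cohort must contain at least 2 samples")
  n <- length(pu$pos); S <- length(pu$samples)
  keep <- pu$ref %in% BASES
  snv <- call_snvs(pu, params, keep)
  idl <- call_indels(pu, params, reference, keep)
  calls <- rbind(snv, idl)
  if (nrow(calls)) calls <- calls[order(calls$chrom, calls$pos), ,
                                  drop = FALSE]
  rownames(calls) <- NULL
  calls
}

call_snvs <- function(pu, params, keep) {
  n <- length(pu$pos); S <- length(pu$samples)
  out <- cbind(empty_mutations(), data.frame(mut_af = numeric(),
                                             cov = integer()))
  if (!any(keep)) return(out)
  cov <- pu$cov
  ## reference-base counts per position/sample
  nref <- matrix(0L, n, S)
  for (b in BASES) {
    i <- pu$ref == b
    if (any(i)) nref[i, ] <- pu$counts[[b]][i, , drop = FALSE]
  }
  ref_af_ok <- cov > 0 & nref >= params$min_other_ref_af * cov - 1e-9
  ## per-sample best alternate allele (alphabetical tie-break via column order)
  alt_n <- matrix(0L, n, S)
  alt_b <- matrix(NA_character_, n, S)
  for (b in BASES) {
    i <- which(pu$ref == b & keep)
    if (!length(i)) next
    others <- setdiff(BASES, b)
    sub <- vapply(others, function(x) pu$counts[[x]][i, , drop = FALSE],
                  matrix(0L, length(i), S))
    ## sub: length(i) x S x 3
    for (s in seq_len(S)) {
      block <- matrix(sub[, s, ], nrow = length(i))
      mx <- max.col(block, ties.method = "first")
      alt_n[i, s] <- block[cbind(seq_len(length(i)), mx)]
      alt_b[i, s] <- others[mx]
    }
  }
  pass <- keep & alt_n > 0 & cov >= params$min_cov_mutated &
    alt_n >= params$min_mut_af * cov - 1e-9
  npass <- rowSums(pass)
  nok <- rowSums(ref_af_ok)
  cand <- which(npass == 1L)
  if (!length(cand)) return(out)
  s_mut <- max.col(pass[cand, , drop = FALSE], ties.method = "first")
  ok <- nok[cand] == S |
    (nok[cand] == S - 1L & !ref_af_ok[cbind(cand, s_mut)])
  cand <- cand[ok]; s_mut <- s_mut[ok]
  if (!length(cand)) return(out)
  df <- mutations(sample_id = pu$samples[s_mut], chrom = pu$chrom[cand],
                  pos = pu$pos[cand], ref_allele = pu$ref[cand],
                  alt_allele = alt_b[cbind(cand, s_mut)], mut_class = "SNV")
  df$mut_af <- alt_n[cbind(cand, s_mut)] / cov[cbind(cand, s_mut)]
  df$cov <- cov[cbind(cand, s_mut)]
  df
}

call_indels <- function(pu, params, reference, keep) {
  out <- cbind(empty_mutations(), data.frame(mut_af = numeric(),
                                             cov = integer()))
  ev <- pu$indels
  if (is.null(ev) || nrow(ev) == 0L) return(out)
  if (is.null(reference)) {
    stop("reference required to call indels from pileup evidence")
  }
  reference <- as_reference(reference)
  S <- length(pu$samples)
  ## total indel support per (row, sample): used for other-sample ref fraction
  tot <- matrix(0L, length(pu$pos), S)
  for (k in seq_len(nrow(ev))) tot[ev$row[k], ev$sample[k]] <-
      tot[ev$row[k], ev$sample[k]] + ev$count[k]
  res <- list()
  for (grp in split(seq_len(nrow(ev)), paste(ev$row, ev$type))) {
    r <- ev$row[grp[1]]; type <- ev$type[grp[1]]
    if (!keep[r]) next
    ## most supported allele per sample within this row/type
    pass_sample <- integer(0); pass_allele <- character(0)
    pass_af <- numeric(0); pass_cov <- integer(0)
    for (s in unique(ev$sample[grp])) {
      rows <- grp[ev$sample[grp] == s]
      o <- order(-ev$count[rows], ev$allele[rows])
      best <- rows[o[1]]
      covs <- pu$cov[r, s]
      if (covs >= params$min_cov_mutated &&
          ev$count[best] >= params$min_mut_af * covs - 1e-9 &&
          ev$count[best] > 0) {
        pass_sample <- c(pass_sample, s)
        pass_allele <- c(pass_allele, ev$allele[best])
        pass_af <- c(pass_af, ev$count[best] / covs)
        pass_cov <- c(pass_cov, covs)
      }
    }
    if (length(pass_sample) != 1L) next
    others <- setdiff(seq_len(S), pass_sample)
    covo <- pu$cov[r, others]
    refo_ok <- covo > 0 &
      (covo - tot[r, others]) >= params$min_other_ref_af * covo - 1e-9
    if (!all(refo_ok)) next
    chrom <- pu$chrom[r]; anchor <- pu$pos[r]
    seq <- reference[[chrom]]
    if (is.null(seq)) stop("chromosome absent from reference: ", chrom)
    if (type == "ins") {
      m <- mutations(pu$samples[pass_sample], chrom, anchor, "",
                     pass_allele, "INS")
    } else {
      len <- as.integer(pass_allele)
      delseq <- ref_window(seq, anchor + 1L, anchor + len)
      if (is.na(delseq)) next
      m <- mutations(pu$samples[pass_sample], chrom, anchor + 1L, delseq,
                     "", "DEL")
    }
    m <- left_align_indel(reference, m)
    m$mut_af <- pass_af; m$cov <- pass_cov
    res[[length(res) + 1L]] <- m
  }
  if (!length(res)) return(out)
  do.call(rbind, res)
}

#' Left-align an indel to its 5'-most equivalent position
#'
#' Within a homopolymer or tandem-repeat context, an insertion or deletion has
#' several equivalent representations; the canonical one used throughout the
#' package is the leftmost. Idempotent; non-indel input is an error.
#'
#' @param reference named character vector of chromosome sequences.
#' @param mut one-or-more-row mutation table of INS/DEL records.
#' @return the mutation table with shifted `pos` (and rotated allele).
#' @export
left_align_indel <- function(reference, mut) {
  shift_indel(reference, mut, direction = "left")
}

#' Right-align an indel to its 3'-most equivalent position
#'
#' Used before strand folding of indel contexts: an indel analysed on the
#' opposite strand is realigned to the right so complementary events share a
#' representation.
#'
#' @inheritParams left_align_indel
#' @export
realign_right <- function(reference, mut) {
  shift_indel(reference, mut, direction = "right")
}

shift_indel <- function(reference, mut, direction) {
  reference <- as_reference(reference)
  if (any(!mut$mut_class %in% c("INS", "DEL"))) {
    stop("indel realignment applies to INS/DEL mutations only")
  }
  out <- mut
  for (k in seq_len(nrow(mut))) {
    seq <- reference[[mut$chrom[k]]]
    if (is.null(seq)) stop("chromosome absent from reference: ", mut$chrom[k])
    n <- nchar(seq)
    if (mut$mut_class[k] == "DEL") {
      pos <- mut$pos[k]; L <- nchar(mut$ref_allele[k])
      obs <- ref_window(seq, pos, pos + L - 1L)
      if (is.na(obs) || obs != mut$ref_allele[k]) {
        stop(sprintf("deletion allele inconsistent with reference at %s:%d",
                     mut$chrom[k], pos))
      }
      if (direction == "left") {
        while (pos > 1L &&
               substr(seq, pos - 1L, pos - 1L) ==
               substr(seq, pos + L - 1L, pos + L - 1L)) {
          pos <- pos - 1L
        }
      } else {
        while (pos + L <= n &&
               substr(seq, pos, pos) == substr(seq, pos + L, pos + L)) {
          pos <- pos + 1L
        }
      }
      out$pos[k] <- pos
      out$ref_allele[k] <- substr(seq, pos, pos + L - 1L)
    } else {
      pos <- mut$pos[k]; ins <- mut$alt_allele[k]; L <- nchar(ins)
      if (direction == "left") {
        ## pos is the base 5' of the insertion; the leftmost expressible
        ## anchor is 1, so shifting stops there
        while (pos > 1L && substr(seq, pos, pos) == substr(ins, L, L)) {
          ins <- paste0(substr(seq, pos, pos), substr(ins, 1L, L - 1L))
          pos <- pos - 1L
        }
      } else {
        while (pos + 1L <= n &&
               substr(seq, pos + 1L, pos + 1L) == substr(ins, 1L, 1L)) {
          ins <- paste0(substr(ins, 2L, L), substr(seq, pos + 1L, pos + 1L))
          pos <- pos + 1L
        }
      }
      out$pos[k] <- pos
      out$alt_allele[k] <- ins
    }
  }
  out
}
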