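## Independent brute-force oracles and small fixture builders. These are
## written directly from the published filter description / definitions and
## deliberately share no code with the package internals they check.

BASES4 <- c("A", "C", "G", "T")

rc_str <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## all-reference pileup over a reference string, constant coverage
toy_pileup <- function(ref_string, samples, coverage = 20, chrom = "chr1") {
  n <- nchar(ref_string)
  S <- length(samples)
  ref <- strsplit(ref_string, "")[[1]]
  cov <- matrix(as.integer(coverage), n, S)
  counts <- setNames(lapply(BASES4, function(b) matrix(0L, n, S)), BASES4)
  for (b in BASES4) counts[[b]][ref == b, ] <- as.integer(coverage)
  pileup(chrom, seq_len(n), ref, samples, cov, counts)
}

## override base counts of one sample at one position
set_counts <- function(pu, pos, sample, counts_named, cov = NULL) {
  s <- match(sample, pu$samples)
  r <- which(pu$pos == pos)
  for (b in BASES4) pu$counts[[b]][r, s] <- 0L
  for (b in names(counts_named)) {
    pu$counts[[b]][r, s] <- as.integer(counts_named[[b]])
  }
  pu$cov[r, s] <- if (is.null(cov)) sum(unlist(counts_named)) else
    as.integer(cov)
  pu
}

add_indel_evidence <- function(pu, pos, sample, type, allele, count) {
  s <- match(sample, pu$samples)
  r <- which(pu$pos == pos)
  pu$indels <- rbind(pu$indels, data.frame(
    row = r, sample = s, type = type, allele = allele,
    count = as.integer(count), stringsAsFactors = FALSE))
  pu
}

## Brute-force unique-mutation filter: a mutation is accepted iff it is
## present in exactly one sample, satisfying minimum mutated allele
## frequency, coverage of the mutated sample, and minimum reference allele
## frequency of each other sample.
oracle_caller <- function(pu, params, reference = NULL) {
  S <- length(pu$samples)
  out <- list()
  for (r in seq_along(pu$pos)) {
    refb <- pu$ref[r]
    if (!refb %in% BASES4) next
    passing <- integer(0); allele <- character(0)
    af <- numeric(0); cv_pass <- integer(0)
    for (s in seq_len(S)) {
      cv <- pu$cov[r, s]
      cnt <- vapply(BASES4, function(b) pu$counts[[b]][r, s], integer(1))
      alts <- cnt[setdiff(BASES4, refb)]
      best <- names(sort(alts, decreasing = TRUE))
      best <- best[order(-alts[best], best)][1]
      if (cv >= params$min_cov_mutated && alts[[best]] > 0 &&
          alts[[best]] / cv >= params$min_mut_af - 1e-12) {
        passing <- c(passing, s); allele <- c(allele, best)
        af <- c(af, alts[[best]] / cv); cv_pass <- c(cv_pass, cv)
      }
    }
    if (length(passing) == 1L) {
      others <- setdiff(seq_len(S), passing)
      ok <- all(vapply(others, function(s) {
        cv <- pu$cov[r, s]
        cv > 0 && pu$counts[[refb]][r, s] / cv >=
          params$min_other_ref_af - 1e-12
      }, logical(1)))
      if (ok) {
        out[[length(out) + 1L]] <- data.frame(
          sample_id = pu$samples[passing], chrom = pu$chrom[r],
          pos = pu$pos[r], ref_allele = refb, alt_allele = allele,
          mut_class = "SNV", stringsAsFactors = FALSE)
      }
    }
    ## indel candidates at this position
    if (!is.null(reference) && nrow(pu$indels)) {
      for (type in c("ins", "del")) {
        ev <- pu$indels[pu$indels$row == r & pu$indels$type == type, ,
                        drop = FALSE]
        if (!nrow(ev)) next
        tot_per_sample <- tapply(pu$indels$count[pu$indels$row == r],
                                 pu$indels$sample[pu$indels$row == r], sum)
        passing <- integer(0); allele <- character(0)
        for (s in unique(ev$sample)) {
          evs <- ev[ev$sample == s, , drop = FALSE]
          evs <- evs[order(-evs$count, evs$allele), , drop = FALSE]
          cv <- pu$cov[r, s]
          if (cv >= params$min_cov_mutated && evs$count[1] > 0 &&
              evs$count[1] / cv >= params$min_mut_af - 1e-12) {
            passing <- c(passing, s); allele <- c(allele, evs$allele[1])
          }
        }
        if (length(passing) != 1L) next
        others <- setdiff(seq_len(S), passing)
        ok <- all(vapply(others, function(s) {
          cv <- pu$cov[r, s]
          ind_s <- tot_per_sample[as.character(s)]
          if (is.na(ind_s)) ind_s <- 0
          cv > 0 && (cv - ind_s) / cv >= params$min_other_ref_af - 1e-12
        }, logical(1)))
        if (!ok) next
        chrom <- pu$chrom[r]; seq <- reference[[chrom]]
        if (type == "ins") {
          m <- data.frame(sample_id = pu$samples[passing], chrom = chrom,
                          pos = pu$pos[r], ref_allele = "",
                          alt_allele = allele, mut_class = "INS",
                          stringsAsFactors = FALSE)
        } else {
          len <- as.integer(allele)
          m <- data.frame(sample_id = pu$samples[passing], chrom = chrom,
                          pos = pu$pos[r] + 1L,
                          ref_allele = substr(seq, pu$pos[r] + 1L,
                                              pu$pos[r] + len),
                          alt_allele = "", mut_class = "DEL",
                          stringsAsFactors = FALSE)
        }
        out[[length(out) + 1L]] <- oracle_left_align(seq, m)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref_allele = character(),
                      alt_allele = character(), mut_class = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$pos), , drop = FALSE]
}

## Brute-force left alignment by enumerating equivalent representations:
## apply the edit, then scan positions from the left for an edit producing
## the identical string.
oracle_left_align <- function(seq, m) {
  if (m$mut_class == "DEL") {
    L <- nchar(m$ref_allele)
    edited <- paste0(substr(seq, 1, m$pos - 1),
                     substr(seq, m$pos + L, nchar(seq)))
    for (p in seq_len(m$pos)) {
      cand <- paste0(substr(seq, 1, p - 1), substr(seq, p + L, nchar(seq)))
      if (cand == edited) {
        m$pos <- p
        m$ref_allele <- substr(seq, p, p + L - 1)
        break
      }
    }
  } else if (m$mut_class == "INS") {
    L <- nchar(m$alt_allele)
    edited <- paste0(substr(seq, 1, m$pos), m$alt_allele,
                     substr(seq, m$pos + 1, nchar(seq)))
    for (p in seq_len(m$pos)) {
      cand_ins <- substr(edited, p + 1, p + L)
      cand <- paste0(substr(seq, 1, p), cand_ins,
                     substr(seq, p + 1, nchar(seq)))
      if (cand == edited) {
        m$pos <- p
        m$alt_allele <- cand_ins
        break
      }
    }
  }
  m
}

oracle_right_align <- function(seq, m) {
  n <- nchar(seq)
  if (m$mut_class == "DEL") {
    L <- nchar(m$ref_allele)
    edited <- paste0(substr(seq, 1, m$pos - 1),
                     substr(seq, m$pos + L, n))
    for (p in seq(n - L + 1, 1)) {
      cand <- paste0(substr(seq, 1, p - 1), substr(seq, p + L, n))
      if (cand == edited) {
        m$pos <- p
        m$ref_allele <- substr(seq, p, p + L - 1)
        break
      }
    }
  } else if (m$mut_class == "INS") {
    L <- nchar(m$alt_allele)
    edited <- paste0(substr(seq, 1, m$pos), m$alt_allele,
                     substr(seq, m$pos + 1, n))
    for (p in seq(n, 1)) {
      cand_ins <- substr(edited, p + 1, p + L)
      cand <- paste0(substr(seq, 1, p), cand_ins, substr(seq, p + 1, n))
      if (cand == edited) {
        m$pos <- p
        m$alt_allele <- cand_ins
        break
      }
    }
  }
  m
}

## Brute-force 96-channel classification, independent string arithmetic
oracle_classify <- function(seq, pos, ref, alt) {
  if (pos < 2 || pos > nchar(seq) - 1) return(NA_integer_)
  trip <- substr(seq, pos - 1, pos + 1)
  if (grepl("[^ACGT]", trip)) return(NA_integer_)
  if (ref %in% c("A", "G")) {
    trip <- rc_str(trip)
    ref <- chartr("ACGT", "TGCA", ref)
    alt <- chartr("ACGT", "TGCA", alt)
  }
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  ci <- match(paste0(ref, ">", alt), classes)
  f5 <- match(substr(trip, 1, 1), BASES4)
  f3 <- match(substr(trip, 3, 3), BASES4)
  (ci - 1L) * 16L + (f5 - 1L) * 4L + f3
}

mut_key <- function(d) {
  paste(d$sample_id, d$chrom, d$pos, d$ref_allele, d$alt_allele, d$mut_class)
}
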