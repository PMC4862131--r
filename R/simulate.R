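## Synthetic isogenic-cohort generator: a random reference genome, shared
## germline heterozygous variants, per-clone unique mutations drawn from
## treatment-specific spectra, and simulated multi-sample pileups with
## Poisson coverage and binomial allele counts.

#' Treatment preset spectra and indel context models
#'
#' Probability models emulating the three mutagenic treatment conditions. The
#' SNV weights are 96-channel probability vectors encoding the published
#' class proportions (mock: C>T/C>A dominated with a strong NCG>NTG excess;
#' cisplatin: 57 % C>A concentrated at NCC/NCT contexts plus NTC>NAC;
#' cyclophosphamide: T>A and C>T dominated with NTT preference). Indel models
#' give weights over concrete sequence contexts (N = any base). These are
#' approximations of published figure proportions, not ground truth.
#'
#' @param name one of "mock", "cisplatin", "cyclophosphamide".
#' @return list with elements `spectrum_weights` (spectrum96),
#'   `ins_model`, `del_model`, `dnv_model` (data.frames of weighted context
#'   classes), `dnv_fraction`, `del_len2_fraction`.
#' @export
treatment_preset <- function(name = c("mock", "cisplatin",
                                      "cyclophosphamide")) {
  name <- match.arg(name)
  lab <- channel_labels()
  w <- setNames(numeric(96), lab)
  add_class <- function(w, cl, total, ctx_weights = NULL) {
    idx <- grep(paste0("\\[", substr(cl, 1, 1), ">", substr(cl, 3, 3), "\\]"),
                lab)
    base <- rep(1, 16)
    if (!is.null(ctx_weights)) {
      ## ctx_weights: named by "<5'><3'>" pairs or "N<3'>" / "<5'>N" patterns
      for (p in names(ctx_weights)) {
        f5 <- substr(p, 1, 1); f3 <- substr(p, 2, 2)
        hit <- rep(TRUE, 16)
        pairs <- as.vector(t(outer(BASES, BASES, paste0)))
        if (f5 != "N") hit <- hit & substr(pairs, 1, 1) == f5
        if (f3 != "N") hit <- hit & substr(pairs, 2, 2) == f3
        base[hit] <- base[hit] * ctx_weights[[p]]
      }
    }
    w[idx] <- total * base / sum(base)
    w
  }
  if (name == "mock") {
    ## C>T with CpG excess, plus broad C>A; loosely the spontaneous spectrum
    w <- add_class(w, "C>T", 0.40, list(NG = 12))
    w <- add_class(w, "C>A", 0.25)
    w <- add_class(w, "C>G", 0.08)
    w <- add_class(w, "T>A", 0.07)
    w <- add_class(w, "T>C", 0.13)
    w <- add_class(w, "T>G", 0.07)
    ins <- data.frame(pre2 = "NN", base = c("T", "C"), fol2 = "NN",
                      weight = c(0.6, 0.4), stringsAsFactors = FALSE)
    del <- data.frame(pre = "N", base = c("T", "C"), fol = "N",
                      weight = c(0.6, 0.4), stringsAsFactors = FALSE)
    dnv <- empty_dnv_model()
    dnv_fraction <- 0; del2 <- 0
  } else if (name == "cisplatin") {
    ## 57 % C>A overall: NCC 40 %, NCT 12 % of all SNVs, remainder spread;
    ## T>A concentrated at NTC (9 % of all SNVs)
    w <- add_class(w, "C>A", 0.57, list(NC = 28, NT = 8.5))
    w <- add_class(w, "T>A", 0.12, list(NC = 12))
    w <- add_class(w, "C>G", 0.06)
    w <- add_class(w, "C>T", 0.10)
    w <- add_class(w, "T>C", 0.09)
    w <- add_class(w, "T>G", 0.06)
    ins <- data.frame(
      pre2 = c("GG", "GG", "GG", "GG", "AG", "NN", "CC", "NN"),
      base = c("T", "T", "T", "T", "T", "T", "C", "C"),
      fol2 = c("TT", "TA", "TC", "TG", "TT", "NN", "NN", "NN"),
      weight = c(0.51, 0.10, 0.10, 0.10, 0.05, 0.09, 0.03, 0.02),
      stringsAsFactors = FALSE)
    ## folded deleted base is T or C; CC contexts mirror GG motifs on the
    ## purine strand, G.C / C.T mirror AG motifs
    del <- data.frame(
      pre = c("C", "C", "G", "A", "T", "N", "N"),
      base = c("C", "C", "C", "T", "T", "T", "C"),
      fol = c("T", "A", "T", "A", "T", "N", "N"),
      weight = c(0.25, 0.15, 0.20, 0.10, 0.10, 0.10, 0.10),
      stringsAsFactors = FALSE)
    dnv <- data.frame(
      ref = c("CC", "CT", "TC", "CA", "CC"),
      alt = c("AA", "AA", "AA", "AC", "AT"),
      weight = c(0.45, 0.15, 0.15, 0.10, 0.15),
      stringsAsFactors = FALSE)
    dnv_fraction <- 0.07; del2 <- 0.27
  } else {
    w <- add_class(w, "T>A", 0.35, list(NT = 10, CN = 2, TN = 2))
    w <- add_class(w, "C>T", 0.30)
    w <- add_class(w, "T>C", 0.12, list(NT = 4))
    w <- add_class(w, "T>G", 0.10, list(NT = 4))
    w <- add_class(w, "C>A", 0.08)
    w <- add_class(w, "C>G", 0.05)
    ins <- data.frame(pre2 = "NN", base = c("T", "C"), fol2 = "NN",
                      weight = c(0.6, 0.4), stringsAsFactors = FALSE)
    del <- data.frame(pre = "N", base = c("T", "C"), fol = "N",
                      weight = c(0.6, 0.4), stringsAsFactors = FALSE)
    dnv <- empty_dnv_model()
    dnv_fraction <- 0; del2 <- 0
  }
  list(spectrum_weights = spectrum96(w / sum(w), type = "rates"),
       ins_model = ins, del_model = del, dnv_model = dnv,
       dnv_fraction = dnv_fraction, del_len2_fraction = del2)
}

empty_dnv_model <- function() {
  data.frame(ref = character(), alt = character(), weight = numeric(),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Full parameterisation of the synthetic cohort generator. Per-clone mutation
#' counts are the exact numbers implanted (the mean-count Poisson draw can be
#' enabled with `poisson_counts = TRUE`).
#'
#' @param genome_length total genome length in bp.
#' @param chrom_count number of chromosomes (equal split).
#' @param base_composition probabilities of A,C,G,T (default uniform).
#' @param triplet_target optional 32-key triplet frequency table; when given,
#'   the reference is generated from a second-order Markov chain matching it.
#' @param n_clones number of isogenic clones.
#' @param germline_het_count shared heterozygous germline SNVs.
#' @param n_snv,n_ins,n_del per-clone unique mutation counts (means when
#'   `poisson_counts`).
#' @param preset a [treatment_preset()] name or list; supplies
#'   `spectrum_weights`, indel context models, `dnv_fraction` and
#'   `del_len2_fraction` unless overridden.
#' @param spectrum_weights optional 96-channel probability vector overriding
#'   the preset.
#' @param dnv_fraction fraction of SNV draws emitted as adjacent dinucleotide
#'   events (NULL = preset value).
#' @param coverage_mean mean sequencing depth (Poisson). The study's clones
#'   have no stated depth; 20 is the package default.
#' @param base_error_rate per-read per-base substitution error rate
#'   (in [0, 0.05]).
#' @param poisson_counts draw actual per-clone counts from Poisson(mean).
#' @param seed RNG seed for every stochastic step.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6, chrom_count = 1,
                       base_composition = c(A = .25, C = .25, G = .25,
                                            T = .25),
                       triplet_target = NULL,
                       n_clones = 3, germline_het_count = 100,
                       n_snv = 100, n_ins = 5, n_del = 5,
                       preset = "mock", spectrum_weights = NULL,
                       dnv_fraction = NULL,
                       coverage_mean = 20, base_error_rate = 0.003,
                       poisson_counts = FALSE, seed = 1) {
  if (genome_length < 10) stop("genome_length too small")
  if (coverage_mean <= 0) stop("coverage_mean must be positive")
  if (base_error_rate < 0 || base_error_rate > 0.05) {
    stop("base_error_rate must be in [0, 0.05]")
  }
  if (n_clones < 1) stop("need at least one clone")
  if (is.character(preset)) preset <- treatment_preset(preset)
  if (is.null(spectrum_weights)) spectrum_weights <- preset$spectrum_weights
  if (abs(sum(spectrum_weights) - 1) > 1e-6) {
    stop("spectrum_weights must sum to 1")
  }
  if (is.null(dnv_fraction)) dnv_fraction <- preset$dnv_fraction
  if (dnv_fraction < 0 || dnv_fraction > 1) stop("dnv_fraction in [0,1]")
  structure(list(
    genome_length = genome_length, chrom_count = chrom_count,
    base_composition = base_composition, triplet_target = triplet_target,
    n_clones = n_clones, germline_het_count = germline_het_count,
    n_snv = n_snv, n_ins = n_ins, n_del = n_del,
    spectrum_weights = spectrum_weights,
    ins_model = preset$ins_model, del_model = preset$del_model,
    dnv_model = preset$dnv_model, dnv_fraction = dnv_fraction,
    del_len2_fraction = preset$del_len2_fraction,
    coverage_mean = coverage_mean, base_error_rate = base_error_rate,
    poisson_counts = poisson_counts, seed = seed
  ), class = "sim_config")
}

#' Generate a random reference genome
#'
#' IID bases at the requested composition, or a second-order Markov chain
#' calibrated (iterative proportional fitting) towards a target triplet
#' frequency table — matched as closely as shift-consistency of the target
#' allows. Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return named character vector of chromosome sequences (chr1, chr2, ...).
#' @export
generate_reference <- function(config) {
  set.seed(config$seed)
  L <- floor(config$genome_length / config$chrom_count)
  if (L < 3) stop("chromosomes shorter than 3 bp are not supported")
  out <- character(config$chrom_count)
  for (c in seq_len(config$chrom_count)) {
    if (is.null(config$triplet_target)) {
      p <- config$base_composition
      if (any(p < 0) || sum(p) <= 0) stop("invalid base composition")
      out[c] <- paste(sample(BASES, L, replace = TRUE, prob = p),
                      collapse = "")
    } else {
      out[c] <- markov_sequence(L, config$triplet_target)
    }
  }
  setNames(out, paste0("chr", seq_len(config$chrom_count)))
}

## order-2 Markov chain whose stationary triplet usage matches a folded
## 32-key triplet table (unfolded symmetrically onto 64 triplets). The naive
## conditional chain P(b3|b1b2) proportional to f(b1b2b3) does not reproduce
## f because its stationary dinucleotide law differs from f's marginal, so
## the weights are calibrated by iterative proportional fitting against the
## chain's stationary triplet distribution.
markov_sequence <- function(L, folded) {
  if (any(folded <= 0)) stop("triplet target must be strictly positive")
  trips <- as.vector(outer(as.vector(outer(BASES, BASES, paste0)), BASES,
                           paste0))
  f <- setNames(numeric(64), trips)
  for (t in trips) {
    key <- if (substr(t, 2, 2) %in% PYRIMIDINES) t else revcomp(t)
    f[t] <- folded[[key]] / 2
  }
  f <- f / sum(f)
  pairs <- as.vector(outer(BASES, BASES, paste0))
  t_pre <- match(substr(trips, 1, 2), pairs)    # state b1b2
  t_suc <- match(substr(trips, 2, 3), pairs)    # state b2b3
  t_nb <- match(substr(trips, 3, 3), BASES)
  make_trans <- function(g) {
    tr <- matrix(0, 16, 4, dimnames = list(pairs, BASES))
    tr[cbind(t_pre, t_nb)] <- g
    rs <- rowSums(tr)
    if (any(rs == 0)) {
      stop("triplet target not normalisable into a Markov chain")
    }
    tr / rs
  }
  stationary_triplets <- function(tr) {
    ## stationary law of the 16-state dinucleotide chain by power iteration
    M <- matrix(0, 16, 16)
    M[cbind(t_pre, t_suc)] <- tr[cbind(t_pre, t_nb)]
    pi <- rep(1 / 16, 16)
    for (it in 1:200) {
      nx <- as.vector(pi %*% M)
      if (max(abs(nx - pi)) < 1e-12) { pi <- nx; break }
      pi <- nx
    }
    pi[t_pre] * tr[cbind(t_pre, t_nb)]
  }
  g <- f
  for (it in 1:60) {
    trans <- make_trans(g)
    fhat <- stationary_triplets(trans)
    if (max(abs(fhat - f)) < 1e-9) break
    g <- g * (f / pmax(fhat, 1e-12))
    g <- g / sum(g)
  }
  trans <- make_trans(g)
  cum <- t(apply(trans, 1, cumsum))
  ## start from the stationary dinucleotide distribution
  fhat <- stationary_triplets(trans)
  pw <- vapply(seq_len(16), function(s) sum(fhat[t_pre == s]), numeric(1))
  pw <- pw / sum(pw)
  s <- character(L)
  start <- sample(pairs, 1, prob = pw)
  s[1] <- substr(start, 1, 1); s[2] <- substr(start, 2, 2)
  u <- runif(L)
  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  prev2 <- base_idx[[s[1]]]; prev1 <- base_idx[[s[2]]]
  for (i in 3:L) {
    ## pairs order puts the first base fastest: index("b1b2") = (b2-1)*4 + b1
    state <- (prev1 - 1L) * 4L + prev2
    nb <- findInterval(u[i], cum[state, ]) + 1L
    if (nb > 4L) nb <- 4L
    s[i] <- BASES[nb]
    prev2 <- prev1; prev1 <- nb
  }
  paste(s, collapse = "")
}

#' Implant germline and per-clone unique mutations
#'
#' SNVs are drawn channel-by-channel from the configured 96-channel weights
#' and placed uniformly among genome sites carrying the required triplet
#' context (either strand; purine-strand placements implant the complementary
#' substitution). Insertions and deletions are placed at sites matching the
#' sampled indel context class. A configurable fraction of SNV draws is
#' emitted as adjacent dinucleotide substitutions. Implanted positions are
#' unique across clones (with a small exclusion buffer so contexts stay
#' intact) and disjoint from germline sites.
#'
#' @param reference named character vector (from [generate_reference()]).
#' @param config a [sim_config()].
#' @return list of class `truth_set`: `clone` (mutation table of all unique
#'   events across clones, sample_id = clone id), `germline` (mutation table,
#'   sample_id = "germline").
#' @export
implant_mutations <- function(reference, config) {
  reference <- as_reference(reference)
  set.seed(config$seed + 1L)
  used <- new.env(hash = TRUE)
  reserve <- function(chrom, from, to) {
    for (p in from:to) assign(paste0(chrom, ":", p), TRUE, envir = used)
  }
  free <- function(chrom, from, to) {
    !any(vapply(from:to, function(p)
      exists(paste0(chrom, ":", p), envir = used), logical(1)))
  }

  clone_ids <- paste0("clone", seq_len(config$n_clones))
  samples_n <- function(mean_n) {
    if (config$poisson_counts) rpois(1, mean_n) else round(mean_n)
  }

  ## --- germline heterozygous SNVs (uniform random positions/alleles)
  germ <- list()
  g_needed <- config$germline_het_count
  chrom_names <- names(reference)
  chrom_len <- nchar(reference)
  while (g_needed > 0) {
    chrom <- sample(chrom_names, 1, prob = chrom_len / sum(chrom_len))
    pos <- sample(chrom_len[[chrom]] - 2L, 1) + 1L
    refb <- substr(reference[[chrom]], pos, pos)
    if (!refb %in% BASES || !free(chrom, pos - 2L, pos + 2L)) next
    altb <- sample(setdiff(BASES, refb), 1)
    reserve(chrom, pos - 2L, pos + 2L)
    germ[[length(germ) + 1L]] <- data.frame(
      sample_id = "germline", chrom = chrom, pos = pos, ref_allele = refb,
      alt_allele = altb, mut_class = "SNV", stringsAsFactors = FALSE)
    g_needed <- g_needed - 1L
  }
  germline <- if (length(germ)) do.call(rbind, germ) else empty_mutations()

  ## --- triplet site index (lazy, per required context)
  site_cache <- new.env(hash = TRUE)
  context_sites <- function(trip) {
    if (!exists(trip, envir = site_cache)) {
      fwd <- locate_all(reference, trip)
      rev <- locate_all(reference, revcomp(trip))
      fwd$strand <- rep("+", nrow(fwd))
      rev$strand <- rep("-", nrow(rev))
      assign(trip, rbind(fwd, rev), envir = site_cache)
    }
    get(trip, envir = site_cache)
  }

  lab <- channel_labels()
  ctx_trip <- channel_context_triplet()
  res <- list()

  for (clone in clone_ids) {
    ## SNVs (a fraction emitted as DNVs)
    n_events <- samples_n(config$n_snv)
    n_dnv <- if (config$dnv_fraction > 0)
      rbinom(1, n_events, config$dnv_fraction) else 0L
    n_snv <- n_events - n_dnv
    if (n_snv > 0) {
      ch <- sample(96L, n_snv, replace = TRUE,
                   prob = as.numeric(config$spectrum_weights))
      for (k in seq_len(n_snv)) {
        trip <- ctx_trip[ch[k]]
        sites <- context_sites(trip)
        if (nrow(sites) == 0L) {
          stop("no eligible site for spectrum channel ", lab[ch[k]])
        }
        placed <- FALSE
        for (try in seq_len(200L)) {
          j <- sample(nrow(sites), 1)
          chrom <- sites$chrom[j]; centre <- sites$pos[j] + 1L
          if (!free(chrom, centre - 2L, centre + 2L)) next
          l <- lab[ch[k]]
          refb <- substr(l, 3, 3); altb <- substr(l, 5, 5)
          if (sites$strand[j] == "-") {
            refb <- complement_base(refb); altb <- complement_base(altb)
          }
          reserve(chrom, centre - 2L, centre + 2L)
          res[[length(res) + 1L]] <- data.frame(
            sample_id = clone, chrom = chrom, pos = centre,
            ref_allele = refb, alt_allele = altb, mut_class = "SNV",
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed) stop("could not place SNV for channel ", lab[ch[k]],
                          " (genome saturated)")
      }
    }
    ## DNVs
    if (n_dnv > 0) {
      model <- config$dnv_model
      if (nrow(model) == 0L) stop("dnv_fraction > 0 with empty DNV model")
      rows <- sample(nrow(model), n_dnv, replace = TRUE,
                     prob = model$weight)
      for (k in rows) {
        placed <- place_patterned(reference, model$ref[k], model$alt[k],
                                  "DNV", used, reserve, free)
        if (is.null(placed)) stop("no eligible site for DNV ", model$ref[k],
                                  ">", model$alt[k])
        placed$sample_id <- clone
        res[[length(res) + 1L]] <- placed
      }
    }
    ## insertions
    n_ins <- samples_n(config$n_ins)
    if (n_ins > 0) {
      model <- config$ins_model
      rows <- sample(nrow(model), n_ins, replace = TRUE, prob = model$weight)
      for (k in rows) {
        placed <- place_insertion(reference, model$pre2[k], model$base[k],
                                  model$fol2[k], used, reserve, free)
        if (is.null(placed)) stop("no eligible insertion site for context ",
                                  model$pre2[k], "^", model$base[k],
                                  model$fol2[k])
        placed$sample_id <- clone
        res[[length(res) + 1L]] <- placed
      }
    }
    ## deletions
    n_del <- samples_n(config$n_del)
    if (n_del > 0) {
      n_del2 <- rbinom(1, n_del, config$del_len2_fraction)
      n_del1 <- n_del - n_del2
      model <- config$del_model
      if (n_del1 > 0) {
        rows <- sample(nrow(model), n_del1, replace = TRUE,
                       prob = model$weight)
        for (k in rows) {
          placed <- place_deletion1(reference, model$pre[k], model$base[k],
                                    model$fol[k], used, reserve, free)
          if (is.null(placed)) stop("no eligible deletion site for context ",
                                    model$pre[k], model$base[k], model$fol[k])
          placed$sample_id <- clone
          res[[length(res) + 1L]] <- placed
        }
      }
      if (n_del2 > 0) {
        ## two-base deletions: mostly at AG/GG (either strand), per the
        ## crosslink-motif observation
        for (k in seq_len(n_del2)) {
          motif <- if (runif(1) < 0.68) sample(c("AG", "GG"), 1)
                   else sample(c("AT", "TA", "CA", "AC", "TT"), 1)
          placed <- place_deletion2(reference, motif, used, reserve, free)
          if (is.null(placed)) stop("no eligible 2-bp deletion site: ", motif)
          placed$sample_id <- clone
          res[[length(res) + 1L]] <- placed
        }
      }
    }
  }
  clone_muts <- if (length(res)) do.call(rbind, res) else empty_mutations()
  rownames(clone_muts) <- NULL
  structure(list(clone = clone_muts, germline = germline),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("truth set: %d unique mutations across %d clones, %d germline hets\n",
              nrow(x$clone), length(unique(x$clone$sample_id)),
              nrow(x$germline)))
  invisible(x)
}

## all (chrom, start) occurrences of a fixed pattern (no wildcards)
locate_all <- function(reference, pattern) {
  out <- list()
  for (chrom in names(reference)) {
    m <- gregexpr(pattern, reference[[chrom]], fixed = TRUE)[[1]]
    if (m[1] != -1L) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, pos = as.integer(m), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), pos = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

## all occurrences of a regex pattern ("N" wildcards expanded)
locate_regex <- function(reference, pattern) {
  rx <- gsub("N", "[ACGT]", pattern, fixed = TRUE)
  out <- list()
  for (chrom in names(reference)) {
    m <- gregexpr(rx, reference[[chrom]])[[1]]
    if (m[1] != -1L) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, pos = as.integer(m), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), pos = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

sample_free_site <- function(sites, width, used, free, max_try = 200L) {
  if (nrow(sites) == 0L) return(NULL)
  for (try in seq_len(max_try)) {
    j <- sample(nrow(sites), 1)
    if (free(sites$chrom[j], sites$pos[j] - 2L, sites$pos[j] + width + 1L)) {
      return(sites[j, , drop = FALSE])
    }
  }
  NULL
}

place_patterned <- function(reference, ref2, alt2, class, used, reserve,
                            free) {
  strand <- sample(c("+", "-"), 1)
  pat <- if (strand == "+") ref2 else revcomp(ref2)
  sites <- locate_all(reference, pat)
  hit <- sample_free_site(sites, nchar(pat), used, free)
  if (is.null(hit)) return(NULL)
  reserve(hit$chrom, hit$pos - 2L, hit$pos + nchar(pat) + 1L)
  ref_out <- if (strand == "+") ref2 else revcomp(ref2)
  alt_out <- if (strand == "+") alt2 else revcomp(alt2)
  data.frame(sample_id = NA_character_, chrom = hit$chrom, pos = hit$pos,
             ref_allele = ref_out, alt_allele = alt_out, mut_class = class,
             stringsAsFactors = FALSE)
}

place_insertion <- function(reference, pre2, base, fol2, used, reserve,
                            free) {
  strand <- sample(c("+", "-"), 1)
  if (strand == "+") {
    pat <- paste0(pre2, fol2)
    sites <- locate_regex(reference, pat)
    hit <- sample_free_site(sites, 4L, used, free)
    if (is.null(hit)) return(NULL)
    anchor <- hit$pos + 1L       # insertion after the second preceding base
    insbase <- base
  } else {
    pat <- paste0(revcomp(fol2), revcomp(pre2))
    sites <- locate_regex(reference, pat)
    hit <- sample_free_site(sites, 4L, used, free)
    if (is.null(hit)) return(NULL)
    anchor <- hit$pos + 1L
    insbase <- complement_base(base)
  }
  reserve(hit$chrom, hit$pos - 2L, hit$pos + 5L)
  data.frame(sample_id = NA_character_, chrom = hit$chrom, pos = anchor,
             ref_allele = "", alt_allele = insbase, mut_class = "INS",
             stringsAsFactors = FALSE)
}

place_deletion1 <- function(reference, pre, base, fol, used, reserve, free) {
  strand <- sample(c("+", "-"), 1)
  pat <- paste0(pre, base, fol)
  if (strand == "-") pat <- revcomp(pat)   # revcomp preserves N
  sites <- locate_regex(reference, pat)
  hit <- sample_free_site(sites, 3L, used, free)
  if (is.null(hit)) return(NULL)
  delpos <- hit$pos + 1L
  reserve(hit$chrom, hit$pos - 2L, hit$pos + 4L)
  data.frame(sample_id = NA_character_, chrom = hit$chrom, pos = delpos,
             ref_allele = substr(reference[[hit$chrom]], delpos, delpos),
             alt_allele = "", mut_class = "DEL", stringsAsFactors = FALSE)
}

place_deletion2 <- function(reference, motif, used, reserve, free) {
  strand <- sample(c("+", "-"), 1)
  pat <- if (strand == "+") motif else revcomp(motif)
  sites <- locate_all(reference, pat)
  hit <- sample_free_site(sites, 2L, used, free)
  if (is.null(hit)) return(NULL)
  reserve(hit$chrom, hit$pos - 2L, hit$pos + 3L)
  data.frame(sample_id = NA_character_, chrom = hit$chrom, pos = hit$pos,
             ref_allele = substr(reference[[hit$chrom]], hit$pos,
                                 hit$pos + 1L),
             alt_allele = "", mut_class = "DEL", stringsAsFactors = FALSE)
}

#' Simulate a multi-sample pileup from a truth set
#'
#' Per position and sample, coverage is Poisson(`coverage_mean`). At a
#' heterozygous variant site of that sample (or at a germline site, in every
#' sample) alternate-supporting reads are Binomial(coverage, 0.5); elsewhere
#' non-reference reads arise at `base_error_rate`, spread uniformly over the
#' three other bases. Indel support is recorded at the anchor column.
#' Deterministic under the config seed.
#'
#' @param reference named character vector.
#' @param truth a `truth_set` from [implant_mutations()].
#' @param config a [sim_config()].
#' @return a [pileup()] over every genome position.
#' @export
simulate_pileup <- function(reference, truth, config) {
  reference <- as_reference(reference)
  set.seed(config$seed + 2L)
  clone_ids <- paste0("clone", seq_len(config$n_clones))
  chroms <- names(reference)
  lens <- nchar(reference)
  n <- sum(lens)
  chrom_v <- rep(chroms, lens)
  pos_v <- unlist(lapply(lens, seq_len), use.names = FALSE)
  ref_v <- unlist(strsplit(paste(reference, collapse = ""), ""),
                  use.names = FALSE)
  offset <- setNames(cumsum(c(0, lens[-length(lens)])), chroms)
  gidx <- function(chrom, pos) offset[chrom] + pos

  S <- length(clone_ids)
  cov <- matrix(rpois(n * S, config$coverage_mean), n, S)
  counts <- setNames(lapply(BASES, function(b) matrix(0L, n, S)), BASES)
  ## sequencing errors
  err <- matrix(rbinom(n * S, cov, config$base_error_rate), n, S)
  nonref <- list()
  e1 <- matrix(rbinom(n * S, err, 1 / 3), n, S)
  e2 <- matrix(rbinom(n * S, err - e1, 1 / 2), n, S)
  e3 <- err - e1 - e2
  errs <- list(e1, e2, e3)
  for (b in BASES) {
    i <- ref_v == b
    counts[[b]][i, ] <- cov[i, , drop = FALSE] - err[i, , drop = FALSE]
    others <- setdiff(BASES, b)
    for (o in seq_along(others)) {
      counts[[others[o]]][i, ] <- errs[[o]][i, , drop = FALSE]
    }
  }

  ## expand the truth into flat per-sample event lists
  all_muts <- rbind(truth$germline, truth$clone)
  snv_row <- integer(0); snv_s <- integer(0)
  snv_ref <- character(0); snv_alt <- character(0)
  ind_row <- integer(0); ind_s <- integer(0)
  ind_type <- character(0); ind_allele <- character(0)
  for (k in seq_len(nrow(all_muts))) {
    m <- all_muts[k, ]
    carriers <- if (m$sample_id == "germline") seq_len(S)
                else match(m$sample_id, clone_ids)
    if (anyNA(carriers)) stop("truth clone id not in cohort: ", m$sample_id)
    row <- unname(gidx(m$chrom, m$pos))
    if (m$mut_class == "SNV") {
      snv_row <- c(snv_row, rep(row, length(carriers)))
      snv_s <- c(snv_s, carriers)
      snv_ref <- c(snv_ref, rep(m$ref_allele, length(carriers)))
      snv_alt <- c(snv_alt, rep(m$alt_allele, length(carriers)))
    } else if (m$mut_class == "DNV") {
      for (off in 0:1) {
        snv_row <- c(snv_row, rep(row + off, length(carriers)))
        snv_s <- c(snv_s, carriers)
        snv_ref <- c(snv_ref, rep(substr(m$ref_allele, off + 1, off + 1),
                                  length(carriers)))
        snv_alt <- c(snv_alt, rep(substr(m$alt_allele, off + 1, off + 1),
                                  length(carriers)))
      }
    } else if (m$mut_class == "INS") {
      ind_row <- c(ind_row, rep(row, length(carriers)))
      ind_s <- c(ind_s, carriers)
      ind_type <- c(ind_type, rep("ins", length(carriers)))
      ind_allele <- c(ind_allele, rep(m$alt_allele, length(carriers)))
    } else if (row > 1L) {
      ind_row <- c(ind_row, rep(row - 1L, length(carriers)))
      ind_s <- c(ind_s, carriers)
      ind_type <- c(ind_type, rep("del", length(carriers)))
      ind_allele <- c(ind_allele, rep(as.character(nchar(m$ref_allele)),
                                      length(carriers)))
    }
  }
  ## heterozygous SNV sites: alt reads ~ Binomial(cov, 0.5), rest reference
  if (length(snv_row)) {
    idx <- cbind(snv_row, snv_s)
    cv <- cov[idx]
    alt_n <- rbinom(length(cv), cv, 0.5)
    for (b in BASES) counts[[b]][idx] <- 0L
    for (b in BASES) {
      i <- snv_ref == b
      if (any(i)) counts[[b]][idx[i, , drop = FALSE]] <- cv[i] - alt_n[i]
    }
    for (b in BASES) {
      i <- snv_alt == b
      if (any(i)) {
        counts[[b]][idx[i, , drop = FALSE]] <-
          counts[[b]][idx[i, , drop = FALSE]] + alt_n[i]
      }
    }
  }
  ## indel support at the anchor column
  indels <- empty_indel_evidence()
  if (length(ind_row)) {
    cv <- cov[cbind(ind_row, ind_s)]
    cnt <- rbinom(length(cv), cv, 0.5)
    keep <- cnt > 0
    indels <- data.frame(row = ind_row[keep], sample = ind_s[keep],
                         type = ind_type[keep], allele = ind_allele[keep],
                         count = cnt[keep], stringsAsFactors = FALSE)
  }
  pileup(chrom_v, pos_v, ref_v, clone_ids, cov, counts, indels)
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper: reference, truth set, pileup.
#'
#' @param config a [sim_config()].
#' @return list with `reference`, `truth`, `pileup`, `config`.
#' @export
simulate_cohort <- function(config) {
  reference <- generate_reference(config)
  truth <- implant_mutations(reference, config)
  pu <- simulate_pileup(reference, truth, config)
  list(reference = reference, truth = truth, pileup = pu, config = config)
}
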