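test_that("SNV classification folds purine references onto pyrimidines", {
  reference <- c(chr1 = "AACATGATT")
  ## bases: A A C A T G A T T; pos 3 = C flanked by A/A, pos 6 = G in TGA
  snv <- mutations(c("x", "x"), "chr1", c(3, 6), c("C", "G"), c("T", "T"),
                   "SNV")
  idx <- classify_snv(reference, snv)
  expect_equal(channel_labels()[idx[1]], "A[C>T]A")
  ## pos 6: G in context TGA; folded -> T[C>A]A
  expect_equal(channel_labels()[idx[2]], "T[C>A]A")
})

test_that("chromosome-end and N-context SNVs are unassignable", {
  reference <- c(chr1 = "CAGNT")
  snv <- mutations(c("x", "x"), "chr1", c(1, 3), c("C", "G"), c("A", "A"),
                   "SNV")
  idx <- classify_snv(reference, snv)
  expect_true(is.na(idx[1]))   # no 5' flank
  expect_true(is.na(idx[2]))   # N in 3' flank
  cs <- count_spectrum(snv, reference)
  expect_equal(cs$n_unassignable, 2L)
  expect_equal(sum(cs$spectrum96), 0)
})

test_that("count_spectrum matches a brute-force tally on random inputs", {
  set.seed(14)
  seq <- paste(sample(BASES4, 5000, replace = TRUE), collapse = "")
  reference <- c(chr1 = seq)
  pos <- sample(2:4999, 300)
  ref <- substring(seq, pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(BASES4, b), 1), character(1))
  snvs <- mutations("x", "chr1", pos, ref, alt, "SNV")
  got <- count_spectrum(snvs, reference)$spectrum96
  want <- tabulate(vapply(seq_along(pos), function(k)
    oracle_classify(seq, pos[k], ref[k], alt[k]), integer(1)), 96)
  expect_equal(as.numeric(got), as.numeric(want))
  expect_equal(sum(got), 300)
  ## one SNV -> one-hot; empty -> all zero
  one <- count_spectrum(snvs[1, ], reference)$spectrum96
  expect_equal(sum(one), 1)
  expect_equal(sum(count_spectrum(snvs[0, ], reference)$spectrum96), 0)
})

test_that("triplet occurrences fold strands and skip N windows", {
  expect_equal(triplet_occurrences(c(chr1 = "ACGT"))[["ACG"]], 2)
  occ <- triplet_occurrences(c(chr1 = "ACGT"))
  expect_equal(sum(occ), 2)  # ACG + CGT (folds to ACG)

  ## a poly-A genome is poly-T on the folded strand: all triplets land on TTT
  polyA <- triplet_occurrences(c(chr1 = paste(rep("A", 50), collapse = "")))
  expect_equal(polyA[["TTT"]], 48)
  expect_equal(sum(polyA), 48)
  ## a genome with no countable triplet is degenerate
  expect_error(triplet_occurrences(c(chr1 = "NNNNN")), "degenerate")
  expect_error(triplet_occurrences(c(chr1 = "")), "empty")

  ## windows containing N are skipped: only the two ACG/CGT pairs count
  withN <- triplet_occurrences(c(chr1 = "ACGTNACGT"))
  expect_equal(withN[["ACG"]], 4)
  expect_equal(sum(withN), 4)
})

test_that("uniform sequence yields near-uniform folded triplet frequencies", {
  cfg <- sim_config(genome_length = 3e5, seed = 10)
  ref <- generate_reference(cfg)
  occ <- triplet_occurrences(ref)
  frac <- occ / sum(occ)
  ## each key pools 2 of 64 triplets: expectation 1/32, multinomial SE tiny
  expect_true(all(abs(frac - 1 / 32) < 0.002))
})

test_that("rate normalisation divides counts by context occurrences", {
  counts <- setNames(numeric(96), channel_labels())
  counts[["A[C>T]G"]] <- 10
  occ <- setNames(rep(500, 32), pyrimidine_triplets())
  occ[["ACG"]] <- 1000
  rates <- normalize_rates(spectrum96(counts), occ)
  expect_equal(rates[["A[C>T]G"]], 0.01)
  ## conservation: sum(rates x occurrences) = sum(counts)
  trip <- paste0(substr(channel_labels(), 1, 1),
                 substr(channel_labels(), 3, 3),
                 substr(channel_labels(), 7, 7))
  expect_equal(sum(as.numeric(rates) * occ[trip]), sum(counts))
  ## all-zero counts -> all-zero rates
  expect_equal(sum(normalize_rates(spectrum96(numeric(96)), occ)), 0)
  ## zero occurrence with non-zero count -> error
  occ0 <- occ; occ0[["ACG"]] <- 0
  expect_error(normalize_rates(spectrum96(counts), occ0), "zero")
})

test_that("fold enrichment is mean-over-subset vs mean-over-all", {
  r <- rep(1, 96)
  r[1] <- 2
  r[2:96] <- (96 - 2) / 95        # constructed so the overall mean is 1
  sp <- spectrum96(r, "rates")
  expect_equal(fold_enrichment(sp, 1L), 2)
  expect_equal(fold_enrichment(sp, seq_len(96)), 1)
  z <- spectrum96(c(0, rep(1, 95)), "rates")
  expect_equal(fold_enrichment(z, 1L), 0)
  expect_error(fold_enrichment(spectrum96(numeric(96), "rates"), 1L),
               "zero overall")
})

test_that("species adjustment is identity for flat tables and linear", {
  set.seed(3)
  v <- runif(96); v <- v / sum(v)
  sp <- spectrum96(v, "rates")
  flat <- setNames(rep(1000, 32), pyrimidine_triplets())
  expect_equal(as.numeric(adjust_to_species(sp, flat, flat)), v,
               tolerance = 1e-12)
  ## doubling one triplet's target frequency doubles that channel's
  ## pre-normalisation weight
  tgt <- flat; tgt[["ACA"]] <- 2000
  adj <- adjust_to_species(sp, flat, tgt)
  pre <- v * ifelse(paste0(substr(channel_labels(), 1, 1),
                           substr(channel_labels(), 3, 3),
                           substr(channel_labels(), 7, 7)) == "ACA",
                    (2000 / sum(tgt)) / (1000 / sum(flat)),
                    (1000 / sum(tgt)) / (1000 / sum(flat)))
  expect_equal(as.numeric(adj), pre / sum(pre), tolerance = 1e-12)
  ## one-hot stays one-hot
  oh <- spectrum96(c(1, numeric(95)), "rates")
  expect_equal(as.numeric(adjust_to_species(oh, flat, tgt)),
               c(1, numeric(95)))
  expect_error(adjust_to_species(sp, flat[-1], flat), "missing")
})

test_that("signature comparison reproduces analytic Pearson/cosine values", {
  v <- as.numeric(treatment_preset("mock")$spectrum_weights)
  sig <- cbind(self = v, orth = c(numeric(95), 1))
  sp <- spectrum96(v, "rates")
  res <- compare_signatures(sp, sig)
  expect_equal(res$pearson[1], 1)
  expect_equal(res$cosine[1], 1)
  ## one-hot vs disjoint one-hot: cosine 0
  oh <- spectrum96(c(1, numeric(95)), "rates")
  expect_equal(compare_signatures(oh, sig)$cosine[2], 0)
  ## anti-monotone repeating patterns: Pearson exactly -1
  x <- rep(c(.4, .3, .2, .1), 24)
  y <- rep(c(.1, .2, .3, .4), 24)
  res2 <- compare_signatures(spectrum96(x / sum(x), "rates"),
                             cbind(anti = y / sum(y)))
  expect_equal(res2$pearson, -1)
  ## zero-variance signature: Pearson undefined with a warning
  expect_warning(
    res3 <- compare_signatures(sp, cbind(flat = rep(1 / 96, 96))),
    "zero-variance")
  expect_true(is.na(res3$pearson))
})

test_that("mutation rate and per-Mb density compute exact quotients", {
  r <- mutation_rate(47, 2.06e9, 100)
  expect_equal(r$per_base_per_division, 47 / 2.06e11)
  expect_equal(signif(r$per_base_per_division, 2), 2.3e-10)
  expect_equal(mutation_rate(0, 1e9, 10)$per_base_per_division, 0)
  expect_equal(mutation_rate(100, 1e9, 10)$per_base_per_division, 1e-8)
  expect_error(mutation_rate(10, 1e9, 0), "generations")

  expect_equal(round(per_mb_density(812, 1.03e9), 1), 0.8)
  expect_equal(per_mb_density(0, 1e9), 0)
  expect_equal(per_mb_density(1000, 1e9), 1)
})

test_that("group tests run one-way ANOVA and Student t-tests vs mock", {
  ## identical groups: F = 0, p = 1
  g <- list(mock = c(40, 50, 60), a = c(40, 50, 60), b = c(40, 50, 60))
  res <- group_tests(g)
  expect_equal(res$anova_F, 0)
  expect_equal(res$anova_p, 1)
  ## textbook two-sample t with pooled variance
  x <- c(47, 47, 47, 47) + c(-.1, .1, -.1, .1)
  y <- c(95, 95, 95) + c(-.1, 0, .1)
  res2 <- group_tests(list(mock = x, treated = y))
  sp2 <- ((3 * var(x) + 2 * var(y)) / 5)
  t_manual <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / 4 + 1 / 3))
  expect_equal(abs(res2$t_tests$t), abs(t_manual))
  expect_lt(res2$t_tests$p, 1e-6)
  expect_error(group_tests(list(mock = 1, a = c(1, 2))), "replicates")
  expect_error(group_tests(list(a = c(1, 2), b = c(2, 3))), "absent")
})

test_that("the cisplatin preset recovers 57% C>A through the full pipeline", {
  cfg <- sim_config(genome_length = 1.5e6, n_clones = 3, n_snv = 350,
                    n_ins = 0, n_del = 0, germline_het_count = 100,
                    preset = "cisplatin", dnv_fraction = 0, seed = 57)
  co <- simulate_cohort(cfg)
  calls <- call_unique_mutations(co$pileup, caller_params(), co$reference)
  sp <- count_spectrum(calls[calls$mut_class == "SNV", ], co$reference)
  frac_ca <- sp$six_class[["C>A"]] / sum(sp$six_class)
  n <- sum(sp$six_class)
  expect_lt(abs(frac_ca - 0.57), 3 * sqrt(0.57 * 0.43 / n))
})
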