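test_that("reference generation matches the requested base composition", {
  cfg <- sim_config(genome_length = 1e6, seed = 1)
  ref <- generate_reference(cfg)
  freq <- table(strsplit(ref[["chr1"]], "")[[1]]) / 1e6
  expect_true(all(abs(freq - 0.25) < 0.01))

  ## determinism
  expect_identical(generate_reference(cfg), ref)

  expect_error(sim_config(genome_length = 0), "too small")
})

test_that("markov generation approximates a skewed triplet target", {
  target <- setNames(rep(1, 32), pyrimidine_triplets())
  target[c("ACA", "TCT")] <- 8
  cfg <- sim_config(genome_length = 3e5, triplet_target = target, seed = 4)
  ref <- generate_reference(cfg)
  occ <- triplet_occurrences(ref)
  expect_identical(generate_reference(cfg), ref)
  ## the exact target is not shift-consistent, so the chain realises its
  ## closest feasible composition: the boosted keys must still be the two
  ## most frequent and well above the uniform 1/32 frequency
  frac <- occ / sum(occ)
  expect_setequal(names(sort(frac, decreasing = TRUE))[1:2],
                  c("ACA", "TCT"))
  expect_gt(frac[["ACA"]], 3 / 32)
  expect_gt(frac[["TCT"]], 3 / 32)
})

test_that("a degenerate one-hot spectrum places every SNV in its context", {
  w <- setNames(numeric(96), channel_labels())
  w[["A[C>T]G"]] <- 1
  cfg <- sim_config(genome_length = 2e5, n_clones = 2, n_snv = 80,
                    n_ins = 0, n_del = 0, germline_het_count = 0,
                    spectrum_weights = spectrum96(w, "rates"), seed = 2)
  ref <- generate_reference(cfg)
  truth <- implant_mutations(ref, cfg)
  ts <- truth$clone
  expect_equal(nrow(ts), 160L)
  ctx <- substring(ref[["chr1"]], ts$pos - 1L, ts$pos + 1L)
  fold <- ts$ref_allele == "G"
  ctx[fold] <- rc_str(ctx[fold])
  expect_true(all(ctx == "ACG"))
  ## and the implanted alleles match the genome
  gbase <- substring(ref[["chr1"]], ts$pos, ts$pos)
  expect_true(all(gbase == ts$ref_allele))
})

test_that("zero mutation counts give empty truth; positions stay disjoint", {
  cfg0 <- sim_config(n_snv = 0, n_ins = 0, n_del = 0,
                     germline_het_count = 0, genome_length = 5e4, seed = 3)
  ref <- generate_reference(cfg0)
  expect_equal(nrow(implant_mutations(ref, cfg0)$clone), 0L)

  cfg <- sim_config(genome_length = 2e5, n_clones = 4, n_snv = 60,
                    n_ins = 6, n_del = 6, germline_het_count = 200,
                    preset = "cisplatin", seed = 8)
  ref <- generate_reference(cfg)
  truth <- implant_mutations(ref, cfg)
  key <- paste(truth$clone$chrom, truth$clone$pos)
  expect_true(all(table(key) == 1))
  expect_length(intersect(key, paste(truth$germline$chrom,
                                     truth$germline$pos)), 0)
})

test_that("heterozygous sites show a mean alternate fraction near 0.5", {
  cfg <- sim_config(genome_length = 1e5, n_clones = 2, n_snv = 150,
                    n_ins = 0, n_del = 0, germline_het_count = 0,
                    coverage_mean = 30, base_error_rate = 0, seed = 6)
  co <- simulate_cohort(cfg)
  ts <- co$truth$clone[co$truth$clone$mut_class == "SNV", ]
  af <- numeric(nrow(ts))
  for (k in seq_len(nrow(ts))) {
    r <- ts$pos[k]
    s <- match(ts$sample_id[k], co$pileup$samples)
    af[k] <- co$pileup$counts[[ts$alt_allele[k]]][r, s] / co$pileup$cov[r, s]
  }
  ## mean of ~300 Binomial(30, .5) fractions: SE ~ 0.0053
  expect_lt(abs(mean(af) - 0.5), 3 * 0.5 / sqrt(30 * nrow(ts)) * 2)
})

test_that("with zero error and no variants, every column is pure reference", {
  cfg <- sim_config(genome_length = 2e4, n_clones = 2, n_snv = 0,
                    n_ins = 0, n_del = 0, germline_het_count = 0,
                    base_error_rate = 0, seed = 7)
  co <- simulate_cohort(cfg)
  pu <- co$pileup
  for (b in BASES4) {
    i <- pu$ref == b
    expect_true(all(pu$counts[[b]][i, ] == pu$cov[i, ]))
    expect_true(all(pu$counts[[b]][!i, ] == 0L))
  }
  expect_equal(nrow(pu$indels), 0L)
})

test_that("germline variants carry alternate reads in every sample", {
  cfg <- sim_config(genome_length = 5e4, n_clones = 3, n_snv = 0,
                    n_ins = 0, n_del = 0, germline_het_count = 50,
                    coverage_mean = 30, seed = 12)
  co <- simulate_cohort(cfg)
  g <- co$truth$germline
  hit <- matrix(0L, nrow(g), 3)
  for (k in seq_len(nrow(g))) {
    hit[k, ] <- co$pileup$counts[[g$alt_allele[k]]][g$pos[k], ]
  }
  ## each sample draws Binomial(cov~30, .5) alt reads; zero only with
  ## probability 2^-30 per site
  expect_true(all(hit > 0))
})

test_that("the whole simulation is deterministic under a fixed seed", {
  cfg <- sim_config(genome_length = 3e4, n_clones = 3, n_snv = 20,
                    n_ins = 3, n_del = 3, germline_het_count = 20,
                    preset = "cisplatin", seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$reference, b$reference)
  expect_identical(a$truth, b$truth)
  expect_identical(a$pileup, b$pileup)
})

test_that("implanting fails loudly when a channel has no eligible site", {
  w <- setNames(numeric(96), channel_labels())
  w[["A[C>T]G"]] <- 1
  cfg <- sim_config(genome_length = 50, n_clones = 1, n_snv = 5,
                    n_ins = 0, n_del = 0, germline_het_count = 0,
                    spectrum_weights = spectrum96(w, "rates"), seed = 1)
  ref <- c(chr1 = paste(rep("A", 50), collapse = ""))
  expect_error(implant_mutations(ref, cfg), "A\\[C>T\\]G")
})

test_that("the 6-class spectrum of implanted SNVs tracks the preset weights", {
  cfg <- sim_config(genome_length = 1e6, n_clones = 2, n_snv = 500,
                    n_ins = 0, n_del = 0, germline_het_count = 0,
                    preset = "cisplatin", dnv_fraction = 0, seed = 31)
  ref <- generate_reference(cfg)
  truth <- implant_mutations(ref, cfg)
  sp <- count_spectrum(truth$clone, ref)
  frac <- sp$six_class / sum(sp$six_class)
  w6 <- six_class_marginal(treatment_preset("cisplatin")$spectrum_weights)
  n <- sum(sp$six_class)
  for (cl in names(w6)) {
    se <- sqrt(w6[[cl]] * (1 - w6[[cl]]) / n)
    expect_lt(abs(frac[[cl]] - w6[[cl]]), 3 * se + 1e-9)
  }
})
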