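params_default <- caller_params()

test_that("the three filters act as published on hand-built columns", {
  ref <- paste(rep("C", 10), collapse = "")
  ## sample1 cov 20 (C:10, A:10), samples 2-3 pure C -> call
  pu <- toy_pileup(ref, c("s1", "s2", "s3"), coverage = 20)
  pu <- set_counts(pu, 5, "s1", c(C = 10, A = 10))
  calls <- call_unique_mutations(pu, params_default)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$sample_id, "s1")
  expect_equal(calls$pos, 5L)
  expect_equal(calls$alt_allele, "A")
  expect_equal(calls$mut_af, 0.5)

  ## same, but sample2 has A:3/20 (ref AF 0.85 < 0.9) -> suppressed
  pu2 <- set_counts(pu, 5, "s2", c(C = 17, A = 3))
  expect_equal(nrow(call_unique_mutations(pu2, params_default)), 0L)

  ## coverage 9 < 10 in the mutated sample -> suppressed despite AF 0.56
  pu3 <- toy_pileup(ref, c("s1", "s2", "s3"), coverage = 20)
  pu3 <- set_counts(pu3, 5, "s1", c(C = 4, A = 5))
  expect_equal(nrow(call_unique_mutations(pu3, params_default)), 0L)

  ## all samples pure reference -> nothing
  pu4 <- toy_pileup(ref, c("s1", "s2", "s3"), coverage = 20)
  expect_equal(nrow(call_unique_mutations(pu4, params_default)), 0L)
})

test_that("zero coverage in another sample suppresses the call", {
  pu <- toy_pileup("CCCCC", c("s1", "s2", "s3"), coverage = 20)
  pu <- set_counts(pu, 3, "s1", c(C = 8, G = 12))
  pu <- set_counts(pu, 3, "s2", c(), cov = 0)
  expect_equal(nrow(call_unique_mutations(pu, params_default)), 0L)
})

test_that("a variant passing in two samples is not unique and not called", {
  pu <- toy_pileup("CCCCC", c("s1", "s2", "s3"), coverage = 20)
  pu <- set_counts(pu, 3, "s1", c(C = 10, A = 10))
  pu <- set_counts(pu, 3, "s2", c(C = 10, A = 10))
  expect_equal(nrow(call_unique_mutations(pu, params_default)), 0L)
})

test_that("caller matches a brute-force oracle on random small cohorts", {
  set.seed(11)
  for (rep in 1:6) {
    n <- 400
    S <- sample(2:5, 1)
    ref <- paste(sample(BASES4, n, replace = TRUE), collapse = "")
    samples <- paste0("s", seq_len(S))
    pu <- toy_pileup(ref, samples, coverage = 20)
    ## random perturbations: noise, het-like sites, low coverage columns
    for (k in 1:120) {
      pos <- sample(n, 1)
      s <- sample(samples, 1)
      refb <- substr(ref, pos, pos)
      cv <- sample(0:30, 1)
      alt <- sample(setdiff(BASES4, refb), 1)
      alt_n <- sample(0:cv, 1)
      cn <- setNames(list(cv - alt_n, alt_n), c(refb, alt))
      pu <- set_counts(pu, pos, s, cn)
    }
    ## sprinkle indel evidence
    reference <- setNames(ref, "chr1")
    for (k in 1:15) {
      pos <- sample(2:(n - 5), 1)
      s <- sample(S, 1)
      type <- sample(c("ins", "del"), 1)
      allele <- if (type == "ins") paste(sample(BASES4, 2, replace = TRUE),
                                         collapse = "") else "1"
      pu <- add_indel_evidence(pu, pos, pu$samples[s], type, allele,
                               sample(1:15, 1))
    }
    got <- call_unique_mutations(pu, params_default, reference)
    want <- oracle_caller(pu, params_default, reference)
    expect_setequal(mut_key(got), mut_key(want))
  }
})

test_that("no emitted position+allele appears in more than one sample", {
  set.seed(5)
  cfg <- sim_config(genome_length = 1e5, n_clones = 4,
                    germline_het_count = 50, n_snv = 40, n_ins = 4,
                    n_del = 4, preset = "cisplatin", seed = 5)
  co <- simulate_cohort(cfg)
  calls <- call_unique_mutations(co$pileup, params_default, co$reference)
  key <- paste(calls$chrom, calls$pos, calls$ref_allele, calls$alt_allele)
  expect_true(all(table(key) == 1))
})

test_that("germline heterozygous variants are never called", {
  cfg <- sim_config(genome_length = 1e5, n_clones = 3,
                    germline_het_count = 300, n_snv = 0, n_ins = 0,
                    n_del = 0, seed = 9)
  co <- simulate_cohort(cfg)
  calls <- call_unique_mutations(co$pileup, params_default, co$reference)
  germ <- paste(co$truth$germline$chrom, co$truth$germline$pos)
  expect_equal(sum(paste(calls$chrom, calls$pos) %in% germ), 0L)
})

test_that("raising any threshold never increases the number of calls", {
  cfg <- sim_config(genome_length = 5e4, n_clones = 3,
                    germline_het_count = 30, n_snv = 30, n_ins = 3,
                    n_del = 3, preset = "mock", seed = 3,
                    coverage_mean = 14, base_error_rate = 0.01)
  co <- simulate_cohort(cfg)
  base <- nrow(call_unique_mutations(co$pileup, caller_params(),
                                     co$reference))
  for (p in list(caller_params(min_mut_af = 0.45),
                 caller_params(min_cov_mutated = 16),
                 caller_params(min_other_ref_af = 0.97))) {
    expect_lte(nrow(call_unique_mutations(co$pileup, p, co$reference)),
               base)
  }
})

test_that("cohorts of fewer than two samples are rejected", {
  pu <- toy_pileup("ACGT", "only")
  expect_error(call_unique_mutations(pu, params_default), "at least 2")
  pu2 <- toy_pileup("ACGT", c("s1", "s2"))
  expect_error(call_unique_mutations(pu2, params_default,
                                     cohort = c("s1", "sX")),
               "do not match")
})

test_that("indel left alignment shifts through repeats and is idempotent", {
  reference <- c(chr1 = "CAAAT")
  del <- mutations("x", "chr1", 4, "A", "", "DEL")
  la <- left_align_indel(reference, del)
  expect_equal(la$pos, 2L)
  expect_equal(left_align_indel(reference, la)$pos, 2L)

  ## mirror: right alignment
  del2 <- mutations("x", "chr1", 2, "A", "", "DEL")
  expect_equal(realign_right(reference, del2)$pos, 4L)

  ## no repeat context: fixed point
  ref2 <- c(chr1 = "ACGTG")
  del3 <- mutations("x", "chr1", 3, "G", "", "DEL")
  expect_equal(left_align_indel(ref2, del3)$pos, 3L)

  ## insertion shifted through a dinucleotide repeat
  ref3 <- c(chr1 = "TAGAGC")
  ins <- mutations("x", "chr1", 5, "", "AG", "INS")
  li <- left_align_indel(ref3, ins)
  expect_equal(li$pos, 1L)
  expect_equal(li$alt_allele, "AG")

  ## left_align after realign_right returns the left alignment
  rr <- realign_right(ref3, ins)
  expect_equal(mut_key(left_align_indel(ref3, rr)), mut_key(li))

  expect_error(left_align_indel(ref2, mutations("x", "chr1", 2, "C", "A",
                                                "SNV")),
               "INS/DEL")
})

test_that("indel realignment agrees with brute-force enumeration", {
  set.seed(21)
  seq <- paste(sample(BASES4, 300, replace = TRUE, prob = c(.4, .1, .1, .4)),
               collapse = "")
  reference <- c(chr1 = seq)
  for (k in 1:60) {
    if (runif(1) < 0.5) {
      L <- sample(1:3, 1)
      pos <- sample(5:(300 - L - 5), 1)
      m <- mutations("x", "chr1", pos, substr(seq, pos, pos + L - 1), "",
                     "DEL")
    } else {
      pos <- sample(5:290, 1)
      m <- mutations("x", "chr1", pos, "",
                     paste(sample(BASES4, sample(1:3, 1), replace = TRUE),
                           collapse = ""), "INS")
    }
    expect_equal(mut_key(left_align_indel(reference, m)),
                 mut_key(oracle_left_align(seq, m)))
    expect_equal(mut_key(realign_right(reference, m)),
                 mut_key(oracle_right_align(seq, m)))
  }
})
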