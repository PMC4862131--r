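test_that("intermutation distances follow the rainfall definition", {
  snvs <- mutations("x", "chr1", c(100, 101, 200), c("C", "C", "C"),
                    c("A", "A", "T"), "SNV")
  d <- intermutation_distances(snvs)
  expect_equal(d$distance, c(1L, 99L))
  expect_equal(d$pos, c(101L, 200L))

  one <- intermutation_distances(snvs[1, ])
  expect_equal(nrow(one), 0L)

  expect_warning(intermutation_distances(snvs[c(3, 1, 2), ]), "not sorted")
})

test_that("dinucleotide folding uses the pyrimidine-rich convention", {
  f <- fold_dinucleotide("GG", "TT")
  expect_equal(paste0(f$ref, ">", f$alt), "CC>AA")
  ## CA>AC is kept over its complement TG>GT (alphabetical tie-break)
  f2 <- fold_dinucleotide("CA", "AC")
  expect_equal(paste0(f2$ref, ">", f2$alt), "CA>AC")
  ## folding is idempotent: re-folding the canonical form changes nothing
  f3 <- fold_dinucleotide(f$ref, f$alt)
  expect_equal(f3$ref, f$ref)
  expect_equal(f3$alt, f$alt)
  ## and the two orientations of any event land on one label
  set.seed(8)
  for (k in 1:25) {
    r <- paste(sample(BASES4, 2, replace = TRUE), collapse = "")
    a <- paste(vapply(strsplit(r, "")[[1]],
                      function(b) sample(setdiff(BASES4, b), 1),
                      character(1)), collapse = "")
    f_fwd <- fold_dinucleotide(r, a)
    f_rev <- fold_dinucleotide(rc_str(r), rc_str(a))
    expect_equal(f_fwd$ref, f_rev$ref)
    expect_equal(f_fwd$alt, f_rev$alt)
  }
})

test_that("adjacent SNV pairs merge into DNVs and conservation holds", {
  snvs <- mutations(
    "x", "chr1", c(150, 151, 300, 500, 501, 502, 800),
    c("C", "C", "T", "G", "G", "A", "C"),
    c("A", "A", "G", "T", "T", "C", "G"), "SNV")
  res <- detect_dinucleotides(snvs)
  expect_equal(nrow(res$dinucleotides), 1L)
  expect_equal(res$dinucleotides$folded_label, "CC>AA")
  expect_equal(res$dinucleotides$ref_dinuc, "CC")
  expect_equal(nrow(res$multi_runs), 1L)
  expect_equal(res$multi_runs$length, 3L)
  ## conservation: isolated + 2 x DNV + run lengths = total SNVs
  expect_equal(nrow(res$isolated) + 2 * nrow(res$dinucleotides) +
                 sum(res$multi_runs$length), nrow(snvs))
  ## GG>TT on the plus strand folds to CC>AA
  gg <- mutations("x", "chr1", c(10, 11), c("G", "G"), c("T", "T"), "SNV")
  expect_equal(detect_dinucleotides(gg)$dinucleotides$folded_label, "CC>AA")
  ## isolated SNV: no DNV
  expect_equal(nrow(detect_dinucleotides(snvs[3, ])$dinucleotides), 0L)
})

test_that("insertion context reads GG^T TT directly and folds A insertions", {
  ##            123456789
  reference <- c(chr1 = "CAGGTTTAC")
  ## T inserted after the GG at 3-4, before TT: preceding GG, following TT.
  ## note the T homopolymer: left-aligned anchor is pos 4.
  ins <- mutations("x", "chr1", 4, "", "T", "INS")
  ctx <- classify_insertion(reference, ins)
  expect_equal(ctx$preceding_2, "GG")
  expect_equal(ctx$inserted, "T")
  expect_equal(ctx$following_2, "TT")
  expect_false(ctx$strand_folded)

  ## A inserted with downstream CC: on the opposite strand this is a T
  ## insertion preceded by GG
  ##             1234567890
  ref2 <- c(chr1 = "TTGACCGTAT")
  insA <- mutations("x", "chr1", 4, "", "A", "INS")
  ctx2 <- classify_insertion(ref2, insA)
  expect_true(ctx2$strand_folded)
  expect_equal(ctx2$inserted, "T")
  expect_equal(ctx2$preceding_2, "GG")

  ## contig edge: unassignable
  edge <- mutations("x", "chr1", 1, "", "C", "INS")
  expect_true(is.na(classify_insertion(ref2, edge)$preceding_2))
})

test_that("deletion context folds purine deletions onto the pyrimidine strand", {
  ##            12345
  reference <- c(chr1 = "TAGCA")
  del <- mutations("x", "chr1", 3, "G", "", "DEL")
  ctx <- classify_deletion(reference, del)
  expect_true(ctx$strand_folded)
  expect_equal(ctx$deleted, "C")
  expect_equal(ctx$preceding, "G")   # complement of the following C
  expect_equal(ctx$following, "T")   # complement of the preceding A

  ## deletion of T between A and A
  ref2 <- c(chr1 = "GATAG")
  del2 <- mutations("x", "chr1", 3, "T", "", "DEL")
  ctx2 <- classify_deletion(ref2, del2)
  expect_equal(unlist(ctx2[1, 1:3], use.names = FALSE), c("A", "T", "A"))

  ## homopolymer deletions collapse to one canonical context
  ref3 <- c(chr1 = "GCAAAATG")
  d1 <- classify_deletion(ref3, mutations("x", "chr1", 4, "A", "", "DEL"))
  d2 <- classify_deletion(ref3, mutations("x", "chr1", 6, "A", "", "DEL"))
  expect_equal(d1, d2)
})

test_that("two-base deletion motif matching follows the crosslink rule", {
  reference <- c(chr1 = "TTAGGGCTATTT")
  del <- mutations(rep("x", 3), "chr1", c(3, 7, 9),
                   c("AG", "CT", "AT"), "", "DEL")
  res <- motif_overlap_two_base_deletions(reference, del)
  expect_equal(res$n_total, 3L)
  expect_equal(res$n_motif, 2L)        # AG counted, CT counted, AT not
  expect_equal(res$fraction, 2 / 3)
})

test_that("context cataloguing recovers constructed flank proportions", {
  ## place TC>AC SNVs with a known 75% TCC flank fraction
  set.seed(19)
  n <- 200
  flank3 <- sample(c("C", "T"), n, replace = TRUE, prob = c(0.75, 0.25))
  chunks <- vapply(seq_len(n), function(k)
    paste0("AT", "TC", flank3[k], "GA"), character(1))
  seq <- paste(chunks, collapse = "")
  reference <- c(chr1 = seq)
  pos <- (seq_len(n) - 1L) * 7L + 4L   # the C of each TC
  snvs <- mutations("x", "chr1", pos, "C", "A", "SNV")
  cat3 <- context_catalogue(reference, snvs, "C>A", five_prime = "T",
                            flank_up = 1, flank_down = 1)
  expect_equal(cat3$n_matching, n)
  frac_tcc <- cat3$tally[["T.C"]] / n
  expect_lt(abs(frac_tcc - mean(flank3 == "C")), 1e-12)
  expect_lt(abs(frac_tcc - 0.75), 3 * sqrt(0.75 * 0.25 / n))
  ## empty input
  empty <- context_catalogue(reference, snvs[0, ], "C>A")
  expect_equal(empty$n_matching, 0L)
})

test_that("cross-clone clustering counts pairs and matches expectation", {
  a <- data.frame(chrom = "chr1", pos = c(100L, 5000L))
  b <- data.frame(chrom = "chr1", pos = c(20000L, 50000L))
  res <- cross_clone_clustering(list(A = a, B = b), 10, 1e5)
  expect_equal(res$total, 0L)

  res2 <- cross_clone_clustering(list(A = a, B = a), 10, 1e5)
  expect_equal(res2$total, 2L)

  set.seed(33)
  L <- 1e6
  sets <- lapply(1:2, function(i)
    data.frame(chrom = "chr1", pos = sample(L, 500)))
  names(sets) <- c("A", "B")
  res3 <- cross_clone_clustering(sets, 100, L)
  expect_lt(abs(res3$total - res3$expected_total),
            4 * sqrt(res3$expected_total) + 1)
})
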