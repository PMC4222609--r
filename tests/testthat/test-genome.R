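# Synthetic genome: reference construction, NAHR products, gene
# conversion, truth copy profiles, on-disk round trips.

test_that("reference build is byte-identical under a fixed seed", {
  p1 <- build_reference(tiny_config(seed = 3))
  p2 <- build_reference(tiny_config(seed = 3))
  expect_identical(p1$x_seq, p2$x_seq)
  expect_identical(p1$y_seq, p2$y_seq)
  expect_identical(p1$snp_catalog, p2$snp_catalog)
  p3 <- build_reference(tiny_config(seed = 4))
  expect_false(identical(p1$x_seq, p3$x_seq))
})

test_that("PSV table has the configured size and valid offsets", {
  pair <- build_reference(analog_config(), with_sequences = FALSE)
  expect_identical(nrow(pair$psv), 15L)
  expect_true(all(pair$psv$offset >= 0 & pair$psv$offset < 548))
  expect_identical(pair$psv$offset, sort(unique(pair$psv$offset)))
  expect_true(all(pair$psv$state_X != pair$psv$state_PAR))
})

test_that("with zero SNP density the PARs are identical and the catalogue empty", {
  pair <- build_reference(tiny_config(snp_density = 0))
  expect_identical(nrow(pair$snp_catalog), 0L)
  pab <- pair$config$pab_position
  expect_identical(substr(pair$x_seq, 1, pab), substr(pair$y_seq, 1, pab))
})

test_that("invalid geometries raise configuration errors naming the conflict", {
  expect_error(genome_config(repeatA_start = 2699400),
               "repeat A.*PAR1")
  expect_error(genome_config(repeatB_start = 2699000),
               "repeat B.*PAB")
  expect_error(genome_config(y_length = 100000), "y_length")
  expect_error(genome_config(repeat_length = 10, n_psv = 15), "n_psv")
})

test_that("NAHR gain equals the distance between the repeats (printed-coordinate analog)", {
  # donor/acceptor repeat starts mirror the printed coordinate pairs; the
  # oracle is the string-length difference of the derived products
  pair <- build_reference(analog_config(snp_density = 1e-4))
  der <- apply_nahr(pair, nahr_event())
  expect_identical(nchar(der$der_y_seq) - nchar(pair$y_seq), 114398L)
  expect_identical(nchar(pair$x_seq) - nchar(der$del_x_seq), 114398L)
  expect_identical(der$gain, 2808549 - 2694151)
})

test_that("reciprocal exchange conserves total length for any crossover offset", {
  pair <- build_reference(tiny_config())
  total <- pair$config$x_length + pair$config$y_length
  for (delta in c(0, 1, 137, 274, 547, 548)) {
    der <- apply_nahr(pair, nahr_event(delta = delta))
    expect_equal(nchar(der$der_y_seq) + nchar(der$del_x_seq), total)
    expect_equal(der$der_y_length + der$del_x_length, total)
  }
  expect_error(apply_nahr(pair, nahr_event(delta = 549)), "outside repeat")
  expect_error(apply_nahr(pair, nahr_event(delta = -1)), "outside repeat")
})

test_that("allelic crossover reproduces the parents", {
  pair <- build_reference(tiny_config(snp_density = 0))
  der <- apply_nahr(pair, nahr_event(delta = 100, allelic = TRUE))
  expect_identical(der$der_y_seq, pair$y_seq)
  expect_identical(der$del_x_seq, pair$x_seq)
  expect_equal(der$gain, 0)
})

test_that("fusion-repeat origin vector has one X-to-PAR switch without conversion", {
  pair <- build_reference(tiny_config(), with_sequences = FALSE)
  offs <- pair$psv$offset
  for (delta in c(offs[2], offs[8] + 1, 274)) {
    der <- apply_nahr(pair, nahr_event(delta = delta))
    org <- der$fusion_derY$origin
    expect_identical(org, c(rep("X", sum(offs < delta)),
                            rep("PAR", sum(offs >= delta))))
    expect_identical(sum(org[-1] != org[-length(org)]), 1L)
  }
})

test_that("the derived Y retains both PAB junctions exactly once", {
  pair <- build_reference(tiny_config())
  der <- apply_nahr(pair)
  km <- pab_junction_kmers(pair, k = 40)
  expect_identical(count_kmer(der$der_y_seq, km[["y_pab"]]), 1L)
  expect_identical(count_kmer(der$der_y_seq, km[["x_pab"]]), 1L)
})

test_that("the deletion X lacks k-mers unique to the deleted interval", {
  pair <- build_reference(tiny_config())
  der <- apply_nahr(pair)
  cfg <- pair$config
  lo <- cfg$repeatA_start + der$delta
  hi <- cfg$repeatB_start + der$delta
  set.seed(99)
  starts <- sample(seq(lo, hi - 40), 25)
  checked <- 0L
  for (s in starts) {
    kmer <- substr(pair$x_seq, s + 1, s + 40)
    if (count_kmer(pair$x_seq, kmer) == 1L &&
        count_kmer(pair$y_seq, kmer) == 0L) {
      expect_identical(count_kmer(der$del_x_seq, kmer), 0L)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 10L)
})

test_that("gene conversion rewrites tract PSVs to X and is identity on empty tracts", {
  pair <- build_reference(tiny_config())
  der <- apply_nahr(pair)  # Junc1-type: distal X block, proximal PAR block
  # full tract: all origins X (the Junc2 genesis)
  conv <- apply_gene_conversion(der, c(0, pair$config$repeat_length))
  expect_true(all(conv$fusion_derY$origin == "X"))
  # empty tract: unchanged
  same <- apply_gene_conversion(der, c(100, 100))
  expect_identical(same$fusion_derY, der$fusion_derY)
  expect_identical(same$der_y_seq, der$der_y_seq)
  # a Junc1-type fusion (13 distal X, 2 proximal PAR): converting only the
  # two proximal PAR-origin offsets makes the vector all-X
  offs <- pair$psv$offset
  junc1 <- apply_nahr(pair, nahr_event(delta = offs[14]))
  prox2 <- apply_gene_conversion(junc1,
                                 c(offs[14], pair$config$repeat_length))
  expect_true(all(prox2$fusion_derY$origin == "X"))
  expect_error(apply_gene_conversion(der, c(-5, 100)), "outside repeat")
})

test_that("truth copy profiles encode the karyotype geometry", {
  pair <- build_reference(tiny_config(), with_sequences = FALSE)
  der <- apply_nahr(pair)
  cfg <- pair$config
  a_cut <- cfg$repeatA_start + der$delta
  b_cut <- cfg$repeatB_start + der$delta

  carrier <- truth_copy_profile(der, "male_carrier")
  expect_identical(carrier$intervals$copies, c(2L, 3L, 2L, 1L))
  expect_identical(carrier$intervals$start, c(0, a_cut, cfg$pab_position, b_cut))
  # triplicated proximal PAR1: alt on one copy -> (m, c) = (1, 3)
  tri <- carrier$snps[carrier$snps$pos >= a_cut &
                        carrier$snps$pos < cfg$pab_position, ]
  expect_true(all(tri$c == 3L))
  expect_true(any(tri$m == 1L))
  expect_true(all(tri$m >= 1L & tri$m <= 2L))  # catalogued sites are het here

  fem <- truth_copy_profile(der, "female_control")
  expect_true(all(fem$intervals$copies == 2L))
  expect_true(all(fem$snps$c == 2L))

  male <- truth_copy_profile(der, "male_control")
  xspec <- male$snps[male$snps$pos >= cfg$pab_position, ]
  expect_true(all(xspec$c == 1L))  # hemizygous: heterozygosity impossible

  del <- truth_copy_profile(der, "deletion_female")
  expect_identical(del$intervals$copies, c(2L, 1L, 2L))
  expect_error(truth_copy_profile(der, "trisomic"), "arg")

  # intervals tile the X coordinate range without gaps
  for (pr in list(carrier, fem, male, del)) {
    iv <- pr$intervals
    expect_identical(iv$start[1], 0)
    expect_identical(iv$end[nrow(iv)], cfg$x_length)
    if (nrow(iv) > 1) expect_identical(iv$start[-1], iv$end[-nrow(iv)])
  }
})

test_that("expected log2 ratios follow the copy model", {
  pair <- build_reference(tiny_config(), with_sequences = FALSE)
  der <- apply_nahr(pair)
  carrier <- expected_log2(truth_copy_profile(der, "male_carrier"),
                           reference_copy = 2)
  expect_equal(carrier$log2_ratio, log2(c(2, 3, 2, 1) / 2))
  expect_equal(carrier$log2_ratio[2], 0.585, tolerance = 1e-3)
  # male duplication against a male (c=1) reference
  m <- expected_log2(truth_copy_profile(der, "male_carrier"),
                     reference_copy = 1)
  expect_identical(m$log2_ratio[3], 1)
  # deletion carrier against a diploid reference over the lost interval
  d <- expected_log2(truth_copy_profile(der, "deletion_female"),
                     reference_copy = 2)
  expect_identical(d$log2_ratio[2], -1)
  zero <- truth_copy_profile(der, "male_carrier")
  zero$intervals$copies[4] <- 0L
  z <- expected_log2(zero)
  expect_identical(z$log2_ratio[4], -Inf)
  expect_true(z$zero_copy[4])
})

test_that("genomes round-trip through FASTA + BED + truth JSON", {
  pair <- build_reference(tiny_config())
  der <- apply_nahr(pair)
  dir <- withr::local_tempdir()
  paths <- write_genome(der, dir, prefix = "toy")

  seqs <- Biostrings::readDNAStringSet(paths[["fasta"]])
  expect_identical(as.character(seqs[["derY"]]), der$der_y_seq)
  expect_identical(as.character(seqs[["delX"]]), der$del_x_seq)

  gr <- read_genome_features(paths[["bed"]])
  reps <- gr[gr$name %in% c("A_PAR", "B_XSPEC")]
  got <- data.frame(id = reps$name,
                    chrom = as.character(GenomicRanges::seqnames(reps)),
                    start = GenomicRanges::start(reps) - 1L,
                    end = GenomicRanges::end(reps))
  got <- got[order(got$chrom, got$start), ]
  want <- pair$repeats[order(pair$repeats$chrom, pair$repeats$start), ]
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  # PAB is a zero-length point feature
  pab <- gr[gr$name == "PAB"]
  expect_true(all(GenomicRanges::width(pab) == 0L))
  # per-chromosome sortedness, and repeats non-overlapping
  for (chr in unique(as.character(GenomicRanges::seqnames(gr)))) {
    s <- GenomicRanges::start(gr[GenomicRanges::seqnames(gr) == chr])
    expect_true(all(diff(s) >= 0))
  }
  expect_lte(pair$repeats$end[1], pair$repeats$start[2])

  truth <- jsonlite::read_json(paths[["json"]], simplifyVector = TRUE)
  expect_equal(truth$gain, der$gain)
  for (iv in truth$copy_profiles$intervals) {
    expect_equal(iv$start[1], 0)
    expect_equal(iv$end[nrow(iv)], pair$config$x_length)
    if (nrow(iv) > 1) expect_equal(iv$start[-1], iv$end[-nrow(iv)])
  }
  expect_identical(truth$config$seed, pair$config$seed)
})
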