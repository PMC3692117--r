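# Filter 1 (read support) and filter 2 (base quality with homopolymer and
# read-end masking).

test_that("pileup counts alleles per column, excluding N, including gaps", {
  rd <- make_reads(paste0("r", 1:4), c(0, 0, 0, 0),
                   c("AAC", "AAC", "GAC", "NA-"))
  p <- pileup(make_contig(rd, length = 4))
  expect_equal(unname(p["A", 1]), 2L)   # A,A,G,N -> {A:2, G:1}
  expect_equal(unname(p["G", 1]), 1L)
  expect_equal(sum(p[, 1]), 3L)         # N excluded
  expect_equal(unname(p["-", 3]), 1L)   # deletion counted as an allele
  expect_equal(sum(p[, 4]), 0L)         # zero coverage
})

test_that("potential SNPs require two alleles at the support threshold", {
  cfg <- filter_config(min_allele_reads = 2L)
  # {A:3, G:1}: G below threshold -> not potential
  rd <- make_reads(paste0("r", 1:4), rep(0, 4), c("A", "A", "A", "G"))
  expect_equal(nrow(detect_potential_snps(make_contig(rd, length = 1), cfg)), 0L)
  # {A:3, G:2} -> potential
  rd <- make_reads(paste0("r", 1:5), rep(0, 5), c("A", "A", "A", "G", "G"))
  sites <- detect_potential_snps(make_contig(rd, length = 1), cfg)
  expect_equal(sites$pos, 0L)
  expect_equal(sites$status, "potential")
  expect_equal(sites$counts[[1]], c(A = 3L, G = 2L))
})

test_that("fraction thresholds round up over covering reads", {
  # brute-force oracle over allele counts: an allele passes iff
  # count >= ceiling(fraction * coverage)
  cfg <- filter_config(threshold_mode = "fraction", min_allele_fraction = 0.05)
  for (na in c(90L, 95L, 96L)) {
    ng <- 100L - na
    rd <- make_reads(paste0("r", 1:100), rep(0, 100),
                     c(rep("A", na), rep("G", ng)))
    sites <- detect_potential_snps(make_contig(rd, length = 1), cfg)
    expected <- sum(c(na, ng) >= max(1L, ceiling(0.05 * 100))) >= 2L
    expect_equal(nrow(sites) == 1L, expected,
                 label = sprintf("A=%d G=%d potential", na, ng))
  }
  # {A:90, G:10} at 5%: 10 >= 5 -> potential
  rd <- make_reads(paste0("r", 1:100), rep(0, 100),
                   c(rep("A", 90), rep("G", 10)))
  expect_equal(nrow(detect_potential_snps(make_contig(rd, length = 1), cfg)), 1L)
})

test_that("quality masks follow Phred, end and homopolymer rules", {
  cfg0 <- filter_config()
  # qualities absent, no masks -> all high quality
  expect_true(all(build_quality_mask("ACGTACGTAC", NULL, FALSE, cfg0)))
  # Phred cutoff
  m <- build_quality_mask("ACGT", c(10L, 20L, 30L, NA), FALSE, cfg0)
  expect_equal(m, c(FALSE, TRUE, TRUE, TRUE))
  # homopolymer run of >= 3 masks the run plus one base on each side
  cfg_hp <- filter_config(mask_homopolymer = TRUE, homopolymer_min_run = 3L)
  m <- build_quality_mask("GACGTAAAAGTCGTA", NULL, FALSE, cfg_hp)
  # G (touches read start, truncated run) masks 1-2; AAAA at 6-9 masks 5-10;
  # A (touches read end) masks 14-15
  expect_equal(which(!m), c(1:2, 5:10, 14:15))
  # the AAAA run and both flanking bases are always masked
  m2 <- build_quality_mask("TTAAAAG", NULL, FALSE, cfg_hp)
  expect_true(all(!m2[2:7]))
  # 5'-end masking in read orientation: reverse reads mask their own ends
  cfg_5p <- filter_config(mask_5prime = 2L)
  expect_equal(which(!build_quality_mask(strrep("A", 10), NULL, FALSE, cfg_5p)),
               1:2)
  expect_equal(which(!build_quality_mask(strrep("A", 10), NULL, TRUE, cfg_5p)),
               9:10)
})

test_that("quality filter recomputes support over unmasked bases only", {
  # a site whose alternate allele is carried only by masked bases is rejected
  rd2 <- make_reads(paste0("r", 1:5), rep(0, 5),
                    c("GAAAT", "GAAAT", "GCCCT", "GCCCT", "GCCCT"),
                    quals = list(rep(40L, 5), rep(40L, 5), rep(40L, 5),
                                 rep(40L, 5), rep(40L, 5)))
  ctg2 <- make_contig(rd2, length = 5)
  sites2 <- detect_potential_snps(ctg2, filter_config())
  expect_true(1L %in% sites2$pos)
  hp <- filter_config(mask_homopolymer = TRUE)
  sites2m <- filter_high_confidence(detect_potential_snps(ctg2, hp), ctg2, hp)
  # every variant column sits inside/adjacent to a run in every read -> all rejected
  expect_true(all(sites2m$status == "rejected_quality"))
  # with all bases high quality and no masks, status moves to high_confidence
  sites2c <- filter_high_confidence(sites2, ctg2, filter_config())
  expect_true(all(sites2c$status == "high_confidence"))
})

test_that("hq counts are a sub-multiset of raw counts at every site", {
  sim <- simulate_alignment(sim_scenario(seed = 21, error_rate = 0.03),
                            write_files = FALSE)
  ctg <- sim$alignment$contigs[[1]]
  cfg <- filter_config(mask_homopolymer = TRUE, mask_5prime = 3L)
  sites <- filter_high_confidence(detect_potential_snps(ctg, cfg), ctg, cfg)
  for (i in seq_len(nrow(sites))) {
    raw <- sites$counts[[i]]
    hq <- sites$hq_counts[[i]]
    expect_true(all(names(hq) %in% names(raw)))
    expect_true(all(hq <= raw[names(hq)]))
  }
})

test_that("with masks off and qualities absent, high-confidence == potential", {
  sim <- simulate_alignment(sim_scenario(seed = 13, error_rate = 0.02),
                            write_files = FALSE)
  ctg <- sim$alignment$contigs[[1]]
  ctg$reads$quals <- rep(list(NULL), nrow(ctg$reads))
  cfg <- filter_config()   # absolute mode, no masking
  pot <- detect_potential_snps(ctg, cfg)
  hc <- filter_high_confidence(pot, ctg, cfg)
  expect_true(all(hc$status == "high_confidence"))
  expect_equal(hc$pos, pot$pos)
})

test_that("raising thresholds or mask widths never adds high-confidence sites", {
  sim <- simulate_alignment(sim_scenario(seed = 31, error_rate = 0.02),
                            write_files = FALSE)
  ctg <- sim$alignment$contigs[[1]]
  n_hc <- function(cfg) {
    s <- filter_high_confidence(detect_potential_snps(ctg, cfg), ctg, cfg)
    sum(s$status == "high_confidence")
  }
  counts_reads <- vapply(1:4, function(k)
    n_hc(filter_config(min_allele_reads = k)), numeric(1))
  expect_true(all(diff(counts_reads) <= 0))
  counts_phred <- vapply(c(2L, 20L, 41L), function(q)
    n_hc(filter_config(phred_high_quality = q)), numeric(1))
  expect_true(all(diff(counts_phred) <= 0))
  counts_mask <- vapply(c(0L, 3L, 10L, 25L), function(w)
    n_hc(filter_config(mask_5prime = w, mask_3prime = w)), numeric(1))
  expect_true(all(diff(counts_mask) <= 0))
})
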