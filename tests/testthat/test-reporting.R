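# CSV persistence, contig-table filtering, marker export.

make_results <- function(seed = 7, cfg = filter_config(mask_homopolymer = TRUE)) {
  sim <- simulate_alignment(sim_scenario(seed = seed), write_files = FALSE)
  call_snps(sim$alignment, cfg)
}

dir_bytes <- function(dir) {
  fs <- sort(list.files(dir))
  lapply(stats::setNames(file.path(dir, fs), fs), function(f)
    readBin(f, "raw", file.size(f)))
}

test_that("write -> read -> write produces byte-identical files", {
  res <- make_results()
  d1 <- tempfile(); d2 <- tempfile()
  write_results(res, d1)
  expect_setequal(list.files(d1),
                  c("contigs.csv", "snps.csv", "haplotypes.csv",
                    "genotypes.csv", "run_config.csv", "manifest.csv"))
  reread <- read_results(d1)
  expect_equal(unclass(reread), unclass(res), ignore_attr = TRUE)
  write_results(reread, d2)
  expect_identical(dir_bytes(d2), dir_bytes(d1))
  # row count of snps.csv equals the number of reliable sites
  snps <- utils::read.csv(file.path(d1, "snps.csv"))
  expect_equal(nrow(snps), sum(res$contigs$n_reliable_snps))
  expect_true(all(snps$status == "reliable"))
})

test_that("an empty alignment yields headers-only CSVs plus manifest", {
  aln <- alignment_set(list(), source_format = "SAM")
  res <- call_snps(aln)
  d <- tempfile()
  write_results(res, d)
  for (f in c("contigs.csv", "snps.csv", "haplotypes.csv", "genotypes.csv")) {
    expect_equal(length(readLines(file.path(d, f))), 1L, label = f)
  }
  expect_true(file.exists(file.path(d, "manifest.csv")))
  expect_equal(nrow(read_results(d)$snps), 0L)
})

test_that("reload failures are diagnosed", {
  res <- make_results()
  d <- tempfile()
  write_results(res, d)
  file.remove(file.path(d, "genotypes.csv"))
  expect_error(read_results(d), "genotypes.csv")
  # config-hash mismatch -> warning
  d2 <- tempfile()
  write_results(res, d2)
  cfg_lines <- readLines(file.path(d2, "run_config.csv"))
  cfg_lines[2] <- sub("\"2\"", "\"3\"", cfg_lines[2])
  writeLines(cfg_lines, file.path(d2, "run_config.csv"))
  expect_warning(read_results(d2), "config hash")
})

test_that("contig table filtering is conjunctive, inclusive and case-insensitive", {
  rows <- data.frame(
    contig_id = c("at1g01010.1", "AT2G33120.1", "chr5_frag"),
    n_reads = c(500L, 1500L, 2500L),
    n_reliable_snps = c(5L, 10L, 30L),
    corrected_haplotype_count = c(2L, 2L, 4L),
    stringsAsFactors = FALSE)
  # snps in [8, 25] -> only the 10-SNP contig
  out <- filter_contig_table(rows, min_snps = 8, max_snps = 25)
  expect_equal(out$contig_id, "AT2G33120.1")
  # reads in [1000, 2000] conjunctively
  out2 <- filter_contig_table(rows, min_snps = 8, max_snps = 25,
                              min_reads = 1000, max_reads = 2000)
  expect_equal(out2$contig_id, "AT2G33120.1")
  # no constraints -> identity (order preserved)
  expect_equal(filter_contig_table(rows), rows)
  # case-insensitive substring
  expect_equal(filter_contig_table(rows, name_substring = "AT1G")$contig_id,
               "at1g01010.1")
  # output is always a subset of the input
  expect_true(all(filter_contig_table(rows, min_reads = 1000)$contig_id %in%
                    rows$contig_id))
  expect_error(filter_contig_table(rows, min_snps = 10, max_snps = 5),
               "exceeds")
})

test_that("marker export truncates flanks at contig edges and flags paralogs", {
  res <- make_results()
  mk <- export_markers(res, flank_length = 60L)
  expect_equal(nrow(mk), sum(res$contigs$n_reliable_snps))
  cons <- res$contigs$consensus[1]
  for (i in seq_len(nrow(mk))) {
    pos1 <- mk$position_1based[i]
    expect_equal(nchar(mk$flank5[i]), min(60L, pos1 - 1L))
    expect_equal(nchar(mk$flank3[i]), min(60L, nchar(cons) - pos1))
    # flanks re-locate exactly in the consensus
    if (nchar(mk$flank5[i]) > 0) {
      expect_equal(substr(cons, pos1 - nchar(mk$flank5[i]), pos1 - 1L),
                   mk$flank5[i])
    }
    expect_equal(substr(cons, pos1 + 1L, pos1 + nchar(mk$flank3[i])),
                 mk$flank3[i])
    # bracket notation [X/Y] in context
    expect_match(mk$context[i], "\\[[ACGT-]+(/[ACGT-]+)+\\]")
  }
  # paralog flag: corrected count above the expected maximum
  expect_false(any(mk$paralog_flag))  # diploid scenario, corrected count 2
  mk2 <- export_markers(res, expected_haplotypes = 1L)
  expect_true(all(mk2$paralog_flag))
  # a site that is not a reliable SNP is refused
  expect_error(
    export_markers(res, sites = data.frame(contig_id = "contig1",
                                           position = 1L)),
    "not reliable")
  # IUPAC mode uses ambiguity codes for pure base pairs
  mki <- export_markers(res, iupac = TRUE)
  expect_false(any(grepl("[", mki$context[1], fixed = TRUE)))
})
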