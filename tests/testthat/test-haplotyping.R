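# Filter 3: allele matrix, greedy haplotype clustering, reliable SNPs,
# fragmentation-corrected counts.

hc_sites <- function(pos) {
  n <- length(pos)
  data.frame(contig_id = rep("ctg1", n), pos = as.integer(pos),
             status = rep("high_confidence", n),
             reason = rep(NA_character_, n),
             stringsAsFactors = FALSE)
}

all_true_masks <- function(ctg) {
  lapply(seq_len(nrow(ctg$reads)),
         function(i) rep(TRUE, nchar(ctg$reads$bases[i])))
}

test_that("allele matrix rows are fragments over covered, unmasked sites", {
  # read covering only site 1 -> (A, NA)
  rd <- make_reads(c("f1", "f2"), c(0, 4), c("ACG", "TTT"))
  ctg <- make_contig(rd, length = 8)
  mat <- build_allele_matrix(ctg, hc_sites(c(0, 5)), all_true_masks(ctg))
  expect_equal(mat["f1", ], c("0" = "A", "5" = NA))
  expect_equal(mat["f2", ], c("0" = NA, "5" = "T"))
  # mate pair covering sites 1 and 2 respectively -> one row with both alleles
  rd2 <- make_reads(c("p1/1", "p1/2"), c(0, 4), c("ACG", "TTT"),
                    fragment_id = c("p1", "p1"),
                    mate_id = c("p1/2", "p1/1"))
  ctg2 <- make_contig(rd2, length = 8)
  mat2 <- build_allele_matrix(ctg2, hc_sites(c(0, 5)), all_true_masks(ctg2))
  expect_equal(nrow(mat2), 1L)
  expect_equal(mat2["p1", ], c("0" = "A", "5" = "T"))
  # mates disagreeing at a shared site -> missing there
  rd3 <- make_reads(c("p1/1", "p1/2"), c(0, 0), c("ACG", "TCG"),
                    fragment_id = c("p1", "p1"),
                    mate_id = c("p1/2", "p1/1"))
  ctg3 <- make_contig(rd3, length = 8)
  mat3 <- build_allele_matrix(ctg3, hc_sites(c(0, 1)), all_true_masks(ctg3))
  expect_equal(mat3["p1", ], c("0" = NA, "1" = "C"))
  # a masked base is missing
  masks <- all_true_masks(ctg)
  masks[[1]][1] <- FALSE
  mat4 <- build_allele_matrix(ctg, hc_sites(c(0, 5)), masks)
  expect_false("f1" %in% rownames(mat4))  # f1 covered only site 1, now masked
})

test_that("greedy clustering groups compatible fragments deterministically", {
  cfg <- filter_config()
  mat <- matrix(c("A", "C", "A", "C", "G", "T", "G", "T"),
                nrow = 4, byrow = TRUE,
                dimnames = list(paste0("f", 1:4), c("0", "1")))
  cl <- cluster_haplotypes(mat, cfg)
  expect_equal(length(cl$haplotypes), 2L)
  expect_equal(vapply(cl$haplotypes, `[[`, integer(1), "support"), c(2L, 2L))
  # singleton disagreeing with all others is discarded and unassigned
  mat2 <- rbind(mat, f5 = c("A", "T"))
  cl2 <- cluster_haplotypes(mat2, cfg)
  expect_equal(length(cl2$haplotypes), 2L)
  expect_equal(cl2$unassigned, "f5")
  # determinism: identical input -> identical assignments
  cl3 <- cluster_haplotypes(mat2, cfg)
  expect_identical(cl2, cl3)
})

test_that("fragments sharing no covered site form separate haplotypes", {
  # unlinked SNP blocks must fragment the haplotype (the basis of the
  # corrected haplotype count); disjoint fragments are never merged
  cfg <- filter_config(min_haplotype_reads = 1L)
  mat <- matrix(c("A", NA, NA, "C"), nrow = 2, byrow = TRUE,
                dimnames = list(c("f1", "f2"), c("0", "1")))
  cl <- cluster_haplotypes(mat, cfg)
  expect_equal(length(cl$haplotypes), 2L)
})

test_that("greedy haplotypes are internally compatible and bounded by the brute-force minimum", {
  cfg <- filter_config(min_haplotype_reads = 1L)
  set.seed(99)
  for (rep in 1:120) {
    mat <- random_allele_matrix(sample(2:8, 1), sample(2:4, 1))
    if (nrow(mat) == 0) next
    cl <- cluster_haplotypes(mat, cfg)
    # internal compatibility: no two members disagree at a shared site
    for (h in cl$haplotypes) {
      rows <- mat[h$fragments, , drop = FALSE]
      for (a in seq_len(nrow(rows) - 1L)) {
        for (b in (a + 1L):nrow(rows)) {
          sh <- !is.na(rows[a, ]) & !is.na(rows[b, ])
          if (any(sh)) expect_true(all(rows[a, sh] == rows[b, sh]))
        }
      }
      # the haplotype allele vector equals the members' unanimous allele
      for (j in colnames(mat)) {
        obs <- unique(stats::na.omit(rows[, j]))
        if (length(obs) > 0) expect_equal(h$alleles[[j]], obs)
      }
    }
    expect_gte(length(cl$haplotypes), brute_force_min_classes(mat))
    # with no missing cells greedy attains the minimum (= distinct rows)
    full <- mat[rowSums(is.na(mat)) == 0L, , drop = FALSE]
    if (nrow(full) > 0) {
      clf <- cluster_haplotypes(full, cfg)
      expect_equal(length(clf$haplotypes), brute_force_min_classes(full))
    }
  }
})

test_that("reliable SNPs need two haplotype-backed alleles", {
  cfg <- filter_config()
  mat <- matrix(c("A", "C", "A", "C", "G", "T", "G", "T"),
                nrow = 4, byrow = TRUE,
                dimnames = list(paste0("f", 1:4), c("3", "7")))
  haps <- cluster_haplotypes(mat, cfg)$haplotypes
  sites <- mark_reliable_snps(hc_sites(c(3, 7)), haps)
  expect_true(all(sites$status == "reliable"))
  # alternate allele only in an unassigned (discarded) fragment -> demoted
  mat2 <- rbind(mat[1:2, , drop = FALSE], f9 = c("T", "C"))
  cl2 <- cluster_haplotypes(mat2, cfg)
  sites2 <- mark_reliable_snps(hc_sites(c(3, 7)), cl2$haplotypes)
  expect_equal(sites2$status[sites2$pos == 3], "rejected_quality")
  expect_equal(sites2$reason[sites2$pos == 3], "no_haplotype_support")
})

test_that("corrected haplotype count is the per-site maximum", {
  cfg <- filter_config()
  # 2 true haplotypes fragmented into 4: no fragment spans both blocks
  mat <- matrix(c("A", "C", NA, NA,
                  "A", "C", NA, NA,
                  "G", "T", NA, NA,
                  "G", "T", NA, NA,
                  NA, NA, "A", "C",
                  NA, NA, "A", "C",
                  NA, NA, "G", "T",
                  NA, NA, "G", "T"),
                nrow = 8, byrow = TRUE,
                dimnames = list(sprintf("f%02d", 1:8), c("0", "1", "2", "3")))
  cl <- cluster_haplotypes(mat, cfg)
  expect_equal(length(cl$haplotypes), 4L)
  summ <- summarize_haplotypes(cl$haplotypes, hc_sites(0:3))
  expect_equal(unname(summ$per_site_haplotype_count), rep(2L, 4))
  expect_equal(summ$corrected_count, 2L)
  # single haplotype across 3 sites -> corrected 1; zero sites -> 0
  one <- matrix(rep(c("A", "C", "G"), 2), nrow = 2, byrow = TRUE,
                dimnames = list(c("f1", "f2"), c("0", "1", "2")))
  cl1 <- cluster_haplotypes(one, cfg)
  expect_equal(summarize_haplotypes(cl1$haplotypes, hc_sites(0:2))$corrected_count, 1L)
  expect_equal(summarize_haplotypes(cl1$haplotypes, hc_sites(integer(0)))$corrected_count, 0L)
  expect_lte(summ$corrected_count, length(cl$haplotypes))
})

test_that("display ordering sorts by position or by haplotype", {
  rd <- make_reads(c("f1", "f2", "f3", "f4", "f5"),
                   c(4, 0, 2, 1, 6),
                   c("AC", "AC", "AC", "AC", "GG"))
  ctg <- make_contig(rd, length = 8)
  by_pos <- sort_reads_for_display(ctg, mode = "by_position")
  expect_true(!is.unsorted(by_pos$start))
  haps <- list(list(haplotype_id = 1L, alleles = c("0" = "A"),
                    fragments = c("f2", "f4"), support = 2L),
               list(haplotype_id = 2L, alleles = c("0" = "G"),
                    fragments = c("f3", "f1"), support = 2L))
  by_hap <- sort_reads_for_display(ctg, haps, mode = "by_haplotype")
  # reads in no haplotype (f5: covers no SNP) are omitted
  expect_false("f5" %in% by_hap$read_id)
  expect_equal(by_hap$read_id, c("f2", "f4", "f3", "f1"))
})

test_that("reliable sites are a subset of high-confidence sites, which are a subset of potential sites", {
  sim <- simulate_alignment(sim_scenario(seed = 17, error_rate = 0.03),
                            write_files = FALSE)
  cfg <- filter_config(mask_homopolymer = TRUE)
  res <- call_snps(sim$alignment, cfg, keep_intermediate = TRUE)
  sites <- attr(res, "details")[[1]]$sites
  pot <- sites$pos
  hc <- sites$pos[sites$status %in% c("high_confidence", "reliable")]
  rel <- sites$pos[sites$status == "reliable"]
  expect_true(all(rel %in% hc))
  expect_true(all(hc %in% pot))
  expect_equal(res$snps$position - 1L, rel)
})
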