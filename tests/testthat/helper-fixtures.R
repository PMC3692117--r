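# Fixture builders shared across the test files. Everything is generated in
# code; no binary fixtures.

# Minimal reads data.frame in the internal contig-coordinate model.
make_reads <- function(read_id, start, bases, quals = NULL, sample = "default",
                       fragment_id = read_id, mate_id = NA_character_,
                       is_reverse = FALSE) {
  n <- length(read_id)
  df <- data.frame(read_id = read_id, fragment_id = fragment_id,
                   start = as.integer(start), bases = bases,
                   sample = rep_len(sample, n),
                   mate_id = rep_len(mate_id, n),
                   is_reverse = rep_len(is_reverse, n),
                   stringsAsFactors = FALSE)
  df$quals <- if (is.null(quals)) rep(list(NULL), n) else quals
  df[c("read_id", "fragment_id", "start", "bases", "quals", "sample",
       "mate_id", "is_reverse")]
}

make_contig <- function(reads, length = NULL, contig_id = "ctg1",
                        consensus = NULL) {
  if (is.null(length)) length <- max(reads$start + nchar(reads$bases))
  new_contig(contig_id, length, reads, consensus = consensus)
}

# A small hand-written SAM fixture: 6 reads, 2 read groups (Col-0, Can-0),
# one 40 bp contig, a SNP at 1-based position 11 (A in Col-0, G in Can-0).
fixture_sam_lines <- function() {
  ref <- "ACGTACGTACATGCATGCATGCATACGTACGTACGTACGT"
  alt <- sub("^(.{10})A", "\\1G", ref)
  mk <- function(qname, pos, seq, rg) {
    paste(qname, 0L, "ctgA", pos, 60L, paste0(nchar(seq), "M"), "*", 0L, 0L,
          seq, paste(rep("I", nchar(seq)), collapse = ""),
          paste0("RG:Z:", rg), sep = "\t")
  }
  c("@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:ctgA\tLN:40",
    "@RG\tID:Col-0\tSM:Col-0",
    "@RG\tID:Can-0\tSM:Can-0",
    mk("r1", 1, substr(ref, 1, 20), "Col-0"),
    mk("r2", 5, substr(ref, 5, 24), "Col-0"),
    mk("r3", 9, substr(ref, 9, 28), "Col-0"),
    mk("r4", 1, substr(alt, 1, 20), "Can-0"),
    mk("r5", 5, substr(alt, 5, 24), "Can-0"),
    mk("r6", 9, substr(alt, 9, 28), "Can-0"))
}

write_fixture_sam <- function(path = tempfile(fileext = ".sam")) {
  writeLines(fixture_sam_lines(), path)
  path
}

# Independent brute-force oracle: minimal number of classes in any partition
# of the matrix rows such that every class is pairwise conflict-free (two
# rows conflict iff they disagree at a mutually covered site; disjoint rows
# are allowed to share a class). Exhaustive recursion over set partitions.
brute_force_min_classes <- function(mat) {
  n <- nrow(mat)
  if (n == 0L) return(0L)
  conflict <- matrix(FALSE, n, n)
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      sh <- !is.na(mat[a, ]) & !is.na(mat[b, ])
      conflict[a, b] <- conflict[b, a] <-
        any(sh) && any(mat[a, sh] != mat[b, sh])
    }
  }
  best <- n
  recurse <- function(i, classes) {
    if (length(classes) >= best) return()
    if (i > n) { best <<- min(best, length(classes)); return() }
    for (k in seq_along(classes)) {
      if (!any(conflict[i, classes[[k]]])) {
        classes[[k]] <- c(classes[[k]], i)
        recurse(i + 1L, classes)
        classes[[k]] <- classes[[k]][-length(classes[[k]])]
      }
    }
    recurse(i + 1L, c(classes, list(i)))
  }
  recurse(1L, list())
  best
}

# Random allele matrix with missing cells for oracle comparisons.
random_allele_matrix <- function(n_frag, n_sites, p_missing = 0.35) {
  alleles <- c("A", "C", "G", "T")
  m <- matrix(sample(alleles, n_frag * n_sites, replace = TRUE),
              nrow = n_frag,
              dimnames = list(sprintf("f%02d", seq_len(n_frag)),
                              as.character(seq_len(n_sites) - 1L)))
  miss <- matrix(stats::runif(n_frag * n_sites) < p_missing, nrow = n_frag)
  m[miss] <- NA_character_
  m[rowSums(!is.na(m)) > 0L, , drop = FALSE]
}
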