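# Filter 1 (potential SNPs by minimum read support) and filter 2
# (high-confidence SNPs by base quality, with homopolymer and read-end
# masking).

ALLELE_BASES <- c("A", "C", "G", "T", "-")

#' Per-column allele counts of a contig
#'
#' Counts, per contig column, how many reads carry each of `A,C,G,T,-`.
#' `N` bases are excluded; a gap (`-`, deletion relative to the contig) is
#' counted as an allele. Each read contributes at most one base per column.
#'
#' @param contig A `hapsnp_contig`.
#' @param masks Optional list of per-read logical quality masks (as returned
#'   by [build_quality_mask()]); when given, masked bases are excluded, i.e.
#'   the result is the high-quality pileup.
#' @return An integer matrix with rows `A,C,G,T,-` and one column per contig
#'   position; attribute `coverage` holds the per-column number of
#'   contributing reads (reads with a counted base at the column).
#' @export
pileup <- function(contig, masks = NULL) {
  L <- contig$length
  m <- matrix(0L, nrow = 5L, ncol = L, dimnames = list(ALLELE_BASES, NULL))
  rd <- contig$reads
  for (i in seq_len(nrow(rd))) {
    chars <- split_bases(rd$bases[i])
    code <- match(chars, ALLELE_BASES)
    keep <- !is.na(code)
    if (!is.null(masks)) keep <- keep & masks[[i]]
    if (!any(keep)) next
    idx <- cbind(code[keep], rd$start[i] + which(keep))
    m[idx] <- m[idx] + 1L
  }
  attr(m, "coverage") <- colSums(m)
  m
}

# Per-column allele support threshold as an integer vector of length L.
# coverage: per-column covering-read counts (basis for fraction mode).
support_threshold <- function(cfg, coverage, n_reads_contig) {
  basis <- if (cfg$fraction_basis == "contig") {
    rep(n_reads_contig, length(coverage))
  } else {
    coverage
  }
  frac_t <- pmax(1L, as.integer(ceiling(cfg$min_allele_fraction * basis)))
  abs_t <- rep(max(1L, cfg$min_allele_reads), length(coverage))
  switch(cfg$threshold_mode,
         absolute = abs_t,
         fraction = frac_t,
         both_or = pmin(abs_t, frac_t))
}

# Named nonzero allele counts for one pileup column.
column_counts <- function(pile, col) {
  v <- pile[, col]
  v[v > 0L]
}

#' Detect potential SNPs (filter 1)
#'
#' A column is a potential SNP iff at least two distinct alleles each meet the
#' read-support threshold. In `"absolute"` mode the threshold is
#' `min_allele_reads`; in `"fraction"` mode it is
#' `ceiling(min_allele_fraction * covering reads)` (never below 1 read); in
#' `"both_or"` mode an allele passes if it meets either threshold.
#'
#' @param contig A `hapsnp_contig`.
#' @param cfg A [filter_config()].
#' @param pile Optional precomputed [pileup()] of the contig.
#' @return A data.frame of sites sorted by position: columns `contig_id`,
#'   `pos` (0-based), `status` (`"potential"`), `reason`, and list-column
#'   `counts` (named nonzero allele counts).
#' @export
detect_potential_snps <- function(contig, cfg, pile = NULL) {
  if (is.null(pile)) pile <- pileup(contig)
  L <- contig$length
  cov <- column_coverage(contig)
  thr <- support_threshold(cfg, cov, nrow(contig$reads))
  pass <- sweep(pile, 2L, thr, ">=") & pile > 0L
  n_pass <- colSums(pass)
  cols <- which(n_pass >= 2L)
  sites <- data.frame(contig_id = rep(contig$contig_id, length(cols)),
                      pos = cols - 1L,
                      status = rep("potential", length(cols)),
                      reason = rep(NA_character_, length(cols)),
                      stringsAsFactors = FALSE)
  sites$counts <- lapply(cols, function(cc) column_counts(pile, cc))
  sites
}

#' Build the per-read quality mask (filter 2 preparation)
#'
#' A base is high quality iff its Phred score is at least
#' `phred_high_quality` (bases without a quality, including all reads lacking
#' qualities and gap columns, are assumed high quality), it does not fall in
#' the first `mask_5prime` / last `mask_3prime` bases of the read in
#' sequencing orientation (for reverse-strand reads the 5' end is the right
#' end of the aligned sequence), and — when `mask_homopolymer` is on — it is
#' not inside or immediately adjacent to a run of `homopolymer_min_run` or
#' more identical bases in the read's own sequence. A run truncated by the
#' read boundary has unknown true length and is conservatively treated as
#' homopolymeric (so recurrent overcall errors at run edges cannot leak in
#' through reads that start or end inside the run).
#'
#' @param bases Aligned bases of the read (string, contig coordinates).
#' @param quals Integer Phred vector (`NA` allowed) or `NULL` when absent.
#' @param is_reverse Whether the read aligned to the reverse strand.
#' @param cfg A [filter_config()].
#' @return Logical vector, `TRUE` = base counts as high quality.
#' @export
build_quality_mask <- function(bases, quals, is_reverse, cfg) {
  n <- nchar(bases)
  hq <- rep(TRUE, n)
  if (!is.null(quals)) {
    low <- !is.na(quals) & quals < cfg$phred_high_quality
    hq[low] <- FALSE
  }
  left <- if (is_reverse) cfg$mask_3prime else cfg$mask_5prime
  right <- if (is_reverse) cfg$mask_5prime else cfg$mask_3prime
  if (left > 0L) hq[seq_len(min(left, n))] <- FALSE
  if (right > 0L && n > 0L) hq[seq(max(1L, n - right + 1L), n)] <- FALSE
  if (cfg$mask_homopolymer && n > 0L) {
    chars <- split_bases(bases)
    r <- rle(chars)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    # a run truncated by the read boundary has unknown true length and is
    # conservatively treated as homopolymeric
    run <- r$values %in% c("A", "C", "G", "T") &
      (r$lengths >= cfg$homopolymer_min_run | starts == 1L | ends == n)
    for (k in which(run)) {
      lo <- max(1L, starts[k] - 1L)
      hi <- min(n, ends[k] + 1L)
      hq[lo:hi] <- FALSE
    }
  }
  hq
}

# Masks for every read of a contig, in read-row order.
contig_quality_masks <- function(contig, cfg) {
  rd <- contig$reads
  lapply(seq_len(nrow(rd)), function(i) {
    build_quality_mask(rd$bases[i], rd$quals[[i]], rd$is_reverse[i], cfg)
  })
}

#' Quality filter on potential SNPs (filter 2)
#'
#' Recomputes allele support using only high-quality, unmasked bases. A site
#' stays iff at least two alleles meet the support threshold among
#' high-quality bases (status `"high_confidence"`); otherwise it is demoted to
#' `"rejected_quality"`.
#'
#' @param sites Potential sites from [detect_potential_snps()].
#' @param contig A `hapsnp_contig`.
#' @param cfg A [filter_config()].
#' @param masks Per-read masks from [build_quality_mask()]; computed when
#'   `NULL`.
#' @param hq_pile Optional precomputed high-quality pileup.
#' @return `sites` with updated `status` and an added `hq_counts` list-column.
#' @export
filter_high_confidence <- function(sites, contig, cfg, masks = NULL,
                                   hq_pile = NULL) {
  if (is.null(masks)) masks <- contig_quality_masks(contig, cfg)
  if (is.null(hq_pile)) hq_pile <- pileup(contig, masks = masks)
  hq_cov <- attr(hq_pile, "coverage")
  thr <- support_threshold(cfg, hq_cov, nrow(contig$reads))
  sites$hq_counts <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    cc <- sites$pos[i] + 1L
    hq <- column_counts(hq_pile, cc)
    sites$hq_counts[[i]] <- hq
    if (sum(hq >= thr[cc]) >= 2L) {
      sites$status[i] <- "high_confidence"
    } else {
      sites$status[i] <- "rejected_quality"
      sites$reason[i] <- "low_quality_support"
    }
  }
  sites
}
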