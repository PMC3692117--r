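# End-to-end SNP calling: alignment -> filter 1 -> filter 2 -> haplotyping
# (filter 3) -> genotyping -> results tables. The filters are applied in this
# order so that haplotypes are built from high-confidence SNPs only.

#' Call reliable SNPs from an alignment
#'
#' Runs the three-filter SNP-calling procedure on every contig: (1) columns
#' where at least two alleles each reach the read-support threshold become
#' potential SNPs; (2) support is recomputed over high-quality bases only
#' (Phred cutoff plus optional homopolymer and read-end masking), leaving the
#' high-confidence SNPs; (3) read fragments are clustered into haplotypes over
#' the high-confidence sites, and only variants whose alleles are each backed
#' by a retained haplotype are reported as reliable SNPs. Samples are
#' genotyped from their read groups at the reliable sites.
#'
#' @param x A `hapsnp_alignment`, or a path to a SAM/BAM or ACE file.
#' @param cfg A [filter_config()].
#' @param format Input format when `x` is a path: `"auto"` (by extension and
#'   content), `"sam"`, or `"ace"`.
#' @param reference Optional FASTA with contig sequences (SAM input only).
#' @param readgroup_mode,name_pattern Passed to [read_sam()]/[read_ace()].
#' @param keep_intermediate Attach per-contig internals (all candidate sites
#'   with their filter status, the allele matrix, haplotype objects, masks) as
#'   attribute `"details"` — useful for inspection and testing.
#' @param input_label Input path recorded in the run configuration (filled
#'   automatically when `x` is a path).
#' @return A `hapsnp_results` object: a list of data.frames `contigs`,
#'   `snps` (reliable SNPs, 1-based positions), `haplotypes`, `genotypes`,
#'   and `config` (key/value). Serializable with [write_results()].
#' @export
call_snps <- function(x, cfg = filter_config(), format = c("auto", "sam", "ace"),
                      reference = NULL,
                      readgroup_mode = NULL, name_pattern = "\\|",
                      keep_intermediate = FALSE, input_label = "") {
  format <- match.arg(format)
  if (is.character(x) && length(x) == 1L) {
    input_label <- x
    fmt <- if (format == "auto") sniff_format(x) else format
    x <- if (fmt == "ace") {
      read_ace(x, readgroup_mode = if (is.null(readgroup_mode)) "name_pattern"
               else match.arg(readgroup_mode, c("name_pattern", "none")),
               name_pattern = name_pattern)
    } else {
      read_sam(x, readgroup_mode = if (is.null(readgroup_mode)) "rg_tag"
               else match.arg(readgroup_mode, c("rg_tag", "name_pattern", "none")),
               name_pattern = name_pattern, reference = reference)
    }
  }
  stopifnot(inherits(x, "hapsnp_alignment"))
  samples <- x$samples

  contig_rows <- list(); snp_rows <- list(); hap_rows <- list()
  gt_rows <- list(); details <- list()
  for (ctg in x$contigs) {
    res <- call_snps_contig(ctg, cfg, samples)
    contig_rows[[ctg$contig_id]] <- res$contig_row
    snp_rows[[ctg$contig_id]] <- res$snp_rows
    hap_rows[[ctg$contig_id]] <- res$hap_rows
    gt_rows[[ctg$contig_id]] <- res$gt_rows
    if (keep_intermediate) details[[ctg$contig_id]] <- res$internals
  }
  schemas <- result_schemas()
  bind <- function(rows, schema) {
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0) {
      df <- as.data.frame(lapply(schema, function(t) {
        switch(t, integer = integer(0), logical = logical(0), character(0))
      }), stringsAsFactors = FALSE)
      names(df) <- names(schema)
      return(df)
    }
    do.call(rbind, rows)
  }
  results <- structure(list(
    contigs = bind(contig_rows, schemas$contigs),
    snps = bind(snp_rows, schemas$snps),
    haplotypes = bind(hap_rows, schemas$haplotypes),
    genotypes = bind(gt_rows, schemas$genotypes),
    config = config_to_df(cfg, extra = list(
      input = input_label,
      source_format = x$source_format,
      samples = paste(samples, collapse = ";")))
  ), class = "hapsnp_results")
  rownames(results$contigs) <- NULL
  rownames(results$snps) <- NULL
  rownames(results$haplotypes) <- NULL
  rownames(results$genotypes) <- NULL
  if (keep_intermediate) attr(results, "details") <- details
  results
}

# Guess alignment format from extension, falling back to content sniffing.
sniff_format <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("sam", "bam")) return("sam")
  if (ext == "ace") return("ace")
  if (is_binary_alignment(path)) return("sam")
  head <- readLines(path, n = 5L, warn = FALSE)
  if (any(grepl("^(AS|CO) ", head))) return("ace")
  if (any(startsWith(head, "@")) || any(grepl("\t", head, fixed = TRUE))) {
    return("sam")
  }
  stop("cannot determine alignment format of ", path,
       " (expected SAM/BAM or ACE)")
}

# One contig through all three filters plus genotyping; returns results rows
# and the internals.
call_snps_contig <- function(ctg, cfg, samples) {
  masks <- contig_quality_masks(ctg, cfg)
  pile <- pileup(ctg)
  sites <- detect_potential_snps(ctg, cfg, pile = pile)
  n_potential <- nrow(sites)
  sites <- filter_high_confidence(sites, ctg, cfg, masks = masks)
  hc <- sites[sites$status == "high_confidence", , drop = FALSE]
  mat <- build_allele_matrix(ctg, hc, masks)
  clus <- cluster_haplotypes(mat, cfg)
  hc_marked <- mark_reliable_snps(hc, clus$haplotypes)
  sites$status[match(hc_marked$pos, sites$pos)] <- hc_marked$status
  sites$reason[match(hc_marked$pos, sites$pos)] <- hc_marked$reason
  rel <- hc_marked[hc_marked$status == "reliable", , drop = FALSE]
  summ <- summarize_haplotypes(clus$haplotypes, rel)
  gt <- sample_allele_table(ctg, rel, samples, cfg, masks = masks)

  cons_chars <- split_bases(ctg$consensus)
  snp_rows <- if (nrow(rel) > 0) {
    data.frame(
      contig_id = rel$contig_id,
      position = rel$pos + 1L,
      ref_allele = cons_chars[rel$pos + 1L],
      alleles = vapply(rel$hq_counts, function(cc) {
        cc <- cc[order(-cc, names(cc), method = "radix")]
        paste(names(cc), collapse = "/")
      }, character(1)),
      allele_counts = vapply(rel$counts, counts_to_string, character(1)),
      hq_allele_counts = vapply(rel$hq_counts, counts_to_string, character(1)),
      n_haplotypes = unname(summ$per_site_haplotype_count[as.character(rel$pos)]),
      indel_flag = vapply(rel$hq_counts, function(cc) "-" %in% names(cc),
                          logical(1)),
      status = rel$status,
      stringsAsFactors = FALSE)
  } else NULL

  site_keys <- as.character(hc$pos)
  hap_rows <- if (length(clus$haplotypes) > 0) {
    do.call(rbind, lapply(clus$haplotypes, function(h) {
      a <- h$alleles[site_keys]
      data.frame(contig_id = ctg$contig_id, haplotype_id = h$haplotype_id,
                 support = h$support, n_sites = sum(!is.na(a)),
                 alleles = paste(ifelse(is.na(a), ".", a), collapse = ""),
                 fragments = paste(h$fragments, collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
  } else NULL

  gt_rows <- if (nrow(gt) > 0) {
    data.frame(contig_id = gt$contig_id, position = gt$pos + 1L,
               sample = gt$sample,
               allele_counts = vapply(gt$counts, counts_to_string, character(1)),
               call = gt$call, stringsAsFactors = FALSE)
  } else NULL

  n_samples_with_data <- if (nrow(gt) > 0) {
    length(unique(gt$sample[gt$call != "no_data"]))
  } else 0L

  contig_row <- data.frame(
    contig_id = ctg$contig_id, length = ctg$length,
    n_reads = nrow(ctg$reads),
    n_potential_snps = n_potential,
    n_high_confidence_snps = nrow(hc),
    n_reliable_snps = nrow(rel),
    n_haplotypes = summ$n_haplotypes,
    corrected_haplotype_count = summ$corrected_count,
    n_samples_with_data = n_samples_with_data,
    consensus = ctg$consensus,
    stringsAsFactors = FALSE)

  list(contig_row = contig_row, snp_rows = snp_rows, hap_rows = hap_rows,
       gt_rows = gt_rows,
       internals = list(sites = sites, allele_matrix = mat,
                        haplotypes = clus$haplotypes,
                        unassigned = clus$unassigned, masks = masks,
                        summary = summ))
}
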