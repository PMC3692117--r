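# Per-sample allele table at reliable SNP sites: the basis for
# genotyping-by-sequencing comparisons between accessions/strains.

#' Per-sample allele table at reliable sites
#'
#' For every reliable SNP and every sample (read group), counts the sample's
#' unmasked high-quality bases per allele and produces a summary call:
#' a single allele with at least `min_allele_reads` supporting reads gives a
#' single-allele call, two or more such alleles give a multi-allele call
#' (e.g. `"A/G"`), a covered site below threshold is flagged
#' `"low_coverage"`, and a sample with no counted base at the site is
#' `"no_data"`.
#'
#' @param contig A `hapsnp_contig`.
#' @param sites Reliable sites data.frame (0-based `pos`).
#' @param samples Character vector of sample labels (table columns).
#' @param cfg A [filter_config()].
#' @param masks Per-read quality masks.
#' @return Data.frame with one row per (site, sample): `contig_id`, `pos`
#'   (0-based), `sample`, `call`, and list-column `counts` (named allele
#'   counts). Summing `counts` over samples reproduces the site's high-quality
#'   allele counts.
#' @export
sample_allele_table <- function(contig, sites, samples, cfg, masks = NULL) {
  if (is.null(masks)) masks <- contig_quality_masks(contig, cfg)
  calls <- site_base_calls(contig, sites$pos, masks)
  rd <- contig$reads
  out <- vector("list", nrow(sites) * length(samples))
  k <- 0L
  for (i in seq_len(nrow(sites))) {
    at_site <- calls[calls$site_idx == i, , drop = FALSE]
    by_sample <- split(at_site$base, rd$sample[at_site$read_row])
    for (s in samples) {
      bases <- by_sample[[s]]
      counts <- if (is.null(bases)) integer(0) else {
        tb <- table(bases)
        v <- as.integer(tb)
        names(v) <- names(tb)
        v[order(-v, names(v), method = "radix")]
      }
      call <- if (length(counts) == 0L) {
        "no_data"
      } else {
        passing <- names(counts)[counts >= cfg$min_allele_reads]
        if (length(passing) == 0L) "low_coverage"
        else paste(passing, collapse = "/")
      }
      k <- k + 1L
      out[[k]] <- list(contig_id = contig$contig_id, pos = sites$pos[i],
                       sample = s, call = call, counts = counts)
    }
  }
  res <- data.frame(
    contig_id = vapply(out, `[[`, character(1), "contig_id"),
    pos = vapply(out, `[[`, integer(1), "pos"),
    sample = vapply(out, `[[`, character(1), "sample"),
    call = vapply(out, `[[`, character(1), "call"),
    stringsAsFactors = FALSE)
  res$counts <- lapply(out, `[[`, "counts")
  if (k == 0L) {
    res <- data.frame(contig_id = character(0), pos = integer(0),
                      sample = character(0), call = character(0),
                      stringsAsFactors = FALSE)
    res$counts <- list()
  }
  res
}
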