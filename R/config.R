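#' Filter configuration for haplotype-based SNP calling
#'
#' Bundles every user-tunable threshold of the three SNP filters plus the
#' marker-export options. All downstream functions take a `hapsnp_config`.
#'
#' @param min_allele_reads Minimum number of reads supporting an allele for it
#'   to count towards a potential SNP (absolute threshold mode). Default 2.
#' @param min_allele_fraction Minimum fraction of covering reads supporting an
#'   allele (fraction threshold mode), in `[0, 1]`. Default 0.
#' @param threshold_mode One of `"absolute"`, `"fraction"`, `"both_or"`.
#'   `"both_or"` accepts an allele that meets either threshold.
#' @param phred_high_quality Phred cutoff: a base with quality below this is
#'   not counted as high quality. Default 20 (~1% call-error probability).
#' @param mask_homopolymer If `TRUE`, bases inside or adjacent to a
#'   homopolymer run of length >= `homopolymer_min_run` in the read's own
#'   sequence are treated as low quality (pyrosequencing-style error
#'   hotspots). Default `FALSE`.
#' @param homopolymer_min_run Minimum run length that triggers homopolymer
#'   masking. Default 3.
#' @param mask_5prime,mask_3prime Number of bases at the read's 5'/3' end
#'   (in sequencing orientation) treated as low quality, e.g. to suppress
#'   false SNPs from incomplete adaptor trimming. Default 0.
#' @param min_haplotype_reads Minimum number of fragments supporting a
#'   haplotype for it to be retained. Default 2.
#' @param flank_length Flanking sequence length for marker export (bp).
#'   Default 60.
#' @param fraction_basis Basis for the fraction threshold: `"column"`
#'   (reads covering the column, the default) or `"contig"` (all reads of the
#'   contig).
#' @param expected_ploidy_haplotypes Maximum expected number of haplotypes per
#'   contig (2 for a diploid); contigs exceeding it get the paralog flag on
#'   marker export. Default 2.
#'
#' @return An object of class `hapsnp_config` (a named list with all values
#'   materialized).
#' @export
filter_config <- function(min_allele_reads = 2L,
                          min_allele_fraction = 0,
                          threshold_mode = c("absolute", "fraction", "both_or"),
                          phred_high_quality = 20L,
                          mask_homopolymer = FALSE,
                          homopolymer_min_run = 3L,
                          mask_5prime = 0L,
                          mask_3prime = 0L,
                          min_haplotype_reads = 2L,
                          flank_length = 60L,
                          fraction_basis = c("column", "contig"),
                          expected_ploidy_haplotypes = 2L) {
  threshold_mode <- match.arg(threshold_mode)
  fraction_basis <- match.arg(fraction_basis)
  cfg <- list(
    min_allele_reads = as.integer(min_allele_reads),
    min_allele_fraction = as.numeric(min_allele_fraction),
    threshold_mode = threshold_mode,
    phred_high_quality = as.integer(phred_high_quality),
    mask_homopolymer = isTRUE(mask_homopolymer),
    homopolymer_min_run = as.integer(homopolymer_min_run),
    mask_5prime = as.integer(mask_5prime),
    mask_3prime = as.integer(mask_3prime),
    min_haplotype_reads = as.integer(min_haplotype_reads),
    flank_length = as.integer(flank_length),
    fraction_basis = fraction_basis,
    expected_ploidy_haplotypes = as.integer(expected_ploidy_haplotypes)
  )
  ints <- c("min_allele_reads", "phred_high_quality", "homopolymer_min_run",
            "mask_5prime", "mask_3prime", "min_haplotype_reads",
            "flank_length", "expected_ploidy_haplotypes")
  for (f in ints) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L) {
      stop("filter_config: '", f, "' must be a non-negative integer")
    }
  }
  if (cfg$min_allele_reads < 1L) {
    stop("filter_config: 'min_allele_reads' must be >= 1")
  }
  if (is.na(cfg$min_allele_fraction) || cfg$min_allele_fraction < 0 ||
      cfg$min_allele_fraction > 1) {
    stop("filter_config: 'min_allele_fraction' must be in [0, 1]")
  }
  structure(cfg, class = "hapsnp_config")
}

#' @export
print.hapsnp_config <- function(x, ...) {
  cat("hapsnp filter configuration:\n")
  for (k in names(x)) cat(sprintf("  %-27s %s\n", k, format(x[[k]])))
  invisible(x)
}

# Serialize a config (plus extra run metadata) to a key/value data.frame.
config_to_df <- function(cfg, extra = list()) {
  vals <- c(lapply(unclass(cfg), function(v) as.character(v)), lapply(extra, as.character))
  data.frame(key = names(vals), value = unlist(vals, use.names = FALSE),
             stringsAsFactors = FALSE)
}

# Rebuild a hapsnp_config from the key/value data.frame written by
# config_to_df(); unknown keys ignored.
config_from_df <- function(df) {
  get <- function(k, default = NULL) {
    i <- match(k, df$key)
    if (is.na(i)) default else df$value[i]
  }
  filter_config(
    min_allele_reads = as.integer(get("min_allele_reads", 2L)),
    min_allele_fraction = as.numeric(get("min_allele_fraction", 0)),
    threshold_mode = get("threshold_mode", "absolute"),
    phred_high_quality = as.integer(get("phred_high_quality", 20L)),
    mask_homopolymer = as.logical(get("mask_homopolymer", FALSE)),
    homopolymer_min_run = as.integer(get("homopolymer_min_run", 3L)),
    mask_5prime = as.integer(get("mask_5prime", 0L)),
    mask_3prime = as.integer(get("mask_3prime", 0L)),
    min_haplotype_reads = as.integer(get("min_haplotype_reads", 2L)),
    flank_length = as.integer(get("flank_length", 60L)),
    fraction_basis = get("fraction_basis", "column"),
    expected_ploidy_haplotypes = as.integer(get("expected_ploidy_haplotypes", 2L))
  )
}
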