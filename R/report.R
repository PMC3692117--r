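# Persist and reload results as structured CSV text, filter the contig
# summary table, and export marker SNPs with flanking sequence.

RESULT_FILES <- c(contigs = "contigs.csv", snps = "snps.csv",
                  haplotypes = "haplotypes.csv", genotypes = "genotypes.csv",
                  config = "run_config.csv")
SCHEMA_VERSION <- "1"

# "A=12;G=9" <-> named integer vector (sorted by count desc, then allele).
counts_to_string <- function(counts) {
  if (length(counts) == 0L) return("")
  counts <- counts[order(-counts, names(counts), method = "radix")]
  paste(paste0(names(counts), "=", counts), collapse = ";")
}

string_to_counts <- function(s) {
  if (is.na(s) || s == "") return(stats::setNames(integer(0), character(0)))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) as.integer(x[2]), integer(1)),
                  vapply(kv, `[[`, character(1), 1))
}

result_schemas <- function() {
  list(
    contigs = c(contig_id = "character", length = "integer",
                n_reads = "integer", n_potential_snps = "integer",
                n_high_confidence_snps = "integer",
                n_reliable_snps = "integer", n_haplotypes = "integer",
                corrected_haplotype_count = "integer",
                n_samples_with_data = "integer", consensus = "character"),
    snps = c(contig_id = "character", position = "integer",
             ref_allele = "character", alleles = "character",
             allele_counts = "character", hq_allele_counts = "character",
             n_haplotypes = "integer", indel_flag = "logical",
             status = "character"),
    haplotypes = c(contig_id = "character", haplotype_id = "integer",
                   support = "integer", n_sites = "integer",
                   alleles = "character", fragments = "character"),
    genotypes = c(contig_id = "character", position = "integer",
                  sample = "character", allele_counts = "character",
                  call = "character"),
    config = c(key = "character", value = "character")
  )
}

#' Write results to a directory of CSV files
#'
#' Produces a deterministic file set — `contigs.csv`, `snps.csv`,
#' `haplotypes.csv`, `genotypes.csv`, `run_config.csv` — with RFC 4180
#' quoting and stable column order, plus `manifest.csv` recording the tool
#' version, schema version and a hash of the run configuration. Output
#' positions are 1-based. Writing is refused up front when the directory is
#' not writable, so no partial file set remains.
#'
#' @param results A `hapsnp_results` object (see [call_snps()]).
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(results, out_dir) {
  stopifnot(inherits(results, "hapsnp_results"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("write_results: cannot create directory: ", out_dir)
  }
  probe <- file.path(out_dir, ".write-probe")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("write_results: directory not writable: ", out_dir)
  unlink(probe)

  written <- character(0)
  on.exit({
    if (!is.null(attr(written, "failed"))) unlink(written)
  })
  for (nm in names(RESULT_FILES)) {
    f <- file.path(out_dir, RESULT_FILES[[nm]])
    utils::write.csv(results[[nm]], f, row.names = FALSE, quote = TRUE,
                     na = "")
    written <- c(written, f)
  }
  cfg_hash <- unname(tools::md5sum(file.path(out_dir, "run_config.csv")))
  manifest <- data.frame(
    key = c("tool", "version", "schema_version", "config_hash"),
    value = c("hapsnp", as.character(utils::packageVersion("hapsnp")),
              SCHEMA_VERSION, cfg_hash),
    stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = TRUE, na = "")
  invisible(out_dir)
}

read_result_csv <- function(path, schema) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!identical(names(df), names(schema))) {
    stop("results schema mismatch in ", basename(path),
         " (schema version ", SCHEMA_VERSION, "): expected columns ",
         paste(names(schema), collapse = ","))
  }
  for (j in seq_along(schema)) {
    df[[j]] <- switch(schema[[j]],
                      integer = as.integer(df[[j]]),
                      logical = as.logical(df[[j]]),
                      df[[j]])
  }
  df
}

#' Reload results written by [write_results()]
#'
#' @param dir Directory containing the CSV file set and manifest.
#' @return A `hapsnp_results` equal in value to the object that produced the
#'   files. A config-hash mismatch between the manifest and `run_config.csv`
#'   raises a warning; a missing file or schema mismatch is an error.
#' @export
read_results <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stop("read_results: missing manifest.csv in ", dir)
  manifest <- utils::read.csv(man_path, stringsAsFactors = FALSE,
                              colClasses = "character")
  get <- function(k) manifest$value[match(k, manifest$key)]
  if (!is.na(get("schema_version")) && get("schema_version") != SCHEMA_VERSION) {
    stop("read_results: results were written with schema version ",
         get("schema_version"), " but this package reads version ",
         SCHEMA_VERSION)
  }
  schemas <- result_schemas()
  out <- list()
  for (nm in names(RESULT_FILES)) {
    f <- file.path(dir, RESULT_FILES[[nm]])
    if (!file.exists(f)) stop("read_results: missing file: ", RESULT_FILES[[nm]])
    out[[nm]] <- read_result_csv(f, schemas[[nm]])
  }
  hash_now <- unname(tools::md5sum(file.path(dir, "run_config.csv")))
  if (!is.na(get("config_hash")) && hash_now != get("config_hash")) {
    warning("read_results: run_config.csv does not match the manifest ",
            "config hash; files may have been edited")
  }
  structure(out, class = "hapsnp_results")
}

#' Filter the contig summary table
#'
#' Conjunctive filtering on read, SNP and haplotype counts (inclusive bounds)
#' and a case-insensitive contig-name substring. A pure function: the output
#' is an order-preserving subset of the input.
#'
#' @param rows Contig summary data.frame (the `contigs` results table).
#' @param min_reads,max_reads,min_snps,max_snps,min_haplotypes,max_haplotypes
#'   Inclusive bounds (NULL = unconstrained). Haplotype bounds apply to the
#'   corrected haplotype count.
#' @param name_substring Case-insensitive substring of `contig_id` (NULL =
#'   unconstrained).
#' @return The filtered data.frame.
#' @export
filter_contig_table <- function(rows, min_reads = NULL, max_reads = NULL,
                                min_snps = NULL, max_snps = NULL,
                                min_haplotypes = NULL, max_haplotypes = NULL,
                                name_substring = NULL) {
  chk <- function(lo, hi, what) {
    if (!is.null(lo) && !is.null(hi) && lo > hi) {
      stop("filter_contig_table: min ", what, " (", lo,
           ") exceeds max ", what, " (", hi, ")")
    }
  }
  chk(min_reads, max_reads, "reads")
  chk(min_snps, max_snps, "snps")
  chk(min_haplotypes, max_haplotypes, "haplotypes")
  keep <- rep(TRUE, nrow(rows))
  if (!is.null(min_reads)) keep <- keep & rows$n_reads >= min_reads
  if (!is.null(max_reads)) keep <- keep & rows$n_reads <= max_reads
  if (!is.null(min_snps)) keep <- keep & rows$n_reliable_snps >= min_snps
  if (!is.null(max_snps)) keep <- keep & rows$n_reliable_snps <= max_snps
  if (!is.null(min_haplotypes)) {
    keep <- keep & rows$corrected_haplotype_count >= min_haplotypes
  }
  if (!is.null(max_haplotypes)) {
    keep <- keep & rows$corrected_haplotype_count <= max_haplotypes
  }
  if (!is.null(name_substring)) {
    keep <- keep & grepl(tolower(name_substring), tolower(rows$contig_id),
                         fixed = TRUE)
  }
  rows[keep, , drop = FALSE]
}

IUPAC_CODES <- c("AC" = "M", "AG" = "R", "AT" = "W",
                 "CG" = "S", "CT" = "Y", "GT" = "K",
                 "ACG" = "V", "ACT" = "H", "AGT" = "D", "CGT" = "B",
                 "ACGT" = "N")

#' Export marker SNPs with flanking sequence
#'
#' For SNP-array/assay design: each selected reliable site is exported with
#' 5' and 3' flanking consensus sequence of the requested length (truncated at
#' contig edges, never padded) and a context string with the SNP in bracket
#' notation (`...[A/G]...`) or, optionally, as an IUPAC ambiguity code. A
#' contig whose corrected haplotype count exceeds the expected maximum (2 for
#' a diploid) gets `paralog_flag = TRUE`: such contigs may mix paralogous
#' sequences and are poor marker sources.
#'
#' @param results A `hapsnp_results`.
#' @param sites Optional data.frame with columns `contig_id`, `position`
#'   (1-based, matching the `snps` table) selecting sites to export; `NULL`
#'   exports every reliable site. Selecting a site that is not a reliable SNP
#'   is an error.
#' @param flank_length Flank length in bp; default from the run config.
#' @param expected_haplotypes Expected maximum haplotype count; default from
#'   the run config (`expected_ploidy_haplotypes`).
#' @param iupac Use IUPAC ambiguity codes in the context string where possible
#'   (sites with a gap allele fall back to bracket notation).
#' @param path Optional CSV output file.
#' @return Data.frame of marker records: `contig`, `position_1based`,
#'   `ref_allele`, `alt_alleles`, `flank5`, `flank3`, `context`,
#'   `haplotype_count`, `paralog_flag`.
#' @export
export_markers <- function(results, sites = NULL, flank_length = NULL,
                           expected_haplotypes = NULL, iupac = FALSE,
                           path = NULL) {
  stopifnot(inherits(results, "hapsnp_results"))
  cfg <- config_from_df(results$config)
  if (is.null(flank_length)) flank_length <- cfg$flank_length
  if (is.null(expected_haplotypes)) {
    expected_haplotypes <- cfg$expected_ploidy_haplotypes
  }
  snps <- results$snps
  snps <- snps[snps$status == "reliable", , drop = FALSE]
  if (!is.null(sites)) {
    want <- paste(sites$contig_id, sites$position)
    have <- paste(snps$contig_id, snps$position)
    missing <- setdiff(want, have)
    if (length(missing) > 0) {
      stop("export_markers: not reliable SNP site(s): ",
           paste(missing, collapse = "; "))
    }
    snps <- snps[match(want, have), , drop = FALSE]
  }
  ctg <- results$contigs
  rows <- vector("list", nrow(snps))
  for (i in seq_len(nrow(snps))) {
    ci <- match(snps$contig_id[i], ctg$contig_id)
    cons <- ctg$consensus[ci]
    pos1 <- snps$position[i]
    f5 <- substr(cons, max(1L, pos1 - flank_length), pos1 - 1L)
    f3 <- substr(cons, pos1 + 1L, min(nchar(cons), pos1 + flank_length))
    alleles <- strsplit(snps$alleles[i], "/", fixed = TRUE)[[1]]
    ref <- snps$ref_allele[i]
    alts <- setdiff(alleles, ref)
    ordered <- c(intersect(ref, alleles), alts)
    token <- paste0("[", paste(ordered, collapse = "/"), "]")
    if (iupac) {
      key <- paste(sort(ordered), collapse = "")
      if (!is.na(IUPAC_CODES[key])) token <- unname(IUPAC_CODES[key])
    }
    hapn <- ctg$corrected_haplotype_count[ci]
    rows[[i]] <- data.frame(
      contig = snps$contig_id[i], position_1based = pos1,
      ref_allele = ref, alt_alleles = paste(alts, collapse = "/"),
      flank5 = f5, flank3 = f3,
      context = paste0(f5, token, f3),
      haplotype_count = hapn,
      paralog_flag = hapn > expected_haplotypes,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    contig = character(0), position_1based = integer(0),
    ref_allele = character(0), alt_alleles = character(0),
    flank5 = character(0), flank3 = character(0), context = character(0),
    haplotype_count = integer(0), paralog_flag = logical(0),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  }
  out
}
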