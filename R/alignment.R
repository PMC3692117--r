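#' @keywords internal
"_PACKAGE"

DEFAULT_SAMPLE <- "default"

#' Construct a contig with its aligned reads
#'
#' A contig holds one aligned reference/assembled sequence (a transcript, in
#' RNA-seq use) together with the reads placed on it. Reads are stored in
#' contig coordinates after alignment gaps have been applied: insertions
#' relative to the contig are dropped from the column model, deletions appear
#' as `-` characters (which may form alleles).
#'
#' @param contig_id Contig identifier.
#' @param length Contig length in bp.
#' @param reads A data.frame with columns `read_id`, `fragment_id`, `start`
#'   (0-based offset on the contig), `bases` (string over `A,C,G,T,N,-` in
#'   contig coordinates), `quals` (list column of integer Phred vectors, with
#'   `NA` at gap columns, or `NULL` elements when qualities are absent),
#'   `sample` (sample label), `mate_id` (paired mate's read id or `NA`),
#'   `is_reverse` (logical).
#' @param consensus Consensus string over `A,C,G,T,N`; computed by majority
#'   vote ([compute_consensus()]) when `NULL`.
#' @return An object of class `hapsnp_contig`.
#' @export
new_contig <- function(contig_id, length, reads, consensus = NULL) {
  stopifnot(is.character(contig_id), length >= 0)
  reads <- as.data.frame(reads, stringsAsFactors = FALSE)
  needed <- c("read_id", "fragment_id", "start", "bases", "quals",
              "sample", "mate_id", "is_reverse")
  missing_cols <- setdiff(needed, names(reads))
  if (length(missing_cols) > 0) {
    stop("new_contig: reads missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(reads) > 0) {
    lens <- nchar(reads$bases)
    if (any(reads$start < 0L) || any(reads$start + lens > length)) {
      stop("new_contig: read span outside [0, contig length) on ", contig_id)
    }
    qlen_ok <- vapply(seq_len(nrow(reads)), function(i) {
      q <- reads$quals[[i]]
      is.null(q) || length(q) == lens[i]
    }, logical(1))
    if (!all(qlen_ok)) {
      stop("new_contig: base_qualities length mismatch on ", contig_id)
    }
  }
  ctg <- structure(list(contig_id = contig_id, length = as.integer(length),
                        consensus = consensus, reads = reads),
                   class = "hapsnp_contig")
  if (is.null(consensus)) ctg$consensus <- compute_consensus(ctg)
  ctg
}

#' @export
print.hapsnp_contig <- function(x, ...) {
  cat(sprintf("<hapsnp_contig> %s: %d bp, %d reads\n",
              x$contig_id, x$length, nrow(x$reads)))
  invisible(x)
}

#' Construct an alignment set
#'
#' @param contigs List of `hapsnp_contig` objects (unique ids).
#' @param source_format `"SAM"` or `"ACE"`.
#' @return An object of class `hapsnp_alignment`; `$samples` is the sorted
#'   union of read sample labels (reads without a label fall into the
#'   `"default"` sample).
#' @export
alignment_set <- function(contigs, source_format = c("SAM", "ACE")) {
  source_format <- match.arg(source_format)
  ids <- vapply(contigs, function(c) c$contig_id, character(1))
  if (anyDuplicated(ids)) stop("alignment_set: duplicated contig ids")
  names(contigs) <- ids
  samples <- sort(unique(unlist(lapply(contigs, function(c) c$reads$sample))))
  if (length(samples) == 0) samples <- character(0)
  structure(list(contigs = contigs, source_format = source_format,
                 samples = samples),
            class = "hapsnp_alignment")
}

#' @export
print.hapsnp_alignment <- function(x, ...) {
  cat(sprintf("<hapsnp_alignment> %s: %d contig(s), %d sample(s)\n",
              x$source_format, length(x$contigs), length(x$samples)))
  invisible(x)
}

# Split a base string into a character vector (single pass, used everywhere).
split_bases <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Majority-vote consensus of a contig
#'
#' Per column, the most frequent base among covering reads; ties broken
#' alphabetically (A < C < G < T); zero-coverage columns (or columns covered
#' only by `N`/gap bases) become `N`. Gaps and `N` do not vote.
#'
#' @param contig A `hapsnp_contig`.
#' @return Consensus string of length `contig$length`.
#' @export
compute_consensus <- function(contig) {
  L <- contig$length
  if (L == 0L) return("")
  votes <- matrix(0L, nrow = 4L, ncol = L)
  bases4 <- c("A", "C", "G", "T")
  rd <- contig$reads
  for (i in seq_len(nrow(rd))) {
    chars <- split_bases(rd$bases[i])
    code <- match(chars, bases4)
    keep <- !is.na(code)
    if (!any(keep)) next
    pos <- rd$start[i] + which(keep)  # 1-based columns
    idx <- cbind(code[keep], pos)
    votes[idx] <- votes[idx] + 1L
  }
  tot <- colSums(votes)
  best <- apply(votes, 2L, which.max)  # first max = alphabetical tie-break
  out <- bases4[best]
  out[tot == 0L] <- "N"
  paste(out, collapse = "")
}

# Per-column read coverage (number of reads whose span includes the column),
# via a difference array. Returns integer vector of length L.
column_coverage <- function(contig) {
  L <- contig$length
  d <- integer(L + 1L)
  rd <- contig$reads
  if (nrow(rd) > 0) {
    s <- rd$start + 1L
    e <- rd$start + nchar(rd$bases) + 1L
    for (i in seq_along(s)) {
      d[s[i]] <- d[s[i]] + 1L
      if (e[i] <= L + 1L) d[e[i]] <- d[e[i]] - 1L
    }
  }
  cumsum(d[seq_len(L)])
}
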