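# SAM/BAM input. Record decoding is delegated to Rsamtools; the projection of
# each read onto contig columns (CIGAR application) and read-group handling
# live here.

CIGAR_RE <- "([0-9]+)([MIDNSHP=X])"

# Apply a CIGAR string to SEQ/QUAL, producing bases in contig coordinates:
# M/=/X copy, I/S consume query only (dropped from the column model), D/N emit
# '-' with NA quality, H/P consume nothing.
apply_cigar <- function(cigar, seq, qual = NULL) {
  m <- gregexpr(CIGAR_RE, cigar)[[1]]
  if (m[1] == -1L) stop("unparsable CIGAR: ", cigar)
  toks <- regmatches(cigar, gregexpr(CIGAR_RE, cigar))[[1]]
  lens <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  ops <- sub("^[0-9]+", "", toks)
  if (sum(nchar(toks)) != nchar(cigar)) stop("unparsable CIGAR: ", cigar)
  chars <- split_bases(seq)
  out_b <- character(0)
  out_q <- integer(0)
  qi <- 1L
  for (k in seq_along(ops)) {
    n <- lens[k]
    op <- ops[k]
    if (op %in% c("M", "=", "X")) {
      out_b <- c(out_b, chars[qi:(qi + n - 1L)])
      if (!is.null(qual)) out_q <- c(out_q, qual[qi:(qi + n - 1L)])
      qi <- qi + n
    } else if (op %in% c("I", "S")) {
      qi <- qi + n
    } else if (op %in% c("D", "N")) {
      out_b <- c(out_b, rep("-", n))
      if (!is.null(qual)) out_q <- c(out_q, rep(NA_integer_, n))
    }
    # H, P: no-op
  }
  list(bases = paste(out_b, collapse = ""),
       quals = if (is.null(qual)) NULL else out_q)
}

is_binary_alignment <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && identical(as.integer(magic), c(0x1fL, 0x8bL))
}

# Cheap structural validation of plain-text SAM so parse errors can name the
# offending line (the BAM conversion layer does not).
validate_sam_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "@")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) {
      stop("malformed SAM line ", i, " in ", path, ": expected >= 11 fields")
    }
    if (is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[2])))) {
      stop("malformed SAM line ", i, " in ", path, ": non-numeric FLAG/POS")
    }
  }
  invisible(TRUE)
}

# Extract a sample label from a read name. `pattern` is a regular
# expression: with a capture group, the label is the group's first match
# (e.g. "\\|([^/]+)" labels "frag00042|S2/1" as "S2"); without one, the label
# is the prefix before the first match (e.g. "\\|" labels "S2|frag00042" as
# "S2"). Returns NA when the pattern does not match.
label_from_name <- function(qnames, pattern) {
  if (grepl("(", pattern, fixed = TRUE)) {
    m <- regexec(pattern, qnames)
    return(vapply(regmatches(qnames, m), function(g) {
      if (length(g) >= 2L) g[2] else NA_character_
    }, character(1)))
  }
  hit <- regexpr(pattern, qnames)
  ifelse(hit > 1L, substr(qnames, 1L, hit - 1L), NA_character_)
}

#' Read a SAM/BAM alignment into an alignment set
#'
#' Parses single-end or paired-end alignments, converting SAM 1-based
#' positions to internal 0-based starts and applying CIGAR strings so that
#' read bases are in contig coordinates (insertions relative to the contig
#' are dropped, deletions become `-`). Unmapped, secondary and supplementary
#' records are skipped; mate pairs are linked by query name.
#'
#' @param path Path to a plain-text SAM or a BAM/BGZF file.
#' @param readgroup_mode How to derive per-read sample labels: `"rg_tag"`
#'   (SAM RG tag), `"name_pattern"` (label embedded in the read name), or
#'   `"none"` (single default sample).
#' @param name_pattern Regular expression marking the label delimiter inside
#'   read names (the label is the prefix before the first match). Default:
#'   prefix up to the first `|`.
#' @param reference Optional FASTA file supplying contig sequences; when
#'   absent, consensus is computed per contig by majority vote.
#' @return A `hapsnp_alignment`.
#' @export
read_sam <- function(path,
                     readgroup_mode = c("rg_tag", "name_pattern", "none"),
                     name_pattern = "\\|",
                     reference = NULL) {
  readgroup_mode <- match.arg(readgroup_mode)
  if (!file.exists(path)) stop("read_sam: no such file: ", path)
  if (is_binary_alignment(path)) {
    bam <- path
  } else {
    validate_sam_text(path)
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("read_sam: SAM parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  targets <- hdr$targets
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"),
    tag = "RG")
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(rec$qname)
  seqs <- as.character(rec$seq)
  quals_chr <- as.character(rec$qual)
  rg <- rec$tag$RG
  if (is.null(rg)) rg <- rep(NA_character_, n)

  flag <- rec$flag
  paired <- bitwAnd(flag, 0x1L) > 0L
  first <- bitwAnd(flag, 0x40L) > 0L
  is_rev <- bitwAnd(flag, 0x10L) > 0L
  read_id <- ifelse(paired, paste0(rec$qname, ifelse(first, "/1", "/2")),
                    as.character(rec$qname))
  # Disambiguate duplicated ids (e.g. unpaired reads reusing a name).
  if (anyDuplicated(read_id)) read_id <- make.unique(read_id, sep = "#")
  fragment_id <- as.character(rec$qname)
  mate_id <- rep(NA_character_, n)
  if (any(paired)) {
    other <- ifelse(first, paste0(rec$qname, "/2"), paste0(rec$qname, "/1"))
    mate_id[paired] <- ifelse(other[paired] %in% read_id, other[paired],
                              NA_character_)
  }

  sample <- switch(readgroup_mode,
    rg_tag = ifelse(is.na(rg), DEFAULT_SAMPLE, rg),
    name_pattern = {
      lab <- label_from_name(rec$qname, name_pattern)
      if (n > 0 && all(is.na(lab))) {
        warning("read_sam: name_pattern matched no reads; ",
                "all reads assigned to the default sample")
      }
      ifelse(is.na(lab), DEFAULT_SAMPLE, lab)
    },
    none = rep(DEFAULT_SAMPLE, n))

  bases <- character(n)
  quals <- vector("list", n)
  for (i in seq_len(n)) {
    qc <- quals_chr[i]
    qv <- if (is.na(qc) || qc == "*" || qc == "") NULL else utf8ToInt(qc) - 33L
    # BAM encodes absent qualities as 0xff bytes.
    if (!is.null(qv) && all(qv == 222L)) qv <- NULL
    proj <- apply_cigar(rec$cigar[i], seqs[i], qv)
    bases[i] <- proj$bases
    quals[[i]] <- proj$quals
  }

  ref_seqs <- NULL
  if (!is.null(reference)) {
    rs <- Biostrings::readDNAStringSet(reference)
    ref_seqs <- stats::setNames(as.character(rs),
                                sub("\\s.*$", "", names(rs)))
  }

  rname <- as.character(rec$rname)
  contigs <- list()
  for (cid in names(targets)) {
    sel <- which(rname == cid)
    if (length(sel) == 0L) next
    rd <- data.frame(read_id = read_id[sel],
                     fragment_id = fragment_id[sel],
                     start = rec$pos[sel] - 1L,
                     bases = toupper(bases[sel]),
                     sample = sample[sel],
                     mate_id = mate_id[sel],
                     is_reverse = is_rev[sel],
                     stringsAsFactors = FALSE)
    rd$quals <- quals[sel]
    rd <- rd[c("read_id", "fragment_id", "start", "bases", "quals",
               "sample", "mate_id", "is_reverse")]
    cons <- if (!is.null(ref_seqs) && cid %in% names(ref_seqs)) {
      toupper(ref_seqs[[cid]])
    } else NULL
    contigs[[cid]] <- new_contig(cid, targets[[cid]], rd, consensus = cons)
  }
  alignment_set(contigs, source_format = "SAM")
}

# --- SAM writing (used by the simulator and for round-trip checks) ----------

# Build a CIGAR from contig-coordinate bases: runs of '-' become D, the rest M.
bases_to_cigar <- function(bases) {
  r <- rle(split_bases(bases) == "-")
  paste0(r$lengths, ifelse(r$values, "D", "M"), collapse = "")
}

#' Write an alignment set as plain-text SAM
#'
#' Emits `@HD`, `@SQ` and `@RG` headers and one record per read. Reads are in
#' contig coordinates internally, so CIGARs contain only M and D operations.
#'
#' @param aln A `hapsnp_alignment`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path) {
  lines <- c("@HD\tVN:1.6\tSO:coordinate")
  for (ctg in aln$contigs) {
    lines <- c(lines, sprintf("@SQ\tSN:%s\tLN:%d", ctg$contig_id, ctg$length))
  }
  for (s in aln$samples) {
    lines <- c(lines, sprintf("@RG\tID:%s\tSM:%s", s, s))
  }
  for (ctg in aln$contigs) {
    rd <- ctg$reads
    if (nrow(rd) == 0) next
    starts <- stats::setNames(rd$start, rd$read_id)
    lens <- stats::setNames(nchar(rd$bases), rd$read_id)
    for (i in seq_len(nrow(rd))) {
      paired <- !is.na(rd$mate_id[i])
      flag <- 0L
      if (paired) {
        flag <- flag + 0x1L + 0x2L
        flag <- flag + if (grepl("/1$", rd$read_id[i])) 0x40L else 0x80L
      }
      if (rd$is_reverse[i]) flag <- flag + 0x10L
      qname <- rd$fragment_id[i]
      rnext <- "*"; pnext <- 0L; tlen <- 0L
      if (paired && rd$mate_id[i] %in% names(starts)) {
        mate <- rd$mate_id[i]
        if (isTRUE(rd$is_reverse[match(mate, rd$read_id)])) flag <- flag + 0x20L
        rnext <- "="
        pnext <- starts[[mate]] + 1L
        lo <- min(rd$start[i], starts[[mate]])
        hi <- max(rd$start[i] + lens[[rd$read_id[i]]],
                  starts[[mate]] + lens[[mate]])
        tlen <- if (rd$start[i] <= starts[[mate]]) hi - lo else -(hi - lo)
      }
      chars <- split_bases(rd$bases[i])
      keep <- chars != "-"
      seq_out <- paste(chars[keep], collapse = "")
      q <- rd$quals[[i]]
      qual_out <- if (is.null(q)) "*" else intToUtf8(q[keep] + 33L)
      lines <- c(lines, paste(
        qname, flag, ctg$contig_id, rd$start[i] + 1L, 60L,
        bases_to_cigar(rd$bases[i]), rnext, pnext, tlen, seq_out, qual_out,
        paste0("RG:Z:", rd$sample[i]),
        sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
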