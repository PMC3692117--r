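# ACE assembly format (phrap/CAP3 dialect: AS, CO, optional BQ, AF, RD,
# optional QA records). No installed R package parses ACE, so the parser is
# implemented here. Padded coordinates ('*' pads) are converted to the same
# gapped column model used for SAM: a '*' in a read becomes '-'; consensus pad
# columns are insertions relative to the contig and are dropped entirely.

#' Read an ACE assembly into an alignment set
#'
#' @param path Path to an ACE file.
#' @param readgroup_mode `"name_pattern"` to derive sample labels from read
#'   names, or `"none"` for a single default sample. ACE carries no read
#'   groups or per-base qualities, so `base_qualities` are absent.
#' @param name_pattern As in [read_sam()].
#' @return A `hapsnp_alignment`. Mates are linked by the `/1` `/2` read-name
#'   convention when both are present.
#' @export
read_ace <- function(path, readgroup_mode = c("name_pattern", "none"),
                     name_pattern = "\\|") {
  readgroup_mode <- match.arg(readgroup_mode)
  if (!file.exists(path)) stop("read_ace: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  co_idx <- grep("^CO ", lines)
  if (length(co_idx) == 0L) stop("read_ace: no CO record in ", path)

  contigs <- list()
  bounds <- c(co_idx, length(lines) + 1L)
  for (k in seq_along(co_idx)) {
    block <- lines[co_idx[k]:(bounds[k + 1L] - 1L)]
    co_f <- strsplit(block[1], " +")[[1]]
    if (length(co_f) < 4L) stop("read_ace: malformed CO record in ", path)
    cid <- co_f[2]
    n_reads_declared <- as.integer(co_f[4])

    # consensus (padded)
    i <- 2L
    cons_lines <- character(0)
    while (i <= length(block) && block[i] != "" &&
           !grepl("^(AF|RD|BQ|BS) ", block[i])) {
      cons_lines <- c(cons_lines, block[i])
      i <- i + 1L
    }
    cons_padded <- toupper(paste(cons_lines, collapse = ""))
    pad <- split_bases(cons_padded) == "*"
    # map padded column -> unpadded column (NA at pads)
    unpadded_pos <- cumsum(!pad)
    unpadded_pos[pad] <- NA_integer_
    cons <- gsub("*", "", cons_padded, fixed = TRUE)
    cons <- chartr("X", "N", cons)
    L <- nchar(cons)

    af_lines <- grep("^AF ", block, value = TRUE)
    rd_idx <- grep("^RD ", block)
    if (length(af_lines) != length(rd_idx)) {
      stop("read_ace: AF/RD record count mismatch for contig ", cid)
    }
    if (length(rd_idx) != n_reads_declared) {
      stop("read_ace: CO declares ", n_reads_declared, " reads but found ",
           length(rd_idx), " RD records for contig ", cid)
    }
    af <- do.call(rbind, lapply(strsplit(af_lines, " +"), function(f) {
      data.frame(read_id = f[2], is_reverse = f[3] == "C",
                 padded_start = as.integer(f[4]), stringsAsFactors = FALSE)
    }))

    rd_list <- vector("list", length(rd_idx))
    for (j in seq_along(rd_idx)) {
      local_lines <- block
      rd_f <- strsplit(local_lines[rd_idx[j]], " +")[[1]]
      rid <- rd_f[2]
      sb <- {
        ii <- rd_idx[j] + 1L
        seqs <- character(0)
        while (ii <= length(local_lines) && local_lines[ii] != "" &&
               !grepl("^(CO|AF|RD|BQ|QA|DS|BS) ", local_lines[ii])) {
          seqs <- c(seqs, local_lines[ii])
          ii <- ii + 1L
        }
        toupper(paste(seqs, collapse = ""))
      }
      ai <- match(rid, af$read_id)
      if (is.na(ai)) stop("read_ace: RD record ", rid, " has no AF line")
      ps <- af$padded_start[ai]  # 1-based padded start
      chars <- split_bases(sb)
      chars[chars == "*"] <- "-"
      chars[!chars %in% c("A", "C", "G", "T", "-")] <- "N"
      cols_padded <- ps + seq_along(chars) - 1L
      ok <- cols_padded >= 1L & cols_padded <= length(unpadded_pos)
      chars <- chars[ok]; cols_padded <- cols_padded[ok]
      cols <- unpadded_pos[cols_padded]
      keep <- !is.na(cols)  # drop bases at consensus pad columns (insertions)
      chars <- chars[keep]; cols <- cols[keep]
      if (length(chars) == 0L) next
      rd_list[[j]] <- data.frame(
        read_id = rid, start = cols[1] - 1L,
        bases = paste(chars, collapse = ""),
        is_reverse = af$is_reverse[ai], stringsAsFactors = FALSE)
    }
    rd <- do.call(rbind, rd_list)
    if (is.null(rd)) {
      rd <- data.frame(read_id = character(0), start = integer(0),
                       bases = character(0), is_reverse = logical(0),
                       stringsAsFactors = FALSE)
    }

    fragment_id <- sub("/[12]$", "", rd$read_id)
    mate_id <- rep(NA_character_, nrow(rd))
    has_suffix <- grepl("/[12]$", rd$read_id)
    if (any(has_suffix)) {
      other <- ifelse(grepl("/1$", rd$read_id),
                      paste0(fragment_id, "/2"), paste0(fragment_id, "/1"))
      mate_id[has_suffix] <- ifelse(other[has_suffix] %in% rd$read_id,
                                    other[has_suffix], NA_character_)
    }
    sample <- if (readgroup_mode == "name_pattern") {
      lab <- label_from_name(rd$read_id, name_pattern)
      if (nrow(rd) > 0 && all(is.na(lab))) {
        warning("read_ace: name_pattern matched no reads; ",
                "all reads assigned to the default sample")
      }
      ifelse(is.na(lab), DEFAULT_SAMPLE, lab)
    } else {
      rep(DEFAULT_SAMPLE, nrow(rd))
    }
    reads <- data.frame(read_id = rd$read_id, fragment_id = fragment_id,
                        start = rd$start, bases = rd$bases,
                        sample = sample, mate_id = mate_id,
                        is_reverse = rd$is_reverse, stringsAsFactors = FALSE)
    reads$quals <- rep(list(NULL), nrow(reads))
    reads <- reads[c("read_id", "fragment_id", "start", "bases", "quals",
                     "sample", "mate_id", "is_reverse")]
    contigs[[cid]] <- new_contig(cid, L, reads, consensus = cons)
  }
  alignment_set(contigs, source_format = "ACE")
}

#' Write an alignment set as ACE
#'
#' Reads in contig coordinates are emitted as padded RD records (`-` becomes
#' `*`); the consensus is written unpadded. Per-base qualities are not part of
#' the ACE read records and are not written.
#'
#' @param aln A `hapsnp_alignment`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ace <- function(aln, path) {
  n_reads <- sum(vapply(aln$contigs, function(c) nrow(c$reads), integer(1)))
  out <- c(sprintf("AS %d %d", length(aln$contigs), n_reads), "")
  wrap <- function(s) {
    if (nchar(s) == 0) return(character(0))
    starts <- seq(1L, nchar(s), by = 50L)
    substring(s, starts, pmin(starts + 49L, nchar(s)))
  }
  for (ctg in aln$contigs) {
    rd <- ctg$reads
    out <- c(out,
             sprintf("CO %s %d %d 0 U", ctg$contig_id, ctg$length, nrow(rd)),
             wrap(ctg$consensus), "")
    for (i in seq_len(nrow(rd))) {
      out <- c(out, sprintf("AF %s %s %d", rd$read_id[i],
                            if (rd$is_reverse[i]) "C" else "U",
                            rd$start[i] + 1L))
    }
    out <- c(out, "")
    for (i in seq_len(nrow(rd))) {
      padded <- gsub("-", "*", rd$bases[i], fixed = TRUE)
      out <- c(out,
               sprintf("RD %s %d 0 0", rd$read_id[i], nchar(padded)),
               wrap(padded), "",
               sprintf("QA 1 %d 1 %d", nchar(padded), nchar(padded)), "")
    }
  }
  writeLines(out, path)
  invisible(path)
}
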