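# Synthetic alignments with planted haplotypes, SNPs, read groups and
# platform-style errors, plus a machine-readable truth table. The generator is
# first-class: its scenarios define the validation conditions for the caller.

#' Define a simulation scenario
#'
#' The default scenario is a diploid transcript: a 600 bp contig carrying 10
#' SNPs (~55 bp apart, so that 80 bp reads span adjacent sites), two
#' haplotypes sampled 50/50 via two samples that are each homozygous for one
#' haplotype, 30x coverage and a 1% substitution error rate. Injected errors
#' receive a low Phred score (`q_low`) with probability `q_informative`,
#' otherwise they keep the high score — modelling base callers that flag most
#' but not all miscalls. SNP sites are planted outside homopolymer context
#' (no two adjacent equal bases within +-3 bp of a site, and alternate alleles
#' differ from both neighbours), since homopolymer masking deliberately
#' discards variants inside or adjacent to runs.
#'
#' @param contig_length Contig length in bp.
#' @param n_haplotypes Number of planted haplotypes (any two differ at >= 1
#'   SNP).
#' @param n_snps Number of planted SNP positions (ignored when
#'   `snp_positions` given).
#' @param snp_positions Optional 0-based SNP positions (strictly increasing).
#' @param samples Named list mapping sample label to the haplotype indices the
#'   sample carries (a vector = a mixture, drawn uniformly per read).
#' @param coverage Mean read depth.
#' @param read_length Read length in bp.
#' @param paired Emit read pairs (FR orientation) instead of single-end reads.
#' @param insert_size Outer fragment span for paired reads.
#' @param error_rate Per-base substitution error probability.
#' @param hp_error_rate Extra, always-high-quality substitution probability at
#'   positions inside/adjacent to reference homopolymer runs of length >=
#'   `hp_min_run`; the miscall copies the run base (pyrosequencing-style
#'   overcall).
#' @param hp_min_run Run length defining a homopolymer tract.
#' @param n_hp_runs Number of homopolymer runs (length `hp_run_length`)
#'   embedded in the reference, placed away from SNP sites.
#' @param hp_run_length Length of each embedded run.
#' @param adaptor_len Number of bases at each read's 3' end replaced by
#'   adaptor sequence (incomplete adaptor trimming), emitted at high quality.
#' @param adaptor_seq Adaptor sequence used for the remnant.
#' @param q_informative Probability that an injected error is flagged with
#'   `q_low`; `0` makes the quality filter blind to errors.
#' @param q_high,q_low Phred scores for high-quality / flagged bases.
#' @param seed RNG seed: identical seed and parameters give byte-identical
#'   emitted files.
#' @param contig_id Contig name in the emitted files.
#' @return An object of class `hapsnp_scenario`.
#' @export
sim_scenario <- function(contig_length = 600L, n_haplotypes = 2L,
                         n_snps = 10L, snp_positions = NULL,
                         samples = NULL, coverage = 30, read_length = 80L,
                         paired = FALSE, insert_size = 300L,
                         error_rate = 0.01, hp_error_rate = 0,
                         hp_min_run = 3L, n_hp_runs = 0L, hp_run_length = 5L,
                         adaptor_len = 0L, adaptor_seq = "AGATCGGAAGAGC",
                         q_informative = 0.9, q_high = 40L, q_low = 2L,
                         seed = 1L, contig_id = "contig1") {
  span <- if (paired) insert_size else read_length
  if (span > contig_length) {
    stop("sim_scenario: read/insert span (", span,
         ") exceeds contig length (", contig_length, ")")
  }
  if (is.null(samples)) {
    samples <- stats::setNames(as.list(seq_len(n_haplotypes)),
                               paste0("S", seq_len(n_haplotypes)))
  }
  if (!is.null(snp_positions)) {
    snp_positions <- as.integer(snp_positions)
    if (any(diff(snp_positions) <= 0L) || any(snp_positions < 0L) ||
        any(snp_positions >= contig_length)) {
      stop("sim_scenario: snp_positions must be strictly increasing and ",
           "within the contig")
    }
    n_snps <- length(snp_positions)
  }
  structure(list(
    contig_length = as.integer(contig_length),
    n_haplotypes = as.integer(n_haplotypes), n_snps = as.integer(n_snps),
    snp_positions = snp_positions, samples = samples,
    coverage = coverage, read_length = as.integer(read_length),
    paired = isTRUE(paired), insert_size = as.integer(insert_size),
    error_rate = error_rate, hp_error_rate = hp_error_rate,
    hp_min_run = as.integer(hp_min_run), n_hp_runs = as.integer(n_hp_runs),
    hp_run_length = as.integer(hp_run_length),
    adaptor_len = as.integer(adaptor_len), adaptor_seq = adaptor_seq,
    q_informative = q_informative, q_high = as.integer(q_high),
    q_low = as.integer(q_low), seed = as.integer(seed),
    contig_id = contig_id
  ), class = "hapsnp_scenario")
}

#' The haplotype-fragmentation scenario
#'
#' Two haplotypes and two SNP blocks (sites at 60/80 and 300/320 on a 400 bp
#' contig) separated by more than the 70 bp read length, so no single-end read
#' links the blocks: the caller sees four read clusters (two fragmented
#' haplotypes per true haplotype) and the per-SNP-position maximum corrects
#' the count back to two. With `paired = TRUE` the 300 bp insert spans the
#' gap and both raw and corrected counts are two. Error-free, so counts are
#' exact and deterministic.
#'
#' @param paired Use read pairs spanning the gap.
#' @param seed RNG seed.
#' @return A `hapsnp_scenario`.
#' @export
fragmentation_scenario <- function(paired = FALSE, seed = 42L) {
  sim_scenario(contig_length = 400L, n_haplotypes = 2L,
               snp_positions = c(60L, 80L, 300L, 320L),
               coverage = 30, read_length = 70L,
               paired = paired, insert_size = 300L,
               error_rate = 0, q_informative = 1, seed = seed,
               contig_id = "frag_contig")
}

# sample() without its undesirable length-1 behaviour.
sample_vec <- function(x, n, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), n, replace = replace, prob = prob)]
}

BASES4 <- c("A", "C", "G", "T")

# Reference sequence with optional embedded homopolymer runs and SNP sites in
# non-homopolymeric context. Returns list(ref chars, snp_pos 0-based).
build_reference <- function(sc) {
  L <- sc$contig_length
  ref <- sample_vec(BASES4, L, replace = TRUE)
  snp_pos <- sc$snp_positions
  if (is.null(snp_pos)) {
    lo <- max(4L, round(L * 0.08)); hi <- min(L - 5L, round(L * 0.92))
    snp_pos <- as.integer(round(seq(lo, hi, length.out = sc$n_snps)))
  }
  if (sc$n_hp_runs > 0L) {
    # place runs midway between SNP sites, clear of the +-3 sanitized windows
    gaps <- cbind(c(0L, snp_pos), c(snp_pos, L - 1L))
    mids <- floor(rowMeans(gaps))
    widths <- gaps[, 2] - gaps[, 1]
    ok <- which(widths >= sc$hp_run_length + 10L)
    picks <- ok[seq_len(min(sc$n_hp_runs, length(ok)))]
    for (m in mids[picks]) {
      b <- sample_vec(BASES4, 1L)
      idx <- (m + 1L):(m + sc$hp_run_length)
      idx <- idx[idx >= 1L & idx <= L]
      ref[idx] <- b
    }
  }
  # sanitize +-3 bp around each SNP: no two adjacent equal bases
  for (p in snp_pos) {
    for (k in (p - 3L):(p + 3L)) {
      i <- k + 1L
      if (i < 2L || i > L) next
      while (ref[i] == ref[i - 1L] || (i < L && ref[i] == ref[i + 1L])) {
        ref[i] <- sample_vec(BASES4, 1L)
      }
    }
  }
  list(ref = ref, snp_pos = snp_pos)
}

# Per-haplotype allele at every SNP; haplotype 1 carries the reference base.
# Alternate alleles differ from the reference and from both neighbours (no
# new homopolymer context). Any two haplotypes differ at >= 1 SNP.
plant_alleles <- function(sc, ref, snp_pos) {
  n <- length(snp_pos)
  alle <- matrix("", nrow = sc$n_haplotypes, ncol = n)
  for (j in seq_len(n)) {
    i <- snp_pos[j] + 1L
    forbidden <- unique(c(ref[i],
                          if (i > 1L) ref[i - 1L],
                          if (i < length(ref)) ref[i + 1L]))
    alt_pool <- setdiff(BASES4, forbidden)
    alt <- sample_vec(alt_pool, 1L)
    alle[1L, j] <- ref[i]
    if (sc$n_haplotypes == 2L) {
      alle[2L, j] <- alt
    } else if (sc$n_haplotypes > 2L) {
      alle[-1L, j] <- sample_vec(c(ref[i], alt), sc$n_haplotypes - 1L,
                                 replace = TRUE)
    }
  }
  if (sc$n_haplotypes > 2L) {
    # ensure pairwise distinct haplotypes
    repeat {
      dup <- FALSE
      for (a in seq_len(sc$n_haplotypes - 1L)) {
        for (b in (a + 1L):sc$n_haplotypes) {
          if (all(alle[a, ] == alle[b, ])) {
            j <- sample.int(ncol(alle), 1L)
            i <- snp_pos[j] + 1L
            cur <- alle[b, j]
            alt_pool <- setdiff(BASES4, unique(c(cur, ref[i - 1L], ref[i + 1L])))
            alle[b, j] <- sample_vec(alt_pool, 1L)
            dup <- TRUE
          }
        }
      }
      if (!dup) break
    }
  }
  alle
}

#' Simulate an alignment with planted haplotypes and errors
#'
#' Draws reads uniformly along the contig at the requested depth, copies bases
#' from each read's assigned haplotype, injects substitution errors (random,
#' homopolymer-associated, adaptor remnants) and emits the alignment as SAM
#' and ACE together with a truth table tracing every read to its haplotype
#' and sample and every injected error to its position.
#'
#' @param sc A [sim_scenario()].
#' @param dir Output directory for the emitted files.
#' @param write_files Write SAM/ACE/truth CSVs (set `FALSE` for in-memory
#'   use, e.g. replicate studies).
#' @return List: `alignment` (in-memory `hapsnp_alignment`), `truth` (list of
#'   data.frames `snps`, `reads`, and `allele_counts` recounted from the
#'   emitted reads), and — when written — paths `sam`, `ace`, `truth_snps`,
#'   `truth_reads`.
#' @export
simulate_alignment <- function(sc, dir = tempfile("hapsnp_sim"),
                               write_files = TRUE) {
  stopifnot(inherits(sc, "hapsnp_scenario"))
  set.seed(sc$seed)
  L <- sc$contig_length
  refinfo <- build_reference(sc)
  ref <- refinfo$ref
  snp_pos <- refinfo$snp_pos
  alle <- plant_alleles(sc, ref, snp_pos)

  haps <- lapply(seq_len(sc$n_haplotypes), function(h) {
    s <- ref
    s[snp_pos + 1L] <- alle[h, ]
    s
  })

  # columns eligible for homopolymer-associated errors: inside/adjacent to
  # reference runs >= hp_min_run, with the run base as the miscall target
  hp_target <- rep(NA_character_, L)
  if (sc$hp_error_rate > 0) {
    r <- rle(ref)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$lengths >= sc$hp_min_run)) {
      lo <- max(1L, starts[k] - 1L); hi <- min(L, ends[k] + 1L)
      hp_target[lo:hi] <- r$values[k]
    }
  }

  span <- if (sc$paired) sc$insert_size else sc$read_length
  n_frag <- max(1L, round(sc$coverage * L /
                            (sc$read_length * (if (sc$paired) 2L else 1L))))
  sample_labels <- names(sc$samples)
  frag_sample <- sample_vec(sample_labels, n_frag, replace = TRUE)
  frag_hap <- vapply(frag_sample, function(s) {
    hs <- sc$samples[[s]]
    if (length(hs) == 1L) hs else sample_vec(hs, 1L)
  }, numeric(1))
  frag_start <- sample.int(L - span + 1L, n_frag, replace = TRUE) - 1L
  ord <- order(frag_start)
  frag_start <- frag_start[ord]; frag_hap <- frag_hap[ord]
  frag_sample <- frag_sample[ord]
  # coordinate-sorted ids: greedy haplotype clustering breaks coverage ties
  # by fragment id, so ids in start-position order chain clusters along the
  # contig instead of processing samples in blocks
  frag_name <- sprintf("frag%05d|%s", seq_len(n_frag), frag_sample)

  adaptor <- split_bases(sc$adaptor_seq)
  make_read <- function(start, hap, reverse) {
    rl <- sc$read_length
    pos <- start + seq_len(rl)           # 1-based contig columns
    bases <- haps[[hap]][pos]
    true_bases <- bases
    qual <- rep(sc$q_high, rl)
    err_kind <- character(0); err_off <- integer(0)
    u_err <- stats::runif(rl)
    hit <- which(u_err < sc$error_rate)
    for (o in hit) {
      bases[o] <- sample_vec(setdiff(BASES4, bases[o]), 1L)
      qual[o] <- if (stats::runif(1) < sc$q_informative) sc$q_low else sc$q_high
      err_kind <- c(err_kind, "random"); err_off <- c(err_off, o)
    }
    if (sc$hp_error_rate > 0) {
      cand <- which(!is.na(hp_target[pos]) & hp_target[pos] != bases)
      if (length(cand) > 0) {
        u_hp <- stats::runif(length(cand))
        for (ii in which(u_hp < sc$hp_error_rate)) {
          o <- cand[ii]
          bases[o] <- hp_target[pos[o]]
          qual[o] <- sc$q_high  # evades the Phred filter by construction
          err_kind <- c(err_kind, "homopolymer"); err_off <- c(err_off, o)
        }
      }
    }
    if (sc$adaptor_len > 0L) {
      n_ad <- min(sc$adaptor_len, rl)
      ad <- rep(adaptor, length.out = n_ad)
      offs <- if (reverse) seq_len(n_ad) else (rl - n_ad + 1L):rl
      changed <- bases[offs] != ad
      bases[offs] <- ad
      qual[offs] <- sc$q_high
      err_kind <- c(err_kind, rep("adaptor", sum(changed)))
      err_off <- c(err_off, offs[changed])
    }
    list(bases = bases, qual = qual, true_bases = true_bases,
         err_off = err_off, err_kind = err_kind)
  }

  reads <- list(); truth_reads <- list()
  for (f in seq_len(n_frag)) {
    if (sc$paired) {
      s1 <- frag_start[f]
      s2 <- frag_start[f] + sc$insert_size - sc$read_length
      r1 <- make_read(s1, frag_hap[f], FALSE)
      r2 <- make_read(s2, frag_hap[f], TRUE)
      ids <- paste0(frag_name[f], c("/1", "/2"))
      reads[[length(reads) + 1L]] <- list(
        read_id = ids[1], fragment_id = frag_name[f], start = s1,
        bases = r1$bases, qual = r1$qual, sample = frag_sample[f],
        mate_id = ids[2], is_reverse = FALSE, hap = frag_hap[f],
        err_off = r1$err_off, err_kind = r1$err_kind)
      reads[[length(reads) + 1L]] <- list(
        read_id = ids[2], fragment_id = frag_name[f], start = s2,
        bases = r2$bases, qual = r2$qual, sample = frag_sample[f],
        mate_id = ids[1], is_reverse = TRUE, hap = frag_hap[f],
        err_off = r2$err_off, err_kind = r2$err_kind)
    } else {
      rev <- stats::runif(1) < 0.5
      r1 <- make_read(frag_start[f], frag_hap[f], rev)
      reads[[length(reads) + 1L]] <- list(
        read_id = frag_name[f], fragment_id = frag_name[f],
        start = frag_start[f], bases = r1$bases, qual = r1$qual,
        sample = frag_sample[f], mate_id = NA_character_, is_reverse = rev,
        hap = frag_hap[f], err_off = r1$err_off, err_kind = r1$err_kind)
    }
  }

  rd <- data.frame(
    read_id = vapply(reads, `[[`, character(1), "read_id"),
    fragment_id = vapply(reads, `[[`, character(1), "fragment_id"),
    start = vapply(reads, `[[`, integer(1), "start"),
    bases = vapply(reads, function(r) paste(r$bases, collapse = ""),
                   character(1)),
    sample = vapply(reads, `[[`, character(1), "sample"),
    mate_id = vapply(reads, `[[`, character(1), "mate_id"),
    is_reverse = vapply(reads, `[[`, logical(1), "is_reverse"),
    stringsAsFactors = FALSE)
  rd$quals <- lapply(reads, `[[`, "qual")
  rd <- rd[order(rd$start, rd$read_id, method = "radix"), ]
  rownames(rd) <- NULL
  rd <- rd[c("read_id", "fragment_id", "start", "bases", "quals",
             "sample", "mate_id", "is_reverse")]
  ctg <- new_contig(sc$contig_id, L, rd, consensus = paste(ref, collapse = ""))
  aln <- alignment_set(list(ctg), source_format = "SAM")

  truth_snps <- data.frame(
    position = snp_pos,
    ref_allele = ref[snp_pos + 1L],
    stringsAsFactors = FALSE)
  for (h in seq_len(sc$n_haplotypes)) {
    truth_snps[[paste0("hap", h)]] <- alle[h, ]
  }
  reads_sorted <- reads[order(vapply(reads, `[[`, integer(1), "start"),
                              vapply(reads, `[[`, character(1), "read_id"),
                              method = "radix")]
  truth_reads <- data.frame(
    read_id = vapply(reads_sorted, `[[`, character(1), "read_id"),
    fragment_id = vapply(reads_sorted, `[[`, character(1), "fragment_id"),
    sample = vapply(reads_sorted, `[[`, character(1), "sample"),
    haplotype = vapply(reads_sorted, `[[`, numeric(1), "hap"),
    start = vapply(reads_sorted, `[[`, integer(1), "start"),
    error_offsets = vapply(reads_sorted, function(r)
      paste(r$err_off, collapse = ";"), character(1)),
    error_kinds = vapply(reads_sorted, function(r)
      paste(r$err_kind, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)

  # allele counts at planted sites, recounted from the emitted reads
  pile <- pileup(ctg)
  truth_counts <- do.call(rbind, lapply(seq_along(snp_pos), function(j) {
    cc <- column_counts(pile, snp_pos[j] + 1L)
    data.frame(position = snp_pos[j],
               allele = names(cc), count = as.integer(cc),
               stringsAsFactors = FALSE)
  }))

  out <- list(alignment = aln,
              truth = list(snps = truth_snps, reads = truth_reads,
                           allele_counts = truth_counts),
              scenario = sc)
  if (write_files) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$sam <- write_sam(aln, file.path(dir, "sim.sam"))
    out$ace <- write_ace(aln, file.path(dir, "sim.ace"))
    out$ref <- file.path(dir, "ref.fasta")
    writeLines(c(paste0(">", sc$contig_id), paste(ref, collapse = "")),
               out$ref)
    utils::write.csv(truth_snps, file.path(dir, "truth_snps.csv"),
                     row.names = FALSE, quote = TRUE)
    utils::write.csv(truth_reads, file.path(dir, "truth_reads.csv"),
                     row.names = FALSE, quote = TRUE)
    out$truth_snps <- file.path(dir, "truth_snps.csv")
    out$truth_reads <- file.path(dir, "truth_reads.csv")
  }
  out
}
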