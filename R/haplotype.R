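# Filter 3: cluster read fragments into haplotypes over the high-confidence
# SNP sites, mark reliable SNPs as those whose alleles are backed by
# haplotypes, and compute the fragmentation-corrected haplotype count.

# Unmasked base calls of every read at the given 0-based site positions.
# Returns a data.frame (read_row, site_idx, base); N and masked bases omitted,
# '-' kept (a deletion can be an allele).
site_base_calls <- function(contig, positions, masks) {
  rd <- contig$reads
  out <- vector("list", nrow(rd))
  for (i in seq_len(nrow(rd))) {
    len <- nchar(rd$bases[i])
    offs <- positions - rd$start[i] + 1L  # 1-based offset into the read
    sel <- which(offs >= 1L & offs <= len)
    if (length(sel) == 0L) next
    chars <- split_bases(rd$bases[i])
    b <- chars[offs[sel]]
    ok <- masks[[i]][offs[sel]] & b %in% ALLELE_BASES
    if (!any(ok)) next
    out[[i]] <- data.frame(read_row = i, site_idx = sel[ok], base = b[ok],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(read_row = integer(0), site_idx = integer(0),
                      base = character(0), stringsAsFactors = FALSE)
  }
  res
}

#' Build the fragment-by-site allele matrix
#'
#' Rows are fragments (mate pairs count as one fragment), columns are
#' high-confidence SNP sites, cells hold the fragment's unmasked allele or
#' `NA` when the fragment does not cover the column, the base is
#' quality-masked, or the two mates disagree there.
#'
#' @param contig A `hapsnp_contig`.
#' @param sites High-confidence sites (data.frame with a `pos` column).
#' @param masks Per-read quality masks ([build_quality_mask()]).
#' @return Character matrix with fragment ids as rownames and 0-based site
#'   positions as colnames; fragments covering no site are excluded. Empty
#'   `sites` yields a 0-column matrix.
#' @export
build_allele_matrix <- function(contig, sites, masks = NULL) {
  if (is.null(masks)) stop("build_allele_matrix: masks required")
  rd <- contig$reads
  frag_ids <- unique(rd$fragment_id)  # first-appearance (position) order
  mat <- matrix(NA_character_, nrow = length(frag_ids), ncol = nrow(sites),
                dimnames = list(frag_ids, as.character(sites$pos)))
  if (nrow(sites) > 0 && nrow(rd) > 0) {
    calls <- site_base_calls(contig, sites$pos, masks)
    if (nrow(calls) > 0) {
      frow <- match(rd$fragment_id[calls$read_row], frag_ids)
      for (k in seq_len(nrow(calls))) {
        i <- frow[k]; j <- calls$site_idx[k]; b <- calls$base[k]
        cur <- mat[i, j]
        if (is.na(cur)) {
          mat[i, j] <- b
        } else if (cur != b) {
          mat[i, j] <- "!"  # conflicting mate calls -> missing
        }
      }
      mat[mat == "!"] <- NA_character_
    }
  }
  mat[rowSums(!is.na(mat)) > 0L, , drop = FALSE]
}

# Two allele vectors are compatible iff they share at least one covered site
# and agree at every mutually covered site. Sharing no site does not link
# fragments: unlinked SNP blocks must yield separate (fragmented) haplotypes.
vectors_compatible <- function(a, b) {
  shared <- !is.na(a) & !is.na(b)
  any(shared) && all(a[shared] == b[shared])
}

#' Greedy haplotype clustering over the allele matrix
#'
#' Fragments are processed in order of (number of covered sites descending,
#' fragment id ascending). Each fragment joins the first existing haplotype it
#' is compatible with — agreeing at every mutually covered site, with at least
#' one mutually covered site — extending that haplotype's allele vector;
#' otherwise it founds a new haplotype. A conflict confined to vector entries
#' attested by fewer than `min_haplotype_reads` member fragments does not veto
#' a join: the attesting fragments are detached and reprocessed once at the
#' end under the plain rule, so a single read carrying a high-Phred miscall at
#' a SNP site cannot break an otherwise consistent haplotype chain (with
#' `min_haplotype_reads = 1` every entry is firm and the rule is the plain
#' greedy one). After support filtering, each haplotype's allele vector is the
#' per-site majority over its members, reported only where at least
#' `min_haplotype_reads` members carry the allele, and haplotypes whose final
#' vectors overlap compatibly are merged; haplotypes over disjoint site sets
#' are never merged — they are fragmented haplotypes, accounted for by the
#' corrected haplotype count. Haplotypes supported by fewer than
#' `min_haplotype_reads` fragments are then discarded and their fragments
#' marked unassigned; likewise, an entry of a retained haplotype's allele
#' vector attested by fewer than `min_haplotype_reads` member fragments is set
#' back to missing (a single read's base — possibly a high-Phred miscall —
#' is not trusted to extend a haplotype, for the same reason a single-read
#' cluster is not a haplotype). Haplotype ids are assigned by decreasing
#' support, ties by founding order.
#'
#' @param mat Allele matrix from [build_allele_matrix()].
#' @param cfg A [filter_config()].
#' @return List with `haplotypes` (each a list: `haplotype_id`, `alleles`
#'   named character vector with `NA` for missing, `fragments`, `support`) and
#'   `unassigned` (fragment ids of discarded clusters).
#' @export
cluster_haplotypes <- function(mat, cfg) {
  if (nrow(mat) == 0L || ncol(mat) == 0L) {
    return(list(haplotypes = list(), unassigned = rownames(mat)))
  }
  covered <- rowSums(!is.na(mat))
  ord <- order(-covered, rownames(mat), method = "radix")
  members <- list()   # cluster member fragment ids
  vecs <- list()      # cluster allele vectors (members' unanimous alleles)
  attest <- list()    # per-site count of members with a non-missing allele

  rebuild <- function(ids) {
    rows <- mat[ids, , drop = FALSE]
    att <- colSums(!is.na(rows))
    vec <- rep(NA_character_, ncol(mat))
    names(vec) <- colnames(mat)
    for (j in which(att > 0L)) vec[j] <- stats::na.omit(rows[, j])[1]
    list(vec = vec, att = att)
  }

  # Try to add fragment `frag` (id `fid`) to cluster k. A conflict at an
  # entry attested by fewer than min_haplotype_reads members (i.e. written by
  # a single fragment under the default of 2 — possibly one high-Phred
  # miscall) does not veto the join: the attesting members are detached for
  # later reprocessing instead, so one bad read cannot break a haplotype
  # chain. With min_haplotype_reads = 1 every entry is firm and this is the
  # plain greedy rule.
  try_join <- function(k, frag, fid, allow_detach) {
    shared <- !is.na(vecs[[k]]) & !is.na(frag)
    if (!any(shared)) return(NULL)
    conf <- shared & vecs[[k]] != frag
    if (!any(conf)) {
      fill <- is.na(vecs[[k]]) & !is.na(frag)
      vecs[[k]][fill] <<- frag[fill]
      att <- attest[[k]]
      att[!is.na(frag)] <- att[!is.na(frag)] + 1L
      attest[[k]] <<- att
      members[[k]] <<- c(members[[k]], fid)
      return(character(0))
    }
    if (!allow_detach || any(attest[[k]][conf] >= cfg$min_haplotype_reads)) {
      return(NULL)
    }
    ids <- members[[k]]
    rows <- mat[ids, , drop = FALSE]
    drop <- ids[rowSums(!is.na(rows[, conf, drop = FALSE])) > 0L]
    keep <- setdiff(ids, drop)
    if (length(keep) == 0L) return(NULL)
    rb <- rebuild(keep)
    shared2 <- !is.na(rb$vec) & !is.na(frag)
    if (!any(shared2) || any(rb$vec[shared2] != frag[shared2])) return(NULL)
    members[[k]] <<- c(keep, fid)
    rb2 <- rebuild(members[[k]])
    vecs[[k]] <<- rb2$vec
    attest[[k]] <<- rb2$att
    drop
  }

  place <- function(i, allow_detach) {
    frag <- mat[i, ]
    fid <- rownames(mat)[i]
    for (k in seq_along(vecs)) {
      res <- try_join(k, frag, fid, allow_detach)
      if (!is.null(res)) return(res)
    }
    members[[length(members) + 1L]] <<- fid
    vecs[[length(vecs) + 1L]] <<- frag
    attest[[length(attest) + 1L]] <<- as.integer(!is.na(frag))
    character(0)
  }

  detached <- character(0)
  for (i in ord) detached <- c(detached, place(i, allow_detach = TRUE))
  # reprocess detached fragments once, in the original processing order,
  # under the plain rule (no further detachment)
  detached <- detached[order(match(detached, rownames(mat)[ord]))]
  for (fid in detached) place(match(fid, rownames(mat)), allow_detach = FALSE)

  support <- lengths(members)
  keep <- which(support >= cfg$min_haplotype_reads)
  unassigned <- unlist(members[setdiff(seq_along(members), keep)])
  if (is.null(unassigned)) unassigned <- character(0)

  # Final allele vector of a cluster: per site, the majority allele over the
  # member fragments, reported only when carried by at least
  # min_haplotype_reads members (ties and weaker evidence give missing). For
  # a conflict-free cluster this is simply the members' unanimous allele; an
  # entry written by a single fragment — possibly one high-Phred miscall —
  # is not trusted evidence, for the same reason a single-fragment cluster is
  # not a haplotype.
  final_vector <- function(ids) {
    rows <- mat[ids, , drop = FALSE]
    vec <- rep(NA_character_, ncol(mat))
    names(vec) <- colnames(mat)
    for (j in seq_len(ncol(mat))) {
      obs <- rows[!is.na(rows[, j]), j]
      if (length(obs) == 0L) next
      tb <- sort(table(obs), decreasing = TRUE)
      if (tb[1] >= cfg$min_haplotype_reads &&
          (length(tb) == 1L || tb[1] > tb[2])) {
        vec[j] <- names(tb)[1]
      }
    }
    vec
  }
  groups <- members[keep]
  fvecs <- lapply(groups, final_vector)

  # Merge pass: two retained clusters whose final vectors share at least one
  # covered site and agree everywhere they overlap describe the same
  # haplotype (greedy founding order can split one haplotype when an early
  # strongly-attested miscall blocks the chain); merge them until a fixed
  # point, deterministically in founding order. Clusters with disjoint site
  # sets stay separate: they are fragmented haplotypes, which the corrected
  # haplotype count accounts for.
  repeat {
    merged <- FALSE
    for (a in seq_along(fvecs)) {
      if (merged) break
      for (b in seq_along(fvecs)) {
        if (b <= a) next
        if (vectors_compatible(fvecs[[a]], fvecs[[b]])) {
          groups[[a]] <- c(groups[[a]], groups[[b]])
          groups[[b]] <- NULL
          fvecs[[a]] <- final_vector(groups[[a]])
          fvecs[[b]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }

  support <- lengths(groups)
  ord_h <- order(-support, seq_along(groups))
  haplotypes <- lapply(seq_along(ord_h), function(r) {
    k <- ord_h[r]
    list(haplotype_id = r, alleles = fvecs[[k]],
         fragments = groups[[k]], support = support[[k]])
  })
  list(haplotypes = haplotypes, unassigned = unassigned)
}

#' Mark reliable SNPs (filter 3 outcome)
#'
#' A high-confidence site is reliable iff at least two distinct alleles at
#' that site each appear in the allele vector of at least one retained
#' haplotype. Sites failing this are demoted with reason
#' `"no_haplotype_support"`.
#'
#' @param sites High-confidence sites data.frame (0-based `pos`).
#' @param haplotypes Retained haplotypes from [cluster_haplotypes()].
#' @return `sites` with `status` updated to `"reliable"` or
#'   `"rejected_quality"` (reason `"no_haplotype_support"`).
#' @export
mark_reliable_snps <- function(sites, haplotypes) {
  for (i in seq_len(nrow(sites))) {
    key <- as.character(sites$pos[i])
    backed <- unique(unlist(lapply(haplotypes, function(h) {
      a <- h$alleles[[key]]
      if (is.null(a) || is.na(a)) NULL else a
    })))
    if (length(backed) >= 2L) {
      sites$status[i] <- "reliable"
    } else {
      sites$status[i] <- "rejected_quality"
      sites$reason[i] <- "no_haplotype_support"
    }
  }
  sites
}

#' Per-site haplotype counts and the fragmentation-corrected count
#'
#' Fragmented haplotypes (one true haplotype split into several read clusters
#' because no fragment links distant SNP blocks) inflate the raw haplotype
#' count; the corrected count is the maximum number of haplotypes carrying a
#' non-missing allele at any single SNP position.
#'
#' @param haplotypes Retained haplotypes from [cluster_haplotypes()].
#' @param sites Sites data.frame (0-based `pos`); typically the reliable ones.
#' @return List: `per_site_haplotype_count` (named integer vector keyed by
#'   position), `corrected_count` (max per-site count, 0 for no sites),
#'   `n_haplotypes` (raw retained count).
#' @export
summarize_haplotypes <- function(haplotypes, sites) {
  keys <- as.character(sites$pos)
  per_site <- vapply(keys, function(key) {
    sum(vapply(haplotypes, function(h) {
      a <- h$alleles[[key]]
      !is.null(a) && !is.na(a)
    }, logical(1)))
  }, integer(1))
  names(per_site) <- keys
  list(per_site_haplotype_count = per_site,
       corrected_count = if (length(per_site)) max(per_site) else 0L,
       n_haplotypes = length(haplotypes))
}

#' Order reads for display
#'
#' @param contig A `hapsnp_contig`.
#' @param haplotypes Retained haplotypes (required for `mode =
#'   "by_haplotype"`).
#' @param mode `"by_position"` (stable sort on start) or `"by_haplotype"`
#'   (group by haplotype id then start; reads whose fragment is in no retained
#'   haplotype — including reads covering no SNP — are omitted).
#' @return The contig's reads data.frame, reordered (and possibly subset).
#' @export
sort_reads_for_display <- function(contig, haplotypes = NULL,
                                   mode = c("by_position", "by_haplotype")) {
  mode <- match.arg(mode)
  rd <- contig$reads
  if (mode == "by_position") {
    return(rd[order(rd$start, rd$read_id, method = "radix"), , drop = FALSE])
  }
  if (is.null(haplotypes)) stop("sort_reads_for_display: haplotypes required")
  frag_hap <- integer(0)
  for (h in haplotypes) {
    frag_hap[h$fragments] <- h$haplotype_id
  }
  hap <- frag_hap[rd$fragment_id]
  keep <- !is.na(hap)
  rd <- rd[keep, , drop = FALSE]
  rd[order(hap[keep], rd$start, rd$read_id, method = "radix"), , drop = FALSE]
}
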