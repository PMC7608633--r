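#' Identify TE-insertion junction pairs
#'
#' From two single-end alignment sets of the same reads — one against the
#' repeat-masked genome, one against the TE consensus library — retains
#' exactly the mate pairs where one read maps uniquely to the genome and
#' its mate maps only to the TE library. Such pairs flank the junction of
#' an insertion absent from the reference. "Uniquely mapped" means
#' mapping quality at least `mapq_min` with a single, non-secondary record
#' for the read. No directionality is imposed on the TE-side mate (TEs
#' insert in either orientation); the genome-side strand determines which
#' flank the pair marks.
#'
#' @param genome_aln data.frame of genome alignments: `qname`, `mate`
#'   (1/2), `chrom`, `start`, `end` (0-based half-open), `strand`,
#'   `mapq`, `secondary`.
#' @param te_aln data.frame of TE-library alignments: `qname`, `mate`,
#'   `family`, plus optional `secondary`.
#' @param mapq_min uniqueness threshold on mapping quality.
#' @param sample_id optional library id carried into downstream calls.
#' @return data.frame of junction pairs: `sample_id`, `qname`, `chrom`,
#'   `start`, `end`, `strand`, `pos` (innermost base toward the
#'   presumed insertion: read end on "+", read start on "-"), `family`.
#' @export
find_junction_pairs <- function(genome_aln, te_aln, mapq_min = 30,
                                sample_id = NA_character_) {
  req <- c("qname", "mate", "chrom", "start", "end", "strand", "mapq")
  if (!all(req %in% names(genome_aln)))
    stop("genome alignments need columns: ", paste(req, collapse = ", "))
  if (!all(c("qname", "mate", "family") %in% names(te_aln)))
    stop("TE alignments need columns qname, mate, family")
  if (!"secondary" %in% names(genome_aln)) genome_aln$secondary <- FALSE
  if (!"secondary" %in% names(te_aln)) te_aln$secondary <- FALSE

  gkey <- paste(genome_aln$qname, genome_aln$mate)
  multi <- gkey %in% gkey[duplicated(gkey)]
  uniq <- !genome_aln$secondary & genome_aln$mapq >= mapq_min & !multi
  tkey_all <- paste(te_aln$qname, te_aln$mate)
  te_primary <- te_aln[!te_aln$secondary, , drop = FALSE]
  tkey <- paste(te_primary$qname, te_primary$mate)

  g <- genome_aln[uniq, , drop = FALSE]
  matekey <- paste(g$qname, 3L - g$mate)
  # mate maps only to the TE library: a TE record and no genome record
  te_only <- matekey %in% tkey_all & !(matekey %in% gkey)
  g <- g[te_only, , drop = FALSE]
  fam <- te_primary$family[match(paste(g$qname, 3L - g$mate), tkey)]
  keep <- !is.na(fam)
  g <- g[keep, , drop = FALSE]
  data.frame(sample_id = rep(sample_id, nrow(g)), qname = g$qname,
             chrom = g$chrom,
             start = g$start, end = g$end, strand = g$strand,
             pos = ifelse(g$strand == "+", g$end, g$start),
             family = fam[keep], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Cluster junction reads into junctions
#'
#' Reads of the same mapping orientation (and chromosome and TE family)
#' whose genomic positions lie within `gap` bp of each other capture the
#' same junction. Chaining is single-linkage by default (consecutive
#' sorted positions less than `gap` apart join one cluster); the
#' max-diameter alternative caps the cluster span at `gap`. The cluster's
#' representative position is its innermost mapped base toward the
#' presumed insertion point: the maximum position for forward clusters,
#' the minimum for reverse clusters.
#'
#' @param pairs output of [find_junction_pairs()].
#' @param gap chaining distance in bp (strictly-less-than rule).
#' @param method "single" (transitive chaining) or "diameter" (cluster
#'   span < `gap`).
#' @return data.frame of clusters: `sample_id`, `chrom`, `orientation`
#'   ("forward"/"reverse"), `family`, `pos` (representative), `support`,
#'   `min_pos`, `max_pos`.
#' @export
cluster_junctions <- function(pairs, gap = 100,
                              method = c("single", "diameter")) {
  method <- match.arg(method)
  if (nrow(pairs) == 0)
    return(data.frame(sample_id = character(), chrom = character(),
                      orientation = character(), family = character(),
                      pos = integer(), support = integer(),
                      min_pos = integer(), max_pos = integer(),
                      stringsAsFactors = FALSE))
  key <- paste(pairs$sample_id, pairs$chrom, pairs$strand, pairs$family,
               sep = "\r")
  out <- lapply(split(seq_len(nrow(pairs)), key), function(idx) {
    p <- pairs[idx, , drop = FALSE]
    o <- order(p$pos)
    p <- p[o, , drop = FALSE]
    if (method == "single") {
      newc <- c(TRUE, diff(p$pos) >= gap)
    } else {
      newc <- logical(nrow(p)); anchor <- p$pos[1]; newc[1] <- TRUE
      for (i in seq_len(nrow(p))[-1]) {
        if (p$pos[i] - anchor >= gap) { newc[i] <- TRUE; anchor <- p$pos[i] }
      }
    }
    cid <- cumsum(newc)
    do.call(rbind, lapply(split(seq_len(nrow(p)), cid), function(ii) {
      q <- p[ii, , drop = FALSE]
      data.frame(sample_id = q$sample_id[1], chrom = q$chrom[1],
                 orientation = if (q$strand[1] == "+") "forward"
                 else "reverse",
                 family = q$family[1],
                 pos = if (q$strand[1] == "+") max(q$pos) else min(q$pos),
                 support = nrow(q),
                 min_pos = min(q$pos), max_pos = max(q$pos),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$sample_id, out$chrom, out$pos), , drop = FALSE]
}

#' Call insertions from dual junction evidence
#'
#' An insertion is called only when a forward (5') junction cluster is
#' followed by a reverse (3') junction cluster of the same TE family less
#' than `gap` bp downstream — the conservative dual-junction rule that
#' rejects single-junction chimeric artifacts. When several candidate
#' partners fall within the gap, clusters are paired one-to-one greedily
#' by nearest distance, ties broken by higher support and then leftmost
#' position; each cluster is used in at most one call.
#'
#' @param clusters output of [cluster_junctions()].
#' @param gap maximum 5'-to-3' junction separation (strict).
#' @param same_family require both junctions to implicate the same TE
#'   family.
#' @return data.frame of calls: `sample_id`, `chrom`, `pos5`, `pos3`,
#'   `family`, `support5`, `support3`, `novel` (NA until
#'   [filter_novel()]).
#' @export
call_insertions <- function(clusters, gap = 100, same_family = TRUE) {
  empty <- data.frame(sample_id = character(), chrom = character(),
                      pos5 = integer(), pos3 = integer(),
                      family = character(), support5 = integer(),
                      support3 = integer(), novel = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(clusters) == 0) return(empty)
  key <- if (same_family)
    paste(clusters$sample_id, clusters$chrom, clusters$family,
          sep = "\r")
  else paste(clusters$sample_id, clusters$chrom, sep = "\r")
  out <- lapply(split(seq_len(nrow(clusters)), key), function(idx) {
    cl <- clusters[idx, , drop = FALSE]
    fw <- cl[cl$orientation == "forward", , drop = FALSE]
    rv <- cl[cl$orientation == "reverse", , drop = FALSE]
    if (nrow(fw) == 0 || nrow(rv) == 0) return(NULL)
    cand <- expand.grid(f = seq_len(nrow(fw)), r = seq_len(nrow(rv)))
    cand$d <- rv$pos[cand$r] - fw$pos[cand$f]
    cand <- cand[cand$d >= 0 & cand$d < gap, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    cand$supp <- pmin(fw$support[cand$f], rv$support[cand$r])
    cand <- cand[order(cand$d, -cand$supp, fw$pos[cand$f]), ,
                 drop = FALSE]
    used_f <- logical(nrow(fw)); used_r <- logical(nrow(rv))
    rows <- list()
    for (i in seq_len(nrow(cand))) {
      fi <- cand$f[i]; ri <- cand$r[i]
      if (used_f[fi] || used_r[ri]) next
      used_f[fi] <- TRUE; used_r[ri] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = fw$sample_id[fi], chrom = fw$chrom[fi],
        pos5 = fw$pos[fi], pos3 = rv$pos[ri],
        family = if (same_family) fw$family[fi]
        else paste(fw$family[fi], rv$family[ri], sep = "|"),
        support5 = fw$support[fi], support3 = rv$support[ri],
        novel = NA, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  out <- do.call(rbind, c(out, list(empty)))
  rownames(out) <- NULL
  out[order(out$sample_id, out$chrom, out$pos5), , drop = FALSE]
}

#' Cross-sample novelty filter
#'
#' A de novo insertion should be private to one embryo: any call lying
#' within `radius` bp (strictly) of a call from another sample — by 5'
#' position on the same chromosome — is removed from both samples. This
#' single mutual-proximity rule removes shared (germline/reference) sites
#' and near-coincident artifacts in one pass. Same-sample neighbours do
#' not trigger removal.
#'
#' @param calls combined calls across all samples (rbind of
#'   [call_insertions()] outputs with distinct `sample_id`s).
#' @param radius proximity radius in bp (strict comparison).
#' @return the surviving calls, with `novel = TRUE`.
#' @export
filter_novel <- function(calls, radius = 50) {
  if (nrow(calls) == 0) return(calls)
  drop <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    near <- calls$chrom == calls$chrom[i] &
      calls$sample_id != calls$sample_id[i] &
      abs(calls$pos5 - calls$pos5[i]) < radius
    drop[i] <- any(near)
  }
  out <- calls[!drop, , drop = FALSE]
  out$novel <- rep(TRUE, nrow(out))
  out
}

#' Run the full caller on one library
#'
#' Convenience wrapper: [find_junction_pairs()] then
#' [cluster_junctions()] then [call_insertions()].
#'
#' @param genome_aln,te_aln alignment sets (see [find_junction_pairs()]);
#'   a `read_set` may be passed as `genome_aln`, in which case its two
#'   compartments are used.
#' @param sample_id library id.
#' @param mapq_min,gap,same_family passed through.
#' @return calls data.frame.
#' @export
call_te_insertions <- function(genome_aln, te_aln = NULL,
                               sample_id = NA_character_,
                               mapq_min = 30, gap = 100,
                               same_family = TRUE) {
  if (inherits(genome_aln, "read_set")) {
    rs <- genome_aln
    if (is.na(sample_id)) sample_id <- rs$sample_id
    te_aln <- rs$te
    genome_aln <- rs$genome
  }
  pairs <- find_junction_pairs(genome_aln, te_aln, mapq_min = mapq_min,
                               sample_id = sample_id)
  call_insertions(cluster_junctions(pairs, gap = gap), gap = gap,
                  same_family = same_family)
}

#' Exon-sequence negative control
#'
#' Re-runs the identical caller with the TE library replaced by exon
#' sequences. Genuine biology cannot produce exon-to-unique dual
#' junctions, so per-library call counts measure the false-positive
#' (chimeric-artifact) floor of the pipeline.
#'
#' @param genome_aln_list named list (per library) of genome alignment
#'   data.frames.
#' @param exon_aln_list named list (per library) of alignments to the
#'   exon index (same shape as TE alignments, `family` = exon id).
#' @param mapq_min,gap passed to the caller.
#' @return named integer vector: control call count per library.
#' @export
exon_control <- function(genome_aln_list, exon_aln_list, mapq_min = 30,
                         gap = 100) {
  if (length(exon_aln_list) == 0)
    stop("exon index is empty: no control alignments supplied")
  stopifnot(identical(names(genome_aln_list), names(exon_aln_list)))
  vapply(names(genome_aln_list), function(s) {
    nrow(call_te_insertions(genome_aln_list[[s]], exon_aln_list[[s]],
                            sample_id = s, mapq_min = mapq_min,
                            gap = gap))
  }, integer(1))
}
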