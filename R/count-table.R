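#' Feature count table
#'
#' A features-by-samples matrix of read counts (integers when raw,
#' non-negative reals after normalization), with a per-feature class
#' ("gene" or "TE") and a one-way normalization-state flag. State
#' transitions are recorded and may only move forward:
#' raw -> autosomal-median -> autosomal-median+pseudocount ->
#' copy-number.
#'
#' @param counts numeric matrix, features x samples, with dimnames.
#' @param feature_class "gene"/"TE" per row (recycled if length 1).
#' @param state normalization state flag.
#' @return object of class `count_table`.
#' @export
count_table <- function(counts,
                        feature_class = "TE",
                        state = c("raw", "autosomal-median",
                                  "autosomal-median+pseudocount",
                                  "copy-number")) {
  state <- match.arg(state)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry feature and sample dimnames")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  feature_class <- rep_len(feature_class, nrow(counts))
  stopifnot(all(feature_class %in% c("gene", "TE")))
  structure(list(counts = counts, feature_class = feature_class,
                 state = state),
            class = "count_table")
}

.norm_states <- c("raw", "autosomal-median",
                  "autosomal-median+pseudocount", "copy-number")

advance_state <- function(tab, new_state) {
  if (match(new_state, .norm_states) <= match(tab$state, .norm_states))
    stop("normalization state may only move forward (", tab$state,
         " -> ", new_state, ")")
  tab$state <- new_state
  tab
}

#' @export
print.count_table <- function(x, ...) {
  cat("Count table:", nrow(x$counts), "features x", ncol(x$counts),
      "samples [", x$state, "]\n")
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$feature_class)),
                                  table(x$feature_class)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
`[.count_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(i)) i <- match(i, rownames(x$counts))
  out <- x
  out$counts <- x$counts[i, j, drop = FALSE]
  out$feature_class <- x$feature_class[i]
  out
}

#' Tally primary alignments per feature per sample
#'
#' Counts one unit per primary, mapped alignment record per target feature
#' (gene id, chromosome-level target, or TE consensus name); secondary
#' records and unmapped reads are excluded. Features present in the target
#' list but absent from the alignments are counted zero with a warning;
#' an empty alignment set yields an all-zero column with a warning.
#'
#' @param alignments named list (one element per sample) of alignment
#'   data.frames; each needs a target column (`family` for TE-library
#'   alignments, otherwise `target` or `chrom`) and optionally `secondary`.
#' @param targets character vector of feature ids to tally.
#' @param feature_class class tag for the resulting rows.
#' @return raw `count_table`, one column per sample.
#' @export
count_features <- function(alignments, targets, feature_class = "TE") {
  stopifnot(is.list(alignments), length(names(alignments)) ==
              length(alignments))
  counts <- matrix(0L, length(targets), length(alignments),
                   dimnames = list(targets, names(alignments)))
  for (j in seq_along(alignments)) {
    aln <- alignments[[j]]
    if (is.null(aln) || nrow(aln) == 0) {
      warning("empty alignment set for sample ", names(alignments)[j],
              "; all-zero column")
      next
    }
    tcol <- intersect(c("family", "target", "chrom"), names(aln))[1]
    if (is.na(tcol)) stop("no target column in alignments for sample ",
                          names(alignments)[j])
    if ("secondary" %in% names(aln)) aln <- aln[!aln$secondary, ,
                                                drop = FALSE]
    tt <- table(factor(aln[[tcol]], levels = targets))
    counts[, j] <- as.integer(tt)
  }
  missing_feats <- targets[rowSums(counts) == 0]
  if (length(missing_feats) > 0 && length(missing_feats) < length(targets))
    warning(length(missing_feats),
            " target(s) absent from all alignments; counted 0")
  count_table(counts, feature_class = feature_class, state = "raw")
}
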