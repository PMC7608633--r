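#' Split alignments between sample and spike-in compartments
#'
#' Reads aligned against a concatenated sample + spike reference are
#' assigned to exactly one compartment by the contig of their primary
#' alignment (a best-alignment mapper reports one placement per read, so
#' reads from the spike genome land on spike contigs).
#'
#' @param reads data.frame of read alignments with a `chrom` column (a
#'   `chip_read_set` element, or any interval table).
#' @param sample_contigs,spike_contigs declared contig names of each
#'   compartment.
#' @return list with `sample` and `spike` data.frames.
#' @export
split_spike_reads <- function(reads, sample_contigs, spike_contigs) {
  seen <- unique(reads$chrom)
  unknown <- setdiff(seen, c(sample_contigs, spike_contigs))
  if (length(unknown) > 0)
    stop("contig(s) not declared in either compartment: ",
         paste(unknown, collapse = ", "))
  list(sample = reads[reads$chrom %in% sample_contigs, , drop = FALSE],
       spike = reads[reads$chrom %in% spike_contigs, , drop = FALSE])
}

#' Window enrichment ratio
#'
#' The closed-form enrichment of one window: ChIP reads over the ChIP
#' library's median autosomal coverage, divided by input reads over the
#' input library's median autosomal coverage. [window_enrichment()]
#' applies this formula per window.
#'
#' @param chip_count,input_count reads in the window per library.
#' @param chip_coverage,input_coverage median autosomal per-bp coverage
#'   per library.
#' @return numeric enrichment; e.g. `enrichment_ratio(200, 20, 100, 20)`
#'   is 2.
#' @export
enrichment_ratio <- function(chip_count, chip_coverage, input_count,
                             input_coverage) {
  (chip_count / chip_coverage) / (input_count / input_coverage)
}

# weighted median over (value, weight) pairs
weighted_median <- function(v, w) {
  o <- order(v)
  v <- v[o]; w <- as.numeric(w[o])
  cw <- cumsum(w) / sum(w)
  i <- which(cw >= 0.5)[1]
  if (cw[i] == 0.5 && i < length(v)) (v[i] + v[i + 1]) / 2 else v[i]
}

# median per-bp coverage over the named contigs
median_coverage <- function(reads, chrom_table, contigs) {
  ct <- chrom_table[chrom_table$name %in% contigs, , drop = FALSE]
  if (nrow(ct) == 0) stop("no contigs to compute coverage over")
  r <- reads[reads$chrom %in% ct$name, , drop = FALSE]
  if (nrow(r) == 0) return(0)
  gr <- GenomicRanges::GRanges(
    r$chrom, IRanges::IRanges(r$start + 1L, r$end),
    seqinfo = GenomeInfoDb::Seqinfo(ct$name, ct$length))
  cov <- GenomicRanges::coverage(gr)
  vals <- unlist(lapply(cov, S4Vectors::runValue), use.names = FALSE)
  lens <- unlist(lapply(cov, S4Vectors::runLength), use.names = FALSE)
  weighted_median(vals, lens)
}

count_midpoints <- function(reads, windows) {
  if (nrow(reads) == 0) return(integer(nrow(windows)))
  mid <- floor((reads$start + reads$end) / 2)
  mgr <- GenomicRanges::GRanges(reads$chrom,
                                IRanges::IRanges(mid + 1L, width = 1L))
  wgr <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start + 1L,
                                                 windows$end))
  GenomicRanges::countOverlaps(wgr, mgr)
}

#' Window-level ChIP/input enrichment
#'
#' For each fixed-width window, enrichment is the ratio of
#' depth-normalized ChIP to depth-normalized input reads:
#' \deqn{\frac{\mathrm{ChIP\ reads} / \mathrm{median\ autosomal\
#' coverage\ of\ ChIP}}{\mathrm{input\ reads} / \mathrm{median\
#' autosomal\ coverage\ of\ input}}}
#' Reads are counted by their midpoint (no double counting at window
#' boundaries); the per-library normalizer is the median per-bp coverage
#' over autosomal contigs, so uniform depth rescaling of either library
#' cancels. Windows with zero input reads get `NA` (missing, not
#' infinite).
#'
#' @param chip_reads,input_reads read-interval data.frames (`chrom`,
#'   `start`, `end`), already restricted to the sample compartment (see
#'   [split_spike_reads()]).
#' @param chrom_table chromosome table (`name`, `length`, `class`); the
#'   `class == "autosome"` contigs define the normalizer. For a spike
#'   compartment pass all its contigs as autosomes.
#' @param window_size window width in bp.
#' @param mapq_min optional minimum mapping quality; reads below it are
#'   dropped when the input carries a `mapq` column (unique-read variant).
#' @return an `enrichment_track` of windows.
#' @export
window_enrichment <- function(chip_reads, input_reads, chrom_table,
                              window_size = 50000L, mapq_min = NULL) {
  if (!is.null(mapq_min)) {
    if ("mapq" %in% names(chip_reads))
      chip_reads <- chip_reads[chip_reads$mapq >= mapq_min, , drop = FALSE]
    if ("mapq" %in% names(input_reads))
      input_reads <- input_reads[input_reads$mapq >= mapq_min, ,
                                 drop = FALSE]
  }
  windows <- tile_windows(chrom_table, window_size)
  aut <- chrom_table$name[chrom_table$class == "autosome"]
  cmed <- median_coverage(chip_reads, chrom_table, aut)
  imed <- median_coverage(input_reads, chrom_table, aut)
  if (cmed <= 0 || imed <= 0)
    stop("median autosomal coverage must be > 0 for both libraries")
  cc <- count_midpoints(chip_reads, windows)
  ic <- count_midpoints(input_reads, windows)
  val <- enrichment_ratio(cc, cmed, ic, imed)
  val[ic == 0] <- NA_real_
  if (any(ic == 0))
    message(sum(ic == 0), " window(s) with zero input reads set to NA")
  enrichment_track(windows$chrom, windows$start, windows$end, val)
}

#' Per-bp ChIP/input enrichment track
#'
#' Same normalization as [window_enrichment()] at 1-bp resolution, for
#' meta-profiles. Positions with zero input coverage are `NA`.
#'
#' @inheritParams window_enrichment
#' @return a `perbp_track`: named list (one numeric vector per
#'   chromosome) of per-bp enrichment values.
#' @export
perbp_enrichment <- function(chip_reads, input_reads, chrom_table) {
  aut <- chrom_table$name[chrom_table$class == "autosome"]
  cmed <- median_coverage(chip_reads, chrom_table, aut)
  imed <- median_coverage(input_reads, chrom_table, aut)
  if (cmed <= 0 || imed <= 0)
    stop("median autosomal coverage must be > 0 for both libraries")
  si <- GenomeInfoDb::Seqinfo(chrom_table$name, chrom_table$length)
  cov_of <- function(r) {
    gr <- GenomicRanges::GRanges(r$chrom,
                                 IRanges::IRanges(r$start + 1L, r$end),
                                 seqinfo = si)
    GenomicRanges::coverage(gr)
  }
  ccov <- cov_of(chip_reads); icov <- cov_of(input_reads)
  out <- lapply(chrom_table$name, function(cn) {
    ch <- as.numeric(ccov[[cn]]); ih <- as.numeric(icov[[cn]])
    v <- (ch / cmed) / (ih / imed)
    v[ih == 0] <- NA_real_
    v
  })
  names(out) <- chrom_table$name
  structure(out, class = "perbp_track")
}

#' Build the spike-in enrichment reference
#'
#' All libraries share the same spike chromatin, so their spike-in
#' enrichment landscapes should agree; systematic differences reflect
#' per-library pulldown efficiency. The reference is the per-window mean
#' of the spike tracks across libraries, sorted into a distribution that
#' each library's spike values are later quantile-matched against.
#'
#' @param spike_tracks list of `enrichment_track`s over identical spike
#'   windows.
#' @return object of class `spike_reference`: list with sorted `values`
#'   and `provenance`.
#' @export
build_spike_reference <- function(spike_tracks) {
  stopifnot(length(spike_tracks) >= 1)
  vals <- sapply(spike_tracks, function(t) t$value)
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = length(spike_tracks))
  means <- rowMeans(vals)
  if (anyNA(means))
    stop("spike tracks contain missing windows; cannot build reference")
  structure(list(values = sort(means),
                 n_windows = length(means),
                 provenance = names(spike_tracks)),
            class = "spike_reference")
}

#' Spike-in quantile normalization of an enrichment track
#'
#' Removes per-library pulldown-efficiency distortion in two steps:
#' (1) the library's own spike enrichment values are quantile-matched to
#' the reference distribution, defining a monotone value-to-value
#' correction map (the i-th smallest spike value is corrected to the i-th
#' smallest reference value); (2) the same correction is applied to every
#' window of the actual sample — a window whose enrichment equals an
#' observed spike value receives exactly that spike value's correction,
#' and values falling between observed spike values are corrected by
#' piecewise-linear interpolation, with constant extrapolation beyond the
#' spike range (flagged).
#'
#' @param sample_track `enrichment_track` of the sample compartment.
#' @param own_spike_track this library's spike `enrichment_track`; its
#'   window count must equal the reference length.
#' @param reference a [build_spike_reference()] result.
#' @return the corrected sample `enrichment_track`; attributes
#'   `correction_map` (data.frame `spike_value`, `corrected`),
#'   `spike_normalized` (the library's corrected spike values, sorted) and
#'   `n_extrapolated`.
#' @export
spikein_quantile_normalize <- function(sample_track, own_spike_track,
                                       reference) {
  stopifnot(inherits(reference, "spike_reference"))
  sv <- own_spike_track$value
  if (length(sv) == 0) stop("empty spike track")
  if (length(sv) != reference$n_windows)
    stop("spike track window count (", length(sv),
         ") must equal reference length (", reference$n_windows, ")")
  if (anyNA(sv)) stop("spike track contains missing windows")
  o <- order(sv)
  s_sorted <- sv[o]
  r_sorted <- reference$values
  # tie-safe map: average the corrected values over tied spike values
  agg <- tapply(r_sorted, s_sorted, mean)
  map <- data.frame(spike_value = as.numeric(names(agg)),
                    corrected = as.numeric(agg))
  x <- sample_track$value
  extrap <- !is.na(x) & (x < min(map$spike_value) |
                           x > max(map$spike_value))
  apply_map <- function(v) {
    if (nrow(map) == 1L) return(ifelse(is.na(v), NA_real_, map$corrected))
    stats::approx(map$spike_value, map$corrected, xout = v,
                  rule = 2, ties = "ordered")$y
  }
  corrected <- apply_map(x)
  out <- enrichment_track(sample_track$chrom, sample_track$start,
                          sample_track$end, pmax(corrected, 0))
  attr(out, "correction_map") <- map
  attr(out, "spike_normalized") <- sort(apply_map(sv))
  attr(out, "n_extrapolated") <- sum(extrap)
  out
}
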