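#' Enrichment track constructor
#'
#' An ordered set of genomic windows (0-based half-open) each carrying one
#' non-negative enrichment value; missing values are explicit `NA`, never
#' silently zero.
#'
#' @param chrom,start,end window coordinates.
#' @param value enrichment values (>= 0 or NA).
#' @param resolution "window" or "perbp".
#' @return data.frame of class `enrichment_track`.
#' @export
enrichment_track <- function(chrom, start, end, value,
                             resolution = c("window", "perbp")) {
  resolution <- match.arg(resolution)
  if (any(value < 0, na.rm = TRUE)) stop("enrichment values must be >= 0")
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  structure(df, class = c("enrichment_track", "data.frame"),
            resolution = resolution)
}

#' Tile a chromosome table into fixed windows
#'
#' @param chrom_table data.frame with `name` and `length` columns.
#' @param window_size window width in bp (last window of each chromosome
#'   is truncated at the chromosome end).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
tile_windows <- function(chrom_table, window_size = 50000L) {
  out <- lapply(seq_len(nrow(chrom_table)), function(i) {
    L <- chrom_table$length[i]
    starts <- seq(0L, L - 1L, by = window_size)
    data.frame(chrom = chrom_table$name[i], start = starts,
               end = pmin(starts + window_size, L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Deterministic spike-in enrichment landscape
#'
#' The spike genome plays the role of fixed foreign chromatin added to
#' every library: its true enrichment landscape is a fixed, library-
#' independent pattern, so between-library differences in its observed
#' enrichment isolate pulldown-efficiency distortion.
#'
#' @param spike_chroms chromosome table for the spike genome.
#' @param window_size window width in bp.
#' @return an `enrichment_track` over the spike windows.
#' @export
spike_truth_track <- function(spike_chroms, window_size = 50000L) {
  w <- tile_windows(spike_chroms, window_size)
  vals <- rep(c(0.5, 1, 1.5, 2, 3, 4), length.out = nrow(w))
  enrichment_track(w$chrom, w$start, w$end, vals)
}

#' Simulate ChIP and input reads with a spike-in compartment
#'
#' Input reads are uniform over the concatenated sample + spike genomes,
#' with the stated fraction of chromatin coming from the spike compartment
#' (mirroring a fixed-percentage spike design). ChIP reads are sampled
#' with window weights proportional to `distortion(true enrichment)`, the
#' monotone pulldown-efficiency distortion applied identically to sample
#' and spike chromatin. A zero-depth request returns empty read sets.
#'
#' @param sample_chroms,spike_chroms chromosome tables (`name`, `length`,
#'   and for the sample genome `class`).
#' @param true_enrichment `enrichment_track` over the sample genome
#'   windows.
#' @param spike_truth `enrichment_track` over the spike windows (default
#'   [spike_truth_track()]).
#' @param spike_fraction fraction of chromatin from the spike genome.
#' @param distortion monotone function applied to true enrichment
#'   (identity by default).
#' @param depth fold coverage of the combined genome (single-end reads).
#' @param read_len read length in bp.
#' @param seed RNG seed.
#' @return list of class `chip_read_set`: `chip` and `input` read-interval
#'   data.frames (`chrom`, `start`, `end`), plus contig bookkeeping.
#' @export
simulate_chip_reads <- function(sample_chroms, true_enrichment,
                                spike_chroms = default_spike_chroms(),
                                spike_truth = spike_truth_track(spike_chroms),
                                spike_fraction = 0.2,
                                distortion = identity,
                                depth = 5, read_len = 100L, seed = 1L) {
  if (depth < 0) stop("depth must be >= 0")
  if (spike_fraction < 0 || spike_fraction >= 1)
    stop("spike_fraction must lie in [0, 1)")
  set.seed(seed)
  G <- sum(sample_chroms$length) + sum(spike_chroms$length)
  n_reads <- round(depth * G / read_len)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (n_reads == 0)
    return(structure(list(chip = empty, input = empty,
                          sample_contigs = sample_chroms$name,
                          spike_contigs = spike_chroms$name,
                          read_len = as.integer(read_len)),
                     class = "chip_read_set"))

  # window tables for both compartments, with sampling weights
  wt_input <- c((1 - spike_fraction) *
                  (true_enrichment$end - true_enrichment$start) /
                  sum(true_enrichment$end - true_enrichment$start),
                spike_fraction *
                  (spike_truth$end - spike_truth$start) /
                  sum(spike_truth$end - spike_truth$start))
  dist_s <- distortion(true_enrichment$value)
  dist_k <- distortion(spike_truth$value)
  wt_chip <- wt_input * c(dist_s, dist_k)
  windows <- rbind(true_enrichment[, c("chrom", "start", "end")],
                   spike_truth[, c("chrom", "start", "end")])

  draw <- function(weights) {
    w <- ifelse(is.na(weights), 0, weights)
    idx <- sample.int(nrow(windows), n_reads, replace = TRUE,
                      prob = w / sum(w))
    st <- windows$start[idx] +
      floor(stats::runif(n_reads) *
              pmax(1L, windows$end[idx] - windows$start[idx] - read_len))
    data.frame(chrom = windows$chrom[idx], start = as.integer(st),
               end = as.integer(st + read_len), stringsAsFactors = FALSE)
  }
  input <- draw(wt_input)
  chip <- draw(wt_chip)
  structure(list(chip = chip, input = input,
                 sample_contigs = sample_chroms$name,
                 spike_contigs = spike_chroms$name,
                 read_len = as.integer(read_len)),
            class = "chip_read_set")
}

#' @rdname simulate_chip_reads
#' @export
default_spike_chroms <- function() {
  data.frame(name = c("spike_1", "spike_2"),
             length = c(400000L, 400000L),
             class = "autosome", stringsAsFactors = FALSE)
}
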