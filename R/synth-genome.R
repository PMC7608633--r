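#' Specify a synthetic genome
#'
#' Describes a small multi-chromosome genome for simulation: chromosome
#' names, lengths and classes (autosome, X, or Y), per-chromosome TE and
#' gene densities, the size of the TE consensus library, and the fraction
#' of genes flagged as zygotically expressed. The Y chromosome is intended
#' to emulate a young, repeat-dense but gene-bearing neo-Y, so its default
#' TE density exceeds the autosomal one.
#'
#' @param chromosomes data.frame with columns `name`, `length` (bp),
#'   `class` (one of "autosome", "X", "Y"), `te_density` (TE copies per Mb)
#'   and `gene_density` (genes per Mb).
#' @param n_te_families number of TE consensus families in the library.
#' @param te_length_range two integers, min/max consensus length in bp.
#' @param gene_length gene interval length in bp.
#' @param zygotic_fraction fraction of genes flagged zygotically expressed.
#' @param gene_near_te_fraction fraction of genes deliberately placed
#'   adjacent (within 1 kb) to a planted TE copy.
#' @param te_divergence per-copy substitution rate applied to planted
#'   copies (0 = identical to consensus).
#' @param seed single RNG seed governing all sampling in [make_genome()].
#' @return an object of class `synth_genome_spec`.
#' @export
synth_genome_spec <- function(chromosomes = default_chromosomes(),
                              n_te_families = 20,
                              te_length_range = c(400L, 1500L),
                              gene_length = 2000L,
                              zygotic_fraction = 0.3,
                              gene_near_te_fraction = 0.25,
                              te_divergence = 0,
                              seed = 1L) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length", "class", "te_density", "gene_density")
                %in% names(chromosomes)))
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be > 0")
  if (any(chromosomes$te_density < 0) || any(chromosomes$gene_density < 0))
    stop("densities must be >= 0")
  if (!all(chromosomes$class %in% c("autosome", "X", "Y")))
    stop("chromosome class must be autosome, X or Y")
  if (length(seed) != 1L) stop("exactly one RNG seed governs all sampling")
  stopifnot(n_te_families >= 0, length(te_length_range) == 2L,
            te_length_range[1] > 0, te_length_range[2] >= te_length_range[1],
            zygotic_fraction >= 0, zygotic_fraction <= 1,
            te_divergence >= 0, te_divergence < 1)
  structure(list(chromosomes = chromosomes,
                 n_te_families = as.integer(n_te_families),
                 te_length_range = as.integer(te_length_range),
                 gene_length = as.integer(gene_length),
                 zygotic_fraction = zygotic_fraction,
                 gene_near_te_fraction = gene_near_te_fraction,
                 te_divergence = te_divergence,
                 seed = as.integer(seed)),
            class = "synth_genome_spec")
}

#' Default chromosome layout: two autosomes, an X, and a repeat-dense Y
#' @rdname synth_genome_spec
#' @export
default_chromosomes <- function() {
  data.frame(name = c("chr2", "chr3", "chrX", "chrY"),
             length = c(800000L, 800000L, 600000L, 600000L),
             class = c("autosome", "autosome", "X", "Y"),
             te_density = c(30, 30, 40, 120),
             gene_density = c(60, 60, 50, 25),
             stringsAsFactors = FALSE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# place `widths` non-overlapping intervals in [0, L), avoiding `avoid`
# (an IRanges); bounded retries, 0-based half-open starts returned
place_intervals <- function(widths, L, avoid = NULL, chrom = "?",
                            max_tries = 200L) {
  placed <- IRanges::IRanges()
  starts <- integer(length(widths))
  for (i in seq_along(widths)) {
    w <- widths[i]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      if (L - w < 1) break
      s <- sample.int(L - w, 1L)  # 1-based start in [1, L-w]
      cand <- IRanges::IRanges(start = s, width = w)
      hit <- length(IRanges::findOverlaps(cand, placed)) > 0L
      if (!hit && !is.null(avoid))
        hit <- length(IRanges::findOverlaps(cand, avoid)) > 0L
      if (!hit) { ok <- TRUE; break }
    }
    if (!ok)
      stop("cannot place interval ", i, " of width ", w, " on ", chrom,
           " after ", max_tries, " tries (density too high?)")
    placed <- c(placed, cand)
    starts[i] <- s - 1L  # back to 0-based
  }
  starts
}

#' Generate a synthetic genome with planted TE copies and genes
#'
#' Builds random-sequence chromosomes, a TE consensus library, germline TE
#' copies planted at the per-chromosome densities, gene intervals (a
#' configurable fraction adjacent to TEs), and a truth set recording all
#' placements. All annotation intervals are 0-based half-open. The same
#' spec and seed always regenerate byte-identical sequences and truth.
#'
#' @param spec a [synth_genome_spec()].
#' @return an object of class `synth_genome`: a list with elements
#'   `seq` (named `DNAStringSet` of chromosomes), `te_library`
#'   (`DNAStringSet` of consensus sequences), `annotation`
#'   (class `genome_annotation`: `$chrom`, `$genes`, `$tes`) and
#'   `truth` (class `truth_set`).
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "synth_genome_spec"))
  set.seed(spec$seed)
  chroms <- spec$chromosomes

  # TE consensus library: fixed random sequence per family
  fam_len <- if (spec$n_te_families > 0)
    spec$te_length_range[1] +
      sample.int(spec$te_length_range[2] - spec$te_length_range[1] + 1L,
                 spec$n_te_families, replace = TRUE) - 1L
  else integer(0)
  fam_names <- sprintf("TE%03d", seq_len(spec$n_te_families))
  te_library <- Biostrings::DNAStringSet(vapply(fam_len, random_dna, ""))
  names(te_library) <- fam_names

  seqs <- character(nrow(chroms))
  te_rows <- vector("list", nrow(chroms))
  gene_rows <- vector("list", nrow(chroms))
  for (ci in seq_len(nrow(chroms))) {
    L <- chroms$length[ci]; cname <- chroms$name[ci]
    chrseq <- random_dna(L)

    n_te <- round(chroms$te_density[ci] * L / 1e6)
    if (n_te > 0 && spec$n_te_families == 0)
      stop("TE density > 0 on ", cname, " but the library has no families")
    if (n_te > 0) {
      fams <- sample(spec$n_te_families, n_te, replace = TRUE)
      widths <- fam_len[fams]
      starts <- place_intervals(widths, L, chrom = cname)
      strands <- sample(c("+", "-"), n_te, replace = TRUE)
      copies <- character(n_te)
      for (k in seq_len(n_te)) {
        s <- as.character(te_library[[fams[k]]])
        if (spec$te_divergence > 0) s <- mutate_seq(s, spec$te_divergence)
        if (strands[k] == "-")
          s <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(s)))
        copies[k] <- s
      }
      # overwrite genome sequence with copy sequences
      ord <- order(starts)
      starts <- starts[ord]; widths <- widths[ord]
      fams <- fams[ord]; strands <- strands[ord]; copies <- copies[ord]
      out <- character(2L * n_te + 1L); prev <- 0L
      for (k in seq_len(n_te)) {
        out[2L * k - 1L] <- substr(chrseq, prev + 1L, starts[k])
        out[2L * k] <- copies[k]
        prev <- starts[k] + widths[k]
      }
      out[2L * n_te + 1L] <- substr(chrseq, prev + 1L, L)
      chrseq <- paste(out, collapse = "")
      te_rows[[ci]] <- data.frame(chrom = cname, start = starts,
                                  end = starts + widths,
                                  strand = strands,
                                  family = fam_names[fams],
                                  stringsAsFactors = FALSE)
    }

    n_gene <- round(chroms$gene_density[ci] * L / 1e6)
    if (n_gene > 0) {
      te_ir <- if (!is.null(te_rows[[ci]]) && nrow(te_rows[[ci]]) > 0)
        IRanges::IRanges(te_rows[[ci]]$start + 1L, te_rows[[ci]]$end)
      else IRanges::IRanges()
      gstarts <- integer(n_gene)
      n_near <- round(spec$gene_near_te_fraction * n_gene)
      if (length(te_ir) == 0L) n_near <- 0L
      placed <- IRanges::IRanges()
      gi <- 1L
      while (gi <= n_gene) {
        ok <- FALSE
        for (try in seq_len(200L)) {
          if (gi <= n_near) {
            anchor <- te_rows[[ci]][sample.int(nrow(te_rows[[ci]]), 1L), ]
            s0 <- anchor$end + sample.int(1000L, 1L)  # just downstream
          } else {
            s0 <- sample.int(L - spec$gene_length, 1L)
          }
          if (s0 < 1L || s0 > L - spec$gene_length) next
          cand <- IRanges::IRanges(s0 + 1L, width = spec$gene_length)
          if (length(IRanges::findOverlaps(cand, placed)) == 0L) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop("cannot place gene ", gi, " on ", cname,
                      " after 200 tries (density too high?)")
        placed <- c(placed, cand)
        gstarts[gi] <- s0
        gi <- gi + 1L
      }
      gstrand <- sample(c("+", "-"), n_gene, replace = TRUE)
      gend <- gstarts + spec$gene_length
      gene_rows[[ci]] <- data.frame(
        chrom = cname, start = gstarts, end = gend, strand = gstrand,
        tss = ifelse(gstrand == "+", gstarts, gend - 1L),
        zygotic = as.logical(stats::rbinom(n_gene, 1, spec$zygotic_fraction)),
        stringsAsFactors = FALSE)
    }
    seqs[ci] <- chrseq
  }

  genes <- do.call(rbind, gene_rows)
  if (is.null(genes))
    genes <- data.frame(chrom = character(), start = integer(),
                        end = integer(), strand = character(),
                        tss = integer(), zygotic = logical())
  genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
  tes <- do.call(rbind, te_rows)
  if (is.null(tes))
    tes <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      family = character())

  genome_seq <- Biostrings::DNAStringSet(seqs)
  names(genome_seq) <- chroms$name
  annotation <- structure(
    list(chrom = chroms[, c("name", "length", "class")],
         genes = genes, tes = tes),
    class = "genome_annotation")
  truth <- structure(
    list(te_copies = tes,
         insertions = empty_insertion_truth(),
         expression = NULL, enrichment = NULL, distortions = NULL),
    class = "truth_set")
  structure(list(seq = genome_seq, te_library = te_library,
                 annotation = annotation, truth = truth, spec = spec),
            class = "synth_genome")
}

mutate_seq <- function(s, rate) {
  n <- nchar(s)
  k <- stats::rbinom(1, n, rate)
  if (k == 0) return(s)
  pos <- sample.int(n, k)
  v <- strsplit(s, "")[[1]]
  v[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
  paste(v, collapse = "")
}

empty_insertion_truth <- function() {
  data.frame(ins_id = character(), chrom = character(), pos = integer(),
             family = character(), sample_id = character(),
             cell_fraction = numeric(), stringsAsFactors = FALSE)
}

#' @export
print.synth_genome <- function(x, ...) {
  cat("Synthetic genome:", length(x$seq), "chromosomes,",
      sum(x$annotation$chrom$length), "bp;",
      length(x$te_library), "TE families;",
      nrow(x$annotation$tes), "planted copies;",
      nrow(x$annotation$genes), "genes\n")
  invisible(x)
}

#' Plant de novo TE insertions into the truth set
#'
#' Registers de novo insertions (the events the dual-junction caller is
#' meant to recover) at positions in unique, TE-free sequence, with a
#' clearance from germline TE copies and chromosome ends so that both
#' flanks are uniquely mappable, and a minimum pairwise separation so
#' calls stay distinct. Each insertion carries a TE family, one or more
#' carrier samples and a cell fraction: the fraction of cells (implemented
#' as the per-fragment sampling probability) bearing the insertion.
#'
#' @param genome a `synth_genome`.
#' @param n number of insertions.
#' @param samples carrier sample id(s): a character vector (each insertion
#'   gets one carrier, recycled) or a list of character vectors (an
#'   insertion may be carried by several samples — used to exercise the
#'   cross-sample novelty filter).
#' @param cell_fraction per-insertion fraction in (0, 1], recycled.
#' @param clearance minimum bp between an insertion point and any germline
#'   TE copy or chromosome end.
#' @param min_separation minimum bp between insertion points.
#' @param seed RNG seed.
#' @return the `synth_genome` with `truth$insertions` filled in.
#' @export
plant_insertions <- function(genome, n, samples, cell_fraction = 1,
                             clearance = 2000L, min_separation = 1000L,
                             seed = 1L) {
  stopifnot(inherits(genome, "synth_genome"), n >= 1)
  if (any(cell_fraction <= 0) || any(cell_fraction > 1))
    stop("cell_fraction must lie in (0, 1]")
  if (length(genome$te_library) == 0)
    stop("no TE families to insert")
  set.seed(seed)
  if (!is.list(samples)) samples <- as.list(samples)
  samples <- rep_len(samples, n)
  cell_fraction <- rep_len(cell_fraction, n)
  chroms <- genome$annotation$chrom
  tes <- genome$annotation$tes

  pos <- integer(n); chrom <- character(n)
  chosen <- list()
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(500L)) {
      ci <- sample.int(nrow(chroms), 1L, prob = chroms$length)
      L <- chroms$length[ci]; cname <- chroms$name[ci]
      p <- sample(seq(clearance, L - clearance), 1L)
      ctes <- tes[tes$chrom == cname, , drop = FALSE]
      if (nrow(ctes) > 0 &&
          any(p > ctes$start - clearance & p < ctes$end + clearance)) next
      near <- vapply(chosen, function(z)
        z$chrom == cname && abs(z$pos - p) < min_separation, logical(1))
      if (any(near)) next
      ok <- TRUE; break
    }
    if (!ok) stop("cannot place insertion ", i,
                  " with the requested clearance")
    chrom[i] <- cname; pos[i] <- p
    chosen[[i]] <- list(chrom = cname, pos = p)
  }
  fam <- sample(names(genome$te_library), n, replace = TRUE)
  ins <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(ins_id = sprintf("ins%03d", i), chrom = chrom[i],
               pos = pos[i], family = fam[i],
               sample_id = samples[[i]],
               cell_fraction = cell_fraction[i],
               stringsAsFactors = FALSE)
  }))
  genome$truth$insertions <- ins
  genome
}
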