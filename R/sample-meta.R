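#' Build a validated sample sheet
#'
#' A sample sheet records the identity of each sequencing library: species,
#' sex, developmental stage, replicate and assay. Every cross-sample
#' comparison in the package (sex fold differences, Wilcoxon tests,
#' Y-enrichment classification, insertion-count models) is driven by this
#' design table.
#'
#' @param sample_id character vector of unique library ids.
#' @param species species label (recycled if length 1).
#' @param sex "female" or "male".
#' @param stage developmental stage; any orderable numeric (embryonic stage
#'   number in this package's conventions).
#' @param replicate integer replicate index within species x sex x stage.
#' @param assay one of "RNA", "DNA", "ChIP", "input".
#' @return a `data.frame` of class `sample_sheet` with one row per library.
#' @examples
#' sample_sheet(c("f1", "m1"), sex = c("female", "male"), stage = 5,
#'              replicate = 1, assay = "RNA")
#' @export
sample_sheet <- function(sample_id, species = "synthetic",
                         sex, stage, replicate = 1L, assay = "RNA") {
  sex <- match.arg(sex, c("female", "male"), several.ok = TRUE)
  assay <- match.arg(assay, c("RNA", "DNA", "ChIP", "input"), several.ok = TRUE)
  df <- data.frame(sample_id = as.character(sample_id),
                   species = species, sex = sex,
                   stage = as.numeric(stage),
                   replicate = as.integer(replicate),
                   assay = assay,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("sample ids must be unique: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (any(is.na(df$stage))) stop("stages must be orderable (non-NA numeric)")
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' @export
print.sample_sheet <- function(x, ...) {
  cat("Sample sheet:", nrow(x), "libraries\n")
  print.data.frame(x, ...)
  invisible(x)
}

# rows of `design` for the given sex/stage/assay; NULL filters are ignored
design_rows <- function(design, sex = NULL, stage = NULL, assay = NULL) {
  keep <- rep(TRUE, nrow(design))
  if (!is.null(sex))   keep <- keep & design$sex == sex
  if (!is.null(stage)) keep <- keep & design$stage == stage
  if (!is.null(assay)) keep <- keep & design$assay == assay
  design[keep, , drop = FALSE]
}
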