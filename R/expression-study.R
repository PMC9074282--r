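#' Construct an expression study
#'
#' Bundles a transcripts x samples expression matrix with the per-sample
#' factors of a line x sex x treatment x replicate design. The matrix can be
#' on the raw count scale or on the log2 normalized scale; the scale is
#' flagged so downstream fitting can refuse unnormalized input.
#'
#' @param values numeric matrix, transcripts in rows, samples in columns.
#'   Row and column names are required.
#' @param samples data.frame with one row per column of `values` and columns
#'   `sample`, `line`, `sex` ("F"/"M"), `treatment` ("ethanol"/"control"),
#'   `replicate`, `wolbachia` ("yes"/"no").
#' @param scale "counts" or "log2".
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(values, samples, scale = c("log2", "counts")) {
  scale <- match.arg(scale)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have transcript rownames and sample colnames")
  req <- c("sample", "line", "sex", "treatment", "replicate", "wolbachia")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("sample sheet is missing columns: ", paste(miss, collapse = ", "))
  if (!identical(colnames(values), as.character(samples$sample)))
    stop("column names of 'values' must match samples$sample exactly")
  if (anyNA(samples[req]))
    stop("sample sheet contains missing factor levels")
  if (!all(samples$sex %in% c("F", "M")))
    stop("sex must be 'F' or 'M'")
  if (!all(samples$treatment %in% c("ethanol", "control")))
    stop("treatment must be 'ethanol' or 'control'")
  if (!all(samples$wolbachia %in% c("yes", "no")))
    stop("wolbachia must be 'yes' or 'no'")
  if (scale == "counts" && any(values < 0))
    stop("counts must be nonnegative")
  structure(list(values = values, samples = samples, scale = scale),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d transcripts x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  %d lines, sexes %s, treatments %s\n",
              length(unique(x$samples$line)),
              paste(sort(unique(x$samples$sex)), collapse = "/"),
              paste(sort(unique(x$samples$treatment)), collapse = "/")))
  invisible(x)
}

## balance check: every line x sex x treatment cell has the same number of
## replicates (>= 1); returns that count
replicates_per_cell <- function(samples) {
  tab <- table(samples$line, samples$sex, samples$treatment)
  r <- unique(as.vector(tab))
  if (length(r) != 1L || r[1] < 1L)
    stop("design is not balanced: line x sex x treatment cells have unequal ",
         "replicate counts (this implementation requires balance)")
  as.integer(r[1])
}

#' Write / read an expression study as counts TSV + sample sheet TSV
#'
#' @param study an `expression_study`.
#' @param counts_file,samples_file output paths.
#' @param provenance header comment string.
#' @return the study (readers) or the paths, invisibly (writers).
#' @export
write_expression_study <- function(study, counts_file, samples_file,
                                   provenance = "gxetrans") {
  df <- data.frame(transcript = rownames(study$values),
                   study$values, check.names = FALSE)
  write_tsv_prov(df, counts_file, paste0(provenance, " scale=", study$scale))
  write_tsv_prov(study$samples, samples_file, provenance)
  invisible(c(counts_file, samples_file))
}

#' @rdname write_expression_study
#' @param scale scale flag for the matrix being read.
#' @export
read_expression_study <- function(counts_file, samples_file,
                                  scale = c("log2", "counts")) {
  scale <- match.arg(scale)
  tab <- read_tsv_prov(counts_file)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab[[1]]
  samples <- read_tsv_prov(samples_file)
  samples$sample <- as.character(samples$sample)
  samples$line <- as.character(samples$line)
  expression_study(values, samples, scale = scale)
}
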