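#' @keywords internal
"_PACKAGE"

#' @importFrom stats pf pt phyper quantile rnorm runif rpois rbinom sd var cor
#'   hclust as.dist p.adjust setNames reformulate model.matrix terms
#'   aggregate lm coef ks.test
#' @importFrom utils read.delim write.table
NULL

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

#' Derive a per-stage random seed from a global seed
#'
#' Stage seeds are the global seed plus a deterministic hash of the stage
#' name, reduced modulo 2^31 - 1 so each stage of the pipeline can be rerun
#' in isolation with the same stream it saw in a full run.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + 1009 * h) %% (2^31 - 1))
}

## TSV writers carry a one-line '#' provenance header so every table is
## self-describing; readers skip comment lines.
write_tsv_prov <- function(df, path, provenance = "gxetrans") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", provenance), con)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_prov <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}
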