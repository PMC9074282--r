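#' Trimmed-mean-of-M-values scale factors
#'
#' Per-sample TMM factors computed against a reference sample (the sample
#' whose upper-quartile count fraction is closest to the mean across
#' samples). For each sample, genewise log2 ratios M and average abundances
#' A against the reference are formed over genes with positive counts in
#' both; the most extreme 30 percent of M (each tail) and 5 percent of A are
#' trimmed by rank, and the factor is 2 to the inverse-variance weighted
#' mean of the remaining M, with the asymptotic binomial delta-method
#' weights. Factors are rescaled to have geometric mean 1.
#'
#' @param counts nonnegative count matrix, genes x samples.
#' @param logratio_trim,abundance_trim two-sided trim fractions for M and A.
#' @return named numeric vector of scale factors; the reference sample name
#'   is attached as `attr(, "ref")`.
#' @export
tmm_norm_factors <- function(counts, logratio_trim = 0.30,
                             abundance_trim = 0.05) {
  lib <- colSums(counts)
  if (any(lib <= 0))
    stop("sample(s) with zero library size: ",
         paste(colnames(counts)[lib <= 0], collapse = ", "))
  f75 <- apply(counts, 2, function(x) quantile(x, 0.75, names = FALSE)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(i)
    tmm_pair(counts[, i], counts[, ref], lib[i], lib[ref],
             logratio_trim, abundance_trim), numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  attr(f, "ref") <- colnames(counts)[ref]
  f
}

tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abundance_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (!length(m) || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abundance_trim) + 1; hi_a <- n + 1 - lo_a
  rm <- rank(m); ra <- rank(a)
  use <- rm >= lo_m & rm <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(use)) return(1)
  2^(sum(m[use] / v[use]) / sum(1 / v[use]))
}

#' TMM-normalize a count-scale study to log2 counts per million
#'
#' Scales each sample's library size by its TMM factor and returns
#' log2(CPM + 0.5), flagged as normalized. The reference sample and trim
#' fractions are recorded in `attr(, "normalization")` for provenance.
#'
#' @param raw a counts-scale [expression_study()]; every sample must have a
#'   positive library size.
#' @param pseudocount added on the CPM scale before the log.
#' @inheritParams tmm_norm_factors
#' @return a log2-scale `expression_study`.
#' @export
normalize_counts <- function(raw, pseudocount = 0.5, logratio_trim = 0.30,
                             abundance_trim = 0.05) {
  stopifnot(inherits(raw, "expression_study"))
  if (raw$scale != "counts") stop("normalize_counts expects count-scale input")
  f <- tmm_norm_factors(raw$values, logratio_trim, abundance_trim)
  eff <- colSums(raw$values) * f
  values <- log2(t(t(raw$values) / eff) * 1e6 + pseudocount)
  out <- expression_study(values, raw$samples, scale = "log2")
  attr(out, "normalization") <- list(method = "TMM", ref = attr(f, "ref"),
                                     factors = as.vector(f),
                                     logratio_trim = logratio_trim,
                                     abundance_trim = abundance_trim,
                                     pseudocount = pseudocount)
  out
}
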