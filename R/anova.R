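## ---------------------------------------------------------------------------
## Balanced factorial ANOVA engine
##
## All per-transcript models in this package share one decomposition: a
## sequential (= orthogonal, for balanced designs) sum-of-squares split over
## an ordered term list, computed once for all transcripts through a single
## QR factorisation of the shared design matrix. F tests are then formed
## from an expected-mean-squares ladder that names, per term, the mean
## square serving as its denominator. Wolbachia status is a line-level
## covariate confounded with line, so it is entered before the line terms
## and its (possibly zero) df are absorbed first; rank deficiencies are
## resolved by the QR pivot exactly as in stats::lm.
## ---------------------------------------------------------------------------

balanced_anova_engine <- function(Y, data, terms) {
  stopifnot(is.matrix(Y), ncol(Y) == nrow(data))
  for (v in all.vars(reformulate(terms))) data[[v]] <- factor(data[[v]])
  tobj <- terms(reformulate(terms), keep.order = TRUE)
  X <- model.matrix(tobj, data)
  asgn <- attr(X, "assign")
  labels <- attr(tobj, "term.labels")
  qx <- qr(X)
  rank <- qx$rank
  piv <- qx$pivot[seq_len(rank)]
  eff <- qr.qty(qx, t(Y))[seq_len(rank), , drop = FALSE]
  term_of_col <- asgn[piv]                      # 0 = intercept
  df <- tabulate(term_of_col + 1L, nbins = length(labels) + 1L)[-1]
  ss <- matrix(0, length(labels), ncol(eff))
  nz <- term_of_col > 0
  if (any(nz))
    ss[sort(unique(term_of_col[nz])), ] <-
      rowsum(eff[nz, , drop = FALSE]^2, group = term_of_col[nz])
  tot <- colSums(t(Y)^2)
  resid_ss <- pmax(tot - colSums(eff^2), 0)
  ## numerical floor below which a sum of squares counts as exactly zero
  ## (constant transcripts accumulate rounding noise of this order)
  noise_floor <- nrow(data) * (1e-7 * (1 + apply(abs(Y), 1, max)))^2
  list(terms = labels, df = df, ss = ss,
       resid_df = nrow(data) - rank, resid_ss = resid_ss,
       noise_floor = noise_floor)
}

## F tests from an EMS ladder. `denom` maps term label -> denominator term
## label or "residual". Terms with zero df get NA statistics. Zero
## numerator SS yields F = 0, p = 1 (the constant-transcript convention).
ems_f_tests <- function(fit, denom) {
  ms <- fit$ss / fit$df
  out <- list()
  for (i in seq_along(fit$terms)) {
    term <- fit$terms[i]
    d <- denom[[term]]
    if (identical(d, "residual")) {
      dms <- fit$resid_ss / fit$resid_df
      ddf <- fit$resid_df
    } else {
      j <- match(d, fit$terms)
      dms <- ms[j, ]
      ddf <- fit$df[j]
    }
    if (fit$df[i] == 0 || ddf == 0) {
      f <- rep(NA_real_, length(fit$resid_ss)); p <- f
    } else {
      f <- ms[i, ] / dms
      p <- pf(f, fit$df[i], ddf, lower.tail = FALSE)
      zero <- fit$ss[i, ] <= fit$noise_floor
      p[!is.finite(f) & !zero] <- 0  # zero denominator, positive signal
      f[zero] <- 0; p[zero] <- 1
    }
    out[[term]] <- data.frame(term = term, df = fit$df[i],
                              ss = fit$ss[i, ], ms = ms[i, ], f = f, p = p)
  }
  out
}

## long AnovaTable with BH q-values per term family
anova_long_table <- function(tests, transcripts) {
  rows <- lapply(names(tests), function(term) {
    tab <- tests[[term]]
    tab$transcript <- transcripts
    tab$q <- if (all(is.na(tab$p))) NA_real_ else bh_fdr(tab$p)
    tab[, c("transcript", "term", "df", "ss", "ms", "f", "p", "q")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjusted p-values (a thin, validating wrapper over
#' [stats::p.adjust()]; the adjustment is idempotent and monotone in p).
#'
#' @param pvalues numeric vector in [0, 1]; NaN/NA input errors.
#' @return adjusted q-values, same length.
#' @export
bh_fdr <- function(pvalues) {
  if (anyNA(pvalues)) stop("p-values contain NA/NaN")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

## term labels used in output tables
.full_terms <- c(wolbachia = "W", sex = "S", treatment = "T", line = "L",
                 "wolbachia:sex" = "WxS", "sex:treatment" = "TxS",
                 "sex:line" = "LxS", "treatment:line" = "LxT",
                 "sex:treatment:line" = "TxSxL")

#' Fit the full factorial mixed model per transcript
#'
#' Per transcript, decomposes log2 expression as
#' Y = S + W + T + L + WxS + LxS + LxT + TxS + TxSxL + e on a balanced
#' line x sex x treatment x replicate design, with line and all its
#' interactions random. F tests use the expected-mean-squares ladder for the
#' balanced mixed factorial: L, LxS and LxT are tested over the TxSxL mean
#' square, TxSxL over the residual; fixed S, T and TxS over their
#' interaction-with-line mean squares (LxS, LxT, TxSxL respectively);
#' line-level Wolbachia (entered before the line terms, which absorb its
#' confounded df) and WxS over the residual. Variance components are
#' method-of-moments from the same mean squares, truncated at zero.
#'
#' @param study a log2-scale [expression_study()] with >= 2 lines, both
#'   sexes, both treatments and >= 2 replicates per cell.
#' @param fdr FDR threshold recorded for downstream significance calls.
#' @return list with `anova` (long table: transcript, term, df, ss, ms, f,
#'   p, q with BH correction per term family), `vc` (per-transcript variance
#'   components and broad-sense heritability) and `design` (r, n_lines).
#' @export
fit_full_model <- function(study, fdr = 0.05) {
  stopifnot(inherits(study, "expression_study"))
  if (study$scale != "log2")
    stop("fit_full_model expects log2-normalized values; run normalize_counts")
  s <- study$samples
  if (length(unique(s$line)) < 2 || length(unique(s$sex)) != 2 ||
      length(unique(s$treatment)) != 2)
    stop("full model needs >= 2 lines, both sexes and both treatments")
  r <- replicates_per_cell(s)
  has_w <- length(unique(s$wolbachia)) == 2
  terms <- c(if (has_w) "wolbachia", "sex", "treatment", "line",
             if (has_w) "wolbachia:sex",
             "sex:treatment", "sex:line", "treatment:line",
             "sex:treatment:line")
  fit <- balanced_anova_engine(study$values, s, terms)
  denom <- list(wolbachia = "residual", sex = "sex:line",
                treatment = "treatment:line", line = "sex:treatment:line",
                "wolbachia:sex" = "residual",
                "sex:treatment" = "sex:treatment:line",
                "sex:line" = "sex:treatment:line",
                "treatment:line" = "sex:treatment:line",
                "sex:treatment:line" = "residual")
  tests <- ems_f_tests(fit, denom)
  anova <- anova_long_table(tests, rownames(study$values))
  anova$term <- unname(.full_terms[anova$term])

  ms <- setNames(lapply(seq_along(fit$terms),
                        function(i) fit$ss[i, ] / fit$df[i]), fit$terms)
  ms_resid <- fit$resid_ss / fit$resid_df
  v_stl <- pmax((ms[["sex:treatment:line"]] - ms_resid) / r, 0)
  v_tl <- pmax((ms[["treatment:line"]] - ms[["sex:treatment:line"]]) /
                 (2 * r), 0)
  v_sl <- pmax((ms[["sex:line"]] - ms[["sex:treatment:line"]]) / (2 * r), 0)
  v_l <- pmax((ms[["line"]] - ms[["sex:line"]] - ms[["treatment:line"]] +
                 ms[["sex:treatment:line"]]) / (4 * r), 0)
  vc <- data.frame(transcript = rownames(study$values),
                   var_line = v_l, var_sexline = v_sl, var_treatline = v_tl,
                   var_sextreatline = v_stl, var_resid = ms_resid)
  vc$h2 <- heritability(vc)
  list(anova = anova, vc = vc,
       design = list(r = r, n_lines = length(unique(s$line)), fdr = fdr))
}

#' Fit the per-sex reduced model Y = W + L + T + LxT + e
#'
#' @inheritParams fit_full_model
#' @param sex "F" or "M".
#' @return as [fit_full_model()], with term set \{W, L, T, LxT\} and
#'   variance components \{var_line, var_treatline, var_resid\}; F tests: L
#'   and T over the LxT mean square, LxT and W over the residual.
#' @export
fit_sex_model <- function(study, sex, fdr = 0.05) {
  stopifnot(inherits(study, "expression_study"), sex %in% c("F", "M"))
  if (study$scale != "log2")
    stop("fit_sex_model expects log2-normalized values")
  keep <- study$samples$sex == sex
  s <- droplevels(study$samples[keep, , drop = FALSE])
  Y <- study$values[, keep, drop = FALSE]
  r <- replicates_per_cell(s)
  has_w <- length(unique(s$wolbachia)) == 2
  terms <- c(if (has_w) "wolbachia", "treatment", "line", "treatment:line")
  fit <- balanced_anova_engine(Y, s, terms)
  denom <- list(wolbachia = "residual", treatment = "treatment:line",
                line = "treatment:line", "treatment:line" = "residual")
  tests <- ems_f_tests(fit, denom)
  anova <- anova_long_table(tests, rownames(Y))
  anova$term <- unname(c(wolbachia = "W", treatment = "T", line = "L",
                         "treatment:line" = "LxT")[anova$term])
  ms <- setNames(lapply(seq_along(fit$terms),
                        function(i) fit$ss[i, ] / fit$df[i]), fit$terms)
  ms_resid <- fit$resid_ss / fit$resid_df
  v_tl <- pmax((ms[["treatment:line"]] - ms_resid) / r, 0)
  v_l <- pmax((ms[["line"]] - ms[["treatment:line"]]) / (2 * r), 0)
  vc <- data.frame(transcript = rownames(Y), var_line = v_l,
                   var_treatline = v_tl, var_resid = ms_resid)
  vc$h2 <- ifelse(v_l + v_tl + ms_resid > 0,
                  (v_l + v_tl) / (v_l + v_tl + ms_resid), 0)
  list(anova = anova, vc = vc,
       design = list(r = r, n_lines = length(unique(s$line)), sex = sex,
                     fdr = fdr))
}

#' Fit the per-condition reduced model Y = W + L + e
#'
#' Used to classify LxT transcripts as significant in one treatment
#' condition, the other, or both; both terms tested over the residual.
#'
#' @inheritParams fit_sex_model
#' @param treatment "ethanol" or "control".
#' @return long AnovaTable (transcript, term, df, ss, ms, f, p, q).
#' @export
fit_condition_model <- function(study, sex, treatment, fdr = 0.05) {
  stopifnot(inherits(study, "expression_study"),
            sex %in% c("F", "M"), treatment %in% c("ethanol", "control"))
  keep <- study$samples$sex == sex & study$samples$treatment == treatment
  s <- droplevels(study$samples[keep, , drop = FALSE])
  Y <- study$values[, keep, drop = FALSE]
  tab <- table(s$line)
  if (length(unique(as.vector(tab))) != 1L)
    stop("design is not balanced within the condition")
  has_w <- length(unique(s$wolbachia)) == 2
  terms <- c(if (has_w) "wolbachia", "line")
  fit <- balanced_anova_engine(Y, s, terms)
  denom <- list(wolbachia = "residual", line = "residual")
  anova <- anova_long_table(ems_f_tests(fit, denom), rownames(Y))
  anova$term <- unname(c(wolbachia = "W", line = "L")[anova$term])
  anova
}

#' Broad-sense heritability from variance components
#'
#' H2 = (var_line + var_sexline + var_treatline + var_sextreatline) /
#' (the same sum + var_resid); 0 when every component is 0. Components must
#' be nonnegative (truncation happens upstream in the model fits).
#'
#' @param vc data.frame with columns var_line, var_resid and optionally
#'   var_sexline, var_treatline, var_sextreatline (missing ones count as 0).
#' @return numeric vector of H2 values in [0, 1].
#' @export
heritability <- function(vc) {
  comp <- c("var_line", "var_sexline", "var_treatline", "var_sextreatline")
  g <- rowSums(as.matrix(vc[, intersect(comp, names(vc)), drop = FALSE]))
  e <- vc$var_resid
  if (any(g < 0) || any(e < 0))
    stop("variance components must be nonnegative")
  ifelse(g + e > 0, g / (g + e), 0)
}

#' Per-line delta-expression (exposed minus control line means)
#'
#' For each line, the mean over ethanol replicates minus the mean over
#' control replicates of log2 expression, restricted to the transcripts in
#' `lxt_hits` (normally those significant for LxT in that sex).
#'
#' @param study a log2-scale `expression_study`.
#' @param lxt_hits character vector of transcript ids.
#' @param sex "F" or "M".
#' @return lines x transcripts numeric matrix, `attr(, "sex")` set.
#' @export
delta_expression <- function(study, lxt_hits, sex) {
  stopifnot(inherits(study, "expression_study"))
  bad <- setdiff(lxt_hits, rownames(study$values))
  if (length(bad)) stop("unknown transcripts: ", paste(bad, collapse = ", "))
  s <- study$samples
  keep <- s$sex == sex
  lines <- sort(unique(s$line))
  miss_e <- lines[!lines %in% s$line[keep & s$treatment == "ethanol"]]
  miss_c <- lines[!lines %in% s$line[keep & s$treatment == "control"]]
  if (length(miss_e) || length(miss_c))
    stop("lines missing a condition: ",
         paste(unique(c(miss_e, miss_c)), collapse = ", "))
  Y <- study$values[lxt_hits, keep, drop = FALSE]
  grp <- interaction(s$line[keep], s$treatment[keep])
  means <- t(rowsum(t(Y), grp) / as.vector(table(grp)))
  eth <- means[, paste0(lines, ".ethanol"), drop = FALSE]
  ctl <- means[, paste0(lines, ".control"), drop = FALSE]
  delta <- t(eth - ctl)
  dimnames(delta) <- list(lines, lxt_hits)
  attr(delta, "sex") <- sex
  delta
}

#' Transcript-class percentage (worked-example arithmetic)
#'
#' Percentage of a transcript class among all expressed transcripts, rounded
#' to one decimal as reported in study summaries.
#'
#' @param n class count.
#' @param total number of expressed transcripts.
#' @return percentage, one decimal.
#' @export
class_percentage <- function(n, total) {
  if (total <= 0) stop("total must be positive")
  round(100 * n / total, 1)
}

#' Count and classify significant transcripts per model term
#'
#' @param anova long AnovaTable from one of the model fits.
#' @param fdr q-value threshold.
#' @return data.frame term, n_significant, percent (of transcripts tested).
#' @export
term_significance_summary <- function(anova, fdr = 0.05) {
  tx <- length(unique(anova$transcript))
  agg <- aggregate(list(n_significant = anova$q < fdr),
                   by = list(term = anova$term), FUN = sum)
  agg$percent <- class_percentage(agg$n_significant, tx)
  agg
}
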