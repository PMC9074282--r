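#' Trim phenotype rows to a balanced design
#'
#' After the survival filter drops dead flies, replicate cells can hold
#' unequal fly counts; the balanced ANOVA requires equal cells. This keeps
#' the first `n` flies of every treatment x line x sex x replicate cell,
#' where `n` is the minimum cell count (errors if any cell is empty or if
#' `n` < 2).
#'
#' @param phenotypes data.frame from [day_night_phenotypes()].
#' @return the trimmed data.frame.
#' @export
rebalance_phenotypes <- function(phenotypes) {
  cell <- interaction(phenotypes$treatment, phenotypes$line, phenotypes$sex,
                      phenotypes$replicate, drop = FALSE)
  counts <- table(cell)
  if (any(counts == 0))
    stop("empty design cells after filtering: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  n <- min(counts)
  if (n < 2) stop("fewer than 2 flies remain in some cell")
  idx <- unlist(lapply(split(seq_len(nrow(phenotypes)), cell),
                       utils::head, n))
  out <- phenotypes[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Factorial Type III ANOVA for sleep and activity phenotypes
#'
#' Fits, per phenotype, the balanced factorial model
#' Y = mu + T + L + S + TxL + TxS + LxS + TxLxS + Rep(TxLxS) + e with
#' replicate-within-cell random: the fixed effects are tested over the
#' Rep(TxLxS) mean square and Rep over the residual (flies within
#' replicate). With `by_sex`, the reduced per-sex model
#' Y = mu + T + L + TxL + Rep(TxL) + e is fitted instead. For balanced data
#' the sequential sums of squares equal the Type III decomposition.
#'
#' @param phenotypes data.frame from [day_night_phenotypes()] (columns line,
#'   sex, treatment, replicate plus numeric traits).
#' @param traits character vector of trait columns to analyze.
#' @param by_sex NULL for the full model, or "F"/"M" for the reduced model.
#' @return long data.frame: trait, term, df, ss, ms, f, p.
#' @export
sleep_anova <- function(phenotypes,
                        traits = c("activity", "day_sleep_prop",
                                   "night_sleep_prop", "day_bouts",
                                   "night_bouts"),
                        by_sex = NULL) {
  ph <- phenotypes
  if (!is.null(by_sex)) {
    ph <- ph[ph$sex == by_sex, , drop = FALSE]
    ph$rep_cell <- interaction(ph$treatment, ph$line, ph$replicate)
    terms <- c("treatment", "line", "treatment:line", "rep_cell")
    labels <- c(treatment = "T", line = "L", "treatment:line" = "TxL",
                rep_cell = "Rep(TxL)")
  } else {
    ph$rep_cell <- interaction(ph$treatment, ph$line, ph$sex, ph$replicate)
    terms <- c("treatment", "line", "sex", "treatment:line",
               "treatment:sex", "line:sex", "treatment:line:sex", "rep_cell")
    labels <- c(treatment = "T", line = "L", sex = "S",
                "treatment:line" = "TxL", "treatment:sex" = "TxS",
                "line:sex" = "LxS", "treatment:line:sex" = "TxLxS",
                rep_cell = "Rep(TxLxS)")
  }
  counts <- table(ph$rep_cell)
  counts <- counts[counts > 0]
  if (length(unique(as.vector(counts))) != 1L)
    stop("unbalanced replicate cells: ",
         paste(names(counts)[counts != max(counts)], collapse = ", "))
  if (min(counts) < 2)
    stop("need >= 2 flies per replicate cell for a residual term")
  Y <- t(as.matrix(ph[, traits, drop = FALSE]))
  fit <- balanced_anova_engine(Y, ph, terms)
  denom <- setNames(as.list(rep("rep_cell", length(terms) - 1)),
                    terms[-length(terms)])
  denom$rep_cell <- "residual"
  tests <- ems_f_tests(fit, denom)
  rows <- lapply(names(tests), function(term) {
    tab <- tests[[term]]
    data.frame(trait = traits, term = labels[[term]], df = tab$df,
               ss = tab$ss, ms = tab$ms, f = tab$f, p = tab$p)
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$trait, traits)), ]
  rownames(out) <- NULL
  out
}
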