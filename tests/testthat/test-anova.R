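full_terms <- c("wolbachia", "sex", "treatment", "line", "wolbachia:sex",
                "sex:treatment", "sex:line", "treatment:line",
                "sex:treatment:line")
term_label <- c(wolbachia = "W", sex = "S", treatment = "T", line = "L",
                "wolbachia:sex" = "WxS", "sex:treatment" = "TxS",
                "sex:line" = "LxS", "treatment:line" = "LxT",
                "sex:treatment:line" = "TxSxL")

test_that("sums of squares decompose the total and match the oracle", {
  sim <- tiny_study(n_lines = 3, n_transcripts = 4, seed = 23)
  fit <- fit_full_model(sim$study)
  or <- oracle_anova(t(sim$study$values), sim$study$samples, full_terms)
  for (tm in full_terms) {
    rows <- fit$anova[fit$anova$term == term_label[[tm]], ]
    expect_equal(rows$df, rep(unname(or$df[tm]), 4))
    expect_equal(rows$ss, unname(or$ss[[tm]]), tolerance = 1e-9)
  }
  ## term SS + residual SS = total SS about the mean
  Y <- sim$study$values
  tot <- rowSums((Y - rowMeans(Y))^2)
  ss_sum <- tapply(fit$anova$ss, fit$anova$transcript, sum)
  resid <- as.vector(tot - ss_sum[names(tot)])
  expect_equal(resid, unname(or$resid_ss), tolerance = 1e-9)
})

test_that("zero-noise line effects decompose exactly", {
  d <- sim_design(n_lines = 5, n_transcripts = 1, sd_line = 1, sd_sexline = 0,
                  sd_treatline = 0, sd_sextreatline = 0, sd_resid = 0,
                  sex_effect = 0, treatment_effect = 0, frac_lxt = 0,
                  wolbachia_frac = 0, seed = 5)
  sim <- simulate_expression(d)
  fit <- fit_full_model(sim$study)
  expect_equal(fit$vc$var_resid, 0)
  expect_equal(fit$vc$var_line,
               unname(var(sim$truth$line_effects[1, ])), tolerance = 1e-10)
})

test_that("variance components are invariant to a constant shift", {
  sim <- tiny_study(seed = 29)
  shifted <- sim$study
  shifted$values <- shifted$values + 7
  expect_equal(fit_full_model(sim$study)$vc, fit_full_model(shifted)$vc,
               tolerance = 1e-10)
})

test_that("unbalanced designs are refused", {
  sim <- tiny_study(seed = 2)
  sub <- sim$study
  sub$values <- sub$values[, -1]
  sub$samples <- sub$samples[-1, ]
  expect_error(fit_full_model(sub), "balanced")
})

test_that("null LxT p-values are uniform in the sex model", {
  d <- sim_design(n_lines = 12, n_transcripts = 500, sd_line = 0.5,
                  sd_sexline = 0.2, sd_treatline = 0, sd_sextreatline = 0,
                  sd_resid = 0.5, frac_lxt = 0, seed = 37)
  sim <- simulate_expression(d)
  fit <- fit_sex_model(sim$study, "F")
  p <- fit$anova$p[fit$anova$term == "LxT"]
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("the sex model detects planted LxT transcripts with power", {
  d <- sim_design(n_lines = 20, n_transcripts = 300, sd_treatline = 1,
                  sd_resid = 0.5, frac_lxt = 0.2, seed = 41)
  sim <- simulate_expression(d)
  fit <- fit_sex_model(sim$study, "F")
  a <- fit$anova[fit$anova$term == "LxT", ]
  hits <- a$transcript[a$q < 0.05]
  expect_gte(mean(sim$truth$lxt_transcripts %in% hits), 0.9)
  ## determinism: identical input, identical table
  expect_identical(fit$anova, fit_sex_model(sim$study, "F")$anova)
})

test_that("condition models separate one-condition line variance", {
  set.seed(43)
  lines <- sprintf("line_%03d", 1:10)
  grid <- expand.grid(replicate = 1:3, treatment = c("control", "ethanol"),
                      sex = "F", line = lines, stringsAsFactors = FALSE)
  grid$sample <- sprintf("s%03d", seq_len(nrow(grid)))
  grid$wolbachia <- "no"
  line_eff <- rnorm(10, 0, 2)
  y <- ifelse(grid$treatment == "ethanol",
              line_eff[match(grid$line, lines)], 0) + rnorm(nrow(grid), 0, .3)
  vals <- rbind(TXA = y, TXB = rep(1, nrow(grid)))
  colnames(vals) <- grid$sample
  study <- expression_study(vals, grid[, c("sample", "line", "sex",
                                           "treatment", "replicate",
                                           "wolbachia")])
  eth <- fit_condition_model(study, "F", "ethanol")
  ctl <- fit_condition_model(study, "F", "control")
  expect_lt(eth$q[eth$transcript == "TXA" & eth$term == "L"], 0.05)
  expect_gt(ctl$q[ctl$transcript == "TXA" & ctl$term == "L"], 0.05)
  ## constant transcript: zero between-line SS, p = 1 by convention
  expect_equal(eth$p[eth$transcript == "TXB" & eth$term == "L"], 1)
})

test_that("heritability follows the variance-component ratio", {
  vc <- data.frame(var_line = 1, var_sexline = 1, var_treatline = 1,
                   var_sextreatline = 1, var_resid = 4)
  expect_equal(heritability(vc), 0.5)
  expect_equal(heritability(data.frame(var_line = 2, var_resid = 0)), 1)
  expect_equal(heritability(data.frame(var_line = 0, var_resid = 0)), 0)
  expect_error(heritability(data.frame(var_line = -1, var_resid = 1)),
               "nonnegative")
})

test_that("bh_fdr reproduces the step-up adjustment", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.3, 5)), rep(0.3, 5))
  expect_error(bh_fdr(c(0.1, NA)), "NA")
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
  ## re-adjusting q-values is conservative: q' >= q pointwise, so the
  ## discovery count can only shrink, and the p-value ordering is preserved
  set.seed(1); p <- runif(100)^2
  q <- bh_fdr(p)
  expect_true(all(bh_fdr(q) >= q - 1e-12))
  expect_lte(sum(bh_fdr(q) < 0.05), sum(q < 0.05))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("delta-expression is the difference of condition line means", {
  lines <- c("line_001", "line_002")
  grid <- expand.grid(replicate = 1:2, treatment = c("control", "ethanol"),
                      sex = c("F", "M"), line = lines,
                      stringsAsFactors = FALSE)
  grid$sample <- sprintf("s%02d", seq_len(nrow(grid)))
  grid$wolbachia <- "no"
  vals <- matrix(0, 1, nrow(grid), dimnames = list("TXA", grid$sample))
  f1 <- grid$sex == "F" & grid$line == "line_001"
  vals[1, f1 & grid$treatment == "ethanol"] <- c(5, 7)
  vals[1, f1 & grid$treatment == "control"] <- c(3, 5)
  study <- expression_study(vals, grid[, c("sample", "line", "sex",
                                           "treatment", "replicate",
                                           "wolbachia")])
  delta <- delta_expression(study, "TXA", "F")
  expect_equal(delta["line_001", "TXA"], 2)
  expect_equal(delta["line_002", "TXA"], 0)
  expect_error(delta_expression(study, "nope", "F"), "unknown")
})

test_that("a purely fixed treatment effect gives constant delta", {
  d <- sim_design(n_lines = 8, n_transcripts = 3, sd_line = 1, sd_sexline = 0,
                  sd_treatline = 0, sd_sextreatline = 0, sd_resid = 0,
                  treatment_effect = 1.5, frac_lxt = 0, seed = 47)
  sim <- simulate_expression(d)
  delta <- delta_expression(sim$study, rownames(sim$study$values), "M")
  expect_equal(unname(apply(delta, 2, var)), rep(0, 3))
  expect_equal(unname(delta[1, ]), rep(1.5, 3))
})

test_that("between-line delta variance matches the design algebra", {
  ## var(delta) = 2 var_TL + 2 var_resid / r for a single sex
  d <- sim_design(n_lines = 200, n_transcripts = 200, sd_line = 0.5,
                  sd_sexline = 0, sd_treatline = 1, sd_sextreatline = 0,
                  sd_resid = 1, frac_lxt = 1, seed = 53)
  sim <- simulate_expression(d)
  delta <- delta_expression(sim$study, rownames(sim$study$values), "F")
  v <- mean(apply(delta, 2, var))
  expected <- 2 * 1 + 2 * 1 / 2
  expect_lt(abs(v - expected), 3 * sd(apply(delta, 2, var)) / sqrt(200))
})
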