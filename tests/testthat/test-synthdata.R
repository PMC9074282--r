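test_that("zero-variance design reproduces the baseline exactly", {
  d <- sim_design(n_lines = 3, n_transcripts = 5, n_replicates = 2,
                  sd_line = 0, sd_sexline = 0, sd_treatline = 0,
                  sd_sextreatline = 0, sd_resid = 0, sex_effect = 0,
                  treatment_effect = 0, frac_lxt = 0, wolbachia_frac = 0,
                  wolbachia_effect = 0, seed = 3)
  sim <- simulate_expression(d)
  expect_equal(unname(apply(sim$study$values, 1, var)), rep(0, 5))
  expect_equal(unname(sim$study$values[, 1]),
               unname(sim$truth$baseline))
})

test_that("generators are deterministic and the design balanced", {
  d <- sim_design(n_lines = 6, n_transcripts = 20, seed = 11)
  s1 <- simulate_expression(d); s2 <- simulate_expression(d)
  expect_identical(s1$study$values, s2$study$values)
  tab <- table(s1$study$samples$line, s1$study$samples$sex,
               s1$study$samples$treatment)
  expect_true(all(tab == d$n_replicates))
  g1 <- simulate_genotypes(10, 50, seed = 5)
  g2 <- simulate_genotypes(10, 50, seed = 5)
  expect_identical(g1$geno, g2$geno)
  dam1 <- simulate_dam(dam_sim_params(seed = 9))
  dam2 <- simulate_dam(dam_sim_params(seed = 9))
  expect_identical(dam1$counts, dam2$counts)
})

test_that("invalid designs are rejected", {
  expect_error(sim_design(n_lines = 0), "invalid design")
  expect_error(sim_design(n_replicates = 1), "n_replicates")
  expect_error(sim_design(frac_lxt = 1.2), "frac_lxt")
  expect_error(simulate_genotypes(1, 10), "n_lines")
  expect_error(simulate_genotypes(10, 10, maf_range = c(0, 0.6)),
               "maf_range")
})

test_that("genotype matrices honor the MAF contract", {
  g <- simulate_genotypes(10, 40, maf_range = c(0.5, 0.5), seed = 2)
  expect_true(all(colSums(g$geno == 2) == 5))
  g2 <- simulate_genotypes(12, 200, maf_range = c(0.05, 0.5), seed = 4)
  expect_true(all(apply(g2$geno, 2, var) > 0))
  expect_true(all(g2$variants$pos >= 1))
})

test_that("LxT-flagged transcripts show larger delta-expression spread", {
  d <- sim_design(n_lines = 30, n_transcripts = 200, sd_treatline = 1,
                  frac_lxt = 0.1, sd_resid = 0.3, seed = 21)
  sim <- simulate_expression(d)
  delta <- delta_expression(sim$study, rownames(sim$study$values), "F")
  spread <- apply(delta, 2, sd)
  lxt <- colnames(delta) %in% sim$truth$lxt_transcripts
  expect_gt(mean(spread[lxt]), mean(spread[!lxt]))
})

test_that("plant_eqtls shifts only the ethanol condition by beta * dosage", {
  d <- sim_design(n_lines = 6, n_transcripts = 4, sd_line = 0,
                  sd_sexline = 0, sd_treatline = 0, sd_sextreatline = 0,
                  sd_resid = 0, frac_lxt = 0, seed = 8)
  sim <- simulate_expression(d)
  g <- simulate_genotypes(6, 10, maf_range = c(0.5, 0.5), seed = 8)
  eff0 <- data.frame(transcript = "TX00001", variant = "VAR00001", beta = 0)
  expect_equal(plant_eqtls(sim$study, g, eff0)$values, sim$study$values)
  eff <- data.frame(transcript = "TX00001", variant = g$variants$variant[1],
                    beta = 2)
  planted <- plant_eqtls(sim$study, g, eff)
  delta <- delta_expression(planted, "TX00001", "F")
  carrier <- g$geno[rownames(delta), eff$variant] == 2
  expect_equal(unname(delta[carrier, 1] - delta[!carrier, 1][1]),
               rep(2, sum(carrier)))
  bad <- data.frame(transcript = "nope", variant = "VAR00001", beta = 1)
  expect_error(plant_eqtls(sim$study, g, bad), "unknown ids")
})

test_that("planted eQTL effect is recovered by a single-variant scan", {
  d <- sim_design(n_lines = 100, n_transcripts = 1, sd_line = 0,
                  sd_sexline = 0, sd_treatline = 0, sd_sextreatline = 0,
                  sd_resid = 0.5, frac_lxt = 0, seed = 13)
  sim <- simulate_expression(d)
  g <- simulate_genotypes(100, 5, maf_range = c(0.3, 0.5), seed = 13)
  eff <- data.frame(transcript = "TX00001", variant = g$variants$variant[1],
                    beta = 1.5)
  planted <- plant_eqtls(sim$study, g, eff)
  delta <- delta_expression(planted, "TX00001", "F")
  sc <- eqtl_scan(setNames(delta[, 1], rownames(delta)), g)
  row <- sc[sc$variant == eff$variant, ]
  ## residual sd of delta = sqrt(2 * 0.25 / 2) = 0.5; 3 SE of the slope
  se <- 0.5 / sqrt(sum((g$geno[, eff$variant] / 2 -
                          mean(g$geno[, eff$variant] / 2))^2))
  expect_lt(abs(row$beta - 1.5), 3 * se)
})

test_that("plant_modules induces within-module correlation only", {
  d <- sim_design(n_lines = 50, n_transcripts = 30, sd_line = 0.2,
                  sd_sexline = 0, sd_treatline = 0, sd_sextreatline = 0,
                  sd_resid = 0.3, frac_lxt = 0, seed = 31)
  sim <- simulate_expression(d)
  tx <- rownames(sim$study$values)
  mods <- list(list(transcripts = tx[1:5], loading = 3),
               list(transcripts = tx[6:10], loading = 3))
  z <- plant_modules(sim$study, list(list(transcripts = tx[1:5],
                                          loading = 0)), seed = 1)
  expect_equal(z$values, sim$study$values)
  planted <- plant_modules(sim$study, mods, seed = 2)
  delta <- delta_expression(planted, tx[1:10], "F")
  r <- cor(delta)
  within <- r[1:5, 1:5][upper.tri(diag(5))]
  between <- r[1:5, 6:10]
  expect_true(all(within > 0.9))
  expect_lt(abs(mean(between)), 3 / sqrt(50))
  overlap <- list(list(transcripts = tx[1:5], loading = 1),
                  list(transcripts = tx[5:9], loading = 1))
  expect_error(plant_modules(sim$study, overlap), "overlap")
})

test_that("count export and study IO round-trip", {
  sim <- tiny_study(seed = 17)
  counts <- as_count_study(sim$study, libsize_factor = c(1, 2))
  expect_true(all(counts$values >= 0))
  expect_equal(counts$scale, "counts")
  dir <- withr::local_tempdir()
  write_expression_study(sim$study, file.path(dir, "c.tsv"),
                         file.path(dir, "s.tsv"))
  back <- read_expression_study(file.path(dir, "c.tsv"),
                                file.path(dir, "s.tsv"))
  expect_equal(back$values, sim$study$values, tolerance = 1e-10)
  expect_equal(back$samples$line, sim$study$samples$line)
})

test_that("genotype TSV and VCF readers agree", {
  g <- simulate_genotypes(8, 12, seed = 3)
  dir <- withr::local_tempdir()
  write_genotypes(g, file.path(dir, "g.tsv"), file.path(dir, "v.tsv"))
  back <- read_genotypes(file.path(dir, "g.tsv"), file.path(dir, "v.tsv"))
  expect_equal(back$geno, g$geno)
  expect_equal(back$variants$pos, g$variants$pos)
  ## equivalent VCF: one row per variant, GT = 0/0 or 1/1
  vcf <- file.path(dir, "g.vcf")
  rows <- vapply(seq_len(ncol(g$geno)), function(j) {
    gt <- ifelse(g$geno[, j] == 2, "1/1", "0/0")
    paste(c(g$variants$chrom[j], g$variants$pos[j], g$variants$variant[j],
            "A", "T", ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      paste(rownames(g$geno), collapse = "\t")), rows), vcf)
  gv <- read_genotypes_vcf(vcf)
  expect_equal(gv$geno[rownames(g$geno), colnames(g$geno)], g$geno)
})
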