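test_that("sleep calling honors the 5-minute boundary", {
  ## 4 consecutive zeros flanked by activity: no sleep
  expect_equal(nrow(call_sleep(c(1, 0, 0, 0, 0, 2, 1))), 0)
  ## exactly 5 zeros: one bout of length 5
  iv <- call_sleep(c(1, 0, 0, 0, 0, 0, 2))
  expect_equal(iv, data.frame(start = 2L, end = 7L))
  expect_equal(iv$end - iv$start, 5L)
  expect_error(call_sleep(c(1, -1)), "nonnegative")
})

test_that("sleep intervals match a brute-force run-length oracle", {
  set.seed(131)
  for (k in 1:50) {
    x <- rbinom(500, 1, 0.5) * (1 + rpois(500, 1))
    expect_equal(call_sleep(x), oracle_sleep_runs(x), ignore_attr = TRUE)
  }
  ## total sleep minutes equal the sum of retained run lengths
  x <- rbinom(2000, 1, 0.3) * 1L
  iv <- call_sleep(x)
  r <- rle(x == 0)
  expect_equal(sum(iv$end - iv$start),
               sum(r$lengths[r$values & r$lengths >= 5]))
})

test_that("simulated ground-truth bouts equal the bout caller output", {
  dam <- simulate_dam(dam_sim_params(n_flies = 2, n_days = 2, seed = 137))
  for (i in seq_len(ncol(dam$counts)))
    expect_equal(call_sleep(dam$counts[, i]), dam$truth[[i]],
                 ignore_attr = TRUE)
})

test_that("monitor files round-trip through write and parse", {
  dam <- simulate_dam(dam_sim_params(n_flies = 2, n_days = 2, seed = 139),
                      lines = c("line_001", "line_002"))
  dir <- withr::local_tempdir()
  paths <- write_dam_files(dam, dir)
  monitors <- grep("Monitor", paths, value = TRUE)
  map <- read_tsv <- utils::read.delim(file.path(dir, "channel_map.tsv"),
                                       comment.char = "#")
  back <- dam_dataset_from_files(monitors, map, lights_on = dam$lights_on)
  expect_equal(unname(back$counts[, dam$meta$fly]),
               unname(dam$counts[, dam$meta$fly]))
  ## phenotypes invariant to monitor file order
  back2 <- dam_dataset_from_files(rev(monitors), map,
                                  lights_on = dam$lights_on)
  expect_equal(day_night_phenotypes(back), day_night_phenotypes(back2))
})

test_that("malformed monitor files are rejected with specifics", {
  dam <- simulate_dam(dam_sim_params(n_flies = 2, n_days = 2, seed = 149),
                      lines = "line_001", sexes = "F",
                      treatments = "control")
  dir <- withr::local_tempdir()
  paths <- write_dam_files(dam, dir)
  mon <- grep("Monitor1", paths, value = TRUE)
  lines <- readLines(mon)
  ## duplicated minute
  writeLines(c(lines[1], lines), file.path(dir, "dup.txt"))
  expect_error(parse_dam(file.path(dir, "dup.txt")), "non-monotone")
  ## wrong column count
  writeLines(sub("\t[0-9]+$", "", lines), file.path(dir, "cols.txt"))
  expect_error(parse_dam(file.path(dir, "cols.txt")), "42")
  ## negative count
  bad <- lines
  bad[2] <- sub("\t([0-9]+)$", "\t-3", bad[2])
  writeLines(bad, file.path(dir, "neg.txt"))
  expect_error(parse_dam(file.path(dir, "neg.txt")), "nonnegative")
})

test_that("day/night phenotypes follow the lights schedule", {
  ## lights on at minute 360; fly asleep all night, awake all day (1/min)
  nmin <- 2 * 1440L
  mod <- (seq_len(nmin) - 1L) %% 1440L
  is_day <- ((mod - 360L) %% 1440L) < 720L
  counts <- matrix(ifelse(is_day, 1L, 0L), ncol = 1)
  dam <- structure(list(
    counts = counts, lights_on = 360L, start_minute = 0L,
    meta = data.frame(fly = "f1", line = "line_001", sex = "F",
                      treatment = "control", replicate = 1)),
    class = "dam_dataset")
  ph <- day_night_phenotypes(dam)
  expect_equal(ph$night_sleep_prop, 1)
  expect_equal(ph$day_sleep_prop, 0)
  expect_equal(ph$activity, 720)
  ## constant 1 count per minute: activity 1440/day, zero sleep
  dam$counts <- matrix(1L, nmin, 1)
  ph2 <- day_night_phenotypes(dam)
  expect_equal(ph2$activity, 1440)
  expect_equal(ph2$day_sleep_prop + ph2$night_sleep_prop, 0)
  ## sleep and awake fractions are complementary per phase
  set.seed(151)
  dam$counts <- matrix(rbinom(nmin, 1, 0.6) * 2L, ncol = 1)
  ph3 <- day_night_phenotypes(dam)
  expect_true(ph3$day_sleep_prop >= 0 && ph3$day_sleep_prop <= 1)
  iv <- call_sleep(dam$counts[, 1])
  expect_equal((ph3$day_sleep_prop + ph3$night_sleep_prop) * 720 * 2,
               sum(iv$end - iv$start))
})

test_that("a bout spanning the day/night boundary is split and both counted", {
  nmin <- 1440L
  counts <- matrix(1L, nmin, 1)
  ## lights on 360; day = [360, 1080); sleep 1075..1084 spans the boundary
  counts[1076:1085, 1] <- 0L
  dam <- structure(list(
    counts = counts, lights_on = 360L, start_minute = 0L,
    meta = data.frame(fly = "f1", line = "line_001", sex = "F",
                      treatment = "control", replicate = 1)),
    class = "dam_dataset")
  ph <- day_night_phenotypes(dam)
  expect_equal(ph$day_bouts, 1)
  expect_equal(ph$night_bouts, 1)
  expect_equal(ph$day_sleep_prop * 720, 5)    # minutes 1076..1080
  expect_equal(ph$night_sleep_prop * 720, 5)  # minutes 1081..1085
})

test_that("the survival filter drops flies dead inside the window", {
  p <- dam_sim_params(n_flies = 2, n_days = 8, death_frac = 0, seed = 157)
  dam <- simulate_dam(p, lines = c("line_001", "line_002"))
  ## kill one fly at recording day 4
  dam$counts[(3 * 1440):(8 * 1440), 3] <- 0L
  filt <- survival_filter(dam, window_days = c(2, 9))
  expect_false(dam$meta$fly[3] %in% filt$meta$fly)
  expect_equal(ncol(filt$counts), ncol(dam$counts) - 1)
  expect_error(survival_filter(dam, window_days = c(2, 20)), "window")
})

test_that("sleep ANOVA matches a hand Type III computation on a toy design", {
  set.seed(163)
  grid <- expand.grid(flyrep = 1:2, replicate = 1:2,
                      treatment = c("control", "ethanol"),
                      line = c("line_001", "line_002"), sex = c("F", "M"),
                      stringsAsFactors = FALSE)
  grid$activity <- rnorm(nrow(grid), 100, 10) +
    ifelse(grid$treatment == "ethanol" & grid$line == "line_002", 15, 0)
  tab <- sleep_anova(grid, traits = "activity")
  terms <- c("treatment", "line", "sex", "treatment:line", "treatment:sex",
             "line:sex", "treatment:line:sex", "rep_cell")
  grid$rep_cell <- interaction(grid$treatment, grid$line, grid$sex,
                               grid$replicate)
  or <- oracle_anova(matrix(grid$activity), grid, terms)
  lbl <- c("T", "L", "S", "TxL", "TxS", "LxS", "TxLxS", "Rep(TxLxS)")
  for (i in seq_along(terms)) {
    row <- tab[tab$term == lbl[i], ]
    expect_equal(row$ss, unname(or$ss[[terms[i]]]), tolerance = 1e-9)
    expect_equal(row$df, unname(or$df[[terms[i]]]))
    ## EMS ladder: fixed terms over Rep MS, Rep over residual
    dms <- if (lbl[i] == "Rep(TxLxS)") or$resid_ss / or$resid_df
           else or$ss[["rep_cell"]] / or$df[["rep_cell"]]
    expect_equal(row$f, unname(or$ss[[terms[i]]] / or$df[[terms[i]]] / dms),
                 tolerance = 1e-9)
  }
  ## per-sex reduced model runs and has the reduced term set
  tabF <- sleep_anova(grid, traits = "activity", by_sex = "F")
  expect_setequal(tabF$term, c("T", "L", "TxL", "Rep(TxL)"))
})

test_that("planted line-by-treatment activity effects are detected", {
  p <- dam_sim_params(n_flies = 4, n_days = 3, seed = 167)
  dam <- simulate_dam(p, lines = sprintf("line_%03d", 1:4))
  ph <- day_night_phenotypes(dam)
  ## plant a strong LxT shift in activity for half the lines
  sel <- ph$treatment == "ethanol" & ph$line %in% c("line_001", "line_002")
  ph$activity[sel] <- ph$activity[sel] + 6 * sd(ph$activity)
  tab <- sleep_anova(ph, traits = "activity")
  expect_lt(tab$p[tab$term == "TxL"], 0.05)
})
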