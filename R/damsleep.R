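#' Parameters for the activity-monitor simulator
#'
#' Activity is a two-state (awake/asleep) Markov chain per fly with
#' phase-dependent stationary activity probability (`p_active_day`,
#' `p_active_night`) and mean inactivity-bout length `mean_bout_minutes`;
#' awake minutes emit `1 + Poisson(1)` beam crossings, asleep minutes emit 0.
#' A fraction `death_frac` of flies dies at a uniform random minute and emits
#' zeros afterwards (monitors keep recording dead channels).
#'
#' @param n_flies flies per line x sex x treatment cell.
#' @param n_days recording length in days (>= 2).
#' @param p_active_day,p_active_night per-minute activity probabilities.
#' @param mean_bout_minutes mean sleep-bout length, minutes.
#' @param death_frac fraction of flies dying during recording.
#' @param n_replicates replicate (monitor) groups per cell; must divide
#'   `n_flies`.
#' @param seed integer seed.
#' @return list of class `dam_sim_params`.
#' @export
dam_sim_params <- function(n_flies = 4, n_days = 4, p_active_day = 0.4,
                           p_active_night = 0.1, mean_bout_minutes = 20,
                           death_frac = 0, n_replicates = 2, seed = 1L) {
  stopifnot_scalar(p_active_day, "p_active_day", 0, 1)
  stopifnot_scalar(p_active_night, "p_active_night", 0, 1)
  stopifnot_scalar(death_frac, "death_frac", 0, 1)
  stopifnot_scalar(n_days, "n_days", 2)
  if (n_flies %% n_replicates != 0)
    stop("n_flies must be divisible by n_replicates")
  structure(as.list(environment()), class = "dam_sim_params")
}

#' Simulate minute-binned activity-monitor traces
#'
#' @param params a [dam_sim_params()].
#' @param lines,sexes,treatments factor levels of the design.
#' @param lights_on lights-on clock time in minutes after midnight (12:12
#'   light-dark cycle).
#' @return list of class `dam_dataset`: `counts` (minutes x flies),
#'   `meta` (fly, line, sex, treatment, replicate, dead, death_minute),
#'   `lights_on`, `start_minute` (minute-of-day of the first row) and
#'   `truth` (per-fly sleep intervals >= 5 min, computed at generation).
#' @export
simulate_dam <- function(params,
                         lines = sprintf("line_%03d", 1:6),
                         sexes = c("F", "M"),
                         treatments = c("control", "ethanol"),
                         lights_on = 360) {
  stopifnot(inherits(params, "dam_sim_params"))
  set.seed(params$seed)
  meta <- expand.grid(flyrep = seq_len(params$n_flies),
                      treatment = treatments, sex = sexes, line = lines,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  per_rep <- params$n_flies / params$n_replicates
  meta$replicate <- ((meta$flyrep - 1L) %/% per_rep) + 1L
  meta$fly <- sprintf("fly_%03d", seq_len(nrow(meta)))
  nf <- nrow(meta)
  nmin <- params$n_days * 1440L
  minute_of_day <- (seq_len(nmin) - 1L) %% 1440L
  is_day <- ((minute_of_day - lights_on) %% 1440L) < 720L
  p_act <- ifelse(is_day, params$p_active_day, params$p_active_night)

  ## two-state chain: wake -> sleep prob b, sleep -> wake prob a
  a <- 1 / params$mean_bout_minutes
  state <- rbinom(nf, 1, p_act[1])            # 1 = awake
  counts <- matrix(0L, nmin, nf)
  for (m in seq_len(nmin)) {
    p <- max(min(p_act[m], 1 - 1e-9), 1e-9)
    b <- min(a * (1 - p) / p, 1)
    u <- runif(nf)
    state <- ifelse(state == 1L, as.integer(u >= b), as.integer(u < a))
    awake <- state == 1L
    counts[m, awake] <- 1L + rpois(sum(awake), 1)
  }
  ## deaths land at least a day before the recording ends so the terminal
  ## zero run is distinguishable from sleep by the 24 h death-call rule
  dead <- runif(nf) < params$death_frac
  death_minute <- ifelse(dead, floor(runif(nf, 1, nmin - 1440)), NA_real_)
  for (i in which(dead)) counts[death_minute[i]:nmin, i] <- 0L
  colnames(counts) <- meta$fly

  truth <- lapply(seq_len(nf), function(i) zero_runs(counts[, i], 5L))
  names(truth) <- meta$fly
  structure(list(counts = counts,
                 meta = meta[, c("fly", "line", "sex", "treatment",
                                 "replicate")],
                 dead = data.frame(fly = meta$fly, dead = dead,
                                   death_minute = death_minute),
                 lights_on = lights_on, start_minute = 0L,
                 truth = truth),
            class = "dam_dataset")
}

## maximal runs of zeros with length >= min_len, as half-open [start, end)
## 1-based minute indices
zero_runs <- function(x, min_len) {
  r <- rle(x == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep] + 1L)
}

#' Call sleep bouts from a minute-binned count series
#'
#' Sleep is defined as at least `min_bout` consecutive minutes without beam
#' crossings; maximal zero runs of that length become sleep intervals
#' (half-open `[start, end)`, 1-based minutes).
#'
#' @param counts integer vector of per-minute counts.
#' @param min_bout minimum inactivity run length, minutes.
#' @return data.frame with columns `start`, `end`.
#' @export
call_sleep <- function(counts, min_bout = 5) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  zero_runs(counts, as.integer(min_bout))
}

#' Day/night sleep and activity phenotypes per fly
#'
#' Day is the 12 h following lights-on; night the other 12 h. Per phase:
#' sleep proportion = sleeping minutes / 720 averaged over whole days, and
#' bout count averaged over days. A bout spanning a phase boundary is split
#' at the boundary and each fragment counts as a bout in its phase (the
#' 5-minute rule was already met by the whole bout). Activity is total beam
#' crossings divided by the number of whole days.
#'
#' @param dam a `dam_dataset`.
#' @param min_bout sleep-bout threshold, minutes.
#' @return data.frame, one row per fly: activity, day_sleep_prop,
#'   night_sleep_prop, day_bouts, night_bouts plus the design factors.
#' @export
day_night_phenotypes <- function(dam, min_bout = 5) {
  nmin <- nrow(dam$counts)
  n_days <- nmin %/% 1440L
  if (n_days < 1) stop("no whole recording days available")
  use <- seq_len(n_days * 1440L)
  minute_of_day <- (dam$start_minute + use - 1L) %% 1440L
  is_day <- ((minute_of_day - dam$lights_on) %% 1440L) < 720L
  ## phase boundaries (1-based minute index at which a new phase starts)
  switches <- which(diff(is_day) != 0L) + 1L
  res <- lapply(seq_len(ncol(dam$counts)), function(i) {
    x <- dam$counts[use, i]
    iv <- call_sleep(x, min_bout)
    day_min <- 0L; night_min <- 0L; day_bouts <- 0L; night_bouts <- 0L
    for (k in seq_len(nrow(iv))) {
      cuts <- switches[switches > iv$start[k] & switches < iv$end[k]]
      segs <- cbind(c(iv$start[k], cuts), c(cuts, iv$end[k]))
      for (s in seq_len(nrow(segs))) {
        len <- segs[s, 2] - segs[s, 1]
        if (is_day[segs[s, 1]]) {
          day_min <- day_min + len; day_bouts <- day_bouts + 1L
        } else {
          night_min <- night_min + len; night_bouts <- night_bouts + 1L
        }
      }
    }
    c(activity = sum(x) / n_days,
      day_sleep_prop = day_min / (720 * n_days),
      night_sleep_prop = night_min / (720 * n_days),
      day_bouts = day_bouts / n_days,
      night_bouts = night_bouts / n_days)
  })
  out <- cbind(dam$meta, do.call(rbind, res))
  rownames(out) <- NULL
  out
}

#' Drop flies that died during the analysis window
#'
#' Restricts the recording to the analysis window (lifespan days
#' `window_days`, assuming recording starts on lifespan day
#' `1 + recording_offset_days`) and drops flies whose counts end in a
#' terminal all-zero run of at least `death_zeros_hours` that begins inside
#' the window — the monitor-data convention for a death call.
#'
#' @param dam a `dam_dataset`.
#' @param window_days length-2 lifespan-day window, default days 2 to 9.
#' @param death_zeros_hours terminal zero-run length treated as death.
#' @param recording_offset_days lifespan days elapsed before recording
#'   started (default 1: recording day 1 is lifespan day 2).
#' @return the filtered `dam_dataset` (window-restricted), with dropped fly
#'   ids in `attr(, "dropped")`.
#' @export
survival_filter <- function(dam, window_days = c(2, 9),
                            death_zeros_hours = 24,
                            recording_offset_days = 1) {
  rec_days <- window_days - recording_offset_days
  nmin <- nrow(dam$counts)
  lo <- (rec_days[1] - 1L) * 1440L + 1L
  hi <- rec_days[2] * 1440L
  if (lo < 1 || hi > nmin)
    stop(sprintf("analysis window (recording days %d-%d) outside recording",
                 rec_days[1], rec_days[2]))
  counts <- dam$counts[lo:hi, , drop = FALSE]
  thr <- death_zeros_hours * 60
  trailing_zeros <- vapply(seq_len(ncol(counts)), function(i) {
    x <- counts[, i]
    nz <- which(x > 0)
    if (!length(nz)) nrow(counts) else nrow(counts) - max(nz)
  }, numeric(1))
  drop <- trailing_zeros >= thr
  out <- dam
  out$counts <- counts[, !drop, drop = FALSE]
  out$meta <- dam$meta[!drop, , drop = FALSE]
  out$start_minute <- (dam$start_minute + lo - 1L) %% 1440L
  out$truth <- dam$truth[!drop]
  attr(out, "dropped") <- dam$meta$fly[drop]
  out
}

#' Write / parse TriKinetics-style monitor files
#'
#' One file per monitor of up to 32 channels; each row is one minute:
#' reading index, date (`d b y`), time (`H:M:S`), a status column, six
#' unused columns, then 32 tab-separated channel counts.
#'
#' @param dam a `dam_dataset`.
#' @param dir output directory.
#' @param start_date date of the first reading.
#' @return paths of files written plus a channel-map TSV.
#' @export
write_dam_files <- function(dam, dir, start_date = as.Date("2026-01-01")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nf <- ncol(dam$counts)
  monitors <- split(seq_len(nf), (seq_len(nf) - 1L) %/% 32L + 1L)
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC") +
    dam$start_minute * 60
  times <- t0 + (seq_len(nrow(dam$counts)) - 1L) * 60
  paths <- character(0)
  map <- NULL
  for (m in seq_along(monitors)) {
    idx <- monitors[[m]]
    block <- matrix(0L, nrow(dam$counts), 32L)
    block[, seq_along(idx)] <- dam$counts[, idx]
    rows <- data.frame(
      index = seq_len(nrow(dam$counts)),
      date = format(times, "%d %b %y"),
      time = format(times, "%H:%M:%S"),
      status = 1L, x1 = 1L, x2 = 0L, x3 = 0L, x4 = 0L, x5 = 0L, x6 = 0L)
    rows <- cbind(rows, as.data.frame(block))
    path <- file.path(dir, sprintf("Monitor%d.txt", m))
    write.table(rows, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    paths <- c(paths, path)
    map <- rbind(map, data.frame(monitor = sprintf("Monitor%d", m),
                                 channel = seq_along(idx),
                                 dam$meta[idx, , drop = FALSE]))
  }
  map_path <- file.path(dir, "channel_map.tsv")
  write_tsv_prov(map, map_path, "gxetrans DAM channel map")
  invisible(c(paths, map_path))
}

#' @rdname write_dam_files
#' @param file a monitor file path.
#' @return `parse_dam`: list with `counts` (minutes x 32), `datetime`
#'   (POSIXct) and `monitor` (file stem).
#' @export
parse_dam <- function(file) {
  raw <- read.delim(file, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) != 42L)
    stop(sprintf("%s: expected 42 tab-separated columns, found %d",
                 basename(file), ncol(raw)))
  dt <- as.POSIXct(paste(raw[[2]], raw[[3]]), format = "%d %b %y %H:%M:%S",
                   tz = "UTC")
  if (anyNA(dt)) {
    bad <- which(is.na(dt))[1]
    stop(sprintf("%s: malformed timestamp on data row %d", basename(file),
                 bad))
  }
  steps <- diff(as.numeric(dt))
  if (any(steps <= 0)) {
    bad <- which(steps <= 0)[1] + 1L
    stop(sprintf("%s: non-monotone or duplicated minute at %s",
                 basename(file), format(dt[bad])))
  }
  if (any(steps != 60))
    stop(sprintf("%s: minutes are not contiguous", basename(file)))
  counts <- as.matrix(raw[, 11:42])
  if (any(counts < 0) || any(counts != round(counts)))
    stop(sprintf("%s: channel counts must be nonnegative integers",
                 basename(file)))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- NULL
  list(counts = counts, datetime = dt,
       monitor = sub("\\.txt$", "", basename(file)))
}

#' Assemble a `dam_dataset` from monitor files and a channel map
#'
#' @param files monitor file paths.
#' @param channel_map data.frame with columns monitor, channel, fly, line,
#'   sex, treatment, replicate.
#' @param lights_on lights-on clock minute.
#' @return a `dam_dataset`.
#' @export
dam_dataset_from_files <- function(files, channel_map, lights_on = 360) {
  parsed <- lapply(files, parse_dam)
  names(parsed) <- vapply(parsed, `[[`, "", "monitor")
  counts <- NULL; meta <- NULL
  ## order by channel map so phenotypes are invariant to file order
  channel_map <- channel_map[order(channel_map$fly), ]
  for (k in seq_len(nrow(channel_map))) {
    p <- parsed[[channel_map$monitor[k]]]
    if (is.null(p)) stop("monitor not supplied: ", channel_map$monitor[k])
    counts <- cbind(counts, p$counts[, channel_map$channel[k]])
  }
  colnames(counts) <- channel_map$fly
  dt0 <- parsed[[1]]$datetime[1]
  start_minute <- as.integer(format(dt0, "%H")) * 60L +
    as.integer(format(dt0, "%M"))
  structure(list(counts = counts,
                 meta = channel_map[, c("fly", "line", "sex", "treatment",
                                        "replicate")],
                 lights_on = lights_on, start_minute = start_minute,
                 truth = NULL),
            class = "dam_dataset")
}
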