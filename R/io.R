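#' Read trajectories from CSV
#'
#' Expects a comma-separated file with header columns `trial_id`, `time_s`,
#' `prawn_id`, `theta_rad` ('.' decimal, UTF-8; times in seconds, angles in
#' radians). Angles are wrapped into `[0, 2pi)` and individual ids are mapped
#' to dense 0-based column indices in ascending id order. Within each trial
#' the frame times must be uniformly spaced (tolerance 1e-6 s) and every
#' (time, individual) cell must be present; gaps are rejected rather than
#' interpolated.
#'
#' @param path CSV file path
#' @param arena the [ArenaSpec-class] the data were recorded in (metadata
#'   only; all downstream computation is purely angular)
#' @return a list of [TrialTrajectory-class], one per trial id
#' @export
readTrajectories <- function(path, arena = arenaSpec()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "time_s", "prawn_id", "theta_rad")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("trajectory file is missing column(s): ", paste(missing, collapse = ", "))
  out <- lapply(split(df, df$trial_id), function(d) {
    times <- sort(unique(d$time_s))
    Tn <- length(times)
    if (Tn >= 2) {
      dts <- diff(times)
      if (max(dts) - min(dts) > 1e-6)
        stop("non-uniform time spacing in trial '", d$trial_id[1], "'")
      dt <- mean(dts)
    } else {
      dt <- NA_real_
    }
    ids <- sort(unique(d$prawn_id))
    th <- matrix(NA_real_, nrow = Tn, ncol = length(ids))
    ti <- match(d$time_s, times)
    pi_ <- match(d$prawn_id, ids)
    if (anyDuplicated(cbind(ti, pi_)))
      stop("duplicate (time, prawn) rows in trial '", d$trial_id[1], "'")
    th[cbind(ti, pi_)] <- d$theta_rad
    if (anyNA(th)) {
      bad <- which(is.na(th), arr.ind = TRUE)[1, ]
      stop("missing cell in trial '", d$trial_id[1], "' at time ",
           times[bad[1]], " s for prawn id ", ids[bad[2]])
    }
    if (Tn < 2) stop("trial '", d$trial_id[1], "' has fewer than 2 frames")
    trialTrajectory(th, frameRate = 1 / dt, trialId = d$trial_id[1],
                    times = times)
  })
  unname(out)
}

#' Write trajectories to CSV
#'
#' Inverse of [readTrajectories()]: one row per (trial, frame, individual),
#' columns `trial_id`, `time_s`, `prawn_id`, `theta_rad`, 0-based ids.
#'
#' @param trajs a [TrialTrajectory-class] or list thereof
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
writeTrajectories <- function(trajs, path) {
  if (is(trajs, "TrialTrajectory")) trajs <- list(trajs)
  rows <- lapply(trajs, function(tr) {
    th <- thetaMatrix(tr)
    data.frame(trial_id = trialId(tr),
               time_s = rep(tr@times, times = ncol(th)),
               prawn_id = rep(seq_len(ncol(th)) - 1L, each = nrow(th)),
               theta_rad = as.vector(th))
  })
  df <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(trial_id = character(), time_s = numeric(),
               prawn_id = integer(), theta_rad = numeric())
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

setMethod("downsample", "TrialTrajectory", function(x, factor) {
  if (length(factor) != 1 || is.na(factor) || factor < 1 ||
      factor != round(factor))
    stop("factor must be a single integer >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(x)
  Tn <- nFrames(x)
  if (Tn <= factor) stop("trajectory too short to down-sample by ", factor)
  keep <- seq(1L, Tn, by = factor)
  trialTrajectory(x@theta[keep, , drop = FALSE],
                  frameRate = x@frameRate / factor,
                  trialId = x@trialId, times = x@times[keep])
})

#' Write and read orientation records as CSV
#'
#' One row per (trial, frame, individual) with columns `trial_id`, `time_s`,
#' `prawn_id`, `state` ("CW"/"ACW") and `event` (1 iff the orientation
#' changed between the previous frame and this one; 0 on the first frame).
#' Events are recomputed from the states on reading, so the round trip
#' `readOrientations(writeOrientations(x))` reproduces `x` exactly.
#'
#' @param recs an [OrientationRecord-class] or list thereof (possibly empty)
#' @param path CSV path
#' @return `writeOrientations`: `path` invisibly; `readOrientations`: a list
#'   of [OrientationRecord-class]
#' @export
writeOrientations <- function(recs, path) {
  if (is(recs, "OrientationRecord")) recs <- list(recs)
  rows <- lapply(recs, function(r) {
    st <- stateMatrix(r)
    ev <- rbind(0L, eventMatrix(r))
    data.frame(trial_id = trialId(r),
               time_s = rep((seq_len(nrow(st)) - 1) * r@dt, times = ncol(st)),
               prawn_id = rep(seq_len(ncol(st)) - 1L, each = nrow(st)),
               state = ifelse(as.vector(st) == 1L, "ACW", "CW"),
               event = as.vector(ev))
  })
  df <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(trial_id = character(), time_s = numeric(),
               prawn_id = integer(), state = character(),
               event = integer())
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeOrientations
#' @export
readOrientations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "time_s", "prawn_id", "state")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("orientation file is missing column(s): ", paste(missing, collapse = ", "))
  if (!all(df$state %in% c("CW", "ACW")))
    stop("state values must be 'CW' or 'ACW'")
  out <- lapply(split(df, df$trial_id), function(d) {
    times <- sort(unique(d$time_s))
    if (length(times) < 2)
      stop("trial '", d$trial_id[1], "' has fewer than 2 frames")
    dts <- diff(times)
    if (max(dts) - min(dts) > 1e-9)
      stop("non-uniform time spacing in trial '", d$trial_id[1], "'")
    ids <- sort(unique(d$prawn_id))
    st <- matrix(NA_integer_, nrow = length(times), ncol = length(ids))
    st[cbind(match(d$time_s, times), match(d$prawn_id, ids))] <-
      ifelse(d$state == "ACW", 1L, -1L)
    if (anyNA(st))
      stop("missing (time, prawn) cell in trial '", d$trial_id[1], "'")
    orientationRecord(st, dt = mean(dts), trialId = d$trial_id[1])
  })
  unname(out)
}
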