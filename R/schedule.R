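#' Event schedules for a cued motor-intention / motor-imagery design
#'
#' An event schedule is an ordered sequence of blocks on the repetition-time
#' (TR) grid. Each trial is a fixation block of pseudo-random duration (1-5
#' TRs), a 1-TR motor-intention cue (left- or right-pointing arrow), and a
#' 3-TR kinesthetic motor-imagery block of the cued hand. Left- and
#' right-hand trials occur equally often within a session, in shuffled order.
#'
#' Blocks are stored as a data.frame with 0-based, half-open TR intervals
#' `[onset_tr, onset_tr + duration_trs)`; the schedule carries the TR
#' duration in seconds, a participant id and a session index as attributes.
#'
#' @name event_schedule
NULL

.CONDITIONS <- c("fixation", "intention", "imagery")
.LATERALITIES <- c("left", "right", "none")

#' Run code with a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so seeded generators do
#' not perturb the global RNG stream.
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

new_event_schedule <- function(blocks, tr_seconds, participant_id = "p01",
                               session = 1L) {
  stopifnot(is.data.frame(blocks))
  structure(blocks,
            class = c("event_schedule", "data.frame"),
            tr_seconds = tr_seconds,
            participant_id = participant_id,
            session = as.integer(session))
}

#' Generate a balanced pseudo-randomized event schedule
#'
#' Builds one session's schedule: `n_runs_per_hand` trials per hand in
#' shuffled order, each trial consisting of fixation (duration drawn
#' uniformly from 1-5 TRs), a 1-TR intention cue, and a 3-TR imagery block.
#'
#' @param n_runs_per_hand non-negative integer, trials per laterality
#'   (20 per hand gives the standard 40-trial session)
#' @param tr_seconds repetition time in seconds (default 1.5)
#' @param seed integer seed; the same seed reproduces the schedule exactly
#' @param participant_id identifier stored with the schedule
#' @param session session index stored with the schedule
#' @return an `event_schedule`: data.frame with columns `onset_tr` (0-based),
#'   `duration_trs`, `condition`, `laterality`, `trial_id`
#' @examples
#' sch <- generate_schedule(20, seed = 1)
#' sum(sch$condition == "intention")  # 40 trials
#' @export
generate_schedule <- function(n_runs_per_hand, tr_seconds = 1.5, seed = 1L,
                              participant_id = "p01", session = 1L) {
  if (length(n_runs_per_hand) != 1L || is.na(n_runs_per_hand) ||
      n_runs_per_hand < 0 || n_runs_per_hand != floor(n_runs_per_hand))
    stop("n_runs_per_hand must be a single non-negative integer")
  n <- as.integer(n_runs_per_hand)
  if (n == 0L) {
    empty <- data.frame(onset_tr = integer(), duration_trs = integer(),
                        condition = character(), laterality = character(),
                        trial_id = integer(), stringsAsFactors = FALSE)
    return(new_event_schedule(empty, tr_seconds, participant_id, session))
  }
  local_seed(seed, {
    sides <- sample(rep(c("left", "right"), each = n))
    fix_dur <- sample(1:5, size = 2L * n, replace = TRUE)
  })
  n_trials <- 2L * n
  cond <- rep(c("fixation", "intention", "imagery"), times = n_trials)
  lat <- as.vector(rbind("none", sides, sides))
  dur <- as.vector(rbind(fix_dur, 1L, 3L))
  trial <- rep(seq_len(n_trials), each = 3L)
  onset <- cumsum(c(0L, dur[-length(dur)]))
  blocks <- data.frame(onset_tr = as.integer(onset),
                       duration_trs = as.integer(dur),
                       condition = cond, laterality = lat,
                       trial_id = as.integer(trial),
                       stringsAsFactors = FALSE)
  new_event_schedule(blocks, tr_seconds, participant_id, session)
}

#' Total TR count of a schedule
#' @param schedule an `event_schedule`
#' @return integer number of TRs
#' @export
n_trs <- function(schedule) {
  as.integer(sum(schedule$duration_trs))
}

#' Convert a schedule to per-TR labels with a hemodynamic delay
#'
#' The BOLD response lags the stimulus; the analysis compensates by shifting
#' block labels forward by `delay_trs` TRs (default 2 TRs = 3 s at
#' TR = 1.5 s). TR `t` receives the condition/laterality/trial of the block
#' active at `t - delay_trs`; the first `delay_trs` TRs are marked unusable.
#' Within each labelled block the within-block TR position is recorded in
#' `block_tr` (1-based), so imagery timepoints T1-T3 can be selected.
#'
#' @param schedule an `event_schedule`
#' @param delay_trs non-negative integer shift
#' @return a data.frame (class `tr_labels`) with one row per TR: `tr`
#'   (0-based), `condition`, `laterality`, `trial_id`, `block_tr`, `usable`;
#'   attribute `delay_trs` records the shift
#' @export
schedule_to_labels <- function(schedule, delay_trs = 2L) {
  if (length(delay_trs) != 1L || is.na(delay_trs) || delay_trs < 0 ||
      delay_trs != floor(delay_trs))
    stop("delay_trs must be a single non-negative integer")
  total <- n_trs(schedule)
  if (delay_trs > total)
    stop("delay_trs exceeds schedule length (", total, " TRs)")
  occ_cond <- rep(schedule$condition, times = schedule$duration_trs)
  occ_lat <- rep(schedule$laterality, times = schedule$duration_trs)
  occ_trial <- rep(schedule$trial_id, times = schedule$duration_trs)
  occ_btr <- unlist(lapply(schedule$duration_trs, seq_len), use.names = FALSE)
  if (total == 0L) occ_btr <- integer()
  d <- as.integer(delay_trs)
  shift <- function(x, fill) c(rep(fill, d), x[seq_len(total - d)])
  labels <- data.frame(
    tr = seq_len(total) - 1L,
    condition = shift(occ_cond, NA_character_),
    laterality = shift(occ_lat, NA_character_),
    trial_id = shift(occ_trial, NA_integer_),
    block_tr = shift(occ_btr, NA_integer_),
    usable = c(rep(FALSE, d), rep(TRUE, total - d)),
    stringsAsFactors = FALSE)
  structure(labels, class = c("tr_labels", "data.frame"), delay_trs = d)
}

#' Write / read an events table
#'
#' Tab-separated events file (one row per block, TR units) with a JSON
#' sidecar recording the TR duration and identifiers.
#'
#' @param schedule an `event_schedule`
#' @param path path of the `.tsv` file; the sidecar replaces the extension
#'   with `.json`
#' @return `write_events` returns `path` invisibly; `read_events` returns an
#'   `event_schedule`
#' @export
write_events <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sidecar <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(
    list(tr_seconds = attr(schedule, "tr_seconds"),
         participant_id = attr(schedule, "participant_id"),
         session = attr(schedule, "session"),
         units = "TR"),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_events
#' @param path path of the `.tsv` events file
#' @export
read_events <- function(path) {
  blocks <- utils::read.delim(path, stringsAsFactors = FALSE)
  sidecar <- sub("\\.tsv$", ".json", path)
  meta <- jsonlite::read_json(sidecar)
  new_event_schedule(blocks, tr_seconds = meta$tr_seconds,
                     participant_id = meta$participant_id,
                     session = meta$session)
}
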