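#' Simulated-annealing temperature schedule
#'
#' One annealing cycle of the ligand ("high") temperature-coupling group:
#' linear heating from `t_base` to `t_max` over `[0, ramp_up_end)` ps, hold
#' at `t_max` over `[ramp_up_end, hold_end)`, linear cooling back to
#' `t_base` over `[hold_end, ramp_down_end)`, and equilibration at `t_base`
#' over `[ramp_down_end, cycle_end)`. The receptor ("low") group follows the
#' same piecewise shape rescaled to `[low_min, low_max]` K, synchronized
#' with the high group. One averaged conformation is emitted per completed
#' cycle's equilibration phase.
#'
#' @param t_base Base temperature, K (default 300).
#' @param t_max Peak temperature, K (e.g. 650, 800 or 1000).
#' @param ramp_up_end,hold_end,ramp_down_end,cycle_end Phase boundaries in
#'   ps within one cycle (defaults 500, 1000, 2000, 2500).
#' @param low_min,low_max Low-group temperature range, K (defaults 300, 350).
#' @return An object of class `annealing_schedule`.
#' @export
annealing_schedule <- function(t_base = 300, t_max = 1000,
                               ramp_up_end = 500, hold_end = 1000,
                               ramp_down_end = 2000, cycle_end = 2500,
                               low_min = 300, low_max = 350) {
  if (!(0 < ramp_up_end && ramp_up_end < hold_end &&
        hold_end < ramp_down_end && ramp_down_end < cycle_end))
    stop("phase boundaries must satisfy 0 < ramp_up_end < hold_end < ",
         "ramp_down_end < cycle_end", call. = FALSE)
  if (t_max < t_base) stop("'t_max' must be >= 't_base'", call. = FALSE)
  structure(list(t_base = t_base, t_max = t_max,
                 ramp_up_end = ramp_up_end, hold_end = hold_end,
                 ramp_down_end = ramp_down_end, cycle_end = cycle_end,
                 low_min = low_min, low_max = low_max),
            class = "annealing_schedule")
}

#' Temperature of a coupling group at a time point
#'
#' Piecewise-linear, continuous and periodic with period `cycle_end`;
#' equals `t_base` throughout the equilibration phase.
#'
#' @param schedule An [annealing_schedule()].
#' @param t Time in ps (vectorized), `>= 0`; mapped into a cycle modulo
#'   `cycle_end`.
#' @param group `"high"` (ligand) or `"low"` (receptor).
#' @return Temperature(s) in K.
#' @export
temperature_at <- function(schedule, t, group = c("high", "low")) {
  stopifnot(inherits(schedule, "annealing_schedule"))
  group <- match.arg(group)
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  lo <- if (group == "high") schedule$t_base else schedule$low_min
  hi <- if (group == "high") schedule$t_max else schedule$low_max
  tc <- t %% schedule$cycle_end
  up <- schedule$ramp_up_end; hold <- schedule$hold_end
  down <- schedule$ramp_down_end
  temp <- numeric(length(tc))
  i <- tc < up
  temp[i] <- lo + (hi - lo) * tc[i] / up
  i <- tc >= up & tc < hold
  temp[i] <- hi
  i <- tc >= hold & tc < down
  temp[i] <- hi - (hi - lo) * (tc[i] - hold) / (down - hold)
  i <- tc >= down
  temp[i] <- lo
  temp
}

#' Sampling plan: annealing runs and their conformation yield
#'
#' A plan is a set of production runs, each with a duration (ns), a number
#' of independent repeats and a schedule. One averaged conformation is
#' emitted per completed annealing cycle (its 300 K equilibration phase);
#' partial cycles emit nothing.
#'
#' @param runs Data frame with columns `duration_ns` and `n_runs`.
#' @param schedule An [annealing_schedule()] shared by all runs (per-run
#'   schedules may be supplied as a list column `schedule`).
#' @return An object of class `sampling_plan`.
#' @export
sampling_plan <- function(runs, schedule = annealing_schedule()) {
  runs <- as.data.frame(runs, stringsAsFactors = FALSE)
  if (!all(c("duration_ns", "n_runs") %in% names(runs)))
    stop("'runs' needs columns duration_ns and n_runs", call. = FALSE)
  if (any(runs$duration_ns <= 0) || any(runs$n_runs < 1L))
    stop("durations must be > 0 and n_runs >= 1", call. = FALSE)
  if (is.null(runs$schedule)) runs$schedule <- list(schedule)
  structure(list(runs = runs), class = "sampling_plan")
}

#' Count the averaged conformations a sampling plan yields
#'
#' Sum over runs of `n_runs * floor(duration_ps / cycle_end)`: e.g. ten
#' 100-ns runs with a 2.5-ns cycle give 400 conformations; five 50-ns plus
#' two blocks of four 100-ns runs give 420.
#'
#' @param plan A [sampling_plan()].
#' @return Integer conformation count (0 with a warning when every run is
#'   shorter than one cycle).
#' @export
count_conformations <- function(plan) {
  stopifnot(inherits(plan, "sampling_plan"))
  per_run <- mapply(function(dur_ns, sched)
    floor(dur_ns * 1000 / sched$cycle_end),
    plan$runs$duration_ns, plan$runs$schedule)
  total <- sum(plan$runs$n_runs * per_run)
  if (total == 0L)
    warning("no run is as long as one annealing cycle; 0 conformations",
            call. = FALSE)
  as.integer(total)
}

#' Trajectory windows attached to one averaged conformation
#'
#' For conformation `i` of a plan (counted in plan order, cycle by cycle
#' within each repeat), returns the absolute time windows (ps, within that
#' repeat's trajectory) of the preceding cooling phase, the equilibration
#' phase the conformation is averaged over, and the subsequent heating
#' phase of the next cycle. For the last cycle of a run the heating window
#' does not exist and the result is flagged `truncated`.
#'
#' @param plan A [sampling_plan()].
#' @param conformation_index 1-based index into the plan's conformations.
#' @return List with `cooling`, `equilibration`, `heating` (each
#'   `c(start, end)` in ps, heating `NULL` when truncated), `averaging`
#'   (= equilibration), `run`, `cycle` and `truncated`.
#' @export
segment_windows <- function(plan, conformation_index) {
  stopifnot(inherits(plan, "sampling_plan"))
  i <- as.integer(conformation_index)
  counted <- 0L
  runs_before <- 0L
  for (r in seq_len(nrow(plan$runs))) {
    sched <- plan$runs$schedule[[r]]
    cyc <- floor(plan$runs$duration_ns[r] * 1000 / sched$cycle_end)
    nrep <- plan$runs$n_runs[r]
    if (cyc > 0L && i <= counted + nrep * cyc) {
      within <- i - counted - 1L
      cycle <- within %% cyc          # 0-based cycle within one repeat
      off <- cycle * sched$cycle_end
      truncated <- (cycle == cyc - 1L)
      return(list(
        cooling = off + c(sched$hold_end, sched$ramp_down_end),
        equilibration = off + c(sched$ramp_down_end, sched$cycle_end),
        averaging = off + c(sched$ramp_down_end, sched$cycle_end),
        heating = if (truncated) NULL else
          off + sched$cycle_end + c(0, sched$ramp_up_end),
        run = runs_before + within %/% cyc + 1L,
        cycle = cycle, truncated = truncated))
    }
    counted <- counted + nrep * cyc
    runs_before <- runs_before + nrep
  }
  stop("conformation_index ", i, " out of range (plan yields ",
       counted, ")", call. = FALSE)
}

#' Select the best structure-prediction model by confidence score
#'
#' Returns the row with the highest `iptm_plus_ptm` from a candidate pool
#' (typically 5 preset models x 5 conformations = 25 predictions); ties are
#' broken deterministically by lexical order of (`model_id`,
#' `conformation_id`).
#'
#' @param scores Data frame with columns `model_id`, `conformation_id`,
#'   `iptm_plus_ptm`.
#' @return The selected row (single-row data frame).
#' @export
select_best_model <- function(scores) {
  scores <- as.data.frame(scores, stringsAsFactors = FALSE)
  if (nrow(scores) == 0L) stop("empty candidate list", call. = FALSE)
  need <- c("model_id", "conformation_id", "iptm_plus_ptm")
  if (!all(need %in% names(scores)))
    stop("'scores' needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  best <- scores[scores$iptm_plus_ptm == max(scores$iptm_plus_ptm), ,
                 drop = FALSE]
  best <- best[order(best$model_id, best$conformation_id), , drop = FALSE]
  best[1L, , drop = FALSE]
}
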