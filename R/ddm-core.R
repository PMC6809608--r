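#' Parameters of one leaky stochastic accumulator
#'
#' Bundles the parameters of a single leaky stochastic accumulator, the
#' building block of the race model. The accumulator integrates
#' \deqn{x_{i+1} = x_i + (I - k x_i)\,\Delta t + c\,\xi_i\sqrt{\Delta t}}
#' from \eqn{x_0 = 0} until its activation reaches the threshold
#' \eqn{\theta} (a decision) or the simulation cap \code{t_max} is hit.
#'
#' @param drift drift rate \eqn{I}, in activation units per second. The
#'   constant "urgency" input to the accumulator.
#' @param leak leak rate \eqn{k} (per second, non-negative): exponential
#'   decay pulling the activation toward the asymptote \eqn{I/k}.
#' @param noise_scale noise scaling factor \eqn{c} (per square-root second,
#'   non-negative) multiplying the standard-normal increments.
#' @param threshold decision threshold \eqn{\theta} (dimensionless
#'   activation, positive). Use \code{Inf} for an unbounded accumulator that
#'   integrates without ever deciding (used for the noise component during
#'   deliberate trials).
#' @param dt integration step \eqn{\Delta t} in seconds (default 0.001 s).
#' @param t_max simulation cap in seconds (default 20 s, the response
#'   deadline of the task the model describes).
#' @return an object of class \code{accumulator_params}.
#' @export
accumulator_params <- function(drift, leak, noise_scale, threshold = 0.3,
                               dt = 0.001, t_max = 20) {
  stopifnot(is.numeric(drift), length(drift) == 1L, is.finite(drift))
  stopifnot(is.numeric(leak), length(leak) == 1L, is.finite(leak), leak >= 0)
  stopifnot(is.numeric(noise_scale), length(noise_scale) == 1L,
            is.finite(noise_scale), noise_scale >= 0)
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  stopifnot(is.numeric(dt), length(dt) == 1L, is.finite(dt), dt > 0)
  stopifnot(is.numeric(t_max), length(t_max) == 1L, is.finite(t_max),
            t_max > 0)
  structure(list(drift = drift, leak = leak, noise_scale = noise_scale,
                 threshold = threshold, dt = dt, t_max = t_max),
            class = "accumulator_params")
}

n_steps <- function(p) as.integer(floor(p$t_max / p$dt + 1e-9))

#' Simulate a single accumulator to first threshold crossing
#'
#' Explicit Euler--Maruyama integration of the accumulator equation. The
#' returned trace holds the activation after each step (time \code{i * dt});
#' the initial activation is 0 at stimulus onset. The trace is truncated at
#' the first crossing, or runs to \code{t_max} when no crossing occurs.
#'
#' @param params an \code{\link{accumulator_params}} object.
#' @param seed optional integer; if given, \code{set.seed(seed)} is called
#'   before simulating.
#' @return list with \code{trace} (numeric vector), \code{crossing} (integer
#'   sample index of the first crossing, or \code{NA} if none) and \code{rt}
#'   (\code{crossing * dt} seconds, or \code{NA}).
#' @export
simulate_accumulator <- function(params, seed = NULL) {
  stopifnot(inherits(params, "accumulator_params"))
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_accumulate(params$drift, params$leak, params$noise_scale,
                        params$threshold, params$dt, n_steps(params))
  crossing <- if (res$crossing > 0L) res$crossing else NA_integer_
  list(trace = res$trace, crossing = crossing,
       rt = if (is.na(crossing)) NA_real_ else crossing * params$dt)
}

#' Closed-form noiseless first-passage time of the leaky accumulator
#'
#' With \code{noise_scale = 0} the accumulator follows
#' \eqn{x(t) = (I/k)(1 - e^{-kt})}, which reaches \eqn{\theta} at
#' \eqn{t^* = -\log(1 - \theta k / I) / k} provided \eqn{\theta k / I < 1}
#' (otherwise the asymptote lies below threshold and the crossing never
#' happens). Used as an independent oracle for the numerical integrator.
#'
#' @param drift,leak,threshold scalar parameters (leak may be 0, giving the
#'   linear-ramp limit \eqn{t^* = \theta / I}).
#' @return crossing time in seconds, or \code{Inf} when unreachable.
#' @export
noiseless_crossing_time <- function(drift, leak, threshold) {
  if (drift <= 0) return(Inf)
  if (leak == 0) return(threshold / drift)
  z <- threshold * leak / drift
  if (z >= 1) Inf else -log(1 - z) / leak
}

#' Race two accumulators to threshold
#'
#' Runs the congruent and incongruent accumulators in parallel with
#' independent noise increments; the first to cross the shared threshold
#' wins and sets the reaction time. A tie at the same sample (probability of
#' order \eqn{\Delta t}) is broken by a fair coin drawn from the same RNG
#' stream. If neither accumulator crosses before \code{t_max} the winner is
#' \code{"none"}.
#'
#' @param congruent,incongruent \code{\link{accumulator_params}} for the two
#'   alternatives; they must share \code{dt}, \code{t_max} and
#'   \code{threshold}.
#' @param seed optional integer seed.
#' @return list with \code{winner} (\code{"congruent"}, \code{"incongruent"}
#'   or \code{"none"}), \code{rt} (s), \code{crossing_index}, and
#'   \code{traces} (list of the two activation traces, both truncated at the
#'   winning crossing).
#' @export
run_race <- function(congruent, incongruent, seed = NULL) {
  stopifnot(inherits(congruent, "accumulator_params"),
            inherits(incongruent, "accumulator_params"))
  if (congruent$dt != incongruent$dt || congruent$t_max != incongruent$t_max)
    stop("the two racing accumulators must share dt and t_max")
  if (congruent$threshold != incongruent$threshold)
    stop("the two racing accumulators must share the threshold")
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_race_trial(congruent$drift, congruent$leak,
                        congruent$noise_scale,
                        incongruent$drift, incongruent$leak,
                        incongruent$noise_scale,
                        congruent$threshold, congruent$dt,
                        n_steps(congruent),
                        FALSE, 0, 0, 0, 0, 0, 0)
  winner <- c("none", "congruent", "incongruent")[res$winner + 1L]
  crossing <- if (res$crossing > 0L) res$crossing else NA_integer_
  list(winner = winner,
       rt = if (is.na(crossing)) NA_real_ else crossing * congruent$dt,
       crossing_index = crossing,
       traces = list(congruent = res$trace1, incongruent = res$trace2))
}

#' Parameters for one experimental condition of the dual-component model
#'
#' A condition couples a congruent/incongruent accumulator pair with the
#' decision type that determines which component of the model decides.
#' In \emph{arbitrary} decisions the noise (SMA) pair races to threshold and
#' decides; in \emph{deliberate} decisions the value (Region X) pair decides
#' while the SMA pair integrates without a threshold, its drift rates scaled
#' down by \code{sma_drift_ratio}.
#'
#' @param decision_type \code{"deliberate"} or \code{"arbitrary"}.
#' @param difficulty \code{"easy"} or \code{"hard"}.
#' @param congruent,incongruent \code{\link{accumulator_params}} of the
#'   deciding pair (Region X for deliberate, SMA for arbitrary conditions).
#' @param sma_drift_ratio factor by which SMA drift rates are smaller than
#'   the deciding Region X drifts during deliberate decisions (default 1.45,
#'   the ratio of central to whole-scalp EEG activity used to set it).
#' @param simulate_region_x during arbitrary trials the value pair is
#'   outcome-irrelevant; set \code{TRUE} to integrate an unbounded auxiliary
#'   pair alongside anyway (default \code{FALSE}).
#' @return object of class \code{condition_params}.
#' @export
condition_params <- function(decision_type, difficulty, congruent,
                             incongruent, sma_drift_ratio = 1.45,
                             simulate_region_x = FALSE) {
  decision_type <- match.arg(decision_type, c("deliberate", "arbitrary"))
  difficulty <- match.arg(difficulty, c("easy", "hard"))
  stopifnot(inherits(congruent, "accumulator_params"),
            inherits(incongruent, "accumulator_params"))
  stopifnot(sma_drift_ratio > 0)
  if (decision_type == "deliberate" &&
      congruent$drift < incongruent$drift)
    stop("deliberate conditions require congruent drift >= incongruent drift")
  structure(list(decision_type = decision_type, difficulty = difficulty,
                 congruent = congruent, incongruent = incongruent,
                 sma_drift_ratio = sma_drift_ratio,
                 simulate_region_x = isTRUE(simulate_region_x)),
            class = "condition_params")
}

#' Best-fit model parameter table
#'
#' The four best-fit parameter sets of the dual-component model, one per
#' decision type x difficulty cell, in the tabular interchange format used
#' throughout the package (threshold fixed at 0.3 for all cells). For
#' deliberate conditions the listed values parameterize the deciding Region
#' X pair; the SMA pair uses the same leak and noise with drifts divided by
#' 1.45.
#'
#' @return data.frame with columns \code{decision_type}, \code{difficulty},
#'   \code{I_congruent}, \code{I_incongruent}, \code{k}, \code{c},
#'   \code{threshold}.
#' @export
default_parameter_table <- function() {
  data.frame(
    decision_type = c("deliberate", "deliberate", "arbitrary", "arbitrary"),
    difficulty = c("easy", "hard", "easy", "hard"),
    I_congruent = c(0.23, 0.18, 0.24, 0.22),
    I_incongruent = c(0.06, 0.09, 0.21, 0.20),
    k = c(0.52, 0.53, 0.53, 0.54),
    c = c(0.08, 0.11, 0.22, 0.23),
    threshold = 0.3,
    stringsAsFactors = FALSE)
}

#' Read / write model parameter tables as CSV
#'
#' @param path file path.
#' @return \code{read_parameter_table} returns the validated data.frame;
#'   \code{write_parameter_table} returns \code{path} invisibly.
#' @export
read_parameter_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("decision_type", "difficulty", "I_congruent", "I_incongruent",
              "k", "c", "threshold")
  if (!all(needed %in% names(tab)))
    stop("parameter table must have columns: ", paste(needed, collapse = ", "))
  tab[, needed]
}

#' @rdname read_parameter_table
#' @param tab parameter table data.frame.
#' @export
write_parameter_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Build condition parameters from a parameter table row
#'
#' @param tab a parameter table (see \code{\link{default_parameter_table}}).
#' @param decision_type,difficulty cell selector.
#' @param dt,t_max integration settings passed to the accumulators.
#' @param ... further arguments to \code{\link{condition_params}}.
#' @return a \code{condition_params} object.
#' @export
condition_from_table <- function(tab, decision_type, difficulty,
                                 dt = 0.001, t_max = 20, ...) {
  row <- tab[tab$decision_type == decision_type &
             tab$difficulty == difficulty, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("no unique table entry for ", decision_type, "-", difficulty)
  condition_params(
    decision_type, difficulty,
    congruent = accumulator_params(row$I_congruent, row$k, row$c,
                                   row$threshold, dt, t_max),
    incongruent = accumulator_params(row$I_incongruent, row$k, row$c,
                                     row$threshold, dt, t_max),
    ...)
}

sma_pair <- function(cond) {
  r <- cond$sma_drift_ratio
  list(
    congruent = accumulator_params(cond$congruent$drift / r,
                                   cond$congruent$leak,
                                   cond$congruent$noise_scale,
                                   Inf, cond$congruent$dt,
                                   cond$congruent$t_max),
    incongruent = accumulator_params(cond$incongruent$drift / r,
                                     cond$incongruent$leak,
                                     cond$incongruent$noise_scale,
                                     Inf, cond$incongruent$dt,
                                     cond$incongruent$t_max))
}

#' Simulate one trial of the dual-component model
#'
#' For arbitrary conditions the SMA (noise) race decides: its traces are both
#' the deciding and the recorded (SMA) traces. For deliberate conditions the
#' Region X (value) race decides while the SMA pair integrates in parallel
#' with an unbounded threshold and drifts divided by \code{sma_drift_ratio};
#' the SMA traces are truncated at the Region X crossing so all four series
#' share the same length.
#'
#' @param cond a \code{\link{condition_params}} object.
#' @param seed optional integer seed.
#' @return list (a trial result) with \code{winner}, \code{rt},
#'   \code{crossing_index}, \code{deciding_traces} and \code{sma_traces}
#'   (each a list of congruent/incongruent series), and \code{decided}
#'   (logical; \code{FALSE} flags the analogue of a 20 s no-response trial).
#' @export
run_trial <- function(cond, seed = NULL) {
  stopifnot(inherits(cond, "condition_params"))
  if (!is.null(seed)) set.seed(seed)
  cg <- cond$congruent; ig <- cond$incongruent
  if (cond$decision_type == "arbitrary") {
    res <- cpp_race_trial(cg$drift, cg$leak, cg$noise_scale,
                          ig$drift, ig$leak, ig$noise_scale,
                          cg$threshold, cg$dt, n_steps(cg),
                          cond$simulate_region_x,
                          cg$drift, cg$leak, cg$noise_scale,
                          ig$drift, ig$leak, ig$noise_scale)
    deciding <- list(congruent = res$trace1, incongruent = res$trace2)
    sma <- deciding
  } else {
    sp <- sma_pair(cond)
    res <- cpp_race_trial(cg$drift, cg$leak, cg$noise_scale,
                          ig$drift, ig$leak, ig$noise_scale,
                          cg$threshold, cg$dt, n_steps(cg),
                          TRUE,
                          sp$congruent$drift, sp$congruent$leak,
                          sp$congruent$noise_scale,
                          sp$incongruent$drift, sp$incongruent$leak,
                          sp$incongruent$noise_scale)
    deciding <- list(congruent = res$trace1, incongruent = res$trace2)
    sma <- list(congruent = res$sma1, incongruent = res$sma2)
  }
  winner <- c("none", "congruent", "incongruent")[res$winner + 1L]
  crossing <- if (res$crossing > 0L) res$crossing else NA_integer_
  list(winner = winner,
       rt = if (is.na(crossing)) NA_real_ else crossing * cg$dt,
       crossing_index = crossing,
       deciding_traces = deciding, sma_traces = sma,
       decided = !is.na(crossing))
}

#' Simulate many trials of one condition
#'
#' Batch simulation used by the fitting loops. Only the deciding race is
#' integrated (traces are not stored); use \code{\link{run_trial}} /
#' \code{\link{predict_rp}} when SMA traces are needed. Undecided trials
#' (no crossing before \code{t_max}) are excluded from the reaction times
#' and the consistency score, with their count reported.
#'
#' @param cond a \code{\link{condition_params}} object.
#' @param n_runs number of trials (>= 1).
#' @param seed optional integer seed.
#' @return list with \code{rt} (seconds, \code{NA} for undecided trials),
#'   \code{winner} (character vector), \code{consistency} (fraction of
#'   congruent winners among decided trials) and \code{n_undecided}.
#' @export
simulate_condition <- function(cond, n_runs, seed = NULL) {
  stopifnot(inherits(cond, "condition_params"),
            is.numeric(n_runs), n_runs >= 1)
  if (!is.null(seed)) set.seed(seed)
  cg <- cond$congruent; ig <- cond$incongruent
  res <- cpp_race_many(as.integer(n_runs),
                       cg$drift, cg$leak, cg$noise_scale,
                       ig$drift, ig$leak, ig$noise_scale,
                       cg$threshold, cg$dt, n_steps(cg))
  winner <- c("none", "congruent", "incongruent")[res$winner + 1L]
  decided <- res$crossing > 0L
  if (!any(decided))
    stop("all ", n_runs, " trials undecided before t_max; ",
         "degenerate parameters")
  rt <- ifelse(decided, res$crossing * cg$dt, NA_real_)
  list(rt = rt, winner = winner,
       consistency = mean(winner[decided] == "congruent"),
       n_undecided = sum(!decided))
}
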