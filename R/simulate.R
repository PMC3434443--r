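# Synchronous discrete-time execution.
#
# The timing rule: the state of a regulated component at instant t+1 depends
# on the full configuration at instant t; all regulated components update
# simultaneously; independent components hold their value unless an input
# schedule changes it.

#' One synchronous update step
#'
#' For every regulated component simultaneously: new value 1 if its
#' `on_guard` holds on `config`, 0 if its `off_guard` holds (with
#' `allow_partial` rules, hold the current value if neither fires).
#' Independent components keep their value. The input is not modified.
#'
#' @param model a `"motif_model"`.
#' @param config named 0/1 vector, total over the model's components.
#' @return the successor configuration (named integer vector, model order).
#' @examples
#' m <- build_feedback("negative")
#' step_state(m, c(X = 1, S_X = 1, Y = 1, S_Y = 1))  # Y switches off
#' @export
step_state <- function(model, config) {
  cfg <- as_model_config(model, config)
  out <- cfg
  for (comp in model$components) {
    if (is_independent(comp)) next
    if (eval_guard(comp$rule$on_guard, cfg)) out[comp$name] <- 1L
    else if (eval_guard(comp$rule$off_guard, cfg)) out[comp$name] <- 0L
    # else: uncovered assignment of a partial rule -> hold state
  }
  out
}

#' Timed input schedule
#'
#' A schedule lists events that set an independent component to a value at a
#' given time instant — the motif's interface to "events outside the motif
#' itself". Events take effect AT their instant: the scheduled value is part
#' of the configuration at that instant, and the next step is computed from
#' the overlaid configuration.
#'
#' @param time non-negative integer instants.
#' @param component component names (recycled against `time`).
#' @param value 0/1 values (recycled).
#' @return a data frame of class `"input_schedule"` with columns
#'   `time`, `component`, `value`.
#' @examples
#' input_schedule(2, "X", 1)
#' @export
input_schedule <- function(time = integer(), component = character(), value = integer()) {
  df <- data.frame(time = as.integer(time), component = as.character(component),
                   value = as.integer(value), stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (anyNA(df)) stop("schedule entries must not contain NA", call. = FALSE)
    if (any(df$time < 0L)) stop("schedule times must be non-negative", call. = FALSE)
    if (!all(df$value %in% c(0L, 1L))) stop("schedule values must be 0 or 1", call. = FALSE)
    key <- paste(df$time, df$component)
    if (anyDuplicated(key))
      stop("at most one event per (time, component) pair; duplicated: ",
           paste(sQuote(unique(key[duplicated(key)])), collapse = ", "), call. = FALSE)
    df <- df[order(df$time, df$component), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("input_schedule", "data.frame")
  df
}

as_input_schedule <- function(x) {
  if (inherits(x, "input_schedule")) return(x)
  if (is.null(x)) return(input_schedule())
  if (is.data.frame(x)) return(input_schedule(x$time, x$component, x$value))
  stop("cannot interpret object as an input schedule", call. = FALSE)
}

#' Simulate a motif under a schedule
#'
#' Deterministic synchronous simulation. The configuration at instant t is
#' first overlaid with all schedule events at time t; the overlaid
#' configuration is recorded in the trace and then stepped to produce
#' instant t+1, and so on for `horizon` instants.
#'
#' @param model a `"motif_model"`.
#' @param initial total 0/1 configuration at the first instant (before
#'   overlay of events scheduled at that instant).
#' @param schedule an [input_schedule()] (or data frame with columns
#'   `time`, `component`, `value`), or `NULL` for none. Events may only
#'   target independent components and must fall within
#'   `[start, start + horizon - 1]`.
#' @param horizon number of instants to record (>= 1).
#' @param start time label of the first instant (default 0); shifts the `t`
#'   axis only, so traces can be printed on the same axis as a reference
#'   timing diagram.
#' @return a `"motif_trace"`: a data frame with column `t` then one 0/1
#'   column per component in model order, one row per instant.
#' @examples
#' m <- build_ffl("c1")
#' tr <- simulate_motif(m, initial_state(m, on = c("S_X", "S_Y")),
#'                      schedule = input_schedule(2, "X", 1), horizon = 8)
#' first_on_time(tr, "Z")  # 4: delayed activation
#' @export
simulate_motif <- function(model, initial, schedule = NULL, horizon, start = 0L) {
  stopifnot(inherits(model, "motif_model"))
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1L) stop("'horizon' must be a positive integer", call. = FALSE)
  start <- as.integer(start)
  cfg <- as_model_config(model, initial)
  sch <- as_input_schedule(schedule)
  if (nrow(sch)) {
    indep <- independent_components(model)
    bad <- setdiff(unique(sch$component), indep)
    if (length(bad))
      stop("schedule targets regulated or unknown component(s): ",
           paste(sQuote(bad), collapse = ", "),
           " (only independent components can be driven)", call. = FALSE)
    out_of_range <- sch$time < start | sch$time >= start + horizon
    if (any(out_of_range))
      stop("schedule time(s) outside [", start, ", ", start + horizon - 1L, "]: ",
           paste(unique(sch$time[out_of_range]), collapse = ", "), call. = FALSE)
  }
  nms <- component_names(model)
  states <- matrix(0L, nrow = horizon, ncol = length(nms), dimnames = list(NULL, nms))
  for (k in seq_len(horizon)) {
    t <- start + k - 1L
    ev <- sch[sch$time == t, , drop = FALSE]
    if (nrow(ev)) cfg[ev$component] <- ev$value
    states[k, ] <- cfg
    if (k < horizon) cfg <- step_state(model, cfg)
  }
  tr <- data.frame(t = start + seq_len(horizon) - 1L, states, check.names = FALSE)
  attr(tr, "model_name") <- model$name
  attr(tr, "components") <- nms
  class(tr) <- c("motif_trace", "data.frame")
  tr
}

#' @export
print.motif_trace <- function(x, ...) {
  cat("Trace of", attr(x, "model_name"), "(", nrow(x), "instants )\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Plot a trace as a timing diagram
#'
#' One horizontal band per component (model order, top first), filled where
#' the component is "on" — the standard on/off bar diagram for boolean motif
#' dynamics.
#'
#' @param x a `"motif_trace"`.
#' @param col fill colour for the "on" state.
#' @param ... ignored.
#' @export
plot.motif_trace <- function(x, col = "grey30", ...) {
  comps <- rev(attr(x, "components"))
  n <- length(comps)
  t <- x$t
  graphics::plot(NULL, xlim = range(t) + c(0, 1), ylim = c(0, n),
                 xlab = "time instant t", ylab = "", yaxt = "n", xaxs = "i",
                 main = attr(x, "model_name"))
  graphics::axis(2, at = seq_len(n) - 0.5, labels = comps, las = 1, tick = FALSE)
  for (i in seq_along(comps)) {
    on <- which(x[[comps[i]]] == 1L)
    if (length(on))
      graphics::rect(t[on], i - 0.9, t[on] + 1, i - 0.1, col = col, border = NA)
    graphics::abline(h = i, col = "grey85")
  }
  invisible(x)
}

trace_column <- function(trace, comp) {
  stopifnot(inherits(trace, "motif_trace"))
  if (!(comp %in% attr(trace, "components")))
    stop("unknown component ", sQuote(comp), " for this trace", call. = FALSE)
  as.integer(trace[[comp]])
}

#' First instant a component is "on"
#'
#' @param trace a `"motif_trace"`.
#' @param comp a component name.
#' @return the smallest time instant at which the component has value 1, or
#'   `NULL` if it is never on within the trace.
#' @export
first_on_time <- function(trace, comp) {
  v <- trace_column(trace, comp)
  i <- which(v == 1L)
  if (!length(i)) return(NULL)
  trace$t[i[1L]]
}

#' Detect pulses in a component's time course
#'
#' A pulse is a maximal run of consecutive "on" instants preceded and
#' followed, within the trace, by "off". Runs touching a trace boundary
#' cannot be confirmed as pulses and are reported with `open_ended = TRUE`.
#' The unit-time impulse of the incoherent type-1 feedforward loop shows up
#' here as a single pulse of width 1.
#'
#' @param trace a `"motif_trace"`.
#' @param comp a component name.
#' @return data frame with columns `start` (instant of the first "on"),
#'   `width` (run length) and `open_ended` (logical); zero rows if the
#'   component is never on.
#' @export
detect_pulses <- function(trace, comp) {
  v <- trace_column(trace, comp)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values == 1L)
  data.frame(
    start = trace$t[starts[on]],
    width = r$lengths[on],
    open_ended = starts[on] == 1L | ends[on] == length(v))
}

#' Period of a trace's eventual cycle
#'
#' Removes the transient (the prefix before the first revisited
#' configuration) and returns the period of the remaining cycle: the
#' distance between the two occurrences of the first configuration to
#' repeat. In a deterministic finite system this is exact. A period of 1
#' means the trace settled to a fixed point.
#'
#' @param trace a `"motif_trace"` of length >= 2.
#' @return the period (positive integer), or `NULL` if no configuration
#'   repeats within the trace.
#' @export
oscillation_period <- function(trace) {
  stopifnot(inherits(trace, "motif_trace"))
  if (nrow(trace) < 2L) stop("trace must have length >= 2", call. = FALSE)
  comps <- attr(trace, "components")
  keys <- do.call(paste, c(unname(as.list(trace[comps])), sep = ""))
  seen <- match(keys, keys)           # index of first occurrence
  rep_at <- which(seen < seq_along(keys))[1L]
  if (is.na(rep_at)) return(NULL)
  as.integer(rep_at - seen[rep_at])
}
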