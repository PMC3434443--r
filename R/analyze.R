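# Exhaustive attractor analysis of the synchronous dynamics.
#
# State spaces here are tiny (<= 2^6 for every shipped motif), so the
# attractors are found by brute force: enumerate every configuration of the
# unclamped components, follow the deterministic successor map until a state
# repeats, and classify fixed points and cycles together with their basins.

# Encode a 0/1 vector over `free` components as 1-based integer index; the
# first component is the most significant bit, so index order IS
# lexicographic order of configurations in component order.
encode_state <- function(bits) as.integer(sum(bits * 2^((length(bits) - 1L):0L)) + 1)

decode_state <- function(index, k) {
  bits <- integer(k)
  v <- index - 1L
  for (i in k:1L) { bits[i] <- v %% 2L; v <- v %/% 2L }
  bits
}

#' Enumerate all attractors of a motif
#'
#' Iterates over every configuration of the unclamped components (clamped
#' components — typically signals held present — keep their given value
#' throughout), follows the synchronous successor map until a state revisits,
#' and collects the distinct fixed points and cycles together with their
#' basin sizes (the number of enumerated start states that reach each
#' attractor, counting the attractor's own states).
#'
#' Cycles are canonicalized: the lexicographically smallest member state (in
#' component order, with 0 < 1) is listed first, and attractors are sorted
#' by that smallest state.
#'
#' @param model a `"motif_model"`.
#' @param clamped named 0/1 vector over independent components to hold fixed
#'   (e.g. `c(S_X = 1, S_Y = 1)`); may be empty.
#' @param max_states cap on the number of enumerated configurations
#'   (default `2^20`); exceeding it is an error.
#' @return a list of class `"motif_attractors"`; each element has
#'   `states` (matrix, one row per configuration, columns in model order),
#'   `kind` (`"fixed_point"` or `"cycle"`), `period`, and `basin_size`.
#' @examples
#' enumerate_attractors(build_feedback("double_positive"),
#'                      clamped = c(S_X = 1, S_Y = 1))
#' @export
enumerate_attractors <- function(model, clamped = NULL, max_states = 2^20) {
  stopifnot(inherits(model, "motif_model"))
  nms <- component_names(model)
  clamped <- if (is.null(clamped)) integer(0) else clamped
  if (length(clamped)) {
    indep <- independent_components(model)
    bad <- setdiff(names(clamped), indep)
    if (length(bad))
      stop("can only clamp independent components; not independent: ",
           paste(sQuote(bad), collapse = ", "), call. = FALSE)
    if (!all(clamped %in% c(0, 1))) stop("clamped values must be 0 or 1", call. = FALSE)
  }
  free <- setdiff(nms, names(clamped))
  k <- length(free)
  n_states <- 2^k
  if (n_states > max_states)
    stop("state space too large: 2^", k, " configurations exceeds cap ",
         max_states, call. = FALSE)

  base_cfg <- stats::setNames(integer(length(nms)), nms)
  base_cfg[names(clamped)] <- as.integer(clamped)
  full_config <- function(index) {
    cfg <- base_cfg
    if (k > 0L) cfg[free] <- decode_state(index, k)
    cfg
  }

  # Successor map over the free sub-state space (clamping re-imposed).
  succ <- integer(n_states)
  for (s in seq_len(n_states)) {
    nxt <- step_state(model, full_config(s))
    succ[s] <- if (k > 0L) encode_state(nxt[free]) else 1L
  }

  # Assign every state to an attractor by path-following with memoization.
  attr_of <- rep(NA_integer_, n_states)
  attractor_cycles <- list()   # each: integer vector of member state indices
  for (s0 in seq_len(n_states)) {
    if (!is.na(attr_of[s0])) next
    path <- integer(0)
    pos <- integer(n_states)   # 1-based position of state within current path
    s <- s0
    repeat {
      if (!is.na(attr_of[s])) { id <- attr_of[s]; break }
      if (pos[s] > 0L) {       # new cycle discovered within this path
        cyc <- path[pos[s]:length(path)]
        shift <- which.min(cyc)            # lexicographically smallest member
        cyc <- c(cyc[shift:length(cyc)], cyc[seq_len(shift - 1L)])
        attractor_cycles[[length(attractor_cycles) + 1L]] <- cyc
        id <- length(attractor_cycles)
        break
      }
      path <- c(path, s)
      pos[s] <- length(path)
      s <- succ[s]
    }
    attr_of[path] <- id
  }

  basin <- tabulate(attr_of, nbins = length(attractor_cycles))
  out <- lapply(seq_along(attractor_cycles), function(id) {
    cyc <- attractor_cycles[[id]]
    states <- do.call(rbind, lapply(cyc, full_config))
    rownames(states) <- NULL
    list(states = states,
         kind = if (length(cyc) == 1L) "fixed_point" else "cycle",
         period = length(cyc),
         basin_size = basin[id])
  })
  ord <- order(vapply(attractor_cycles, `[`, integer(1L), 1L))
  out <- out[ord]
  structure(out, class = "motif_attractors",
            model_name = model$name, clamped = clamped, free = free)
}

#' @export
print.motif_attractors <- function(x, ...) {
  cl <- attr(x, "clamped")
  cat("Attractors of ", attr(x, "model_name"),
      if (length(cl)) paste0(" (clamped: ", paste0(names(cl), "=", cl, collapse = ", "), ")"),
      ": ", length(x), " found over ", 2^length(attr(x, "free")),
      " start states\n", sep = "")
  for (i in seq_along(x)) {
    a <- x[[i]]
    states <- apply(a$states, 1L, function(r) paste0(colnames(a$states), "=", r, collapse = ","))
    cat(sprintf("  [%d] %s (period %d, basin %d)\n      %s\n", i, a$kind,
                a$period, a$basin_size, paste(states, collapse = " -> ")))
  }
  invisible(x)
}

config_in_attractor <- function(attractor, config) {
  any(apply(attractor$states, 1L, function(r) all(r == config[colnames(attractor$states)])))
}

#' Check bistability of a motif
#'
#' For each candidate pair of steady states, reports whether both are fixed
#' points of the clamped synchronous dynamics, and lists the initial states
#' whose trajectories reach neither — the states trapped in an oscillating
#' pattern, which the two-valued state domain cannot funnel into either
#' steady state. The double-positive feedback loop is jointly bistable
#' ((off,off)/(on,on) fixed) and the double-negative loop exclusively
#' bistable ((on,off)/(off,on) fixed).
#'
#' @param model a `"motif_model"`.
#' @param clamped named 0/1 vector over independent components (see
#'   [enumerate_attractors()]).
#' @param pairs list of pairs (each a list of two total 0/1 configurations).
#' @return a list of class `"bistability_report"` with elements `pairs`
#'   (per input pair: the pair, `fixed` flags, `both_fixed`),
#'   `non_converging` (matrix of start states reaching no fixed point among
#'   the pairs), and `attractors`.
#' @examples
#' m <- build_feedback("double_positive")
#' check_bistability(m, clamped = c(S_X = 1, S_Y = 1),
#'   pairs = list(list(c(X = 0, S_X = 1, Y = 0, S_Y = 1),
#'                     c(X = 1, S_X = 1, Y = 1, S_Y = 1))))
#' @export
check_bistability <- function(model, clamped = NULL, pairs = list()) {
  atts <- enumerate_attractors(model, clamped = clamped)
  nms <- component_names(model)
  free <- attr(atts, "free")

  fixed_points <- Filter(function(a) a$kind == "fixed_point", atts)
  pair_reports <- lapply(pairs, function(p) {
    if (length(p) != 2L) stop("each pair must contain exactly two configurations", call. = FALSE)
    cfgs <- lapply(p, as_model_config, model = model)
    fixed <- vapply(cfgs, function(cfg)
      any(vapply(fixed_points, config_in_attractor, logical(1L), config = cfg)), logical(1L))
    list(pair = cfgs, fixed = fixed, both_fixed = all(fixed))
  })

  # Start states (over the free components) attracted to none of the pair
  # fixed points.
  target_ids <- which(vapply(atts, function(a) {
    a$kind == "fixed_point" &&
      any(vapply(pair_reports, function(pr)
        pr$both_fixed && any(vapply(pr$pair, function(cfg)
          config_in_attractor(a, cfg), logical(1L))), logical(1L)))
  }, logical(1L)))

  k <- length(free)
  non_conv <- matrix(integer(0), nrow = 0L, ncol = length(nms), dimnames = list(NULL, nms))
  if (length(pairs)) {
    base_cfg <- stats::setNames(integer(length(nms)), nms)
    if (length(attr(atts, "clamped"))) {
      cl <- attr(atts, "clamped")
      base_cfg[names(cl)] <- as.integer(cl)
    }
    rows <- list()
    for (s in seq_len(2^k)) {
      cfg <- base_cfg
      if (k > 0L) cfg[free] <- decode_state(s, k)
      # follow to the attractor
      tr <- simulate_motif(model, cfg, horizon = 2^k + 2L)
      last <- as_model_config(model, unlist(tr[nrow(tr), component_names(model)]))
      reached <- which(vapply(atts, config_in_attractor, logical(1L), config = last))[1L]
      if (!(reached %in% target_ids)) rows[[length(rows) + 1L]] <- cfg
    }
    if (length(rows)) non_conv <- do.call(rbind, rows)
  }

  structure(list(pairs = pair_reports, non_converging = non_conv, attractors = atts),
            class = "bistability_report", model_name = model$name)
}

#' @export
print.bistability_report <- function(x, ...) {
  cat("Bistability report for", attr(x, "model_name"), "\n")
  if (!length(x$pairs)) {
    cat("  (no candidate steady-state pairs given)\n")
  } else {
    for (i in seq_along(x$pairs)) {
      pr <- x$pairs[[i]]
      fmt <- function(cfg) paste0("{", paste0(names(cfg), "=", cfg, collapse = ","), "}")
      cat(sprintf("  pair %d: %s / %s -> %s\n", i, fmt(pr$pair[[1L]]), fmt(pr$pair[[2L]]),
                  if (pr$both_fixed) "both fixed points" else "NOT both fixed"))
    }
    cat("  start states reaching neither steady state:",
        if (nrow(x$non_converging)) "" else "none", "\n")
    if (nrow(x$non_converging))
      for (i in seq_len(nrow(x$non_converging)))
        cat("    {", paste0(colnames(x$non_converging), "=", x$non_converging[i, ],
                            collapse = ","), "}\n", sep = "")
  }
  invisible(x)
}
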