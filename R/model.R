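# Motif models: a parallel composition of two-state (on/off) components.
#
# Each component is either *independent* (no incoming transitions; its state
# only changes through externally supplied timed events) or *regulated* by an
# update rule: a pair of guards labelling the off->on and on->off transitions
# of its two-state machine. This is exactly the statechart fragment needed
# for GRN motifs: one parallel composite, one exclusive on/off composite per
# element, condition-guarded transitions, no events, actions or deeper
# hierarchy.

#' Update rule for a regulated component
#'
#' The off->on transition fires when `on_guard` is true, the on->off
#' transition when `off_guard` is true, both read against the full
#' configuration at the previous time instant. [make_model()] validates that
#' the two guards are mutually exclusive, and (unless `allow_partial`)
#' jointly exhaustive, over all assignments of their variables — making the
#' regulated component a deterministic boolean function of the previous
#' state.
#'
#' @param on_guard,off_guard guards (anything [as_guard()] accepts).
#' @return an object of class `"update_rule"`.
#' @seealso [rule_from_next_state()] for the canonical constructor.
#' @examples
#' update_rule(~ X & S_X, ~ !(X & S_X))
#' @export
update_rule <- function(on_guard, off_guard) {
  structure(list(on_guard = as_guard(on_guard), off_guard = as_guard(off_guard)),
            class = "update_rule")
}

#' Update rule from a next-state function
#'
#' The canonical way to define regulation: a boolean next-state function `f`
#' yields `on_guard = f`, `off_guard = !f`, which satisfies the
#' exclusivity/exhaustiveness invariant by construction. `f = TRUE` switches
#' the component on and keeps it on; `f = ~ Y` (the component itself) is
#' positive autoregulation, a state-holding rule.
#'
#' @param f a guard (anything [as_guard()] accepts), read as the component's
#'   next-state function of the previous configuration.
#' @return an `"update_rule"`.
#' @examples
#' rule_from_next_state(~ X & S_X)
#' @export
rule_from_next_state <- function(f) {
  f <- as_guard(f)
  update_rule(f, negate_guard(f))
}

#' @export
print.update_rule <- function(x, ...) {
  cat("<update_rule>\n  on:  ", deparse_guard(x$on_guard),
      "\n  off: ", deparse_guard(x$off_guard), "\n", sep = "")
  invisible(x)
}

#' Declare a motif component
#'
#' @param name component name: letters, digits, underscore, starting with a
#'   letter (e.g. `"X"`, `"S_X"`).
#' @param kind `"gene"` or `"signal"`. Signals mediate a gene's action and in
#'   the shipped motif catalogue are always independent.
#' @param rule an [update_rule()], or `NULL` for an independent component
#'   (the motif's marker for an externally driven element).
#' @return an object of class `"motif_component"`.
#' @examples
#' component("X")
#' component("S_X", kind = "signal")
#' component("Y", rule = rule_from_next_state(~ X & S_X))
#' @export
component <- function(name, kind = c("gene", "signal"), rule = NULL) {
  kind <- match.arg(kind)
  if (!is_component_name(name))
    stop("invalid component name ", sQuote(name),
         " (letters, digits, underscore; must start with a letter)", call. = FALSE)
  if (!is.null(rule) && !inherits(rule, "update_rule"))
    stop("'rule' must be an update_rule or NULL", call. = FALSE)
  structure(list(name = name, kind = kind, rule = rule), class = "motif_component")
}

is_independent <- function(comp) is.null(comp$rule)

#' Build and validate a motif model
#'
#' Assembles components into a validated model. Validation enforces:
#' * at least one component, unique names;
#' * every guard variable names a component of the model;
#' * for every rule, `on_guard` and `off_guard` never hold simultaneously
#'   (exclusivity; violations report a witness assignment);
#' * unless `allow_partial`, the guards cover every assignment
#'   (exhaustiveness), so the component is a total boolean function of the
#'   previous configuration.
#'
#' With `allow_partial = TRUE` a gap is allowed and the component holds its
#' state on uncovered assignments; overlap remains a hard error — silent
#' nondeterminism is never admitted. No shipped motif uses partial rules.
#'
#' Component order is fixed at construction and defines the column order of
#' traces and the lexicographic order used to canonicalize attractors.
#'
#' @param components list of [component()] objects.
#' @param name model name (string).
#' @param description optional free-text description.
#' @param allow_partial admit non-exhaustive guard pairs (hold-state
#'   semantics on the gap). Default `FALSE`.
#' @return an object of class `"motif_model"`.
#' @examples
#' m <- make_model(
#'   list(component("X"),
#'        component("Y", rule = rule_from_next_state(~ X))),
#'   name = "minimal activation")
#' m
#' @export
make_model <- function(components, name, description = "", allow_partial = FALSE) {
  if (!is.list(components) || length(components) == 0L)
    stop("'components' must be a non-empty list of components", call. = FALSE)
  if (!all(vapply(components, inherits, logical(1L), "motif_component")))
    stop("'components' must all be created with component()", call. = FALSE)
  nms <- vapply(components, `[[`, character(1L), "name")
  dup <- unique(nms[duplicated(nms)])
  if (length(dup))
    stop("duplicate component name(s): ", paste(sQuote(dup), collapse = ", "), call. = FALSE)
  names(components) <- nms

  for (comp in components) {
    if (is_independent(comp)) next
    rule <- comp$rule
    vars <- union(guard_vars(rule$on_guard), guard_vars(rule$off_guard))
    dangling <- setdiff(vars, nms)
    if (length(dangling))
      stop("guard of ", sQuote(comp$name), " references undeclared component(s): ",
           paste(sQuote(dangling), collapse = ", "), call. = FALSE)
    check_rule_guards(rule, comp$name, allow_partial = allow_partial)
  }

  structure(list(components = components, name = as.character(name)[1L],
                 description = as.character(description)[1L]),
            class = "motif_model")
}

# Exclusivity always; exhaustiveness unless allow_partial. Reports a witness
# assignment on failure.
check_rule_guards <- function(rule, comp_name, allow_partial = FALSE) {
  vars <- union(guard_vars(rule$on_guard), guard_vars(rule$off_guard))
  assigns <- all_assignments(vars)
  gap_witness <- NULL
  for (i in seq_len(nrow(assigns))) {
    cfg <- assigns[i, , drop = TRUE]
    names(cfg) <- vars
    on <- eval_guard(rule$on_guard, cfg)
    off <- eval_guard(rule$off_guard, cfg)
    witness <- if (length(vars)) paste0("{", paste0(vars, "=", cfg, collapse = ", "), "}") else "{}"
    if (on && off)   # overlap is the graver defect: report it first
      stop("guards of ", sQuote(comp_name), " overlap: both fire on ", witness, call. = FALSE)
    if (!on && !off && is.null(gap_witness)) gap_witness <- witness
  }
  if (!is.null(gap_witness) && !allow_partial)
    stop("guards of ", sQuote(comp_name), " leave a gap: neither fires on ", gap_witness,
         " (use allow_partial = TRUE for hold-state semantics)", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.motif_model <- function(x, ...) {
  cat("Motif model:", x$name, "\n")
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  cat("  components (", length(x$components), "), state space ",
      state_space_size(x), ":\n", sep = "")
  for (comp in x$components) {
    if (is_independent(comp)) {
      cat(sprintf("    %-6s %-7s independent\n", comp$name, paste0("[", comp$kind, "]")))
    } else {
      cat(sprintf("    %-6s %-7s next <- %s\n", comp$name, paste0("[", comp$kind, "]"),
                  deparse_guard(comp$rule$on_guard)))
    }
  }
  invisible(x)
}

#' Component names of a model
#' @param model a `"motif_model"`.
#' @return character vector in model (column/encoding) order.
#' @export
component_names <- function(model) {
  stopifnot(inherits(model, "motif_model"))
  names(model$components)
}

independent_components <- function(model) {
  names(model$components)[vapply(model$components, is_independent, logical(1L))]
}

#' Size of a model's state space
#' @param model a `"motif_model"`.
#' @return `2 ^ (number of components)`.
#' @examples
#' state_space_size(build_simple_regulation("s1"))  # 8
#' @export
state_space_size <- function(model) {
  stopifnot(inherits(model, "motif_model"))
  2^length(model$components)
}

# Check that `config` is a total 0/1 assignment over the model's components;
# returns it coerced to a named integer vector in model order.
as_model_config <- function(model, config) {
  nms <- component_names(model)
  if (is.null(names(config)) || anyNA(names(config)))
    stop("configuration must be a named vector of 0/1 values", call. = FALSE)
  missing <- setdiff(nms, names(config))
  if (length(missing))
    stop("configuration is not total: missing component(s) ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  extra <- setdiff(names(config), nms)
  if (length(extra))
    stop("configuration names unknown component(s): ",
         paste(sQuote(extra), collapse = ", "), call. = FALSE)
  vals <- as.integer(as.numeric(config[nms]))
  if (anyNA(vals) || !all(vals %in% c(0L, 1L)))
    stop("configuration values must be 0 or 1", call. = FALSE)
  names(vals) <- nms
  vals
}

#' Convenience constructor for an initial configuration
#'
#' All components start "off" except those listed in `on`.
#'
#' @param model a `"motif_model"`.
#' @param on character vector of components to start "on" (typically the
#'   mediating signals, e.g. `c("S_X", "S_Y")`).
#' @return named integer vector of 0/1 in model order.
#' @examples
#' initial_state(build_ffl("c1"), on = c("S_X", "S_Y"))
#' @export
initial_state <- function(model, on = character()) {
  nms <- component_names(model)
  unknown <- setdiff(on, nms)
  if (length(unknown))
    stop("unknown component(s): ", paste(sQuote(unknown), collapse = ", "), call. = FALSE)
  cfg <- stats::setNames(integer(length(nms)), nms)
  cfg[on] <- 1L
  cfg
}
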