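# Guard formulas: the transition-condition language.
#
# A guard is an unevaluated R expression over component names, restricted to
# the connectives `&` (AND), `|` (OR), `!` (NOT), parentheses, and the
# constants TRUE/FALSE. Presence of a component X is written `X`, absence
# `!X`. This is deliberately the same concrete syntax as BoolNet-style rule
# files, so serialization is the identity up to whitespace.

RESERVED_NAMES <- c("TRUE", "FALSE", "T", "F", "NA", "NULL", "Inf", "NaN")

is_component_name <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) &&
    grepl("^[A-Za-z][A-Za-z0-9_]*$", x) && !(x %in% RESERVED_NAMES)
}

#' Construct a guard formula
#'
#' Converts its argument into a validated guard: a boolean expression over
#' component presence/absence using `&`, `|`, `!`, parentheses and the
#' constants `TRUE`/`FALSE`. Accepted inputs are one-sided formulas
#' (`~ X & S_X`), quoted expressions (`quote(!(Y & S_Y))`), single strings
#' (`"X & S_X"`), logical scalars, and guards themselves.
#'
#' A component written bare (`X`) denotes its presence (state "on", value 1);
#' under `!` it denotes absence (state "off", value 0).
#'
#' @param x a formula, call, symbol, string or logical scalar.
#' @return an object of class `"guard"` (a language object or logical constant).
#' @examples
#' as_guard(~ X & S_X)
#' as_guard("X & !S_X")
#' as_guard(TRUE)
#' @export
as_guard <- function(x) {
  expr <-
    if (inherits(x, "guard")) unclass_guard(x)
    else if (inherits(x, "formula")) {
      if (length(x) != 2L) stop("guard formulas must be one-sided, e.g. ~ X & S_X", call. = FALSE)
      x[[2L]]
    }
    else if (is.character(x) && length(x) == 1L) {
      parsed <- tryCatch(str2lang(x), error = function(e)
        stop("cannot parse guard text ", sQuote(x), ": ", conditionMessage(e), call. = FALSE))
      parsed
    }
    else if (is.language(x) || is.logical(x)) x
    else stop("cannot interpret object of class ", sQuote(class(x)[1L]), " as a guard", call. = FALSE)
  check_guard_syntax(expr)
  structure(list(expr = expr), class = "guard")
}

unclass_guard <- function(g) g$expr

check_guard_syntax <- function(e) {
  if (is.symbol(e)) {
    nm <- as.character(e)
    if (!is_component_name(nm))
      stop("invalid component name in guard: ", sQuote(nm), call. = FALSE)
    return(invisible(TRUE))
  }
  if (is.logical(e) && length(e) == 1L && !is.na(e)) return(invisible(TRUE))
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (op == "(" && length(e) == 2L) return(check_guard_syntax(e[[2L]]))
    if (op == "!" && length(e) == 2L) return(check_guard_syntax(e[[2L]]))
    if (op %in% c("&", "|") && length(e) == 3L) {
      check_guard_syntax(e[[2L]])
      check_guard_syntax(e[[3L]])
      return(invisible(TRUE))
    }
    stop("guards may only use '&', '|', '!', parentheses, component names and ",
         "TRUE/FALSE; found call to ", sQuote(op), call. = FALSE)
  }
  stop("invalid guard element of type ", sQuote(typeof(e)), call. = FALSE)
}

#' @export
print.guard <- function(x, ...) {
  cat("<guard> ", deparse_guard(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.guard <- function(x, ...) deparse_guard(x)

deparse_guard <- function(g) {
  paste(deparse(unclass_guard(g), width.cutoff = 500L), collapse = " ")
}

#' Component names referenced by a guard
#'
#' @param guard a guard (or anything [as_guard()] accepts).
#' @return character vector of distinct component names, in order of first
#'   occurrence; empty for constant guards.
#' @examples
#' guard_vars(~ X & S_X & Y)
#' guard_vars(TRUE)
#' @export
guard_vars <- function(guard) {
  g <- as_guard(guard)
  all.vars(unclass_guard(g))
}

#' Evaluate a guard against a configuration
#'
#' A configuration assigns 0 ("off", absent) or 1 ("on", present) to each
#' component. Standard boolean semantics: `X` is true iff the configuration
#' maps X to 1, `!X` iff it maps X to 0.
#'
#' @param guard a guard (or anything [as_guard()] accepts).
#' @param config named vector of 0/1 (or logical) values; must assign every
#'   component the guard mentions.
#' @return a single logical.
#' @examples
#' eval_guard(~ X & S_X, c(X = 1, S_X = 1))
#' eval_guard(~ !X | S_X, c(X = 0, S_X = 0))
#' @export
eval_guard <- function(guard, config) {
  g <- as_guard(guard)
  vars <- all.vars(unclass_guard(g))
  missing <- setdiff(vars, names(config))
  if (length(missing))
    stop("configuration does not assign component(s): ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  vals <- as.list(as.logical(as.numeric(config[vars])))
  names(vals) <- vars
  isTRUE(eval(unclass_guard(g), envir = vals, enclos = baseenv()))
}

#' Negate a guard
#'
#' Returns a guard evaluating to the logical complement of the input on every
#' configuration. Double negations are collapsed.
#'
#' @param guard a guard (or anything [as_guard()] accepts).
#' @return a guard.
#' @examples
#' negate_guard(~ X & S_X)   # !(X & S_X)
#' negate_guard(~ !X)        # X
#' @export
negate_guard <- function(guard) {
  g <- as_guard(guard)
  e <- unclass_guard(g)
  e <- strip_parens(e)
  out <-
    if (is.logical(e)) !e
    else if (is.call(e) && as.character(e[[1L]]) == "!" && length(e) == 2L) strip_parens(e[[2L]])
    else if (is.symbol(e)) call("!", e)
    else call("!", call("(", e))
  as_guard(out)
}

strip_parens <- function(e) {
  while (is.call(e) && as.character(e[[1L]]) == "(" && length(e) == 2L) e <- e[[2L]]
  e
}

# All 2^k assignments over the given variable names, as a 0/1 matrix with one
# row per assignment (k = 0 gives a single empty assignment).
all_assignments <- function(vars, max_vars = 20L) {
  k <- length(vars)
  if (k > max_vars)
    stop("refusing to enumerate 2^", k, " assignments (cap ", max_vars, " variables)", call. = FALSE)
  if (k == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  m <- as.matrix(expand.grid(rep(list(c(0L, 1L)), k))[, k:1, drop = FALSE])
  colnames(m) <- vars
  m
}

# Extensional equality of two guards over the union of their variables.
guards_equivalent <- function(a, b) {
  a <- as_guard(a); b <- as_guard(b)
  vars <- union(guard_vars(a), guard_vars(b))
  assigns <- all_assignments(vars)
  for (i in seq_len(nrow(assigns))) {
    cfg <- assigns[i, , drop = TRUE]
    names(cfg) <- vars
    if (eval_guard(a, cfg) != eval_guard(b, cfg)) return(FALSE)
  }
  TRUE
}
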