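# The motif catalogue: builders over the canonical names X, S_X, Y, S_Y, Z.
#
# Conventions shared by every builder: genes are X, Y, Z; S_X and S_Y are the
# signals mediating X's and Y's regulatory action; X and all signals are
# independent. Where a signal mediates, the active form of a regulator is the
# conjunction gene & signal (X & S_X); repression negates that conjunction.
# All shipped motifs are presence-mediated; absence-mediated variants can be
# assembled generically with component()/make_model() by negating the signal
# literal.

sig <- function(name) component(name, kind = "signal")

#' Simple regulation motifs (s1--s4)
#'
#' One gene X regulating a gene Y, the interaction mediated by a signal S_X.
#' Four variants arise from the polarity of the regulation
#' (activation/repression) crossed with the mediating mode of the signal
#' (presence/absence):
#'
#' * `s1` (coherent): activation of Y in presence of S_X — `next(Y) = X & S_X`
#' * `s2` (coherent): repression of Y in absence of S_X — `next(Y) = !(X & !S_X)`
#' * `s3` (incoherent): repression of Y in presence of S_X — `next(Y) = !(X & S_X)`
#' * `s4` (incoherent): activation of Y in absence of S_X — `next(Y) = X & !S_X`
#'
#' The four next-state tables over (X, S_X) are pairwise distinct, so the
#' four motifs map to four distinguishable models. The s2/s4 formulas are
#' inferred from the motif definitions (the signal stays the mediator of X's
#' action); they are the unique reading consistent with s1/s3.
#'
#' @param variant one of `"s1"`, `"s2"`, `"s3"`, `"s4"`.
#' @return a validated `"motif_model"` with components X, S_X, Y.
#' @examples
#' build_simple_regulation("s1")
#' @export
build_simple_regulation <- function(variant = c("s1", "s2", "s3", "s4")) {
  variant <- match.arg(variant)
  f <- switch(variant,
    s1 = ~ X & S_X,
    s2 = ~ !(X & !S_X),
    s3 = ~ !(X & S_X),
    s4 = ~ X & !S_X)
  desc <- switch(variant,
    s1 = "coherent simple regulation: activation of Y in presence of S_X",
    s2 = "coherent simple regulation: repression of Y in absence of S_X",
    s3 = "incoherent simple regulation: repression of Y in presence of S_X",
    s4 = "incoherent simple regulation: activation of Y in absence of S_X")
  make_model(
    list(component("X"), sig("S_X"),
         component("Y", rule = rule_from_next_state(f))),
    name = paste0("simple-regulation-", variant), description = desc)
}

#' Feedback loop motifs
#'
#' Two genes X and Y regulating each other, each interaction mediated by a
#' signal (S_X for X acting on Y, S_Y for Y acting on X). Both X and Y are
#' regulated — the concurrent-component representation is what makes this
#' reciprocal regulation expressible at all.
#'
#' * `double_positive`: mutual activation —
#'   `next(X) = Y & S_Y`, `next(Y) = X & S_X`. Exhibits joint bistability:
#'   (off, off) and (on, on) are the steady states.
#' * `double_negative`: mutual repression —
#'   `next(X) = !(Y & S_Y)`, `next(Y) = !(X & S_X)`. Exhibits exclusive
#'   bistability: (on, off) and (off, on) are the steady states.
#' * `negative`: X represses Y, Y activates X —
#'   `next(X) = Y & S_Y`, `next(Y) = !(X & S_X)`. Oscillates.
#'
#' @param variant one of `"double_positive"`, `"double_negative"`, `"negative"`.
#' @return a validated `"motif_model"` with components X, S_X, Y, S_Y.
#' @examples
#' build_feedback("negative")
#' @export
build_feedback <- function(variant = c("double_positive", "double_negative", "negative")) {
  variant <- match.arg(variant)
  fx <- switch(variant,
    double_positive = ~ Y & S_Y,
    double_negative = ~ !(Y & S_Y),
    negative        = ~ Y & S_Y)
  fy <- switch(variant,
    double_positive = ~ X & S_X,
    double_negative = ~ !(X & S_X),
    negative        = ~ !(X & S_X))
  desc <- switch(variant,
    double_positive = "feedback loop: X and Y activate each other (joint bistability)",
    double_negative = "feedback loop: X and Y repress each other (exclusive bistability)",
    negative        = "feedback loop: X represses Y, Y activates X (oscillatory)")
  make_model(
    list(component("X", rule = rule_from_next_state(fx)), sig("S_X"),
         component("Y", rule = rule_from_next_state(fy)), sig("S_Y")),
    name = paste0("feedback-", sub("_", "-", variant)), description = desc)
}

#' Feedforward loop motifs (c1, i1)
#'
#' Three genes X, Y, Z: X regulates Y and Z, Y regulates Z. Each regulator's
#' active form is gene AND signal (`X & S_X`, `Y & S_Y`), and the two input
#' branches on Z are combined by `gate`:
#'
#' * `c1` (coherent type-1, all activations):
#'   `next(Y) = X & S_X`; `next(Z) = (X & S_X) <gate> (Y & S_Y)`.
#'   With the AND gate this reproduces the sign-sensitive delay: Z turns on
#'   one step after Y (delayed activation) but turns off immediately when X
#'   disappears.
#' * `i1` (incoherent type-1, Y represses Z):
#'   `next(Y) = X & S_X`; `next(Z) = (X & S_X) <gate> !(Y & S_Y)`.
#'   With the AND gate, switching X on yields a unit-time pulse of Z.
#'
#' @param variant `"c1"` or `"i1"`.
#' @param gate `"AND"` or `"OR"` — how Z's two input branches are combined.
#' @return a validated `"motif_model"` with components X, S_X, Y, S_Y, Z.
#' @examples
#' build_ffl("c1", gate = "AND")
#' @export
build_ffl <- function(variant = c("c1", "i1"), gate = c("AND", "OR")) {
  variant <- match.arg(variant)
  gate <- match.arg(gate)
  x_branch <- quote(X & S_X)
  y_branch <- switch(variant, c1 = quote(Y & S_Y), i1 = quote(!(Y & S_Y)))
  op <- switch(gate, AND = as.name("&"), OR = as.name("|"))
  fz <- as.call(list(op, call("(", x_branch), call("(", y_branch)))
  desc <- paste0(
    switch(variant,
      c1 = "coherent type-1 feedforward loop (sign-sensitive delay)",
      i1 = "incoherent type-1 feedforward loop (pulse generator)"),
    ", ", gate, " gate on Z")
  make_model(
    list(component("X"), sig("S_X"),
         component("Y", rule = rule_from_next_state(~ X & S_X)), sig("S_Y"),
         component("Z", rule = rule_from_next_state(as_guard(fz)))),
    name = paste0("ffl-", variant, "-", tolower(gate)), description = desc)
}

#' Autoregulation motifs
#'
#' A gene Y regulating itself: positive (`next(Y) = Y`, the "lock-in"
#' state-holding rule) or negative (`next(Y) = !Y`, alternating). With
#' `with_activator = TRUE`, Y is additionally regulated by the AND
#' combination of itself and an independent activating gene X:
#' `next(Y) = X & Y` (positive) or `next(Y) = X & !Y` (negative). When X is
#' held on, the Y-dynamics of the with-activator models coincide with the
#' plain ones. With `with_signals = TRUE` the activator's action is mediated
#' by a signal S_X (`X & S_X` replaces `X`); this gating is off by default
#' as the plain activator form is the canonical one.
#'
#' Positive autoregulation differs from every simple-regulation model —
#' self-regulation and external regulation stay distinguishable in the
#' logical domain.
#'
#' @param sign `"positive"` or `"negative"`.
#' @param with_activator add the independent activating gene X.
#' @param with_signals (only with activator) mediate X's action by signal S_X.
#' @return a validated `"motif_model"` with components Y, or X (S_X) and Y.
#' @examples
#' build_autoregulation("negative")
#' build_autoregulation("positive", with_activator = TRUE)
#' @export
build_autoregulation <- function(sign = c("positive", "negative"),
                                 with_activator = FALSE, with_signals = FALSE) {
  sign <- match.arg(sign)
  if (with_signals && !with_activator)
    stop("'with_signals' only applies when 'with_activator' is TRUE", call. = FALSE)
  self <- switch(sign, positive = quote(Y), negative = quote(!Y))
  if (!with_activator) {
    f <- as_guard(self)
    comps <- list(component("Y", rule = rule_from_next_state(f)))
  } else {
    act <- if (with_signals) quote(X & S_X) else quote(X)
    f <- as_guard(as.call(list(as.name("&"), call("(", act), call("(", self))))
    comps <- c(list(component("X")),
               if (with_signals) list(sig("S_X")),
               list(component("Y", rule = rule_from_next_state(f))))
  }
  make_model(
    comps,
    name = paste0("autoreg-", substr(sign, 1L, 3L),
                  if (with_activator) "-act" else "",
                  if (with_signals) "-sig" else ""),
    description = paste0(sign, " autoregulation",
                         if (with_activator) " with activating gene X" else ""))
}

# Registry used by the CLI and by whole-catalogue tests.
shipped_motifs <- function() {
  list(
    s1 = function() build_simple_regulation("s1"),
    s2 = function() build_simple_regulation("s2"),
    s3 = function() build_simple_regulation("s3"),
    s4 = function() build_simple_regulation("s4"),
    `feedback-dp` = function() build_feedback("double_positive"),
    `feedback-dn` = function() build_feedback("double_negative"),
    `feedback-neg` = function() build_feedback("negative"),
    `ffl-c1` = function(gate = "AND") build_ffl("c1", gate),
    `ffl-i1` = function(gate = "AND") build_ffl("i1", gate),
    `autoreg-pos` = function(with_activator = FALSE) build_autoregulation("positive", with_activator),
    `autoreg-neg` = function(with_activator = FALSE) build_autoregulation("negative", with_activator))
}
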