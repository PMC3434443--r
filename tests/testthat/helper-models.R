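# Shared test plumbing: exhaustive next-state tables and a seeded generator
# of random valid models for round-trip / property tests.

# All 2^n configurations of a model, one per row, columns in model order.
all_configs <- function(model) {
  nms <- component_names(model)
  k <- length(nms)
  m <- as.matrix(expand.grid(rep(list(c(0L, 1L)), k))[, k:1, drop = FALSE])
  colnames(m) <- nms
  m
}

# The full synchronous next-state table: row i is step(config i).
next_state_table <- function(model) {
  cfgs <- all_configs(model)
  t(apply(cfgs, 1L, function(row) step_state(model, row)))
}

# The next-state function of one component as a 0/1 vector over all
# configurations of `over` (model-independent signature comparison).
component_function <- function(model, comp, over = component_names(model)) {
  k <- length(over)
  cfgs <- as.matrix(expand.grid(rep(list(c(0L, 1L)), k))[, k:1, drop = FALSE])
  colnames(cfgs) <- over
  full <- component_names(model)
  apply(cfgs, 1L, function(row) {
    cfg <- setNames(integer(length(full)), full)
    cfg[intersect(over, full)] <- row[intersect(over, full)]
    step_state(model, cfg)[[comp]]
  })
}

# Random boolean formula text over `vars` (depth-bounded; may collapse to a
# literal or constant).
random_formula_text <- function(vars, depth = 3L) {
  if (depth == 0L || runif(1) < 0.35) {
    if (runif(1) < 0.08) return(sample(c("TRUE", "FALSE"), 1L))
    v <- sample(vars, 1L)
    return(if (runif(1) < 0.4) paste0("!", v) else v)
  }
  op <- sample(c("&", "|", "!"), 1L, prob = c(0.4, 0.4, 0.2))
  if (op == "!") paste0("!(", random_formula_text(vars, depth - 1L), ")")
  else paste0("(", random_formula_text(vars, depth - 1L), " ", op, " ",
              random_formula_text(vars, depth - 1L), ")")
}

# A random valid model: each component independent with prob p_indep, else
# regulated by a random next-state formula over all component names.
random_motif_model <- function(n_components = 4L, p_indep = 0.3, name = "random") {
  nms <- LETTERS[seq_len(n_components)]
  comps <- lapply(nms, function(nm) {
    if (runif(1) < p_indep) component(nm)
    else component(nm, rule = rule_from_next_state(random_formula_text(nms)))
  })
  # ensure at least one regulated component so the model is non-trivial
  if (all(vapply(comps, function(c) is.null(c$rule), logical(1L))))
    comps[[1L]] <- component(nms[1L], rule = rule_from_next_state(random_formula_text(nms)))
  make_model(comps, name = name)
}

# Every shipped motif, instantiated (FFLs in both gates).
catalogue_models <- function() {
  list(
    build_simple_regulation("s1"), build_simple_regulation("s2"),
    build_simple_regulation("s3"), build_simple_regulation("s4"),
    build_feedback("double_positive"), build_feedback("double_negative"),
    build_feedback("negative"),
    build_ffl("c1", "AND"), build_ffl("c1", "OR"),
    build_ffl("i1", "AND"), build_ffl("i1", "OR"),
    build_autoregulation("positive"), build_autoregulation("negative"),
    build_autoregulation("positive", with_activator = TRUE),
    build_autoregulation("negative", with_activator = TRUE))
}

signals_on <- function(model) {
  s <- grep("^S_", component_names(model), value = TRUE)
  setNames(rep(1L, length(s)), s)
}
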