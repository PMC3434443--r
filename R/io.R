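# Serialization: BoolNet-style rule files (read/write), Graphviz DOT and
# SCXML statechart exports (write-only), and trace CSV.
#
# The .bnet dialect: a `targets, factors` header, then one line per
# component `<name>, <next-state formula>` using `&`, `|`, `!` and
# parentheses. The dialect has no native notion of an exogenous input, so an
# independent component is serialized as the self-hold rule `<name>, <name>`
# preceded by an `# independent: <name>` comment; signals carry a
# `# signal: <name>` comment so the component kind survives a round-trip.

#' Serialize a model to BoolNet-style text
#'
#' @param model a validated `"motif_model"`.
#' @param path optional file path; if `NULL` the text is returned.
#' @return the text (single string, LF line endings), invisibly when written
#'   to a file.
#' @examples
#' cat(write_bnet(build_simple_regulation("s1")))
#' @export
write_bnet <- function(model, path = NULL) {
  stopifnot(inherits(model, "motif_model"))
  lines <- c(paste0("# model: ", model$name), "targets, factors")
  for (comp in model$components) {
    if (identical(comp$kind, "signal"))
      lines <- c(lines, paste0("# signal: ", comp$name))
    if (is_independent(comp)) {
      lines <- c(lines, paste0("# independent: ", comp$name),
                 paste0(comp$name, ", ", comp$name))
    } else {
      lines <- c(lines, paste0(comp$name, ", ", deparse_guard(comp$rule$on_guard)))
    }
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}

#' Read a model from BoolNet-style text
#'
#' Parses the dialect written by [write_bnet()]. Components marked
#' `# independent:` become independent; every other component's formula is
#' taken as its next-state function via [rule_from_next_state()]. The result
#' passes full [make_model()] validation.
#'
#' @param x a file path, or a character vector of lines (length > 1), or the
#'   full text as a single string containing newlines.
#' @return a validated `"motif_model"`.
#' @export
read_bnet <- function(x) {
  lines <-
    if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) readLines(x, warn = FALSE)
    else if (length(x) == 1L) strsplit(x, "\n", fixed = TRUE)[[1L]]
    else as.character(x)

  model_name <- "bnet model"
  independents <- character(0)
  signals <- character(0)
  rules <- list()   # ordered: name -> guard text
  header_seen <- FALSE
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (startsWith(line, "#")) {
      body <- trimws(sub("^#", "", line))
      if (grepl("^independent:", body)) independents <- c(independents, trimws(sub("^independent:", "", body)))
      else if (grepl("^signal:", body)) signals <- c(signals, trimws(sub("^signal:", "", body)))
      else if (grepl("^model:", body)) model_name <- trimws(sub("^model:", "", body))
      next
    }
    if (!header_seen && grepl("^targets\\s*,\\s*factors$", line, ignore.case = TRUE)) {
      header_seen <- TRUE
      next
    }
    m <- regexpr(",", line, fixed = TRUE)
    if (m < 0L)
      stop("parse error at line ", i, ": expected '<name>, <formula>', got ",
           sQuote(lines[i]), call. = FALSE)
    nm <- trimws(substr(line, 1L, m - 1L))
    formula_txt <- trimws(substr(line, m + 1L, nchar(line)))
    if (!is_component_name(nm))
      stop("parse error at line ", i, ": invalid component name ", sQuote(nm), call. = FALSE)
    if (!nzchar(formula_txt))
      stop("parse error at line ", i, ": empty formula for ", sQuote(nm), call. = FALSE)
    if (nm %in% names(rules))
      stop("parse error at line ", i, ": duplicate rule for ", sQuote(nm), call. = FALSE)
    rules[[nm]] <- formula_txt
  }
  if (!length(rules)) stop("no component rules found", call. = FALSE)

  comps <- lapply(names(rules), function(nm) {
    kind <- if (nm %in% signals) "signal" else "gene"
    if (nm %in% independents) component(nm, kind = kind)
    else component(nm, kind = kind, rule = rule_from_next_state(as_guard(rules[[nm]])))
  })
  make_model(comps, name = model_name)
}

#' Export a model as a statechart drawing or interchange document
#'
#' DOT: one cluster per component with the two presence states `<name>=0`
#' and `<name>=1` and, for regulated components, two directed edges labeled
#' with the transition guards (independent components have no edges — the
#' marker for an externally driven element). Render with Graphviz, e.g.
#' `dot -Tpdf model.dot`.
#'
#' SCXML: one `<parallel>` root region containing a two-state machine per
#' component, transitions carrying the guard formula in the `cond`
#' attribute.
#'
#' @param model a validated `"motif_model"`.
#' @param format `"dot"` or `"scxml"`.
#' @param path optional file path; if `NULL` the text is returned.
#' @return the document text, invisibly when written to a file.
#' @examples
#' cat(export_statechart(build_simple_regulation("s1"), "dot"))
#' @export
export_statechart <- function(model, format = c("dot", "scxml"), path = NULL) {
  stopifnot(inherits(model, "motif_model"))
  format <- match.arg(format)
  txt <- switch(format, dot = statechart_dot(model), scxml = statechart_scxml(model))
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}

statechart_dot <- function(model) {
  esc <- function(s) gsub('"', '\\\\"', s)
  lines <- c(paste0("digraph \"", esc(model$name), "\" {"),
             "  rankdir=LR;", "  node [shape=box, style=rounded];")
  i <- 0L
  for (comp in model$components) {
    i <- i + 1L
    nm <- comp$name
    lines <- c(lines,
      paste0("  subgraph cluster_", i, " {"),
      paste0("    label=\"", esc(nm), " [", comp$kind, "]\";"),
      paste0("    \"", nm, "=0\"; \"", nm, "=1\";"))
    if (!is_independent(comp)) {
      lines <- c(lines,
        paste0("    \"", nm, "=0\" -> \"", nm, "=1\" [label=\"",
               esc(deparse_guard(comp$rule$on_guard)), "\"];"),
        paste0("    \"", nm, "=1\" -> \"", nm, "=0\" [label=\"",
               esc(deparse_guard(comp$rule$off_guard)), "\"];"))
    }
    lines <- c(lines, "  }")
  }
  paste0(paste(c(lines, "}"), collapse = "\n"), "\n")
}

statechart_scxml <- function(model) {
  doc <- xml2::xml_new_root("scxml",
    xmlns = "http://www.w3.org/2005/07/scxml", version = "1.0",
    name = model$name, initial = "motif")
  par <- xml2::xml_add_child(doc, "parallel", id = "motif")
  for (comp in model$components) {
    machine <- xml2::xml_add_child(par, "state",
                                   id = comp$name, initial = paste0(comp$name, "_off"))
    off <- xml2::xml_add_child(machine, "state", id = paste0(comp$name, "_off"))
    on <- xml2::xml_add_child(machine, "state", id = paste0(comp$name, "_on"))
    if (!is_independent(comp)) {
      xml2::xml_add_child(off, "transition",
                          cond = deparse_guard(comp$rule$on_guard),
                          target = paste0(comp$name, "_on"))
      xml2::xml_add_child(on, "transition",
                          cond = deparse_guard(comp$rule$off_guard),
                          target = paste0(comp$name, "_off"))
    }
  }
  as.character(doc)
}

#' Write / read a trace as CSV
#'
#' The CSV has a `# model:` comment line, then a header `t,<components in
#' model order>` and one row of 0/1 values per instant.
#'
#' @param trace a `"motif_trace"`.
#' @param path file path.
#' @return `write_trace_csv` returns `trace` invisibly; `read_trace_csv`
#'   returns the reconstructed `"motif_trace"`.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "motif_trace"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# model: ", attr(trace, "model_name")), con)
  utils::write.csv(as.data.frame(trace), con, row.names = FALSE, quote = FALSE)
  invisible(trace)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  first <- readLines(path, n = 1L)
  model_name <- if (grepl("^# model:", first)) trimws(sub("^# model:", "", first)) else NA_character_
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (names(df)[1L] != "t") stop("trace CSV must start with a 't' column", call. = FALSE)
  comps <- names(df)[-1L]
  df[] <- lapply(df, as.integer)
  attr(df, "model_name") <- model_name
  attr(df, "components") <- comps
  class(df) <- c("motif_trace", "data.frame")
  df
}
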