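test_that("simple regulation variants implement their defining next-state functions", {
  # variant -> expected next(Y) over (X, S_X)
  expected <- list(
    s1 = function(x, s) x & s,          # activation in presence of S_X
    s2 = function(x, s) !(x & !s),      # repression in absence of S_X
    s3 = function(x, s) !(x & s),       # repression in presence of S_X
    s4 = function(x, s) x & !s)         # activation in absence of S_X
  for (v in names(expected)) {
    m <- build_simple_regulation(v)
    expect_identical(component_names(m), c("X", "S_X", "Y"))
    for (x in 0:1) for (s in 0:1) for (y in 0:1) {
      nxt <- step_state(m, c(X = x, S_X = s, Y = y))
      expect_identical(nxt[["Y"]], as.integer(expected[[v]](x, s)),
                       info = sprintf("%s at X=%d,S_X=%d,Y=%d", v, x, s, y))
      # X and S_X are independent: unchanged by the step
      expect_identical(nxt[c("X", "S_X")], c(X = x, S_X = s))
    }
  }
  expect_error(build_simple_regulation("s5"))
})

test_that("the four simple-regulation next-state tables are pairwise distinct", {
  tabs <- lapply(c("s1", "s2", "s3", "s4"), function(v)
    component_function(build_simple_regulation(v), "Y", over = c("X", "S_X")))
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(identical(tabs[[i]], tabs[[j]]),
                 info = sprintf("s%d vs s%d", i, j))
})

test_that("feedback builders regulate both X and Y with the stated functions", {
  on <- c(S_X = 1, S_Y = 1)
  dp <- build_feedback("double_positive")
  expect_identical(step_state(dp, c(X = 1, Y = 1, on))[c("X", "Y")], c(X = 1L, Y = 1L))
  expect_identical(step_state(dp, c(X = 0, Y = 0, on))[c("X", "Y")], c(X = 0L, Y = 0L))
  dn <- build_feedback("double_negative")
  expect_identical(step_state(dn, c(X = 1, Y = 0, on))[c("X", "Y")], c(X = 1L, Y = 0L))
  expect_identical(step_state(dn, c(X = 0, Y = 1, on))[c("X", "Y")], c(X = 0L, Y = 1L))
  neg <- build_feedback("negative")
  expect_identical(step_state(neg, c(X = 1, Y = 1, on))[c("X", "Y")], c(X = 1L, Y = 0L))
  # with its signal absent a regulator cannot act
  expect_identical(step_state(dp, c(X = 1, Y = 1, S_X = 0, S_Y = 1))[["Y"]], 0L)
})

test_that("feedforward loops follow the paper-catalogue gate structure", {
  on <- c(S_X = 1, S_Y = 1)
  c1 <- build_ffl("c1", "AND")
  expect_identical(component_names(c1), c("X", "S_X", "Y", "S_Y", "Z"))
  expect_identical(step_state(c1, c(X = 1, Y = 0, Z = 0, on))[c("Y", "Z")], c(Y = 1L, Z = 0L))
  expect_identical(step_state(c1, c(X = 1, Y = 1, Z = 0, on))[c("Y", "Z")], c(Y = 1L, Z = 1L))
  i1 <- build_ffl("i1", "AND")
  expect_identical(step_state(i1, c(X = 1, Y = 0, Z = 0, on))[c("Y", "Z")], c(Y = 1L, Z = 1L))
  expect_identical(step_state(i1, c(X = 1, Y = 1, Z = 1, on))[c("Y", "Z")], c(Y = 1L, Z = 0L))
  # OR gate: either active branch suffices on Z
  c1or <- build_ffl("c1", "OR")
  expect_identical(step_state(c1or, c(X = 1, Y = 0, Z = 0, on))[["Z"]], 1L)
  expect_identical(step_state(c1or, c(X = 0, Y = 1, Z = 0, on))[["Z"]], 1L)
  expect_identical(step_state(c1or, c(X = 0, Y = 0, Z = 1, on))[["Z"]], 0L)
})

test_that("c1/AND is monotone in every input and i1/AND antitone in Y", {
  on <- c(S_X = 1, S_Y = 1)
  c1 <- build_ffl("c1", "AND")
  genes <- expand.grid(X = 0:1, Y = 0:1, Z = 0:1)
  leq <- function(a, b) all(a <= b)
  for (i in seq_len(nrow(genes))) for (j in seq_len(nrow(genes))) {
    a <- unlist(genes[i, ]); b <- unlist(genes[j, ])
    if (leq(a, b)) {
      sa <- step_state(c1, c(a, on)); sb <- step_state(c1, c(b, on))
      expect_true(leq(sa, sb), info = paste(i, j))
    }
  }
  i1 <- build_ffl("i1", "AND")
  for (x in 0:1) for (z in 0:1) {
    z0 <- step_state(i1, c(X = x, Y = 0, Z = z, on))[["Z"]]
    z1 <- step_state(i1, c(X = x, Y = 1, Z = z, on))[["Z"]]
    expect_true(z1 <= z0)
  }
})

test_that("autoregulation locks in (positive) or alternates (negative)", {
  pos <- build_autoregulation("positive")
  expect_identical(step_state(pos, c(Y = 1))[["Y"]], 1L)
  expect_identical(step_state(pos, c(Y = 0))[["Y"]], 0L)
  neg <- build_autoregulation("negative")
  y <- 0L
  seen <- integer(0)
  for (k in 1:4) { y <- step_state(neg, c(Y = y))[["Y"]]; seen <- c(seen, y) }
  expect_identical(seen, c(1L, 0L, 1L, 0L))
})

test_that("with the activator held on, autoregulation dynamics match the plain motifs", {
  for (sign in c("positive", "negative")) {
    plain <- build_autoregulation(sign)
    act <- build_autoregulation(sign, with_activator = TRUE)
    expect_identical(component_names(act), c("X", "Y"))
    for (y in 0:1)
      expect_identical(step_state(act, c(X = 1, Y = y))[["Y"]],
                       step_state(plain, c(Y = y))[["Y"]])
    # with X off, Y is driven (and stays) off
    expect_identical(step_state(act, c(X = 0, Y = 1))[["Y"]], 0L)
  }
  # signal-gated form: S_X absent blocks the activator
  sg <- build_autoregulation("positive", with_activator = TRUE, with_signals = TRUE)
  expect_identical(component_names(sg), c("X", "S_X", "Y"))
  expect_identical(step_state(sg, c(X = 1, S_X = 0, Y = 1))[["Y"]], 0L)
  expect_error(build_autoregulation("positive", with_signals = TRUE), "with_activator")
})

test_that("every catalogue motif passes full validation and they are pairwise distinguishable", {
  models <- catalogue_models()
  for (m in models)
    expect_s3_class(make_model(m$components, m$name), "motif_model")
  # distinctness: the (component set, full next-state table) signature is
  # unique across the catalogue
  sigs <- vapply(models, function(m)
    paste(paste(component_names(m), collapse = ","),
          paste(next_state_table(m), collapse = ""), sep = "|"),
    character(1L))
  expect_identical(anyDuplicated(sigs), 0L)
  # autoregulation is distinguishable from every simple-regulation model:
  # next(Y) as a function of (X, S_X, Y) differs
  for (v in c("s1", "s2", "s3", "s4")) {
    fy_simple <- component_function(build_simple_regulation(v), "Y",
                                    over = c("X", "S_X", "Y"))
    for (sign in c("positive", "negative")) {
      fy_auto <- component_function(build_autoregulation(sign, with_activator = TRUE),
                                    "Y", over = c("X", "S_X", "Y"))
      expect_false(identical(fy_simple, fy_auto), info = paste(v, sign))
    }
  }
})
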