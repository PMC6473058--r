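# small deterministic synthetic lead field for solver-level tests
toy_leadfield <- function(n_regions = 29, n_stim = 2, seed = 7) {
  set.seed(seed)
  regions <- c(paste0("R", seq_len(n_regions - 1L)), "NonCerebellarBrain")
  ids <- sprintf("E%02d", seq_len(n_stim))
  mk <- function(s) matrix(rnorm(n_regions * n_stim, sd = s), n_regions,
                           dimnames = list(regions, ids))
  structure(list(LF = list(X = mk(1), Y = mk(0.5), Z = mk(2)),
                 regions = regions,
                 electrodes = data.frame(id = c(ids, "Cz"),
                                         role = c(rep("stim", n_stim),
                                                  "reference")),
                 reference_id = "Cz",
                 provenance = list()), class = "lead_field")
}

toy_target <- function(lf, b, direction = "X", cap = 4) {
  tg <- uniform_target(lf, lf$regions[1], direction = direction,
                       magnitude = 0, total_cap_mA = cap)
  tg$b[] <- b
  tg$weights[] <- 1
  tg
}

test_that("target construction places fields only on the target rows", {
  lf <- toy_leadfield()
  tg <- uniform_target(lf, c("R3", "R5"), direction = "Z", magnitude = 0.4,
                       spillover_weight = 0.5)
  expect_equal(sort(names(which(tg$b != 0))), c("R3", "R5"))
  expect_equal(unname(tg$b[c("R3", "R5")]), c(0.4, 0.4))
  expect_equal(unname(tg$weights[c("R3", "R4")]), c(1, 0.5))
  expect_error(uniform_target(lf, "NotARegion", "Z", 0.1), "unknown region")
  expect_error(uniform_target(lf, "R3", "Z", 0.1, total_cap_mA = 0),
               "cap")
})

test_that("zero and composed-zero targets give zero currents", {
  lf <- toy_leadfield()
  ms <- optimize_montage(lf, toy_target(lf, 0))
  expect_equal(unname(ms$x), rep(0, 3), tolerance = 1e-12)
  expect_equal(ms$residual, 0, tolerance = 1e-12)
  ms2 <- optimize_montage(lf, uniform_target(lf, "R2", "Y", magnitude = 0))
  expect_equal(unname(ms2$x), rep(0, 3), tolerance = 1e-12)
})

test_that("a feasible planted target is recovered exactly", {
  lf <- small_leadfield()
  ids <- colnames(lf$LF$X)
  x0 <- setNames(c(0.6, -0.2, 0.4, 0, 0), ids)
  x0 <- c(x0, Cz = -sum(x0))
  b0 <- predict_fields(lf, x0)
  tg <- uniform_target(lf, lf$regions[1], "Z", 0)
  tg$b[] <- b0[, "Z"]; tg$weights[] <- 1
  ms <- optimize_montage(lf, tg)
  expect_lt(ms$residual, 1e-6)
  expect_lt(max(abs(predict_fields(lf, ms$x)[, "Z"] - b0[, "Z"])), 1e-6)
  expect_false(ms$constraints$cap_active)
})

test_that("safety constraints hold when the target is unattainable", {
  lf <- toy_leadfield()
  set.seed(8)
  tg <- toy_target(lf, rnorm(29) * 50) # far out of reach: cap must bind
  ms <- optimize_montage(lf, tg)
  expect_lt(abs(ms$constraints$net_current_mA), 1e-9)
  expect_lte(ms$constraints$total_abs_mA, 4 + 1e-9)
  expect_lte(ms$constraints$total_anodal_mA, 2 + 1e-9)
  expect_true(ms$constraints$cap_active)
})

test_that("solver matches a brute-force search on a 3-electrode lead field", {
  lf <- toy_leadfield(n_stim = 2)
  set.seed(9)
  b <- rnorm(29) * 2
  tg <- toy_target(lf, b)
  ms <- optimize_montage(lf, tg)
  A <- lf$LF$X
  gr <- seq(-2, 2, by = 0.004)
  best <- Inf
  for (x1 in gr) {
    ok <- abs(x1) + abs(gr) + abs(x1 + gr) <= 4 + 1e-12
    if (!any(ok)) next
    x2 <- gr[ok]
    obj <- colSums((outer(A[, 1], rep(1, length(x2))) * x1 +
                      outer(A[, 2], x2) - b)^2)
    best <- min(best, min(obj))
  }
  expect_lt(ms$residual^2, best + 1e-4)
  expect_gt(ms$residual^2, best - 1)
})

test_that("the feasible set is convex and the residual is monotone in the cap", {
  lf <- toy_leadfield(n_stim = 4)
  set.seed(10)
  b <- rnorm(29) * 3
  obj <- function(x) sum((lf$LF$X %*% x - b)^2)
  res <- vapply(c(2, 4, 8, 16), function(cap) {
    optimize_montage(lf, toy_target(lf, b, cap = cap))$residual
  }, 0)
  expect_true(all(diff(res) <= 1e-8))
  # convexity along the segment between two feasible points
  ms4 <- optimize_montage(lf, toy_target(lf, b, cap = 4))
  ms2 <- optimize_montage(lf, toy_target(lf, b, cap = 2))
  xa <- ms4$x[colnames(lf$LF$X)]; xb <- ms2$x[colnames(lf$LF$X)]
  mid <- obj((xa + xb) / 2)
  expect_lte(mid, (obj(xa) + obj(xb)) / 2 + 1e-9)
})

test_that("zero-weight spillover rows do not influence the solution", {
  lf <- toy_leadfield(n_stim = 3)
  tg1 <- uniform_target(lf, c("R1", "R2"), "X", 0.5, spillover_weight = 0)
  tg2 <- tg1
  tg2$b[c("R10", "R20")] <- 99 # changing ignored rows
  m1 <- optimize_montage(lf, tg1)
  m2 <- optimize_montage(lf, tg2)
  expect_equal(m1$x, m2$x, tolerance = 1e-10)
})

test_that("per-direction and stacked modes agree on a single direction", {
  lf <- small_leadfield()
  tg <- uniform_target(lf, grep("^Right_", lf$regions, value = TRUE)[6:9],
                       "Z", 0.3)
  m1 <- optimize_montage(lf, tg)
  m2 <- optimize_montage(lf, list(tg), stacked = TRUE)
  expect_equal(m1$x, m2$x, tolerance = 1e-8)
})
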