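test_that("constant responses give zero eta-squared for every term", {
  tab <- balanced_anova_table(
    array(5, dim = c(2, 2), dimnames = list(A = c("a1", "a2"),
                                            B = c("b1", "b2"))),
    n_per_cell = 4)
  names(tab)[1:2] <- c("A", "B")
  an <- anova_eta(tab, "y", c("A", "B"))
  expect_true(all(an$eta_sq[an$term != "Residuals"] == 0))
})

test_that("a fully determining balanced factor has eta-squared one", {
  tab <- data.frame(g = rep(c("lo", "hi"), each = 10),
                    y = rep(c(0, 1), each = 10))
  an <- anova_eta(tab, "y", "g")
  expect_equal(an$eta_sq[an$term != "Residuals"], 1, tolerance = 1e-12)
  expect_equal(an$sum_sq[an$term == "Residuals"], 0, tolerance = 1e-12)
})

test_that("balanced three-way table matches brute-force sums of squares", {
  # independent oracle: group-mean formulas computed directly
  mu <- array(c(1, 3, 2, 5, 0, 4, 1, 2, 3, 6, 2, 1),
              dim = c(2, 2, 3),
              dimnames = list(A = c("a1", "a2"), B = c("b1", "b2"),
                              C = c("c1", "c2", "c3")))
  tab <- balanced_anova_table(mu, n_per_cell = 5, sd = 0.5, seed = 42)
  names(tab)[1:3] <- c("A", "B", "C")
  an <- anova_eta(tab, "y", c("A", "B", "C"))
  y <- tab$y; n <- nrow(tab); gm <- mean(y)
  ss_main <- function(f) {
    m <- tapply(y, tab[[f]], mean); cnt <- tapply(y, tab[[f]], length)
    sum(cnt * (m - gm)^2)
  }
  ss_int <- function(f1, f2) {
    m12 <- tapply(y, list(tab[[f1]], tab[[f2]]), mean)
    c12 <- tapply(y, list(tab[[f1]], tab[[f2]]), length)
    m1 <- tapply(y, tab[[f1]], mean); m2 <- tapply(y, tab[[f2]], mean)
    sum(c12 * (m12 - outer(m1, rep(1, length(m2))) -
                 outer(rep(1, length(m1)), m2) + gm)^2)
  }
  expected <- c(A = ss_main("A"), B = ss_main("B"), C = ss_main("C"),
                "A:B" = ss_int("A", "B"), "A:C" = ss_int("A", "C"),
                "B:C" = ss_int("B", "C"))
  got <- setNames(an$sum_sq, an$term)[names(expected)]
  expect_equal(unname(got), unname(expected), tolerance = 1e-8)
  ss_total <- sum((y - gm)^2)
  expect_equal(attr(an, "total_ss"), ss_total, tolerance = 1e-12)
  expect_equal(setNames(an$eta_sq, an$term)[names(expected)],
               expected / ss_total, tolerance = 1e-8,
               ignore_attr = TRUE)
  # F statistics against the direct ratio of mean squares
  mse <- an$sum_sq[an$term == "Residuals"] / an$df[an$term == "Residuals"]
  expect_equal(an$F[an$term == "A"], expected["A"] / 1 / mse,
               tolerance = 1e-8, ignore_attr = TRUE)
  # terms + residual tile the total on a balanced design
  expect_equal(sum(an$sum_sq), ss_total, tolerance = 1e-8)
})

test_that("type I and type III coincide on balanced designs", {
  mu <- array(c(1, 4, 2, 2), dim = c(2, 2),
              dimnames = list(A = c("a1", "a2"), B = c("b1", "b2")))
  tab <- balanced_anova_table(mu, n_per_cell = 6, sd = 1, seed = 3)
  names(tab)[1:2] <- c("A", "B")
  a1 <- anova_eta(tab, "y", c("A", "B"), ss_type = 1)
  a3 <- anova_eta(tab, "y", c("A", "B"), ss_type = 3)
  o <- match(a1$term, a3$term)
  expect_equal(a1$sum_sq, a3$sum_sq[o], tolerance = 1e-10)
  expect_equal(a1$eta_sq, a3$eta_sq[o], tolerance = 1e-10)
})

test_that("results are invariant to row order and response rescaling", {
  mu <- array(1:4, dim = c(2, 2),
              dimnames = list(A = c("a1", "a2"), B = c("b1", "b2")))
  tab <- balanced_anova_table(mu, n_per_cell = 5, sd = 1, seed = 4)
  names(tab)[1:2] <- c("A", "B")
  an <- anova_eta(tab, "y", c("A", "B"))
  set.seed(5)
  tab_p <- tab[sample(nrow(tab)), ]
  an_p <- anova_eta(tab_p, "y", c("A", "B"))
  expect_equal(an$sum_sq, an_p$sum_sq, tolerance = 1e-10)
  tab_s <- tab; tab_s$y <- 7 * tab_s$y
  an_s <- anova_eta(tab_s, "y", c("A", "B"))
  expect_equal(an_s$eta_sq, an$eta_sq, tolerance = 1e-10)
  expect_equal(an_s$sum_sq, 49 * an$sum_sq, tolerance = 1e-10)
})

test_that("inestimable designs report their empty cells", {
  tab <- data.frame(A = c("a1", "a1", "a2", "a2"),
                    B = c("b1", "b1", "b1", "b1"),
                    y = rnorm(4))
  expect_error(anova_eta(tab, "y", c("A", "B")), "fewer than 2")
  tab2 <- data.frame(A = c("a1", "a1", "a2", "a2", "a1", "a2"),
                     B = c("b1", "b2", "b1", "b1", "b1", "b1"),
                     y = rnorm(6))
  expect_error(anova_eta(tab2, "y", c("A", "B")), "a2:b2")
})

test_that("Bonferroni post-hoc counts, flags and p-values are correct", {
  set.seed(6)
  k <- 4
  tab <- data.frame(g = rep(paste0("g", 1:k), each = 12),
                    y = rnorm(12 * k))
  ph <- bonferroni_posthoc(tab, "y", "g")
  expect_identical(nrow(ph), as.integer(k * (k - 1) / 2))
  expect_identical(attr(ph, "n_comparisons"), k * (k - 1) / 2)
  # cross-check adjusted p-values against the standard pairwise test
  ref <- stats::pairwise.t.test(tab$y, tab$g, p.adjust.method = "bonferroni",
                                pool.sd = TRUE)
  ref_p <- ref$p.value["g2", "g1"]
  got_p <- ph$p_adj[ph$level_a == "g1" & ph$level_b == "g2"]
  expect_equal(got_p, ref_p, tolerance = 1e-10)
})

test_that("identical groups are not flagged; well-separated groups are", {
  set.seed(7)
  base <- rnorm(50)
  tab_same <- data.frame(g = rep(c("u", "v"), each = 50), y = c(base, base))
  ph_same <- bonferroni_posthoc(tab_same, "y", "g")
  expect_false(ph_same$significant[1])
  expect_true(ph_same$lwr[1] <= 0 && ph_same$upr[1] >= 0)
  # two groups separated by 10 pooled SDs at n = 50: the direct t
  # statistic is sqrt(n/2)*10, far beyond any Bonferroni critical value
  tab_far <- data.frame(g = rep(c("u", "v"), each = 50),
                        y = c(rnorm(50), rnorm(50) + 10))
  ph_far <- bonferroni_posthoc(tab_far, "y", "g")
  expect_true(ph_far$significant[1])
  expect_lt(ph_far$p_adj[1], 1e-10)
  expect_error(bonferroni_posthoc(tab_far[tab_far$g == "u", ], "y", "g"),
               "2 factor levels")
})

test_that("voxel observation tables expose lobule factors with finite fields", {
  m <- small_mesh(); parc <- small_parc()
  sol <- solve_potential(m, make_montage_preset("celnik", m))
  fv <- rasterize_field(sol, small_grid())
  obs <- field_observations(fv, parc, montage = "celnik")
  expect_identical(nlevels(obs$lobule), 28L)
  expect_true(all(is.finite(obs$Enorm)))
  expect_identical(nrow(obs), sum(region_voxel_counts(parc)[1:28]))
  expect_true(all(obs$Enorm + 1e-15 >= abs(obs$Ex)))
})
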