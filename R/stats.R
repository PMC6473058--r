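#' Voxel-wise field observation table
#'
#' Builds the long-format observation table for the ANOVA layer: one
#' row per valid cerebellar voxel, with the field components and
#' magnitude as responses and the lobule (plus caller-supplied montage
#' and head-model identifiers) as factors.
#'
#' @param field A `field_volume`.
#' @param parc A `parcellation_volume` on the same grid.
#' @param montage Montage label for these observations.
#' @param head_model Head-model label.
#' @param lobules_only Keep only lobule voxels (default), or include
#'   the non-cerebellar brain mask as its own level.
#' @return Data frame with columns `Ex`, `Ey`, `Ez`, `Enorm` (V/m),
#'   `lobule`, `montage`, `head_model` (factors).
#' @export
field_observations <- function(field, parc, montage = "montage",
                               head_model = "phantom",
                               lobules_only = TRUE) {
  stopifnot(inherits(field, "field_volume"),
            inherits(parc, "parcellation_volume"))
  if (!same_grid(field, parc)) stop("field and parcellation grids differ")
  lab <- as.integer(parc$labels)
  keep_ids <- if (lobules_only) parc$lobule_ids else
    c(parc$lobule_ids, parc$brain_mask_id)
  valid <- as.logical(field$mask) & lab %in% keep_ids
  ex <- as.numeric(field$Ex)[valid]
  ey <- as.numeric(field$Ey)[valid]
  ez <- as.numeric(field$Ez)[valid]
  data.frame(
    Ex = ex, Ey = ey, Ez = ez, Enorm = sqrt(ex^2 + ey^2 + ez^2),
    lobule = factor(parc$region_names[lab[valid]],
                    levels = parc$region_names[keep_ids]),
    montage = factor(montage), head_model = factor(head_model),
    stringsAsFactors = FALSE)
}

#' N-way fixed-effects ANOVA with eta-squared effect sizes
#'
#' Linear-model decomposition of a response over crossed factors (main
#' effects plus, by default, all pairwise interactions), reporting the
#' classical eta-squared effect size `SS_term / SS_total` per term.
#' Type III sums of squares (with sum-to-zero contrasts) are the
#' default since region voxel counts are inherently unbalanced; on
#' balanced designs all types coincide and the term and residual sums
#' of squares add up to the total.
#'
#' @param table Data frame of observations.
#' @param response Response column name (e.g. `"Enorm"`).
#' @param factors Character vector of >= 1 factor column names, each
#'   with >= 2 levels present.
#' @param interactions `"two-way"` (default), `"none"`, or `"full"`.
#' @param ss_type 3 (default) or 1.
#' @return Object of class `anova_eta`: data frame with one row per
#'   term plus residuals (`term`, `df`, `sum_sq`, `mean_sq`,
#'   `F`, `p`, `eta_sq`), with attributes `total_ss` and `ss_type`.
#' @export
anova_eta <- function(table, response, factors,
                      interactions = c("two-way", "none", "full"),
                      ss_type = 3) {
  interactions <- match.arg(interactions)
  stopifnot(is.data.frame(table), response %in% names(table),
            all(factors %in% names(table)), length(factors) >= 1L)
  if (!ss_type %in% c(1, 3)) stop("ss_type must be 1 or 3")
  y <- table[[response]]
  if (!all(is.finite(y))) stop("response contains non-finite values")
  dat <- table[, c(response, factors), drop = FALSE]
  for (f in factors) {
    dat[[f]] <- droplevels(factor(dat[[f]]))
    if (nlevels(dat[[f]]) < 2L) {
      stop("factor '", f, "' has fewer than 2 levels")
    }
  }
  # inestimable designs: empty cells in any pairwise crossing
  if (length(factors) >= 2L && interactions != "none") {
    combs <- utils::combn(factors, 2L, simplify = FALSE)
    for (cc in combs) {
      tb <- table(dat[[cc[1L]]], dat[[cc[2L]]])
      if (any(tb == 0L)) {
        idx <- which(tb == 0L, arr.ind = TRUE)
        cells <- paste(rownames(tb)[idx[, 1L]], colnames(tb)[idx[, 2L]],
                       sep = ":")
        stop("empty design cells make the model inestimable: ",
             paste(cells, collapse = ", "))
      }
    }
  }
  rhs <- switch(interactions,
                "none" = paste(factors, collapse = " + "),
                "two-way" = if (length(factors) == 1L) factors else
                  paste0("(", paste(factors, collapse = " + "), ")^2"),
                "full" = paste(factors, collapse = " * "))
  fml <- stats::as.formula(paste(response, "~", rhs))
  ctr <- stats::setNames(
    rep(list("contr.sum"), length(factors)), factors)
  fit <- stats::lm(fml, data = dat, contrasts = ctr)
  if (stats::df.residual(fit) < 1L) stop("no residual degrees of freedom")
  ss_resid <- sum(stats::residuals(fit)^2)
  y_scale <- sum((y - mean(y))^2)
  saturated <- ss_resid <= 1e-12 * max(y_scale, 1)
  if (ss_type == 3 && saturated) {
    # saturated or constant response: the type III machinery divides by
    # the residual SS; fall back to the sequential decomposition, which
    # coincides on such designs
    ss_type <- 1
  }
  if (ss_type == 1) {
    a <- if (saturated) suppressWarnings(stats::anova(fit)) else
      stats::anova(fit)
    terms <- rownames(a)
    ss <- a[["Sum Sq"]]; df <- a[["Df"]]
    Fv <- a[["F value"]]; pv <- a[["Pr(>F)"]]
  } else {
    a <- car::Anova(fit, type = 3)
    keep <- !rownames(a) %in% "(Intercept)"
    terms <- rownames(a)[keep]
    ss <- a[["Sum Sq"]][keep]; df <- a[["Df"]][keep]
    Fv <- a[["F value"]][keep]; pv <- a[["Pr(>F)"]][keep]
  }
  ss_total <- sum((y - mean(y))^2)
  res <- data.frame(term = terms, df = df, sum_sq = ss,
                    mean_sq = ss / pmax(df, 1L), F = Fv, p = pv,
                    eta_sq = if (ss_total > 0) ss / ss_total else 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  res$eta_sq[res$term == "Residuals"] <- NA_real_
  res$F[res$term == "Residuals"] <- NA_real_
  res$p[res$term == "Residuals"] <- NA_real_
  structure(res, class = c("anova_eta", "data.frame"),
            total_ss = ss_total, ss_type = ss_type, model = fit)
}

#' @export
print.anova_eta <- function(x, digits = 4, ...) {
  cat(sprintf("ANOVA (type %s SS), total SS = %.6g\n",
              attr(x, "ss_type"), attr(x, "total_ss")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Bonferroni-corrected pairwise comparisons of means
#'
#' All pairwise differences of factor-level means with confidence
#' intervals built from Bonferroni-adjusted critical values of the
#' fitted model's residual variance: each of the k(k-1)/2 comparisons
#' is tested at `alpha / m`, so the family-wise error stays at `alpha`
#' (95% family confidence by default).
#'
#' @param table Data frame of observations.
#' @param response Response column name.
#' @param factor_name Factor column (or character vector of columns,
#'   compared by their interaction cells).
#' @param alpha Family-wise significance level (default 0.05).
#' @param model Optional fitted ANOVA ([anova_eta()] result) supplying
#'   the residual variance; by default a one-way model on
#'   `factor_name` is used.
#' @return Data frame with one row per pair: `level_a`, `level_b`,
#'   `diff`, `se`, `lwr`, `upr` (Bonferroni-adjusted CI), `t`, `p_adj`
#'   and `significant`.
#' @export
bonferroni_posthoc <- function(table, response, factor_name, alpha = 0.05,
                               model = NULL) {
  stopifnot(response %in% names(table), all(factor_name %in% names(table)))
  g <- if (length(factor_name) == 1L) factor(table[[factor_name]]) else
    interaction(table[factor_name], sep = ":", drop = TRUE)
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("need at least 2 factor levels to compare")
  y <- table[[response]]
  if (is.null(model)) {
    fit <- stats::lm(y ~ g)
    mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
    dfres <- stats::df.residual(fit)
  } else {
    fit <- attr(model, "model")
    mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
    dfres <- stats::df.residual(fit)
  }
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  lev <- levels(g)
  k <- length(lev)
  m <- k * (k - 1L) / 2L
  tcrit <- stats::qt(1 - alpha / (2 * m), dfres)
  pairs <- utils::combn(k, 2L)
  out <- data.frame(
    level_a = lev[pairs[1L, ]], level_b = lev[pairs[2L, ]],
    diff = means[pairs[1L, ]] - means[pairs[2L, ]],
    se = sqrt(mse * (1 / ns[pairs[1L, ]] + 1 / ns[pairs[2L, ]])),
    row.names = NULL, stringsAsFactors = FALSE)
  out$lwr <- out$diff - tcrit * out$se
  out$upr <- out$diff + tcrit * out$se
  out$t <- out$diff / out$se
  out$p_adj <- pmin(1, 2 * stats::pt(-abs(out$t), dfres) * m)
  out$significant <- out$p_adj < alpha
  attr(out, "alpha") <- alpha
  attr(out, "n_comparisons") <- m
  attr(out, "t_critical") <- tcrit
  out
}
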