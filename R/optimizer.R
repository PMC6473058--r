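#' Uniform region-field target
#'
#' Desired-field specification: a uniform field of the given magnitude
#' over the listed target regions in one direction, zero elsewhere
#' (including the non-cerebellar brain row). Weights are 1 on targets
#' and `spillover_weight` on all other regions, so spillover outside
#' the target set can be penalized or ignored.
#'
#' @param lf A `lead_field` (supplies region names), or a character
#'   vector of all region names.
#' @param regions Target region names (nonempty subset).
#' @param direction `"X"`, `"Y"` or `"Z"`.
#' @param magnitude Desired field in V/m (no default is assumed for
#'   you; typical request magnitudes are a few tenths of a V/m).
#' @param spillover_weight Weight (>= 0) on non-target regions.
#' @param total_cap_mA Safety cap on the total injected current
#'   magnitude, `sum(|x|) <= total_cap_mA` (default 4 mA, i.e. at most
#'   2 mA total anodal under the zero-net-current constraint).
#' @param per_electrode_cap_mA Optional per-electrode current cap.
#' @return Object of class `target_spec`.
#' @export
uniform_target <- function(lf, regions, direction = "Z", magnitude,
                           spillover_weight = 1, total_cap_mA = 4,
                           per_electrode_cap_mA = NULL) {
  region_names <- if (inherits(lf, "lead_field")) lf$regions else lf
  stopifnot(length(regions) >= 1L, is.numeric(magnitude))
  direction <- match.arg(direction, c("X", "Y", "Z"))
  unknown <- setdiff(regions, region_names)
  if (length(unknown) > 0L) {
    stop("unknown region(s): ", paste(unknown, collapse = ", "))
  }
  if (total_cap_mA <= 0) stop("total current cap must be > 0 mA")
  if (!is.null(per_electrode_cap_mA) && per_electrode_cap_mA <= 0) {
    stop("per-electrode cap must be > 0 mA")
  }
  b <- setNames(numeric(length(region_names)), region_names)
  b[regions] <- magnitude
  w <- setNames(rep(spillover_weight, length(region_names)), region_names)
  w[regions] <- 1
  if (all(w == 0)) stop("at least one region weight must be nonzero")
  structure(list(b = b, weights = w, direction = direction,
                 target_regions = regions,
                 total_cap_mA = total_cap_mA,
                 per_electrode_cap_mA = per_electrode_cap_mA),
            class = "target_spec")
}

# Constrained least squares for one direction:
#   min ||A x - b||^2  s.t.  sum(x_full) = 0,  sum(|x_full|) <= cap,
# where x are the non-reference currents and the reference carries
# -sum(x). Variable splitting x_full = p - q with p, q >= 0 turns the
# L1 constraint into a linear one; the reference enters as an explicit
# variable with a zero objective column.
solve_current_qp <- function(A, b, cap, per_cap = NULL) {
  nstim <- ncol(A)
  N <- nstim + 1L # + reference
  Af <- cbind(A, 0)
  # unconstrained minimum-norm least squares first: the cap may be slack
  sv <- svd(A)
  pos <- sv$d > max(sv$d, 0) * 1e-10
  x_ls <- if (any(pos)) {
    sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos])
  } else {
    matrix(0, nstim, 1L)
  }
  x_full <- c(as.numeric(x_ls), -sum(x_ls))
  feasible <- sum(abs(x_full)) <= cap + 1e-12 &&
    (is.null(per_cap) || all(abs(x_full) <= per_cap + 1e-12))
  if (feasible) {
    return(list(x_full = x_full, active_cap = FALSE,
                rank = sum(pos), note = if (all(!pos)) "rank-deficient: x = 0"))
  }
  # split form z = [p; q], x_full = p - q; the split Hessian is singular,
  # so a tiny ridge keeps the QP solver happy and an exact equality-
  # constrained polish on the detected support removes the ridge bias
  C <- rbind(cbind(Af, -Af), sqrt(1e-10) * diag(2L * N))
  d <- c(b, rep(0, 2L * N))
  Aeq <- matrix(rep(c(1, -1), each = N), 1L)
  Ain <- matrix(1, 1L, 2L * N)
  lb <- rep(0, 2L * N)
  ub <- rep(if (is.null(per_cap)) cap else min(cap, per_cap), 2L * N)
  z <- pracma::lsqlincon(C, d, A = Ain, b = cap, Aeq = Aeq, beq = 0,
                         lb = lb, ub = ub)
  x_full <- z[seq_len(N)] - z[N + seq_len(N)]
  x_polish <- polish_active_set(Af, b, x_full, cap, per_cap)
  if (!is.null(x_polish)) x_full <- x_polish
  # numerical guards: exact zero net current and cap feasibility
  x_full[N] <- -sum(x_full[-N])
  tot <- sum(abs(x_full))
  if (tot > cap) x_full <- x_full * (cap / tot)
  list(x_full = x_full, active_cap = TRUE, rank = sum(pos), note = NULL)
}

# Exact refinement of a QP solution: freeze the support and signs found
# by the interior solve, then solve the equality-constrained least
# squares (zero net current plus the L1 cap as a linear equality on the
# signed support) via KKT; accept only if it stays sign-consistent,
# feasible, and at least as good.
polish_active_set <- function(Af, b, x_full, cap, per_cap) {
  N <- length(x_full)
  supp <- which(abs(x_full) > 1e-7 * cap)
  if (length(supp) < 2L) return(NULL)
  sgn <- sign(x_full[supp])
  As <- Af[, supp, drop = FALSE]
  k <- length(supp)
  # constraints: sum(x_supp) = 0, sgn' x_supp = cap
  Ce <- rbind(rep(1, k), sgn)
  H <- crossprod(As)
  KKT <- rbind(cbind(2 * H, t(Ce)), cbind(Ce, matrix(0, 2L, 2L)))
  rhs <- c(2 * crossprod(As, b), 0, cap)
  sol <- tryCatch(solve(KKT, rhs), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  xs <- sol[seq_len(k)]
  if (any(sign(xs) * sgn < 0)) return(NULL) # sign flipped: keep QP result
  if (!is.null(per_cap) && any(abs(xs) > per_cap + 1e-9)) return(NULL)
  x_new <- numeric(N)
  x_new[supp] <- xs
  f_old <- sum((Af %*% x_full - b)^2)
  f_new <- sum((Af %*% x_new - b)^2)
  if (f_new > f_old + 1e-12) return(NULL)
  x_new
}

#' Optimize a stimulation montage against a lead field
#'
#' Solves the convex current-steering problem
#' `argmin_x || W (LF x - b) ||^2` subject to zero net current
#' (`sum(x) = 0`) and the total-current safety cap
#' (`sum(|x|) <= cap`, default 4 mA so that the total anodal or
#' cathodal current stays below 2 mA), by exact variable-splitting
#' quadratic programming. By default each requested direction is
#' optimized independently (one montage per field direction); with
#' `stacked = TRUE` a single montage is fit to all requested
#' directions jointly.
#'
#' @param lf A `lead_field`.
#' @param target A [uniform_target()] (or a `target_spec` with
#'   matching regions), or a list of them for multiple directions.
#' @param stacked Fit all directions with a single current vector.
#' @param sparsify Drop electrodes with `|x|` below 1% of the cap and
#'   re-solve once (off by default).
#' @return For a single direction, an object of class
#'   `montage_solution`: `x` (named currents, mA, including the
#'   reference), `residual` (weighted L2 error), `achieved` (predicted
#'   region fields), `active` (electrodes carrying >1% of the cap),
#'   `constraints` (net current, total magnitude, cap, slack) and
#'   `direction`. For several directions, a named list of such objects.
#' @export
optimize_montage <- function(lf, target, stacked = FALSE, sparsify = FALSE) {
  stopifnot(inherits(lf, "lead_field"))
  targets <- if (inherits(target, "target_spec")) list(target) else target
  stopifnot(all(vapply(targets, inherits, TRUE, "target_spec")))
  dirs <- vapply(targets, `[[`, "", "direction")
  if (anyDuplicated(dirs)) stop("duplicate target directions")
  cap <- targets[[1L]]$total_cap_mA
  per_cap <- targets[[1L]]$per_electrode_cap_mA

  build_Ab <- function(tg) {
    if (!identical(names(tg$b), lf$regions)) {
      stop("target regions do not align with the lead field regions")
    }
    W <- tg$weights
    list(A = lf$LF[[tg$direction]] * W, b = tg$b * W)
  }
  solve_one <- function(A, b, direction) {
    qp <- solve_current_qp(A, b, cap, per_cap)
    ids <- c(colnames(lf$LF$X), lf$reference_id)
    x <- setNames(qp$x_full, ids)
    if (sparsify) {
      keep <- abs(x) >= 0.01 * cap
      keep[lf$reference_id] <- TRUE
      if (any(!keep) && sum(keep) >= 2L) {
        A2 <- A[, colnames(A) %in% names(x)[keep], drop = FALSE]
        qp2 <- solve_current_qp(A2, b, cap, per_cap)
        x[] <- 0
        x[c(colnames(A2), lf$reference_id)] <- qp2$x_full
        qp <- qp2
      }
    }
    achieved <- predict_fields(lf, x)
    res <- sqrt(sum((A %*% x[colnames(A)] - b)^2))
    structure(list(
      x = x, residual = res, achieved = achieved,
      active = names(x)[abs(x) > 0.01 * cap],
      direction = direction,
      constraints = list(net_current_mA = sum(x),
                         total_abs_mA = sum(abs(x)),
                         total_anodal_mA = sum(x[x > 0]),
                         cap_mA = cap,
                         cap_slack_mA = cap - sum(abs(x)),
                         cap_active = qp$active_cap),
      note = qp$note), class = "montage_solution")
  }
  if (stacked) {
    Ab <- lapply(targets, build_Ab)
    A <- do.call(rbind, lapply(Ab, `[[`, "A"))
    b <- unlist(lapply(Ab, `[[`, "b"))
    return(solve_one(A, b, paste(dirs, collapse = "+")))
  }
  out <- lapply(targets, function(tg) {
    ab <- build_Ab(tg)
    solve_one(ab$A, ab$b, tg$direction)
  })
  names(out) <- dirs
  if (length(out) == 1L) out[[1L]] else out
}

#' @export
print.montage_solution <- function(x, ...) {
  cat(sprintf(paste0("montage_solution (direction %s): residual %.4g, ",
                     "net current %.2e mA, total |I| %.3f of %.3f mA\n"),
              x$direction, x$residual, x$constraints$net_current_mA,
              x$constraints$total_abs_mA, x$constraints$cap_mA))
  act <- x$x[abs(x$x) > 0.01 * x$constraints$cap_mA]
  if (length(act)) {
    cat("  active electrodes (mA):\n")
    for (nm in names(sort(-abs(act)))) {
      cat(sprintf("    %-8s %+0.3f\n", nm, act[nm]))
    }
  }
  invisible(x)
}
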