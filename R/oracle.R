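#' Series potential for point current injection on concentric shells
#'
#' Closed-form Legendre-series solution of the current-flow (Laplace)
#' problem in a ball of concentric isotropic shells, driven by a point
#' current source and a point current sink on the outer surface. Serves
#' as the independent reference solution for verifying the finite
#' element solver.
#'
#' Within shell j the degree-n radial factor is
#' `A_j (r/R)^n + B_j (r/R)^(-(n+1))`; the coefficients are determined
#' per degree by continuity of the potential and of the radial current
#' density `sigma dPhi/dr` at each interface, regularity at the center,
#' and the Neumann condition at the surface, where a point electrode of
#' current I expands as `I (2n+1) / (4 pi R^2)` per degree. Degree 0 is
#' absent (balanced currents), which fixes the zero-mean gauge over the
#' outer surface.
#'
#' Units: mm, S/m and mA, which combine to potentials in volts.
#'
#' @param shells Shell table (outermost first), as for
#'   [build_shell_phantom()].
#' @param source,sink Lists with `position` (length-3, mm; must lie on
#'   the outer surface within 1% of the radius) and `current` (mA).
#'   Currents must be balanced: `source$current + sink$current == 0`.
#' @param obs_points Matrix (k x 3) of observation points, strictly
#'   inside the outer radius.
#' @param n_terms Truncation degree of the Legendre series (>= 1).
#' @return An object of class `series_solution`: list with `potential`
#'   (volts at `obs_points`), `n_terms`, `convergence` (largest relative
#'   contribution of the final degree over the observation points) and
#'   the input geometry.
#' @export
potential_multishell <- function(shells, source, sink, obs_points,
                                 n_terms = 100) {
  shells <- as_shell_table(shells)
  stopifnot(n_terms >= 1)
  R <- shells$outer_radius[1]
  obs_points <- as.matrix(obs_points)
  stopifnot(ncol(obs_points) == 3L)
  if (any(sqrt(rowSums(obs_points^2)) >= R)) {
    stop("observation points must lie strictly inside the outer radius")
  }
  for (el in list(source, sink)) {
    stopifnot(is.list(el), length(el$position) == 3L,
              is.numeric(el$current), length(el$current) == 1L)
    rp <- sqrt(sum(el$position^2))
    if (abs(rp - R) > 0.01 * R) {
      stop("source/sink positions must lie on the outer surface (radius ",
           R, " mm)")
    }
  }
  if (abs(source$current + sink$current) > 1e-12) {
    stop("source and sink currents must balance (Neumann compatibility); got ",
         source$current, " + ", sink$current)
  }

  # Radial coefficients per degree, with per-shell scaling for numerical
  # stability at high degree: within shell j (inner radius a_j, outer b_j,
  # in units of R) the radial factor is
  #   A_j (rho / b_j)^n + B_j (a_j / rho)^(n + 1),
  # so every power that enters the interface system is <= 1 in magnitude.
  sig <- rev(shells$conductivity)           # innermost first
  iface <- rev(shells$outer_radius)[-nrow(shells)] / R # interface rho, inner->outer
  S <- length(sig)
  a_sh <- c(0, iface)   # inner radius of shell j (rho units)
  b_sh <- c(iface, 1)   # outer radius of shell j
  coefA <- matrix(0, n_terms, S)
  coefB <- matrix(0, n_terms, S)
  for (nn in seq_len(n_terms)) {
    # unknowns: A_1, A_2, B_2, ..., A_S, B_S
    nunk <- 2L * S - 1L
    M <- matrix(0, nunk, nunk)
    rhs <- numeric(nunk)
    colA <- function(j) if (j == 1L) 1L else 2L * j - 2L
    colB <- function(j) 2L * j - 1L # only j >= 2
    row <- 0L
    for (j in seq_len(S - 1L)) {
      rho <- iface[j] # = b_j = a_{j+1}
      rA_j <- (a_sh[j] / b_sh[j])^(nn + 1)
      rA_jp <- (b_sh[j] / b_sh[j + 1L])^nn
      # potential continuity at rho (shell j side minus shell j+1 side)
      row <- row + 1L
      M[row, colA(j)] <- 1
      if (j > 1L) M[row, colB(j)] <- rA_j
      M[row, colA(j + 1L)] <- -rA_jp
      M[row, colB(j + 1L)] <- -1
      # radial current continuity (scaled by rho; common 1/R dropped)
      row <- row + 1L
      M[row, colA(j)] <- sig[j] * nn
      if (j > 1L) M[row, colB(j)] <- -sig[j] * (nn + 1) * rA_j
      M[row, colA(j + 1L)] <- -sig[j + 1L] * nn * rA_jp
      M[row, colB(j + 1L)] <- sig[j + 1L] * (nn + 1)
    }
    # Neumann condition at the outer surface (rho = 1, b_S = 1)
    row <- row + 1L
    M[row, colA(S)] <- sig[S] * nn
    if (S > 1L) M[row, colB(S)] <- -sig[S] * (nn + 1) * a_sh[S]^(nn + 1)
    rhs[row] <- (2 * nn + 1) / (4 * pi * R)
    sol <- solve(M, rhs)
    coefA[nn, ] <- sol[vapply(seq_len(S), colA, 1L)]
    if (S > 1L) coefB[nn, 2:S] <- sol[vapply(2:S, colB, 1L)]
  }

  r_obs <- sqrt(rowSums(obs_points^2))
  rho_obs <- r_obs / R
  # shell (innermost-first index) containing each observation point
  shell_of <- findInterval(r_obs, c(iface * R, R), rightmost.closed = TRUE) + 1L
  shell_of[shell_of > S] <- S

  eval_monopole <- function(pos, current) {
    u <- pos / sqrt(sum(pos^2))
    x <- pmin(pmax((obs_points %*% u) / pmax(r_obs, .Machine$double.eps), -1), 1)
    x[r_obs == 0] <- 0 # P_n(cos gamma) irrelevant at the center for n >= 1
    # Legendre recurrence, accumulate
    Pnm1 <- rep(1, length(x)) # P_0
    Pn <- as.numeric(x)       # P_1
    total <- numeric(length(x))
    last <- numeric(length(x))
    for (nn in seq_len(n_terms)) {
      radial <- coefA[cbind(nn, shell_of)] * (rho_obs / b_sh[shell_of])^nn
      hasB <- shell_of > 1L
      if (any(hasB)) {
        sj <- shell_of[hasB]
        radial[hasB] <- radial[hasB] +
          coefB[cbind(nn, sj)] * (a_sh[sj] / rho_obs[hasB])^(nn + 1)
      }
      last <- current * radial * Pn
      total <- total + last
      if (nn < n_terms) {
        Pnp1 <- ((2 * nn + 1) * x * Pn - nn * Pnm1) / (nn + 1)
        Pnm1 <- Pn; Pn <- Pnp1
      }
    }
    list(total = total, last = last)
  }

  a <- eval_monopole(source$position, source$current)
  b <- eval_monopole(sink$position, sink$current)
  pot <- a$total + b$total
  denom <- max(abs(pot), .Machine$double.eps)
  conv <- max(abs(a$last) + abs(b$last)) / denom
  structure(list(potential = as.numeric(pot), n_terms = n_terms,
                 convergence = conv, shells = shells,
                 source = source, sink = sink, obs_points = obs_points),
            class = "series_solution")
}

#' @export
print.series_solution <- function(x, ...) {
  cat(sprintf(paste0("series_solution: %d observation points, %d terms, ",
                     "last-degree contribution %.2e\n"),
              length(x$potential), x$n_terms, x$convergence))
  invisible(x)
}
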