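# Cancer-free homeostatic equilibrium of the healthy tissue.
#
# With healthy cells fixed at the natural density theta* = 0.6, no cancer
# and no macrophages, the spatially uniform steady state satisfies a small
# algebraic system: healthy-cell birth/death balance, angiogenesis/occlusion
# balance, volume closure (theta_v + theta_int = 0.4), oxygen supply/
# consumption balance, and VEGF production/decay/binding balance.  The
# solution supplies the initial conditions of every simulation.
#
# The angiogenesis constant is treated as the unknown of the second
# equation.  Solving the system literally at the converged VEGF level gives
# k_ang_implied ~ 8.1e-3; the simulator's default k_ang is the independent
# published value 4.87e-3 (which the second equation yields if the VEGF
# concentration is replaced by 1).  Both numbers are reported; the solve
# never silently overwrites the configured k_ang.

# residuals of the five equilibrium equations at (theta_v, theta_int, c, g)
# with healthy cells at theta_star; k_ang enters only equation 2
homeo_residuals <- function(x, params, k_ang) {
  p <- params
  th_h <- p$theta_star
  th_v <- x[1]; th_int <- x[2]; cc <- x[3]; g <- x[4]
  c(
    th_int * cc / (p$c_p + cc) - p$k_d_h * (p$c_c1 + cc) / (p$c_c2 + cc),
    k_ang * g * th_int / (p$eps + th_int) -
      p$k_occ * smooth_heaviside(-p$p_crit, p$h_smooth),
    th_v + th_int - (1 - th_h),
    th_v * p$k_rep * (p$c_v_ref - cc) - p$k_c_h * th_h * cc -
      p$k_cm_h * th_h * th_int * cc / (p$c_p + cc),
    p$k_p_g * th_h * cc / (p$c_a + cc)^2 - p$k_assoc_g * th_v * g -
      p$k_d_g * g
  )
}

#' Solve the healthy-tissue homeostatic equilibrium
#'
#' Damped Newton iteration (numerical Jacobian, fixed initial guess
#' `(0.02, 0.38, 0.25, 0.5)`) on the four equations that determine the
#' uniform vessel, interstitial-fluid, oxygen, and VEGF levels; the
#' angiogenesis constant implied by the vessel balance is then evaluated in
#' closed form.  Deterministic and grid-independent.
#'
#' @param params a [model_parameters()] object.
#' @param tol maximum absolute residual accepted (default `1e-12`).
#' @param max_iter Newton iteration cap.
#' @return an object of class `tp_homeostasis`: list with `theta_v0`,
#'   `theta_int0`, `c0`, `g0`, `k_ang_implied`, and `residual_norm`.
#' @examples
#' h <- solve_homeostasis(model_parameters())
#' round(c(h$theta_v0, h$theta_int0, h$c0, h$g0), 4)
#' @export
solve_homeostasis <- function(params, tol = 1e-12, max_iter = 100L) {
  validate_parameters(params)
  # equations 1, 3, 4, 5 in the unknowns (theta_v, theta_int, c, g)
  fn <- function(x) homeo_residuals(x, params, k_ang = 0)[c(1, 3, 4, 5)]
  x <- c(0.02, 0.38, 0.25, 0.5)
  for (it in seq_len(max_iter)) {
    r <- fn(x)
    if (max(abs(r)) < tol) break
    J <- matrix(0, 4, 4)
    for (k in 1:4) {
      hstep <- 1e-7 * max(abs(x[k]), 1e-3)
      xp <- x; xp[k] <- xp[k] + hstep
      J[, k] <- (fn(xp) - r) / hstep
    }
    dx <- tryCatch(solve(J, -r), error = function(e)
      stop("homeostasis solve failed: singular Jacobian at iterate (",
           paste(signif(x, 6), collapse = ", "), ")"))
    lambda <- 1
    repeat {                                   # damping: require descent
      xn <- x + lambda * dx
      if (all(is.finite(xn)) && max(abs(fn(xn))) < max(abs(r)) ||
          lambda < 1e-6) break
      lambda <- lambda / 2
    }
    x <- x + lambda * dx
  }
  r <- fn(x)
  if (max(abs(r)) >= tol * 10)
    stop("homeostasis solve did not converge: residuals (",
         paste(signif(r, 3), collapse = ", "), ") at iterate (",
         paste(signif(x, 6), collapse = ", "), ")")
  if (any(x <= 0) || any(x >= 1))
    stop("homeostasis solve left (0,1): iterate (",
         paste(signif(x, 6), collapse = ", "), ")")
  # vessel balance solved for the angiogenesis constant
  k_ang_implied <-
    params$k_occ * smooth_heaviside(-params$p_crit, params$h_smooth) /
    (x[4] * x[2] / (params$eps + x[2]))
  res <- list(theta_v0 = x[1], theta_int0 = x[2], c0 = x[3], g0 = x[4],
              k_ang_implied = k_ang_implied,
              residual_norm = max(abs(homeo_residuals(x, params,
                                                      k_ang_implied))))
  class(res) <- "tp_homeostasis"
  res
}

#' Independently evaluate the equilibrium residuals
#'
#' Re-evaluates all five balance equations at a candidate equilibrium
#' without reusing any solver internals, returning the absolute residual of
#' each.  Useful for checking the internal consistency of rounded printed
#' values.
#'
#' @param params a [model_parameters()] object.
#' @param result a `tp_homeostasis` object (or a list with the same
#'   fields); `k_ang_implied` may be omitted, in which case `params$k_ang`
#'   is used in the vessel balance.
#' @return named numeric vector of five absolute residuals.
#' @export
verify_homeostasis <- function(params, result) {
  k_ang <- result$k_ang_implied %||% params$k_ang
  r <- homeo_residuals(c(result$theta_v0, result$theta_int0,
                         result$c0, result$g0), params, k_ang)
  stats::setNames(abs(r), c("healthy_balance", "vessel_balance",
                            "volume_closure", "oxygen_balance",
                            "vegf_balance"))
}

#' @export
print.tp_homeostasis <- function(x, ...) {
  cat("Homeostatic equilibrium (dimensionless):\n")
  cat(sprintf("  theta_v0   = %.6g\n", x$theta_v0))
  cat(sprintf("  theta_int0 = %.6g\n", x$theta_int0))
  cat(sprintf("  c0         = %.6g\n", x$c0))
  cat(sprintf("  g0         = %.6g\n", x$g0))
  cat(sprintf("  k_ang implied by the vessel balance = %.6g\n",
              x$k_ang_implied))
  cat(sprintf("  max |residual| = %.3g\n", x$residual_norm))
  invisible(x)
}
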