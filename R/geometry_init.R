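# Initial conditions: homeostatic background plus cosine-squared tumor
# seeds, and the equal-mass multi-seed placement protocol.

#' Tumor seed specification
#'
#' A radially symmetric lesion `theta_c(r) = amplitude * cos^2(pi r_s /
#' (2 radius))` for distance `r_s <= radius` from `center`, zero outside.
#'
#' @param center length-2 coordinates (1D runs require the origin).
#' @param radius seed radius (> 0; default 1, the reference lesion).
#' @param amplitude peak cancer concentration (default 0.05).
#' @return an object of class `tp_seed`.
#' @export
seed_spec <- function(center = c(0, 0), radius = 1, amplitude = 0.05) {
  center <- as.numeric(center)
  if (length(center) == 1) center <- c(center, 0)
  stopifnot(length(center) == 2, is.finite(center))
  if (!(radius > 0)) stop("seed radius must be positive")
  if (!(amplitude > 0) || amplitude >= 0.6)
    stop("seed amplitude must lie in (0, theta*)")
  structure(list(center = center, radius = radius, amplitude = amplitude),
            class = "tp_seed")
}

#' Equal-mass multi-seed placement
#'
#' Divides the reference single-seed cancer mass equally between `n` seeds
#' placed on a regular polygon (`n = 1`: center; `n = 2`: symmetric pair;
#' `n = 3`: equilateral triangle with side `spacing`).  Equal division is
#' achieved by shrinking each seed radius to `radius / sqrt(n)` at fixed
#' amplitude: the planar integral of the scaled cosine-squared profile is
#' proportional to the squared radius.
#'
#' @param n number of seeds (>= 1).
#' @param spacing center-to-center distance between neighboring seeds.
#' @param radius reference single-seed radius.
#' @param amplitude peak concentration of every seed.
#' @return list of [seed_spec()] objects.
#' @export
make_multiseed <- function(n, spacing = 3, radius = 1, amplitude = 0.05) {
  stopifnot(n >= 1, n == round(n))
  if (!(spacing > 0)) stop("seed spacing must be positive")
  rs <- radius / sqrt(n)
  centers <- if (n == 1) list(c(0, 0)) else {
    circum <- spacing / (2 * sin(pi / n))
    ang <- 2 * pi * (seq_len(n) - 1) / n + pi / 2
    lapply(seq_len(n), function(k) circum * c(cos(ang[k]), sin(ang[k])))
  }
  seeds <- lapply(centers, seed_spec, radius = rs, amplitude = amplitude)
  if (n > 1 && spacing < 2 * rs)
    stop("seeds overlap at spacing ", spacing, " (seed radius ", rs, ")")
  seeds
}

#' Build the initial phase and chemical state
#'
#' Homeostatic background everywhere (healthy cells at `theta* = 0.6`
#' minus the local cancer concentration, vessels/fluid/oxygen/VEGF at the
#' equilibrium values, macrophages and inflammation-associated chemicals
#' absent) with the cancer seeds superposed.
#'
#' @param domain a `tp_domain`.
#' @param homeo a `tp_homeostasis` from [solve_homeostasis()].
#' @param seeds list of [seed_spec()] (empty list for a cancer-free run).
#' @param theta_star natural tissue density (default 0.6).
#' @return `list(phases = <tp_phase_state>, chems = <tp_chemical_state>)`.
#' @export
initial_state <- function(domain, homeo, seeds = list(seed_spec()),
                          theta_star = 0.6) {
  th_c <- rep(0, domain$n)
  for (s in seeds) {
    rs <- if (domain$mode == "radial_1d") {
      if (any(s$center != 0))
        stop("1D radial runs require seeds centered at the origin; ",
             "use cartesian_2d for off-center or multiple seeds")
      abs(domain$r_cell)
    } else sqrt((domain$x - s$center[1])^2 + (domain$y - s$center[2])^2)
    inside <- rs <= s$radius
    th_c[inside] <- th_c[inside] +
      s$amplitude * cos(pi * rs[inside] / (2 * s$radius))^2
  }
  if (length(seeds) > 1 && domain$mode == "radial_1d")
    stop("multi-seed scenarios require a cartesian_2d domain")
  if (any(th_c >= theta_star))
    stop("overlapping seeds exceed the natural tissue density theta*")
  phases <- phase_state(domain, h = theta_star - th_c, c = th_c,
                        v = homeo$theta_v0, int = homeo$theta_int0)
  chems <- chemical_state(domain, c = homeo$c0, g = homeo$g0)
  list(phases = phases, chems = chems)
}
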