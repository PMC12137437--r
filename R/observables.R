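# Summary metrics: spatial averages, M2/M1 ratio, radial profiles, and
# the tumor boundary radius.

#' Volume-weighted spatial average
#'
#' Mean of a field over the disk: `(1/S) * integral(f)` with `S` the
#' (discrete) domain area.
#'
#' @param domain a `tp_domain`.
#' @param f cell field.
#' @return scalar average.
#' @export
spatial_average <- function(domain, f) {
  volume_integral(domain, f) / sum(domain$vol)
}

#' Area-weighted radial profile
#'
#' 1D: cell values at cell radii.  2D: area-weighted averages over annular
#' bins one cell width wide.
#'
#' @param domain a `tp_domain`.
#' @param f cell field.
#' @return `data.frame(r, value)` with increasing `r` (empty bins dropped).
#' @export
radial_profile <- function(domain, f) {
  if (domain$mode == "radial_1d")
    return(data.frame(r = domain$r_cell, value = as.numeric(f)))
  h <- domain$dx
  r <- sqrt(domain$x^2 + domain$y^2)
  bin <- pmin(floor(r / h), ceiling(domain$R / h) - 1)
  w <- domain$vol
  num <- rowsum(w * f, bin)
  den <- rowsum(w, bin)
  data.frame(r = (as.numeric(rownames(num)) + 0.5) * h,
             value = num[, 1] / den[, 1])
}

#' Tumor boundary radius
#'
#' Outermost radius at which the (azimuthally averaged) cancer
#' concentration crosses `threshold`, located by linear interpolation of
#' the radial profile; 0 when the tumor is everywhere below threshold, and
#' the domain radius when it exceeds threshold out to the boundary.
#'
#' @param domain a `tp_domain`.
#' @param theta_c cancer concentration field.
#' @param threshold boundary contour level (default 0.01).
#' @return scalar radius.
#' @export
tumor_radius <- function(domain, theta_c, threshold = 0.01) {
  pr <- radial_profile(domain, theta_c)
  above <- pr$value >= threshold
  if (!any(above)) return(0)
  i <- max(which(above))
  if (i == nrow(pr)) return(domain$R)
  # interpolate the outermost downward crossing
  p1 <- pr$value[i]; p2 <- pr$value[i + 1]
  pr$r[i] + (p1 - threshold) / (p1 - p2) * (pr$r[i + 1] - pr$r[i])
}

#' M2 to M1 macrophage ratio
#'
#' Ratio of the average pro-tumor concentration to the average
#' anti-tumor concentration, counting drug-bound macrophages in the
#' denominator: `mean(theta_M2) / (mean(theta_M1) + mean(theta_M1p))`.
#' Returns `NA` (undefined, not zero) when the denominator is below
#' `1e-12` -- before any macrophages have entered the tissue the ratio
#' carries no information.
#'
#' @param domain a `tp_domain`.
#' @param phases a `tp_phase_state`.
#' @return scalar ratio, or `NA_real_`.
#' @export
m2_m1_ratio <- function(domain, phases) {
  den <- spatial_average(domain, phases$M1) +
    spatial_average(domain, phases$M1p)
  if (den < 1e-12) return(NA_real_)
  spatial_average(domain, phases$M2) / den
}

# one observable record row
observable_record <- function(domain, t, phases) {
  bars <- vapply(tp_phases, function(ph) spatial_average(domain, phases[[ph]]),
                 numeric(1))
  data.frame(t = t,
             theta_bar_h = bars[["h"]], theta_bar_c = bars[["c"]],
             theta_bar_v = bars[["v"]], theta_bar_int = bars[["int"]],
             theta_bar_M1 = bars[["M1"]], theta_bar_M1p = bars[["M1p"]],
             theta_bar_M2 = bars[["M2"]],
             ratio_M2_M1 = m2_m1_ratio(domain, phases),
             tumor_radius = tumor_radius(domain, phases$c))
}

#' Phase flux field
#'
#' The mass flux `theta_i u_i` of one phase, interpolated to cell centers
#' (1D: radial component).
#'
#' @param domain a `tp_domain`.
#' @param phases a `tp_phase_state`.
#' @param flow a `tp_flow`.
#' @param phase phase name.
#' @return cell field (1D) or `list(x, y)` of cell fields (2D).
#' @export
phase_flux <- function(domain, phases, flow, phase) {
  th <- phases[[phase]]
  if (domain$mode == "radial_1d") {
    u <- flow$u[[phase]]
    th * (u[-1] + u[-(domain$n + 1)]) / 2
  } else {
    u <- flow$u[[phase]]
    ux <- uy <- numeric(domain$n)
    cnt <- matrix(0, domain$n, 2)
    accum <- function(vals, L, R, comp) {
      acc <- rowsum(c(vals, vals), c(L, R))
      idx <- as.integer(rownames(acc))
      if (comp == 1) ux[idx] <<- ux[idx] + acc[, 1]
      else uy[idx] <<- uy[idx] + acc[, 1]
      cn <- rowsum(rep(1, 2 * length(vals)), c(L, R))
      cnt[idx, comp] <<- cnt[idx, comp] + cn[, 1]
    }
    accum(u$x, domain$fx$L, domain$fx$R, 1)
    accum(u$y, domain$fy$L, domain$fy$R, 2)
    list(x = th * ifelse(cnt[, 1] > 0, ux / pmax(cnt[, 1], 1), 0),
         y = th * ifelse(cnt[, 2] > 0, uy / pmax(cnt[, 2], 1), 0))
  }
}
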