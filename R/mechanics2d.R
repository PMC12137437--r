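# Multiphase creeping flow on the 2D masked Cartesian grid.
#
# Same physics as the radial solver (per-phase momentum with the full
# deviatoric viscous stress, inter-phase drag, pressure closure, mixture
# continuity) on a MAC-staggered layout: x/y velocity components live on
# cell faces, the interstitial pressure at cell centers.  The disk
# boundary is the staircase of mask faces; normal stress conditions are
# imposed face-wise (sigma_nn = 0 for all phases except the interstitial
# fluid, whose normal velocity vanishes) and the shear stress is dropped
# at partial corners, a first-order treatment adequate for the coarse
# qualitative 2D runs this mode is meant for.

solve_flow_2d <- function(domain, phases, params, sigma = NULL,
                          continuity_rhs = NULL) {
  m <- domain$m; dx <- domain$dx; nc <- domain$n
  id <- domain$id_mat
  ci <- domain$ci; cj <- domain$cj
  fx <- domain$fx; fy <- domain$fy
  if (is.null(sigma)) sigma <- sigma_closure(phases, params)
  if (is.null(continuity_rhs)) continuity_rhs <- rep(0, nc)
  mu <- params$mu
  dmat <- params$d_drag

  # phases with no mass anywhere are dropped from the velocity system:
  # they carry no flux and their velocities would be pure regularization
  # artifacts; they re-enter the solve as soon as any mass appears
  active <- vapply(tp_phases, function(ph)
    ph %in% c("h", "v", "int") || max(phases[[ph]]) > 1e-10, logical(1))
  act_idx <- which(active)
  nact <- length(act_idx)

  nxi <- length(fx$L); nxb <- length(fx$b_owner)
  nyi <- length(fy$L); nyb <- length(fy$b_owner)
  nf <- nxi + nxb + nyi + nyb
  # slot maps: XS[i+1, j] = unknown slot of the x-face at position (i, j)
  XS <- matrix(0L, m + 1, m)
  XS[cbind(fx$i + 1L, fx$j)] <- seq_len(nxi)
  XS[cbind(fx$b_i + 1L, fx$b_j)] <- nxi + seq_len(nxb)
  YS <- matrix(0L, m, m + 1)
  YS[cbind(fy$i, fy$j + 1L)] <- nxi + nxb + seq_len(nyi)
  YS[cbind(fy$b_i, fy$b_j + 1L)] <- nxi + nxb + nyi + seq_len(nyb)

  # per-cell face slots (within a phase block)
  uw <- XS[cbind(ci, cj)];     ue <- XS[cbind(ci + 1L, cj)]
  vs <- YS[cbind(ci, cj)];     vn <- YS[cbind(ci, cj + 1L)]
  stopifnot(all(uw > 0), all(ue > 0), all(vs > 0), all(vn > 0))

  # row slots: interior-face rows are the face's own slot; which interior
  # faces border each cell
  west_int  <- ci > 1L & id[cbind(pmax(ci - 1L, 1L), cj)] > 0L
  east_int  <- ci < m  & id[cbind(pmin(ci + 1L, m), cj)] > 0L
  south_int <- cj > 1L & id[cbind(ci, pmax(cj - 1L, 1L))] > 0L
  north_int <- cj < m  & id[cbind(ci, pmin(cj + 1L, m))] > 0L

  thf <- lapply(phases, pmax, tp_theta_floor)
  # floored concentration matrices with zero outside the mask
  as_mat <- function(v) {
    out <- matrix(0, m, m)
    out[cbind(ci, cj)] <- v
    out
  }

  # full corners: all four surrounding cells inside the mask; corner
  # (i, j) with i, j in 1..m-1 joins cells (i,j), (i+1,j), (i,j+1), (i+1,j+1)
  cg <- expand.grid(i = seq_len(m - 1), j = seq_len(m - 1))
  full <- id[cbind(cg$i, cg$j)] > 0 & id[cbind(cg$i + 1L, cg$j)] > 0 &
    id[cbind(cg$i, cg$j + 1L)] > 0 & id[cbind(cg$i + 1L, cg$j + 1L)] > 0
  cor_i <- cg$i[full]; cor_j <- cg$j[full]
  # velocity slots around each full corner
  cu_above <- XS[cbind(cor_i + 1L, cor_j + 1L)]
  cu_below <- XS[cbind(cor_i + 1L, cor_j)]
  cv_east  <- YS[cbind(cor_i + 1L, cor_j + 1L)]
  cv_west  <- YS[cbind(cor_i, cor_j + 1L)]
  # x-faces directly below/above each corner, and y-faces west/east
  cfx_below <- XS[cbind(cor_i + 1L, cor_j)]
  cfx_above <- XS[cbind(cor_i + 1L, cor_j + 1L)]
  cfy_west  <- YS[cbind(cor_i, cor_j + 1L)]
  cfy_east  <- YS[cbind(cor_i + 1L, cor_j + 1L)]
  fx_is_int <- c(rep(TRUE, nxi), rep(FALSE, nxb),
                 rep(TRUE, nyi), rep(FALSE, nyb))  # interior-face flag by slot

  nun <- nact * nf + nc
  blk <- integer(7L); blk[act_idx] <- seq_len(nact) - 1L   # block index
  uix <- function(p, slot) blk[p] * nf + slot
  pix <- function(cid) nact * nf + cid

  trips <- vector("list", 4096L); ntrip <- 0L
  rhs <- numeric(nun)
  add <- function(i, j, x) {
    ntrip <<- ntrip + 1L
    trips[[ntrip]] <<- cbind(i, j, x)
  }

  has_pint <- stats::setNames(tp_phases != "v", tp_phases)
  cellular <- tp_phases %in% tp_cellular

  for (p in act_idx) {
    ph <- tp_phases[p]
    th <- thf[[ph]]
    thm <- as_mat(th)
    mup <- mu[[ph]]
    base <- blk[p] * nf

    # ---- normal viscous stresses T_xx, T_yy at cells --------------------
    # T_xx(c)/dx = th mu / dx^2 [4/3 (ue - uw) - 2/3 (vn - vs)]
    w <- th * mup / dx^2
    scat <- function(rows, sgn, sel) {
      # scatter T_xx of cells sel to rows (their east/west face rows)
      add(base + rows, base + ue[sel],  sgn * (4 / 3) * w[sel])
      add(base + rows, base + uw[sel], -sgn * (4 / 3) * w[sel])
      add(base + rows, base + vn[sel], -sgn * (2 / 3) * w[sel])
      add(base + rows, base + vs[sel],  sgn * (2 / 3) * w[sel])
    }
    scat(uw[west_int], +1, west_int)    # cell is east neighbor of its west face
    scat(ue[east_int], -1, east_int)
    scaty <- function(rows, sgn, sel) {
      add(base + rows, base + vn[sel],  sgn * (4 / 3) * w[sel])
      add(base + rows, base + vs[sel], -sgn * (4 / 3) * w[sel])
      add(base + rows, base + ue[sel], -sgn * (2 / 3) * w[sel])
      add(base + rows, base + uw[sel],  sgn * (2 / 3) * w[sel])
    }
    scaty(vs[south_int], +1, south_int)
    scaty(vn[north_int], -1, north_int)

    # ---- shear stress T_xy at full corners ------------------------------
    if (length(cor_i) > 0) {
      thcor <- (thm[cbind(cor_i, cor_j)] + thm[cbind(cor_i + 1L, cor_j)] +
                thm[cbind(cor_i, cor_j + 1L)] +
                thm[cbind(cor_i + 1L, cor_j + 1L)]) / 4
      wc <- thcor * mup / dx^2
      cols <- list(cu_above, cu_below, cv_east, cv_west)
      sgns <- c(+1, -1, +1, -1)
      scatc <- function(rows, sgn, sel) {
        for (k in 1:4)
          add(base + rows, base + cols[[k]][sel], sgn * sgns[k] * wc[sel])
      }
      selb <- fx_is_int[cfx_below]      # corner feeds the face below (+)
      scatc(cfx_below[selb], +1, selb)
      sela <- fx_is_int[cfx_above]
      scatc(cfx_above[sela], -1, sela)
      selw <- fx_is_int[cfy_west]       # and the y-faces west (+) / east (-)
      scatc(cfy_west[selw], +1, selw)
      sele <- fx_is_int[cfy_east]
      scatc(cfy_east[sele], -1, sele)
    }

    # ---- pressure gradient and Sigma forcing on interior faces ----------
    thfx <- (th[fx$L] + th[fx$R]) / 2
    if (has_pint[[ph]]) {
      add(base + seq_len(nxi), pix(fx$R), -thfx / dx)
      add(base + seq_len(nxi), pix(fx$L),  thfx / dx)
    }
    if (cellular[p])
      rhs[base + seq_len(nxi)] <- rhs[base + seq_len(nxi)] +
        thfx * (sigma[fx$R] - sigma[fx$L]) / dx
    thfy <- (th[fy$L] + th[fy$R]) / 2
    yoff <- nxi + nxb
    if (has_pint[[ph]]) {
      add(base + yoff + seq_len(nyi), pix(fy$R), -thfy / dx)
      add(base + yoff + seq_len(nyi), pix(fy$L),  thfy / dx)
    }
    if (cellular[p])
      rhs[base + yoff + seq_len(nyi)] <- rhs[base + yoff + seq_len(nyi)] +
        thfy * (sigma[fy$R] - sigma[fy$L]) / dx

    # ---- drag on interior faces ----------------------------------------
    for (q in act_idx) {
      if (q == p) next
      dpq <- dmat[p, q]
      if (dpq == 0) next
      thq <- thf[[tp_phases[q]]]
      wx <- dpq * thfx * (thq[fx$L] + thq[fx$R]) / 2
      add(base + seq_len(nxi), uix(q, seq_len(nxi)),  wx)
      add(base + seq_len(nxi), base + seq_len(nxi),  -wx)
      wy <- dpq * thfy * (thq[fy$L] + thq[fy$R]) / 2
      add(base + yoff + seq_len(nyi), uix(q, yoff + seq_len(nyi)),  wy)
      add(base + yoff + seq_len(nyi), base + yoff + seq_len(nyi),  -wy)
    }

    # ---- boundary rows ---------------------------------------------------
    bslotx <- nxi + seq_len(nxb)
    bsloty <- nxi + nxb + nyi + seq_len(nyb)
    if (ph == "int") {
      add(base + bslotx, base + bslotx, rep(1, nxb))
      add(base + bsloty, base + bsloty, rep(1, nyb))
    } else {
      # sigma_xx(owner) = 0 (x-boundary) / sigma_yy(owner) = 0 (y-boundary)
      ox <- fx$b_owner
      add(base + bslotx, base + ue[ox],  (4 / 3) * mup / dx)
      add(base + bslotx, base + uw[ox], -(4 / 3) * mup / dx)
      add(base + bslotx, base + vn[ox], -(2 / 3) * mup / dx)
      add(base + bslotx, base + vs[ox],  (2 / 3) * mup / dx)
      if (has_pint[[ph]]) add(base + bslotx, pix(ox), rep(-1, nxb))
      if (cellular[p]) rhs[base + bslotx] <- rhs[base + bslotx] + sigma[ox]
      oy <- fy$b_owner
      add(base + bsloty, base + vn[oy],  (4 / 3) * mup / dx)
      add(base + bsloty, base + vs[oy], -(4 / 3) * mup / dx)
      add(base + bsloty, base + ue[oy], -(2 / 3) * mup / dx)
      add(base + bsloty, base + uw[oy],  (2 / 3) * mup / dx)
      if (has_pint[[ph]]) add(base + bsloty, pix(oy), rep(-1, nyb))
      if (cellular[p]) rhs[base + bsloty] <- rhs[base + bsloty] + sigma[oy]
    }
  }

  # ---- mixture continuity (unfloored concentrations) ---------------------
  for (p in act_idx) {
    th <- phases[[tp_phases[p]]]
    # face concentration = mean over adjacent mask cells (owner value at
    # boundary faces)
    face_th <- function(sel_int, nb) ifelse(sel_int, (th + th[nb]) / 2, th)
    nb_e <- id[cbind(pmin(ci + 1L, m), cj)]; nb_e[nb_e == 0] <- 1L
    nb_w <- id[cbind(pmax(ci - 1L, 1L), cj)]; nb_w[nb_w == 0] <- 1L
    nb_n <- id[cbind(ci, pmin(cj + 1L, m))]; nb_n[nb_n == 0] <- 1L
    nb_s <- id[cbind(ci, pmax(cj - 1L, 1L))]; nb_s[nb_s == 0] <- 1L
    the <- face_th(east_int, nb_e);  thw <- face_th(west_int, nb_w)
    thn <- face_th(north_int, nb_n); ths <- face_th(south_int, nb_s)
    cells <- seq_len(nc)
    add(pix(cells), uix(p, ue),  the / dx)
    add(pix(cells), uix(p, uw), -thw / dx)
    add(pix(cells), uix(p, vn),  thn / dx)
    add(pix(cells), uix(p, vs), -ths / dx)
  }
  rhs[pix(seq_len(nc))] <- continuity_rhs

  tr <- do.call(rbind, trips[seq_len(ntrip)])
  keep <- tr[, 3] != 0
  M <- Matrix::sparseMatrix(i = tr[keep, 1], j = tr[keep, 2],
                            x = tr[keep, 3], dims = c(nun, nun))
  sol <- tryCatch(as.numeric(Matrix::solve(M, rhs)),
                  error = function(e)
                    stop("2D flow solve failed (singular system): ",
                         conditionMessage(e)))
  resid <- max(abs(M %*% sol - rhs))

  u <- stats::setNames(vector("list", 7L), tp_phases)
  for (p in seq_along(tp_phases)) {
    if (!active[p]) {
      u[[tp_phases[p]]] <- list(x = rep(0, nxi), bx = rep(0, nxb),
                                y = rep(0, nyi), by = rep(0, nyb))
      next
    }
    base <- blk[p] * nf
    u[[tp_phases[p]]] <- list(
      x = sol[base + seq_len(nxi)],
      bx = fx$b_normal * sol[base + nxi + seq_len(nxb)],
      y = sol[base + nxi + nxb + seq_len(nyi)],
      by = fy$b_normal * sol[base + nxi + nxb + nyi + seq_len(nyb)])
  }
  p_int <- sol[pix(seq_len(nc))]
  pc <- cell_pressure(phases,
                      p_h = p_int + sigma, p_c = p_int + sigma,
                      p_M1 = p_int + sigma, p_M1p = p_int + sigma,
                      p_M2 = p_int + sigma)
  structure(list(u = u, p_int = p_int, sigma = sigma, p_cell = pc,
                 residual = resid), class = "tp_flow")
}
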