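# Model constants, therapy schedule, scenario description, config loading.
#
# Everything is dimensionless: the time unit is the healthy-cell doubling
# time (~1 day) and the length unit is 400 um.  Defaults are the published
# dimensionless rates of the base model and its immunotherapy extension.

#' Phase names used throughout the package
#'
#' Order is fixed: healthy cells, cancer cells, vasculature, unbound
#' pro-inflammatory macrophages, drug-bound pro-inflammatory macrophages,
#' pro-tumor macrophages, interstitial fluid.
#' @export
tp_phases <- c("h", "c", "v", "M1", "M1p", "M2", "int")

#' Chemical species names
#'
#' Oxygen, VEGF, CSF-1, CXCL12, EGF, TGF-beta, and the TGF-beta-receptor
#' inhibitor (drug).
#' @export
tp_chemicals <- c("c", "g", "a", "b", "l", "f", "d")

# cellular phases entering the pressure closure and the cell pressure
tp_cellular <- c("h", "c", "M1", "M1p", "M2")

#' Dimensionless model parameters
#'
#' Constructs the full parameter set of the multiphase tumor model with
#' published defaults.  Any subset of fields may be overridden by name.
#' Two defaults are derived unless given explicitly: `k_cm_c = k_cm_h *
#' k_m_c` (cancer cells consume oxygen for mitosis in proportion to their
#' faster division rate) and `chi_b = 5 * chi_a` (CXCL12 chemotaxis is five
#' times stronger than CSF-1 chemotaxis).
#'
#' @param ... named overrides of individual parameters.
#' @return an object of class `tp_params`: a named list of numeric values
#'   plus `mu` (named length-7 viscosity vector) and `d_drag` (7x7 symmetric
#'   drag-coefficient matrix, zero diagonal).
#' @examples
#' p <- model_parameters()
#' p$k_m_c            # 2.0
#' model_parameters(k_aa = 2.5)$k_aa
#' @export
model_parameters <- function(...) {
  defaults <- list(
    # proliferation / death (healthy-cell proliferation rate is the time unit)
    k_m_h = 1.0, k_m_c = 2.0, k_d_h = 0.15, k_d_c = 0.075,
    # oxygen response constants
    c_p = 0.25, c_c1 = 0.2, c_c2 = 0.1, c_a = 0.05,
    # oxygen consumption
    k_c_h = 0.01, k_c_c = 0.01, k_cm_h = 0.1, k_cm_c = NA_real_,
    # vascular occlusion and angiogenesis
    k_occ = 0.1, p_crit = 0.3, eps = 0.01, h_smooth = 0.2, k_ang = 4.87e-3,
    # mechanics
    Lambda = 0.1, theta_star = 0.6,
    # diffusion coefficients
    D_c = 1.0, D_g = 0.05, D_a = 0.11, D_b = 0.001, D_l = 0.11, D_f = 0.5,
    # cytokine production / decay / receptor binding
    k_p_g = 0.00959, k_d_g = 0.0264,    k_assoc_g = 6.57e-6,
    k_p_a = 0.00959, k_d_a = 0.0216,    k_assoc_a = 8.75e-6,
    k_p_b = 0.54806, k_d_b = 2.273e-3,  k_assoc_b = 7e-6,
    k_p_l = 0.00959, k_d_l = 0.0216,    k_assoc_l = 6.93e-6,
    k_p_f = 0.00959, k_d_f = 0.436,     k_assoc_f = 7e-6,
    # macrophage constants
    theta_M = 0.1, k_c_M1 = 0.2, k_c_M2 = 5.0,
    k_d_M1 = 0.075, k_d_M2 = 0.075, k_aa = 0.5, k_ext_M1 = 2.0,
    a_p = 0.25, f_p = 0.015,
    # chemotaxis strengths
    chi_g = 0.14, chi_a = 0.14, chi_l = 0.14, chi_b = NA_real_,
    # oxygen supply (both equal to 1 in dimensionless form)
    c_v_ref = 1.0, k_rep = 1.0,
    # viscosity (scalar recycled over phases) and drag (scalar for all pairs)
    mu = 10.0, d_drag = 1.0
  )
  ov <- list(...)
  if (length(ov) > 0 && (is.null(names(ov)) || any(names(ov) == "")))
    stop("all parameter overrides must be named")
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown) > 0)
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p <- utils::modifyList(defaults, ov)
  # everything numeric is stored as double (serialization round-trips)
  for (nm in setdiff(names(p), c("mu", "d_drag")))
    p[[nm]] <- as.numeric(p[[nm]])
  storage.mode(p$mu) <- "double"

  # derived defaults
  if (is.na(p$k_cm_c)) p$k_cm_c <- p$k_cm_h * p$k_m_c
  if (is.na(p$chi_b))  p$chi_b  <- 5 * p$chi_a

  # expand viscosity and drag to their per-phase forms
  if (length(p$mu) == 1) p$mu <- stats::setNames(rep(p$mu, 7L), tp_phases)
  if (is.null(names(p$mu)) && length(p$mu) == 7L) names(p$mu) <- tp_phases
  if (!identical(sort(names(p$mu)), sort(tp_phases)))
    stop("mu must be a scalar or a named length-7 vector over the phases")
  p$mu <- p$mu[tp_phases]
  if (length(p$d_drag) == 1) {
    m <- matrix(p$d_drag, 7, 7, dimnames = list(tp_phases, tp_phases))
    diag(m) <- 0
    p$d_drag <- m
  } else {
    p$d_drag <- as.matrix(p$d_drag)
    if (!all(dim(p$d_drag) == c(7, 7)))
      stop("d_drag must be a scalar or a 7x7 matrix")
    dimnames(p$d_drag) <- list(tp_phases, tp_phases)
  }
  class(p) <- "tp_params"
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks positivity/sign constraints: every rate and diffusivity is
#' nonnegative, `c_c1 > c_c2`, `k_m_c > k_m_h`, `k_d_c < k_d_h`,
#' `h_smooth > 0`, and the drag matrix is symmetric and nonnegative.
#'
#' @param p a `tp_params` object.
#' @return `p`, invisibly; signals an error naming the violated constraint.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "tp_params"))
  scal <- setdiff(names(p), c("mu", "d_drag"))
  vals <- unlist(p[scal])
  if (any(!is.finite(vals)))
    stop("non-finite parameter(s): ",
         paste(scal[!is.finite(vals)], collapse = ", "))
  nonneg <- setdiff(scal, "p_crit")  # p_crit is a pressure threshold, >= 0 too
  bad <- nonneg[unlist(p[nonneg]) < 0]
  if (length(bad) > 0)
    stop("parameter(s) must be nonnegative: ", paste(bad, collapse = ", "))
  if (!(p$c_c1 > p$c_c2)) stop("invariant violated: c_c1 > c_c2")
  if (!(p$k_m_c > p$k_m_h)) stop("invariant violated: k_m_c > k_m_h")
  if (!(p$k_d_c < p$k_d_h)) stop("invariant violated: k_d_c < k_d_h")
  if (!(p$h_smooth > 0)) stop("invariant violated: h_smooth > 0")
  if (any(p$mu < 0)) stop("invariant violated: mu >= 0")
  if (any(p$d_drag < 0) || !isTRUE(all.equal(p$d_drag, t(p$d_drag))))
    stop("invariant violated: d_drag symmetric and nonnegative")
  invisible(p)
}

#' Immunotherapy parameters and dosing schedule
#'
#' Parameters of the TGF-beta-receptor-inhibitor extension: the drug-bound
#' macrophage compartment, the drug reaction-diffusion field, and the pulsed
#' oral dosing schedule (`N_pills` doses, one every `T_pill` time units from
#' `t0_pill`, each raising the vascular drug concentration to `d_max` with
#' exponential elimination at rate `k_el_d` between doses).
#'
#' @param enabled logical; when `FALSE` the drug field is identically zero
#'   and the drug-bound compartment stays empty.
#' @param ... named overrides of therapy constants.
#' @return an object of class `tp_therapy`.
#' @export
therapy_parameters <- function(enabled = FALSE, ...) {
  defaults <- list(
    enabled = FALSE,
    k_d_M1p = 0.075,     # equals the unbound-M1 death rate
    D_d = 0.231, d_p = 3e-3,
    k_rep_d = 0.25, k_d_d = 0.016, k_assoc_d = 0.016,
    k_assoc_M1 = 2.0, k_el_d = 4.8,
    d_max = 1.0, T_pill = 0.5, t0_pill = 100, N_pills = 10L
  )
  ov <- c(list(enabled = enabled), list(...))
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown) > 0)
    stop("unknown therapy parameter(s): ", paste(unknown, collapse = ", "))
  th <- utils::modifyList(defaults, ov)
  th$enabled <- isTRUE(th$enabled)
  for (nm in setdiff(names(th), c("enabled", "N_pills")))
    th[[nm]] <- as.numeric(th[[nm]])
  if (th$N_pills == round(th$N_pills)) th$N_pills <- as.integer(th$N_pills)
  class(th) <- "tp_therapy"
  validate_therapy(th)
  th
}

#' @rdname therapy_parameters
#' @param th a `tp_therapy` object.
#' @export
validate_therapy <- function(th) {
  stopifnot(inherits(th, "tp_therapy"))
  num <- unlist(th[setdiff(names(th), "enabled")])
  if (any(!is.finite(num)) || any(num < 0))
    stop("therapy parameters must be finite and nonnegative")
  if (!(th$T_pill > 0)) stop("invariant violated: T_pill > 0")
  if (th$N_pills < 0 || th$N_pills != round(th$N_pills))
    stop("invariant violated: N_pills is a nonnegative integer")
  invisible(th)
}

#' Scenario description
#'
#' Bundles everything that defines one simulation: macrophage mode, tumor
#' seed placement, domain geometry, end time, stepping controls, therapy,
#' output cadence, and ad-hoc parameter overrides.
#'
#' @param macrophage_mode one of `"both"` (full model), `"m1_only"`
#'   (alternative activation switched off, `k_aa = 0`), `"inert"`
#'   (macrophages occupy space and polarize but neither kill nor boost,
#'   `k_c_M1 = k_c_M2 = 0`), `"none"` (no extravasation, `k_ext_M1 = 0`).
#' @param seeds list of [seed_spec()] objects (empty for a cancer-free run).
#' @param domain geometry spec passed to [make_domain()]: a list with
#'   `mode` (`"radial_1d"` or `"cartesian_2d"`), `R`, and `n_cells` (1D) or
#'   `dx` (2D).
#' @param t_end dimensionless end time.
#' @param dt_max,cfl stepping controls for the explicit transport update.
#' @param therapy a [therapy_parameters()] object.
#' @param output_every cadence (time units) of observable records.
#' @param param_overrides named list applied on top of [model_parameters()].
#' @return an object of class `tp_scenario`.
#' @export
scenario <- function(macrophage_mode = c("both", "m1_only", "inert", "none"),
                     seeds = list(seed_spec()),
                     domain = list(mode = "radial_1d", R = 30, n_cells = 300),
                     t_end = 10, dt_max = 0.1, cfl = 0.4,
                     therapy = therapy_parameters(),
                     output_every = 1,
                     param_overrides = list()) {
  macrophage_mode <- match.arg(macrophage_mode)
  stopifnot(is.list(seeds), is.list(domain))
  if (!(t_end > 0)) stop("invariant violated: t_end > 0")
  if (!(dt_max > 0) || !(cfl > 0) || cfl > 1)
    stop("dt_max must be positive and cfl in (0, 1]")
  validate_therapy(therapy)
  R <- domain$R
  for (s in seeds) {
    stopifnot(inherits(s, "tp_seed"))
    if (sqrt(sum(s$center^2)) + s$radius > R)
      stop("seed at (", paste(s$center, collapse = ", "),
           ") does not lie inside the domain")
  }
  sc <- list(macrophage_mode = macrophage_mode, seeds = seeds,
             domain = domain, t_end = t_end, dt_max = dt_max, cfl = cfl,
             therapy = therapy, output_every = output_every,
             param_overrides = param_overrides)
  class(sc) <- "tp_scenario"
  sc
}

#' Apply scenario mode to the base parameters
#'
#' The macrophage-mode variants of the model are parameter restrictions:
#' `m1_only` forces `k_aa = 0` so alternative activation cannot occur;
#' `inert` forces `k_c_M1 = k_c_M2 = 0` so macrophages neither kill cancer
#' cells nor boost their proliferation; `none` forces `k_ext_M1 = 0` so no
#' macrophages enter the tissue.  Scenario `param_overrides` are applied
#' first, then the mode restriction.
#'
#' @param params a `tp_params` object.
#' @param scen a `tp_scenario` object.
#' @return a `tp_params` object with the effective rates.
#' @export
effective_parameters <- function(params, scen) {
  stopifnot(inherits(params, "tp_params"), inherits(scen, "tp_scenario"))
  if (length(scen$param_overrides) > 0) {
    args <- utils::modifyList(params_as_list(params), scen$param_overrides)
    params <- do.call(model_parameters, args)
  }
  mode_ov <- switch(scen$macrophage_mode,
    both    = list(),
    m1_only = list(k_aa = 0),
    inert   = list(k_c_M1 = 0, k_c_M2 = 0),
    none    = list(k_ext_M1 = 0))
  if (length(mode_ov) > 0) {
    args <- utils::modifyList(params_as_list(params), mode_ov)
    params <- do.call(model_parameters, args)
  }
  params
}

# plain-list view of a tp_params suitable for re-construction; collapses the
# expanded mu / d_drag back to scalars when they are uniform
params_as_list <- function(p) {
  out <- unclass(p)
  if (length(unique(out$mu)) == 1) out$mu <- unname(out$mu[1])
  off <- out$d_drag[upper.tri(out$d_drag)]
  if (length(unique(off)) == 1 && all(diag(out$d_drag) == 0))
    out$d_drag <- off[1]
  out
}

#' Serialize / deserialize parameters
#'
#' `params_serialize()` renders a parameter or therapy object as a JSON
#' string; `params_deserialize()` reconstructs it.  Round-tripping
#' reproduces every field exactly (full double precision is retained).
#'
#' @param p a `tp_params` or `tp_therapy` object.
#' @return a JSON string, or the reconstructed object.
#' @export
params_serialize <- function(p) {
  if (inherits(p, "tp_params")) {
    jsonlite::toJSON(c(list(.class = "tp_params"), params_as_list(p)),
                     auto_unbox = TRUE, digits = I(17))
  } else if (inherits(p, "tp_therapy")) {
    jsonlite::toJSON(c(list(.class = "tp_therapy"), unclass(p)),
                     auto_unbox = TRUE, digits = I(17))
  } else stop("cannot serialize object of class ", class(p)[1])
}

#' @rdname params_serialize
#' @param text JSON produced by `params_serialize()`.
#' @export
params_deserialize <- function(text) {
  x <- jsonlite::fromJSON(text, simplifyVector = TRUE)
  cls <- x$.class
  x$.class <- NULL
  if (identical(cls, "tp_params")) {
    if (is.list(x$d_drag) || is.data.frame(x$d_drag))
      x$d_drag <- as.matrix(as.data.frame(x$d_drag))
    do.call(model_parameters, x)
  } else if (identical(cls, "tp_therapy")) {
    do.call(therapy_parameters, x)
  } else stop("unrecognized serialized object")
}

#' Load a configuration document
#'
#' Reads a YAML or JSON configuration (a file path or literal text) and
#' returns the model parameters and scenario with defaults filled in.
#' Recognized top-level keys: `parameters` (named overrides of
#' [model_parameters()] fields), `therapy` (overrides of
#' [therapy_parameters()] fields, including `enabled`), and `scenario`
#' (`macrophage_mode`, `seeds` -- each a list with `center`, `radius`,
#' `amplitude` -- `domain`, `t_end`, `dt_max`, `cfl`, `output_every`).
#' Unknown keys at any level are rejected with an error naming the key.
#'
#' @param path_or_text path to a config file, or the document itself.
#' @return `list(params = <tp_params>, scenario = <tp_scenario>)`.
#' @examples
#' cfg <- load_config("parameters: {k_aa: 2.5}")
#' cfg$params$k_aa
#' @export
load_config <- function(path_or_text) {
  txt <- if (length(path_or_text) == 1 && file.exists(path_or_text)) {
    paste(readLines(path_or_text, warn = FALSE), collapse = "\n")
  } else paste(path_or_text, collapse = "\n")
  doc <- if (grepl("^\\s*\\{", txt)) {
    jsonlite::fromJSON(txt, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  } else yaml::yaml.load(txt)
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) stop("configuration must be a mapping")
  unknown <- setdiff(names(doc), c("parameters", "therapy", "scenario"))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))

  params <- do.call(model_parameters, as.list(doc$parameters))
  therapy <- do.call(therapy_parameters, as.list(doc$therapy))

  sc <- as.list(doc$scenario)
  known_sc <- c("macrophage_mode", "seeds", "domain", "t_end", "dt_max",
                "cfl", "output_every")
  unknown <- setdiff(names(sc), known_sc)
  if (length(unknown) > 0)
    stop("unknown scenario key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(sc$seeds))
    sc$seeds <- lapply(sc$seeds, function(s) do.call(seed_spec, as.list(s)))
  sc$therapy <- therapy
  sc$param_overrides <- as.list(doc$parameters)
  scen <- do.call(scenario, sc)
  list(params = params, scenario = scen)
}
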