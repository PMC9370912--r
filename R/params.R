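#' Pacemaker oscillator parameters
#'
#' Parameters of one modified Van der Pol pacemaker oscillator (SA node, AV
#' node, or His-Purkinje system) in the heterogeneous conduction-system model.
#' The oscillator obeys
#' \deqn{\dot x = y, \quad
#'       \dot y = -a (x^2 - u)\, y - f\, x (x + d)(x + e)
#'                + K \,(y_{up}(t - \tau) - y),}
#' where \eqn{y_{up}} is the velocity variable of the upstream pacemaker in the
#' SA \eqn{\to} AV \eqn{\to} HP cascade (the SA node is autonomous and takes
#' `K = 0`).
#'
#' @param a Damping coefficient (dimensionless).
#' @param u Nonlinearity offset; `a * u` sets the self-excitation rate near the
#'   rest state.
#' @param f Cubic-term strength.
#' @param d,e Root offsets of the restoring cubic `x (x + d)(x + e)`.
#' @param K Coupling constant to the upstream pacemaker (0 = uncoupled).
#' @param tau Coupling time delay, in model time units; must be non-negative.
#'
#' @return A `pacemaker_params` list.
#' @seealso [het_params()]
#' @export
pacemaker_params <- function(a, u, f, d, e, K = 0, tau = 0) {
  p <- list(a = a, u = u, f = f, d = d, e = e, K = K, tau = tau)
  check_finite(unlist(p), "pacemaker parameters")
  if (tau < 0) abort("`tau` must be >= 0")
  structure(p, class = "pacemaker_params")
}

#' Cardiac muscle (FitzHugh-Nagumo) parameters
#'
#' Parameters of one modified FitzHugh-Nagumo excitable unit describing the
#' electrical response of atrial or ventricular muscle (one of the P, Ta, QRS,
#' or T waveform channels):
#' \deqn{\dot z = k \left(-c\, z (z - w_1)(z - w_2) - b v - g v z + I\right),
#'       \quad \dot v = k h (z - v),}
#' with stimulation current \eqn{I = C \, Y \, H(Y)} gated by the unit step
#' \eqn{H} (with the convention \eqn{H(0) = 0}), where \eqn{Y} is the driving
#' pacemaker velocity (\eqn{y_{SA}} or \eqn{-y_{SA}} for the atrial channels,
#' \eqn{y_{HP}} or \eqn{-y_{HP}} for the ventricular ones).
#'
#' @param k Rate scale.
#' @param c Excitability.
#' @param w1,w2 Roots of the action-potential cubic.
#' @param b Recovery coupling.
#' @param g Cross-term strength.
#' @param h Recovery rate.
#' @param C Stimulation coupling coefficient.
#'
#' @return A `muscle_params` list.
#' @seealso [het_params()]
#' @export
muscle_params <- function(k, c, w1, w2, b, g, h, C) {
  p <- list(k = k, c = c, w1 = w1, w2 = w2, b = b, g = g, h = h, C = C)
  check_finite(unlist(p), "muscle parameters")
  structure(p, class = "muscle_params")
}

#' Heterogeneous conduction-system model parameters
#'
#' Assembles the full parameter set of the heterogeneous-oscillator model:
#' three pacemakers (SA, AV, HP) modeled as modified Van der Pol oscillators in
#' a delayed unidirectional cascade, and four muscle channels (P wave, Ta wave,
#' QRS complex, T wave) modeled as modified FitzHugh-Nagumo units. The surface
#' ECG on a given lead channel is the linear composition
#' \deqn{ECG(t) = z_0 + \alpha_1 z_1 - \alpha_2 z_2 + \alpha_3 z_3 + \alpha_4 z_4}
#' with per-channel weights \eqn{\alpha_1..\alpha_4} (see
#' [compose_ecg_heterogeneous()]).
#'
#' @param pacemakers Named list of three [pacemaker_params()]: `SA`, `AV`, `HP`.
#'   `AV$K`/`AV$tau` couple AV to SA; `HP$K`/`HP$tau` couple HP to AV.
#' @param muscles Named list of four [muscle_params()]: `P`, `Ta`, `QRS`, `T`.
#' @param z0 Baseline value added to every composed channel (may be overridden
#'   per lead in `lead_weights`).
#' @param lead_weights Data frame with columns `channel`, `a1`..`a4`, `z0`: one
#'   row per composable lead channel. The default table (see
#'   [default_lead_weights()]) is a synthetic stand-in for clinically fitted
#'   per-lead weights and produces canonical lead-II morphology on channel
#'   `"II"`.
#'
#' @return A `heterogeneous_params` list.
#' @export
het_params <- function(pacemakers, muscles, z0 = 0.2,
                       lead_weights = default_lead_weights(z0)) {
  stopifnot(is.list(pacemakers), is.list(muscles))
  if (!identical(sort(names(pacemakers)), sort(c("SA", "AV", "HP")))) {
    abort("`pacemakers` must be a named list with elements SA, AV, HP")
  }
  if (!identical(sort(names(muscles)), sort(c("P", "Ta", "QRS", "T")))) {
    abort("`muscles` must be a named list with elements P, Ta, QRS, T")
  }
  lead_weights <- as_tibble(lead_weights)
  needed <- c("channel", "a1", "a2", "a3", "a4", "z0")
  if (!all(needed %in% names(lead_weights))) {
    abort("`lead_weights` needs columns channel, a1..a4, z0")
  }
  p <- structure(
    list(
      pacemakers = pacemakers[c("SA", "AV", "HP")],
      muscles = muscles[c("P", "Ta", "QRS", "T")],
      z0 = z0,
      lead_weights = lead_weights
    ),
    class = c("heterogeneous_params", "ecg_params")
  )
  stop_on_problems(validate_params("heterogeneous", p))
  p
}

#' Synthetic per-lead composition weights for the heterogeneous model
#'
#' The clinically fitted per-lead weighting coefficients for the
#' heterogeneous-oscillator model are not part of this package; this table is a
#' synthetic replacement chosen so that channel `"II"` carries the canonical
#' lead-II morphology (upright P, dominant R, upright T) and `V1`-`V6` follow
#' the textbook precordial R-wave progression (negative-dominant QRS in V1,
#' transition around V3/V4). Users with fitted weights should supply their own
#' table to [het_params()].
#'
#' @param z0 Baseline value used for every row.
#' @return A tibble with columns `channel`, `a1`..`a4`, `z0`.
#' @export
default_lead_weights <- function(z0 = 0.2) {
  tibble::tribble(
    ~channel,   ~a1,   ~a2,   ~a3,  ~a4,
    "I",       0.06,  0.03,  0.60, 0.18,
    "II",      0.10,  0.05,  1.00, 0.30,
    "V1",      0.04,  0.02, -0.60, -0.10,
    "V2",      0.05,  0.02, -0.40, 0.05,
    "V3",      0.06,  0.03,  0.20, 0.15,
    "V4",      0.08,  0.04,  0.70, 0.25,
    "V5",      0.09,  0.04,  0.90, 0.30,
    "V6",      0.09,  0.04,  0.80, 0.28
  ) %>% mutate(z0 = z0)
}

#' Discretized reaction-diffusion (BVAM) model parameters
#'
#' Parameters of the four-variable network obtained by spatial discretization
#' of the BVAM reaction-diffusion system:
#' \deqn{\dot x_1 = x_1 - x_2 - C x_1 x_2 - x_1 x_2^2}
#' \deqn{\dot x_2 = H x_1 - 3 x_2 + C x_1 x_2 + x_1 x_2^2 + \beta (x_4 - x_2)}
#' \deqn{\dot x_3 = x_3 - x_4 - C x_3 x_4 - x_3 x_4^2}
#' \deqn{\dot x_4 = H x_3 - 3 x_4 + C x_3 x_4 + x_3 x_4^2 + 2\beta (x_2 - x_4)}
#' with ECG read-out \eqn{K_1 x_1 + K_2 x_2 + K_3 x_3 + K_4 x_4}.
#'
#' @param H,C Parameters controlling the network's dynamical behavior.
#' @param beta Local interaction strength between the oscillator pairs.
#' @param K Numeric length-4 mixing weights of the ECG read-out.
#' @param Gamma_t Time-scale factor: the output time axis is the model time
#'   divided by `Gamma_t`, so larger values give faster rhythms.
#'
#' @return A `reaction_diffusion_params` list.
#' @export
rd_params <- function(H, C, beta, K, Gamma_t = 1) {
  p <- structure(
    list(H = H, C = C, beta = beta, K = as.numeric(K), Gamma_t = Gamma_t),
    class = c("reaction_diffusion_params", "ecg_params")
  )
  stop_on_problems(validate_params("reaction_diffusion", p))
  p
}

#' Ring-of-three delay-coupled oscillators parameters
#'
#' Parameters of the ring model: three modified Van der Pol oscillators (SA,
#' AV, HP) coupled through time-delayed position differences, each optionally
#' driven by a sinusoid. For node X with position/velocity \eqn{(x, v)}:
#' \deqn{\dot x = v,\quad
#'   \dot v = -a_X v (x - w_{X1})(x - w_{X2}) + \rho_X \sin(\omega_X t)
#'            - \frac{x (x - d_X)(x - e_X)}{d_X e_X}
#'            - \sum_Y k_{X\!-\!Y} (x - x_Y(t - \tau_{X\!-\!Y})).}
#' The restoring cubic is normalized by \eqn{d_X e_X} so the small-amplitude
#' natural frequency is about 1 rad per model time unit, as in the oscillator
#' family this model derives from. Drive frequencies `omega` are taken to be
#' expressed in the un-normalized time base (natural frequency
#' \eqn{\sqrt{|d_X e_X|}}) and are converted by that factor inside the
#' derivative, so the drive-to-natural frequency ratio of a parameter set is
#' preserved.
#' The ECG read-out is \eqn{(\alpha_0 + \alpha_1 x_1 + \alpha_3 x_3 +
#' \alpha_5 x_5)\,\beta_G}.
#'
#' @param nodes Named list (`SA`, `AV`, `HP`), each a list with fields `a`,
#'   `w1`, `w2`, `d`, `e`, `rho`, `omega`.
#' @param k Named numeric of the six directed coupling constants:
#'   `SA_AV`, `SA_HP`, `AV_SA`, `AV_HP`, `HP_SA`, `HP_AV` (coupling `X_Y`
#'   enters node X's velocity equation with the delayed position of node Y).
#' @param tau Named numeric of the six matching transport delays (>= 0).
#' @param alpha Numeric length-4 composition weights
#'   \eqn{(\alpha_0, \alpha_1, \alpha_3, \alpha_5)}.
#' @param beta_G Output scaling factor (nonzero).
#' @param beta_T Time-scale factor (output time = model time / `beta_T`).
#'
#' @return A `ring_params` list.
#' @export
ring_params <- function(nodes, k, tau, alpha, beta_G, beta_T = 1) {
  p <- structure(
    list(
      nodes = nodes, k = k, tau = tau, alpha = as.numeric(alpha),
      beta_G = beta_G, beta_T = beta_T
    ),
    class = c("ring_params", "ecg_params")
  )
  stop_on_problems(validate_params("ring", p))
  p
}

ring_coupling_names <- function() {
  c("SA_AV", "SA_HP", "AV_SA", "AV_HP", "HP_SA", "HP_AV")
}

#' Gaussian kernel of the quasi-periodic model
#'
#' One push-pull event on the limit cycle: amplitude `a`, angular width `b`
#' (radians, strictly positive) and angular position `theta` in
#' \eqn{[-\pi, \pi]}. Angles may be given as strings in multiples of pi (e.g.
#' `"-pi/12"`, `"3*pi/8"`), which are parsed exactly.
#'
#' @param a Amplitude (sign sets push vs pull).
#' @param b Width in radians; must be positive.
#' @param theta Angular position in radians, or a string like `"pi/12"`.
#' @return A `gaussian_kernel` list.
#' @export
gaussian_kernel <- function(a, b, theta) {
  theta <- parse_angle(theta)
  check_finite(c(a, b, theta), "kernel parameters")
  if (b <= 0) abort("kernel width must be positive")
  if (theta < -pi || theta > pi) abort("`theta` must lie in [-pi, pi]")
  structure(list(a = a, b = b, theta = theta), class = "gaussian_kernel")
}

qp_kernel_names <- function() c("Pminus", "Pplus", "Q", "R", "S", "Tminus", "Tplus")

#' Quasi-periodic Gaussian-kernel model parameters
#'
#' Parameters of the quasi-periodic ECG model: a planar limit-cycle oscillator
#' \eqn{(x, y)} rotating at angular frequency \eqn{\omega}, and three waveform
#' channels \eqn{P}, \eqn{C} (QRS) and \eqn{T}, each pushed and pulled by
#' Gaussian kernels as the trajectory angle passes their angular positions:
#' \deqn{\dot P = -\sum_{i \in \{P^-, P^+\}} a_i \Delta\theta_i
#'   e^{-\Delta\theta_i^2 / (2 b_i^2)} - (P - P_0),}
#' and analogously for \eqn{C} (kernels Q, R, S) and \eqn{T} (kernels
#' \eqn{T^-}, \eqn{T^+}); \eqn{\Delta\theta_i} is the angle difference wrapped
#' to \eqn{[-\pi, \pi)}. The common baseline \eqn{P_0 = C_0 = T_0 =
#' A \sin(2\pi f_r t)} couples the channels to respiration. The synthetic ECG
#' is \eqn{P + C + T}.
#'
#' @param kernels Named list of seven [gaussian_kernel()] entries:
#'   `Pminus`, `Pplus`, `Q`, `R`, `S`, `Tminus`, `Tplus`.
#' @param hr Heart rate in beats per minute; sets the constant angular
#'   frequency \eqn{\omega = 2\pi \cdot hr / 60}. Ignored when `tachogram` is
#'   supplied.
#' @param A Baseline (respiratory) wander amplitude, model units.
#' @param fr Respiratory frequency in Hz (>= 0).
#' @param tachogram Optional [rr_tachogram_spec()] describing a stochastic
#'   beat-to-beat RR-interval series; when present, \eqn{\omega} varies per
#'   beat as \eqn{2\pi / RR_k}.
#' @param a_transform If `TRUE`, kernel amplitudes are re-expressed as
#'   \eqn{a_i b_i^2} before use (the convention of the underlying dynamical
#'   model family); off by default since the shipped tables are calibrated for
#'   direct use.
#'
#' @return A `quasi_periodic_params` list.
#' @export
qp_params <- function(kernels, hr = 60, A = 0.005, fr = 0.25,
                      tachogram = NULL, a_transform = FALSE) {
  if (is.data.frame(kernels)) {
    kernels <- purrr::pmap(
      kernels[c("a", "b", "theta")],
      function(a, b, theta) gaussian_kernel(a, b, theta)
    ) %>% setNames(kernels$wave)
  }
  p <- structure(
    list(
      kernels = kernels, hr = hr, A = A, fr = fr,
      tachogram = tachogram, a_transform = isTRUE(a_transform)
    ),
    class = c("quasi_periodic_params", "ecg_params")
  )
  stop_on_problems(validate_params("quasi_periodic", p))
  p
}

#' Parse an angle written in multiples of pi
#'
#' Parses strings of the form `"0"`, `"pi"`, `"-pi/12"`, `"3*pi/8"`,
#' `"10pi/13"` into radians exactly; numeric input passes through unchanged.
#'
#' @param x Numeric or character scalar (or vector).
#' @return Numeric radians.
#' @export
parse_angle <- function(x) {
  if (is.numeric(x)) return(x)
  vapply(as.character(x), function(s) {
    s0 <- gsub(" ", "", s)
    m <- regmatches(
      s0,
      regexec("^([+-]?)([0-9.]+)?\\*?pi(?:/([0-9.]+))?$", s0)
    )[[1]]
    if (length(m) == 0) {
      v <- suppressWarnings(as.numeric(s0))
      if (is.na(v)) abort(paste0("cannot parse angle: '", s, "'"))
      return(v)
    }
    sign <- if (m[2] == "-") -1 else 1
    num <- if (nzchar(m[3])) as.numeric(m[3]) else 1
    den <- if (length(m) >= 4 && nzchar(m[4])) as.numeric(m[4]) else 1
    sign * num * pi / den
  }, numeric(1), USE.NAMES = FALSE)
}

# ---- validation ------------------------------------------------------------

stop_on_problems <- function(problems) {
  if (length(problems)) {
    abort(paste0(
      "invalid parameter set:\n", paste0("- ", problems, collapse = "\n")
    ))
  }
  invisible(NULL)
}

finite_or <- function(x, msg) {
  if (!is.numeric(x) || length(x) == 0 || !all(is.finite(x))) msg else character(0)
}

#' Validate a model parameter set
#'
#' Checks completeness and the numeric invariants of a parameter set for one of
#' the four models (finiteness, non-negative delays, positive kernel widths).
#' Returns a character vector of problems, empty when valid; used by
#' [validate_preset()] to build structured validation reports.
#'
#' @param model Model identifier.
#' @param params Parameter list (as built by [het_params()], [rd_params()],
#'   [ring_params()], [qp_params()], or an equivalent plain list).
#' @return Character vector of human-readable problems (length 0 when valid).
#' @export
validate_params <- function(model, params) {
  model <- check_model(model)
  problems <- character(0)
  add <- function(p) problems <<- c(problems, p)

  need <- function(x, fields, where) {
    missing <- setdiff(fields, names(x))
    if (length(missing)) {
      add(paste0("missing field(s) in ", where, ": ",
                 paste(missing, collapse = ", ")))
      FALSE
    } else TRUE
  }

  if (model == "heterogeneous") {
    if (need(params, c("pacemakers", "muscles", "z0", "lead_weights"), "params")) {
      for (nm in c("SA", "AV", "HP")) {
        pc <- params$pacemakers[[nm]]
        if (is.null(pc)) { add(paste0("missing pacemaker ", nm)); next }
        if (need(pc, c("a", "u", "f", "d", "e", "K", "tau"), paste0("pacemaker ", nm))) {
          add(finite_or(unlist(pc[c("a", "u", "f", "d", "e", "K", "tau")]),
                        paste0("pacemaker ", nm, ": non-finite value")))
          if (is.finite(pc$tau) && pc$tau < 0) add(paste0("pacemaker ", nm, ": tau must be >= 0"))
        }
      }
      for (nm in c("P", "Ta", "QRS", "T")) {
        mu <- params$muscles[[nm]]
        if (is.null(mu)) { add(paste0("missing muscle ", nm)); next }
        if (need(mu, c("k", "c", "w1", "w2", "b", "g", "h", "C"), paste0("muscle ", nm))) {
          add(finite_or(unlist(mu[c("k", "c", "w1", "w2", "b", "g", "h", "C")]),
                        paste0("muscle ", nm, ": non-finite value")))
        }
      }
      add(finite_or(params$z0, "z0: non-finite"))
      lw <- params$lead_weights
      if (!is.data.frame(lw) ||
          !all(c("channel", "a1", "a2", "a3", "a4", "z0") %in% names(lw))) {
        add("lead_weights must have columns channel, a1..a4, z0")
      } else {
        add(finite_or(unlist(lw[c("a1", "a2", "a3", "a4", "z0")]),
                      "lead_weights: non-finite value"))
        if (anyDuplicated(lw$channel)) add("lead_weights: duplicated channel")
      }
    }
  } else if (model == "reaction_diffusion") {
    if (need(params, c("H", "C", "beta", "K", "Gamma_t"), "params")) {
      add(finite_or(c(params$H, params$C, params$beta, params$Gamma_t),
                    "H, C, beta, Gamma_t must be finite"))
      if (!is.numeric(params$K) || length(params$K) != 4L) {
        add("K must be numeric of length 4 (K1..K4)")
      } else add(finite_or(params$K, "K: non-finite value"))
      if (is.numeric(params$Gamma_t) && is.finite(params$Gamma_t) &&
          params$Gamma_t <= 0) add("Gamma_t must be > 0")
    }
  } else if (model == "ring") {
    if (need(params, c("nodes", "k", "tau", "alpha", "beta_G", "beta_T"), "params")) {
      for (nm in c("SA", "AV", "HP")) {
        nd <- params$nodes[[nm]]
        if (is.null(nd)) { add(paste0("missing node ", nm)); next }
        if (need(nd, c("a", "w1", "w2", "d", "e", "rho", "omega"), paste0("node ", nm))) {
          add(finite_or(unlist(nd[c("a", "w1", "w2", "d", "e", "rho", "omega")]),
                        paste0("node ", nm, ": non-finite value")))
        }
      }
      cn <- ring_coupling_names()
      if (!all(cn %in% names(params$k))) {
        add(paste0("k must name all couplings: ", paste(cn, collapse = ", ")))
      } else add(finite_or(unlist(params$k[cn]), "k: non-finite value"))
      if (!all(cn %in% names(params$tau))) {
        add(paste0("tau must name all couplings: ", paste(cn, collapse = ", ")))
      } else {
        tv <- unlist(params$tau[cn])
        add(finite_or(tv, "tau: non-finite value"))
        if (is.numeric(tv) && all(is.finite(tv)) && any(tv < 0)) {
          add("delays must be >= 0")
        }
      }
      if (!is.numeric(params$alpha) || length(params$alpha) != 4L) {
        add("alpha must be numeric of length 4 (alpha0, alpha1, alpha3, alpha5)")
      } else add(finite_or(params$alpha, "alpha: non-finite value"))
      for (nm in c("SA", "AV", "HP")) {
        nd <- params$nodes[[nm]]
        if (!is.null(nd$d) && !is.null(nd$e) && is.numeric(c(nd$d, nd$e)) &&
            all(is.finite(c(nd$d, nd$e))) && nd$d * nd$e == 0) {
          add(paste0("node ", nm, ": d and e must be nonzero"))
        }
      }
      add(finite_or(c(params$beta_G, params$beta_T), "beta_G, beta_T must be finite"))
      if (is.numeric(params$beta_G) && is.finite(params$beta_G) &&
          params$beta_G == 0) add("beta_G must be nonzero")
      if (is.numeric(params$beta_T) && is.finite(params$beta_T) &&
          params$beta_T <= 0) add("beta_T must be > 0")
    }
  } else if (model == "quasi_periodic") {
    if (need(params, c("kernels", "hr", "A", "fr"), "params")) {
      kn <- qp_kernel_names()
      missing <- setdiff(kn, names(params$kernels))
      if (length(missing)) {
        add(paste0("missing kernel(s): ", paste(missing, collapse = ", ")))
      } else {
        for (nm in kn) {
          kr <- params$kernels[[nm]]
          if (!all(c("a", "b", "theta") %in% names(kr))) {
            add(paste0("kernel ", nm, " needs fields a, b, theta")); next
          }
          th <- tryCatch(parse_angle(kr$theta), error = function(e) NA_real_)
          add(finite_or(c(kr$a, kr$b, th), paste0("kernel ", nm, ": non-finite value")))
          if (is.numeric(kr$b) && is.finite(kr$b) && kr$b <= 0) {
            add(paste0("kernel ", nm, ": width must be positive"))
          }
          if (is.finite(th) && (th < -pi || th > pi)) {
            add(paste0("kernel ", nm, ": theta must lie in [-pi, pi]"))
          }
        }
      }
      add(finite_or(c(params$hr, params$A, params$fr), "hr, A, fr must be finite"))
      if (is.numeric(params$fr) && is.finite(params$fr) && params$fr < 0) {
        add("fr must be >= 0")
      }
      if (is.numeric(params$hr) && is.finite(params$hr) && params$hr <= 0) {
        add("hr must be > 0")
      }
    }
  }
  problems
}
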