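#' Parameters of the minimal model corticotroph
#'
#' A three-variable conductance-based model (membrane potential `V`,
#' delayed-rectifier activation `n`, A-current inactivation `h`) of a
#' pituitary corticotroph. The currents are an instantaneously activating
#' L-type calcium current, a delayed-rectifier potassium current, an
#' optional A-type (transient) potassium current, and an ohmic leak:
#'
#' \deqn{C\,dV/dt = -[g_{Ca} m_\infty(V)(V-V_{Ca}) + g_K n (V-V_K)
#'   + g_A a_\infty(V) h (V-V_K) + g_L(V-V_L)] + I_{app} + I_{inject} + \eta}
#'
#' with logistic steady-state activations
#' \eqn{x_\infty(V) = [1+\exp((v_x - V)/s_x)]^{-1}},
#' \eqn{\tau_n\,dn/dt = n_\infty(V)-n}, \eqn{\tau_h\,dh/dt = h_\infty(V)-h}
#' (where \eqn{h_\infty} falls with depolarization), and
#' Ornstein--Uhlenbeck current noise \eqn{\eta} of stationary standard
#' deviation `noise_amp_pa` and correlation time `noise_tau_ms`.
#' Units: nS, mV, pF, pA, ms; nS x mV = pA and pA/pF = mV/ms, so no
#' conversion factors appear.
#'
#' All parameter values are calibrations chosen for this package (no
#' measured corticotroph model constants exist for these cells); see the
#' methods vignette for the calibration targets.
#'
#' @param c_pf Membrane capacitance (pF).
#' @param gca_ns,vca_mv,vm_mv,sm_mv Calcium conductance (nS), reversal (mV),
#'   activation midpoint and slope (mV).
#' @param gk_ns,vk_mv,vn_mv,sn_mv,tau_n_ms Delayed-rectifier conductance,
#'   K reversal, activation midpoint/slope, activation time constant.
#' @param ga_ns,va_mv,sa_mv,vh_mv,sh_mv,tau_h_ms A-current conductance,
#'   activation midpoint/slope, inactivation midpoint/slope and time
#'   constant. `ga_ns = 0` disables the A-current.
#' @param gl_ns,vl_mv Leak conductance and reversal.
#' @param i_app_pa Applied (background/secretagogue) current (pA).
#' @param noise_amp_pa,noise_tau_ms Ornstein--Uhlenbeck current noise:
#'   stationary sd (pA) and correlation time (ms). `noise_amp_pa = 0` gives
#'   a deterministic cell.
#' @param v_init_mv Initial membrane potential (mV); gating variables start
#'   at their steady states for this voltage.
#' @return A list of class `"ctph_cell_params"`.
#' @seealso [cell_preset()], [simulate_cell()], [crh_stimulus()]
#' @export
cell_params <- function(c_pf = 5,
                        gca_ns = 2, vca_mv = 60, vm_mv = -14, sm_mv = 9,
                        gk_ns = 2.5, vk_mv = -80, vn_mv = -5, sn_mv = 10,
                        tau_n_ms = 25,
                        ga_ns = 0, va_mv = -20, sa_mv = 8,
                        vh_mv = -50, sh_mv = 6, tau_h_ms = 40,
                        gl_ns = 0.4, vl_mv = -58.14,
                        i_app_pa = -1.75,
                        noise_amp_pa = 2.4, noise_tau_ms = 10,
                        v_init_mv = -51) {
  p <- list(c_pf = c_pf, gca_ns = gca_ns, vca_mv = vca_mv, vm_mv = vm_mv,
            sm_mv = sm_mv, gk_ns = gk_ns, vk_mv = vk_mv, vn_mv = vn_mv,
            sn_mv = sn_mv, tau_n_ms = tau_n_ms, ga_ns = ga_ns, va_mv = va_mv,
            sa_mv = sa_mv, vh_mv = vh_mv, sh_mv = sh_mv, tau_h_ms = tau_h_ms,
            gl_ns = gl_ns, vl_mv = vl_mv, i_app_pa = i_app_pa,
            noise_amp_pa = noise_amp_pa, noise_tau_ms = noise_tau_ms,
            v_init_mv = v_init_mv)
  if (p$c_pf <= 0) stop("capacitance must be positive")
  for (g in c("gca_ns", "gk_ns", "ga_ns", "gl_ns"))
    if (p[[g]] < 0) stop(g, " must be non-negative")
  if (p$tau_n_ms <= 0 || p$tau_h_ms <= 0 || p$noise_tau_ms <= 0)
    stop("time constants must be positive")
  if (p$noise_amp_pa < 0) stop("noise_amp_pa must be non-negative")
  class(p) <- "ctph_cell_params"
  p
}

#' Model-cell presets
#'
#' `"B"`: a B-like corticotroph — noise-driven low-frequency single spikes
#' with a shallow afterhyperpolarization; transitions to pseudo-plateau
#' bursting when a fast BK conductance is added under CRH-like drive.
#' `"A"`: an A-like corticotroph — stronger, deeper-reversing delayed
#' rectifier plus a small A-type current giving a deeper AHP; resists
#' BK-induced bursting.
#'
#' @param kind `"B"` or `"A"`.
#' @param ... Overrides passed to [cell_params()].
#' @return A `"ctph_cell_params"` object.
#' @export
cell_preset <- function(kind = c("B", "A"), ...) {
  kind <- match.arg(kind)
  if (kind == "B") {
    cell_params(...)
  } else {
    # stronger/deeper delayed rectifier + small A-current; the applied
    # current offsets the extra standing K conductance at -51 mV so the
    # resting state stays comparable to the B preset
    cell_params(gk_ns = 5, vk_mv = -95, ga_ns = 0.5,
                i_app_pa = -0.04, ...)
  }
}

# steady-state logistic activation, shared with the dynamic clamp
.boltz <- function(v, vhalf, slope) 1 / (1 + exp((vhalf - v) / slope))

#' Time derivatives of the model-cell state
#'
#' Evaluates the right-hand side of the model equations at one state; used
#' for unit auditing and cross-checks of the compiled integrator. Currents
#' follow the convention that `i_inject_pa` is *added* to the capacitive
#' balance (a positive injected current depolarizes).
#'
#' @param state List with `v_mv`, `n`, `h`.
#' @param params A `"ctph_cell_params"` object.
#' @param i_inject_pa Injected current (pA), e.g. from a dynamic clamp.
#' @return List with `dv_dt_mv_ms`, `dn_dt`, `dh_dt` and the individual
#'   currents in pA (`i_ca_pa`, `i_k_pa`, `i_a_pa`, `i_l_pa`).
#' @export
cell_derivatives <- function(state, params, i_inject_pa = 0) {
  stopifnot(inherits(params, "ctph_cell_params"))
  v <- state$v_mv; n <- state$n; h <- state$h
  if (!all(is.finite(c(v, n, h)))) stop("non-finite state")
  if (n < 0 || n > 1 || h < 0 || h > 1) stop("gating variables must be in [0, 1]")
  p <- params
  ica <- p$gca_ns * .boltz(v, p$vm_mv, p$sm_mv) * (v - p$vca_mv)
  ik  <- p$gk_ns * n * (v - p$vk_mv)
  ia  <- p$ga_ns * .boltz(v, p$va_mv, p$sa_mv) * h * (v - p$vk_mv)
  il  <- p$gl_ns * (v - p$vl_mv)
  list(dv_dt_mv_ms = (-(ica + ik + ia + il) + p$i_app_pa + i_inject_pa) / p$c_pf,
       dn_dt = (.boltz(v, p$vn_mv, p$sn_mv) - n) / p$tau_n_ms,
       dh_dt = ((1 - .boltz(v, p$vh_mv, p$sh_mv)) - h) / p$tau_h_ms,
       i_ca_pa = ica, i_k_pa = ik, i_a_pa = ia, i_l_pa = il)
}

#' Simulate the model corticotroph
#'
#' Fixed-step forward Euler (Euler--Maruyama for the noise term)
#' integration of the model cell. An optional `clamp_hook` is called once
#' per step with `(t_ms, v_mv)` and must return a current in pA that is
#' added to that step — the generic closed-loop injection point (the
#' built-in BK clamp of [run_closed_loop()] uses a compiled fast path
#' instead).
#'
#' @param params A `"ctph_cell_params"` object.
#' @param duration_ms Simulated time (ms).
#' @param dt_ms Integration step (ms); must be at most 0.1 ms.
#' @param seed Integer seed for the noise process (required when
#'   `noise_amp_pa > 0`).
#' @param clamp_hook Optional `function(t_ms, v_mv) -> pA`.
#' @param record_gating Also return `n`, `h`, BK activation and injected
#'   current time courses.
#' @param fs_out_hz Output sampling rate (default 10000); the integration
#'   grid is decimated to the closest achievable rate
#'   (`record_every = max(1, round(1000 / (fs_out_hz * dt_ms)))` steps).
#' @return A `"ctph_trace"` (metadata records the preset and seed), with
#'   attribute `gating` (data.frame) when `record_gating = TRUE`.
#' @export
simulate_cell <- function(params, duration_ms, dt_ms = 0.05, seed = NULL,
                          clamp_hook = NULL, record_gating = FALSE,
                          fs_out_hz = 10000) {
  stopifnot(inherits(params, "ctph_cell_params"))
  if (dt_ms > 0.1) stop("dt_ms must be <= 0.1 ms")
  if (params$noise_amp_pa > 0 && is.null(seed))
    stop("a seed is required when the noise amplitude is non-zero")
  .sim_with_bk(params, bk = NULL, duration_ms = duration_ms, dt_ms = dt_ms,
               seed = seed, clamp_hook = clamp_hook,
               record_gating = record_gating, fs_out_hz = fs_out_hz)
}

# shared driver for simulate_cell and run_closed_loop; bk = NULL means gBK = 0
.sim_with_bk <- function(params, bk, duration_ms, dt_ms, seed,
                         clamp_hook = NULL, record_gating = FALSE,
                         fs_out_hz = 10000) {
  gbk <- if (is.null(bk)) 0 else bk$gbk_ns
  vf <- if (is.null(bk)) -10 else bk$vf_mv
  sf <- if (is.null(bk)) 2 else bk$sf_mv
  taubk <- if (is.null(bk)) 2 else bk$taubk_ms
  vkbk <- if (is.null(bk)) -75 else bk$vk_mv
  record_every <- max(1L, as.integer(round(1000 / (fs_out_hz * dt_ms))))
  if (!is.null(seed)) set.seed(seed)
  res <- sim_core_cpp(unclass(params), gbk, vf, sf, taubk, vkbk,
                      duration_ms, dt_ms, record_every, record_gating,
                      clamp_hook)
  fs <- 1000 / (record_every * dt_ms)
  tr <- voltage_trace(res$v_mv, fs_hz = fs,
              metadata = list(model = "corticotroph-3var", seed = seed,
                              gbk_ns = gbk, dt_ms = dt_ms))
  attr(tr, "summary") <- list(injected_charge_pc = res$injected_charge_pc,
                              mean_abs_ibk_pa = res$mean_abs_ibk_pa)
  if (record_gating)
    attr(tr, "gating") <- data.frame(t_ms = res$t_ms, v_mv = res$v_mv,
                                     n = res$n, h = res$h,
                                     f = res$f, ibk_pa = res$ibk_pa)
  tr
}

#' Apply a CRH-like stimulus to model-cell parameters
#'
#' CRH acts on corticotrophs through cAMP/PKA, producing a small
#' depolarization and increased firing. The model implements this as a
#' graded increase of the applied current: at `level = 1` the applied
#' current rises by 2.75 pA, calibrated so the B-like preset depolarizes by
#' roughly 3--6 mV (three-point membrane-potential estimator) and its event
#' frequency increases several-fold.
#'
#' @param params A `"ctph_cell_params"` object.
#' @param level Stimulus level in `[0, 1]`; 0 returns `params` unchanged.
#' @param delta_i_pa Applied-current increase at `level = 1` (pA).
#' @return Modified `"ctph_cell_params"`.
#' @export
crh_stimulus <- function(params, level, delta_i_pa = 2.75) {
  stopifnot(inherits(params, "ctph_cell_params"))
  if (level < 0 || level > 1) stop("level must be in [0, 1]")
  params$i_app_pa <- params$i_app_pa + level * delta_i_pa
  params
}
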