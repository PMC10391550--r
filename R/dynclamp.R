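#' BK dynamic-clamp parameters
#'
#' The software dynamic clamp computes a BK-channel current from the
#' membrane potential each time step and injects it back into the cell.
#' BK activation `f` follows first-order kinetics
#' \eqn{\tau_{BK}\,df/dt = f_\infty(V) - f} integrated by forward Euler,
#' with \eqn{f_\infty(V) = [1+\exp((v_f - V)/s_f)]^{-1}}, and the injected
#' current is \eqn{I_{BK} = g_{BK} f (V_K - V)}.
#'
#' @param gbk_ns BK conductance (nS); typical range 0.5--2, default 1.
#' @param vf_mv Activation midpoint (mV, default -10).
#' @param sf_mv Activation slope (mV, default 2); must be positive.
#' @param taubk_ms Activation time constant (ms, default 2).
#' @param vk_mv Potassium reversal used by the clamp (mV, default -75).
#' @param dt_us Clamp integration step (microseconds, default 21,
#'   maximum 100).
#' @return A list of class `"ctph_bk_params"`.
#' @export
bk_params <- function(gbk_ns = 1, vf_mv = -10, sf_mv = 2, taubk_ms = 2,
                      vk_mv = -75, dt_us = 21) {
  if (gbk_ns < 0) stop("gbk_ns must be non-negative")
  if (sf_mv <= 0) stop("sf_mv must be positive")
  if (taubk_ms <= 0) stop("taubk_ms must be positive")
  if (dt_us <= 0 || dt_us > 100) stop("dt_us must be in (0, 100]")
  structure(list(gbk_ns = gbk_ns, vf_mv = vf_mv, sf_mv = sf_mv,
                 taubk_ms = taubk_ms, vk_mv = vk_mv, dt_us = dt_us),
            class = "ctph_bk_params")
}

#' Steady-state BK activation
#'
#' \eqn{f_\infty(V) = [1+\exp((v_f - V)/s_f)]^{-1}}: strictly increasing in
#' `V` with range (0, 1) and value 1/2 at `V = vf_mv`.
#'
#' @param v_mv Membrane potential (mV); vectorized.
#' @param vf_mv,sf_mv Activation midpoint and slope (mV); `sf_mv > 0`.
#' @return Activation fraction(s) in (0, 1).
#' @export
f_inf <- function(v_mv, vf_mv = -10, sf_mv = 2) {
  if (sf_mv <= 0) stop("sf_mv must be positive")
  1 / (1 + exp((vf_mv - v_mv) / sf_mv))
}

#' One forward-Euler step of the BK activation variable
#'
#' `f' = f + dt (f_inf(V) - f) / tau_BK`, clipped to `[0, 1]` to guard
#' against overshoot near the stability boundary. Steps larger than
#' `tau_BK` are rejected as unstable; steps above `tau_BK / 10` warn.
#'
#' @param f Current activation in `[0, 1]`.
#' @param v_mv Membrane potential (mV).
#' @param dt_ms Step (ms).
#' @param params A `"ctph_bk_params"` object.
#' @return Updated activation fraction.
#' @export
euler_step_f <- function(f, v_mv, dt_ms, params = bk_params()) {
  if (any(f < 0) || any(f > 1)) stop("f must be in [0, 1]")
  if (dt_ms > params$taubk_ms)
    stop("dt_ms exceeds taubk_ms: forward Euler step is unstable")
  if (dt_ms > params$taubk_ms / 10)
    warning("dt_ms exceeds taubk_ms/10; accuracy of the Euler step degrades")
  fnew <- f + dt_ms * (f_inf(v_mv, params$vf_mv, params$sf_mv) - f) / params$taubk_ms
  pmin(1, pmax(0, fnew))
}

#' BK current from activation and voltage
#'
#' `I_BK = gBK f (VK - V)` in the injected-current convention: the returned
#' value is added to the cell's capacitive balance, so it is negative
#' (hyperpolarizing) whenever `V > VK` and `f > 0`.
#'
#' @param f Activation fraction in `[0, 1]`.
#' @param v_mv Membrane potential (mV).
#' @param params A `"ctph_bk_params"` object.
#' @return Current in pA.
#' @export
bk_current <- function(f, v_mv, params = bk_params()) {
  if (any(f < 0) || any(f > 1)) stop("f must be in [0, 1]")
  params$gbk_ns * f * (params$vk_mv - v_mv)
}

#' Closed-loop BK dynamic clamp on the model cell
#'
#' Runs the model corticotroph with the BK clamp in closed loop: each
#' integration step reads the membrane potential, advances the BK
#' activation by one forward-Euler step, and injects the resulting current
#' into the cell's next step. Cell and clamp share the clamp's fixed step
#' (`dt_us`, at most 100 us). With `gbk_ns = 0` the result is bit-identical
#' to [simulate_cell()] at the same step and seed.
#'
#' @param cell A `"ctph_cell_params"` object.
#' @param bk A `"ctph_bk_params"` object.
#' @param duration_ms Simulated time (ms).
#' @param crh_level CRH stimulus level in `[0, 1]` applied via
#'   [crh_stimulus()] before simulation (default 0).
#' @param seed Integer seed for the noise process.
#' @param record_gating Record `f` and `I_BK` time courses (default TRUE).
#' @return A `"ctph_bk_result"`: list with `trace` (a `ctph_trace`),
#'   `t_ms`, `v_mv`, `f`, `ibk_pa` (decimated audit time courses, present
#'   when `record_gating`), and `summary` (injected charge in pC, mean
#'   absolute injected current in pA).
#' @export
run_closed_loop <- function(cell, bk, duration_ms, crh_level = 0, seed = NULL,
                            record_gating = TRUE) {
  stopifnot(inherits(cell, "ctph_cell_params"), inherits(bk, "ctph_bk_params"))
  cell <- crh_stimulus(cell, crh_level)
  dt_ms <- bk$dt_us / 1000
  tr <- .sim_with_bk(cell, bk, duration_ms = duration_ms, dt_ms = dt_ms,
                     seed = seed, record_gating = record_gating)
  g <- attr(tr, "gating")
  out <- list(trace = tr,
              t_ms = g$t_ms, v_mv = g$v_mv, f = g$f, ibk_pa = g$ibk_pa,
              summary = attr(tr, "summary"),
              bk = bk, crh_level = crh_level, seed = seed)
  class(out) <- "ctph_bk_result"
  out
}

#' @export
print.ctph_bk_result <- function(x, ...) {
  cat(sprintf("<ctph_bk_result> %.1f s, gBK = %g nS, CRH level %g\n",
              trace_duration(x$trace), x$bk$gbk_ns, x$crh_level))
  cat(sprintf("  injected charge %.2f pC, mean |I_BK| %.2f pA\n",
              x$summary$injected_charge_pc, x$summary$mean_abs_ibk_pa))
  invisible(x)
}
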