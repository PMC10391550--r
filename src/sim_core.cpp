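#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double boltz(double v, double vhalf, double slope) {
    return 1.0 / (1.0 + std::exp((vhalf - v) / slope));
}

// Forward-Euler integration of the model corticotroph, optionally with the
// BK dynamic clamp in closed loop.  All currents are in pA (nS * mV), all
// voltages in mV, all times in ms; pA/pF = mV/ms so no conversion factor
// appears in the V update.
//
// Per step (synchronous update from the state at time t):
//   I_ion  = gCa*m_inf(V)*(V-VCa) + gK*n*(V-VK) + gA*a_inf(V)*h*(V-VK)
//            + gL*(V-VL)
//   I_BK   = gBK * f' * (VKbk - V)   with f' the freshly advanced activation
//   dV/dt  = ( -I_ion + I_app + I_BK + I_hook + eta ) / C
//   tau_n dn/dt = n_inf(V) - n ;  tau_h dh/dt = h_inf(V) - h
//   tau_BK df/dt = f_inf(V) - f   (f clipped to [0,1] after the step)
//   eta: Ornstein-Uhlenbeck current noise, stationary sd = noise_amp pA,
//        correlation time tau_noise ms, driven by R's RNG (norm_rand).
//
// Recording: every `record_every` steps (plus the initial state).
// [[Rcpp::export]]
List sim_core_cpp(List cell,
                  double gbk, double vf, double sf, double taubk, double vkbk,
                  double duration_ms, double dt_ms, int record_every,
                  bool record_gating,
                  Nullable<Function> hook) {
    const double C     = as<double>(cell["c_pf"]);
    const double gca   = as<double>(cell["gca_ns"]);
    const double vca   = as<double>(cell["vca_mv"]);
    const double vm    = as<double>(cell["vm_mv"]);
    const double sm    = as<double>(cell["sm_mv"]);
    const double gk    = as<double>(cell["gk_ns"]);
    const double vk    = as<double>(cell["vk_mv"]);
    const double vn    = as<double>(cell["vn_mv"]);
    const double sn    = as<double>(cell["sn_mv"]);
    const double taun  = as<double>(cell["tau_n_ms"]);
    const double ga    = as<double>(cell["ga_ns"]);
    const double va    = as<double>(cell["va_mv"]);
    const double sa    = as<double>(cell["sa_mv"]);
    const double vh    = as<double>(cell["vh_mv"]);
    const double sh    = as<double>(cell["sh_mv"]);
    const double tauh  = as<double>(cell["tau_h_ms"]);
    const double gl    = as<double>(cell["gl_ns"]);
    const double vl    = as<double>(cell["vl_mv"]);
    const double iapp  = as<double>(cell["i_app_pa"]);
    const double namp  = as<double>(cell["noise_amp_pa"]);
    const double ntau  = as<double>(cell["noise_tau_ms"]);
    const double v0    = as<double>(cell["v_init_mv"]);

    if (dt_ms <= 0.0) stop("dt_ms must be positive");
    const R_xlen_t nsteps = (R_xlen_t) std::llround(duration_ms / dt_ms);
    if (nsteps < 1) stop("duration shorter than one time step");
    if (record_every < 1) stop("record_every must be >= 1");

    const R_xlen_t nrec = nsteps / record_every + 1;
    NumericVector t_out(nrec), v_out(nrec);
    NumericVector f_out(record_gating ? nrec : 0),
                  ibk_out(record_gating ? nrec : 0),
                  n_out(record_gating ? nrec : 0),
                  h_out(record_gating ? nrec : 0);

    bool has_hook = hook.isNotNull();
    Function hookfun("identity");           // placeholder, unused when no hook
    if (has_hook) hookfun = Function(hook);

    double V = v0;
    double n = boltz(V, vn, sn);
    double h = 1.0 - boltz(V, vh, sh);   // inactivation: closed when depolarized
    double f = boltz(V, vf, sf);
    double eta = 0.0;
    const double noise_pref = (namp > 0.0) ? namp * std::sqrt(2.0 * dt_ms / ntau) : 0.0;

    RNGScope rng;

    R_xlen_t irec = 0;
    t_out[irec] = 0.0; v_out[irec] = V;
    double ibk0 = gbk * f * (vkbk - V);
    if (record_gating) { f_out[0] = f; ibk_out[0] = ibk0; n_out[0] = n; h_out[0] = h; }
    ++irec;

    double q_inj = 0.0, abs_ibk_sum = 0.0;   // injected charge (pA*ms), mean |I_BK|

    for (R_xlen_t step = 1; step <= nsteps; ++step) {
        const double t = (double)(step - 1) * dt_ms;

        // advance BK activation from V(t), then inject into this V step
        double fnew = f + dt_ms * (boltz(V, vf, sf) - f) / taubk;
        if (fnew < 0.0) fnew = 0.0; else if (fnew > 1.0) fnew = 1.0;
        const double ibk = gbk * fnew * (vkbk - V);

        double ihook = 0.0;
        if (has_hook) ihook = as<double>(hookfun(t, V));

        const double iion = gca * boltz(V, vm, sm) * (V - vca)
                          + gk * n * (V - vk)
                          + ga * boltz(V, va, sa) * h * (V - vk)
                          + gl * (V - vl);
        const double dv = (-iion + iapp + ibk + ihook + eta) / C;

        const double nnew = n + dt_ms * (boltz(V, vn, sn) - n) / taun;
        const double hnew = h + dt_ms * ((1.0 - boltz(V, vh, sh)) - h) / tauh;

        if (namp > 0.0)
            eta += dt_ms * (-eta / ntau) + noise_pref * norm_rand();

        V += dt_ms * dv;
        n = (nnew < 0.0) ? 0.0 : (nnew > 1.0 ? 1.0 : nnew);
        h = (hnew < 0.0) ? 0.0 : (hnew > 1.0 ? 1.0 : hnew);
        f = fnew;

        q_inj += ibk * dt_ms;
        abs_ibk_sum += std::fabs(ibk);

        if (!std::isfinite(V) || std::fabs(V) > 200.0)
            stop("numerical blow-up at step %d (t = %.3f ms): |V| > 200 mV; "
                 "reduce dt or check parameters", (int)step, t);

        if (step % record_every == 0) {
            t_out[irec] = (double)step * dt_ms;
            v_out[irec] = V;
            if (record_gating) {
                f_out[irec] = f; ibk_out[irec] = ibk;
                n_out[irec] = n; h_out[irec] = h;
            }
            ++irec;
        }
    }

    List out = List::create(
        _["t_ms"] = t_out, _["v_mv"] = v_out,
        _["injected_charge_pc"] = q_inj * 1e-3,      // pA*ms -> pC
        _["mean_abs_ibk_pa"] = abs_ibk_sum / (double)nsteps);
    if (record_gating) {
        out["f"] = f_out; out["ibk_pa"] = ibk_out;
        out["n"] = n_out; out["h"] = h_out;
    }
    return out;
}
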