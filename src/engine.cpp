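// Network simulation engine: conductance-based Adex neurons, event-queue
// delivery of delayed recurrent spikes, shared-train Poissonian drive.
//
// Unit system (paper units, self-consistent): capacitance pF, conductance nS,
// voltage mV, time ms, current pA.  nS * mV = pA and pA / pF = mV / ms, so the
// membrane equation integrates without conversion factors.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Parameter-matrix column layout (one row per cell type).
enum ParCol {
  P_C = 0, P_GL, P_EL, P_VTH, P_DELTA, P_TREF, P_TAUW, P_A, P_B,
  P_VRESET, P_EE, P_EI, P_VCUT, P_NCOL
};

// [[Rcpp::export]]
List cpp_simulate_network(IntegerVector type_idx,      // per neuron, 0-based row of par
                          NumericMatrix par,           // cell-type constants (ParCol)
                          LogicalVector is_inh,        // per neuron: inhibitory class
                          NumericVector tau_e,         // per neuron, ms
                          NumericVector tau_i,         // per neuron, ms
                          IntegerVector syn_ptr,       // CSR over sources, length n+1
                          IntegerVector syn_tgt,       // 0-based targets
                          NumericVector syn_q,         // per-edge strength, nS
                          int delay_steps,             // synaptic delay in dt steps (>= 1)
                          IntegerVector train_ptr,     // CSR over external trains
                          IntegerVector train_tgt,
                          NumericVector q_ext,         // per neuron, nS
                          NumericVector drive_rate,    // per step, per-train rate, Hz
                          NumericVector stim_rate,     // per step extra rate, Hz (len 0 = none)
                          NumericVector i_ext,         // per step injected current, pA (len 0 = none)
                          double dt, int n_steps,
                          int seed_init, int seed_drive, int seed_stim,
                          IntegerVector record_idx,    // 0-based neurons with full traces
                          bool exact_decay,
                          NumericVector v_init)        // per neuron initial V (len 0 = sample)
{
  const int n = type_idx.size();
  const int n_trains = train_ptr.size() - 1;
  if (delay_steps < 1) stop("synaptic delay must be at least one time step");
  if ((int)drive_rate.size() < n_steps && n_trains > 0)
    stop("drive_rate must cover every step");

  std::mt19937_64 rng_init(seed_init);
  std::mt19937_64 rng_drive(seed_drive);
  std::mt19937_64 rng_stim(seed_stim);
  std::uniform_real_distribution<double> unif01(0.0, 1.0);

  // Cell-type constants hoisted out of the Rcpp matrix for the inner loop.
  const int n_types = par.nrow();
  std::vector<double> pC(n_types), pGL(n_types), pEL(n_types), pVTH(n_types),
      pDELTA(n_types), pTAUW(n_types), pA(n_types), pB(n_types),
      pVRESET(n_types), pEE(n_types), pEI(n_types), pVCUT(n_types);
  for (int ty = 0; ty < n_types; ++ty) {
    pC[ty] = par(ty, P_C); pGL[ty] = par(ty, P_GL); pEL[ty] = par(ty, P_EL);
    pVTH[ty] = par(ty, P_VTH); pDELTA[ty] = par(ty, P_DELTA);
    pTAUW[ty] = par(ty, P_TAUW); pA[ty] = par(ty, P_A); pB[ty] = par(ty, P_B);
    pVRESET[ty] = par(ty, P_VRESET); pEE[ty] = par(ty, P_EE);
    pEI[ty] = par(ty, P_EI); pVCUT[ty] = par(ty, P_VCUT);
  }
  const int *type_p = INTEGER(type_idx);
  const int *syn_ptr_p = INTEGER(syn_ptr);
  const int *syn_tgt_p = INTEGER(syn_tgt);
  const double *syn_q_p = REAL(syn_q);
  const int *train_ptr_p = n_trains > 0 ? INTEGER(train_ptr) : nullptr;
  const int *train_tgt_p = train_tgt.size() > 0 ? INTEGER(train_tgt) : nullptr;
  const double *q_ext_p = REAL(q_ext);
  std::vector<int> inh(n);
  for (int i = 0; i < n; ++i) inh[i] = is_inh[i] ? 1 : 0;

  // State.
  std::vector<double> V(n), w(n, 0.0), gE(n, 0.0), gI(n, 0.0), gX(n, 0.0);
  std::vector<int> ref_left(n, 0);
  std::vector<double> decE(n), decI(n);
  std::vector<int> ref_steps(n);
  for (int i = 0; i < n; ++i) {
    const int ty = type_p[i];
    if (v_init.size() == n) {
      V[i] = v_init[i];
    } else {
      // V ~ uniform in [E_L, V_th): startup transient absorbed by burn-in.
      const double lo = pEL[ty], hi = pVTH[ty];
      V[i] = lo + (hi - lo) * unif01(rng_init);
    }
    decE[i] = exact_decay ? std::exp(-dt / tau_e[i]) : 1.0 - dt / tau_e[i];
    decI[i] = exact_decay ? std::exp(-dt / tau_i[i]) : 1.0 - dt / tau_i[i];
    ref_steps[i] = (int)std::lround(par(ty, P_TREF) / dt);
  }

  // Ring buffers for delayed conductance increments.
  const int ring = delay_steps + 1;
  std::vector<double> incE((size_t)ring * n, 0.0), incI((size_t)ring * n, 0.0);

  // Outputs.
  std::vector<int> spike_id;
  std::vector<double> spike_t;
  spike_id.reserve(1 << 16);
  spike_t.reserve(1 << 16);
  const int n_rec = record_idx.size();
  NumericMatrix rec_V(n_rec > 0 ? n_steps : 0, n_rec),
      rec_gE(n_rec > 0 ? n_steps : 0, n_rec),
      rec_gI(n_rec > 0 ? n_steps : 0, n_rec),
      rec_gX(n_rec > 0 ? n_steps : 0, n_rec),
      rec_Iexc(n_rec > 0 ? n_steps : 0, n_rec),
      rec_Iinh(n_rec > 0 ? n_steps : 0, n_rec),
      rec_Idrv(n_rec > 0 ? n_steps : 0, n_rec);

  const bool has_stim = stim_rate.size() > 0;
  const bool has_iext = i_ext.size() > 0;

  for (int step = 0; step < n_steps; ++step) {
    const int slot = step % ring;
    double *incEs = &incE[(size_t)slot * n];
    double *incIs = &incI[(size_t)slot * n];

    // 1. Conductance decay + arrival of events delayed to this step.
    for (int i = 0; i < n; ++i) {
      gE[i] = gE[i] * decE[i] + incEs[i];
      gI[i] = gI[i] * decI[i] + incIs[i];
      gX[i] *= decE[i];
      incEs[i] = 0.0;
      incIs[i] = 0.0;
    }

    // 2. External Poissonian drive (shared trains, immediate delivery).
    if (n_trains > 0) {
      const double lam = n_trains * drive_rate[step] * dt * 1e-3;
      if (lam > 0) {
        std::poisson_distribution<int> pois(lam);
        const int k = pois(rng_drive);
        for (int e = 0; e < k; ++e) {
          const int tr = std::min((int)(unif01(rng_drive) * n_trains), n_trains - 1);
          for (int j = train_ptr_p[tr]; j < train_ptr_p[tr + 1]; ++j) {
            const int tgt = train_tgt_p[j];
            gX[tgt] += q_ext_p[tgt];
          }
        }
      }
      if (has_stim) {
        const double lam_s = n_trains * stim_rate[step] * dt * 1e-3;
        if (lam_s > 0) {
          std::poisson_distribution<int> pois_s(lam_s);
          const int k = pois_s(rng_stim);
          for (int e = 0; e < k; ++e) {
            const int tr = std::min((int)(unif01(rng_stim) * n_trains), n_trains - 1);
            for (int j = train_ptr_p[tr]; j < train_ptr_p[tr + 1]; ++j) {
              const int tgt = train_tgt_p[j];
              gX[tgt] += q_ext_p[tgt];
            }
          }
        }
      }
    }

    const double iext_now = has_iext ? i_ext[step] : 0.0;

    // 3. Membrane update (forward Euler), spike detection, reset.
    // A spike detected by this update carries time (step+1)*dt; its increments
    // must join the conductance state used by the update at step+1+delay_steps,
    // i.e. exactly delay after the spike time. That slot is the one drained in
    // phase 1 of this very step (ring = delay_steps + 1).
    const int dslot = (step + delay_steps + 1) % ring;
    double *incEd = &incE[(size_t)dslot * n];
    double *incId = &incI[(size_t)dslot * n];
    for (int i = 0; i < n; ++i) {
      if (ref_left[i] > 0) {
        // V and w held during refractoriness; conductances evolve above.
        --ref_left[i];
        continue;
      }
      const int ty = type_p[i];
      double Vi = V[i], wi = w[i];
      double x = (Vi - pVTH[ty]) / pDELTA[ty];
      if (x > 30.0) x = 30.0;  // guard exp overflow when v_cut > V_th
      const double i_exp = pGL[ty] * pDELTA[ty] * std::exp(x);
      const double i_syn = (gE[i] + gX[i]) * (Vi - pEE[ty]) +
                           gI[i] * (Vi - pEI[ty]);
      const double dV = (-pGL[ty] * (Vi - pEL[ty]) + i_exp - wi - i_syn +
                         iext_now) / pC[ty];
      const double dw = (pA[ty] * (Vi - pEL[ty]) - wi) / pTAUW[ty];
      Vi += dt * dV;
      wi += dt * dw;
      if (!std::isfinite(Vi) || !std::isfinite(wi))
        stop("non-finite state for neuron %d at t = %.2f ms", i + 1, step * dt);
      if (Vi >= pVCUT[ty]) {
        spike_id.push_back(i + 1);
        spike_t.push_back((step + 1) * dt);
        Vi = pVRESET[ty];
        wi += pB[ty];
        ref_left[i] = ref_steps[i];
        const double *qv = syn_q_p;
        if (inh[i]) {
          for (int j = syn_ptr_p[i]; j < syn_ptr_p[i + 1]; ++j)
            incId[syn_tgt_p[j]] += qv[j];
        } else {
          for (int j = syn_ptr_p[i]; j < syn_ptr_p[i + 1]; ++j)
            incEd[syn_tgt_p[j]] += qv[j];
        }
      }
      V[i] = Vi;
      w[i] = wi;
    }

    for (int r = 0; r < n_rec; ++r) {
      const int i = record_idx[r];
      const int ty = type_p[i];
      rec_V(step, r) = V[i];
      rec_gE(step, r) = gE[i];
      rec_gI(step, r) = gI[i];
      rec_gX(step, r) = gX[i];
      rec_Iexc(step, r) = gE[i] * (V[i] - pEE[ty]);
      rec_Iinh(step, r) = gI[i] * (V[i] - pEI[ty]);
      rec_Idrv(step, r) = gX[i] * (V[i] - pEE[ty]);
    }
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  List traces = R_NilValue;
  if (n_rec > 0)
    traces = List::create(_["V"] = rec_V, _["g_E"] = rec_gE, _["g_I"] = rec_gI,
                          _["g_ext"] = rec_gX, _["I_exc"] = rec_Iexc,
                          _["I_inh"] = rec_Iinh, _["I_drive"] = rec_Idrv);
  return List::create(_["neuron"] = wrap(spike_id), _["time"] = wrap(spike_t),
                      _["traces"] = traces);
}

// Rasterize spike trains into an LFP trace via the spatiotemporal Gaussian
// kernel: one Gaussian pulse per spike, amplitude decaying exponentially with
// the neuron-electrode distance, peak delayed by d + distance / v_a.
// [[Rcpp::export]]
NumericVector cpp_kernel_lfp(NumericVector spike_t,   // ms
                             NumericVector amp,       // per spike, uV
                             NumericVector t_peak,    // per spike, ms
                             double sigma,            // ms
                             double dt_out, int n_out)
{
  NumericVector lfp(n_out);
  const double half_w = 5.0 * sigma;  // truncation: error < 4e-6 of peak
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int s = 0; s < spike_t.size(); ++s) {
    const double tc = t_peak[s];
    int j0 = (int)std::ceil((tc - half_w) / dt_out);
    int j1 = (int)std::floor((tc + half_w) / dt_out);
    if (j0 < 0) j0 = 0;
    if (j1 > n_out - 1) j1 = n_out - 1;
    for (int j = j0; j <= j1; ++j) {
      const double u = j * dt_out - tc;
      lfp[j] += amp[s] * std::exp(-u * u * inv2s2);
    }
  }
  return lfp;
}
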