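// Compiled core: Hodgkin-Huxley E-I network integrator with AMPA/NMDA/GABA-A
// double-exponential synapses, event-driven accumulators and classical RK4,
// plus fast cross-correlogram and pairwise phase-coherence kernels.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

#if defined(__GNUC__)
#define ANES_INLINE2 inline __attribute__((always_inline))
#else
#define ANES_INLINE2 inline
#endif

// ---------------------------------------------------------------------------
// Deterministic RNG (splitmix64 -> xorshift128+), independent of R's RNG so a
// simulation is reproducible from its integer seed alone.
struct XRng {
  uint64_t s0, s1;
  explicit XRng(uint64_t seed) {
    // splitmix64 to expand the seed
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s0 = z ^ (z >> 31);
    z = seed + 2 * 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s1 = z ^ (z >> 31);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  uint64_t next() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() { // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  double unif(double lo, double hi) { return lo + (hi - lo) * unif(); }
  double expvar(double rate) { // exponential waiting time, rate per ms
    double u = unif();
    if (u <= 0.0) u = 5e-324;
    return -std::log1p(-u) / rate;
  }
};

// ---------------------------------------------------------------------------
// Gating kinetics (steady states and time constants) and the NMDA voltage
// gate, tabulated on a fine voltage grid with linear interpolation.
static inline double f_minf(double V) { return 1.0 / (1.0 + std::exp(-(V + 30.0) / 9.5)); }
static inline double f_hinf(double V) { return 1.0 / (1.0 + std::exp((V + 53.0) / 7.0)); }
static inline double f_ninf(double V) { return 1.0 / (1.0 + std::exp(-(V + 30.0) / 10.0)); }
static inline double f_zinf(double V) { return 1.0 / (1.0 + std::exp(-(V + 39.0) / 5.0)); }
static inline double f_tauh(double V) { return 0.37 + 2.78 / (1.0 + std::exp((V + 40.5) / 5.0)); }
static inline double f_taun(double V) { return 0.37 + 1.85 / (1.0 + std::exp((V + 27.0) / 15.0)); }
static inline double f_bnmda(double V) { return 1.0 / (1.0 + std::exp(-(V + 10.0) / 3.57)); }
static const double TAU_Z = 75.0;

struct GateRow { double minf, hinf, ninf, zinf, itauh, itaun, bnmda, pad; };

struct GateTable {
  static const int N = 2301;       // -150 .. +80 mV, 0.1 mV grid
  static constexpr double V0 = -150.0, STEP = 0.1, ISTEP = 10.0;
  std::vector<GateRow> row;
  GateTable() : row(N) {
    for (int i = 0; i < N; ++i) {
      double V = V0 + i * STEP;
      row[i].minf = f_minf(V);
      row[i].hinf = f_hinf(V);
      row[i].ninf = f_ninf(V);
      row[i].zinf = f_zinf(V);
      row[i].itauh = 1.0 / f_tauh(V);
      row[i].itaun = 1.0 / f_taun(V);
      row[i].bnmda = f_bnmda(V);
    }
  }
  ANES_INLINE2 void at(double V, GateRow &out) const {
    double x = (V - V0) * ISTEP;
    if (x < 0.0) x = 0.0;
    if (x > N - 1.001) x = N - 1.001;
    int i = (int)x;
    double f = x - i;
    const GateRow &a = row[i], &b = row[i + 1];
    out.minf = a.minf + f * (b.minf - a.minf);
    out.hinf = a.hinf + f * (b.hinf - a.hinf);
    out.ninf = a.ninf + f * (b.ninf - a.ninf);
    out.zinf = a.zinf + f * (b.zinf - a.zinf);
    out.itauh = a.itauh + f * (b.itauh - a.itauh);
    out.itaun = a.itaun + f * (b.itaun - a.itaun);
    out.bnmda = a.bnmda + f * (b.bnmda - a.bnmda);
  }
};

static const GateTable &gate_table() {
  static GateTable tab;
  return tab;
}

// ---------------------------------------------------------------------------
// Membrane parameters shared by the network and single-cell integrators.
struct MemPar {
  double gNa, gKd, gL, ENa, EK, EL, Cm, IDC;
};

// Per-neuron synaptic state: double-exponential accumulators
// (slow/fast per receptor class). Kernel value is A_slow - A_fast >= 0.
enum { A_AS = 0, A_AF, A_NS, A_NF, A_GS, A_GF, NACC = 6 };

struct SynPar {
  double tau_f;                     // shared fast time constant (ms)
  double tau_as, tau_ns, tau_gs;    // slow time constants (ms)
  double E_exc, E_inh;
  double P_AMPA, P_NMDA, P_GABA;
};

// RK4 right-hand side for one neuron given interpolated accumulator values.
static ANES_INLINE2 void rhs(const GateTable &tab, const MemPar &mp,
                       const SynPar &sp, double gKs,
                       double Inoise, const double *acc,
                       double V, double h, double n, double z,
                       double &dV, double &dh, double &dn, double &dz) {
  GateRow g;
  tab.at(V, g);
  double m = g.minf;
  double m3 = m * m * m;
  double n2 = n * n;
  double kA = acc[A_AS] - acc[A_AF]; if (kA < 0) kA = 0;
  double kN = acc[A_NS] - acc[A_NF]; if (kN < 0) kN = 0;
  double kG = acc[A_GS] - acc[A_GF]; if (kG < 0) kG = 0;
  double Isyn = sp.P_AMPA * kA * (V - sp.E_exc)
              + sp.P_NMDA * g.bnmda * kN * (V - sp.E_exc)
              + sp.P_GABA * kG * (V - sp.E_inh);
  dV = (-mp.gNa * m3 * h * (V - mp.ENa)
        - mp.gKd * n2 * n2 * (V - mp.EK)
        - gKs * z * (V - mp.EK)
        - mp.gL * (V - mp.EL)
        + Inoise - Isyn + mp.IDC) / mp.Cm;
  dh = (g.hinf - h) * g.itauh;
  dn = (g.ninf - n) * g.itaun;
  dz = (g.zinf - z) / TAU_Z;
}

// Clip a gate variable: tiny numerical excursions are clamped, larger ones
// indicate integrator failure.
static inline bool clip_gate(double &x) {
  if (x < 0.0) { if (x > -1e-9) { x = 0.0; return true; } return false; }
  if (x > 1.0) { if (x < 1.0 + 1e-9) { x = 1.0; return true; } return false; }
  return true;
}

// Precomputed accumulator decay factors for a given substep size.
struct Decay {
  double df_f, df_as, df_ns, df_gs, dh_f, dh_as, dh_ns, dh_gs;
  void set(const SynPar &sp, double ddt) {
    df_f = std::exp(-ddt / sp.tau_f);
    df_as = std::exp(-ddt / sp.tau_as);
    df_ns = std::exp(-ddt / sp.tau_ns);
    df_gs = std::exp(-ddt / sp.tau_gs);
    dh_f = std::sqrt(df_f); dh_as = std::sqrt(df_as);
    dh_ns = std::sqrt(df_ns); dh_gs = std::sqrt(df_gs);
  }
};

// Advance one neuron by one outer step dt, substepping when the synaptic
// conductance bound makes the explicit step stiff. Accumulators decay
// analytically within the step. dec1 must hold the factors for substep size
// dt. Returns false on numerical failure.
static bool step_neuron_k(const GateTable &tab, const MemPar &mp,
                          const SynPar &sp, double gKs,
                          double Inoise, double dt, const Decay &dec1, int k,
                          double &V, double &h, double &n, double &z,
                          double *acc) {
  double ddt = dt / k;
  Decay dloc;
  const Decay *dp = &dec1;
  if (k > 1) { dloc.set(sp, ddt); dp = &dloc; }
  const double df_f = dp->df_f, df_as = dp->df_as, df_ns = dp->df_ns,
               df_gs = dp->df_gs, dh_f = dp->dh_f, dh_as = dp->dh_as,
               dh_ns = dp->dh_ns, dh_gs = dp->dh_gs;

  double Vl = V, hl = h, nl = n, zl = z;
  double al[NACC];
  for (int a = 0; a < NACC; ++a) al[a] = acc[a];
  double amid[NACC], aend[NACC];
  for (int s = 0; s < k; ++s) {
    amid[A_AS] = al[A_AS] * dh_as; aend[A_AS] = al[A_AS] * df_as;
    amid[A_AF] = al[A_AF] * dh_f;  aend[A_AF] = al[A_AF] * df_f;
    amid[A_NS] = al[A_NS] * dh_ns; aend[A_NS] = al[A_NS] * df_ns;
    amid[A_NF] = al[A_NF] * dh_f;  aend[A_NF] = al[A_NF] * df_f;
    amid[A_GS] = al[A_GS] * dh_gs; aend[A_GS] = al[A_GS] * df_gs;
    amid[A_GF] = al[A_GF] * dh_f;  aend[A_GF] = al[A_GF] * df_f;

    double k1V, k1h, k1n, k1z, k2V, k2h, k2n, k2z;
    double k3V, k3h, k3n, k3z, k4V, k4h, k4n, k4z;
    rhs(tab, mp, sp, gKs, Inoise, al, Vl, hl, nl, zl, k1V, k1h, k1n, k1z);
    rhs(tab, mp, sp, gKs, Inoise, amid, Vl + 0.5 * ddt * k1V, hl + 0.5 * ddt * k1h,
        nl + 0.5 * ddt * k1n, zl + 0.5 * ddt * k1z, k2V, k2h, k2n, k2z);
    rhs(tab, mp, sp, gKs, Inoise, amid, Vl + 0.5 * ddt * k2V, hl + 0.5 * ddt * k2h,
        nl + 0.5 * ddt * k2n, zl + 0.5 * ddt * k2z, k3V, k3h, k3n, k3z);
    rhs(tab, mp, sp, gKs, Inoise, aend, Vl + ddt * k3V, hl + ddt * k3h,
        nl + ddt * k3n, zl + ddt * k3z, k4V, k4h, k4n, k4z);
    Vl += ddt / 6.0 * (k1V + 2.0 * k2V + 2.0 * k3V + k4V);
    hl += ddt / 6.0 * (k1h + 2.0 * k2h + 2.0 * k3h + k4h);
    nl += ddt / 6.0 * (k1n + 2.0 * k2n + 2.0 * k3n + k4n);
    zl += ddt / 6.0 * (k1z + 2.0 * k2z + 2.0 * k3z + k4z);
    for (int a = 0; a < NACC; ++a) al[a] = aend[a];
  }
  if (!std::isfinite(Vl) || std::fabs(Vl) > 500.0) return false;
  if (!clip_gate(hl) || !clip_gate(nl) || !clip_gate(zl)) return false;
  V = Vl; h = hl; n = nl; z = zl;
  for (int a = 0; a < NACC; ++a) acc[a] = al[a];
  return true;
}

// Substep count from the conductance bound (NMDA gate evaluated 40 mV up
// as a pessimistic cap on in-step activation).
static inline int choose_k(const GateTable &tab, const MemPar &mp,
                           const SynPar &sp, double gKs,
                           double V, double h, double n, double z,
                           const double *acc, double dt) {
  GateRow gg;
  tab.at(V + 40.0, gg);
  double gb = sp.P_AMPA * acc[A_AS] + sp.P_NMDA * gg.bnmda * acc[A_NS] +
              sp.P_GABA * acc[A_GS];
  double m40 = gg.minf;
  double n2b = n * n;
  double gint = mp.gNa * m40 * m40 * m40 * h + mp.gKd * n2b * n2b +
                gKs * z + mp.gL + 1.0;
  double load = (gb + gint) * dt;
  if (load <= 2.6) return 1;
  return (int)std::ceil(load / 2.0);
}

// Interleaved single-substep advance of two neurons: the RK4 stage chain is
// serial within one neuron, so processing two independent neurons in
// lockstep roughly doubles instruction-level parallelism on the hot path.
static void step_pair_1(const GateTable &tab, const MemPar &mp,
                        const SynPar &sp, double gKsA, double gKsB,
                        double InoA, double InoB, double dt,
                        const Decay &dec,
                        double *stA, double *stB,
                        double *accA, double *accB) {
  double amidA[NACC], aendA[NACC], amidB[NACC], aendB[NACC];
  amidA[A_AS] = accA[A_AS] * dec.dh_as; aendA[A_AS] = accA[A_AS] * dec.df_as;
  amidA[A_AF] = accA[A_AF] * dec.dh_f;  aendA[A_AF] = accA[A_AF] * dec.df_f;
  amidA[A_NS] = accA[A_NS] * dec.dh_ns; aendA[A_NS] = accA[A_NS] * dec.df_ns;
  amidA[A_NF] = accA[A_NF] * dec.dh_f;  aendA[A_NF] = accA[A_NF] * dec.df_f;
  amidA[A_GS] = accA[A_GS] * dec.dh_gs; aendA[A_GS] = accA[A_GS] * dec.df_gs;
  amidA[A_GF] = accA[A_GF] * dec.dh_f;  aendA[A_GF] = accA[A_GF] * dec.df_f;
  amidB[A_AS] = accB[A_AS] * dec.dh_as; aendB[A_AS] = accB[A_AS] * dec.df_as;
  amidB[A_AF] = accB[A_AF] * dec.dh_f;  aendB[A_AF] = accB[A_AF] * dec.df_f;
  amidB[A_NS] = accB[A_NS] * dec.dh_ns; aendB[A_NS] = accB[A_NS] * dec.df_ns;
  amidB[A_NF] = accB[A_NF] * dec.dh_f;  aendB[A_NF] = accB[A_NF] * dec.df_f;
  amidB[A_GS] = accB[A_GS] * dec.dh_gs; aendB[A_GS] = accB[A_GS] * dec.df_gs;
  amidB[A_GF] = accB[A_GF] * dec.dh_f;  aendB[A_GF] = accB[A_GF] * dec.df_f;

  double k1VA, k1hA, k1nA, k1zA, k2VA, k2hA, k2nA, k2zA;
  double k3VA, k3hA, k3nA, k3zA, k4VA, k4hA, k4nA, k4zA;
  double k1VB, k1hB, k1nB, k1zB, k2VB, k2hB, k2nB, k2zB;
  double k3VB, k3hB, k3nB, k3zB, k4VB, k4hB, k4nB, k4zB;
  const double VA = stA[0], hA = stA[1], nA = stA[2], zA = stA[3];
  const double VB = stB[0], hB = stB[1], nB = stB[2], zB = stB[3];
  rhs(tab, mp, sp, gKsA, InoA, accA, VA, hA, nA, zA, k1VA, k1hA, k1nA, k1zA);
  rhs(tab, mp, sp, gKsB, InoB, accB, VB, hB, nB, zB, k1VB, k1hB, k1nB, k1zB);
  rhs(tab, mp, sp, gKsA, InoA, amidA, VA + 0.5 * dt * k1VA, hA + 0.5 * dt * k1hA,
      nA + 0.5 * dt * k1nA, zA + 0.5 * dt * k1zA, k2VA, k2hA, k2nA, k2zA);
  rhs(tab, mp, sp, gKsB, InoB, amidB, VB + 0.5 * dt * k1VB, hB + 0.5 * dt * k1hB,
      nB + 0.5 * dt * k1nB, zB + 0.5 * dt * k1zB, k2VB, k2hB, k2nB, k2zB);
  rhs(tab, mp, sp, gKsA, InoA, amidA, VA + 0.5 * dt * k2VA, hA + 0.5 * dt * k2hA,
      nA + 0.5 * dt * k2nA, zA + 0.5 * dt * k2zA, k3VA, k3hA, k3nA, k3zA);
  rhs(tab, mp, sp, gKsB, InoB, amidB, VB + 0.5 * dt * k2VB, hB + 0.5 * dt * k2hB,
      nB + 0.5 * dt * k2nB, zB + 0.5 * dt * k2zB, k3VB, k3hB, k3nB, k3zB);
  rhs(tab, mp, sp, gKsA, InoA, aendA, VA + dt * k3VA, hA + dt * k3hA,
      nA + dt * k3nA, zA + dt * k3zA, k4VA, k4hA, k4nA, k4zA);
  rhs(tab, mp, sp, gKsB, InoB, aendB, VB + dt * k3VB, hB + dt * k3hB,
      nB + dt * k3nB, zB + dt * k3zB, k4VB, k4hB, k4nB, k4zB);
  stA[0] = VA + dt / 6.0 * (k1VA + 2.0 * k2VA + 2.0 * k3VA + k4VA);
  stA[1] = hA + dt / 6.0 * (k1hA + 2.0 * k2hA + 2.0 * k3hA + k4hA);
  stA[2] = nA + dt / 6.0 * (k1nA + 2.0 * k2nA + 2.0 * k3nA + k4nA);
  stA[3] = zA + dt / 6.0 * (k1zA + 2.0 * k2zA + 2.0 * k3zA + k4zA);
  stB[0] = VB + dt / 6.0 * (k1VB + 2.0 * k2VB + 2.0 * k3VB + k4VB);
  stB[1] = hB + dt / 6.0 * (k1hB + 2.0 * k2hB + 2.0 * k3hB + k4hB);
  stB[2] = nB + dt / 6.0 * (k1nB + 2.0 * k2nB + 2.0 * k3nB + k4nB);
  stB[3] = zB + dt / 6.0 * (k1zB + 2.0 * k2zB + 2.0 * k3zB + k4zB);
  for (int a = 0; a < NACC; ++a) { accA[a] = aendA[a]; accB[a] = aendB[a]; }
}

// Choose the substep count from a conductance bound (using the NMDA voltage
// gate evaluated 40 mV above the current voltage as a pessimistic cap on its
// in-step activation) and integrate, retrying with finer substeps if the
// explicit step turns out unstable anyway.
static bool step_neuron(const GateTable &tab, const MemPar &mp,
                        const SynPar &sp, double gKs,
                        double Inoise, double dt, const Decay &dec1,
                        double &V, double &h, double &n, double &z,
                        double *acc, bool &spiked, int k0 = 0) {
  int k = k0 > 0 ? k0
                 : choose_k(tab, mp, sp, gKs, V, h, n, z, acc, dt);
  const double Vprev = V;
  double V0 = V, h0 = h, n0 = n, z0 = z, a0[NACC];
  for (int a = 0; a < NACC; ++a) a0[a] = acc[a];
  for (int attempt = 0; attempt < 5; ++attempt) {
    if (k > 20000) return false;
    if (step_neuron_k(tab, mp, sp, gKs, Inoise, dt, dec1, k,
                      V, h, n, z, acc)) {
      spiked = (Vprev < 0.0 && V >= 0.0);
      return true;
    }
    // restore and refine
    V = V0; h = h0; n = n0; z = z0;
    for (int a = 0; a < NACC; ++a) acc[a] = a0[a];
    k *= 4;
  }
  return false;
}

// ---------------------------------------------------------------------------
// Network simulation.
//
// Neurons 0..n_exc-1 are excitatory, the rest inhibitory. Edges are 0-based
// (pre, post) with lognormal conductances; excitatory edges deliver AMPA+NMDA
// sharing the edge weight, inhibitory edges deliver GABA-A. Each presynaptic
// spike draws an event-scale factor v_half ~ U[0.5, 1] per edge. Weights are
// capped at w_cap for numerical stability (documented in the package
// vignette). Spikes within the transient are discarded; reported times are
// relative to the end of the transient.
// [[Rcpp::export]]
List cpp_simulate_network(int n_exc, int n_inh,
                          IntegerVector edge_pre, IntegerVector edge_post,
                          NumericVector edge_w,
                          List neuron_par, List syn_par, List noise_par,
                          double gKs_exc, double gKs_inh,
                          double duration, double dt, double transient,
                          double w_cap, int seed,
                          bool quiescent_init,
                          Nullable<NumericMatrix> init_state) {
  const int N = n_exc + n_inh;
  if (N <= 0) stop("network must contain at least one neuron");
  if (dt <= 0) stop("dt must be positive");
  if (duration < transient) stop("duration shorter than the transient");

  MemPar mp;
  mp.gNa = as<double>(neuron_par["g_Na"]);
  mp.gKd = as<double>(neuron_par["g_Kd"]);
  mp.gL = as<double>(neuron_par["g_L"]);
  mp.ENa = as<double>(neuron_par["E_Na"]);
  mp.EK = as<double>(neuron_par["E_K"]);
  mp.EL = as<double>(neuron_par["E_L"]);
  mp.Cm = as<double>(neuron_par["C_m"]);
  mp.IDC = as<double>(neuron_par["I_DC"]);

  SynPar sp;
  sp.tau_f = as<double>(syn_par["tau_fast"]);
  sp.tau_as = as<double>(syn_par["tau_ampa_slow"]);
  sp.tau_ns = as<double>(syn_par["tau_nmda_slow"]);
  sp.tau_gs = as<double>(syn_par["tau_gaba_slow"]);
  sp.E_exc = as<double>(syn_par["E_exc"]);
  sp.E_inh = as<double>(syn_par["E_inh"]);
  sp.P_AMPA = as<double>(syn_par["P_AMPA"]);
  sp.P_NMDA = as<double>(syn_par["P_NMDA"]);
  sp.P_GABA = as<double>(syn_par["P_GABA"]);

  double noise_rate = as<double>(noise_par["rate_hz"]) / 1000.0; // per ms
  double noise_dur = as<double>(noise_par["duration_ms"]);
  double noise_amp = as<double>(noise_par["amplitude"]);

  // CSR adjacency
  const int M = edge_pre.size();
  std::vector<int> deg(N, 0);
  for (int e = 0; e < M; ++e) deg[edge_pre[e]]++;
  std::vector<int> ptr(N + 1, 0);
  for (int i = 0; i < N; ++i) ptr[i + 1] = ptr[i] + deg[i];
  std::vector<int> tgt(M);
  std::vector<double> wgt(M);
  {
    std::vector<int> fill(ptr.begin(), ptr.end() - 1);
    for (int e = 0; e < M; ++e) {
      int p = edge_pre[e];
      double w = edge_w[e];
      if (w > w_cap) w = w_cap;
      tgt[fill[p]] = edge_post[e];
      wgt[fill[p]] = w;
      fill[p]++;
    }
  }

  // Two independent streams: membrane noise + initial conditions on one,
  // synaptic event scales on the other, so that coupling strength does not
  // perturb the noise realisation (an uncoupled network then matches the
  // union of isolated cells exactly).
  XRng rng((uint64_t)(uint32_t)seed);
  XRng rng_syn(((uint64_t)(uint32_t)seed) ^ 0xA5A5A5A512345678ULL);

  std::vector<double> V(N), h(N), n(N), z(N);
  std::vector<double> acc(N * NACC, 0.0);
  if (init_state.isNotNull()) {
    NumericMatrix im(init_state);
    if (im.nrow() != N || im.ncol() < 4) stop("init_state must be n_neurons x 4");
    for (int i = 0; i < N; ++i) {
      V[i] = im(i, 0); h[i] = im(i, 1); n[i] = im(i, 2); z[i] = im(i, 3);
    }
  } else if (quiescent_init) {
    for (int i = 0; i < N; ++i) {
      V[i] = -70.0;
      h[i] = f_hinf(-70.0); n[i] = f_ninf(-70.0); z[i] = f_zinf(-70.0);
    }
  } else {
    for (int i = 0; i < N; ++i) {
      V[i] = rng.unif(-72.0, -32.0);
      n[i] = rng.unif(0.2, 0.6);
      z[i] = rng.unif(0.2, 0.3);
      h[i] = rng.unif(0.2, 0.6);
    }
  }

  std::vector<double> next_pulse(N), pulse_end(N, -1.0);
  for (int i = 0; i < N; ++i)
    next_pulse[i] = (noise_rate > 0) ? rng.expvar(noise_rate) : 1e300;

  std::vector<double> last_spike(N, -1e9);
  std::vector<int> spk_id;
  std::vector<double> spk_t;
  std::vector<int> fired;
  fired.reserve(64);

  const GateTable &tab = gate_table();
  Decay dec1;
  dec1.set(sp, dt);
  std::vector<double> Ino(N);
  std::vector<double> state(N * 4);
  for (int i = 0; i < N; ++i) {
    state[4 * i] = V[i]; state[4 * i + 1] = h[i];
    state[4 * i + 2] = n[i]; state[4 * i + 3] = z[i];
  }
  const long nstep = (long)std::llround(duration / dt);
  for (long s = 0; s < nstep; ++s) {
    double t = s * dt;
    fired.clear();
    for (int i = 0; i < N; ++i) {
      if (t >= next_pulse[i]) {
        pulse_end[i] = next_pulse[i] + noise_dur;
        next_pulse[i] += rng.expvar(noise_rate);
      }
      Ino[i] = (t < pulse_end[i]) ? noise_amp : 0.0;
    }
    int i = 0;
    while (i < N) {
      double *st = &state[4 * i];
      double gKs = (i < n_exc) ? gKs_exc : gKs_inh;
      int ki = choose_k(tab, mp, sp, gKs, st[0], st[1], st[2], st[3],
                        &acc[i * NACC], dt);
      bool pairable = false;
      int j = i + 1;
      double *stj = NULL, gKsj = 0;
      if (ki == 1 && j < N) {
        stj = &state[4 * j];
        gKsj = (j < n_exc) ? gKs_exc : gKs_inh;
        pairable = choose_k(tab, mp, sp, gKsj, stj[0], stj[1], stj[2],
                            stj[3], &acc[j * NACC], dt) == 1;
      }
      if (pairable) {
        double savA[10], savB[10];
        for (int a = 0; a < 4; ++a) { savA[a] = st[a]; savB[a] = stj[a]; }
        for (int a = 0; a < NACC; ++a) {
          savA[4 + a] = acc[i * NACC + a]; savB[4 + a] = acc[j * NACC + a];
        }
        step_pair_1(tab, mp, sp, gKs, gKsj, Ino[i], Ino[j], dt, dec1,
                    st, stj, &acc[i * NACC], &acc[j * NACC]);
        bool okA = std::isfinite(st[0]) && std::fabs(st[0]) <= 500.0 &&
                   clip_gate(st[1]) && clip_gate(st[2]) && clip_gate(st[3]);
        bool okB = std::isfinite(stj[0]) && std::fabs(stj[0]) <= 500.0 &&
                   clip_gate(stj[1]) && clip_gate(stj[2]) && clip_gate(stj[3]);
        if (!okA || !okB) {
          // rare: redo both scalar (with retry) from the saved state
          for (int a = 0; a < 4; ++a) { st[a] = savA[a]; stj[a] = savB[a]; }
          for (int a = 0; a < NACC; ++a) {
            acc[i * NACC + a] = savA[4 + a]; acc[j * NACC + a] = savB[4 + a];
          }
          bool sp1 = false, sp2 = false;
          if (!step_neuron(tab, mp, sp, gKs, Ino[i], dt, dec1, st[0], st[1],
                           st[2], st[3], &acc[i * NACC], sp1, 4) ||
              !step_neuron(tab, mp, sp, gKsj, Ino[j], dt, dec1, stj[0],
                           stj[1], stj[2], stj[3], &acc[j * NACC], sp2, 4))
            stop("numerical integration failed near neuron %d at t = %.2f ms",
                 i, t);
          if (sp1) fired.push_back(i);
          if (sp2) fired.push_back(j);
          i += 2;
          continue;
        }
        if (savA[0] < 0.0 && st[0] >= 0.0) fired.push_back(i);
        if (savB[0] < 0.0 && stj[0] >= 0.0) fired.push_back(j);
        i += 2;
      } else {
        bool spiked = false;
        if (!step_neuron(tab, mp, sp, gKs, Ino[i], dt, dec1, st[0], st[1],
                         st[2], st[3], &acc[i * NACC], spiked, ki)) {
          stop("numerical integration failed for neuron %d at t = %.2f ms",
               i, t);
        }
        if (spiked) fired.push_back(i);
        i += 1;
      }
    }
    // refractory lockout + spike bookkeeping (fired is in ascending order)
    {
      size_t w = 0;
      for (size_t f = 0; f < fired.size(); ++f) {
        int id = fired[f];
        if ((t + dt - last_spike[id]) >= 2.0) {
          last_spike[id] = t + dt;
          fired[w++] = id;
          if (t + dt >= transient) {
            spk_id.push_back(id);
            spk_t.push_back(t + dt - transient);
          }
        }
      }
      fired.resize(w);
    }
    // synaptic delivery (zero axonal delay: effective from the next step)
    for (size_t f = 0; f < fired.size(); ++f) {
      int pre = fired[f];
      bool exc = pre < n_exc;
      for (int e = ptr[pre]; e < ptr[pre + 1]; ++e) {
        double inc = wgt[e] * rng_syn.unif(0.5, 1.0);
        double *a = &acc[tgt[e] * NACC];
        if (exc) {
          a[A_AS] += inc; a[A_AF] += inc;
          a[A_NS] += inc; a[A_NF] += inc;
        } else {
          a[A_GS] += inc; a[A_GF] += inc;
        }
      }
    }
    if ((s & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix fin(N, 4);
  for (int i = 0; i < N; ++i) {
    fin(i, 0) = state[4 * i]; fin(i, 1) = state[4 * i + 1];
    fin(i, 2) = state[4 * i + 2]; fin(i, 3) = state[4 * i + 3];
  }
  return List::create(_["neuron"] = wrap(spk_id),
                      _["time"] = wrap(spk_t),
                      _["final_state"] = fin);
}

// ---------------------------------------------------------------------------
// Single-cell simulation: constant extra current, optional deterministic
// current pulses and optional excitatory synaptic events (AMPA+NMDA sharing a
// weight, v_half = 1). Used for f-I curves, rheobase and the single-spike
// threshold bisection.
// [[Rcpp::export]]
List cpp_simulate_single(List neuron_par, double gKs, List syn_par,
                         double duration, double dt,
                         double I_extra,
                         NumericVector pulse_times, double pulse_dur,
                         double pulse_amp,
                         NumericVector event_times, NumericVector event_w,
                         NumericVector init, bool record_trace) {
  if (dt <= 0) stop("dt must be positive");
  MemPar mp;
  mp.gNa = as<double>(neuron_par["g_Na"]);
  mp.gKd = as<double>(neuron_par["g_Kd"]);
  mp.gL = as<double>(neuron_par["g_L"]);
  mp.ENa = as<double>(neuron_par["E_Na"]);
  mp.EK = as<double>(neuron_par["E_K"]);
  mp.EL = as<double>(neuron_par["E_L"]);
  mp.Cm = as<double>(neuron_par["C_m"]);
  mp.IDC = as<double>(neuron_par["I_DC"]);
  SynPar sp;
  sp.tau_f = as<double>(syn_par["tau_fast"]);
  sp.tau_as = as<double>(syn_par["tau_ampa_slow"]);
  sp.tau_ns = as<double>(syn_par["tau_nmda_slow"]);
  sp.tau_gs = as<double>(syn_par["tau_gaba_slow"]);
  sp.E_exc = as<double>(syn_par["E_exc"]);
  sp.E_inh = as<double>(syn_par["E_inh"]);
  sp.P_AMPA = as<double>(syn_par["P_AMPA"]);
  sp.P_NMDA = as<double>(syn_par["P_NMDA"]);
  sp.P_GABA = as<double>(syn_par["P_GABA"]);

  double V, h, n, z;
  if (init.size() >= 4) {
    V = init[0]; h = init[1]; n = init[2]; z = init[3];
  } else {
    V = -70.0; h = f_hinf(V); n = f_ninf(V); z = f_zinf(V);
  }
  double acc[NACC] = {0, 0, 0, 0, 0, 0};

  const GateTable &tab = gate_table();
  Decay dec1;
  dec1.set(sp, dt);
  const long nstep = (long)std::llround(duration / dt);
  std::vector<double> trace;
  if (record_trace) trace.reserve(nstep + 1);
  std::vector<double> spikes;
  double last_spike = -1e9;
  int next_pulse = 0, next_event = 0;

  if (record_trace) trace.push_back(V);
  for (long s = 0; s < nstep; ++s) {
    double t = s * dt;
    while (next_event < event_times.size() && event_times[next_event] <= t + 1e-12) {
      double inc = event_w[next_event];
      acc[A_AS] += inc; acc[A_AF] += inc;
      acc[A_NS] += inc; acc[A_NF] += inc;
      next_event++;
    }
    double Inoise = I_extra;
    while (next_pulse < pulse_times.size() &&
           pulse_times[next_pulse] + pulse_dur <= t) next_pulse++;
    if (next_pulse < pulse_times.size() && pulse_times[next_pulse] <= t &&
        t < pulse_times[next_pulse] + pulse_dur) Inoise += pulse_amp;
    bool spiked = false;
    if (!step_neuron(tab, mp, sp, gKs, Inoise, dt, dec1, V, h, n, z, acc, spiked))
      stop("numerical integration failed at t = %.2f ms", t);
    if (spiked && (t + dt - last_spike) >= 2.0) {
      last_spike = t + dt;
      spikes.push_back(t + dt);
    }
    if (record_trace) trace.push_back(V);
  }
  return List::create(_["spikes"] = wrap(spikes),
                      _["final_state"] = NumericVector::create(V, h, n, z),
                      _["trace"] = record_trace ? wrap(trace) : R_NilValue);
}

// ---------------------------------------------------------------------------
// Cross-correlogram: comparison-spike lags relative to each reference spike,
// binned at `binw` over `nbins` bins with edges lo + binw * (0..nbins).
// [[Rcpp::export]]
IntegerVector cpp_ccg_counts(NumericVector ref, NumericVector cmp,
                             double lo, double binw, int nbins) {
  IntegerVector counts(nbins);
  double hi = lo + binw * nbins;
  int j0 = 0;
  const int nr = ref.size(), nc = cmp.size();
  for (int i = 0; i < nr; ++i) {
    double t = ref[i];
    while (j0 < nc && cmp[j0] < t + lo) j0++;
    for (int j = j0; j < nc; ++j) {
      double lag = cmp[j] - t;
      if (lag >= hi) break;
      int b = (int)std::floor((lag - lo) / binw);
      if (b >= 0 && b < nbins) counts[b]++;
    }
  }
  return counts;
}

// Jittered-surrogate analysis for one ordered pair: observed CCG plus, for
// each of n_surr surrogates (comparison spikes jittered U[-jit, +jit]),
// the peak/trough within the strength window and the global extrema.
// [[Rcpp::export]]
List cpp_pair_surrogates(NumericVector ref, NumericVector cmp,
                         double lo, double binw, int nbins,
                         IntegerVector strength_bins, // 1-based bin indices
                         int n_surr, double jit, int seed) {
  IntegerVector obs = cpp_ccg_counts(ref, cmp, lo, binw, nbins);
  XRng rng((uint64_t)(uint32_t)seed);
  NumericVector s_peak(n_surr), s_trough(n_surr), g_peak(n_surr), g_trough(n_surr);
  NumericMatrix surr_counts_sum(2, nbins); // row 0: sum, row 1: sum of squares
  std::vector<double> jc(cmp.size());
  for (int s = 0; s < n_surr; ++s) {
    for (int j = 0; j < cmp.size(); ++j) jc[j] = cmp[j] + rng.unif(-jit, jit);
    std::sort(jc.begin(), jc.end());
    NumericVector jcv = wrap(jc);
    IntegerVector cs = cpp_ccg_counts(ref, jcv, lo, binw, nbins);
    double pk = R_NegInf, tr = R_PosInf, gpk = R_NegInf, gtr = R_PosInf;
    for (int b = 0; b < nbins; ++b) {
      double c = cs[b];
      if (c > gpk) gpk = c;
      if (c < gtr) gtr = c;
      surr_counts_sum(0, b) += c;
      surr_counts_sum(1, b) += c * c;
    }
    for (int k = 0; k < strength_bins.size(); ++k) {
      double c = cs[strength_bins[k] - 1];
      if (c > pk) pk = c;
      if (c < tr) tr = c;
    }
    s_peak[s] = pk; s_trough[s] = tr; g_peak[s] = gpk; g_trough[s] = gtr;
  }
  return List::create(_["observed"] = obs,
                      _["surr_peak"] = s_peak,
                      _["surr_trough"] = s_trough,
                      _["surr_global_peak"] = g_peak,
                      _["surr_global_trough"] = g_trough,
                      _["surr_bin_moments"] = surr_counts_sum);
}

// ---------------------------------------------------------------------------
// Pairwise mean phase coherence matrix. trains: list of sorted spike-time
// vectors. For ordered pair (i, j), each comparison spike of j that falls in
// a reference interspike interval of i contributes a unit phasor at phase
// (t_j - t_i,k) / (t_i,k+1 - t_i,k). Pairs without contributing spikes (or
// with < 2 reference spikes) are NA.
// [[Rcpp::export]]
NumericMatrix cpp_mpc_matrix(List trains) {
  const int N = trains.size();
  NumericMatrix sig(N, N);
  std::fill(sig.begin(), sig.end(), NA_REAL);
  std::vector<NumericVector> tr(N);
  for (int i = 0; i < N; ++i) tr[i] = as<NumericVector>(trains[i]);
  for (int i = 0; i < N; ++i) {
    const NumericVector &ri = tr[i];
    const int nr = ri.size();
    if (nr < 2) continue;
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      const NumericVector &cj = tr[j];
      double sre = 0.0, sim = 0.0;
      int cnt = 0, k = 0;
      for (int q = 0; q < cj.size(); ++q) {
        double t = cj[q];
        if (t < ri[0] || t >= ri[nr - 1]) continue;
        while (k + 1 < nr && ri[k + 1] <= t) k++;
        double phase = (t - ri[k]) / (ri[k + 1] - ri[k]);
        double ang = 2.0 * M_PI * phase;
        sre += std::cos(ang); sim += std::sin(ang);
        cnt++;
      }
      if (cnt > 0) sig(i, j) = std::sqrt(sre * sre + sim * sim) / cnt;
      k = 0;
    }
  }
  return sig;
}
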