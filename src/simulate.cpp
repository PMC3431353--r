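// Stochastic tug-of-war engine: overdamped Langevin cargo + stepping motors.
//
// Cargo: dx_c = (sum_i f_i / gamma) dt + sqrt(2 kBT dt / gamma) N(0,1)
// Motor i (attached): steps +pol*dx with prob v(L_i)/dx * dt,
//                     detaches with prob eps*exp(|f_i|/Fd) * dt.
// Motor i (detached): attaches with prob pi_att * dt, uniformly on the
//                     lattice sites strictly inside the slack zone |x-x_c|<x0.
//
// All per-event probabilities must stay <= 0.1 per dt (first-order thinning);
// exceeding the guard throws "dt_too_large" and the R wrapper refines dt.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// splitmix64: scrambles (seed, stream index) into a well-mixed 64-bit state,
// so per-trajectory RNG streams are decorrelated and order-independent.
inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// xoshiro256++ (Blackman & Vigna): fast counter-free generator; one
// instance per trajectory keeps ensembles order-independent.
struct Xoshiro256 {
  uint64_t s[4];
  explicit Xoshiro256(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) {
      sm += 0x9E3779B97F4A7C15ULL;
      uint64_t z = sm;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // uniform on [0, 1)
    return (double)(next() >> 11) * 0x1.0p-53;
  }
  // Marsaglia polar method with cached second deviate
  bool has_spare = false;
  double spare = 0.0;
  inline double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f; has_spare = true;
    return u * f;
  }
  inline long unif_int(long lo, long hi) {  // inclusive, small ranges
    uint64_t n = (uint64_t)(hi - lo + 1);
    return lo + (long)(next() % n);
  }
};

struct Motor {
  int pol;        // +1 forward, -1 backward
  double v0, Fs, w, eps, Fd, pi_att, k, x0, dx;
  double p_step0, p_det0, p_att;  // per-dt probabilities at zero load
  bool attached;
  double x;       // lattice position (multiple of dx) when attached
};

inline double linker_force(double d, double k, double x0) {
  if (d >= x0)  return k * (d - x0);
  if (d <= -x0) return k * (d + x0);
  return 0.0;
}

// load-velocity relation: v0 for assisting loads (capped), stall at L >= Fs
inline double step_velocity(double L, double v0, double Fs, double w) {
  if (L <= 0.0) return v0;
  if (L >= Fs)  return 0.0;
  double frac = L / Fs;
  double p = (w == 2.0) ? frac * frac : std::pow(frac, w);
  return v0 * (1.0 - p);
}

// uniform draw over lattice sites strictly inside |x - x_c| < x0
inline double draw_attach_site(double x_c, double x0, double dx,
                               Xoshiro256 &rng) {
  double lo = (x_c - x0) / dx, hi = (x_c + x0) / dx;
  long jlo = (long)std::ceil(lo), jhi = (long)std::floor(hi);
  if ((double)jlo == lo) ++jlo;  // zone is open: exclude |d| == x0
  if ((double)jhi == hi) --jhi;
  if (jhi < jlo) stop("internal error: no lattice site in attachment zone");
  return (double)rng.unif_int(jlo, jhi) * dx;
}

} // namespace

// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(List motors_in, double gamma, double kBT,
                  double dt, double t_max, double sample_dt,
                  double base_seed, int stream, bool noise,
                  bool stop_on_full_detach) {
  const int M = motors_in.size();
  std::vector<Motor> motors(M);
  for (int i = 0; i < M; ++i) {
    List m = motors_in[i];
    motors[i].pol    = as<int>(m["polarity"]);
    motors[i].v0     = as<double>(m["v0"]);
    motors[i].Fs     = as<double>(m["Fs"]);
    motors[i].w      = as<double>(m["w"]);
    motors[i].eps    = as<double>(m["eps"]);
    motors[i].Fd     = as<double>(m["Fd"]);
    motors[i].pi_att = as<double>(m["pi_att"]);
    motors[i].k      = as<double>(m["k"]);
    motors[i].x0     = as<double>(m["x0"]);
    motors[i].dx     = as<double>(m["dx"]);
    motors[i].p_step0 = motors[i].v0 / motors[i].dx * dt;
    motors[i].p_det0  = motors[i].eps * dt;
    motors[i].p_att   = motors[i].pi_att * dt;
    if (motors[i].p_step0 > 0.1 || motors[i].p_det0 > 0.1 ||
        motors[i].p_att > 0.1)
      stop("dt_too_large: per-event probability exceeded 0.1");
  }

  uint64_t s = (uint64_t)base_seed;
  s = splitmix64(s ^ splitmix64((uint64_t)(stream + 1)));
  Xoshiro256 rng(s);

  // initial condition: all motors engaged at relaxed (slack-zone) sites
  double x_c = 0.0;
  for (int i = 0; i < M; ++i) {
    motors[i].attached = true;
    motors[i].x = draw_attach_site(x_c, motors[i].x0, motors[i].dx, rng);
  }

  const long steps_per_sample = (long)std::lround(sample_dt / dt);
  const long n_samples = (long)std::floor(t_max / sample_dt + 1e-9) + 1;
  const double noise_amp = noise ? std::sqrt(2.0 * kBT * dt / gamma) : 0.0;

  NumericVector t_out(n_samples), xc_out(n_samples);
  IntegerMatrix att_out(n_samples, M);
  NumericMatrix xm_out(n_samples, M);
  IntegerVector nf_out(n_samples), nb_out(n_samples),
                qf_out(n_samples), qb_out(n_samples);

  std::vector<double> force(M);
  bool full_detach = false;
  long samples_done = 0;

  for (long samp = 0; samp < n_samples; ++samp) {
    // record current state
    t_out[samp] = (double)samp * sample_dt;
    xc_out[samp] = x_c;
    int nf = 0, nb = 0, qf = 0, qb = 0;
    for (int i = 0; i < M; ++i) {
      att_out(samp, i) = motors[i].attached ? 1 : 0;
      xm_out(samp, i) = motors[i].attached ? motors[i].x : NA_REAL;
      if (motors[i].attached) {
        bool pulling = std::fabs(motors[i].x - x_c) > motors[i].x0;
        if (motors[i].pol > 0) { ++nf; if (pulling) ++qf; }
        else                   { ++nb; if (pulling) ++qb; }
      }
    }
    nf_out[samp] = nf; nb_out[samp] = nb;
    qf_out[samp] = qf; qb_out[samp] = qb;
    samples_done = samp + 1;
    if (full_detach && stop_on_full_detach) break;
    if (samp == n_samples - 1) break;

    // advance one sampling interval
    for (long k = 0; k < steps_per_sample; ++k) {
      double fsum = 0.0;
      for (int i = 0; i < M; ++i) {
        if (motors[i].attached) {
          force[i] = linker_force(motors[i].x - x_c, motors[i].k, motors[i].x0);
          fsum += force[i];
        } else {
          force[i] = 0.0;
        }
      }
      // cargo Euler-Maruyama update
      x_c += (fsum / gamma) * dt;
      if (noise) x_c += noise_amp * rng.norm();

      // motor events (independent Bernoulli thinning within dt)
      int n_att = 0;
      for (int i = 0; i < M; ++i) {
        Motor &m = motors[i];
        if (m.attached) {
          double p_step, p_det;
          if (force[i] == 0.0) {
            p_step = m.p_step0;
            p_det = m.p_det0;
          } else {
            double L = m.pol > 0 ? force[i] : -force[i];
            p_step = step_velocity(L, m.v0, m.Fs, m.w) / m.dx * dt;
            p_det = m.p_det0 * std::exp(std::fabs(force[i]) / m.Fd);
            if (p_det > 0.1)
              stop("dt_too_large: per-event probability exceeded 0.1");
          }
          if (p_step > 0.0 && rng.unif() < p_step) m.x += m.pol * m.dx;
          if (rng.unif() < p_det) m.attached = false;
        } else {
          if (m.p_att > 0.0 && rng.unif() < m.p_att) {
            m.attached = true;
            m.x = draw_attach_site(x_c, m.x0, m.dx, rng);
          }
        }
        if (m.attached) ++n_att;
      }
      if (n_att == 0 && stop_on_full_detach) { full_detach = true; break; }
    }
  }

  // truncate to recorded samples
  Range keep(0, samples_done - 1);
  IntegerMatrix att_keep(samples_done, M);
  NumericMatrix xm_keep(samples_done, M);
  for (int i = 0; i < M; ++i)
    for (long ss = 0; ss < samples_done; ++ss) {
      att_keep(ss, i) = att_out(ss, i);
      xm_keep(ss, i) = xm_out(ss, i);
    }
  return List::create(
    _["t"] = t_out[keep],
    _["x_c"] = xc_out[keep],
    _["attached"] = att_keep,
    _["x_m"] = xm_keep,
    _["nf"] = nf_out[keep],
    _["nb"] = nb_out[keep],
    _["qf"] = qf_out[keep],
    _["qb"] = qb_out[keep],
    _["termination"] = full_detach ? "full_detach" : "t_max");
}
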