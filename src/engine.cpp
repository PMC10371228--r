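#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <climits>
#include <cmath>
using namespace Rcpp;

// Fast counter-based RNG for the hot loop (xoshiro256++), seeded from R's RNG
// stream so that set.seed() fully determines every trajectory.
static inline uint64_t rotl64(const uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro() {
    // two 32-bit words per state element, drawn from R's RNG
    for (int i = 0; i < 4; i++) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo;
    }
    if ((s[0] | s[1] | s[2] | s[3]) == 0) s[0] = 0x9E3779B97F4A7C15ULL;
    for (int i = 0; i < 16; i++) next();  // warm up
  }
  inline uint64_t next() {
    const uint64_t result = rotl64(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl64(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline int below(int n) {  // uniform integer in [0, n), multiply-shift
    return (int)(((uint64_t)(uint32_t)next() * (uint64_t)n) >> 32);
  }
  // geometric countdown: number of further Bernoulli(p) trials skipped
  // before the next success (0 = the next trial fires); exact inverse CDF
  inline long geom(double p) {
    if (p <= 0) return LONG_MAX;
    if (p >= 1) return 0;
    double u = unif();
    while (u <= 0) u = unif();
    double g = std::floor(std::log(u) / std::log1p(-p));
    return g > 1e18 ? LONG_MAX : (long)g;
  }
};

// occupancy codes
#define EMPTY 0
#define CCELL 1
#define FCELL 2

// ledger columns
enum {
  L_ICSTA = 0, L_ICEXA, L_IFSTA, L_IFEXA,
  L_PCBAS, L_PCIND, L_DCBAS, L_DCIND, L_DF,
  L_NC, L_NF, L_NCOL
};

struct Params {
  double p_ista_C, p_ista_F, p_iexa_C, p_iexa_F;
  int exac_burst, exac_per_year;
  double p_C, p_C_F, p_dC, p_dC_plus, p_dF;
  int k_crowd;
  double p_move_C, p_move_F, beta_C, beta_F;
};

static Params read_params(const List& par) {
  Params p;
  p.p_ista_C  = as<double>(par["p_ista_C"]);
  p.p_ista_F  = as<double>(par["p_ista_F"]);
  p.p_iexa_C  = as<double>(par["p_iexa_C"]);
  p.p_iexa_F  = as<double>(par["p_iexa_F"]);
  p.exac_burst = as<int>(par["exac_burst"]);
  p.exac_per_year = as<int>(par["exac_per_year"]);
  p.p_C       = as<double>(par["p_C"]);
  p.p_C_F     = as<double>(par["p_C_F"]);
  p.p_dC      = as<double>(par["p_dC"]);
  p.p_dC_plus = as<double>(par["p_dC_plus"]);
  p.p_dF      = as<double>(par["p_dF"]);
  p.k_crowd   = as<int>(par["k_crowd"]);
  p.p_move_C  = as<double>(par["p_move_C"]);
  p.p_move_F  = as<double>(par["p_move_F"]);
  p.beta_C    = as<double>(par["beta_C"]);
  p.beta_F    = as<double>(par["beta_F"]);
  return p;
}

// Run the automaton for n_steps 3-minute iterations on a domain given by its
// Moore-neighbour table.  One cell per site; per step: (optional) exacerbation
// burst at year boundaries, stable-state infiltration, then every cell in a
// fresh random order attempts one action with priority death -> division (C
// only) -> movement.  Death and division trials are advanced by per-cell
// geometric countdowns at the zone probabilities (p_dC_plus / p_dF and
// p_C_F), which is distributionally identical to independent per-step
// Bernoulli draws; the basal-vs-induced split is resolved when a countdown
// fires.  Events are accumulated per month of `month_len` steps.
//
// occ: length n_sites, 0 empty / 1 C / 2 F (not modified; copied)
// nbr: n_sites x 8 matrix of 0-based neighbour indices, -1 where absent
// step_offset: steps already elapsed before this phase (year boundaries are
//   counted in absolute time so multi-phase runs keep their annual schedule)
// [[Rcpp::export]]
List cpp_run_phase(IntegerVector occ_in, IntegerMatrix nbr, List par,
                   int n_steps, int month_len, int year_len, int step_offset) {
  Params P = read_params(par);
  const int n_sites = occ_in.size();
  std::vector<int> occ(occ_in.begin(), occ_in.end());

  Xoshiro rng;  // consumes R RNG for seeding (RNGScope via Rcpp attributes)

  // cell registry: parallel arrays, site < 0 marks a dead slot
  std::vector<int> cell_site, cell_type;
  std::vector<long> cnt_death, cnt_div;
  cell_site.reserve(4096); cell_type.reserve(4096);
  cnt_death.reserve(4096); cnt_div.reserve(4096);
  int n_occ = 0, nC = 0, nF = 0;

  const double death_zone_C = P.p_dC_plus;   // >= p_dC by validation
  const double div_zone_C = P.p_C_F;         // >= p_C by validation

  for (int s = 0; s < n_sites; s++) {
    if (occ[s] != EMPTY) {
      cell_site.push_back(s);
      cell_type.push_back(occ[s]);
      if (occ[s] == CCELL) {
        cnt_death.push_back(rng.geom(death_zone_C));
        cnt_div.push_back(rng.geom(div_zone_C));
        nC++;
      } else {
        cnt_death.push_back(rng.geom(P.p_dF));
        cnt_div.push_back(LONG_MAX);
        nF++;
      }
      n_occ++;
    }
  }

  // movement bias lookup: weight exp(beta * n_opp), n_opp in 0..8
  double wtab_C[9], wtab_F[9];
  for (int k = 0; k <= 8; k++) {
    wtab_C[k] = std::exp(P.beta_C * k);
    wtab_F[k] = std::exp(P.beta_F * k);
  }

  const int n_months = n_steps / month_len;
  NumericMatrix ledger(n_months, L_NCOL);
  std::vector<double> acc(L_NCOL, 0.0);

  const int exac_every = (P.exac_per_year > 0 && year_len > 0)
                           ? year_len / P.exac_per_year : 0;

  std::vector<int> order; order.reserve(4096);

  for (int t = 1; t <= n_steps; t++) {
    // -- exacerbation burst on the annual schedule --------------------------
    if (exac_every > 0 && ((step_offset + t) % exac_every == 0)) {
      for (int b = 0; b < P.exac_burst && n_occ < n_sites; b++) {
        if (P.p_iexa_F > 0 && rng.unif() < P.p_iexa_F) {
          int s; do { s = rng.below(n_sites); } while (occ[s] != EMPTY);
          occ[s] = FCELL; cell_site.push_back(s); cell_type.push_back(FCELL);
          cnt_death.push_back(rng.geom(P.p_dF)); cnt_div.push_back(LONG_MAX);
          n_occ++; nF++; acc[L_IFEXA] += 1;
        }
        if (n_occ >= n_sites) break;
        if (P.p_iexa_C > 0 && rng.unif() < P.p_iexa_C) {
          int s; do { s = rng.below(n_sites); } while (occ[s] != EMPTY);
          occ[s] = CCELL; cell_site.push_back(s); cell_type.push_back(CCELL);
          cnt_death.push_back(rng.geom(death_zone_C));
          cnt_div.push_back(rng.geom(div_zone_C));
          n_occ++; nC++; acc[L_ICEXA] += 1;
        }
      }
    }

    // -- stable-state infiltration: at most one cell of each type per step --
    if (n_occ < n_sites && P.p_ista_C > 0 && rng.unif() < P.p_ista_C) {
      int s; do { s = rng.below(n_sites); } while (occ[s] != EMPTY);
      occ[s] = CCELL; cell_site.push_back(s); cell_type.push_back(CCELL);
      cnt_death.push_back(rng.geom(death_zone_C));
      cnt_div.push_back(rng.geom(div_zone_C));
      n_occ++; nC++; acc[L_ICSTA] += 1;
    }
    if (n_occ < n_sites && P.p_ista_F > 0 && rng.unif() < P.p_ista_F) {
      int s; do { s = rng.below(n_sites); } while (occ[s] != EMPTY);
      occ[s] = FCELL; cell_site.push_back(s); cell_type.push_back(FCELL);
      cnt_death.push_back(rng.geom(P.p_dF)); cnt_div.push_back(LONG_MAX);
      n_occ++; nF++; acc[L_IFSTA] += 1;
    }

    // -- compact registry (deferred: dead slots are rare) and draw order ----
    if ((int)cell_site.size() - n_occ > 32) {
      size_t keep = 0;
      for (size_t i = 0; i < cell_site.size(); i++) {
        if (cell_site[i] >= 0) {
          cell_site[keep] = cell_site[i];
          cell_type[keep] = cell_type[i];
          cnt_death[keep] = cnt_death[i];
          cnt_div[keep] = cnt_div[i];
          keep++;
        }
      }
      cell_site.resize(keep); cell_type.resize(keep);
      cnt_death.resize(keep); cnt_div.resize(keep);
    }
    const int ncell = (int)cell_site.size();
    order.resize(ncell);
    for (int i = 0; i < ncell; i++) order[i] = i;
    for (int i = ncell - 1; i > 0; i--) {  // Fisher-Yates
      int j = rng.below(i + 1);
      int tmp = order[i]; order[i] = order[j]; order[j] = tmp;
    }

    // -- per-cell updates ---------------------------------------------------
    for (int oi = 0; oi < ncell; oi++) {
      const int id = order[oi];
      const int s = cell_site[id];
      if (s < 0) continue;  // died earlier this step
      const int ty = cell_type[id];

      if (ty == CCELL) {
        // death trial at the zone probability p_dC_plus
        if (cnt_death[id] == 0) {
          cnt_death[id] = rng.geom(death_zone_C);
          bool dies = false, induced = false;
          if (death_zone_C <= 0 || rng.unif() < P.p_dC / death_zone_C) {
            dies = true;            // within the basal sub-zone
          } else {
            int ncn = 0;
            for (int k = 0; k < 8; k++) {
              int nb = nbr(s, k);
              if (nb >= 0 && occ[nb] == CCELL) ncn++;
            }
            if (ncn >= P.k_crowd) { dies = true; induced = true; }
          }
          if (dies) {
            occ[s] = EMPTY; cell_site[id] = -1; n_occ--; nC--;
            acc[induced ? L_DCIND : L_DCBAS] += 1;
            continue;
          }
        } else {
          cnt_death[id]--;
        }
        // division trial at the zone probability p_C_F
        if (cnt_div[id] == 0) {
          cnt_div[id] = rng.geom(div_zone_C);
          bool attempt = false, induced = false;
          if (div_zone_C <= 0 || rng.unif() < P.p_C / div_zone_C) {
            attempt = true;         // basal division sub-zone
          } else {
            for (int k = 0; k < 8; k++) {
              int nb = nbr(s, k);
              if (nb >= 0 && occ[nb] == FCELL) { attempt = true; induced = true; break; }
            }
          }
          if (attempt) {
            int cand[8], nc = 0;
            for (int k = 0; k < 8; k++) {
              int nb = nbr(s, k);
              if (nb >= 0 && occ[nb] == EMPTY) cand[nc++] = nb;
            }
            if (nc > 0) {  // silently fails when no empty neighbour
              int d = cand[rng.below(nc)];
              occ[d] = CCELL; cell_site.push_back(d); cell_type.push_back(CCELL);
              cnt_death.push_back(rng.geom(death_zone_C));
              cnt_div.push_back(rng.geom(div_zone_C));
              n_occ++; nC++;
              acc[induced ? L_PCIND : L_PCBAS] += 1;
            }
            continue;  // division attempt consumes the step's action
          }
        } else {
          cnt_div[id]--;
        }
      } else {  // fibrocyte: basal death only, no proliferation
        if (cnt_death[id] == 0) {
          occ[s] = EMPTY; cell_site[id] = -1; n_occ--; nF--;
          acc[L_DF] += 1;
          continue;
        }
        cnt_death[id]--;
      }

      // movement to an empty Moore neighbour, biased by opposite-type contacts
      const double pmv = (ty == CCELL) ? P.p_move_C : P.p_move_F;
      if (pmv > 0 && rng.unif() < pmv) {
        int cand[8], nc = 0;
        for (int k = 0; k < 8; k++) {
          int nb = nbr(s, k);
          if (nb >= 0 && occ[nb] == EMPTY) cand[nc++] = nb;
        }
        if (nc > 0) {
          int dest;
          const double beta = (ty == CCELL) ? P.beta_C : P.beta_F;
          if (beta == 0.0) {
            dest = cand[rng.below(nc)];
          } else {
            const double* wtab = (ty == CCELL) ? wtab_C : wtab_F;
            const int opp = (ty == CCELL) ? FCELL : CCELL;
            double w[8], tot = 0.0;
            for (int c = 0; c < nc; c++) {
              int nopp = 0;
              for (int k = 0; k < 8; k++) {
                int nb = nbr(cand[c], k);
                if (nb >= 0 && occ[nb] == opp) nopp++;
              }
              w[c] = wtab[nopp];
              tot += w[c];
            }
            double r = rng.unif() * tot;
            int c = 0;
            while (c < nc - 1 && r > w[c]) { r -= w[c]; c++; }
            dest = cand[c];
          }
          occ[s] = EMPTY; occ[dest] = ty; cell_site[id] = dest;
        }
      }
    }

    // -- monthly ledger row -------------------------------------------------
    if (t % month_len == 0) {
      int m = t / month_len - 1;
      if (m < n_months) {
        for (int c = 0; c < L_NC; c++) { ledger(m, c) = acc[c]; acc[c] = 0.0; }
        ledger(m, L_NC) = nC;
        ledger(m, L_NF) = nF;
      }
    }
  }

  IntegerVector occ_out(occ.begin(), occ.end());
  colnames(ledger) = CharacterVector::create(
    "iC_sta", "iC_exa", "iF_sta", "iF_exa",
    "pC_basal", "pC_induced", "dC_basal", "dC_induced", "dF", "N_C", "N_F");
  // residual (partial-month) event counts, for single-step unit runs
  NumericVector resid(L_NC);
  for (int c = 0; c < L_NC; c++) resid[c] = acc[c];
  resid.names() = CharacterVector::create(
    "iC_sta", "iC_exa", "iF_sta", "iF_exa",
    "pC_basal", "pC_induced", "dC_basal", "dC_induced", "dF");

  return List::create(_["occ"] = occ_out, _["ledger"] = ledger,
                      _["residual_events"] = resid,
                      _["N_C"] = nC, _["N_F"] = nF);
}
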