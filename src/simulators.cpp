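// Stochastic cores for the smFRET trajectory simulators and the
// scanning-collision activation model. All randomness goes through R's RNG
// (unif_rand / norm_rand) so set.seed() on the R side gives bit-identical
// trajectories.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <utility>
#include <set>
using namespace Rcpp;

// Fold x into [lo, hi] by reflection (reflecting boundaries / hard-core walls).
static inline double reflect_into(double x, double lo, double hi) {
  if (hi <= lo) return lo;
  double span = hi - lo;
  while (x < lo || x > hi) {
    if (x < lo) x = 2.0 * lo - x;
    if (x > hi) x = 2.0 * hi - x;
    // pathological huge excursions: clamp via modular fold
    if (x < lo - 4.0 * span || x > hi + 4.0 * span) {
      double z = std::fabs(x - lo);
      double p = 2.0 * span;
      x = lo + (z - std::floor(z / p) * p);
    }
  }
  return x;
}

// [[Rcpp::export]]
List cpp_simulate_trajectory(int n_frames, int substeps, double dt,
                             double l_eff, double diffusion,
                             double kon_c, double koff) {
  LogicalVector bound(n_frames);
  NumericVector pos(n_frames, NA_REAL);
  bool b = false;
  double x = 0.0;
  const double p_bind = 1.0 - std::exp(-kon_c * dt);
  const double p_unbind = 1.0 - std::exp(-koff * dt);
  const double step_sd = std::sqrt(2.0 * diffusion * dt);
  for (int f = 0; f < n_frames; ++f) {
    double sum = 0.0;
    int nb = 0;
    for (int s = 0; s < substeps; ++s) {
      if (!b) {
        if (unif_rand() < p_bind) {
          b = true;
          x = unif_rand() * l_eff;
        }
      } else if (unif_rand() < p_unbind) {
        b = false;
      } else if (step_sd > 0.0) {
        x = reflect_into(x + norm_rand() * step_sd, 0.0, l_eff);
      }
      if (b) { sum += x; ++nb; }
    }
    bound[f] = b;
    if (b) pos[f] = sum / nb;
  }
  return List::create(_["bound"] = bound, _["position"] = pos);
}

// Sample a uniform position for a footprint of width fp on [0, L - fp],
// excluding intervals blocked by occupants at occ_x with widths occ_fp.
// Returns -1 if no feasible placement exists.
static double sample_feasible(double L, double fp,
                              const std::vector<double>& occ_x,
                              const std::vector<double>& occ_fp) {
  // allowed left-edge range [0, L - fp] minus union of (x - fp, x + w)
  std::vector<std::pair<double, double> > blocked;
  for (size_t i = 0; i < occ_x.size(); ++i) {
    blocked.push_back(std::make_pair(occ_x[i] - fp, occ_x[i] + occ_fp[i]));
  }
  std::sort(blocked.begin(), blocked.end());
  std::vector<std::pair<double, double> > allowed;
  double lo = 0.0, hi = L - fp;
  double cur = lo;
  for (size_t i = 0; i < blocked.size(); ++i) {
    double b0 = std::max(blocked[i].first, lo);
    double b1 = std::min(blocked[i].second, hi);
    if (b1 < cur) continue;
    if (b0 > cur) allowed.push_back(std::make_pair(cur, std::min(b0, hi)));
    cur = std::max(cur, b1);
    if (cur >= hi) break;
  }
  if (cur < hi) allowed.push_back(std::make_pair(cur, hi));
  double total = 0.0;
  for (size_t i = 0; i < allowed.size(); ++i) total += allowed[i].second - allowed[i].first;
  if (total <= 0.0) {
    // degenerate: maybe a zero-length allowed point survives; reject
    return -1.0;
  }
  double u = unif_rand() * total;
  for (size_t i = 0; i < allowed.size(); ++i) {
    double w = allowed[i].second - allowed[i].first;
    if (u <= w) return allowed[i].first + u;
    u -= w;
  }
  return allowed.back().second;
}

// Allowed interval for a particle currently at x (width fp) on [0, L - fp],
// bounded by the nearest occupants on either side.
static void neighbour_bounds(double x, double fp, double L,
                             const std::vector<double>& occ_x,
                             const std::vector<double>& occ_fp,
                             double* lo, double* hi) {
  *lo = 0.0;
  *hi = L - fp;
  for (size_t i = 0; i < occ_x.size(); ++i) {
    if (occ_x[i] + occ_fp[i] <= x + 1e-12 && occ_x[i] + occ_fp[i] > *lo) {
      *lo = occ_x[i] + occ_fp[i];
    }
    if (occ_x[i] - fp >= x - 1e-12 && occ_x[i] - fp < *hi) {
      *hi = occ_x[i] - fp;
    }
  }
}

// Single PKR + n_pact obstacle particles on one duplex.
// pact_init: initial left-edge positions (NaN = start unbound).
// [[Rcpp::export]]
List cpp_simulate_obstacle(int n_frames, int substeps, double dt,
                           double duplex_length, double fp_pkr, double fp_pact,
                           double diffusion, double kon_c, double koff,
                           double pact_diffusion, double pact_kon_c,
                           double pact_koff, double evict_prob,
                           double contact_tol, NumericVector pact_init) {
  const int n_pact = pact_init.size();
  LogicalVector bound(n_frames);
  NumericVector pos(n_frames, NA_REAL);
  LogicalMatrix pact_bound(n_frames, n_pact);
  NumericMatrix pact_pos(n_frames, n_pact);
  std::fill(pact_pos.begin(), pact_pos.end(), NA_REAL);
  int evictions = 0;

  bool b = false;
  double x = 0.0;
  std::vector<bool> pb(n_pact, false);
  std::vector<double> px(n_pact, 0.0);
  std::vector<bool> in_contact(n_pact, false);
  for (int j = 0; j < n_pact; ++j) {
    if (!ISNAN(pact_init[j])) { pb[j] = true; px[j] = pact_init[j]; }
  }

  const double p_bind = 1.0 - std::exp(-kon_c * dt);
  const double p_unbind = 1.0 - std::exp(-koff * dt);
  const double pp_bind = 1.0 - std::exp(-pact_kon_c * dt);
  const double pp_unbind = 1.0 - std::exp(-pact_koff * dt);
  const double sd_pkr = std::sqrt(2.0 * diffusion * dt);
  const double sd_pact = std::sqrt(2.0 * pact_diffusion * dt);

  std::vector<double> occ_x, occ_fp;
  for (int f = 0; f < n_frames; ++f) {
    double sum = 0.0;
    int nb = 0;
    for (int s = 0; s < substeps; ++s) {
      // --- PKR update ---
      if (!b) {
        if (unif_rand() < p_bind) {
          occ_x.clear(); occ_fp.clear();
          for (int j = 0; j < n_pact; ++j) {
            if (pb[j]) { occ_x.push_back(px[j]); occ_fp.push_back(fp_pact); }
          }
          double xs = sample_feasible(duplex_length, fp_pkr, occ_x, occ_fp);
          if (xs >= 0.0) { b = true; x = xs; }
        }
      } else if (unif_rand() < p_unbind) {
        b = false;
        std::fill(in_contact.begin(), in_contact.end(), false);
      } else if (sd_pkr > 0.0) {
        occ_x.clear(); occ_fp.clear();
        for (int j = 0; j < n_pact; ++j) {
          if (pb[j]) { occ_x.push_back(px[j]); occ_fp.push_back(fp_pact); }
        }
        double lo, hi;
        neighbour_bounds(x, fp_pkr, duplex_length, occ_x, occ_fp, &lo, &hi);
        x = reflect_into(x + norm_rand() * sd_pkr, lo, hi);
      }
      // --- PACT updates ---
      for (int j = 0; j < n_pact; ++j) {
        if (!pb[j]) {
          if (unif_rand() < pp_bind) {
            occ_x.clear(); occ_fp.clear();
            if (b) { occ_x.push_back(x); occ_fp.push_back(fp_pkr); }
            for (int k = 0; k < n_pact; ++k) {
              if (k != j && pb[k]) { occ_x.push_back(px[k]); occ_fp.push_back(fp_pact); }
            }
            double xs = sample_feasible(duplex_length, fp_pact, occ_x, occ_fp);
            if (xs >= 0.0) { pb[j] = true; px[j] = xs; }
          }
        } else if (unif_rand() < pp_unbind) {
          pb[j] = false;
          in_contact[j] = false;
        } else if (sd_pact > 0.0) {
          occ_x.clear(); occ_fp.clear();
          if (b) { occ_x.push_back(x); occ_fp.push_back(fp_pkr); }
          for (int k = 0; k < n_pact; ++k) {
            if (k != j && pb[k]) { occ_x.push_back(px[k]); occ_fp.push_back(fp_pact); }
          }
          double lo, hi;
          neighbour_bounds(px[j], fp_pact, duplex_length, occ_x, occ_fp, &lo, &hi);
          px[j] = reflect_into(px[j] + norm_rand() * sd_pact, lo, hi);
        }
      }
      // --- contact / eviction ---
      if (b) {
        for (int j = 0; j < n_pact; ++j) {
          if (!pb[j]) { in_contact[j] = false; continue; }
          double gap = (px[j] >= x) ? px[j] - (x + fp_pkr) : x - (px[j] + fp_pact);
          bool now = gap <= contact_tol;
          if (now && !in_contact[j]) {
            // new collision
            if (evict_prob > 0.0 && unif_rand() < evict_prob) {
              b = false;
              ++evictions;
              std::fill(in_contact.begin(), in_contact.end(), false);
              break;
            }
          }
          in_contact[j] = now;
        }
      }
      if (b) { sum += x; ++nb; }
    }
    bound[f] = b;
    if (b) pos[f] = sum / nb;
    for (int j = 0; j < n_pact; ++j) {
      pact_bound(f, j) = pb[j];
      if (pb[j]) pact_pos(f, j) = px[j];
    }
  }
  return List::create(_["bound"] = bound, _["position"] = pos,
                      _["pact_bound"] = pact_bound, _["pact_position"] = pact_pos,
                      _["evictions"] = evictions);
}

// Scanning-collision activation model: n_pkr + n_pact particles on n_dup
// duplexes, fixed-step kinetic Monte Carlo. Trans-only phosphorylation on new
// PKR-PKR contacts; eviction on new PKR-PACT contacts.
// [[Rcpp::export]]
List cpp_simulate_activation(int n_steps, double dt, int record_every,
                             int n_pkr, int n_pact, int n_dup,
                             double duplex_length,
                             double fp_pkr, double fp_pact,
                             double pkr_diffusion, double pact_diffusion,
                             double p_pkr_bind, double p_pkr_off,
                             double p_pact_bind, double p_pact_off,
                             double p_phos, double p_evict,
                             double contact_tol) {
  std::vector<int> dup_pkr(n_pkr, -1), dup_pact(n_pact, -1);
  std::vector<double> x_pkr(n_pkr, 0.0), x_pact(n_pact, 0.0);
  std::vector<bool> phos(n_pkr, false);
  const double sd_pkr = std::sqrt(2.0 * pkr_diffusion * dt);
  const double sd_pact = std::sqrt(2.0 * pact_diffusion * dt);

  int n_rec = n_steps / record_every + 1;
  NumericVector rec_t(n_rec), rec_phos(n_rec);
  NumericVector rec_cooc(n_rec);     // fraction of duplexes with >=1 PKR & >=1 PACT
  NumericVector rec_pact_occ(n_rec); // fraction of duplex bp covered by PACT
  NumericVector rec_multi(n_rec);    // mean PKR count on PKR-occupied duplexes
  int rec_i = 0;

  // species: 0 = PKR, 1 = PACT; ids 0..n_pkr-1 PKR, n_pkr.. PACT
  std::set<std::pair<int, int> > prev_contacts, cur_contacts;
  std::vector<std::vector<int> > occupants(n_dup); // molecule ids per duplex

  for (int step = 0; step <= n_steps; ++step) {
    if (step % record_every == 0 && rec_i < n_rec) {
      rec_t[rec_i] = step * dt;
      int np = 0;
      for (int i = 0; i < n_pkr; ++i) if (phos[i]) ++np;
      rec_phos[rec_i] = n_pkr > 0 ? (double)np / n_pkr : 0.0;
      std::vector<int> cnt_pkr(n_dup, 0), cnt_pact(n_dup, 0);
      for (int i = 0; i < n_pkr; ++i) if (dup_pkr[i] >= 0) ++cnt_pkr[dup_pkr[i]];
      for (int i = 0; i < n_pact; ++i) if (dup_pact[i] >= 0) ++cnt_pact[dup_pact[i]];
      int cooc = 0, occd = 0, tot_on_occ = 0, pact_bound = 0;
      for (int d = 0; d < n_dup; ++d) {
        if (cnt_pkr[d] > 0) { ++occd; tot_on_occ += cnt_pkr[d]; }
        if (cnt_pkr[d] > 0 && cnt_pact[d] > 0) ++cooc;
        pact_bound += cnt_pact[d];
      }
      rec_cooc[rec_i] = n_dup > 0 ? (double)cooc / n_dup : 0.0;
      rec_pact_occ[rec_i] = n_dup > 0 ? pact_bound * fp_pact / (n_dup * duplex_length) : 0.0;
      rec_multi[rec_i] = occd > 0 ? (double)tot_on_occ / occd : 0.0;
      ++rec_i;
    }
    if (step == n_steps) break;

    // 1. dissociation
    for (int i = 0; i < n_pkr; ++i) {
      if (dup_pkr[i] >= 0 && unif_rand() < p_pkr_off) dup_pkr[i] = -1;
    }
    for (int i = 0; i < n_pact; ++i) {
      if (dup_pact[i] >= 0 && unif_rand() < p_pact_off) dup_pact[i] = -1;
    }

    // occupancy snapshot
    for (int d = 0; d < n_dup; ++d) occupants[d].clear();
    for (int i = 0; i < n_pkr; ++i) if (dup_pkr[i] >= 0) occupants[dup_pkr[i]].push_back(i);
    for (int i = 0; i < n_pact; ++i) if (dup_pact[i] >= 0) occupants[dup_pact[i]].push_back(n_pkr + i);

    // 2. binding of free molecules
    std::vector<double> occ_x, occ_fp;
    for (int i = 0; i < n_pkr; ++i) {
      if (dup_pkr[i] >= 0 || n_dup == 0) continue;
      if (unif_rand() < p_pkr_bind) {
        int d = std::min((int)(unif_rand() * n_dup), n_dup - 1);
        occ_x.clear(); occ_fp.clear();
        for (size_t k = 0; k < occupants[d].size(); ++k) {
          int id = occupants[d][k];
          if (id < n_pkr) { occ_x.push_back(x_pkr[id]); occ_fp.push_back(fp_pkr); }
          else { occ_x.push_back(x_pact[id - n_pkr]); occ_fp.push_back(fp_pact); }
        }
        double xs = sample_feasible(duplex_length, fp_pkr, occ_x, occ_fp);
        if (xs >= 0.0) { dup_pkr[i] = d; x_pkr[i] = xs; occupants[d].push_back(i); }
      }
    }
    for (int i = 0; i < n_pact; ++i) {
      if (dup_pact[i] >= 0 || n_dup == 0) continue;
      if (unif_rand() < p_pact_bind) {
        int d = std::min((int)(unif_rand() * n_dup), n_dup - 1);
        occ_x.clear(); occ_fp.clear();
        for (size_t k = 0; k < occupants[d].size(); ++k) {
          int id = occupants[d][k];
          if (id < n_pkr) { occ_x.push_back(x_pkr[id]); occ_fp.push_back(fp_pkr); }
          else { occ_x.push_back(x_pact[id - n_pkr]); occ_fp.push_back(fp_pact); }
        }
        double xs = sample_feasible(duplex_length, fp_pact, occ_x, occ_fp);
        if (xs >= 0.0) { dup_pact[i] = d; x_pact[i] = xs; occupants[d].push_back(n_pkr + i); }
      }
    }

    // 3. diffusion with hard-core reflection, left-to-right per duplex
    for (int d = 0; d < n_dup; ++d) {
      std::vector<int>& occ = occupants[d];
      if (occ.empty()) continue;
      std::sort(occ.begin(), occ.end(), [&](int a, int bb) {
        double xa = a < n_pkr ? x_pkr[a] : x_pact[a - n_pkr];
        double xb = bb < n_pkr ? x_pkr[bb] : x_pact[bb - n_pkr];
        return xa < xb;
      });
      for (size_t k = 0; k < occ.size(); ++k) {
        int id = occ[k];
        bool is_pkr = id < n_pkr;
        double fp = is_pkr ? fp_pkr : fp_pact;
        double sd = is_pkr ? sd_pkr : sd_pact;
        if (sd <= 0.0) continue;
        double xx = is_pkr ? x_pkr[id] : x_pact[id - n_pkr];
        double lo = 0.0, hi = duplex_length - fp;
        if (k > 0) {
          int idl = occ[k - 1];
          double xl = idl < n_pkr ? x_pkr[idl] : x_pact[idl - n_pkr];
          double fpl = idl < n_pkr ? fp_pkr : fp_pact;
          lo = std::max(lo, xl + fpl);
        }
        if (k + 1 < occ.size()) {
          int idr = occ[k + 1];
          double xr = idr < n_pkr ? x_pkr[idr] : x_pact[idr - n_pkr];
          hi = std::min(hi, xr - fp);
        }
        if (hi < lo) { lo = hi = std::min(std::max(xx, 0.0), duplex_length - fp); }
        xx = reflect_into(xx + norm_rand() * sd, lo, hi);
        if (is_pkr) x_pkr[id] = xx; else x_pact[id - n_pkr] = xx;
      }
    }

    // 4. contacts: adjacent occupants with gap <= contact_tol
    cur_contacts.clear();
    for (int d = 0; d < n_dup; ++d) {
      std::vector<int>& occ = occupants[d];
      for (size_t k = 0; k + 1 < occ.size(); ++k) {
        int a = occ[k], bb = occ[k + 1];
        double xa = a < n_pkr ? x_pkr[a] : x_pact[a - n_pkr];
        double fpa = a < n_pkr ? fp_pkr : fp_pact;
        double xb = bb < n_pkr ? x_pkr[bb] : x_pact[bb - n_pkr];
        double gap = xb - (xa + fpa);
        if (gap > contact_tol) continue;
        std::pair<int, int> key(std::min(a, bb), std::max(a, bb));
        cur_contacts.insert(key);
        if (prev_contacts.count(key)) continue; // persisting contact, no new event
        bool a_pkr = a < n_pkr, b_pkr = bb < n_pkr;
        if (a_pkr && b_pkr) {
          if (unif_rand() < p_phos) { phos[a] = true; phos[bb] = true; }
        } else if (a_pkr != b_pkr) {
          if (p_evict > 0.0 && unif_rand() < p_evict) {
            int pkr_id = a_pkr ? a : bb;
            dup_pkr[pkr_id] = -1; // evicted, keeps phospho state
          }
        }
      }
    }
    prev_contacts.swap(cur_contacts);
  }

  return List::create(_["time"] = rec_t, _["phospho_fraction"] = rec_phos,
                      _["co_occupancy"] = rec_cooc,
                      _["pact_site_occupancy"] = rec_pact_occ,
                      _["mean_pkr_per_occupied_duplex"] = rec_multi);
}
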