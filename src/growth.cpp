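// Stochastic attachment/detachment engine on a fixed crystal-site lattice.
//
// Each iteration proposes one site drawn uniformly from the candidate list
// (non-frozen sites that are either empty with an occupied neighbor, or
// occupied with an empty neighbor). An empty candidate attaches, an occupied
// one detaches, with Metropolis acceptance on the site interaction energy
// U_i = sum over occupied neighbors of dG_cryst(type) plus the driving force,
// times the Metropolis-Hastings proposal correction |C(x)|/|C(x')| for the
// state-dependent candidate-list size, so the attach/detach rate ratio is
// exactly exp(beta * (U_i + dmu)) and detailed balance holds.
//
// Sign convention: dG_cryst > 0 favours crystallization.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct CandList {
  std::vector<int> items;     // site ids
  std::vector<int> pos;       // site -> index+1 in items, 0 = absent
  explicit CandList(int n) : pos(n, 0) {}
  inline bool has(int s) const { return pos[s] != 0; }
  inline void add(int s) {
    if (pos[s]) return;
    items.push_back(s);
    pos[s] = (int)items.size();
  }
  inline void remove(int s) {
    int p = pos[s];
    if (!p) return;
    int last = items.back();
    items[p - 1] = last;
    pos[last] = p;
    items.pop_back();
    pos[s] = 0;
  }
  inline int size() const { return (int)items.size(); }
};

} // namespace

// [[Rcpp::export(name = ".grow_cpp")]]
List grow_cpp(IntegerMatrix nbr, IntegerMatrix nbr_type, NumericMatrix dg,
              double beta, double dmu0, double dmu_offset,
              double descent_start, double equil_iter, double total_iter,
              double guest_fraction, IntegerVector init_sites,
              LogicalVector frozen, int record_every, double measure_from,
              bool check_connectivity) {
  const int n = nbr.nrow(), K = nbr.ncol();
  if (dg.nrow() < 1) stop("growth: empty interaction table");
  std::vector<signed char> occ(n, 0);  // 0 empty, 1 host, 2 guest
  std::vector<int> nocc(n, 0), deg(n, 0);
  for (int s = 0; s < n; ++s) {
    int d = 0;
    for (int k = 0; k < K; ++k) if (nbr(s, k) > 0) ++d;
    deg[s] = d;
  }
  // seed nucleus
  long size = 0;
  for (int idx = 0; idx < init_sites.size(); ++idx) {
    int s = init_sites[idx] - 1;
    if (s < 0 || s >= n) stop("growth: nucleus site out of range");
    if (occ[s]) continue;
    occ[s] = 1;
    ++size;
  }
  for (int s = 0; s < n; ++s) {
    if (!occ[s]) continue;
    for (int k = 0; k < K; ++k) {
      int t = nbr(s, k);
      if (t > 0) ++nocc[t - 1];
    }
  }
  CandList cand(n);
  for (int s = 0; s < n; ++s) {
    if (frozen[s]) continue;
    if (!occ[s] && nocc[s] > 0) cand.add(s);
    else if (occ[s] && nocc[s] < deg[s]) cand.add(s);
  }

  // connectivity scratch
  std::vector<int> stamp(n, 0), bfs;
  int stamp_ctr = 0;
  bfs.reserve(1024);

  // occupancy-time accounting (from measure_from onward)
  std::vector<double> acc(n, 0.0), tstart(n, 0.0);

  long n_attach = 0, n_detach = 0, n_reject_conn = 0;
  int nrec = (int)(total_iter / record_every) + 2;
  std::vector<double> rec_it, rec_size, rec_dmu;
  rec_it.reserve(nrec); rec_size.reserve(nrec); rec_dmu.reserve(nrec);

  RNGScope rng;

  for (double it = 0; it < total_iter; ++it) {
    double dmu_ss = (it < descent_start) ? dmu0
      : (it < equil_iter
           ? dmu0 * (equil_iter - it) / (equil_iter - descent_start)
           : 0.0);
    double dmu = dmu_ss + dmu_offset;

    if (((long)it) % record_every == 0) {
      rec_it.push_back(it); rec_size.push_back((double)size);
      rec_dmu.push_back(dmu);
    }
    int ncand = cand.size();
    if (ncand == 0) break;
    int pick = (int)(unif_rand() * ncand);
    if (pick >= ncand) pick = ncand - 1;
    int s = cand.items[pick];

    if (!occ[s]) {
      // ---- attachment ----
      signed char sp = 1;
      if (guest_fraction > 0 && unif_rand() < guest_fraction) sp = 2;
      double U = 0.0;
      int delta = (nocc[s] < deg[s]) ? 0 : -1;
      for (int k = 0; k < K; ++k) {
        int t = nbr(s, k);
        if (t <= 0) continue;
        --t;
        if (occ[t]) {
          U += dg(nbr_type(s, k) - 1, sp - 1);
          if (!frozen[t] && nocc[t] + 1 == deg[t]) --delta;
        } else {
          if (!frozen[t] && nocc[t] == 0) ++delta;
        }
      }
      double A = std::exp(beta * (U + dmu)) * (double)ncand /
                 (double)(ncand + delta);
      if (A >= 1.0 || unif_rand() < A) {
        occ[s] = sp;
        ++size; ++n_attach;
        if (it >= measure_from) tstart[s] = it;
        // update membership: s and neighbors
        if (nocc[s] >= deg[s]) cand.remove(s); // became bulk-in-hole
        for (int k = 0; k < K; ++k) {
          int t = nbr(s, k);
          if (t <= 0) continue;
          --t;
          ++nocc[t];
          if (frozen[t]) continue;
          if (!occ[t]) cand.add(t);
          else if (nocc[t] >= deg[t]) cand.remove(t);
        }
      }
    } else {
      // ---- detachment ----
      if (size <= 1) continue;
      signed char sp = occ[s];
      double U = 0.0;
      int nbr_occ = 0, first_occ = -1;
      for (int k = 0; k < K; ++k) {
        int t = nbr(s, k);
        if (t <= 0) continue;
        --t;
        if (occ[t]) {
          U += dg(nbr_type(s, k) - 1, sp - 1);
          ++nbr_occ;
          if (first_occ < 0) first_occ = t;
        }
      }
      if (check_connectivity && nbr_occ > 1) {
        // would removal split the local crystal? BFS from one occupied
        // neighbor until all others are reached (s excluded)
        ++stamp_ctr;
        stamp[s] = stamp_ctr;           // excluded
        bfs.clear();
        bfs.push_back(first_occ);
        stamp[first_occ] = stamp_ctr;
        int found = 1;
        size_t head = 0;
        while (head < bfs.size() && found < nbr_occ) {
          int u = bfs[head++];
          for (int k = 0; k < K; ++k) {
            int t = nbr(u, k);
            if (t <= 0) continue;
            --t;
            if (stamp[t] == stamp_ctr || !occ[t]) continue;
            stamp[t] = stamp_ctr;
            bfs.push_back(t);
            // is t one of s's occupied neighbors?
            for (int k2 = 0; k2 < K; ++k2) {
              int v = nbr(s, k2);
              if (v > 0 && v - 1 == t) { ++found; break; }
            }
          }
        }
        if (found < nbr_occ) { ++n_reject_conn; continue; }
      }
      int delta = (nocc[s] > 0) ? 0 : -1;
      for (int k = 0; k < K; ++k) {
        int t = nbr(s, k);
        if (t <= 0) continue;
        --t;
        if (occ[t]) {
          if (!frozen[t] && nocc[t] == deg[t]) ++delta;
        } else {
          if (!frozen[t] && nocc[t] == 1) --delta;
        }
      }
      double A = std::exp(-beta * (U + dmu)) * (double)ncand /
                 (double)(ncand + delta);
      if (A >= 1.0 || unif_rand() < A) {
        occ[s] = 0;
        --size; ++n_detach;
        if (it >= measure_from) acc[s] += it - std::max(tstart[s], measure_from);
        if (nocc[s] == 0) cand.remove(s);
        for (int k = 0; k < K; ++k) {
          int t = nbr(s, k);
          if (t <= 0) continue;
          --t;
          --nocc[t];
          if (frozen[t]) continue;
          if (!occ[t]) { if (nocc[t] == 0) cand.remove(t); }
          else cand.add(t);
        }
      }
    }
  }
  for (int s = 0; s < n; ++s)
    if (occ[s] && total_iter > measure_from)
      acc[s] += total_iter - std::max(tstart[s], measure_from);
  double window = std::max(total_iter - measure_from, 1.0);
  NumericVector occ_frac(n);
  IntegerVector occ_out(n);
  for (int s = 0; s < n; ++s) {
    occ_out[s] = occ[s];
    occ_frac[s] = acc[s] / window;
  }
  rec_it.push_back(total_iter); rec_size.push_back((double)size);
  rec_dmu.push_back(dmu_offset);
  return List::create(
    _["occ"] = occ_out, _["occ_frac"] = occ_frac,
    _["size"] = (double)size,
    _["trace_iter"] = wrap(rec_it), _["trace_size"] = wrap(rec_size),
    _["trace_dmu"] = wrap(rec_dmu),
    _["n_attach"] = (double)n_attach, _["n_detach"] = (double)n_detach,
    _["n_reject_conn"] = (double)n_reject_conn);
}
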