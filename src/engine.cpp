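// Metropolis-Hastings sweep for the graph-based CPM.
//
// The lattice graph arrives as two CSR adjacency structures (connectivity
// order for cell contiguity, interaction order for adhesion/perimeter sums),
// both 1-based as stored on the R side. Per-id vectors (volume, perimeter,
// type, targets) are padded with a slot for id 0 (medium) so they can be
// indexed by cell id directly. All randomness is drawn from R's RNG so a
// single set.seed() on the R side fixes the whole trajectory.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Csr {
  const int* ptr; // length n+1, 1-based offsets
  const int* idx; // 1-based node ids
  int begin(int node0) const { return ptr[node0] - 1; }
  int end(int node0) const { return ptr[node0 + 1] - 1; }
};

// is b (0-based) a neighbor of a (0-based)? idx runs are sorted.
inline bool adjacent(const Csr& g, int a, int b) {
  const int* lo = g.idx + g.begin(a);
  const int* hi = g.idx + g.end(a);
  return std::binary_search(lo, hi, b + 1);
}

class Guard {
public:
  Guard(const Csr& conn, const Csr& inter, const int* cell, int n)
    : conn_(conn), inter_(inter), cell_(cell), stamp_(n, 0), clock_(0) {}

  // Can `node0` be removed from cell `id` without disconnecting it?
  // volume = current node count of the cell.
  bool safe(int node0, int id, int volume) {
    if (volume <= 1) return false; // a cell's last node never flips away
    int verdict = local_check(node0, id);
    if (verdict != 0) return verdict > 0;
    return exact_check(node0, id, volume);
  }

  // 1 = safe, -1 = unsafe, 0 = inconclusive. Sound both ways: "safe" only
  // when every same-cell connectivity neighbor of node0 is joined to the
  // others through same-cell nodes of the surrounding interaction ring, in
  // which case any path through node0 can be rerouted locally.
  int local_check(int node0, int id) {
    same_.clear();
    ring_.clear();
    for (int k = conn_.begin(node0); k < conn_.end(node0); ++k) {
      int nb = conn_.idx[k] - 1;
      if (cell_[nb] == id) same_.push_back(nb);
    }
    if (same_.empty()) return -1; // isolated remainder: cannot happen for a connected cell
    if (same_.size() == 1) return 1; // leaf node
    for (int k = inter_.begin(node0); k < inter_.end(node0); ++k) {
      int nb = inter_.idx[k] - 1;
      if (nb != node0 && cell_[nb] == id) ring_.push_back(nb);
    }
    for (int nb : same_) { // connectivity order need not nest inside interaction order
      if (std::find(ring_.begin(), ring_.end(), nb) == ring_.end()) ring_.push_back(nb);
    }
    // BFS over the ring's same-cell nodes from the first conn neighbor
    ++clock_;
    stamp_[same_[0]] = clock_;
    queue_.clear();
    queue_.push_back(same_[0]);
    for (size_t head = 0; head < queue_.size(); ++head) {
      int cur = queue_[head];
      for (int nb : ring_) {
        if (stamp_[nb] != clock_ && adjacent(conn_, cur, nb)) {
          stamp_[nb] = clock_;
          queue_.push_back(nb);
        }
      }
    }
    for (int nb : same_) {
      if (stamp_[nb] != clock_) return 0; // not locally reroutable: fall back
    }
    return 1;
  }

  // exact connectivity check on the cell's induced subgraph minus node0
  bool exact_check(int node0, int id, int volume) {
    ++clock_;
    stamp_[node0] = clock_; // excluded
    int start = -1;
    for (int k = conn_.begin(node0); k < conn_.end(node0); ++k) {
      int nb = conn_.idx[k] - 1;
      if (cell_[nb] == id) { start = nb; break; }
    }
    if (start < 0) return false;
    queue_.clear();
    queue_.push_back(start);
    stamp_[start] = clock_;
    int reached = 1;
    for (size_t head = 0; head < queue_.size(); ++head) {
      int cur = queue_[head];
      for (int k = conn_.begin(cur); k < conn_.end(cur); ++k) {
        int nb = conn_.idx[k] - 1;
        if (stamp_[nb] != clock_ && cell_[nb] == id) {
          stamp_[nb] = clock_;
          queue_.push_back(nb);
          ++reached;
        }
      }
    }
    return reached == volume - 1;
  }

private:
  const Csr& conn_;
  const Csr& inter_;
  const int* cell_;
  std::vector<int> stamp_;
  int clock_;
  std::vector<int> same_, ring_, queue_;
};

inline int type_of(const int* type_by_id, int id) { return type_by_id[id]; }

// geometric mean of activity over a node and its same-cell connectivity
// neighbors; 0 for medium or if any activity is 0
double activity_gm(const Csr& conn, const int* cell, const double* act, int node0) {
  int id = cell[node0];
  if (id == 0) return 0.0;
  double logsum = 0.0;
  int count = 0;
  double a = act[node0];
  if (a <= 0) return 0.0;
  logsum += std::log(a); ++count;
  for (int k = conn.begin(node0); k < conn.end(node0); ++k) {
    int nb = conn.idx[k] - 1;
    if (cell[nb] == id) {
      a = act[nb];
      if (a <= 0) return 0.0;
      logsum += std::log(a); ++count;
    }
  }
  return std::exp(logsum / count);
}

} // namespace

// One Monte Carlo step: `flips` proposal/guard/score/accept cycles over the
// current state, with incremental statistics. Returns the updated state
// vectors, the accepted-flip deltas, and sweep statistics.
// [[Rcpp::export]]
List cpp_mcs_sweep(IntegerVector conn_ptr, IntegerVector conn_idx,
                   IntegerVector conn_from, IntegerVector int_ptr,
                   IntegerVector int_idx, IntegerVector cell_id_in,
                   IntegerVector volume_in, IntegerVector perimeter_in,
                   NumericVector activity_in, IntegerVector type_by_id,
                   IntegerVector target_volume_by_id,
                   IntegerVector target_perimeter_by_id, NumericMatrix J,
                   NumericVector lambda_v, NumericVector lambda_p,
                   double lambda_act, int max_act, NumericVector lambda_chem,
                   NumericVector chem_field, double temperature, int flips) {
  const int n = cell_id_in.size();
  const int e2 = conn_idx.size();
  IntegerVector cell_id = clone(cell_id_in);
  IntegerVector volume = clone(volume_in);
  IntegerVector perimeter = clone(perimeter_in);
  NumericVector activity = clone(activity_in);

  Csr conn{conn_ptr.begin(), conn_idx.begin()};
  Csr inter{int_ptr.begin(), int_idx.begin()};
  int* cell = cell_id.begin();
  int* vol = volume.begin();
  int* per = perimeter.begin();
  double* act = activity.begin();
  const int* tby = type_by_id.begin();
  const bool has_adh = J.nrow() > 0;
  const bool has_vol = lambda_v.size() > 0;
  const bool has_per = lambda_p.size() > 0;
  const bool has_act = lambda_act >= 0;
  const bool has_chem = lambda_chem.size() > 0;

  Guard guard(conn, inter, cell, n);
  std::vector<int> rec; // accepted flips: (node, old, new) triples, 1-based node
  int accepted = 0, vetoed = 0;
  bool exhausted = false;

  RNGScope scope;
  for (int f = 0; f < flips; ++f) {
    // sample a uniform heterotypic connectivity edge slot (directed)
    int slot = -1;
    for (int tries = 0; tries < 1000; ++tries) {
      int e = (int)(unif_rand() * e2);
      if (e >= e2) e = e2 - 1;
      if (cell[conn_from[e] - 1] != cell[conn_idx[e] - 1]) { slot = e; break; }
    }
    if (slot < 0) { // rare: scan exhaustively, pick uniformly
      int count = 0;
      for (int e = 0; e < e2; ++e)
        if (cell[conn_from[e] - 1] != cell[conn_idx[e] - 1]) ++count;
      if (count == 0) { exhausted = true; break; }
      int pick = (int)(unif_rand() * count);
      if (pick >= count) pick = count - 1;
      for (int e = 0; e < e2; ++e) {
        if (cell[conn_from[e] - 1] != cell[conn_idx[e] - 1] && pick-- == 0) {
          slot = e;
          break;
        }
      }
    }
    const int target = conn_from[slot] - 1; // slot owner loses its id
    const int source = conn_idx[slot] - 1;
    const int old_id = cell[target];
    const int new_id = cell[source];

    if (old_id > 0 && !guard.safe(target, old_id, vol[old_id])) {
      ++vetoed;
      continue;
    }

    double dH = 0.0;
    int dp_old = 0, dp_new = 0; // perimeter changes (also used for updates)
    {
      const int t_old = type_of(tby, old_id);
      const int t_new = type_of(tby, new_id);
      for (int k = inter.begin(target); k < inter.end(target); ++k) {
        int nb = inter.idx[k] - 1;
        int nb_id = cell[nb];
        if (has_adh) {
          int t_nb = type_of(tby, nb_id);
          if (nb_id != old_id) dH -= J(t_old, t_nb);
          if (nb_id != new_id) dH += J(t_new, t_nb);
        }
        if (nb_id == old_id) ++dp_old; else --dp_old;
        if (nb_id != new_id) ++dp_new; else --dp_new;
      }
      if (has_vol) {
        if (old_id > 0) {
          double lam = lambda_v[lambda_v.size() == 1 ? 0 : t_old - 1];
          double v = vol[old_id], V = target_volume_by_id[old_id];
          dH += lam * ((v - 1 - V) * (v - 1 - V) - (v - V) * (v - V));
        }
        if (new_id > 0) {
          double lam = lambda_v[lambda_v.size() == 1 ? 0 : t_new - 1];
          double v = vol[new_id], V = target_volume_by_id[new_id];
          dH += lam * ((v + 1 - V) * (v + 1 - V) - (v - V) * (v - V));
        }
      }
      if (has_per) {
        if (old_id > 0) {
          double lam = lambda_p[lambda_p.size() == 1 ? 0 : t_old - 1];
          if (lam > 0) {
            double p = per[old_id], P = target_perimeter_by_id[old_id];
            dH += lam * ((p + dp_old - P) * (p + dp_old - P) - (p - P) * (p - P));
          }
        }
        if (new_id > 0) {
          double lam = lambda_p[lambda_p.size() == 1 ? 0 : t_new - 1];
          if (lam > 0) {
            double p = per[new_id], P = target_perimeter_by_id[new_id];
            dH += lam * ((p + dp_new - P) * (p + dp_new - P) - (p - P) * (p - P));
          }
        }
      }
      if (has_act && lambda_act > 0) {
        double gm_s = activity_gm(conn, cell, act, source);
        double gm_t = activity_gm(conn, cell, act, target);
        dH += -(lambda_act / max_act) * (gm_s - gm_t);
      }
      if (has_chem && new_id > 0) {
        double lam = lambda_chem[lambda_chem.size() == 1 ? 0 : t_new - 1];
        dH += -lam * (chem_field[target] - chem_field[source]);
      }
    }

    double prob = dH <= 0 ? 1.0 : std::exp(-dH / temperature);
    if (unif_rand() < prob) {
      cell[target] = new_id;
      if (old_id > 0) { --vol[old_id]; per[old_id] += dp_old; }
      if (new_id > 0) { ++vol[new_id]; per[new_id] += dp_new; }
      if (has_act) act[target] = new_id > 0 ? (double)max_act : 0.0;
      rec.push_back(target + 1);
      rec.push_back(old_id);
      rec.push_back(new_id);
      ++accepted;
    }
  }

  if (has_act) {
    for (int i = 0; i < n; ++i) act[i] = act[i] > 1 ? act[i] - 1 : 0.0;
  }

  // boundary statistics (each undirected edge appears twice in the CSR)
  double b_total = 0, b_hetero = 0;
  {
    const int en = int_idx.size();
    int u = 0;
    for (int e = 0; e < en; ++e) {
      while (e >= inter.end(u)) ++u;
      int cu = cell[u], cv = cell[int_idx[e] - 1];
      if (cu != cv) {
        b_total += 0.5;
        if (cu > 0 && cv > 0 && type_of(tby, cu) != type_of(tby, cv)) b_hetero += 0.5;
      }
    }
  }

  IntegerMatrix deltas(rec.size() / 3, 3);
  for (int i = 0; i < deltas.nrow(); ++i) {
    deltas(i, 0) = rec[3 * i];
    deltas(i, 1) = rec[3 * i + 1];
    deltas(i, 2) = rec[3 * i + 2];
  }
  return List::create(
    _["cell_id"] = cell_id, _["volume"] = volume, _["perimeter"] = perimeter,
    _["activity"] = activity, _["deltas"] = deltas, _["accepted"] = accepted,
    _["vetoed"] = vetoed, _["exhausted"] = exhausted,
    _["boundary_total"] = b_total, _["boundary_hetero_type"] = b_hetero);
}
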