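#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Monotone optimal transport between two sorted unit-mass spike trains.
//
// Each spike of `a` carries mass 1/n_a, each spike of `b` mass 1/n_b.  The
// 1-D optimal plan is the monotone coupling of cumulative mass, which we
// stream with two pointers.  Mass bookkeeping is done in integer units of
// 1/(n_a*n_b) so segment masses are exact (equivalent to replicating spikes
// to the least common multiple of the counts, without materializing them).
// Consecutive segments with identical shift are merged; at most
// n_a + n_b - 1 segments result.
// ---------------------------------------------------------------------------
static void emd_flows_core(const double* a, int na, const double* b, int nb,
                           std::vector<double>& shifts,
                           std::vector<double>& masses) {
  const size_t base = shifts.size();  // never merge across neuron boundaries
  const double unit = 1.0 / (static_cast<double>(na) * static_cast<double>(nb));
  long ra = nb, rb = na;  // remaining units on current spike of a resp. b
  int i = 0, j = 0;
  while (i < na && j < nb) {
    long m = ra < rb ? ra : rb;
    double shift = b[j] - a[i];
    double mass = m * unit;
    if (shifts.size() > base && shifts.back() == shift)
      masses.back() += mass;
    else {
      shifts.push_back(shift);
      masses.push_back(mass);
    }
    ra -= m; rb -= m;
    if (ra == 0) { ++i; ra = nb; }
    if (rb == 0) { ++j; rb = na; }
  }
}

// [[Rcpp::export(name = ".cppEmdFlows")]]
List cppEmdFlows(NumericVector a, NumericVector b) {
  if (a.size() == 0 || b.size() == 0)
    stop("emdFlows: both spike trains must contain at least one spike");
  std::vector<double> shifts, masses;
  shifts.reserve(a.size() + b.size());
  masses.reserve(a.size() + b.size());
  emd_flows_core(REAL(a), a.size(), REAL(b), b.size(), shifts, masses);
  return List::create(_["shift"] = wrap(shifts), _["mass"] = wrap(masses));
}

// ---------------------------------------------------------------------------
// Weighted median with the interval-midpoint tie convention.
//
// Returns a minimizer g of sum_i w_i |v_i - g|.  When the cumulative weight
// hits exactly half the total at some value (within 1e-9 relative
// tolerance), the minimizer is a whole interval and the midpoint of that
// interval is returned; the objective value is tie-invariant.
// ---------------------------------------------------------------------------
static double wmedian_sorted(std::vector<std::pair<double,double> >& vw) {
  double total = 0.0;
  for (size_t i = 0; i < vw.size(); ++i) total += vw[i].second;
  std::sort(vw.begin(), vw.end());
  const double half = 0.5 * total, tol = 1e-9 * total;
  double cum = 0.0;
  for (size_t i = 0; i < vw.size(); ++i) {
    cum += vw[i].second;
    if (cum >= half - tol) {
      if (std::fabs(cum - half) <= tol && i + 1 < vw.size())
        return 0.5 * (vw[i].first + vw[i + 1].first);
      return vw[i].first;
    }
  }
  return vw.back().first;  // unreachable for positive weights
}

// Expected-linear-time selection on cumulative weight (quickselect over
// values); scans for the successor value only when the half-mass boundary is
// hit exactly.  Agrees exactly with the sort-based path.
static double wmedian_select(std::vector<double> v, std::vector<double> w) {
  double total = 0.0;
  for (size_t i = 0; i < v.size(); ++i) total += w[i];
  const double half = 0.5 * total, tol = 1e-9 * total;
  size_t lo = 0, hi = v.size();           // active window [lo, hi)
  double w_below = 0.0;                   // weight of values left of window
  unsigned int state = 123456789u;        // xorshift pivot picker
  while (hi - lo > 1) {
    state ^= state << 13; state ^= state >> 17; state ^= state << 5;
    double pivot = v[lo + state % (hi - lo)];
    // three-way partition of the window around pivot
    size_t lt = lo, gt = hi, k = lo;
    while (k < gt) {
      if (v[k] < pivot) { std::swap(v[k], v[lt]); std::swap(w[k], w[lt]); ++lt; ++k; }
      else if (v[k] > pivot) { --gt; std::swap(v[k], v[gt]); std::swap(w[k], w[gt]); }
      else ++k;
    }
    double w_lt = 0.0, w_eq = 0.0;
    for (size_t u = lo; u < lt; ++u) w_lt += w[u];
    for (size_t u = lt; u < gt; ++u) w_eq += w[u];
    double w_left = w_below + w_lt;
    if (w_left >= half - tol && lt > lo) {
      if (std::fabs(w_left - half) <= tol) {
        // boundary exactly between the left partition and the pivot class
        double lower = v[lo];
        for (size_t u = lo + 1; u < lt; ++u) if (v[u] > lower) lower = v[u];
        return 0.5 * (lower + pivot);
      }
      hi = lt; continue;
    }
    double cum_eq = w_below + w_lt + w_eq;
    if (cum_eq >= half - tol) {
      if (std::fabs(cum_eq - half) <= tol) {
        // boundary hit exactly at `pivot`: midpoint with the next value up
        double succ = R_PosInf;
        for (size_t u = gt; u < hi; ++u) if (v[u] < succ) succ = v[u];
        // successor may lie outside the window (all larger values already
        // discarded to the right keep their minimum in `hi` side) — but we
        // only ever discard the right side when its weight is needed, so the
        // successor is inside the window whenever the tie is genuine.
        if (R_finite(succ)) return 0.5 * (pivot + succ);
        return pivot;
      }
      return pivot;
    }
    w_below += w_lt + w_eq;
    lo = gt;
  }
  return v[lo];
}

// [[Rcpp::export(name = ".cppWeightedMedian")]]
double cppWeightedMedian(NumericVector values, NumericVector weights,
                         std::string method) {
  int n = values.size();
  if (n == 0) stop("weightedMedian: empty input");
  if (weights.size() != n)
    stop("weightedMedian: values and weights must have equal length");
  for (int i = 0; i < n; ++i)
    if (!(weights[i] > 0)) stop("weightedMedian: weights must be positive");
  if (method == "select") {
    std::vector<double> v(values.begin(), values.end());
    std::vector<double> w(weights.begin(), weights.end());
    return wmedian_select(v, w);
  }
  std::vector<std::pair<double,double> > vw(n);
  for (int i = 0; i < n; ++i) vw[i] = std::make_pair(values[i], weights[i]);
  return wmedian_sorted(vw);
}

// ---------------------------------------------------------------------------
// SpikeShip between two epochs given as lists of N per-neuron spike-time
// vectors.  Shift convention: c = t_m - t_k, so gMin > 0 means epoch m
// occurs later.  Returns the full flow decomposition.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cppSpikeShipPair")]]
List cppSpikeShipPair(List trainsK, List trainsM, bool keepFlows) {
  int N = trainsK.size();
  if (trainsM.size() != N)
    stop("spikeShipPair: epochs must share the neuron index space");
  std::vector<double> shifts, masses;
  std::vector<int> neuron, segStart;
  std::vector<int> active;
  segStart.push_back(0);
  for (int i = 0; i < N; ++i) {
    NumericVector a = trainsK[i], b = trainsM[i];
    if (a.size() > 0 && b.size() > 0) {
      emd_flows_core(REAL(a), a.size(), REAL(b), b.size(), shifts, masses);
      active.push_back(i + 1);
      while ((int)neuron.size() < (int)shifts.size()) neuron.push_back(i + 1);
      segStart.push_back((int)shifts.size());
    }
  }
  int nact = active.size();
  if (nact == 0) {
    return List::create(_["F"] = NumericVector::create(R_NaN),
                        _["gMin"] = NumericVector::create(R_NaN),
                        _["activeSet"] = IntegerVector(0),
                        _["perNeuronCost"] = NumericVector(0),
                        _["shift"] = NumericVector(0),
                        _["mass"] = NumericVector(0),
                        _["neuron"] = IntegerVector(0),
                        _["degenerate"] = true);
  }
  std::vector<std::pair<double,double> > vw(shifts.size());
  for (size_t u = 0; u < shifts.size(); ++u)
    vw[u] = std::make_pair(shifts[u], masses[u]);
  double g = wmedian_sorted(vw);
  NumericVector perNeuron(nact);
  double F = 0.0;
  for (int ai = 0; ai < nact; ++ai) {
    double cost = 0.0;
    for (int u = segStart[ai]; u < segStart[ai + 1]; ++u)
      cost += masses[u] * std::fabs(shifts[u] - g);
    perNeuron[ai] = cost;
    F += cost;
  }
  F /= nact;
  NumericVector outShift(0), outMass(0);
  IntegerVector outNeuron(0);
  if (keepFlows) {
    outShift = wrap(shifts);
    outMass = wrap(masses);
    outNeuron = wrap(neuron);
  }
  return List::create(_["F"] = F, _["gMin"] = g,
                      _["activeSet"] = wrap(active),
                      _["perNeuronCost"] = perNeuron,
                      _["shift"] = outShift, _["mass"] = outMass,
                      _["neuron"] = outNeuron, _["degenerate"] = false);
}

// Pairwise SpikeShip over all epoch pairs.  `epochs` is a list of M epochs,
// each a list of N per-neuron spike-time vectors.  Fills the symmetric F
// matrix and the global-shift matrix with G[k,m] = weighted median of
// t_m - t_k (antisymmetric under the midpoint convention).
// [[Rcpp::export(name = ".cppSpikeShipMatrix")]]
List cppSpikeShipMatrix(List epochs) {
  int M = epochs.size();
  NumericMatrix F(M, M), G(M, M);
  std::vector<int> degK, degM;
  for (int k = 0; k < M; ++k)
    for (int m = k + 1; m < M; ++m) {
      List res = cppSpikeShipPair(epochs[k], epochs[m], false);
      bool degen = as<bool>(res["degenerate"]);
      if (degen) {
        F(k, m) = F(m, k) = R_NaN;
        G(k, m) = G(m, k) = R_NaN;
        degK.push_back(k + 1); degM.push_back(m + 1);
      } else {
        double f = as<double>(res["F"]), g = as<double>(res["gMin"]);
        F(k, m) = F(m, k) = f;
        G(k, m) = g; G(m, k) = -g;
      }
    }
  return List::create(_["F"] = F, _["G"] = G,
                      _["degenerateK"] = wrap(degK),
                      _["degenerateM"] = wrap(degM));
}
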