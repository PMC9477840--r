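#include <Rcpp.h>
using namespace Rcpp;

// Effect codes shared with R/effects.R (keep in sync):
//  1 outdegree            2 reciprocity
//  3 dyadic covariate X   4 covariate-weighted reciprocity XRecip
//  5 outdegree activity   6 indegree popularity   7 outdegree popularity
//  8 transitive triplets  9 transitive reciprocated triplets
// 10 three cycles        11 dense triads
// 12 transitive triplets jumping households
// 13 shared popularity
//
// All covariate effects (alter, ego, same, similarity, plain dyadic) reduce
// to code 3 or 4 with a precomputed n x n weight matrix W.

struct CompiledEffects {
  std::vector<int> codes;
  std::vector<NumericMatrix> W;
  std::vector<bool> hasW;
};

static CompiledEffects compile_effects(IntegerVector codes, List weights) {
  CompiledEffects ce;
  int K = codes.size();
  ce.codes.resize(K);
  ce.hasW.resize(K);
  ce.W.resize(K);
  for (int k = 0; k < K; ++k) {
    ce.codes[k] = codes[k];
    SEXP w = weights[k];
    if (w != R_NilValue) {
      ce.W[k] = as<NumericMatrix>(w);
      ce.hasW[k] = true;
    } else ce.hasW[k] = false;
  }
  return ce;
}

// Gain of the arc i->j for effect `code`, evaluated on x with x_ij = 0
// (callers must clear the arc and the running degree sums beforehand).
// The toggle change statistic is +gain when adding, -gain when removing.
static double gain_one(int code, const IntegerMatrix &x, int i, int j,
                       const NumericMatrix *W, const IntegerVector &hh,
                       const IntegerVector &rs, const IntegerVector &cs) {
  const int n = x.nrow();
  double g = 0.0;
  switch (code) {
  case 1: // outdegree
    g = 1.0; break;
  case 2: // reciprocity
    g = x(j, i); break;
  case 3: // dyadic covariate
    g = (*W)(i, j); break;
  case 4: // covariate x reciprocity
    g = x(j, i) * (*W)(i, j); break;
  case 5: // outdegree activity: s_i = outdeg_i^2
    g = 2.0 * rs[i] + 1.0; break;
  case 6: // indegree popularity: s_i = sum_j x_ij indeg_j
    g = cs[j] + 1.0; break;
  case 7: // outdegree popularity: s_i = sum_j x_ij outdeg_j
    g = rs[j]; break;
  case 8: { // transitive triplets: closures with x_ij as i->j or as i->h
    double a = 0.0;
    for (int h = 0; h < n; ++h) {
      if (h == i || h == j) continue;
      if (x(i, h)) a += x(h, j) + x(j, h);
    }
    g = a; break;
  }
  case 9: { // transitive reciprocated triplets
    double a = 0.0, b = 0.0;
    for (int h = 0; h < n; ++h) {
      if (h == i || h == j) continue;
      if (x(i, h)) {
        a += x(h, j);
        if (x(h, i)) b += x(j, h);
      }
    }
    g = x(j, i) * a + b; break;
  }
  case 10: { // three cycles: i->j->h->i
    double a = 0.0;
    for (int h = 0; h < n; ++h) {
      if (h == i || h == j) continue;
      a += x(j, h) * x(h, i);
    }
    g = a; break;
  }
  case 11: { // dense triads (all six arcs present)
    if (!x(j, i)) { g = 0.0; break; }
    double a = 0.0;
    for (int h = 0; h < n; ++h) {
      if (h == i || h == j) continue;
      if (x(i, h) && x(h, i) && x(j, h) && x(h, j)) a += 1.0;
    }
    g = a; break;
  }
  case 12: { // transitive triplets jumping households
    double a = 0.0, b = 0.0;
    const int hi = hh[i], hj = hh[j];
    for (int h = 0; h < n; ++h) {
      if (h == i || h == j) continue;
      if (!x(i, h)) continue;
      if (hh[h] == hi) a += x(h, j); // i -> h (same HH) -> j
      else b += x(j, h);             // i -> j (same HH) -> target h elsewhere
    }
    g = (hj != hi) ? a : b;
    break;
  }
  case 13: { // shared popularity: s_i = sum_{h != i} C(m_ih, 2)
    // m_ih = # common targets of i and h; toggling x_ij changes m_ih by
    // x_hj for every h, so Delta C(m,2) = m_ih (with x_ij = 0).
    double a = 0.0;
    for (int h = 0; h < n; ++h) {
      if (h == i || h == j) continue;
      if (!x(h, j)) continue;
      int m0 = 0;
      for (int t = 0; t < n; ++t) {
        if (t == i || t == h) continue;
        if (x(i, t) && x(h, t)) ++m0;
      }
      a += m0;
    }
    g = a; break;
  }
  default:
    stop("unknown effect code");
  }
  return g;
}

// [[Rcpp::export(name = ".change_stats_cpp")]]
NumericMatrix change_stats_cpp(IntegerMatrix x, int i1,
                               IntegerVector codes, List weights,
                               IntegerVector hh) {
  const int n = x.nrow(), K = codes.size();
  const int i = i1 - 1;
  CompiledEffects ce = compile_effects(codes, weights);
  IntegerVector rs(n), cs(n);
  for (int a = 0; a < n; ++a)
    for (int b = 0; b < n; ++b) {
      rs[a] += x(a, b);
      cs[b] += x(a, b);
    }
  NumericMatrix out(K, n);
  for (int j = 0; j < n; ++j) {
    if (j == i) { for (int k = 0; k < K; ++k) out(k, j) = NA_REAL; continue; }
    int xij = x(i, j);
    double d = xij ? -1.0 : 1.0;
    if (xij) { x(i, j) = 0; rs[i]--; cs[j]--; }
    for (int k = 0; k < K; ++k) {
      const NumericMatrix *W = ce.hasW[k] ? &ce.W[k] : NULL;
      out(k, j) = d * gain_one(ce.codes[k], x, i, j, W, hh, rs, cs);
    }
    if (xij) { x(i, j) = 1; rs[i]++; cs[j]++; }
  }
  return out;
}

// Run `nsteps` ministeps of the actor-oriented process.
// Each ministep: focal actor uniform; alternatives = toggle x_ij for each
// j != i plus no-change (gain 0); multinomial logit over evaluation gains.
// Optionally accumulates the per-chain score vector
//   score_k = sum_t [ Delta_k(chosen) - sum_a pi_a Delta_k(a) ]
// used by the score-function estimate of the moment Jacobian, and optionally
// records the bit-encoded state after every ministep (small n only).
// [[Rcpp::export(name = ".simulate_chain_cpp")]]
List simulate_chain_cpp(IntegerMatrix x0, IntegerVector codes, List weights,
                        NumericVector beta, IntegerVector hh, int nsteps,
                        bool score = false, bool record = false) {
  IntegerMatrix x = clone(x0);
  const int n = x.nrow(), K = codes.size();
  CompiledEffects ce = compile_effects(codes, weights);
  IntegerVector rs(n), cs(n);
  for (int a = 0; a < n; ++a)
    for (int b = 0; b < n; ++b) {
      rs[a] += x(a, b);
      cs[b] += x(a, b);
    }
  NumericVector sc(K);
  std::vector<double> gain(n + 1), prob(n + 1);
  std::vector<std::vector<double>> delta(K, std::vector<double>(n));
  IntegerVector states(record ? nsteps : 0);
  if (record && n > 5) stop("state recording supported only for n <= 5");

  RNGScope scope;
  for (int t = 0; t < nsteps; ++t) {
    int i = (int)std::floor(unif_rand() * n);
    if (i == n) i = n - 1;
    // toggle change statistics for all alternatives
    for (int j = 0; j < n; ++j) {
      if (j == i) { for (int k = 0; k < K; ++k) delta[k][j] = 0.0; continue; }
      int xij = x(i, j);
      double d = xij ? -1.0 : 1.0;
      if (xij) { x(i, j) = 0; rs[i]--; cs[j]--; }
      for (int k = 0; k < K; ++k) {
        const NumericMatrix *W = ce.hasW[k] ? &ce.W[k] : NULL;
        delta[k][j] = d * gain_one(ce.codes[k], x, i, j, W, hh, rs, cs);
      }
      if (xij) { x(i, j) = 1; rs[i]++; cs[j]++; }
    }
    // evaluation gains; alternative n is "no change" with gain 0
    double gmax = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) { gain[j] = R_NegInf; continue; }
      double g = 0.0;
      for (int k = 0; k < K; ++k) g += beta[k] * delta[k][j];
      if (!R_finite(g)) stop("non-finite evaluation gain");
      gain[j] = g;
      if (g > gmax) gmax = g;
    }
    gain[n] = 0.0;
    double Z = 0.0;
    for (int j = 0; j <= n; ++j) {
      prob[j] = (j == i) ? 0.0 : std::exp(gain[j] - gmax);
      Z += prob[j];
    }
    double u = unif_rand() * Z, acc = 0.0;
    int choice = n;
    for (int j = 0; j <= n; ++j) {
      acc += prob[j];
      if (u <= acc) { choice = j; break; }
    }
    if (score) {
      for (int k = 0; k < K; ++k) {
        double e = 0.0;
        for (int j = 0; j < n; ++j)
          if (j != i) e += (prob[j] / Z) * delta[k][j];
        double chosen = (choice == n) ? 0.0 : delta[k][choice];
        sc[k] += chosen - e;
      }
    }
    if (choice != n) {
      int old = x(i, choice);
      x(i, choice) = 1 - old;
      rs[i] += old ? -1 : 1;
      cs[choice] += old ? -1 : 1;
    }
    if (record) {
      int code = 0, bit = 0;
      for (int a = 0; a < n; ++a)
        for (int b = 0; b < n; ++b) {
          if (a == b) continue;
          if (x(a, b)) code |= (1 << bit);
          ++bit;
        }
      states[t] = code;
    }
  }
  List out = List::create(_["net"] = x, _["score"] = sc);
  if (record) out["states"] = states;
  return out;
}
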