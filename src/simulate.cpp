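// Uniform-asynchronous Boolean ensemble simulator.
//
// Rules arrive as postfix bytecode: positive tokens push the value of a
// node (1-based index), negative tokens are operators (AND -1, OR -2,
// NOT -3, constants 0/1 as -4/-5).  Per step, one node whose rule output
// differs from its current value is chosen uniformly and flipped; clamped
// nodes never update.  The engine also pools full-state observations over
// repeats and steps for the entropy profile H(t).

#include <Rcpp.h>

#include <algorithm>
#include <cmath>
#include <cstdint>
#include <random>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

const int OP_AND = -1, OP_OR = -2, OP_NOT = -3, OP_ZERO = -4, OP_ONE = -5;

inline int eval_code(const std::vector<int>& code,
                     const std::vector<uint8_t>& s,
                     std::vector<uint8_t>& stk) {
  size_t top = 0;
  for (int tok : code) {
    if (tok > 0) {
      stk[top++] = s[tok - 1];
    } else if (tok == OP_NOT) {
      stk[top - 1] = stk[top - 1] ? 0 : 1;
    } else if (tok == OP_AND) {
      uint8_t b = stk[--top];
      stk[top - 1] = (stk[top - 1] && b) ? 1 : 0;
    } else if (tok == OP_OR) {
      uint8_t b = stk[--top];
      stk[top - 1] = (stk[top - 1] || b) ? 1 : 0;
    } else if (tok == OP_ZERO) {
      stk[top++] = 0;
    } else {
      stk[top++] = 1;
    }
  }
  return stk[0];
}

}  // namespace

// [[Rcpp::export(name = ".simulate_ensemble_cpp")]]
List simulate_ensemble_cpp(List rule_codes, IntegerMatrix init,
                           IntegerMatrix clamp, int steps, int seed,
                           int stride, bool return_traj, int repeat_from) {
  const int n = init.nrow();
  const int R = init.ncol();
  if (clamp.nrow() != n || clamp.ncol() != R)
    stop("clamp matrix must match the init matrix dimensions");
  if (steps < 1) stop("steps must be >= 1");
  if (stride < 1) stop("entropy stride must be >= 1");

  std::vector<std::vector<int>> codes(n);
  size_t max_code = 1;
  for (int i = 0; i < n; ++i) {
    codes[i] = as<std::vector<int>>(rule_codes[i]);
    max_code = std::max(max_code, codes[i].size());
  }

  const int nb = steps / stride + 1;
  NumericMatrix actsum(n, steps + 1);
  IntegerMatrix finals(n, R);
  const bool want_rep = repeat_from >= 0;
  NumericMatrix repmeans(want_rep ? n : 0, want_rep ? R : 0);
  std::unordered_map<std::string, std::vector<double>> counts;
  List trajs(return_traj ? R : 0);

  std::vector<uint8_t> s(n), stk(max_code + 1);
  std::vector<int> updatable(n);

  for (int r = 0; r < R; ++r) {
    std::seed_seq seq{seed, r};
    std::mt19937_64 rng(seq);
    std::vector<int8_t> cl(n);
    for (int i = 0; i < n; ++i) cl[i] = static_cast<int8_t>(clamp(i, r));
    for (int i = 0; i < n; ++i) {
      int v = init(i, r);
      if (v != 0 && v != 1) stop("initial states must be 0/1");
      s[i] = cl[i] >= 0 ? static_cast<uint8_t>(cl[i]) : static_cast<uint8_t>(v);
    }
    IntegerMatrix tr(return_traj ? n : 0, return_traj ? steps + 1 : 0);
    std::string key(n, '\0');
    int t_break = steps;  // last step recorded inside the loop
    bool fixed = false;

    for (int t = 0; t <= steps; ++t) {
      for (int i = 0; i < n; ++i) {
        actsum(i, t) += s[i];
        key[i] = static_cast<char>(s[i]);
      }
      if (return_traj)
        for (int i = 0; i < n; ++i) tr(i, t) = s[i];
      if (want_rep && t >= repeat_from)
        for (int i = 0; i < n; ++i) repmeans(i, r) += s[i];
      auto& v = counts[key];
      if (v.empty()) v.assign(nb, 0.0);
      v[t / stride] += 1.0;
      if (t == steps) break;

      int k = 0;
      for (int i = 0; i < n; ++i) {
        if (cl[i] >= 0) continue;
        if (eval_code(codes[i], s, stk) != static_cast<int>(s[i]))
          updatable[k++] = i;
      }
      if (k == 0) {  // fixed point: all later states identical
        t_break = t;
        fixed = true;
        break;
      }
      std::uniform_int_distribution<int> pick(0, k - 1);
      int j = updatable[pick(rng)];
      s[j] = s[j] ? 0 : 1;
    }

    if (fixed && t_break < steps) {
      auto& v = counts[key];
      for (int tt = t_break + 1; tt <= steps; ++tt) {
        for (int i = 0; i < n; ++i) actsum(i, tt) += s[i];
        if (return_traj)
          for (int i = 0; i < n; ++i) tr(i, tt) = s[i];
        v[tt / stride] += 1.0;
      }
      if (want_rep) {
        int from = std::max(repeat_from, t_break + 1);
        int cnt = steps - from + 1;
        if (cnt > 0)
          for (int i = 0; i < n; ++i) repmeans(i, r) += double(s[i]) * cnt;
      }
    }

    for (int i = 0; i < n; ++i) finals(i, r) = s[i];
    if (return_traj) trajs[r] = tr;
  }

  // Cumulative pooled entropy at checkpoint times.
  NumericVector H(nb);
  IntegerVector Ht(nb);
  {
    std::vector<const std::vector<double>*> vs;
    vs.reserve(counts.size());
    for (auto& kv : counts) vs.push_back(&kv.second);
    std::vector<double> cum(vs.size(), 0.0);
    for (int b = 0; b < nb; ++b) {
      double tot = 0.0;
      for (size_t q = 0; q < vs.size(); ++q) {
        cum[q] += (*vs[q])[b];
        tot += cum[q];
      }
      double h = 0.0;
      for (double x : cum) {
        if (x > 0.0) {
          double p = x / tot;
          h -= p * std::log2(p);
        }
      }
      H[b] = h;
      Ht[b] = std::min((b + 1) * stride - 1, steps);
    }
  }

  NumericMatrix activity(n, steps + 1);
  for (int t = 0; t <= steps; ++t)
    for (int i = 0; i < n; ++i) activity(i, t) = actsum(i, t) / R;

  List out = List::create(
      Named("activity") = activity, Named("entropy") = H,
      Named("entropy_t") = Ht, Named("final") = finals);
  if (want_rep) {
    double len = steps - repeat_from + 1;
    for (int r = 0; r < R; ++r)
      for (int i = 0; i < n; ++i) repmeans(i, r) /= len;
    out["repeat_means"] = repmeans;
  }
  if (return_traj) out["traj"] = trajs;
  return out;
}
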