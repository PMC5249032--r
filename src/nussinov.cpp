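#include <Rcpp.h>
#include <stack>
using namespace Rcpp;

// pairing weight: Watson-Crick = 1, G:T wobble = gu_weight, else 0
static inline double pair_weight(char a, char b, double gu) {
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
      (a == 'C' && b == 'G') || (a == 'G' && b == 'C')) return 1.0;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return gu;
  return 0.0;
}

// Maximum-weight nested base pairing with a minimum hairpin loop.
// Traceback ties are broken toward pairing the 5'-most position first,
// and toward the smallest partner index, so the structure is deterministic.
//
// An optional anchor region [anchor_start, anchor_end] (0-based inclusive,
// anchor_start < 0 disables it) marks the mature read: pairs with exactly
// one endpoint in the anchor receive a small score bonus and pairs with
// both endpoints inside the anchor are disallowed, so the optimal
// structure pairs the anchored arm outward before maximizing the rest.
// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, double gu_weight = 1.0,
                   int min_loop = 3, int anchor_start = -1,
                   int anchor_end = -1, double anchor_bonus = 1e-3) {
  const int n = seq.size();
  IntegerVector partner(n, 0);
  if (n == 0)
    return List::create(_["partner"] = partner, _["score"] = 0.0);

  std::vector<double> S((size_t)n * n, 0.0);
  auto idx = [n](int i, int j) { return (size_t)i * n + j; };
  auto in_anchor = [anchor_start, anchor_end](int i) {
    return anchor_start >= 0 && i >= anchor_start && i <= anchor_end;
  };
  auto weight = [&](int i, int k) {
    bool ai = in_anchor(i), ak = in_anchor(k);
    if (ai && ak) return 0.0;
    double w = pair_weight(seq[i], seq[k], gu_weight);
    if (w > 0.0 && (ai || ak)) w += anchor_bonus;
    return w;
  };

  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = S[idx(i + 1, j)];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        double w = weight(i, k);
        if (w <= 0.0) continue;
        double v = w + (k - 1 >= i + 1 ? S[idx(i + 1, k - 1)] : 0.0) +
                   (k + 1 <= j ? S[idx(k + 1, j)] : 0.0);
        if (v > best) best = v;
      }
      S[idx(i, j)] = best;
    }
  }

  std::stack<std::pair<int, int> > todo;
  todo.push(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    int i = todo.top().first, j = todo.top().second;
    todo.pop();
    if (i >= j || j - i < min_loop + 1) continue;
    double target = S[idx(i, j)];
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      double w = weight(i, k);
      if (w <= 0.0) continue;
      double v = w + (k - 1 >= i + 1 ? S[idx(i + 1, k - 1)] : 0.0) +
                 (k + 1 <= j ? S[idx(k + 1, j)] : 0.0);
      if (v >= target - 1e-9) {
        partner[i] = k + 1;  // 1-based
        partner[k] = i + 1;
        todo.push(std::make_pair(i + 1, k - 1));
        todo.push(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) todo.push(std::make_pair(i + 1, j));
  }

  return List::create(_["partner"] = partner,
                      _["score"] = S[idx(0, n - 1)]);
}
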