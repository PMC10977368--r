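#include <Rcpp.h>
using namespace Rcpp;

// Base encoding used throughout: A=0, C=1, G=2, U/T=3.
// Watson-Crick complement is 3 - x under this encoding.

// Pair strengths for the stacking-weighted fold. A helix stack formed by
// pairs (i,j) and (i+1,j-1) scores strength(i,j) + strength(i+1,j-1), so
// isolated pairs contribute nothing and are dropped by the tie-breaks.
static inline double pair_strength(int a, int b) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 1.5; // G:C
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 1.0; // A:U
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 0.5; // G:U wobble
  return -1.0; // not pairable
}

static inline bool can_pair(int a, int b) { return pair_strength(a, b) > 0; }

// Maximum-score nested secondary structure.
//
// Two tables:
//   M(i,j) = best score on [i..j]
//   P(i,j) = best score on [i..j] given that (i,j) is paired
// P(i,j) = max( M(i+1,j-1), P(i+1,j-1) + w(i,j,i+1,j-1) )
// M(i,j) = max( M(i+1,j), max_k { P(i,k) + M(k+1,j) } ) with strict
// improvement required to open a pair, so zero-scoring pairs are never kept.
//
// `banned` is an m x 2 matrix of 0-based (i,j) pairs excluded from pairing;
// it drives the pair-exclusion suboptimal re-folds.
// [[Rcpp::export]]
List fold_nussinov_cpp(IntegerVector seq, int min_loop, IntegerMatrix banned) {
  const int n = seq.size();
  const double NEG = -1e18;
  if (n == 0) stop("empty sequence");

  std::vector<bool> is_banned(static_cast<size_t>(n) * n, false);
  for (int r = 0; r < banned.nrow(); ++r) {
    int i = banned(r, 0), j = banned(r, 1);
    if (i >= 0 && j >= 0 && i < n && j < n) {
      is_banned[static_cast<size_t>(i) * n + j] = true;
      is_banned[static_cast<size_t>(j) * n + i] = true;
    }
  }

  NumericMatrix M(n, n), P(n, n);
  std::fill(P.begin(), P.end(), NEG);
  // M defaults to 0 (all-unpaired always feasible)

  auto allowed = [&](int i, int j) {
    return j - i - 1 >= min_loop && can_pair(seq[i], seq[j]) &&
           !is_banned[static_cast<size_t>(i) * n + j];
  };

  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      if (allowed(i, j)) {
        double inner = (i + 1 <= j - 1) ? M(i + 1, j - 1) : 0.0;
        double best = inner;
        if (i + 1 <= j - 1 && P(i + 1, j - 1) > NEG / 2 &&
            can_pair(seq[i + 1], seq[j - 1])) {
          double w = pair_strength(seq[i], seq[j]) +
                     pair_strength(seq[i + 1], seq[j - 1]);
          double st = P(i + 1, j - 1) + w;
          if (st > best) best = st;
        }
        P(i, j) = best;
      }
      double best = M(i + 1, j); // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (P(i, k) > NEG / 2) {
          double cand = P(i, k) + ((k + 1 <= j) ? M(k + 1, j) : 0.0);
          if (cand > best) best = cand; // strict: prefer unpaired on ties
        }
      }
      M(i, j) = best;
    }
  }

  // traceback
  std::vector<std::pair<int, int>> pairs;
  std::vector<std::array<int, 3>> stack; // (i, j, which) which: 0=M, 1=P
  if (n >= 2) stack.push_back({0, n - 1, 0});
  while (!stack.empty()) {
    auto fr = stack.back();
    stack.pop_back();
    int i = fr[0], j = fr[1], which = fr[2];
    if (i >= j) continue;
    if (which == 0) {
      if (M(i, j) == M(i + 1, j)) {
        stack.push_back({i + 1, j, 0});
        continue;
      }
      bool found = false;
      for (int k = i + min_loop + 1; k <= j && !found; ++k) {
        if (P(i, k) > NEG / 2) {
          double cand = P(i, k) + ((k + 1 <= j) ? M(k + 1, j) : 0.0);
          if (cand == M(i, j)) {
            stack.push_back({i, k, 1});
            if (k + 1 <= j) stack.push_back({k + 1, j, 0});
            found = true;
          }
        }
      }
      if (!found) stop("traceback failure (M)");
    } else {
      pairs.emplace_back(i, j);
      if (i + 1 > j - 1) continue;
      double w = NEG;
      if (P(i + 1, j - 1) > NEG / 2 && can_pair(seq[i + 1], seq[j - 1])) {
        w = pair_strength(seq[i], seq[j]) +
            pair_strength(seq[i + 1], seq[j - 1]);
      }
      if (w > NEG / 2 && P(i, j) == P(i + 1, j - 1) + w &&
          P(i + 1, j - 1) + w > M(i + 1, j - 1)) {
        stack.push_back({i + 1, j - 1, 1});
      } else {
        stack.push_back({i + 1, j - 1, 0});
      }
    }
  }

  IntegerMatrix pm(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    pm(r, 0) = pairs[r].first;
    pm(r, 1) = pairs[r].second;
  }
  double score = (n >= 2) ? M(0, n - 1) : 0.0;
  return List::create(_["score"] = score, _["pairs"] = pm);
}

// Best ungapped antiparallel duplex between a and b.
//
// a and b are 5'->3'; a[i] can pair with b[j] when b[j] == 3 - a[i]
// (Watson-Crick only). For every alignment offset the longest runs of
// consecutive complementary positions are scored by summing nearest-neighbor
// stack free energies indexed by the top-strand (a) dinucleotide:
// stack_dg[4 * a[i] + a[i+1]]. A run must hold at least two stacks
// (three consecutive pairs) to count as a duplex.
// [[Rcpp::export]]
List duplex_scan_cpp(IntegerVector a, IntegerVector b, NumericVector stack_dg) {
  const int la = a.size(), lb = b.size();
  if (la == 0 || lb == 0) stop("empty sequence");
  if (stack_dg.size() != 16) stop("stack_dg must have 16 entries");

  double best = 0.0;
  int best_a0 = -1, best_a1 = -1, best_b0 = -1, best_b1 = -1, best_np = 0;

  // reverse of b: br[t] = b[lb - 1 - t]; a[i] aligns with br[i + d]
  for (int d = -(la - 1); d <= lb - 1; ++d) {
    int i = std::max(0, -d);
    int imax = std::min(la - 1, lb - 1 - d);
    while (i <= imax) {
      // find maximal complementary run starting at i
      if (b[lb - 1 - (i + d)] == 3 - a[i]) {
        int s = i;
        while (i + 1 <= imax && b[lb - 1 - (i + 1 + d)] == 3 - a[i + 1]) ++i;
        int e = i; // run over a[s..e]
        int np = e - s + 1;
        if (np >= 3) {
          double dg = 0.0;
          for (int t = s; t < e; ++t) dg += stack_dg[4 * a[t] + a[t + 1]];
          if (dg < best) {
            best = dg;
            best_a0 = s;
            best_a1 = e;
            // b indices (ascending): pair partner of a[t] is b[lb-1-(t+d)]
            best_b0 = lb - 1 - (e + d);
            best_b1 = lb - 1 - (s + d);
            best_np = np;
          }
        }
      }
      ++i;
    }
  }

  return List::create(_["delta_g"] = best, _["n_pairs"] = best_np,
                      _["a_start"] = best_a0, _["a_end"] = best_a1,
                      _["b_start"] = best_b0, _["b_end"] = best_b1);
}
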