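// Affine-gap pairwise alignment (Gotoh three-state recurrences).
//
// Scoring convention: a gap of length L costs gap_open + (L - 1) * gap_ext,
// i.e. the opening penalty is charged on the first gapped position.
// Tracebacks are deterministic: on ties the diagonal move wins over the
// vertical (template consumed, deletion in the query), which wins over the
// horizontal (query consumed, insertion in the query).
//
// The query character '#' is a mask sentinel: it can never be matched
// (large negative substitution score), which lets callers exclude already
// aligned query stretches when probing for secondary local hits.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static const double NEG_INF = -1e18;
static const double MASK_PENALTY = -1e9;

static inline double subscore(char a, char b, double match, double mismatch) {
  if (a == '#' || b == '#') return MASK_PENALTY;
  return (a == b) ? match : mismatch;
}

// state codes: 0 = M (diagonal), 1 = X (vertical/deletion), 2 = Y
// (horizontal/insertion); priority on ties is M > X > Y.
static inline int argmax3(double m, double x, double y) {
  if (m >= x && m >= y) return 0;
  if (x >= y) return 1;
  return 2;
}

// [[Rcpp::export(name = ".gotoh_global_cpp")]]
List gotoh_global_cpp(std::string ref, std::string query,
                      double match, double mismatch,
                      double gap_open, double gap_ext) {
  const int n = ref.size(), m = query.size();
  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG_INF));
  std::vector<std::vector<double>> X(n + 1, std::vector<double>(m + 1, NEG_INF));
  std::vector<std::vector<double>> Y(n + 1, std::vector<double>(m + 1, NEG_INF));
  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i][0] = -(gap_open + (i - 1) * gap_ext);
  for (int j = 1; j <= m; ++j) Y[0][j] = -(gap_open + (j - 1) * gap_ext);

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = subscore(ref[i - 1], query[j - 1], match, mismatch);
      double dm = M[i - 1][j - 1], dx = X[i - 1][j - 1], dy = Y[i - 1][j - 1];
      M[i][j] = std::max(dm, std::max(dx, dy)) + s;
      X[i][j] = std::max(M[i - 1][j] - gap_open,
                std::max(X[i - 1][j] - gap_ext, Y[i - 1][j] - gap_open));
      Y[i][j] = std::max(M[i][j - 1] - gap_open,
                std::max(X[i][j - 1] - gap_open, Y[i][j - 1] - gap_ext));
    }
  }

  int state = argmax3(M[n][m], X[n][m], Y[n][m]);
  double score = state == 0 ? M[n][m] : (state == 1 ? X[n][m] : Y[n][m]);

  std::vector<int> col_ref, col_query;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      col_ref.push_back(i); col_query.push_back(j);
      double s = subscore(ref[i - 1], query[j - 1], match, mismatch);
      double target = M[i][j] - s;
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M[i][j] == target) state = 0;
      else if (X[i][j] == target) state = 1;
      else state = 2;
    } else if (state == 1) {
      col_ref.push_back(i); col_query.push_back(0);
      double target = X[i][j];
      --i;
      if (M[i][j] - gap_open == target) state = 0;
      else if (X[i][j] - gap_ext == target) state = 1;
      else state = 2;
      if (i == 0 && j == 0) break;
    } else {
      col_ref.push_back(0); col_query.push_back(j);
      double target = Y[i][j];
      --j;
      if (M[i][j] - gap_open == target) state = 0;
      else if (X[i][j] - gap_open == target) state = 1;
      else state = 2;
      if (i == 0 && j == 0) break;
    }
  }
  std::reverse(col_ref.begin(), col_ref.end());
  std::reverse(col_query.begin(), col_query.end());

  return List::create(_["score"] = score,
                      _["ref"] = IntegerVector(col_ref.begin(), col_ref.end()),
                      _["query"] = IntegerVector(col_query.begin(), col_query.end()));
}

// [[Rcpp::export(name = ".sw_local_cpp")]]
List sw_local_cpp(std::string ref, std::string query,
                  double match, double mismatch,
                  double gap_open, double gap_ext) {
  const int n = ref.size(), m = query.size();
  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, 0.0));
  std::vector<std::vector<double>> X(n + 1, std::vector<double>(m + 1, NEG_INF));
  std::vector<std::vector<double>> Y(n + 1, std::vector<double>(m + 1, NEG_INF));
  for (int i = 0; i <= n; ++i) M[i][0] = NEG_INF;
  for (int j = 0; j <= m; ++j) M[0][j] = NEG_INF;

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = subscore(ref[i - 1], query[j - 1], match, mismatch);
      double prev = std::max(0.0, std::max(M[i - 1][j - 1],
                    std::max(X[i - 1][j - 1], Y[i - 1][j - 1])));
      M[i][j] = prev + s;
      X[i][j] = std::max(M[i - 1][j] - gap_open,
                std::max(X[i - 1][j] - gap_ext, Y[i - 1][j] - gap_open));
      Y[i][j] = std::max(M[i][j - 1] - gap_open,
                std::max(X[i][j - 1] - gap_open, Y[i][j - 1] - gap_ext));
      if (M[i][j] > best) { best = M[i][j]; bi = i; bj = j; }
    }
  }

  std::vector<int> col_ref, col_query;
  if (best > 0.0) {
    int i = bi, j = bj, state = 0;
    while (true) {
      if (state == 0) {
        col_ref.push_back(i); col_query.push_back(j);
        double s = subscore(ref[i - 1], query[j - 1], match, mismatch);
        double target = M[i][j] - s;
        --i; --j;
        if (target == 0.0) break;  // fresh start: the local alignment begins here
        if (M[i][j] == target) state = 0;
        else if (X[i][j] == target) state = 1;
        else state = 2;
      } else if (state == 1) {
        col_ref.push_back(i); col_query.push_back(0);
        double target = X[i][j];
        --i;
        if (M[i][j] - gap_open == target) state = 0;
        else if (X[i][j] - gap_ext == target) state = 1;
        else state = 2;
      } else {
        col_ref.push_back(0); col_query.push_back(j);
        double target = Y[i][j];
        --j;
        if (M[i][j] - gap_open == target) state = 0;
        else if (X[i][j] - gap_open == target) state = 1;
        else state = 2;
      }
    }
    std::reverse(col_ref.begin(), col_ref.end());
    std::reverse(col_query.begin(), col_query.end());
  }

  int ref_start = 0, ref_end = 0, q_start = 0, q_end = 0;
  for (size_t k = 0; k < col_ref.size(); ++k) {
    if (col_ref[k] > 0) { if (!ref_start) ref_start = col_ref[k]; ref_end = col_ref[k]; }
    if (col_query[k] > 0) { if (!q_start) q_start = col_query[k]; q_end = col_query[k]; }
  }

  return List::create(_["score"] = best,
                      _["ref"] = IntegerVector(col_ref.begin(), col_ref.end()),
                      _["query"] = IntegerVector(col_query.begin(), col_query.end()),
                      _["ref_span"] = IntegerVector::create(ref_start, ref_end),
                      _["query_span"] = IntegerVector::create(q_start, q_end));
}
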