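#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh three-state DP).
//
// A gap run of length L costs gap_open + (L - 1) * gap_extend, with
// gap_open <= gap_extend <= 0 (the opening penalty already pays for the
// first gapped symbol). 'N' scores as a mismatch against every symbol,
// including another 'N'.
//
// Traceback is deterministic: on score ties the diagonal (match/mismatch)
// state is preferred over a deletion (gap in the read), which is preferred
// over an insertion (gap in the reference), so aligned strings are stable
// across runs and platforms.

static const double NEG_INF = -1e300;
static const double EPS = 1e-9;

static inline double subst_score(char a, char b, double match, double mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

struct AlnResult {
  std::string aligned_read;
  std::string aligned_ref;
  double score;
};

// state codes: 0 = M (diagonal), 1 = X (gap in ref; consumes a read base,
// an insertion relative to the reference), 2 = Y (gap in read; consumes a
// reference base, a deletion from the read).
static AlnResult align_core(const std::string &read, const std::string &ref,
                            double match, double mismatch,
                            double gap_open, double gap_extend) {
  const int n = (int) read.size();
  const int m = (int) ref.size();
  const int W = m + 1;

  std::vector<double> M((n + 1) * W), X((n + 1) * W), Y((n + 1) * W);

  M[0] = 0.0; X[0] = NEG_INF; Y[0] = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M[i * W] = NEG_INF;
    X[i * W] = gap_open + (i - 1) * gap_extend;
    Y[i * W] = NEG_INF;
  }
  for (int j = 1; j <= m; ++j) {
    M[j] = NEG_INF;
    X[j] = NEG_INF;
    Y[j] = gap_open + (j - 1) * gap_extend;
  }

  for (int i = 1; i <= n; ++i) {
    const char ri = read[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j, up = (i - 1) * W + j,
                left = i * W + (j - 1), diag = (i - 1) * W + (j - 1);
      const double s = subst_score(ri, ref[j - 1], match, mismatch);
      M[idx] = std::max(M[diag], std::max(X[diag], Y[diag])) + s;
      X[idx] = std::max(std::max(M[up] + gap_open, X[up] + gap_extend),
                        Y[up] + gap_open);
      Y[idx] = std::max(std::max(M[left] + gap_open, Y[left] + gap_extend),
                        X[left] + gap_open);
    }
  }

  int i = n, j = m, state;
  double final_score;
  {
    const int idx = n * W + m;
    final_score = M[idx]; state = 0;
    if (Y[idx] > final_score + EPS) { final_score = Y[idx]; state = 2; }
    if (X[idx] > final_score + EPS) { final_score = X[idx]; state = 1; }
  }

  std::string ar, af;
  ar.reserve(n + m);
  af.reserve(n + m);

  while (i > 0 || j > 0) {
    if (i == 0) {            // only reference bases remain: forced deletions
      ar.push_back('-');
      af.push_back(ref[j - 1]);
      --j;
      continue;
    }
    if (j == 0) {            // only read bases remain: forced insertions
      ar.push_back(read[i - 1]);
      af.push_back('-');
      --i;
      continue;
    }
    const int idx = i * W + j;
    if (state == 0) {
      ar.push_back(read[i - 1]);
      af.push_back(ref[j - 1]);
      const int diag = (i - 1) * W + (j - 1);
      const double target =
        M[idx] - subst_score(read[i - 1], ref[j - 1], match, mismatch);
      if (std::abs(M[diag] - target) < EPS) state = 0;
      else if (std::abs(Y[diag] - target) < EPS) state = 2;
      else state = 1;
      --i; --j;
    } else if (state == 2) {
      ar.push_back('-');
      af.push_back(ref[j - 1]);
      const int left = i * W + (j - 1);
      if (std::abs(M[left] + gap_open - Y[idx]) < EPS) state = 0;
      else if (std::abs(Y[left] + gap_extend - Y[idx]) < EPS) state = 2;
      else state = 1;
      --j;
    } else {
      ar.push_back(read[i - 1]);
      af.push_back('-');
      const int up = (i - 1) * W + j;
      if (std::abs(M[up] + gap_open - X[idx]) < EPS) state = 0;
      else if (std::abs(Y[up] + gap_open - X[idx]) < EPS) state = 2;
      else state = 1;
      --i;
    }
  }
  std::reverse(ar.begin(), ar.end());
  std::reverse(af.begin(), af.end());

  AlnResult out;
  out.aligned_read = ar;
  out.aligned_ref = af;
  out.score = final_score;
  return out;
}

// [[Rcpp::export(name = ".nw_align_pair")]]
List nw_align_pair(std::string read, std::string ref,
                   double match, double mismatch,
                   double gap_open, double gap_extend) {
  if (read.empty() || ref.empty())
    stop("sequences must be non-empty");
  AlnResult r = align_core(read, ref, match, mismatch, gap_open, gap_extend);
  return List::create(_["aligned_read"] = r.aligned_read,
                      _["aligned_ref"] = r.aligned_ref,
                      _["score"] = r.score);
}

// [[Rcpp::export(name = ".nw_align_batch")]]
List nw_align_batch(CharacterVector reads, std::string ref,
                    double match, double mismatch,
                    double gap_open, double gap_extend) {
  const int n = reads.size();
  CharacterVector ar(n), af(n);
  NumericVector sc(n);
  for (int k = 0; k < n; ++k) {
    std::string rd = as<std::string>(reads[k]);
    if (rd.empty() || ref.empty())
      stop("sequences must be non-empty");
    AlnResult r = align_core(rd, ref, match, mismatch, gap_open, gap_extend);
    ar[k] = r.aligned_read;
    af[k] = r.aligned_ref;
    sc[k] = r.score;
  }
  return List::create(_["aligned_read"] = ar,
                      _["aligned_ref"] = af,
                      _["score"] = sc);
}

// [[Rcpp::export(name = ".nw_score_batch")]]
NumericVector nw_score_batch(CharacterVector reads, std::string ref,
                             double match, double mismatch,
                             double gap_open, double gap_extend) {
  const int nr = reads.size();
  const int m = (int) ref.size();
  const int W = m + 1;
  NumericVector sc(nr);
  for (int k = 0; k < nr; ++k) {
    std::string rd = as<std::string>(reads[k]);
    if (rd.empty() || ref.empty())
      stop("sequences must be non-empty");
    const int n = (int) rd.size();
    std::vector<double> M((n + 1) * W), X((n + 1) * W), Y((n + 1) * W);
    M[0] = 0.0; X[0] = NEG_INF; Y[0] = NEG_INF;
    for (int i = 1; i <= n; ++i) {
      M[i * W] = NEG_INF;
      X[i * W] = gap_open + (i - 1) * gap_extend;
      Y[i * W] = NEG_INF;
    }
    for (int j = 1; j <= m; ++j) {
      M[j] = NEG_INF; X[j] = NEG_INF;
      Y[j] = gap_open + (j - 1) * gap_extend;
    }
    for (int i = 1; i <= n; ++i) {
      const char ri = rd[i - 1];
      for (int j = 1; j <= m; ++j) {
        const int idx = i * W + j, up = (i - 1) * W + j,
                  left = i * W + (j - 1), diag = (i - 1) * W + (j - 1);
        const double s = subst_score(ri, ref[j - 1], match, mismatch);
        M[idx] = std::max(M[diag], std::max(X[diag], Y[diag])) + s;
        X[idx] = std::max(std::max(M[up] + gap_open, X[up] + gap_extend),
                          Y[up] + gap_open);
        Y[idx] = std::max(std::max(M[left] + gap_open, Y[left] + gap_extend),
                          X[left] + gap_open);
      }
    }
    const int idx = n * W + m;
    sc[k] = std::max(M[idx], std::max(X[idx], Y[idx]));
  }
  return sc;
}
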