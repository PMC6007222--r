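// Global alignment (Gotoh affine-gap DP) and the greedy identity-threshold
// clustering core. Scoring contract: match +1, mismatch -1, a gap of length L
// costs gap_open + L * gap_extend (default 2 + L). Identity is the number of
// matching columns of one optimal traceback divided by the chosen denominator.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int NEG_INF = INT_MIN / 4;
static const int MATCH = 1, MISMATCH = -1, GAP_OPEN = 2, GAP_EXT = 1;

struct AlnStats {
  int score;
  int matches;
  int aln_length;
};

// Three-state DP (M = aligned pair, X = gap in b consuming a, Y = gap in a
// consuming b). Scores use two rolling rows; predecessor states are kept in
// full for the traceback. Traceback ties prefer M, then X, then Y:
// deterministic. NEG_INF is far below any reachable score yet safe to add
// penalties to without overflow.
static AlnStats gotoh(const std::string& a, const std::string& b) {
  const int n = (int)a.size(), m = (int)b.size();
  const size_t W = (size_t)m + 1, SZ = (size_t)(n + 1) * W;
  std::vector<int> Mp(W), Xp(W), Yp(W), Mc(W), Xc(W), Yc(W);
  std::vector<signed char> pM(SZ, -1), pX(SZ, -1), pY(SZ, -1);
  Mp[0] = 0; Xp[0] = NEG_INF; Yp[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG_INF; Xp[j] = NEG_INF;
    Yp[j] = -(GAP_OPEN + GAP_EXT * j);
    pY[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG_INF; Yc[0] = NEG_INF;
    Xc[0] = -(GAP_OPEN + GAP_EXT * i);
    pX[(size_t)i * W] = (i == 1) ? 0 : 1;
    const char ai = a[i - 1];
    signed char* rM = &pM[(size_t)i * W];
    signed char* rX = &pX[(size_t)i * W];
    signed char* rY = &pY[(size_t)i * W];
    for (int j = 1; j <= m; ++j) {
      const int s = (ai == b[j - 1]) ? MATCH : MISMATCH;
      // M from diagonal (previous row, previous column)
      int best = Mp[j - 1];
      signed char arg = 0;
      if (Xp[j - 1] > best) { best = Xp[j - 1]; arg = 1; }
      if (Yp[j - 1] > best) { best = Yp[j - 1]; arg = 2; }
      Mc[j] = best + s; rM[j] = arg;
      // X from above (previous row, same column)
      best = Mp[j] - (GAP_OPEN + GAP_EXT); arg = 0;
      if (Xp[j] - GAP_EXT > best) { best = Xp[j] - GAP_EXT; arg = 1; }
      if (Yp[j] - (GAP_OPEN + GAP_EXT) > best) {
        best = Yp[j] - (GAP_OPEN + GAP_EXT); arg = 2;
      }
      Xc[j] = best; rX[j] = arg;
      // Y from the left (same row, previous column)
      best = Mc[j - 1] - (GAP_OPEN + GAP_EXT); arg = 0;
      if (Xc[j - 1] - (GAP_OPEN + GAP_EXT) > best) {
        best = Xc[j - 1] - (GAP_OPEN + GAP_EXT); arg = 1;
      }
      if (Yc[j - 1] - GAP_EXT > best) { best = Yc[j - 1] - GAP_EXT; arg = 2; }
      Yc[j] = best; rY[j] = arg;
    }
    Mp.swap(Mc); Xp.swap(Xc); Yp.swap(Yc);
  }
  int state = 0, score = Mp[m];
  if (Xp[m] > score) { score = Xp[m]; state = 1; }
  if (Yp[m] > score) { score = Yp[m]; state = 2; }
  AlnStats st{score, 0, 0};
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t c = (size_t)i * W + j;
    st.aln_length++;
    if (state == 0) {
      if (a[i - 1] == b[j - 1]) st.matches++;
      state = pM[c]; --i; --j;
    } else if (state == 1) {
      state = pX[c]; --i;
    } else {
      state = pY[c]; --j;
    }
  }
  return st;
}

// [[Rcpp::export]]
List align_stats_cpp(std::string a, std::string b) {
  if (a.empty() || b.empty()) stop("sequences must be non-empty");
  AlnStats st = gotoh(a, b);
  return List::create(_["score"] = st.score, _["matches"] = st.matches,
                      _["aln_length"] = st.aln_length);
}

// 2-bit encode a k-mer starting at pos; returns false if a non-ACGT base falls
// inside the window.
static bool encode_kmer(const std::string& s, int pos, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    switch (s[pos + i]) {
      case 'A': v = (v << 2) | 0; break;
      case 'C': v = (v << 2) | 1; break;
      case 'G': v = (v << 2) | 2; break;
      case 'T': v = (v << 2) | 3; break;
      default: return false;
    }
  }
  out = v;
  return true;
}

static void kmer_set(const std::string& s, int k,
                     std::unordered_set<uint64_t>& out) {
  if ((int)s.size() < k) return;
  uint64_t v;
  for (int p = 0; p + k <= (int)s.size(); ++p)
    if (encode_kmer(s, p, k, v)) out.insert(v);
}

// number of k-mer start positions in the SHORTER sequence whose word occurs
// anywhere in the other sequence
// [[Rcpp::export]]
int kmer_shared_cpp(std::string a, std::string b, int word_size) {
  const std::string& shorter = (a.size() <= b.size()) ? a : b;
  const std::string& longer = (a.size() <= b.size()) ? b : a;
  std::unordered_set<uint64_t> set;
  kmer_set(longer, word_size, set);
  if ((int)shorter.size() < word_size) return 0;
  int shared = 0;
  uint64_t v;
  for (int p = 0; p + word_size <= (int)shorter.size(); ++p)
    if (encode_kmer(shorter, p, word_size, v) && set.count(v)) ++shared;
  return shared;
}

static int min_shared_words(int len_short, int word_size, double cutoff) {
  double bound = len_short - word_size * (1.0 - cutoff) * len_short -
                 word_size + 1;
  int req = (int)std::floor(bound);
  return req > 0 ? req : 0;
}

// Greedy incremental clustering: sequences must arrive pre-sorted (length
// descending, ties by identifier ascending); each joins the first earlier
// representative at identity >= cutoff. denominator: 0 = shorter sequence,
// 1 = alignment length. Returns 1-based group ids and identities.
// [[Rcpp::export]]
List cluster_core_cpp(CharacterVector seqs, double cutoff, int word_size,
                      int denominator, bool use_prefilter) {
  const int n = seqs.size();
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
  std::vector<int> rep_idx;
  std::vector<std::unordered_set<uint64_t> > rep_kmers;
  IntegerVector group(n);
  NumericVector ident(n);
  for (int i = 0; i < n; ++i) {
    const std::string& q = ss[i];
    int joined = -1;
    double joined_id = 1.0;
    for (size_t g = 0; g < rep_idx.size(); ++g) {
      const std::string& rep = ss[rep_idx[g]];
      // reps are never shorter than the query (length-descending scan order)
      if (use_prefilter) {
        int req = min_shared_words((int)q.size(), word_size, cutoff);
        if (req > 0) {
          int shared = 0;
          uint64_t v;
          for (int p = 0; p + word_size <= (int)q.size(); ++p)
            if (encode_kmer(q, p, word_size, v) && rep_kmers[g].count(v))
              ++shared;
          if (shared < req) continue;
        }
      }
      AlnStats st = gotoh(q, rep);
      int denom = denominator == 0
                      ? (int)std::min(q.size(), rep.size())
                      : st.aln_length;
      double id = (double)st.matches / denom;
      if (id >= cutoff) {
        joined = (int)g;
        joined_id = id;
        break;
      }
    }
    if (joined >= 0) {
      group[i] = joined + 1;
      ident[i] = joined_id;
    } else {
      group[i] = (int)rep_idx.size() + 1;
      ident[i] = 1.0;
      rep_idx.push_back(i);
      rep_kmers.push_back(std::unordered_set<uint64_t>());
      kmer_set(q, word_size, rep_kmers.back());
    }
  }
  IntegerVector reps(rep_idx.begin(), rep_idx.end());
  return List::create(_["group"] = group, _["identity"] = ident,
                      _["rep_index"] = reps + 1);
}
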