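#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

static inline int matches(const std::string &a, const std::string &b) {
    int m = 0;
    const size_t n = a.size();
    for (size_t i = 0; i < n; ++i)
        if (a[i] == b[i]) ++m;
    return m;
}

// Number of positions at which two equal-length strings agree.
// [[Rcpp::export]]
int match_count_cpp(const std::string &a, const std::string &b) {
    if (a.size() != b.size())
        stop("k-mers must have equal length (got %d and %d)",
             (int)a.size(), (int)b.size());
    return matches(a, b);
}

// Symmetric matrix of pairwise match counts over a k-mer vector.
// [[Rcpp::export]]
IntegerMatrix kmer_match_matrix_cpp(const CharacterVector &kmers) {
    const int n = kmers.size();
    std::vector<std::string> ks(n);
    for (int i = 0; i < n; ++i) ks[i] = as<std::string>(kmers[i]);
    for (int i = 1; i < n; ++i)
        if (ks[i].size() != ks[0].size()) stop("k-mers must have equal length");
    IntegerMatrix M(n, n);
    const int k = n > 0 ? (int)ks[0].size() : 0;
    for (int i = 0; i < n; ++i) {
        M(i, i) = k;
        for (int j = i + 1; j < n; ++j) {
            int m = matches(ks[i], ks[j]);
            M(i, j) = m;
            M(j, i) = m;
        }
    }
    return M;
}

// Edge weights between windows: for every window pair (u < v) the weight is
// the maximum match count over all admissible k-mer pairs; pairs whose weight
// reaches `alpha` are returned as an edge list. `win_ptr` is a 0-based CSR
// offset vector of length n_windows + 1 into `kmers` (k-mers grouped by
// window, windows with no admissible k-mers have an empty range).
// [[Rcpp::export]]
DataFrame window_pair_weights_cpp(const CharacterVector &kmers,
                                  const IntegerVector &win_ptr,
                                  const int alpha) {
    const int nw = win_ptr.size() - 1;
    const int nk = kmers.size();
    std::vector<std::string> ks(nk);
    for (int i = 0; i < nk; ++i) ks[i] = as<std::string>(kmers[i]);
    const int k = nk > 0 ? (int)ks[0].size() : 0;
    for (int i = 1; i < nk; ++i)
        if ((int)ks[i].size() != k) stop("k-mers must have equal length");
    if (alpha < 1) stop("alpha must be >= 1");

    std::vector<int> U, V, W;
    for (int u = 0; u < nw; ++u) {
        const int ua = win_ptr[u], ub = win_ptr[u + 1];
        if (ua == ub) continue;
        for (int v = u + 1; v < nw; ++v) {
            const int va = win_ptr[v], vb = win_ptr[v + 1];
            if (va == vb) continue;
            int best = 0;
            for (int i = ua; i < ub && best < k; ++i)
                for (int j = va; j < vb; ++j) {
                    const int m = matches(ks[i], ks[j]);
                    if (m > best) {
                        best = m;
                        if (best == k) break;
                    }
                }
            if (best >= alpha) {
                U.push_back(u + 1);
                V.push_back(v + 1);
                W.push_back(best);
            }
        }
    }
    return DataFrame::create(_["u"] = U, _["v"] = V, _["w"] = W);
}

// Maximum match count of k-mer `a` over all gapless alignments against
// sequence `s` (0 when s is shorter than a).
// [[Rcpp::export]]
int scan_max_match_cpp(const std::string &a, const std::string &s) {
    const int k = a.size();
    const int L = s.size();
    int best = 0;
    for (int p = 0; p + k <= L; ++p) {
        int m = 0;
        for (int i = 0; i < k; ++i)
            if (a[i] == s[p + i]) ++m;
        if (m > best) {
            best = m;
            if (best == k) break;
        }
    }
    return best;
}
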