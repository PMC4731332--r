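#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static inline bool pair_ok(char a, char b, bool gu) {
    if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return true;
    if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return true;
    if (gu && ((a == 'G' && b == 'T') || (a == 'T' && b == 'G'))) return true;
    return false;
}

// Maximum base-pairing DP over s[i..j] (0-based, inclusive).
// Recurrence: M[i][j] = max( M[i][j-1],
//                            max_{k: i<=k<j-minh, pair(k,j)} M[i][k-1] + 1 + M[k+1][j-1] )
static void fill_dp(const std::string& s, int minh, bool gu,
                    std::vector< std::vector<int> >& M) {
    int n = (int) s.size();
    M.assign(n, std::vector<int>(n, 0));
    for (int len = minh + 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            int best = M[i][j - 1];
            for (int k = i; k < j - minh; ++k) {
                if (!pair_ok(s[k], s[j], gu)) continue;
                int v = 1;
                if (k > i) v += M[i][k - 1];
                if (k + 1 <= j - 1) v += M[k + 1][j - 1];
                if (v > best) best = v;
            }
            M[i][j] = best;
        }
    }
}

// [[Rcpp::export(name = ".nussinovCountC")]]
int nussinov_count_c(std::string seq, int min_hairpin, bool allow_gu) {
    int n = (int) seq.size();
    if (n < 2) return 0;
    std::vector< std::vector<int> > M;
    fill_dp(seq, min_hairpin, allow_gu, M);
    return M[0][n - 1];
}

// Deterministic traceback: prefer the pair (i2, j) with the largest i2
// admissible -- checking k = i (the outermost pairing of j with the interval
// start, i.e. the pair (i, j)) first, then "j unpaired", then inner k.
// [[Rcpp::export(name = ".nussinovFoldC")]]
List nussinov_fold_c(std::string seq, int min_hairpin, bool allow_gu) {
    int n = (int) seq.size();
    std::vector< std::vector<int> > M;
    std::vector<int> pi, pj;
    if (n >= 2) {
        fill_dp(seq, min_hairpin, allow_gu, M);
        std::vector< std::pair<int,int> > stack;
        stack.push_back(std::make_pair(0, n - 1));
        while (!stack.empty()) {
            int i = stack.back().first, j = stack.back().second;
            stack.pop_back();
            if (j - i <= min_hairpin) continue;
            int target = M[i][j];
            if (target == 0) continue;
            // pair (i, j) first
            bool done = false;
            if (pair_ok(seq[i], seq[j], allow_gu)) {
                int v = 1 + ((i + 1 <= j - 1) ? M[i + 1][j - 1] : 0);
                if (v == target) {
                    pi.push_back(i); pj.push_back(j);
                    stack.push_back(std::make_pair(i + 1, j - 1));
                    done = true;
                }
            }
            if (!done && M[i][j - 1] == target) {
                stack.push_back(std::make_pair(i, j - 1));
                done = true;
            }
            if (!done) {
                for (int k = i + 1; k < j - min_hairpin; ++k) {
                    if (!pair_ok(seq[k], seq[j], allow_gu)) continue;
                    int v = 1 + M[i][k - 1] + ((k + 1 <= j - 1) ? M[k + 1][j - 1] : 0);
                    if (v == target) {
                        pi.push_back(k); pj.push_back(j);
                        stack.push_back(std::make_pair(i, k - 1));
                        stack.push_back(std::make_pair(k + 1, j - 1));
                        done = true;
                        break;
                    }
                }
            }
        }
    }
    std::string db(n, '.');
    IntegerMatrix pairs(pi.size(), 2);
    for (size_t t = 0; t < pi.size(); ++t) {
        db[pi[t]] = '(';
        db[pj[t]] = ')';
        pairs(t, 0) = pi[t] + 1;  // 1-based
        pairs(t, 1) = pj[t] + 1;
    }
    return List::create(_["nPairs"] = (int) pi.size(),
                        _["pairs"] = pairs,
                        _["dotbracket"] = db);
}
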