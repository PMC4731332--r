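#include <Rcpp.h>
#include <vector>
#include <string>
#include <set>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps.  A gap of length L costs
// gapOpen + L * gapExtend.  Returns the best score and all co-optimal
// alignments (distinct endpoint/startpoint placements), each with mismatch
// and gapped-column counts from a deterministic traceback
// (diagonal > vertical > horizontal on ties).
// [[Rcpp::export(name = ".swAlignC")]]
List sw_align_c(std::string read, std::string ref,
                int match, int mismatch, int gap_open, int gap_extend) {
    int m = (int) read.size(), n = (int) ref.size();
    const int NEG = -1000000000;
    std::vector<int> H((m + 1) * (n + 1), 0);
    std::vector<int> E((m + 1) * (n + 1), NEG);  // gap in read (consumes ref)
    std::vector<int> F((m + 1) * (n + 1), NEG);  // gap in ref (consumes read)
    int gtot = gap_open + gap_extend;
#define IX(i, j) ((i) * (n + 1) + (j))
    int best = 0;
    for (int i = 1; i <= m; ++i) {
        for (int j = 1; j <= n; ++j) {
            int e = std::max(H[IX(i, j - 1)] - gtot, E[IX(i, j - 1)] - gap_extend);
            int f = std::max(H[IX(i - 1, j)] - gtot, F[IX(i - 1, j)] - gap_extend);
            int s = (read[i - 1] == ref[j - 1]) ? match : mismatch;
            int h = H[IX(i - 1, j - 1)] + s;
            h = std::max(h, std::max(e, f));
            h = std::max(h, 0);
            E[IX(i, j)] = e;
            F[IX(i, j)] = f;
            H[IX(i, j)] = h;
            if (h > best) best = h;
        }
    }
    std::vector<int> rs, re, qs, qe, nmm, ngap;
    if (best > 0) {
        std::set< std::vector<int> > seen;
        for (int ei = 1; ei <= m; ++ei) {
            for (int ej = 1; ej <= n; ++ej) {
                if (H[IX(ei, ej)] != best) continue;
                // traceback from (ei, ej)
                int i = ei, j = ej, mm = 0, gp = 0;
                int state = 0;  // 0=H, 1=E, 2=F
                while (true) {
                    if (state == 0) {
                        int h = H[IX(i, j)];
                        if (h == 0) break;
                        int s = (read[i - 1] == ref[j - 1]) ? match : mismatch;
                        if (i >= 1 && j >= 1 && H[IX(i - 1, j - 1)] + s == h) {
                            if (read[i - 1] != ref[j - 1]) ++mm;
                            --i; --j;
                        } else if (F[IX(i, j)] == h) {
                            state = 2;
                        } else {
                            state = 1;
                        }
                    } else if (state == 1) {  // E: gap column consuming ref
                        ++gp;
                        if (H[IX(i, j - 1)] - gtot == E[IX(i, j)]) {
                            --j; state = 0;
                        } else {
                            --j;  // stay in E (E[i][j-1] - ext == E[i][j])
                        }
                    } else {  // F: gap column consuming read
                        ++gp;
                        if (H[IX(i - 1, j)] - gtot == F[IX(i, j)]) {
                            --i; state = 0;
                        } else {
                            --i;
                        }
                    }
                }
                std::vector<int> key;
                key.push_back(i + 1); key.push_back(ei);
                key.push_back(j + 1); key.push_back(ej);
                if (seen.count(key)) continue;
                seen.insert(key);
                qs.push_back(i + 1); qe.push_back(ei);
                rs.push_back(j + 1); re.push_back(ej);
                nmm.push_back(mm); ngap.push_back(gp);
            }
        }
    }
#undef IX
    return List::create(
        _["score"] = best,
        _["readStart"] = wrap(qs), _["readEnd"] = wrap(qe),
        _["refStart"] = wrap(rs), _["refEnd"] = wrap(re),
        _["nMismatch"] = wrap(nmm), _["nGap"] = wrap(ngap));
}
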