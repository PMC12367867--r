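#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Scoring convention shared by every aligner entry point below:
// 'N' is treated as a mismatch against everything, including another 'N'.
static inline int subScore(char a, char b, int match, int mismatch) {
    if (a == 'N' || b == 'N') return mismatch;
    return (a == b) ? match : mismatch;
}

struct NwResult {
    int score;
    std::string a;
    std::string b;
};

// Global (Needleman-Wunsch) alignment with linear gap penalty.
// Traceback ties are broken deterministically: diagonal, then up
// (consume a base of `a` against a gap), then left.
static NwResult nwCore(const std::string& a, const std::string& b,
                       int match, int mismatch, int gap, bool traceback) {
    const int n = (int) a.size(), m = (int) b.size();
    std::vector<int> prev(m + 1), cur(m + 1);
    std::vector<std::vector<int> > S;
    if (traceback) S.assign(n + 1, std::vector<int>(m + 1));
    for (int j = 0; j <= m; ++j) prev[j] = j * gap;
    if (traceback) S[0] = prev;
    for (int i = 1; i <= n; ++i) {
        cur[0] = i * gap;
        for (int j = 1; j <= m; ++j) {
            int d = prev[j - 1] + subScore(a[i - 1], b[j - 1], match, mismatch);
            int u = prev[j] + gap;
            int l = cur[j - 1] + gap;
            int best = d;
            if (u > best) best = u;
            if (l > best) best = l;
            cur[j] = best;
        }
        std::swap(prev, cur);
        if (traceback) S[i] = prev;
    }
    NwResult res;
    res.score = prev[m];
    if (!traceback) return res;

    std::string aa, bb;
    int i = n, j = m;
    while (i > 0 || j > 0) {
        if (i > 0 && j > 0 &&
            S[i][j] == S[i - 1][j - 1] + subScore(a[i - 1], b[j - 1], match, mismatch)) {
            aa.push_back(a[i - 1]); bb.push_back(b[j - 1]); --i; --j;
        } else if (i > 0 && S[i][j] == S[i - 1][j] + gap) {
            aa.push_back(a[i - 1]); bb.push_back('-'); --i;
        } else {
            aa.push_back('-'); bb.push_back(b[j - 1]); --j;
        }
    }
    std::reverse(aa.begin(), aa.end());
    std::reverse(bb.begin(), bb.end());
    res.a = aa;
    res.b = bb;
    return res;
}

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  int match, int mismatch, int gap, bool score_only) {
    NwResult r = nwCore(a, b, match, mismatch, gap, !score_only);
    if (score_only) return List::create(_["score"] = r.score);
    return List::create(_["score"] = r.score,
                        _["aligned_a"] = r.a,
                        _["aligned_b"] = r.b);
}

// All-pairs global alignment scores (used for center selection in the
// center-star MSA).
// [[Rcpp::export]]
NumericMatrix nw_score_many_cpp(CharacterVector seqs,
                                int match, int mismatch, int gap) {
    const int n = seqs.size();
    std::vector<std::string> s(n);
    for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
    NumericMatrix out(n, n);
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            NwResult r = nwCore(s[i], s[j], match, mismatch, gap, false);
            out(i, j) = r.score;
            out(j, i) = r.score;
        }
    }
    return out;
}

// All-pairs alignment-based distances: (mismatch columns + gap columns) /
// alignment length, from the deterministic global alignment.
// [[Rcpp::export]]
NumericMatrix nw_dist_cpp(CharacterVector seqs,
                          int match, int mismatch, int gap) {
    const int n = seqs.size();
    std::vector<std::string> s(n);
    for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
    NumericMatrix out(n, n);
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            NwResult r = nwCore(s[i], s[j], match, mismatch, gap, true);
            int bad = 0, len = (int) r.a.size();
            for (int k = 0; k < len; ++k) {
                char x = r.a[k], y = r.b[k];
                if (x == '-' || y == '-' ||
                    subScore(x, y, 1, -1) < 0) ++bad;
            }
            double d = len > 0 ? (double) bad / len : 0.0;
            out(i, j) = d;
            out(j, i) = d;
        }
    }
    return out;
}

// Per-query-position mismatch profile against each reference: entry [i, j]
// is 1 when base i of the query is aligned to a gap or a mismatching base
// in reference j. Used by the bootstrap rank-confidence classifier.
// [[Rcpp::export]]
IntegerMatrix mismatch_profile_cpp(std::string query, CharacterVector refs,
                                   int match, int mismatch, int gap) {
    const int n = (int) query.size(), k = refs.size();
    IntegerMatrix out(n, k);
    for (int j = 0; j < k; ++j) {
        NwResult r = nwCore(query, as<std::string>(refs[j]),
                            match, mismatch, gap, true);
        int qi = 0;
        for (size_t c = 0; c < r.a.size(); ++c) {
            if (r.a[c] == '-') continue;
            out(qi, j) = (r.b[c] == '-' ||
                          subScore(r.a[c], r.b[c], 1, -1) < 0) ? 1 : 0;
            ++qi;
        }
    }
    return out;
}

// Longest single-base run per sequence (homopolymer screen).
// [[Rcpp::export]]
IntegerVector max_run_cpp(CharacterVector seqs) {
    const int n = seqs.size();
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        int best = 0, cur = 0;
        char last = 0;
        for (size_t k = 0; k < s.size(); ++k) {
            cur = (s[k] == last) ? cur + 1 : 1;
            last = s[k];
            if (cur > best) best = cur;
        }
        out[i] = best;
    }
    return out;
}

// Vectorized paired-end merge: the reverse mate must already be
// reverse-complemented (and its quality string reversed). The best overlap
// is the longest suffix(fwd)/prefix(revc) agreement with at most `max_mm`
// mismatches and at least `min_ov` bases. Output is the overlap region only;
// disagreements resolve to the higher-quality base, quality ties to 'N'.
// [[Rcpp::export]]
List merge_pairs_cpp(CharacterVector fwd, CharacterVector revc,
                     CharacterVector fq, CharacterVector rq,
                     int max_mm, int min_ov) {
    const int n = fwd.size();
    CharacterVector seq(n), qual(n), status(n);
    IntegerVector ovl(n);
    for (int i = 0; i < n; ++i) {
        std::string f = as<std::string>(fwd[i]);
        std::string r = as<std::string>(revc[i]);
        std::string qf = as<std::string>(fq[i]);
        std::string qr = as<std::string>(rq[i]);
        const int n1 = (int) f.size(), n2 = (int) r.size();
        int found = -1;
        for (int o = std::min(n1, n2); o >= min_ov; --o) {
            int mm = 0;
            for (int t = 0; t < o && mm <= max_mm; ++t) {
                char x = f[n1 - o + t], y = r[t];
                if (x == 'N' || y == 'N' || x != y) ++mm;
            }
            if (mm <= max_mm) { found = o; break; }
        }
        if (found < 0) {
            seq[i] = NA_STRING; qual[i] = NA_STRING;
            status[i] = "no_overlap"; ovl[i] = 0;
            continue;
        }
        std::string ms(found, 'N'), mq(found, '!');
        for (int t = 0; t < found; ++t) {
            char x = f[n1 - found + t], y = r[t];
            char qx = qf[n1 - found + t], qy = qr[t];
            if (x == y && x != 'N') {
                ms[t] = x; mq[t] = std::max(qx, qy);
            } else if (x == 'N' && y != 'N') {
                ms[t] = y; mq[t] = qy;
            } else if (y == 'N' && x != 'N') {
                ms[t] = x; mq[t] = qx;
            } else if (qx > qy) {
                ms[t] = x; mq[t] = qx;
            } else if (qy > qx) {
                ms[t] = y; mq[t] = qy;
            } else {
                ms[t] = 'N'; mq[t] = '!';
            }
        }
        seq[i] = ms; qual[i] = mq; status[i] = "merged"; ovl[i] = found;
    }
    return List::create(_["seq"] = seq, _["qual"] = qual,
                        _["status"] = status, _["overlap_len"] = ovl);
}
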