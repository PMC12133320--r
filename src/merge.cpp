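#include <Rcpp.h>
using namespace Rcpp;

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'a': return 't';
    case 'c': return 'g';
    case 'g': return 'c';
    case 't': return 'a';
    default:  return 'N';
    }
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
    R_xlen_t n = seqs.size();
    CharacterVector out(n);
    std::string buf;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
        const char *s = CHAR(seqs[i]);
        size_t len = LENGTH(seqs[i]);
        buf.assign(len, 'N');
        for (size_t j = 0; j < len; ++j) buf[j] = comp_base(s[len - 1 - j]);
        out[i] = buf;
    }
    return out;
}

// Merge read pairs by overlap consensus. r2 is reverse-complemented here.
// For each admissible overlap length o in [min_overlap, min(L1, L2)] the
// mismatch fraction between the r1 suffix and the r2rc prefix is computed;
// the merge with the smallest fraction (ties -> longest overlap) wins,
// provided it is <= max_mismatch_frac. Disagreeing overlap bases resolve to
// the higher-quality base, ties to r1.
// [[Rcpp::export]]
List merge_pairs_cpp(CharacterVector s1, CharacterVector q1,
                     CharacterVector s2, CharacterVector q2,
                     int min_overlap, double max_mismatch_frac) {
    R_xlen_t n = s1.size();
    if (s2.size() != n)
        stop("r1 and r2 must have the same number of reads");
    bool use_q = q1.size() == n && q2.size() == n;
    CharacterVector mseq(n), mqual(n);
    IntegerVector overlap(n);
    LogicalVector ok(n);
    std::string rc2, rq2, merged, mq;
    for (R_xlen_t i = 0; i < n; ++i) {
        const char *a = CHAR(s1[i]);
        int L1 = LENGTH(s1[i]);
        const char *b0 = CHAR(s2[i]);
        int L2 = LENGTH(s2[i]);
        rc2.assign(L2, 'N');
        for (int j = 0; j < L2; ++j) rc2[j] = comp_base(b0[L2 - 1 - j]);
        const char *qa = NULL;
        if (use_q && q1[i] != NA_STRING && LENGTH(q1[i]) == L1) qa = CHAR(q1[i]);
        rq2.clear();
        if (use_q && q2[i] != NA_STRING && LENGTH(q2[i]) == L2) {
            const char *qb = CHAR(q2[i]);
            rq2.assign(L2, '!');
            for (int j = 0; j < L2; ++j) rq2[j] = qb[L2 - 1 - j];
        }
        int omax = L1 < L2 ? L1 : L2;
        int best_o = -1;
        double best_frac = 2.0;
        for (int o = min_overlap; o <= omax; ++o) {
            int max_mm = (int)std::floor(max_mismatch_frac * o + 1e-9);
            int mm = 0;
            const char *suf = a + (L1 - o);
            bool aborted = false;
            for (int j = 0; j < o; ++j) {
                if (suf[j] != rc2[(size_t)j]) {
                    if (++mm > max_mm) { aborted = true; break; }
                }
            }
            if (aborted) continue;
            double frac = (double)mm / (double)o;
            if (frac < best_frac - 1e-12 ||
                (std::abs(frac - best_frac) <= 1e-12 && o > best_o)) {
                best_frac = frac;
                best_o = o;
            }
        }
        if (best_o < 0 || best_frac > max_mismatch_frac + 1e-12) {
            mseq[i] = NA_STRING;
            mqual[i] = NA_STRING;
            overlap[i] = 0;
            ok[i] = false;
            continue;
        }
        int o = best_o;
        int mlen = L1 + L2 - o;
        merged.assign(mlen, 'N');
        mq.assign(mlen, 'I');
        for (int j = 0; j < L1 - o; ++j) {
            merged[j] = a[j];
            if (qa) mq[j] = qa[j];
        }
        for (int j = 0; j < o; ++j) {
            char ca = a[L1 - o + j], cb = rc2[(size_t)j];
            char qca = qa ? qa[L1 - o + j] : 'I';
            char qcb = !rq2.empty() ? rq2[(size_t)j] : 'I';
            int pos = L1 - o + j;
            if (ca == cb) {
                merged[pos] = ca;
                mq[pos] = qca > qcb ? qca : qcb;
            } else if (qcb > qca) {
                merged[pos] = cb;
                mq[pos] = qcb;
            } else {
                merged[pos] = ca;  // tie or r1 higher -> r1 base
                mq[pos] = qca;
            }
        }
        for (int j = o; j < L2; ++j) {
            merged[(size_t)(L1 + j - o)] = rc2[(size_t)j];
            if (!rq2.empty()) mq[(size_t)(L1 + j - o)] = rq2[(size_t)j];
        }
        mseq[i] = merged;
        mqual[i] = mq;
        overlap[i] = o;
        ok[i] = true;
    }
    return List::create(_["sequence"] = mseq, _["quality"] = mqual,
                        _["overlap_len"] = overlap, _["ok"] = ok);
}

// Unique best Hamming hit among equal-length library sequences, within
// max_mm. Returns 1-based library index, or NA when no hit / ambiguous.
// [[Rcpp::export]]
IntegerVector hamming_match_cpp(CharacterVector inserts, CharacterVector lib,
                                int max_mm) {
    R_xlen_t n = inserts.size(), m = lib.size();
    IntegerVector out(n, NA_INTEGER);
    for (R_xlen_t i = 0; i < n; ++i) {
        if (inserts[i] == NA_STRING) continue;
        const char *q = CHAR(inserts[i]);
        int L = LENGTH(inserts[i]);
        int best = max_mm + 1, best_idx = -1, n_best = 0;
        for (R_xlen_t k = 0; k < m; ++k) {
            if (LENGTH(lib[k]) != L) continue;
            const char *t = CHAR(lib[k]);
            int d = 0;
            for (int j = 0; j < L && d <= best; ++j)
                if (q[j] != t[j]) ++d;
            if (d < best) {
                best = d;
                best_idx = (int)k;
                n_best = 1;
            } else if (d == best && d <= max_mm) {
                ++n_best;
            }
        }
        if (best <= max_mm && n_best == 1) out[i] = best_idx + 1;
    }
    return out;
}
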