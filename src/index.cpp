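#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Prefix-doubling suffix array over an integer alphabet. The text must end
// with a unique smallest sentinel (symbol 0) so every suffix comparison
// resolves before running off the end. O(n log^2 n), adequate for the
// desk-scale texts this index targets.
static std::vector<int> suffix_array(const std::vector<int>& text) {
    const int n = (int)text.size();
    std::vector<int> sa(n), rnk(text.begin(), text.end()), tmp(n);
    for (int i = 0; i < n; ++i) sa[i] = i;
    for (int k = 1;; k <<= 1) {
        auto cmp = [&](int a, int b) {
            if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
            const int ra = a + k < n ? rnk[a + k] : -1;
            const int rb = b + k < n ? rnk[b + k] : -1;
            return ra < rb;
        };
        std::sort(sa.begin(), sa.end(), cmp);
        tmp[sa[0]] = 0;
        for (int i = 1; i < n; ++i)
            tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
        rnk = tmp;
        if (rnk[sa[n - 1]] == n - 1) break;
    }
    return sa;
}

// Kasai's algorithm: lcp[i] = longest common prefix of suffixes at SA rows
// i-1 and i (lcp[0] = 0).
static std::vector<int> kasai_lcp(const std::vector<int>& text,
                                  const std::vector<int>& sa) {
    const int n = (int)text.size();
    std::vector<int> rank_of(n), lcp(n, 0);
    for (int i = 0; i < n; ++i) rank_of[sa[i]] = i;
    int h = 0;
    for (int i = 0; i < n; ++i) {
        if (rank_of[i] > 0) {
            const int j = sa[rank_of[i] - 1];
            while (i + h < n && j + h < n && text[i + h] == text[j + h]) ++h;
            lcp[rank_of[i]] = h;
            if (h > 0) --h;
        } else {
            h = 0;
        }
    }
    return lcp;
}

// Builds the run-length BWT index: SA -> BWT -> runs, MONI-style thresholds
// between consecutive runs of the same symbol (argmin of LCP in the gap,
// smallest row on ties), and document (shred) labels sampled at the first and
// last row of every run. The SA and LCP are discarded on return.
//
// text: encoded symbols; 0 = end-of-text sentinel (exactly once, last
// position), 1 = shred separator, bin b -> b + 2.
// doc_of_pos: shred id (0-based) for every text position.
// [[Rcpp::export]]
List build_index_cpp(IntegerVector text_, IntegerVector doc_of_pos) {
    const int n = text_.size();
    if (n < 2) stop("index text is empty");
    std::vector<int> text(text_.begin(), text_.end());
    if (text[n - 1] != 0) stop("text must end with the sentinel symbol");
    std::vector<int> sa = suffix_array(text);
    std::vector<int> lcp = kasai_lcp(text, sa);

    std::vector<int> bwt(n);
    for (int i = 0; i < n; ++i)
        bwt[i] = text[(sa[i] + n - 1) % n];

    // run-length encode
    std::vector<int> run_start, run_sym, doc_first, doc_last;
    for (int i = 0; i < n; ++i) {
        if (i == 0 || bwt[i] != bwt[i - 1]) {
            run_start.push_back(i);
            run_sym.push_back(bwt[i]);
            doc_first.push_back(doc_of_pos[sa[i]]);
            doc_last.push_back(doc_of_pos[sa[i]]);
        } else {
            doc_last.back() = doc_of_pos[sa[i]];
        }
    }
    const int r = (int)run_start.size();

    // thresholds: for run j (of symbol c) with previous run p of the same
    // symbol ending at row e_p, the threshold is the row t in
    // (e_p, run_start[j]] minimizing lcp[t]; rows below t jump up to run p,
    // rows at or above jump down to run j. First run of a symbol: 0.
    const int max_sym = *std::max_element(text.begin(), text.end());
    std::vector<int> thr(r, 0);
    std::vector<int> prev_run_of(max_sym + 1, -1);
    for (int j = 0; j < r; ++j) {
        const int c = run_sym[j];
        const int p = prev_run_of[c];
        if (p >= 0) {
            const int e_p = (p + 1 < r ? run_start[p + 1] : n) - 1;
            int best = e_p + 1;
            for (int t = e_p + 1; t <= run_start[j]; ++t) {
                if (lcp[t] < lcp[best]) best = t;
            }
            thr[j] = best;
        }
        prev_run_of[c] = j;
    }

    return List::create(
        _["n"] = n, _["r"] = r,
        _["run_start"] = IntegerVector(run_start.begin(), run_start.end()),
        _["run_sym"] = IntegerVector(run_sym.begin(), run_sym.end()),
        _["doc_first"] = IntegerVector(doc_first.begin(), doc_first.end()),
        _["doc_last"] = IntegerVector(doc_last.begin(), doc_last.end()),
        _["thr"] = IntegerVector(thr.begin(), thr.end()),
        _["start_doc"] = doc_of_pos[sa[n - 1]]);
}

// Streaming pseudo-matching-length pass (right to left over the query).
//
// State: the backward-search interval [lo, hi] of BWT rows whose suffixes
// start with the currently matched string, one concrete row inside it, the
// match length, and the row's document label. Per query symbol c:
//   - if the interval can be extended with c (rank arithmetic over the
//     run-length structures, O(log r)), the match grows by one. The tracked
//     row either already carries c (plain LF step, document label kept: a
//     matched symbol is never a separator, so the text position moves left
//     within the same shred) or the matcher hops to the nearest c-run
//     boundary *inside* the interval -- a sampled row, so the label is
//     picked up there -- and LF-steps from it. Ties between the two inside
//     boundaries are broken by the threshold (larger path-LCP side).
//   - if no occurrence of (c + matched string) exists, the match resets:
//     jump to the nearest c-run boundary in the threshold direction, take
//     its label, and restart with length 1; the new interval is all
//     suffixes starting with c.
// P[i] is therefore the length of the longest uninterrupted backward match
// ending at query position i (a matching statistic truncated at mismatch
// resets), and D[i] the shred holding it.
//
// q: encoded query symbols (bin b -> b + 2).
// sym_runs/sym_off/sym_cum: per-symbol run lists (see prepare_rank in R).
// C: C[c] = number of text symbols with encoded value < c.
// [[Rcpp::export]]
List compute_pmls_cpp(IntegerVector q, IntegerVector run_start,
                      IntegerVector run_sym, IntegerVector doc_first,
                      IntegerVector doc_last, IntegerVector thr,
                      IntegerVector C, IntegerVector sym_runs,
                      IntegerVector sym_off, IntegerVector sym_cum, int n,
                      int row0, int len0, int doc0, int lo0, int hi0) {
    const int m = q.size();
    const int r = run_start.size();
    IntegerVector P(m), D(m);
    int row = row0, len = len0, doc = doc0, lo = lo0, hi = hi0;
    const int n_sym = sym_off.size() - 1;

    auto run_end = [&](int k) { return (k + 1 < r ? run_start[k + 1] : n) - 1; };

    // number of occurrences of symbol c in BWT[0 .. row_ex - 1]
    auto rank_before = [&](int c, int row_ex) {
        const int off = sym_off[c], cnt = sym_off[c + 1] - sym_off[c];
        if (cnt == 0 || row_ex <= 0) return 0;
        // last c-run starting before row_ex
        int a = 0, b = cnt;
        while (a < b) {
            const int mid = (a + b) / 2;
            if (run_start[sym_runs[off + mid]] >= row_ex) b = mid;
            else a = mid + 1;
        }
        if (a == 0) return 0;
        const int t = a - 1, k = sym_runs[off + t];
        const int within = std::min(row_ex - 1, run_end(k)) - run_start[k] + 1;
        return sym_cum[off + t] + within;
    };

    for (int i = m - 1; i >= 0; --i) {
        const int c = q[i];
        if (c < 0 || c >= n_sym) stop("query symbol out of range");
        const int off = sym_off[c], cnt = sym_off[c + 1] - sym_off[c];
        const int tot_c = (c + 1 < n_sym ? C[c + 1] : n) - C[c];
        if (cnt == 0) {
            // symbol absent from the text: empty string matched
            len = 0;
            lo = 0;
            hi = n - 1;
            P[i] = 0;
            D[i] = doc;
            continue;
        }
        // can the current match be extended with c anywhere in [lo, hi]?
        const int ext_lo = C[c] + rank_before(c, lo);
        const int ext_hi = C[c] + rank_before(c, hi + 1) - 1;
        // run containing the tracked row
        int k = (int)(std::upper_bound(run_start.begin(), run_start.end(), row) -
                      run_start.begin()) - 1;
        if (ext_lo <= ext_hi) {
            // extension exists; reposition the row onto a c-row if needed
            if (run_sym[k] != c) {
                int j = (int)(std::upper_bound(sym_runs.begin() + off,
                                               sym_runs.begin() + off + cnt,
                                               k) -
                              (sym_runs.begin() + off));
                // candidate boundaries: end of previous c-run (j - 1),
                // start of next c-run (j); at least one lies in [lo, hi]
                const bool has_prev = j > 0 &&
                    run_end(sym_runs[off + j - 1]) >= lo;
                const bool has_next = j < cnt &&
                    run_start[sym_runs[off + j]] <= hi;
                bool go_prev;
                if (has_prev && has_next) {
                    go_prev = row < thr[sym_runs[off + j]];
                } else {
                    go_prev = has_prev;
                }
                if (go_prev) {
                    k = sym_runs[off + j - 1];
                    row = run_end(k);
                    doc = doc_last[k];
                } else {
                    k = sym_runs[off + j];
                    row = run_start[k];
                    doc = doc_first[k];
                }
            }
            row = C[c] + rank_before(c, row);
            lo = ext_lo;
            hi = ext_hi;
            ++len;
        } else {
            // true mismatch: restart from the nearest c-run boundary
            int j = (int)(std::upper_bound(sym_runs.begin() + off,
                                           sym_runs.begin() + off + cnt, k) -
                          (sym_runs.begin() + off));
            if (j == 0) {
                k = sym_runs[off];
                row = run_start[k];
                doc = doc_first[k];
            } else if (j == cnt) {
                k = sym_runs[off + cnt - 1];
                row = run_end(k);
                doc = doc_last[k];
            } else {
                const int k_next = sym_runs[off + j];
                if (row < thr[k_next]) {
                    k = sym_runs[off + j - 1];
                    row = run_end(k);
                    doc = doc_last[k];
                } else {
                    k = k_next;
                    row = run_start[k];
                    doc = doc_first[k];
                }
            }
            row = C[c] + rank_before(c, row);
            lo = C[c];
            hi = C[c] + tot_c - 1;
            len = 1;
        }
        P[i] = len;
        D[i] = doc;
    }
    return List::create(_["P"] = P, _["D"] = D, _["row"] = row, _["len"] = len,
                        _["doc"] = doc, _["lo"] = lo, _["hi"] = hi);
}
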