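#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Rolling Welch t-statistic between the w samples before and after each
// candidate boundary. t[i] compares [i-w, i) against [i, i+w); positions with
// an incomplete window are defined as 0 so read ends never produce cuts.
static std::vector<double> tstat_trace(const NumericVector& x, int w,
                                       double var_floor) {
    const int n = x.size();
    std::vector<double> t(n, 0.0);
    if (n < 2 * w) return t;
    std::vector<long double> s(n + 1, 0.0L), ss(n + 1, 0.0L);
    for (int i = 0; i < n; ++i) {
        s[i + 1] = s[i] + x[i];
        ss[i + 1] = ss[i] + (long double)x[i] * x[i];
    }
    for (int i = w; i <= n - w && i < n; ++i) {
        const double m1 = (double)(s[i] - s[i - w]) / w;
        const double m2 = (double)(s[i + w] - s[i]) / w;
        double v1 = (double)(ss[i] - ss[i - w]) / w - m1 * m1;
        double v2 = (double)(ss[i + w] - ss[i]) / w - m2 * m2;
        if (v1 < var_floor) v1 = var_floor;
        if (v2 < var_floor) v2 = var_floor;
        t[i] = std::fabs(m2 - m1) / std::sqrt(v1 / w + v2 / w);
    }
    return t;
}

struct Detector {
    const std::vector<double>* sig;
    double threshold;
    int window;
    int peak_pos;
    double peak_value;
    bool valid_peak;
    int masked_to;
};

static const double DEF_PEAK_VAL = 1e100;

// Scrappie-style two-detector peak caller: the short-window trace is the
// primary boundary source and masks the long-window trace whenever it is
// about to fire; the long trace catches gradual level changes the short one
// misses. Returns 0-based sample indices of event boundaries.
// [[Rcpp::export]]
IntegerVector detect_boundaries_cpp(NumericVector x, int w_short, int w_long,
                                    double thr_short, double thr_long,
                                    double peak_height, double var_floor) {
    const int n = x.size();
    std::vector<double> t_short = tstat_trace(x, w_short, var_floor);
    std::vector<double> t_long = tstat_trace(x, w_long, var_floor);
    std::vector<int> peaks;
    Detector det[2] = {
        {&t_short, thr_short, w_short, -1, DEF_PEAK_VAL, false, -1},
        {&t_long, thr_long, w_long, -1, DEF_PEAK_VAL, false, -1}};
    for (int i = 0; i < n; ++i) {
        for (int k = 0; k < 2; ++k) {
            Detector& d = det[k];
            if (d.masked_to >= i) continue;
            const double cur = (*d.sig)[i];
            if (d.peak_pos == -1) {
                // Not yet tracking a maximum: deepen the minimum or detect a
                // qualifying rise.
                if (cur < d.peak_value) {
                    d.peak_value = cur;
                } else if (cur - d.peak_value > peak_height) {
                    d.peak_value = cur;
                    d.peak_pos = i;
                }
            } else {
                if (cur > d.peak_value) {
                    d.peak_value = cur;
                    d.peak_pos = i;
                }
                if (k == 0 && d.peak_value > d.threshold) {
                    det[1].masked_to = d.peak_pos + d.window;
                    det[1].peak_pos = -1;
                    det[1].peak_value = DEF_PEAK_VAL;
                    det[1].valid_peak = false;
                }
                if (d.peak_value - cur > peak_height &&
                    d.peak_value > d.threshold) {
                    d.valid_peak = true;
                }
                if (d.valid_peak && (i - d.peak_pos) > d.window / 2) {
                    peaks.push_back(d.peak_pos);
                    d.peak_pos = -1;
                    d.peak_value = cur;
                    d.valid_peak = false;
                }
            }
        }
    }
    std::sort(peaks.begin(), peaks.end());
    peaks.erase(std::unique(peaks.begin(), peaks.end()), peaks.end());
    return IntegerVector(peaks.begin(), peaks.end());
}
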