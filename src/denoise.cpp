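#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Border mapping for 0-based index i on an axis of length n.
// mode 1 = reflect (symmetric, edge included), mode 2 = edge replicate.
static inline int map_index(int i, int n, int mode) {
  if (i >= 0 && i < n) return i;
  if (mode == 2) return i < 0 ? 0 : n - 1;
  int p = 2 * n;
  int r = i % p;
  if (r < 0) r += p;
  return r < n ? r : p - 1 - r;
}

struct WinStats {
  int center, s_min, s_max, s_med;
  int n1, n2;      // 0-based; -1 when undefined (constant window)
  int mm;          // M * M
};

static WinStats window_stats(const IntegerMatrix &img, int a, int b, int M,
                             int border_mode, std::vector<int> &buf) {
  const int h = img.nrow(), w = img.ncol(), k = (M - 1) / 2;
  buf.clear();
  for (int dr = -k; dr <= k; ++dr) {
    const int r = map_index(a + dr, h, border_mode);
    for (int dc = -k; dc <= k; ++dc) {
      const int c = map_index(b + dc, w, border_mode);
      buf.push_back(img(r, c));
    }
  }
  std::sort(buf.begin(), buf.end());
  WinStats ws;
  ws.mm = M * M;
  ws.center = img(a, b);
  ws.s_min = buf.front();
  ws.s_max = buf.back();
  ws.s_med = buf[(ws.mm - 1) / 2];
  if (ws.s_min == ws.s_max) {
    ws.n1 = ws.n2 = -1;
  } else {
    int i = 0;
    while (buf[i] == ws.s_min) ++i;
    ws.n1 = i;
    int j = ws.mm - 1;
    while (buf[j] == ws.s_max) --j;
    ws.n2 = j;
  }
  return ws;
}

// [[Rcpp::export]]
List denoise_cpp(IntegerMatrix img, int epsilon, int M0, int M_max,
                 int k1_variant, int confirm_rule, int border_mode) {
  const int h = img.nrow(), w = img.ncol();
  IntegerMatrix out(h, w), labels(h, w);
  std::vector<int> buf;
  buf.reserve(M_max * M_max);

  for (int b = 0; b < w; ++b) {
    for (int a = 0; a < h; ++a) {
      const int center = img(a, b);
      out(a, b) = center;
      WinStats ws = window_stats(img, a, b, M0, border_mode, buf);

      // stage 1: centre is the extreme point of the window (an extreme not
      // tied with the median) while the window median is not an impulse
      // value (0 < S_med < 255); constant windows are signal
      if (ws.s_min == ws.s_max) continue;
      const bool is_extreme =
          (center == ws.s_min || center == ws.s_max) && center != ws.s_med;
      const bool med_clean = ws.s_med > 0 && ws.s_med < 255;
      if (!(is_extreme && med_clean)) continue;  // signal, label 0

      // stage 2: slope confirmation against Q = S_med / epsilon
      const std::vector<int> &S = buf;
      double k1;
      if (center == ws.s_min) {
        k1 = (S[ws.n1] - center) / ((ws.n1 + 1) / 2.0);
      } else if (k1_variant == 2) {  // as printed
        k1 = (center - S[ws.n1]) / double(ws.mm - 1 - ws.n2);
      } else {                       // symmetric: mirror of the minimum case
        k1 = (center - S[ws.n2]) / ((ws.mm - ws.n2) / 2.0);
      }
      const double k2 =
          (ws.n2 <= ws.n1) ? 0.0
                           : (S[ws.n2] - S[ws.n1]) / double(ws.n2 - ws.n1);
      const double q = ws.s_med / double(epsilon);
      const bool noisy = (confirm_rule == 1)
                             ? std::abs(k1) >= q
                             : (std::abs(k1) > std::abs(k2) && std::abs(k1) >= q);
      if (!noisy) {
        labels(a, b) = 1;  // quasi-noise candidate, left unchanged
        continue;
      }
      labels(a, b) = 2;

      // replacement: median of the smallest window whose median is not an
      // extreme of that window; fall back to the M_max median
      int repl = NA_INTEGER;
      for (int m = M0; m <= M_max; m += 2) {
        WinStats wm = window_stats(img, a, b, m, border_mode, buf);
        repl = wm.s_med;
        if (wm.s_med > wm.s_min && wm.s_med < wm.s_max) break;
      }
      out(a, b) = repl;
    }
  }
  return List::create(_["image"] = out, _["labels"] = labels);
}
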