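#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Non-parametric exemplar-based texture synthesis (Efros-Leung style).
//
// The output is grown outward from a seed patch copied from the exemplar.
// Each unfilled pixel bordering the filled region is synthesised by
// comparing its partially filled, Gaussian-weighted neighbourhood with every
// exemplar patch; all patches whose masked SSD is within
// (1 + error_threshold) of the best match are candidates and one is chosen
// uniformly at random (using R's RNG, so results are reproducible under
// set.seed()). Every output value therefore exists in the exemplar.
//
// [[Rcpp::export]]
NumericMatrix synth_nonparametric_cpp(NumericMatrix exemplar,
                                      int out_h, int out_w,
                                      int window_radius,
                                      double error_threshold) {
  const int eh = exemplar.nrow(), ew = exemplar.ncol();
  const int w = window_radius, win = 2 * w + 1;
  if (eh < win || ew < win)
    stop("exemplar smaller than the synthesis window");

  RNGScope scope;

  // Gaussian neighbourhood weights (sigma = window/6.4, the usual choice)
  std::vector<double> gw(win * win);
  const double sigma = win / 6.4;
  for (int dx = -w; dx <= w; ++dx)
    for (int dy = -w; dy <= w; ++dy)
      gw[(dx + w) * win + (dy + w)] =
        std::exp(-(dx * dx + dy * dy) / (2.0 * sigma * sigma));

  // all fully interior exemplar patches, flattened column-major
  const int ph = eh - 2 * w, pw = ew - 2 * w, np = ph * pw;
  std::vector<double> patches((size_t)np * win * win);
  std::vector<double> centres(np);
  for (int pc = 0; pc < pw; ++pc) {
    for (int pr = 0; pr < ph; ++pr) {
      const int id = pc * ph + pr;
      centres[id] = exemplar(pr + w, pc + w);
      double* dst = &patches[(size_t)id * win * win];
      for (int dx = -w; dx <= w; ++dx)
        for (int dy = -w; dy <= w; ++dy)
          dst[(dx + w) * win + (dy + w)] = exemplar(pr + w + dy, pc + w + dx);
    }
  }

  NumericMatrix out(out_h, out_w);
  std::vector<char> filled((size_t)out_h * out_w, 0);
  std::fill(out.begin(), out.end(), NA_REAL);

  // seed: copy a random window-sized exemplar patch into the centre
  int sr = (int)std::floor(unif_rand() * ph);
  int sc = (int)std::floor(unif_rand() * pw);
  if (sr >= ph) sr = ph - 1;
  if (sc >= pw) sc = pw - 1;
  const int cr = out_h / 2 - w, cc = out_w / 2 - w;
  for (int dx = 0; dx < win && cc + dx < out_w; ++dx)
    for (int dy = 0; dy < win && cr + dy < out_h; ++dy) {
      if (cr + dy < 0 || cc + dx < 0) continue;
      out(cr + dy, cc + dx) = exemplar(sr + dy, sc + dx);
      filled[(size_t)(cc + dx) * out_h + (cr + dy)] = 1;
    }

  std::vector<int> cand;
  cand.reserve(np);
  std::vector<double> neigh(win * win);
  std::vector<char> known(win * win);

  int n_filled = 0;
  for (size_t i = 0; i < filled.size(); ++i) n_filled += filled[i];

  while (n_filled < out_h * out_w) {
    // frontier: unfilled pixels with at least one filled 8-neighbour,
    // processed most-constrained first
    std::vector<std::pair<int, int> > frontier; // (-count, index)
    for (int c = 0; c < out_w; ++c) {
      for (int r = 0; r < out_h; ++r) {
        if (filled[(size_t)c * out_h + r]) continue;
        int cnt = 0;
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy) {
            const int rr = r + dy, cx = c + dx;
            if (rr < 0 || rr >= out_h || cx < 0 || cx >= out_w) continue;
            cnt += filled[(size_t)cx * out_h + rr];
          }
        if (cnt > 0) frontier.push_back(std::make_pair(-cnt, c * out_h + r));
      }
    }
    if (frontier.empty()) stop("synthesis stalled"); // cannot happen
    std::stable_sort(frontier.begin(), frontier.end());

    for (size_t f = 0; f < frontier.size(); ++f) {
      const int idx = frontier[f].second;
      const int c = idx / out_h, r = idx % out_h;
      if (filled[(size_t)c * out_h + r]) continue;

      double wsum = 0.0;
      for (int dx = -w; dx <= w; ++dx)
        for (int dy = -w; dy <= w; ++dy) {
          const int rr = r + dy, cx = c + dx, k = (dx + w) * win + (dy + w);
          if (rr >= 0 && rr < out_h && cx >= 0 && cx < out_w &&
              filled[(size_t)cx * out_h + rr]) {
            known[k] = 1;
            neigh[k] = out(rr, cx);
            wsum += gw[k];
          } else known[k] = 0;
        }
      if (wsum <= 0.0) continue;

      // weighted SSD against every exemplar patch; patches whose partial
      // sum already exceeds the current acceptance bound are pruned (safe:
      // the bound only shrinks as better matches appear)
      double best = R_PosInf;
      cand.clear();
      for (int p = 0; p < np; ++p) {
        const double* pat = &patches[(size_t)p * win * win];
        const double bound =
          (best == R_PosInf) ? R_PosInf : best * (1.0 + error_threshold);
        double d = 0.0;
        bool pruned = false;
        for (int k = 0; k < win * win; ++k) {
          if (!known[k]) continue;
          const double diff = neigh[k] - pat[k];
          d += gw[k] * diff * diff;
          if (d > bound) { pruned = true; break; }
        }
        if (pruned) continue;
        if (d < best) best = d;
        cand.push_back(p);
      }
      // keep only candidates within the final threshold
      const double thr = best * (1.0 + error_threshold) + 1e-12;
      int n_ok = 0;
      for (size_t k = 0; k < cand.size(); ++k) {
        const double* pat = &patches[(size_t)cand[k] * win * win];
        double d = 0.0;
        for (int kk = 0; kk < win * win; ++kk) {
          if (!known[kk]) continue;
          const double diff = neigh[kk] - pat[kk];
          d += gw[kk] * diff * diff;
        }
        if (d <= thr) cand[n_ok++] = cand[k];
      }
      if (n_ok == 0) continue;
      int pick = (int)std::floor(unif_rand() * n_ok);
      if (pick >= n_ok) pick = n_ok - 1;
      out(r, c) = centres[cand[pick]];
      filled[(size_t)c * out_h + r] = 1;
      ++n_filled;
    }
  }
  return out;
}
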