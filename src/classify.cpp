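#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

// Gap-and-count rules for one product/schedule. Limits are indexed by the
// 1-based position of the dose that opens the gap; positions past the head
// vector use the steady-state value (benralizumab's Q4W->Q8W phase change is
// the only product with a non-empty head).
struct Rules {
  std::vector<double> gap_head;   // prolonged-gap limits by opening position
  double gap_rest;
  std::vector<double> disc_head;  // terminal (end-of-follow-up) gap limits
  double disc_rest;
  int min_adherent;               // minimum dose count for "adherent"
  int minimal_max;                // maximum dose count for "minimally adherent"
};

Rules as_rules(const List& r) {
  Rules out;
  out.gap_head = as<std::vector<double> >(r["gap_head"]);
  out.gap_rest = as<double>(r["gap_rest"]);
  out.disc_head = as<std::vector<double> >(r["disc_head"]);
  out.disc_rest = as<double>(r["disc_rest"]);
  out.min_adherent = as<int>(r["min_adherent"]);
  out.minimal_max = as<int>(r["minimal_max"]);
  return out;
}

inline double limit_at(const std::vector<double>& head, double rest, int pos) {
  return pos <= (int)head.size() ? head[pos - 1] : rest;
}

// Categories: 1 adherent, 2 partially adherent, 3 minimally adherent,
// 4 treatment discontinuation. Discontinuation is evaluated first
// (precedence rule), then the all-gaps-within-window / dose-count grid.
int classify_one(const double* d, int n, const Rules& r, double followup) {
  if ((followup - d[n - 1]) >= limit_at(r.disc_head, r.disc_rest, n)) return 4;
  bool prolonged = false;
  for (int i = 1; i < n && !prolonged; ++i)
    if ((d[i] - d[i - 1]) >= limit_at(r.gap_head, r.gap_rest, i)) prolonged = true;
  if (!prolonged && n >= r.min_adherent) return 1;
  if (prolonged && n <= r.minimal_max) return 3;
  return 2;
}

double median_gap(const double* d, int n) {
  if (n < 2) return NA_REAL;
  std::vector<double> g(n - 1);
  for (int i = 1; i < n; ++i) g[i - 1] = d[i] - d[i - 1];
  std::sort(g.begin(), g.end());
  int m = n - 1;
  return (m % 2) ? g[m / 2] : 0.5 * (g[m / 2 - 1] + g[m / 2]);
}

} // namespace

// Classify many equal-length dose-date sequences (one per row).
// [[Rcpp::export]]
IntegerVector classify_dates_cpp(NumericMatrix dates, List rules,
                                 double followup) {
  Rules r = as_rules(rules);
  int nseq = dates.nrow(), k = dates.ncol();
  IntegerVector out(nseq);
  std::vector<double> d(k);
  for (int i = 0; i < nseq; ++i) {
    for (int j = 0; j < k; ++j) d[j] = dates(i, j);
    out[i] = classify_one(d.data(), k, r, followup);
  }
  return out;
}

// Same, but infer the Q2W vs Q4W schedule per sequence from the median
// inter-dose gap (used for omalizumab, whose schedule is not in claims).
// [[Rcpp::export]]
IntegerVector classify_dates_infer_cpp(NumericMatrix dates, List rules_q2w,
                                       List rules_q4w, double followup,
                                       double q2w_below) {
  Rules r2 = as_rules(rules_q2w), r4 = as_rules(rules_q4w);
  int nseq = dates.nrow(), k = dates.ncol();
  IntegerVector out(nseq);
  std::vector<double> d(k);
  for (int i = 0; i < nseq; ++i) {
    for (int j = 0; j < k; ++j) d[j] = dates(i, j);
    double mg = median_gap(d.data(), k);
    const Rules& r = (k >= 2 && mg < q2w_below) ? r2 : r4;
    out[i] = classify_one(d.data(), k, r, followup);
  }
  return out;
}

namespace {

struct EnumCtx {
  Rules r;
  double followup;
  int grid_step;
  int ngrid;
  int max_doses;
  std::vector<double> d;
  IntegerMatrix counts; // max_doses x 4
};

// Depth-first enumeration of dose sequences starting at day 0 with all later
// doses on the grid; every prefix is itself a complete sequence and is
// classified with the same kernel classify_adherence() uses.
void enum_rec(EnumCtx& ctx, int n) {
  ctx.counts(n - 1, classify_one(ctx.d.data(), n, ctx.r, ctx.followup) - 1)++;
  if (n == ctx.max_doses) return;
  int start = (int)(ctx.d[n - 1] / ctx.grid_step) + 1;
  for (int g = start; g <= ctx.ngrid; ++g) {
    ctx.d[n] = (double)(g * ctx.grid_step);
    enum_rec(ctx, n + 1);
  }
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix enumerate_grid_cpp(int grid_step, int max_day, int max_doses,
                                 List rules, double followup) {
  EnumCtx ctx;
  ctx.r = as_rules(rules);
  ctx.followup = followup;
  ctx.grid_step = grid_step;
  ctx.ngrid = max_day / grid_step;
  ctx.max_doses = max_doses;
  ctx.d.assign(max_doses, 0.0);
  ctx.counts = IntegerMatrix(max_doses, 4);
  enum_rec(ctx, 1);
  return ctx.counts;
}
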