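#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Founder-origin labels of gametes transmitted down one side of a
// consanguinity loop. The common-ancestor couple contributes four founder
// haplotypes, labelled 1-4 (ancestor A: 1,2; ancestor B: 3,4); chromatin
// from outside the loop is 0.
//
// A homolog transmitted m meioses below the couple is a deterministic
// function of independent two-state crossover phase processes, each
// flipping at Haldane's rate of 1/100 per cM along the chromosome:
//   bit 0      : haplotype 1 vs 2 within the gamete made by ancestor A
//   bit 1      : haplotype 3 vs 4 within the gamete made by ancestor B
//   bit 2      : which grandparental gamete (A's or B's) the couple's
//                child passed on
//   bits 3..m  : loop vs outside chromatin at each subsequent meiosis
// For m == 1 (the subject's parent IS one of the ancestors) only bit 0
// exists and the homolog is a mosaic of haplotypes 1/2.

namespace {

struct Mosaic {
  std::vector<double> cut;  // positions where the label changes, sorted
  std::vector<int> lab;     // labels; lab.size() == cut.size() + 1
};

inline int state_label(const std::vector<int>& bits, int m) {
  if (m == 1) return bits[0] ? 2 : 1;
  for (int k = 3; k <= m; ++k)
    if (bits[k]) return 0;
  return bits[2] ? (bits[1] ? 4 : 3) : (bits[0] ? 2 : 1);
}

Mosaic sim_homolog(double len, int m) {
  const int p = (m == 1) ? 1 : m + 1;
  const int nb = (int) R::rpois(len * p / 100.0);
  std::vector<double> pos(nb);
  for (int i = 0; i < nb; ++i) pos[i] = R::unif_rand() * len;
  std::sort(pos.begin(), pos.end());
  std::vector<int> comp(nb);
  for (int i = 0; i < nb; ++i) {
    int c = (int) (R::unif_rand() * p);
    comp[i] = (c >= p) ? (p - 1) : c;
  }
  std::vector<int> bits(p);
  for (int j = 0; j < p; ++j) bits[j] = (R::unif_rand() < 0.5) ? 1 : 0;

  Mosaic mo;
  int cur = state_label(bits, m);
  mo.lab.push_back(cur);
  for (int i = 0; i < nb; ++i) {
    bits[comp[i]] ^= 1;
    const int l = state_label(bits, m);
    if (l != cur) {
      mo.cut.push_back(pos[i]);
      mo.lab.push_back(l);
      cur = l;
    }
  }
  return mo;
}

// partition of [0, len] into intervals of constant (paternal, maternal) label
struct Joint {
  std::vector<double> start, end;
  std::vector<int> labp, labm;
};

Joint merge_mosaics(const Mosaic& a, const Mosaic& b, double len) {
  Joint j;
  size_t ia = 0, ib = 0;
  double cur = 0.0;
  for (;;) {
    const double na = (ia < a.cut.size()) ? a.cut[ia] : len;
    const double nb = (ib < b.cut.size()) ? b.cut[ib] : len;
    const double nxt = std::min(na, nb);
    j.start.push_back(cur);
    j.end.push_back(nxt);
    j.labp.push_back(a.lab[ia]);
    j.labm.push_back(b.lab[ib]);
    if (nxt >= len) break;
    if (na <= nxt) ++ia;
    if (nb <= nxt) ++ib;
    cur = nxt;
  }
  return j;
}

void check_args(int m, int n, const NumericVector& lengths) {
  if (m < 1 || n < 1) stop("m and n must be >= 1");
  for (R_xlen_t i = 0; i < lengths.size(); ++i)
    if (!(lengths[i] > 0)) stop("chromosome lengths must be > 0");
}

}  // namespace

// Simulate n_events independent descents through the loop and report, per
// event, the number, total genetic length, and maximal genetic length of
// the autozygous segments (intervals where the paternal and maternal
// homologs carry the same founder haplotype). If keep_chrom > 0, the AS
// endpoints on that chromosome (1-based index into `lengths`) are returned
// for every event.
// [[Rcpp::export]]
List cpp_loop_events(int m, int n, NumericVector lengths, int n_events,
                     int keep_chrom) {
  check_args(m, n, lengths);
  if (n_events < 1) stop("n_events must be >= 1");
  NumericMatrix stats(n_events, 3);
  std::vector<int> seg_ev;
  std::vector<double> seg_s, seg_e;
  for (int ev = 0; ev < n_events; ++ev) {
    int cnt = 0;
    double tot = 0.0, mx = 0.0;
    for (R_xlen_t c = 0; c < lengths.size(); ++c) {
      const double L = lengths[c];
      const Mosaic mp = sim_homolog(L, m);
      const Mosaic mm = sim_homolog(L, n);
      const Joint j = merge_mosaics(mp, mm, L);
      for (size_t k = 0; k < j.start.size(); ++k) {
        if (j.labp[k] > 0 && j.labp[k] == j.labm[k]) {
          const double l = j.end[k] - j.start[k];
          ++cnt;
          tot += l;
          if (l > mx) mx = l;
          if (keep_chrom == (int) (c + 1)) {
            seg_ev.push_back(ev + 1);
            seg_s.push_back(j.start[k]);
            seg_e.push_back(j.end[k]);
          }
        }
      }
    }
    stats(ev, 0) = cnt;
    stats(ev, 1) = tot;
    stats(ev, 2) = mx;
  }
  return List::create(_["stats"] = stats, _["seg_event"] = wrap(seg_ev),
                      _["seg_start"] = wrap(seg_s), _["seg_end"] = wrap(seg_e));
}

// Full founder-origin partition for a single descent: one data frame per
// chromosome with the joint (paternal, maternal) labels on each interval.
// [[Rcpp::export]]
List cpp_loop_mosaic(int m, int n, NumericVector lengths) {
  check_args(m, n, lengths);
  List out(lengths.size());
  for (R_xlen_t c = 0; c < lengths.size(); ++c) {
    const double L = lengths[c];
    const Mosaic mp = sim_homolog(L, m);
    const Mosaic mm = sim_homolog(L, n);
    const Joint j = merge_mosaics(mp, mm, L);
    out[c] = DataFrame::create(
        _["start_cm"] = wrap(j.start), _["end_cm"] = wrap(j.end),
        _["lab_p"] = wrap(j.labp), _["lab_m"] = wrap(j.labm));
  }
  return out;
}
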