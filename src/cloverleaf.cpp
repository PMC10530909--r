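#include <Rcpp.h>
using namespace Rcpp;

// Constrained cloverleaf placement enumeration.
//
// A placement lays the canonical four-arm tRNA geometry over the sequence:
//   acceptor 5' (7) | spacer1 (1-3) | D stem (3-4) + D loop (3-12) + D stem'
//   | spacer2 (0-2) | anticodon stem (5) + 7-nt loop + stem' | variable loop
//   (3-23) | T stem (4-5) + T loop (3-9) + stem' | acceptor 3' (7) | tail
//   (0-4, discriminator + NCCA)
// Pairs allowed in stems: Watson-Crick plus G-U. For every (start, total
// length) the best placement is kept: maximal number of paired (non-
// mismatch) bases, ties broken by fewer total mismatches, then leftmost
// anticodon, then canonical loop order (s1, d, dloop, s2, v, t, tloop, tail
// ascending).
//
// Sequence encoding: A=0, C=1, G=2, T=3 (anything else = -1, never pairs).

static inline bool pairs_ok(int a, int b) {
  if (a < 0 || b < 0) return false;
  if (a + b == 3) return true;                 // A-T / C-G
  return (a == 2 && b == 3) || (a == 3 && b == 2);  // G-U wobble
}

struct Best {
  int paired = -1, mm = 1000, ac = 1 << 30;
  int vals[16];
  bool set = false;
};

// require_signature additionally demands the semi-invariant bases of real
// tRNAs: U33 (immediately 5' of the anticodon), a purine at 37 (immediately
// 3' of it) and the T-loop's TTC (the T54-Psi55-C56 motif the loop is named
// for) -- the classical invariant-base constraint of tRNA gene searches,
// used by the control-region scanner to suppress the spurious cloverleafs
// that A+T-rich DNA folds by chance.
// [[Rcpp::export]]
IntegerMatrix cpp_cloverleaf_scan(IntegerVector seq,
                                  int start_min, int start_max,
                                  int len_min, int len_max,
                                  int max_stem_mismatch, int min_paired,
                                  bool require_signature = false) {
  const int L = seq.size();
  const int *s = INTEGER(seq);
  // per-(start,len) best placements, keyed densely
  std::map<std::pair<int, int>, Best> best;

  // precompute anticodon-stem mismatches for every possible stem start q
  std::vector<int> acmm(L, 1000);
  for (int q = 0; q + 17 <= L; ++q) {
    int mm = 0;
    for (int i = 0; i < 5; ++i)
      if (!pairs_ok(s[q + i], s[q + 16 - i])) ++mm;
    acmm[q] = mm;
  }

  if (start_max > L - 1) start_max = L - 1;
  for (int start = start_min; start <= start_max; ++start) {
    if (start + len_min > L) break;
    for (int s1 = 1; s1 <= 3; ++s1)
      for (int d = 3; d <= 4; ++d)
        for (int dl = 3; dl <= 12; ++dl) {
          int d5 = start + 7 + s1;
          int d3 = d5 + d + dl;
          if (d3 + d > L) continue;
          int mmD = 0;
          for (int i = 0; i < d; ++i)
            if (!pairs_ok(s[d5 + i], s[d3 + d - 1 - i])) ++mmD;
          if (mmD > max_stem_mismatch) continue;
          for (int s2 = 0; s2 <= 2; ++s2) {
            int q = d3 + d + s2;  // anticodon stem start
            if (q + 17 > L) continue;
            int mmC = acmm[q];
            if (mmC > max_stem_mismatch) continue;
            if (require_signature) {
              // U33, purine 37 (loop positions 2 and 6 of the 7-nt loop)
              if (s[q + 6] != 3) continue;
              if (s[q + 10] != 0 && s[q + 10] != 2) continue;
            }
            for (int v = 3; v <= 23; ++v)
              for (int t = 4; t <= 5; ++t)
                for (int tl = 3; tl <= 9; ++tl) {
                  int r = q + 17 + v;
                  int u = r + 2 * t + tl;  // acceptor 3' start
                  if (u + 7 > L) continue;
                  if (require_signature &&
                      (s[r + t] != 3 || s[r + t + 1] != 3 ||
                       s[r + t + 2] != 1)) continue;  // T54 T55 C56
                  int core = u + 7 - start;
                  if (core > len_max) continue;
                  int mmT = 0;
                  for (int i = 0; i < t; ++i)
                    if (!pairs_ok(s[r + i], s[r + t + tl + t - 1 - i])) ++mmT;
                  if (mmT > max_stem_mismatch) continue;
                  int mmA = 0;
                  for (int i = 0; i < 7; ++i)
                    if (!pairs_ok(s[start + i], s[u + 6 - i])) ++mmA;
                  if (mmA > max_stem_mismatch) continue;
                  int paired = (7 - mmA) + (d - mmD) + (5 - mmC) + (t - mmT);
                  if (paired < min_paired) continue;
                  int mm = mmA + mmD + mmC + mmT;
                  int ac = q + 7;  // anticodon start (0-based)
                  for (int tail = 0; tail <= 4; ++tail) {
                    int len = core + tail;
                    if (len < len_min || len > len_max) continue;
                    if (start + len > L) break;
                    Best &b = best[{start, len}];
                    bool better = false;
                    if (!b.set) better = true;
                    else if (paired != b.paired) better = paired > b.paired;
                    else if (mm != b.mm) better = mm < b.mm;
                    else if (ac != b.ac) better = ac < b.ac;
                    if (better) {
                      b.set = true;
                      b.paired = paired; b.mm = mm; b.ac = ac;
                      int vals[16] = {start, len, s1, d, dl, s2, v, t, tl,
                                      tail, mmA, mmD, mmC, mmT, paired, ac};
                      std::copy(vals, vals + 16, b.vals);
                    }
                  }
                }
          }
        }
  }

  IntegerMatrix out(best.size(), 16);
  int row = 0;
  for (auto &kv : best) {
    for (int j = 0; j < 16; ++j) out(row, j) = kv.second.vals[j];
    ++row;
  }
  colnames(out) = CharacterVector::create(
      "start", "len", "s1", "d", "dloop", "s2", "v", "t", "tloop", "tail",
      "mm_acc", "mm_d", "mm_ac", "mm_t", "paired", "ac_pos");
  return out;
}
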