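#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Frame-shift-aware local DNA-vs-protein alignment (Gotoh-style affine gaps,
// plus 2-nt and 4-nt codon columns carrying a fixed per-event penalty).
//
// States per cell (i query bases consumed, j subject residues consumed):
//   H  - last column is a codon column ('=', 'X', '/', '\') or local start
//   E  - last column is 'I' (gap in query, consumes 1 subject residue)
//   G  - last column is 'D' (gap in subject, consumes 3 query bases)
//
// Codon columns consume 3 ('='/'X'), 2 ('/') or 4 ('\') query bases and one
// subject residue; 2-nt codons are translated with an N padded on the 5' side
// (always X under the N-containing-codon rule), 4-nt codons translate their
// last 3 bases.  Each '/' or '\' column subtracts the frame-shift penalty
// once.  Gap runs of length k cost gap_open + k * gap_extend.
//
// Tie-break order (equal scores): codon match > 2-nt shift > 4-nt shift >
// gaps, and for gaps open-from-H > extend; realised by strict '>' over an
// ordered candidate list.

static const double NEG = -1e18;

// query bases coded 0=A,1=C,2=G,3=T,4=N; codon index b1*25 + b2*5 + b3
static inline int codon_idx(const IntegerVector& q, int i1, int i2, int i3) {
  return q[i1] * 25 + q[i2] * 5 + q[i3];
}

// [[Rcpp::export(name = ".fs_align_core")]]
List fs_align_core(IntegerVector q, IntegerVector s,
                   NumericMatrix smat, IntegerVector codon_to_res,
                   double gap_open, double gap_extend, double fs_penalty,
                   LogicalVector mask) {
  const int n = q.size(), m = s.size();
  const int ncol = m + 1;
  std::vector<double> H((n + 1) * ncol, NEG), E((n + 1) * ncol, NEG),
      G((n + 1) * ncol, NEG);
  // traceback codes for H: 0 local start; 1..9 = 3*t + p + 1 with
  // t in {0:M3,1:M2,2:M4}, p in {0:H,1:E,2:G}
  std::vector<signed char> tbH((n + 1) * ncol, 0), tbE((n + 1) * ncol, 0),
      tbG((n + 1) * ncol, 0);

  // prefix of usable (unmasked) bases: ok[i] true if base i-1 (1-based i) usable
  std::vector<char> ok(n + 1, 1);
  for (int i = 1; i <= n; ++i) ok[i] = mask[i - 1] ? 0 : 1;
  // run[i] = number of consecutive usable bases ending at i (1-based)
  std::vector<int> run(n + 1, 0);
  for (int i = 1; i <= n; ++i) run[i] = ok[i] ? run[i - 1] + 1 : 0;

  double best = 0.0;
  int bi = -1, bj = -1;

  for (int i = 0; i <= n; ++i) {
    const int base = i * ncol;
    for (int j = 0; j <= m; ++j) {
      // ---- H ----
      double hbest = 0.0;
      signed char hcode = 0;
      const int widths[3] = {3, 2, 4};
      for (int t = 0; t < 3; ++t) {
        const int w = widths[t];
        if (i < w || j < 1) continue;
        if (run[i] < w) continue;  // consumed bases must all be unmasked
        int res;
        if (t == 1) {
          res = codon_to_res[4 * 25 + q[i - 2] * 5 + q[i - 1]];  // N-padded
        } else {
          res = codon_to_res[codon_idx(q, i - 3, i - 2, i - 1)];
        }
        double col = smat(res, s[j - 1]) - (t == 0 ? 0.0 : fs_penalty);
        const int pb = (i - w) * ncol + (j - 1);
        const double prev[3] = {H[pb], E[pb], G[pb]};
        for (int p = 0; p < 3; ++p) {
          if (prev[p] <= NEG / 2) continue;
          double cand = prev[p] + col;
          if (cand > hbest) {
            hbest = cand;
            hcode = (signed char)(3 * t + p + 1);
          }
        }
      }
      H[base + j] = hbest;
      tbH[base + j] = hcode;
      if (hcode != 0 && hbest > best) {
        best = hbest;
        bi = i;
        bj = j;
      }

      // ---- E : gap in query, consume s[j-1] ----
      if (j >= 1) {
        const int pb = base + (j - 1);
        double e = NEG;
        signed char ec = 0;
        if (tbH[pb] != 0 || H[pb] == 0.0) {  // any reachable H (incl. start)
          double cand = H[pb] - gap_open - gap_extend;
          if (cand > e) { e = cand; ec = 0; }
        }
        if (E[pb] > NEG / 2) {
          double cand = E[pb] - gap_extend;
          if (cand > e) { e = cand; ec = 1; }
        }
        if (G[pb] > NEG / 2) {
          double cand = G[pb] - gap_open - gap_extend;
          if (cand > e) { e = cand; ec = 2; }
        }
        E[base + j] = e;
        tbE[base + j] = ec;
      }

      // ---- G : gap in subject, consume 3 query bases ----
      if (i >= 3 && run[i] >= 3) {
        const int pb = (i - 3) * ncol + j;
        double g = NEG;
        signed char gc = 0;
        if (tbH[pb] != 0 || H[pb] == 0.0) {
          double cand = H[pb] - gap_open - gap_extend;
          if (cand > g) { g = cand; gc = 0; }
        }
        if (G[pb] > NEG / 2) {
          double cand = G[pb] - gap_extend;
          if (cand > g) { g = cand; gc = 1; }
        }
        if (E[pb] > NEG / 2) {
          double cand = E[pb] - gap_open - gap_extend;
          if (cand > g) { g = cand; gc = 2; }
        }
        G[base + j] = g;
        tbG[base + j] = gc;
      }
    }
  }

  if (bi < 0 || best <= 0.0) {
    return List::create(_["score"] = 0.0, _["found"] = false);
  }

  // traceback from (bi, bj) in state H
  std::string transcript;
  std::vector<int> ev_off, ev_kind;  // kind 1 = '/', 2 = '\'
  int i = bi, j = bj, state = 0;  // 0=H,1=E,2=G
  while (true) {
    if (state == 0) {
      signed char c = tbH[i * ncol + j];
      if (c == 0) break;
      int t = (c - 1) / 3, p = (c - 1) % 3;
      if (t == 0) {
        int res = codon_to_res[codon_idx(q, i - 3, i - 2, i - 1)];
        transcript.push_back(res == s[j - 1] ? '=' : 'X');
        i -= 3;
      } else if (t == 1) {
        transcript.push_back('/');
        ev_off.push_back(i - 2);
        ev_kind.push_back(1);
        i -= 2;
      } else {
        transcript.push_back('\\');
        ev_off.push_back(i - 4);
        ev_kind.push_back(2);
        i -= 4;
      }
      j -= 1;
      state = p;
    } else if (state == 1) {
      signed char c = tbE[i * ncol + j];
      transcript.push_back('I');
      j -= 1;
      state = (c == 0) ? 0 : (c == 1 ? 1 : 2);
    } else {
      signed char c = tbG[i * ncol + j];
      transcript.push_back('D');
      i -= 3;
      state = (c == 0) ? 0 : (c == 1 ? 2 : 1);
    }
  }
  std::reverse(transcript.begin(), transcript.end());
  std::reverse(ev_off.begin(), ev_off.end());
  std::reverse(ev_kind.begin(), ev_kind.end());

  return List::create(_["score"] = best, _["found"] = true,
                      _["qstart"] = i, _["qend"] = bi,
                      _["sstart"] = j, _["send"] = bj,
                      _["transcript"] = transcript,
                      _["ev_off"] = wrap(ev_off), _["ev_kind"] = wrap(ev_kind));
}
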