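#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Wraparound global alignment of a DNA segment against indefinite repetition
// of a short unit (period <= 3 in practice, any small p supported).
//
// Base encoding: A=0, C=1, G=2, T=3, N/other=4. N never matches.
//
// DP state j in [0, p): the next unit position to be aligned. Transitions:
//   diagonal  (i,j) -> (i+1, (j+1)%p)  consume seq[i] vs unit[j], +match/-mismatch
//   insertion (i,j) -> (i+1, j)        consume seq[i], -indel
//   deletion  (i,j) -> (i, (j+1)%p)    skip unit[j], -indel
// The unit repeats indefinitely, so alignment may stop at any phase: the
// segment score is max_j D[end][j]. A full deletion cycle costs p*indel > 0,
// so two relaxation passes over the cyclic deletion edges suffice.

struct Cell {
  int score;
  int m, x, g; // matches, mismatches, indels on the best path
};

static inline bool better(const Cell &a, const Cell &b) {
  // prefer higher score, then more matches, then fewer indels
  if (a.score != b.score) return a.score > b.score;
  if (a.m != b.m) return a.m > b.m;
  return a.g < b.g;
}

static const Cell NEG = { INT_MIN / 4, 0, 0, 0 };

static inline void relax_deletions(std::vector<Cell> &row, int p, int indel) {
  for (int pass = 0; pass < 2; ++pass) {
    for (int j = 0; j < p; ++j) {
      int jn = (j + 1) % p;
      Cell cand = row[j];
      cand.score -= indel;
      cand.g += 1;
      if (better(cand, row[jn])) row[jn] = cand;
    }
  }
}

static inline void init_row(std::vector<Cell> &row, int p, int indel) {
  for (int j = 0; j < p; ++j) row[j] = NEG;
  row[0].score = 0; row[0].m = row[0].x = row[0].g = 0;
  relax_deletions(row, p, indel);
}

static inline void step_row(const std::vector<Cell> &cur, std::vector<Cell> &nxt,
                            int base, const int *unit, int p,
                            int match, int mismatch, int indel) {
  for (int j = 0; j < p; ++j) nxt[j] = NEG;
  for (int j = 0; j < p; ++j) {
    if (cur[j].score <= NEG.score) continue;
    int jn = (j + 1) % p;
    // diagonal
    Cell d = cur[j];
    bool is_match = (base == unit[j]) && base >= 0 && base <= 3;
    if (is_match) { d.score += match; d.m += 1; }
    else          { d.score -= mismatch; d.x += 1; }
    if (better(d, nxt[jn])) nxt[jn] = d;
    // insertion (gap in unit side)
    Cell ins = cur[j];
    ins.score -= indel;
    ins.g += 1;
    if (better(ins, nxt[j])) nxt[j] = ins;
  }
  relax_deletions(nxt, p, indel);
}

static inline Cell row_best(const std::vector<Cell> &row, int p) {
  Cell best = row[0];
  for (int j = 1; j < p; ++j) if (better(row[j], best)) best = row[j];
  return best;
}

// [[Rcpp::export]]
IntegerVector C_score_tract(IntegerVector seq, IntegerVector unit,
                            int match, int mismatch, int indel) {
  int p = unit.size();
  int n = seq.size();
  std::vector<Cell> cur(p), nxt(p);
  init_row(cur, p, indel);
  std::vector<int> u(unit.begin(), unit.end());
  Cell best0 = row_best(cur, p); // empty sequence: score 0
  for (int i = 0; i < n; ++i) {
    step_row(cur, nxt, seq[i], u.data(), p, match, mismatch, indel);
    cur.swap(nxt);
  }
  Cell best = (n == 0) ? best0 : row_best(cur, p);
  return IntegerVector::create(best.score, best.m, best.x, best.g);
}

// Enumerate every candidate tract (start, end, period) with score >= min_score.
// unit = the leading p-mer at `start`; starts/ends on N are excluded, and units
// containing N are excluded. Intended for windows of a few hundred nt.
// [[Rcpp::export]]
IntegerMatrix C_enumerate_candidates(IntegerVector seq, int max_period,
                                     int match, int mismatch, int indel,
                                     int min_score) {
  int n = seq.size();
  std::vector<int> out; // rows of 7: start, end, period, score, m, x, g
  for (int p = 1; p <= max_period; ++p) {
    std::vector<Cell> cur(p), nxt(p);
    int u[8];
    for (int s = 0; s + p <= n; ++s) {
      bool okunit = true;
      for (int j = 0; j < p; ++j) {
        u[j] = seq[s + j];
        if (u[j] < 0 || u[j] > 3) { okunit = false; break; }
      }
      if (!okunit) continue;
      init_row(cur, p, indel);
      int maxlook = 0;
      for (int i = s; i < n; ++i) {
        step_row(cur, nxt, seq[i], u, p, match, mismatch, indel);
        cur.swap(nxt);
        Cell best = row_best(cur, p);
        // prune: even perfect matching ahead cannot reach min_score
        if (best.score + 2 * match * (n - i - 1) < min_score) break;
        int e = i + 1;
        if (seq[e - 1] >= 0 && seq[e - 1] <= 3 && best.score >= min_score) {
          out.push_back(s); out.push_back(e); out.push_back(p);
          out.push_back(best.score); out.push_back(best.m);
          out.push_back(best.x); out.push_back(best.g);
        }
        (void)maxlook;
      }
    }
  }
  int nrow = (int)(out.size() / 7);
  IntegerMatrix res(nrow, 7);
  for (int r = 0; r < nrow; ++r)
    for (int c = 0; c < 7; ++c) res(r, c) = out[r * 7 + c];
  colnames(res) = CharacterVector::create("start", "end", "period", "score",
                                          "matches", "mismatches", "indels");
  return res;
}

// Sample n bases from an order-2 Markov chain. cond is 16x4 (rows indexed by
// dinucleotide context 4*b1+b2, columns by next base), dinuc is the length-16
// initial dinucleotide distribution. Uses R's RNG (respects set.seed()).
// [[Rcpp::export]]
IntegerVector C_markov2_sample(int n, NumericMatrix cond, NumericVector dinuc) {
  IntegerVector res(n);
  if (n == 0) return res;
  double r = R::unif_rand();
  int ctx = 15;
  double acc = 0.0;
  for (int k = 0; k < 16; ++k) { acc += dinuc[k]; if (r <= acc) { ctx = k; break; } }
  int b1 = ctx / 4, b2 = ctx % 4;
  res[0] = b1;
  if (n == 1) return res;
  res[1] = b2;
  for (int i = 2; i < n; ++i) {
    int c = 4 * b1 + b2;
    double rr = R::unif_rand();
    int nb = 3;
    double a = 0.0;
    for (int k = 0; k < 4; ++k) { a += cond(c, k); if (rr <= a) { nb = k; break; } }
    res[i] = nb;
    b1 = b2; b2 = nb;
  }
  return res;
}
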