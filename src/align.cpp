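// Pairwise sequence alignment engine.
//
// Gotoh affine-gap dynamic programming with a deterministic traceback,
// in local (Smith-Waterman) and global (Needleman-Wunsch) modes, over
// either BLOSUM62 (amino acids) or a simple +1/-1 nucleotide score.
// A gap of length L costs open + ext * L.
//
// Traceback is deterministic: on ties the diagonal move is preferred
// over a gap in the subject, which is preferred over a gap in the
// query; the best local cell is the first maximum in row-major order.

#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <string>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const char AA_ALPHABET[] = "ARNDCQEGHILKMFPSTWYVBZX";
static const int N_AA = 23;

// BLOSUM62, NCBI ordering ARNDCQEGHILKMFPSTWYVBZX
static const int BLOSUM62[N_AA][N_AA] = {
  { 4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,-2,-1, 0},
  {-1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,-1, 0,-1},
  {-2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3, 3, 0,-1},
  {-2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3, 4, 1,-1},
  { 0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,-3,-3,-2},
  {-1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2, 0, 3,-1},
  {-1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2, 1, 4,-1},
  { 0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,-1,-2,-1},
  {-2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3, 0, 0,-1},
  {-1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,-3,-3,-1},
  {-1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,-4,-3,-1},
  {-1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2, 0, 1,-1},
  {-1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,-3,-1,-1},
  {-2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,-3,-3,-1},
  {-1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,-2,-1,-2},
  { 1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2, 0, 0, 0},
  { 0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,-1,-1, 0},
  {-3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,-4,-3,-2},
  {-2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,-3,-2,-1},
  { 0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4,-3,-2,-1},
  {-2,-1, 3, 4,-3, 0, 1,-1, 0,-3,-4, 0,-3,-3,-2, 0,-1,-4,-3,-3, 4, 1,-1},
  {-1, 0, 0, 1,-3, 3, 4,-2, 0,-3,-3, 1,-1,-3,-1, 0,-1,-3,-2,-2, 1, 4,-1},
  { 0,-1,-1,-1,-2,-1,-1,-1,-1,-1,-1,-1,-1,-1,-2, 0, 0,-2,-1,-1,-1,-1,-1}
};

static int aa_index_table[256];
static bool tables_ready = false;

static void init_tables() {
  if (tables_ready) return;
  for (int i = 0; i < 256; ++i) aa_index_table[i] = 22; // unknown -> X
  for (int i = 0; i < N_AA; ++i)
    aa_index_table[(unsigned char) AA_ALPHABET[i]] = i;
  tables_ready = true;
}

static inline int score_pair(char a, char b, bool dna) {
  if (dna) {
    // A/C/G/T match +1; anything else (incl. N vs anything) mismatch -1
    if (a == b && (a == 'A' || a == 'C' || a == 'G' || a == 'T')) return 1;
    return -1;
  }
  return BLOSUM62[aa_index_table[(unsigned char) a]]
                 [aa_index_table[(unsigned char) b]];
}

struct AlnResult {
  double score;
  int matches, cols, qres, sres;
  bool hit;
};

static const double NEG_INF = -1e18;

// Full DP with traceback. local = Smith-Waterman (score floored at 0,
// best cell anywhere); global = Needleman-Wunsch end-to-end.
static AlnResult align_full(const std::string& q, const std::string& s,
                            bool local, bool dna,
                            double gopen, double gext) {
  init_tables();
  const int n = (int) q.size(), m = (int) s.size();
  AlnResult res = {0.0, 0, 0, 0, 0, false};

  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), NEG_INF);
  std::vector<double> F((n + 1) * (m + 1), NEG_INF);
  // pointers: ptrH 0=stop, 1=diag, 2=E (gap in query), 3=F (gap in subject)
  // ptrE/ptrF: 1=opened from H, 2=extended
  std::vector<unsigned char> ptrH((n + 1) * (m + 1), 0);
  std::vector<unsigned char> ptrE((n + 1) * (m + 1), 0);
  std::vector<unsigned char> ptrF((n + 1) * (m + 1), 0);

  #define IDX(i, j) ((i) * (m + 1) + (j))

  if (!local) {
    for (int j = 1; j <= m; ++j) {
      E[IDX(0, j)] = -(gopen + gext * j);
      ptrE[IDX(0, j)] = (j == 1) ? 1 : 2;
      H[IDX(0, j)] = E[IDX(0, j)];
      ptrH[IDX(0, j)] = 2;
    }
    for (int i = 1; i <= n; ++i) {
      F[IDX(i, 0)] = -(gopen + gext * i);
      ptrF[IDX(i, 0)] = (i == 1) ? 1 : 2;
      H[IDX(i, 0)] = F[IDX(i, 0)];
      ptrH[IDX(i, 0)] = 3;
    }
  }

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double e_open = H[IDX(i, j - 1)] - gopen - gext;
      double e_ext  = E[IDX(i, j - 1)] - gext;
      double e = (e_open >= e_ext) ? e_open : e_ext;
      E[IDX(i, j)] = e;
      ptrE[IDX(i, j)] = (e_open >= e_ext) ? 1 : 2;

      double f_open = H[IDX(i - 1, j)] - gopen - gext;
      double f_ext  = F[IDX(i - 1, j)] - gext;
      double f = (f_open >= f_ext) ? f_open : f_ext;
      F[IDX(i, j)] = f;
      ptrF[IDX(i, j)] = (f_open >= f_ext) ? 1 : 2;

      double d = H[IDX(i - 1, j - 1)] + score_pair(q[i - 1], s[j - 1], dna);

      double h = d;
      unsigned char p = 1;
      if (e > h) { h = e; p = 2; }
      if (f > h) { h = f; p = 3; }
      if (local && h <= 0.0) { h = 0.0; p = 0; }
      H[IDX(i, j)] = h;
      ptrH[IDX(i, j)] = p;

      if (local && h > best) { best = h; bi = i; bj = j; }
    }
  }

  int si, sj;
  if (local) {
    if (best <= 0.0) return res; // no positive-scoring local alignment
    res.score = best;
    si = bi; sj = bj;
  } else {
    res.score = H[IDX(n, m)];
    si = n; sj = m;
  }
  res.hit = true;

  // traceback
  int i = si, j = sj;
  int state = 1; // start in H
  while (i > 0 || j > 0) {
    if (state == 1) {
      unsigned char p = ptrH[IDX(i, j)];
      if (local && p == 0) break;
      if (p == 1) {
        res.cols++; res.qres++; res.sres++;
        if (q[i - 1] == s[j - 1]) res.matches++;
        --i; --j;
      } else if (p == 2) {
        state = 2;
      } else if (p == 3) {
        state = 3;
      } else {
        break; // global corner
      }
    } else if (state == 2) { // E: gap in query, consumes subject
      unsigned char p = ptrE[IDX(i, j)];
      res.cols++; res.sres++;
      --j;
      if (p == 1) state = 1;
    } else { // F: gap in subject, consumes query
      unsigned char p = ptrF[IDX(i, j)];
      res.cols++; res.qres++;
      --i;
      if (p == 1) state = 1;
    }
  }
  #undef IDX
  return res;
}

// Score-only Smith-Waterman over index-encoded protein sequences
// (integer DP, rolling arrays), used to screen all-vs-all searches
// before the (more expensive) traceback pass. Integer gap penalties
// are assumed (true for the BLOSUM62 11/1 defaults).
static int sw_score_encoded(const std::vector<signed char>& q,
                            const std::vector<signed char>& s,
                            int gopen, int gext,
                            std::vector<int>& H, std::vector<int>& F) {
  const int n = (int) q.size(), m = (int) s.size();
  const int NEG = -(1 << 28);
  H.assign(m + 1, 0);
  F.assign(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    const int* row = BLOSUM62[(int) q[i - 1]];
    int e = NEG;
    int diag = H[0]; // H[i-1][j-1]
    for (int j = 1; j <= m; ++j) {
      int e_open = H[j - 1] - gopen - gext;
      int e_ext  = e - gext;
      e = (e_open >= e_ext) ? e_open : e_ext;
      int f_open = H[j] - gopen - gext;
      int f_ext  = F[j] - gext;
      int f = (f_open >= f_ext) ? f_open : f_ext;
      F[j] = f;
      int h = diag + row[(int) s[j - 1]];
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

static std::vector<signed char> encode_aa(const std::string& x) {
  init_tables();
  std::vector<signed char> out(x.size());
  for (size_t k = 0; k < x.size(); ++k) {
    out[k] = (signed char) aa_index_table[(unsigned char) x[k]];
  }
  return out;
}

static List result_to_list(const AlnResult& r) {
  return List::create(
    _["score"] = r.score, _["matches"] = r.matches, _["cols"] = r.cols,
    _["qres"] = r.qres, _["sres"] = r.sres, _["hit"] = r.hit);
}

// [[Rcpp::export(name = ".align_one_cpp")]]
List align_one_cpp(std::string q, std::string s, bool local, bool dna,
                   double gopen, double gext) {
  return result_to_list(align_full(q, s, local, dna, gopen, gext));
}

// All-vs-all Smith-Waterman between two protein sets. Scores are
// computed for every pair; full alignment statistics (identity etc.)
// only for pairs whose Karlin-Altschul e-value at the raw score is at
// most emax_full (pass R_PosInf to get statistics everywhere).
// [[Rcpp::export(name = ".sw_batch_cpp")]]
List sw_batch_cpp(std::vector<std::string> a, std::vector<std::string> b,
                  double gopen, double gext,
                  double lambda, double Kparam, double emax_full) {
  const int na = (int) a.size(), nb = (int) b.size();
  NumericMatrix score(na, nb), matches(na, nb), cols(na, nb),
                qres(na, nb), sres(na, nb);
  std::fill(matches.begin(), matches.end(), NA_REAL);
  std::fill(cols.begin(), cols.end(), NA_REAL);
  std::fill(qres.begin(), qres.end(), NA_REAL);
  std::fill(sres.begin(), sres.end(), NA_REAL);

  std::vector<std::vector<signed char> > ea(na), eb(nb);
  for (int i = 0; i < na; ++i) ea[i] = encode_aa(a[i]);
  for (int j = 0; j < nb; ++j) eb[j] = encode_aa(b[j]);
  const int igopen = (int) gopen, igext = (int) gext;
  std::vector<int> Hbuf, Fbuf;

  for (int i = 0; i < na; ++i) {
    Rcpp::checkUserInterrupt();
    for (int j = 0; j < nb; ++j) {
      double sc = sw_score_encoded(ea[i], eb[j], igopen, igext,
                                   Hbuf, Fbuf);
      score(i, j) = sc;
      if (sc > 0.0) {
        double ev = Kparam * (double) a[i].size() * (double) b[j].size()
                    * std::exp(-lambda * sc);
        if (ev <= emax_full) {
          AlnResult r = align_full(a[i], b[j], true, false, gopen, gext);
          matches(i, j) = r.matches;
          cols(i, j) = r.cols;
          qres(i, j) = r.qres;
          sres(i, j) = r.sres;
        }
      }
    }
  }
  return List::create(
    _["score"] = score, _["matches"] = matches, _["cols"] = cols,
    _["qres"] = qres, _["sres"] = sres);
}
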