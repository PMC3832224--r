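// Seed-and-extend local aligner with affine-gap banded extension.
//
// Scoring (fixed convention, shared with the test oracle): match +1,
// mismatch -2, gap of length L costs open + L*ext (default 5 + 2L).
// Alignment columns with N never match. Percent identity counts gap
// columns in the denominator.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4; // N and anything else
  }
}

static inline char comp(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

struct SeedIndex {
  std::string seq;        // subject, uppercased on ingest is not required
  int k;
  std::unordered_map<uint64_t, std::vector<int>> pos;
  size_t n_seeds;
};

static void index_build(SeedIndex &idx) {
  const std::string &s = idx.seq;
  const int k = idx.k;
  const int n = (int) s.size();
  idx.n_seeds = 0;
  if (n < k) return;
  uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0; // length of current valid (ACGT-only) run
  for (int i = 0; i < n; ++i) {
    int e = enc(s[i]);
    if (e > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t) e) & mask;
    if (++run >= k) {
      idx.pos[key].push_back(i - k + 1);
      ++idx.n_seeds;
    }
  }
}

// [[Rcpp::export(name = ".cpp_build_index")]]
SEXP cpp_build_index(std::string subject, int k) {
  if (subject.size() == 0) stop("subject sequence is empty");
  if (k < 8 || k > 31) stop("k must be in [8, 31]");
  XPtr<SeedIndex> p(new SeedIndex(), true);
  p->seq = subject;
  p->k = k;
  index_build(*p);
  return p;
}

// [[Rcpp::export(name = ".cpp_index_info")]]
List cpp_index_info(SEXP xp) {
  XPtr<SeedIndex> p(xp);
  return List::create(_["length"] = (double) p->seq.size(),
                      _["k"] = p->k,
                      _["n_seeds"] = (double) p->n_seeds,
                      _["n_distinct"] = (double) p->pos.size());
}

// [[Rcpp::export(name = ".cpp_seed_positions")]]
IntegerVector cpp_seed_positions(SEXP xp, std::string kmer) {
  XPtr<SeedIndex> p(xp);
  if ((int) kmer.size() != p->k) stop("kmer length must equal index k");
  uint64_t key = 0;
  for (char c : kmer) {
    int e = enc(c);
    if (e > 3) return IntegerVector(0);
    key = (key << 2) | (uint64_t) e;
  }
  auto it = p->pos.find(key);
  if (it == p->pos.end()) return IntegerVector(0);
  return wrap(it->second); // 0-based
}

struct Candidate {
  bool found = false;
  int score = -1, matches = 0, columns = 0;
  int sstart = 0, send = 0, qstart = 0, qend = 0;
  char strand = '+';
};

// Banded affine Smith-Waterman of query vs subject[slo, shi) restricted to
// subject diagonals (j - i) in [dlo, dhi], with full traceback.
// Coordinates in the returned candidate are subject-absolute, query-local.
static Candidate banded_sw(const std::string &q, const std::string &s,
                           int slo, int shi, int dlo, int dhi,
                           int match, int mismatch, int gap_open, int gap_ext) {
  Candidate best;
  const int m = (int) q.size();
  const int NEG = -1000000000;
  // clamp diagonal window to the subject slice
  dlo = std::max(dlo, slo - m);
  dhi = std::min(dhi, shi - 1);
  if (dlo > dhi) return best;
  const int w = dhi - dlo + 1;
  // H/E/F for row i over band offset b where j = i + dlo + b
  std::vector<int> H(w, 0), E(w, NEG), F(w, NEG);
  std::vector<int> Hp(w, 0), Ep(w, NEG), Fp(w, NEG);
  // traceback: 2 bits per cell per matrix packed in one byte
  // 0 = stop, 1 = diag, 2 = up(F: gap in subject col dir), 3 = left(E)
  std::vector<uint8_t> tbH((size_t) (m + 1) * w, 0);
  std::vector<uint8_t> tbE((size_t) (m + 1) * w, 0); // 1 => extend, 0 => open
  std::vector<uint8_t> tbF((size_t) (m + 1) * w, 0);
  int bi = -1, bb = -1; // best cell (row, band offset)
  // row 0: all zeros (local)
  for (int i = 1; i <= m; ++i) {
    std::swap(H, Hp); std::swap(E, Ep); std::swap(F, Fp);
    size_t row = (size_t) i * w;
    for (int b = 0; b < w; ++b) {
      int j = i + dlo + b; // subject position (0-based) of column j-1 pairing
      if (j < slo + 1 || j > shi) { H[b] = 0; E[b] = NEG; F[b] = NEG; continue; }
      // E: gap in query consumption of subject? convention:
      // E = alignment ending with gap in query (consumes subject base j-1)
      int eo = (b >= 1) ? H[b - 1] - gap_open - gap_ext : NEG;
      int ee = (b >= 1) ? E[b - 1] - gap_ext : NEG;
      E[b] = std::max(eo, ee);
      tbE[row + b] = (ee > eo) ? 1 : 0;
      // F = ends with gap in subject (consumes query base i-1), j constant
      // previous row same j => band offset b+1 in row i-1
      int fo = (b + 1 < w) ? Hp[b + 1] - gap_open - gap_ext : NEG;
      int fe = (b + 1 < w) ? Fp[b + 1] - gap_ext : NEG;
      F[b] = std::max(fo, fe);
      tbF[row + b] = (fe > fo) ? 1 : 0;
      int eq = enc(q[i - 1]), es = enc(s[j - 1]);
      bool is_match = (eq <= 3 && es <= 3 && eq == es);
      int diag = Hp[b] + (is_match ? match : mismatch);
      int h = 0; uint8_t tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (F[b] > h) { h = F[b]; tb = 2; }
      if (E[b] > h) { h = E[b]; tb = 3; }
      H[b] = h; tbH[row + b] = tb;
      if (h > best.score ||
          (h == best.score && bi >= 0 && (i + dlo + b) < (bi + dlo + bb))) {
        best.score = h; bi = i; bb = b;
      }
    }
  }
  if (best.score <= 0) return best;
  // traceback from (bi, bb)
  int i = bi, b = bb, state = 0; // state 0=H,1=E,2=F
  int matches = 0, columns = 0;
  int qend = bi, send = bi + dlo + bb;
  while (i > 0) {
    size_t row = (size_t) i * w;
    if (state == 0) {
      uint8_t tb = tbH[row + b];
      if (tb == 0) break;
      if (tb == 1) {
        int j = i + dlo + b;
        int eq = enc(q[i - 1]), es = enc(s[j - 1]);
        if (eq <= 3 && es <= 3 && eq == es) ++matches;
        ++columns; --i; /* b unchanged: j-1 with i-1 keeps offset */
      } else if (tb == 2) { state = 2; }
      else { state = 1; }
    } else if (state == 1) { // E: consume subject base, gap col
      ++columns;
      uint8_t ext = tbE[row + b];
      --b;
      state = ext ? 1 : 0;
    } else { // F: consume query base
      ++columns;
      uint8_t ext = tbF[row + b];
      --i; ++b;
      state = ext ? 2 : 0;
    }
  }
  best.found = true;
  best.matches = matches;
  best.columns = columns;
  best.qstart = i;          // 0-based
  best.qend = qend;         // half-open
  best.sstart = i + dlo + b;
  best.send = send;
  return best;
}

struct SeedMatch { int diag, qpos, spos; };

// Evaluate one query (already oriented) against the index; returns the
// best candidate meeting thresholds, searching clustered seed diagonals.
static Candidate query_one_strand(const std::string &q, const SeedIndex &idx,
                                  double min_identity, int min_cols,
                                  int band, int max_clusters,
                                  int match, int mismatch,
                                  int gap_open, int gap_ext) {
  Candidate best;
  const int m = (int) q.size();
  const int k = idx.k;
  const int n = (int) idx.seq.size();
  if (m < k) return best;
  std::vector<SeedMatch> seeds;
  uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int i = 0; i < m; ++i) {
    int e = enc(q[i]);
    if (e > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t) e) & mask;
    if (++run >= k) {
      int qpos = i - k + 1;
      auto it = idx.pos.find(key);
      if (it != idx.pos.end())
        for (int spos : it->second)
          seeds.push_back({spos - qpos, qpos, spos});
    }
  }
  if (seeds.empty()) return best;
  // small subject: one exhaustive DP over everything
  if ((double) n * m <= 4e5) {
    Candidate c = banded_sw(q, idx.seq, 0, n, -m, n, match, mismatch,
                            gap_open, gap_ext);
    if (c.found) {
      double ident = 100.0 * c.matches / c.columns;
      if (ident >= min_identity && c.columns >= min_cols) return c;
    }
    return best;
  }
  std::sort(seeds.begin(), seeds.end(),
            [](const SeedMatch &a, const SeedMatch &b) { return a.diag < b.diag; });
  // cluster diagonals closer than `band`
  struct Cluster { int dlo, dhi, count; };
  std::vector<Cluster> clusters;
  for (size_t i = 0; i < seeds.size();) {
    size_t j = i + 1;
    int dhi = seeds[i].diag;
    while (j < seeds.size() && seeds[j].diag - dhi <= band) {
      dhi = seeds[j].diag; ++j;
    }
    clusters.push_back({seeds[i].diag, dhi, (int) (j - i)});
    i = j;
  }
  std::sort(clusters.begin(), clusters.end(),
            [](const Cluster &a, const Cluster &b) { return a.count > b.count; });
  if ((int) clusters.size() > max_clusters) clusters.resize(max_clusters);
  // thin, seed-poor clusters cannot carry the best alignment when a much
  // denser one exists; skipping them trades nothing measurable for speed
  int top = clusters.front().count;
  for (const Cluster &cl : clusters) {
    if (top >= 4 && cl.count < (top + 3) / 4) break;
    int slo = std::max(0, cl.dlo - band);
    int shi = std::min(n, cl.dhi + m + band);
    Candidate c = banded_sw(q, idx.seq, slo, shi,
                            cl.dlo - band, cl.dhi + band,
                            match, mismatch, gap_open, gap_ext);
    if (!c.found) continue;
    double ident = 100.0 * c.matches / c.columns;
    if (ident < min_identity || c.columns < min_cols) continue;
    if (!best.found || c.score > best.score ||
        (c.score == best.score && c.sstart < best.sstart))
      best = c;
  }
  return best;
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (char &c : r) c = comp(c);
  return r;
}

// Batch best-hit search. min_cols is per-query (recycled if length 1).
// Returns a data.frame-ready list; subject coordinates 0-based half-open.
// [[Rcpp::export(name = ".cpp_best_hits")]]
List cpp_best_hits(CharacterVector queries, SEXP xp,
                   double min_identity, IntegerVector min_cols,
                   int band, int max_clusters,
                   int match, int mismatch, int gap_open, int gap_ext,
                   bool both_strands) {
  XPtr<SeedIndex> idx(xp);
  const int nq = queries.size();
  LogicalVector found(nq);
  CharacterVector strand(nq);
  IntegerVector sstart(nq), send(nq), qstart(nq), qend(nq),
      matches(nq), columns(nq), score(nq);
  NumericVector identity(nq);
  for (int qi = 0; qi < nq; ++qi) {
    std::string q = as<std::string>(queries[qi]);
    int mc = min_cols[min_cols.size() == 1 ? 0 : qi];
    Candidate fw = query_one_strand(q, *idx, min_identity, mc, band,
                                    max_clusters, match, mismatch,
                                    gap_open, gap_ext);
    Candidate rv;
    if (both_strands) {
      std::string qr = revcomp(q);
      rv = query_one_strand(qr, *idx, min_identity, mc, band,
                            max_clusters, match, mismatch, gap_open, gap_ext);
      if (rv.found) {
        // re-express query span on the original read
        int m = (int) q.size();
        int qs = m - rv.qend, qe = m - rv.qstart;
        rv.qstart = qs; rv.qend = qe; rv.strand = '-';
      }
    }
    Candidate best;
    if (fw.found && rv.found) {
      // ties: lower subject start, then forward strand first
      if (fw.score != rv.score) best = (fw.score > rv.score) ? fw : rv;
      else if (fw.sstart != rv.sstart) best = (fw.sstart < rv.sstart) ? fw : rv;
      else best = fw;
    } else best = fw.found ? fw : rv;
    found[qi] = best.found;
    if (best.found) {
      strand[qi] = std::string(1, best.strand);
      sstart[qi] = best.sstart; send[qi] = best.send;
      qstart[qi] = best.qstart; qend[qi] = best.qend;
      matches[qi] = best.matches; columns[qi] = best.columns;
      score[qi] = best.score;
      identity[qi] = 100.0 * best.matches / best.columns;
    } else {
      strand[qi] = NA_STRING;
      sstart[qi] = NA_INTEGER; send[qi] = NA_INTEGER;
      qstart[qi] = NA_INTEGER; qend[qi] = NA_INTEGER;
      matches[qi] = NA_INTEGER; columns[qi] = NA_INTEGER;
      score[qi] = NA_INTEGER; identity[qi] = NA_REAL;
    }
    if (qi % 512 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["found"] = found, _["strand"] = strand,
                      _["sstart"] = sstart, _["send"] = send,
                      _["qstart"] = qstart, _["qend"] = qend,
                      _["matches"] = matches, _["columns"] = columns,
                      _["score"] = score, _["identity"] = identity);
}
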