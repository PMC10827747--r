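#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// ---- sequence utilities -----------------------------------------------------

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default:  return 4;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(std::string(seqs[i]));
  return out;
}

// enumerate 2-bit packed k-mers; positions with non-ACGT bases are skipped
template <typename F>
static void for_each_kmer(const std::string& s, int k, int stride, F fun) {
  int n = (int)s.size();
  if (n < k) return;
  uint64_t kmer = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;  // valid bases accumulated
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c == 4) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      int pos = i - k + 1;
      if (pos % stride == 0) fun(kmer, pos);
    }
  }
}

// ---- local alignment (affine gaps, optional band) ---------------------------

struct AlnResult {
  double score = 0;
  int matches = 0, columns = 0;
  int qstart = 0, qend = 0, sstart = 0, send = 0;  // 0-based, half-open
  bool seeded = false;
};

// Banded affine-gap Smith-Waterman around diagonal d0 (d = j - i), with
// traceback so identity (= matches / alignment columns) and the aligned spans
// are exact. tb codes: 0 start, 1 from M, 2 from X (query-consuming gap),
// 3 from Y (subject-consuming gap).
static AlnResult sw_banded(const std::string& a, const std::string& b,
                           int d0, int band,
                           double mat, double mis, double go, double ge) {
  const int m = (int)a.size(), n = (int)b.size();
  const int W = 2 * band + 1;
  const double NEG = -1e18;
  std::vector<double> Mp(W, NEG), Xp(W, NEG), Yp(W, NEG);
  std::vector<double> Mc(W, NEG), Xc(W, NEG), Yc(W, NEG);
  std::vector<uint8_t> tbM((size_t)(m + 1) * W, 0), tbX((size_t)(m + 1) * W, 0),
      tbY((size_t)(m + 1) * W, 0);
  // row 0: alignment may start anywhere
  for (int c = 0; c < W; ++c) Mp[c] = 0;
  double best = 0; int bi = -1, bc = -1;

  for (int i = 1; i <= m; ++i) {
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Xc.begin(), Xc.end(), NEG);
    std::fill(Yc.begin(), Yc.end(), NEG);
    const size_t row = (size_t)i * W;
    for (int c = 0; c < W; ++c) {
      const int j = i + d0 + c - band;
      if (j < 1 || j > n) continue;
      // M: diagonal predecessor is same band column in row i-1
      double pb = 0; uint8_t code = 0;
      if (Mp[c] > pb) { pb = Mp[c]; code = 1; }
      if (Xp[c] > pb) { pb = Xp[c]; code = 2; }
      if (Yp[c] > pb) { pb = Yp[c]; code = 3; }
      const double s = (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? mat : mis;
      Mc[c] = pb + s;
      tbM[row + c] = code;
      if (Mc[c] > best) { best = Mc[c]; bi = i; bc = c; }
      // X: consumes a[i-1]; predecessor (i-1, j) = band column c+1 in row i-1
      if (c + 1 < W) {
        double xm = Mp[c + 1] - go, xx = Xp[c + 1] - ge;
        if (xm >= xx) { Xc[c] = xm; tbX[row + c] = 1; }
        else          { Xc[c] = xx; tbX[row + c] = 2; }
      }
      // Y: consumes b[j-1]; predecessor (i, j-1) = band column c-1, same row
      if (c - 1 >= 0) {
        double ym = Mc[c - 1] - go, yy = Yc[c - 1] - ge;
        if (ym >= yy) { Yc[c] = ym; tbY[row + c] = 1; }
        else          { Yc[c] = yy; tbY[row + c] = 3; }
      }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  AlnResult res;
  if (bi < 0 || best <= 0) return res;
  res.score = best;
  // traceback
  int i = bi, c = bc, state = 0;  // 0=M,1=X,2=Y
  res.qend = bi;
  res.send = bi + d0 + bc - band;
  while (true) {
    const size_t row = (size_t)i * W;
    if (state == 0) {
      const int j = i + d0 + c - band;
      ++res.columns;
      if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ++res.matches;
      res.qstart = i - 1; res.sstart = j - 1;
      uint8_t code = tbM[row + c];
      if (code == 0) break;
      state = (code == 1) ? 0 : (code == 2 ? 1 : 2);
      --i;
    } else if (state == 1) {
      ++res.columns;
      uint8_t code = tbX[row + c];
      state = (code == 1) ? 0 : 1;
      --i; ++c;
    } else {
      ++res.columns;
      uint8_t code = tbY[row + c];
      state = (code == 1) ? 0 : 2;
      --c;
    }
  }
  return res;
}

// Unbanded (full-matrix) variant, used when no k-mer seed exists and the
// sequences are short enough for exhaustive dynamic programming.
static AlnResult sw_full(const std::string& a, const std::string& b,
                         double mat, double mis, double go, double ge) {
  const int m = (int)a.size(), n = (int)b.size();
  if ((double)(m + 1) * (double)(n + 1) > 6.4e7)
    stop("sequences too long for unseeded full alignment");
  const int W = n + 1;
  const double NEG = -1e18;
  std::vector<double> Mp(W, 0), Xp(W, NEG), Yp(W, NEG);
  std::vector<double> Mc(W, NEG), Xc(W, NEG), Yc(W, NEG);
  std::vector<uint8_t> tbM((size_t)(m + 1) * W, 0), tbX((size_t)(m + 1) * W, 0),
      tbY((size_t)(m + 1) * W, 0);
  double best = 0; int bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Xc.begin(), Xc.end(), NEG);
    std::fill(Yc.begin(), Yc.end(), NEG);
    const size_t row = (size_t)i * W;
    for (int j = 1; j <= n; ++j) {
      double pb = 0; uint8_t code = 0;
      if (Mp[j - 1] > pb) { pb = Mp[j - 1]; code = 1; }
      if (Xp[j - 1] > pb) { pb = Xp[j - 1]; code = 2; }
      if (Yp[j - 1] > pb) { pb = Yp[j - 1]; code = 3; }
      const double s = (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? mat : mis;
      Mc[j] = pb + s; tbM[row + j] = code;
      if (Mc[j] > best) { best = Mc[j]; bi = i; bj = j; }
      double xm = Mp[j] - go, xx = Xp[j] - ge;
      if (xm >= xx) { Xc[j] = xm; tbX[row + j] = 1; } else { Xc[j] = xx; tbX[row + j] = 2; }
      double ym = Mc[j - 1] - go, yy = Yc[j - 1] - ge;
      if (ym >= yy) { Yc[j] = ym; tbY[row + j] = 1; } else { Yc[j] = yy; tbY[row + j] = 3; }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  AlnResult res;
  if (bi < 0 || best <= 0) return res;
  res.score = best; res.qend = bi; res.send = bj;
  int i = bi, j = bj, state = 0;
  while (true) {
    const size_t row = (size_t)i * W;
    if (state == 0) {
      ++res.columns;
      if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ++res.matches;
      res.qstart = i - 1; res.sstart = j - 1;
      uint8_t code = tbM[row + j];
      if (code == 0) break;
      state = (code == 1) ? 0 : (code == 2 ? 1 : 2);
      --i; --j;
    } else if (state == 1) {
      ++res.columns;
      uint8_t code = tbX[row + j];
      state = (code == 1) ? 0 : 1;
      --i;
    } else {
      ++res.columns;
      uint8_t code = tbY[row + j];
      state = (code == 1) ? 0 : 2;
      --j;
    }
  }
  return res;
}

// choose the most k-mer-supported diagonal of b relative to a; returns false
// when the two sequences share no exact k-mer
static bool best_diagonal(const std::string& a, const std::string& b, int k, int& d0) {
  std::unordered_map<uint64_t, std::vector<int>> idx;
  for_each_kmer(b, k, 1, [&](uint64_t km, int pos) { idx[km].push_back(pos); });
  std::unordered_map<int, int> votes;
  for_each_kmer(a, k, 1, [&](uint64_t km, int pos) {
    auto it = idx.find(km);
    if (it == idx.end()) return;
    for (int sp : it->second) votes[sp - pos]++;
  });
  if (votes.empty()) return false;
  int bestd = 0, bestv = -1;
  for (auto& kv : votes)
    if (kv.second > bestv || (kv.second == bestv && kv.first < bestd)) {
      bestv = kv.second; bestd = kv.first;
    }
  d0 = bestd;
  return true;
}

static AlnResult align_pair(const std::string& a, const std::string& b,
                            int k, int band,
                            double mat, double mis, double go, double ge) {
  int d0 = 0;
  if ((int)a.size() >= k && (int)b.size() >= k && best_diagonal(a, b, k, d0)) {
    AlnResult r = sw_banded(a, b, d0, band, mat, mis, go, ge);
    r.seeded = true;
    return r;
  }
  return sw_full(a, b, mat, mis, go, ge);
}

// [[Rcpp::export]]
NumericVector align_pair_cpp(std::string a, std::string b, int k, int band,
                             double match, double mismatch,
                             double gap_open, double gap_ext) {
  AlnResult r = align_pair(a, b, k, band, match, mismatch, gap_open, gap_ext);
  return NumericVector::create(
      _["score"] = r.score, _["matches"] = (double)r.matches,
      _["columns"] = (double)r.columns, _["qstart"] = (double)r.qstart,
      _["qend"] = (double)r.qend, _["sstart"] = (double)r.sstart,
      _["send"] = (double)r.send, _["seeded"] = (double)r.seeded);
}

// ---- greedy length-sorted gene clustering -----------------------------------

// seqs must arrive sorted by decreasing length (ties broken lexicographically);
// each gene joins the lowest-id existing cluster whose representative (the
// founder) it matches at >= id_thr identity over >= cov_thr of the shorter
// sequence, else founds a new cluster.
// [[Rcpp::export]]
List greedy_cluster_cpp(CharacterVector seqs, double id_thr, double cov_thr,
                        int k, int band, int rep_stride,
                        double match, double mismatch,
                        double gap_open, double gap_ext) {
  const int n = (int)seqs.size();
  IntegerVector assign(n);
  std::vector<int> rep_gene;  // founder index per cluster
  std::vector<std::string> reps;
  std::unordered_map<uint64_t, std::vector<int>> idx;  // k-mer -> cluster ids

  for (int g = 0; g < n; ++g) {
    const std::string s = as<std::string>(seqs[g]);
    // vote for candidate clusters by shared k-mers
    std::unordered_set<int> cand_set;
    for_each_kmer(s, k, 1, [&](uint64_t km, int) {
      auto it = idx.find(km);
      if (it == idx.end()) return;
      for (int cl : it->second) cand_set.insert(cl);
    });
    std::vector<int> cand(cand_set.begin(), cand_set.end());
    std::sort(cand.begin(), cand.end());
    int chosen = -1;
    for (int cl : cand) {
      const std::string& rep = reps[cl];
      AlnResult r = align_pair(s, rep, k, band, match, mismatch, gap_open, gap_ext);
      if (r.columns == 0) continue;
      double identity = (double)r.matches / (double)r.columns;
      int short_len = std::min((int)s.size(), (int)rep.size());
      int short_span = (s.size() <= rep.size()) ? (r.qend - r.qstart) : (r.send - r.sstart);
      double cov = (double)short_span / (double)short_len;
      if (identity >= id_thr && cov >= cov_thr) { chosen = cl; break; }
    }
    if (chosen < 0) {
      chosen = (int)reps.size();
      reps.push_back(s);
      rep_gene.push_back(g + 1);
      for_each_kmer(s, k, rep_stride, [&](uint64_t km, int) { idx[km].push_back(chosen); });
    }
    assign[g] = chosen + 1;
    if (g % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["assignment"] = assign,
                      _["rep_gene"] = IntegerVector(rep_gene.begin(), rep_gene.end()));
}

// which subjects share at least one exact k-mer with each query
// [[Rcpp::export]]
List seed_filter_cpp(CharacterVector queries, CharacterVector subjects, int k) {
  std::unordered_map<uint64_t, std::vector<int>> idx;
  for (R_xlen_t s = 0; s < subjects.size(); ++s) {
    const std::string sub = as<std::string>(subjects[s]);
    for_each_kmer(sub, k, 1, [&](uint64_t km, int) {
      auto& v = idx[km];
      if (v.empty() || v.back() != (int)s) v.push_back((int)s);
    });
  }
  List out(queries.size());
  for (R_xlen_t q = 0; q < queries.size(); ++q) {
    const std::string qs = as<std::string>(queries[q]);
    std::unordered_set<int> hits;
    for_each_kmer(qs, k, 1, [&](uint64_t km, int) {
      auto it = idx.find(km);
      if (it == idx.end()) return;
      for (int s : it->second) hits.insert(s);
    });
    std::vector<int> v(hits.begin(), hits.end());
    std::sort(v.begin(), v.end());
    IntegerVector iv(v.size());
    for (size_t t = 0; t < v.size(); ++t) iv[t] = v[t] + 1;
    out[q] = iv;
  }
  return out;
}

// ---- read mapping against a marker database ---------------------------------

// Ungapped, k-mer seeded mapping. For each read (both orientations), candidate
// (marker, diagonal) pairs are gathered from a stride-1 marker k-mer index,
// each is scored by ungapped comparison over the read/marker overlap, and the
// read is assigned to its best marker. Reads whose best identities in the two
// clades differ by < ambig_delta go to the species-level pool (status 2);
// exact best-identity ties between distinct markers of the winning clade
// discard the read as ambiguous (status 3). Status 0 = unmapped, 1 = assigned.
// [[Rcpp::export]]
List map_reads_cpp(CharacterVector reads, CharacterVector markers,
                   IntegerVector clade, int k, int probe_step,
                   double min_identity, int min_aligned, double ambig_delta) {
  const int nm = (int)markers.size();
  std::vector<std::string> mseq(nm);
  std::vector<int> mlen(nm);
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> idx;
  for (int m = 0; m < nm; ++m) {
    mseq[m] = as<std::string>(markers[m]);
    mlen[m] = (int)mseq[m].size();
    for_each_kmer(mseq[m], k, 1, [&](uint64_t km, int pos) {
      idx[km].push_back({m, pos});
    });
  }

  const int nr = (int)reads.size();
  IntegerVector status(nr), marker_out(nr, NA_INTEGER), mstart(nr, NA_INTEGER),
      read_lo(nr, NA_INTEGER), aligned(nr, NA_INTEGER);
  NumericVector identity(nr, NA_REAL);
  LogicalVector rev(nr, NA_LOGICAL);

  struct Best { double id = -1; int aligned = 0, mstart = 0, read_lo = 0; bool rev = false; bool tie = false; };

  for (int r = 0; r < nr; ++r) {
    const std::string fwd = as<std::string>(reads[r]);
    const int rl = (int)fwd.size();
    std::unordered_map<int, Best> per_marker;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string seq = strand ? revcomp(fwd) : fwd;
      if (rl < k) continue;
      std::unordered_set<uint64_t> seen;
      for (int p = 0; p <= rl - k; p += probe_step) {
        uint64_t km = 0; bool ok = true;
        for (int t = 0; t < k; ++t) {
          int c = base_code(seq[p + t]);
          if (c == 4) { ok = false; break; }
          km = (km << 2) | (uint64_t)c;
        }
        if (!ok) continue;
        auto it = idx.find(km);
        if (it == idx.end()) continue;
        for (auto& hit : it->second) {
          const int m = hit.first, diag = hit.second - p;
          const uint64_t key = ((uint64_t)m << 33) |
              ((uint64_t)(uint32_t)(diag + 1000000) << 1) | (uint64_t)strand;
          if (!seen.insert(key).second) continue;
          const int lo = std::max(0, -diag);
          const int hi = std::min(rl, mlen[m] - diag);
          const int alen = hi - lo;
          if (alen < min_aligned) continue;
          int matches = 0;
          const std::string& ms = mseq[m];
          for (int t = lo; t < hi; ++t)
            if (seq[t] == ms[t + diag] && seq[t] != 'N') ++matches;
          const double id = (double)matches / (double)alen;
          auto& b = per_marker[m];
          if (id > b.id) {
            b.id = id; b.aligned = alen; b.mstart = lo + diag;
            b.read_lo = lo; b.rev = (strand == 1); b.tie = false;
          }
        }
      }
    }
    // best per clade among eligible hits
    int bm1 = -1, bm2 = -1; double b1 = -1, b2 = -1; bool tie1 = false, tie2 = false;
    for (auto& kv : per_marker) {
      if (kv.second.id < min_identity) continue;
      if (clade[kv.first] == 1) {
        if (kv.second.id > b1) { b1 = kv.second.id; bm1 = kv.first; tie1 = false; }
        else if (kv.second.id == b1) tie1 = true;
      } else {
        if (kv.second.id > b2) { b2 = kv.second.id; bm2 = kv.first; tie2 = false; }
        else if (kv.second.id == b2) tie2 = true;
      }
    }
    if (bm1 < 0 && bm2 < 0) { status[r] = 0; continue; }
    int chosen; bool species = false, dropped = false;
    if (bm1 >= 0 && bm2 >= 0 && std::abs(b1 - b2) < ambig_delta) {
      species = true; chosen = (b1 >= b2) ? bm1 : bm2;
    } else {
      chosen = (b1 >= b2) ? bm1 : bm2;
      if ((chosen == bm1 && tie1) || (chosen == bm2 && tie2)) dropped = true;
    }
    const Best& b = per_marker[chosen];
    if (dropped) { status[r] = 3; continue; }
    status[r] = species ? 2 : 1;
    marker_out[r] = species ? NA_INTEGER : chosen + 1;
    identity[r] = b.id; aligned[r] = b.aligned;
    mstart[r] = b.mstart; read_lo[r] = b.read_lo; rev[r] = b.rev;
    if (r % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["status"] = status, _["marker"] = marker_out,
                      _["identity"] = identity, _["aligned"] = aligned,
                      _["mstart"] = mstart, _["read_lo"] = read_lo, _["rev"] = rev);
}

// ---- pileup over markers ----------------------------------------------------

// counts matrix: 5 rows (A,C,G,T,N) x sum(marker_len) columns; marker m's
// positions occupy [offset[m], offset[m] + marker_len[m])
// [[Rcpp::export]]
IntegerMatrix pileup_cpp(CharacterVector reads, IntegerVector read_idx,
                         IntegerVector marker_idx, IntegerVector mstart,
                         IntegerVector read_lo, IntegerVector aligned,
                         LogicalVector rev, IntegerVector marker_len) {
  const int nm = (int)marker_len.size();
  std::vector<int> offset(nm, 0);
  int total = 0;
  for (int m = 0; m < nm; ++m) { offset[m] = total; total += marker_len[m]; }
  IntegerMatrix counts(5, total);
  for (R_xlen_t h = 0; h < read_idx.size(); ++h) {
    if (IntegerVector::is_na(marker_idx[h]) || marker_idx[h] < 1 ||
        marker_idx[h] > nm)
      stop("pileup: marker index out of range at hit %d", (int)h + 1);
    std::string seq = as<std::string>(reads[read_idx[h] - 1]);
    if (rev[h]) seq = revcomp(seq);
    const int m = marker_idx[h] - 1;
    if (mstart[h] < 0 || mstart[h] + aligned[h] > marker_len[m] ||
        read_lo[h] < 0 || read_lo[h] + aligned[h] > (int)seq.size())
      stop("pileup: alignment span out of range at hit %d", (int)h + 1);
    const int base0 = offset[m] + mstart[h];
    const int lo = read_lo[h];
    for (int t = 0; t < aligned[h]; ++t) {
      int c = base_code(seq[lo + t]);
      counts(c, base0 + t)++;
    }
  }
  return counts;
}

// ---- read simulation --------------------------------------------------------

// substitute bases at the given per-base rate using R's RNG stream
static void mutate_inplace(std::string& s, double rate) {
  if (rate <= 0) return;
  const char bases[4] = {'A', 'C', 'G', 'T'};
  const int n = (int)s.size();
  int nmut = (int)R::rbinom((double)n, rate);
  for (int t = 0; t < nmut; ++t) {
    int pos = (int)(unif_rand() * n);
    if (pos >= n) pos = n - 1;
    const char old = s[pos];
    char nb = old;
    while (nb == old) nb = bases[(int)(unif_rand() * 4) % 4];
    s[pos] = nb;
  }
}

// [[Rcpp::export]]
CharacterVector mutate_seqs_cpp(CharacterVector seqs, double rate) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    mutate_inplace(s, rate);
    out[i] = s;
  }
  return out;
}

// uniform-start shotgun reads from weighted genomes, substitution errors only
// [[Rcpp::export]]
List sim_reads_cpp(CharacterVector genomes, NumericVector weights,
                   int n_reads, int read_len, double error_rate) {
  const int ng = (int)genomes.size();
  std::vector<std::string> gs(ng);
  for (int g = 0; g < ng; ++g) gs[g] = as<std::string>(genomes[g]);
  std::vector<double> cum(ng);
  double tot = 0;
  for (int g = 0; g < ng; ++g) { tot += weights[g]; cum[g] = tot; }
  CharacterVector reads(n_reads);
  IntegerVector genome(n_reads), start(n_reads);
  LogicalVector rev(n_reads);
  for (int i = 0; i < n_reads; ++i) {
    const double u = unif_rand() * tot;
    int g = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (g >= ng) g = ng - 1;
    const int glen = (int)gs[g].size();
    const int rl = std::min(read_len, glen);
    int pos = (int)(unif_rand() * (glen - rl + 1));
    if (pos > glen - rl) pos = glen - rl;
    std::string s = gs[g].substr(pos, rl);
    const bool rv = unif_rand() < 0.5;
    if (rv) s = revcomp(s);
    mutate_inplace(s, error_rate);
    reads[i] = s; genome[i] = g + 1; start[i] = pos; rev[i] = rv;
    if (i % 16384 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["read"] = reads, _["genome"] = genome,
                      _["start"] = start, _["rev"] = rev);
}
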