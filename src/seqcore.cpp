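#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <vector>
#include <string>

using namespace Rcpp;

// 2-bit base encoding A=0, C=1, G=2, T=3; anything else (N) = -1.
static inline int baseCode(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// splitmix64 finalizer; fixed published mixer used for hash subsampling.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t revcompCode(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

// [[Rcpp::export]]
List hpc_compress_cpp(CharacterVector seqs) {
  int n = seqs.size();
  List out(n);
  for (int s = 0; s < n; ++s) {
    std::string sq = as<std::string>(seqs[s]);
    std::string h;
    std::vector<int> runs, offs;
    h.reserve(sq.size());
    size_t i = 0;
    while (i < sq.size()) {
      char c = sq[i];
      size_t j = i + 1;
      while (j < sq.size() && sq[j] == c) ++j;
      h.push_back(c);
      runs.push_back((int)(j - i));
      offs.push_back((int)i);
      i = j;
    }
    out[s] = List::create(_["hseq"] = h,
                          _["runs"] = wrap(runs),
                          _["offsets"] = wrap(offs));
  }
  return out;
}

// [[Rcpp::export]]
std::string revcomp_cpp(std::string s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
    case 'A': r[i] = 'T'; break;
    case 'C': r[i] = 'G'; break;
    case 'G': r[i] = 'C'; break;
    case 'T': r[i] = 'A'; break;
    default: break; // N stays N
    }
  }
  return r;
}

// [[Rcpp::export]]
List canonical_kmer_cpp(std::string kmer) {
  int k = (int)kmer.size();
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int b = baseCode(kmer[i]);
    if (b < 0) stop("k-mer contains a non-ACGT base");
    code = (code << 2) | (uint64_t)b;
  }
  uint64_t rc = revcompCode(code, k);
  bool flipped = rc < code;
  uint64_t canon = flipped ? rc : code;
  std::string cs(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    cs[i] = BASES[canon & 3ULL];
    canon >>= 2;
  }
  return List::create(_["canonical"] = cs, _["flipped"] = flipped);
}

struct SeedEntry {
  int32_t rid;
  int32_t pos;
  uint8_t flipped;
};

struct KmerIdx {
  int k;
  int maxCount;
  int denom;
  std::vector<int> readLen;
  std::unordered_map<uint64_t, std::pair<uint64_t, uint32_t>> table; // code -> (start, len)
  std::vector<SeedEntry> entries;
};

// Iterate canonical k-mers of an HPC string; cb(pos, canon, flipped).
template <typename F>
static void forEachKmer(const std::string &s, int k, int denom, F cb) {
  int n = (int)s.size();
  if (n < k) return;
  uint64_t code = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = baseCode(s[i]);
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++valid < k) continue;
    uint64_t rc = revcompCode(code, k);
    bool flip = rc < code;
    uint64_t canon = flip ? rc : code;
    if (denom > 1 && (mix64(canon) % (uint64_t)denom) != 0) continue;
    cb(i - k + 1, canon, flip);
  }
}

// [[Rcpp::export]]
SEXP build_index_cpp(CharacterVector hseqs, int k, int maxCount, int denom) {
  if (k < 8 || k > 31) stop("k must be in [8, 31]");
  KmerIdx *idx = new KmerIdx();
  idx->k = k;
  idx->maxCount = maxCount;
  idx->denom = denom;
  int n = hseqs.size();
  idx->readLen.resize(n);
  // pass 1: count
  std::unordered_map<uint64_t, uint32_t> counts;
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(hseqs[r]);
    idx->readLen[r] = (int)s.size();
    forEachKmer(s, k, denom, [&](int, uint64_t canon, bool) { counts[canon]++; });
  }
  // allocate slices for k-mers passing the occurrence cap
  uint64_t total = 0;
  for (auto &kv : counts) {
    if (kv.second <= (uint32_t)maxCount) {
      idx->table[kv.first] = std::make_pair(total, 0u);
      total += kv.second;
    }
  }
  idx->entries.resize(total);
  // pass 2: fill seed array
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(hseqs[r]);
    forEachKmer(s, k, denom, [&](int pos, uint64_t canon, bool flip) {
      auto it = idx->table.find(canon);
      if (it == idx->table.end()) return;
      SeedEntry &e = idx->entries[it->second.first + it->second.second];
      e.rid = r;
      e.pos = pos;
      e.flipped = flip ? 1 : 0;
      it->second.second++;
    });
  }
  XPtr<KmerIdx> p(idx, true);
  return p;
}

// [[Rcpp::export]]
List index_info_cpp(SEXP xp) {
  XPtr<KmerIdx> idx(xp);
  return List::create(_["k"] = idx->k, _["maxCount"] = idx->maxCount,
                      _["subsampleDenominator"] = idx->denom,
                      _["nReads"] = (int)idx->readLen.size(),
                      _["nKmers"] = (double)idx->table.size(),
                      _["nSeeds"] = (double)idx->entries.size());
}

// [[Rcpp::export]]
int index_kmer_count_cpp(SEXP xp, std::string kmer) {
  XPtr<KmerIdx> idx(xp);
  List ck = canonical_kmer_cpp(kmer);
  std::string cs = as<std::string>(ck["canonical"]);
  uint64_t code = 0;
  for (char c : cs) code = (code << 2) | (uint64_t)baseCode(c);
  auto it = idx->table.find(code);
  if (it == idx->table.end()) return 0;
  return (int)it->second.second;
}

struct CandHit {
  int tid;
  int strand; // 0 = '+', 1 = '-'
  double cov;
  double wcov;
};

// Candidate discovery with repeat-depth weighting. Returns hits kept at
// coverage > minCov, ranked by (weighted) coverage, plus the per-base seed
// depth over the query used for the weights.
// [[Rcpp::export]]
List find_candidates_cpp(SEXP xp, std::string qh, int qid, double minCov,
                         int maxCand, int lowDepth, int highDepth,
                         bool weighted) {
  XPtr<KmerIdx> idx(xp);
  int k = idx->k;
  int qlen = (int)qh.size();
  struct Match { int tid; int strand; int qpos; };
  std::vector<Match> ms;
  forEachKmer(qh, k, idx->denom, [&](int pos, uint64_t canon, bool fq) {
    auto it = idx->table.find(canon);
    if (it == idx->table.end()) return;
    uint64_t st = it->second.first;
    uint32_t len = it->second.second;
    for (uint32_t j = 0; j < len; ++j) {
      const SeedEntry &e = idx->entries[st + j];
      if (e.rid == qid) continue;
      ms.push_back({e.rid, (e.flipped == (fq ? 1 : 0)) ? 0 : 1, pos});
    }
  });
  std::sort(ms.begin(), ms.end(), [](const Match &a, const Match &b) {
    if (a.tid != b.tid) return a.tid < b.tid;
    if (a.strand != b.strand) return a.strand < b.strand;
    return a.qpos < b.qpos;
  });
  // per-base depth over query: per tid, union of seed intervals (both strands)
  std::vector<int> diff(qlen + 1, 0);
  size_t i = 0;
  while (i < ms.size()) {
    size_t j = i;
    while (j < ms.size() && ms[j].tid == ms[i].tid) ++j;
    // union of [qpos, qpos+k) for this tid
    std::vector<int> ps;
    ps.reserve(j - i);
    for (size_t t = i; t < j; ++t) ps.push_back(ms[t].qpos);
    std::sort(ps.begin(), ps.end());
    int cs = -1, ce = -1;
    for (int p : ps) {
      int e = std::min(p + k, qlen);
      if (cs < 0) { cs = p; ce = e; }
      else if (p <= ce) ce = std::max(ce, e);
      else { diff[cs]++; diff[ce]--; cs = p; ce = e; }
    }
    if (cs >= 0) { diff[cs]++; diff[ce]--; }
    i = j;
  }
  std::vector<int> depth(qlen, 0);
  int acc = 0;
  for (int b = 0; b < qlen; ++b) { acc += diff[b]; depth[b] = acc; }
  // weights: 1 at depth <= low, 0 at depth >= high, linear between
  std::vector<double> w(qlen, 1.0), wps(qlen + 1, 0.0);
  double span = (double)(highDepth - lowDepth);
  for (int b = 0; b < qlen; ++b) {
    int d = depth[b];
    if (d <= lowDepth) w[b] = 1.0;
    else if (d >= highDepth) w[b] = 0.0;
    else w[b] = (double)(highDepth - d) / span;
    wps[b + 1] = wps[b] + w[b];
  }
  // per (tid, strand) coverage = query extent spanned by shared seeds
  // (first seed start to last seed end); weighted coverage integrates the
  // repeat-depth weights over that span
  std::vector<CandHit> hits;
  i = 0;
  while (i < ms.size()) {
    size_t j = i;
    while (j < ms.size() && ms[j].tid == ms[i].tid && ms[j].strand == ms[i].strand)
      ++j;
    int cs = ms[i].qpos;
    int ce = std::min(ms[j - 1].qpos + k, qlen);
    double cov = ce - cs;
    double wcov = wps[ce] - wps[cs];
    if (cov > minCov)
      hits.push_back({ms[i].tid, ms[i].strand, cov, wcov});
    i = j;
  }
  std::sort(hits.begin(), hits.end(), [&](const CandHit &a, const CandHit &b) {
    double ka = weighted ? a.wcov : a.cov, kb = weighted ? b.wcov : b.cov;
    if (ka != kb) return ka > kb;
    if (a.tid != b.tid) return a.tid < b.tid;
    return a.strand < b.strand;
  });
  if ((int)hits.size() > maxCand) hits.resize(maxCand);
  int nh = (int)hits.size();
  IntegerVector tid(nh);
  CharacterVector strand(nh);
  NumericVector cov(nh), wcov(nh);
  for (int h = 0; h < nh; ++h) {
    tid[h] = hits[h].tid;
    strand[h] = hits[h].strand == 0 ? "+" : "-";
    cov[h] = hits[h].cov;
    wcov[h] = hits[h].wcov;
  }
  return List::create(
      _["hits"] = DataFrame::create(_["tid"] = tid, _["strand"] = strand,
                                    _["coverage"] = cov,
                                    _["weightedCoverage"] = wcov,
                                    _["stringsAsFactors"] = false),
      _["depth"] = wrap(depth));
}

// All maximal exact z-mer match runs between two (already oriented) HPC
// strings; rows (qpos, tpos, len) 0-based, sorted by qpos then tpos.
// [[Rcpp::export]]
IntegerMatrix extract_anchors_cpp(std::string qh, std::string th, int z,
                                  int maxOcc = 64) {
  int nq = (int)qh.size(), nt = (int)th.size();
  std::unordered_map<uint64_t, std::vector<int>> qmap;
  if (nq >= z && nt >= z) {
    uint64_t code = 0, mask = (z < 32) ? ((1ULL << (2 * z)) - 1ULL) : ~0ULL;
    int valid = 0;
    for (int i2 = 0; i2 < nq; ++i2) {
      int b = baseCode(qh[i2]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++valid >= z) qmap[code].push_back(i2 - z + 1);
    }
    std::vector<std::pair<int64_t, int>> pairs; // (diag<<32|qpos surrogate)
    std::vector<std::pair<int, int>> raw;       // (qpos, tpos)
    code = 0; valid = 0;
    for (int i2 = 0; i2 < nt; ++i2) {
      int b = baseCode(th[i2]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++valid < z) continue;
      auto it = qmap.find(code);
      if (it == qmap.end() || (int)it->second.size() > maxOcc) continue;
      int tpos = i2 - z + 1;
      for (int qp : it->second) raw.push_back({qp, tpos});
    }
    // merge diagonal runs
    std::sort(raw.begin(), raw.end(), [](const std::pair<int, int> &a,
                                         const std::pair<int, int> &b) {
      long da = (long)a.first - a.second, db = (long)b.first - b.second;
      if (da != db) return da < db;
      return a.first < b.first;
    });
    std::vector<std::array<int, 3>> anchors;
    size_t i = 0;
    while (i < raw.size()) {
      int q0 = raw[i].first, t0 = raw[i].second;
      long d0 = (long)q0 - t0;
      int qe = q0;
      size_t j = i + 1;
      while (j < raw.size() &&
             (long)raw[j].first - raw[j].second == d0 &&
             raw[j].first <= qe + 1) {
        qe = std::max(qe, raw[j].first);
        ++j;
      }
      anchors.push_back({q0, t0, qe - q0 + z});
      i = j;
    }
    std::sort(anchors.begin(), anchors.end(),
              [](const std::array<int, 3> &a, const std::array<int, 3> &b) {
                if (a[0] != b[0]) return a[0] < b[0];
                return a[1] < b[1];
              });
    IntegerMatrix out((int)anchors.size(), 3);
    for (int r = 0; r < (int)anchors.size(); ++r) {
      out(r, 0) = anchors[r][0];
      out(r, 1) = anchors[r][1];
      out(r, 2) = anchors[r][2];
    }
    colnames(out) = CharacterVector::create("qpos", "tpos", "len");
    return out;
  }
  IntegerMatrix out(0, 3);
  colnames(out) = CharacterVector::create("qpos", "tpos", "len");
  return out;
}

// Greedy syntenic-block chain over anchors sorted by qpos:
//   S_1 = L_1; S_{i+1} = S_i + L_{i+1} - Distance_{i,i+1};
//   reset when S_{i+1} < L_{i+1}.
// Distance = |(tpos[i+1] - tpos[i]) - (qpos[i+1] - qpos[i])|: the
// collinearity drift between adjacent seeds (how far the candidate-side
// spacing deviates from the query-side spacing). Perfectly collinear
// seeds chain for free however sparse they are -- indels between two
// noisy reads make seed spacing highly variable -- while off-diagonal
// jumps pay their full magnitude and break the block.
// Returns the maximizing contiguous run (block truncated at its score peak),
// 1-based inclusive indices; ties -> earliest end then earliest start.
// [[Rcpp::export]]
List chain_anchors_cpp(IntegerVector qpos, IntegerVector tpos,
                       IntegerVector len) {
  int n = qpos.size();
  if (n == 0)
    return List::create(_["start"] = 0, _["end"] = 0, _["score"] = 0);
  long S = len[0];
  int cs = 0;
  long best = S;
  int bs = 0, be = 0;
  for (int i = 1; i < n; ++i) {
    long d = std::labs(((long)tpos[i] - tpos[i - 1]) -
                       ((long)qpos[i] - qpos[i - 1]));
    long cont = S + len[i] - d;
    if (cont >= len[i]) {
      S = cont;
    } else {
      S = len[i];
      cs = i;
    }
    if (S > best) { best = S; bs = cs; be = i; }
  }
  return List::create(_["start"] = bs + 1, _["end"] = be + 1,
                      _["score"] = (double)best);
}

// Full window-chaining pass for one candidate pair (the hot path of the
// overlap stage): windows over query HPC coordinates, per-window diagonal
// grouping, per-group greedy block chain, window-match filter, window-level
// chain, final collinearity trim. Mirrors the R-level chainQuery contract.
// [[Rcpp::export]]
List chain_query_cpp(IntegerMatrix anchors, int windowSize,
                     double minWindowMatch, double minChainTotal,
                     int diagBin) {
  int n = anchors.nrow();
  if (n == 0) return List::create(_["ok"] = false);
  std::vector<int> qp(n), tp(n), ln(n);
  for (int i = 0; i < n; ++i) {
    qp[i] = anchors(i, 0); tp[i] = anchors(i, 1); ln[i] = anchors(i, 2);
  }
  // order anchors by (window, diagBin, qpos, tpos)
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  auto winOf = [&](int i) { return qp[i] / windowSize; };
  auto binOf = [&](int i) {
    long d = (long)qp[i] - tp[i];
    long b = d >= 0 ? d / diagBin : -(((-d) + diagBin - 1) / diagBin);
    return (int)b;
  };
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (winOf(a) != winOf(b)) return winOf(a) < winOf(b);
    if (binOf(a) != binOf(b)) return binOf(a) < binOf(b);
    if (qp[a] != qp[b]) return qp[a] < qp[b];
    return tp[a] < tp[b];
  });

  // greedy Kadane chain over a sorted-by-qpos index list; returns best
  // contiguous run [s, e] and its score
  auto chainRun = [&](const std::vector<int> &v, int &bs, int &be) {
    long S = ln[v[0]];
    int cs = 0;
    long best = S;
    bs = 0; be = 0;
    for (size_t i = 1; i < v.size(); ++i) {
      long d = std::labs(((long)tp[v[i]] - tp[v[i - 1]]) -
                         ((long)qp[v[i]] - qp[v[i - 1]]));
      long cont = S + ln[v[i]] - d;
      if (cont >= ln[v[i]]) S = cont;
      else { S = ln[v[i]]; cs = (int)i; }
      if (S > best) { best = S; bs = cs; be = (int)i; }
    }
    return best;
  };
  auto unionCov = [&](const std::vector<int> &v) {
    // v sorted by qpos
    long cov = 0, cs = qp[v[0]], ce = qp[v[0]] + ln[v[0]];
    for (size_t i = 1; i < v.size(); ++i) {
      long s = qp[v[i]], e = s + ln[v[i]];
      if (s <= ce) { if (e > ce) ce = e; }
      else { cov += ce - cs; cs = s; ce = e; }
    }
    return cov + (ce - cs);
  };

  struct WinBlock { int win; long qpos, tpos, matched; std::vector<int> members; };
  std::vector<WinBlock> blocks;
  size_t i0 = 0;
  while (i0 < idx.size()) {
    size_t i1 = i0;
    int w = winOf(idx[i0]);
    while (i1 < idx.size() && winOf(idx[i1]) == w) ++i1;
    // bins present in this window (idx sorted by bin within window)
    long bestScore = -1;
    std::vector<int> bestGrp;
    size_t b0 = i0;
    while (b0 < i1) {
      int b = binOf(idx[b0]);
      // group = bins b-1 .. b+1
      std::vector<int> grp;
      for (size_t t = i0; t < i1; ++t) {
        int bb = binOf(idx[t]);
        if (bb >= b - 1 && bb <= b + 1) grp.push_back(idx[t]);
      }
      std::sort(grp.begin(), grp.end(), [&](int a, int c) {
        if (qp[a] != qp[c]) return qp[a] < qp[c];
        return tp[a] < tp[c];
      });
      int bs, be;
      long sc = chainRun(grp, bs, be);
      if (sc > bestScore) {
        bestScore = sc;
        bestGrp.assign(grp.begin() + bs, grp.begin() + be + 1);
      }
      while (b0 < i1 && binOf(idx[b0]) == b) ++b0;
    }
    if (!bestGrp.empty()) {
      long m = unionCov(bestGrp);
      if (m >= minWindowMatch) {
        WinBlock wb;
        wb.win = w;
        wb.matched = m;
        wb.qpos = qp[bestGrp.front()];
        long tmin = tp[bestGrp.front()];
        for (int a : bestGrp) tmin = std::min(tmin, (long)tp[a]);
        wb.tpos = tmin;
        wb.members = bestGrp;
        blocks.push_back(wb);
      }
    }
    i0 = i1;
  }
  if (blocks.empty()) return List::create(_["ok"] = false);
  // window-level chain on the super-anchors (already in qpos order)
  int nb = (int)blocks.size();
  {
    long S = blocks[0].matched;
    int cs = 0;
    long best = S;
    int bs = 0, be = 0;
    for (int i = 1; i < nb; ++i) {
      long d = std::labs((blocks[i].tpos - blocks[i - 1].tpos) -
                         (blocks[i].qpos - blocks[i - 1].qpos));
      long cont = S + blocks[i].matched - d;
      if (cont >= blocks[i].matched) S = cont;
      else { S = blocks[i].matched; cs = i; }
      if (S > best) { best = S; bs = cs; be = i; }
    }
    blocks.assign(blocks.begin() + bs, blocks.begin() + be + 1);
  }
  long total = 0;
  std::vector<int> sel;
  for (auto &b : blocks) {
    total += b.matched;
    for (int a : b.members) sel.push_back(a);
  }
  if (total <= minChainTotal) return List::create(_["ok"] = false);
  // joint monotonic trim (anchors are exact matches: trimming the start of
  // one by d keeps it exact)
  std::vector<std::array<int, 3>> out;
  long lastQ = -1, lastT = -1;
  for (int a : sel) {
    long q = qp[a], t = tp[a], l = ln[a];
    long d = std::max(std::max(lastQ - q, lastT - t), 0L);
    if (l - d <= 0) continue;
    q += d; t += d; l -= d;
    out.push_back({(int)q, (int)t, (int)l});
    lastQ = q + l; lastT = t + l;
  }
  if (out.empty()) return List::create(_["ok"] = false);
  IntegerMatrix m((int)out.size(), 3);
  for (int r = 0; r < (int)out.size(); ++r) {
    m(r, 0) = out[r][0]; m(r, 1) = out[r][1]; m(r, 2) = out[r][2];
  }
  colnames(m) = CharacterVector::create("qpos", "tpos", "len");
  return List::create(_["ok"] = true, _["anchors"] = m,
                      _["total"] = (double)total,
                      _["windows"] = (int)blocks.size());
}
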