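#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Backbone-anchored alignment DAG (PBDAG-Con style). Nodes are
// (backbone position, insertion offset, base); the backbone and every
// aligned read thread a path through the graph, incrementing edge weights.
// Consensus = maximum-weight source->sink path (DP over topological order,
// ties resolved toward the backbone base).

struct DagNode {
  int pos;   // -1 = source, L = sink
  int off;   // 0 = backbone column, >=1 = insertion after pos
  char base; // '\0' for sentinels
};

static inline uint64_t nodeKey(int pos, int off, int baseIdx) {
  return (((uint64_t)(pos + 1)) << 24) | (((uint64_t)off) << 4) |
         (uint64_t)baseIdx;
}

static const double MAJOR = 0.4; // majority factor: a consensus node (or skip)
// must be backed by more than MAJOR x local depth. True run-extension
// evidence is discounted by double-intactness of the run in each noisy read
// (~0.6-0.8 x depth) while uncorrelated noise stays below ~0.3 x depth, so
// the bar sits between the two classes.

static inline int baseIdxOf(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return 5; // N and friends get their own slot
  }
}

// When `backboneRuns` / per-read `runs` are supplied, sequences are
// homopolymer-compressed and each node accumulates the raw run lengths of
// its supporting reads; the consensus expands each path node to the modal
// run length. Run-length errors -- the dominant error class of the reads
// this assembler targets -- then never enter the base-level DAG at all,
// and each run length is called from the full spanning pileup instead of
// from alignment-split insertion evidence.
// [[Rcpp::export]]
List consensus_dag_cpp(std::string backbone, List reads,
                       Nullable<IntegerVector> backboneRuns = R_NilValue) {
  int L = (int)backbone.size();
  if (L == 0) stop("empty backbone");
  bool rle = backboneRuns.isNotNull();
  IntegerVector bbRuns;
  if (rle) {
    bbRuns = backboneRuns.get();
    if ((int)bbRuns.size() != L) stop("backboneRuns length mismatch");
  }
  // per-node tally of raw run lengths (node id << 8 | clamped length)
  std::unordered_map<uint64_t, int> runTally;
  auto tallyRun = [&](int node, int len) {
    if (!rle) return;
    if (len < 1) len = 1;
    if (len > 250) len = 250;
    runTally[(((uint64_t)node) << 8) | (uint64_t)len] += 1;
  };

  std::unordered_map<uint64_t, int> ids;
  std::vector<DagNode> nodes;
  auto getNode = [&](int pos, int off, char base) -> int {
    uint64_t k = nodeKey(pos, off, baseIdxOf(base));
    auto it = ids.find(k);
    if (it != ids.end()) return it->second;
    int id = (int)nodes.size();
    nodes.push_back({pos, off, base});
    ids.emplace(k, id);
    return id;
  };
  int source = getNode(-1, 0, '\0');
  int sink = getNode(L, 0, '\1');

  std::unordered_map<uint64_t, double> edges;
  auto addEdge = [&](int u, int v, double w) {
    edges[(((uint64_t)u) << 32) | (uint64_t)v] += w;
  };

  double totalWeight = 0.0;
  // thread the backbone once
  {
    int prev = source;
    for (int p = 0; p < L; ++p) {
      int u = getNode(p, 0, backbone[p]);
      addEdge(prev, u, 1.0);
      totalWeight += 1.0;
      tallyRun(u, rle ? bbRuns[p] : 1);
      prev = u;
    }
    addEdge(prev, sink, 1.0);
    totalWeight += 1.0;
  }

  // Score-preserving left-normalization of gaps: a deletion run may shift
  // left while the backbone base before it equals its last base, an
  // insertion run while the read base before it equals its last base.
  // Without this, reads place equivalent indels at different positions in
  // repeat/homopolymer context and the correction evidence fragments
  // across the DAG.
  auto normalizeOps = [&](std::vector<char> &ops, const std::string &seq,
                          int tstart) {
    bool changed = true;
    int guard = 0;
    while (changed && ++guard <= 20) {
      changed = false;
      // positions of read (qi) and backbone (ti) before each column
      int n2 = (int)ops.size();
      std::vector<int> qpre(n2 + 1), tpre(n2 + 1);
      qpre[0] = 0; tpre[0] = tstart;
      for (int c = 0; c < n2; ++c) {
        qpre[c + 1] = qpre[c] + (ops[c] != 'D' ? 1 : 0);
        tpre[c + 1] = tpre[c] + (ops[c] != 'I' ? 1 : 0);
      }
      for (int c = 0; c < n2; ++c) {
        if (ops[c] != 'I' && ops[c] != 'D') continue;
        int e = c;
        while (e + 1 < n2 && ops[e + 1] == ops[c]) ++e;
        // shift the run [c, e] left over the preceding aligned column
        while (c > 0 && ops[c - 1] != 'I' && ops[c - 1] != 'D') {
          bool ok;
          if (ops[c] == 'D')
            ok = backbone[tpre[c] - 1] == backbone[tpre[e + 1] - 1];
          else
            ok = seq[qpre[c] - 1] == seq[qpre[e + 1] - 1];
          if (!ok) break;
          // move the run one column left; the aligned column lands at e
          char g = ops[c];
          char aligned = ops[c - 1];
          for (int t = c - 1; t < e; ++t) ops[t] = g;
          ops[e] = aligned;
          --c; --e;
          changed = true;
          for (int t = c - 1; t <= e + 1 && t < n2; ++t) {
            if (t < 0) continue;
            qpre[t + 1] = qpre[t] + (ops[t] != 'D' ? 1 : 0);
            tpre[t + 1] = tpre[t] + (ops[t] != 'I' ? 1 : 0);
          }
        }
        c = e;
      }
    }
  };

  // per-backbone-position read coverage (for minority pruning in the DP)
  std::vector<double> covDiff(L + 1, 0.0);

  int nr = reads.size();
  for (int r = 0; r < nr; ++r) {
    List rec = reads[r];
    std::string seq = as<std::string>(rec["seq"]);
    int tstart = as<int>(rec["tstart"]);
    std::string cig = as<std::string>(rec["cigar"]);
    IntegerVector rdRuns;
    if (rle) {
      rdRuns = as<IntegerVector>(rec["runs"]);
      if ((int)rdRuns.size() != (int)seq.size())
        stop("read runs length mismatch");
    }
    int p = tstart;      // next backbone position to consume
    int qi = 0;          // next read base
    int anchor = tstart - 1; // last consumed backbone position
    int off = 0;
    int prev = -1;
    // connectivity (weight 0) from the backbone into a mid-backbone start
    if (tstart > 0) prev = getNode(tstart - 1, 0, backbone[tstart - 1]);
    else prev = source;
    bool prevIsEntry = true; // first edge from entry point carries weight 0
    // expand the cigar and left-normalize its gaps
    std::vector<char> opv;
    {
      size_t ci = 0;
      while (ci < cig.size()) {
        long len = 0;
        while (ci < cig.size() && cig[ci] >= '0' && cig[ci] <= '9') {
          len = len * 10 + (cig[ci] - '0');
          ++ci;
        }
        if (ci >= cig.size()) stop("malformed cigar");
        char op = cig[ci++];
        for (long t = 0; t < len; ++t) opv.push_back(op);
      }
    }
    normalizeOps(opv, seq, tstart);
    for (size_t oi = 0; oi < opv.size(); ++oi) {
      char op = opv[oi];
      {
        if (op == '=' || op == 'X') {
          if (p >= L || qi >= (int)seq.size()) stop("cigar overruns backbone/read");
          int u = getNode(p, 0, seq[qi]);
          double w = prevIsEntry && tstart > 0 ? 0.0 : 1.0;
          if (prev == source) w = 1.0; // reads starting at 0 enter from source
          addEdge(prev, u, w);
          totalWeight += w;
          tallyRun(u, rle ? rdRuns[qi] : 1);
          prev = u;
          prevIsEntry = false;
          anchor = p;
          off = 0;
          ++p; ++qi;
        } else if (op == 'I') {
          if (qi >= (int)seq.size()) stop("cigar overruns read");
          ++off;
          int u = getNode(anchor, off, seq[qi]);
          double w = prevIsEntry && tstart > 0 ? 0.0 : 1.0;
          if (prev == source) w = 1.0;
          addEdge(prev, u, w);
          totalWeight += w;
          tallyRun(u, rle ? rdRuns[qi] : 1);
          prev = u;
          prevIsEntry = false;
          ++qi;
        } else if (op == 'D') {
          if (p >= L) stop("cigar overruns backbone");
          ++p; // deletion: the next emitted node's edge spans this position
          anchor = p - 1;
          off = 0;
        } else {
          stop("unknown cigar op");
        }
      }
    }
    // connectivity (weight 0) back onto the backbone / sink
    int exitNode = (p >= L) ? sink : getNode(p, 0, backbone[p]);
    addEdge(prev, exitNode, (p >= L) ? 1.0 : 0.0);
    if (p >= L) totalWeight += 1.0;
    covDiff[std::max(0, tstart)] += 1.0;
    covDiff[std::min(L, p)] -= 1.0;
  }
  std::vector<double> cov(L, 1.0); // backbone itself counts once
  {
    double acc = 0.0;
    for (int p2 = 0; p2 < L; ++p2) { acc += covDiff[p2]; cov[p2] += acc; }
  }

  // topological order: by (pos, off, id)
  int N = (int)nodes.size();
  std::vector<int> ord(N);
  for (int i = 0; i < N; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (nodes[a].pos != nodes[b].pos) return nodes[a].pos < nodes[b].pos;
    if (nodes[a].off != nodes[b].off) return nodes[a].off < nodes[b].off;
    return a < b;
  });
  std::vector<int> topoRank(N);
  for (int i = 0; i < N; ++i) topoRank[ord[i]] = i;

  // incoming adjacency grouped by target
  struct E { int u, v; double w; };
  std::vector<E> elist;
  elist.reserve(edges.size());
  for (auto &kv : edges)
    elist.push_back({(int)(kv.first >> 32), (int)(kv.first & 0xFFFFFFFFULL),
                     kv.second});
  std::sort(elist.begin(), elist.end(), [&](const E &a, const E &b) {
    if (topoRank[a.v] != topoRank[b.v]) return topoRank[a.v] < topoRank[b.v];
    return topoRank[a.u] < topoRank[b.u];
  });

  // node score = read support minus half the local read depth: a node kept
  // on the consensus path must be backed by a majority of the reads
  // covering its locus. Summing raw edge weights instead would let a
  // minority branch of two light edges outscore one heavy skip edge, so
  // correlated minority variants (clustered indel evidence near backbone
  // errors) would enter the consensus and persist across rounds.
  std::vector<double> inWeight(N, 0.0);
  for (auto &e : elist) inWeight[e.v] += e.w;
  auto nodeScore = [&](int v) {
    if (v == source || v == sink) return 0.0;
    int p = nodes[v].pos;
    if (p < 0) p = 0;
    if (p >= L) p = L - 1;
    return inWeight[v] - MAJOR * cov[p];
  };
  // skipping backbone positions must also clear the majority bar: an edge
  // jumping from position pos(u) to pos(v) scores (w - 0.5 cov) for every
  // position it skips, so a deletion wins only where more reads skip a
  // base than thread any of its nodes
  std::vector<double> covPre(L + 1, 0.0);
  for (int p2 = 0; p2 < L; ++p2) covPre[p2 + 1] = covPre[p2] + cov[p2];
  auto edgeScore = [&](const E &e) {
    int pu = nodes[e.u].pos, pv = nodes[e.v].pos;
    int lo2 = std::max(pu + 1, 0), hi2 = std::min(pv, L);
    if (hi2 <= lo2) return 0.0;
    double d = (double)(hi2 - lo2);
    return e.w * d - MAJOR * (covPre[hi2] - covPre[lo2]);
  };
  std::vector<double> dp(N, -1e18);
  std::vector<int> pred(N, -1);
  dp[source] = 0.0;
  auto isBackboneNode = [&](int u) {
    return nodes[u].off == 0 && nodes[u].pos >= 0 && nodes[u].pos < L &&
           nodes[u].base == backbone[nodes[u].pos];
  };
  size_t ei = 0;
  for (int oi = 0; oi < N; ++oi) {
    int v = ord[oi];
    double sc = nodeScore(v);
    while (ei < elist.size() && elist[ei].v == v) {
      const E &e = elist[ei];
      if (dp[e.u] > -1e17) {
        double cand = dp[e.u] + sc + edgeScore(e);
        if (cand > dp[v] ||
            (cand == dp[v] && pred[v] >= 0 && !isBackboneNode(pred[v]) &&
             isBackboneNode(e.u))) {
          dp[v] = cand;
          pred[v] = e.u;
        }
      }
      ++ei;
    }
  }
  if (dp[sink] < -1e17) stop("sink unreachable in consensus DAG");

  // modal raw run length of a path node (ties -> shorter run)
  auto runOf = [&](int v) {
    if (!rle) return 1;
    int best = 1, bestCnt = -1;
    for (int len = 1; len <= 250; ++len) {
      auto it = runTally.find((((uint64_t)v) << 8) | (uint64_t)len);
      if (it != runTally.end() && it->second > bestCnt) {
        bestCnt = it->second;
        best = len;
      }
    }
    return bestCnt > 0 ? best : 1;
  };

  std::string seq, hseq;
  std::vector<double> support, hsupport, hcov;
  std::vector<int> hruns, hpos, hoff;
  int cur = pred[sink];
  while (cur != source && cur != -1) {
    int rep = runOf(cur);
    for (int t = 0; t < rep; ++t) {
      seq.push_back(nodes[cur].base);
      support.push_back(inWeight[cur]);
    }
    hseq.push_back(nodes[cur].base);
    hruns.push_back(rep);
    hsupport.push_back(inWeight[cur]);
    hpos.push_back(nodes[cur].pos);
    hoff.push_back(nodes[cur].off);
    int p2 = nodes[cur].pos;
    if (p2 < 0) p2 = 0;
    if (p2 >= L) p2 = L - 1;
    hcov.push_back(cov[p2]);
    cur = pred[cur];
  }
  std::reverse(seq.begin(), seq.end());
  std::reverse(support.begin(), support.end());
  std::reverse(hseq.begin(), hseq.end());
  std::reverse(hruns.begin(), hruns.end());
  std::reverse(hsupport.begin(), hsupport.end());
  std::reverse(hcov.begin(), hcov.end());
  std::reverse(hpos.begin(), hpos.end());
  std::reverse(hoff.begin(), hoff.end());
  return List::create(_["seq"] = seq, _["support"] = wrap(support),
                      _["hseq"] = hseq, _["hruns"] = wrap(hruns),
                      _["hsupport"] = wrap(hsupport), _["hcov"] = wrap(hcov),
                      _["hpos"] = wrap(hpos), _["hoff"] = wrap(hoff),
                      _["totalWeight"] = totalWeight,
                      _["nNodes"] = N, _["nEdges"] = (double)edges.size(),
                      _["pathScore"] = dp[sink]);
}

// Windowed plurality vote: for each backbone window [winL, winR) collect
// from every spanning read the segment aligned to that interval (HPC
// string plus raw run lengths) and return the plurality string with its
// vote counts and averaged run lengths. Used to repair compound-divergence
// sites where per-column voting splits: each read carries the true local
// string verbatim, but their alignments to an erroneous backbone represent
// it with heterogeneous mixes of mismatches and indels, so no single DAG
// node ever collects a majority.
// [[Rcpp::export]]
List window_vote_cpp(List alns, IntegerVector winL, IntegerVector winR) {
  int nw = winL.size();
  int nr = alns.size();
  std::vector<std::vector<std::string>> segs(nw);
  std::vector<std::vector<std::vector<int>>> segRuns(nw);
  for (int r = 0; r < nr; ++r) {
    List a = alns[r];
    std::string seq = as<std::string>(a["seq"]);
    int tstart = as<int>(a["tstart"]);
    std::string cig = as<std::string>(a["cigar"]);
    IntegerVector runs = a["runs"];
    // expand cigar walk, recording read position at each window boundary
    std::vector<int> ops;
    {
      size_t ci = 0;
      while (ci < cig.size()) {
        long len = 0;
        while (ci < cig.size() && cig[ci] >= '0' && cig[ci] <= '9')
          len = len * 10 + (cig[ci++] - '0');
        char op = cig[ci++];
        for (long t2 = 0; t2 < len; ++t2) ops.push_back(op);
      }
    }
    int tEnd = tstart;
    for (char op : ops) if (op != 'I') ++tEnd;
    for (int w = 0; w < nw; ++w) {
      if (tstart > winL[w] - 2 || tEnd < winR[w] + 2) continue;
      int t = tstart, q = 0, qs = -1, qe = -1;
      if (t == winL[w]) qs = q;
      for (char op : ops) {
        if (op == 'I') { ++q; }
        else { ++t; if (op != 'D') ++q; }
        if (t == winL[w] && qs < 0) qs = q;
        if (t == winR[w]) { qe = q; break; }
      }
      if (qs < 0 || qe < 0 || qe < qs) continue;
      segs[w].push_back(seq.substr(qs, qe - qs));
      std::vector<int> rr(runs.begin() + qs, runs.begin() + qe);
      segRuns[w].push_back(rr);
    }
  }
  List out(nw);
  for (int w = 0; w < nw; ++w) {
    std::map<std::string, int> counts;
    for (auto &s : segs[w]) counts[s]++;
    std::string best;
    int bestN = -1;
    for (auto &kv : counts)
      if (kv.second > bestN) { bestN = kv.second; best = kv.first; }
    // averaged run lengths over the winner's supporters
    std::vector<double> rsum(best.size(), 0.0);
    int nsup = 0;
    for (size_t i = 0; i < segs[w].size(); ++i) {
      if (segs[w][i] != best) continue;
      ++nsup;
      for (size_t j = 0; j < best.size(); ++j) rsum[j] += segRuns[w][i][j];
    }
    IntegerVector rr(best.size());
    for (size_t j = 0; j < best.size(); ++j)
      rr[j] = nsup > 0 ? (int)(rsum[j] / nsup + 0.5) : 1;
    out[w] = List::create(_["winner"] = best, _["votes"] = bestN,
                          _["voters"] = (int)segs[w].size(),
                          _["runs"] = rr);
  }
  return out;
}
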