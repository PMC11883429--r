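// Anchored gapped alignment of amplicon reads against a short reference.
//
// Strategy: the read 5' end is expected to start at a PCR primer site, so a
// 20-mer anchor (<= 1 mismatch, unique best hit over both strands) fixes
// ref_start; the full read is then aligned by semi-global affine-gap
// alignment (read fully consumed, free reference suffix), ties preferring
// diagonal moves so substitutions never become indels. Indels are
// left-aligned after traceback. Coordinates returned are 0-based half-open
// on the forward strand of the reference.

#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
#include <climits>

using namespace Rcpp;

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    case 'a': c = 't'; break;
    case 'c': c = 'g'; break;
    case 'g': c = 'c'; break;
    case 't': c = 'a'; break;
    default: c = 'N';
    }
  }
  return r;
}

struct Op {   // code 1 = insertion (ref footprint zero-width), 2 = deletion
  int code;
  int ref_pos;   // insertion point / deletion start (alignment space)
  int len;
  std::string seq; // inserted bases (insertions only)
};

struct Aln {
  bool mapped = false;
  char strand = '+';
  int ref_start = 0, ref_end = 0, n_mismatch = 0;
  std::vector<Op> ops;
};

// all anchor hits with <= max_mm mismatches; returns (pos, mm) pairs
static void anchor_hits(const std::string& S, const std::string& anchor,
                        int max_mm, std::vector<std::pair<int,int> >& hits) {
  const int L = (int)S.size(), a = (int)anchor.size();
  for (int p = 0; p + a <= L; ++p) {
    int mm = 0;
    for (int i = 0; i < a; ++i) {
      if (S[p + i] != anchor[i] && ++mm > max_mm) break;
    }
    if (mm <= max_mm) hits.push_back(std::make_pair(p, mm));
  }
}

// semi-global affine-gap DP of read r against S starting at ref position p.
// Costs (x10): match 0, mismatch 10, gap open 25 (first gapped base
// included); deletions (ref gaps) extend at 1, insertions (read gaps) at
// 10. Cheap deletion extension makes a long inter-site deletion far
// cheaper than the mismatch run it would otherwise become; expensive
// insertion extension stops the free reference suffix from swallowing the
// read tail as a bogus insertion. A single substitution (10) stays cheaper
// than any indel pair, so sequencing errors never become indel events.
static const int MIS = 10, OPEN = 25, EXT_DEL = 1, EXT_INS = 10;
static const int INF = INT_MAX / 4;

static void dp_align(const std::string& r, const std::string& S, int p,
                     Aln& out) {
  const int m = (int)r.size();
  const int W = (int)S.size() - p;
  const int stride = W + 1;
  // state 0 = M (diagonal), 1 = Ix (insertion, consumes read),
  // 2 = Iy (deletion, consumes ref)
  std::vector<int> cM((m + 1) * stride, INF), cX((m + 1) * stride, INF),
                   cY((m + 1) * stride, INF);
  std::vector<unsigned char> bM((m + 1) * stride), bX((m + 1) * stride),
                             bY((m + 1) * stride);
  cM[0] = 0;
  for (int j = 1; j <= W; ++j) {
    cY[j] = OPEN + (j - 1) * EXT_DEL;
    bY[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= m; ++i) {
    cX[i * stride] = OPEN + (i - 1) * EXT_INS;
    bX[i * stride] = (i == 1) ? 0 : 1;
    const char rc = r[i - 1];
    for (int j = 1; j <= W; ++j) {
      const int idx = i * stride + j;
      const int dg = (i - 1) * stride + (j - 1);
      const int up = (i - 1) * stride + j;
      const int lf = i * stride + (j - 1);
      const int sub = (rc == S[p + j - 1]) ? 0 : MIS;
      // M: prefer continuing from M on ties
      int best = cM[dg], from = 0;
      if (cX[dg] < best) { best = cX[dg]; from = 1; }
      if (cY[dg] < best) { best = cY[dg]; from = 2; }
      cM[idx] = (best >= INF) ? INF : best + sub;
      bM[idx] = (unsigned char)from;
      // Ix: open from M/Iy, extend from Ix
      int oX = std::min(cM[up] >= INF ? INF : cM[up] + OPEN,
                        cY[up] >= INF ? INF : cY[up] + OPEN);
      int eX = cX[up] >= INF ? INF : cX[up] + EXT_INS;
      if (eX <= oX) { cX[idx] = eX; bX[idx] = 1; }
      else { cX[idx] = oX; bX[idx] = (cM[up] + OPEN <= cY[up] + OPEN &&
                                      cM[up] < INF) ? 0 : 2; }
      // Iy: open from M/Ix, extend from Iy
      int oY = std::min(cM[lf] >= INF ? INF : cM[lf] + OPEN,
                        cX[lf] >= INF ? INF : cX[lf] + OPEN);
      int eY = cY[lf] >= INF ? INF : cY[lf] + EXT_DEL;
      if (eY <= oY) { cY[idx] = eY; bY[idx] = 2; }
      else { cY[idx] = oY; bY[idx] = (cM[lf] + OPEN <= cX[lf] + OPEN &&
                                      cM[lf] < INF) ? 0 : 1; }
    }
  }
  // end anywhere on the reference (smallest span on ties); do not end in a
  // deletion (a trailing deletion is always dominated by stopping earlier)
  int jbest = 0, sbest = 0, cbest = INF;
  for (int j = 0; j <= W; ++j) {
    int cm = cM[m * stride + j], cx = cX[m * stride + j];
    if (cm < cbest) { cbest = cm; jbest = j; sbest = 0; }
    if (cx < cbest) { cbest = cx; jbest = j; sbest = 1; }
  }
  int i = m, j = jbest, state = sbest, nmm = 0;
  std::vector<Op> ops;
  while (i > 0 || j > 0) {
    const int idx = i * stride + j;
    if (state == 0) {
      if (r[i - 1] != S[p + j - 1]) ++nmm;
      state = bM[idx];
      --i; --j;
    } else if (state == 1) {
      // insertion of r[i-1] at ref between-base position p+j
      if (!ops.empty() && ops.back().code == 1 &&
          ops.back().ref_pos == p + j) {
        ops.back().len += 1;
        ops.back().seq.insert(0, 1, r[i - 1]);
      } else {
        Op o; o.code = 1; o.ref_pos = p + j; o.len = 1;
        o.seq = std::string(1, r[i - 1]);
        ops.push_back(o);
      }
      state = bX[idx];
      --i;
    } else {
      // deletion of S[p+j-1]
      if (!ops.empty() && ops.back().code == 2 &&
          ops.back().ref_pos == p + j) {
        ops.back().ref_pos = p + j - 1;
        ops.back().len += 1;
      } else {
        Op o; o.code = 2; o.ref_pos = p + j - 1; o.len = 1;
        ops.push_back(o);
      }
      state = bY[idx];
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  // left-align indels (standard shift: indel moves left while its last base
  // equals the reference base immediately 5' of it)
  for (size_t k = 0; k < ops.size(); ++k) {
    int lower = p;
    if (k > 0) {
      const Op& prev = ops[k - 1];
      lower = std::max(lower, prev.code == 2 ? prev.ref_pos + prev.len
                                             : prev.ref_pos);
    }
    Op& o = ops[k];
    if (o.code == 2) {
      while (o.ref_pos > lower &&
             S[o.ref_pos - 1] == S[o.ref_pos + o.len - 1]) {
        o.ref_pos -= 1;
      }
    } else {
      while (o.ref_pos > lower && S[o.ref_pos - 1] == o.seq[o.len - 1]) {
        o.seq.insert(0, 1, S[o.ref_pos - 1]);
        o.seq.erase(o.seq.size() - 1);
        o.ref_pos -= 1;
      }
    }
  }
  out.mapped = true;
  out.ref_start = p;
  out.ref_end = p + jbest;
  out.n_mismatch = nmm;
  out.ops = ops;
}

// align one read against S (single orientation); fast path for
// substitution-only reads
static bool align_oriented(const std::string& r, const std::string& S,
                           int p, int fast_max_mm, Aln& out) {
  const int m = (int)r.size(), L = (int)S.size();
  if (p + m <= L) {
    int mm = 0;
    for (int i = 0; i < m && mm <= fast_max_mm; ++i)
      if (r[i] != S[p + i]) ++mm;
    if (mm <= fast_max_mm) {
      out.mapped = true;
      out.ref_start = p;
      out.ref_end = p + m;
      out.n_mismatch = mm;
      out.ops.clear();
      return true;
    }
  }
  dp_align(r, S, p, out);
  return true;
}

// [[Rcpp::export(name = ".alignReadsCpp")]]
List alignReadsCpp(CharacterVector reads, std::string ref,
                   int anchor_len = 20, int anchor_max_mm = 1,
                   int fast_max_mm = 2) {
  const std::string rc_ref = revcomp(ref);
  const int L = (int)ref.size();
  const int n = reads.size();
  List res(n);
  for (int q = 0; q < n; ++q) {
    std::string r = as<std::string>(reads[q]);
    Aln aln;
    if ((int)r.size() < anchor_len) {
      res[q] = List::create(_["mapped"] = false,
                            _["reason"] = "read shorter than anchor");
      continue;
    }
    std::string anchor = r.substr(0, anchor_len);
    std::vector<std::pair<int,int> > hf, hr;
    anchor_hits(ref, anchor, anchor_max_mm, hf);
    anchor_hits(rc_ref, anchor, anchor_max_mm, hr);
    // unique best hit over both orientations
    int best_mm = INT_MAX;
    for (size_t i = 0; i < hf.size(); ++i) best_mm = std::min(best_mm, hf[i].second);
    for (size_t i = 0; i < hr.size(); ++i) best_mm = std::min(best_mm, hr[i].second);
    int cnt = 0, pos = -1;
    char strand = '+';
    for (size_t i = 0; i < hf.size(); ++i)
      if (hf[i].second == best_mm) { ++cnt; pos = hf[i].first; strand = '+'; }
    for (size_t i = 0; i < hr.size(); ++i)
      if (hr[i].second == best_mm) { ++cnt; pos = hr[i].first; strand = '-'; }
    if (best_mm == INT_MAX) {
      res[q] = List::create(_["mapped"] = false,
                            _["reason"] = "anchor not found");
      continue;
    }
    if (cnt > 1) {
      res[q] = List::create(_["mapped"] = false,
                            _["reason"] = "ambiguous anchor");
      continue;
    }
    const std::string& S = (strand == '+') ? ref : rc_ref;
    align_oriented(r, S, pos, fast_max_mm, aln);
    aln.strand = strand;
    // map to forward coordinates
    int fs = aln.ref_start, fe = aln.ref_end;
    if (strand == '-') { fs = L - aln.ref_end; fe = L - aln.ref_start; }
    const int k = (int)aln.ops.size();
    IntegerMatrix ops(k, 3);
    CharacterVector insSeq(k);
    for (int t = 0; t < k; ++t) {
      const Op& o = aln.ops[t];
      int rp = o.ref_pos, re = o.ref_pos + (o.code == 2 ? o.len : 0);
      if (strand == '-') {
        int nrp = L - re, nre = L - rp;
        rp = nrp; re = nre;
      }
      ops(t, 0) = o.code;
      ops(t, 1) = rp;
      ops(t, 2) = o.len;
      insSeq[t] = (o.code == 1)
        ? (strand == '-' ? revcomp(o.seq) : o.seq)
        : "";
    }
    colnames(ops) = CharacterVector::create("code", "refStart", "len");
    res[q] = List::create(
      _["mapped"] = true,
      _["strand"] = std::string(1, strand),
      _["refStart"] = fs,
      _["refEnd"] = fe,
      _["nMismatch"] = aln.n_mismatch,
      _["ops"] = ops,
      _["insSeq"] = insSeq);
  }
  return res;
}
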