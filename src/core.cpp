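#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <cctype>
#include <cmath>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Genetic code and translation
// ---------------------------------------------------------------------------

static inline int base_idx(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': case 'U': case 'u': return 3;
  default: return -1;
  }
}

// codon table indexed 16*b1 + 4*b2 + b3 (TCAG order not used; ACGT order)
static const char CODON_TABLE[65] =
  // AAA AAC AAG AAT  ACA ACC ACG ACT  AGA AGC AGG AGT  ATA ATC ATG ATT
  "KNKN" "TTTT" "RSRS" "IIMI"
  // CAA CAC CAG CAT  CCA CCC CCG CCT  CGA CGC CGG CGT  CTA CTC CTG CTT
  "QHQH" "PPPP" "RRRR" "LLLL"
  // GAA GAC GAG GAT  GCA GCC GCG GCT  GGA GGC GGG GGT  GTA GTC GTG GTT
  "EDED" "AAAA" "GGGG" "VVVV"
  // TAA TAC TAG TAT  TCA TCC TCG TCT  TGA TGC TGG TGT  TTA TTC TTG TTT
  "*Y*Y" "SSSS" "*CWC" "LFLF";

static inline char translate_codon(const char *c) {
  int b1 = base_idx(c[0]), b2 = base_idx(c[1]), b3 = base_idx(c[2]);
  if (b1 < 0 || b2 < 0 || b3 < 0) return 'X';
  return CODON_TABLE[16 * b1 + 4 * b2 + b3];
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C';
  case 'T': return 'A'; case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a'; case 'N': return 'N';
  case 'n': return 'n';
  default: return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp_base(c);
  return r;
}

static std::string translate_offset(const std::string &nt, int offset) {
  int n = (int)nt.size();
  int naa = (n - offset) / 3;
  if (naa < 0) naa = 0;
  std::string aa(naa, 'X');
  for (int i = 0; i < naa; ++i) aa[i] = translate_codon(nt.c_str() + offset + 3 * i);
  return aa;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}

// six frames: +1,+2,+3,-1,-2,-3 (columns)
// [[Rcpp::export]]
CharacterMatrix cpp_translate_frames(CharacterVector seqs) {
  int n = seqs.size();
  CharacterMatrix out(n, 6);
  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(seqs[i]);
    std::string rev = revcomp(fwd);
    for (int f = 0; f < 3; ++f) {
      out(i, f) = translate_offset(fwd, f);
      out(i, 3 + f) = translate_offset(rev, f);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Scoring machinery
// ---------------------------------------------------------------------------

struct Scoring {
  std::vector<int> sub;   // nalpha x nalpha
  int nalpha;
  int idx[128];
  int gap_open;           // cost of opening a gap (a gap of length L costs open + L*ext)
  int gap_ext;
  void init(const IntegerMatrix &mat, const std::string &alpha, int go, int ge) {
    gap_open = go;
    gap_ext = ge;
    nalpha = (int)alpha.size();
    sub.assign(nalpha * nalpha, 0);
    for (int i = 0; i < nalpha; ++i)
      for (int j = 0; j < nalpha; ++j) sub[i * nalpha + j] = mat(i, j);
    for (int i = 0; i < 128; ++i) idx[i] = -1;
    for (int i = 0; i < nalpha; ++i) {
      idx[(unsigned char)alpha[i]] = i;
      idx[(unsigned char)tolower(alpha[i])] = i;
    }
  }
  inline int code(char c) const {
    int v = idx[(unsigned char)c];
    if (v < 0) v = idx[(unsigned char)'X'];
    return v;
  }
  inline int score(int a, int b) const { return sub[a * nalpha + b]; }
};

static std::vector<int> encode_seq(const std::string &s, const Scoring &sc) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = sc.code(s[i]);
  return v;
}

struct AlnResult {
  int score = 0;
  int matches = 0;
  int columns = 0;
  int q_start = 0, q_end = 0, s_start = 0, s_end = 0; // 0-based half-open
  bool found = false;
  double identity() const { return columns > 0 ? 100.0 * matches / columns : 0.0; }
};

static const int NEG_INF = -1000000000;

// Affine-gap alignment with traceback. local=true: Smith-Waterman (returns
// best-scoring local alignment, found=false when optimal score <= 0);
// local=false: Needleman-Wunsch over the full lengths.
// Direction codes per matrix cell: which matrix the predecessor came from.
static AlnResult align_pair(const std::vector<int> &q, const std::vector<int> &s,
                            const Scoring &sc, bool local) {
  int n = (int)q.size(), m = (int)s.size();
  AlnResult res;
  int go = sc.gap_open, ge = sc.gap_ext;
  int open_cost = go + ge;

  std::vector<int> M((n + 1) * (m + 1), NEG_INF);
  std::vector<int> Ix((n + 1) * (m + 1), NEG_INF); // gap in subject (consumes query)
  std::vector<int> Iy((n + 1) * (m + 1), NEG_INF); // gap in query (consumes subject)
  // traceback: 2 bits per matrix; tbM: 0=M,1=Ix,2=Iy,3=start; tbIx: 0=from M,1=from Ix; tbIy likewise
  std::vector<uint8_t> tb((n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0;
  if (!local) {
    for (int i = 1; i <= n; ++i) {
      Ix[at(i, 0)] = -(go + i * ge);
      tb[at(i, 0)] |= (i == 1 ? 0 : 1) << 2;
    }
    for (int j = 1; j <= m; ++j) {
      Iy[at(0, j)] = -(go + j * ge);
      tb[at(0, j)] |= (j == 1 ? 0 : 1) << 4;
    }
  } else {
    for (int i = 1; i <= n; ++i) M[at(i, 0)] = 0;
    for (int j = 1; j <= m; ++j) M[at(0, j)] = 0;
  }

  int best = 0, bi = 0, bj = 0;
  bool any = false;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int d = at(i, j), dd = at(i - 1, j - 1), du = at(i - 1, j), dl = at(i, j - 1);
      // Ix: query residue i aligned to gap
      int fromM = (M[du] == NEG_INF) ? NEG_INF : M[du] - open_cost;
      int fromIx = (Ix[du] == NEG_INF) ? NEG_INF : Ix[du] - ge;
      if (fromM >= fromIx) { Ix[d] = fromM; }
      else { Ix[d] = fromIx; tb[d] |= 1 << 2; }
      // Iy
      int gM = (M[dl] == NEG_INF) ? NEG_INF : M[dl] - open_cost;
      int gIy = (Iy[dl] == NEG_INF) ? NEG_INF : Iy[dl] - ge;
      if (gM >= gIy) { Iy[d] = gM; }
      else { Iy[d] = gIy; tb[d] |= 1 << 4; }
      // M
      int sc_ij = sc.score(q[i - 1], s[j - 1]);
      int mM = M[dd], mIx = Ix[dd], mIy = Iy[dd];
      int bestprev = mM; uint8_t code = 0;
      if (mIx > bestprev) { bestprev = mIx; code = 1; }
      if (mIy > bestprev) { bestprev = mIy; code = 2; }
      int val = (bestprev == NEG_INF) ? NEG_INF : bestprev + sc_ij;
      if (local && val < 0) { val = 0; code = 3; } // empty-alignment restart
      M[d] = val;
      tb[d] |= code;
      if (local && val > best) { best = val; bi = i; bj = j; any = true; }
    }
  }

  int mat_sel; // 0=M,1=Ix,2=Iy
  if (local) {
    if (!any || best <= 0) { res.found = false; res.score = 0; return res; }
    res.score = best; mat_sel = 0;
  } else {
    int d = at(n, m);
    int vM = M[d], vIx = Ix[d], vIy = Iy[d];
    res.score = vM; mat_sel = 0;
    if (vIx > res.score) { res.score = vIx; mat_sel = 1; }
    if (vIy > res.score) { res.score = vIy; mat_sel = 2; }
    bi = n; bj = m;
  }
  res.found = true;

  // traceback (gap columns count toward alignment columns, not matches)
  int i = bi, j = bj;
  res.q_end = i; res.s_end = j;
  while (!(i == 0 && j == 0)) {
    if (local && mat_sel == 0 && M[at(i, j)] == 0) break; // local alignment start
    if (mat_sel == 0) {
      if (i == 0 || j == 0) break; // safety; unreachable on valid paths
      res.columns++;
      if (q[i - 1] == s[j - 1]) res.matches++;
      uint8_t code = tb[at(i, j)] & 3;
      --i; --j;
      mat_sel = (code == 3) ? 0 : code; // code 3 only on zero cells (local)
    } else if (mat_sel == 1) {
      res.columns++;
      uint8_t code = (tb[at(i, j)] >> 2) & 1;
      --i;
      mat_sel = code ? 1 : 0;
    } else {
      res.columns++;
      uint8_t code = (tb[at(i, j)] >> 4) & 1;
      --j;
      mat_sel = code ? 2 : 0;
    }
  }
  res.q_start = i; res.s_start = j;
  return res;
}

// [[Rcpp::export]]
List cpp_align(std::string q, std::string s, IntegerMatrix submat,
               std::string alphabet, int gap_open, int gap_ext, bool local) {
  Scoring sc; sc.init(submat, alphabet, gap_open, gap_ext);
  std::vector<int> qe = encode_seq(q, sc), se = encode_seq(s, sc);
  AlnResult r = align_pair(qe, se, sc, local);
  return List::create(
    _["found"] = r.found, _["score"] = r.score, _["matches"] = r.matches,
    _["columns"] = r.columns, _["identity_pct"] = r.identity(),
    _["q_start"] = r.q_start, _["q_end"] = r.q_end,
    _["s_start"] = r.s_start, _["s_end"] = r.s_end);
}

// ---------------------------------------------------------------------------
// k-mer seeded translated read classification
// ---------------------------------------------------------------------------

static inline int aa20(char c) {
  static const char *AA = "ACDEFGHIKLMNPQRSTVWY";
  switch (toupper(c)) {
  case 'A': return 0; case 'C': return 1; case 'D': return 2; case 'E': return 3;
  case 'F': return 4; case 'G': return 5; case 'H': return 6; case 'I': return 7;
  case 'K': return 8; case 'L': return 9; case 'M': return 10; case 'N': return 11;
  case 'P': return 12; case 'Q': return 13; case 'R': return 14; case 'S': return 15;
  case 'T': return 16; case 'V': return 17; case 'W': return 18; case 'Y': return 19;
  default: (void)AA; return -1;
  }
}

struct KmerIndex {
  int k;
  // kmer -> flat (seq index, kmer start position in seq) pairs
  std::unordered_map<uint32_t, std::vector<int>> postings;
  std::vector<uint8_t> present; // bitmap over 2^(5k) (k<=5) or hash-only for larger k
  bool use_bitmap;

  void build(const std::vector<std::string> &seqs, int k_) {
    k = k_;
    use_bitmap = (5 * k <= 25);
    if (use_bitmap) present.assign((size_t)1 << (5 * k), 0);
    for (int si = 0; si < (int)seqs.size(); ++si) {
      const std::string &s = seqs[si];
      if ((int)s.size() < k) continue;
      uint32_t code = 0; int run = 0;
      for (size_t i = 0; i < s.size(); ++i) {
        int a = aa20(s[i]);
        if (a < 0) { run = 0; code = 0; continue; }
        code = ((code << 5) | (uint32_t)a) & (((uint32_t)1 << (5 * k)) - 1);
        if (++run >= k) {
          auto &v = postings[code];
          v.push_back(si);
          v.push_back((int)i - k + 1);
          if (use_bitmap) present[code] = 1;
        }
      }
    }
  }
};

struct BestHit {
  bool found = false;
  int subject = -1;
  double identity = 0.0;
  int score = 0;
  double evalue = R_PosInf;
  int frame = 0; // +-1..3
  // better(): ranking is identity desc, then raw score desc, then subject id asc
};

static bool hit_better(const BestHit &a, const BestHit &b,
                       const std::vector<std::string> &ids) {
  if (a.identity != b.identity) return a.identity > b.identity;
  if (a.score != b.score) return a.score > b.score;
  if (a.subject != b.subject) return ids[a.subject] < ids[b.subject];
  return false;
}

struct DbSet {
  std::vector<std::string> seqs, ids;
  std::vector<std::vector<int>> enc;
  double total_residues = 0;
  KmerIndex index;
  void build(CharacterVector s, CharacterVector id, const Scoring &sc, int k) {
    for (int i = 0; i < s.size(); ++i) {
      seqs.push_back(as<std::string>(s[i]));
      ids.push_back(as<std::string>(id[i]));
      enc.push_back(encode_seq(seqs.back(), sc));
      total_residues += seqs.back().size();
    }
    if (k > 0) index.build(seqs, k);
  }
};

// scan one peptide segment against one database, updating best.
// With seeding (k > 0), the local alignment for each candidate subject is
// computed on a subject window spanning the seed diagonals padded by the
// segment length plus a gap allowance, so scores equal the full-subject
// optimum whenever the optimal alignment involves a seed region.
static void scan_segment(const std::string &seg, const std::vector<int> &seg_enc,
                         DbSet &db, const Scoring &sc, int k, int frame,
                         double K, double lam, double db_residues,
                         double evalue_cutoff, double floor_pct, BestHit &best,
                         std::vector<int> &seen, int stamp) {
  const int GAP_PAD = 25;
  int L = (int)seg.size();
  std::vector<int> cands;
  std::vector<int> dmin, dmax; // subject-position bounds of seed hits per candidate
  if (k > 0) {
    if (L < k) return;
    uint32_t mask = (((uint32_t)1 << (5 * k)) - 1);
    uint32_t code = 0; int run = 0;
    for (int i = 0; i < L; ++i) {
      int a = aa20(seg[i]);
      if (a < 0) { run = 0; code = 0; continue; }
      code = ((code << 5) | (uint32_t)a) & mask;
      if (++run >= k) {
        if (db.index.use_bitmap && !db.index.present[code]) continue;
        auto it = db.index.postings.find(code);
        if (it == db.index.postings.end()) continue;
        for (size_t pi = 0; pi < it->second.size(); pi += 2) {
          int si = it->second[pi];
          int spos = it->second[pi + 1];
          if (seen[si] != stamp) {
            seen[si] = stamp;
            cands.push_back(si);
            dmin.push_back(spos);
            dmax.push_back(spos);
          } else {
            // locate the candidate slot (small candidate lists; linear scan)
            for (size_t c = 0; c < cands.size(); ++c) {
              if (cands[c] == si) {
                if (spos < dmin[c]) dmin[c] = spos;
                if (spos > dmax[c]) dmax[c] = spos;
                break;
              }
            }
          }
        }
      }
    }
  } else {
    for (int si = 0; si < (int)db.seqs.size(); ++si) {
      cands.push_back(si);
      dmin.push_back(0);
      dmax.push_back((int)db.seqs[si].size());
    }
  }
  for (size_t c = 0; c < cands.size(); ++c) {
    int si = cands[c];
    const std::vector<int> &subj = db.enc[si];
    int slen = (int)subj.size();
    int lo = 0, hi = slen;
    if (k > 0) {
      lo = std::max(0, dmin[c] - L - GAP_PAD);
      hi = std::min(slen, dmax[c] + k + L + GAP_PAD);
    }
    AlnResult r;
    if (lo == 0 && hi == slen) {
      r = align_pair(seg_enc, subj, sc, true);
    } else {
      std::vector<int> window(subj.begin() + lo, subj.begin() + hi);
      r = align_pair(seg_enc, window, sc, true);
      r.s_start += lo; r.s_end += lo;
    }
    if (!r.found) continue;
    double E = K * (double)L * db_residues * std::exp(-lam * (double)r.score);
    double id = r.identity();
    if (E >= evalue_cutoff || id <= floor_pct) continue;
    BestHit h; h.found = true; h.subject = si; h.identity = id;
    h.score = r.score; h.evalue = E; h.frame = frame;
    if (!best.found || hit_better(h, best, db.ids)) best = h;
  }
}

// split a translated frame at '*' into segments; scan each
static void scan_frame(const std::string &aa, int frame, DbSet &db, const Scoring &sc,
                       int k, double K, double lam, double db_residues,
                       double evalue_cutoff, double floor_pct, BestHit &best,
                       std::vector<int> &seen, int &stamp) {
  size_t pos = 0;
  while (pos < aa.size()) {
    size_t stop = aa.find('*', pos);
    size_t end = (stop == std::string::npos) ? aa.size() : stop;
    if (end > pos) {
      std::string seg = aa.substr(pos, end - pos);
      std::vector<int> seg_enc = encode_seq(seg, sc);
      ++stamp;
      scan_segment(seg, seg_enc, db, sc, k, frame, K, lam, db_residues,
                   evalue_cutoff, floor_pct, best, seen, stamp);
    }
    if (stop == std::string::npos) break;
    pos = stop + 1;
  }
}

// [[Rcpp::export]]
DataFrame cpp_classify_reads(CharacterVector reads, CharacterVector read_ids,
                             CharacterVector marker_seqs, CharacterVector marker_ids,
                             CharacterVector decoy_seqs, CharacterVector decoy_ids,
                             IntegerMatrix submat, std::string alphabet,
                             int gap_open, int gap_ext, int k,
                             double K, double lam, double evalue_cutoff,
                             double floor_pct, double pos_cutoff_pct) {
  Scoring sc; sc.init(submat, alphabet, gap_open, gap_ext);
  DbSet mdb, ddb;
  mdb.build(marker_seqs, marker_ids, sc, k);
  ddb.build(decoy_seqs, decoy_ids, sc, k);

  int n = reads.size();
  int min_len = std::max(3, 3 * std::max(k, 1));
  CharacterVector o_mid(n), o_did(n);
  NumericVector o_mident(n, NA_REAL), o_meval(n, NA_REAL);
  NumericVector o_dident(n, NA_REAL), o_deval(n, NA_REAL);
  IntegerVector o_mscore(n, NA_INTEGER), o_mframe(n, NA_INTEGER);
  IntegerVector o_dscore(n, NA_INTEGER), o_dframe(n, NA_INTEGER);
  LogicalVector o_pos(n), o_short(n);

  std::vector<int> seen_m(mdb.seqs.size(), -1), seen_d(ddb.seqs.size(), -1);
  int stamp = 0;
  const int FRAME_LAB[6] = {1, 2, 3, -1, -2, -3};
  // E-values use the combined database length for both searches, so the
  // competitive marker-vs-decoy comparison is symmetric under the cutoff
  double db_residues = mdb.total_residues + ddb.total_residues;

  for (int ri = 0; ri < n; ++ri) {
    std::string rd = as<std::string>(reads[ri]);
    o_mid[ri] = NA_STRING; o_did[ri] = NA_STRING;
    if ((int)rd.size() < min_len) { o_short[ri] = true; o_pos[ri] = false; continue; }
    std::string rc = revcomp(rd);
    BestHit bm, bd;
    for (int f = 0; f < 6; ++f) {
      std::string aa = (f < 3) ? translate_offset(rd, f) : translate_offset(rc, f - 3);
      scan_frame(aa, FRAME_LAB[f], mdb, sc, k, K, lam, db_residues,
                 evalue_cutoff, floor_pct, bm, seen_m, stamp);
      scan_frame(aa, FRAME_LAB[f], ddb, sc, k, K, lam, db_residues,
                 evalue_cutoff, floor_pct, bd, seen_d, stamp);
    }
    if (bm.found) {
      o_mid[ri] = mdb.ids[bm.subject]; o_mident[ri] = bm.identity;
      o_meval[ri] = bm.evalue; o_mscore[ri] = bm.score; o_mframe[ri] = bm.frame;
    }
    if (bd.found) {
      o_did[ri] = ddb.ids[bd.subject]; o_dident[ri] = bd.identity;
      o_deval[ri] = bd.evalue; o_dscore[ri] = bd.score; o_dframe[ri] = bd.frame;
    }
    o_pos[ri] = bm.found && bm.identity > pos_cutoff_pct &&
      (!bd.found || bm.identity >= bd.identity);
  }

  return DataFrame::create(
    _["read_id"] = read_ids, _["too_short"] = o_short,
    _["marker_id"] = o_mid, _["marker_identity"] = o_mident,
    _["marker_score"] = o_mscore, _["marker_evalue"] = o_meval,
    _["marker_frame"] = o_mframe,
    _["decoy_id"] = o_did, _["decoy_identity"] = o_dident,
    _["decoy_score"] = o_dscore, _["decoy_evalue"] = o_deval,
    _["decoy_frame"] = o_dframe,
    _["positive"] = o_pos, _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// tblastn-style contig screening: protein queries vs six translated frames
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_screen_contigs(CharacterVector contigs, CharacterVector contig_ids,
                             CharacterVector queries, CharacterVector query_ids,
                             IntegerMatrix submat, std::string alphabet,
                             int gap_open, int gap_ext, int k,
                             double K, double lam, double evalue_cutoff,
                             double floor_pct) {
  Scoring sc; sc.init(submat, alphabet, gap_open, gap_ext);
  // index the queries (small database); contig segments supply the k-mers
  DbSet qdb;
  qdb.build(queries, query_ids, sc, k);

  std::vector<std::string> r_contig, r_query;
  std::vector<int> r_frame, r_start, r_end, r_score;
  std::vector<double> r_ident, r_eval;
  std::vector<bool> r_endflag;

  std::vector<int> seen(qdb.seqs.size(), -1);
  int stamp = 0;
  const int FRAME_LAB[6] = {1, 2, 3, -1, -2, -3};

  for (int ci = 0; ci < contigs.size(); ++ci) {
    std::string fwd = as<std::string>(contigs[ci]);
    std::string rev = revcomp(fwd);
    int L = (int)fwd.size();
    for (int f = 0; f < 6; ++f) {
      int off = f % 3;
      std::string aa = (f < 3) ? translate_offset(fwd, off) : translate_offset(rev, off);
      // stop-delimited segments with their aa offset within the frame
      size_t pos = 0;
      while (pos < aa.size()) {
        size_t stop = aa.find('*', pos);
        size_t end = (stop == std::string::npos) ? aa.size() : stop;
        if (end > pos) {
          std::string seg = aa.substr(pos, end - pos);
          std::vector<int> seg_enc = encode_seq(seg, sc);
          // candidates: queries sharing a k-mer with this segment
          std::vector<int> cands;
          ++stamp;
          if (k > 0) {
            uint32_t mask = (((uint32_t)1 << (5 * k)) - 1);
            uint32_t code = 0; int run = 0;
            for (size_t i = 0; i < seg.size(); ++i) {
              int a = aa20(seg[i]);
              if (a < 0) { run = 0; code = 0; continue; }
              code = ((code << 5) | (uint32_t)a) & mask;
              if (++run >= k) {
                if (qdb.index.use_bitmap && !qdb.index.present[code]) continue;
                auto it = qdb.index.postings.find(code);
                if (it == qdb.index.postings.end()) continue;
                for (size_t pi = 0; pi < it->second.size(); pi += 2) {
                  int si = it->second[pi];
                  if (seen[si] != stamp) { seen[si] = stamp; cands.push_back(si); }
                }
              }
            }
          } else {
            for (int si = 0; si < (int)qdb.seqs.size(); ++si) cands.push_back(si);
          }
          for (int qi : cands) {
            // query = protein, subject = translated segment
            AlnResult r = align_pair(qdb.enc[qi], seg_enc, sc, true);
            if (!r.found) continue;
            double E = K * (double)qdb.seqs[qi].size() * (double)L *
              std::exp(-lam * (double)r.score);
            double id = r.identity();
            if (E >= evalue_cutoff || id <= floor_pct) continue;
            // subject span in segment aa coords -> frame aa coords -> nt
            int a0 = (int)pos;
            int aa_s = a0 + r.s_start, aa_e = a0 + r.s_end;
            int nt_s, nt_e;
            if (f < 3) {
              nt_s = off + 3 * aa_s;
              nt_e = off + 3 * aa_e;
            } else {
              nt_s = L - (off + 3 * aa_e);
              nt_e = L - (off + 3 * aa_s);
            }
            bool at_end = (nt_s < 3) || ((L - nt_e) < 3);
            r_contig.push_back(as<std::string>(contig_ids[ci]));
            r_query.push_back(qdb.ids[qi]);
            r_frame.push_back(FRAME_LAB[f]);
            r_start.push_back(nt_s); r_end.push_back(nt_e);
            r_score.push_back(r.score); r_ident.push_back(id); r_eval.push_back(E);
            r_endflag.push_back(at_end);
          }
        }
        if (stop == std::string::npos) break;
        pos = stop + 1;
      }
    }
  }

  return DataFrame::create(
    _["contig_id"] = r_contig, _["query_id"] = r_query, _["frame"] = r_frame,
    _["nt_start"] = r_start, _["nt_end"] = r_end,
    _["identity_pct"] = r_ident, _["raw_score"] = r_score, _["evalue"] = r_eval,
    _["at_contig_end"] = r_endflag, _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Simulation primitives (use R's RNG: reproducible under set.seed)
// ---------------------------------------------------------------------------

static const char *SENSE_CODONS[61] = {
  "AAA","AAC","AAG","AAT","ACA","ACC","ACG","ACT","AGA","AGC","AGG","AGT",
  "ATA","ATC","ATG","ATT","CAA","CAC","CAG","CAT","CCA","CCC","CCG","CCT",
  "CGA","CGC","CGG","CGT","CTA","CTC","CTG","CTT","GAA","GAC","GAG","GAT",
  "GCA","GCC","GCG","GCT","GGA","GGC","GGG","GGT","GTA","GTC","GTG","GTT",
  "TAC","TAT","TCA","TCC","TCG","TCT","TGC","TGG","TGT","TTA","TTC","TTG","TTT"};

// random sense-codon background sequences (one string per genome)
// [[Rcpp::export]]
CharacterVector cpp_random_codons(int n_seqs, int n_codons) {
  CharacterVector out(n_seqs);
  std::string buf;
  for (int g = 0; g < n_seqs; ++g) {
    buf.clear();
    buf.reserve(3 * n_codons);
    for (int i = 0; i < n_codons; ++i) {
      int c = (int)(unif_rand() * 61.0);
      if (c >= 61) c = 60;
      buf.append(SENSE_CODONS[c], 3);
    }
    out[g] = buf;
  }
  return out;
}

// sample reads from weighted sources. Each source row: genome index (0-based),
// start_lo..start_hi (inclusive 0-based start positions), weight.
// [[Rcpp::export]]
List cpp_sample_reads(CharacterVector genomes, IntegerVector src_genome,
                      IntegerVector src_lo, IntegerVector src_hi,
                      NumericVector src_weight, int n_reads, int read_len,
                      double error_rate) {
  int ns = src_genome.size();
  std::vector<double> cum(ns);
  double tot = 0;
  for (int i = 0; i < ns; ++i) { tot += src_weight[i]; cum[i] = tot; }
  if (tot <= 0) stop("total source weight must be positive");

  // cache genome strings
  int ng = genomes.size();
  std::vector<const char *> gptr(ng);
  std::vector<int> glen(ng);
  for (int g = 0; g < ng; ++g) {
    gptr[g] = CHAR(STRING_ELT(genomes, g));
    glen[g] = LENGTH(STRING_ELT(genomes, g));
    if (glen[g] < read_len) stop("read length exceeds a genome length");
  }

  CharacterVector reads(n_reads);
  IntegerVector r_genome(n_reads), r_start(n_reads);
  CharacterVector r_strand(n_reads);
  std::string buf(read_len, 'N');
  const char BASES[4] = {'A', 'C', 'G', 'T'};

  for (int r = 0; r < n_reads; ++r) {
    double u = unif_rand() * tot;
    int s = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (s >= ns) s = ns - 1;
    int g = src_genome[s];
    int lo = src_lo[s], hi = src_hi[s];
    if (hi > glen[g] - read_len) hi = glen[g] - read_len;
    if (lo < 0) lo = 0;
    if (hi < lo) hi = lo;
    int start = lo + (int)(unif_rand() * (double)(hi - lo + 1));
    if (start > hi) start = hi;
    std::memcpy(&buf[0], gptr[g] + start, read_len);
    bool rev = unif_rand() < 0.5;
    if (rev) {
      std::reverse(buf.begin(), buf.end());
      for (auto &c : buf) c = comp_base(c);
    }
    if (error_rate > 0) {
      int nerr = (int)R::rbinom((double)read_len, error_rate);
      for (int e = 0; e < nerr; ++e) {
        int p = (int)(unif_rand() * read_len);
        if (p >= read_len) p = read_len - 1;
        char old = buf[p];
        char nb;
        do { nb = BASES[(int)(unif_rand() * 4) & 3]; } while (nb == old);
        buf[p] = nb;
      }
    }
    reads[r] = buf;
    r_genome[r] = g + 1; // 1-based for R
    r_start[r] = start;  // 0-based
    r_strand[r] = rev ? "-" : "+";
  }
  return List::create(_["read"] = reads, _["genome"] = r_genome,
                      _["start"] = r_start, _["strand"] = r_strand);
}
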