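#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <string>
using namespace Rcpp;

// A=0 C=1 G=2 T=3, everything else (N, IUPAC, gap) = 4 and never matches.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g'; case 'g': return 'c'; case 't': return 'a';
  case 'R': return 'Y'; case 'Y': return 'R'; case 'S': return 'S'; case 'W': return 'W';
  case 'K': return 'M'; case 'M': return 'K'; case 'B': return 'V'; case 'V': return 'B';
  case 'D': return 'H'; case 'H': return 'D'; case '-': return '-';
  default: return 'N';
  }
}

// [[Rcpp::export(rng = false)]]
std::string revcomp_cpp(std::string s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) out[i] = comp_base(out[i]);
  return out;
}

// For every candidate overlap length o = 1..min(len1, len2), count informative
// aligned positions (both bases in ACGT) and matches among them, aligning the
// last o bases of s1 against the first o bases of s2 (s2 already in s1's
// orientation).  Columns: m (matches), n (informative positions).
// [[Rcpp::export(rng = false)]]
IntegerMatrix overlap_scan_cpp(std::string s1, std::string s2) {
  int l1 = s1.size(), l2 = s2.size();
  int L = std::min(l1, l2);
  IntegerMatrix out(L, 2);
  for (int o = 1; o <= L; o++) {
    int m = 0, n = 0;
    const char *a = s1.c_str() + (l1 - o);
    const char *b = s2.c_str();
    for (int j = 0; j < o; j++) {
      int ca = base_code(a[j]), cb = base_code(b[j]);
      if (ca < 4 && cb < 4) { n++; if (ca == cb) m++; }
    }
    out(o - 1, 0) = m;
    out(o - 1, 1) = n;
  }
  return out;
}

// Batch read-pair merging: for every pair, scan all candidate overlap
// lengths, compute the binomial upper-tail probability of the observed match
// count (null p = 1/4, N positions uninformative), keep the smallest
// probability (ties -> longest overlap) and merge when it is below alpha.
// Overlap consensus: agreeing bases get min(q1 + q2, 93); disagreements take
// the higher-quality base (ties -> mate 1) with quality |q1 - q2|.
// [[Rcpp::export(rng = false)]]
List merge_pairs_cpp(CharacterVector s1v, CharacterVector q1v,
                     CharacterVector s2v, CharacterVector q2v, double alpha) {
  int n = s1v.size();
  CharacterVector status(n), mseq(n), mqual(n);
  IntegerVector ovl(n);
  NumericVector pval(n);
  for (int r = 0; r < n; r++) {
    std::string s1 = as<std::string>(s1v[r]);
    std::string s2 = revcomp_cpp(as<std::string>(s2v[r]));
    std::string q1 = as<std::string>(q1v[r]);
    std::string q2 = as<std::string>(q2v[r]);
    std::reverse(q2.begin(), q2.end());
    int l1 = s1.size(), l2 = s2.size();
    int L = std::min(l1, l2);
    double best_p = 2.0;
    int best_o = 0;
    for (int o = 1; o <= L; o++) {
      int m = 0, ni = 0;
      const char *a = s1.c_str() + (l1 - o);
      const char *b = s2.c_str();
      for (int j = 0; j < o; j++) {
        int ca = base_code(a[j]), cb = base_code(b[j]);
        if (ca < 4 && cb < 4) { ni++; if (ca == cb) m++; }
      }
      double p = (ni == 0) ? 1.0
        : R::pbinom((double)(m - 1), (double)ni, 0.25, 0, 0);
      if (p <= best_p) { best_p = p; best_o = o; }
    }
    ovl[r] = best_o;
    pval[r] = best_p;
    if (best_p < alpha) {
      status[r] = "merged";
      int o = best_o;
      std::string seq = s1.substr(0, l1 - o);
      std::string qual = q1.substr(0, l1 - o);
      for (int j = 0; j < o; j++) {
        char ca = s1[l1 - o + j], cb = s2[j];
        int qa = (int)q1[l1 - o + j] - 33, qb = (int)q2[j] - 33;
        if (base_code(ca) == base_code(cb) && base_code(ca) < 4) {
          seq.push_back(ca);
          qual.push_back((char)(std::min(qa + qb, 93) + 33));
        } else {
          seq.push_back(qa >= qb ? ca : cb);
          qual.push_back((char)(std::abs(qa - qb) + 33));
        }
      }
      seq += s2.substr(o);
      qual += q2.substr(o);
      mseq[r] = seq;
      mqual[r] = qual;
    } else {
      status[r] = "unmerged";
      mseq[r] = NA_STRING;
      mqual[r] = NA_STRING;
    }
  }
  return List::create(_["status"] = status, _["overlap_len"] = ovl,
                      _["p_value"] = pval, _["merged_seq"] = mseq,
                      _["merged_qual"] = mqual);
}

struct Placement {
  bool pass = false;
  int offset = 0;
  int seed = 0;
  int seed_pos = -1;   // consensus coordinate of the best seed window start
  double identity = -1.0;
};

// Evaluate one ungapped diagonal of read against consensus: require a spaced
// seed window with >= seed_min care-position matches, then confirmation by the
// best window of confirm_window consecutive aligned positions (proportional
// rule on the full overlap when shorter than confirm_window but >= min_confirm_len).
static void eval_diag(const std::string &cons, const std::string &read, int d,
                      const std::vector<int> &care, int span, int seed_min,
                      int confirm_window, int confirm_min, int min_confirm_len,
                      Placement &best) {
  int Lc = cons.size(), Lr = read.size();
  int lo = std::max(0, -d);
  int hi = std::min(Lr, Lc - d);
  int ov = hi - lo;
  if (ov < span) return;
  std::vector<int> match(ov);
  for (int i = 0; i < ov; i++) {
    int ca = base_code(read[lo + i]), cb = base_code(cons[d + lo + i]);
    match[i] = (ca < 4 && ca == cb) ? 1 : 0;
  }
  int nc = care.size();
  int best_seed = 0, best_seed_w = 0;
  for (int w = 0; w + span <= ov; w++) {
    int s = 0;
    for (int j = 0; j < nc; j++) s += match[w + care[j]];
    if (s > best_seed) { best_seed = s; best_seed_w = w; }
    if (best_seed == nc) break;
  }
  if (best_seed < seed_min) return;
  bool ok = false;
  double ident = 0.0;
  if (ov >= confirm_window) {
    int s = 0;
    for (int i = 0; i < confirm_window; i++) s += match[i];
    int bestw = s;
    for (int i = confirm_window; i < ov; i++) {
      s += match[i] - match[i - confirm_window];
      if (s > bestw) bestw = s;
    }
    ok = bestw >= confirm_min;
    ident = (double)bestw / confirm_window;
  } else if (ov >= min_confirm_len) {
    int tot = 0;
    for (int i = 0; i < ov; i++) tot += match[i];
    ident = (double)tot / ov;
    ok = ident >= (double)confirm_min / (double)confirm_window;
  }
  if (!ok) return;
  if (!best.pass || ident > best.identity ||
      (ident == best.identity && best_seed > best.seed) ||
      (ident == best.identity && best_seed == best.seed && d < best.offset)) {
    best.pass = true;
    best.offset = d;
    best.identity = ident;
    best.seed = best_seed;
    best.seed_pos = d + lo + best_seed_w;
  }
}

// turn a sorted diagonal list into (diagonal, hits) candidates
static void count_diag_runs(std::vector<int> &diags, int min_hits,
                            std::vector<std::pair<int, int>> &out) {
  std::sort(diags.begin(), diags.end());
  size_t i = 0;
  while (i < diags.size()) {
    size_t j = i;
    while (j < diags.size() && diags[j] == diags[i]) j++;
    if ((int)(j - i) >= min_hits)
      out.push_back(std::make_pair(diags[i], (int)(j - i)));
    i = j;
  }
}

// Seed-and-confirm placement of reads on a consensus.  Candidate diagonals come
// from exact shared words of word_size (hash index of the consensus), computed
// for both orientations in a single rolling pass over each read; each candidate
// is scored with the spaced seed + confirmation rules and the best passing
// placement wins.  Returns per read: pass (0/1), orient (0 fwd / 1 revcomp),
// offset of read base 1 in consensus coordinates (0-based, may be negative),
// identity.
// [[Rcpp::export(rng = false)]]
List recruit_reads_cpp(std::string consensus, CharacterVector reads,
                       IntegerVector care0, int span, int seed_min,
                       int confirm_window, int confirm_min, int min_confirm_len,
                       int word_size, int max_diags) {
  int Lc = consensus.size();
  std::vector<int> care(care0.begin(), care0.end());
  uint32_t wmask = (word_size >= 16) ? 0xFFFFFFFFu : ((1u << (2 * word_size)) - 1u);
  int rc_shift = 2 * (word_size - 1);
  std::unordered_map<uint32_t, std::vector<int>> index;
  index.reserve(Lc > 0 ? 2 * Lc : 16);
  {
    uint32_t w = 0;
    int run = 0;
    for (int i = 0; i < Lc; i++) {
      int c = base_code(consensus[i]);
      if (c == 4) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint32_t)c) & wmask;
      run++;
      if (run >= word_size) index[w].push_back(i - word_size + 1);
    }
  }
  int n = reads.size();
  IntegerVector pass(n), orient(n), offset(n), seedpos(n);
  NumericVector identity(n);
  std::vector<int> dfwd, drev;
  std::vector<std::pair<int, int>> cand;
  for (int r = 0; r < n; r++) {
    const char *rd = CHAR(STRING_ELT(reads, r));
    int Lr = LENGTH(STRING_ELT(reads, r));
    dfwd.clear();
    drev.clear();
    // rolling words for the read and its reverse complement in one pass
    uint32_t w = 0, v = 0;
    int run = 0;
    for (int i = 0; i < Lr; i++) {
      int c = base_code(rd[i]);
      if (c == 4) { run = 0; w = 0; v = 0; continue; }
      w = ((w << 2) | (uint32_t)c) & wmask;
      v = (v >> 2) | ((uint32_t)(3 - c) << rc_shift);
      run++;
      if (run < word_size) continue;
      int rp = i - word_size + 1;               // word start in the read
      std::unordered_map<uint32_t, std::vector<int>>::iterator it = index.find(w);
      if (it != index.end())
        for (size_t q = 0; q < it->second.size(); ++q)
          dfwd.push_back(it->second[q] - rp);
      it = index.find(v);
      if (it != index.end()) {
        int rp_rc = Lr - word_size - rp;        // word start in the rc read
        for (size_t q = 0; q < it->second.size(); ++q)
          drev.push_back(it->second[q] - rp_rc);
      }
    }
    Placement best;
    int best_or = 0;
    std::string fwd_s, rev_s;
    for (int ori = 0; ori < 2; ori++) {
      std::vector<int> &dd = ori ? drev : dfwd;
      if (dd.empty()) continue;
      cand.clear();
      count_diag_runs(dd, 2, cand);
      if (cand.empty()) continue;
      std::sort(cand.begin(), cand.end(),
                [](const std::pair<int, int> &a, const std::pair<int, int> &b) {
                  if (a.second != b.second) return a.second > b.second;
                  return a.first < b.first;
                });
      const std::string &rds = ori
        ? (rev_s.empty() ? (rev_s = revcomp_cpp(std::string(rd, Lr))) : rev_s)
        : (fwd_s.empty() ? (fwd_s = std::string(rd, Lr)) : fwd_s);
      int nd = std::min((int)cand.size(), max_diags);
      Placement cur;
      for (int q = 0; q < nd; q++)
        eval_diag(consensus, rds, cand[q].first, care, span, seed_min,
                  confirm_window, confirm_min, min_confirm_len, cur);
      if (cur.pass && (!best.pass || cur.identity > best.identity ||
                       (cur.identity == best.identity && cur.seed > best.seed))) {
        best = cur;
        best_or = ori;
      }
    }
    pass[r] = best.pass ? 1 : 0;
    orient[r] = best_or;
    offset[r] = best.offset;
    seedpos[r] = best.seed_pos;
    identity[r] = best.pass ? best.identity : NA_REAL;
  }
  return List::create(_["pass"] = pass, _["orient"] = orient,
                      _["offset"] = offset, _["seedpos"] = seedpos,
                      _["identity"] = identity);
}

// Column base counts for reads placed ungapped at global offsets.
// Rows: A, C, G, T, other.  Column j is global coordinate start + j - 1.
// [[Rcpp::export(rng = false)]]
IntegerMatrix pile_cpp(CharacterVector reads, IntegerVector offsets,
                       int start, int len) {
  IntegerMatrix counts(5, len);
  int n = reads.size();
  for (int r = 0; r < n; r++) {
    std::string s = as<std::string>(reads[r]);
    int off = offsets[r] - start;
    for (int i = 0; i < (int)s.size(); i++) {
      int col = off + i;
      if (col < 0 || col >= len) continue;
      counts(base_code(s[i]), col)++;
    }
  }
  return counts;
}
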