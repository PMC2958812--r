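#include <Rcpp.h>
#include <string>
#include <vector>
#include <unordered_set>
#include <unordered_map>
#include <cstring>
#include <cstdint>
using namespace Rcpp;

// A=0, C=1, G=2, T=3, other=-1. Complementary pairs sum to 3.
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Enumerate imperfect inverted repeats: arms of arm_min..arm_max bp around a
// spacer of sp_min..sp_max bp, with at most max_mm mismatches between arm1
// and the reverse complement of arm2. Windows containing non-ACGT are
// skipped. Coordinates are 0-based offsets into `seq`.
// [[Rcpp::export]]
DataFrame cpp_enumerate_ir(std::string seq, int arm_min, int arm_max,
                           int sp_min, int sp_max, int max_mm) {
  const int n = (int) seq.size();
  std::vector<int> code(n);
  std::vector<int> bad(n + 1, 0);  // prefix count of non-ACGT
  for (int i = 0; i < n; ++i) {
    code[i] = base_code(seq[i]);
    bad[i + 1] = bad[i] + (code[i] < 0 ? 1 : 0);
  }
  std::vector<int> starts, arms, spacers, mms;
  for (int st = 0; st < n; ++st) {
    for (int a = arm_min; a <= arm_max; ++a) {
      for (int sp = sp_min; sp <= sp_max; ++sp) {
        int tot = 2 * a + sp;
        if (st + tot > n) continue;
        if (bad[st + tot] - bad[st] > 0) continue;
        int mm = 0;
        for (int j = 0; j < a; ++j) {
          // arm1[j] vs complement of arm2[a-1-j] (arm2 read backwards)
          if (code[st + j] + code[st + tot - 1 - j] != 3) {
            if (++mm > max_mm) break;
          }
        }
        if (mm <= max_mm) {
          starts.push_back(st);
          arms.push_back(a);
          spacers.push_back(sp);
          mms.push_back(mm);
        }
      }
    }
  }
  return DataFrame::create(_["start"] = starts, _["arm_len"] = arms,
                           _["spacer_len"] = spacers, _["mismatches"] = mms,
                           _["stringsAsFactors"] = false);
}

// Hamming distance for pairs of equal-length strings (element-wise).
// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector a, CharacterVector b) {
  if (a.size() != b.size()) stop("vectors must have equal length");
  const int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *x = CHAR(STRING_ELT(a, i));
    const char *y = CHAR(STRING_ELT(b, i));
    int la = LENGTH(STRING_ELT(a, i)), lb = LENGTH(STRING_ELT(b, i));
    if (la != lb) stop("strings in pair %d differ in length", i + 1);
    int d = 0;
    for (int j = 0; j < la; ++j) d += (x[j] != y[j]);
    out[i] = d;
  }
  return out;
}

// Score every window of width ncol(mat) against a 4 x W log-odds matrix
// (rows A,C,G,T). Windows containing non-ACGT score NA.
// [[Rcpp::export]]
NumericVector cpp_pwm_scan(std::string seq, NumericMatrix mat) {
  const int W = mat.ncol();
  const int n = (int) seq.size();
  if (mat.nrow() != 4) stop("profile matrix must have 4 rows");
  if (n < W) return NumericVector(0);
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);
  NumericVector out(n - W + 1);
  for (int i = 0; i + W <= n; ++i) {
    double s = 0.0;
    bool ok = true;
    for (int j = 0; j < W; ++j) {
      int c = code[i + j];
      if (c < 0) { ok = false; break; }
      s += mat(c, j);
    }
    out[i] = ok ? s : NA_REAL;
  }
  return out;
}

// Altschul-Erikson dinucleotide-preserving shuffle. Uses R's RNG so results
// are reproducible under set.seed(). Works over any byte alphabet.
// [[Rcpp::export]]
std::string cpp_dinuc_shuffle(std::string seq) {
  const int n = (int) seq.size();
  if (n < 3) return seq;
  // map characters to vertex ids
  int id[256];
  for (int i = 0; i < 256; ++i) id[i] = -1;
  std::vector<char> chars;
  std::vector<int> v(n);
  for (int i = 0; i < n; ++i) {
    unsigned char c = (unsigned char) seq[i];
    if (id[c] < 0) { id[c] = (int) chars.size(); chars.push_back(seq[i]); }
    v[i] = id[c];
  }
  const int nv = (int) chars.size();
  if (nv == 1) return seq;
  // adjacency: ordered successor lists
  std::vector< std::vector<int> > adj(nv);
  for (int i = 0; i + 1 < n; ++i) adj[v[i]].push_back(v[i + 1]);
  const int last = v[n - 1];
  // choose a random "last edge" per vertex (except the terminal vertex) so
  // that last edges form a tree into `last`; rejection-sample until valid
  std::vector<int> last_edge(nv, -1);
  for (int tries = 0; tries < 10000; ++tries) {
    for (int u = 0; u < nv; ++u) {
      last_edge[u] = -1;
      if (u == last || adj[u].empty()) continue;
      int k = (int) (unif_rand() * adj[u].size());
      if (k == (int) adj[u].size()) k--;
      last_edge[u] = adj[u][k];
    }
    bool ok = true;
    for (int u = 0; u < nv && ok; ++u) {
      if (u == last || adj[u].empty()) continue;
      int cur = u;
      for (int step = 0; step <= nv; ++step) {
        if (cur == last) break;
        cur = last_edge[cur];
        if (cur < 0) { ok = false; break; }
        if (step == nv) ok = false;
      }
      if (cur != last) ok = false;
    }
    if (ok) break;
    if (tries == 9999) stop("dinucleotide shuffle failed to find an Eulerian ordering");
  }
  // shuffle each adjacency list, forcing the chosen last edge to the end
  for (int u = 0; u < nv; ++u) {
    std::vector<int> &e = adj[u];
    if (e.empty()) continue;
    if (last_edge[u] >= 0) {
      // move one instance of last_edge[u] to the back
      for (int i = 0; i < (int) e.size(); ++i) {
        if (e[i] == last_edge[u]) { std::swap(e[i], e.back()); break; }
      }
      for (int i = (int) e.size() - 2; i > 0; --i) {
        int j = (int) (unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(e[i], e[j]);
      }
    } else {
      for (int i = (int) e.size() - 1; i > 0; --i) {
        int j = (int) (unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(e[i], e[j]);
      }
    }
  }
  // Eulerian walk from the first character
  std::vector<size_t> next(nv, 0);
  std::string out;
  out.reserve(n);
  int cur = v[0];
  out.push_back(chars[cur]);
  for (int i = 0; i + 1 < n; ++i) {
    int nxt = adj[cur][next[cur]++];
    out.push_back(chars[nxt]);
    cur = nxt;
  }
  return out;
}

// Generate an order-m Markov chain over A,C,G,T. `trans` has 4^m rows
// (states in lexicographic order, A=0) and 4 columns of transition
// probabilities. Uses R's RNG.
// [[Rcpp::export]]
std::string cpp_markov_seq(int L, NumericMatrix trans, int order) {
  if (order < 1) stop("order must be >= 1");
  int ns = 1;
  for (int i = 0; i < order; ++i) ns *= 4;
  if (trans.nrow() != ns || trans.ncol() != 4)
    stop("transition matrix must be 4^order x 4");
  static const char bases[] = "ACGT";
  std::string out;
  out.reserve(L);
  int state = 0;
  for (int i = 0; i < order && i < L; ++i) {
    int b = (int) (unif_rand() * 4); if (b > 3) b = 3;
    out.push_back(bases[b]);
    state = (state * 4 + b) % ns;
  }
  for (int i = order; i < L; ++i) {
    double u = unif_rand(), acc = 0.0;
    int b = 3;
    for (int j = 0; j < 4; ++j) {
      acc += trans(state, j);
      if (u <= acc) { b = j; break; }
    }
    out.push_back(bases[b]);
    state = (state * 4 + b) % ns;
  }
  return out;
}

static inline char comp_char(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    case 'N': case 'n': return 'N';
    default: return c;
  }
}

// Reverse complement over {A,C,G,T,N}; no validation (internal fast path).
// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  const int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(x, i));
    int l = LENGTH(STRING_ELT(x, i));
    std::string r(l, ' ');
    for (int j = 0; j < l; ++j) r[j] = comp_char(s[l - 1 - j]);
    out[i] = r;
  }
  return out;
}

// As cpp_enumerate_ir but also materializes the site sequence and the
// canonical sequence (lexicographic min of site and its reverse complement).
// [[Rcpp::export]]
DataFrame cpp_enumerate_ir_full(std::string seq, int arm_min, int arm_max,
                                int sp_min, int sp_max, int max_mm) {
  const int n = (int) seq.size();
  std::vector<int> code(n);
  std::vector<int> bad(n + 1, 0);
  for (int i = 0; i < n; ++i) {
    code[i] = base_code(seq[i]);
    bad[i + 1] = bad[i] + (code[i] < 0 ? 1 : 0);
  }
  std::vector<int> starts, arms, spacers, mms;
  std::vector<std::string> seqv, canv;
  for (int st = 0; st < n; ++st) {
    for (int a = arm_min; a <= arm_max; ++a) {
      for (int sp = sp_min; sp <= sp_max; ++sp) {
        int tot = 2 * a + sp;
        if (st + tot > n) continue;
        if (bad[st + tot] - bad[st] > 0) continue;
        int mm = 0;
        for (int j = 0; j < a; ++j) {
          if (code[st + j] + code[st + tot - 1 - j] != 3) {
            if (++mm > max_mm) break;
          }
        }
        if (mm > max_mm) continue;
        starts.push_back(st);
        arms.push_back(a);
        spacers.push_back(sp);
        mms.push_back(mm);
        std::string site = seq.substr(st, tot);
        int cmp = 0;  // site vs its revcomp, lexicographically
        for (int j = 0; j < tot; ++j) {
          char rcj = comp_char(site[tot - 1 - j]);
          if (site[j] != rcj) { cmp = site[j] < rcj ? -1 : 1; break; }
        }
        if (cmp <= 0) canv.push_back(site);
        else {
          std::string rc(tot, ' ');
          for (int j = 0; j < tot; ++j) rc[j] = comp_char(site[tot - 1 - j]);
          canv.push_back(rc);
        }
        seqv.push_back(site);
      }
    }
  }
  return DataFrame::create(
    _["start"] = starts, _["arm_len"] = arms, _["spacer_len"] = spacers,
    _["mismatches"] = mms, _["seq"] = seqv, _["canonical_seq"] = canv,
    _["stringsAsFactors"] = false);
}

// number of nonzero bytes in a word whose bytes are all < 0x80
static inline int neq_bytes(uint64_t t) {
  uint64_t z = (t - 0x0101010101010101ULL) & ~t & 0x8080808080808080ULL;
  return 8 - __builtin_popcountll(z);
}

// zero-padded packing of equal-width strings into nw 64-bit words per row
static void pack_rows(const CharacterVector &v, int w, int nw,
                      std::vector<uint64_t> &out) {
  out.assign((size_t) v.size() * nw, 0ULL);
  for (int i = 0; i < v.size(); ++i) {
    const char *s = CHAR(STRING_ELT(v, i));
    memcpy(&out[(size_t) i * nw], s, w);
  }
}

// Seed-block hash join between two candidate sets of one geometry class.
// a: canonical sites of genome i; b / brc: canonical sites of genome j and
// their reverse complements (all the same width). Two sites within max_mm
// mismatches (orientation-minimized) must share one of nb equal blocks
// exactly (pigeonhole), so only block-sharing pairs are scored. Blocks
// longer than 8 bp are filtered on their first 8 bp (a superset; the exact
// mismatch count decides). Returns 1-based index pairs with the
// orientation-minimized mismatch count <= max_mm.
// [[Rcpp::export]]
DataFrame cpp_match_pairs(CharacterVector a, CharacterVector b,
                          CharacterVector brc, int nb, int max_mm) {
  const int na = a.size(), nbn = b.size();
  if (na == 0 || nbn == 0)
    return DataFrame::create(_["i"] = IntegerVector(0),
                             _["j"] = IntegerVector(0),
                             _["mismatches"] = IntegerVector(0));
  const int w = LENGTH(STRING_ELT(a, 0));
  const int nw = (w + 7) / 8;
  std::vector<int> cuts(nb + 1);
  for (int t = 0; t <= nb; ++t) cuts[t] = (int) ((long long) w * t / nb);
  std::vector<uint64_t> pa, pb, pr;
  pack_rows(a, w, nw, pa);
  pack_rows(b, w, nw, pb);
  pack_rows(brc, w, nw, pr);
  // per-block hash of a's block words
  auto block_key = [&](const char *s, int t) {
    uint64_t k = 0;
    int len = cuts[t + 1] - cuts[t];
    if (len > 8) len = 8;
    memcpy(&k, s + cuts[t], len);
    return k;
  };
  std::vector< std::unordered_multimap<uint64_t, int> > maps(nb);
  for (int t = 0; t < nb; ++t) maps[t].reserve(na);
  for (int i = 0; i < na; ++i) {
    const char *s = CHAR(STRING_ELT(a, i));
    for (int t = 0; t < nb; ++t)
      maps[t].insert(std::make_pair(block_key(s, t), i));
  }
  std::unordered_set<long long> accepted;
  std::vector<int> iv, jv, mv;
  for (int j = 0; j < nbn; ++j) {
    const char *s1 = CHAR(STRING_ELT(b, j));
    const char *s2 = CHAR(STRING_ELT(brc, j));
    const uint64_t *w1 = &pb[(size_t) j * nw];
    const uint64_t *w2 = &pr[(size_t) j * nw];
    for (int o = 0; o < 2; ++o) {
      const char *s = o == 0 ? s1 : s2;
      for (int t = 0; t < nb; ++t) {
        auto range = maps[t].equal_range(block_key(s, t));
        for (auto it = range.first; it != range.second; ++it) {
          int i = it->second;
          const uint64_t *wa = &pa[(size_t) i * nw];
          int d1 = 0, d2 = 0;
          for (int p = 0; p < nw; ++p) {
            d1 += neq_bytes(wa[p] ^ w1[p]);
            d2 += neq_bytes(wa[p] ^ w2[p]);
            if (d1 > max_mm && d2 > max_mm) break;
          }
          int d = d1 < d2 ? d1 : d2;
          if (d > max_mm) continue;
          long long pk = (long long) i * (long long) nbn + j;
          if (!accepted.insert(pk).second) continue;
          iv.push_back(i + 1); jv.push_back(j + 1); mv.push_back(d);
        }
      }
    }
  }
  return DataFrame::create(_["i"] = iv, _["j"] = jv, _["mismatches"] = mv,
                           _["stringsAsFactors"] = false);
}

// i.i.d. DNA of length L with base probabilities (A,C,G,T); R RNG.
// [[Rcpp::export]]
std::string cpp_random_dna(int L, NumericVector probs) {
  if (probs.size() != 4) stop("probs must have length 4");
  double c1 = probs[0], c2 = c1 + probs[1], c3 = c2 + probs[2];
  static const char bases[] = "ACGT";
  std::string out(L, 'A');
  for (int i = 0; i < L; ++i) {
    double u = unif_rand();
    out[i] = u < c1 ? bases[0] : (u < c2 ? bases[1] :
             (u < c3 ? bases[2] : bases[3]));
  }
  return out;
}

// Per-position substitution (uniform exchange to one of the three other
// bases) at position-specific rates; R RNG. Non-ACGT positions are skipped.
// [[Rcpp::export]]
std::string cpp_mutate(std::string seq, NumericVector rate) {
  const int n = (int) seq.size();
  if (rate.size() != n) stop("rate vector must match sequence length");
  static const char bases[] = "ACGT";
  for (int i = 0; i < n; ++i) {
    if (unif_rand() >= rate[i]) continue;
    int c = base_code(seq[i]);
    if (c < 0) continue;
    int shift = 1 + (int) (unif_rand() * 3);
    if (shift > 3) shift = 3;
    seq[i] = bases[(c + shift) % 4];
  }
  return seq;
}
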