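#include "core.h"

using namespace Rcpp;

// ---- k-mer primitives -------------------------------------------------

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
  }
}

std::string rc_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

std::string canon_str(const std::string& s) {
  std::string r = rc_str(s);
  return (r < s) ? r : s;
}

bool acgt_only(const std::string& s) {
  if (s.empty()) return false;
  for (char c : s)
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T') return false;
  return true;
}

std::string upper_str(const std::string& s) {
  std::string r = s;
  for (auto& c : r)
    if (c >= 'a' && c <= 'z') c -= 32;
  return r;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    std::string s = upper_str(as<std::string>(x[i]));
    if (!acgt_only(s)) stop("revcomp: sequence %d contains non-ACGT symbols", (int)(i + 1));
    out[i] = rc_str(s);
  }
  return out;
}

// [[Rcpp::export(name = ".canonical_cpp")]]
CharacterVector canonical_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    std::string s = upper_str(as<std::string>(x[i]));
    if (!acgt_only(s)) stop("canonical: word %d contains non-ACGT symbols", (int)(i + 1));
    out[i] = canon_str(s);
  }
  return out;
}

// Canonical k-mers of a read, one per position whose window is pure ACGT.
// [[Rcpp::export(name = ".kmerize_cpp")]]
CharacterVector kmerize_cpp(std::string read, int k) {
  if (k < 1) stop("k must be >= 1");
  read = upper_str(read);
  std::vector<std::string> out;
  int L = (int)read.size();
  if (L >= k) {
    // next_bad[i]: window starting at i contains a non-ACGT base
    std::vector<int> bad(L, 0);
    for (int i = 0; i < L; ++i) {
      char c = read[i];
      bad[i] = (c != 'A' && c != 'C' && c != 'G' && c != 'T');
    }
    int run = 0;  // count of valid bases ending at i
    for (int i = 0; i < L; ++i) {
      run = bad[i] ? 0 : run + 1;
      if (run >= k) out.push_back(canon_str(read.substr(i - k + 1, k)));
    }
  }
  return wrap(out);
}

// ---- Bloom filter -----------------------------------------------------

// FNV-1a over bytes followed by a murmur-style finalizer; two fixed seeds
// feed enhanced double hashing so filter files are reproducible.
static inline uint64_t hash_seed(const std::string& s, uint64_t seed) {
  uint64_t x = seed ^ 0xcbf29ce484222325ULL;
  for (unsigned char c : s) {
    x ^= (uint64_t)c;
    x *= 0x100000001b3ULL;
  }
  x ^= x >> 33;
  x *= 0xff51afd7ed558ccdULL;
  x ^= x >> 33;
  x *= 0xc4ceb9fe1a85ec53ULL;
  x ^= x >> 33;
  return x;
}

static const uint64_t BLOOM_SEED1 = 0x9E3779B97F4A7C15ULL;
static const uint64_t BLOOM_SEED2 = 0xC2B2AE3D27D4EB4FULL;

void Bloom::insert(const std::string& key) {
  uint64_t a = hash_seed(key, BLOOM_SEED1);
  uint64_t b = hash_seed(key, BLOOM_SEED2);
  for (int i = 0; i < h; ++i) {
    set_bit(a % m);
    a += b;
    b += (uint64_t)i;  // enhanced double hashing
  }
  ++n_inserted;
}

bool Bloom::contains(const std::string& key) const {
  uint64_t a = hash_seed(key, BLOOM_SEED1);
  uint64_t b = hash_seed(key, BLOOM_SEED2);
  for (int i = 0; i < h; ++i) {
    if (!get_bit(a % m)) return false;
    a += b;
    b += (uint64_t)i;
  }
  return true;
}

// [[Rcpp::export(name = ".bloom_new")]]
SEXP bloom_new(double m, int h) {
  return XPtr<Bloom>(new Bloom((uint64_t)m, h), true);
}

// [[Rcpp::export(name = ".bloom_insert_cpp")]]
void bloom_insert_cpp(SEXP ptr, CharacterVector keys) {
  XPtr<Bloom> f(ptr);
  for (R_xlen_t i = 0; i < keys.size(); ++i) f->insert(as<std::string>(keys[i]));
}

// [[Rcpp::export(name = ".bloom_contains_cpp")]]
LogicalVector bloom_contains_cpp(SEXP ptr, CharacterVector keys) {
  XPtr<Bloom> f(ptr);
  LogicalVector out(keys.size());
  for (R_xlen_t i = 0; i < keys.size(); ++i)
    out[i] = f->contains(as<std::string>(keys[i]));
  return out;
}

// [[Rcpp::export(name = ".bloom_state_cpp")]]
List bloom_state_cpp(SEXP ptr) {
  XPtr<Bloom> f(ptr);
  RawVector bits((R_xlen_t)f->bits.size());
  std::copy(f->bits.begin(), f->bits.end(), bits.begin());
  return List::create(_["m"] = (double)f->m, _["h"] = f->h,
                      _["n_inserted"] = (double)f->n_inserted,
                      _["bits"] = bits);
}

// [[Rcpp::export(name = ".bloom_from_state_cpp")]]
SEXP bloom_from_state_cpp(double m, int h, double n_inserted, RawVector bits) {
  XPtr<Bloom> f(new Bloom((uint64_t)m, h), true);
  if ((R_xlen_t)f->bits.size() != bits.size())
    stop("bit array length does not match filter size");
  std::copy(bits.begin(), bits.end(), f->bits.begin());
  f->n_inserted = (uint64_t)n_inserted;
  return f;
}

// ---- cascading Bloom filter ------------------------------------------

// [[Rcpp::export(name = ".cascade_new")]]
SEXP cascade_new(int k, double m_per_level, int h) {
  return XPtr<Cascade>(new Cascade(k, (uint64_t)m_per_level, h), true);
}

// [[Rcpp::export(name = ".cascade_insert_cpp")]]
void cascade_insert_cpp(SEXP ptr, CharacterVector words) {
  XPtr<Cascade> c(ptr);
  for (R_xlen_t i = 0; i < words.size(); ++i) {
    std::string w = upper_str(as<std::string>(words[i]));
    if ((int)w.size() != c->k) stop("k-mer %d has length != k", (int)(i + 1));
    if (!acgt_only(w)) stop("k-mer %d contains non-ACGT symbols", (int)(i + 1));
    c->insert(canon_str(w));
  }
}

// Quality-aware read loading: hard 3' trim at the first base with
// Phred < qmin (offset-33 encoding), split at non-ACGT, insert canonical
// k-mers into the cascade.
// [[Rcpp::export(name = ".cascade_insert_reads_cpp")]]
double cascade_insert_reads_cpp(SEXP ptr, CharacterVector seqs,
                                Nullable<CharacterVector> quals, int qmin) {
  XPtr<Cascade> c(ptr);
  int k = c->k;
  double kmers_loaded = 0;
  bool have_q = quals.isNotNull();
  CharacterVector qv;
  if (have_q) qv = quals.get();
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    std::string s = upper_str(as<std::string>(seqs[r]));
    int L = (int)s.size();
    if (have_q && qmin > 0) {
      std::string q = as<std::string>(qv[r]);
      int cut = L;
      int qn = (int)q.size();
      for (int i = 0; i < L && i < qn; ++i) {
        if ((int)q[i] - 33 < qmin) { cut = i; break; }
      }
      L = cut;
    }
    if (L < k) continue;
    int run = 0;
    for (int i = 0; i < L; ++i) {
      char ch = s[i];
      bool ok = (ch == 'A' || ch == 'C' || ch == 'G' || ch == 'T');
      run = ok ? run + 1 : 0;
      if (run >= k) {
        c->insert(canon_str(s.substr(i - k + 1, k)));
        kmers_loaded += 1;
      }
    }
  }
  return kmers_loaded;
}

// [[Rcpp::export(name = ".cascade_contains_cpp")]]
LogicalVector cascade_contains_cpp(SEXP ptr, CharacterVector words, int level) {
  XPtr<Cascade> c(ptr);
  LogicalVector out(words.size());
  for (R_xlen_t i = 0; i < words.size(); ++i) {
    std::string w = canon_str(upper_str(as<std::string>(words[i])));
    if (level == 1) {
      if (c->level1_dropped) stop("level 1 was discarded after loading");
      out[i] = c->l1.contains(w);
    } else {
      out[i] = c->l2.contains(w);
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cascade_info_cpp")]]
List cascade_info_cpp(SEXP ptr) {
  XPtr<Cascade> c(ptr);
  return List::create(_["k"] = c->k, _["levels"] = c->levels,
                      _["m_per_level"] = (double)c->l2.m, _["h"] = c->l2.h,
                      _["n_level1"] = (double)c->l1.n_inserted,
                      _["n_level2"] = (double)c->l2.n_inserted,
                      _["level1_dropped"] = c->level1_dropped);
}

// [[Rcpp::export(name = ".cascade_drop_level1_cpp")]]
void cascade_drop_level1_cpp(SEXP ptr) {
  XPtr<Cascade> c(ptr);
  c->level1_dropped = true;
  std::vector<uint8_t>().swap(c->l1.bits);
}

// [[Rcpp::export(name = ".cascade_state_cpp")]]
List cascade_state_cpp(SEXP ptr) {
  XPtr<Cascade> c(ptr);
  RawVector b2((R_xlen_t)c->l2.bits.size());
  std::copy(c->l2.bits.begin(), c->l2.bits.end(), b2.begin());
  return List::create(_["k"] = c->k, _["levels"] = c->levels,
                      _["m"] = (double)c->l2.m, _["h"] = c->l2.h,
                      _["n_level2"] = (double)c->l2.n_inserted,
                      _["bits_level2"] = b2);
}

// Rebuild a cascade from a saved level-2 array (level 1 was discarded at
// the end of loading, mirroring the on-disk format).
// [[Rcpp::export(name = ".cascade_from_state_cpp")]]
SEXP cascade_from_state_cpp(int k, double m, int h, double n_level2,
                            RawVector bits_level2) {
  XPtr<Cascade> c(new Cascade(k, (uint64_t)m, h), true);
  if ((R_xlen_t)c->l2.bits.size() != bits_level2.size())
    stop("level-2 bit array length does not match filter size");
  std::copy(bits_level2.begin(), bits_level2.end(), c->l2.bits.begin());
  c->l2.n_inserted = (uint64_t)n_level2;
  c->level1_dropped = true;
  std::vector<uint8_t>().swap(c->l1.bits);
  return c;
}

// ---- graph handle -----------------------------------------------------

// [[Rcpp::export(name = ".graph_new_bloom_cpp")]]
SEXP graph_new_bloom_cpp(SEXP cascade_ptr) {
  XPtr<Cascade> c(cascade_ptr);
  return XPtr<Graph>(new Graph(c->k, &c->l2), true);
}

// [[Rcpp::export(name = ".graph_new_exact_cpp")]]
SEXP graph_new_exact_cpp(CharacterVector kmers, int k) {
  XPtr<Graph> g(new Graph(k), true);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string w = upper_str(as<std::string>(kmers[i]));
    if ((int)w.size() != k) stop("k-mer %d has length != k", (int)(i + 1));
    if (!acgt_only(w)) stop("k-mer %d contains non-ACGT symbols", (int)(i + 1));
    g->exact.insert(canon_str(w));
  }
  return g;
}

// [[Rcpp::export(name = ".graph_contains_cpp")]]
LogicalVector graph_contains_cpp(SEXP ptr, CharacterVector words) {
  XPtr<Graph> g(ptr);
  LogicalVector out(words.size());
  for (R_xlen_t i = 0; i < words.size(); ++i) {
    std::string w = upper_str(as<std::string>(words[i]));
    out[i] = acgt_only(w) && (int)w.size() == g->k && g->contains_word(w);
  }
  return out;
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

std::vector<std::string> word_neighbors(const Graph& g, const std::string& w,
                                        bool right) {
  std::vector<std::string> out;
  int k = (int)w.size();
  std::string cand;
  if (right) {
    cand = w.substr(1) + "A";
    for (int b = 0; b < 4; ++b) {
      cand[k - 1] = BASES[b];
      if (g.contains_word(cand)) out.push_back(cand);
    }
  } else {
    cand = "A" + w.substr(0, k - 1);
    for (int b = 0; b < 4; ++b) {
      cand[0] = BASES[b];
      if (g.contains_word(cand)) out.push_back(cand);
    }
  }
  return out;
}

static bool dir_is_right(const std::string& direction) {
  if (direction == "right") return true;
  if (direction == "left") return false;
  stop("direction must be \"left\" or \"right\"");
}

// [[Rcpp::export(name = ".graph_neighbors_cpp")]]
CharacterVector graph_neighbors_cpp(SEXP ptr, std::string word,
                                    std::string direction) {
  XPtr<Graph> g(ptr);
  word = upper_str(word);
  if ((int)word.size() != g->k) stop("query word length differs from k");
  if (!acgt_only(word)) stop("query word contains non-ACGT symbols");
  return wrap(word_neighbors(*g, word, dir_is_right(direction)));
}

// [[Rcpp::export(name = ".graph_classify_cpp")]]
std::string graph_classify_cpp(SEXP ptr, std::string word,
                               std::string direction) {
  XPtr<Graph> g(ptr);
  word = upper_str(word);
  size_t n = word_neighbors(*g, word, dir_is_right(direction)).size();
  if (n == 0) return "dead_end";
  if (n == 1) return "linear";
  return "branching";
}

// ---- anchoring --------------------------------------------------------

std::vector<int> solid_mask_impl(const Graph& g, const std::string& read) {
  int k = g.k, L = (int)read.size();
  std::vector<int> mask;
  if (L < k) return mask;
  mask.assign(L - k + 1, 0);
  int run = 0;
  for (int i = 0; i < L; ++i) {
    char c = read[i];
    bool ok = (c == 'A' || c == 'C' || c == 'G' || c == 'T');
    run = ok ? run + 1 : 0;
    if (i >= k - 1 && run >= k)
      mask[i - k + 1] = g.contains_word(read.substr(i - k + 1, k)) ? 1 : 0;
  }
  return mask;
}

// [[Rcpp::export(name = ".solid_mask_cpp")]]
LogicalVector solid_mask_cpp(SEXP ptr, std::string read) {
  XPtr<Graph> g(ptr);
  std::vector<int> m = solid_mask_impl(*g, upper_str(read));
  LogicalVector out(m.size());
  for (size_t i = 0; i < m.size(); ++i) out[i] = m[i] != 0;
  return out;
}

void select_anchor_impl(const Graph& g, const std::string& read, int* offset,
                        int* run_len) {
  *offset = -1;
  *run_len = 0;
  std::vector<int> mask = solid_mask_impl(g, read);
  int n = (int)mask.size();
  // maximal runs of solid positions
  int best3_start = -1, best3_len = 0;   // run of >= 3 closest to 3' end
  int bestL_start = -1, bestL_len = 0;   // longest run (ties toward 3')
  int i = 0;
  while (i < n) {
    if (!mask[i]) { ++i; continue; }
    int j = i;
    while (j < n && mask[j]) ++j;
    int len = j - i;
    if (len >= 3) { best3_start = i; best3_len = len; }  // later runs win
    if (len >= bestL_len) { bestL_start = i; bestL_len = len; }
    i = j;
  }
  if (best3_start >= 0) {
    *offset = best3_start;
    *run_len = best3_len;
  } else if (bestL_start >= 0) {
    *offset = bestL_start;
    *run_len = bestL_len;
  }
}

// [[Rcpp::export(name = ".select_anchor_cpp")]]
List select_anchor_cpp(SEXP ptr, std::string read) {
  XPtr<Graph> g(ptr);
  read = upper_str(read);
  int offset, run_len;
  select_anchor_impl(*g, read, &offset, &run_len);
  if (offset < 0) return List::create();
  return List::create(_["kmer"] = read.substr(offset, g->k),
                      _["offset"] = offset, _["run_len"] = run_len);
}
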