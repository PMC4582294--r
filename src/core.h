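#pragma once

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

// ---- k-mer primitives -------------------------------------------------

// Reverse complement of an ACGT word (caller guarantees alphabet).
std::string rc_str(const std::string& s);
// Lexicographic min of word and its reverse complement.
std::string canon_str(const std::string& s);
// True if s is non-empty and contains only A/C/G/T (uppercase).
bool acgt_only(const std::string& s);
// Uppercase a copy.
std::string upper_str(const std::string& s);

// ---- Bloom filter -----------------------------------------------------

// Plain Bloom filter over byte strings. Double hashing from two fixed
// 64-bit seed hashes keeps filter files reproducible across runs.
struct Bloom {
  uint64_t m;           // size in bits
  int h;                // number of hash functions
  uint64_t n_inserted;  // count of insert() calls
  std::vector<uint8_t> bits;

  Bloom(uint64_t m_, int h_)
      : m(m_), h(h_), n_inserted(0), bits((size_t)((m_ + 7) / 8), 0) {
    if (m_ == 0) Rcpp::stop("Bloom filter size must be positive");
    if (h_ < 1) Rcpp::stop("Bloom filter needs at least one hash function");
  }

  inline void set_bit(uint64_t i) {
    bits[(size_t)(i >> 3)] |= (uint8_t)(1u << (i & 7));
  }
  inline bool get_bit(uint64_t i) const {
    return (bits[(size_t)(i >> 3)] >> (i & 7)) & 1;
  }

  void insert(const std::string& key);
  bool contains(const std::string& key) const;
};

// Two-level cascade: level1 = seen >= 1, level2 = seen >= 2. After read
// loading completes level1 may be dropped; downstream queries use level2.
struct Cascade {
  int k;
  int levels;
  bool level1_dropped;
  Bloom l1, l2;

  Cascade(int k_, uint64_t m_per_level, int h_)
      : k(k_), levels(2), level1_dropped(false),
        l1(m_per_level, h_), l2(m_per_level, h_) {}

  void insert(const std::string& canon) {
    if (level1_dropped)
      Rcpp::stop("cannot insert: level 1 was discarded after loading");
    if (l1.contains(canon)) {
      l2.insert(canon);
    } else {
      l1.insert(canon);
    }
  }
};

// ---- implicit de Bruijn graph ----------------------------------------

// Node membership backend: level-2 Bloom filter of a cascade, or an exact
// hash set (zero-FPR stand-in used as a test oracle; same contract).
struct Graph {
  int k;
  const Bloom* level2;  // borrowed; R side keeps the cascade alive
  std::unordered_set<std::string> exact;
  bool use_exact;

  Graph(int k_, const Bloom* bf) : k(k_), level2(bf), use_exact(false) {}
  explicit Graph(int k_) : k(k_), level2(nullptr), use_exact(true) {}

  inline bool contains_canon(const std::string& s) const {
    return use_exact ? (exact.count(s) > 0) : level2->contains(s);
  }
  inline bool contains_word(const std::string& w) const {
    return contains_canon(canon_str(w));
  }
};

// Oriented single-base extensions of w present in the graph. right=true
// appends to the 3' side of the oriented word.
std::vector<std::string> word_neighbors(const Graph& g, const std::string& w,
                                        bool right);

// Anchor rule: run of >= 3 solid k-mers closest to the 3' end, anchor at
// the run's 5'-most k-mer; fallback to the longest run (ties toward 3').
// Returns offset in *offset (or -1 if no solid k-mer) and run length.
void select_anchor_impl(const Graph& g, const std::string& read, int* offset,
                        int* run_len);

std::vector<int> solid_mask_impl(const Graph& g, const std::string& read);
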