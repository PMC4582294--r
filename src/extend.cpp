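#include "core.h"

using namespace Rcpp;

// ---- false-positive branch model --------------------------------------

// A branch is assumed to be a Bloom-filter false positive if it dies out
// within three nodes. Branches that reach a fourth node or fork within
// the look-ahead are treated as real.
static bool is_fp_branch(const Graph& g, const std::string& first,
                         bool right) {
  std::string cur = first;
  int n = 1;
  while (true) {
    if (n > 3) return false;
    std::vector<std::string> nb = word_neighbors(g, cur, right);
    if (nb.empty()) return true;   // dead end within <= 3 nodes
    if (nb.size() >= 2) return false;
    cur = nb[0];
    ++n;
  }
}

static std::vector<std::string> surviving_branches(const Graph& g,
                                                   const std::string& word,
                                                   bool right) {
  std::vector<std::string> nb = word_neighbors(g, word, right);
  if (nb.size() < 2) return nb;
  std::vector<std::string> keep;
  for (const auto& v : nb)
    if (!is_fp_branch(g, v, right)) keep.push_back(v);
  return keep;
}

// ---- bubble collapse --------------------------------------------------

// Walk one bubble arm linearly (false-positive spurs skipped) for at most
// k+1 nodes; stops early at a real fork or dead end.
static std::vector<std::string> walk_arm(const Graph& g,
                                         const std::string& first, bool right,
                                         int max_nodes) {
  std::vector<std::string> arm;
  arm.push_back(first);
  std::string cur = first;
  while ((int)arm.size() < max_nodes) {
    std::vector<std::string> nb = surviving_branches(g, cur, right);
    if (nb.size() != 1) break;
    cur = nb[0];
    arm.push_back(cur);
  }
  return arm;
}

// Shared bubble logic: given the two surviving branch heads of a fork,
// look ahead k+1 nodes per arm for a same-position reconvergence node.
// On success fills the chosen (lexicographically smaller) arm and returns
// true.
static bool try_collapse(const Graph& g, const std::string& a,
                         const std::string& b, bool right,
                         std::vector<std::string>& chosen_arm) {
  int k = g.k;
  std::vector<std::string> A = walk_arm(g, a, right, k + 1);
  std::vector<std::string> B = walk_arm(g, b, right, k + 1);
  size_t t = std::min(A.size(), B.size());
  for (size_t i = 0; i < t; ++i) {
    if (A[i] == B[i]) {
      // reconverged; spell both arms and keep the smaller
      std::vector<std::string> armA(A.begin(), A.begin() + i + 1);
      std::vector<std::string> armB(B.begin(), B.begin() + i + 1);
      std::string sa, sb;
      for (auto& w : armA) sa.push_back(right ? w.back() : w.front());
      for (auto& w : armB) sb.push_back(right ? w.back() : w.front());
      chosen_arm = (sa <= sb) ? armA : armB;
      return true;
    }
  }
  return false;
}

// [[Rcpp::export(name = ".collapse_bubble_cpp")]]
List collapse_bubble_cpp(SEXP ptr, std::string word, std::string direction) {
  XPtr<Graph> g(ptr);
  word = upper_str(word);
  if ((int)word.size() != g->k) stop("fork word must have length k");
  bool right = (direction == "right");
  if (!right && direction != "left")
    stop("direction must be \"left\" or \"right\"");
  std::vector<std::string> keep = surviving_branches(*g, word, right);
  if (keep.size() != 2) return List::create();  // only 2-branch bubbles
  std::vector<std::string> arm;
  if (!try_collapse(*g, keep[0], keep[1], right, arm)) return List::create();
  return List::create(_["continuation"] = arm.back(),
                      _["arm"] = wrap(arm),
                      _["n_nodes"] = (int)arm.size());
}

// ---- sequence extension -----------------------------------------------

// Extend seq rightward until a dead end, an uncollapsable fork, a revisit
// (cycle guard) or max_append appended bases. The seed is the 3'-most
// solid k-mer preceded by two solid k-mers where one exists (anchor-style
// protection against a false-positive seed), else the 3'-most solid
// k-mer; bases 3' of the seed are re-derived through the graph.
static std::string extend_right_impl(const Graph& g, const std::string& seq,
                                     double max_append) {
  int k = g.k, L = (int)seq.size();
  if (L < k) return seq;
  std::vector<int> mask = solid_mask_impl(g, seq);
  int seed = -1, fallback = -1;
  for (int p = (int)mask.size() - 1; p >= 0; --p) {
    if (!mask[p]) continue;
    if (fallback < 0) fallback = p;
    if (p >= 2 && mask[p - 1] && mask[p - 2]) { seed = p; break; }
  }
  if (seed < 0) seed = fallback;
  if (seed < 0) return seq;  // nothing trusted to extend from

  std::string out = seq.substr(0, seed + k);
  std::string cur = seq.substr(seed, k);
  std::unordered_set<std::string> visited;
  // guard against re-entering the sequence itself on circular paths
  for (int p = 0; p + k <= (int)out.size(); ++p)
    visited.insert(out.substr(p, k));
  double appended = 0;
  while (appended < max_append) {
    std::vector<std::string> keep = surviving_branches(g, cur, true);
    if (keep.empty()) break;  // dead end (or all branches false positive)
    if (keep.size() == 1) {
      if (visited.count(keep[0])) break;
      visited.insert(keep[0]);
      cur = keep[0];
      out.push_back(cur.back());
      appended += 1;
    } else if (keep.size() == 2) {
      std::vector<std::string> arm;
      if (!try_collapse(g, keep[0], keep[1], true, arm)) break;
      bool seen = false;
      for (auto& w : arm)
        if (visited.count(w)) { seen = true; break; }
      if (seen) break;
      for (auto& w : arm) {
        visited.insert(w);
        out.push_back(w.back());
      }
      appended += (double)arm.size();
      cur = arm.back();
    } else {
      break;  // 3+ real branches: genuinely ambiguous
    }
  }
  return out;
}

// [[Rcpp::export(name = ".extend_seq_cpp")]]
std::string extend_seq_cpp(SEXP ptr, std::string seq, bool left, bool right,
                           double max_left, double max_right) {
  XPtr<Graph> g(ptr);
  std::string s = upper_str(seq);
  if (right) s = extend_right_impl(*g, s, max_right);
  if (left) s = rc_str(extend_right_impl(*g, rc_str(s), max_left));
  return s;
}

// ---- unconnected-read correction --------------------------------------

// From the longest run of solid k-mers (ties toward the 3' end): step
// left exactly k nodes through the graph, aborting on any branch or dead
// end; then step right up to k+1 nodes, stopping early but keeping the
// sequence built so far. Escapes any branch/bubble a single sequencing
// error can create (error branches are at most k nodes long).
// [[Rcpp::export(name = ".correct_unconnected_cpp")]]
SEXP correct_unconnected_cpp(SEXP ptr, std::string read) {
  XPtr<Graph> g(ptr);
  int k = g->k;
  read = upper_str(read);
  std::vector<int> mask = solid_mask_impl(*g, read);
  int n = (int)mask.size();
  int best_start = -1, best_len = 0;
  int i = 0;
  while (i < n) {
    if (!mask[i]) { ++i; continue; }
    int j = i;
    while (j < n && mask[j]) ++j;
    if (j - i >= best_len) { best_start = i; best_len = j - i; }
    i = j;
  }
  if (best_start < 0) return R_NilValue;

  std::string cur = read.substr(best_start + best_len - 1, k);
  for (int s = 0; s < k; ++s) {
    std::vector<std::string> nb = word_neighbors(*g, cur, false);
    if (nb.size() != 1) return R_NilValue;  // branch or dead end: abort
    cur = nb[0];
  }
  std::string out = cur;
  for (int s = 0; s < k + 1; ++s) {
    std::vector<std::string> nb = word_neighbors(*g, cur, true);
    if (nb.size() != 1) break;  // stop early, keep what we have
    cur = nb[0];
    out.push_back(cur.back());
  }
  return wrap(out);
}
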