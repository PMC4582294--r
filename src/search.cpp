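#include "core.h"

using namespace Rcpp;

// ---- bidirectional depth-limited BFS ---------------------------------

// Record of a bidirectional (or one-sided) breadth-first search between
// two oriented anchor words. Nodes are oriented words on the fragment's
// forward strand; adjacency holds every rightward edge touched by a
// dequeued node of either frontier.
struct SearchGraph {
  int k;
  std::string start, goal;
  int depth_limit;  // max nodes on a connecting path
  double branches;  // dequeue-time fork children beyond the first
  std::string status;  // success | no_path | too_many_branches
  std::unordered_map<std::string, std::vector<std::string>> adj;
  std::vector<std::pair<std::string, std::string>> common;

  void add_edge(const std::string& u, const std::string& v) {
    auto& vec = adj[u];
    for (auto& x : vec)
      if (x == v) return;
    vec.push_back(v);
  }
};

// Expand one BFS level. right=true expands the forward frontier (edges go
// rightward from the dequeued node); right=false expands the reverse
// frontier through left neighbors, recording the same rightward edges.
static bool expand_level(const Graph& g, SearchGraph& sg, double B,
                         std::vector<std::string>& frontier,
                         std::unordered_set<std::string>& mine,
                         std::unordered_set<std::string>& other, bool right) {
  std::vector<std::string> next;
  for (const auto& u : frontier) {
    std::vector<std::string> nb = word_neighbors(g, u, right);
    if (nb.size() > 1) {
      sg.branches += (double)(nb.size() - 1);
      if (sg.branches > B) {
        sg.status = "too_many_branches";
        return false;
      }
    }
    for (const auto& v : nb) {
      if (right)
        sg.add_edge(u, v);
      else
        sg.add_edge(v, u);
      if (other.count(v)) {
        // seen by the other frontier: seal as a common edge
        if (right)
          sg.common.push_back(std::make_pair(u, v));
        else
          sg.common.push_back(std::make_pair(v, u));
      } else if (!mine.count(v)) {
        mine.insert(v);
        next.push_back(v);
      }
    }
  }
  frontier.swap(next);
  return true;
}

// [[Rcpp::export(name = ".bfs_cpp")]]
List bfs_cpp(SEXP ptr, std::string start, std::string goal, int depth_limit,
             double B, bool bidirectional) {
  XPtr<Graph> g(ptr);
  start = upper_str(start);
  goal = upper_str(goal);
  if ((int)start.size() != g->k || (int)goal.size() != g->k)
    stop("anchor words must have length k");
  XPtr<SearchGraph> sg(new SearchGraph(), true);
  sg->k = g->k;
  sg->start = start;
  sg->goal = goal;
  sg->depth_limit = depth_limit;
  sg->branches = 0;
  sg->status = "no_path";

  if (depth_limit < 1) {
    return List::create(_["ptr"] = sg, _["status"] = sg->status,
                        _["branches"] = sg->branches, _["n_common"] = 0);
  }
  if (start == goal) {
    sg->status = "success";  // degenerate: anchors coincide
    return List::create(_["ptr"] = sg, _["status"] = sg->status,
                        _["branches"] = sg->branches, _["n_common"] = 0);
  }

  std::unordered_set<std::string> vis_f, vis_r;
  std::vector<std::string> fr_f, fr_r;
  vis_f.insert(start);
  fr_f.push_back(start);
  vis_r.insert(goal);
  fr_r.push_back(goal);

  // node-depth caps per frontier: ceil(d/2)+1 each side when
  // bidirectional, the full depth for a one-sided search
  int cap_f = bidirectional ? (depth_limit + 1) / 2 + 1 : depth_limit;
  int cap_r = bidirectional ? (depth_limit + 1) / 2 + 1 : 1;
  int depth_f = 1, depth_r = 1;
  bool ok = true;
  // strict alternation, forward first
  while (ok) {
    bool can_f = depth_f < cap_f && !fr_f.empty();
    bool can_r = depth_r < cap_r && !fr_r.empty();
    if (!can_f && !can_r) break;
    if (can_f) {
      ok = expand_level(*g, *sg, B, fr_f, vis_f, vis_r, true);
      ++depth_f;
      if (!ok) break;
    }
    can_r = depth_r < cap_r && !fr_r.empty();
    if (can_r) {
      ok = expand_level(*g, *sg, B, fr_r, vis_r, vis_f, false);
      ++depth_r;
    }
  }
  if (sg->status != "too_many_branches")
    sg->status = sg->common.empty() ? "no_path" : "success";
  return List::create(_["ptr"] = sg, _["status"] = sg->status,
                      _["branches"] = sg->branches,
                      _["n_common"] = (int)sg->common.size());
}

// ---- path enumeration -------------------------------------------------

// Exhaustive depth-limited DFS over the recorded search graph. Returns
// every start->goal node path with at most depth_limit nodes; bails out
// with too_many_paths once more than max_paths are found.
// [[Rcpp::export(name = ".enumerate_paths_cpp")]]
List enumerate_paths_cpp(SEXP sg_ptr, int max_paths) {
  XPtr<SearchGraph> sg(sg_ptr);
  List paths;
  if (sg->status != "success")
    return List::create(_["status"] = sg->status, _["paths"] = paths);

  std::vector<std::vector<std::string>> found;
  if (sg->start == sg->goal) {
    found.push_back(std::vector<std::string>(1, sg->start));
  } else {
    // iterative DFS carrying the current path
    std::vector<std::string> path;
    std::vector<std::pair<std::string, size_t>> stack;  // node, child index
    stack.push_back(std::make_pair(sg->start, 0));
    path.push_back(sg->start);
    double steps = 0;
    bool overflow = false;
    while (!stack.empty()) {
      if (++steps > 2e7) { overflow = true; break; }
      auto& top = stack.back();
      if (top.first == sg->goal) {
        found.push_back(path);
        if ((int)found.size() > max_paths) { overflow = true; break; }
        stack.pop_back();
        path.pop_back();
        continue;
      }
      std::vector<std::string>* kids = nullptr;
      auto it = sg->adj.find(top.first);
      if (it != sg->adj.end()) kids = &it->second;
      if ((int)path.size() >= sg->depth_limit || kids == nullptr ||
          top.second >= kids->size()) {
        stack.pop_back();
        path.pop_back();
        continue;
      }
      const std::string& child = (*kids)[top.second++];
      stack.push_back(std::make_pair(child, 0));
      path.push_back(child);
    }
    if (overflow)
      return List::create(_["status"] = "too_many_paths", _["paths"] = paths);
  }
  if (found.empty())
    return List::create(_["status"] = "no_path", _["paths"] = paths);
  if ((int)found.size() > max_paths)
    return List::create(_["status"] = "too_many_paths", _["paths"] = paths);
  paths = List(found.size());
  for (size_t i = 0; i < found.size(); ++i) paths[i] = wrap(found[i]);
  return List::create(_["status"] = "success", _["paths"] = paths);
}

// [[Rcpp::export(name = ".path_to_seq_cpp")]]
std::string path_to_seq_cpp(CharacterVector nodes) {
  if (nodes.size() == 0) stop("empty path");
  std::string s = upper_str(as<std::string>(nodes[0]));
  size_t k = s.size();
  for (R_xlen_t i = 1; i < nodes.size(); ++i) {
    std::string w = upper_str(as<std::string>(nodes[i]));
    if (w.size() != k) stop("path nodes must share one k");
    if (w.compare(0, k - 1, s, s.size() - k + 1, k - 1) != 0)
      stop("consecutive path nodes must overlap by k-1 bases");
    s.push_back(w[k - 1]);
  }
  return s;
}

// ---- consensus of alternate paths ------------------------------------

// Global alignment (Needleman-Wunsch; match +1, mismatch -1, gap -2) with
// deterministic traceback preference diagonal > up > left.
static void nw_align(const std::string& a, const std::string& b,
                     std::string& ga, std::string& gb) {
  int n = (int)a.size(), m = (int)b.size();
  const int GAP = -2, MATCH = 1, MISMATCH = -1;
  std::vector<std::vector<int>> S(n + 1, std::vector<int>(m + 1, 0));
  for (int i = 1; i <= n; ++i) S[i][0] = i * GAP;
  for (int j = 1; j <= m; ++j) S[0][j] = j * GAP;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      int d = S[i - 1][j - 1] + (a[i - 1] == b[j - 1] ? MATCH : MISMATCH);
      int u = S[i - 1][j] + GAP;
      int l = S[i][j - 1] + GAP;
      S[i][j] = std::max(d, std::max(u, l));
    }
  ga.clear();
  gb.clear();
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i][j] == S[i - 1][j - 1] + (a[i - 1] == b[j - 1] ? MATCH : MISMATCH)) {
      ga.push_back(a[i - 1]);
      gb.push_back(b[j - 1]);
      --i;
      --j;
    } else if (i > 0 && S[i][j] == S[i - 1][j] + GAP) {
      ga.push_back(a[i - 1]);
      gb.push_back('-');
      --i;
    } else {
      ga.push_back('-');
      gb.push_back(b[j - 1]);
      --j;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
}

// Majority base of an alignment column; ties prefer a base over a gap and
// the lexicographically smallest base among tied bases.
static char column_consensus(const std::vector<std::string>& rows, size_t col) {
  int cnt[5] = {0, 0, 0, 0, 0};  // A C G T -
  for (const auto& r : rows) {
    switch (r[col]) {
      case 'A': ++cnt[0]; break;
      case 'C': ++cnt[1]; break;
      case 'G': ++cnt[2]; break;
      case 'T': ++cnt[3]; break;
      default: ++cnt[4];
    }
  }
  int best = *std::max_element(cnt, cnt + 5);
  static const char SYM[5] = {'A', 'C', 'G', 'T', '-'};
  for (int i = 0; i < 4; ++i)
    if (cnt[i] == best) return SYM[i];
  return '-';
}

// Progressive multiple alignment (adequate for the <= P alternate paths
// collapsed to a consensus), then column-wise vote. Pairwise mismatch and
// identity are computed on the aligned rows, skipping columns where both
// members are gaps; a gap against a base counts as a mismatch column.
// [[Rcpp::export(name = ".consensus_cpp")]]
List consensus_cpp(CharacterVector seqs, double M, double X) {
  int n = (int)seqs.size();
  if (n < 1) stop("consensus needs at least one path");
  std::vector<std::string> in(n);
  bool same_len = true;
  for (int i = 0; i < n; ++i) {
    in[i] = upper_str(as<std::string>(seqs[i]));
    if (in[i].size() != in[0].size()) same_len = false;
  }
  if (n == 1)
    return List::create(_["status"] = "success", _["seq"] = in[0],
                        _["max_mismatches"] = 0.0, _["min_identity"] = 100.0);

  std::vector<std::string> rows;
  if (same_len) {
    rows = in;
  } else {
    // progressive MSA against the running consensus
    rows.push_back(in[0]);
    for (int s = 1; s < n; ++s) {
      std::string cons(rows[0].size(), 'N');
      for (size_t c = 0; c < rows[0].size(); ++c)
        cons[c] = column_consensus(rows, c);
      std::string gc, gs;
      nw_align(cons, in[s], gc, gs);
      // propagate gaps opened in the consensus into all existing rows
      std::vector<std::string> nrows(rows.size());
      size_t ci = 0;
      for (size_t c = 0; c < gc.size(); ++c) {
        if (gc[c] == '-') {
          for (size_t r = 0; r < rows.size(); ++r) nrows[r].push_back('-');
        } else {
          for (size_t r = 0; r < rows.size(); ++r)
            nrows[r].push_back(rows[r][ci]);
          ++ci;
        }
      }
      nrows.push_back(gs);
      rows.swap(nrows);
    }
  }

  size_t ncol = rows[0].size();
  double max_mm = 0.0, min_id = 100.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double cols = 0, match = 0;
      for (size_t c = 0; c < ncol; ++c) {
        if (rows[i][c] == '-' && rows[j][c] == '-') continue;
        cols += 1;
        if (rows[i][c] == rows[j][c]) match += 1;
      }
      double mm = cols - match;
      double id = cols > 0 ? 100.0 * match / cols : 100.0;
      if (mm > max_mm) max_mm = mm;
      if (id < min_id) min_id = id;
    }
  std::string status = "success";
  if (max_mm > M || min_id < X) status = "paths_disagree";
  std::string cons;
  for (size_t c = 0; c < ncol; ++c) {
    char b = column_consensus(rows, c);
    if (b != '-') cons.push_back(b);
  }
  return List::create(_["status"] = status, _["seq"] = cons,
                      _["max_mismatches"] = max_mm, _["min_identity"] = min_id);
}

// ---- read-pair connection --------------------------------------------

// Join a read pair through the graph. read2 is as sequenced (3' facing
// the gap); its anchor is reverse-complemented onto the fragment's
// forward strand to serve as the search goal.
// [[Rcpp::export(name = ".connect_pair_cpp")]]
List connect_pair_cpp(SEXP ptr, std::string read1, std::string read2, double B,
                      double F, int P, double M, double X, bool all_paths) {
  XPtr<Graph> g(ptr);
  int k = g->k;
  read1 = upper_str(read1);
  read2 = upper_str(read2);
  List fail_tpl = List::create(
      _["status"] = "no_anchor", _["pseudo"] = R_NilValue,
      _["connector"] = R_NilValue, _["offset1"] = -1, _["offset2"] = -1,
      _["n_paths"] = 0, _["branches"] = 0.0, _["paths"] = R_NilValue,
      _["depth_limit"] = 0);

  int o1, r1len, o2, r2len;
  select_anchor_impl(*g, read1, &o1, &r1len);
  select_anchor_impl(*g, read2, &o2, &r2len);
  if (o1 < 0 || o2 < 0) return fail_tpl;
  fail_tpl["offset1"] = o1;
  fail_tpl["offset2"] = o2;

  std::string start = read1.substr(o1, k);
  std::string goal = rc_str(read2.substr(o2, k));
  // connecting path may not push the pseudo-read past F bases
  int depth_limit = (int)(F - o1 - o2 - k + 1);
  fail_tpl["depth_limit"] = depth_limit;
  if (depth_limit < 1) {
    fail_tpl["status"] = "no_path";
    return fail_tpl;
  }

  List bfs = bfs_cpp(ptr, start, goal, depth_limit, B, true);
  fail_tpl["branches"] = bfs["branches"];
  std::string status = as<std::string>(bfs["status"]);
  if (status != "success") {
    fail_tpl["status"] = status;
    return fail_tpl;
  }
  List en = enumerate_paths_cpp(bfs["ptr"], P);
  status = as<std::string>(en["status"]);
  if (status != "success") {
    fail_tpl["status"] = status;
    return fail_tpl;
  }
  List plist = en["paths"];
  int np = plist.size();
  CharacterVector pseqs(np);
  for (int i = 0; i < np; ++i)
    pseqs[i] = path_to_seq_cpp(plist[i]);
  fail_tpl["n_paths"] = np;
  List cons = consensus_cpp(pseqs, M, X);
  status = as<std::string>(cons["status"]);
  if (status != "success") {
    fail_tpl["status"] = status;
    if (all_paths) fail_tpl["paths"] = pseqs;
    return fail_tpl;
  }
  std::string connector = as<std::string>(cons["seq"]);
  std::string rc2 = rc_str(read2);
  // flanks verbatim from the reads; bases between anchors from the graph
  std::string pseudo =
      read1.substr(0, o1) + connector + rc2.substr(rc2.size() - o2);
  fail_tpl["status"] = "success";
  fail_tpl["pseudo"] = pseudo;
  fail_tpl["connector"] = connector;
  if (all_paths) fail_tpl["paths"] = pseqs;
  return fail_tpl;
}
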