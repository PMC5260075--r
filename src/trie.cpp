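#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Alignment cell: edit cost split by operation. Insertions/deletions are
// relative to the library (reference) sequence: an insertion is an extra
// read base, a deletion is a reference base absent from the read.
struct Cell {
  int cost, mism, ins, del;
};

// Deterministic preference: lowest total cost, then fewest indels, then
// fewest insertions.
static inline bool better(const Cell &a, const Cell &b) {
  if (a.cost != b.cost) return a.cost < b.cost;
  const int ai = a.ins + a.del, bi = b.ins + b.del;
  if (ai != bi) return ai < bi;
  return a.ins < b.ins;
}

static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

struct TrieNode {
  int child[4];
  std::vector<int> term;  // indices of library records ending here
  TrieNode() { child[0] = child[1] = child[2] = child[3] = -1; }
};

struct Trie {
  std::vector<TrieNode> nodes;
  std::vector<std::string> ids;
  int max_depth;
  Trie() : max_depth(0) { nodes.push_back(TrieNode()); }
};

// [[Rcpp::export(name = ".trie_build")]]
SEXP trie_build(CharacterVector seqs, CharacterVector ids) {
  Trie *tr = new Trie();
  tr->nodes.reserve(seqs.size() * 8 + 1);
  for (int k = 0; k < seqs.size(); ++k) {
    std::string s = as<std::string>(seqs[k]);
    if (s.empty()) {
      delete tr;
      stop("empty sequence at position %d", k + 1);
    }
    int cur = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      int b = base_idx(s[p]);
      if (b < 0) {
        delete tr;
        stop("non-ACGT base '%c' in sequence %d", s[p], k + 1);
      }
      if (tr->nodes[cur].child[b] < 0) {
        tr->nodes[cur].child[b] = (int)tr->nodes.size();
        tr->nodes.push_back(TrieNode());
      }
      cur = tr->nodes[cur].child[b];
    }
    tr->nodes[cur].term.push_back(k);
    if ((int)s.size() > tr->max_depth) tr->max_depth = (int)s.size();
    tr->ids.push_back(as<std::string>(ids[k]));
  }
  XPtr<Trie> p(tr, true);
  return p;
}

// [[Rcpp::export(name = ".trie_size")]]
IntegerVector trie_size(SEXP triePtr) {
  XPtr<Trie> tr(triePtr);
  return IntegerVector::create(_["nodes"] = (int)tr->nodes.size(),
                               _["sequences"] = (int)tr->ids.size(),
                               _["max_depth"] = tr->max_depth);
}

struct Hit {
  Cell c;
  int consumed;
  bool set;
};

// Reusable search workspace: one DP row per trie depth, plus the per-id
// best-hit table, so batch mapping allocates nothing per read.
struct SearchSpace {
  std::vector<std::vector<Cell> > rows;
  std::vector<Hit> best;
};

// Recursive DFS over depth-indexed row buffers: ws.rows[d] holds the DP
// row of the node currently visited at depth d. A sibling only reuses
// ws.rows[d + 1] after the previous child's subtree has been fully
// explored, so one buffer per depth suffices and nothing is allocated
// per read.
static void dfs_ws(const Trie &tr, int node, int depth,
                   const std::string &segment, int Lc, int budget,
                   SearchSpace &ws) {
  const TrieNode &nd = tr.nodes[node];
  const std::vector<Cell> &row = ws.rows[depth];
  if (!nd.term.empty()) {
    Cell bc = {0, 0, 0, 0};
    int bj = -1;
    for (int j = 0; j <= Lc; ++j) {
      if (row[j].cost > budget) continue;
      if (bj < 0 || !better(bc, row[j])) {
        bc = row[j];
        bj = j;
      }
    }
    if (bj >= 0) {
      for (size_t t = 0; t < nd.term.size(); ++t) {
        Hit &h = ws.best[nd.term[t]];
        if (!h.set || better(bc, h.c)) {
          h.c = bc;
          h.consumed = bj;
          h.set = true;
        }
      }
    }
  }
  for (int b = 0; b < 4; ++b) {
    const int ch = nd.child[b];
    if (ch < 0) continue;
    const char base = "ACGT"[b];
    std::vector<Cell> &nrow = ws.rows[depth + 1];
    nrow[0] = Cell{depth + 1, 0, 0, depth + 1};
    int minc = nrow[0].cost;
    for (int j = 1; j <= Lc; ++j) {
      Cell cand = row[j - 1];
      if (segment[j - 1] != base) {
        cand.cost += 1;
        cand.mism += 1;
      }
      Cell left = nrow[j - 1];
      left.cost += 1;
      left.ins += 1;
      if (better(left, cand)) cand = left;
      Cell up = row[j];
      up.cost += 1;
      up.del += 1;
      if (better(up, cand)) cand = up;
      nrow[j] = cand;
      if (cand.cost < minc) minc = cand.cost;
    }
    if (minc <= budget) dfs_ws(tr, ch, depth + 1, segment, Lc, budget, ws);
  }
}

static void search_into(const Trie &tr, const std::string &segment,
                        int max_errors, SearchSpace &ws) {
  const int n = (int)tr.ids.size();
  int Lc = (int)segment.size();
  const int cap = tr.max_depth + max_errors;
  if (Lc > cap) Lc = cap;
  if ((int)ws.rows.size() < (size_t)tr.max_depth + 1)
    ws.rows.resize(tr.max_depth + 1);
  for (int d = 0; d <= tr.max_depth; ++d)
    if ((int)ws.rows[d].size() < Lc + 1) ws.rows[d].resize(Lc + 1);
  if ((int)ws.best.size() != n) ws.best.resize(n);
  for (int i = 0; i < n; ++i) ws.best[i].set = false;
  for (int j = 0; j <= Lc; ++j) ws.rows[0][j] = Cell{j, 0, j, 0};
  dfs_ws(tr, 0, 0, segment, Lc, max_errors, ws);
}

// [[Rcpp::export(name = ".trie_search")]]
DataFrame trie_search(SEXP triePtr, std::string segment, int max_errors) {
  XPtr<Trie> tr(triePtr);
  const int n = (int)tr->ids.size();
  SearchSpace ws;
  search_into(*tr, segment, max_errors, ws);
  std::vector<std::string> oid;
  std::vector<int> oerr, omis, oins, odel, ocon;
  for (int i = 0; i < n; ++i) {
    if (!ws.best[i].set) continue;
    oid.push_back(tr->ids[i]);
    oerr.push_back(ws.best[i].c.cost);
    omis.push_back(ws.best[i].c.mism);
    oins.push_back(ws.best[i].c.ins);
    odel.push_back(ws.best[i].c.del);
    ocon.push_back(ws.best[i].consumed);
  }
  return DataFrame::create(
      _["barcode_id"] = oid, _["errors"] = oerr, _["mismatches"] = omis,
      _["insertions"] = oins, _["deletions"] = odel, _["consumed"] = ocon,
      _["stringsAsFactors"] = false);
}

static std::vector<Cell> dp_table(const std::string &a, const std::string &b);

// Exact walk: ids of every library sequence that is a verbatim prefix of
// seg. A 0-error hit is always the unique minimum against any inexact
// hit, so reads with an exact match never need the full DFS; ambiguity
// can then only come from a second exact (identical or nested) barcode.
static void exact_prefix_hits(const Trie &tr, const std::string &seg,
                              std::vector<int> &out) {
  out.clear();
  int cur = 0;
  for (size_t p = 0; p < seg.size(); ++p) {
    const int b = base_idx(seg[p]);
    if (b < 0) return;
    cur = tr.nodes[cur].child[b];
    if (cur < 0) return;
    for (size_t t = 0; t < tr.nodes[cur].term.size(); ++t)
      out.push_back(tr.nodes[cur].term[t]);
  }
}

// Rolling-row prefix alignment: minimal cost of ref against any prefix of
// query, with the consumed length (largest j at the minimal cost).
static int prefix_cost(const std::string &ref, const std::string &query,
                       std::vector<int> &prev, std::vector<int> &cur,
                       int *consumed) {
  const int m = (int)ref.size(), n = (int)query.size();
  prev.assign(n + 1, 0);
  cur.assign(n + 1, 0);
  for (int j = 0; j <= n; ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    for (int j = 1; j <= n; ++j) {
      int c = prev[j - 1] + (ref[i - 1] != query[j - 1] ? 1 : 0);
      if (cur[j - 1] + 1 < c) c = cur[j - 1] + 1;
      if (prev[j] + 1 < c) c = prev[j] + 1;
      cur[j] = c;
    }
    std::swap(prev, cur);
  }
  int bc = prev[0], bj = 0;
  for (int j = 1; j <= n; ++j)
    if (prev[j] <= bc) { bc = prev[j]; bj = j; }
  *consumed = bj;
  return bc;
}

// Classify a batch of unique read sequences in one pass: optional primer
// prefix alignment locates the barcode start (net primer indels shift
// it), then the trie is searched with the barcode budget. Returns, per
// read: status (0 unique, 1 ambiguous, 2 unmapped), the hit index
// (1-based into the trie's insertion order, NA otherwise), the error
// count and the consumed barcode segment for mutated unique hits.
// start_pos: 0-based fixed barcode start, or -1 for primer/auto.
// [[Rcpp::export(name = ".map_batch")]]
List map_batch(SEXP triePtr, CharacterVector seqs, std::string primer,
               int primer_budget, int barcode_budget, int start_pos) {
  XPtr<Trie> tr(triePtr);
  const int nr = seqs.size();
  IntegerVector status(nr), hit(nr), errors(nr);
  CharacterVector variant(nr);
  SearchSpace ws;
  std::vector<int> prow, crow, exact_ids;
  for (int k = 0; k < nr; ++k) {
    std::string read = as<std::string>(seqs[k]);
    int start = 0;
    if (start_pos >= 0) {
      start = start_pos;
    } else if (!primer.empty()) {
      if (read.compare(0, primer.size(), primer) == 0) {
        start = (int)primer.size();  // verbatim primer: no DP needed
      } else {
        int consumed = 0;
        const int bc = prefix_cost(primer, read, prow, crow, &consumed);
        if (bc > primer_budget) {
          status[k] = 2; hit[k] = NA_INTEGER; errors[k] = NA_INTEGER;
          continue;
        }
        start = consumed;
      }
    }
    if (start >= (int)read.size()) {
      status[k] = 2; hit[k] = NA_INTEGER; errors[k] = NA_INTEGER;
      continue;
    }
    const std::string seg = read.substr(start);
    // exact-walk shortcut: a 0-error hit is always the unique minimum,
    // so only a second exact (identical/nested) barcode can tie with it
    exact_prefix_hits(*tr, seg, exact_ids);
    if (!exact_ids.empty()) {
      if (exact_ids.size() > 1) {
        status[k] = 1; hit[k] = NA_INTEGER; errors[k] = 0;
      } else {
        status[k] = 0; hit[k] = exact_ids[0] + 1;
        errors[k] = 0; variant[k] = NA_STRING;
      }
      continue;
    }
    search_into(*tr, seg, barcode_budget, ws);
    int best_i = -1, nmin = 0;
    for (int i = 0; i < (int)ws.best.size(); ++i) {
      if (!ws.best[i].set) continue;
      if (best_i < 0 || ws.best[i].c.cost < ws.best[best_i].c.cost) {
        best_i = i; nmin = 1;
      } else if (ws.best[i].c.cost == ws.best[best_i].c.cost) {
        nmin += 1;
      }
    }
    if (best_i < 0) {
      status[k] = 2; hit[k] = NA_INTEGER; errors[k] = NA_INTEGER;
    } else if (nmin > 1) {
      status[k] = 1; hit[k] = NA_INTEGER;
      errors[k] = ws.best[best_i].c.cost;
    } else {
      status[k] = 0; hit[k] = best_i + 1;
      errors[k] = ws.best[best_i].c.cost;
      if (ws.best[best_i].c.cost > 0)
        variant[k] = seg.substr(0, ws.best[best_i].consumed);
      else
        variant[k] = NA_STRING;
    }
  }
  return List::create(_["status"] = status, _["hit"] = hit,
                      _["errors"] = errors, _["variant"] = variant);
}

// Full DP table of ref (rows) vs query (cols); shared by the pairwise
// distance modes and the primer/MID prefix aligner.
static std::vector<Cell> dp_table(const std::string &a, const std::string &b) {
  const int m = (int)a.size(), n = (int)b.size();
  std::vector<Cell> D((m + 1) * (n + 1));
  for (int j = 0; j <= n; ++j) D[j] = {j, 0, j, 0};
  for (int i = 1; i <= m; ++i) {
    Cell *cur = &D[i * (n + 1)];
    const Cell *prev = &D[(i - 1) * (n + 1)];
    cur[0].cost = i;
    cur[0].mism = 0;
    cur[0].ins = 0;
    cur[0].del = i;
    for (int j = 1; j <= n; ++j) {
      Cell cand = prev[j - 1];
      if (a[i - 1] != b[j - 1]) {
        cand.cost += 1;
        cand.mism += 1;
      }
      Cell left = cur[j - 1];
      left.cost += 1;
      left.ins += 1;
      if (better(left, cand)) cand = left;
      Cell up = prev[j];
      up.cost += 1;
      up.del += 1;
      if (better(up, cand)) cand = up;
      cur[j] = cand;
    }
  }
  return D;
}

// [[Rcpp::export(name = ".edit_static")]]
int edit_static(std::string a, std::string b) {
  std::vector<Cell> D = dp_table(a, b);
  return D[(a.size() + 1) * (b.size() + 1) - 1].cost;
}

// Minimal edit distance between ref and any prefix of query, with the
// consumed query length and the operation breakdown of the chosen alignment.
// [[Rcpp::export(name = ".prefix_align")]]
IntegerVector prefix_align(std::string ref, std::string query) {
  const int m = (int)ref.size(), n = (int)query.size();
  std::vector<Cell> D = dp_table(ref, query);
  const Cell *last = &D[m * (n + 1)];
  Cell bc = last[0];
  int bj = 0;
  // minimal cost, then longest consumed span: a shifted primer must claim
  // the inserted bases so the following segment starts where it should
  for (int j = 1; j <= n; ++j) {
    if (last[j].cost <= bc.cost) {
      bc = last[j];
      bj = j;
    }
  }
  return IntegerVector::create(_["errors"] = bc.cost, _["mismatches"] = bc.mism,
                               _["insertions"] = bc.ins,
                               _["deletions"] = bc.del, _["consumed"] = bj);
}

// True iff cand is at static distance >= min_dist from every sequence in
// seqs (early exit; length-difference lower bound applied first).
// [[Rcpp::export(name = ".dist_at_least")]]
bool dist_at_least(std::string cand, CharacterVector seqs, int min_dist) {
  const int lc = (int)cand.size();
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if (std::abs((int)s.size() - lc) >= min_dist) continue;
    if (edit_static(cand, s) < min_dist) return false;
  }
  return true;
}

// All pairs within max_distance under static or dynamic comparison.
// One DP table per pair yields the static distance D[m,n], the dynamic
// distance in both directions (min over the last row / last column), and
// the reported dynamic value is the smaller of the two directions.
// [[Rcpp::export(name = ".pair_report")]]
DataFrame pair_report(CharacterVector seqs, int max_distance) {
  const int n = seqs.size();
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
  std::vector<int> oi, oj, ost, ody;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const std::string &a = ss[i], &b = ss[j];
      // length difference bounds every distance variant we report
      const int la = (int)a.size(), lb = (int)b.size();
      std::vector<Cell> D = dp_table(a, b);
      const int stat = D[(la + 1) * (lb + 1) - 1].cost;
      int dab = D[la * (lb + 1)].cost;
      for (int q = 1; q <= lb; ++q)
        dab = std::min(dab, D[la * (lb + 1) + q].cost);
      int dba = D[lb].cost;
      for (int p = 1; p <= la; ++p) dba = std::min(dba, D[p * (lb + 1) + lb].cost);
      const int dyn = std::min(dab, dba);
      if (stat <= max_distance || dyn <= max_distance) {
        oi.push_back(i + 1);
        oj.push_back(j + 1);
        ost.push_back(stat);
        ody.push_back(dyn);
      }
    }
  }
  return DataFrame::create(_["i"] = oi, _["j"] = oj,
                           _["distance_static"] = ost,
                           _["distance_dynamic"] = ody,
                           _["stringsAsFactors"] = false);
}
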