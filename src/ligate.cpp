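#include <Rcpp.h>
using namespace Rcpp;

// Sequential uniform end-joining of a pool of linear molecules.
//
// type[i]: 0 = 5' adapter (right end ligation-competent only),
//          1 = block (both ends competent),
//          2 = 3' adapter (left end competent only).
//
// At each step one chain with an open right end and one with an open left
// end are drawn uniformly (equal end reactivity). Self-joining
// (circularization) and direct adapter-adapter dimerization are excluded
// in-model; joining continues until no two distinct chains present a
// permitted compatible pair. Uses R's RNG, so set.seed() applies.
//
// Returns molecule indices (1-based) concatenated chain by chain, plus the
// chain lengths.
// [[Rcpp::export]]
List ligate_chains(IntegerVector type) {
  const int n = type.size();
  if (n == 0) stop("empty pool");

  // chain state, indexed by chain id (initially chain i = molecule i)
  std::vector<int> head(n), tail(n), nxt(n, -1);
  for (int i = 0; i < n; ++i) head[i] = tail[i] = i;

  // open-end membership lists with position back-pointers (-1 = absent)
  std::vector<int> rlist, llist, rpos(n, -1), lpos(n, -1);
  rlist.reserve(n); llist.reserve(n);
  int nr_bare5 = 0, nl_bare3 = 0; // lone adapters still in the lists
  for (int i = 0; i < n; ++i) {
    if (type[i] != 2) { rpos[i] = rlist.size(); rlist.push_back(i); }
    if (type[i] != 0) { lpos[i] = llist.size(); llist.push_back(i); }
    if (type[i] == 0) ++nr_bare5;
    if (type[i] == 2) ++nl_bare3;
  }

  auto rm = [](std::vector<int>& list, std::vector<int>& pos, int chain) {
    int p = pos[chain];
    if (p < 0) return;
    int last = list.back();
    list[p] = last; pos[last] = p;
    list.pop_back(); pos[chain] = -1;
  };

  // a chain is a bare adapter iff it still consists of one adapter molecule
  auto bare5 = [&](int c) { return head[c] == tail[c] && type[head[c]] == 0; };
  auto bare3 = [&](int c) { return head[c] == tail[c] && type[head[c]] == 2; };

  RNGScope scope;
  auto pick = [](int m) { // uniform 0..m-1 via R RNG
    int k = (int)(unif_rand() * m);
    return k >= m ? m - 1 : k;
  };

  for (;;) {
    int nr = rlist.size(), nl = llist.size();
    if (nr == 0 || nl == 0) break;
    // only adapter-dimer joins left
    if (nr_bare5 == nr && nl_bare3 == nl) break;
    // lone chain with both ends open cannot self-ligate
    if (nr == 1 && nl == 1 && rlist[0] == llist[0]) break;

    int r, l;
    for (;;) {
      r = rlist[pick(nr)];
      l = llist[pick(nl)];
      if (r != l && !(bare5(r) && bare3(l))) break;
    }
    bool r_was_bare5 = bare5(r), l_was_bare3 = bare3(l);
    bool l_right_open = (rpos[l] >= 0);
    // join: tail of r ligates to head of l
    nxt[tail[r]] = head[l];
    tail[r] = tail[l];
    rm(llist, lpos, l);
    rm(rlist, rpos, l);
    if (!l_right_open) rm(rlist, rpos, r); // merged chain ends in a 3' adapter
    if (r_was_bare5) --nr_bare5;           // r is no longer a lone adapter
    if (l_was_bare3) --nl_bare3;
  }

  std::vector<bool> is_head(n, true);
  for (int i = 0; i < n; ++i) if (nxt[i] >= 0) is_head[nxt[i]] = false;

  std::vector<int> order, lens;
  order.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (!is_head[i]) continue;
    int len = 0;
    for (int m = i; m >= 0; m = nxt[m]) { order.push_back(m + 1); ++len; }
    lens.push_back(len);
  }
  return List::create(_["order"] = wrap(order), _["len"] = wrap(lens));
}
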