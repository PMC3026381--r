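#include <Rcpp.h>
#include <queue>
#include <vector>
#include <array>
using namespace Rcpp;

// Aho-Corasick multi-pattern search over the uppercase amino-acid
// alphabet. Linear in total pattern + text length plus output size,
// which keeps peptide-to-protein mapping sub-quadratic.

static const int ALPHA = 27; // 'A'..'Z' plus one bucket for anything else

static inline int code(char c) {
  if (c >= 'a' && c <= 'z') c = c - 'a' + 'A';
  if (c >= 'A' && c <= 'Z') return c - 'A';
  return 26;
}

// [[Rcpp::export(name = ".ac_search")]]
DataFrame ac_search(CharacterVector patterns, CharacterVector texts) {
  int np = patterns.size();
  std::vector<std::array<int, ALPHA>> go;
  std::vector<int> fail;
  std::vector<std::vector<int>> out;
  go.push_back({});
  go[0].fill(-1);
  fail.push_back(0);
  out.push_back({});
  std::vector<int> plen(np);

  for (int p = 0; p < np; ++p) {
    const char *s = CHAR(STRING_ELT(patterns, p));
    int node = 0, n = LENGTH(STRING_ELT(patterns, p));
    plen[p] = n;
    if (n == 0) stop("empty pattern");
    for (int i = 0; i < n; ++i) {
      int c = code(s[i]);
      if (go[node][c] == -1) {
        go[node][c] = (int)go.size();
        go.push_back({});
        go.back().fill(-1);
        fail.push_back(0);
        out.push_back({});
      }
      node = go[node][c];
    }
    out[node].push_back(p);
  }

  // BFS failure links; convert goto into full transition function
  std::queue<int> q;
  for (int c = 0; c < ALPHA; ++c) {
    if (go[0][c] == -1) {
      go[0][c] = 0;
    } else {
      fail[go[0][c]] = 0;
      q.push(go[0][c]);
    }
  }
  while (!q.empty()) {
    int u = q.front();
    q.pop();
    for (int pat : out[fail[u]]) out[u].push_back(pat);
    for (int c = 0; c < ALPHA; ++c) {
      int v = go[u][c];
      if (v == -1) {
        go[u][c] = go[fail[u]][c];
      } else {
        fail[v] = go[fail[u]][c];
        q.push(v);
      }
    }
  }

  std::vector<int> r_text, r_pat, r_start;
  for (int t = 0; t < texts.size(); ++t) {
    const char *s = CHAR(STRING_ELT(texts, t));
    int n = LENGTH(STRING_ELT(texts, t));
    int node = 0;
    for (int i = 0; i < n; ++i) {
      node = go[node][code(s[i])];
      for (int pat : out[node]) {
        r_text.push_back(t + 1);
        r_pat.push_back(pat + 1);
        r_start.push_back(i - plen[pat] + 2); // 1-based start offset
      }
    }
  }
  return DataFrame::create(_["text"] = r_text, _["pattern"] = r_pat,
                           _["start"] = r_start);
}
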