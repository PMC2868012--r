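// Aho-Corasick multi-pattern exact matcher over the DNA alphabet {A,C,G,T}.
// Any other character (N, lowercase slips, ...) matches nothing and resets
// the automaton to the root, so matches never span ambiguous bases.

#include <Rcpp.h>
#include <array>
#include <deque>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

class ACAutomaton {
public:
  // delta holds trie edges during construction (-1 = absent) and the dense
  // goto function afterwards; fail links point to the longest proper suffix
  // state; out[s] = 0-based indices of patterns recognized at state s.
  std::vector< std::array<int, 4> > delta;
  std::vector<int> fail;
  std::vector< std::vector<int> > out;
  std::vector<int> pat_len;
  int n_trie_states;
  double transitions;

  explicit ACAutomaton(const std::vector<std::string>& patterns)
    : n_trie_states(0), transitions(0.0) {
    delta.push_back({{-1, -1, -1, -1}});
    fail.push_back(0);
    out.push_back(std::vector<int>());

    for (int pi = 0; pi < (int) patterns.size(); ++pi) {
      const std::string& p = patterns[pi];
      if (p.empty()) stop("empty pattern at index %d", pi + 1);
      pat_len.push_back((int) p.size());
      int s = 0;
      for (size_t j = 0; j < p.size(); ++j) {
        int c = base_code(p[j]);
        if (c < 0)
          stop("pattern %d contains illegal character '%c' (alphabet is A/C/G/T)",
               pi + 1, p[j]);
        if (delta[s][c] < 0) {
          delta.push_back({{-1, -1, -1, -1}});
          fail.push_back(0);
          out.push_back(std::vector<int>());
          delta[s][c] = (int) delta.size() - 1;
        }
        s = delta[s][c];
      }
      out[s].push_back(pi); // duplicate patterns share this terminal state
    }
    n_trie_states = (int) delta.size();

    // Breadth-first failure-link computation; states are finalized in order
    // of increasing depth, so out[fail[t]] is complete when merged into out[t].
    std::deque<int> q;
    for (int c = 0; c < 4; ++c) {
      int t = delta[0][c];
      if (t < 0) {
        delta[0][c] = 0;
      } else {
        fail[t] = 0;
        q.push_back(t);
      }
    }
    while (!q.empty()) {
      int s = q.front();
      q.pop_front();
      for (int c = 0; c < 4; ++c) {
        int t = delta[s][c];
        if (t < 0) {
          delta[s][c] = delta[fail[s]][c];
        } else {
          fail[t] = delta[fail[s]][c];
          const std::vector<int>& fo = out[fail[t]];
          out[t].insert(out[t].end(), fo.begin(), fo.end());
          q.push_back(t);
        }
      }
    }
  }
};

// [[Rcpp::export(name = ".ac_build_cpp")]]
SEXP ac_build_cpp(std::vector<std::string> patterns) {
  if (patterns.empty()) stop("pattern list is empty");
  XPtr<ACAutomaton> ptr(new ACAutomaton(patterns), true);
  return ptr;
}

// [[Rcpp::export(name = ".ac_n_states_cpp")]]
int ac_n_states_cpp(SEXP aptr) {
  XPtr<ACAutomaton> ptr(aptr);
  return ptr->n_trie_states;
}

// Scans `text`; returns 1-based pattern indices and 0-based start offsets of
// every (possibly overlapping) occurrence, in left-to-right order.
// [[Rcpp::export(name = ".ac_scan_cpp")]]
List ac_scan_cpp(SEXP aptr, std::string text) {
  XPtr<ACAutomaton> ptr(aptr);
  ACAutomaton& A = *ptr;
  std::vector<int> mpat, mpos;
  int s = 0;
  const int n = (int) text.size();
  for (int i = 0; i < n; ++i) {
    int c = base_code(text[i]);
    A.transitions += 1.0;
    if (c < 0) {            // N or other symbol: matches nothing
      s = 0;
      continue;
    }
    s = A.delta[s][c];
    const std::vector<int>& hits = A.out[s];
    for (size_t k = 0; k < hits.size(); ++k) {
      int pid = hits[k];
      mpat.push_back(pid + 1);
      mpos.push_back(i - A.pat_len[pid] + 1);
    }
  }
  return List::create(_["pattern"] = wrap(mpat), _["start"] = wrap(mpos));
}

// [[Rcpp::export(name = ".ac_transitions_cpp")]]
double ac_transitions_cpp(SEXP aptr) {
  XPtr<ACAutomaton> ptr(aptr);
  return ptr->transitions;
}

// [[Rcpp::export(name = ".ac_reset_transitions_cpp")]]
void ac_reset_transitions_cpp(SEXP aptr) {
  XPtr<ACAutomaton> ptr(aptr);
  ptr->transitions = 0.0;
}
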