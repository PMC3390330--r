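#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Depth-first tree enumeration of primitive pseudoknot shadows with n arcs.
//
// A partial pattern token is grown one endpoint at a time.  Symbols are
// introduced in first-occurrence order (their left ends appear in
// alphabetical order, which is exactly the canonical token labelling), so
// every distinct token is generated along exactly one root-to-leaf path.
// Three rules prune the tree:
//   Rule 1: a symbol becomes right-eligible only one level after its left
//           end was emitted (no (p, p+1) arc).
//   Rule 2: closing a symbol must not complete a crossing-connected
//           component that contains no open symbol; such a component can
//           never be crossed by later arcs, so the leaf would be reducible
//           or contain a nested sub-diagram.
//   Rule 3: closing a symbol must not create the collapsible adjacent
//           pattern ...YX...XY... (two arcs that would form one stem).
// Leaves are folded into per-genus counters immediately (O(n) space); an
// optional collector stores the tokens for small n.

namespace {

struct EnumState {
    int n;                    // arcs
    int n2;                   // 2n endpoints
    std::vector<int> word;    // symbol id at each filled position (0-based)
    std::vector<int> posL;    // 1-based position of left end, 0 = unset
    std::vector<int> posR;    // 1-based position of right end, 0 = unset
    int k;                    // symbols introduced so far
    int level;                // endpoints placed
    std::vector<int64_t> genus_count;  // index = genus
    int64_t leaves;
    bool collect;
    std::vector<std::string> tokens;
};

// Number of cycles of r -> tau(sigma(r)) on the completed word:
// sigma swaps the two occurrences of each symbol, tau is the cyclic
// successor of 1..2n.
int loop_count(const EnumState& st) {
    int n2 = st.n2;
    std::vector<int> sigma(n2);
    for (int s = 0; s < st.n; ++s) {
        sigma[st.posL[s] - 1] = st.posR[s] - 1;
        sigma[st.posR[s] - 1] = st.posL[s] - 1;
    }
    std::vector<char> seen(n2, 0);
    int L = 0;
    for (int s0 = 0; s0 < n2; ++s0) {
        if (seen[s0]) continue;
        ++L;
        int r = s0;
        while (!seen[r]) {
            seen[r] = 1;
            r = (sigma[r] + 1) % n2;
        }
    }
    return L;
}

// Determined crossing test between symbols x and y.  A closed arc (a,b)
// crosses a closed arc (c,d) iff the endpoints interleave; it crosses an
// open symbol iff that symbol's left end lies strictly inside (a,b).
// Open-open crossings are undetermined and not needed.
inline bool det_cross(const EnumState& st, int x, int y) {
    bool xc = st.posR[x] != 0, yc = st.posR[y] != 0;
    if (xc && yc) {
        int a = st.posL[x], b = st.posR[x], c = st.posL[y], d = st.posR[y];
        return (a < c && c < b && b < d) || (c < a && a < d && d < b);
    }
    if (!xc && !yc) return false;
    if (!xc) std::swap(x, y);
    int a = st.posL[x], b = st.posR[x], l = st.posL[y];
    return a < l && l < b;
}

// Rule 2: after closing symbol e, is e's component (under determined
// crossings) still connected to an open symbol?
bool component_alive(const EnumState& st, int e) {
    std::vector<char> inc(st.k, 0);
    std::vector<int> queue;
    inc[e] = 1;
    queue.push_back(e);
    while (!queue.empty()) {
        int x = queue.back();
        queue.pop_back();
        for (int y = 0; y < st.k; ++y) {
            if (inc[y] || !det_cross(st, x, y)) continue;
            if (st.posR[y] == 0) return true;  // reached an open symbol
            inc[y] = 1;
            queue.push_back(y);
        }
    }
    return false;
}

std::string word_token(const EnumState& st) {
    std::string out;
    for (int p = 0; p < st.n2; ++p) {
        int s = st.word[p];
        if (s < 26) out.push_back('A' + s);
        else out += "a" + std::to_string(s - 25);
    }
    return out;
}

void leaf(EnumState& st) {
    int L = loop_count(st);
    int g = (st.n - L + 1) / 2;
    if (g >= (int)st.genus_count.size()) st.genus_count.resize(g + 1, 0);
    st.genus_count[g] += 1;
    st.leaves += 1;
    if (st.collect) st.tokens.push_back(word_token(st));
}

void dfs(EnumState& st) {
    int p = st.level + 1;  // 1-based position about to be filled
    // (a) introduce the next fresh symbol as a left end
    if (st.k < st.n) {
        int s = st.k;
        st.k += 1;
        st.posL[s] = p;
        st.word[p - 1] = s;
        st.level = p;
        dfs(st);
        st.level = p - 1;
        st.posL[s] = 0;
        st.k -= 1;
    }
    // (b) close an open symbol as a right end
    for (int e = 0; e < st.k; ++e) {
        if (st.posR[e] != 0) continue;       // already closed
        if (st.posL[e] == p - 1) continue;   // Rule 1
        // Rule 3: previous position is the right end of X whose left end
        // immediately follows e's left end -> collapsible stem
        if (p >= 2) {
            int X = st.word[p - 2];
            if (st.posR[X] == p - 1 && st.posL[X] == st.posL[e] + 1) continue;
        }
        st.posR[e] = p;
        st.word[p - 1] = e;
        st.level = p;
        if (p == st.n2) {
            leaf(st);
        } else if (component_alive(st, e)) {  // Rule 2
            dfs(st);
        }
        st.level = p - 1;
        st.posR[e] = 0;
    }
}

EnumState run_enum(int n, bool collect) {
    if (n < 2) stop("no primitive pseudoknot exists with fewer than 2 arcs");
    EnumState st;
    st.n = n;
    st.n2 = 2 * n;
    st.word.assign(st.n2, -1);
    st.posL.assign(n, 0);
    st.posR.assign(n, 0);
    st.k = 0;
    st.level = 0;
    st.leaves = 0;
    st.collect = collect;
    dfs(st);
    return st;
}

}  // namespace

// [[Rcpp::export(name = ".enum_counts_cpp")]]
NumericVector enum_counts_cpp(int n) {
    EnumState st = run_enum(n, false);
    int gmax = (int)st.genus_count.size() - 1;
    NumericVector out;
    CharacterVector names;
    for (int g = 0; g <= gmax; ++g) {
        if (st.genus_count[g] == 0) continue;
        out.push_back((double)st.genus_count[g]);
        names.push_back(std::to_string(g));
    }
    out.attr("names") = names;
    return out;
}

// [[Rcpp::export(name = ".enum_tokens_cpp")]]
CharacterVector enum_tokens_cpp(int n) {
    EnumState st = run_enum(n, true);
    return wrap(st.tokens);
}
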