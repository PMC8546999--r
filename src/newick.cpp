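#include <Rcpp.h>
#include <cstdlib>
#include <string>
#include <vector>

using namespace Rcpp;

// Newick -> balanced parentheses, names and branch lengths in preorder.
//
// Dialect: quoted labels with '' escaping; [] comments skipped (nesting
// allowed); underscores kept verbatim; internal labels are names, not
// support values; a missing branch length stays missing (NA), never 0.
// Errors report 1-based character offsets; end-of-input reports len+1.

namespace {

struct NewickParser {
  const std::string& s;
  size_t i;
  std::vector<int> bits;            // 1 = open, 0 = close
  std::vector<std::string> names;   // preorder
  std::vector<double> lens;
  std::vector<bool> has_len;

  explicit NewickParser(const std::string& text) : s(text), i(0) {}

  [[noreturn]] void fail(size_t pos, const std::string& msg) {
    stop("newick parse error at offset %d: %s", (int)(pos + 1), msg.c_str());
  }

  void skip_space_and_comments() {
    while (i < s.size()) {
      char c = s[i];
      if (c == ' ' || c == '\t' || c == '\n' || c == '\r') {
        ++i;
      } else if (c == '[') {
        size_t start = i;
        int depth = 0;
        while (i < s.size()) {
          if (s[i] == '[') ++depth;
          else if (s[i] == ']' && --depth == 0) { ++i; break; }
          ++i;
        }
        if (depth != 0) fail(start, "unterminated [] comment");
      } else {
        break;
      }
    }
  }

  static bool is_delim(char c) {
    return c == '(' || c == ')' || c == ',' || c == ':' || c == ';' ||
           c == '[' || c == ' ' || c == '\t' || c == '\n' || c == '\r';
  }

  std::string read_label() {
    skip_space_and_comments();
    std::string out;
    if (i < s.size() && s[i] == '\'') {
      size_t start = i++;
      for (;;) {
        if (i >= s.size()) fail(start, "unterminated quoted label");
        if (s[i] == '\'') {
          if (i + 1 < s.size() && s[i + 1] == '\'') { out += '\''; i += 2; }
          else { ++i; break; }
        } else {
          out += s[i++];
        }
      }
      return out;
    }
    while (i < s.size() && !is_delim(s[i])) out += s[i++];
    return out;
  }

  void read_length(int node) {
    skip_space_and_comments();
    if (i >= s.size() || s[i] != ':') return;
    ++i;
    skip_space_and_comments();
    size_t start = i;
    while (i < s.size()) {
      char c = s[i];
      if ((c >= '0' && c <= '9') || c == '+' || c == '-' || c == '.' ||
          c == 'e' || c == 'E') ++i;
      else break;
    }
    if (i == start) fail(start, "expected branch length after ':'");
    std::string tok = s.substr(start, i - start);
    char* end = nullptr;
    double v = std::strtod(tok.c_str(), &end);
    if (end != tok.c_str() + tok.size())
      fail(start, "invalid branch length '" + tok + "'");
    lens[node] = v;
    has_len[node] = true;
  }

  int new_node() {
    names.push_back("");
    lens.push_back(NA_REAL);
    has_len.push_back(false);
    bits.push_back(1);
    return (int)names.size() - 1;
  }

  void parse() {
    skip_space_and_comments();
    if (i >= s.size()) fail(i, "empty input");
    std::vector<int> open_stack;      // internal nodes awaiting ')'
    bool expect_node = true;
    for (;;) {
      if (expect_node) {
        skip_space_and_comments();
        if (i >= s.size()) fail(i, "unexpected end of input");
        if (s[i] == '(') {
          open_stack.push_back(new_node());
          ++i;
          continue;                   // first child of the new clade
        }
        int node = new_node();
        names[node] = read_label();
        read_length(node);
        bits.push_back(0);
        expect_node = false;
        continue;
      }
      skip_space_and_comments();
      if (i >= s.size()) fail(i, "unexpected end of input");
      char c = s[i];
      if (c == ',') {
        ++i;
        expect_node = true;
      } else if (c == ')') {
        if (open_stack.empty()) fail(i, "unbalanced ')'");
        int node = open_stack.back();
        open_stack.pop_back();
        ++i;
        names[node] = read_label();
        read_length(node);
        bits.push_back(0);
      } else if (c == ';') {
        if (!open_stack.empty()) fail(i, "unbalanced '(': expected ')'");
        ++i;
        skip_space_and_comments();
        if (i < s.size()) fail(i, "trailing characters after ';'");
        return;
      } else {
        fail(i, std::string("unexpected character '") + c + "'");
      }
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List parse_newick_cpp(std::string text) {
  NewickParser p(text);
  p.parse();
  int n = (int)p.names.size();
  LogicalVector bits(p.bits.size());
  for (size_t k = 0; k < p.bits.size(); ++k) bits[k] = p.bits[k] == 1;
  CharacterVector nm(n);
  NumericVector ln(n);
  for (int k = 0; k < n; ++k) {
    nm[k] = p.names[k];
    ln[k] = p.has_len[k] ? p.lens[k] : NA_REAL;
  }
  return List::create(_["bits"] = bits, _["names"] = nm, _["lengths"] = ln);
}

// Parse decimal strings with the exact strtod the newick parser uses, so
// the writer can verify its formatted lengths round-trip bit for bit.
// [[Rcpp::export]]
NumericVector strtod_cpp(CharacterVector s) {
  NumericVector out(s.size());
  for (R_xlen_t k = 0; k < s.size(); ++k)
    out[k] = std::strtod(CHAR(STRING_ELT(s, k)), nullptr);
  return out;
}

// Per-node index over a balanced parenthesis vector: opening/closing
// positions (1-based) and parent preorder rank (0 for the root).
// [[Rcpp::export]]
List bp_index_cpp(LogicalVector bits) {
  int m = bits.size();
  if (m == 0 || m % 2 != 0) stop("bit vector length must be positive and even");
  int n = m / 2;
  IntegerVector open_pos(n), close_pos(n), parent(n);
  std::vector<int> stack;
  stack.reserve(64);
  int node = -1;
  for (int p = 0; p < m; ++p) {
    if (bits[p] == NA_LOGICAL) stop("bit vector contains NA");
    if (bits[p]) {
      ++node;
      if (node >= n) stop("unbalanced parenthesis vector: too many opens");
      open_pos[node] = p + 1;
      parent[node] = stack.empty() ? 0 : stack.back() + 1;
      stack.push_back(node);
    } else {
      if (stack.empty()) stop("unbalanced parenthesis vector at position %d", p + 1);
      close_pos[stack.back()] = p + 1;
      stack.pop_back();
    }
  }
  if (!stack.empty() || node != n - 1)
    stop("unbalanced parenthesis vector");
  return List::create(_["open_pos"] = open_pos, _["close_pos"] = close_pos,
                      _["parent"] = parent);
}
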