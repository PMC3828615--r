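#include <Rcpp.h>
using namespace Rcpp;

// 'N' mismatches every base, including another 'N'.
static inline bool base_match(char a, char b) {
  return a == b && a != 'N' && a != 'n';
}

// Minimal Hamming distance of `read` over all same-length windows of `ref`.
// Exact whenever the result is <= cap; anything larger is reported as some
// value > cap. Reads longer than the reference never hit (INT_MAX).
static int min_window_dist(const char *read, int rl, const char *ref, int fl,
                           int cap) {
  if (rl > fl) return INT_MAX;
  int best = INT_MAX;
  for (int off = 0; off <= fl - rl; ++off) {
    int d = 0;
    for (int i = 0; i < rl; ++i) {
      if (!base_match(read[i], ref[off + i])) {
        if (++d > cap) break;
      }
    }
    if (d < best) best = d;
    if (best == 0) return 0;
  }
  return best;
}

//' @name hamming_map_cpp
//' @title Mismatch-tolerant read-to-reference assignment (internal)
//' @description For each read, finds the reference entries at minimal Hamming
//'   distance over all same-length windows, keeping hits with distance
//'   <= max_mismatch. Used by [map_to_reference()].
//' @keywords internal
// [[Rcpp::export]]
List hamming_map_cpp(CharacterVector reads, CharacterVector refs,
                     int max_mismatch) {
  int nr = reads.size(), nf = refs.size();
  List hits(nr);
  IntegerVector dist(nr, NA_INTEGER);
  std::vector<std::string> refstr(nf);
  for (int j = 0; j < nf; ++j) refstr[j] = as<std::string>(refs[j]);
  std::vector<int> buf;
  for (int i = 0; i < nr; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int best = max_mismatch + 1;
    buf.clear();
    for (int j = 0; j < nf; ++j) {
      int d = min_window_dist(rd.c_str(), (int)rd.size(), refstr[j].c_str(),
                              (int)refstr[j].size(), max_mismatch);
      if (d < best) {
        best = d;
        buf.clear();
        buf.push_back(j + 1);
      } else if (d == best && d <= max_mismatch) {
        buf.push_back(j + 1);
      }
    }
    if (best <= max_mismatch) {
      hits[i] = IntegerVector(buf.begin(), buf.end());
      dist[i] = best;
    } else {
      hits[i] = IntegerVector(0);
    }
  }
  return List::create(_["hits"] = hits, _["distance"] = dist);
}

//' @name trim_adapter_cpp
//' @title 3'-adapter trimming by exact prefix match (internal)
//' @description Cuts each read at the leftmost position where a prefix of the
//'   adapter of length >= min_overlap matches exactly, allowing the adapter
//'   to run off the read's 3' end. Used by [trim_adapter()].
//' @keywords internal
// [[Rcpp::export]]
CharacterVector trim_adapter_cpp(CharacterVector reads, std::string adapter,
                                 int min_overlap) {
  int n = reads.size();
  int al = (int)adapter.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int rl = (int)rd.size();
    int cut = rl;
    for (int pos = 0; pos + min_overlap <= rl; ++pos) {
      int ov = std::min(al, rl - pos);
      bool ok = true;
      for (int k = 0; k < ov; ++k) {
        if (rd[pos + k] != adapter[k]) { ok = false; break; }
      }
      if (ok) { cut = pos; break; }
    }
    out[i] = rd.substr(0, cut);
  }
  return out;
}
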