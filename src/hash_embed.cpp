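#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <string>
#include <vector>
#include <unordered_map>

// Deterministic text -> unit vector embedding. FNV-1a over UTF-8 bytes mixed
// with the seed feeds a splitmix64 stream; Box-Muller turns it into gaussian
// coordinates which are L2-normalised. Pure integer/IEEE arithmetic, so the
// result is identical across platforms and R sessions.

static inline std::uint64_t splitmix64(std::uint64_t &state) {
  std::uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline std::uint64_t fnv1a(const std::string &text, std::uint64_t seed) {
  std::uint64_t h = 1469598103934665603ULL ^ (seed * 0x9E3779B97F4A7C15ULL + 0xD1B54A32D192ED03ULL);
  for (unsigned char ch : text) {
    h ^= static_cast<std::uint64_t>(ch);
    h *= 1099511628211ULL;
  }
  return h;
}

static inline double u01(std::uint64_t &state) {
  // 53-bit mantissa uniform in (0, 1); never exactly 0 (log() safe)
  double u = (splitmix64(state) >> 11) * (1.0 / 9007199254740992.0);
  return (u <= 0.0) ? 5e-324 : u;
}

static std::vector<double> hash_vector(const std::string &text, int d, std::uint64_t seed) {
  std::uint64_t state = fnv1a(text, seed);
  std::vector<double> v(static_cast<size_t>(d));
  for (int j = 0; j < d; j += 2) {
    double u1 = u01(state), u2 = u01(state);
    double r = std::sqrt(-2.0 * std::log(u1));
    v[j] = r * std::cos(2.0 * M_PI * u2);
    if (j + 1 < d) v[j + 1] = r * std::sin(2.0 * M_PI * u2);
  }
  double nrm = 0.0;
  for (double x : v) nrm += x * x;
  nrm = std::sqrt(nrm);
  if (nrm > 0) for (double &x : v) x /= nrm;
  return v;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_hash_embed(std::string text, int d, double seed) {
  std::vector<double> v = hash_vector(text, d, static_cast<std::uint64_t>(seed));
  return Rcpp::NumericVector(v.begin(), v.end());
}

// Subword-compositional token embedding (fastText-style): the normalised
// mean of the hash vectors of the token's character 3-5-grams (with < >
// boundary markers) plus the whole token. Tokens sharing morphemes get
// correlated vectors, mirroring the semantic smoothness of a trained
// encoder; unrelated tokens stay near-orthogonal.
static std::vector<double> token_vector(const std::string &tok, int d,
                                        std::uint64_t seed) {
  std::string marked = "<" + tok + ">";
  std::vector<double> acc(static_cast<size_t>(d), 0.0);
  int count = 0;
  auto add = [&](const std::string &piece) {
    std::vector<double> v = hash_vector(piece, d, seed);
    for (int j = 0; j < d; ++j) acc[j] += v[j];
    ++count;
  };
  add(marked);
  const size_t L = marked.size();
  for (size_t n = 3; n <= 5; ++n) {
    if (L < n) break;
    for (size_t s = 0; s + n <= L; ++s) add(marked.substr(s, n));
  }
  double nrm = 0.0;
  for (int j = 0; j < d; ++j) { acc[j] /= count; nrm += acc[j] * acc[j]; }
  nrm = std::sqrt(nrm);
  if (nrm > 0) for (double &x : acc) x /= nrm;
  return acc;
}

// Embed a batch of texts. token_mean = TRUE averages the subword token
// vectors of whitespace tokens (renormalised), preserving bag-of-words
// composition; FALSE embeds the raw string as one token.
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_embed_texts(Rcpp::CharacterVector texts, int d, double seed,
                                    bool token_mean) {
  const std::uint64_t s = static_cast<std::uint64_t>(seed);
  const int n = texts.size();
  Rcpp::NumericMatrix out(n, d);
  std::unordered_map<std::string, std::vector<double>> cache;

  for (int i = 0; i < n; ++i) {
    std::string text = Rcpp::as<std::string>(texts[i]);
    std::vector<double> acc(static_cast<size_t>(d), 0.0);
    int count = 0;
    if (token_mean) {
      size_t pos = 0;
      while (pos < text.size()) {
        while (pos < text.size() && std::isspace(static_cast<unsigned char>(text[pos]))) ++pos;
        size_t start = pos;
        while (pos < text.size() && !std::isspace(static_cast<unsigned char>(text[pos]))) ++pos;
        if (pos > start) {
          std::string tok = text.substr(start, pos - start);
          auto it = cache.find(tok);
          if (it == cache.end())
            it = cache.emplace(tok, token_vector(tok, d, s)).first;
          for (int j = 0; j < d; ++j) acc[j] += it->second[j];
          ++count;
        }
      }
    }
    if (count == 0) {
      acc = token_vector(text, d, s);
      count = 1;
    }
    double nrm = 0.0;
    for (int j = 0; j < d; ++j) { acc[j] /= count; nrm += acc[j] * acc[j]; }
    nrm = std::sqrt(nrm);
    if (nrm < 1e-300) { acc = hash_vector(text, d, s); nrm = 1.0; }
    for (int j = 0; j < d; ++j) out(i, j) = acc[j] / nrm;
  }
  return out;
}
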