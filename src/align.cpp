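#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Gapless seed-and-extend aligner over an exact-match k-mer index of the
// (optionally transformed) forward genome. Reverse strand is handled by
// aligning the read's reverse complement; the alphabet transform is applied
// to the strand-resolved read copy, so the screen is symmetric across the
// 12 ordered mismatch types.

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'N': return 'N';
  default:  return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (char &c : r) c = comp_base(c);
  return r;
}

static inline void transform_seq(std::string &s, char from, char to) {
  if (from == 0) return;
  for (char &c : s) if (c == from) c = to;
}

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1;
  case 'G': return 2; case 'T': return 3;
  default:  return -1;
  }
}

struct GenomeIndex {
  std::vector<std::string> names;
  std::vector<std::string> native;   // forward strand, uppercase
  std::vector<std::string> xform;    // transformed forward strand
  int k;
  char tfrom, tto;                   // 0 if no transform
  // 2-bit-coded k-mer -> (chrom, pos) occurrences
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t,int32_t>>> kmers;
};

static bool encode_kmer(const std::string &s, size_t pos, int k, uint64_t &out) {
  uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_code(s[pos + i]);
    if (b < 0) return false;  // k-mers containing N are not indexed
    code = (code << 2) | (uint64_t)b;
  }
  out = code;
  return true;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector names, CharacterVector seqs, int k,
                     std::string tfrom, std::string tto) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  GenomeIndex *gi = new GenomeIndex();
  gi->k = k;
  gi->tfrom = tfrom.empty() ? 0 : tfrom[0];
  gi->tto   = tto.empty()   ? 0 : tto[0];
  for (int i = 0; i < names.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (char &c : s) c = toupper(c);
    if ((int)s.size() < k) {
      delete gi;
      stop("k (%d) exceeds length of sequence '%s'", k,
           as<std::string>(names[i]).c_str());
    }
    gi->names.push_back(as<std::string>(names[i]));
    gi->native.push_back(s);
    transform_seq(s, gi->tfrom, gi->tto);
    gi->xform.push_back(s);
    for (size_t p = 0; p + k <= s.size(); ++p) {
      uint64_t code;
      if (encode_kmer(s, p, k, code))
        gi->kmers[code].push_back(std::make_pair((int32_t)i, (int32_t)p));
    }
  }
  XPtr<GenomeIndex> ptr(gi, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp) {
  XPtr<GenomeIndex> gi(xp);
  return List::create(_["k"] = gi->k,
                      _["names"] = wrap(gi->names),
                      _["n_kmers"] = (double)gi->kmers.size(),
                      _["transform_from"] = gi->tfrom ? std::string(1, gi->tfrom) : std::string(""),
                      _["transform_to"]   = gi->tto   ? std::string(1, gi->tto)   : std::string(""));
}

// [[Rcpp::export]]
DataFrame cpp_index_lookup(SEXP xp, std::string kmer) {
  XPtr<GenomeIndex> gi(xp);
  for (char &c : kmer) c = toupper(c);
  std::vector<int> chrom; std::vector<int> pos;
  uint64_t code;
  if ((int)kmer.size() == gi->k && encode_kmer(kmer, 0, gi->k, code)) {
    auto it = gi->kmers.find(code);
    if (it != gi->kmers.end())
      for (auto &pr : it->second) { chrom.push_back(pr.first + 1); pos.push_back(pr.second); }
  }
  return DataFrame::create(_["chrom_i"] = chrom, _["pos"] = pos);
}

// distinct k-mers present in the index, as strings (small genomes only)
// [[Rcpp::export]]
CharacterVector cpp_index_kmers(SEXP xp) {
  XPtr<GenomeIndex> gi(xp);
  CharacterVector out(gi->kmers.size());
  const char *alpha = "ACGT";
  size_t j = 0;
  for (auto &kv : gi->kmers) {
    std::string s(gi->k, 'N');
    uint64_t code = kv.first;
    for (int i = gi->k - 1; i >= 0; --i) { s[i] = alpha[code & 3]; code >>= 2; }
    out[j++] = s;
  }
  return out;
}

static int count_mm(const std::string &ref, size_t start,
                    const std::string &query, int cap) {
  int mm = 0;
  for (size_t i = 0; i < query.size(); ++i) {
    char r = ref[start + i], q = query[i];
    if (r != q || r == 'N' || q == 'N') {   // N never matches
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

struct Placement { int chrom; int start; int strand; int mm; };

// Align one read (both strands) against the index. Pigeonhole seeding:
// max_mm+1 non-overlapping tiles each contribute one exact k-seed, so any
// gapless placement with <= max_mm mismatches is guaranteed to be found
// (provided tile length >= k; otherwise fewer tiles are used and the
// guarantee is best-effort).
static void align_one(const GenomeIndex &gi, const std::string &read_native,
                      int max_mm, Placement &best, int &best_count, int &second_mm) {
  int L = (int)read_native.size();
  int k = gi.k;
  best.mm = L + 1; best_count = 0; second_mm = L + 1;
  int nseeds = max_mm + 1;
  if (L / nseeds < k) nseeds = std::max(1, L / k);
  int tile = L / nseeds;

  for (int strand = 0; strand < 2; ++strand) {
    std::string oriented = strand == 0 ? read_native : revcomp(read_native);
    std::string xread = oriented;
    transform_seq(xread, gi.tfrom, gi.tto);
    // distinct candidate diagonals for this strand
    std::map<std::pair<int,int>, bool> seen;
    for (int s = 0; s < nseeds; ++s) {
      int off = s * tile;
      if (off + k > L) off = L - k;
      uint64_t code;
      if (!encode_kmer(xread, off, k, code)) continue;
      auto it = gi.kmers.find(code);
      if (it == gi.kmers.end()) continue;
      for (auto &pr : it->second) {
        int ci = pr.first;
        int start = pr.second - off;
        if (start < 0 || start + L > (int)gi.xform[ci].size()) continue;
        auto key = std::make_pair(ci, start);
        if (seen.count(key)) continue;
        seen[key] = true;
        int mm = count_mm(gi.xform[ci], start, xread, second_mm);
        if (mm < best.mm) {
          second_mm = best.mm;
          best.mm = mm; best.chrom = ci; best.start = start; best.strand = strand;
          best_count = 1;
        } else if (mm == best.mm) {
          best_count++;
          second_mm = mm;
        } else if (mm < second_mm) {
          second_mm = mm;
        }
      }
    }
  }
}

// Native-alphabet mismatch recovery at a placement; returns "off:R>Q;..."
// with offsets in reference-forward order (0-based within the alignment).
static std::string native_mismatches(const std::string &ref, int start,
                                     const std::string &oriented, int &n_mm) {
  std::string out;
  n_mm = 0;
  for (size_t i = 0; i < oriented.size(); ++i) {
    char r = ref[start + i], q = oriented[i];
    if (r != q || r == 'N' || q == 'N') {
      if (!out.empty()) out += ';';
      out += std::to_string(i); out += ':'; out += r; out += '>'; out += q;
      n_mm++;
    }
  }
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_align_reads(SEXP xp, CharacterVector ids, CharacterVector seqs,
                          int max_mm) {
  XPtr<GenomeIndex> gi(xp);
  int n = seqs.size();
  CharacterVector out_id(n), out_chrom(n), out_strand(n), out_mismatches(n);
  IntegerVector out_start(n), out_mm(n), out_nat(n), out_len(n);
  LogicalVector out_mapped(n), out_unique(n);

  for (int i = 0; i < n; ++i) {
    std::string read = as<std::string>(seqs[i]);
    for (char &c : read) c = toupper(c);
    out_id[i] = ids[i];
    out_len[i] = (int)read.size();
    Placement best; int best_count, second_mm;
    if ((int)read.size() < gi->k) {
      out_mapped[i] = false; out_chrom[i] = NA_STRING; out_start[i] = NA_INTEGER;
      out_strand[i] = NA_STRING; out_mm[i] = NA_INTEGER; out_nat[i] = NA_INTEGER;
      out_unique[i] = NA_LOGICAL; out_mismatches[i] = NA_STRING;
      continue;
    }
    align_one(*gi, read, max_mm, best, best_count, second_mm);
    if (best.mm <= max_mm) {
      out_mapped[i] = true;
      out_chrom[i] = gi->names[best.chrom];
      out_start[i] = best.start;
      out_strand[i] = best.strand == 0 ? "+" : "-";
      out_mm[i] = best.mm;
      out_unique[i] = (best_count == 1);
      std::string oriented = best.strand == 0 ? read : revcomp(read);
      int nat;
      out_mismatches[i] = native_mismatches(gi->native[best.chrom], best.start, oriented, nat);
      out_nat[i] = nat;
    } else {
      out_mapped[i] = false; out_chrom[i] = NA_STRING; out_start[i] = NA_INTEGER;
      out_strand[i] = NA_STRING; out_mm[i] = NA_INTEGER; out_nat[i] = NA_INTEGER;
      out_unique[i] = NA_LOGICAL; out_mismatches[i] = NA_STRING;
    }
  }
  return DataFrame::create(
    _["read_id"] = out_id, _["mapped"] = out_mapped, _["chrom"] = out_chrom,
    _["start"] = out_start, _["aln_len"] = out_len, _["strand"] = out_strand,
    _["mm_transformed"] = out_mm, _["unique"] = out_unique,
    _["n_native_mm"] = out_nat, _["mismatches"] = out_mismatches,
    _["stringsAsFactors"] = false);
}
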