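#include <Rcpp.h>
using namespace Rcpp;

static inline int base_idx(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;  // ambiguity codes contribute coverage nowhere
  }
}

// Accumulate per-position base/deletion/insertion counts from alignments.
// CIGAR ops are restricted to M/I/D/S; insertions are attributed to the
// reference base preceding the inserted run. Reads overhanging the reference
// end are clipped; the number of clipped reads is returned as an attribute.
// [[Rcpp::export(name = ".pileup_accumulate")]]
IntegerMatrix pileup_accumulate(int ref_len, IntegerVector pos,
                                CharacterVector cigar, CharacterVector seq) {
  IntegerMatrix counts(ref_len, 6);  // A C G T del ins
  int n = pos.size();
  int clipped = 0;
  for (int r = 0; r < n; ++r) {
    const char *cg = CHAR(STRING_ELT(cigar, r));
    const char *sq = CHAR(STRING_ELT(seq, r));
    int refpos = pos[r];       // 1-based
    int qpos = 0;              // 0-based index into seq
    int num = 0;
    bool clip_hit = false;
    for (const char *p = cg; *p; ++p) {
      char c = *p;
      if (c >= '0' && c <= '9') { num = num * 10 + (c - '0'); continue; }
      if (num == 0) stop("malformed CIGAR '%s'", cg);
      switch (c) {
      case 'M':
        for (int k = 0; k < num; ++k) {
          if (refpos > ref_len) { clip_hit = true; break; }
          int b = base_idx(sq[qpos]);
          if (b >= 0) counts(refpos - 1, b)++;
          ++refpos; ++qpos;
        }
        if (clip_hit) qpos += 0;
        break;
      case 'I':
        if (refpos - 2 >= 0 && refpos - 2 < ref_len)
          counts(refpos - 2, 5)++;
        qpos += num;
        break;
      case 'D':
        for (int k = 0; k < num; ++k) {
          if (refpos > ref_len) { clip_hit = true; break; }
          counts(refpos - 1, 4)++;
          ++refpos;
        }
        break;
      case 'S':
        qpos += num;
        break;
      default:
        stop("unsupported CIGAR op '%c' (only M/I/D/S allowed)", c);
      }
      num = 0;
      if (clip_hit) break;
    }
    if (clip_hit) ++clipped;
  }
  counts.attr("clipped") = clipped;
  return counts;
}

// Inject uniform per-base errors into read sequences using R's RNG
// (deterministic under set.seed). Each base is replaced, with probability
// error_rate, by one of the other three bases chosen uniformly.
// [[Rcpp::export(name = ".mutate_reads")]]
CharacterVector mutate_reads(CharacterVector seqs, double error_rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int n = seqs.size();
  CharacterVector out(n);
  RNGScope scope;
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    for (size_t i = 0; i < s.size(); ++i) {
      if (unif_rand() < error_rate) {
        int b = base_idx(s[i]);
        if (b < 0) continue;
        int shift = 1 + (int)(unif_rand() * 3.0);
        if (shift > 3) shift = 3;
        s[i] = bases[(b + shift) % 4];
      }
    }
    out[r] = s;
  }
  return out;
}
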