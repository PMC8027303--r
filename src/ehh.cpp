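#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Integrated EHH (iHH) scan.
//
// alleles: variants x haplotypes 0/1 integer matrix (NA = missing, treated as
//   a third allele state so missing data break haplotype identity).
// cm:      per-variant genetic-map position (cM), non-decreasing per chrom.
// chrom:   integer chromosome code per variant; extension stops at chromosome
//   boundaries.
// cores:   0-based variant indices at which to anchor the scan.
// haps:    0-based haplotype column indices to use.
// partition: -1 = use all `haps`; 0/1 = restrict to carriers of that allele
//   at the core.
// cutoff:  EHH level at which integration stops (interpolated crossing).
// maxExtendCm: hard cap on one-sided extension; reaching it (or a chromosome
//   edge) with EHH still above cutoff sets the truncation flag.
//
// Returns a numeric matrix n_cores x 3: iHH (cM), truncated (0/1), nCarriers.
// [[Rcpp::export]]
NumericMatrix cpp_ihh(IntegerMatrix alleles, NumericVector cm,
                      IntegerVector chrom, IntegerVector cores,
                      IntegerVector haps, int partition,
                      double cutoff, double maxExtendCm) {
    const int nv = alleles.nrow();
    NumericMatrix out(cores.size(), 3);
    std::vector<int> carriers;
    std::vector<int> grp, key;

    for (int ci = 0; ci < cores.size(); ++ci) {
        const int core = cores[ci];
        carriers.clear();
        for (int k = 0; k < haps.size(); ++k) {
            int h = haps[k];
            if (partition < 0) {
                carriers.push_back(h);
            } else {
                int a = alleles(core, h);
                if (a != NA_INTEGER && a == partition) carriers.push_back(h);
            }
        }
        const int n = carriers.size();
        if (n < 2) {
            out(ci, 0) = NA_REAL; out(ci, 1) = NA_REAL; out(ci, 2) = n;
            continue;
        }
        const double denom = (double)n * (n - 1) / 2.0;
        double ihh = 0.0;
        bool truncated = false;

        for (int dir = -1; dir <= 1; dir += 2) {
            grp.assign(n, 0);
            int nGroups = 1;
            double ehhPrev = 1.0, cmPrev = cm[core];
            int idx = core;
            for (;;) {
                idx += dir;
                if (idx < 0 || idx >= nv || chrom[idx] != chrom[core] ||
                    std::abs(cm[idx] - cm[core]) > maxExtendCm) {
                    truncated = true;  // ran out of data with EHH >= cutoff
                    break;
                }
                // split groups by the allele at idx
                key.resize(n);
                std::unordered_map<long long, int> remap;
                remap.reserve(2 * nGroups);
                int nNew = 0;
                for (int k = 0; k < n; ++k) {
                    int a = alleles(idx, carriers[k]);
                    int av = (a == NA_INTEGER) ? 2 : a;
                    long long kk = (long long)grp[k] * 3 + av;
                    auto it = remap.find(kk);
                    if (it == remap.end()) {
                        remap[kk] = nNew;
                        key[k] = nNew++;
                    } else key[k] = it->second;
                }
                std::swap(grp, key);
                nGroups = nNew;
                // homozygosity
                std::vector<int> tab(nGroups, 0);
                for (int k = 0; k < n; ++k) tab[grp[k]]++;
                double s = 0.0;
                for (int g = 0; g < nGroups; ++g)
                    s += (double)tab[g] * (tab[g] - 1) / 2.0;
                double ehh = s / denom;
                double dx = std::abs(cm[idx] - cmPrev);
                if (ehh >= cutoff) {
                    ihh += dx * (ehhPrev + ehh) / 2.0;
                    ehhPrev = ehh;
                    cmPrev = cm[idx];
                    if (nGroups == n) break;  // all singletons: fully decayed
                } else {
                    // trapezoid up to the interpolated cutoff crossing
                    if (ehhPrev > cutoff && dx > 0) {
                        double f = (ehhPrev - cutoff) / (ehhPrev - ehh);
                        ihh += dx * f * (ehhPrev + cutoff) / 2.0;
                    }
                    break;
                }
            }
        }
        out(ci, 0) = ihh;
        out(ci, 1) = truncated ? 1.0 : 0.0;
        out(ci, 2) = n;
    }
    return out;
}
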