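#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Haplotypes are stored as a raw matrix, sites in rows (0/1 allele index),
// haploid genomes in columns; individual i owns columns 2i and 2i+1.
// genpos holds, per site, the genetic position in Morgans relative to the
// start of its chromosome (already sex-adjusted); chrom_offsets delimits the
// site blocks of the (sorted) chromosomes; chrom_len is the full effective
// map length of each chromosome, which may extend beyond the last site.

// Draw one gamete from parent columns (2p, 2p+1) of src into dst.
// Crossover count is Poisson(chrom_len); breakpoints uniform in genetic
// distance; no interference. Returns the number of crossovers drawn.
static int draw_gamete(const Rbyte* src, R_xlen_t nsites, int parent,
                       const double* genpos, const int* coff, int nchrom,
                       const double* clen, Rbyte* dst, std::vector<double>& bp,
                       int* per_chrom) {
    const Rbyte* h[2] = { src + (R_xlen_t)2 * parent * nsites,
                          src + ((R_xlen_t)2 * parent + 1) * nsites };
    int total = 0;
    for (int c = 0; c < nchrom; ++c) {
        R_xlen_t s0 = coff[c], s1 = coff[c + 1];
        double L = clen[c];
        int ncx = (L > 0.0) ? (int) R::rpois(L) : 0;
        if (per_chrom) per_chrom[c] = ncx;
        total += ncx;
        int cur = (unif_rand() < 0.5) ? 0 : 1;
        if (ncx == 0) {
            std::memcpy(dst + s0, h[cur] + s0, (size_t)(s1 - s0));
            continue;
        }
        bp.clear();
        for (int j = 0; j < ncx; ++j) bp.push_back(unif_rand() * L);
        std::sort(bp.begin(), bp.end());
        R_xlen_t pos = s0;
        for (int j = 0; j <= ncx; ++j) {
            R_xlen_t seg_end;
            if (j == ncx) {
                seg_end = s1;
            } else {
                const double* lo = genpos + pos;
                const double* hi = genpos + s1;
                seg_end = std::lower_bound(lo, hi, bp[j]) - genpos;
            }
            if (seg_end > pos) {
                std::memcpy(dst + pos, h[cur] + pos, (size_t)(seg_end - pos));
                pos = seg_end;
            }
            cur ^= 1;
        }
    }
    return total;
}

// Multiplicative fitness over selected loci; log-space above 50 loci to keep
// precision with many strong-effect loci (e.g. 150 loci at s = 0.5).
static void comp_fitness(const Rbyte* H, R_xlen_t nsites, int N,
                         const int* ssite, const int* sallele,
                         const double* w1, const double* w2, int nloci,
                         std::vector<double>& fit, bool normalize = true) {
    if (nloci == 0) {
        std::fill(fit.begin(), fit.end(), 1.0);
        return;
    }
    const bool uselog = nloci > 50;
    std::vector<double> lw1, lw2;
    if (uselog) {
        lw1.resize(nloci); lw2.resize(nloci);
        for (int l = 0; l < nloci; ++l) {
            lw1[l] = std::log(w1[l]);
            lw2[l] = std::log(w2[l]);
        }
    }
    for (int i = 0; i < N; ++i) {
        const Rbyte* a = H + (R_xlen_t)2 * i * nsites;
        const Rbyte* b = H + ((R_xlen_t)2 * i + 1) * nsites;
        double acc = uselog ? 0.0 : 1.0;
        for (int l = 0; l < nloci; ++l) {
            R_xlen_t s = ssite[l];
            int cnt = (a[s] == (Rbyte)sallele[l]) + (b[s] == (Rbyte)sallele[l]);
            if (cnt == 0) continue;
            if (uselog) acc += (cnt == 1) ? lw1[l] : lw2[l];
            else        acc *= (cnt == 1) ? w1[l] : w2[l];
        }
        fit[i] = acc;
    }
    if (uselog) {
        // normalize by the max before exponentiating when only relative
        // fitness matters (parent sampling); absolute values otherwise
        double m = normalize ? *std::max_element(fit.begin(), fit.end()) : 0.0;
        for (int i = 0; i < N; ++i) fit[i] = std::exp(fit[i] - m);
    }
    for (int i = 0; i < N; ++i)
        if (!(fit[i] > 0.0)) stop("non-positive fitness encountered");
}

static int pick_parent(const std::vector<double>& cum, double tot) {
    double u = unif_rand() * tot;
    return (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
}

static void count_allele1(const Rbyte* H, R_xlen_t nsites, int nhap,
                          std::vector<int>& cnt) {
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int j = 0; j < nhap; ++j) {
        const Rbyte* col = H + (R_xlen_t)j * nsites;
        for (R_xlen_t s = 0; s < nsites; ++s) cnt[s] += col[s];
    }
}

// [[Rcpp::export]]
List evolve_cpp(RawMatrix haps, NumericVector genpos, IntegerVector chrom_offsets,
                NumericVector chrom_len, IntegerVector sel_site,
                IntegerVector sel_allele, NumericVector sel_w1,
                NumericVector sel_w2, int generations, IntegerVector record_at,
                bool return_haps) {
    const R_xlen_t nsites = haps.nrow();
    const int nhap = haps.ncol();
    if (nhap % 2 != 0) stop("haplotype matrix needs an even number of columns");
    const int N = nhap / 2;
    const int nchrom = chrom_offsets.size() - 1;
    const int nloci = sel_site.size();
    const int nrec = record_at.size();

    std::vector<Rbyte> A(haps.begin(), haps.end()), B(A.size());
    NumericMatrix freq(nsites, nrec);
    std::vector<int> cnt(nsites);
    std::vector<double> fit(N), cum(N), bp;

    int rec_idx = 0;
    for (int r = 0; r < nrec; ++r) {
        if (record_at[r] == 0) {
            count_allele1(A.data(), nsites, nhap, cnt);
            for (R_xlen_t s = 0; s < nsites; ++s)
                freq(s, r) = (double)cnt[s] / nhap;
            rec_idx = r + 1;
        }
    }

    for (int g = 1; g <= generations; ++g) {
        if (N < 2) stop("population size must be at least 2 to exclude selfing");
        comp_fitness(A.data(), nsites, N, sel_site.begin(), sel_allele.begin(),
                     sel_w1.begin(), sel_w2.begin(), nloci, fit);
        double tot = 0.0;
        for (int i = 0; i < N; ++i) { tot += fit[i]; cum[i] = tot; }
        for (int i = 0; i < N; ++i) {
            int p1 = pick_parent(cum, tot);
            int p2;
            do { p2 = pick_parent(cum, tot); } while (p2 == p1);
            draw_gamete(A.data(), nsites, p1, genpos.begin(),
                        chrom_offsets.begin(), nchrom, chrom_len.begin(),
                        B.data() + (R_xlen_t)2 * i * nsites, bp, 0);
            draw_gamete(A.data(), nsites, p2, genpos.begin(),
                        chrom_offsets.begin(), nchrom, chrom_len.begin(),
                        B.data() + ((R_xlen_t)2 * i + 1) * nsites, bp, 0);
        }
        A.swap(B);
        while (rec_idx < nrec && record_at[rec_idx] == g) {
            count_allele1(A.data(), nsites, nhap, cnt);
            for (R_xlen_t s = 0; s < nsites; ++s)
                freq(s, rec_idx) = (double)cnt[s] / nhap;
            ++rec_idx;
        }
    }

    List out = List::create(_["freq"] = freq);
    if (return_haps) {
        RawMatrix H(nsites, nhap);
        std::copy(A.begin(), A.end(), H.begin());
        out["haps"] = H;
    }
    return out;
}

// [[Rcpp::export]]
List gamete_cpp(RawMatrix haps, int parent0, NumericVector genpos,
                IntegerVector chrom_offsets, NumericVector chrom_len) {
    const R_xlen_t nsites = haps.nrow();
    const int nchrom = chrom_offsets.size() - 1;
    RawVector out(nsites);
    IntegerVector cx(nchrom);
    std::vector<double> bp;
    draw_gamete(haps.begin(), nsites, parent0, genpos.begin(),
                chrom_offsets.begin(), nchrom, chrom_len.begin(),
                out.begin(), bp, cx.begin());
    return List::create(_["gamete"] = out, _["crossovers"] = cx);
}

// [[Rcpp::export]]
IntegerVector site_counts_cpp(RawMatrix haps) {
    const R_xlen_t nsites = haps.nrow();
    const int nhap = haps.ncol();
    std::vector<int> cnt(nsites);
    count_allele1(haps.begin(), nsites, nhap, cnt);
    return IntegerVector(cnt.begin(), cnt.end());
}

// [[Rcpp::export]]
NumericVector fitness_cpp(RawMatrix haps, IntegerVector sel_site,
                          IntegerVector sel_allele, NumericVector sel_w1,
                          NumericVector sel_w2) {
    const R_xlen_t nsites = haps.nrow();
    const int N = haps.ncol() / 2;
    std::vector<double> fit(N);
    comp_fitness(haps.begin(), nsites, N, sel_site.begin(), sel_allele.begin(),
                 sel_w1.begin(), sel_w2.begin(), sel_site.size(), fit, false);
    return NumericVector(fit.begin(), fit.end());
}
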