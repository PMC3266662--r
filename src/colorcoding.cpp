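#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Color-coding search for the maximum-score simple path on exactly k nodes.
// Nodes are randomly k-colored; a dynamic program over (color subset, end
// node) finds the best "colorful" path, which is simple by construction.
// Each coloring succeeds with probability k!/k^k, so ncolorings >=
// ln(1/delta)*e^k gives success probability >= 1-delta.

static const double NEG = -1e300;

// one coloring's DP; fills bestScore/bestEnd/bestSet and (optionally)
// predecessor tables for path reconstruction
static void dp_run(int n, const std::vector<int>& efrom,
                   const std::vector<int>& eto,
                   const std::vector<double>& nscore,
                   const std::vector<double>& escore,
                   const std::vector<int>& color, int k,
                   bool track, double& bestScore, std::vector<int>& bestPath) {
    int S = 1 << k;
    std::vector<double> dp((size_t)S * n, NEG);
    std::vector<int> preNode, preSet;
    if (track) {
        preNode.assign((size_t)S * n, -1);
        preSet.assign((size_t)S * n, -1);
    }
    for (int v = 0; v < n; ++v)
        dp[(size_t)(1 << color[v]) * n + v] = nscore[v];
    int m = (int)efrom.size();
    for (int s = 1; s < S; ++s) {
        size_t base = (size_t)s * n;
        for (int e = 0; e < m; ++e) {
            // undirected edge: relax both directions
            for (int d = 0; d < 2; ++d) {
                int u = d ? eto[e] : efrom[e];
                int v = d ? efrom[e] : eto[e];
                double du = dp[base + u];
                if (du <= NEG) continue;
                int cb = 1 << color[v];
                if (s & cb) continue;
                int ns = s | cb;
                double cand = du + nscore[v] + escore[e];
                size_t idx = (size_t)ns * n + v;
                if (cand > dp[idx]) {
                    dp[idx] = cand;
                    if (track) { preNode[idx] = u; preSet[idx] = s; }
                }
            }
        }
    }
    // best over full-size color sets
    for (int s = 1; s < S; ++s) {
        int pc = 0; for (int b = s; b; b &= b - 1) ++pc;
        if (pc != k) continue;
        size_t base = (size_t)s * n;
        for (int v = 0; v < n; ++v) {
            if (dp[base + v] > bestScore) {
                bestScore = dp[base + v];
                if (track) {
                    bestPath.clear();
                    int cs = s, cv = v;
                    while (cv >= 0) {
                        bestPath.push_back(cv);
                        size_t idx = (size_t)cs * n + cv;
                        int pu = preNode[idx], ps = preSet[idx];
                        cv = pu; cs = ps;
                    }
                }
            }
        }
    }
}

static void draw_colors(std::vector<int>& color, int k) {
    for (size_t v = 0; v < color.size(); ++v) {
        int c = (int)std::floor(unif_rand() * k);
        if (c >= k) c = k - 1;
        color[v] = c;
    }
}

// [[Rcpp::export(name = ".colorCodingSearch")]]
List colorCodingSearch(int n, IntegerVector efrom, IntegerVector eto,
                       NumericVector nodeScore, NumericVector edgeScore,
                       int k, int ncolorings) {
    std::vector<int> ef(efrom.begin(), efrom.end()),
        et(eto.begin(), eto.end());
    std::vector<double> ns(nodeScore.begin(), nodeScore.end()),
        es(edgeScore.begin(), edgeScore.end());
    std::vector<int> color(n), path;
    double best = NEG;
    for (int it = 0; it < ncolorings; ++it) {
        draw_colors(color, k);
        dp_run(n, ef, et, ns, es, color, k, true, best, path);
    }
    if (best <= NEG)
        return List::create(Named("score") = R_NegInf,
                            Named("path") = IntegerVector(0));
    return List::create(Named("score") = best,
                        Named("path") = wrap(path));
}

// [[Rcpp::export(name = ".colorCodingNull")]]
NumericVector colorCodingNull(int n, IntegerVector efrom, IntegerVector eto,
                              NumericVector nodeScore,
                              NumericVector edgeScore, bool shuffleEdges,
                              int k, int ncolorings, int nshuffle) {
    std::vector<int> ef(efrom.begin(), efrom.end()),
        et(eto.begin(), eto.end());
    std::vector<double> ns(nodeScore.begin(), nodeScore.end()),
        es(edgeScore.begin(), edgeScore.end());
    std::vector<int> color(n), dummy;
    NumericVector out(nshuffle);
    for (int b = 0; b < nshuffle; ++b) {
        // Fisher-Yates permutation of node (and optionally edge) scores
        for (int i = (int)ns.size() - 1; i > 0; --i) {
            int j = (int)std::floor(unif_rand() * (i + 1));
            if (j > i) j = i;
            std::swap(ns[i], ns[j]);
        }
        if (shuffleEdges) {
            for (int i = (int)es.size() - 1; i > 0; --i) {
                int j = (int)std::floor(unif_rand() * (i + 1));
                if (j > i) j = i;
                std::swap(es[i], es[j]);
            }
        }
        double best = NEG;
        for (int it = 0; it < ncolorings; ++it) {
            draw_colors(color, k);
            dp_run(n, ef, et, ns, es, color, k, false, best, dummy);
        }
        out[b] = (best <= NEG) ? R_NegInf : best;
    }
    return out;
}
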