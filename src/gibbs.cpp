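#include <Rcpp.h>
using namespace Rcpp;

// Draw a Dirichlet vector via normalized gammas into out[0..n-1].
// shape[i] may be 0 (R::rgamma(0, 1) returns 0); a degenerate all-zero
// draw falls back to uniform.
static void rdirichlet(const double *shape, int n, double *out) {
    double tot = 0.0;
    for (int i = 0; i < n; ++i) {
        out[i] = R::rgamma(shape[i], 1.0);
        tot += out[i];
    }
    if (tot <= 0.0) {
        for (int i = 0; i < n; ++i) out[i] = 1.0 / n;
    } else {
        for (int i = 0; i < n; ++i) out[i] /= tot;
    }
}

// Supervised admixture Gibbs sampler for one sample.
//
// The sample is a single polyploid "individual": at locus l it carries a
// multiset of allele copies given as counts over the locus allele catalogue
// (missing copies are simply not counted).  Population allele frequencies
// are informed only by the labelled learning set, supplied as per-locus
// K x J count matrices of learning allele copies.  Each sweep:
//   (i)   p[k][l][.] ~ Dirichlet(lambda + n[k][l][.])   (unless fixed)
//   (ii)  the c_lj copies of allele j at locus l are assigned to groups by
//         a multinomial with weights q_k * p[k][l][j]
//   (iii) q ~ Dirichlet(alpha + m), m_k = copies assigned to group k
// Optionally a common alpha is Metropolis-updated under a Uniform(0,
// alpha_max] prior.  Posterior means are accumulated after burn-in and a
// Monte-Carlo standard error is estimated by batch means.
//
// [[Rcpp::export(name = ".gibbs_admixture_cpp")]]
List gibbs_admixture_cpp(List sample_counts,   // per locus: IntegerVector J_l
                         List learn_counts,    // per locus: NumericMatrix K x J_l
                         double lambda,
                         NumericVector alpha,  // length K
                         int burnin,
                         int sweeps,
                         bool sample_freqs,
                         Nullable<List> fixed_freqs, // per locus K x J_l probs
                         bool update_alpha,
                         double alpha_max,
                         double alpha_prop_sd,
                         CharacterVector locus_names) {
    const int L = sample_counts.size();
    const int K = alpha.size();
    if (sweeps < 1) stop("need at least one post-burn-in sweep");

    std::vector<IntegerVector> cs(L);
    std::vector<NumericMatrix> ns(L);
    std::vector<NumericMatrix> ps(L);
    for (int l = 0; l < L; ++l) {
        cs[l] = as<IntegerVector>(sample_counts[l]);
        ns[l] = as<NumericMatrix>(learn_counts[l]);
        if (ns[l].nrow() != K)
            stop("learning count matrix rows must equal K");
        if (ns[l].ncol() != cs[l].size())
            stop("allele catalogue mismatch at locus %d", l + 1);
        ps[l] = NumericMatrix(K, cs[l].size());
    }

    // Initialize p at the posterior mean of the learning counts, or at the
    // supplied fixed frequencies (also used throughout when !sample_freqs).
    if (fixed_freqs.isNotNull()) {
        List ff(fixed_freqs);
        for (int l = 0; l < L; ++l) {
            NumericMatrix f = as<NumericMatrix>(ff[l]);
            if (f.nrow() != K || f.ncol() != cs[l].size())
                stop("fixed frequency matrix dimensions are wrong at locus %d", l + 1);
            ps[l] = clone(f);
        }
    } else {
        for (int l = 0; l < L; ++l) {
            const int J = cs[l].size();
            for (int k = 0; k < K; ++k) {
                double tot = 0.0;
                for (int j = 0; j < J; ++j) tot += lambda + ns[l](k, j);
                for (int j = 0; j < J; ++j)
                    ps[l](k, j) = tot > 0 ? (lambda + ns[l](k, j)) / tot : 1.0 / J;
            }
        }
    }

    std::vector<double> q(K, 1.0 / K), qnew(K), shape(K), w(K);
    std::vector<int> m(K), draw(K);
    double acur = alpha[0];

    std::vector<double> q_sum(K, 0.0);
    int nbatch = sweeps >= 100 ? 50 : (sweeps >= 10 ? 10 : 1);
    int batch_len = sweeps / nbatch;       // trailing remainder joins last batch
    std::vector<double> batch_acc(K, 0.0);
    std::vector<std::vector<double> > batch_means(K);
    double alpha_sum = 0.0;
    int kept = 0, in_batch = 0, batches_done = 0;

    const int total = burnin + sweeps;
    for (int it = 0; it < total; ++it) {
        if (it % 4096 == 0) Rcpp::checkUserInterrupt();

        if (sample_freqs) {
            for (int l = 0; l < L; ++l) {
                const int J = cs[l].size();
                std::vector<double> sh(J), pr(J);
                for (int k = 0; k < K; ++k) {
                    for (int j = 0; j < J; ++j) sh[j] = lambda + ns[l](k, j);
                    rdirichlet(sh.data(), J, pr.data());
                    for (int j = 0; j < J; ++j) ps[l](k, j) = pr[j];
                }
            }
        }

        std::fill(m.begin(), m.end(), 0);
        for (int l = 0; l < L; ++l) {
            const int J = cs[l].size();
            for (int j = 0; j < J; ++j) {
                const int c = cs[l][j];
                if (c <= 0) continue;
                double sw = 0.0;
                for (int k = 0; k < K; ++k) {
                    w[k] = q[k] * ps[l](k, j);
                    sw += w[k];
                }
                if (sw <= 0.0)
                    stop("allele copy has zero probability in every group at locus '%s' (allele index %d); use lambda > 0",
                         std::string(locus_names[l]).c_str(), j + 1);
                for (int k = 0; k < K; ++k) w[k] /= sw;
                ::rmultinom(c, w.data(), K, draw.data());
                for (int k = 0; k < K; ++k) m[k] += draw[k];
            }
        }

        for (int k = 0; k < K; ++k)
            shape[k] = (update_alpha ? acur : alpha[k]) + m[k];
        rdirichlet(shape.data(), K, qnew.data());
        q = qnew;

        if (update_alpha) {
            // common symmetric alpha, Uniform(0, alpha_max] prior, MH step
            double prop = acur + R::norm_rand() * alpha_prop_sd;
            if (prop > 0.0 && prop <= alpha_max) {
                double slq = 0.0;
                for (int k = 0; k < K; ++k)
                    slq += std::log(q[k] > 1e-300 ? q[k] : 1e-300);
                double logr = (R::lgammafn(K * prop) - K * R::lgammafn(prop)) -
                              (R::lgammafn(K * acur) - K * R::lgammafn(acur)) +
                              (prop - acur) * slq;
                if (std::log(R::unif_rand()) < logr) acur = prop;
            }
        }

        if (it >= burnin) {
            ++kept;
            alpha_sum += acur;
            for (int k = 0; k < K; ++k) {
                q_sum[k] += q[k];
                batch_acc[k] += q[k];
            }
            if (++in_batch == batch_len && batches_done < nbatch - 1) {
                for (int k = 0; k < K; ++k) {
                    batch_means[k].push_back(batch_acc[k] / in_batch);
                    batch_acc[k] = 0.0;
                }
                in_batch = 0;
                ++batches_done;
            }
        }
    }
    if (in_batch > 0)
        for (int k = 0; k < K; ++k)
            batch_means[k].push_back(batch_acc[k] / in_batch);

    NumericVector q_mean(K), q_se(K);
    for (int k = 0; k < K; ++k) {
        q_mean[k] = q_sum[k] / kept;
        const std::vector<double> &bm = batch_means[k];
        const int B = bm.size();
        if (B > 1) {
            double mb = 0.0;
            for (int b = 0; b < B; ++b) mb += bm[b];
            mb /= B;
            double v = 0.0;
            for (int b = 0; b < B; ++b) v += (bm[b] - mb) * (bm[b] - mb);
            q_se[k] = std::sqrt(v / (B - 1) / B);
        } else {
            q_se[k] = NA_REAL;
        }
    }

    return List::create(_["q_mean"] = q_mean,
                        _["q_se"] = q_se,
                        _["alpha_mean"] = alpha_sum / kept,
                        _["n_kept"] = kept);
}
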