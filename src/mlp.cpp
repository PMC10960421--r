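// Fully-connected feed-forward regression network with rectifier hidden
// units and a linear output layer, trained by mini-batch Adam on the mean
// squared error. Small and self-contained: the surrogate of the kinetic
// model needs a multi-output multi-layer perceptron and nothing more.
//
// Inputs and targets are expected pre-standardized (done on the R side).

#include <RcppArmadillo.h>

using namespace arma;

static void forward(const std::vector<mat> &W, const std::vector<vec> &b,
                    const mat &X, std::vector<mat> &A)
{
    // X: d x n (columns are samples); A[i] activations after layer i
    const size_t L = W.size();
    A.resize(L + 1);
    A[0] = X;
    for (size_t l = 0; l < L; l++) {
        mat Z = W[l] * A[l];
        Z.each_col() += b[l];
        if (l + 1 < L) Z = clamp(Z, 0.0, datum::inf);   // ReLU
        A[l + 1] = Z;
    }
}

extern "C" SEXP mlp_train(SEXP Xs, SEXP Ys, SEXP hiddenS, SEXP epochsS,
                          SEXP batchS, SEXP lrS, SEXP seedS,
                          SEXP XvalS, SEXP YvalS, SEXP patienceS)
{
    Rcpp::NumericMatrix Xr(Xs), Yr(Ys);
    Rcpp::IntegerVector hidden(hiddenS);
    const int epochs = Rcpp::as<int>(epochsS);
    const int batch = Rcpp::as<int>(batchS);
    const double lr = Rcpp::as<double>(lrS);
    const unsigned seed = (unsigned) Rcpp::as<double>(seedS);
    Rcpp::NumericMatrix Xvr(XvalS), Yvr(YvalS);
    const int patience = Rcpp::as<int>(patienceS);
    const bool use_val = Xvr.nrow() > 0 && patience > 0;

    mat X(Xr.begin(), Xr.nrow(), Xr.ncol());   // n x d
    mat Y(Yr.begin(), Yr.nrow(), Yr.ncol());   // n x k
    mat Xv(Xvr.begin(), Xvr.nrow(), Xvr.ncol());
    mat Yv(Yvr.begin(), Yvr.nrow(), Yvr.ncol());
    mat Xvt = Xv.t(), Yvt = Yv.t();
    const uword n = X.n_rows, d = X.n_cols, k = Y.n_cols;

    std::vector<uword> sizes;
    sizes.push_back(d);
    for (int i = 0; i < hidden.size(); i++) sizes.push_back((uword) hidden[i]);
    sizes.push_back(k);
    const size_t L = sizes.size() - 1;

    std::mt19937 gen(seed);
    std::normal_distribution<double> gauss(0.0, 1.0);

    std::vector<mat> W(L), mW(L), vW(L);
    std::vector<vec> b(L), mb(L), vb(L);
    for (size_t l = 0; l < L; l++) {
        // He initialization for rectifier layers; own generator so results
        // are reproducible from the seed argument alone
        double sd = std::sqrt(2.0 / sizes[l]);
        W[l].set_size(sizes[l + 1], sizes[l]);
        for (uword j = 0; j < W[l].n_elem; j++) W[l](j) = gauss(gen) * sd;
        b[l] = zeros<vec>(sizes[l + 1]);
        mW[l] = zeros<mat>(sizes[l + 1], sizes[l]);
        vW[l] = zeros<mat>(sizes[l + 1], sizes[l]);
        mb[l] = zeros<vec>(sizes[l + 1]);
        vb[l] = zeros<vec>(sizes[l + 1]);
    }

    const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
    long step = 0;
    std::vector<uword> idx(n);
    for (uword i = 0; i < n; i++) idx[i] = i;

    mat Xt = X.t();   // d x n
    mat Yt = Y.t();   // k x n

    // early stopping on held-out loss: keep the best-so-far snapshot
    std::vector<mat> Wbest = W;
    std::vector<vec> bbest = b;
    double best_val = datum::inf;
    int best_epoch = 0, since_best = 0, last_epoch = 0;
    std::vector<double> history;

    for (int ep = 0; ep < epochs; ep++) {
        last_epoch = ep + 1;
        std::shuffle(idx.begin(), idx.end(), gen);
        for (uword start = 0; start < n; start += (uword) batch) {
            uword stop = std::min(n, start + (uword) batch);
            uvec sel(stop - start);
            for (uword i = start; i < stop; i++) sel[i - start] = idx[i];
            mat Xb = Xt.cols(sel);
            mat Yb = Yt.cols(sel);
            const double m = (double) Xb.n_cols;

            std::vector<mat> A;
            forward(W, b, Xb, A);

            // backward pass: dZ for output layer of MSE/2-like loss
            mat dZ = (A[L] - Yb) * (2.0 / m);
            for (size_t l = L; l-- > 0; ) {
                mat dW = dZ * A[l].t();
                vec db = sum(dZ, 1);
                if (l > 0) {
                    mat dA = W[l].t() * dZ;
                    dZ = dA % conv_to<mat>::from(A[l] > 0.0);
                }
                step++;
                double c1 = 1.0 - std::pow(beta1, (double) step);
                double c2 = 1.0 - std::pow(beta2, (double) step);
                mW[l] = beta1 * mW[l] + (1 - beta1) * dW;
                vW[l] = beta2 * vW[l] + (1 - beta2) * square(dW);
                W[l] -= lr * (mW[l] / c1) / (sqrt(vW[l] / c2) + eps);
                mb[l] = beta1 * mb[l] + (1 - beta1) * db;
                vb[l] = beta2 * vb[l] + (1 - beta2) * square(db);
                b[l] -= lr * (mb[l] / c1) / (sqrt(vb[l] / c2) + eps);
            }
        }
        if (ep % 10 == 0) Rcpp::checkUserInterrupt();
        if (use_val) {
            std::vector<mat> Av;
            forward(W, b, Xvt, Av);
            double vl = accu(square(Av[L] - Yvt)) / (double) Yvt.n_elem;
            history.push_back(vl);
            if (vl < best_val) {
                best_val = vl;
                best_epoch = ep + 1;
                Wbest = W;
                bbest = b;
                since_best = 0;
            } else if (++since_best >= patience) {
                break;
            }
        }
    }
    if (!use_val) {
        Wbest = W;
        bbest = b;
        best_epoch = last_epoch;
    }

    Rcpp::List out(2 * L);
    Rcpp::CharacterVector nm(2 * L);
    for (size_t l = 0; l < L; l++) {
        out[2 * l] = Rcpp::wrap(Wbest[l]);
        out[2 * l + 1] = Rcpp::wrap(bbest[l]);
        nm[2 * l] = "W" + std::to_string(l + 1);
        nm[2 * l + 1] = "b" + std::to_string(l + 1);
    }
    out.attr("names") = nm;
    out.attr("best_epoch") = best_epoch;
    out.attr("val_history") = history;
    return out;
}

extern "C" SEXP mlp_predict(SEXP weightsS, SEXP Xs)
{
    Rcpp::List weights(weightsS);
    Rcpp::NumericMatrix Xr(Xs);
    mat X(Xr.begin(), Xr.nrow(), Xr.ncol());
    const size_t L = weights.size() / 2;

    std::vector<mat> W(L);
    std::vector<vec> b(L);
    for (size_t l = 0; l < L; l++) {
        W[l] = Rcpp::as<mat>(weights[2 * l]);
        b[l] = Rcpp::as<vec>(weights[2 * l + 1]);
    }
    std::vector<mat> A;
    forward(W, b, X.t(), A);
    mat Y = A[L].t();
    return Rcpp::wrap(Y);
}
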