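// Small from-scratch CNN: stacked (conv 3x3 same -> ReLU -> maxpool 2x2)
// blocks followed by two fully connected layers and softmax cross-entropy.
// Single-threaded, deterministic. Feature maps are stored column-major per
// channel: value(r, c, ch) = buf[r + c*H + ch*H*W].
#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Convolution is organized as 9*IC*OC shifted plane accumulations so the
// inner loops run over contiguous rows and auto-vectorize.
static void conv3_forward(const std::vector<double>& in, int H, int Wd,
                          int IC, const double* Wt, const double* b, int OC,
                          std::vector<double>& out) {
  for (int oc = 0; oc < OC; ++oc) {
    double* op = &out[(size_t)oc * H * Wd];
    std::fill(op, op + (size_t)H * Wd, b[oc]);
    for (int ic = 0; ic < IC; ++ic) {
      const double* base = &in[(size_t)ic * H * Wd];
      const double* wb = Wt + ((size_t)oc * IC + ic) * 9;
      for (int kx = -1; kx <= 1; ++kx) {
        for (int ky = -1; ky <= 1; ++ky) {
          double w = wb[(ky + 1) + (kx + 1) * 3];
          int c0 = std::max(0, -kx), c1 = std::min(Wd, Wd - kx);
          int r0 = std::max(0, -ky), r1 = std::min(H, H - ky);
          for (int c = c0; c < c1; ++c) {
            double* o = op + (size_t)c * H + r0;
            const double* s = base + (size_t)(c + kx) * H + r0 + ky;
            for (int r = r0; r < r1; ++r) *o++ += w * *s++;
          }
        }
      }
    }
  }
}

static void conv3_backward(const std::vector<double>& in,
                           const std::vector<double>& dout, int H, int Wd,
                           int IC, const double* Wt, int OC,
                           std::vector<double>& din, double* dW, double* db) {
  std::fill(din.begin(), din.end(), 0.0);
  for (int oc = 0; oc < OC; ++oc) {
    const double* gp = &dout[(size_t)oc * H * Wd];
    double s = 0.0;
    for (size_t i = 0; i < (size_t)H * Wd; ++i) s += gp[i];
    db[oc] += s;
    for (int ic = 0; ic < IC; ++ic) {
      const double* base = &in[(size_t)ic * H * Wd];
      double* dbase = &din[(size_t)ic * H * Wd];
      const double* wb = Wt + ((size_t)oc * IC + ic) * 9;
      double* dwb = dW + ((size_t)oc * IC + ic) * 9;
      for (int kx = -1; kx <= 1; ++kx) {
        for (int ky = -1; ky <= 1; ++ky) {
          int wi = (ky + 1) + (kx + 1) * 3;
          double w = wb[wi], acc = 0.0;
          int c0 = std::max(0, -kx), c1 = std::min(Wd, Wd - kx);
          int r0 = std::max(0, -ky), r1 = std::min(H, H - ky);
          for (int c = c0; c < c1; ++c) {
            const double* g = gp + (size_t)c * H + r0;
            const double* x = base + (size_t)(c + kx) * H + r0 + ky;
            double* dx = dbase + (size_t)(c + kx) * H + r0 + ky;
            for (int r = r0; r < r1; ++r) {
              acc += *x++ * *g;
              *dx++ += w * *g++;
            }
          }
          dwb[wi] += acc;
        }
      }
    }
  }
}

static void pool2_forward(const std::vector<double>& in, int H, int Wd,
                          int C, std::vector<double>& out,
                          std::vector<int>& arg) {
  int Ho = H / 2, Wo = Wd / 2;
  for (int ch = 0; ch < C; ++ch) {
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        double best = -1e300;
        int bi = 0;
        for (int dc = 0; dc < 2; ++dc) {
          for (int drr = 0; drr < 2; ++drr) {
            size_t idx = (2 * r + drr) + (size_t)(2 * c + dc) * H
                         + (size_t)ch * H * Wd;
            if (in[idx] > best) { best = in[idx]; bi = (int)idx; }
          }
        }
        size_t oi = r + (size_t)c * Ho + (size_t)ch * Ho * Wo;
        out[oi] = best;
        arg[oi] = bi;
      }
    }
  }
}

struct Cache {
  std::vector<std::vector<double> > act;   // input of each block
  std::vector<std::vector<double> > convz; // conv output pre-ReLU
  std::vector<std::vector<double> > relu;  // post-ReLU
  std::vector<std::vector<double> > pooled;
  std::vector<std::vector<int> > arg;
  std::vector<double> h1pre, h1, logits, probs;
};

struct Net {
  int nblocks, H0, W0, hidden, nclass, flat;
  std::vector<const double*> cW, cb;
  std::vector<int> IC, OC, Hs, Ws;   // Hs/Ws: input size of each block
  const double *W1, *b1, *W2, *b2;
};

static Net make_net(List params, int H0, int W0) {
  Net net;
  List convW = params["conv_W"], convb = params["conv_b"];
  net.nblocks = convW.size();
  net.H0 = H0; net.W0 = W0;
  int H = H0, Wd = W0;
  for (int l = 0; l < net.nblocks; ++l) {
    NumericVector w = convW[l];
    IntegerVector d = w.attr("dim");
    net.IC.push_back(d[2]); net.OC.push_back(d[3]);
    net.cW.push_back(REAL(w));
    NumericVector b = convb[l];
    net.cb.push_back(REAL(b));
    net.Hs.push_back(H); net.Ws.push_back(Wd);
    H /= 2; Wd /= 2;
  }
  net.flat = net.OC.back() * H * Wd;
  NumericMatrix W1 = params["fc1_W"], W2 = params["fc2_W"];
  NumericVector b1 = params["fc1_b"], b2 = params["fc2_b"];
  net.hidden = W1.nrow(); net.nclass = W2.nrow();
  if (W1.ncol() != net.flat) stop("fc1 width does not match conv output");
  net.W1 = REAL(W1); net.b1 = REAL(b1);
  net.W2 = REAL(W2); net.b2 = REAL(b2);
  return net;
}

static void forward_one(const Net& net, const double* x, Cache& cc) {
  cc.act.assign(net.nblocks + 1, std::vector<double>());
  cc.convz.assign(net.nblocks, std::vector<double>());
  cc.relu.assign(net.nblocks, std::vector<double>());
  cc.pooled.assign(net.nblocks, std::vector<double>());
  cc.arg.assign(net.nblocks, std::vector<int>());
  cc.act[0].assign(x, x + (size_t)net.H0 * net.W0);
  for (int l = 0; l < net.nblocks; ++l) {
    int H = net.Hs[l], Wd = net.Ws[l];
    size_t zn = (size_t)net.OC[l] * H * Wd;
    cc.convz[l].assign(zn, 0.0);
    conv3_forward(cc.act[l], H, Wd, net.IC[l], net.cW[l], net.cb[l],
                  net.OC[l], cc.convz[l]);
    cc.relu[l] = cc.convz[l];
    for (size_t i = 0; i < zn; ++i) if (cc.relu[l][i] < 0) cc.relu[l][i] = 0;
    int Ho = H / 2, Wo = Wd / 2;
    cc.pooled[l].assign((size_t)net.OC[l] * Ho * Wo, 0.0);
    cc.arg[l].assign((size_t)net.OC[l] * Ho * Wo, 0);
    pool2_forward(cc.relu[l], H, Wd, net.OC[l], cc.pooled[l], cc.arg[l]);
    cc.act[l + 1] = cc.pooled[l];
  }
  const std::vector<double>& flat = cc.act[net.nblocks];
  cc.h1pre.assign(net.hidden, 0.0);
  for (int i = 0; i < net.hidden; ++i) {
    double s = net.b1[i];
    for (int j = 0; j < net.flat; ++j)
      s += net.W1[i + (size_t)j * net.hidden] * flat[j];
    cc.h1pre[i] = s;
  }
  cc.h1 = cc.h1pre;
  for (int i = 0; i < net.hidden; ++i) if (cc.h1[i] < 0) cc.h1[i] = 0;
  cc.logits.assign(net.nclass, 0.0);
  double mx = -1e300;
  for (int k = 0; k < net.nclass; ++k) {
    double s = net.b2[k];
    for (int i = 0; i < net.hidden; ++i)
      s += net.W2[k + (size_t)i * net.nclass] * cc.h1[i];
    cc.logits[k] = s;
    if (s > mx) mx = s;
  }
  cc.probs.assign(net.nclass, 0.0);
  double z = 0.0;
  for (int k = 0; k < net.nclass; ++k) {
    cc.probs[k] = std::exp(cc.logits[k] - mx);
    z += cc.probs[k];
  }
  for (int k = 0; k < net.nclass; ++k) cc.probs[k] /= z;
}

// Mean cross-entropy loss and mean gradients over one minibatch.
// X has dim (H, W, N); `samples` and `labels` are 0-based.
// [[Rcpp::export]]
List cpp_cnn_batch(List params, NumericVector X, IntegerVector samples,
                   IntegerVector labels, bool want_grad) {
  IntegerVector dim = X.attr("dim");
  int H0 = dim[0], W0 = dim[1];
  Net net = make_net(params, H0, W0);
  int B = samples.size();
  const double* xp = REAL(X);

  List convW = params["conv_W"];
  std::vector<std::vector<double> > gW(net.nblocks), gb(net.nblocks);
  for (int l = 0; l < net.nblocks; ++l) {
    gW[l].assign((size_t)net.OC[l] * net.IC[l] * 9, 0.0);
    gb[l].assign(net.OC[l], 0.0);
  }
  std::vector<double> gW1((size_t)net.hidden * net.flat, 0.0),
      gb1(net.hidden, 0.0), gW2((size_t)net.nclass * net.hidden, 0.0),
      gb2(net.nclass, 0.0);

  double loss = 0.0;
  int correct = 0;
  Cache cc;
  for (int bi = 0; bi < B; ++bi) {
    const double* x = xp + (size_t)samples[bi] * H0 * W0;
    forward_one(net, x, cc);
    int y = labels[bi];
    loss += -std::log(std::max(cc.probs[y], 1e-12));
    int pred = 0;
    for (int k = 1; k < net.nclass; ++k)
      if (cc.probs[k] > cc.probs[pred]) pred = k;
    if (pred == y) ++correct;
    if (!want_grad) continue;

    // softmax cross-entropy gradient on logits
    std::vector<double> dlog(cc.probs);
    dlog[y] -= 1.0;
    std::vector<double> dh1(net.hidden, 0.0);
    for (int k = 0; k < net.nclass; ++k) {
      gb2[k] += dlog[k];
      for (int i = 0; i < net.hidden; ++i) {
        gW2[k + (size_t)i * net.nclass] += dlog[k] * cc.h1[i];
        dh1[i] += net.W2[k + (size_t)i * net.nclass] * dlog[k];
      }
    }
    for (int i = 0; i < net.hidden; ++i)
      if (cc.h1pre[i] <= 0) dh1[i] = 0.0;
    std::vector<double> dflat(net.flat, 0.0);
    const std::vector<double>& flat = cc.act[net.nblocks];
    for (int i = 0; i < net.hidden; ++i) {
      if (dh1[i] == 0.0) continue;
      gb1[i] += dh1[i];
      for (int j = 0; j < net.flat; ++j) {
        gW1[i + (size_t)j * net.hidden] += dh1[i] * flat[j];
        dflat[j] += net.W1[i + (size_t)j * net.hidden] * dh1[i];
      }
    }
    // back through the blocks
    std::vector<double> dpool = dflat;
    for (int l = net.nblocks - 1; l >= 0; --l) {
      int H = net.Hs[l], Wd = net.Ws[l];
      std::vector<double> drelu((size_t)net.OC[l] * H * Wd, 0.0);
      for (size_t i = 0; i < cc.arg[l].size(); ++i)
        drelu[cc.arg[l][i]] += dpool[i];
      for (size_t i = 0; i < drelu.size(); ++i)
        if (cc.convz[l][i] <= 0) drelu[i] = 0.0;
      std::vector<double> din((size_t)net.IC[l] * H * Wd, 0.0);
      conv3_backward(cc.act[l], drelu, H, Wd, net.IC[l], net.cW[l],
                     net.OC[l], din, gW[l].data(), gb[l].data());
      dpool = din;
    }
  }

  List out = List::create(_["loss"] = loss / B,
                          _["accuracy"] = (double)correct / B);
  if (want_grad) {
    List oW(net.nblocks), ob(net.nblocks);
    for (int l = 0; l < net.nblocks; ++l) {
      NumericVector w(gW[l].begin(), gW[l].end());
      w.attr("dim") = IntegerVector::create(3, 3, net.IC[l], net.OC[l]);
      oW[l] = w;
      ob[l] = NumericVector(gb[l].begin(), gb[l].end());
    }
    NumericMatrix mW1(net.hidden, net.flat), mW2(net.nclass, net.hidden);
    std::copy(gW1.begin(), gW1.end(), REAL(mW1));
    std::copy(gW2.begin(), gW2.end(), REAL(mW2));
    for (size_t i = 0; i < gW1.size(); ++i) REAL(mW1)[i] /= B;
    for (size_t i = 0; i < gW2.size(); ++i) REAL(mW2)[i] /= B;
    NumericVector vb1(gb1.begin(), gb1.end()), vb2(gb2.begin(), gb2.end());
    for (int l = 0; l < net.nblocks; ++l) {
      NumericVector w = oW[l];
      for (R_xlen_t i = 0; i < w.size(); ++i) w[i] /= B;
      NumericVector b = ob[l];
      for (R_xlen_t i = 0; i < b.size(); ++i) b[i] /= B;
    }
    for (int i = 0; i < net.hidden; ++i) vb1[i] /= B;
    for (int k = 0; k < net.nclass; ++k) vb2[k] /= B;
    out["grads"] = List::create(_["conv_W"] = oW, _["conv_b"] = ob,
                                _["fc1_W"] = mW1, _["fc1_b"] = vb1,
                                _["fc2_W"] = mW2, _["fc2_b"] = vb2);
  }
  return out;
}

// Class probabilities for a set of samples.
// [[Rcpp::export]]
NumericMatrix cpp_cnn_predict(List params, NumericVector X,
                              IntegerVector samples) {
  IntegerVector dim = X.attr("dim");
  int H0 = dim[0], W0 = dim[1];
  Net net = make_net(params, H0, W0);
  int B = samples.size();
  NumericMatrix probs(B, net.nclass);
  const double* xp = REAL(X);
  Cache cc;
  for (int bi = 0; bi < B; ++bi) {
    forward_one(net, xp + (size_t)samples[bi] * H0 * W0, cc);
    for (int k = 0; k < net.nclass; ++k) probs(bi, k) = cc.probs[k];
  }
  return probs;
}
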