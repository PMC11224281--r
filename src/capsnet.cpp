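#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Capsule-network forward pass and margin-loss fitness.
//
// Parameter vector layout (column-major, matching R's as.vector()):
//   conv_w : dim (K, K, F)
//   conv_b : length F
//   caps_w : dim (class_dim, primary_dim, n_primary, n_class)
//   caps_b : dim (class_dim, n_class)
// Images arrive as an n x (H*W) matrix, each row one image flattened
// column-major from an H x W matrix.

namespace {

struct Arch {
  int H, W, F, K, stride, primary_dim, n_class, class_dim, routing;
  int out_h, out_w, n_primary;
  int off_conv_b, off_caps_w, off_caps_b, n_params;
};

Arch make_arch(const List& arch) {
  Arch a;
  a.H = as<int>(arch["input_height"]);
  a.W = as<int>(arch["input_width"]);
  a.F = as<int>(arch["conv_filters"]);
  a.K = as<int>(arch["conv_kernel"]);
  a.stride = as<int>(arch["conv_stride"]);
  a.primary_dim = as<int>(arch["primary_dim"]);
  a.n_class = as<int>(arch["class_caps"]);
  a.class_dim = as<int>(arch["class_dim"]);
  a.routing = as<int>(arch["routing_iterations"]);
  a.out_h = (a.H - a.K) / a.stride + 1;
  a.out_w = (a.W - a.K) / a.stride + 1;
  a.n_primary = a.out_h * a.out_w * (a.F / a.primary_dim);
  int n_conv_w = a.K * a.K * a.F;
  a.off_conv_b = n_conv_w;
  a.off_caps_w = n_conv_w + a.F;
  a.off_caps_b = a.off_caps_w +
    a.class_dim * a.primary_dim * a.n_primary * a.n_class;
  a.n_params = a.off_caps_b + a.class_dim * a.n_class;
  return a;
}

// Squash in place: v = (||s||^2 / (1 + ||s||^2)) * s / ||s||; 0 -> 0.
void squash_vec(double* s, int d) {
  double n2 = 0.0;
  for (int i = 0; i < d; ++i) n2 += s[i] * s[i];
  if (n2 == 0.0) return;
  double scale = n2 / ((1.0 + n2) * std::sqrt(n2));
  for (int i = 0; i < d; ++i) s[i] *= scale;
}

// Forward pass for one image; writes the n_class output-vector lengths.
void forward_one(const double* img, const double* p, const Arch& a,
                 double* lengths,
                 std::vector<double>& conv, std::vector<double>& prim,
                 std::vector<double>& uhat, std::vector<double>& blog,
                 std::vector<double>& coup, std::vector<double>& v) {
  const int OH = a.out_h, OW = a.out_w;
  const int cpl = a.F / a.primary_dim;   // capsules per spatial location
  const double* conv_w = p;
  const double* conv_b = p + a.off_conv_b;
  const double* caps_w = p + a.off_caps_w;
  const double* caps_b = p + a.off_caps_b;

  // Convolution (valid padding) + tanh, conv[ho + OH*(wo + OW*f)].
  for (int f = 0; f < a.F; ++f) {
    const double* w = conv_w + a.K * a.K * f;
    for (int wo = 0; wo < OW; ++wo) {
      for (int ho = 0; ho < OH; ++ho) {
        double acc = conv_b[f];
        int r0 = ho * a.stride, c0 = wo * a.stride;
        for (int kj = 0; kj < a.K; ++kj) {
          const double* col = img + (c0 + kj) * a.H + r0;
          const double* wk = w + kj * a.K;
          for (int ki = 0; ki < a.K; ++ki) acc += wk[ki] * col[ki];
        }
        conv[ho + OH * (wo + OW * f)] = std::tanh(acc);
      }
    }
  }

  // Primary capsules: at each location, cpl capsules of primary_dim taken
  // from consecutive filter blocks; squash each.
  for (int wo = 0; wo < OW; ++wo) {
    for (int ho = 0; ho < OH; ++ho) {
      int loc = ho + OH * wo;
      for (int cb = 0; cb < cpl; ++cb) {
        int i = loc * cpl + cb;
        double* x = &prim[i * a.primary_dim];
        for (int d = 0; d < a.primary_dim; ++d) {
          int f = cb * a.primary_dim + d;
          x[d] = conv[ho + OH * (wo + OW * f)];
        }
        squash_vec(x, a.primary_dim);
      }
    }
  }

  // Prediction vectors u_hat[j|i] = W_ij x_i,
  // uhat[d + class_dim*(i + n_primary*j)].
  for (int j = 0; j < a.n_class; ++j) {
    for (int i = 0; i < a.n_primary; ++i) {
      const double* W = caps_w +
        a.class_dim * a.primary_dim * (i + a.n_primary * j);
      const double* x = &prim[i * a.primary_dim];
      double* u = &uhat[a.class_dim * (i + a.n_primary * j)];
      for (int d = 0; d < a.class_dim; ++d) u[d] = 0.0;
      for (int q = 0; q < a.primary_dim; ++q) {
        double xq = x[q];
        const double* Wc = W + a.class_dim * q;   // column q of W_ij
        for (int d = 0; d < a.class_dim; ++d) u[d] += Wc[d] * xq;
      }
    }
  }

  // Dynamic routing, log priors start at zero.
  std::fill(blog.begin(), blog.end(), 0.0);
  for (int it = 0; it < a.routing; ++it) {
    // coupling: softmax over classes for each primary capsule
    for (int i = 0; i < a.n_primary; ++i) {
      double mx = blog[i];
      for (int j = 1; j < a.n_class; ++j)
        mx = std::max(mx, blog[i + a.n_primary * j]);
      double sum = 0.0;
      for (int j = 0; j < a.n_class; ++j) {
        double e = std::exp(blog[i + a.n_primary * j] - mx);
        coup[i + a.n_primary * j] = e;
        sum += e;
      }
      for (int j = 0; j < a.n_class; ++j) coup[i + a.n_primary * j] /= sum;
    }
    // s_j = sum_i c_ij u_hat[j|i] + caps_b[, j]; v_j = squash(s_j)
    for (int j = 0; j < a.n_class; ++j) {
      double* vj = &v[j * a.class_dim];
      for (int d = 0; d < a.class_dim; ++d) vj[d] = caps_b[d + a.class_dim * j];
      for (int i = 0; i < a.n_primary; ++i) {
        double c = coup[i + a.n_primary * j];
        const double* u = &uhat[a.class_dim * (i + a.n_primary * j)];
        for (int d = 0; d < a.class_dim; ++d) vj[d] += c * u[d];
      }
      squash_vec(vj, a.class_dim);
    }
    // agreement update (skipped after the last pass)
    if (it + 1 < a.routing) {
      for (int j = 0; j < a.n_class; ++j) {
        const double* vj = &v[j * a.class_dim];
        for (int i = 0; i < a.n_primary; ++i) {
          const double* u = &uhat[a.class_dim * (i + a.n_primary * j)];
          double dot = 0.0;
          for (int d = 0; d < a.class_dim; ++d) dot += u[d] * vj[d];
          blog[i + a.n_primary * j] += dot;
        }
      }
    }
  }

  for (int j = 0; j < a.n_class; ++j) {
    const double* vj = &v[j * a.class_dim];
    double n2 = 0.0;
    for (int d = 0; d < a.class_dim; ++d) n2 += vj[d] * vj[d];
    lengths[j] = std::sqrt(n2);
  }
}

struct Buffers {
  std::vector<double> conv, prim, uhat, blog, coup, v;
  explicit Buffers(const Arch& a)
    : conv(a.out_h * a.out_w * a.F),
      prim(a.n_primary * a.primary_dim),
      uhat(a.class_dim * a.n_primary * a.n_class),
      blog(a.n_primary * a.n_class),
      coup(a.n_primary * a.n_class),
      v(a.n_class * a.class_dim) {}
};

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_capsnet_lengths(NumericMatrix images, NumericVector params,
                                  List arch) {
  Arch a = make_arch(arch);
  if (params.size() != a.n_params)
    stop("parameter vector has length %d, expected %d",
         (int)params.size(), a.n_params);
  if (images.ncol() != a.H * a.W)
    stop("images must have %d columns (flattened %dx%d)", a.H * a.W, a.H, a.W);
  int n = images.nrow();
  NumericMatrix out(n, a.n_class);
  Buffers buf(a);
  std::vector<double> img(a.H * a.W), len(a.n_class);
  for (int s = 0; s < n; ++s) {
    for (int c = 0; c < a.H * a.W; ++c) img[c] = images(s, c);
    forward_one(img.data(), params.begin(), a, len.data(),
                buf.conv, buf.prim, buf.uhat, buf.blog, buf.coup, buf.v);
    for (int j = 0; j < a.n_class; ++j) out(s, j) = len[j];
  }
  return out;
}

// [[Rcpp::export]]
double cpp_capsnet_fitness(NumericMatrix images, IntegerVector labels0,
                           NumericVector params, List arch, double m_plus,
                           double m_minus, double lambda) {
  Arch a = make_arch(arch);
  if (params.size() != a.n_params)
    stop("parameter vector has length %d, expected %d",
         (int)params.size(), a.n_params);
  int n = images.nrow();
  if (labels0.size() != n) stop("labels length must match image count");
  Buffers buf(a);
  std::vector<double> img(a.H * a.W), len(a.n_class);
  double total = 0.0;
  for (int s = 0; s < n; ++s) {
    for (int c = 0; c < a.H * a.W; ++c) img[c] = images(s, c);
    forward_one(img.data(), params.begin(), a, len.data(),
                buf.conv, buf.prim, buf.uhat, buf.blog, buf.coup, buf.v);
    int y = labels0[s];
    for (int j = 0; j < a.n_class; ++j) {
      double L = len[j];
      if (j == y) {
        double h = m_plus - L;
        if (h > 0) total += h * h;
      } else {
        double h = L - m_minus;
        if (h > 0) total += lambda * h * h;
      }
    }
  }
  return total / n;
}
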