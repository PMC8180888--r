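// Event-driven simulation of a multi-layer convolutional spiking network of
// leaky integrate-and-fire neurons with input delay lines, shared (weight-
// tied) 5x5 kernels, lateral inhibition across filters at a retinotopic
// position, an adaptive (inverted-V) threshold penalty, and a simplified
// multiplicative STDP rule applied at postsynaptic spike times.
//
// Conventions shared with the R side:
//  * pixel/map coordinates are 0-based, x rightward, y downward;
//  * layer k has a (W - 4k) x (H - 4k) retinotopic map (valid 5x5, stride 1);
//  * input channels of layer 1 are c = 2*delay_index + polarity (6 channels);
//    deeper layers use c = previous-layer filter index;
//  * weights for a layer are stored as an R array dim (n_filters, 5, 5, C)
//    indexed [filter, dy, dx, channel];
//  * simultaneous events are processed in (t, layer, y, x, channel) order,
//    and one delivered event updates target neurons in raster order (y, x)
//    with filters ascending.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Ev {
  double t;
  int layer;  // 0 = sensor events entering layer 1's input
  int x, y, c;
};

struct EvCmp {
  // std::priority_queue is a max-heap: return true when a comes AFTER b.
  bool operator()(const Ev& a, const Ev& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.layer != b.layer) return a.layer > b.layer;
    if (a.y != b.y) return a.y > b.y;
    if (a.x != b.x) return a.x > b.x;
    return a.c > b.c;
  }
};

struct Pen {
  double t;  // spike time
  double a;  // peak amplitude f_long * U_PropInh
};

struct Layer {
  int n_filters, in_ch, in_w, in_h, map_w, map_h;
  double w_max, tau_memb, tau_ltp, a_ltp, a_ltd;
  double f_inst, f_long, t_thresh, u_thresh;
  std::vector<double> w;       // n_filters * 5 * 5 * in_ch, R array layout
  std::vector<double> u;       // membrane potentials
  std::vector<double> last_t;  // per-neuron last leak time
  std::vector<std::vector<Pen>> pens;  // per-neuron own-spike penalties
  std::vector<double> last_in; // last input spike per (c, x, y)

  inline int widx(int f, int dy, int dx, int c) const {
    return f + n_filters * (dy + 5 * (dx + 5 * c));
  }
  inline int nidx(int f, int x, int y) const {
    return f + n_filters * (x + map_w * y);
  }
  inline int iidx(int c, int x, int y) const {
    return c + in_ch * (x + in_w * y);
  }

  // Triangular threshold penalty: each past own-spike at ts with amplitude a
  // contributes a*(t-ts)/T on [ts, ts+T], a*(2-(t-ts)/T) on [ts+T, ts+2T].
  double penalty(int n, double t) {
    std::vector<Pen>& v = pens[n];
    double total = 0.0;
    size_t keep = 0;
    for (size_t i = 0; i < v.size(); ++i) {
      double dt = t - v[i].t;
      if (dt >= 2.0 * t_thresh) continue;  // expired, prune
      if (dt >= t_thresh) total += v[i].a * (2.0 - dt / t_thresh);
      else if (dt >= 0) total += v[i].a * (dt / t_thresh);
      v[keep++] = v[i];
    }
    v.resize(keep);
    return total;
  }

  inline void leak(int n, double t) {
    double dt = t - last_t[n];
    if (dt > 0 && u[n] != 0.0) u[n] *= std::exp(-dt / tau_memb);
    last_t[n] = t;
  }
};

}  // namespace

// [[Rcpp::export]]
List run_snn_cpp(NumericVector ev_t, IntegerVector ev_x, IntegerVector ev_y,
                 IntegerVector ev_p, int width, int height, List layer_list,
                 NumericVector delays, int learning_layer, int n_active) {
  const int n_layers = n_active > 0 ?
    std::min<int>(n_active, layer_list.size()) : layer_list.size();
  std::vector<Layer> L(n_layers);
  for (int k = 0; k < n_layers; ++k) {
    List ll = layer_list[k];
    Layer& lay = L[k];
    lay.n_filters = as<int>(ll["n_filters"]);
    lay.w_max = as<double>(ll["w_max"]);
    lay.tau_memb = as<double>(ll["tau_memb"]);
    lay.tau_ltp = as<double>(ll["tau_ltp"]);
    lay.a_ltp = as<double>(ll["a_ltp"]);
    lay.a_ltd = as<double>(ll["a_ltd"]);
    lay.f_inst = as<double>(ll["f_inst"]);
    lay.f_long = as<double>(ll["f_long"]);
    lay.t_thresh = as<double>(ll["t_thresh"]);
    lay.u_thresh = as<double>(ll["u_thresh"]);
    lay.in_ch = (k == 0) ? 6 : L[k - 1].n_filters;
    lay.in_w = (k == 0) ? width : L[k - 1].map_w;
    lay.in_h = (k == 0) ? height : L[k - 1].map_h;
    lay.map_w = lay.in_w - 4;
    lay.map_h = lay.in_h - 4;
    if (lay.map_w < 1 || lay.map_h < 1)
      stop("layer %d input (%d x %d) too small for a 5x5 patch", k + 1,
           lay.in_w, lay.in_h);
    NumericVector wv = ll["weights"];
    if ((int)wv.size() != lay.n_filters * 25 * lay.in_ch)
      stop("layer %d weights have wrong length", k + 1);
    lay.w.assign(wv.begin(), wv.end());
    int n_neur = lay.n_filters * lay.map_w * lay.map_h;
    lay.u.assign(n_neur, 0.0);
    lay.last_t.assign(n_neur, 0.0);
    lay.pens.assign(n_neur, std::vector<Pen>());
    lay.last_in.assign(lay.in_ch * lay.in_w * lay.in_h, -1e300);
  }

  std::priority_queue<Ev, std::vector<Ev>, EvCmp> q;
  const int n_ev = ev_t.size();
  for (int i = 0; i < n_ev; ++i) {
    if (ev_x[i] < 0 || ev_x[i] >= width || ev_y[i] < 0 || ev_y[i] >= height)
      stop("event %d at (%d, %d) lies outside the %d x %d sensor frame",
           i + 1, ev_x[i], ev_y[i], width, height);
    if (ev_p[i] != 0 && ev_p[i] != 1)
      stop("event polarity must be 0 (OFF) or 1 (ON)");
    for (int d = 0; d < (int)delays.size(); ++d)
      q.push(Ev{ev_t[i] + delays[d], 0, ev_x[i], ev_y[i], 2 * d + ev_p[i]});
  }

  std::vector<double> sp_t, sp_u;
  std::vector<int> sp_layer, sp_filter, sp_x, sp_y;

  while (!q.empty()) {
    Ev e = q.top();
    q.pop();
    Layer& lay = L[e.layer];
    lay.last_in[lay.iidx(e.c, e.x, e.y)] = e.t;

    int y_lo = std::max(0, e.y - 4), y_hi = std::min(lay.map_h - 1, e.y);
    int x_lo = std::max(0, e.x - 4), x_hi = std::min(lay.map_w - 1, e.x);
    for (int Y = y_lo; Y <= y_hi; ++Y) {
      int dy = e.y - Y;
      for (int X = x_lo; X <= x_hi; ++X) {
        int dx = e.x - X;
        for (int f = 0; f < lay.n_filters; ++f) {
          int n = lay.nidx(f, X, Y);
          lay.leak(n, e.t);
          lay.u[n] += lay.w[lay.widx(f, dy, dx, e.c)] * lay.w_max;
          double thr = lay.u_thresh + lay.penalty(n, e.t);
          if (lay.u[n] >= thr) {
            // record the spike with its suprathreshold membrane value
            sp_t.push_back(e.t);
            sp_layer.push_back(e.layer + 1);
            sp_filter.push_back(f + 1);
            sp_x.push_back(X);
            sp_y.push_back(Y);
            sp_u.push_back(lay.u[n]);

            // U_PropInh: mean squared membrane potential over all filters at
            // this position, the spiker's value taken pre-reset.
            double s2 = lay.u[n] * lay.u[n];
            for (int g = 0; g < lay.n_filters; ++g) {
              if (g == f) continue;
              int m = lay.nidx(g, X, Y);
              lay.leak(m, e.t);
              s2 += lay.u[m] * lay.u[m];
            }
            double uprop = s2 / lay.n_filters;

            if (learning_layer == e.layer + 1) {
              // STDP on the shared kernel from this neuron's afferent view
              for (int c = 0; c < lay.in_ch; ++c)
                for (int ddy = 0; ddy < 5; ++ddy)
                  for (int ddx = 0; ddx < 5; ++ddx) {
                    double ti =
                      lay.last_in[lay.iidx(c, X + ddx, Y + ddy)];
                    double& wij = lay.w[lay.widx(f, ddy, ddx, c)];
                    if (e.t - ti < lay.tau_ltp)
                      wij += (1.0 - wij) * lay.a_ltp;
                    else
                      wij -= wij * lay.a_ltd;
                  }
            }

            // lateral inhibition of the other filters at this position
            double u_inst = lay.f_inst * uprop;
            for (int g = 0; g < lay.n_filters; ++g) {
              if (g == f) continue;
              lay.u[lay.nidx(g, X, Y)] -= u_inst;
            }
            // homeostatic threshold penalty for the spiking neuron
            lay.pens[n].push_back(Pen{e.t, lay.f_long * uprop});
            lay.u[n] = 0.0;  // reset to rest

            if (e.layer + 1 < n_layers)
              q.push(Ev{e.t, e.layer + 1, X, Y, f});
          }
        }
      }
    }
  }

  List w_out(n_layers);
  for (int k = 0; k < n_layers; ++k)
    w_out[k] = NumericVector(L[k].w.begin(), L[k].w.end());

  return List::create(
    _["spikes"] = DataFrame::create(
      _["t"] = sp_t, _["layer"] = sp_layer, _["filter"] = sp_filter,
      _["x"] = sp_x, _["y"] = sp_y, _["u"] = sp_u),
    _["weights"] = w_out);
}
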