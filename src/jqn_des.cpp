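// Discrete-event simulation of an open Jackson network: Poisson external
// arrivals, exponential single-server FCFS service, probabilistic routing.
// Each (node, purpose) pair owns its own mt19937_64 stream derived from the
// master seed via splitmix64, so adding a node never perturbs the streams of
// the others and trajectories are reproducible bit-for-bit given the seed.
#include <Rcpp.h>
#include <deque>
#include <vector>
#include <cstdint>
#include <limits>
#include <random>
using namespace Rcpp;

static inline std::uint64_t splitmix64(std::uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct Stream {
  std::mt19937_64 eng;
  void seed_from(std::uint64_t master, std::uint64_t node,
                 std::uint64_t purpose) {
    // hash the triple through two splitmix rounds
    eng.seed(splitmix64(splitmix64(master ^ (node * 0x100000001B3ULL)) ^
                        (purpose + 0x9E3779B9ULL)));
  }
  // uniform on the open interval (0, 1)
  double unif() {
    return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double expo(double rate) { return -std::log(unif()) / rate; }
};

// [[Rcpp::export(name = ".jqn_des")]]
List jqn_des(NumericVector lambda_o, NumericVector mu, NumericMatrix routing,
             double horizon, double burn_in, double seed, double max_events,
             bool keep_log) {
  const int n = lambda_o.size();
  const double INF = std::numeric_limits<double>::infinity();
  const std::uint64_t master = static_cast<std::uint64_t>(seed);

  std::vector<Stream> arr(n), srv(n), rte(n);
  for (int i = 0; i < n; ++i) {
    arr[i].seed_from(master, i, 0);
    srv[i].seed_from(master, i, 1);
    rte[i].seed_from(master, i, 2);
  }

  std::vector<double> next_arrival(n, INF), next_completion(n, INF);
  for (int i = 0; i < n; ++i)
    if (lambda_o[i] > 0) next_arrival[i] = arr[i].expo(lambda_o[i]);

  std::vector<int> occ(n, 0);
  std::vector<std::deque<double> > fifo(n);

  // accumulated statistics (restricted to [burn_in, horizon])
  std::vector<std::vector<double> > occ_time(n);
  for (int i = 0; i < n; ++i) occ_time[i].assign(8, 0.0);
  std::vector<double> sojourn_sum(n, 0.0);
  std::vector<double> completions(n, 0.0);
  double departures = 0.0;

  std::vector<double> log_time, log_node, log_kind, log_dest;

  double t = 0.0;
  double n_events = 0.0;

  auto accumulate = [&](double from, double to) {
    double a = std::max(from, burn_in), b = std::min(to, horizon);
    if (b <= a) return;
    for (int i = 0; i < n; ++i) {
      if ((int) occ_time[i].size() <= occ[i])
        occ_time[i].resize(occ[i] + 1, 0.0);
      occ_time[i][occ[i]] += b - a;
    }
  };

  bool hit_horizon = false;
  while (n_events < max_events) {
    // next event: smallest (time, node, kind); arrivals before completions
    double tmin = INF; int node = -1; int kind = 0; // kind 0 arrival, 1 completion
    for (int i = 0; i < n; ++i) {
      if (next_arrival[i] < tmin) { tmin = next_arrival[i]; node = i; kind = 0; }
    }
    for (int i = 0; i < n; ++i) {
      if (next_completion[i] < tmin) { tmin = next_completion[i]; node = i; kind = 1; }
    }
    if (node < 0 || tmin > horizon) { hit_horizon = true; break; }

    accumulate(t, tmin);
    t = tmin;
    n_events += 1.0;

    if (kind == 0) {                         // external arrival at `node`
      next_arrival[node] = t + arr[node].expo(lambda_o[node]);
      fifo[node].push_back(t);
      occ[node] += 1;
      if (occ[node] == 1)
        next_completion[node] = t + srv[node].expo(mu[node]);
      if (keep_log) {
        log_time.push_back(t); log_node.push_back(node + 1);
        log_kind.push_back(1); log_dest.push_back(0);
      }
    } else {                                 // service completion at `node`
      double entry = fifo[node].front();
      fifo[node].pop_front();
      occ[node] -= 1;
      if (occ[node] > 0)
        next_completion[node] = t + srv[node].expo(mu[node]);
      else
        next_completion[node] = INF;
      if (t >= burn_in) {
        completions[node] += 1.0;
        sojourn_sum[node] += t - entry;
      }
      // route onward or depart
      double u = rte[node].unif(), acc = 0.0; int dest = -1;
      for (int j = 0; j < n; ++j) {
        acc += routing(node, j);
        if (u < acc) { dest = j; break; }
      }
      if (dest >= 0) {
        fifo[dest].push_back(t);
        occ[dest] += 1;
        if (occ[dest] == 1)
          next_completion[dest] = t + srv[dest].expo(mu[dest]);
        if (keep_log) {
          log_time.push_back(t); log_node.push_back(node + 1);
          log_kind.push_back(2); log_dest.push_back(dest + 1);
        }
      } else {
        if (t >= burn_in) departures += 1.0;
        if (keep_log) {
          log_time.push_back(t); log_node.push_back(node + 1);
          log_kind.push_back(3); log_dest.push_back(0);
        }
      }
    }
  }
  double end_time = t;
  if (hit_horizon) {            // close the window at the horizon
    accumulate(t, horizon);
    end_time = horizon;
  }
  double observed = std::max(0.0, end_time - burn_in);

  NumericVector tao(n), thr(n), soj(n), comp(n);
  List occl(n);
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    for (size_t k = 0; k < occ_time[i].size(); ++k)
      tot += k * occ_time[i][k];
    tao[i] = observed > 0 ? tot / observed : NA_REAL;
    thr[i] = observed > 0 ? completions[i] / observed : NA_REAL;
    soj[i] = completions[i] > 0 ? sojourn_sum[i] / completions[i] : NA_REAL;
    comp[i] = completions[i];
    occl[i] = NumericVector(occ_time[i].begin(), occ_time[i].end());
  }

  List out = List::create(
    _["time_avg_occupancy"] = tao, _["throughput"] = thr,
    _["mean_sojourn"] = soj, _["completions"] = comp,
    _["departures"] = departures, _["occ_time"] = occl,
    _["observed_time"] = observed, _["end_time"] = end_time,
    _["n_events"] = n_events);
  if (keep_log)
    out["events"] = DataFrame::create(
      _["time"] = log_time, _["node"] = log_node,
      _["kind"] = log_kind, _["dest"] = log_dest);
  return out;
}
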