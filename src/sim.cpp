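// Tick-level engine for the polychronous network.
//
// The whole network advances on a single discrete clock (one tick = one
// axon-array update period, 62 us by default).  Within a tick the phases are
// fixed: (a) active ramps increment and delay paths whose ramp has reached
// their programmed delay emit pre-synaptic spikes; (b) pre-synaptic spikes
// are delivered to neuron synapse timers in ascending module index;
// (c) neurons whose active-timer count reaches the coincidence threshold
// fire; (d) post-synaptic spikes (and externally injected spikes) restart
// the ramps of every module whose input address matches.  Timers expire
// lazily once their elapsed time passes the coincidence window.
//
// Unset addresses/delays are encoded as -1 (R wrappers map NA <-> -1).

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct NetConfig {
  int M, N;
  const int* in;   // module input address, length M, -1 unset
  const int* out;  // M x 4 column-major: out[m + j*M]
  const int* del;  // M x 4 column-major, ticks, -1 unset
  int window, threshold, refractory, delay_max;
  std::vector<std::vector<int> > addr_map;  // neuron address -> module indices

  void build_map() {
    addr_map.assign(N, std::vector<int>());
    for (int m = 0; m < M; ++m)
      if (in[m] >= 0 && in[m] < N) addr_map[in[m]].push_back(m);
  }
};

struct NetState {
  std::vector<int> ramp;       // M
  std::vector<char> ramp_on;   // M
  std::vector<int> tstart;     // N*4 timer start ticks, -1 inactive
  std::vector<int> refract;    // N: neuron may fire again at tick >= refract
  std::vector<int> active;     // indices of modules with ramp_on

  void init(int M, int N) {
    ramp.assign(M, 0);
    ramp_on.assign(M, 0);
    tstart.assign((size_t)N * 4, -1);
    refract.assign(N, 0);
    active.clear();
  }
};

struct Emission { int m, line, tgt; };

inline void route_spike(const NetConfig& cfg, NetState& st, int addr) {
  const std::vector<int>& ms = cfg.addr_map[addr];
  for (size_t k = 0; k < ms.size(); ++k) {
    int m = ms[k];
    st.ramp[m] = 0;
    if (!st.ramp_on[m]) { st.ramp_on[m] = 1; st.active.push_back(m); }
  }
}

// Run n_ticks starting at t0.  Returns true if the runaway guard tripped.
bool run_ticks(const NetConfig& cfg, NetState& st, int t0, int n_ticks,
               const int* inj_tick, const int* inj_addr, int n_inj,
               std::vector<int>& out_tick, std::vector<int>& out_addr,
               int max_emit) {
  std::vector<Emission> emit;
  std::vector<int> touched, fired;
  std::vector<char> touch_flag(cfg.N, 0);
  int ip = 0;
  const int M = cfg.M;

  for (int T = t0; T < t0 + n_ticks; ++T) {
    // (a) ramps advance; a path emits once, when the ramp reaches its delay
    emit.clear();
    bool any_off = false;
    for (size_t i = 0; i < st.active.size(); ++i) {
      int m = st.active[i];
      int rv = ++st.ramp[m];
      for (int j = 0; j < 4; ++j) {
        if (cfg.del[m + j * M] == rv) {
          int tgt = cfg.out[m + j * M];
          if (tgt >= 0) { Emission e = {m, j, tgt}; emit.push_back(e); }
        }
      }
      if (rv >= cfg.delay_max) { st.ramp_on[m] = 0; any_off = true; }  // saturate
    }
    if (any_off) {
      size_t k = 0;
      for (size_t i = 0; i < st.active.size(); ++i)
        if (st.ramp_on[st.active[i]]) st.active[k++] = st.active[i];
      st.active.resize(k);
    }
    std::sort(emit.begin(), emit.end(), [](const Emission& a, const Emission& b) {
      return a.m != b.m ? a.m < b.m : a.line < b.line;
    });

    // (b) deliver pre-synaptic spikes in ascending module index
    touched.clear();
    for (size_t i = 0; i < emit.size(); ++i) {
      int tgt = emit[i].tgt;
      if (T < st.refract[tgt]) continue;  // refractory: spike ignored
      int* t4 = &st.tstart[(size_t)tgt * 4];
      int& ts = t4[emit[i].line];
      if (ts >= 0 && T - ts > cfg.window) ts = -1;  // stale timer
      if (ts < 0) {
        ts = T;
        if (!touch_flag[tgt]) { touch_flag[tgt] = 1; touched.push_back(tgt); }
      }
      // else: timer already active, spike ignored
    }

    // (c) coincidence detection on neurons that gained a timer this tick
    fired.clear();
    for (size_t i = 0; i < touched.size(); ++i) {
      int tgt = touched[i];
      touch_flag[tgt] = 0;
      int* t4 = &st.tstart[(size_t)tgt * 4];
      int c = 0;
      for (int j = 0; j < 4; ++j) {
        if (t4[j] >= 0) {
          if (T - t4[j] > cfg.window) t4[j] = -1; else ++c;
        }
      }
      if (c >= cfg.threshold) {
        fired.push_back(tgt);
        for (int j = 0; j < 4; ++j) t4[j] = -1;  // timers reset on fire
        st.refract[tgt] = T + cfg.refractory;
      }
    }

    // (d) post-synaptic spikes are emitted and routed back to the axon array,
    //     together with externally injected spikes scheduled for this tick
    for (size_t i = 0; i < fired.size(); ++i) {
      out_tick.push_back(T);
      out_addr.push_back(fired[i]);
      route_spike(cfg, st, fired[i]);
    }
    while (ip < n_inj && inj_tick[ip] < T) ++ip;
    while (ip < n_inj && inj_tick[ip] == T) route_spike(cfg, st, inj_addr[ip++]);

    if (max_emit > 0 && (int)out_tick.size() > max_emit) return true;
  }
  return false;
}

}  // namespace

// [[Rcpp::export]]
List cpp_run_network(IntegerVector mod_in, IntegerMatrix mod_out,
                     IntegerMatrix mod_del, int n_neurons,
                     IntegerVector ramp, IntegerVector ramp_on,
                     IntegerMatrix timer_start, IntegerVector refract_until,
                     int current_tick, int n_ticks,
                     IntegerVector inj_tick, IntegerVector inj_addr,
                     int window, int threshold, int refractory, int delay_max,
                     int max_emit) {
  NetConfig cfg;
  cfg.M = mod_in.size();
  cfg.N = n_neurons;
  cfg.in = INTEGER(mod_in);
  cfg.out = INTEGER(mod_out);
  cfg.del = INTEGER(mod_del);
  cfg.window = window;
  cfg.threshold = threshold;
  cfg.refractory = refractory;
  cfg.delay_max = delay_max;
  cfg.build_map();

  NetState st;
  st.ramp.assign(INTEGER(ramp), INTEGER(ramp) + cfg.M);
  st.ramp_on.assign(cfg.M, 0);
  for (int m = 0; m < cfg.M; ++m) {
    st.ramp_on[m] = (char)(ramp_on[m] != 0);
    if (st.ramp_on[m]) st.active.push_back(m);
  }
  st.tstart.assign(INTEGER(timer_start), INTEGER(timer_start) + (size_t)cfg.N * 4);
  // R stores the timer matrix N x 4 column-major; engine wants per-neuron rows
  std::vector<int> tcol = st.tstart;
  for (int n = 0; n < cfg.N; ++n)
    for (int j = 0; j < 4; ++j) st.tstart[(size_t)n * 4 + j] = tcol[n + (size_t)j * cfg.N];
  st.refract.assign(INTEGER(refract_until), INTEGER(refract_until) + cfg.N);

  std::vector<int> out_tick, out_addr;
  bool runaway = run_ticks(cfg, st, current_tick, n_ticks,
                           INTEGER(inj_tick), INTEGER(inj_addr), inj_tick.size(),
                           out_tick, out_addr, max_emit);

  IntegerMatrix ts_out(cfg.N, 4);
  for (int n = 0; n < cfg.N; ++n)
    for (int j = 0; j < 4; ++j) ts_out(n, j) = st.tstart[(size_t)n * 4 + j];
  IntegerVector ramp_out(cfg.M), on_out(cfg.M), ref_out(cfg.N);
  for (int m = 0; m < cfg.M; ++m) { ramp_out[m] = st.ramp[m]; on_out[m] = st.ramp_on[m]; }
  for (int n = 0; n < cfg.N; ++n) ref_out[n] = st.refract[n];

  return List::create(
      _["tick"] = IntegerVector(out_tick.begin(), out_tick.end()),
      _["address"] = IntegerVector(out_addr.begin(), out_addr.end()),
      _["ramp"] = ramp_out, _["ramp_on"] = on_out,
      _["timer_start"] = ts_out, _["refract_until"] = ref_out,
      _["current_tick"] = current_tick + n_ticks, _["runaway"] = runaway);
}

// Run many independent recall trials against one trained network.  Each trial
// starts from an idle network at tick 0 with its own injected spike stream.
// [[Rcpp::export]]
List cpp_recall_batch(IntegerVector mod_in, IntegerMatrix mod_out,
                      IntegerMatrix mod_del, int n_neurons,
                      int window, int threshold, int refractory, int delay_max,
                      IntegerVector inj_tick, IntegerVector inj_addr,
                      IntegerVector trial_offsets,  // length n_trials+1, 0-based
                      IntegerVector durations, IntegerVector max_emit) {
  NetConfig cfg;
  cfg.M = mod_in.size();
  cfg.N = n_neurons;
  cfg.in = INTEGER(mod_in);
  cfg.out = INTEGER(mod_out);
  cfg.del = INTEGER(mod_del);
  cfg.window = window;
  cfg.threshold = threshold;
  cfg.refractory = refractory;
  cfg.delay_max = delay_max;
  cfg.build_map();

  int n_trials = durations.size();
  List res(n_trials);
  NetState st;
  std::vector<int> out_tick, out_addr;
  for (int t = 0; t < n_trials; ++t) {
    st.init(cfg.M, cfg.N);
    out_tick.clear();
    out_addr.clear();
    int lo = trial_offsets[t], hi = trial_offsets[t + 1];
    bool runaway = run_ticks(cfg, st, 0, durations[t],
                             INTEGER(inj_tick) + lo, INTEGER(inj_addr) + lo,
                             hi - lo, out_tick, out_addr, max_emit[t]);
    res[t] = List::create(
        _["tick"] = IntegerVector(out_tick.begin(), out_tick.end()),
        _["address"] = IntegerVector(out_addr.begin(), out_addr.end()),
        _["runaway"] = runaway);
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return res;
}

// Spike stream of the two-LFSR pattern generator.  Each register is clocked
// one full turnover (width shifts) per spike, i.e. standard serial word
// output, and the address word is reduced modulo the array size.  The
// address register is wider than any array's address bus, so the joint
// sample sequence has period lcm(2^wa-1, 2^wb-1) -- tens of millions of
// spikes -- and no training stream ever revisits a register state: patterns
// cannot become shifted copies of one short orbit, and sample distance is
// unrelated to tick time (a stride commensurate with the tick clock would
// make all stored delays globally coherent and resonate).  The interval
// register depends only on its own seed, so runs with the same interval
// seed share inter-spike intervals across network sizes.
// [[Rcpp::export]]
List cpp_pattern_stream(int width_a, IntegerVector taps_a, int state_a,
                        int width_b, IntegerVector taps_b, int state_b,
                        int n_spikes, int iv_lo, int iv_hi, int n_neurons) {
  const int mask_a = (1 << width_a) - 1;
  const int mask_b = (1 << width_b) - 1;
  const int span = iv_hi - iv_lo + 1;
  IntegerVector addr(n_spikes), interval(n_spikes);
  for (int s = 0; s < n_spikes; ++s) {
    int sa = width_a;
    int sb = width_b;
    for (int i = 0; i < sa; ++i) {
      int fb = 0;
      for (int k = 0; k < taps_a.size(); ++k) fb ^= (state_a >> (taps_a[k] - 1)) & 1;
      state_a = ((state_a << 1) & mask_a) | fb;
    }
    for (int i = 0; i < sb; ++i) {
      int fb = 0;
      for (int k = 0; k < taps_b.size(); ++k) fb ^= (state_b >> (taps_b[k] - 1)) & 1;
      state_b = ((state_b << 1) & mask_b) | fb;
    }
    addr[s] = state_a % n_neurons;
    interval[s] = iv_lo + (state_b - 1) % span;
  }
  return List::create(_["address"] = addr, _["interval"] = interval);
}

// Draw n values from a Fibonacci LFSR, advancing the register `stride`
// shifts per value (stride = width gives one full register turnover per
// draw, i.e. serially-clocked word output).  taps are 1-based bit
// positions; state must be nonzero.
// [[Rcpp::export]]
IntegerVector cpp_lfsr_sequence(int width, IntegerVector taps, int state,
                                int n, int stride) {
  int mask = (1 << width) - 1;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    for (int s = 0; s < stride; ++s) {
      int fb = 0;
      for (int k = 0; k < taps.size(); ++k) fb ^= (state >> (taps[k] - 1)) & 1;
      state = ((state << 1) & mask) | fb;
    }
    out[i] = state;
  }
  return out;
}
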