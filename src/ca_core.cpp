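#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Synchronous update loop for the excitable lattice.
//
// Grid matrices are L x L and indexed [x, y]: x is the longitudinal (cable)
// direction with open boundaries, y indexes cables and wraps periodically.
// R stores these column-major, so the linear index i = x + L*y enumerates
// cells in row-major order (x fastest within cable y).
//
// Counter convention: a cell excited at step t has counter tau + 1 at t
// (the single depolarizing step), then counts down through tau refractory
// steps and is resting (0) from t + tau + 1 onward. Neighbour reads all
// use the pre-update state, so the update order inside a step is
// immaterial except for the documented row-major order of the per-cell
// epsilon trials, which fixes the RNG stream.
//
// Each step runs in two phases. Phase A walks the cells excited at the
// pre-update time and stamps their coupled resting, non-ablated
// neighbours as stimulated. Phase B is a single in-place row-major pass:
// refractory counters decrement, stamped cells fire (dysfunctional cells
// through one epsilon trial each, in row-major order), and on pacing
// steps resting pacemaker-column cells fire unconditionally. The two
// phases are equivalent to a full synchronous update from the pre-update
// state.
//
// Reentry bookkeeping: a firing of cell (x, y) at time t is attributable
// to the sinus (pacemaker) rhythm if some pacemaker firing at time tb
// with last_excite < tb <= t satisfies tb + x <= t (x 0-based; a wave
// needs at least x steps to reach column x). A re-excitation with no
// such tb cannot stem from a fresh paced wave and is recorded as a
// reentry event.

// [[Rcpp::export(name = ".ca_run")]]
List ca_run(IntegerMatrix counters, int t0, LogicalMatrix vertical_edges,
            LogicalMatrix dysfunctional, LogicalMatrix ablated,
            int tau, int t_pace, double eps, int n_steps,
            IntegerVector snapshot_steps, bool record_activations,
            bool detect_reentry, bool stop_at_reentry,
            bool detect_all_reentry,
            Nullable<IntegerMatrix> last_excite_init,
            IntegerVector beats_init) {
  const int L = counters.nrow();
  const int n = L * L;
  const int C = tau + 1;  // counter value of a freshly excited cell

  std::vector<int> cnt(n);
  std::vector<char> dys(n), abl(n), ve(n);
  std::vector<int> excited;  // cells excited at the current time
  excited.reserve(n / 4 + 8);
  for (int i = 0; i < n; ++i) {
    cnt[i] = counters[i];
    dys[i] = dysfunctional[i];
    abl[i] = ablated[i];
    ve[i]  = vertical_edges[i];
    if (cnt[i] == C) excited.push_back(i);
  }

  std::vector<int> last_exc(n, -1);
  if (last_excite_init.isNotNull()) {
    IntegerMatrix le(last_excite_init);
    for (int i = 0; i < n; ++i) last_exc[i] = le[i];
  }
  std::vector<int> beats(beats_init.begin(), beats_init.end());

  std::vector<int> snap_req(snapshot_steps.begin(), snapshot_steps.end());
  std::sort(snap_req.begin(), snap_req.end());
  size_t snap_idx = 0;
  while (snap_idx < snap_req.size() && snap_req[snap_idx] <= t0) ++snap_idx;

  IntegerVector n_excited(n_steps);
  List snapshots;
  CharacterVector snap_names;
  std::vector<int> act_t, act_x, act_y;
  int reentry_t = -1, reentry_x = -1, reentry_y = -1;
  int last_re_t = -1, last_re_x = -1, last_re_y = -1;
  int n_reentry = 0;

  // stamp[i] == s + 1 marks cell i as stimulated during step s
  std::vector<int> stamp(n, 0);
  std::vector<int> fired;
  fired.reserve(n / 4 + 8);

  int t = t0;
  int steps_done = 0;

  for (int s = 0; s < n_steps; ++s) {
    const bool pace = (t % t_pace == 0);
    const int t_new = t + 1;
    const int mark = s + 1;
    bool pacer_fired = false;
    fired.clear();

    // phase A: stamp coupled resting neighbours of excited cells
    for (size_t k = 0; k < excited.size(); ++k) {
      const int i = excited[k];
      const int x = i % L, y = i / L;
      if (x > 0 && cnt[i - 1] == 0 && !abl[i - 1]) stamp[i - 1] = mark;
      if (x < L - 1 && cnt[i + 1] == 0 && !abl[i + 1]) stamp[i + 1] = mark;
      if (ve[i]) {  // edge to the cable below (y + 1, wrapped)
        const int j = x + L * ((y + 1) % L);
        if (cnt[j] == 0 && !abl[j]) stamp[j] = mark;
      }
      const int yu = (y - 1 + L) % L;
      if (ve[x + L * yu]) {  // edge to the cable above
        const int j = x + L * yu;
        if (cnt[j] == 0 && !abl[j]) stamp[j] = mark;
      }
    }

    // phase B: in-place row-major pass (decrement + firing)
    if (pace) {
      for (int y = 0; y < L; ++y) {  // pacemaker column x = 0
        const int i = L * y;
        if (cnt[i] == 0 && !abl[i] && stamp[i] != mark) stamp[i] = -mark;
      }
    }
    for (int i = 0; i < n; ++i) {
      const int c = cnt[i];
      if (c > 0) {
        cnt[i] = c - 1;
        continue;
      }
      const int st = stamp[i];
      if (st != mark && st != -mark) continue;
      bool fire;
      if (st == mark) {  // neighbour-stimulated
        fire = dys[i] ? (unif_rand() >= eps) : true;
        if (pace && i % L == 0) {  // pacing overrides a failed trial
          fire = true;
          pacer_fired = true;
        }
      } else {  // pacing only
        fire = true;
        pacer_fired = true;
      }
      if (fire) {
        cnt[i] = C;
        fired.push_back(i);
      }
    }

    if (pacer_fired) beats.push_back(t_new);

    for (size_t k = 0; k < fired.size(); ++k) {
      const int i = fired[k];
      const int x = i % L, y = i / L;
      if (record_activations) {
        act_t.push_back(t_new);
        act_x.push_back(x + 1);
        act_y.push_back(y + 1);
      }
      if (detect_reentry && (reentry_t < 0 || detect_all_reentry) &&
          last_exc[i] >= 0) {
        std::vector<int>::iterator it =
          std::upper_bound(beats.begin(), beats.end(), last_exc[i]);
        bool feasible = (it != beats.end() && *it <= t_new && *it + x <= t_new);
        if (!feasible) {
          if (reentry_t < 0) {
            reentry_t = t_new;
            reentry_x = x + 1;
            reentry_y = y + 1;
          }
          last_re_t = t_new;
          last_re_x = x + 1;
          last_re_y = y + 1;
          ++n_reentry;
        }
      }
      last_exc[i] = t_new;
    }

    excited.swap(fired);
    t = t_new;
    n_excited[s] = (int) excited.size();
    ++steps_done;

    if (snap_idx < snap_req.size() && snap_req[snap_idx] == t) {
      IntegerMatrix snap(L, L);
      for (int i = 0; i < n; ++i) snap[i] = cnt[i];
      snapshots.push_back(snap);
      snap_names.push_back(std::to_string(t));
      while (snap_idx < snap_req.size() && snap_req[snap_idx] <= t) ++snap_idx;
    }

    if (stop_at_reentry && reentry_t >= 0) break;
  }

  IntegerMatrix out_cnt(L, L), out_last(L, L);
  for (int i = 0; i < n; ++i) {
    out_cnt[i] = cnt[i];
    out_last[i] = last_exc[i];
  }
  if (snapshots.size() > 0) snapshots.attr("names") = snap_names;

  IntegerVector first_reentry, last_reentry;
  if (reentry_t >= 0) {
    first_reentry = IntegerVector::create(
      Named("t") = reentry_t, Named("x") = reentry_x, Named("y") = reentry_y);
    last_reentry = IntegerVector::create(
      Named("t") = last_re_t, Named("x") = last_re_x, Named("y") = last_re_y);
  }

  return List::create(
    Named("n_excited") = n_excited[Range(0, std::max(steps_done - 1, 0))],
    Named("steps_done") = steps_done,
    Named("counters") = out_cnt,
    Named("t") = t,
    Named("first_reentry") = first_reentry,
    Named("last_reentry") = last_reentry,
    Named("n_reentry_events") = n_reentry,
    Named("snapshots") = snapshots,
    Named("act_t") = IntegerVector(act_t.begin(), act_t.end()),
    Named("act_x") = IntegerVector(act_x.begin(), act_x.end()),
    Named("act_y") = IntegerVector(act_y.begin(), act_y.end()),
    Named("beats") = IntegerVector(beats.begin(), beats.end()),
    Named("last_excite") = out_last);
}
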