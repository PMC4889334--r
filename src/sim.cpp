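#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Event-driven simulation of ribosome traffic on one mRNA.
//
// Stochastic waits are exponential (per-codon clocks; Gillespie selection),
// so the process is an exact TASEP-like simulation with steric exclusion.
// Pause/damage sites add an exponential dwell stage on arrival.  Frame
// boundaries, drug additions and forced initiations are deterministic
// events interleaved with the stochastic ones.  Uses R's RNG throughout,
// so set.seed() on the R side makes runs reproducible.

namespace {

struct Rib {
  int id;
  int pos;        // 1-based codon index
  bool paused;    // waiting out a site dwell before the next step
  double exit_rate;       // pause-exit rate while paused (stochastic mode)
  double next_step_time;  // deterministic mode only
};

// drug codes: 0 none, 1 initiation block (harringtonine / hippuristanol),
//             2 puromycin, 3 cycloheximide
enum { DRUG_NONE = 0, DRUG_INIT_BLOCK = 1, DRUG_PURO = 2, DRUG_CHX = 3 };

// event codes for the optional log
enum { EV_INIT = 1, EV_STEP = 2, EV_PAUSE_ENTER = 3, EV_PAUSE_EXIT = 4,
       EV_TERMINATE = 5, EV_PURO_RELEASE = 6 };

}  // namespace

// [[Rcpp::export]]
List sim_translation_cpp(int L,
                         double k_init,
                         double k_elong,
                         int footprint,
                         double k_shutdown,   // per second, on -> off
                         double k_reinit,     // per second, off -> on
                         bool reinit_requires_empty,
                         IntegerVector pause_pos,
                         NumericVector pause_short,
                         NumericVector pause_long,
                         NumericVector pause_frac,
                         IntegerVector dmg_pos,
                         NumericVector dmg_dwell,
                         double duration,
                         double frame_interval,
                         int drug_code,
                         double drug_eff_time,  // add_time + entry_delay
                         NumericVector inject_times,
                         bool deterministic,
                         bool log_events) {
  if (L < 1) stop("orf length must be >= 1");
  if (duration <= 0) stop("duration must be positive");
  if (frame_interval <= 0) stop("frame interval must be positive");
  if (footprint < 1) stop("footprint must be >= 1");
  if (k_init < 0 || k_elong <= 0) stop("rates must be nonnegative (k_elong > 0)");

  // site lookup tables: position -> index into pause/damage vectors, -1 none
  std::vector<int> pause_at(L + 2, -1), dmg_at(L + 2, -1);
  for (int i = 0; i < pause_pos.size(); ++i) {
    if (pause_pos[i] < 1 || pause_pos[i] > L) stop("pause site beyond ORF");
    pause_at[pause_pos[i]] = i;
  }
  for (int i = 0; i < dmg_pos.size(); ++i) {
    if (dmg_pos[i] < 1 || dmg_pos[i] > L) stop("damage site beyond ORF");
    dmg_at[dmg_pos[i]] = i;
  }

  std::vector<Rib> ribs;  // sorted ascending by pos (front of queue = back())
  int next_id = 0;
  bool on_state = true;
  bool init_blocked = false, frozen = false;
  // an initiation attempt that found the start region occupied waits there
  // and enters as soon as the region clears (at most one pending complex),
  // so the initiation flux is insensitive to the footprint at the ribosome
  // spacings of interest
  bool pending_init = false;
  bool drug_applied = (drug_code == DRUG_NONE);

  // outputs
  std::vector<int> fr_frame, fr_id, fr_pos;
  std::vector<double> sw_time; std::vector<int> sw_state;
  std::vector<double> ev_time; std::vector<int> ev_id, ev_code;
  std::vector<double> rb_init, rb_term; std::vector<int> rb_id;
  std::vector<int> rb_released;

  int n_frames = (int)std::floor(duration / frame_interval + 1e-9) + 1;
  int frame_idx = 0;  // next frame to record
  int inj_idx = 0;
  double t = 0.0;

  auto record_frame = [&](int f) {
    for (size_t i = 0; i < ribs.size(); ++i) {
      fr_frame.push_back(f);
      fr_id.push_back(ribs[i].id);
      fr_pos.push_back(ribs[i].pos);
    }
  };
  auto log_ev = [&](double tt, int id, int code) {
    if (log_events) { ev_time.push_back(tt); ev_id.push_back(id); ev_code.push_back(code); }
  };
  auto enter_site = [&](Rib &r, double tt) {
    // arriving at a pause/damage site inserts an extra dwell stage
    int pi = pause_at[r.pos], di = dmg_at[r.pos];
    double mean_dwell = -1.0;
    if (pi >= 0) {
      if (deterministic) {
        mean_dwell = pause_frac[pi] * pause_long[pi] + (1.0 - pause_frac[pi]) * pause_short[pi];
      } else {
        mean_dwell = (R::unif_rand() < pause_frac[pi]) ? pause_long[pi] : pause_short[pi];
      }
    } else if (di >= 0) {
      mean_dwell = dmg_dwell[di];
    }
    if (mean_dwell > 0) {
      r.paused = true;
      r.exit_rate = 1.0 / mean_dwell;
      if (deterministic) r.next_step_time = tt + mean_dwell + 1.0 / k_elong;
      log_ev(tt, r.id, EV_PAUSE_ENTER);
    }
  };
  auto new_rib = [&](double tt) {
    Rib r; r.id = next_id++; r.pos = 1; r.paused = false; r.exit_rate = 0.0;
    r.next_step_time = tt + 1.0 / k_elong;
    ribs.insert(ribs.begin(), r);
    rb_id.push_back(r.id); rb_init.push_back(tt);
    rb_term.push_back(NA_REAL); rb_released.push_back(0);
    log_ev(tt, r.id, EV_INIT);
    enter_site(ribs.front(), tt);
  };
  auto can_initiate = [&]() {
    return ribs.empty() || ribs.front().pos > footprint;
  };
  auto can_step = [&](size_t i) {
    if (ribs[i].paused) return false;
    if (i + 1 == ribs.size()) return true;  // frontmost (includes step off L)
    return ribs[i + 1].pos - ribs[i].pos > footprint;
  };
  auto do_step = [&](size_t i, double tt) {
    if (ribs[i].pos >= L) {  // termination
      rb_term[ribs[i].id] = tt;
      log_ev(tt, ribs[i].id, EV_TERMINATE);
      ribs.erase(ribs.begin() + i);
      return;
    }
    ribs[i].pos += 1;
    ribs[i].next_step_time = tt + 1.0 / k_elong;
    log_ev(tt, ribs[i].id, EV_STEP);
    enter_site(ribs[i], tt);
  };
  auto apply_drug = [&](double tt) {
    drug_applied = true;
    if (drug_code != DRUG_NONE) pending_init = false;
    switch (drug_code) {
      case DRUG_INIT_BLOCK: init_blocked = true; break;
      case DRUG_PURO:
        init_blocked = true;
        for (size_t i = 0; i < ribs.size(); ++i) {
          rb_released[ribs[i].id] = 1;
          log_ev(tt, ribs[i].id, EV_PURO_RELEASE);
        }
        ribs.clear();
        break;
      case DRUG_CHX: frozen = true; break;
      default: break;
    }
  };

  record_frame(frame_idx);  // frame 0 at t = 0 (empty unless injected below)
  frame_idx = 1;

  while (t < duration) {
    // next deterministic boundary: drug, injection, frame, or end of run
    double t_det = duration + 1e-9;
    int det_kind = 0;  // 1 drug, 2 inject, 3 frame, 0 end
    if (frame_idx < n_frames) { t_det = frame_idx * frame_interval; det_kind = 3; }
    if (inj_idx < inject_times.size() && inject_times[inj_idx] <= t_det) {
      t_det = inject_times[inj_idx]; det_kind = 2;
    }
    if (!drug_applied && drug_eff_time <= t_det) { t_det = drug_eff_time; det_kind = 1; }

    double t_next;
    if (deterministic) {
      // fixed per-codon step times; stochastic rates ignored (k_init must be 0)
      t_next = R_PosInf;
      size_t which = 0;
      for (size_t i = 0; i < ribs.size(); ++i) {
        if (frozen) break;
        double ts = ribs[i].next_step_time;
        if (i + 1 < ribs.size() && ribs[i + 1].pos - ribs[i].pos <= footprint)
          ts = ribs[i + 1].next_step_time + 1e-9;  // blocked: wait for the front
        if (ts < t_next) { t_next = ts; which = i; }
      }
      if (t_next >= t_det) {
        t = t_det;
        if (det_kind == 1) apply_drug(t);
        else if (det_kind == 2) { if (!init_blocked && !frozen) new_rib(t); ++inj_idx; }
        else if (det_kind == 3) { record_frame(frame_idx); ++frame_idx; }
        else break;
        continue;
      }
      t = t_next;
      ribs[which].paused = false;
      do_step(which, t);
      continue;
    }

    // total stochastic rate
    double r_init = (!frozen && !init_blocked && on_state && k_init > 0 && !pending_init)
                        ? k_init : 0.0;
    double r_ribs = 0.0;
    if (!frozen) {
      for (size_t i = 0; i < ribs.size(); ++i) {
        if (ribs[i].paused) r_ribs += ribs[i].exit_rate;
        else if (can_step(i)) r_ribs += k_elong;
      }
    }
    double r_switch = on_state ? k_shutdown
                               : ((reinit_requires_empty && !ribs.empty()) ? 0.0 : k_reinit);
    double total = r_init + r_ribs + r_switch;

    t_next = (total > 0) ? t + R::exp_rand() / total : R_PosInf;
    if (t_next >= t_det) {
      t = t_det;
      if (det_kind == 1) apply_drug(t);
      else if (det_kind == 2) { if (!init_blocked && !frozen) new_rib(t); ++inj_idx; }
      else if (det_kind == 3) { record_frame(frame_idx); ++frame_idx; }
      else break;
      continue;
    }
    t = t_next;

    double u = R::unif_rand() * total;
    if (u < r_init) {
      if (can_initiate()) new_rib(t); else pending_init = true;
      continue;
    }
    u -= r_init;
    bool done = false;
    if (!frozen) {
      for (size_t i = 0; i < ribs.size(); ++i) {
        double ri = ribs[i].paused ? ribs[i].exit_rate : (can_step(i) ? k_elong : 0.0);
        if (u < ri) {
          if (ribs[i].paused) { ribs[i].paused = false; log_ev(t, ribs[i].id, EV_PAUSE_EXIT); }
          else do_step(i, t);
          done = true; break;
        }
        u -= ri;
      }
    }
    if (done) {
      if (pending_init && !frozen && !init_blocked && on_state && can_initiate()) {
        new_rib(t); pending_init = false;
      }
      continue;
    }
    // state switch
    on_state = !on_state;
    if (!on_state) pending_init = false;
    sw_time.push_back(t); sw_state.push_back(on_state ? 1 : 0);
  }
  // record any remaining frames (e.g. total rate hit zero before the end)
  while (frame_idx < n_frames) { record_frame(frame_idx); ++frame_idx; }

  List out = List::create(
      _["frame"] = wrap(fr_frame), _["ribosome"] = wrap(fr_id), _["position"] = wrap(fr_pos),
      _["switch_time"] = wrap(sw_time), _["switch_state"] = wrap(sw_state),
      _["rib_id"] = wrap(rb_id), _["init_time"] = wrap(rb_init),
      _["term_time"] = wrap(rb_term), _["released"] = wrap(rb_released),
      _["n_frames"] = n_frames);
  if (log_events) {
    out["ev_time"] = wrap(ev_time);
    out["ev_id"] = wrap(ev_id);
    out["ev_code"] = wrap(ev_code);
  }
  return out;
}
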