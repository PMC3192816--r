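// Continuous-time kinetic Monte Carlo engine for the multi-lattice exclusion
// process with extended ribosomes and finite, dynamically recharged aa-tRNA
// pools shared across all lattices.
//
// Conventions (kept identical to the pure-R reference engine in R/simulator.R):
//  * codon positions are 1-based; the "reader" is the rightmost covered codon;
//  * an entering ribosome places its reader at codon 1 (body overhangs left),
//    so initiation is blocked iff some reader sits at a position <= w;
//  * a reader at j < L advances to j+1 with rate kappa * a_{s(j)} provided the
//    next-ahead reader is at >= j+1+w and a charged tRNA of species s(j) exists;
//  * a reader at L leaves with rate beta; by default this consumes one charged
//    tRNA of species s(L) (the hop "out of" codon L);
//  * each tRNA species has one aggregated recharge channel with rate
//    V_i * b_i / (K_i + b_i);
//  * in fixed-rate mode (infinite recharging) a_i is pinned at T_i and the
//    recharge channels are absent.
//
// Sampling is exactly proportional to the instantaneous rates: the enabled
// event list is rebuilt from the state at every step (no stale caches), and
// the waiting time is exponential with the total rate.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <map>
#include <sstream>

using namespace Rcpp;

namespace {

struct Slot {
  // type: 0 = initiation, 1 = elongation, 2 = termination, 3 = recharge
  int type;
  int lattice;   // for types 0-2
  int rib;       // ribosome index within lattice (types 1-2)
  int species;   // tRNA species consumed / recharged (types 1-3), -1 if none
};

std::string state_key(const std::vector<std::vector<int> >& pos,
                      const std::vector<int>& a, bool fixed) {
  std::ostringstream os;
  for (size_t l = 0; l < pos.size(); ++l) {
    os << 'L';
    for (size_t i = 0; i < pos[l].size(); ++i) os << pos[l][i] << ',';
  }
  if (!fixed) {
    os << '|';
    for (size_t i = 0; i < a.size(); ++i) os << a[i] << ',';
  }
  return os.str();
}

} // namespace

// [[Rcpp::export]]
List sim_run_cpp(List mrna_codons,        // list over mRNA species: IntegerVector of 1-based tRNA ids
                 IntegerVector mrna_copies,
                 NumericVector mrna_alpha,
                 NumericVector mrna_beta,
                 IntegerVector T_counts,  // per tRNA species totals
                 NumericVector Vmax,
                 NumericVector Km,
                 double kappa,
                 int w,
                 double burn_in,
                 double measure,
                 int n_blocks,
                 bool fixed_rates,
                 bool charge_on_termination,
                 bool track_states,
                 double max_events) {
  const int R = mrna_codons.size();
  const int S = T_counts.size();

  std::vector<std::vector<int> > codons(R);
  for (int r = 0; r < R; ++r) {
    IntegerVector cv = mrna_codons[r];
    codons[r].assign(cv.begin(), cv.end());
    for (size_t j = 0; j < codons[r].size(); ++j) codons[r][j] -= 1; // 0-based species
  }

  // expand copies into lattices
  std::vector<int> lat_species;   // mRNA species index per lattice
  for (int r = 0; r < R; ++r)
    for (int c = 0; c < mrna_copies[r]; ++c) lat_species.push_back(r);
  const int n_lat = (int)lat_species.size();

  std::vector<std::vector<int> > pos(n_lat); // ascending reader positions, back() = leader
  std::vector<int> a(S), b(S, 0);
  for (int i = 0; i < S; ++i) a[i] = T_counts[i];

  const double t_end = burn_in + measure;
  const double block_len = measure / n_blocks;

  // accumulators (measurement window only)
  std::vector<std::vector<double> > occ(R);       // reader dwell time per site
  std::vector<std::vector<double> > hop_cnt(R);   // hops out of each site (incl. termination at L)
  for (int r = 0; r < R; ++r) {
    occ[r].assign(codons[r].size(), 0.0);
    hop_cnt[r].assign(codons[r].size(), 0.0);
  }
  NumericMatrix term_blocks(R, n_blocks);
  NumericMatrix a_int_blocks(S, n_blocks);        // integral of a_i dt per block
  NumericMatrix rib_blocks(R, n_blocks);          // integral of (#ribosomes on species r) dt
  std::map<std::string, double> state_time;

  std::vector<double> rate;
  std::vector<Slot> slot;
  rate.reserve(1024);
  slot.reserve(1024);

  RNGScope scope;
  double t = 0.0;
  double n_events = 0.0;
  bool max_events_hit = false;

  // distribute a weight ww starting at time tt (within measurement window)
  // across measurement blocks
  auto add_blocks = [&](NumericMatrix& M, int row, double tt, double ww, double scale) {
    double s = tt - burn_in;
    double remaining = ww;
    while (remaining > 1e-15) {
      int blk = (int)(s / block_len);
      if (blk >= n_blocks) blk = n_blocks - 1;
      double blk_end = (blk + 1) * block_len;
      double take = std::min(remaining, blk_end - s);
      if (take <= 0) take = remaining; // numerical guard at the upper edge
      M(row, blk) += take * scale;
      s += take;
      remaining -= take;
    }
  };

  while (t < t_end) {
    // ---- build enabled-event catalogue from scratch ----
    rate.clear();
    slot.clear();
    double total = 0.0;
    for (int l = 0; l < n_lat; ++l) {
      const int r = lat_species[l];
      const std::vector<int>& cd = codons[r];
      const int L = (int)cd.size();
      const std::vector<int>& p = pos[l];
      const int n = (int)p.size();
      // initiation
      if (n == 0 || p[0] > w) {
        rate.push_back(mrna_alpha[r]);
        slot.push_back({0, l, -1, -1});
        total += mrna_alpha[r];
      }
      // elongation / termination
      for (int i = 0; i < n; ++i) {
        const int pj = p[i];
        const int sp = cd[pj - 1];
        double rt = 0.0;
        int type;
        if (pj == L) {
          type = 2;
          bool ok = fixed_rates || !charge_on_termination || a[sp] > 0;
          rt = ok ? mrna_beta[r] : 0.0;
        } else {
          type = 1;
          bool free_ahead = (i == n - 1) || (p[i + 1] >= pj + 1 + w);
          int avail = fixed_rates ? T_counts[sp] : a[sp];
          rt = (free_ahead && avail > 0) ? kappa * avail : 0.0;
        }
        if (rt > 0) {
          rate.push_back(rt);
          slot.push_back({type, l, i, sp});
          total += rt;
        }
      }
    }
    if (!fixed_rates) {
      for (int i = 0; i < S; ++i) {
        if (b[i] > 0) {
          double rt = Vmax[i] * b[i] / (Km[i] + b[i]);
          if (rt > 0) {
            rate.push_back(rt);
            slot.push_back({3, -1, -1, i});
            total += rt;
          }
        }
      }
    }

    double dt;
    bool absorbing = (total <= 0.0);
    if (absorbing) {
      dt = t_end - t; // frozen state: coast to the end of the schedule
    } else {
      dt = exp_rand() / total;
    }
    double t_next = t + dt;

    // ---- time-weighted accumulation over [t, t+dt] ∩ [burn_in, t_end] ----
    double seg_lo = std::max(t, burn_in);
    double seg_hi = std::min(t_next, t_end);
    if (seg_hi > seg_lo) {
      double ww = seg_hi - seg_lo;
      for (int l = 0; l < n_lat; ++l) {
        const int r = lat_species[l];
        const int cnt = (int)pos[l].size();
        for (int i = 0; i < cnt; ++i) occ[r][pos[l][i] - 1] += ww;
        if (cnt > 0) add_blocks(rib_blocks, r, seg_lo, ww, (double)cnt);
      }
      for (int i = 0; i < S; ++i) {
        double ai = fixed_rates ? (double)T_counts[i] : (double)a[i];
        if (ai > 0) add_blocks(a_int_blocks, i, seg_lo, ww, ai);
      }
      if (track_states) state_time[state_key(pos, a, fixed_rates)] += ww;
    }

    if (absorbing || t_next >= t_end) { t = t_end; break; }

    // ---- select one event proportional to rate ----
    double u = unif_rand() * total;
    size_t k = 0;
    for (; k + 1 < rate.size(); ++k) {
      if (u < rate[k]) break;
      u -= rate[k];
    }
    const Slot ev = slot[k];
    const bool in_window = (t_next >= burn_in && t_next <= t_end);

    switch (ev.type) {
      case 0: { // initiation
        pos[ev.lattice].insert(pos[ev.lattice].begin(), 1);
        break;
      }
      case 1: { // elongation out of codon p
        int r = lat_species[ev.lattice];
        int pj = pos[ev.lattice][ev.rib];
        pos[ev.lattice][ev.rib] = pj + 1;
        if (!fixed_rates) { a[ev.species] -= 1; b[ev.species] += 1; }
        if (in_window) hop_cnt[r][pj - 1] += 1.0;
        break;
      }
      case 2: { // termination
        int r = lat_species[ev.lattice];
        int L = (int)codons[r].size();
        pos[ev.lattice].pop_back();
        if (!fixed_rates && charge_on_termination) { a[ev.species] -= 1; b[ev.species] += 1; }
        if (in_window) {
          hop_cnt[r][L - 1] += 1.0;
          double s = t_next - burn_in;
          int blk = (int)(s / block_len);
          if (blk >= n_blocks) blk = n_blocks - 1;
          term_blocks(r, blk) += 1.0;
        }
        break;
      }
      case 3: { // recharge
        b[ev.species] -= 1;
        a[ev.species] += 1;
        break;
      }
    }

    // conservation assertion: no event may drive a pool negative
    if (!fixed_rates && ev.species >= 0 &&
        (a[ev.species] < 0 || b[ev.species] < 0))
      stop("internal error: negative tRNA count");

    t = t_next;
    n_events += 1.0;
    if (n_events >= max_events) { max_events_hit = true; break; }
  }

  // final state snapshot
  List final_pos(n_lat);
  for (int l = 0; l < n_lat; ++l) final_pos[l] = wrap(pos[l]);

  List occ_out(R), hop_out(R);
  for (int r = 0; r < R; ++r) {
    occ_out[r] = wrap(occ[r]);
    hop_out[r] = wrap(hop_cnt[r]);
  }

  List st = R_NilValue;
  if (track_states) {
    std::vector<std::string> keys;
    std::vector<double> times;
    for (std::map<std::string, double>::iterator it = state_time.begin();
         it != state_time.end(); ++it) {
      keys.push_back(it->first);
      times.push_back(it->second);
    }
    NumericVector tv = wrap(times);
    tv.names() = wrap(keys);
    st = List::create(Named("time") = tv);
  }

  return List::create(
    Named("occupancy") = occ_out,
    Named("hops") = hop_out,
    Named("term_blocks") = term_blocks,
    Named("a_int_blocks") = a_int_blocks,
    Named("rib_blocks") = rib_blocks,
    Named("measure") = measure,
    Named("n_blocks") = n_blocks,
    Named("n_events") = n_events,
    Named("max_events_hit") = max_events_hit,
    Named("final_a") = wrap(a),
    Named("final_b") = wrap(b),
    Named("final_pos") = final_pos,
    Named("state_time") = st);
}
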