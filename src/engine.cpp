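#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// One contiguous block of simulation steps.
//
// All populations update synchronously from pre-step values: at step t the
// new excitatory state reads s_e(t-1) and s_in(t-1), the new inhibitory
// state reads s_e(t-1), and the output potentials read s_e(t-1). A neuron
// fires when its summed input reaches its threshold (step function value 1
// at exactly 0). Binary states let every matrix-vector product reduce to a
// sum over the columns of currently active presynaptic neurons.
//
// reward_mode: 0 = none (inference), 1 = next-element prediction,
//              2 = autonomous generation (longest-run reward).
// In feedback mode the read-out symbol of the previous step is re-encoded
// as the next external drive; inputs[0] seeds the very first step when no
// previous prediction is carried in.
//
// Structural plasticity draws the number of new synapses from the binomial
// law over currently unconnected off-diagonal pairs and places them by
// rejection sampling; growth candidates are the pairs unconnected before
// the call, so a synapse pruned in the same step cannot regrow immediately.
//
// Only the R random number generator is used (RNGScope), so runs are
// reproducible from set.seed().
// [[Rcpp::export]]
List engine_run(NumericMatrix w_ee_in, NumericMatrix c_ee_in,
                NumericMatrix w_ei, NumericMatrix w_ie,
                NumericMatrix w_oe_in,
                NumericVector theta_e_in, NumericVector theta_in,
                NumericVector theta_o_in,
                NumericVector s_e_in, NumericVector s_in_in,
                NumericVector s_o_in,
                NumericMatrix e_ee_in, NumericMatrix e_oe_in,
                double baseline, int t0,
                IntegerMatrix subsets,
                IntegerVector inputs,
                bool feedback,
                int steps,
                int reward_mode,
                List toggles,
                List par,
                NumericVector mu_o,
                int prev_pred) {
  RNGScope rngscope;

  NumericMatrix w_ee = clone(w_ee_in);
  NumericMatrix c_ee = clone(c_ee_in);
  NumericMatrix w_oe = clone(w_oe_in);
  NumericVector theta_e = clone(theta_e_in);
  NumericVector theta_o = clone(theta_o_in);
  NumericVector s_e = clone(s_e_in);
  NumericVector s_in = clone(s_in_in);
  NumericVector s_o = clone(s_o_in);
  NumericMatrix e_ee = clone(e_ee_in);
  NumericMatrix e_oe = clone(e_oe_in);

  const int ne = w_ee.nrow();
  const int ni = w_ie.nrow();
  const int no = w_oe.nrow();
  const int nsub = subsets.ncol();

  const bool tg_rstdp_ee = toggles["rstdp_ee"];
  const bool tg_rstdp_oe = toggles["rstdp_oe"];
  const bool tg_sn = toggles["sn"];
  const bool tg_ip_e = toggles["ip_e"];
  const bool tg_ip_o = toggles["ip_o"];
  const bool tg_sp = toggles["sp"];
  const bool learning = reward_mode != 0 &&
    (tg_rstdp_ee || tg_rstdp_oe || tg_sn || tg_ip_e || tg_ip_o || tg_sp);

  const double eta = par["eta"];
  const double eta_oe = par["eta_oe"];
  const double eta_ip = par["eta_ip"];
  const double tau_e = par["tau_e"];
  const double f_ee = par["f_ee"];
  const double f_oe = par["f_oe"];
  const double p_sp = par["p_sp"];
  const double w_th = par["w_th"];
  const double w_new = par["w_new"];
  const double r_incorrect = par["reward_incorrect"];
  const double alpha = par["baseline_alpha"];
  const double mu_ip = par["mu_ip"];
  const double decay = 1.0 - 1.0 / tau_e;

  // Column-compressed view of the E-E connectivity: for each presynaptic
  // neuron j, the sorted postsynaptic rows i with an existing connection.
  // All stage-one passes (trace update, reward update, normalization,
  // pruning) walk these lists, so their cost scales with the number of
  // synapses rather than with N^2. Kept in sync incrementally by the
  // structural-plasticity updates.
  std::vector<std::vector<int> > cols(ne);
  long nnz = 0;
  for (int j = 0; j < ne; ++j)
    for (int i = 0; i < ne; ++i)
      if (c_ee(i, j) == 1.0) { cols[j].push_back(i); ++nnz; }

  std::vector<int> act_e, act_in;
  act_e.reserve(ne); act_in.reserve(ni);
  for (int i = 0; i < ne; ++i) if (s_e[i] == 1.0) act_e.push_back(i);
  for (int i = 0; i < ni; ++i) if (s_in[i] == 1.0) act_in.push_back(i);

  std::vector<double> psi_e(ne), psi_in(ni), psi_o(no);
  std::vector<double> se_new(ne), sin_new(ni), so_new(no);
  std::vector<double> se_prev(ne), so_prev(no);

  IntegerVector predictions(steps);
  NumericVector rewards(steps);
  std::vector<int> ev_t, ev_i, ev_j;
  std::vector<std::string> ev_kind;
  std::vector<double> ev_w;

  // generation-reward window: last `no` read-out symbols (cycle = 1..no)
  std::vector<int> win(no, -1);
  int last_pred = prev_pred;  // 1-based, 0 = none yet

  for (int k = 0; k < steps; ++k) {
    // --- input symbol for this step ---
    int in_sym;
    if (feedback) {
      in_sym = (last_pred > 0) ? last_pred
                               : (inputs.size() > 0 ? inputs[0] : 0);
      if (k == 0 && prev_pred == 0 && inputs.size() > 0) in_sym = inputs[0];
    } else {
      in_sym = inputs[k];
    }

    // --- output potentials and prediction (from s_e(t-1)) ---
    for (int q = 0; q < no; ++q) psi_o[q] = -theta_o[q];
    for (size_t a = 0; a < act_e.size(); ++a) {
      const int j = act_e[a];
      for (int q = 0; q < no; ++q) psi_o[q] += w_oe(q, j);
    }
    int pred = 0;
    double best = psi_o[0];
    for (int q = 1; q < no; ++q)
      if (psi_o[q] > best) { best = psi_o[q]; pred = q; }
    pred += 1;  // 1-based symbol index
    // The output layer competes winner-take-all: the neuron with the
    // largest potential is the one that spikes and emits its symbol.
    // One-hot output activity gives the reward-gated update per-neuron
    // credit (only the winning row is potentiated or depressed), and the
    // per-neuron homeostatic rate targets then control how often each
    // output *wins*, which forces exploration for outputs that never win.
    for (int q = 0; q < no; ++q) so_new[q] = (q == pred - 1) ? 1.0 : 0.0;

    // --- inhibitory update (from s_e(t-1)) ---
    for (int i = 0; i < ni; ++i) psi_in[i] = -theta_in[i];
    for (size_t a = 0; a < act_e.size(); ++a) {
      const int j = act_e[a];
      for (int i = 0; i < ni; ++i) psi_in[i] += w_ie(i, j);
    }
    for (int i = 0; i < ni; ++i) sin_new[i] = (psi_in[i] >= 0.0) ? 1.0 : 0.0;
    act_in.clear();
    for (int i = 0; i < ni; ++i) if (sin_new[i] == 1.0) act_in.push_back(i);

    // --- excitatory update ---
    // Recurrent drive comes from s_e(t-1); the inhibitory term is the
    // inhibitory layer's response to that same state (fast feedforward
    // inhibition), which keeps excitation and inhibition balanced within
    // each step instead of lagging by one.
    for (int i = 0; i < ne; ++i) psi_e[i] = -theta_e[i];
    for (size_t a = 0; a < act_e.size(); ++a) {
      const int j = act_e[a];
      const std::vector<int>& cj = cols[j];
      for (size_t q = 0; q < cj.size(); ++q) psi_e[cj[q]] += w_ee(cj[q], j);
    }
    for (size_t a = 0; a < act_in.size(); ++a) {
      const int j = act_in[a];
      for (int i = 0; i < ne; ++i) psi_e[i] -= w_ei(i, j);
    }
    if (in_sym > 0)
      for (int c = 0; c < nsub; ++c)
        psi_e[subsets(in_sym - 1, c) - 1] += 1.0;
    for (int i = 0; i < ne; ++i) se_new[i] = (psi_e[i] >= 0.0) ? 1.0 : 0.0;

    predictions[k] = pred;

    // --- reward ---
    double r = NA_REAL;
    if (reward_mode == 1) {
      r = (in_sym > 0 && pred == in_sym) ? 1.0 : r_incorrect;
    } else if (reward_mode == 2) {
      for (int q = 0; q + 1 < no; ++q) win[q] = win[q + 1];
      win[no - 1] = pred;
      int last = win[no - 1];
      if (last < 1) {
        r = 0.0;
      } else {
        int run = 1;
        while (run < no) {
          int cur = win[no - run];
          int prev = win[no - run - 1];
          int expected_prev = (cur == 1) ? no : cur - 1;
          if (prev != expected_prev) break;
          ++run;
        }
        r = (double) run / no;
      }
    }
    rewards[k] = r;

    if (learning) {
      for (int i = 0; i < ne; ++i) se_prev[i] = s_e[i];
      for (int q = 0; q < no; ++q) so_prev[q] = s_o[q];

      // eligibility traces: decay plus the causal/anti-causal coincidences
      if (tg_rstdp_ee) {
        for (int j = 0; j < ne; ++j) {
          const double sp_j = se_prev[j], sn_j = se_new[j];
          const std::vector<int>& cj = cols[j];
          for (size_t a = 0; a < cj.size(); ++a) {
            const int i = cj[a];
            e_ee(i, j) = e_ee(i, j) * decay +
              se_new[i] * sp_j - f_ee * se_prev[i] * sn_j;
          }
        }
      }
      if (tg_rstdp_oe) {
        for (int j = 0; j < ne; ++j) {
          const double sp_j = se_prev[j], sn_j = se_new[j];
          for (int q = 0; q < no; ++q)
            e_oe(q, j) = e_oe(q, j) * decay +
              so_new[q] * sp_j - f_oe * so_prev[q] * sn_j;
        }
      }

      const double m = r - baseline;
      baseline = (1.0 - alpha) * baseline + alpha * r;

      // reward-gated weight update, floored at zero
      if (tg_rstdp_ee && m != 0.0) {
        for (int j = 0; j < ne; ++j) {
          const std::vector<int>& cj = cols[j];
          for (size_t a = 0; a < cj.size(); ++a) {
            const int i = cj[a];
            double v = w_ee(i, j) + eta * m * e_ee(i, j);
            w_ee(i, j) = (v > 0.0) ? v : 0.0;
          }
        }
      }
      if (tg_rstdp_oe && m != 0.0) {
        for (int j = 0; j < ne; ++j)
          for (int q = 0; q < no; ++q) {
            double v = w_oe(q, j) + eta_oe * m * e_oe(q, j);
            w_oe(q, j) = (v > 0.0) ? v : 0.0;
          }
      }

      // synaptic normalization of the plastic matrices
      if (tg_sn && tg_rstdp_ee) {
        // row sums accumulated in column-major order over existing
        // connections (adding structural zeros would not change them)
        std::vector<double> rs(ne, 0.0);
        for (int j = 0; j < ne; ++j) {
          const std::vector<int>& cj = cols[j];
          for (size_t a = 0; a < cj.size(); ++a) rs[cj[a]] += w_ee(cj[a], j);
        }
        for (int j = 0; j < ne; ++j) {
          const std::vector<int>& cj = cols[j];
          for (size_t a = 0; a < cj.size(); ++a)
            if (rs[cj[a]] > 0.0) w_ee(cj[a], j) /= rs[cj[a]];
        }
      }
      if (tg_sn && tg_rstdp_oe) {
        for (int q = 0; q < no; ++q) {
          double rs = 0.0;
          for (int j = 0; j < ne; ++j) rs += w_oe(q, j);
          if (rs > 0.0)
            for (int j = 0; j < ne; ++j) w_oe(q, j) /= rs;
        }
      }

      // intrinsic plasticity
      if (tg_ip_e)
        for (int i = 0; i < ne; ++i)
          theta_e[i] += eta_ip * (se_new[i] - mu_ip);
      if (tg_ip_o)
        for (int q = 0; q < no; ++q)
          theta_o[q] += eta_ip * (so_new[q] - mu_o[q]);

      // structural plasticity on the E-E synapses
      if (tg_sp) {
        const int t_now = t0 + k + 1;
        // growth count over pairs unconnected before this call's prune
        long n_zero = (long) ne * (ne - 1) - nnz;
        int nb = (n_zero > 0) ? (int) R::rbinom((double) n_zero, p_sp) : 0;
        std::vector<std::pair<int,int> > births;
        births.reserve(nb);
        int guard = 0;
        while ((int) births.size() < nb && guard < 100000) {
          int i = (int) (unif_rand() * ne); if (i >= ne) i = ne - 1;
          int j = (int) (unif_rand() * ne); if (j >= ne) j = ne - 1;
          ++guard;
          if (i == j || c_ee(i, j) != 0.0) continue;
          c_ee(i, j) = 2.0;  // temporary marker: selected for growth
          births.push_back(std::make_pair(i, j));
        }
        // prune existing connections below threshold
        for (int j = 0; j < ne; ++j) {
          std::vector<int>& cj = cols[j];
          size_t keep = 0;
          for (size_t a = 0; a < cj.size(); ++a) {
            const int i = cj[a];
            if (w_ee(i, j) < w_th) {
              ev_t.push_back(t_now); ev_kind.push_back("death");
              ev_i.push_back(i + 1); ev_j.push_back(j + 1);
              ev_w.push_back(w_ee(i, j));
              c_ee(i, j) = 0.0;
              w_ee(i, j) = 0.0;
              e_ee(i, j) = 0.0;
              --nnz;
            } else {
              cj[keep++] = i;
            }
          }
          cj.resize(keep);
        }
        // realize growth (insert sorted to keep column order canonical)
        for (size_t bq = 0; bq < births.size(); ++bq) {
          int i = births[bq].first, j = births[bq].second;
          c_ee(i, j) = 1.0;
          w_ee(i, j) = w_new;
          e_ee(i, j) = 0.0;
          std::vector<int>& cj = cols[j];
          cj.insert(std::lower_bound(cj.begin(), cj.end(), i), i);
          ++nnz;
          ev_t.push_back(t_now); ev_kind.push_back("birth");
          ev_i.push_back(i + 1); ev_j.push_back(j + 1);
          ev_w.push_back(w_new);
        }
      }
    }

    // --- commit the synchronous state update ---
    act_e.clear(); act_in.clear();
    for (int i = 0; i < ne; ++i) {
      s_e[i] = se_new[i];
      if (se_new[i] == 1.0) act_e.push_back(i);
    }
    for (int i = 0; i < ni; ++i) {
      s_in[i] = sin_new[i];
      if (sin_new[i] == 1.0) act_in.push_back(i);
    }
    for (int q = 0; q < no; ++q) s_o[q] = so_new[q];
    last_pred = pred;
  }

  DataFrame events = DataFrame::create(
    Named("t") = wrap(ev_t),
    Named("kind") = wrap(ev_kind),
    Named("i") = wrap(ev_i),
    Named("j") = wrap(ev_j),
    Named("w") = wrap(ev_w),
    Named("stringsAsFactors") = false);

  return List::create(
    Named("w_ee") = w_ee, Named("c_ee") = c_ee, Named("w_oe") = w_oe,
    Named("theta_e") = theta_e, Named("theta_o") = theta_o,
    Named("s_e") = s_e, Named("s_in") = s_in, Named("s_o") = s_o,
    Named("e_ee") = e_ee, Named("e_oe") = e_oe,
    Named("baseline") = baseline,
    Named("t") = t0 + steps,
    Named("predictions") = predictions,
    Named("rewards") = rewards,
    Named("events") = events,
    Named("last_pred") = last_pred);
}
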