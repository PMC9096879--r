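#include <Rcpp.h>
using namespace Rcpp;

// Whole-schedule simulation of a working-memory actor-critic agent on the
// six-arm track. This mirrors, step for step, the R reference functions
// total_propensity(), action_probabilities(), prediction_error() and
// apply_updates(); tests assert agreement between the two routes.
//
// Conventions: arms are 1..6, REST is 0. States are 0-based here:
// (prev-1)*6 + (cur-1) for arm-arm pairs (0..35), 36 + (cur-1) for
// (REST, cur) (36..41), 42 for the start state (REST, REST). The R API is
// 1-based (1..43).

static const int N_STATES = 43;

static inline int state_idx(int prev, int cur) {
  if (cur == 0) return 42;                 // (REST, REST)
  if (prev == 0) return 36 + (cur - 1);    // (REST, cur)
  return (prev - 1) * 6 + (cur - 1);
}

// probabilities over the 6 arms, zero on cur (when cur > 0)
static inline void softmax_probs(const double *m, int cur, double *p) {
  double mx = R_NegInf;
  for (int a = 0; a < 6; ++a) {
    if (a + 1 == cur) continue;
    if (m[a] > mx) mx = m[a];
  }
  double tot = 0.0;
  for (int a = 0; a < 6; ++a) {
    if (a + 1 == cur) { p[a] = 0.0; continue; }
    p[a] = std::exp(m[a] - mx);
    tot += p[a];
  }
  for (int a = 0; a < 6; ++a) p[a] /= tot;
}

// [[Rcpp::export]]
List sim_agent_cpp(List phases, bool use_arm, bool use_neighbor,
                   double alpha, double gamma, double omega,
                   NumericMatrix b_trans_in, NumericVector b_arm_in,
                   double b_n1, double b_n2, NumericVector V_in,
                   int max_session_visits = 5000) {
  NumericMatrix b_trans = clone(b_trans_in);
  NumericVector b_arm = clone(b_arm_in);
  NumericVector V = clone(V_in);
  if (b_trans.nrow() != 6 || b_trans.ncol() != N_STATES)
    stop("b_trans must be 6 x 43");
  double *BT = REAL(b_trans);    // column-major, 6 x 43
  double *BA = REAL(b_arm);
  double *VV = REAL(V);

  std::vector<int> out_arm, out_rew, out_phase, out_sess, out_cont;
  out_arm.reserve(4096);

  RNGScope scope;

  for (int ph = 0; ph < phases.size(); ++ph) {
    List phase = phases[ph];
    int kind = as<int>(phase["kind"]);          // 0 explore, 1 alternation
    int n_sessions = as<int>(phase["n_sessions"]);
    int limit = as<int>(phase["limit"]);
    int cont_index = as<int>(phase["cont_index"]);
    int center = 0, outer1 = 0, outer2 = 0;
    if (kind == 1) {
      IntegerVector arms = phase["arms"];
      outer1 = arms[0]; center = arms[1]; outer2 = arms[2];
    }
    IntegerVector forced = phase["forced"];       // length 0 => free play
    IntegerVector forced_sess = phase["forced_sess"];
    bool is_forced = forced.size() > 0;
    int fpos = 0;
    if (is_forced) {
      n_sessions = 0;
      for (int i = 0; i < forced_sess.size(); ++i)
        if (forced_sess[i] > n_sessions) n_sessions = forced_sess[i];
    }

    for (int sess = 1; sess <= n_sessions; ++sess) {
      int prev = 0, cur = 0;         // agent state: (REST, REST)
      int last_arm = 0, last_outer = 0, center_visits = 0, n_rewards = 0;
      int visits = 0;

      while (true) {
        int s = state_idx(prev, cur);
        double m[6];
        for (int a = 0; a < 6; ++a) m[a] = BT[6 * s + a];
        if (use_arm) for (int a = 0; a < 6; ++a) m[a] += BA[a];
        if (use_neighbor && cur > 0) {
          for (int d = 1; d <= 2; ++d) {
            double b = (d == 1) ? b_n1 : b_n2;
            if (cur - d >= 1) m[cur - d - 1] += b;
            if (cur + d <= 6) m[cur + d - 1] += b;
          }
        }
        double p[6];
        softmax_probs(m, cur, p);

        int chosen;
        if (is_forced) {
          if (fpos >= forced.size() || forced_sess[fpos] != sess) break;
          chosen = forced[fpos++];
          if (chosen == cur)
            stop("forced trajectory repeats the current arm");
        } else {
          double u = unif_rand(), acc = 0.0;
          chosen = 6;
          for (int a = 0; a < 6; ++a) {
            acc += p[a];
            if (u <= acc) { chosen = a + 1; break; }
          }
        }

        // reward
        int r;
        if (kind == 0) {
          r = (chosen != last_arm) ? 1 : 0;
        } else {
          r = 0;
          if (chosen == center) {
            r = (last_arm != center) ? 1 : 0;
            ++center_visits;
          } else if (chosen == outer1 || chosen == outer2) {
            r = (last_arm == center &&
                 (last_outer == 0 || last_outer != chosen)) ? 1 : 0;
            last_outer = chosen;
          }
        }
        last_arm = chosen;
        n_rewards += r;

        // TD error against the successor state (cur, chosen)
        int s_next = state_idx(cur, chosen);
        double delta = (double)r + gamma * VV[s_next] - VV[s];

        // forgetting decay on every component, then REINFORCE increments
        double decay = 1.0 - omega;
        for (int j = 0; j < 6 * N_STATES; ++j) BT[j] *= decay;
        for (int a = 0; a < 6; ++a) {
          double ind = (a + 1 == chosen) ? 1.0 : 0.0;
          BT[6 * s + a] += alpha * delta * (ind - p[a]);
        }
        if (use_arm) {
          for (int a = 0; a < 6; ++a) {
            double ind = (a + 1 == chosen) ? 1.0 : 0.0;
            BA[a] = BA[a] * decay + alpha * delta * (ind - p[a]);
          }
        }
        if (use_neighbor) {
          for (int d = 1; d <= 2; ++d) {
            double mass = 0.0; bool hit = false;
            if (cur > 0) {
              if (cur - d >= 1) { mass += p[cur - d - 1]; hit = hit || (chosen == cur - d); }
              if (cur + d <= 6) { mass += p[cur + d - 1]; hit = hit || (chosen == cur + d); }
            }
            double inc = alpha * delta * ((hit ? 1.0 : 0.0) - mass);
            if (d == 1) b_n1 = b_n1 * decay + inc; else b_n2 = b_n2 * decay + inc;
          }
        }
        for (int j = 0; j < N_STATES; ++j) VV[j] *= decay;
        VV[s] += alpha * delta;

        out_arm.push_back(chosen);
        out_rew.push_back(r);
        out_phase.push_back(ph + 1);
        out_sess.push_back(sess);
        out_cont.push_back(cont_index);
        ++visits;

        prev = cur; cur = chosen;

        if (!is_forced) {
          if (kind == 0) {
            if (n_rewards >= limit) break;
          } else {
            if ((center_visits >= limit && chosen != center) ||
                center_visits > limit) break;
          }
          if (visits >= max_session_visits) break;  // numerical guard
        }
      }
    }
  }

  return List::create(
    _["arm"] = wrap(out_arm), _["rewarded"] = wrap(out_rew),
    _["phase"] = wrap(out_phase), _["session"] = wrap(out_sess),
    _["cont"] = wrap(out_cont),
    _["b_trans"] = b_trans, _["b_arm"] = b_arm,
    _["b_n1"] = b_n1, _["b_n2"] = b_n2, _["V"] = V);
}
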