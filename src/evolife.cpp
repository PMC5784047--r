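#include <Rcpp.h>
using namespace Rcpp;

// Recurrent forager networks and their grid-world ecosystem.
//
// Genome layout (doubles), H_MAX = 20 hidden units, 36 inputs, 4 effectors:
//   [0,720)    W_in  : gene h*36 + i  = weight input i -> hidden h
//   [720,1120) W_rec : gene 720 + h*20 + j = weight hidden j -> hidden h
//   [1120,1140) b_h
//   [1140,1220) W_out : gene 1140 + o*20 + h = weight hidden h -> effector o
//   [1220,1224) b_out
// Only the first `hidden_size` hidden units are active; the rest of the
// genome is carried silently (and can be re-activated by size mutations).
// All randomness comes from R's RNG (unif_rand/norm_rand), so set.seed()
// in R makes every simulation bit-reproducible.

static const int H_MAX = 20;
static const int N_IN = 36;
static const int N_OUT = 4;
static const int GENOME_LEN = H_MAX * N_IN + H_MAX * H_MAX + H_MAX + N_OUT * H_MAX + N_OUT;

static const int OFF_WIN = 0;
static const int OFF_WREC = H_MAX * N_IN;
static const int OFF_BH = OFF_WREC + H_MAX * H_MAX;
static const int OFF_WOUT = OFF_BH + H_MAX;
static const int OFF_BOUT = OFF_WOUT + N_OUT * H_MAX;

// actions
enum { ACT_LEFT = 0, ACT_RIGHT = 1, ACT_FORWARD = 2, ACT_EAT = 3 };

static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// food quantity n -> n distinct active units among 9 (partial Fisher-Yates)
static void encode_food_into(int n, double* block) {
  int idx[9] = {0, 1, 2, 3, 4, 5, 6, 7, 8};
  for (int k = 0; k < 9; ++k) block[k] = 0.0;
  for (int k = 0; k < n; ++k) {
    int j = k + (int)std::floor(unif_rand() * (9 - k));
    if (j > 8) j = 8;
    std::swap(idx[k], idx[j]);
    block[idx[k]] = 1.0;
  }
}

// [[Rcpp::export]]
IntegerVector cpp_encode_food(int n) {
  if (n < 0 || n > 9) stop("food quantity must be in 0..9");
  double block[9];
  encode_food_into(n, block);
  IntegerVector out(9);
  for (int k = 0; k < 9; ++k) out[k] = (int)block[k];
  return out;
}

// visible cells in fixed order: current, ahead-left, ahead, ahead-right.
// heading: 0 = N (row - 1), 1 = E (col + 1), 2 = S, 3 = W.
// wrap: toroidal; otherwise out-of-grid cells are flagged (row = col = -1).
static void visible_cells(int nr, int nc, int r, int c, int heading, bool wrap,
                          int rows[4], int cols[4]) {
  static const int dr[4] = {-1, 0, 1, 0};
  static const int dc[4] = {0, 1, 0, -1};
  int fr = dr[heading], fc = dc[heading];
  int lh = (heading + 3) % 4, rh = (heading + 1) % 4;
  int offs[4][2] = {
    {0, 0},
    {fr + dr[lh], fc + dc[lh]},
    {fr, fc},
    {fr + dr[rh], fc + dc[rh]}
  };
  for (int k = 0; k < 4; ++k) {
    int rr = r + offs[k][0], cc = c + offs[k][1];
    if (wrap) {
      rr = ((rr % nr) + nr) % nr;
      cc = ((cc % nc) + nc) % nc;
    } else if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) {
      rr = -1; cc = -1;
    }
    rows[k] = rr; cols[k] = cc;
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_visible_cells(int nr, int nc, int r, int c, int heading,
                                bool wrap) {
  int rows[4], cols[4];
  visible_cells(nr, nc, r, c, heading, wrap, rows, cols);
  IntegerMatrix out(4, 2);
  for (int k = 0; k < 4; ++k) { out(k, 0) = rows[k]; out(k, 1) = cols[k]; }
  return out;
}

// sense into a 36-vector (4 blocks of 9); cells outside a walled grid read 0
static void sense_into(const int* grid, int nr, int nc, int r, int c,
                       int heading, bool wrap, double* x) {
  int rows[4], cols[4];
  visible_cells(nr, nc, r, c, heading, wrap, rows, cols);
  for (int k = 0; k < 4; ++k) {
    int n = 0;
    if (rows[k] >= 0) n = grid[cols[k] * nr + rows[k]];
    encode_food_into(n, x + 9 * k);
  }
}

// one recurrent update + action selection; h (length H_MAX) updated in place
static int forward_action(const double* g, int H, const double* x, double* h,
                          double* eff_out) {
  double hnew[H_MAX];
  for (int u = 0; u < H; ++u) {
    double s = g[OFF_BH + u];
    const double* wi = g + OFF_WIN + u * N_IN;
    for (int i = 0; i < N_IN; ++i) if (x[i] != 0.0) s += wi[i] * x[i];
    const double* wr = g + OFF_WREC + u * H_MAX;
    for (int j = 0; j < H; ++j) s += wr[j] * h[j];
    hnew[u] = sigm(s);
  }
  for (int u = 0; u < H; ++u) h[u] = hnew[u];
  for (int u = H; u < H_MAX; ++u) h[u] = 0.0;
  double eff[N_OUT];
  double best = -1e300;
  for (int o = 0; o < N_OUT; ++o) {
    double s = g[OFF_BOUT + o];
    const double* wo = g + OFF_WOUT + o * H_MAX;
    for (int u = 0; u < H; ++u) s += wo[u] * h[u];
    eff[o] = sigm(s);
    if (eff[o] > best) best = eff[o];
  }
  if (eff_out) for (int o = 0; o < N_OUT; ++o) eff_out[o] = eff[o];
  // argmax with uniform random tie-break
  int ties[N_OUT], nt = 0;
  for (int o = 0; o < N_OUT; ++o) if (eff[o] == best) ties[nt++] = o;
  if (nt == 1) return ties[0];
  int pick = (int)std::floor(unif_rand() * nt);
  if (pick >= nt) pick = nt - 1;
  return ties[pick];
}

// [[Rcpp::export]]
List cpp_step_network(const NumericVector& genome, int hidden_size,
                      const NumericVector& input,
                      const NumericVector& hidden_state) {
  if (genome.size() != GENOME_LEN) stop("bad genome length");
  if (input.size() != N_IN) stop("input must have 36 units");
  double h[H_MAX];
  for (int u = 0; u < H_MAX; ++u)
    h[u] = (u < hidden_state.size()) ? hidden_state[u] : 0.0;
  double eff[N_OUT];
  int act = forward_action(REAL(genome), hidden_size, REAL(input), h, eff);
  return List::create(
    _["action"] = act + 1,  // 1-based for R: left, right, forward, eat
    _["hidden"] = NumericVector(h, h + H_MAX),
    _["effectors"] = NumericVector(eff, eff + N_OUT));
}

// [[Rcpp::export]]
int cpp_genome_length() { return GENOME_LEN; }

// Full ecosystem simulation: every iteration all agents sense and act, then
// one genetic-algorithm replacement event occurs (two random fitness-eligible
// parents; the weaker is replaced by their recombined, mutated child).
// [[Rcpp::export]]
List cpp_evolve(IntegerMatrix grid, NumericMatrix genomes,
                IntegerVector hidden_sizes, IntegerVector pos_r,
                IntegerVector pos_c, IntegerVector headings,
                NumericVector collected, IntegerVector age,
                int iterations, int regrow_delay, int burn_in,
                double mut_sd, double mut_prob, double hmut_prob,
                int h_min, int h_max, int trace_every, double food_zero_prob,
                bool wrap_world, IntegerVector pending_delay, IntegerVector pending_r,
                IntegerVector pending_c) {
  int nr = grid.nrow(), nc = grid.ncol();
  int n_agents = genomes.ncol();
  if (genomes.nrow() != GENOME_LEN) stop("bad genome matrix");
  std::vector<double> hidden(n_agents * H_MAX, 0.0);
  // regrowth queue: times non-decreasing since the delay is constant.
  // pending events from a previous run are re-queued first.
  std::vector<int> q_iter, q_r, q_c;
  size_t q_head = 0;
  for (int i = 0; i < pending_delay.size(); ++i) {
    q_iter.push_back(pending_delay[i]);
    q_r.push_back(pending_r[i]);
    q_c.push_back(pending_c[i]);
  }
  double x[N_IN];
  std::vector<double> trace_fit;
  std::vector<int> trace_it;
  int n_repl = 0;

  for (int it = 1; it <= iterations; ++it) {
    // regrow eaten cells whose delay has elapsed
    while (q_head < q_iter.size() && q_iter[q_head] <= it) {
      // sparse stationary food supply: empty with probability
      // food_zero_prob, otherwise a uniform quantity in 1..9
      int v = 0;
      if (unif_rand() >= food_zero_prob) {
        v = 1 + (int)std::floor(unif_rand() * 9.0);
        if (v > 9) v = 9;
      }
      grid(q_r[q_head], q_c[q_head]) = v;
      // a zero draw keeps the cell renewable: schedule a fresh draw, so the
      // food supply stays stationary instead of decaying to an empty grid
      if (v == 0) {
        q_iter.push_back(it + regrow_delay);
        q_r.push_back(q_r[q_head]);
        q_c.push_back(q_c[q_head]);
      }
      ++q_head;
    }
    for (int a = 0; a < n_agents; ++a) {
      const double* g = &genomes(0, a);
      int H = hidden_sizes[a];
      sense_into(grid.begin(), nr, nc, pos_r[a], pos_c[a], headings[a], wrap_world, x);
      int act = forward_action(g, H, x, &hidden[a * H_MAX], nullptr);
      if (act == ACT_LEFT) headings[a] = (headings[a] + 3) % 4;
      else if (act == ACT_RIGHT) headings[a] = (headings[a] + 1) % 4;
      else if (act == ACT_FORWARD) {
        static const int dr[4] = {-1, 0, 1, 0};
        static const int dc[4] = {0, 1, 0, -1};
        if (wrap_world) {
          pos_r[a] = ((pos_r[a] + dr[headings[a]]) % nr + nr) % nr;
          pos_c[a] = ((pos_c[a] + dc[headings[a]]) % nc + nc) % nc;
        } else {
          int r2 = pos_r[a] + dr[headings[a]], c2 = pos_c[a] + dc[headings[a]];
          if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc) {
            pos_r[a] = r2; pos_c[a] = c2;
          }
        }
      } else {  // eat
        int food = grid(pos_r[a], pos_c[a]);
        if (food > 0) {
          collected[a] += food;
          grid(pos_r[a], pos_c[a]) = 0;
          q_iter.push_back(it + regrow_delay);
          q_r.push_back(pos_r[a]);
          q_c.push_back(pos_c[a]);
        }
      }
      age[a] += 1;
    }
    // one replacement event per iteration
    std::vector<int> elig;
    elig.reserve(n_agents);
    for (int a = 0; a < n_agents; ++a) if (age[a] >= burn_in) elig.push_back(a);
    if (elig.size() >= 2) {
      int i1 = (int)std::floor(unif_rand() * elig.size());
      int i2 = (int)std::floor(unif_rand() * (elig.size() - 1));
      if (i2 >= i1) ++i2;
      int p1 = elig[i1], p2 = elig[i2];
      double f1 = collected[p1] / age[p1], f2 = collected[p2] / age[p2];
      int weak = (f1 < f2) ? p1 : p2;
      int strong = (weak == p1) ? p2 : p1;
      // child built in place of the weaker parent
      for (int gidx = 0; gidx < GENOME_LEN; ++gidx) {
        double gene = (unif_rand() < 0.5) ? genomes(gidx, p1) : genomes(gidx, p2);
        if (unif_rand() < mut_prob) gene += norm_rand() * mut_sd;
        if (!std::isfinite(gene)) gene = 0.0;  // clamp pathological genes
        genomes(gidx, weak) = gene;
      }
      int hs = (unif_rand() < 0.5) ? hidden_sizes[p1] : hidden_sizes[p2];
      if (unif_rand() < hmut_prob) hs += (unif_rand() < 0.5) ? -1 : 1;
      if (hs < h_min) hs = h_min;
      if (hs > h_max) hs = h_max;
      hidden_sizes[weak] = hs;
      collected[weak] = 0.0;
      age[weak] = 0;
      headings[weak] = (int)std::floor(unif_rand() * 4.0);
      for (int u = 0; u < H_MAX; ++u) hidden[weak * H_MAX + u] = 0.0;
      (void)strong;
      ++n_repl;
    }
    if (trace_every > 0 && it % trace_every == 0) {
      double s = 0.0; int m = 0;
      for (int a = 0; a < n_agents; ++a)
        if (age[a] > 0) { s += collected[a] / age[a]; ++m; }
      trace_fit.push_back(m > 0 ? s / m : 0.0);
      trace_it.push_back(it);
    }
  }
  // unresolved regrowth events, exported as remaining delays
  std::vector<int> out_d, out_r, out_c;
  for (size_t i = q_head; i < q_iter.size(); ++i) {
    out_d.push_back(q_iter[i] - iterations);
    out_r.push_back(q_r[i]);
    out_c.push_back(q_c[i]);
  }
  return List::create(
    _["grid"] = grid, _["genomes"] = genomes,
    _["hidden_sizes"] = hidden_sizes,
    _["pos_r"] = pos_r, _["pos_c"] = pos_c, _["headings"] = headings,
    _["collected"] = collected, _["age"] = age,
    _["trace_iter"] = wrap(trace_it), _["trace_fitness"] = wrap(trace_fit),
    _["n_replacements"] = n_repl,
    _["pending_delay"] = wrap(out_d), _["pending_r"] = wrap(out_r),
    _["pending_c"] = wrap(out_c));
}

// Quantity-comparison test battery in a walled 3x3 arena. The agent starts
// at the centre facing the baited row (top-left and top-right corners hold
// the two quantities); a trial ends when it steps onto a baited cell.
// choice: 1 = left cell, 2 = right cell, 0 = timeout. policy: 0 = network,
// 1 = uniform random action (chance baseline), 2 = greedy oracle that
// steers to the larger baited cell (bookkeeping ground truth).
// [[Rcpp::export]]
IntegerMatrix cpp_test_agent(const NumericVector& genome, int hidden_size,
                             const IntegerVector& left_vals,
                             const IntegerVector& right_vals,
                             int step_cap, int policy) {
  if (genome.size() != GENOME_LEN) stop("bad genome length");
  int n_trials = left_vals.size();
  IntegerMatrix out(n_trials, 4);
  int grid[9];
  double x[N_IN];
  double h[H_MAX];
  const double* g = REAL(genome);
  for (int t = 0; t < n_trials; ++t) {
    for (int k = 0; k < 9; ++k) grid[k] = 0;
    // column-major 3x3: (r, c) -> c*3 + r
    grid[0 * 3 + 0] = left_vals[t];   // top-left
    grid[2 * 3 + 0] = right_vals[t];  // top-right
    int r = 1, c = 1, heading = 0;    // centre, facing the baited row
    for (int u = 0; u < H_MAX; ++u) h[u] = 0.0;
    int choice = 0, rt = step_cap;
    for (int step = 1; step <= step_cap; ++step) {
      sense_into(grid, 3, 3, r, c, heading, false, x);
      int act;
      if (policy == 1) {
        act = (int)std::floor(unif_rand() * 4.0);
        if (act > 3) act = 3;
      } else if (policy == 2) {
        // greedy oracle: head for the corner with the larger true quantity
        int tc = (left_vals[t] >= right_vals[t]) ? 0 : 2;
        int want;  // desired heading
        if (c != tc) want = (tc < c) ? 3 : 1;  // west : east
        else want = 0;                         // north
        if (heading == want) act = ACT_FORWARD;
        else if ((heading + 1) % 4 == want) act = ACT_RIGHT;
        else act = ACT_LEFT;
      } else {
        act = forward_action(g, hidden_size, x, h, nullptr);
      }
      if (act == ACT_LEFT) heading = (heading + 3) % 4;
      else if (act == ACT_RIGHT) heading = (heading + 1) % 4;
      else if (act == ACT_FORWARD) {
        static const int dr[4] = {-1, 0, 1, 0};
        static const int dc[4] = {0, 1, 0, -1};
        int r2 = r + dr[heading], c2 = c + dc[heading];
        if (r2 >= 0 && r2 < 3 && c2 >= 0 && c2 < 3) { r = r2; c = c2; }
      }
      // eat has no consequence in the arena (centre cell is empty)
      if (r == 0 && c == 0) { choice = 1; rt = step; break; }
      if (r == 0 && c == 2) { choice = 2; rt = step; break; }
    }
    out(t, 0) = left_vals[t];
    out(t, 1) = right_vals[t];
    out(t, 2) = choice;
    out(t, 3) = rt;
  }
  return out;
}

// Mean hidden activation per presented food quantity: the quantity is shown
// in the cell directly ahead (all other visible cells empty), the hidden
// state is reset, and a single network update is recorded.
// [[Rcpp::export]]
NumericMatrix cpp_probe_hidden(const NumericVector& genome, int hidden_size,
                               const IntegerVector& values, int reps) {
  if (genome.size() != GENOME_LEN) stop("bad genome length");
  NumericMatrix out(values.size(), H_MAX);
  double x[N_IN];
  double h[H_MAX];
  const double* g = REAL(genome);
  for (int vi = 0; vi < values.size(); ++vi) {
    for (int rep = 0; rep < reps; ++rep) {
      for (int i = 0; i < N_IN; ++i) x[i] = 0.0;
      encode_food_into(values[vi], x + 9 * 2);  // block 2 = cell ahead
      for (int u = 0; u < H_MAX; ++u) h[u] = 0.0;
      forward_action(g, hidden_size, x, h, nullptr);
      for (int u = 0; u < hidden_size; ++u) out(vi, u) += h[u];
    }
  }
  for (int vi = 0; vi < values.size(); ++vi)
    for (int u = 0; u < H_MAX; ++u) out(vi, u) /= reps;
  return out;
}
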