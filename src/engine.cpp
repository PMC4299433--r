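#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-millisecond simulation kernel for one segment [t0, t1).
//
// All neurons live in one global index space (0-based here, 1-based on the R
// side).  Spike sources are neurons with is_lif == false: they never
// integrate, they fire exactly at the scheduled stimulus times.  LIF neurons
// use an exact exponential propagator per 1 ms step (current-based synapses
// with exponential decay), so sub-threshold behaviour matches the closed-form
// solution of the membrane equation.
//
// Within-step order (fixed contract):
//   1. scheduled source spikes at t are emitted and delivered (slot t + d),
//   2. ring-buffer slot t is read into the synaptic current and zeroed,
//   3. LIF neurons are updated; threshold crossings emit spikes which are
//      delivered into slots t + d (d >= 1, so never the slot just consumed).
// A spike arriving at t therefore influences the spike emitted at t.
//
// Projections are passed as a list of lists with fields:
//   row_ptr : IntegerVector length n_neurons + 1 (CSR over pre id, 0-based)
//   post    : IntegerVector (0-based global post ids)
//   w       : NumericVector (signed weights, nA)
//   d       : IntegerVector (integer delays, ms, >= 1)
//   lane    : int, 0 = excitatory lane, 1 = inhibitory lane
//
// State vectors are modified on local copies and returned.

// [[Rcpp::export]]
List cpp_run_segment(int t0, int t1,
                     LogicalVector is_lif,
                     NumericVector v_rest, NumericVector v_reset,
                     NumericVector v_thresh,
                     NumericVector em, NumericVector es,
                     NumericVector c_syn, NumericVector c_off,
                     IntegerVector t_refrac,
                     NumericVector v0, NumericVector ise0, NumericVector isi0,
                     IntegerVector refrac0,
                     NumericMatrix buf_e, NumericMatrix buf_i,
                     List projections,
                     IntegerVector stim_t, IntegerVector stim_id,
                     IntegerVector record_v_idx,
                     IntegerVector vgate_idx) {
  const int n = is_lif.size();
  const int buf_len = buf_e.nrow();
  const int nsteps = t1 - t0;

  NumericVector v = clone(v0), ise = clone(ise0), isi = clone(isi0);
  IntegerVector refrac = clone(refrac0);
  NumericMatrix be = clone(buf_e), bi = clone(buf_i);

  const int nproj = projections.size();
  std::vector<IntegerVector> p_rowptr(nproj), p_post(nproj), p_d(nproj);
  std::vector<NumericVector> p_w(nproj);
  std::vector<int> p_lane(nproj);
  for (int p = 0; p < nproj; ++p) {
    List pr = projections[p];
    p_rowptr[p] = as<IntegerVector>(pr["row_ptr"]);
    p_post[p] = as<IntegerVector>(pr["post"]);
    p_w[p] = as<NumericVector>(pr["w"]);
    p_d[p] = as<IntegerVector>(pr["d"]);
    p_lane[p] = as<int>(pr["lane"]);
  }

  std::vector<int> out_t, out_id;
  out_t.reserve(1024); out_id.reserve(1024);

  const int nrec = record_v_idx.size();
  const int ngate = vgate_idx.size();
  NumericMatrix v_trace(nrec > 0 ? nsteps : 0, nrec);
  NumericMatrix v_before(ngate > 0 ? nsteps : 0, ngate);

  int sp = 0;
  const int nstim = stim_t.size();

  for (int t = t0; t < t1; ++t) {
    const int step = t - t0;
    const int slot = ((t % buf_len) + buf_len) % buf_len;

    for (int g = 0; g < ngate; ++g)
      v_before(step, g) = v[vgate_idx[g]];

    // 1. scheduled source spikes
    while (sp < nstim && stim_t[sp] == t) {
      const int id = stim_id[sp];
      out_t.push_back(t); out_id.push_back(id);
      for (int p = 0; p < nproj; ++p) {
        const int from = p_rowptr[p][id], to = p_rowptr[p][id + 1];
        NumericMatrix &buf = (p_lane[p] == 0) ? be : bi;
        for (int k = from; k < to; ++k) {
          const int dst = (slot + p_d[p][k]) % buf_len;
          buf(dst, p_post[p][k]) += p_w[p][k];
        }
      }
      ++sp;
    }

    // 2.+3. consume inputs and update LIF neurons
    for (int i = 0; i < n; ++i) {
      if (!is_lif[i]) continue;
      const double in_e = be(slot, i), in_i = bi(slot, i);
      be(slot, i) = 0.0; bi(slot, i) = 0.0;
      const double i0e = ise[i] + in_e, i0i = isi[i] + in_i;
      const double i0 = i0e + i0i;
      bool spiked = false;
      if (refrac[i] > 0) {
        refrac[i] -= 1;
        v[i] = v_reset[i];
      } else {
        v[i] = v_rest[i] + (v[i] - v_rest[i]) * em[i] + c_off[i] +
               i0 * c_syn[i];
        if (!std::isfinite(v[i]) || !std::isfinite(i0))
          stop("non-finite state for neuron %d at t = %d ms", i + 1, t);
        if (v[i] >= v_thresh[i]) {
          spiked = true;
          v[i] = v_reset[i];
          refrac[i] = t_refrac[i];
        }
      }
      ise[i] = i0e * es[i];
      isi[i] = i0i * es[i];
      if (spiked) {
        out_t.push_back(t); out_id.push_back(i);
        for (int p = 0; p < nproj; ++p) {
          const int from = p_rowptr[p][i], to = p_rowptr[p][i + 1];
          NumericMatrix &buf = (p_lane[p] == 0) ? be : bi;
          for (int k = from; k < to; ++k) {
            const int dst = (slot + p_d[p][k]) % buf_len;
            buf(dst, p_post[p][k]) += p_w[p][k];
          }
        }
      }
    }

    for (int r = 0; r < nrec; ++r)
      v_trace(step, r) = v[record_v_idx[r]];
  }

  return List::create(
      _["spike_t"] = wrap(out_t), _["spike_id"] = wrap(out_id),
      _["v"] = v, _["ise"] = ise, _["isi"] = isi, _["refrac"] = refrac,
      _["buf_e"] = be, _["buf_i"] = bi,
      _["v_trace"] = v_trace, _["v_before"] = v_before);
}
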