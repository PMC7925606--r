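// Per-sample closed-loop core. The feedback path (light signal ->
// filter cascade -> beat-based setpoint + continuous PID -> antiresonance
// notch -> slew-limited actuator -> light signal) is inherently sequential
// at the sampling rate, so it runs compiled; everything around it
// (scenario generation, resonance detection, mode scheduling, statistics)
// stays in R. State is passed in and returned so the loop can be chunked.

#include <Rcpp.h>
using namespace Rcpp;

// Slew-limit, quantize and range-clamp a command trajectory.
// max_step is the per-sample slew bound of the internal continuous
// trajectory; res > 0 rounds the output to multiples of res.
// [[Rcpp::export]]
NumericVector slew_quantize_cpp(NumericVector x, double init,
                                double max_step, double res,
                                double lo, double hi) {
  int n = x.size();
  NumericVector out(n);
  double z = init;
  for (int i = 0; i < n; ++i) {
    double d = x[i] - z;
    if (d > max_step) d = max_step;
    if (d < -max_step) d = -max_step;
    z += d;
    if (z < lo) z = lo;
    if (z > hi) z = hi;
    out[i] = (res > 0) ? res * std::round(z / res) : z;
  }
  return out;
}

struct Stage {
  double uc;
  int dec;
  double y;
  double acc;  // block accumulator of the anti-alias (boxcar) decimator
};

// Decimated stages average each block of `dec` input samples before the
// recursion advances (at the last sample of the block); the boxcar nulls
// sit exactly at multiples of the decimated rate, so pulse harmonics
// cannot alias into the very-low-frequency trend.
static inline double stage_step(Stage &s, double x, long long g) {
  if (s.dec == 1) {
    s.y = (1.0 - s.uc) * s.y + s.uc * x;
    return s.y;
  }
  s.acc += x;
  if ((g + 1) % s.dec == 0) {
    s.y = (1.0 - s.uc) * s.y + s.uc * (s.acc / s.dec);
    s.acc = 0.0;
  }
  return s.y;
}

// [[Rcpp::export]]
List vct_chunk_cpp(NumericVector p_a, NumericVector tone,
                   NumericVector noise, List par, List st) {
  int n = p_a.size();
  double fs = as<double>(par["fs"]);

  // filter cascade
  // stage order: pulse1 pulse2 vct1 rhy_hp1 rhy_hp2 rhy_lp1..4 drh_lp1..2
  NumericVector ucs = par["uc"];
  IntegerVector decs = par["dec"];
  NumericVector fst = st["filt"];
  const int NSTAGE = 11;
  NumericVector facc = st["filt_acc"];
  std::vector<Stage> S(NSTAGE);
  for (int k = 0; k < NSTAGE; ++k) {
    S[k].uc = ucs[k];
    S[k].dec = decs[k];
    S[k].y = fst[k];
    S[k].acc = facc[k];
  }
  double drh_prev = as<double>(st["drh_prev"]);
  int dec_r = S[5].dec;  // rhythm/derivative decimation
  double fs_d = fs / dec_r;
  double drh_hold = as<double>(st["drh_hold"]);

  // controller
  double c_BBI = as<double>(par["c_BBI"]), c_BBP = as<double>(par["c_BBP"]);
  double c_P = as<double>(par["c_P"]), c_D = as<double>(par["c_D"]);
  double c_I = as<double>(par["c_I"]);
  double leak = as<double>(par["y_I_leak"]);  // per-sample forgetting
  double P0 = as<double>(st["P0"]), Pn = as<double>(st["Pn"]);
  double sum_V = as<double>(st["sum_V"]), y_I = as<double>(st["y_I"]);
  double PI_est = as<double>(st["PI_est"]);
  double clamp_lo = as<double>(par["clamp_lo"]);
  double clamp_hi = as<double>(par["clamp_hi"]);
  bool beat_control = as<bool>(par["beat_control"]);
  bool pid_control = as<bool>(par["pid_control"]);
  bool vbar_pulse_free = as<bool>(par["vbar_pulse_free"]);
  double fixed_command = as<double>(par["fixed_command"]);  // NaN: closed loop

  // pressure-volume model
  double v_high = as<double>(par["v_high"]), v_low0 = as<double>(par["v_low0"]);
  double tone_gain = as<double>(par["tone_gain"]), w0 = as<double>(par["w"]);
  double x0 = as<double>(par["center_offset"]);
  double w_narrow = as<double>(par["w_narrow"]);

  // antiresonance notch (unity-DC biquad in the command path)
  bool notch_on = as<bool>(st["notch_on"]);
  NumericVector nb = st["notch_b"], na_ = st["notch_a"];
  double nx1 = as<double>(st["nx1"]), nx2 = as<double>(st["nx2"]);
  double ny1 = as<double>(st["ny1"]), ny2 = as<double>(st["ny2"]);

  // actuator
  double max_step = as<double>(par["act_step"]);
  double res = as<double>(par["act_res"]);
  double rng_lo = as<double>(par["act_lo"]), rng_hi = as<double>(par["act_hi"]);
  double z_act = as<double>(st["z_act"]);
  double p_applied = as<double>(st["p_applied"]);
  NumericVector dline = st["delay_line"];  // actuator transport delay
  int nd = dline.size();
  int dpos = as<int>(st["dpos"]);

  // online beat detector on v_Pulse (systole = trough)
  double amp_est = as<double>(st["amp_est"]);
  double cur_min = as<double>(st["cur_min"]), cur_max = as<double>(st["cur_max"]);
  bool armed = as<bool>(st["armed"]);
  // ring buffer of recent raw light samples for the fat/spiky shape
  // anchor (each beat window is linearly detrended before the statistic,
  // so slow rhythm drift within the beat does not rectify into it)
  NumericVector vbuf = st["vbuf"];
  int nbuf = vbuf.size();
  double anchor_sum = as<double>(st["anchor_sum"]);
  double c_SA = as<double>(par["c_SA"]);
  double S0 = as<double>(par["S0"]);
  long long last_beat = as<double>(st["last_beat"]);  // global sample index
  long long g = as<double>(st["g"]);                  // global sample counter
  double vct_acc = as<double>(st["vct_acc"]);
  double vct_n = as<double>(st["vct_n"]);
  int refract = as<int>(par["refract"]);
  double confirm = as<double>(par["confirm"]);
  double min_amp = as<double>(par["min_amp"]);

  NumericVector v_out(n), vp_out(n), vr_out(n), vdr_out(n), vv_out(n);
  NumericVector cmd_out(n), pc_out(n);
  std::vector<double> bt, bPI, bV, bPn, bS;
  std::vector<int> bclamp;
  bool clamped = as<bool>(st["clamped"]);

  for (int i = 0; i < n; ++i, ++g) {
    // sensor: light from the previous applied pressure
    double tn = tone[i];
    double v_low = v_low0 + tone_gain * tn;
    double w = w0 * (1.0 - w_narrow * tn);
    double v = v_low + (v_high - v_low) *
      (std::atan((p_applied - p_a[i] - x0) / w) + M_PI / 2.0) / M_PI;
    v += noise[i];
    v_out[i] = v;

    // filter cascade
    double l1 = stage_step(S[0], v, g);
    double u1 = v - l1;
    double l2 = stage_step(S[1], u1, g);
    double v_pulse = u1 - l2;

    double l3 = stage_step(S[2], v, g);
    double v_vct = v - l3;  // first-order washout keeps the step area

    double h1 = stage_step(S[3], v, g);
    double r1 = v - h1;
    double h2 = stage_step(S[4], r1, g);
    double r2 = r1 - h2;
    double r3 = stage_step(S[5], r2, g);
    double r4 = stage_step(S[6], r3, g);
    double r5 = stage_step(S[7], r4, g);
    double v_rhythm = stage_step(S[8], r5, g);

    if ((g + 1) % dec_r == 0) {
      drh_hold = (v_rhythm - drh_prev) * fs_d;
      drh_prev = v_rhythm;
    }
    double d1 = stage_step(S[9], drh_hold, g);
    double v_drhythm = stage_step(S[10], d1, g);

    vp_out[i] = v_pulse;
    vr_out[i] = v_rhythm;
    vdr_out[i] = v_drhythm;
    vv_out[i] = v_vct;

    // beat detection state machine: after the diastolic peak the signal
    // must first DESCEND by drop_frac * amp_est (arming: a systolic trough
    // is forming; the smaller dicrotic dip does not arm), then RISE by
    // confirm * amp_est above the running minimum to confirm the beat.
    // the balance integrand: v_VCT carries the balance offset plus the
    // pulse; subtracting v_Pulse (whose full-beat integral is zero at
    // balance) removes the pulsatile component, whose only contribution
    // to a detection-to-detection window is edge noise that rectifies
    // under rhythmic amplitude modulation
    double v_bal = vbar_pulse_free ? (v_vct - v_pulse) : v_vct;
    if (v_pulse > cur_max && !armed) cur_max = v_pulse;
    if (!armed && (cur_max - v_pulse) >
          std::max(0.35 * amp_est, 2.0 * min_amp)) {
      armed = true;
      cur_min = v_pulse;
    }
    if (armed && v_pulse < cur_min) cur_min = v_pulse;
    vct_acc += v_bal;
    vct_n += 1.0;
    vbuf[g % nbuf] = v;
    // the integral branch accumulates continuously: the running sum of the
    // per-beat integrals equals (1/PI) * integral of the balance signal,
    // and the sample-wise form has no beat-window edges to rectify under
    // rhythmic amplitude modulation
    if (beat_control && !clamped) {
      double bcap = 0.6 * std::max(amp_est, min_amp);
      double vb = std::min(std::max(v_bal, -bcap), bcap);
      sum_V += vb / (fs * PI_est);
    }
    bool beat = false;
    if (armed && (g - last_beat) >= refract &&
        (v_pulse - cur_min) > confirm * std::max(amp_est, min_amp)) {
      beat = true;
      double PIs = (g - last_beat) / fs;
      double Vbar = (vct_n > 0) ? vct_acc / vct_n : 0.0;
      // artifact robustness: a physiological beat integral cannot exceed
      // a fraction of the pulse amplitude, and a beat whose amplitude
      // explodes against the running estimate is a motion artifact --
      // its integral must not move the setpoint
      double vcap = 0.6 * std::max(amp_est, min_amp);
      double Vuse = std::min(std::max(Vbar, -vcap), vcap);
      bool artifact_beat = ((cur_max - cur_min) > 2.5 * amp_est &&
                            amp_est > min_amp) ||
        (g - last_beat) < (long long)(1.25 * refract);
      // fat/spiky shape anchor: the beat mean of the raw light relative to
      // the beat's extremes is invariant to asymptote shifts (vasomotor
      // tone) and amplitude scaling, and increases monotonically with
      // contact pressure; its deviation from the balanced value S0 is an
      // absolute error signal integrated slowly into the setpoint
      double S_b = NA_REAL;
      long long L = g - last_beat;
      if (L > 2 && L <= (long long)nbuf) {
        double tbar = (L - 1) / 2.0, sxy = 0, sxx = 0, xbar = 0;
        for (long long j = 0; j < L; ++j)
          xbar += vbuf[(last_beat + 1 + j) % nbuf];
        xbar /= L;
        for (long long j = 0; j < L; ++j) {
          double xv = vbuf[(last_beat + 1 + j) % nbuf];
          sxy += (j - tbar) * (xv - xbar);
          sxx += (j - tbar) * (j - tbar);
        }
        double slope = (sxx > 0) ? sxy / sxx : 0.0;
        double dmin = R_PosInf, dmax = R_NegInf;
        for (long long j = 0; j < L; ++j) {
          double d = vbuf[(last_beat + 1 + j) % nbuf] - slope * (j - tbar);
          if (d < dmin) dmin = d;
          if (d > dmax) dmax = d;
        }
        if (dmax - dmin > 5.0 * min_amp)
          S_b = (xbar - (dmax + dmin) / 2.0) / (dmax - dmin);
      }
      if (beat_control && !clamped && !artifact_beat) {
        if (c_SA > 0 && R_finite(S_b) && R_finite(S0)) {
          double eS = S_b - S0;
          if (eS > 0.05) eS = 0.05;
          if (eS < -0.05) eS = -0.05;
          anchor_sum += eS;
        }
        Pn = P0 - c_BBI * sum_V - c_BBP * Vuse - c_SA * anchor_sum;
        PI_est = 0.7 * PI_est + 0.3 * PIs;
      }
      bt.push_back((double)g / fs);  // time of the confirming sample
      bPI.push_back(PIs);
      bV.push_back(Vbar);
      bPn.push_back(Pn);
      bS.push_back(S_b);
      bclamp.push_back(clamped ? 1 : 0);
      amp_est = 0.8 * amp_est +
        0.2 * std::min(cur_max - cur_min, 2.5 * amp_est);
      last_beat = g;
      cur_min = v_pulse;
      cur_max = v_pulse;
      armed = false;
      vct_acc = 0.0;
      vct_n = 0.0;
    }
    if ((g - last_beat) > (long long)(3.0 * fs)) {
      // signal loss: reset the trackers and shrink the amplitude estimate,
      // keep the setpoint
      cur_min = v_pulse;
      cur_max = v_pulse;
      armed = false;
      amp_est *= 0.5;
      last_beat = g;
      vct_acc = 0.0;
      vct_n = 0.0;
    }
    (void)beat;

    // continuous PID with anti-windup (y_I frozen while clamped); the
    // rhythm inputs are clipped against artifact bursts
    double y_PD = 0.0;
    if (pid_control) {
      double rcap = 0.6 * std::max(amp_est, min_amp);
      double dcap = 4.0 * std::max(amp_est, min_amp);
      double vr = std::min(std::max(v_rhythm, -rcap), rcap);
      double vdr = std::min(std::max(v_drhythm, -dcap), dcap);
      y_PD = c_P * vr + c_D * vdr;
      if (!clamped) y_I = (1.0 - leak) * y_I + c_I * y_PD;
    }

    double cmd;
    if (R_finite(fixed_command)) {
      cmd = fixed_command;
      clamped = false;
    } else {
      double raw = Pn - y_I - y_PD;
      // antiresonance notch in the command path
      if (notch_on) {
        double yn = nb[0] * raw + nb[1] * nx1 + nb[2] * nx2 -
                    na_[1] * ny1 - na_[2] * ny2;
        nx2 = nx1; nx1 = raw;
        ny2 = ny1; ny1 = yn;
        raw = yn;
      }
      cmd = raw;
      clamped = false;
      if (cmd < clamp_lo) { cmd = clamp_lo; clamped = true; }
      if (cmd > clamp_hi) { cmd = clamp_hi; clamped = true; }
    }
    cmd_out[i] = cmd;

    // actuator: transport delay, slew limit, quantization
    double target = cmd;
    if (nd > 0) {
      target = dline[dpos];
      dline[dpos] = cmd;
      dpos = (dpos + 1) % nd;
    }
    double d = target - z_act;
    if (d > max_step) d = max_step;
    if (d < -max_step) d = -max_step;
    z_act += d;
    if (z_act < rng_lo) z_act = rng_lo;
    if (z_act > rng_hi) z_act = rng_hi;
    p_applied = (res > 0) ? res * std::round(z_act / res) : z_act;
    pc_out[i] = p_applied;
  }

  for (int k = 0; k < NSTAGE; ++k) {
    fst[k] = S[k].y;
    facc[k] = S[k].acc;
  }
  List new_st = List::create(
    _["filt"] = fst, _["filt_acc"] = facc,
    _["drh_prev"] = drh_prev, _["drh_hold"] = drh_hold,
    _["P0"] = P0, _["Pn"] = Pn, _["sum_V"] = sum_V, _["y_I"] = y_I,
    _["PI_est"] = PI_est,
    _["notch_on"] = notch_on, _["notch_b"] = nb, _["notch_a"] = na_,
    _["nx1"] = nx1, _["nx2"] = nx2, _["ny1"] = ny1, _["ny2"] = ny2,
    _["z_act"] = z_act, _["p_applied"] = p_applied,
    _["delay_line"] = dline, _["dpos"] = dpos,
    _["amp_est"] = amp_est, _["cur_min"] = cur_min, _["cur_max"] = cur_max,
    _["last_beat"] = (double)last_beat, _["g"] = (double)g,
    _["vct_acc"] = vct_acc, _["vct_n"] = vct_n, _["clamped"] = clamped,
    _["armed"] = armed, _["vbuf"] = vbuf,
    _["anchor_sum"] = anchor_sum);
  return List::create(
    _["v"] = v_out, _["v_Pulse"] = vp_out, _["v_Rhythm"] = vr_out,
    _["v_dRhythm"] = vdr_out, _["v_VCT"] = vv_out,
    _["command"] = cmd_out, _["p_c"] = pc_out,
    _["beat_t"] = wrap(bt), _["beat_PI"] = wrap(bPI),
    _["beat_V"] = wrap(bV), _["beat_Pn"] = wrap(bPn),
    _["beat_S"] = wrap(bS), _["beat_clamped"] = wrap(bclamp),
    _["state"] = new_st);
}
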