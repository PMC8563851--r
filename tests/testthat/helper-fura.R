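# shared fixtures: the packaged reference parameter set and small builders

ref <- fura_default_params()
ref_cal <- ref$acquisition$calibration
ref_ccd <- ref$acquisition$ccd

# short simulated transient for quick tests (21 points over 3 s)
quick_sim <- function(seed = 1, span = 3, by = 0.15, params = ref) {
  simulate_transient(decay_grid(params$decay, span = span, by = by),
                     params$decay, params$illumination, params$acquisition,
                     seed = seed)
}

# one representative mid-transient quadruple of expected (noise-free) counts
expected_counts_at <- function(ca, params = ref) {
  ii <- intensities(ca, params$illumination, params$acquisition)
  g <- params$acquisition$ccd$gain
  list(adu340 = g * ii$i340, adu340_bg = g * ii$i340_bg,
       adu380 = g * ii$i380, adu380_bg = g * ii$i380_bg)
}

# delta-method SE for one count quadruple, assembled from exported pieces
delta_se_at <- function(cc, params = ref) {
  acq <- params$acquisition
  cal <- acq$calibration
  f340 <- flux(cc$adu340, cc$adu340_bg, acq$t_340, acq$p_roi, acq$p_bg)
  f380 <- flux(cc$adu380, cc$adu380_bg, acq$t_380, acq$p_roi, acq$p_bg)
  v340 <- flux_variance(adu_variance(cc$adu340, acq$ccd, acq$p_roi),
                        adu_variance(cc$adu340_bg, acq$ccd, acq$p_bg),
                        acq$t_340, acq$p_roi, acq$p_bg)
  v380 <- flux_variance(adu_variance(cc$adu380, acq$ccd, acq$p_roi),
                        adu_variance(cc$adu380_bg, acq$ccd, acq$p_bg),
                        acq$t_380, acq$p_roi, acq$p_bg)
  r <- f340 / f380
  ca <- ca_from_ratio(r, cal)
  sqrt(ca_variance_delta(r, ca, ratio_variance(f340, f380, v340, v380), cal))
}
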