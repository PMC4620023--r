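# Published summary parameters of the two treatment arms (aqueous-humor
# table of the microsphere study): inputs for summary-mode analyses.
gcm_summary <- function() {
  list(ka = 0.7252, ke = 0.1233, cmax = 51.23, auc_0_24 = 607.187,
       auc_0_inf = 645.116)
}

soln_summary <- function() {
  list(ka = 1.2981, ke = 0.1662, cmax = 18.98, auc_0_24 = 121.634,
       auc_0_inf = 137.692)
}

gcm_fit <- function() {
  s <- gcm_summary()
  calibrate_from_summary(s$ka, s$ke, s$cmax)
}

soln_fit <- function() {
  s <- soln_summary()
  calibrate_from_summary(s$ka, s$ke, s$cmax)
}

# --- independent brute-force oracles -----------------------------------

# grid maximization of a Bateman curve
oracle_grid_argmax <- function(fit, t_max = 50, step = 1e-3) {
  tt <- seq(0, t_max, by = step)
  cc <- bateman_conc(fit, tt)
  i <- which.max(cc)
  list(tmax = tt[i], cmax = cc[i])
}

# grid measure of {t : C(t) > thr}
oracle_grid_time_above <- function(fit, thr, window, step = 1e-4) {
  tt <- seq(window[1], window[2], by = step)
  step * sum(bateman_conc(fit, tt) > thr)
}

# last grid time with C(t) >= thr (down-crossing scan)
oracle_grid_down_crossing <- function(fit, thr, t_max = 200, step = 1e-4) {
  tt <- seq(0, t_max, by = step)
  above <- bateman_conc(fit, tt) > thr
  tt[max(which(above))]
}

# naive shifted-sum superposition at arbitrary times
oracle_shifted_sum <- function(fit, dose_times, t) {
  vapply(t, function(ti) {
    sum(vapply(dose_times[dose_times <= ti],
               function(d) bateman_conc(fit, ti - d), numeric(1)))
  }, numeric(1))
}

# exhaustive lattice search for the one-term power law Q = k * t^n
oracle_peppas_grid <- function(t, y, k_grid, n_grid) {
  best <- c(k = NA, n = NA, sse = Inf)
  for (k in k_grid) {
    for (n in n_grid) {
      sse <- sum((y - k * t^n)^2)
      if (sse < best["sse"]) best <- c(k = k, n = n, sse = sse)
    }
  }
  best
}
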