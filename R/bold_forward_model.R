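#' Physiological parameters of the laminar BOLD forward model
#'
#' Baseline vascular and coupling constants for the steady-state venous
#' drainage simulation. Defaults follow typical human visual-cortex
#' physiology at 7 T:
#' \itemize{
#'   \item `cbv0_total` = 2 mL/100 g total venous baseline blood volume, split
#'     `omega_v` = 0.5 into microvasculature (venules) and `omega_d` = 0.5 into
#'     ascending veins;
#'   \item `s_d` = 0.4: linear increase of ascending-vein baseline volume
#'     toward the cortical surface;
#'   \item Grubb exponents `alpha_v` = 0.35 (microvasculature) and
#'     `alpha_d` = 0.1 (ascending veins), relating volume to flow, v = f^alpha;
#'   \item `n` = 3: flow-metabolism coupling ratio, m = 1 + (f - 1)/n;
#'   \item `e0` = 0.35: baseline O2 extraction fraction at the venule entrance
#'     (65% of O2 remains), uniform across depths;
#'   \item `t_v0` = 1 s mean microvascular transit time, so microvascular
#'     CBF0 = CBV0_micro / t_v0 (central volume principle);
#'   \item `te` = 0.015 s echo time;
#'   \item `signal_constants`: per-compartment constants (c1, c2, c3) of the
#'     static BOLD signal equation `k1 = c1 e0 te`, `k2 = c2 e0 te`,
#'     `k3 = c3`. Defaults represent a 7 T gradient-echo regime with
#'     near-negligible intravascular contribution: for the ascending vein
#'     (static dephasing around a large vessel) c1 = 4.3 * 188.1 s^-1; for
#'     venules, diffusion narrowing around microvessels reduces the
#'     extravascular efficacy, modelled as 25% of the macrovascular value;
#'     c2 = 0.01 * 102 s^-1 and c3 = 0.01 - 1 for both. All are
#'     configuration-exposed.
#' }
#'
#' @param cbv0_total,omega_v,omega_d,s_d,alpha_v,alpha_d,n,e0,t_v0,te see above.
#' @param signal_constants list with elements `venule` and `vein`, each a list
#'   with `c1`, `c2`, `c3`.
#' @param tissue_volume reference tissue volume (mL/100 g) converting baseline
#'   blood volumes to volume fractions; default 100.
#' @return an object of class `physiology_params`.
#' @export
physiology_params <- function(cbv0_total = 2, omega_v = 0.5, omega_d = 0.5,
                              s_d = 0.4, alpha_v = 0.35, alpha_d = 0.1,
                              n = 3, e0 = 0.35, t_v0 = 1, te = 0.015,
                              signal_constants = NULL, tissue_volume = 100) {
  if (abs(omega_v + omega_d - 1) > 1e-9)
    stop("omega_v + omega_d must equal 1")
  if (e0 <= 0 || e0 >= 1) stop("e0 must lie in (0, 1)")
  if (any(c(cbv0_total, omega_v, omega_d, alpha_v, alpha_d, t_v0, te,
            tissue_volume) <= 0))
    stop("all physiological magnitudes must be positive")
  if (n < 1) stop("flow-metabolism coupling n must be >= 1")
  if (s_d < 0) stop("ascending-vein volume slope s_d must be >= 0")
  if (is.null(signal_constants)) {
    macro <- list(c1 = 4.3 * 188.1, c2 = 0.01 * 102, c3 = 0.01 - 1)
    micro <- macro
    micro$c1 <- 0.25 * macro$c1
    signal_constants <- list(venule = micro, vein = macro)
  }
  structure(list(cbv0_total = cbv0_total, omega_v = omega_v, omega_d = omega_d,
                 s_d = s_d, alpha_v = alpha_v, alpha_d = alpha_d, n = n,
                 e0 = e0, t_v0 = t_v0, te = te,
                 signal_constants = signal_constants,
                 tissue_volume = tissue_volume),
            class = "physiology_params")
}

#' Rescale arbitrary-unit baseline perfusion to physical units
#'
#' The measured ASL baseline perfusion is in arbitrary MRI units. The central
#' volume principle fixes the depth-mean physical baseline perfusion at
#' `CBV0_micro / t_v0` (1 mL/s/100 g, i.e. 60 mL/min/100 g, at the defaults),
#' so the scaling factor is
#' `x = (omega_v cbv0_total / t_v0) / mean(baseline_cbf_arb)`. The forward
#' simulation itself depends only on relative flow changes, so this scaling
#' serves reporting in physiological units rather than the prediction.
#'
#' @param baseline_cbf_arb per-depth baseline perfusion in arbitrary units,
#'   positive.
#' @param params a `physiology_params`.
#' @return list with `x` (scaling, (mL/s/100 g) per arbitrary unit) and
#'   `cbf0` (per-depth baseline perfusion in mL/s/100 g).
#' @export
rescale_cbf <- function(baseline_cbf_arb, params = physiology_params()) {
  if (any(baseline_cbf_arb <= 0)) stop("baseline perfusion must be positive")
  m <- mean(baseline_cbf_arb)
  if (m == 0) stop("zero mean baseline perfusion")
  x <- (params$omega_v * params$cbv0_total / params$t_v0) / m
  list(x = x, cbf0 = x * baseline_cbf_arb)
}

#' Baseline vascular distributions across depths
#'
#' Microvascular (venule) baseline blood volume is split uniformly across the
#' K depths; ascending-vein baseline volume increases linearly toward the
#' surface, `V0_vein,k proportional to 1 + s_d (k-1)/(K-1)`, normalised so the
#' compartment totals are `omega_v cbv0_total` and `omega_d cbv0_total`.
#' Baseline venule flows are proportional to the per-depth baseline perfusion
#' (uniform when none is supplied); ascending-vein baseline flow at depth k is
#' the cumulative venule flow of all depths at or below k (the vein drains
#' deeper laminae on its way to the surface).
#'
#' @param params a `physiology_params`.
#' @param K number of depths (>= 2); depth k = 1 is the deepest (WM-side).
#' @param baseline_cbf optional per-depth baseline perfusion setting the
#'   venule flow distribution.
#' @return list with `V0_venule`, `V0_vein` (mL/100 g) and `F0_venule`,
#'   `F0_vein` (flow units; venule flows sum to 1).
#' @export
baseline_distributions <- function(params, K, baseline_cbf = NULL) {
  if (K < 2 || K != round(K)) stop("K must be an integer >= 2")
  V0_venule <- rep(params$omega_v * params$cbv0_total / K, K)
  ramp <- 1 + params$s_d * (seq_len(K) - 1) / (K - 1)
  V0_vein <- params$omega_d * params$cbv0_total * ramp / sum(ramp)
  F0_venule <- if (is.null(baseline_cbf)) rep(1 / K, K) else {
    if (length(baseline_cbf) != K) stop("baseline_cbf must have length K")
    if (any(baseline_cbf <= 0)) stop("baseline_cbf must be positive")
    baseline_cbf / sum(baseline_cbf)
  }
  list(V0_venule = V0_venule, V0_vein = V0_vein,
       F0_venule = F0_venule, F0_vein = cumsum(F0_venule))
}

#' Flow-metabolism coupling
#'
#' Relative CMRO2 from relative CBF under linear coupling:
#' `m = 1 + (f - 1) / n`.
#'
#' @param f relative cerebral blood flow (activation / baseline), positive.
#' @param n coupling ratio (>= 1); larger n means flow changes outrun
#'   metabolism.
#' @return relative CMRO2.
#' @export
cmro2_coupling <- function(f, n) {
  if (any(f <= 0)) stop("relative flow must be positive")
  if (n < 1) stop("n must be >= 1")
  1 + (f - 1) / n
}

#' Venule steady state
#'
#' Relative venule volume by the Grubb relation `v = f^alpha_v`, and relative
#' deoxyhaemoglobin content from steady-state mass balance: dHb production m
#' (relative CMRO2) balances clearance `f q / v`, giving `q = m v / f`. For
#' f > 1 and n > 1 the dilution m/f < 1 lowers the dHb concentration.
#'
#' @param f relative flow per depth, positive.
#' @param params a `physiology_params`.
#' @return list with `v`, `q`, `m` (each per depth).
#' @export
venule_steady_state <- function(f, params = physiology_params()) {
  if (any(f <= 0)) stop("relative flow must be positive")
  v <- f^params$alpha_v
  m <- cmro2_coupling(f, params$n)
  list(v = v, q = m * v / f, m = m)
}

#' Ascending-vein drainage at steady state
#'
#' The intra-cortical ascending vein collects venule outflow depth by depth on
#' its way to the surface. Absolute vein flow at depth k during activation is
#' the cumulative venule outflow `F_k = sum_{j<=k} f_j F0_venule,j`; relative
#' vein flow is `f_vein,k = F_k / F0_vein,k`; vein volume follows its Grubb
#' relation `v_vein = f_vein^alpha_d`. The dHb concentration in the vein mixes
#' the local venule outflow with the vein inflow from below, flux-weighted:
#' \deqn{\frac{q_{d,k}}{v_{d,k}} = \frac{f_k F^0_{v,k} (q_{v,k}/v_{v,k}) +
#'   f_{d,k-1} F^0_{d,k-1} (q_{d,k-1}/v_{d,k-1})}{f_{d,k} F^0_{d,k}}}
#' with the deepest vein segment fed only by its venule. This cumulative
#' mixing is what biases the BOLD signal toward the surface even when the
#' underlying flow response decreases with depth.
#'
#' @param f relative venule flow per depth (k = 1 deepest).
#' @param baselines output of [baseline_distributions()].
#' @param params a `physiology_params`.
#' @return list with `f_vein`, `v_vein`, `q_vein` per depth.
#' @export
vein_drainage <- function(f, baselines, params = physiology_params()) {
  if (any(f <= 0)) stop("relative flow must be positive")
  F0v <- baselines$F0_venule
  F0d <- baselines$F0_vein
  if (any(F0v <= 0) || any(F0d <= 0)) stop("baseline flows must be positive")
  K <- length(f)
  if (length(F0v) != K) stop("flow profile and baselines disagree on K")
  ven <- venule_steady_state(f, params)
  conc_v <- ven$q / ven$v
  f_vein <- cumsum(f * F0v) / F0d
  v_vein <- f_vein^params$alpha_d
  conc_d <- numeric(K)
  conc_d[1] <- conc_v[1]
  if (K > 1) for (k in 2:K) {
    conc_d[k] <- (f[k] * F0v[k] * conc_v[k] +
                    f_vein[k - 1] * F0d[k - 1] * conc_d[k - 1]) /
      (f_vein[k] * F0d[k])
  }
  list(f_vein = f_vein, v_vein = v_vein, q_vein = conc_d * v_vein)
}

#' Steady-state BOLD signal change from a vascular state
#'
#' Static BOLD signal equation summed over the venule and ascending-vein
#' compartments:
#' \deqn{\Delta S/S_k = \sum_j w_{j,k} [(k_{1,j} + k_{2,j})(1 - q_{j,k})
#'   - (k_{2,j} + k_{3,j})(1 - v_{j,k})]}
#' with `k1 = c1 e0 te`, `k2 = c2 e0 te`, `k3 = c3`. The weight `w_{j,k}` is
#' the baseline volume fraction of compartment j within lamina k's tissue:
#' the per-depth `V0` (mL/100 g, summing to the compartment total across
#' depths) divided by the lamina's tissue volume `tissue_volume / K`. Output
#' in percent.
#'
#' @param state list with elements `venule` and `vein`, each holding per-depth
#'   `v`, `q` and `V0`.
#' @param params a `physiology_params`.
#' @return per-depth BOLD signal change in percent.
#' @export
bold_signal <- function(state, params = physiology_params()) {
  if (is.null(state$venule) || is.null(state$vein))
    stop("state must contain both venule and vein compartments")
  K <- length(state$venule$v)
  total <- 0
  for (comp in c("venule", "vein")) {
    s <- state[[comp]]
    if (is.null(s$v) || is.null(s$q) || is.null(s$V0))
      stop("compartment '", comp, "' must provide v, q and V0")
    if (length(s$v) != K || length(s$q) != K)
      stop("compartments disagree on the number of depths")
    cc <- params$signal_constants[[comp]]
    k1 <- cc$c1 * params$e0 * params$te
    k2 <- cc$c2 * params$e0 * params$te
    k3 <- cc$c3
    w <- s$V0 / (params$tissue_volume / K)
    total <- total + w * ((k1 + k2) * (1 - s$q) - (k2 + k3) * (1 - s$v))
  }
  100 * total
}

#' Laminar perfusion input for the forward simulation
#'
#' Measured (or synthetic) baseline and activation perfusion per depth in
#' arbitrary units; the simulation uses their ratio, the relative flow
#' `f = active / baseline`.
#'
#' @param baseline,active positive per-depth perfusion values (a.u.).
#' @param depth_norm optional normalised depths (default: evenly spaced,
#'   0 = WM-side).
#' @return an object of class `laminar_perfusion_input`.
#' @export
laminar_perfusion_input <- function(baseline, active, depth_norm = NULL) {
  K <- length(baseline)
  if (length(active) != K) stop("baseline and active lengths differ")
  if (any(baseline <= 0) || any(active <= 0))
    stop("perfusion values must be positive")
  if (is.null(depth_norm)) depth_norm <- seq(0, 1, length.out = K)
  if (length(depth_norm) != K) stop("depth_norm length must match")
  structure(list(baseline = baseline, active = active,
                 depth_norm = depth_norm, K = K),
            class = "laminar_perfusion_input")
}

#' Simulate the laminar BOLD profile from perfusion profiles
#'
#' Composes the forward chain: CBF rescaling (reporting only), baseline
#' vascular distributions, flow-metabolism coupling, venule steady state,
#' ascending-vein drainage, and the BOLD signal equation. The prediction is
#' driven by the depth-dependent relative flow `f = active / baseline`; it is
#' invariant to a common rescaling of both inputs. Under the default
#' parameters the cumulative vein drainage and the rising vein baseline volume
#' produce a BOLD profile increasing toward the surface even when the relative
#' perfusion response decreases toward the surface — reconciling the opposing
#' measured profiles.
#'
#' @param perfusion a `laminar_perfusion_input`.
#' @param params a `physiology_params`.
#' @return a `laminar_profile` of simulated BOLD change (percent), with
#'   attributes `x` (CBF scaling), `cbf0` (physical baseline perfusion),
#'   `f` (relative flow) and `state` (full vascular state).
#' @export
simulate_bold_profile <- function(perfusion, params = physiology_params()) {
  stopifnot(inherits(perfusion, "laminar_perfusion_input"))
  K <- perfusion$K
  if (K < 2) stop("need at least 2 depths")
  f <- perfusion$active / perfusion$baseline
  resc <- rescale_cbf(perfusion$baseline, params)
  baselines <- baseline_distributions(params, K,
                                      baseline_cbf = perfusion$baseline)
  ven <- venule_steady_state(f, params)
  vein <- vein_drainage(f, baselines, params)
  state <- list(
    venule = list(v = ven$v, q = ven$q, V0 = baselines$V0_venule,
                  F0 = baselines$F0_venule, f = f),
    vein = list(v = vein$v_vein, q = vein$q_vein, V0 = baselines$V0_vein,
                F0 = baselines$F0_vein, f = vein$f_vein))
  ds <- bold_signal(state, params)
  out <- laminar_profile(perfusion$depth_norm, ds)
  attr(out, "x") <- resc$x
  attr(out, "cbf0") <- resc$cbf0
  attr(out, "f") <- f
  attr(out, "state") <- state
  out
}
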