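# Membrane mechanisms: HH-type gates, six-state Markov Ca2+ channels, GHK
# flux, chloride Nernst potential, and the double-exponential synaptic
# conductance waveform.

#' Steady state and time constant of an HH-type gate
#'
#' Gates are parameterized as `x_inf(V) = 1/(1 + exp(-(V - vhalf)/k))` (a
#' negative slope `k` gives an inactivation gate) and
#' `tau_x(V) = tau_base + tau_amp * exp(-((V - tau_vmid)/tau_sigma)^2)`.
#' Equivalent forward/backward rates are `alpha = x_inf/tau`,
#' `beta = (1 - x_inf)/tau`.
#'
#' @param gate a gate parameter list (e.g. `default_params()$na$m`).
#' @param v membrane potential, mV (vectorized).
#' @return list with components `inf`, `tau` (ms), `alpha`, `beta` (1/ms).
#' @export
#' @examples
#' gate_dynamics(default_params()$na$h, c(-80, -40))
gate_dynamics <- function(gate, v) {
  inf <- 1 / (1 + exp(-(v - gate$vhalf) / gate$k))
  tau <- gate$tau_base +
    gate$tau_amp * exp(-((v - gate$tau_vmid) / gate$tau_sigma)^2)
  list(inf = inf, tau = tau, alpha = inf / tau, beta = (1 - inf) / tau)
}

#' Generator matrix of a six-state Ca2+ channel at a given voltage
#'
#' Linear chain C0-C1-C2-C3-C4-O.  The four closed-state transitions are
#' voltage dependent with statistical factors (forward `(5-i)*a*exp(V/kf)`,
#' backward `i*b*exp(-V/kb)`); the final opening step C4<->O is voltage
#' independent (`kon`, `koff`).  Row sums are zero.
#'
#' @param spec subtype parameter list (e.g.
#'   `default_params()$ca$subtypes$pq`).
#' @param v membrane potential, mV.
#' @return 6 x 6 generator matrix (1/ms), rows/cols `C0..C4, O`;
#'   `Q[i, j]` is the rate from state i to state j.
#' @export
markov_generator <- function(spec, v) {
  fwd <- c((4:1) * spec$a * exp(v / spec$kf), spec$kon)
  bwd <- c((1:4) * spec$b * exp(-v / spec$kb), spec$koff)
  q <- matrix(0, 6, 6,
              dimnames = list(c(paste0("C", 0:4), "O"),
                              c(paste0("C", 0:4), "O")))
  for (i in 1:5) {
    q[i, i + 1] <- fwd[i]
    q[i + 1, i] <- bwd[i]
  }
  diag(q) <- -rowSums(q)
  q
}

#' Stationary state occupancy of a six-state Ca2+ channel
#'
#' Computed in closed form from detailed balance of the birth-death chain.
#' @inheritParams markov_generator
#' @return named numeric vector of 6 occupancies summing to 1.
#' @export
markov_stationary <- function(spec, v) {
  p <- chain_stationary_cpp(as.numeric(c(spec$a, spec$kf, spec$b, spec$kb,
                                         spec$kon, spec$koff)), v)
  setNames(p, c(paste0("C", 0:4), "O"))
}

#' GHK flux density for Ca2+
#'
#' Goldman-Hodgkin-Katz current density carried by a divalent ion.
#' @param v membrane potential, mV (vectorized).
#' @param perm_cm_s permeability, cm/s.
#' @param cai,cao internal/external concentration, mM.
#' @param temp temperature, K.
#' @return current density, mA/cm^2 (inward negative).
#' @export
ghk_flux <- function(v, perm_cm_s, cai = 1e-4, cao = 2, temp = 296) {
  perm_cm_s * vapply(v, ghk2_factor_cpp, numeric(1), ci = cai, co = cao,
                     temp = temp)
}

#' Membrane current density of a channel in a given gating state
#'
#' Ohmic channels: `gbar * open_frac * (V - E_rev)` with `gbar` in mS/cm^2
#' giving mA/cm^2.  Ca2+ channels: open occupancy times the GHK flux.
#'
#' @param v membrane potential, mV.
#' @param gbar_ms_cm2,e_rev ohmic channel density and reversal (omit for Ca).
#' @param open_frac open fraction (gate product or O-state occupancy).
#' @param perm_cm_s,cai,cao,temp GHK parameters for a Ca2+ channel.
#' @return current density, mA/cm^2 (inward negative).
#' @export
channel_current_density <- function(v, open_frac, gbar_ms_cm2 = NULL,
                                    e_rev = NULL, perm_cm_s = NULL,
                                    cai = 1e-4, cao = 2, temp = 296) {
  if (!is.null(gbar_ms_cm2)) {
    gbar_ms_cm2 * open_frac * (v - e_rev) * 1e-3
  } else {
    open_frac * ghk_flux(v, perm_cm_s, cai, cao, temp)
  }
}

#' Chloride Nernst potential
#'
#' `E_Cl = (RT/F) * ln([Cl]_in/[Cl]_out)` for a channel permeable exclusively
#' to chloride (valence -1).
#' @param cl_in,cl_out internal/external chloride concentration, mM.
#' @param temp temperature, K.
#' @return reversal potential, mV.
#' @export
#' @examples
#' nernst_chloride(12)   # about -65 mV
nernst_chloride <- function(cl_in, cl_out = 154, temp = 296) {
  if (any(cl_in <= 0) || any(cl_out <= 0)) {
    stop("domain error: concentrations must be positive")
  }
  1e3 * (8.31446262 * temp / 96485.33212) * log(cl_in / cl_out)
}

#' Double-exponential synaptic conductance waveform
#'
#' `g(t) = gmax * norm * (exp(-(t-onset)/tau_decay) - exp(-(t-onset)/tau_rise))`
#' for `t >= onset`, 0 before; `norm` scales the peak to `gmax`.
#'
#' @param t time, ms (vectorized).
#' @param gmax peak conductance, nS.
#' @param tau_rise,tau_decay rise/decay time constants, ms
#'   (`tau_decay > tau_rise > 0`).
#' @param onset onset time, ms.
#' @return conductance, nS.
#' @export
synaptic_conductance <- function(t, gmax, tau_rise, tau_decay, onset = 0) {
  if (tau_decay <= tau_rise || tau_rise <= 0) {
    stop("configuration error: need tau_decay > tau_rise > 0")
  }
  tp <- syn_time_to_peak(tau_rise, tau_decay)
  norm <- 1 / (exp(-tp / tau_decay) - exp(-tp / tau_rise))
  ifelse(t < onset, 0,
         gmax * norm * (exp(-(t - onset) / tau_decay) -
                        exp(-(t - onset) / tau_rise)))
}

#' Time to peak of the double-exponential conductance
#' @inheritParams synaptic_conductance
#' @return time from onset to peak, ms.
#' @export
syn_time_to_peak <- function(tau_rise, tau_decay) {
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}
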