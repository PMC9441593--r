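#' Load a named model parameter set
#'
#' Parameter sets are YAML files shipped under `inst/extdata/params/`.  The
#' default set, `"default-calibrated-v1"`, contains the passive membrane
#' properties and geometry of the granule-cell model together with channel
#' gating parameters calibrated so that the single-compartment voltage-clamp
#' protocols reproduce the reference kinetics (Na+ activation/inactivation at
#' -40 mV, K+ inactivation at +30 mV, Ca2+ subtype activation at 0 mV and
#' deactivation at -80 mV).
#'
#' @param name name of the parameter set (file basename without extension),
#'   or a path to a YAML file.
#' @return a nested list of parameters; see the shipped YAML for the schema
#'   (every field carries its unit in its name or in a comment).
#' @export
#' @examples
#' p <- default_params()
#' p$passive$rm_kohm_cm2
default_params <- function(name = "default-calibrated-v1") {
  path <- if (file.exists(name)) {
    name
  } else {
    system.file("extdata", "params", paste0(name, ".yaml"),
                package = "mfaxon", mustWork = FALSE)
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown parameter set: ", name)
  }
  p <- yaml::read_yaml(path)
  validate_params(p)
  p
}

validate_params <- function(p) {
  need <- c("passive", "na", "k", "ca", "syn_glu", "gaba", "geometry", "sim")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("parameter set missing fields: ",
                         paste(miss, collapse = ", "))
  pv <- p$passive
  if (pv$cm_uf_cm2 <= 0 || pv$rm_kohm_cm2 <= 0 || pv$ri_ohm_cm <= 0) {
    stop("passive resistivities and capacitance must be positive")
  }
  invisible(p)
}

# gate parameter list -> numeric vector used by the solver
gate_vec <- function(g) {
  as.numeric(c(g$vhalf, g$k, g$tau_base, g$tau_amp, g$tau_vmid, g$tau_sigma))
}

# 4 x 6 gate matrix (rows m, h, n, hk) for the solver
gate_matrix <- function(params) {
  rbind(gate_vec(params$na$m), gate_vec(params$na$h),
        gate_vec(params$k$n), gate_vec(params$k$hk))
}

# 6 x nsub Markov rate matrix (rows a, kf, b, kb, kon, koff), columns PQ, N, R
ca_rate_matrix <- function(params) {
  sub <- params$ca$subtypes
  sapply(c("pq", "n", "r"), function(s) {
    r <- sub[[s]]
    as.numeric(c(r$a, r$kf, r$b, r$kb, r$kon, r$koff))
  })
}
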