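# Shared fixtures (built lazily, cached for the whole run) and the
# independent brute-force rate-law oracle.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

default_model <- function() cached("model", build_reference_network(spore_parameters()))
basal_state <- function() cached("basal", pre_equilibrate(default_model()))
default_dr <- function() cached("dr", dose_response(default_model(), "IPTG"))

random_state <- function() {
  s <- spore_state()
  s[] <- stats::runif(length(s), 0, 1000)
  s
}

# Independent oracle: a direct, reaction-by-reaction transcription of the
# published rate-law formula strings (plus the turnover inventory), written
# without reference to the package's evaluator.
oracle_rates <- function(state, p) {
  L <- state[["LacI"]]; A <- state[["Spo0AP"]]
  v <- c(
    tr1 = p[["tr1.k"]],
    tl1 = p[["tl1.k"]] * state[["lacI_t"]],
    k1 = p[["k1.k"]] * state[["LacI"]] * state[["IPTG"]],
    k2 = p[["k2.k"]] * state[["LacI_d"]],
    tr2 = (p[["tr2.k1"]] + p[["tr2.k2"]] * p[["tr2.KL"]]^2 /
             (p[["tr2.KL"]]^2 + L^2)) *
      (1 + p[["tr2.k3"]] * A^2 / (p[["tr2.KS"]]^2 + A^2)),
    tl2 = p[["tl2.k"]] * state[["kinA_t"]],
    k3 = p[["k3.k"]] * state[["KinA"]]^2,
    k4 = p[["k4.k"]] * state[["KinA2"]],
    k5 = p[["k5.k"]] * state[["KinA2"]] * state[["SS"]],
    tr3 = p[["tr3.k1"]] + p[["tr3.k2"]] * A^2 / (p[["tr3.KS"]]^2 + A^2),
    tl3 = p[["tl3.k"]] * state[["spo0F_t"]],
    k6 = p[["k6.k"]] * state[["Spo0F"]] * state[["KinA2P"]],
    k7 = p[["k7.k"]] * state[["Spo0FP"]],
    tr4 = p[["tr4.k"]],
    tl4 = p[["tl4.k"]] * state[["spo0B_t"]],
    k8 = p[["k8.k"]] * state[["Spo0B"]] * state[["Spo0FP"]],
    tr5 = p[["tr5.k1"]] * p[["tr5.Kk1"]] / (p[["tr5.Kk1"]] + A) +
      p[["tr5.k2"]] * A^2 / (p[["tr5.Kk2"]]^2 + A^2),
    tl5 = p[["tl5.k"]] * state[["spo0A_t"]],
    k9 = p[["k9.k"]] * state[["Spo0A"]] * state[["Spo0BP"]],
    k10 = p[["k10.k"]] * state[["Spo0AP"]],
    kBdeph = p[["kBdeph.k"]] * state[["Spo0BP"]],
    tr6 = p[["tr6.k1"]] + p[["tr6.k2"]] * A^4 / (p[["tr6.Kk"]]^4 + A^4),
    tl6A = p[["tl6A.k"]] * state[["spoIIA_t"]],
    tl6B = p[["tl6B.k"]] * state[["spoIIA_t"]],
    tl6C = p[["tl6C.k"]] * state[["spoIIA_t"]],
    tr7 = p[["tr7.k1"]] + p[["tr7.k2"]] * A^4 / (p[["tr7.Kk"]]^4 + A^4),
    tl7 = p[["tl7.k"]] * state[["spoIIE_t"]],
    tr8 = p[["tr8.k1"]] + p[["tr8.k2"]] * A^4 / (p[["tr8.Kk"]]^4 + A^4),
    tl8A = p[["tl8A.k"]] * state[["spoIIG_t"]],
    tl8B = p[["tl8B.k"]] * state[["spoIIG_t"]])
  deg_forms <- setdiff(spore_forms(), c("IPTG", "SS"))
  deg <- vapply(deg_forms, function(f)
    p[[paste0("deg_", f, ".k")]] * state[[f]], numeric(1))
  names(deg) <- paste0("deg_", deg_forms)
  c(v, deg)
}

# model copy with synthesis, translation and turnover silenced (phosphotransfer
# core only) for conservation checks
phosphotransfer_only_model <- function() {
  cached("core_model", {
    off <- c("tr1.k", "tl1.k", "tr2.k1", "tr2.k2", "tr2.k3",
             "tr3.k1", "tr3.k2", "tr4.k", "tr5.k1", "tr5.k2",
             "tr6.k1", "tr6.k2", "tr7.k1", "tr7.k2", "tr8.k1", "tr8.k2",
             "tl2.k", "tl3.k", "tl4.k", "tl5.k",
             "tl6A.k", "tl6B.k", "tl6C.k", "tl7.k", "tl8A.k", "tl8B.k",
             "d_mRNA", "d_prot")
    set_parameters(default_model(),
                   stats::setNames(rep(0, length(off)), off))
  })
}
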