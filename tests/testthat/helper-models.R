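# shared model builders for the test suite

two_compartment <- function(f1 = 0.5, d = c(1, 3), k = 0.01) {
  # symmetric conductance c gives R[1,2] = c/f2, R[2,1] = c/f1
  cmat <- matrix(0, 2, 2)
  cmat[1, 2] <- k * f1 * (1 - f1) / max(f1, 1 - f1)  # arbitrary valid scale
  karger_model_from_conductances(c(f1, 1 - f1), d, cmat)
}

# simple equal-fraction pair exchanging at rate k in both directions
symmetric_pair <- function(d = c(1, 3), k = 0.01) {
  karger_model(c(0.5, 0.5), d, matrix(c(0, k, k, 0), 2, 2))
}

modes_of <- function(model) {
  spectral_modes(build_generator(model), model$fractions,
                 model$diffusivities)
}

random_neurite_system <- function(seed) {
  set.seed(seed)
  nc <- sample(1:32, 1)
  neurite_system(
    fex = runif(1, 0.15, 0.85),
    Dex = runif(1, 0.5, 2.5),
    Din = runif(1, 1, 3),
    angles = runif(nc, 0, pi / 2),
    Rin = exp(runif(1, log(0.005), log(0.08))))
}

# neurite system hitting a prescribed kurtosis ratio kappaN/K0 at given fex
neurite_with_kappa_ratio <- function(fex, kappa_ratio, Rin,
                                     dn = c(2.0, 0.5)) {
  ratio_of <- function(dex) {
    cf <- neurite_closed_form(
      neurite_system(fex = fex, Dex = dex, diffusivities = dn, Rin = Rin),
      0)
    cf$kappaN / cf$K0
  }
  # ratio -> 1 as Dex moves far from mean(dn); 0 at Dex = mean(dn)
  dex <- stats::uniroot(function(d) ratio_of(d) - kappa_ratio,
                        lower = mean(dn) + 1e-9, upper = 50,
                        tol = 1e-12)$root
  neurite_system(fex = fex, Dex = dex, diffusivities = dn, Rin = Rin)
}
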