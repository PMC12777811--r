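# Closed-form oracles for the linear cannulated-animal model, independent of
# the ODE integrator, plus small fixture builders shared across test files.

MGNG <- 1e6

# One-compartment (k12 = k21 = 0) oral serum concentration (ng/ml):
# absorbable depot D = fa * dose decaying at ka; central input fraction
# Fin = (1 - phi_lymph) * (1 - eh); elimination rate ke = cl / vc.
oral_conc_1cpt <- function(p, dose_mg, t) {
  D <- p$fa * dose_mg * MGNG
  fin <- (1 - p$phi_lymph) * (1 - p$eh)
  ke <- p$cl / p$vc
  stopifnot(abs(ke - p$ka) > 1e-8)
  amt <- fin * p$ka * D / (ke - p$ka) * (exp(-p$ka * t) - exp(-ke * t))
  amt / (p$vc * 1000)
}

# One-compartment IV bolus serum concentration (ng/ml).
iv_conc_1cpt <- function(p, dose_mg, t) {
  dose_mg * MGNG / (p$vc * 1000) * exp(-p$cl / p$vc * t)
}

# Analytic serum AUC_inf (ng*h/ml) of the linear model, any compartment count:
# oral: Fin * fa * dose / CL;  iv: dose / CL.
analytic_auc_oral <- function(p, dose_mg) {
  (1 - p$phi_lymph) * (1 - p$eh) * p$fa * dose_mg * MGNG / (p$cl * 1000)
}
analytic_auc_iv <- function(p, dose_mg) dose_mg * MGNG / (p$cl * 1000)

# Reference trapezoid, written independently of the package implementation.
ref_trapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1))
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  s
}

prepend0 <- function(p) {
  concentration_profile(c(0, p$times), c(0, p$concentrations),
                        fluid = p$fluid, route = p$route, dose = p$dose,
                        blq = c(FALSE, p$blq))
}

make_params <- function(...) {
  args <- list(fa = 0.172, phi_lymph = 0.07, eh = 0.7, ka = 0.2, klt = 0.4,
               cl = 33.6, vc = 50, k12 = 1.532, k21 = 0.2924)
  over <- list(...)
  args[names(over)] <- over
  do.call(pk_parameters, args)
}

no_flow_noise <- function() lymph_flow_model(mean_flow = 70, cv_flow = 0)
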