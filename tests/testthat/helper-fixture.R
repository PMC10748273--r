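# shared fixtures, generated once per test run
fixture_sites <- local({
  cache <- NULL
  function(seed = 1L) {
    if (seed == 1L) {
      if (is.null(cache)) cache <<- generate_study(study_fixture(), seed = 1L)
      return(cache)
    }
    generate_study(study_fixture(), seed = seed)
  }
})

# closed-form P(Er < b) for a lognormal corrected concentration folded at c0:
# Er = tr * (|X - c0| + c0) / c0,  X ~ LN(meanlog, sdlog)
folded_lnorm_er_cdf <- function(b, meanlog, sdlog, c0, tr) {
  t <- b * c0 / tr
  if (t <= c0) return(0)
  stats::plnorm(t, meanlog, sdlog) -
    stats::plnorm(max(2 * c0 - t, 0), meanlog, sdlog)
}

# analytic class probabilities of Er under the folded lognormal model
folded_lnorm_class_probs <- function(scheme, meanlog, sdlog, c0, tr) {
  below <- vapply(scheme$boundaries, folded_lnorm_er_cdf,
                  numeric(1), meanlog, sdlog, c0, tr)
  diff(c(0, below, 1))
}

# minimal single-metal toxicity bundle for targeted probabilistic tests
one_metal_tox <- function(metal = "As", tr = 10) {
  default_toxicity(tr = stats::setNames(tr, metal))
}
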