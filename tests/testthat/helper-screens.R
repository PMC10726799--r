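# The bidirectional filter can only tell direction apart in the
# weak-total-association regime: the mediator-outcome partial association is
# direction-symmetric, so the discriminating factor is the exposure's total
# association with the outcome, which must be weak while both path
# associations are strong (path z about 4.5, total z about 0.2 here).
screen_one_chain <- function(n, a, b, noise_m, seed, reverse = FALSE) {
  ch <- generate_mediation_chain(n, a = a, b = b, c_prime = 0,
                                 noise_m = noise_m, noise_y = 1, seed = seed)
  samples <- sprintf("s%05d", seq_len(n))
  if (reverse) {  # truth is microbe -> age -> metabolite
    met <- ch$data$y; age <- ch$data$m
  } else {        # truth is microbe -> metabolite -> age
    met <- ch$data$m; age <- ch$data$y
  }
  x <- ch$data$x - min(ch$data$x) + 0.01
  met <- met - min(met) + 0.01
  bidirectional_screen(
    as_abundance(matrix(x, 1, dimnames = list("mgs1", samples))),
    as_abundance(matrix(met, 1, dimnames = list("met1", samples))),
    setNames(age, samples), n_sims = 500, seed = seed)
}
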