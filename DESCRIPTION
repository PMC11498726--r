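Package: sivsou
Title: Stochastic SIVS Epidemic Model with Ornstein-Uhlenbeck Transmission Noise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a stochastic susceptible-infected-vaccinated-susceptible
    (SIVS) epidemic model in which the transmission coefficient is perturbed by
    a mean-reverting Ornstein-Uhlenbeck process and a fraction of newborns is
    vaccinated. Provides closed-form reproduction numbers and their stochastic
    extinction and persistence counterparts, disease-free and endemic
    equilibria, Milstein and exact-transition path simulation with seeded
    ensembles, extinction/persistence diagnostics on simulated paths, and the
    Gaussian stationary density around the quasi-endemic equilibrium obtained
    from the Fokker-Planck linearization, with the stationary covariance
    computed both by a direct Lyapunov solve and by an explicit transformation
    chain to companion form.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
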