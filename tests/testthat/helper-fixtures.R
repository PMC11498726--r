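g1 <- sivs_fixture("group1")
g2 <- sivs_fixture("group2")

# fixture with some parameters overridden
with_pars <- function(base, ...) {
  suppressWarnings(validate_params(utils::modifyList(unclass(base), list(...))))
}

# bare trajectory object for diagnostics that only need (times, I, ...)
fake_traj <- function(times, I, S = NULL, V = NULL, m = NULL) {
  structure(list(times = times, I = I,
                 S = if (is.null(S)) rep(1, length(times)) else S,
                 V = if (is.null(V)) rep(1, length(times)) else V,
                 m = if (is.null(m)) rep(0, length(times)) else m),
            class = "sivs_trajectory")
}
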