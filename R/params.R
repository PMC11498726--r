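#' Model parameters for the stochastic SIVS model
#'
#' Constructs and validates the ten rate constants of the SIVS model with
#' newborn vaccination and an Ornstein-Uhlenbeck (OU) perturbation of the
#' transmission coefficient.  The compartments are susceptible \eqn{S},
#' infected \eqn{I} and vaccinated \eqn{V}; vaccine immunity wanes (\eqn{V}
#' returns to \eqn{S}) and recovery returns \eqn{I} to \eqn{S}.  The effective
#' transmission coefficient is \eqn{\beta + m(t)} where \eqn{m} follows
#' \eqn{dm = -k\,m\,dt + \theta\,dB(t)}.
#'
#' @param A recruitment rate (individuals/time); must be > 0.
#' @param g fraction of newborns vaccinated, in (0, 1).
#' @param eta natural mortality rate (1/time); must be > 0.
#' @param p vaccination rate of susceptibles (1/time).
#' @param beta transmission coefficient (1/(individuals * time)).
#' @param gamma recovery rate (1/time).
#' @param alpha immunity-loss rate (1/time).
#' @param epsilon disease-induced mortality rate (1/time).
#' @param k OU reversion speed (1/time); must be > 0.
#' @param theta OU volatility intensity (1/sqrt(time)); must be >= 0.
#'
#' @details All rates must be non-negative.  The model is usually studied
#'   under the additional assumption that disease-induced mortality is smaller
#'   than the vaccination rate of susceptibles (\code{epsilon < p}); violating
#'   it is a modelling oddity rather than a mathematical error, so it raises a
#'   warning, not an error.
#'
#' @return An object of class \code{"sivs_params"}: a named list with the ten
#'   parameters.
#'
#' @examples
#' pars <- sivs_params(A = 0.5, g = 0.8, eta = 0.1, p = 0.6, beta = 0.9,
#'                     gamma = 0.3, alpha = 0.2, epsilon = 0.15,
#'                     k = 0.7, theta = 0.1)
#' reproduction_number(pars)
#' @seealso [validate_params()], [sivs_fixture()]
#' @export
sivs_params <- function(A, g, eta, p, beta, gamma, alpha, epsilon, k, theta) {
  validate_params(list(A = A, g = g, eta = eta, p = p, beta = beta,
                       gamma = gamma, alpha = alpha, epsilon = epsilon,
                       k = k, theta = theta))
}

.param_names <- c("A", "g", "eta", "p", "beta", "gamma", "alpha",
                  "epsilon", "k", "theta")

#' Validate a raw parameter mapping
#'
#' Checks a named list (or named numeric vector) of the ten model parameters
#' and returns a validated \code{"sivs_params"} object, or signals an error
#' describing the violated constraint.
#'
#' @param raw named list or numeric vector with entries \code{A, g, eta, p,
#'   beta, gamma, alpha, epsilon, k, theta}.
#' @return A \code{"sivs_params"} object.
#' @export
validate_params <- function(raw) {
  raw <- as.list(raw)
  missing <- setdiff(.param_names, names(raw))
  if (length(missing) > 0L)
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  pars <- lapply(raw[.param_names], function(x) {
    x <- as.numeric(x)
    if (length(x) != 1L || !is.finite(x)) stop("parameters must be finite scalars")
    x
  })
  names(pars) <- .param_names
  with(pars, {
    if (any(c(A, g, eta, p, beta, gamma, alpha, epsilon, k, theta) < 0))
      stop("all parameters must be non-negative")
    if (eta <= 0) stop("natural mortality rate 'eta' must be > 0")
    if (A <= 0) stop("recruitment rate 'A' must be > 0")
    if (g <= 0 || g >= 1) stop("newborn vaccination fraction 'g' must lie in (0, 1)")
    if (k <= 0) stop("OU reversion speed 'k' must be > 0")
  })
  if (pars$epsilon >= pars$p)
    warning("epsilon >= p: disease-induced mortality is not smaller than the ",
            "vaccination rate of susceptibles; the model is usually studied ",
            "with epsilon < p", call. = FALSE)
  structure(pars, class = "sivs_params")
}

#' @export
print.sivs_params <- function(x, ...) {
  cat("SIVS model parameters (OU-perturbed transmission):\n")
  vals <- unlist(x[.param_names])
  cat(paste0("  ", format(.param_names, width = 8), " = ",
             format(vals, digits = 6)), sep = "\n")
  invisible(x)
}

#' Built-in parameter fixtures
#'
#' Two standard parameter sets used throughout the documentation and tests.
#' \code{"group1"} is a sub-threshold (extinction) regime, \code{"group2"} a
#' super-threshold (persistent) regime.  Each fixture includes the OU noise
#' parameters under which the two regimes are usually illustrated
#' (\code{group1}: k = 0.65, theta = 0.14; \code{group2}: k = 0.7,
#' theta = 0.1).
#'
#' @param name \code{"group1"} or \code{"group2"}.
#' @return A \code{"sivs_params"} object.
#' @examples
#' stochastic_thresholds(sivs_fixture("group2"))
#' @export
sivs_fixture <- function(name = c("group1", "group2")) {
  name <- match.arg(name)
  raw <- switch(name,
    group1 = list(A = 0.05, g = 0.6, eta = 0.05, p = 0.2, beta = 0.5,
                  gamma = 0.2, alpha = 0.1, epsilon = 0.1,
                  k = 0.65, theta = 0.14),
    group2 = list(A = 0.5, g = 0.8, eta = 0.1, p = 0.6, beta = 0.9,
                  gamma = 0.3, alpha = 0.2, epsilon = 0.15,
                  k = 0.7, theta = 0.1))
  validate_params(raw)
}

#' Read parameters from a flat config file
#'
#' Reads a parameter set from a flat key/value file.  Two dialects are
#' accepted: a flat JSON object (parsed with \pkg{jsonlite}) or plain
#' \code{key: value} lines (one pair per line, \code{#} comments allowed).
#' Keys must be exactly \code{A, g, eta, p, beta, gamma, alpha, epsilon, k,
#' theta}.
#'
#' @param path path to the config file.
#' @return A \code{"sivs_params"} object.
#' @export
read_params_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  first <- trimws(paste(txt, collapse = " "))
  raw <- if (startsWith(first, "{")) {
    jsonlite::fromJSON(paste(txt, collapse = "\n"))
  } else {
    lines <- grep("^\\s*(#|$)", txt, invert = TRUE, value = TRUE)
    kv <- strsplit(lines, "[:=]")
    bad <- vapply(kv, length, 1L) != 2L
    if (any(bad)) stop("malformed line(s) in config file: ",
                       paste(lines[bad], collapse = "; "))
    vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
    stats::setNames(as.list(vals), trimws(vapply(kv, `[`, "", 1L)))
  }
  validate_params(raw)
}

#' A state of the stochastic SIVS system
#'
#' Bundles one point \eqn{(S, I, V, m)} of the system: the three compartment
#' sizes plus the current OU perturbation of the transmission coefficient.
#'
#' @param S,I,V compartment sizes (individuals).
#' @param m OU perturbation of the transmission coefficient (defaults to 0).
#' @return A named numeric vector of class \code{"sivs_state"}.
#' @export
sivs_state <- function(S, I, V, m = 0) {
  x <- c(S = as.numeric(S), I = as.numeric(I), V = as.numeric(V),
         m = as.numeric(m))
  if (any(!is.finite(x))) stop("state components must be finite")
  structure(x, class = "sivs_state")
}

#' Membership in the invariant region
#'
#' The region \eqn{\Gamma = \{S > 0, I > 0, V > 0, S + I + V \le A/\eta\}} is
#' positively invariant: trajectories started inside it stay inside it with
#' probability one (the OU component \eqn{m} is unconstrained).
#'
#' @param state a [sivs_state()] (or any numeric vector with named components
#'   \code{S}, \code{I}, \code{V}).
#' @param params a \code{"sivs_params"} object.
#' @return \code{TRUE} if the state lies in \eqn{\Gamma}.
#' @examples
#' in_invariant_region(sivs_state(0.6111, 0.7333, 2.5555), sivs_fixture("group2"))
#' @export
in_invariant_region <- function(state, params) {
  s <- as.numeric(state[c("S", "I", "V")])
  all(s > 0) && sum(s) <= params$A / params$eta
}

#' Sample random parameter sets in the persistent regime
#'
#' Rejection-samples parameter sets from broad uniform ranges, keeping only
#' those whose stochastic persistence number satisfies \eqn{R_{0S} > 1} and
#' whose linearization around the endemic equilibrium is Hurwitz with
#' non-degenerate transformation denominators.  Used for property-based
#' checks of the stationary-covariance algebra.
#'
#' @param n number of parameter sets to return.
#' @param seed RNG seed (integer).
#' @return A list of \code{n} \code{"sivs_params"} objects.
#' @export
sample_persistent_params <- function(n, seed = 1L) {
  set.seed(seed)
  out <- vector("list", n)
  got <- 0L
  tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > 200000L) stop("rejection sampling failed to find enough persistent parameter sets")
    raw <- list(A = stats::runif(1, 0.2, 1.5), g = stats::runif(1, 0.2, 0.9),
                eta = stats::runif(1, 0.05, 0.3), p = stats::runif(1, 0.1, 0.8),
                beta = stats::runif(1, 0.5, 2.5), gamma = stats::runif(1, 0.1, 0.5),
                alpha = stats::runif(1, 0.1, 0.5), epsilon = stats::runif(1, 0.01, 0.25),
                k = stats::runif(1, 0.2, 1.5), theta = stats::runif(1, 0.02, 0.3))
    if (raw$epsilon >= raw$p) next
    pars <- validate_params(raw)
    th <- stochastic_thresholds(pars)
    if (th$R0S <= 1) next
    lin <- linearize(pars)
    cc <- characteristic_coefficients(lin)
    if (!cc$hurwitz) next
    # guard the chain's denominators away from degeneracy
    if (abs(lin$a12 + lin$a21 - lin$a11) < 1e-3) next
    got <- got + 1L
    out[[got]] <- pars
  }
  out
}
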