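#' Standard 21-state lambda schedule
#'
#' The alchemical transformation is controlled by a coupling parameter lambda
#' running from 0 to 1 in increments of 0.05 (21 states, 20 adjacent pairs).
#'
#' @return numeric vector of lambda values
#' @export
lambda_schedule <- function() seq(0, 1, by = 0.05)

#' Generate Crooks-consistent bidirectional perturbation samples for one leg
#'
#' For each adjacent lambda pair with ground-truth free-energy increment
#' dg (kBT), forward perturbation energies dU are drawn from
#' N(dg + sigma^2/2, sigma^2) and backward (reverse-direction) energies from
#' N(-dg + sigma^2/2, sigma^2).  These two Gaussians satisfy the Crooks
#' fluctuation relation P_F(w) / P_R(-w) = exp(w - dg), so the Bennett
#' acceptance ratio applied to the pair recovers dg in expectation.
#'
#' @param increments ground-truth per-pair free-energy increments (kBT), one
#'   per adjacent lambda pair
#' @param environment `"protein"` or `"solution"`
#' @param sigma Gaussian work spread (kBT), > 0
#' @param n_per_pair samples per direction per pair (>= 2)
#' @param seed integer seed; per-pair streams are derived deterministically
#' @param lambdas lambda schedule (strictly increasing, endpoints 0 and 1)
#' @return object of class `alch_leg` with elements `lambdas`, `environment`,
#'   `forward`/`backward` (lists of numeric vectors, one per pair) and the
#'   planted `increments`
#' @export
sample_alchemical <- function(increments, environment = c("protein", "solution"),
                              sigma = 0.5, n_per_pair = 5000, seed = 20190327,
                              lambdas = lambda_schedule()) {
  environment <- match.arg(environment)
  if (sigma <= 0) stop("sigma must be > 0")
  if (n_per_pair < 2) stop("need >= 2 samples per direction")
  if (is.unsorted(lambdas, strictly = TRUE) ||
      abs(lambdas[1]) > 1e-12 || abs(lambdas[length(lambdas)] - 1) > 1e-12)
    stop("lambda schedule must increase strictly from 0 to 1")
  n_pair <- length(lambdas) - 1
  if (length(increments) != n_pair)
    stop("need one increment per adjacent lambda pair (", n_pair, "), got ",
         length(increments))
  env_off <- if (environment == "protein") 0L else 1L
  fwd <- vector("list", n_pair); bwd <- vector("list", n_pair)
  for (i in seq_len(n_pair)) {
    set.seed(derive_seed(seed, 2L * i + env_off))
    fwd[[i]] <- stats::rnorm(n_per_pair, mean = increments[i] + sigma^2 / 2,
                             sd = sigma)
    bwd[[i]] <- stats::rnorm(n_per_pair, mean = -increments[i] + sigma^2 / 2,
                             sd = sigma)
  }
  structure(list(lambdas = lambdas, environment = environment,
                 forward = fwd, backward = bwd, increments = increments,
                 sigma = sigma),
            class = "alch_leg")
}

#' @export
print.alch_leg <- function(x, ...) {
  cat(sprintf("<alch_leg> %s leg, %d lambda states, %d samples/direction/pair\n",
              x$environment, length(x$lambdas), length(x$forward[[1]])))
  cat(sprintf("  planted leg total: %.3f kBT\n", sum(x$increments)))
  invisible(x)
}

#' Packaged alchemical cycle fixtures
#'
#' Ground-truth per-pair increments for the protein and solution legs of the
#' rATP -> rGTP and rATP -> dATP transformations.  The protein-minus-solution
#' difference equals the reported relative binding free energies (+3 kBT for
#' rGTP, -1 kBT for dATP); the split between legs is a fixture convention
#' (solution legs sum to zero with non-trivial per-pair structure).
#'
#' @param species `"rGTP"` or `"dATP"`
#' @param file fixture file; defaults to the packaged one
#' @return list with `protein` and `solution` increment vectors (kBT)
#' @export
packaged_cycle_increments <- function(species = c("rGTP", "dATP"), file = NULL) {
  species <- match.arg(species)
  if (is.null(file))
    file <- system.file("extdata", "alchemical_cycles.cfg", package = "polfid",
                        mustWork = TRUE)
  cfg <- read_kv_config(file)
  sect <- cfg[[species]]
  if (is.null(sect)) stop("no cycle fixture for ", species)
  list(protein = as.numeric(strsplit(trimws(sect[["protein"]]), "\\s+")[[1]]),
       solution = as.numeric(strsplit(trimws(sect[["solution"]]), "\\s+")[[1]]))
}

#' Generate both legs of a packaged alchemical cycle
#'
#' @param species `"rGTP"` or `"dATP"`
#' @param sigma,n_per_pair,seed passed to [sample_alchemical()]
#' @return list with `protein` and `solution` `alch_leg` objects
#' @export
sample_cycle <- function(species = c("rGTP", "dATP"), sigma = 0.5,
                         n_per_pair = 5000, seed = 20190327) {
  species <- match.arg(species)
  inc <- packaged_cycle_increments(species)
  list(protein = sample_alchemical(inc$protein, "protein", sigma = sigma,
                                   n_per_pair = n_per_pair,
                                   seed = derive_seed(seed, 1001L)),
       solution = sample_alchemical(inc$solution, "solution", sigma = sigma,
                                    n_per_pair = n_per_pair,
                                    seed = derive_seed(seed, 2002L)))
}
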