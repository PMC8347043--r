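#' Chi-square statistic of an FID model
#'
#' sum_i ((y_i - F(t_i)) / sigma_i)^2, with unit sigma when the signal
#' carries no per-point uncertainties.
#'
#' @param signal list with `times`, `amplitudes`, optional `sigma`
#' @param model_id 1 or 2
#' @param params a [relax_params()]
#' @return chi-square value
#' @export
fid_chi2 <- function(signal, model_id, params) {
  .fid_chi2(signal, model_id, params)
}

## order-sensitive checksum of the data a chain was run on
.data_hash <- function(signal) {
  raw <- serialize(list(signal$times, signal$amplitudes, signal$sigma),
                   connection = NULL, version = 2)
  sum(as.double(as.integer(raw)) * (seq_along(raw) %% 251 + 1)) %% 2147483647
}

#' Metropolis sampling of a chi-square landscape
#'
#' Random-walk Metropolis with Gaussian proposals and acceptance probability
#' min(1, exp(-delta chi^2 / 2)) — the Gaussian-error likelihood
#' exp(-chi^2/2). Proposals falling outside the box bounds are rejected.
#' Proposal scales are adapted towards ~30% acceptance during burn-in only,
#' so the retained chain is a fixed-kernel Metropolis sample. Bit-for-bit
#' reproducible for a fixed seed.
#'
#' @param chi2_fun function mapping a named parameter vector to chi-square
#' @param init named initial parameter vector
#' @param lower,upper named bound vectors
#' @param steps total chain length
#' @param burn_in steps discarded (and used for adaptation); default 20%
#' @param proposal_sd per-parameter proposal SDs; default 2% of the bound
#'   range (capped for unbounded parameters)
#' @param seed integer seed
#' @param data_hash optional checksum tying the chain to its data
#' @return object of class `mcmc_chain`: `samples` (steps x parameters),
#'   `chi2_values`, `acceptance_rate` (post burn-in), `burn_in`, `chi2_min`,
#'   `best`, `n_free`, `data_hash`, `seed`
#' @export
metropolis_chain <- function(chi2_fun, init, lower, upper,
                             steps = 50000, burn_in = floor(steps * 0.2),
                             proposal_sd = NULL, seed = 1, data_hash = 0) {
  stopifnot(steps > burn_in, length(init) >= 1,
            all(names(lower) == names(init)), all(names(upper) == names(init)))
  finite_range <- pmin(upper, 1e4) - pmax(lower, -1e4)
  if (is.null(proposal_sd)) proposal_sd <- 0.02 * finite_range
  stopifnot(all(proposal_sd > 0))
  v <- pmin(pmax(init, lower), upper)
  k <- length(v)
  chi2_cur <- chi2_fun(v)

  set.seed(seed)
  samples <- matrix(NA_real_, nrow = steps, ncol = k,
                    dimnames = list(NULL, names(init)))
  chi2_values <- numeric(steps)
  accepted_post <- 0L
  acc_win <- 0L; win_len <- 0L
  for (i in seq_len(steps)) {
    prop <- v + stats::rnorm(k, 0, proposal_sd)
    acc <- FALSE
    if (all(prop >= lower & prop <= upper)) {
      chi2_prop <- chi2_fun(prop)
      if (stats::runif(1) < exp(-(chi2_prop - chi2_cur) / 2)) {
        v <- prop; chi2_cur <- chi2_prop; acc <- TRUE
      }
    }
    if (acc && i > burn_in) accepted_post <- accepted_post + 1L
    acc_win <- acc_win + acc; win_len <- win_len + 1L
    samples[i, ] <- v
    chi2_values[i] <- chi2_cur
    ## adapt proposal scale towards ~30% acceptance, burn-in only; the
    ## factor is clipped so a dead window shrinks the scale by at most 3x
    if (i <= burn_in && win_len >= 50L) {
      fac <- exp(2 * (acc_win / win_len - 0.3))
      proposal_sd <- proposal_sd * min(max(fac, 1 / 3), 3)
      acc_win <- 0L; win_len <- 0L
    }
  }
  n_post <- steps - burn_in
  if (accepted_post == 0L)
    warning("zero acceptance after burn-in; reduce proposal_sd (try a tenth of the current scale)")
  best <- which.min(chi2_values)
  structure(
    list(samples = samples, chi2_values = chi2_values,
         acceptance_rate = accepted_post / n_post,
         burn_in = burn_in, chi2_min = chi2_values[best],
         best = samples[best, ], n_free = k,
         data_hash = data_hash, seed = seed),
    class = "mcmc_chain"
  )
}

#' Bayesian chi-square exploration of an FID relaxation model
#'
#' Runs [metropolis_chain()] on the chi-square landscape of an FID model,
#' yielding parameter probability distributions, the chi-square distribution,
#' and the minimal chi-square used for model selection.
#'
#' @param signal an FID signal (see [gen_fid()])
#' @param model_id 1 or 2
#' @param init [relax_params()] starting point (e.g. a [fit_fid()] estimate)
#' @param lower,upper optional named bound overrides (defaults as in
#'   [fit_fid()])
#' @param steps,burn_in,proposal_sd,seed passed to [metropolis_chain()]
#' @return an `mcmc_chain` with extra fields `model_id` and `best_params`
#' @export
run_mcmc <- function(signal, model_id, init, lower = NULL, upper = NULL,
                     steps = 50000, burn_in = floor(steps * 0.2),
                     proposal_sd = NULL, seed = 1) {
  stopifnot(inherits(init, "relax_params"))
  bounds <- .fid_default_bounds(model_id, signal)
  if (!is.null(lower)) bounds$lower[names(lower)] <- lower
  if (!is.null(upper)) bounds$upper[names(upper)] <- upper
  chi2_fun <- function(v) .fid_chi2(signal, model_id, .vec_to_relax(v, model_id))
  chain <- metropolis_chain(chi2_fun, .relax_to_vec(init, model_id),
                            bounds$lower, bounds$upper, steps = steps,
                            burn_in = burn_in, proposal_sd = proposal_sd,
                            seed = seed, data_hash = .data_hash(signal))
  chain$model_id <- model_id
  chain$best_params <- .vec_to_relax(chain$best, model_id)
  chain
}

#' Marginal posterior histogram of one chain parameter
#'
#' Post-burn-in histogram using the Freedman-Diaconis bin rule (single bin
#' for a constant chain). Probability masses sum to one; densities integrate
#' to one.
#'
#' @param chain an `mcmc_chain`
#' @param parameter parameter name (column of the chain) or `"chi2"`
#' @return list with `breaks`, `mids`, `density`, `mass`, `mode`
#' @export
marginal_pdf <- function(chain, parameter) {
  stopifnot(inherits(chain, "mcmc_chain"))
  post <- (chain$burn_in + 1):length(chain$chi2_values)
  if (length(post) == 0) stop("no post-burn-in samples")
  x <- if (identical(parameter, "chi2")) chain$chi2_values[post]
       else chain$samples[post, parameter]
  rng <- range(x)
  if (diff(rng) == 0) {
    eps <- max(abs(rng[1]), 1) * 1e-8
    breaks <- c(rng[1] - eps, rng[1] + eps)
  } else {
    iqr <- stats::IQR(x)
    bw <- if (iqr > 0) 2 * iqr / length(x)^(1 / 3) else diff(rng) / 30
    nb <- max(1, ceiling(diff(rng) / bw))
    breaks <- seq(rng[1], rng[2], length.out = nb + 1)
  }
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  mass <- h$counts / sum(h$counts)
  list(breaks = h$breaks, mids = h$mids,
       density = mass / diff(h$breaks), mass = mass,
       mode = h$mids[which.max(h$counts)])
}

#' Compare two models by their chi-square chains
#'
#' Reports the minimal and most probable (histogram-mode) chi-square of each
#' chain and selects the model with the smaller minimal chi-square; on a tie
#' the model with fewer free parameters wins.
#'
#' @param chain_1,chain_2 `mcmc_chain` objects run on the same data
#' @param tie_tol chi-square difference treated as a tie
#' @return list with per-model `chi2_min`, `chi2_mode`, `n_free`, and
#'   `selected` (1 or 2, index into the argument order)
#' @export
model_compare <- function(chain_1, chain_2, tie_tol = 1e-9) {
  stopifnot(inherits(chain_1, "mcmc_chain"), inherits(chain_2, "mcmc_chain"))
  if (chain_1$data_hash != chain_2$data_hash)
    stop("chains were not run on the same data")
  mode1 <- marginal_pdf(chain_1, "chi2")$mode
  mode2 <- marginal_pdf(chain_2, "chi2")$mode
  d <- chain_1$chi2_min - chain_2$chi2_min
  selected <- if (abs(d) <= tie_tol) {
    if (chain_1$n_free <= chain_2$n_free) 1L else 2L
  } else if (d < 0) 1L else 2L
  list(
    chi2_min = c(chain_1$chi2_min, chain_2$chi2_min),
    chi2_mode = c(mode1, mode2),
    n_free = c(chain_1$n_free, chain_2$n_free),
    model_id = c(chain_1$model_id, chain_2$model_id),
    selected = selected
  )
}
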