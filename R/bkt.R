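#' Bayesian Knowledge Tracing parameters
#'
#' The two-state hidden Markov model behind the learner model: a skill is
#' either unknown or known. `p_L0` is the prior probability of starting in
#' the known state, `p_T` the per-opportunity learning (unknown -> known)
#' probability, `p_S` the slip probability (wrong answer despite mastery)
#' and `p_G` the guess probability (right answer without mastery). The
#' model has no forgetting: known -> unknown has probability 0. The
#' identifiability guard `p_S + p_G < 1` keeps "knowing" better than
#' "guessing".
#'
#' @param p_L0,p_T,p_S,p_G Probabilities in `[0, 1]`.
#' @return An object of class `bkt_params` (a named list).
#' @export
bkt_params <- function(p_L0, p_T, p_S, p_G) {
  p <- c(p_L0 = p_L0, p_T = p_T, p_S = p_S, p_G = p_G)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("bkt_params: all four parameters must lie in [0, 1]")
  }
  structure(as.list(p), class = "bkt_params")
}

#' @export
print.bkt_params <- function(x, ...) {
  cat(sprintf("<bkt_params> p_L0=%.3f p_T=%.3f p_S=%.3f p_G=%.3f\n",
              x$p_L0, x$p_T, x$p_S, x$p_G))
  invisible(x)
}

#' One Bayesian Knowledge Tracing update
#'
#' Evidence step (Bayes):
#' after a correct response,
#' `p* = p(1-p_S) / (p(1-p_S) + (1-p) p_G)`;
#' after an incorrect response,
#' `p* = p p_S / (p p_S + (1-p)(1-p_G))`.
#' Learning step: `p' = p* + (1-p*) p_T`.
#'
#' @param params A [bkt_params()].
#' @param p Prior mastery probability in `[0, 1]`.
#' @param correct Logical (or 0/1): was the observed response correct?
#' @return Posterior mastery probability in `[0, 1]`.
#' @export
bkt_update <- function(params, p, correct) {
  stopifnot(inherits(params, "bkt_params"), p >= 0, p <= 1)
  correct <- as.logical(correct)
  num <- if (correct) p * (1 - params$p_S) else p * params$p_S
  den <- if (correct) {
    p * (1 - params$p_S) + (1 - p) * params$p_G
  } else {
    p * params$p_S + (1 - p) * (1 - params$p_G)
  }
  if (den == 0) {
    stop("bkt_update: observation has probability zero under the model ",
         "(impossible evidence)")
  }
  p_star <- num / den
  p_star + (1 - p_star) * params$p_T
}

# observation probabilities for the two states (unknown, known)
bkt_emission <- function(params, correct) {
  if (correct) c(params$p_G, 1 - params$p_S)
  else c(1 - params$p_G, params$p_S)
}

#' Likelihood of a binary observation sequence under the BKT model
#'
#' Forward-algorithm likelihood of the sequence under the two-state HMM
#' with transitions unknown -> known only. Equal (to numerical precision)
#' to the sum over all `2^T` hidden-state paths.
#'
#' @param params A [bkt_params()].
#' @param observations Vector of 0/1 (or logical), length >= 1.
#' @return The sequence probability.
#' @export
bkt_sequence_likelihood <- function(params, observations) {
  stopifnot(inherits(params, "bkt_params"), length(observations) >= 1)
  obs <- check_binary(observations, "bkt_sequence_likelihood")
  # states: 1 = unknown, 2 = known; A[s, s']
  A <- matrix(c(1 - params$p_T, params$p_T, 0, 1), 2, 2, byrow = TRUE)
  alpha <- c(1 - params$p_L0, params$p_L0) * bkt_emission(params, obs[1])
  for (t in seq_along(obs)[-1]) {
    alpha <- drop(alpha %*% A) * bkt_emission(params, obs[t])
  }
  sum(alpha)
}

check_binary <- function(x, where) {
  if (is.logical(x)) x <- as.integer(x)
  if (!is.numeric(x) || any(is.na(x)) || !all(x %in% c(0, 1))) {
    stop(where, ": observations must be binary (0/1)")
  }
  as.integer(x)
}

# scaled forward-backward for one sequence; returns gamma (T x 2),
# xi sums for the unknown->unknown and unknown->known transitions, and
# the log-likelihood. States: 1 unknown, 2 known.
bkt_forward_backward <- function(params, obs) {
  T_ <- length(obs)
  A <- matrix(c(1 - params$p_T, params$p_T, 0, 1), 2, 2, byrow = TRUE)
  B <- t(vapply(obs, function(o) bkt_emission(params, o), numeric(2))) # T x 2
  alpha <- matrix(0, T_, 2); scale <- numeric(T_)
  a <- c(1 - params$p_L0, params$p_L0) * B[1, ]
  scale[1] <- sum(a)
  alpha[1, ] <- a / scale[1]
  if (T_ > 1) for (t in 2:T_) {
    a <- drop(alpha[t - 1, ] %*% A) * B[t, ]
    scale[t] <- sum(a)
    alpha[t, ] <- a / scale[t]
  }
  beta <- matrix(0, T_, 2)
  beta[T_, ] <- 1
  if (T_ > 1) for (t in (T_ - 1):1) {
    beta[t, ] <- drop(A %*% (B[t + 1, ] * beta[t + 1, ])) / scale[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi_uu <- 0; xi_uk <- 0
  if (T_ > 1) for (t in 1:(T_ - 1)) {
    den <- scale[t + 1]
    xi_uu <- xi_uu + alpha[t, 1] * A[1, 1] * B[t + 1, 1] * beta[t + 1, 1] / den
    xi_uk <- xi_uk + alpha[t, 1] * A[1, 2] * B[t + 1, 2] * beta[t + 1, 2] / den
  }
  list(gamma = gamma, xi_uu = xi_uu, xi_uk = xi_uk, loglik = sum(log(scale)))
}

as_sequence_list <- function(sequences) {
  if (is.data.frame(sequences)) {
    stopifnot(all(c("learner", "opportunity", "correct") %in% names(sequences)))
    sequences <- sequences[order(sequences$learner, sequences$opportunity), ]
    sequences <- split(as.integer(sequences$correct), sequences$learner)
  }
  lapply(sequences, check_binary, where = "bkt_fit")
}

#' Fit BKT parameters by expectation-maximization
#'
#' Baum-Welch on the two-state no-forgetting HMM, run from several seeded
#' random starts; the start with the best final log-likelihood wins.
#' The log-likelihood is non-decreasing across EM iterations. Fits where
#' the identifiability guard `p_S + p_G < 1` fails are label-switched
#' (states relabeled, which maps `p_S -> 1 - p_G'` etc.) before
#' comparison.
#'
#' @param sequences Either a list of binary vectors (one per learner) or
#'   a long data frame with columns `learner`, `opportunity`, `correct`
#'   as produced by [simulate_learners()]. At least two sequences and
#'   both outcomes must be present.
#' @param seed Integer seed for the random restarts.
#' @param restarts Number of random initializations (default 5).
#' @param max_iter Maximum EM iterations per start (default 200).
#' @param tol Stop when the log-likelihood gain drops below `tol`
#'   (default 1e-6).
#' @return An object of class `bkt_fit`: `params` ([bkt_params()]),
#'   `loglik`, `trace` (tibble of per-iteration log-likelihoods of the
#'   winning start), `n_sequences`, `n_observations`, `iterations`,
#'   `converged`.
#' @export
bkt_fit <- function(sequences, seed = 1L, restarts = 5, max_iter = 200,
                    tol = 1e-6) {
  seqs <- as_sequence_list(sequences)
  if (length(seqs) < 2) stop("bkt_fit: need at least two sequences")
  allobs <- unlist(seqs)
  if (length(unique(allobs)) < 2) {
    stop("bkt_fit: all observations identical; parameters are not identifiable")
  }

  em_run <- function(theta) {
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      fb <- lapply(seqs, function(o) bkt_forward_backward(theta, o))
      ll <- sum(vapply(fb, `[[`, numeric(1), "loglik"))
      trace <- c(trace, ll)
      # M-step
      g1 <- vapply(fb, function(f) f$gamma[1, 2], numeric(1))
      p_L0 <- mean(g1)
      xi_uk <- sum(vapply(fb, `[[`, numeric(1), "xi_uk"))
      xi_uu <- sum(vapply(fb, `[[`, numeric(1), "xi_uu"))
      p_T <- if (xi_uk + xi_uu > 0) xi_uk / (xi_uk + xi_uu) else theta$p_T
      num_s <- 0; den_s <- 0; num_g <- 0; den_g <- 0
      for (j in seq_along(seqs)) {
        gk <- fb[[j]]$gamma[, 2]; gu <- fb[[j]]$gamma[, 1]
        o <- seqs[[j]]
        num_s <- num_s + sum(gk * (1 - o)); den_s <- den_s + sum(gk)
        num_g <- num_g + sum(gu * o);       den_g <- den_g + sum(gu)
      }
      p_S <- if (den_s > 0) num_s / den_s else theta$p_S
      p_G <- if (den_g > 0) num_g / den_g else theta$p_G
      clip <- function(x) min(max(x, 1e-6), 1 - 1e-6)
      new_theta <- bkt_params(clip(p_L0), clip(p_T), clip(p_S), clip(p_G))
      done <- it > 1 && (trace[it] - trace[it - 1]) < tol
      theta <- new_theta
      if (done) break
    }
    list(theta = theta, trace = trace,
         converged = length(trace) < max_iter ||
           (length(trace) > 1 && diff(utils::tail(trace, 2)) < tol))
  }

  withr::local_seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- bkt_params(stats::runif(1, 0.05, 0.6), stats::runif(1, 0.05, 0.6),
                       stats::runif(1, 0.05, 0.35), stats::runif(1, 0.05, 0.35))
    run <- em_run(init)
    # label switching: if the guard fails, the "known" state is acting as
    # "unknown"; swapping states gives the equivalent canonical solution
    th <- run$theta
    if (th$p_S + th$p_G >= 1) {
      run$theta <- bkt_params(1 - th$p_L0, th$p_T, 1 - th$p_G, 1 - th$p_S)
    }
    if (is.null(best) || utils::tail(run$trace, 1) > utils::tail(best$trace, 1)) {
      best <- run
    }
  }

  structure(
    list(params = best$theta,
         loglik = utils::tail(best$trace, 1),
         trace = tibble::tibble(iteration = seq_along(best$trace),
                                loglik = best$trace),
         n_sequences = length(seqs),
         n_observations = length(allobs),
         iterations = length(best$trace),
         converged = best$converged),
    class = "bkt_fit"
  )
}

#' @export
print.bkt_fit <- function(x, ...) {
  cat(sprintf("<bkt_fit> %d sequences, %d observations, logLik %.2f\n",
              x$n_sequences, x$n_observations, x$loglik))
  print(x$params)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted BKT model
#'
#' @param x A `bkt_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @method tidy bkt_fit
#' @export
tidy.bkt_fit <- function(x, ...) {
  tibble::tibble(term = c("p_L0", "p_T", "p_S", "p_G"),
                 estimate = c(x$params$p_L0, x$params$p_T,
                              x$params$p_S, x$params$p_G))
}

#' One-row summary of a fitted BKT model
#'
#' @param x A `bkt_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `n_sequences`, `n_observations`,
#'   `iterations`, `converged`.
#' @method glance bkt_fit
#' @export
glance.bkt_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_sequences = x$n_sequences,
                 n_observations = x$n_observations,
                 iterations = x$iterations, converged = x$converged)
}
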