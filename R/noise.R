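#' Specify the active noise type
#'
#' A noise specification bundles which noise type acts during a simulation,
#' its level `nu`, and the distribution family of the deviations.
#' `nu` is the *standard deviation* of the zero-mean Gaussian deviations
#' (or the half-width of the bounded uniform alternative); for exogenous
#' noise it additionally plays the role of the per-step jump probability
#' `omega = nu`, so it must then not exceed 1.
#'
#' @param type one of `"none"`, `"ambiguity"`, `"selectivity"`,
#'   `"adaptation"`, `"exogenous"`.
#' @param level noise level `nu >= 0`. `level = 0` is behaviourally
#'   identical to `type = "none"`.
#' @param distribution `"gaussian"` (deviations `N(0, nu)`) or
#'   `"bounded_uniform"` (deviations `U[-nu, nu]`).
#' @return an object of class `noise_spec`.
#' @export
#' @examples
#' noise_spec("ambiguity", 0.13)
noise_spec <- function(type = c("none", "ambiguity", "selectivity",
                                "adaptation", "exogenous"),
                       level = 0,
                       distribution = c("gaussian", "bounded_uniform")) {
  type <- match.arg(type)
  distribution <- match.arg(distribution)
  if (!is.numeric(level) || length(level) != 1L || is.na(level) || level < 0)
    stop("noise `level` must be a single non-negative number", call. = FALSE)
  if (type == "exogenous" && level > 1)
    stop("exogenous noise level doubles as a probability (omega = nu) and ",
         "must not exceed 1", call. = FALSE)
  structure(list(type = type, level = as.numeric(level),
                 distribution = distribution),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("<noise_spec> type=%s level=%g distribution=%s\n",
              x$type, x$level, x$distribution))
  invisible(x)
}

# zero-mean deviations, one per element requested
draw_deviation <- function(k, nu, distribution) {
  if (distribution == "gaussian") rnorm(k) * nu else -nu + 2 * nu * runif(k)
}

# additive deviation around `anchor`, resampled until the result lies in
# [0,1]; vectorized, with per-call attempt cap (defensive: for anchors in
# [0,1] acceptance probability is always >= some fixed bound, so the cap is
# unreachable in practice)
rtrunc_add <- function(anchor, nu, distribution = "gaussian",
                       max_attempts = 1e6) {
  if (any(anchor < 0 | anchor > 1))
    stop("anchor opinion outside [0,1]", call. = FALSE)
  if (nu == 0) return(anchor)
  out <- anchor + draw_deviation(length(anchor), nu, distribution)
  bad <- which(out < 0 | out > 1)
  attempts <- 1L
  while (length(bad)) {
    if (attempts >= max_attempts)
      stop("truncated-noise resampling exceeded the attempt cap",
           call. = FALSE)
    out[bad] <- anchor[bad] + draw_deviation(length(bad), nu, distribution)
    bad <- bad[out[bad] < 0 | out[bad] > 1]
    attempts <- attempts + 1L
  }
  out
}

#' Bounded-confidence pair update
#'
#' The deterministic Deffuant assimilation rule: the receiver moves a
#' fraction `mu` toward the message if and only if the message lies within
#' the confidence bound `epsilon` of its own opinion (non-strict
#' comparison); otherwise the opinion is unchanged.
#'
#' @param x_i receiver opinion(s) in \[0,1\].
#' @param m_j message(s) in \[0,1\] (the sender's opinion, possibly
#'   perturbed by ambiguity noise).
#' @param epsilon confidence bound in \[0,1\].
#' @param mu convergence speed in (0, 0.5\].
#' @return updated opinion(s); always a convex combination, hence in \[0,1\].
#' @export
#' @examples
#' bc_pair_update(0.5, 0.6, epsilon = 0.2, mu = 0.5) # 0.55
#' bc_pair_update(0.1, 0.9, epsilon = 0.2, mu = 0.5) # unchanged
bc_pair_update <- function(x_i, m_j, epsilon, mu) {
  if (any(x_i < 0 | x_i > 1)) stop("x_i outside [0,1]", call. = FALSE)
  if (any(m_j < 0 | m_j > 1)) stop("m_j outside [0,1]", call. = FALSE)
  if (epsilon < 0 || epsilon > 1) stop("epsilon outside [0,1]", call. = FALSE)
  if (mu <= 0 || mu > 0.5) stop("mu outside (0, 0.5]", call. = FALSE)
  ifelse(abs(m_j - x_i) <= epsilon, x_i + mu * (m_j - x_i), x_i)
}

#' Draw an ambiguous message
#'
#' Ambiguity noise acts on the communicated message: the receiver sees the
#' sender's opinion plus a zero-mean deviation, resampled until the message
#' lies in the opinion space \[0,1\] (a truncated distribution by
#' rejection; never clipped). A sender at the boundary `x = 1` therefore
#' emits messages from a half-normal distribution with mean
#' `1 - nu * sqrt(2/pi)`.
#'
#' @param x_j sender opinion(s) in \[0,1\].
#' @param nu noise level (standard deviation of the deviation); `nu = 0`
#'   returns `x_j` exactly, consuming no random numbers.
#' @param distribution `"gaussian"` or `"bounded_uniform"`.
#' @param max_attempts defensive resampling cap.
#' @return message(s) in \[0,1\], one per element of `x_j`.
#' @export
draw_ambiguous_message <- function(x_j, nu, distribution = "gaussian",
                                   max_attempts = 1e6) {
  if (nu < 0) stop("nu must be non-negative", call. = FALSE)
  rtrunc_add(x_j, nu, distribution, max_attempts)
}

#' Selectivity acceptance draw
#'
#' Selectivity noise perturbs the confidence bound itself: a fresh
#' deviation is drawn per interaction and the partner is accepted iff the
#' opinion gap does not exceed `epsilon` plus that deviation. A negative
#' effective bound rejects every partner, including an identical one.
#'
#' @param x_i,x_j the two opinions in \[0,1\] (vectorized in parallel).
#' @param epsilon confidence bound.
#' @param nu noise level; `nu = 0` draws nothing and reduces to the
#'   deterministic bound.
#' @param distribution `"gaussian"` or `"bounded_uniform"`.
#' @return logical vector: accept the interaction?
#' @export
accept_selectivity <- function(x_i, x_j, epsilon, nu,
                               distribution = "gaussian") {
  if (any(x_i < 0 | x_i > 1) || any(x_j < 0 | x_j > 1))
    stop("opinions outside [0,1]", call. = FALSE)
  if (nu < 0) stop("nu must be non-negative", call. = FALSE)
  k <- max(length(x_i), length(x_j))
  xi <- if (nu > 0) draw_deviation(k, nu, distribution) else 0
  abs(x_j - x_i) <= epsilon + xi
}

#' Adaptation noise shift
#'
#' Adaptation noise perturbs the receiver's opinion *after* an accepted
#' interaction: the deterministic BC result is shifted by a zero-mean
#' deviation, resampled until the posterior opinion stays in \[0,1\].
#'
#' @param x_post the deterministic post-interaction opinion(s) in \[0,1\].
#' @param nu noise level; `nu = 0` returns `x_post` exactly.
#' @param distribution `"gaussian"` or `"bounded_uniform"`.
#' @param max_attempts defensive resampling cap.
#' @return shifted opinion(s) in \[0,1\].
#' @export
adaptation_shift <- function(x_post, nu, distribution = "gaussian",
                             max_attempts = 1e6) {
  if (nu < 0) stop("nu must be non-negative", call. = FALSE)
  rtrunc_add(x_post, nu, distribution, max_attempts)
}

#' Apply exogenous opinion jumps
#'
#' Exogenous noise acts outside the social interaction: once per time step,
#' each agent independently jumps with probability `omega = nu` by a
#' zero-mean deviation of scale `nu`, resampled so the opinion stays in
#' \[0,1\]. The draw order (one binomial count, a partial Fisher-Yates
#' selection of the jumpers, then one truncated deviation per jumper)
#' matches the compiled engine draw-for-draw.
#'
#' @param opinions opinion vector in \[0,1\].
#' @param nu jump probability and amplitude scale, in \[0,1\];
#'   `nu = 0` returns the input unchanged, consuming no random numbers.
#' @param distribution `"gaussian"` or `"bounded_uniform"`.
#' @return perturbed opinion vector.
#' @export
apply_exogenous_jumps <- function(opinions, nu, distribution = "gaussian") {
  if (nu < 0 || nu > 1)
    stop("exogenous nu must lie in [0,1] (it is also a probability)",
         call. = FALSE)
  if (any(opinions < 0 | opinions > 1))
    stop("opinions outside [0,1]", call. = FALSE)
  if (nu == 0) return(opinions)
  n <- length(opinions)
  nj <- rbinom(1L, n, nu)
  if (nj > 0) {
    idx <- seq_len(n)
    for (l in seq_len(nj)) {
      r <- l + floor(runif(1) * (n - l + 1))
      tmp <- idx[l]; idx[l] <- idx[r]; idx[r] <- tmp
    }
    for (l in seq_len(nj)) {
      a <- idx[l]
      opinions[a] <- rtrunc_add(opinions[a], nu, distribution)
    }
  }
  opinions
}
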