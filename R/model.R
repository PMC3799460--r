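#' Box-convolved-with-Gaussian edge profile
#'
#' Evaluates the along-channel intensity profile of a uniformly labelled,
#' channel-stretched molecule imaged through a Gaussian point-spread
#' function: a box of width `width` centred at `center`, convolved with a
#' Gaussian of standard deviation `sigma`. The closed form is a difference
#' of two error functions,
#' \deqn{m(x) = b + \frac{A}{2}\left[\mathrm{erf}\!\left(\frac{x-c+w/2}{\sqrt{2}\sigma}\right)
#'   - \mathrm{erf}\!\left(\frac{x-c-w/2}{\sqrt{2}\sigma}\right)\right].}
#' This is both the forward model of the simulator and the fit model of
#' [fit_frame()].
#'
#' @param x positions at which to evaluate (same units as `center`, `width`,
#'   `sigma`; pixels by convention, with pixel centres at index + 0.5).
#' @param center box centre \eqn{c}.
#' @param width box width \eqn{w} (molecule extension), must be > 0.
#' @param plateau plateau amplitude \eqn{A} above background.
#' @param background baseline \eqn{b}.
#' @param sigma Gaussian blur standard deviation \eqn{\sigma} > 0.
#' @return numeric vector of model values, same length as `x`.
#' @examples
#' x <- seq_len(64) - 0.5
#' y <- box_erf_profile(x, center = 32, width = 16, plateau = 100,
#'                      background = 5, sigma = 2)
#' @export
box_erf_profile <- function(x, center, width, plateau, background, sigma) {
  stopifnot(width > 0, sigma > 0)
  # erf((u)/(sqrt(2) sigma)) = 2*pnorm(u/sigma) - 1, so A/2*(erf - erf)
  # collapses to A*(Phi(z1) - Phi(z2))
  z1 <- (x - center + width / 2) / sigma
  z2 <- (x - center - width / 2) / sigma
  background + plateau * (stats::pnorm(z1) - stats::pnorm(z2))
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-item seed derived from a master seed; kept < 2^31.
derive_seed <- function(master, i) {
  as.integer((as.double(master) + 7919 * as.double(i)) %% 2147483629)
}
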