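# Resolution-weight schemes for the simple entropy.
#
# The weights a_k, k = 1..L, set how much each suffix length
# contributes to SE_w.  No normalisation is stored here: the divisor
# sum(a_k) is applied inside the entropy computation, so the Gaussian
# and geometric families share one code path.

#' Gaussian resolution weights
#'
#' `a_k = exp(-(L - k)^2 / (2 sigma^2))`: a Gaussian kernel centred at
#' the maximum resolution `k = L`, so `a_L = 1` and shorter suffixes
#' are down-weighted. Small `sigma` collapses the statistic to a
#' single-resolution (fixed k-mer) one; large `sigma` weights all
#' lengths equally.
#'
#' @param L Maximum word length (resolution).
#' @param sigma Positive kernel width.
#' @return An object of class `weight_scheme`.
#' @export
#' @examples
#' round(gaussian_weights(4, 1.5)$weights, 2)
gaussian_weights <- function(L, sigma) {
  if (!.is_count(L) || L < 1L) stop("`L` must be a positive integer",
                                    call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be positive", call. = FALSE)
  k <- seq_len(L)
  structure(list(L = as.integer(L), kind = "gaussian", sigma = sigma,
                 weights = exp(-(L - k)^2 / (2 * sigma^2))),
            class = "weight_scheme")
}

#' Geometric resolution weights
#'
#' `a_k = 4^k phi^k`, the weighting used by the original per-position
#' Entropic Profile with smoothing parameter `phi`.
#'
#' @param L Maximum word length.
#' @param phi Positive smoothing parameter.
#' @return An object of class `weight_scheme`.
#' @export
geometric_weights <- function(L, phi) {
  if (!.is_count(L) || L < 1L) stop("`L` must be a positive integer",
                                    call. = FALSE)
  if (!is.numeric(phi) || length(phi) != 1L || phi <= 0)
    stop("`phi` must be positive", call. = FALSE)
  k <- seq_len(L)
  structure(list(L = as.integer(L), kind = "geometric", phi = phi,
                 weights = 4^k * phi^k),
            class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  par <- if (x$kind == "gaussian") paste0("sigma=", x$sigma)
         else paste0("phi=", x$phi)
  cat("weight_scheme (", x$kind, ", L=", x$L, ", ", par, ")\n", sep = "")
  print(signif(x$weights, 4))
  invisible(x)
}

.as_weights <- function(weights, L) {
  if (inherits(weights, "weight_scheme")) {
    if (weights$L != L)
      stop("weight scheme has L = ", weights$L, " but L = ", L,
           " was requested", call. = FALSE)
    return(weights)
  }
  if (is.numeric(weights) && length(weights) == L && all(weights >= 0))
    return(structure(list(L = as.integer(L), kind = "custom", weights = weights),
                     class = "weight_scheme"))
  stop("`weights` must be a weight_scheme or a numeric vector of length L",
       call. = FALSE)
}
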