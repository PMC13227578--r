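# Adam optimizer with decoupled weight decay over nested parameter lists.

#' Initialize an Adam optimizer state
#'
#' Standard Adam moments (beta1 = 0.9, beta2 = 0.999, eps = 1e-8) with
#' decoupled weight decay: after the Adam update each parameter is
#' additionally shrunk by `learning_rate * weight_decay * theta`.
#'
#' @param params Nested list of numeric arrays (e.g. `vit_params`).
#' @param learning_rate Step size eta0 (> 0).
#' @param weight_decay Decay coefficient gamma (>= 0).
#' @param beta1,beta2,eps Adam constants.
#' @return Optimizer state (class `adam_state`) holding the parameters, both
#'   moment trees and the step counter.
#' @export
adam_init <- function(params, learning_rate = 1e-3, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (learning_rate <= 0) stop_invalid("learning_rate must be > 0")
  if (weight_decay < 0) stop_invalid("weight_decay must be >= 0")
  structure(list(params = params,
                 m = nl_zeros_like(params), v = nl_zeros_like(params),
                 t = 0L, learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "adam_state")
}

#' Apply one Adam step
#'
#' @param state An `adam_state`.
#' @param grads Gradient tree with the same structure as `state$params`.
#' @return Updated `adam_state` (step counter incremented).
#' @export
adam_step <- function(state, grads) {
  ok <- tryCatch({
    nl_map(function(p, g) if (length(p) != length(g)) stop("len") else 0,
           state$params, grads)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_invalid("gradient shape does not match parameter shape")
  t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  lr <- state$learning_rate; wd <- state$weight_decay; eps <- state$eps
  state$m <- nl_map(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- nl_map(function(v, g) b2 * v + (1 - b2) * g^2, state$v, grads)
  bc1 <- 1 - b1^t; bc2 <- 1 - b2^t
  state$params <- nl_map(function(p, m, v)
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps) - lr * wd * p,
    state$params, state$m, state$v)
  state$t <- t
  state
}
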