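#' Announcement-probability functions
#'
#' The announcement probability q(t) = P(Y = 1 | T = t) is the conditional
#' probability that a subject whose patience runs out at time t announces the
#' abandonment. It is treated as an unknown nuisance function: the estimators
#' never use it, but the simulator needs it to generate data.
#'
#' Three named shapes cover the simulation settings: an exponentially
#' decaying probability `exp(-rate * t)` (late abandoners leave silently), an
#' exponentially rising one `1 - exp(-rate * t)`, and a constant. `t` is in
#' the same unit as the simulated times (hours by default).
#'
#' @param rate Decay/rise rate of the announcement probability (per hour).
#' @return A function of class `announce_fn` mapping times to probabilities
#'   in \[0, 1\].
#' @examples
#' q <- q_exp_decay()
#' q(c(0, 1, 10))
#' @export
q_exp_decay <- function(rate = 1) {
  stopifnot(rate > 0)
  new_announce_fn(function(t) exp(-rate * t), "exp_decay")
}

#' @rdname q_exp_decay
#' @export
q_exp_rise <- function(rate = 1) {
  stopifnot(rate > 0)
  new_announce_fn(function(t) 1 - exp(-rate * t), "exp_rise")
}

#' @rdname q_exp_decay
#' @param p Constant announcement probability.
#' @export
q_constant <- function(p = 0.5) {
  stopifnot(p >= 0, p <= 1)
  new_announce_fn(function(t) rep_len(p, length(t)), "constant")
}

#' @rdname q_exp_decay
#' @param fn An arbitrary vectorized function of time returning values in
#'   \[0, 1\]; validated on a probe grid.
#' @export
announce_fn <- function(fn) {
  stopifnot(is.function(fn))
  probe <- fn(c(0, 0.1, 1, 10, 100, 1000))
  if (any(!is.finite(probe)) || any(probe < 0) || any(probe > 1))
    stop("announcement function must map [0, Inf) into [0, 1]")
  new_announce_fn(fn, "custom")
}

new_announce_fn <- function(fn, name) {
  structure(fn, class = c("announce_fn", "function"), q_name = name)
}

#' @export
print.announce_fn <- function(x, ...) {
  cat(sprintf("<announce_fn: %s>\n", attr(x, "q_name")))
  invisible(x)
}

announce_from_config <- function(config) {
  if (is.function(config)) return(announce_fn(config))
  stopifnot(is.list(config), !is.null(config$name))
  switch(config$name,
    exp_decay = q_exp_decay(rate = config$rate %||% 1),
    exp_rise = q_exp_rise(rate = config$rate %||% 1),
    constant = q_constant(p = config$p %||% 0.5),
    stop("unknown announcement function: ", config$name)
  )
}
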