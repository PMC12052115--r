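#' Model parameters for the covariate-adjusted triggering process
#'
#' Bundles the parameter set \eqn{\Theta = \{\theta, \alpha, \beta, \gamma\}}
#' of the conditional intensity
#' \deqn{\lambda_i(t \mid H_i(t)) = \theta t^{\theta-1} e^{\alpha^\top x_i}
#'   + \sum_{j: t_{ij} < t} \beta \gamma e^{-\gamma (t - t_{ij})}.}
#' `theta` is the power-law time-shape of the baseline rate (`theta = 1`
#' constant, `< 1` decreasing, `> 1` increasing), `alpha` the log-linear
#' covariate coefficients, `beta` the expected number of directly triggered
#' offspring per event (branching ratio), and `gamma` the exponential decay
#' rate of the triggering effect in 1/days.
#'
#' `beta < 1` (subcriticality) is required by the simulator but deliberately
#' not enforced here: fitting must be free to explore the full box.
#'
#' @param theta positive scalar, baseline power-law shape.
#' @param alpha numeric vector of covariate coefficients (may be length 0).
#' @param beta non-negative scalar triggering magnitude.
#' @param gamma positive scalar decay rate (1/days).
#'
#' @return An object of class `"tpp_params"`.
#' @examples
#' model_params(theta = 0.9, alpha = c(0.3, -0.2), beta = 0.5, gamma = 0.1)
#' @export
model_params <- function(theta = 1, alpha = numeric(0), beta = 0, gamma = 1) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta <= 0)
    stop("`theta` must be a positive finite scalar", call. = FALSE)
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("`gamma` must be a positive finite scalar", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta < 0)
    stop("`beta` must be a non-negative finite scalar", call. = FALSE)
  if (!is.numeric(alpha) || anyNA(alpha))
    stop("`alpha` must be a numeric vector without NA", call. = FALSE)
  alpha_num <- as.numeric(alpha)
  names(alpha_num) <- names(alpha)
  structure(
    list(theta = as.numeric(theta), alpha = alpha_num,
         beta = as.numeric(beta), gamma = as.numeric(gamma)),
    class = "tpp_params"
  )
}

#' @export
print.tpp_params <- function(x, digits = 4, ...) {
  cat("Triggering point process parameters\n")
  cat("  theta (baseline shape): ", format(x$theta, digits = digits), "\n", sep = "")
  if (length(x$alpha)) {
    nm <- names(x$alpha)
    lab <- if (is.null(nm)) paste0("alpha", seq_along(x$alpha)) else nm
    cat("  alpha (covariates):     ",
        paste(paste0(lab, "=", format(x$alpha, digits = digits)), collapse = ", "),
        "\n", sep = "")
  } else {
    cat("  alpha: (no covariates)\n")
  }
  cat("  beta  (branching ratio):", format(x$beta, digits = digits), "\n")
  cat("  gamma (decay, 1/day):   ", format(x$gamma, digits = digits), "\n")
  invisible(x)
}

# internal: flatten/unflatten for the optimizer (order: theta, alpha, beta, gamma)
params_to_vector <- function(params) {
  c(params$theta, params$alpha, params$beta, params$gamma)
}

vector_to_params <- function(par, p, alpha_names = NULL) {
  alpha <- if (p > 0) par[seq(2L, 1L + p)] else numeric(0)
  if (!is.null(alpha_names)) names(alpha) <- alpha_names
  model_params(theta = par[1L], alpha = alpha,
               beta = par[2L + p], gamma = par[3L + p])
}

check_covariate_dim <- function(x, alpha) {
  if (length(x) != length(alpha))
    stop(sprintf("covariate vector has length %d but alpha has length %d",
                 length(x), length(alpha)), call. = FALSE)
  invisible(TRUE)
}
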