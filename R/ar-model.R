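#' Bivariate (or univariate) autoregressive model
#'
#' Container for a stationary AR model
#' \deqn{y(t) = \sum_{l\ge1} \Phi(l)\, y(t-l) + \epsilon(t),\qquad
#'       \mathrm{cov}(\epsilon) = \Sigma,}
#' entered in the "natural" form above (positive feedback coefficients). In
#' the lag-operator form used for the spectral representation the lag-0
#' coefficient matrix is the identity and the lag-\eqn{l} coefficients are
#' \eqn{-\Phi(l)}; `ar_model()` performs that conversion internally so that,
#' e.g., a diagonal coefficient of 0.1 produces a spectrum that decays with
#' frequency.
#'
#' @param coeffs A single numeric matrix (lag 1) or a list of p x p matrices,
#'   one per lag. Scalars are accepted for univariate models.
#' @param noise_cov Innovation covariance matrix (symmetric positive
#'   semi-definite). Defaults to the identity.
#' @return An object of class `ar_model` with elements `coeffs` (list of
#'   matrices), `noise_cov`, `p` (number of channels) and `order`.
#' @examples
#' m <- ar_model(matrix(c(0.1, 0.1, 0, 0.4), 2, 2), diag(2))
#' glance(m)
#' @export
ar_model <- function(coeffs, noise_cov = NULL) {
  if (is.numeric(coeffs) && !is.list(coeffs)) coeffs <- list(as.matrix(coeffs))
  coeffs <- lapply(coeffs, as.matrix)
  p <- nrow(coeffs[[1]])
  for (cc in coeffs) {
    if (!is.numeric(cc) || nrow(cc) != p || ncol(cc) != p || any(!is.finite(cc))) {
      abort("all coefficient matrices must be finite p x p numeric matrices")
    }
  }
  if (is.null(noise_cov)) noise_cov <- diag(p)
  noise_cov <- as.matrix(noise_cov)
  if (nrow(noise_cov) != p || ncol(noise_cov) != p ||
      max(abs(noise_cov - t(noise_cov))) > 1e-10) {
    abort("noise_cov must be a symmetric p x p matrix")
  }
  ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    abort("noise_cov must be positive semi-definite")
  }
  structure(
    list(coeffs = coeffs, noise_cov = noise_cov, p = p, order = length(coeffs)),
    class = "ar_model"
  )
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("<ar_model> %d channel(s), order %d, spectral radius %.4f\n",
              x$p, x$order, ar_spectral_radius(x)))
  invisible(x)
}

# companion-matrix spectral radius; < 1 means stationary
ar_spectral_radius <- function(model) {
  p <- model$p
  q <- model$order
  comp <- matrix(0, p * q, p * q)
  for (l in seq_len(q)) {
    comp[1:p, ((l - 1) * p + 1):(l * p)] <- model$coeffs[[l]]
  }
  if (q > 1) {
    comp[(p + 1):(p * q), 1:(p * (q - 1))] <- diag(p * (q - 1))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

# hard stationarity gate shared by the spectral and simulation paths
check_stable <- function(model, margin = 1e-6) {
  r <- ar_spectral_radius(model)
  if (r >= 1 - margin) {
    abort(sprintf("AR model is not stable: companion spectral radius %.6f", r))
  }
  invisible(r)
}

#' @describeIn ar_model Coefficients as a tibble (one row per lag and entry).
#' @param x,object An `ar_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ar_model <- function(x, ...) {
  purrr::imap_dfr(x$coeffs, function(m, l) {
    tibble::tibble(
      lag = l,
      row = rep(seq_len(nrow(m)), times = ncol(m)),
      col = rep(seq_len(ncol(m)), each = nrow(m)),
      estimate = as.vector(m)
    )
  })
}

#' @describeIn ar_model One-row model summary.
#' @exportS3Method generics::glance
glance.ar_model <- function(x, ...) {
  tibble::tibble(
    n_channels = x$p,
    order = x$order,
    spectral_radius = ar_spectral_radius(x),
    stable = ar_spectral_radius(x) < 1 - 1e-6
  )
}

#' Serialize / deserialize an AR model as JSON
#'
#' The JSON carries lag-indexed coefficient arrays in the natural sign
#' convention (tagged `"sign": "natural"`), plus the innovation covariance.
#'
#' @param model An `ar_model`.
#' @param path File path; for `ar_model_from_json` an existing file.
#' @return `ar_model_to_json` returns `path` invisibly; `ar_model_from_json`
#'   returns an `ar_model`.
#' @export
ar_model_to_json <- function(model, path) {
  stopifnot(inherits(model, "ar_model"))
  jsonlite::write_json(
    list(
      sign = "natural",
      coeffs = lapply(model$coeffs, function(m) unclass(m)),
      noise_cov = unclass(model$noise_cov)
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname ar_model_to_json
#' @export
ar_model_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$sign, "natural")) {
    abort("unsupported AR sign convention tag in JSON")
  }
  coeffs <- x$coeffs
  if (is.array(coeffs) && length(dim(coeffs)) == 3) {
    coeffs <- lapply(seq_len(dim(coeffs)[1]), function(l) coeffs[l, , ])
  }
  ar_model(coeffs, as.matrix(x$noise_cov))
}

#' Simulate a realization of an AR model
#'
#' Draws Gaussian innovations with covariance `noise_cov`, runs the
#' recursion, and discards an initial burn-in so the output is (approximately)
#' stationary. Deterministic for a fixed `seed`.
#'
#' @param model An `ar_model`; must be stable.
#' @param n_samples Number of samples to return (after burn-in).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param burn_in Initial samples to discard (default 1000).
#' @return `n_samples` x p numeric matrix.
#' @examples
#' m <- scenario_model("connected")
#' y <- simulate_ar(m, 500, seed = 1)
#' dim(y)
#' @export
simulate_ar <- function(model, n_samples, seed = NULL, burn_in = 1000L) {
  stopifnot(inherits(model, "ar_model"))
  q <- model$order
  if (n_samples < 10 * q) abort("n_samples must be at least 10x the model order")
  check_stable(model)
  p <- model$p
  ntot <- n_samples + burn_in
  L <- t(chol(model$noise_cov + diag(1e-14, p)))
  with_seed(seed, function() {
    eps <- matrix(rnorm(ntot * p), ntot, p) %*% t(L)
    y <- matrix(0, ntot, p)
    if (q == 1L) {
      phi1 <- t(model$coeffs[[1]])
      offdiag <- model$coeffs[[1]]
      diag(offdiag) <- 0
      if (max(abs(offdiag)) == 0) {
        # diagonal lag-1 model: p independent recursive filters
        for (k in seq_len(p)) {
          y[, k] <- stats::filter(eps[, k], model$coeffs[[1]][k, k],
                                  method = "recursive")
        }
      } else {
        for (t in 2:ntot) y[t, ] <- y[t - 1, ] %*% phi1 + eps[t, ]
      }
    } else {
      phis <- lapply(model$coeffs, t)
      for (t in (q + 1):ntot) {
        acc <- eps[t, ]
        for (l in seq_len(q)) acc <- acc + y[t - l, ] %*% phis[[l]]
        y[t, ] <- acc
      }
    }
    y[(burn_in + 1):ntot, , drop = FALSE]
  })
}
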