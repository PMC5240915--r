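#' Parameters of the one-tailed (noncentral) Dunnett max-t distribution
#'
#' The many-to-one Dunnett statistic is `max_i T_i` over `m` equicorrelated
#' t-statistics sharing one variance estimate: `T_i = (Z_i + delta_i) / W`,
#' where the `Z_i` are standard normal with common correlation `rho`
#' (`Z_i = sqrt(rho) Z_0 + sqrt(1-rho) E_i`) and `W = sqrt(chi^2_df / df)`.
#' In a balanced many-to-one design `rho = 1/2`. For per-peptide epitope
#' calling `m` is the peptide length minus 1 and `df` the number of
#' substitution values minus the peptide length.
#'
#' @param m Number of comparisons against the control (>= 1).
#' @param df Error degrees of freedom (positive; `Inf` for the known-variance
#'   limit).
#' @param rho Common correlation in (0, 1); default 0.5.
#' @param delta Noncentrality vector (length 1 or `m`); default 0 (central).
#' @return An object of class `"dunnett_params"`.
#' @export
dunnett_params <- function(m, df = Inf, rho = 0.5, delta = 0) {
  m <- as.integer(m)
  stopifnot(length(m) == 1L, m >= 1L,
            length(df) == 1L, df >= 1,
            length(rho) == 1L, rho > 0, rho < 1,
            length(delta) %in% c(1L, m), all(is.finite(delta)))
  delta <- rep_len(as.numeric(delta), m)
  structure(list(m = m, df = as.numeric(df), rho = rho, delta = delta),
            class = "dunnett_params")
}

#' @export
print.dunnett_params <- function(x, ...) {
  cat(sprintf("Dunnett max-t parameters: m = %d, df = %s, rho = %g, %s\n",
              x$m, format(x$df), x$rho,
              if (all(x$delta == 0)) "central" else
                paste0("delta = [", paste(signif(x$delta, 4), collapse = ", "), "]")))
  invisible(x)
}

## Gauss-Legendre nodes/weights on [a, b] via the Golub-Welsch eigenproblem.
## The [-1, 1] rule is cached per node count; only the affine map is redone.
.gl_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(n, a = -1, b = 1) {
  if (n == 1L) return(list(nodes = (a + b) / 2, weights = b - a))
  key <- as.character(n)
  ref <- get0(key, envir = .gl_cache, inherits = FALSE)
  if (is.null(ref)) {
    k <- seq_len(n - 1L)
    beta <- k / sqrt(4 * k^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(k, k + 1L)] <- beta
    J[cbind(k + 1L, k)] <- beta
    e <- eigen(J, symmetric = TRUE)
    ref <- list(x = rev(e$values), w = rev(2 * e$vectors[1L, ]^2))
    assign(key, ref, envir = .gl_cache)
  }
  list(nodes = (b - a) / 2 * ref$x + (a + b) / 2,
       weights = (b - a) / 2 * ref$w)
}

## Inner integral over the shared normal factor, for one studentizing scale u:
## returns E_z[ prod_i Phi((q*u - delta_i + sqrt(rho) z) / sqrt(1-rho)) ]
## evaluated at each q*u in `qu` (vector). zq: precomputed z-quadrature.
dunnett_inner <- function(qu, delta, rho, zq) {
  sr <- sqrt(rho); s1r <- sqrt(1 - rho)
  ## matrix over (qu, z)
  base <- outer(qu, sr * zq$nodes, "+")
  if (length(unique(delta)) == 1L) {
    lp <- length(delta) * pnorm((base - delta[1L]) / s1r, log.p = TRUE)
  } else {
    lp <- 0
    for (d in delta) lp <- lp + pnorm((base - d) / s1r, log.p = TRUE)
  }
  exp(lp) %*% (zq$weights * stats::dnorm(zq$nodes))
}

#' CDF of the one-tailed Dunnett max-t distribution
#'
#' `P(max_i T_i <= q)` computed by nested Gauss-Legendre quadrature: the outer
#' integral runs over the studentizing scale `W = sqrt(chi^2_df/df)` (skipped
#' when `df` exceeds `1e5`, the known-variance limit), the inner over the
#' shared standard-normal factor, with integrand
#' `prod_i Phi((q w - delta_i + sqrt(rho) z) / sqrt(1 - rho))`.
#' Absolute accuracy is approximately 1e-7 with the default node counts.
#' For `m = 1` the distribution is the (noncentral) Student t and
#' `method = "auto"` uses the closed form.
#'
#' @param q Quantile(s), finite numeric vector.
#' @param params A [dunnett_params()] object.
#' @param method `"auto"` (closed form when exact, else quadrature),
#'   `"quadrature"` (always the numeric path), or `"analytic"` (only valid for
#'   `m = 1`).
#' @param nodes_z,nodes_w Gauss-Legendre node counts for the inner (normal)
#'   and outer (chi-scale) integrals.
#' @return Probabilities, same length as `q`.
#' @export
dunnett_cdf <- function(q, params, method = c("auto", "quadrature", "analytic"),
                        nodes_z = 128L, nodes_w = 96L) {
  method <- match.arg(method)
  stopifnot(inherits(params, "dunnett_params"), all(is.finite(q)))
  m <- params$m; df <- params$df; rho <- params$rho; delta <- params$delta
  if (method == "analytic" && m != 1L) {
    stop("analytic form only exists for m = 1", call. = FALSE)
  }
  if (m == 1L && method != "quadrature") {
    return(if (is.infinite(df)) pnorm(q - delta)
           else if (delta == 0) pt(q, df)
           else pt(q, df, ncp = delta))
  }
  zq <- gauss_legendre(nodes_z, -8, 8)
  if (is.infinite(df) || df > 1e5) {
    return(as.numeric(dunnett_inner(q, delta, rho, zq)))
  }
  wr <- sqrt(qchisq(c(1e-11, 1 - 1e-11), df) / df)
  wq <- gauss_legendre(nodes_w, wr[1L], wr[2L])
  ## density of W = sqrt(X/df), X ~ chisq_df
  fw <- 2 * wq$nodes * df * dchisq(wq$nodes^2 * df, df)
  out <- vapply(q, function(qi) {
    inner <- dunnett_inner(qi * wq$nodes, delta, rho, zq)
    sum(wq$weights * fw * inner)
  }, numeric(1L))
  pmin(pmax(out, 0), 1)
}

#' Quantile of the one-tailed Dunnett max-t distribution
#'
#' Inverse of [dunnett_cdf()], by Bonferroni-based bracketing plus root
#' refinement; monotone in `p`. This supplies the critical value `t_d` from
#' which the least-significant difference `LSD_i = t_d * SE_i` is formed.
#'
#' @param p Probability (or vector) in (0, 1).
#' @param params A [dunnett_params()] object.
#' @param ... Passed to [dunnett_cdf()] (e.g. `method`, node counts).
#' @return Quantile(s) `q` with `dunnett_cdf(q) = p` to ~1e-7.
#' @export
dunnett_quantile <- function(p, params, ...) {
  stopifnot(inherits(params, "dunnett_params"),
            all(p > 0), all(p < 1))
  m <- params$m; df <- params$df; delta <- params$delta
  qt0 <- function(pp) if (is.infinite(df)) qnorm(pp) else qt(pp, df)
  vapply(p, function(pp) {
    if (m == 1L && all(delta == 0) &&
        !identical(list(...)$method, "quadrature")) {
      return(qt0(pp))
    }
    ## max_i T_i is bounded below (stochastically) by any single T_i and above
    ## by the Bonferroni union bound, after shifting by the noncentrality range
    lo <- qt0(pp) + min(delta) - 1e-9
    hi <- qt0(1 - (1 - pp) / m) + max(delta) + 1e-9
    ## widen defensively for studentization at small df
    f <- function(q) dunnett_cdf(q, params, ...) - pp
    flo <- f(lo); fhi <- f(hi)
    while (flo > 0) { lo <- lo - 1; flo <- f(lo) }
    while (fhi < 0) { hi <- hi + 1; fhi <- f(hi) }
    uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi, tol = 1e-9)$root
  }, numeric(1L))
}

#' Seeded Monte-Carlo oracle for the Dunnett max-t distribution
#'
#' Simulates `max_i T_i` directly through the shared-factor construction
#' (`T_i = (sqrt(rho) Z_0 + sqrt(1-rho) E_i + delta_i) / W`). Used as the
#' independent reference for validating the quadrature engine; the empirical
#' CDF comes with binomial standard errors.
#'
#' @param params A [dunnett_params()] object.
#' @param n_draws Number of simulated maxima (>= 1e4).
#' @param seed Integer seed; identical seeds give identical oracles.
#' @return An object of class `"dunnett_mc"`: a list with elements
#'   `cdf(q)` (empirical probabilities), `se(q)` (binomial standard errors),
#'   `n_draws`, and the sorted draws.
#' @export
dunnett_mc_oracle <- function(params, n_draws = 1e6, seed) {
  stopifnot(inherits(params, "dunnett_params"), n_draws >= 1e4)
  if (missing(seed)) stop("dunnett_mc_oracle: seed is required", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  m <- params$m; df <- params$df; rho <- params$rho; delta <- params$delta
  n_draws <- as.integer(n_draws)
  chunk <- 250000L
  draws <- numeric(n_draws)
  done <- 0L
  while (done < n_draws) {
    n <- min(chunk, n_draws - done)
    z0 <- rnorm(n) * sqrt(rho)
    mx <- rep(-Inf, n)
    for (i in seq_len(m)) {
      mx <- pmax(mx, z0 + sqrt(1 - rho) * rnorm(n) + delta[i])
    }
    w <- if (is.infinite(df)) 1 else sqrt(rchisq(n, df) / df)
    draws[(done + 1L):(done + n)] <- mx / w
    done <- done + n
  }
  draws <- sort(draws)
  obj <- list(
    cdf = function(q) findInterval(q, draws) / n_draws,
    se = function(q) {
      p <- findInterval(q, draws) / n_draws
      sqrt(p * (1 - p) / n_draws)
    },
    n_draws = n_draws,
    draws = draws
  )
  class(obj) <- "dunnett_mc"
  obj
}

#' @export
print.dunnett_mc <- function(x, ...) {
  cat(sprintf("Dunnett Monte-Carlo oracle: %d draws, range [%.3f, %.3f]\n",
              x$n_draws, x$draws[1L], x$draws[x$n_draws]))
  invisible(x)
}
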