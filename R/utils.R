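#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores whatever
#' RNG state existed before the call. All generators in this package route
#' their randomness through this helper so that they are pure functions of
#' `(params, seed)` and never clobber the caller's stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# stop() wrapper giving errors a class so callers/tests can condition on them
mrdam_stop <- function(msg, class) {
  stop(structure(class = c(class, "mrdam_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# fast marginal simple regression of y on each column of G (with intercept);
# returns beta, se, t, p per column.  Used by the summary-statistic
# generators; scan_snps() goes through the full QR path instead.
marginal_ols <- function(G, y) {
  n <- length(y)
  stopifnot(nrow(G) == n, n > 2L)
  gbar <- colMeans(G)
  ybar <- mean(y)
  yc <- y - ybar
  sxx <- colSums(G^2) - n * gbar^2
  sxy <- as.vector(crossprod(G, yc))
  beta <- sxy / sxx
  # RSS = Syy - beta * Sxy for each simple regression
  syy <- sum(yc^2)
  rss <- syy - beta * sxy
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  data.frame(beta = beta, se = se, t = tval, pval = pval)
}
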