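#' Weighted Gaussian GLM of diversity on infrapopulation size
#'
#' Fits the identity-link Gaussian GLM pi ~ load by weighted least squares,
#' weighting each species by its number of sequenced mites so better-sampled
#' species carry more confidence. Reports the weighted null and residual
#' deviances, the fraction of deviance explained, and the F test of the
#' slope on (1, n_obs - 2) degrees of freedom.
#'
#' @param pi per-species nucleotide diversity (response).
#' @param load per-species (possibly jittered) median infrapopulation size.
#' @param weights per-species sample sizes (sequenced mites).
#' @return A one-row `data.frame`: `slope, intercept, null_deviance,
#'   resid_deviance, deviance_explained, F, df_resid, p_F, n_obs`.
#' @examples
#' fit_wls_glm(c(.002, .004, .009, .012), c(5, 10, 30, 45), c(30, 28, 35, 20))
#' @export
fit_wls_glm <- function(pi, load, weights) {
  ok <- is.finite(pi) & is.finite(load) & is.finite(weights)
  pi <- pi[ok]; load <- load[ok]; w <- weights[ok]
  n_obs <- length(pi)
  if (n_obs < 3L) stop("need at least 3 species for the regression",
                       call. = FALSE)
  if (stats::var(load) == 0)
    stop("singular fit: no variance in infrapopulation size", call. = FALSE)
  fit <- stats::glm(pi ~ load, family = stats::gaussian(),
                    weights = w)
  d0 <- fit$null.deviance
  d1 <- fit$deviance
  df_resid <- n_obs - 2L
  Fstat <- (d0 - d1) / (d1 / df_resid)
  data.frame(slope = unname(stats::coef(fit)[2L]),
             intercept = unname(stats::coef(fit)[1L]),
             null_deviance = d0, resid_deviance = d1,
             deviance_explained = 1 - d1 / d0,
             F = Fstat, df_resid = df_resid,
             p_F = stats::pf(Fstat, 1, df_resid, lower.tail = FALSE),
             n_obs = n_obs)
}
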