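#' Intraclass correlation (repeatability) of a grouped trait
#'
#' One-way ANOVA intraclass correlation with the unbalanced-design
#' correction: with a groups and N observations, n0 = (N - sum(n_i^2)/N) /
#' (a - 1) and R = (MSB - MSW) / (MSB + (n0 - 1) MSW). The 95% confidence
#' interval comes from F-distribution bounds on the variance ratio MSB/MSW
#' (Searle-type), transformed to the ICC scale. Used here to ask how
#' repeatable per-infrapopulation nucleotide diversity is within a symbiont
#' species relative to the differences between species.
#'
#' @param values numeric vector (e.g. per-infrapopulation pi).
#' @param groups grouping factor (e.g. species).
#' @param conf confidence level (default 0.95).
#' @return An object of class `icc_result`: list with `R`, `ci` (lo, hi),
#'   `groups`, `observations`, `MSB`, `MSW`, `n0`.
#' @export
icc_repeatability <- function(values, groups, conf = 0.95) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(as.factor(groups[ok]))
  a <- nlevels(groups)
  N <- length(values)
  if (a < 2L || N - a < 1L)
    stop("need at least 2 groups and some replication for the ICC",
         call. = FALSE)
  ni <- as.numeric(table(groups))
  if (all(ni < 2L))
    stop("need at least one group with >= 2 observations", call. = FALSE)
  an <- stats::anova(stats::lm(values ~ groups))
  MSB <- an$`Mean Sq`[1L]
  MSW <- an$`Mean Sq`[2L]
  n0 <- (N - sum(ni^2) / N) / (a - 1)
  R <- (MSB - MSW) / (MSB + (n0 - 1) * MSW)
  Fobs <- MSB / MSW
  alpha <- 1 - conf
  FL <- Fobs / stats::qf(1 - alpha / 2, a - 1, N - a)
  FU <- Fobs * stats::qf(1 - alpha / 2, N - a, a - 1)
  ci <- c((FL - 1) / (FL + n0 - 1), (FU - 1) / (FU + n0 - 1))
  structure(list(R = R, ci = ci, groups = a, observations = N,
                 MSB = MSB, MSW = MSW, n0 = n0, conf = conf),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC repeatability R = %.3f (%d%% CI %.3f-%.3f); %d groups, %d observations\n",
              x$R, round(100 * x$conf), x$ci[1L], x$ci[2L], x$groups,
              x$observations))
  invisible(x)
}
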