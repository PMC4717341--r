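#' Subsample one mite per bird
#'
#' Draws, uniformly at random, a single individual from each host bird of a
#' species dataset. Mites within a bird are kin-structured under vertical
#' transmission, so species-level diversity is estimated from these
#' one-per-host subsamples rather than from the full (pseudo-replicated)
#' sample.
#'
#' @param dataset a [species_dataset()].
#' @return A `species_dataset` whose alignment holds exactly one sequence
#'   per bird. Errors when the dataset has fewer than 2 distinct birds.
#' @export
subsample_one_per_bird <- function(dataset) {
  stopifnot(inherits(dataset, "species_dataset"))
  birds <- dataset$metadata$bird_id
  ub <- unique(birds)
  if (length(ub) < 2L)
    stop("species '", dataset$species, "' has < 2 birds; cannot subsample",
         call. = FALSE)
  pick <- vapply(ub, function(b) {
    ids <- dataset$metadata$sample_id[birds == b]
    if (length(ids) == 1L) ids else ids[sample.int(length(ids), 1L)]
  }, "")
  species_dataset(dataset$species, dataset$alignment[pick],
                  dataset$metadata[match(pick, dataset$metadata$sample_id), ,
                                   drop = FALSE],
                  dataset$median_load)
}

#' Jitter a median infrapopulation size
#'
#' Host-survey mite counts pool all mite species on a wing, so a species'
#' recorded median load is an upper bound for the focal species. This
#' uncertainty is propagated by drawing, each iteration, a load uniformly
#' between half the recorded median and the median itself.
#'
#' @param M recorded median infrapopulation size (> 0).
#' @return One draw from Uniform(M/2, M).
#' @export
jitter_load <- function(M) {
  if (!is.numeric(M) || length(M) != 1L || !is.finite(M) || M <= 0)
    stop("median load must be a positive number", call. = FALSE)
  stats::runif(1L, M / 2, M)
}

#' Significance mark from a percentage of significant iterations
#'
#' Species whose test is significant in more than 95% of resampling
#' iterations are marked `"**"`, more than 75% `"*"`, otherwise `""`
#' (strict inequalities; exactly 95 is marginal, exactly 75 is unmarked).
#'
#' @param pct percentage in \[0, 100\] (vectorised).
#' @return Character vector of marks.
#' @export
classify_significance <- function(pct) {
  if (any(!is.finite(pct) | pct < 0 | pct > 100))
    stop("percentages must lie in [0, 100]", call. = FALSE)
  ifelse(pct > 95, "**", ifelse(pct > 75, "*", ""))
}

#' Fit the diversity ~ infrapopulation-size model by resampling
#'
#' The package's central estimator. For each of `iterations` resampling
#' iterations it (i) subsamples one mite per bird in every species, (ii)
#' recomputes that species' nucleotide diversity, Tajima's D and R2 (with a
#' coalescent p-value when `r2_reps > 0`), (iii) jitters every species'
#' median infrapopulation size on Uniform(M/2, M), and (iv) fits a weighted
#' Gaussian identity-link GLM of diversity on load, weighting species by
#' their full sequenced-mite counts. Per-species statistics are averaged
#' over iterations, test significance is summarised as the percentage of
#' significant iterations, and the regression is summarised by the mean and
#' empirical 95% interval (2.5/97.5 percentiles) of F, p and deviance
#' explained. A secondary fixed-load GLM of the per-species mean diversity
#' on the unjittered loads is always fitted.
#'
#' Randomness is fully reproducible: every (iteration, species) pair draws
#' under its own sub-stream seed derived from `seed`, so excluding a species
#' does not perturb the draws of the others.
#'
#' @param datasets named list of [species_dataset()] objects (e.g. from
#'   [build_species_datasets()] or [simulate_system()]).
#' @param iterations number of resampling iterations (default 100).
#' @param alpha per-iteration significance level for counting significant
#'   D and R2 tests (default 0.05).
#' @param r2_reps coalescent replicates behind each R2 p-value (default
#'   1000); `0` skips R2 p-values (the R2 statistic is still tracked).
#' @param exclude character vector of species to drop before fitting
#'   (e.g. a recently diverged species, or star-like expansion species).
#' @param jitter logical; `FALSE` uses the recorded loads unchanged in
#'   every iteration.
#' @param seed master seed (integer). `NULL` draws one from the session
#'   stream and records it in the result.
#' @return An object of class `divload`; see [summary.divload()],
#'   [coef.divload()], [plot.divload()].
#' @examples
#' sys <- simulate_system(default_preset(n_species = 5), seed = 7)
#' fit <- divload(sys$datasets, iterations = 10, r2_reps = 0, seed = 1)
#' coef(fit)
#' @export
divload <- function(datasets, iterations = 100L, alpha = 0.05,
                    r2_reps = 1000L, exclude = NULL, jitter = TRUE,
                    seed = NULL) {
  stopifnot(is.list(datasets), length(datasets) > 0L)
  if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
    names(datasets) <- vapply(datasets, `[[`, "", "species")
  if (length(exclude)) datasets <- datasets[setdiff(names(datasets), exclude)]
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  seed <- as.integer(seed)

  eligible <- vapply(datasets, function(d)
    length(unique(d$metadata$bird_id)) >= 2L, logical(1L))
  if (any(!eligible))
    warning("skipping species with < 2 birds: ",
            paste(names(datasets)[!eligible], collapse = ", "), call. = FALSE)
  datasets <- datasets[eligible]
  if (length(datasets) < 3L)
    stop("need at least 3 eligible species for the regression", call. = FALSE)

  sp_names <- names(datasets)
  n_full <- vapply(datasets, function(d) length(d$alignment$ids), numeric(1L))
  n_birds <- vapply(datasets, function(d)
    length(unique(d$metadata$bird_id)), numeric(1L))
  loads <- vapply(datasets, `[[`, numeric(1L), "median_load")

  # per-species precomputation: code matrix and row indices per bird, in
  # order of first appearance (keeps draws identical to
  # subsample_one_per_bird on the species_dataset)
  prep <- lapply(datasets, function(d) {
    birds <- d$metadata$bird_id
    rows <- match(d$metadata$sample_id, d$alignment$ids)
    groups <- lapply(unique(birds),
                     function(b) rows[birds == b])
    list(code = d$alignment$code, groups = groups, M = d$median_load)
  })

  n_sp <- length(datasets)
  stat_names <- c("S", "k_hat", "pi", "D", "p_D", "R2", "p_R2")
  stats_mat <- matrix(NA_real_, iterations * n_sp, length(stat_names),
                      dimnames = list(NULL, stat_names))
  M_mat <- matrix(NA_real_, iterations, n_sp)
  sampled <- character(iterations * n_sp)
  reg_rows <- vector("list", iterations)
  k <- 0L
  for (it in seq_len(iterations)) {
    pi_it <- numeric(n_sp)
    for (s in seq_len(n_sp)) {
      p <- prep[[s]]
      k <- k + 1L
      with_seed(substream_seed(seed, it, sp_names[s]), {
        rows <- vapply(p$groups, function(g)
          if (length(g) == 1L) g else g[sample.int(length(g), 1L)],
          integer(1L))
        stats_mat[k, ] <- .stats_code(p$code[rows, , drop = FALSE],
                                      r2_reps = r2_reps)
        M_mat[it, s] <- if (jitter) jitter_load(p$M) else p$M
        sampled[k] <- paste(rownames(p$code)[rows], collapse = ",")
      })
      pi_it[s] <- stats_mat[k, "pi"]
    }
    reg_rows[[it]] <- cbind(iteration = it,
                            fit_wls_glm(pi_it, M_mat[it, ], n_full))
  }
  iter_df <- data.frame(iteration = rep(seq_len(iterations), each = n_sp),
                        species = rep(sp_names, iterations),
                        n = rep(n_birds, iterations),
                        stats_mat,
                        M_star = as.vector(t(M_mat)),
                        sampled_ids = sampled,
                        stringsAsFactors = FALSE, row.names = NULL)
  reg_df <- do.call(rbind, reg_rows)

  agg <- function(col, f) vapply(sp_names, function(sp)
    f(iter_df[[col]][iter_df$species == sp]), numeric(1L))
  mean_na <- function(v) mean(v, na.rm = TRUE)
  pct_sig <- function(p) 100 * mean(!is.na(p) & p <= alpha)
  species_summary <- data.frame(
    species = sp_names,
    n = as.integer(n_full),
    If = as.integer(n_birds),
    S_full = vapply(datasets, function(d)
      segregating_sites(d$alignment)$S, numeric(1L)),
    median_load = loads,
    mean_pi = agg("pi", mean_na),
    mean_D = agg("D", mean_na),
    mean_R2 = agg("R2", mean_na),
    pct_D_sig = agg("p_D", pct_sig),
    pct_R2_sig = if (r2_reps > 0L) agg("p_R2", pct_sig) else NA_real_,
    row.names = NULL)
  species_summary$mark_D <- classify_significance(species_summary$pct_D_sig)
  species_summary$mark_R2 <- if (r2_reps > 0L)
    classify_significance(species_summary$pct_R2_sig) else NA_character_

  ci <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
  regression_summary <- data.frame(
    mean_slope = mean(reg_df$slope),
    mean_F = mean(reg_df$F), F_lo = ci(reg_df$F)[1L], F_hi = ci(reg_df$F)[2L],
    mean_p = mean(reg_df$p_F), p_lo = ci(reg_df$p_F)[1L],
    p_hi = ci(reg_df$p_F)[2L],
    mean_dev_expl = mean(reg_df$deviance_explained),
    dev_lo = ci(reg_df$deviance_explained)[1L],
    dev_hi = ci(reg_df$deviance_explained)[2L],
    df_resid = reg_df$df_resid[1L])

  fixed_glm <- stats::glm(species_summary$mean_pi ~ species_summary$median_load,
                          family = stats::gaussian(), weights = n_full)
  fixed_load <- fit_wls_glm(species_summary$mean_pi, loads, n_full)

  structure(list(iterations = iter_df, regressions = reg_df,
                 species_summary = species_summary,
                 regression_summary = regression_summary,
                 fixed_load = fixed_load, fixed_glm = fixed_glm,
                 datasets = datasets, weights = n_full,
                 call = match.call(),
                 settings = list(iterations = iterations, alpha = alpha,
                                 r2_reps = r2_reps, jitter = jitter,
                                 seed = seed, exclude = exclude)),
            class = "divload")
}

#' @export
print.divload <- function(x, ...) {
  s <- x$regression_summary
  cat("Diversity ~ infrapopulation size (resampled weighted Gaussian GLM)\n")
  cat(sprintf("  %d species, %d iterations (seed %d)\n",
              nrow(x$species_summary), x$settings$iterations,
              x$settings$seed))
  cat(sprintf("  mean F = %.2f (95%% CI %.2f-%.2f), df = %d, mean P = %.3f\n",
              s$mean_F, s$F_lo, s$F_hi, s$df_resid, s$mean_p))
  cat(sprintf("  mean deviance explained = %.0f%% (95%% CI %.0f-%.0f%%)\n",
              100 * s$mean_dev_expl, 100 * s$dev_lo, 100 * s$dev_hi))
  cat(sprintf("  fixed-load GLM: F = %.2f, df = %d, P = %.3g, deviance explained = %.0f%%\n",
              x$fixed_load$F, x$fixed_load$df_resid, x$fixed_load$p_F,
              100 * x$fixed_load$deviance_explained))
  invisible(x)
}

#' Summarise a resampled diversity-load fit
#'
#' @param object a [divload()] fit.
#' @param ... unused.
#' @return The per-species summary table (mean diversity and demographic
#'   statistics over iterations, significance percentages and marks) with
#'   the regression summary attached as attribute `regression`.
#' @export
summary.divload <- function(object, ...) {
  out <- object$species_summary
  attr(out, "regression") <- object$regression_summary
  attr(out, "fixed_load") <- object$fixed_load
  class(out) <- c("summary.divload", "data.frame")
  out
}

#' @export
print.summary.divload <- function(x, ...) {
  df <- x
  class(df) <- "data.frame"
  df$mean_pi <- signif(df$mean_pi, 3)
  df$mean_D <- round(df$mean_D, 2)
  df$mean_R2 <- round(df$mean_R2, 2)
  df$R2_sig <- if (all(is.na(df$pct_R2_sig))) "-"
               else paste0(round(df$pct_R2_sig), df$mark_R2)
  print(df[, c("species", "n", "If", "S_full", "median_load", "mean_pi",
               "mean_D", "mean_R2", "R2_sig")], row.names = FALSE)
  r <- attr(x, "regression")
  cat(sprintf("\nmean F (95%% CI) = %.2f (%.2f-%.2f), df = %d, mean P (95%% CI) = %.3f (%.3f-%.3f)\n",
              r$mean_F, r$F_lo, r$F_hi, r$df_resid, r$mean_p, r$p_lo, r$p_hi))
  cat(sprintf("mean deviance explained (95%% CI) = %.0f%% (%.0f-%.0f%%)\n",
              100 * r$mean_dev_expl, 100 * r$dev_lo, 100 * r$dev_hi))
  invisible(x)
}

#' @export
coef.divload <- function(object, ...) {
  c(intercept = mean(object$regressions$intercept),
    slope = mean(object$regressions$slope))
}

#' @export
fitted.divload <- function(object, ...) {
  stats::setNames(as.numeric(stats::fitted(object$fixed_glm)),
                  object$species_summary$species)
}

#' @export
residuals.divload <- function(object, ...) {
  stats::setNames(as.numeric(stats::residuals(object$fixed_glm,
                                              type = "response")),
                  object$species_summary$species)
}

#' Predict mean diversity at new infrapopulation sizes
#'
#' Uses the fixed-load GLM (per-species mean diversity on recorded medians).
#'
#' @param object a [divload()] fit.
#' @param newdata numeric vector of median infrapopulation sizes; `NULL`
#'   returns the fitted per-species values.
#' @param ... unused.
#' @export
predict.divload <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  cf <- stats::coef(object$fixed_glm)
  as.numeric(cf[1L] + cf[2L] * newdata)
}

#' Plot the diversity-load relationship
#'
#' Per-species mean nucleotide diversity (averaged over the one-mite-per-
#' bird iterations) against recorded median infrapopulation size, point
#' area proportional to the regression weight, with the fixed-load GLM line.
#'
#' @param x a [divload()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.divload <- function(x, ...) {
  ss <- x$species_summary
  graphics::plot(ss$median_load, ss$mean_pi,
                 cex = 2 * sqrt(x$weights / max(x$weights)),
                 pch = 21, bg = "grey70",
                 xlab = "median infrapopulation size (mites per bird)",
                 ylab = expression("nucleotide diversity" ~ (pi)), ...)
  graphics::abline(stats::coef(x$fixed_glm), lty = 1)
  invisible(x)
}

#' Write the tables of a resampled fit to TSV files
#'
#' Dumps `iterations.tsv` (per-iteration per-species statistics),
#' `species_summary.tsv`, `regressions.tsv` (per-iteration GLMs) and
#' `regression_summary.tsv` into `dir`.
#'
#' @param fit a [divload()] fit.
#' @param dir output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_results <- function(fit, dir) {
  stopifnot(inherits(fit, "divload"))
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create output directory: ", dir, call. = FALSE)
  tabs <- list(iterations = fit$iterations,
               species_summary = fit$species_summary,
               regressions = fit$regressions,
               regression_summary = fit$regression_summary)
  paths <- vapply(names(tabs), function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tabs[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }, "")
  invisible(paths)
}

#' Infrapopulation-level diversity table
#'
#' Nucleotide diversity of every infrapopulation (all sampled mites of one
#' species on one bird) with at least `min_mites` sequences - the input of
#' the repeatability (ICC) diagnostic.
#'
#' @param datasets named list of [species_dataset()] objects.
#' @param min_mites minimum mites per bird (default 2).
#' @return data.frame with columns `species`, `bird_id`, `n_mites`, `pi`.
#' @export
infrapopulation_diversity <- function(datasets, min_mites = 2L) {
  rows <- list()
  for (d in datasets) {
    for (b in unique(d$metadata$bird_id)) {
      ids <- d$metadata$sample_id[d$metadata$bird_id == b]
      if (length(ids) < min_mites) next
      rows[[length(rows) + 1L]] <-
        data.frame(species = d$species, bird_id = b,
                   n_mites = length(ids),
                   pi = nucleotide_diversity(d$alignment[ids]))
    }
  }
  if (!length(rows))
    return(data.frame(species = character(0), bird_id = character(0),
                      n_mites = integer(0), pi = numeric(0)))
  do.call(rbind, rows)
}

#' Repeatability of infrapopulation diversity across species
#'
#' Intraclass correlation of per-infrapopulation nucleotide diversity
#' grouped by species, restricted to species with at least `min_groups`
#' infrapopulations of `min_mites`+ mites.
#'
#' @inheritParams infrapopulation_diversity
#' @param min_groups minimum qualifying infrapopulations per species.
#' @return An [icc_repeatability()] result with the underlying table
#'   attached as attribute `table`.
#' @export
repeatability_diversity <- function(datasets, min_mites = 2L,
                                    min_groups = 2L) {
  tab <- infrapopulation_diversity(datasets, min_mites = min_mites)
  keep <- names(which(table(tab$species) >= min_groups))
  tab <- tab[tab$species %in% keep, , drop = FALSE]
  if (length(unique(tab$species)) < 2L)
    stop("need >= 2 species with >= ", min_groups,
         " infrapopulations each for the ICC", call. = FALSE)
  res <- icc_repeatability(tab$pi, tab$species)
  attr(res, "table") <- tab
  res
}

#' Robustness checks on a fitted diversity-load model
#'
#' Two diagnostics of the species-level diversity estimates: (a) the
#' Spearman rank correlation between each species' mean infrapopulation
#' diversity (computed from whole infrapopulations) and its subsampled
#' species-level mean diversity from the fit - agreement indicates the
#' one-per-bird estimates are not driven by particular infrapopulations;
#' (b) a paired t-test across species of diversity computed with versus
#' without the samples from a designated locality subset - agreement
#' indicates no strong geographic artefact.
#'
#' @param datasets the species datasets used for the fit.
#' @param fit the [divload()] result.
#' @param exclude_locality character vector of locality labels for check
#'   (b); `NULL` or an empty/unmatched set reports that check as skipped.
#' @return list with components `spearman` (rho, p, n) and `locality`
#'   (t, df, p, n, or a skip notice).
#' @export
robustness_checks <- function(datasets, fit, exclude_locality = NULL) {
  stopifnot(inherits(fit, "divload"))
  out <- list()
  infra <- infrapopulation_diversity(datasets)
  mean_infra <- tapply(infra$pi, infra$species, mean, na.rm = TRUE)
  ss <- fit$species_summary
  common <- intersect(names(mean_infra), ss$species)
  if (length(common) < 4L) {
    warning("fewer than 4 species with infrapopulation diversity; Spearman check skipped",
            call. = FALSE)
    out$spearman <- list(skipped = TRUE, n = length(common))
  } else {
    ct <- suppressWarnings(
      stats::cor.test(mean_infra[common],
                      ss$mean_pi[match(common, ss$species)],
                      method = "spearman"))
    out$spearman <- list(rho = unname(ct$estimate), p = ct$p.value,
                         n = length(common))
  }
  pi_full <- pi_part <- numeric(0)
  if (length(exclude_locality)) {
    for (d in datasets) {
      drop <- d$metadata$sample_id[d$metadata$locality %in% exclude_locality]
      keep <- setdiff(d$alignment$ids, drop)
      if (length(drop) == 0L || length(keep) < 2L) next
      pi_full <- c(pi_full, nucleotide_diversity(d$alignment))
      pi_part <- c(pi_part, nucleotide_diversity(d$alignment[keep]))
    }
  }
  if (length(pi_full) < 2L || stats::sd(pi_full - pi_part) == 0) {
    out$locality <- list(skipped = TRUE, n = length(pi_full))
  } else {
    tt <- stats::t.test(pi_full, pi_part, paired = TRUE)
    out$locality <- list(t = unname(tt$statistic),
                         df = unname(tt$parameter), p = tt$p.value,
                         n = length(pi_full))
  }
  out
}
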