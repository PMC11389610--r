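#' Slide-level rank-based quantile normalization
#'
#' Within each slide, angular deviations are mapped to standard-normal
#' quantiles by rank: `z_i = qnorm(r_i / (n + 1))` with `r_i` the average
#' rank of `dev_i` (ties share their average rank). The transform is
#' rank-preserving and slide-local: other slides' data never influence a
#' slide's scores. A high `z` means the neuron ranks among the highest
#' angular deviations within its slide. Slides with fewer than two
#' observations are skipped with a warning (`z = NA`).
#'
#' @param observations data.frame with the response and slide columns.
#' @param value name of the response column (default `"dev_i"`).
#' @param slide name of the slide grouping column (default `"slide_id"`).
#' @param offset rank-to-quantile convention: `"n+1"` uses `r/(n+1)`
#'   (default), `"half"` uses `(r - 0.5)/n`.
#' @return `observations` with a `z` column appended.
#' @examples
#' d <- data.frame(dev_i = c(1, 2, 3), slide_id = "s1")
#' quantile_normalize_by_slide(d)$z  # -0.674, 0, 0.674
#' @export
quantile_normalize_by_slide <- function(observations, value = "dev_i",
                                        slide = "slide_id",
                                        offset = c("n+1", "half")) {
  offset <- match.arg(offset)
  stopifnot(value %in% names(observations), slide %in% names(observations))
  z <- rep(NA_real_, nrow(observations))
  for (ix in split(seq_len(nrow(observations)), observations[[slide]])) {
    n <- length(ix)
    if (n < 2L) {
      warning("slide group with n < 2 skipped in quantile normalization")
      next
    }
    r <- rank(observations[[value]][ix], ties.method = "average")
    p <- if (offset == "n+1") r / (n + 1) else (r - 0.5) / n
    z[ix] <- stats::qnorm(p)
  }
  observations$z <- z
  observations
}

#' Mixed-model comparison of subregions
#'
#' Fits a linear mixed model on the quantile-normalized angular deviation
#' with subregion as a fixed effect and random intercepts for case and
#' slide (crossed by default; `nested = TRUE` nests slide within case), and
#' tests the overall subregion effect with a likelihood-ratio test against
#' the intercept-only model that retains the same random effects. Both
#' models are fitted by maximum likelihood (not REML), since REML
#' likelihoods are not comparable across fixed-effect structures.
#'
#' @param observations data.frame with columns `z`, `subregion`, `case_id`,
#'   `slide_id` (see [quantile_normalize_by_slide()]).
#' @param nested nest slide within case instead of crossing.
#' @return object of class `subregion_model`: the fitted `model` (lme4),
#'   `null_model`, `lrt_stat`, `lrt_df`, `lrt_p`, and `singular` flag.
#' @export
fit_subregion_model <- function(observations, nested = FALSE) {
  obs <- observations[!is.na(observations$z), , drop = FALSE]
  obs$subregion <- factor(obs$subregion)
  if (nlevels(obs$subregion) < 2L) stop("need >= 2 subregion levels")
  if (length(unique(obs$case_id)) < 2L) stop("need >= 2 cases")
  re <- if (nested) "(1 | case_id) + (1 | case_id:slide_id)"
        else "(1 | case_id) + (1 | slide_id)"
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  full <- lme4::lmer(stats::as.formula(paste("z ~ subregion +", re)),
                     data = obs, REML = FALSE, control = ctrl)
  null <- lme4::lmer(stats::as.formula(paste("z ~ 1 +", re)),
                     data = obs, REML = FALSE, control = ctrl)
  stat <- as.numeric(2 * (stats::logLik(full) - stats::logLik(null)))
  stat <- max(stat, 0)
  df <- nlevels(obs$subregion) - 1L
  res <- list(model = full, null_model = null,
              lrt_stat = stat, lrt_df = df,
              lrt_p = stats::pchisq(stat, df, lower.tail = FALSE),
              singular = lme4::isSingular(full),
              n = nrow(obs), levels = levels(obs$subregion))
  class(res) <- "subregion_model"
  res
}

#' @export
print.subregion_model <- function(x, ...) {
  cat(sprintf("<subregion_model: %d obs, %d levels; LRT chi2(%d) = %.2f, p = %.3g%s>\n",
              x$n, length(x$levels), x$lrt_df, x$lrt_stat, x$lrt_p,
              if (x$singular) " [singular fit]" else ""))
  invisible(x)
}

#' Tukey-style multiplicity-adjusted pairwise contrasts
#'
#' All pairwise subregion contrasts of the fitted mixed model, adjusted by
#' the single-step procedure based on the joint multivariate-normal
#' distribution of the contrast z-statistics (multcomp), with a
#' conservative Bonferroni alternative. The adjustment mode is recorded in
#' the result.
#'
#' @param fit a `subregion_model` from [fit_subregion_model()].
#' @param adjust `"single-step"` (default) or `"bonferroni"`.
#' @return data.frame with `pair`, `estimate`, `std_error`, `z_value`,
#'   `p_adj`, plus attribute `adjust`.
#' @export
tukey_adjusted_contrasts <- function(fit, adjust = c("single-step", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(fit, "subregion_model"))
  glht <- multcomp::glht(fit$model,
                         linfct = multcomp::mcp(subregion = "Tukey"))
  test <- if (adjust == "single-step") multcomp::adjusted("single-step")
          else multcomp::adjusted("bonferroni")
  s <- summary(glht, test = test)
  out <- data.frame(pair = names(s$test$coefficients),
                    estimate = as.numeric(s$test$coefficients),
                    std_error = as.numeric(s$test$sigma),
                    z_value = as.numeric(s$test$tstat),
                    p_adj = as.numeric(s$test$pvalues))
  rownames(out) <- NULL
  attr(out, "adjust") <- adjust
  out
}

#' Write pairwise contrasts in the per-comparison table layout
#'
#' @param contrasts data.frame from [tukey_adjusted_contrasts()].
#' @param observations the observations the model was fitted on (to count
#'   neurons per subregion); optional.
#' @param path output CSV path.
#' @export
write_comparison_table <- function(contrasts, path, observations = NULL) {
  tab <- contrasts
  if (!is.null(observations)) {
    counts <- table(observations$subregion)
    parts <- strsplit(tab$pair, " - ", fixed = TRUE)
    tab$n_neurons <- vapply(parts, function(p)
      sprintf("%d vs %d", counts[[p[1]]], counts[[p[2]]]), character(1))
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
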