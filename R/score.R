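#' Associate component scores with subject covariates
#'
#' Fits, for every (component, covariate) pair, the simple linear
#' regression of the per-subject score on the covariate, and reports slope,
#' intercept, Pearson correlation, R-squared, the two-sided p-value of the
#' slope and a significance flag at level `alpha`. Rows with a missing
#' covariate are dropped pairwise.
#'
#' @param scores numeric matrix (`N x K`) of per-subject scores with
#'   subject ids as rownames, or a vector (treated as one component).
#' @param covariates data frame with a `subject_id` column and numeric
#'   covariate columns, one row per subject.
#' @param alpha significance level for the flag (default 0.05).
#' @param adjust `"none"` (default; one test per pair, as when covariates
#'   are inspected individually) or `"BY"` to correct the whole grid.
#' @return data frame of class `score_association` with columns
#'   `component`, `covariate`, `slope`, `intercept`, `r`, `r_squared`,
#'   `p_value`, `n`, `significant`.
#' @export
associate <- function(scores, covariates, alpha = 0.05,
                      adjust = c("none", "BY")) {
  adjust <- match.arg(adjust)
  if (is.null(dim(scores))) scores <- cbind(scores)
  if (is.null(rownames(scores)))
    stop_validation("scores must carry subject ids as rownames")
  if (is.null(covariates$subject_id))
    stop_validation("covariates need a subject_id column")
  idx <- match(rownames(scores), as.character(covariates$subject_id))
  if (all(is.na(idx)))
    stop_validation("no covariate subjects match the score subjects")
  covnames <- setdiff(names(covariates), "subject_id")
  out <- NULL
  for (k in seq_len(ncol(scores))) {
    for (cn in covnames) {
      x <- as.numeric(covariates[[cn]])[idx]
      y <- scores[, k]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3L)
        stop_data(sprintf(
          "covariate '%s': fewer than 3 complete pairs (%d)", cn, sum(ok)))
      fit <- lm(y[ok] ~ x[ok])
      sm <- summary(fit)
      r <- cor(x[ok], y[ok])
      pv <- sm$coefficients[2, 4]
      out <- rbind(out, data.frame(
        component = k, covariate = cn,
        slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
        r = r, r_squared = r^2, p_value = pv, n = sum(ok),
        stringsAsFactors = FALSE))
    }
  }
  out$p_adjusted <- if (adjust == "BY") p.adjust(out$p_value, "BY")
                    else out$p_value
  out$significant <- out$p_adjusted <= alpha
  class(out) <- c("score_association", "data.frame")
  out
}

#' Summary report of an LFPCA fit with optional covariate associations
#'
#' Emits the variance table (with longitudinal ratios) and, when
#' covariates are supplied and subject components were retained, the full
#' score-covariate association grid. Scatter panels are rendered only on
#' request and only when ggplot2 is installed.
#'
#' @param fit an `lfpca_fit` (with scores for associations).
#' @param covariates optional covariate data frame (see [associate()]).
#' @param alpha significance level for association flags.
#' @param plot render ggplot2 scatter panels (default `FALSE`).
#' @return list of class `score_report` with `variance`, `associations`
#'   (`NULL` without covariates or components) and `panels` (`NULL` unless
#'   `plot = TRUE`).
#' @export
score_report <- function(fit, covariates = NULL, alpha = 0.05, plot = FALSE) {
  vt <- variance_table(fit)
  assoc <- NULL
  panels <- NULL
  if (!is.null(covariates) && length(fit$lambda_x) > 0 && !is.null(fit$xi)) {
    assoc <- associate(fit$xi, covariates, alpha = alpha)
    if (plot && requireNamespace("ggplot2", quietly = TRUE)) {
      idx <- match(rownames(fit$xi), as.character(covariates$subject_id))
      long <- do.call(rbind, lapply(seq_len(nrow(assoc)), function(i) {
        data.frame(component = assoc$component[i],
                   covariate = assoc$covariate[i],
                   x = as.numeric(covariates[[assoc$covariate[i]]])[idx],
                   score = fit$xi[, assoc$component[i]],
                   significant = assoc$significant[i])
      }))
      panels <- ggplot2::ggplot(long, ggplot2::aes(x = x, y = score)) +
        ggplot2::geom_point(size = 0.8) +
        ggplot2::geom_smooth(method = "lm", se = FALSE, formula = y ~ x,
                             ggplot2::aes(colour = significant)) +
        ggplot2::scale_colour_manual(
          values = c(`TRUE` = "red", `FALSE` = "darkgreen"),
          name = sprintf("slope p <= %.2g", alpha)) +
        ggplot2::facet_grid(component ~ covariate, scales = "free") +
        ggplot2::labs(x = "covariate", y = "subject score")
    }
  }
  structure(list(variance = vt, associations = assoc, panels = panels),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat("LFPCA variance attribution:\n")
  print(x$variance, digits = 4)
  if (!is.null(x$associations)) {
    cat("\nScore-covariate associations:\n")
    print(as.data.frame(x$associations), digits = 4)
  }
  invisible(x)
}
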