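#' Binder category from ic50
#'
#' Standard affinity categories: strong binder (SB) at ic50 <= 50 nM,
#' weak binder (WB) at 50 < ic50 <= 500 nM, non-binder (NB) above
#' 500 nM. Boundaries are inclusive on the stronger side.
#'
#' @param ic50_nM positive numeric vector, nanomolar.
#' @return factor with levels SB, WB, NB.
#' @export
categorize <- function(ic50_nM) {
  if (any(!is.finite(ic50_nM)) || any(ic50_nM <= 0)) {
    stop("ic50 must be positive and finite")
  }
  factor(ifelse(ic50_nM <= 50, "SB",
                ifelse(ic50_nM <= 500, "WB", "NB")),
         levels = c("SB", "WB", "NB"))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen positive receives a higher
#' score than a randomly chosen negative, with ties counted half. When
#' scoring affinity predictions, pass the negated predicted ln(ic50) so
#' that stronger predicted binding ranks higher.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param positives logical vector of the same length.
#' @return AUC in [0, 1], or NA if only one class is present.
#' @export
auroc <- function(scores, positives) {
  stopifnot(length(scores) == length(positives))
  positives <- as.logical(positives)
  n_pos <- sum(positives); n_neg <- sum(!positives)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positives]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate predicted against observed binding affinities
#'
#' Continuous agreement is the Pearson correlation (and its square)
#' between predicted and observed ln(ic50). Categorical agreement is the
#' AROC over two nested dichotomies of the observed affinities: strong
#' binders (<= 50 nM) vs the rest, and binders (<= 500 nM, SB plus WB)
#' vs non-binders. The ranking score is the negated prediction, so an
#' AROC above 0.5 means better-than-random affinity ranking.
#'
#' @param predicted_ln predicted ln(ic50) values.
#' @param observed_ic50_nM observed ic50 in nM.
#' @param allele allele tag carried into the result.
#' @return object of class \code{evaluation_result}: list with
#'   \code{allele}, \code{n}, \code{pearson_r}, \code{r2},
#'   \code{aroc_sb}, \code{aroc_wb}.
#' @export
evaluate <- function(predicted_ln, observed_ic50_nM,
                     allele = NA_character_) {
  if (length(predicted_ln) != length(observed_ic50_nM)) {
    stop("predicted and observed lengths differ")
  }
  n <- length(predicted_ln)
  if (n < 3) stop("need at least 3 observations")
  obs_ln <- log(observed_ic50_nM)
  r <- if (sd(predicted_ln) == 0 || sd(obs_ln) == 0) NA_real_
       else cor(predicted_ln, obs_ln)
  structure(list(allele = allele, n = n,
                 pearson_r = r, r2 = r^2,
                 aroc_sb = auroc(-predicted_ln, observed_ic50_nM <= 50),
                 aroc_wb = auroc(-predicted_ln, observed_ic50_nM <= 500)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("evaluation%s: n = %d, r2 = %.3f, AROC(SB) = %.3f, AROC(WB) = %.3f\n",
              if (is.na(x$allele)) "" else paste0(" [", x$allele, "]"),
              x$n, x$r2, x$aroc_sb, x$aroc_wb))
  invisible(x)
}

#' Tabulate evaluation results across alleles
#'
#' Benchmark-table layout: one row per allele with AROC_SB, AROC_WB and
#' r2 columns, plus a final Average row.
#'
#' @param results list of \code{evaluation_result} objects.
#' @param path optional TSV output path.
#' @return data frame (invisibly if \code{path} given).
#' @export
evaluation_table <- function(results, path = NULL) {
  df <- data.frame(
    allele = vapply(results, function(r) r$allele, character(1)),
    n = vapply(results, function(r) r$n, integer(1)),
    AROC_SB = vapply(results, function(r) r$aroc_sb, numeric(1)),
    AROC_WB = vapply(results, function(r) r$aroc_wb, numeric(1)),
    r2 = vapply(results, function(r) r$r2, numeric(1)))
  avg <- data.frame(allele = "Average", n = sum(df$n),
                    AROC_SB = mean(df$AROC_SB, na.rm = TRUE),
                    AROC_WB = mean(df$AROC_WB, na.rm = TRUE),
                    r2 = mean(df$r2, na.rm = TRUE))
  out <- rbind(df, avg)
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
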