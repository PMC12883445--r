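# Sex-group inference from Xhet alone: an unsupervised 1-D two-means
# threshold, margin-based ambiguity flagging, and a supervised logistic fit
# with complete-separation handling. Labels are "xx-like"/"xy-like", never
# "female"/"male": the statistic measures a genotype pattern, not reported
# sex.

#' Unsupervised Xhet cutoff by 1-D two-means
#'
#' Runs 2-means on the defined Xhet values, deterministically initialized
#' at the minimum and maximum, and returns the midpoint of the two cluster
#' means as the classification cutoff.
#'
#' @param xhet Numeric vector of Xhet values (`NA` allowed, ignored).
#' @return The cutoff (scalar).
#' @examples
#' unsupervised_threshold(c(0.0, 0.01, 0.48, 0.52)) # 0.2525
#' @export
unsupervised_threshold <- function(xhet) {
  x <- xhet[!is.na(xhet)]
  if (length(x) < 2L) stop("need at least 2 defined Xhet values", call. = FALSE)
  if (diff(range(x)) == 0) {
    stop("no separation: all Xhet values identical", call. = FALSE)
  }
  if (length(x) == 2L) return(mean(x)) # each point its own cluster
  km <- stats::kmeans(x, centers = matrix(range(x), ncol = 1))
  mean(km$centers)
}

#' Classify samples into sex-like groups from Xhet
#'
#' `xhet < cutoff` is `"xy-like"`, `xhet >= cutoff` is `"xx-like"`; values
#' within `margin` of the cutoff are forced to `"ambiguous"` (possible
#' aneuploidy, contamination, or extended X homozygosity); undefined Xhet
#' stays `"undefined"`.
#'
#' @param xhet Numeric vector of Xhet values.
#' @param cutoff Classification cutoff in (0, 1).
#' @param margin Half-width of the ambiguity band; default `0.1 * cutoff`.
#' @param sample_id Optional ids (defaults to `names(xhet)` or an index).
#' @return data.frame with columns `sample_id`, `xhet`, `label`, `method`,
#'   `score` (signed distance to the cutoff), `threshold_used`.
#' @export
classify_sex <- function(xhet, cutoff, margin = 0.1 * cutoff, sample_id = NULL) {
  stopifnot(cutoff > 0, cutoff < 1, margin >= 0)
  if (is.null(sample_id)) {
    sample_id <- if (!is.null(names(xhet))) names(xhet) else as.character(seq_along(xhet))
  }
  label <- ifelse(is.na(xhet), "undefined",
                  ifelse(xhet < cutoff, "xy-like", "xx-like"))
  label[!is.na(xhet) & abs(xhet - cutoff) < margin] <- "ambiguous"
  data.frame(
    sample_id = sample_id, xhet = unname(xhet), label = label,
    method = "threshold",
    score = unname(ifelse(is.na(xhet), NA_real_, xhet - cutoff)),
    threshold_used = cutoff,
    stringsAsFactors = FALSE
  )
}

#' Logistic confirmation of the Xhet separation
#'
#' Fits a one-feature logistic regression of a binary class label on Xhet
#' (by iteratively reweighted least squares via [stats::glm()]). With
#' perfectly separated classes the unpenalized maximum-likelihood estimate
#' does not exist; this is detected (the real-data regime, where clusters
#' are completely separated) and a ridge-stabilized refit (small quadratic
#' penalty on the slope) supplies finite coefficients and a decision
#' boundary instead of diverging estimates.
#'
#' @param xhet Numeric Xhet values.
#' @param labels Binary class labels: logical, 0/1, or a 2-level factor
#'   (second level is the positive, xx-like, class).
#' @param ridge Ridge penalty used only in the separated fallback.
#' @return List of class `xk_logistic`: `intercept`, `slope`, `separated`
#'   (flag), `boundary` (Xhet where fitted probability = 0.5), `method`.
#' @export
fit_logistic <- function(xhet, labels, ridge = 1e-2) {
  if (is.character(labels)) labels <- factor(labels)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  y <- as.numeric(labels)
  keep <- !is.na(xhet) & !is.na(y)
  x <- xhet[keep]
  y <- y[keep]
  if (length(unique(y)) < 2L) {
    stop("logistic fit needs both classes present", call. = FALSE)
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- stats::coef(fit)
  if (!separated && (!fit$converged || any(abs(cf) > 1e3))) separated <- TRUE
  method <- "irls"
  if (separated) {
    cf <- ridge_logistic(x, y, lambda = ridge)
    method <- "irls+ridge"
  }
  structure(
    list(
      intercept = unname(cf[1]), slope = unname(cf[2]),
      separated = separated,
      boundary = unname(-cf[1] / cf[2]),
      method = method
    ),
    class = "xk_logistic"
  )
}

#' @export
print.xk_logistic <- function(x, ...) {
  cat(sprintf(
    "<logistic sex model> intercept %.4g, slope %.4g, boundary %.4g%s\n",
    x$intercept, x$slope, x$boundary,
    if (x$separated) " [complete separation; ridge-stabilized]" else ""
  ))
  invisible(x)
}

# Newton/IRLS for logistic regression with a quadratic penalty on the slope
# (intercept unpenalized). Used only when the unpenalized MLE does not
# exist; no installed package fits a single-predictor penalized logistic.
ridge_logistic <- function(x, y, lambda = 1e-2, maxit = 200L, tol = 1e-10) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  pen <- diag(c(0, lambda))
  for (it in seq_len(maxit)) {
    p <- stats::plogis(drop(X %*% beta))
    w <- pmax(p * (1 - p), 1e-12)
    grad <- drop(crossprod(X, y - p)) - pen %*% beta
    H <- crossprod(X, X * w) + pen
    step <- drop(solve(H, grad))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  names(beta) <- c("(Intercept)", "x")
  beta
}
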