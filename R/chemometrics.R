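## Linear baselines, cross-validation and reference-model comparison.
##
## Single and multiple linear regressions are the field's traditional
## colour-pigment models and are kept as baselines; the multiple linear
## fit standardizes predictors so coefficient magnitudes are comparable
## across light conditions, and deliberately errors on exact collinearity
## (the failure mode that motivates PLS).  Cross-validation follows the
## 10-random-segment scheme: a seeded permutation splits the samples into
## near-equal segments, nine calibrate and one validates in turn, the
## standardisation parameters are re-estimated inside each training fold
## (no leakage), and held-out predictions are reverted to original units
## before RMSEP is computed.

.signif_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Single linear regression of a pigment on one colour parameter
#'
#' @param x Numeric predictor (one colour parameter).
#' @param y Numeric pigment content.
#' @param predictor_name Label for the report.
#' @return List of class `model_report`: `model_type = "single_linear"`,
#'   `slope`, `intercept`, `r2`, `p_value` (two-sided slope test),
#'   `rmse_cal`, `rmse_cal_pct`, `n`.
#' @export
fit_single_linear <- function(x, y, predictor_name = deparse(substitute(x))) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("zero-variance predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  res <- stats::residuals(fit)
  structure(list(model_type = "single_linear",
                 predictor = predictor_name,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = if (stats::sd(y) == 0) 0 else sm$r.squared,
                 p_value = if (stats::sd(y) == 0) NA_real_ else
                   sm$coefficients[2, 4],
                 rmse_cal = sqrt(mean(res^2)),
                 rmse_cal_pct = 100 * sqrt(mean(res^2)) / mean(y),
                 n = length(y)),
            class = "model_report")
}

#' Multiple linear regression on standardized colour parameters
#'
#' Ordinary least squares of the pigment on all colour parameters after
#' z-score standardisation of the predictors, so that coefficient
#' magnitudes are comparable across light conditions.  The design must be
#' full rank: exactly collinear columns (e.g. chroma reconstructed from
#' a* and b* in degenerate data) raise an error naming the dependent
#' columns -- this is the structural failure PLS is used to avoid.
#'
#' @param X Predictor matrix or data frame (samples x colour parameters).
#' @param y Pigment content vector.
#' @return List of class `model_report` with `model_type =
#'   "multiple_linear"`, standardized `coefficients` (with columns
#'   estimate, std_error, t, p, stars), `r2`, overall `p_value` (F test),
#'   `rmse_cal`, `rmse_cal_pct`, `n`.
#' @export
fit_multiple_linear <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X) + 1)
    stop("need n > p + 1 observations")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant predictor column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  Z <- scale(X)
  qz <- qr(cbind(1, Z))
  if (qz$rank < ncol(Z) + 1) {
    piv <- qz$pivot[(qz$rank + 1):(ncol(Z) + 1)] - 1L
    stop("collinear predictor column(s): ",
         paste(colnames(X)[piv], collapse = ", "))
  }
  df <- data.frame(y = y, Z)
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)
  ct <- sm$coefficients[-1, , drop = FALSE]
  coefs <- data.frame(estimate = ct[, 1], std_error = ct[, 2],
                      t = ct[, 3], p = ct[, 4],
                      stars = .signif_stars(ct[, 4]))
  rownames(coefs) <- colnames(X)
  res <- stats::residuals(fit)
  fstat <- sm$fstatistic
  structure(list(model_type = "multiple_linear",
                 coefficients = coefs,
                 r2 = sm$r.squared,
                 p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                            lower.tail = FALSE)),
                 rmse_cal = sqrt(mean(res^2)),
                 rmse_cal_pct = 100 * sqrt(mean(res^2)) / mean(y),
                 n = length(y)),
            class = "model_report")
}

#' @export
print.model_report <- function(x, digits = 4, ...) {
  cat("Model report (", x$model_type, "), n = ", x$n, "\n", sep = "")
  if (x$model_type == "single_linear")
    cat(sprintf("  %s: slope %.4g, intercept %.4g, p = %.3g\n",
                x$predictor, x$slope, x$intercept, x$p_value))
  if (x$model_type == "multiple_linear") print(round_df(x$coefficients, digits))
  cat(sprintf("  R2 = %.3f, RMSE(cal) = %.4g (%.1f%%)\n",
              x$r2, x$rmse_cal, x$rmse_cal_pct))
  invisible(x)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  df
}

#' Cross-validate a colour-pigment model (10 random segments)
#'
#' Splits the samples into `n_segments` near-equal random segments using a
#' seeded permutation, then in turn calibrates on all but one segment and
#' predicts the held-out one.  Standardisation (and everything else the
#' model estimates) is re-computed inside each training fold; held-out
#' predictions are reverted to original units before the error is taken.
#'
#' @param X Predictor matrix (samples x colour parameters).
#' @param y Pigment content vector.
#' @param model_spec List describing the model: `type` (`"pls"`,
#'   `"multiple_linear"`) plus `ncomp` for PLS.  Defaults to 5-component
#'   PLS.
#' @param n_segments Number of segments (default 10).
#' @param seed Mandatory RNG seed for the segment assignment.
#' @return List with `rmsep` (root mean square error of prediction over all
#'   held-out samples), `rmsep_pct` (100 * RMSEP / mean(y)), `predictions`,
#'   `fold` (segment index per sample), `n_segments`, `seed`.
#' @export
cross_validate <- function(X, y, model_spec = list(type = "pls", ncomp = 5),
                           n_segments = 10L, seed) {
  if (missing(seed)) stop("a seed is required for the random segmentation")
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < n_segments)
    stop("cannot form ", n_segments, " non-empty segments from ", n,
         " samples")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_segments), n))
  pred <- numeric(n)
  for (k in seq_len(n_segments)) {
    test <- fold == k
    Xtr <- X[!test, , drop = FALSE]; ytr <- y[!test]
    fit <- switch(model_spec$type,
      pls = fit_pls(Xtr, ytr,
                    ncomp = if (is.null(model_spec$ncomp)) 5L
                            else model_spec$ncomp),
      multiple_linear = {
        Ztr <- scale(Xtr)
        lmfit <- stats::lm.fit(cbind(1, Ztr), ytr)
        list(lm = lmfit, centre = attr(Ztr, "scaled:center"),
             scl = attr(Ztr, "scaled:scale"))
      },
      stop("unknown model type '", model_spec$type, "'"))
    Xte <- X[test, , drop = FALSE]
    pred[test] <- if (model_spec$type == "pls") {
      predict(fit, Xte)
    } else {
      Zte <- sweep(sweep(Xte, 2, fit$centre), 2, fit$scl, "/")
      drop(cbind(1, Zte) %*% fit$lm$coefficients)
    }
  }
  rmsep <- sqrt(mean((pred - y)^2))
  list(rmsep = rmsep, rmsep_pct = 100 * rmsep / mean(y),
       predictions = pred, fold = fold, n_segments = n_segments,
       seed = seed)
}

#' Published reference prediction equations
#'
#' The coefficient vectors of published PLS prediction equations for carrot
#' pigments from (L*, a*, b*, C*, h), keyed by equation id
#' (`eq8`..`eq11`: total anthocyanins and total carotenoids under the
#' default and the polarised zero-exposure conditions) and by
#' `table3:<pigment>` (the default-condition models for each pigment).
#' Shipped as a versioned JSON data file.  Note the two printed versions of
#' the default-condition total-carotenoid model (`eq9` vs `table3`) differ;
#' both are shipped verbatim and the package does not arbitrate.
#'
#' @return Named list; each element has `pigment`, `light_condition` and a
#'   named `coefficients` vector over the five colour predictors.
#' @export
reference_models <- function() {
  path <- system.file("extdata", "reference_models.json",
                      package = "carotlab")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(obj$models, function(m) {
    m$coefficients <- unlist(m$coefficients)
    m
  })
}

.coef_vector <- function(x) {
  if (inherits(x, "carot_pls")) {
    b <- x$coefficients_original_scale
    b[names(b) != "(Intercept)"]
  } else if (is.list(x) && !is.null(x$coefficients)) {
    x$coefficients
  } else {
    x
  }
}

#' Compare fitted coefficients with a reference equation
#'
#' Reports signed per-coefficient differences, cosine similarity, and the
#' fraction of coefficients whose signs agree.  Printed equations show no
#' intercept (it is implicit in the centring), so the comparison is over
#' the five predictor coefficients only.
#'
#' @param model A `carot_pls` fit, a named coefficient vector, or a
#'   reference entry.
#' @param reference A key into [reference_models()] or a named coefficient
#'   vector / reference entry.
#' @return List with `delta` (model - reference, named), `cosine`,
#'   `sign_agreement`, `model_coef`, `reference_coef`.
#' @export
compare_to_reference <- function(model, reference) {
  if (is.character(reference)) {
    refs <- reference_models()
    if (!reference %in% names(refs))
      stop("unknown reference key '", reference, "'; known: ",
           paste(names(refs), collapse = ", "))
    reference <- refs[[reference]]
  }
  a <- .coef_vector(model)
  b <- .coef_vector(reference)
  if (!is.null(names(a)) && !is.null(names(b)) &&
      all(names(b) %in% names(a)))
    a <- a[names(b)]
  if (length(a) != length(b))
    stop("coefficient vectors have different lengths")
  list(delta = a - b,
       cosine = sum(a * b) / sqrt(sum(a^2) * sum(b^2)),
       sign_agreement = mean(sign(a) == sign(b)),
       model_coef = a, reference_coef = b)
}

#' Assemble model reports into result tables
#'
#' Pivots a long data frame of per-model statistics into the standard
#' layouts: one wide table per pigment with light conditions as rows and
#' R2 / calibration RMSE / RMSEP columns, plus the long form.  Cells
#' without a fitted model are left `NA`.
#'
#' @param reports Data frame with columns `pigment`, `light_condition`,
#'   `model_type`, `r2`, `rmse_cal`, `rmse_cal_pct`, `rmsep`, `rmsep_pct`.
#' @return List with `long` (input, row-ordered) and `by_pigment` (named
#'   list of wide per-pigment data frames).
#' @export
build_report_tables <- function(reports) {
  cols <- c("pigment", "light_condition", "model_type", "r2",
            "rmse_cal", "rmse_cal_pct", "rmsep", "rmsep_pct")
  if (nrow(reports) == 0L) {
    empty <- reports[, intersect(cols, names(reports)), drop = FALSE]
    return(list(long = empty, by_pigment = list()))
  }
  long <- reports[order(reports$pigment, reports$light_condition), ,
                  drop = FALSE]
  by_pigment <- lapply(split(long, long$pigment), function(d) {
    d[, setdiff(names(d), "pigment"), drop = FALSE]
  })
  list(long = long, by_pigment = by_pigment)
}

#' Write report tables as markdown
#'
#' @param tables Output of [build_report_tables()].
#' @param path Markdown file to write.
#' @return `path`, invisibly.
#' @export
write_report_markdown <- function(tables, path) {
  lines <- character(0)
  for (pig in names(tables$by_pigment)) {
    d <- tables$by_pigment[[pig]]
    lines <- c(lines, paste0("## ", pig), "")
    num <- vapply(d, is.numeric, TRUE)
    d[num] <- lapply(d[num], function(v) formatC(v, digits = 3,
                                                 format = "fg"))
    header <- paste("|", paste(names(d), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(d)), collapse = " | "), "|")
    body <- apply(d, 1, function(r) paste("|", paste(r, collapse = " | "),
                                          "|"))
    lines <- c(lines, header, sep, body, "")
  }
  writeLines(lines, path)
  invisible(path)
}
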