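# Cohort-level statistics: pairwise-deletion Pearson correlations and
# block-wise hierarchical regression with R^2-change tests and VIFs.

#' Pearson correlation with pairwise deletion
#'
#' Product-moment correlation over rows complete for this specific pair, with
#' the two-sided p from the t(n - 2) transform.
#'
#' @param x,y Numeric vectors of equal length (may contain `NA`).
#' @return A tibble with `r`, `p`, `n`.
#' @export
pearson_pairwise <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3L) stop("fewer than 3 complete pairs", call. = FALSE)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) stop("zero variance in a column", call. = FALSE)
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Marker-by-outcome correlation grid
#'
#' One [pearson_pairwise()] cell per marker/outcome pair, with pairwise
#' deletion so each cell uses every row complete for that pair. Cells whose
#' pair cannot be computed (too few rows, zero variance) are returned with
#' `NA` statistics rather than aborting the grid. `large` flags |r| > 0.6.
#'
#' @param data Data frame.
#' @param markers,outcomes Character vectors of column names.
#' @param large_r Threshold for the `large` flag.
#' @return A tibble: `marker`, `outcome`, `r`, `p`, `n`, `large`.
#' @export
correlation_report <- function(data, markers, outcomes, large_r = 0.6) {
  stopifnot(all(c(markers, outcomes) %in% names(data)))
  grid <- tidyr::expand_grid(marker = markers, outcome = outcomes)
  res <- purrr::pmap_dfr(grid, function(marker, outcome) {
    cell <- tryCatch(pearson_pairwise(data[[marker]], data[[outcome]]),
                     error = function(e) tibble::tibble(r = NA_real_, p = NA_real_,
                                                        n = NA_integer_))
    dplyr::bind_cols(tibble::tibble(marker = marker, outcome = outcome), cell)
  })
  res <- dplyr::mutate(res, large = !is.na(.data$r) & abs(.data$r) > large_r)
  class(res) <- c("correlation_report", class(res))
  res
}

#' Hierarchical (block-wise) multiple regression
#'
#' OLS with an intercept, fitted on the cumulative designs block 1 and
#' block 1 + block 2 over the rows complete for all predictors and the outcome
#' (listwise within the regression). Reports per block the R^2, adjusted R^2,
#' overall F and p; between blocks the R^2 change with
#' `F_change = (dR2 / q) / ((1 - R2_2) / (n - p_2 - 1))` and its p; and per
#' final-block predictor the coefficient and variance inflation factor
#' (`1 / (1 - R2_j)` from regressing predictor j on the others).
#'
#' @param data Data frame.
#' @param y Outcome column name.
#' @param block1,block2 Character vectors of predictor column names.
#' @return A `hier_reg` object; see [tidy.hier_reg()] and [glance.hier_reg()].
#' @export
hierarchical_regression <- function(data, y, block1, block2) {
  vars <- c(y, block1, block2)
  stopifnot(all(vars %in% names(data)))
  cc <- stats::complete.cases(data[vars])
  d <- data[cc, vars]
  n <- nrow(d)
  p2 <- length(block1) + length(block2)
  if (n < p2 + 2L) stop("insufficient complete rows for the final block", call. = FALSE)

  fit_block <- function(preds) {
    X <- as.matrix(d[preds])
    if (qr(cbind(1, X))$rank < length(preds) + 1L) {
      stop("rank-deficient design", call. = FALSE)
    }
    model <- lm(stats::reformulate(preds, response = y), data = d)
    s <- summary(model)
    k <- length(preds)
    tibble::tibble(r2 = s$r.squared, adj_r2 = s$adj.r.squared,
                   f = unname(s$fstatistic[1]), df1 = k, df2 = n - k - 1,
                   p = unname(pf(s$fstatistic[1], k, n - k - 1, lower.tail = FALSE)),
                   fit = list(model))
  }
  b1 <- fit_block(block1)
  b2 <- fit_block(c(block1, block2))
  q <- length(block2)
  dr2 <- b2$r2 - b1$r2
  f_change <- (dr2 / q) / ((1 - b2$r2) / (n - p2 - 1))
  p_change <- pf(f_change, q, n - p2 - 1, lower.tail = FALSE)

  preds <- c(block1, block2)
  vif <- vapply(preds, function(pj) {
    others <- setdiff(preds, pj)
    if (length(others) == 0) return(1)
    r2j <- summary(lm(stats::reformulate(others, response = pj), data = d))$r.squared
    1 / (1 - r2j)
  }, numeric(1))

  structure(list(
    blocks = tibble::tibble(block = 1:2,
                            predictors = c(paste(block1, collapse = "+"),
                                           paste(preds, collapse = "+")),
                            dplyr::bind_rows(b1[1:6], b2[1:6])),
    change = tibble::tibble(delta_r2 = dr2, f_change = f_change,
                            df1 = q, df2 = n - p2 - 1, p_change = p_change),
    coefficients = tibble::tibble(term = names(stats::coef(b2$fit[[1]])),
                                  estimate = unname(stats::coef(b2$fit[[1]]))),
    vif = tibble::tibble(term = preds, vif = unname(vif)),
    n = n, y = y), class = "hier_reg")
}

#' @export
print.hier_reg <- function(x, ...) {
  cat(sprintf("Hierarchical regression of %s (n = %d)\n", x$y, x$n))
  print(x$blocks)
  cat(sprintf("R2 change = %.3f, F(%d, %d) = %.3f, p = %.4g\n",
              x$change$delta_r2, x$change$df1, x$change$df2,
              x$change$f_change, x$change$p_change))
  invisible(x)
}

#' Tidy a hierarchical regression
#'
#' @param x A `hier_reg`.
#' @param ... Unused.
#' @return Final-block coefficients with VIFs as a tibble.
#' @export
tidy.hier_reg <- function(x, ...) {
  dplyr::left_join(x$coefficients, x$vif, by = "term")
}

#' One-row summary of a hierarchical regression
#'
#' @param x A `hier_reg`.
#' @param ... Unused.
#' @return A one-row tibble with both blocks' R^2 and the change test.
#' @export
glance.hier_reg <- function(x, ...) {
  tibble::tibble(n = x$n,
                 r2_block1 = x$blocks$r2[1], r2_block2 = x$blocks$r2[2],
                 adj_r2_block1 = x$blocks$adj_r2[1], adj_r2_block2 = x$blocks$adj_r2[2],
                 delta_r2 = x$change$delta_r2, f_change = x$change$f_change,
                 p_change = x$change$p_change, max_vif = max(x$vif$vif))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
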