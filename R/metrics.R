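#' Regression diagnostics
#'
#' The four diagnostics reported for every model split: PRESS, the residual
#' sum of squares `sum((y - yhat)^2)`; RMSE `sqrt(PRESS / n)`; MAE
#' `mean(|y - yhat|)`; and the coefficient of determination
#' `R2 = 1 - PRESS / sum((y - mean(y))^2)` (which can be negative for a
#' model worse than the mean). `r2(..., squared_pearson = TRUE)` returns
#' the squared Pearson correlation instead.
#'
#' @param y observed values (mg/kg).
#' @param yhat predicted values, same length.
#' @return a single number.
#' @examples
#' press(c(0, 0), c(3, 4))  # 25
#' rmse(c(0, 0), c(3, 4))   # sqrt(12.5)
#' @name diagnostics
NULL

check_paired <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("`y` and `yhat` must match in length")
  if (length(y) < 1L) stop("empty vectors")
  invisible(NULL)
}

#' @rdname diagnostics
#' @export
press <- function(y, yhat) {
  check_paired(y, yhat)
  sum((y - yhat)^2)
}

#' @rdname diagnostics
#' @export
rmse <- function(y, yhat) sqrt(press(y, yhat) / length(y))

#' @rdname diagnostics
#' @export
mae <- function(y, yhat) {
  check_paired(y, yhat)
  mean(abs(y - yhat))
}

#' @rdname diagnostics
#' @param squared_pearson return the squared Pearson correlation instead of
#'   the coefficient of determination.
#' @export
r2 <- function(y, yhat, squared_pearson = FALSE) {
  check_paired(y, yhat)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("`y` is constant; R2 undefined")
  if (squared_pearson) {
    if (stats::sd(yhat) == 0) return(0)
    return(stats::cor(y, yhat)^2)
  }
  1 - press(y, yhat) / tss
}

#' Evaluation report over model splits
#'
#' One row of PRESS / RMSE / MAE / R2 per split (training, testing and,
#' when supplied, validation).
#'
#' @param y_train,yhat_train training-set observed and predicted values.
#' @param y_test,yhat_test testing-set pair.
#' @param y_val,yhat_val optional validation pair.
#' @return data frame of class `eval_report` with columns `split`, `n`,
#'   `press`, `rmse`, `mae`, `r2`.
#' @export
eval_report <- function(y_train, yhat_train, y_test, yhat_test,
                        y_val = NULL, yhat_val = NULL) {
  one <- function(split, y, yhat) {
    data.frame(split = split, n = length(y), press = press(y, yhat),
               rmse = rmse(y, yhat), mae = mae(y, yhat), r2 = r2(y, yhat))
  }
  out <- rbind(one("training", y_train, yhat_train),
               one("testing", y_test, yhat_test))
  if (!is.null(y_val))
    out <- rbind(out, one("validation", y_val, yhat_val))
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat("Residue prediction diagnostics (mg/kg):\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
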