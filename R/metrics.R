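#' Confusion matrix of predicted vs visual scores
#'
#' @param pred,truth integer score vectors of equal length, values in
#'   `0:(K-1)`.
#' @param K number of classes (6 centrilobular, 3 paraseptal).
#' @return K x K integer matrix, rows = predicted, columns = visual.
#' @export
confusion <- function(pred, truth, K) {
  if (length(pred) == 0) stop("confusion: empty input")
  if (length(pred) != length(truth)) stop("confusion: length mismatch")
  if (any(pred < 0 | pred >= K) || any(truth < 0 | truth >= K))
    stop("confusion: labels out of range")
  cm <- matrix(0L, K, K, dimnames = list(pred = 0:(K - 1),
                                         visual = 0:(K - 1)))
  for (i in seq_along(pred))
    cm[pred[i] + 1L, truth[i] + 1L] <- cm[pred[i] + 1L, truth[i] + 1L] + 1L
  cm
}

check_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || nrow(cm) < 2)
    stop("expected a square confusion matrix (K >= 2)")
  if (any(cm < 0)) stop("confusion matrix has negative counts")
  if (sum(cm) == 0) stop("confusion matrix is empty")
  invisible(cm)
}

#' Agreement statistics from a confusion matrix
#'
#' `accuracy()` is `100 * trace / total`; `precision_recall()` returns
#' per-class precision (`100 * diag / rowSums`) and recall
#' (`100 * diag / colSums`); `macro_f()` is the unweighted mean over classes
#' of `2PR/(P+R)` (0 for classes with no support on either margin).
#'
#' @param cm confusion matrix, rows = predicted, columns = visual.
#' @return `accuracy()` and `macro_f()` return a percentage;
#'   `precision_recall()` a data.frame with columns `class`, `precision`,
#'   `recall` (percent).
#' @export
accuracy <- function(cm) {
  check_cm(cm)
  100 * sum(diag(cm)) / sum(cm)
}

#' @rdname accuracy
#' @export
precision_recall <- function(cm) {
  check_cm(cm)
  rs <- rowSums(cm); cs <- colSums(cm)
  data.frame(class = seq_len(nrow(cm)) - 1L,
             precision = ifelse(rs > 0, 100 * diag(cm) / rs, 0),
             recall = ifelse(cs > 0, 100 * diag(cm) / cs, 0))
}

#' @rdname accuracy
#' @export
macro_f <- function(cm) {
  pr <- precision_recall(cm)
  f <- ifelse(pr$precision + pr$recall > 0,
              2 * pr$precision * pr$recall / (pr$precision + pr$recall), 0)
  mean(f)
}

#' Linear weighted kappa with 95\% confidence interval
#'
#' Chance-corrected agreement with disagreement weights `|i - j| / (K - 1)`:
#' `kappa = 1 - sum(d * o) / sum(d * e)` where `o` are observed proportions
#' and `e` the outer product of the marginals. Reported on the x100 scale.
#' The standard error uses the Fleiss-Cohen-Everitt (1969) asymptotic
#' variance of weighted kappa; the interval is `kappa +/- 1.96 SE`.
#'
#' @param cm confusion matrix (rows predicted, columns visual).
#' @param weights `"linear"` (the only scheme implemented).
#' @return list with `kappa` (x100), `se` (x100), `ci` (length-2, x100).
#' @export
weighted_kappa <- function(cm, weights = "linear") {
  check_cm(cm)
  if (!identical(weights, "linear"))
    stop("weighted_kappa: only linear weights are implemented")
  K <- nrow(cm)
  n <- sum(cm)
  p <- cm / n
  pr <- rowSums(p); pc <- colSums(p)
  d <- abs(outer(seq_len(K), seq_len(K), `-`)) / (K - 1)
  w <- 1 - d
  e <- outer(pr, pc)
  if (sum(d * e) == 0)
    stop("weighted_kappa: degenerate marginals, kappa undefined")
  kappa <- 1 - sum(d * p) / sum(d * e)
  # Fleiss, Cohen & Everitt (1969) large-sample variance, agreement weights
  pe <- sum(w * e)
  wbar_i <- as.vector(w %*% pc)     # row-position average vs column marginal
  wbar_j <- as.vector(pr %*% w)     # column-position average vs row marginal
  term <- outer(wbar_i, wbar_j, `+`)
  v <- (sum(p * (w - term * (1 - kappa))^2) -
          (kappa - pe * (1 - kappa))^2) / (n * (1 - pe)^2)
  se <- sqrt(max(v, 0))
  list(kappa = 100 * kappa, se = 100 * se,
       ci = 100 * (kappa + c(-1, 1) * qnorm(0.975) * se))
}

#' Qualitative agreement band for a kappa value
#'
#' Bands at the conventional thresholds on the x100 scale, applied to kappa
#' rounded to two decimals: <= 20 slight, 21-40 fair, 41-60 moderate,
#' 61-80 good, >= 81 excellent.
#'
#' @param kappa100 kappa on the x100 scale.
#' @return One of `"slight"`, `"fair"`, `"moderate"`, `"good"`,
#'   `"excellent"`.
#' @export
agreement_band <- function(kappa100) {
  k <- round(kappa100, 2)
  if (k <= 20) "slight"
  else if (k <= 40) "fair"
  else if (k <= 60) "moderate"
  else if (k <= 80) "good"
  else "excellent"
}

#' Full agreement report for a confusion matrix
#'
#' @param cm confusion matrix (rows predicted, columns visual).
#' @return An `agreement_report` list: `accuracy`, `per_class`
#'   (precision/recall/F per class, percent), `macro_f`, `kappa`, `kappa_ci`,
#'   `band`, `n`.
#' @export
agreement_report <- function(cm) {
  check_cm(cm)
  pr <- precision_recall(cm)
  pr$f <- ifelse(pr$precision + pr$recall > 0,
                 2 * pr$precision * pr$recall / (pr$precision + pr$recall),
                 0)
  wk <- weighted_kappa(cm)
  structure(list(accuracy = accuracy(cm), per_class = pr,
                 macro_f = macro_f(cm), kappa = wk$kappa,
                 kappa_ci = wk$ci, band = agreement_band(wk$kappa),
                 n = sum(cm)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("n = %d  ACC %.2f%%  macro-F %.2f  kappa %.2f (%.2f-%.2f) [%s]\n",
              x$n, x$accuracy, x$macro_f, x$kappa, x$kappa_ci[1],
              x$kappa_ci[2], x$band))
  invisible(x)
}

#' Read a confusion matrix from CSV
#'
#' Expects a square table of counts, rows = predicted, columns = visual, with
#' a header row of class labels.
#'
#' @param path CSV path.
#' @return Integer matrix.
#' @export
load_confusion_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  check_cm(m)
  m
}

#' Published evaluation confusion matrices
#'
#' Count matrices of the classification and regression subtyping networks and
#' of the prior Humphries centrilobular scoring algorithm, all evaluated
#' against Fleischner visual scores on the same COPDGene evaluation set
#' (n = 7143). Shipped as CSV fixtures; rows are predicted scores, columns
#' visual scores.
#'
#' @param which one of `"classification_cle"`, `"classification_pse"`,
#'   `"regression_cle"`, `"regression_pse"`, `"humphries_cle"`.
#' @return Integer confusion matrix.
#' @export
published_confusion <- function(which = c("classification_cle",
                                          "classification_pse",
                                          "regression_cle",
                                          "regression_pse",
                                          "humphries_cle")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("cm_", which, ".csv"),
                      package = "emphysemap", mustWork = TRUE)
  load_confusion_csv(path)
}
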