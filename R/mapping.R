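#' Fleischner score / emphysema-percentage interval mapping
#'
#' The Fleischner system grades centrilobular emphysema on a 6-level ordinal
#' scale (absent, trace, mild, moderate, confluent, advanced destructive) and
#' paraseptal emphysema on a 3-level scale (absent, mild, substantial). Each
#' grade corresponds to an interval of emphysema involvement expressed as a
#' fraction of the lung volume: centrilobular 0-1, 1-5, 5-10, 10-20, 20-30 and
#' 30-100 percent; paraseptal 0-1, 1-5 and 5-100 percent. These intervals are
#' the weak regression targets for training and the decoding rule that turns a
#' predicted percentage back into an ordinal score.
#'
#' Intervals partition [0, 1] with a closed-lower / open-upper convention
#' \code{[r_l, r_u)}; a percentage exactly on a boundary takes the higher
#' score, and 1.0 belongs to the top score.
#'
#' @param subtype `"cle"`/`"centrilobular"` or `"pse"`/`"paraseptal"`.
#' @param table optional replacement interval table, a data.frame with columns
#'   `score`, `r_l`, `r_u` forming a gap-free increasing partition of [0, 1].
#' @return `interval_table()` returns the data.frame of intervals for a
#'   subtype.
#' @examples
#' interval_table("cle")
#' score_to_interval("cle", 1)     # [0.01, 0.05], K = 4e-4
#' percent_to_score("pse", 0.07)   # 2
#' @export
interval_table <- function(subtype, table = NULL) {
  if (!is.null(table)) {
    validate_interval_table(table)
    return(table)
  }
  switch(match_subtype(subtype),
    cle = data.frame(
      score = 0:5,
      label = c("absent", "trace", "mild", "moderate", "confluent", "advanced"),
      r_l = c(0, 0.01, 0.05, 0.10, 0.20, 0.30),
      r_u = c(0.01, 0.05, 0.10, 0.20, 0.30, 1)
    ),
    pse = data.frame(
      score = 0:2,
      label = c("absent", "mild", "substantial"),
      r_l = c(0, 0.01, 0.05),
      r_u = c(0.01, 0.05, 1)
    )
  )
}

match_subtype <- function(subtype) {
  s <- match.arg(tolower(subtype),
                 c("cle", "centrilobular", "pse", "paraseptal"))
  if (s %in% c("cle", "centrilobular")) "cle" else "pse"
}

validate_interval_table <- function(tab) {
  stopifnot(is.data.frame(tab), all(c("score", "r_l", "r_u") %in% names(tab)))
  if (tab$r_l[1] != 0 || tab$r_u[nrow(tab)] != 1)
    stop("interval table must span [0, 1]")
  if (any(tab$r_l >= tab$r_u)) stop("intervals must have r_l < r_u")
  if (nrow(tab) > 1 && any(abs(tab$r_l[-1] - tab$r_u[-nrow(tab)]) > 1e-12))
    stop("intervals must partition [0, 1] with no gaps or overlaps")
  invisible(tab)
}

#' @rdname interval_table
#' @param score integer ordinal score, 0-based.
#' @return `score_to_interval()` returns a list with `r_l`, `r_u` and
#'   `K = (0.5 * (r_l - r_u))^2`, the squared half-width used by
#'   [interval_loss()].
#' @export
score_to_interval <- function(subtype, score, table = NULL) {
  tab <- interval_table(subtype, table)
  if (length(score) != 1L || is.na(score) || score != as.integer(score) ||
      !(score %in% tab$score))
    stop(sprintf("score %s out of range for subtype '%s'",
                 paste(score, collapse = ","), subtype))
  i <- match(as.integer(score), tab$score)
  r_l <- tab$r_l[i]; r_u <- tab$r_u[i]
  list(r_l = r_l, r_u = r_u, K = (0.5 * (r_l - r_u))^2)
}

#' @rdname interval_table
#' @param p emphysema percentage as a fraction of the lung in [0, 1]
#'   (vectorized).
#' @return `percent_to_score()` returns the integer score(s) whose half-open
#'   interval contains `p`.
#' @export
percent_to_score <- function(subtype, p, table = NULL) {
  tab <- interval_table(subtype, table)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]")
  tab$score[findInterval(p, tab$r_l)]
}
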