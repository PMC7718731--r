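# Window-level ROC evaluation: partial AUC up to a false-positive rate of
# 0.05 (pAUC5), rescaled so that a random classifier scores 1.

#' Partial AUC up to FPR 0.05
#'
#' Area under the empirical ROC curve restricted to false-positive rates
#' in [0, 0.05], computed by the trapezoidal rule with tied scores moving
#' the threshold simultaneously (standard empirical ROC) and vertical
#' interpolation at FPR = 0.05.
#'
#' @param scores numeric per-window scores (higher = more associated).
#' @param labels binary truth per window (logical or 0/1); both classes
#'   must be present.
#' @param fprMax upper false-positive-rate bound (default 0.05).
#' @return raw partial area in [0, fprMax].
#' @export
pauc5 <- function(scores, labels, fprMax = 0.05) {
  labels <- as.logical(labels)
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0 || nNeg == 0)
    stop("pAUC requires at least one positive and one negative label")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # ROC vertices at each distinct threshold (ties grouped)
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / nPos)
  fpr <- c(0, fp[last] / nNeg)
  # trapezoidal area over [0, fprMax] with interpolation at the bound
  area <- 0
  for (v in seq_len(length(fpr) - 1)) {
    x0 <- fpr[v]; x1 <- fpr[v + 1]
    y0 <- tpr[v]; y1 <- tpr[v + 1]
    if (x0 >= fprMax) break
    if (x1 > fprMax) {
      y1 <- y0 + (y1 - y0) * (fprMax - x0) / (x1 - x0)
      x1 <- fprMax
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  area
}

#' Rescale a raw pAUC5 against the random classifier
#'
#' The random classifier's ROC is the diagonal, whose area over the
#' [0, 0.05] strip is \eqn{0.05^2 / 2 = 0.00125}; raw partial areas are
#' divided by this so a random classifier scores 1 (and a perfect one
#' 0.05 / 0.00125 = 40).
#'
#' @param raw raw partial area from [pauc5()].
#' @param fprMax the bound used (default 0.05).
#' @return rescaled pAUC5.
#' @export
rescalePauc5 <- function(raw, fprMax = 0.05) {
  raw / (fprMax^2 / 2)
}

#' Score a window table against simulation truth
#'
#' Uses WPPA as the per-window score for each effect type and trait
#' against the matching truth column and returns the rescaled pAUC5.
#' Combinations whose truth has a single class (e.g. indirect effects on
#' a trait with no causal ancestor, where no window is truly associated)
#' are reported as NA.
#'
#' @param table a [WindowTable-class] object (or an array of WPPA values,
#'   windows x traits x effects).
#' @param truth logical array from [truthWindows()] with matching windows.
#' @return data.frame with columns trait, effect, raw_pauc5,
#'   rescaled_pauc5.
#' @export
evaluateRun <- function(table, truth) {
  wp <- if (is(table, "WindowTable")) table@wppa else table
  traits <- dimnames(truth)[[2]]
  effects <- c("direct", "indirect", "overall")
  out <- list()
  for (k in seq_along(traits)) for (e in seq_along(effects)) {
    lab <- truth[, k, e]
    raw <- if (length(unique(lab)) < 2) NA_real_
           else pauc5(wp[, k, e], lab)
    out[[length(out) + 1L]] <- data.frame(
      trait = traits[k], effect = effects[e], raw_pauc5 = raw,
      rescaled_pauc5 = if (is.na(raw)) NA_real_ else rescalePauc5(raw)
    )
  }
  do.call(rbind, out)
}
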