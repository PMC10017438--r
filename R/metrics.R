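# Evaluation suite: confusion matrices, multiclass MCC (Gorodkin form),
# per-stage and macro F1, accuracy, Cohen's kappa, stage proportions,
# transition rates, and the 4-class light-sleep (N1+N2) merge.  Headline
# numbers across many PSGs should be aggregated as medians (robust to
# outlier nights); means may be reported alongside but labelled as such.

drop_unknown_pairs <- function(true, pred) {
  t <- as.character(true); p <- as.character(pred)
  if (length(t) != length(p))
    stop("hypnogram length mismatch: ", length(t), " vs ", length(p))
  keep <- t != "UNKNOWN" & p != "UNKNOWN"
  list(true = t[keep], pred = p[keep])
}

#' Confusion matrix of two hypnograms
#'
#' Rows are the true stages, columns the predicted stages, in the fixed
#' order W, N1, N2, N3, REM.  Epochs where either hypnogram is `UNKNOWN`
#' are dropped pairwise.
#'
#' @param true,pred hypnograms (or character vectors) of equal length.
#' @return 5 x 5 integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(true, pred) {
  z <- drop_unknown_pairs(true, pred)
  lv <- if (all(c(z$true, z$pred) %in% STAGES)) STAGES else
    stop("labels outside the 5-stage vocabulary; merge first?")
  cm <- table(factor(z$true, levels = lv), factor(z$pred, levels = lv))
  structure(unclass(cm), dimnames = list(true = lv, pred = lv),
            class = "confusion_matrix")
}

#' Row-normalized view of a confusion matrix
#' @param cm a [confusion()] matrix.
#' @return Matrix whose rows sum to 1 (0 for absent stages).
#' @export
row_normalize <- function(cm) {
  rs <- rowSums(cm)
  sweep(unclass(cm), 1, ifelse(rs == 0, 1, rs), "/")
}

check_cm <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix (no scored epochs)")
  unclass(cm)
}

#' Multiclass Matthews correlation coefficient (Gorodkin)
#'
#' `MCC = (c*s - sum_k p_k t_k) / sqrt((s^2 - sum p_k^2)(s^2 - sum t_k^2))`
#' with `c` the diagonal sum, `s` the total, `t_k`/`p_k` the row/column
#' sums.  Returns 0 when a marginal is degenerate (single observed class).
#'
#' @param cm a [confusion()] matrix.
#' @export
mcc <- function(cm) {
  cm <- check_cm(cm)
  s <- sum(cm); c0 <- sum(diag(cm))
  tk <- rowSums(cm); pk <- colSums(cm)
  num <- c0 * s - sum(pk * tk)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  if (den == 0) return(0)
  num / den
}

#' Per-stage F1 scores
#'
#' `F1_k = 2 TP_k / (2 TP_k + FP_k + FN_k)`.  A stage absent from both
#' hypnograms gets F1 = 0 and a warning (it drags the macro mean; use
#' `drop_absent` in [f1_macro()] to exclude such stages instead).
#'
#' @param cm a [confusion()] matrix.
#' @return Named numeric vector of length 5.
#' @export
f1_per_stage <- function(cm) {
  cm <- check_cm(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  den <- 2 * tp + fp + fn
  absent <- den == 0
  if (any(absent))
    warning("stage(s) absent from both hypnograms, F1 set to 0: ",
            paste(rownames(cm)[absent], collapse = ", "))
  f1 <- ifelse(absent, 0, 2 * tp / den)
  setNames(as.numeric(f1), rownames(cm))
}

#' Macro F1
#' @param cm a [confusion()] matrix.
#' @param drop_absent exclude stages absent from both hypnograms from the
#'   unweighted mean instead of counting them as 0.
#' @export
f1_macro <- function(cm, drop_absent = FALSE) {
  f1 <- suppressWarnings(f1_per_stage(cm))
  if (drop_absent) {
    present <- rowSums(cm) + colSums(cm) > 0
    f1 <- f1[present]
  }
  mean(f1)
}

#' Simple accuracy
#' @param cm a [confusion()] matrix.
#' @export
accuracy <- function(cm) {
  cm <- check_cm(cm)
  sum(diag(cm)) / sum(cm)
}

#' Cohen's kappa
#' @param cm a [confusion()] matrix.
#' @export
kappa_score <- function(cm) {
  cm <- check_cm(cm)
  s <- sum(cm)
  po <- sum(diag(cm)) / s
  pe <- sum(rowSums(cm) * colSums(cm)) / s^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

#' Stage proportions of a hypnogram
#'
#' @param hyp a hypnogram; `UNKNOWN` epochs are excluded.
#' @return Named length-5 vector of fractions summing to 1.
#' @export
stage_proportions <- function(hyp) {
  s <- as.character(hyp)
  s <- s[s != "UNKNOWN"]
  if (!length(s)) stop("no scored epochs")
  tb <- table(factor(s, levels = STAGES))
  setNames(as.numeric(tb) / length(s), STAGES)
}

#' Stage-transition rate
#'
#' Number of stage changes divided by the number of evaluable consecutive
#' epoch pairs (`length - 1` for a fully scored hypnogram; pairs touching
#' an `UNKNOWN` epoch are excluded).  With `denominator = "length"` the
#' rate is divided by the epoch count instead.
#'
#' @param hyp a hypnogram of length >= 2.
#' @param denominator `"pairs"` (default) or `"length"`.
#' @export
transition_rate <- function(hyp, denominator = c("pairs", "length")) {
  denominator <- match.arg(denominator)
  s <- as.character(hyp)
  if (length(s) < 2) stop("hypnogram too short to count transitions")
  a <- s[-length(s)]; b <- s[-1]
  ok <- a != "UNKNOWN" & b != "UNKNOWN"
  if (!any(ok)) stop("no evaluable consecutive pairs")
  n_trans <- sum(a[ok] != b[ok])
  n_trans / if (denominator == "pairs") sum(ok) else length(s)
}

#' Merge N1 and N2 into light sleep
#'
#' Many portable sleep trackers score N1/N2 jointly as "Light" sleep; this
#' recodes a hypnogram (or collapses a confusion matrix) to the 4-class
#' vocabulary W, LIGHT, N3, REM.  Merging commutes with [confusion()].
#'
#' @param x a hypnogram or a [confusion()] matrix.
#' @return 4-class hypnogram (character vector with class
#'   `hypnogram_light`) or 4 x 4 confusion matrix.
#' @export
merge_light_sleep <- function(x) {
  if (inherits(x, "hypnogram_light") ||
      (is.matrix(x) && nrow(x) == 4))
    stop("input is already light-sleep merged")
  if (is.matrix(x)) {
    cm <- unclass(x)
    stopifnot(nrow(cm) == 5, ncol(cm) == 5)
    g <- c(1, 2, 2, 3, 4)  # W, N1->LIGHT, N2->LIGHT, N3, REM
    out <- matrix(0L, 4, 4, dimnames = list(true = STAGES4, pred = STAGES4))
    for (i in 1:5) for (j in 1:5)
      out[g[i], g[j]] <- out[g[i], g[j]] + cm[i, j]
    return(structure(out, class = "confusion_matrix"))
  }
  s <- as.character(x)
  s[s %in% c("N1", "N2")] <- "LIGHT"
  structure(s, class = "hypnogram_light")
}

#' Confusion matrix on the 4-class light-sleep vocabulary
#' @param true,pred 4-class hypnograms from [merge_light_sleep()].
#' @export
confusion_light <- function(true, pred) {
  t <- as.character(true); p <- as.character(pred)
  if (length(t) != length(p)) stop("length mismatch")
  keep <- t != "UNKNOWN" & p != "UNKNOWN"
  cm <- table(factor(t[keep], levels = STAGES4),
              factor(p[keep], levels = STAGES4))
  structure(unclass(cm), dimnames = list(true = STAGES4, pred = STAGES4),
            class = "confusion_matrix")
}

#' Per-PSG metrics report
#'
#' Computes accuracy, per-stage F1, macro F1, MCC and kappa for each
#' true/predicted hypnogram pair, plus median and mean aggregates (medians
#' are the headline aggregate).
#'
#' @param true_list,pred_list lists of hypnograms.
#' @return List with `per_psg` (data frame) and `median`/`mean` rows.
#' @export
metrics_report <- function(true_list, pred_list) {
  stopifnot(length(true_list) == length(pred_list))
  rows <- lapply(seq_along(true_list), function(i) {
    cm <- confusion(true_list[[i]], pred_list[[i]])
    f1 <- suppressWarnings(f1_per_stage(cm))
    c(accuracy = accuracy(cm), f1_macro = f1_macro(cm), mcc = mcc(cm),
      kappa = kappa_score(cm), setNames(f1, paste0("f1_", names(f1))),
      transition_rate_true = transition_rate(true_list[[i]]),
      transition_rate_pred = transition_rate(pred_list[[i]]))
  })
  per_psg <- as.data.frame(do.call(rbind, rows))
  list(per_psg = per_psg,
       median = apply(per_psg, 2, median),
       mean = colMeans(per_psg))
}
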