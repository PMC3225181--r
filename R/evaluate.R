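#' Is a truth site recovered by a prediction?
#'
#' A binding site counts as identified when at least 50\% of its
#' nucleotides overlap the predicted interval (ceiling on odd lengths:
#' bases are integral). The denominator is the truth site's length, so the
#' test is directional. Sites on different sequences never match.
#'
#' @param truth,pred Single-row site data frames (or lists) with
#'   `seq_index`, `start` (0-based) and `length`.
#' @return Logical scalar.
#' @export
site_recovered <- function(truth, pred) {
  if (truth$seq_index != pred$seq_index) return(FALSE)
  ov <- min(truth$start + truth$length, pred$start + pred$length) -
    max(truth$start, pred$start)
  ov >= ceiling(0.5 * truth$length)
}

#' Confusion counts from greedy one-to-one site matching
#'
#' Predictions are processed in motif-rank then coordinate order; each
#' prediction is a true positive if it recovers a truth site not yet
#' matched by an earlier prediction (the first such site in coordinate
#' order), otherwise a false positive. Truth sites left unmatched are
#' false negatives.
#'
#' @param truth Site data frame with `seq_index`, `start`, `length`.
#' @param preds Prediction data frame with the same columns (and optionally
#'   `motif_rank` used for ordering).
#' @return List of class `"confusion_counts"` with `tp`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, preds) {
  nt <- if (is.null(truth)) 0L else nrow(truth)
  np <- if (is.null(preds)) 0L else nrow(preds)
  if (np > 0L) {
    ord <- if ("motif_rank" %in% names(preds))
      order(preds$motif_rank, preds$seq_index, preds$start)
    else order(preds$seq_index, preds$start)
    preds <- preds[ord, , drop = FALSE]
  }
  if (nt > 0L) {
    truth <- truth[order(truth$seq_index, truth$start), , drop = FALSE]
  }
  matched <- rep(FALSE, nt)
  tp <- 0L
  if (np > 0L && nt > 0L) {
    for (i in seq_len(np)) {
      for (j in seq_len(nt)) {
        if (!matched[j] &&
            site_recovered(truth[j, , drop = FALSE],
                           preds[i, , drop = FALSE])) {
          matched[j] <- TRUE
          tp <- tp + 1L
          break
        }
      }
    }
  }
  structure(list(tp = tp, fp = np - tp, fn = nt - tp),
            class = "confusion_counts")
}

#' Site-level accuracy metrics
#'
#' Sensitivity Sn = TP/(TP+FN), specificity Sp = TP/(TP+FP), performance
#' coefficient PC = TP/(TP+FP+FN) and F-measure F = 2·Sn·Sp/(Sn+Sp), with
#' the convention 0/0 = 0.
#'
#' @param cc A `"confusion_counts"` object or list with `tp`, `fp`, `fn`.
#' @return One-row data frame with columns `sn`, `sp`, `pc`, `f`.
#' @export
accuracy_metrics <- function(cc) {
  rat <- function(num, den) if (den == 0) 0 else num / den
  sn <- rat(cc$tp, cc$tp + cc$fn)
  sp <- rat(cc$tp, cc$tp + cc$fp)
  data.frame(sn = sn, sp = sp,
             pc = rat(cc$tp, cc$tp + cc$fp + cc$fn),
             f = rat(2 * sn * sp, sn + sp))
}

#' Lower-bound specificity
#'
#' When the truth annotation is incomplete (real genomic scans), the number
#' of recovered known sites divided by the number of predicted sites bounds
#' the specificity from below.
#'
#' @param recovered_known Number of known sites recovered.
#' @param predicted_total Total number of predicted sites.
#' @return A number in \[0, 1\]; 0 when nothing was predicted.
#' @export
lb_specificity <- function(recovered_known, predicted_total) {
  stopifnot(recovered_known >= 0, predicted_total >= 0)
  if (recovered_known > predicted_total)
    stop("recovered sites cannot exceed predicted sites")
  if (predicted_total == 0) return(0)
  recovered_known / predicted_total
}

#' Log-odds complementarity ratio between two site finders
#'
#' Over the restricted universe U of sites found by at least one algorithm
#' of the panel and missed by at least one, returns
#' \eqn{\ln[P(A \cap B) / (P(A) P(B))]} with \eqn{P(X) = |X \cap U| / |U|}.
#' A value near 0 means the two finders recover sites independently (good
#' complementarity); large positive values mean redundant recoveries.
#' Returns `-Inf` with a warning when either marginal or the intersection
#' is empty on U.
#'
#' @param found_by Named list mapping each algorithm of the panel to the
#'   vector of site ids it recovered.
#' @param A,B Names of the two algorithms to compare.
#' @return A single number (natural log scale).
#' @export
log_odds_ratio <- function(found_by, A, B) {
  stopifnot(length(found_by) >= 2L, all(c(A, B) %in% names(found_by)))
  all_sites <- unique(unlist(found_by))
  by_all <- Reduce(intersect, found_by)
  U <- setdiff(all_sites, by_all)
  if (length(U) == 0L)
    stop("restricted universe is empty: every site is found by all or none")
  pa <- length(intersect(found_by[[A]], U)) / length(U)
  pb <- length(intersect(found_by[[B]], U)) / length(U)
  pab <- length(intersect(intersect(found_by[[A]], found_by[[B]]), U)) /
    length(U)
  if (pa == 0 || pb == 0 || pab == 0) {
    warning("empty marginal or intersection on the restricted universe; ",
            "returning -Inf")
    return(-Inf)
  }
  log(pab / (pa * pb))
}
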