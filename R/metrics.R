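#' Normalized mutual information between two partitions
#'
#' NMI of a predicted OTU partition against ground-truth taxon labels
#' (or any two partitions of the same read set), computed from the label
#' co-occurrence contingency table with natural-log entropies and, by
#' default, geometric-mean normalisation:
#' `NMI = I(U;V) / sqrt(H(U) * H(V))`.
#'
#' Conventions: if both partitions have a single cluster the agreement is
#' perfect and 1 is returned; if exactly one partition has zero entropy
#' (no information to recover), 0 is returned.
#'
#' @param true_labels,pred_labels Named vectors (names are read ids) or
#'   plain vectors of equal length; both must cover the same read set.
#' @param normalization `"geometric"` (default) or `"arithmetic"`
#'   (`I / ((H(U)+H(V))/2)`).
#' @return A value in `[0, 1]`.
#' @export
nmi <- function(true_labels, pred_labels,
                normalization = c("geometric", "arithmetic")) {
  normalization <- match.arg(normalization)
  if (length(true_labels) == 0)
    stop("empty label vectors")
  if (!is.null(names(true_labels)) && !is.null(names(pred_labels))) {
    if (!setequal(names(true_labels), names(pred_labels)))
      stop("label vectors cover different read sets")
    pred_labels <- pred_labels[names(true_labels)]
  } else if (length(true_labels) != length(pred_labels)) {
    stop("label vectors cover different read sets")
  }
  tab <- table(as.character(true_labels), as.character(pred_labels))
  n <- sum(tab)
  pu <- rowSums(tab) / n
  pv <- colSums(tab) / n
  hu <- -sum(ifelse(pu > 0, pu * log(pu), 0))
  hv <- -sum(ifelse(pv > 0, pv * log(pv), 0))
  if (hu == 0 && hv == 0) return(1)
  if (hu == 0 || hv == 0) return(0)
  pij <- tab / n
  pp <- outer(pu, pv)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / pp[nz]))
  den <- if (normalization == "geometric") sqrt(hu * hv) else (hu + hv) / 2
  max(0, min(1, mi / den))
}

#' Reference-free pair confusion counts at a distance threshold
#'
#' Over all unordered pairs of dereplicated records, a pair is "positive"
#' when its alignment distance is within `theta` and "predicted positive"
#' when the two records share an OTU: TP = within threshold and
#' co-clustered, FN = within threshold but split, FP = beyond threshold but
#' co-clustered, TN = beyond threshold and split. Pairs are
#' abundance-unweighted. The all-pairs distance computation is quadratic
#' and gated to `max_n` records.
#'
#' @param records Sequences (`seq_records`, character vector, FASTA path).
#' @param partition A fitted [dmsc()] object or named vector mapping record
#'   id to OTU.
#' @param theta Distance threshold.
#' @param model A [dist_model()].
#' @param max_n Refuse larger inputs unless `force = TRUE`. Default 20000.
#' @param force Override the size gate.
#' @return Object of class `pair_confusion`: list with `tp`, `tn`, `fp`,
#'   `fn` summing to `choose(N, 2)`.
#' @export
pair_confusion <- function(records, partition, theta, model = dist_model(),
                           max_n = 20000, force = FALSE) {
  rec <- .as_records(records)
  n <- nrow(rec)
  if (n > max_n && !force)
    stop("all-pairs distances on ", n, " records exceed max_n = ", max_n,
         "; set force = TRUE to override")
  otus <- if (inherits(partition, "dmsc")) partition$assignments else partition
  otus <- otus[rec$id]
  if (anyNA(otus)) stop("partition does not cover all records")
  dm <- distance_matrix(rec, model)
  ut <- upper.tri(dm)
  within <- dm[ut] <= theta
  same <- outer(otus, otus, "==")[ut]
  # doubles, not integers: downstream MCC products overflow int range
  out <- list(tp = as.numeric(sum(within & same)),
              tn = as.numeric(sum(!within & !same)),
              fp = as.numeric(sum(!within & same)),
              fn = as.numeric(sum(within & !same)))
  class(out) <- "pair_confusion"
  out
}

#' Matthews correlation coefficient from pair confusion counts
#'
#' `MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, with 0
#' returned when any marginal factor is zero.
#'
#' @param confusion A [pair_confusion()] object, or `tp` directly.
#' @param tn,fp,fn Counts when `confusion` is given as a number.
#' @return A value in `[-1, 1]`.
#' @export
mcc <- function(confusion, tn = NULL, fp = NULL, fn = NULL) {
  if (inherits(confusion, "pair_confusion") || is.list(confusion)) {
    tp <- confusion$tp
    tn <- confusion$tn
    fp <- confusion$fp
    fn <- confusion$fn
  } else {
    tp <- confusion
  }
  if (tp + tn + fp + fn == 0) stop("at least one pair is required")
  m1 <- tp + fp
  m2 <- tp + fn
  m3 <- tn + fp
  m4 <- tn + fn
  if (m1 == 0 || m2 == 0 || m3 == 0 || m4 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(m1 * m2 * m3 * m4)
}

#' @export
print.pair_confusion <- function(x, ...) {
  cat(sprintf("pair confusion: TP=%.0f TN=%.0f FP=%.0f FN=%.0f (MCC = %.4f)\n",
              x$tp, x$tn, x$fp, x$fn, mcc(x)))
  invisible(x)
}
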