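#' Pairwise-alignment distance model
#'
#' Configuration of the genetic distance used throughout the clustering:
#' a global pairwise sequence alignment (PSA) under unit edit cost, with the
#' distance defined as the number of difference columns divided by a
#' normalising length. Among all cost-optimal alignments the one with the
#' fewest gap columns is used, which makes the alignment length (and hence
#' the distance) a deterministic function of the sequence pair.
#'
#' @param normalize `"alignment"` (default) divides by the alignment length;
#'   `"shortest"` divides by the shorter sequence length (values above 1 are
#'   clamped to 1).
#' @param end_gaps_free If `TRUE`, leading/trailing gaps cost nothing and
#'   are excluded from the alignment length (semi-global alignment).
#' @param gap_counts_as_difference If `FALSE`, gap columns are excluded from
#'   the difference count (the alignment itself is still optimised under
#'   unit cost).
#'
#' An `N` base never matches anything, including another `N`, so ambiguous
#' bases cannot glue clusters together.
#'
#' @return An object of class `dmsc_dist_model`.
#' @export
dist_model <- function(normalize = c("alignment", "shortest"),
                       end_gaps_free = FALSE,
                       gap_counts_as_difference = TRUE) {
  normalize <- match.arg(normalize)
  structure(list(normalize = normalize,
                 end_gaps_free = isTRUE(end_gaps_free),
                 gap_counts_as_difference = isTRUE(gap_counts_as_difference)),
            class = "dmsc_dist_model")
}

.is_default_model <- function(model) {
  model$normalize == "alignment" && !model$end_gaps_free &&
    model$gap_counts_as_difference
}

# Core distance kernel: one query against many targets.
#   cutoff < 0  -> exact distances (adaptive band, always the full-DP optimum)
#   cutoff >= 0 -> exact whenever d <= cutoff; larger distances may be
#                  reported as Inf ("known greater than cutoff")
#   full = TRUE -> plain full-matrix DP (no banding at all)
# Returns a list(d, rawD, L); rawD is the raw edit cost (a metric), used for
# triangle-inequality pruning bounds.
.dist_query <- function(query, targets, model = dist_model(), cutoff = -1,
                        full = FALSE) {
  if (nchar(query) == 0 || any(nchar(targets) == 0))
    stop("sequences must be non-empty")
  res <- cpp_dist_batch(query, targets, cutoff, model$end_gaps_free,
                        if (model$normalize == "shortest") 1L else 0L,
                        model$gap_counts_as_difference, full)
  .dmsc_state$alignments <- .dmsc_state$alignments + length(targets)
  list(d = unname(res[, 1]), rawD = unname(res[, 2]), L = unname(res[, 3]))
}

#' Genetic distance between two sequences
#'
#' Distance in `[0, 1]` from an optimal global unit-cost alignment:
#' difference columns (mismatches and gaps) divided by the alignment length
#' (see [dist_model()] for variants). `seq_distance` is vectorised over `b`.
#'
#' @param a A single DNA string.
#' @param b One or more DNA strings.
#' @param model A [dist_model()].
#' @return Numeric vector of distances in `[0, 1]`.
#' @examples
#' seq_distance("ACGTACGTAC", "ACGTACGTAT")  # 0.1
#' seq_distance("ACGT", "ACG")               # 0.25
#' @export
seq_distance <- function(a, b, model = dist_model()) {
  a <- toupper(a)
  b <- toupper(b)
  .dist_query(a, b, model)$d
}

#' All-pairs distance matrix
#'
#' @param x Sequences: a `seq_records` table, named character vector, or
#'   `XStringSet`.
#' @param model A [dist_model()].
#' @param full Use the plain (unbanded) dynamic program for every pair;
#'   result is identical, only slower. Used by the straight-line reference
#'   engine.
#' @return Symmetric matrix with zero diagonal, dimnames from record ids.
#' @export
distance_matrix <- function(x, model = dist_model(), full = FALSE) {
  rec <- .as_records(x)
  n <- nrow(rec)
  if (n == 0) return(matrix(numeric(0), 0, 0))
  m <- matrix(0, n, n, dimnames = list(rec$id, rec$id))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      d <- .dist_query(rec$bases[i], rec$bases[(i + 1):n], model,
                       full = full)$d
      m[i, (i + 1):n] <- d
      m[(i + 1):n, i] <- d
    }
  }
  m
}
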