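#' @export
print.dmsc <- function(x, ...) {
  cat("Dynamic multi-seeds clustering (DMSC)\n")
  if (!is.null(x$call)) {
    cat("Call: ")
    print(x$call)
  }
  cat(sprintf("  %d reads, %d dereplicated records, theta = %g\n",
              x$n_reads, x$n_records, x$params$theta))
  cat(sprintf("  OTUs: %d   (MCS-represented: %d, single-seed: %d)\n",
              x$n_otus, sum(x$mcs_sizes > 0), sum(x$mcs_sizes == 0)))
  if (!is.na(x$alignment_calls))
    cat(sprintf("  alignment calls: %d\n", as.integer(x$alignment_calls)))
  invisible(x)
}

#' @export
#' @method summary dmsc
summary.dmsc <- function(object, ...) {
  out <- list(
    n_reads = object$n_reads,
    n_records = object$n_records,
    n_otus = object$n_otus,
    theta = object$params$theta,
    eta = object$params$eta,
    mu = object$params$mu,
    assign_policy = object$params$assign_policy,
    mcs_sizes = object$mcs_sizes,
    otu_reads = object$otu_reads,
    alignment_calls = object$alignment_calls
  )
  class(out) <- "summary.dmsc"
  out
}

#' @export
print.summary.dmsc <- function(x, ...) {
  cat("DMSC clustering summary\n")
  cat(sprintf("  parameters: theta = %g, eta = %s, mu = %g, policy = %s\n",
              x$theta, format(x$eta), x$mu, x$assign_policy))
  cat(sprintf("  %d reads -> %d records -> %d OTUs\n",
              x$n_reads, x$n_records, x$n_otus))
  if (length(x$otu_reads)) {
    cat("  reads per OTU:\n")
    print(summary(x$otu_reads))
    cat("  MCS sizes (0 = single-seed cluster):\n")
    print(summary(as.integer(x$mcs_sizes)))
  }
  if (!is.na(x$alignment_calls))
    cat(sprintf("  alignment calls: %d\n", as.integer(x$alignment_calls)))
  invisible(x)
}

#' Assign new sequences to the OTUs of a fitted clustering
#'
#' Applies the fitted model's assignment rule (seed distance for
#' single-seed OTUs, average-distance-to-MCS with the standard-deviation
#' relaxation for MCS OTUs) to new sequences without updating any cluster.
#'
#' @param object A fitted [dmsc()] object.
#' @param newdata Sequences (`seq_records`, character vector, FASTA path or
#'   `XStringSet`).
#' @param ... Unused.
#' @return Named character vector of OTU ids; `NA` where no OTU qualifies.
#' @export
predict.dmsc <- function(object, newdata, ...) {
  rec <- .as_records(newdata)
  params <- object$params
  base_of <- function(id) object$records$bases[match(id, object$records$id)]
  out <- rep(NA_character_, nrow(rec))
  otus <- names(object$clusters)
  for (i in seq_len(nrow(rec))) {
    best_d <- Inf
    best <- NA_character_
    for (k in seq_along(object$clusters)) {
      info <- object$clusters[[k]]
      if (length(info$mcs)) {
        ds <- .dist_query(rec$bases[i], base_of(info$mcs), params$model)$d
        dval <- sum(ds) / length(ds)
        qual <- .mcs_qualifies(dval, info$mean, info$sigma, params$theta,
                               params$mu, params$eq1_literal)
      } else {
        dval <- .dist_query(rec$bases[i], base_of(info$seed), params$model,
                            cutoff = params$theta)$d
        qual <- is.finite(dval) && dval <= params$theta
      }
      if (qual && dval < best_d) {
        best_d <- dval
        best <- otus[k]
      }
      if (qual && params$assign_policy == "first") break
    }
    out[i] <- best
  }
  names(out) <- rec$id
  out
}

#' Plot the OTU abundance profile of a fitted clustering
#'
#' Barplot of reads per OTU in decreasing order; MCS-represented OTUs are
#' distinguished from single-seed OTUs by colour.
#'
#' @param x A fitted [dmsc()] object.
#' @param ... Passed to [graphics::barplot()].
#' @export
#' @method plot dmsc
plot.dmsc <- function(x, ...) {
  if (x$n_otus == 0) {
    warning("empty clustering; nothing to plot")
    return(invisible(x))
  }
  ord <- order(-x$otu_reads)
  cols <- ifelse(x$mcs_sizes[ord] > 0, "steelblue", "grey70")
  graphics::barplot(x$otu_reads[ord], names.arg = names(x$mcs_sizes)[ord],
                    col = cols, las = 2, cex.names = 0.6,
                    ylab = "reads", main = "Reads per OTU", ...)
  graphics::legend("topright", fill = c("steelblue", "grey70"),
                   legend = c("MCS cluster", "single seed"), bty = "n")
  invisible(x)
}
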