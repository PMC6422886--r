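#' Straight-line reference implementation of the clustering
#'
#' A deliberately simple re-implementation of the dynamic multi-seeds
#' algorithm used as an internal correctness oracle: the complete pairwise
#' distance matrix is computed up front with the plain (unbanded) dynamic
#' program, the MCS of every activated cluster is re-selected from scratch
#' after every merge, and all statistics are recomputed from scratch. No
#' caching, banding, pruning or incremental shortcuts. On identical inputs
#' and parameters its partition is identical to [dmsc()]'s; it is quadratic
#' in both time and memory and only suitable for small datasets.
#'
#' @inheritParams dmsc
#' @return An object of class `dmsc` (without alignment-call accounting).
#' @seealso [dmsc()]
#' @export
dmsc_reference <- function(x, theta, eta = 25L, mu = 3, min_core = 3L,
                           max_core = Inf,
                           assign_policy = c("best", "first"),
                           rescue_singletons = TRUE, eq1_literal = FALSE,
                           sigma_divisor = c("size", "pairs"),
                           model = dist_model()) {
  params <- .dmsc_params(theta, eta, mu, min_core, max_core,
                         match.arg(assign_policy), rescue_singletons,
                         eq1_literal, match.arg(sigma_divisor), model,
                         prune = FALSE, rng_seed = NULL)
  rec <- dereplicate(.as_records(x))
  n <- nrow(rec)
  D <- distance_matrix(rec, model, full = TRUE)

  members <- list()   # per cluster: global record indices in arrival order
  mcs <- list()       # per cluster: global record indices (subset of members)
  act <- logical(0)
  means <- sigmas <- numeric(0)

  greedy_clique <- function(mem) {
    core <- mem[1]
    for (g in mem[-1]) {
      if (length(core) >= params$max_core) break
      if (all(D[g, core] < theta)) core <- c(core, g)
    }
    if (length(core) >= params$min_core) core else integer(0)
  }
  stats_of <- function(core) {
    sub <- D[core, core, drop = FALSE]
    dv <- sub[upper.tri(sub)]
    mn <- sum(dv) / length(dv)
    den <- if (params$sigma_divisor == "size") length(core) - 1L
           else length(dv) - 1L
    c(mn, sqrt(sum((dv - mn)^2) / den))
  }
  reselect <- function(k) {
    core <- greedy_clique(members[[k]])
    mcs[[k]] <<- core
    if (length(core)) {
      s <- stats_of(core)
      means[k] <<- s[1]
      sigmas[k] <<- s[2]
    } else {
      means[k] <<- NA_real_
      sigmas[k] <<- NA_real_
    }
  }

  for (g in seq_len(n)) {
    hit <- 0L
    best_d <- Inf
    for (k in seq_along(members)) {
      if (length(mcs[[k]]) == 0) {
        dval <- D[g, members[[k]][1]]
        qual <- dval <= theta
      } else {
        dval <- sum(D[g, mcs[[k]]]) / length(mcs[[k]])
        qual <- .mcs_qualifies(dval, means[k], sigmas[k], theta, mu,
                               params$eq1_literal)
      }
      if (!qual) next
      if (params$assign_policy == "first") {
        hit <- k
        break
      }
      if (dval < best_d) {
        best_d <- dval
        hit <- k
      }
    }
    if (hit > 0L) {
      members[[hit]] <- c(members[[hit]], g)
      if (!act[hit]) {
        if (length(members[[hit]]) >= params$eta) {
          act[hit] <- TRUE
          reselect(hit)
        }
      } else {
        reselect(hit)
      }
    } else {
      members[[length(members) + 1L]] <- g
      mcs[[length(members)]] <- integer(0)
      act[length(members)] <- FALSE
      means[length(members)] <- NA_real_
      sigmas[length(members)] <- NA_real_
    }
  }

  # finalization: rescue isolated reads, then one OTU per surviving cluster
  assign_k <- integer(n)
  for (k in seq_along(members)) assign_k[members[[k]]] <- k
  reads_per_cluster <- vapply(members,
                              function(m) sum(rec$abundance[m]), 0)
  singleton <- reads_per_cluster == 1
  targets <- which(!singleton)
  if (params$rescue_singletons && length(targets) > 0 && any(singleton)) {
    for (k in which(singleton)) {
      g <- members[[k]]
      dvals <- vapply(targets, function(j) {
        if (length(mcs[[j]]) > 0) sum(D[g, mcs[[j]]]) / length(mcs[[j]])
        else D[g, members[[j]][1]]
      }, 0)
      assign_k[g] <- targets[which.min(dvals)]
    }
    keep <- targets
  } else {
    keep <- seq_along(members)
  }
  otu_ids <- sprintf("OTU_%04d", seq_along(keep))
  k_to_otu <- rep(NA_character_, length(members))
  k_to_otu[keep] <- otu_ids
  assignments <- k_to_otu[assign_k]
  names(assignments) <- rec$id

  representatives <- character(length(keep))
  core_flags <- rep(FALSE, n)
  mcs_sizes <- integer(length(keep))
  for (i in seq_along(keep)) {
    k <- keep[i]
    if (length(mcs[[k]]) > 0) {
      mg <- mcs[[k]]
      core_flags[mg] <- TRUE
      representatives[i] <- rec$id[mg[which.max(rec$abundance[mg])]]
      mcs_sizes[i] <- length(mg)
    } else {
      representatives[i] <- rec$id[members[[k]][1]]
    }
  }
  names(representatives) <- otu_ids
  names(core_flags) <- rec$id
  names(mcs_sizes) <- otu_ids

  structure(list(
    assignments = assignments,
    representatives = representatives,
    core_flags = core_flags,
    records = rec,
    n_reads = attr(rec, "n_reads") %||% sum(rec$abundance),
    n_records = n,
    n_otus = length(keep),
    mcs_sizes = mcs_sizes,
    params = params,
    alignment_calls = NA_real_
  ), class = "dmsc")
}
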