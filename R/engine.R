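#' Cluster 16S rRNA reads into OTUs by dynamic multi-seeds clustering
#'
#' Fits the dynamic multi-seeds clustering (DMSC) model to a set of amplicon
#' reads. Reads are dereplicated and streamed in abundance order; each read
#' either joins a qualifying cluster or founds a new one. Once a cluster
#' reaches `eta` members, a set of multi-core sequences (MCS) is selected: a
#' greedy clique of at least `min_core` members whose pairwise distances are
#' all strictly below `theta`. From then on a read `s` qualifies for the
#' cluster when its average distance to the MCS, `d(s, M)`, satisfies
#' `d(s, M) <= theta` or `|d(s, M) - mean(M)| <= mu * sigma(M)`, where
#' `mean(M)` and `sigma(M)` are the mean and standard deviation of all
#' within-MCS pairwise distances. The MCS is updated after every merge.
#' Finally, isolated reads (clusters holding a single raw read) are rescued
#' into their nearest surviving cluster.
#'
#' @param x Input reads: a FASTA path, a `seq_records` table from
#'   [read_fasta()], a named character vector of sequences, or an
#'   `XStringSet`.
#' @param theta Distance threshold in (0, 1); 0.03 corresponds to the common
#'   97 percent identity OTU definition.
#' @param eta Minimum number of (dereplicated) members a cluster needs
#'   before MCS selection is activated. Default 25.
#' @param mu Multiplier on the within-MCS distance standard deviation in the
#'   assignment relaxation. Default 3.
#' @param min_core Minimum MCS size; if no clique of at least this size
#'   exists the cluster stays represented by its single seed. Default 3.
#' @param max_core Optional cap on the MCS size (an approximation for
#'   speed); default `Inf` (no cap).
#' @param assign_policy `"best"` (default): among qualifying clusters the one
#'   with the smallest relevant distance accepts, ties by creation order;
#'   `"first"`: the first qualifying cluster in creation order accepts.
#' @param rescue_singletons Rescue isolated reads into their nearest
#'   non-singleton cluster at the end. Default `TRUE`.
#' @param eq1_literal Use the literal assignment predicate
#'   `|d(s, M)| <= mu * sigma` instead of the default reading (see Details).
#' @param sigma_divisor `"size"` (default) divides the pair-summed squared
#'   deviations by `|M| - 1`; `"pairs"` divides by the pair count minus 1.
#' @param model Distance model, see [dist_model()].
#' @param prune Allow provably-exact pruning of cluster evaluations via
#'   triangle-inequality lower bounds (never changes the result; disabled
#'   automatically for non-default distance models). Default `TRUE`.
#' @param rng_seed Optional integer recorded in the fit metadata. The
#'   algorithm itself is deterministic and uses no randomness.
#'
#' @details The deviation branch of the assignment rule is what
#' distinguishes multi-seeds clustering from plain greedy single-seed
#' clustering: it admits reads whose average distance to the core lies
#' within the cluster's own distance spread, even slightly beyond `theta`.
#' With `eq1_literal = TRUE` the rule collapses to `d(s, M) <= mu * sigma`,
#' which rejects nearly everything when `sigma` is small; it is provided for
#' comparison only.
#'
#' Setting `min_core` above any attainable clique size (or `eta` above the
#' input size) degenerates the algorithm to a plain single-seed greedy
#' clusterer.
#'
#' @return An object of class `dmsc` with components `assignments` (named
#'   OTU id per dereplicated record), `representatives`, `core_flags`,
#'   `records`, `n_otus`, `otu_sizes`, `otu_reads`, `mcs_sizes`, `params`,
#'   `alignment_calls`, and `clusters` (per-OTU seed/MCS state used by
#'   [predict.dmsc()]).
#'
#' @examples
#' reads <- make_reads(dmsc_preset("stacked60", scale = 0.05, rng_seed = 1))
#' fit <- dmsc(reads, theta = 0.03)
#' fit
#' @export
dmsc <- function(x, theta, eta = 25L, mu = 3, min_core = 3L, max_core = Inf,
                 assign_policy = c("best", "first"),
                 rescue_singletons = TRUE, eq1_literal = FALSE,
                 sigma_divisor = c("size", "pairs"),
                 model = dist_model(), prune = TRUE, rng_seed = NULL) {
  cl_call <- match.call()
  params <- .dmsc_params(theta, eta, mu, min_core, max_core,
                         match.arg(assign_policy), rescue_singletons,
                         eq1_literal, match.arg(sigma_divisor), model,
                         prune, rng_seed)
  rec <- dereplicate(.as_records(x))
  calls0 <- .dmsc_state$alignments
  st <- .greedy_pass(rec, params)
  fit <- .finalize(st, params)
  fit$alignment_calls <- .dmsc_state$alignments - calls0
  fit$call <- cl_call
  fit
}

.dmsc_params <- function(theta, eta, mu, min_core, max_core, assign_policy,
                         rescue_singletons, eq1_literal, sigma_divisor,
                         model, prune, rng_seed) {
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0 || theta >= 1)
    stop("theta must be a single number in (0, 1)")
  if (mu <= 0) stop("mu must be positive")
  min_core <- as.integer(min_core)
  if (min_core < 3L) stop("min_core must be at least 3")
  if (is.finite(eta)) eta <- as.integer(eta)
  if (eta < min_core) stop("eta must be >= min_core")
  if (is.finite(max_core) && max_core < min_core)
    stop("max_core must be >= min_core")
  stopifnot(inherits(model, "dmsc_dist_model"))
  list(theta = theta, eta = eta, mu = mu, min_core = min_core,
       max_core = max_core, assign_policy = assign_policy,
       rescue_singletons = isTRUE(rescue_singletons),
       eq1_literal = isTRUE(eq1_literal), sigma_divisor = sigma_divisor,
       model = model, prune = isTRUE(prune) && .is_default_model(model),
       rng_seed = rng_seed)
}

# ---- streaming state ------------------------------------------------------

.new_state <- function(rec, params) {
  st <- new.env(parent = emptyenv())
  st$rec <- rec
  st$bases <- rec$bases
  st$ids <- rec$id
  st$abund <- rec$abundance
  st$lens <- nchar(rec$bases)
  st$clusters <- list()
  st
}

.new_cluster <- function(g) {
  cl <- new.env(parent = emptyenv())
  cl$mem <- g                 # global record indices, arrival order
  cl$mcs <- integer(0)        # local indices into mem, ascending
  cl$act <- FALSE
  cl$mean <- NA_real_
  cl$sigma <- NA_real_
  cl$dmat <- matrix(NA_real_, 4, 4)  # cached pairwise distances (local idx)
  cl$rmat <- matrix(NA_real_, 4, 4)  # cached raw edit costs
  cl$dmat[1, 1] <- cl$rmat[1, 1] <- 0
  cl
}

.cl_grow <- function(cl, need) {
  cap <- nrow(cl$dmat)
  if (need <= cap) return(invisible())
  newcap <- max(need, 2L * cap)
  for (f in c("dmat", "rmat")) {
    m <- matrix(NA_real_, newcap, newcap)
    m[seq_len(cap), seq_len(cap)] <- cl[[f]]
    cl[[f]] <- m
  }
  invisible()
}

# Cached within-cluster pair distance between local member indices.
# Computed with a theta cutoff: finite values are exact; Inf means the
# distance is known to exceed theta (sufficient for all clique checks).
.cl_pair <- function(cl, li, lj, st, params) {
  v <- cl$dmat[li, lj]
  if (!is.na(v)) return(v)
  q <- .dist_query(st$bases[cl$mem[li]], st$bases[cl$mem[lj]], params$model,
                   cutoff = params$theta)
  cl$dmat[li, lj] <- cl$dmat[lj, li] <- q$d
  cl$rmat[li, lj] <- cl$rmat[lj, li] <- q$rawD
  q$d
}

# ---- MCS selection and statistics ----------------------------------------

# Greedy clique over the sub-threshold distance graph: members are scanned
# in arrival order starting from the seed; a member joins the core when its
# distance to every current core member is strictly below theta. Arrival
# order equals (abundance desc, sequence asc) from the dereplication sort,
# so the scan is a pure function of the sequence multiset, and an
# incremental re-scan after appending one member provably equals a full
# re-scan.
.select_mcs <- function(cl, st, params) {
  m <- length(cl$mem)
  core <- 1L
  for (li in seq_len(m)[-1]) {
    if (length(core) >= params$max_core) break
    ok <- TRUE
    for (cj in core) {
      if (!(.cl_pair(cl, cj, li, st, params) < params$theta)) {
        ok <- FALSE
        break
      }
    }
    if (ok) core <- c(core, li)
  }
  if (length(core) >= params$min_core) {
    cl$mcs <- core
    .update_stats(cl, params)
  } else {
    cl$mcs <- integer(0)
    cl$mean <- NA_real_
    cl$sigma <- NA_real_
  }
  cl$act <- TRUE
  invisible()
}

# Within-MCS mean pairwise distance and standard deviation. The deviation
# sum runs over all unordered pairs but is divided by |M| - 1 (the printed
# definition); sigma_divisor = "pairs" gives the pair-count - 1 variant.
.update_stats <- function(cl, params) {
  sub <- cl$dmat[cl$mcs, cl$mcs, drop = FALSE]
  dv <- sub[upper.tri(sub)]
  mean_d <- sum(dv) / length(dv)
  den <- if (params$sigma_divisor == "size") length(cl$mcs) - 1L
         else length(dv) - 1L
  cl$mean <- mean_d
  cl$sigma <- if (den > 0) sqrt(sum((dv - mean_d)^2) / den) else 0
  invisible()
}

#' Mean and standard deviation of within-MCS pairwise distances
#'
#' For a candidate multi-core sequence set, computes the mean of all
#' pairwise distances and the standard deviation defined as the square root
#' of the pair-summed squared deviations divided by `|M| - 1` (the size of
#' the set minus one, not the pair count minus one; set
#' `sigma_divisor = "pairs"` for that variant).
#'
#' @param x At least three sequences (`seq_records`, character vector, or
#'   `XStringSet`).
#' @param model A [dist_model()].
#' @param sigma_divisor `"size"` (default) or `"pairs"`.
#' @return A list with `mean`, `sigma`, `n` (set size) and `n_pairs`.
#' @examples
#' s <- c(a = strrep("A", 50), b = paste0("T", strrep("A", 49)),
#'        c = paste0("TT", strrep("A", 48)))
#' mcs_stats(s)
#' @export
mcs_stats <- function(x, model = dist_model(),
                      sigma_divisor = c("size", "pairs")) {
  sigma_divisor <- match.arg(sigma_divisor)
  rec <- .as_records(x)
  m <- nrow(rec)
  if (m < 3) stop("an MCS must contain at least 3 sequences")
  dm <- distance_matrix(rec, model)
  dv <- dm[upper.tri(dm)]
  mean_d <- sum(dv) / length(dv)
  den <- if (sigma_divisor == "size") m - 1L else length(dv) - 1L
  list(mean = mean_d, sigma = sqrt(sum((dv - mean_d)^2) / den),
       n = m, n_pairs = length(dv))
}

# ---- assignment -----------------------------------------------------------

# Assignment predicate for MCS clusters: default reading admits a
# sequence whose average distance to the core is within theta OR within
# mu*sigma of the within-core mean; the literal variant uses only
# |d(s,M)| <= mu*sigma.
.mcs_qualifies <- function(dval, mean_d, sigma, theta, mu, literal = FALSE) {
  if (literal) abs(dval) <= mu * sigma
  else dval <= theta || abs(dval - mean_d) <= mu * sigma
}

# Qualification supremum of a cluster: no sequence with relevant distance
# above this value can qualify.
.cl_sup <- function(cl, params) {
  if (length(cl$mcs) == 0) return(params$theta)
  if (params$eq1_literal) params$mu * cl$sigma
  else max(params$theta, cl$mean + params$mu * cl$sigma)
}

# Anchor step: one alignment against the first core member (or the seed),
# plus member-wise triangle-inequality lower bounds on the remaining core
# distances. For single-seed clusters the anchor already decides
# qualification.
.eval_anchor <- function(g, cl, st, params) {
  if (length(cl$mcs) == 0) {
    q <- .dist_query(st$bases[g], st$bases[cl$mem[1]], params$model,
                     cutoff = params$theta)
    return(list(kind = "seed", dval = q$d, bound = q$d,
                qual = is.finite(q$d) && q$d <= params$theta,
                ds = q$d, rawD = q$rawD, complete = TRUE))
  }
  q1 <- .dist_query(st$bases[g], st$bases[cl$mem[cl$mcs[1]]], params$model)
  nm <- length(cl$mcs)
  if (params$prune && nm > 1) {
    # d_j >= 2*max(0, D1 - D(anchor, j)) / (|s| + |m_j| + that bound):
    # D1 and D(anchor, j) are raw edit costs (a metric), and the
    # denominator over-estimates the alignment length, so each term is a
    # true lower bound on the normalized distance to core member j.
    rvec <- cl$rmat[cl$mcs[1], cl$mcs][-1]
    bj <- pmax(0, q1$rawD - rvec)
    lens <- st$lens[cl$mem[cl$mcs]][-1]
    lbv <- ifelse(bj > 0, 2 * bj / (st$lens[g] + lens + bj), 0)
    bound <- (q1$d + sum(lbv)) / nm
  } else {
    lbv <- numeric(nm - 1L)
    bound <- q1$d / nm
  }
  list(kind = "mcs", dval = NA_real_, bound = bound, qual = NA,
       d1 = q1$d, rawD1 = q1$rawD, lbv = lbv, complete = FALSE)
}

# Complete an MCS evaluation: exact distances to all core members,
# evaluated in blocks with early abandon once exact-so-far plus lower
# bounds for the rest prove the average exceeds `thr` (in which case the
# cluster provably cannot qualify and/or cannot win best-fit).
.eval_mcs_full <- function(g, cl, a, thr, st, params) {
  mg <- cl$mem[cl$mcs]
  nm <- length(mg)
  ds <- rawD <- numeric(nm)
  ds[1] <- a$d1
  rawD[1] <- a$rawD1
  if (nm > 1) {
    tl <- c(rev(cumsum(rev(a$lbv))), 0)      # tl[k] = bounds for k+1..nm
    sumd <- a$d1
    i <- 2L
    while (i <= nm) {
      if ((sumd + tl[i - 1L]) / nm > thr + 1e-9)
        return(list(qual = FALSE, dval = Inf, kind = "mcs",
                    complete = FALSE))
      j2 <- min(nm, i + 15L)
      qr <- .dist_query(st$bases[g], st$bases[mg[i:j2]], params$model)
      ds[i:j2] <- qr$d
      rawD[i:j2] <- qr$rawD
      sumd <- sumd + sum(qr$d)
      i <- j2 + 1L
    }
  }
  dval <- sum(ds) / nm
  qual <- .mcs_qualifies(dval, cl$mean, cl$sigma, params$theta, params$mu,
                         params$eq1_literal)
  list(qual = qual, dval = dval, ds = ds, rawD = rawD, kind = "mcs",
       complete = TRUE)
}

# Evaluate one candidate against one cluster, unconditionally (used by the
# first-fit policy, which must test clusters in creation order).
.eval_one <- function(g, cl, st, params) {
  a <- .eval_anchor(g, cl, st, params)
  if (a$complete) return(a)
  .eval_mcs_full(g, cl, a, .cl_sup(cl, params), st, params)
}

# Merge an accepted record into a cluster and maintain the MCS:
# first activation runs the full greedy selection; afterwards a member
# within theta of every current core joins the MCS directly (equivalent to
# a full re-scan), and clusters whose previous selection fell back to a
# single seed re-attempt selection after every merge.
.accept <- function(g, cl, r, st, params) {
  m <- length(cl$mem) + 1L
  .cl_grow(cl, m)
  cl$mem <- c(cl$mem, g)
  cl$dmat[m, m] <- cl$rmat[m, m] <- 0
  if (r$kind == "seed") {
    cl$dmat[1, m] <- cl$dmat[m, 1] <- r$ds
    cl$rmat[1, m] <- cl$rmat[m, 1] <- r$rawD
  } else {
    loc <- cl$mcs
    cl$dmat[cbind(loc, m)] <- cl$dmat[cbind(m, loc)] <- r$ds
    cl$rmat[cbind(loc, m)] <- cl$rmat[cbind(m, loc)] <- r$rawD
  }
  if (!cl$act) {
    if (length(cl$mem) >= params$eta) .select_mcs(cl, st, params)
  } else if (length(cl$mcs) > 0) {
    if (r$kind == "mcs" && all(r$ds < params$theta) &&
        length(cl$mcs) < params$max_core) {
      cl$mcs <- c(cl$mcs, m)
      .update_stats(cl, params)
    }
  } else {
    .select_mcs(cl, st, params)
  }
  invisible()
}

# Best-fit winner among clusters for one record, or NULL. Anchor bounds
# are computed for every cluster first; clusters are then completed in
# ascending-bound order, so a cluster is fully evaluated only while its
# lower bound could still beat the best qualifying distance found so far.
# All skips are provably loss-free, so the winner is identical to the
# straight-line evaluation of every cluster.
.assign_best <- function(g, st, params) {
  K <- length(st$clusters)
  anchors <- vector("list", K)
  bounds <- numeric(K)
  for (k in seq_len(K)) {
    anchors[[k]] <- .eval_anchor(g, st$clusters[[k]], st, params)
    bounds[k] <- anchors[[k]]$bound
  }
  best_d <- Inf
  best_k <- 0L
  best_r <- NULL
  for (k in order(bounds, seq_len(K))) {
    a <- anchors[[k]]
    if (a$bound - 1e-9 > best_d) break   # ascending: nothing later can win
    if (a$kind == "seed") {
      if (!a$qual) next
      if (a$dval < best_d || (a$dval == best_d && k < best_k)) {
        best_d <- a$dval
        best_k <- k
        best_r <- a
      }
      next
    }
    cl <- st$clusters[[k]]
    sup <- .cl_sup(cl, params)
    if (a$bound - 1e-9 > sup) next       # cannot qualify at all
    r <- .eval_mcs_full(g, cl, a, min(sup, best_d), st, params)
    if (!isTRUE(r$qual)) next
    if (r$dval < best_d || (r$dval == best_d && k < best_k)) {
      best_d <- r$dval
      best_k <- k
      best_r <- r
    }
  }
  if (best_k == 0L) NULL else list(k = best_k, r = best_r)
}

.assign_first <- function(g, st, params) {
  for (k in seq_along(st$clusters)) {
    r <- .eval_one(g, st$clusters[[k]], st, params)
    if (isTRUE(r$qual)) return(list(k = k, r = r))
  }
  NULL
}

# Stream dereplicated records through the clusters.
.greedy_pass <- function(rec, params) {
  st <- .new_state(rec, params)
  for (g in seq_len(nrow(rec))) {
    hit <- if (params$assign_policy == "best") .assign_best(g, st, params)
           else .assign_first(g, st, params)
    if (!is.null(hit)) {
      .accept(g, st$clusters[[hit$k]], hit$r, st, params)
    } else {
      st$clusters[[length(st$clusters) + 1L]] <- .new_cluster(g)
    }
  }
  st
}

# ---- finalization ---------------------------------------------------------

# Isolated reads (clusters whose total read abundance is 1) are reassigned
# to the nearest non-singleton cluster: smallest seed distance for
# single-seed clusters, smallest average distance to the MCS otherwise,
# ties by creation order. Each surviving cluster becomes one OTU.
.finalize <- function(st, params) {
  clusters <- st$clusters
  K <- length(clusters)
  rec <- st$rec
  n <- nrow(rec)
  assign_k <- integer(n)
  for (k in seq_len(K)) assign_k[clusters[[k]]$mem] <- k
  reads_per_cluster <- vapply(clusters, function(cl) sum(st$abund[cl$mem]), 0)
  singleton <- reads_per_cluster == 1
  targets <- which(!singleton)
  if (params$rescue_singletons && length(targets) > 0 && any(singleton)) {
    for (k in which(singleton)) {
      g <- clusters[[k]]$mem
      best_d <- Inf
      best_j <- 0L
      for (j in targets) {
        cl <- clusters[[j]]
        if (length(cl$mcs) > 0) {
          mg <- cl$mem[cl$mcs]
          ds <- .dist_query(st$bases[g], st$bases[mg], params$model)$d
          dval <- sum(ds) / length(ds)
        } else {
          dval <- .dist_query(st$bases[g], st$bases[cl$mem[1]],
                              params$model)$d
        }
        if (dval < best_d) {
          best_d <- dval
          best_j <- j
        }
      }
      assign_k[g] <- best_j
    }
    keep <- targets
  } else {
    keep <- seq_len(K)
  }
  keep <- keep[order(keep)]
  otu_ids <- sprintf("OTU_%04d", seq_along(keep))
  k_to_otu <- rep(NA_character_, K)
  k_to_otu[keep] <- otu_ids
  assignments <- k_to_otu[assign_k]
  names(assignments) <- rec$id

  representatives <- character(length(keep))
  mcs_sizes <- integer(length(keep))
  core_flags <- rep(FALSE, n)
  cluster_info <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    cl <- clusters[[keep[i]]]
    if (length(cl$mcs) > 0) {
      mg <- cl$mem[cl$mcs]
      core_flags[mg] <- TRUE
      best <- mg[which.max(st$abund[mg])]  # first max = earliest arrival
      representatives[i] <- st$ids[best]
      mcs_sizes[i] <- length(cl$mcs)
      cluster_info[[i]] <- list(seed = st$ids[cl$mem[1]],
                                mcs = st$ids[mg],
                                mean = cl$mean, sigma = cl$sigma)
    } else {
      representatives[i] <- st$ids[cl$mem[1]]
      cluster_info[[i]] <- list(seed = st$ids[cl$mem[1]],
                                mcs = character(0),
                                mean = NA_real_, sigma = NA_real_)
    }
  }
  names(representatives) <- otu_ids
  names(mcs_sizes) <- otu_ids
  names(core_flags) <- rec$id
  names(cluster_info) <- otu_ids

  otu_sizes <- if (n) table(factor(assignments, levels = otu_ids)) else
    integer(0)
  otu_reads <- if (n)
    tapply(rec$abundance, factor(assignments, levels = otu_ids), sum) else
    integer(0)

  structure(list(
    assignments = assignments,
    representatives = representatives,
    core_flags = core_flags,
    records = rec,
    n_reads = attr(rec, "n_reads") %||% sum(rec$abundance),
    n_records = n,
    n_otus = length(keep),
    otu_sizes = as.integer(otu_sizes),
    otu_reads = as.integer(otu_reads),
    mcs_sizes = mcs_sizes,
    clusters = cluster_info,
    params = params,
    alignment_calls = NA_real_
  ), class = "dmsc")
}
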