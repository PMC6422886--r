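BASES <- c("A", "C", "G", "T")

#' Specification of one simulated taxon
#'
#' @param taxon_id Label carried into read headers as ground truth.
#' @param reference Reference DNA string the taxon's reads derive from.
#' @param read_count Number of reads to emit (>= 1).
#' @param sub_rate Per-base substitution probability in `[0, 0.5)`.
#' @param indel_rate Per-base indel probability in `[0, 0.5)`; an indel is
#'   a single-base insertion or deletion with equal probability.
#' @return Object of class `taxon_spec`.
#' @export
taxon_spec <- function(taxon_id, reference, read_count, sub_rate,
                       indel_rate = 0) {
  stopifnot(read_count >= 1, sub_rate >= 0, sub_rate < 0.5,
            indel_rate >= 0, indel_rate < 0.5, nchar(reference) > 0)
  structure(list(taxon_id = as.character(taxon_id),
                 reference = toupper(reference),
                 read_count = as.integer(read_count),
                 sub_rate = sub_rate, indel_rate = indel_rate),
            class = "taxon_spec")
}

#' Specification of a simulated amplicon community
#'
#' @param taxa List of [taxon_spec()] objects.
#' @param rng_seed Integer seed making read generation deterministic.
#' @param divergence Optional record of the reference divergence targets
#'   (range or matrix) the taxa were built to.
#' @return Object of class `community_spec`.
#' @export
community_spec <- function(taxa, rng_seed, divergence = NULL) {
  stopifnot(length(taxa) > 0,
            all(vapply(taxa, inherits, TRUE, "taxon_spec")))
  structure(list(taxa = taxa, rng_seed = as.integer(rng_seed),
                 divergence = divergence),
            class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  nt <- length(x$taxa)
  reads <- sum(vapply(x$taxa, function(t) t$read_count, 0L))
  lens <- range(vapply(x$taxa, function(t) nchar(t$reference), 0L))
  cat(sprintf(
    "amplicon community spec: %d taxa, %d reads, reference length %s, seed %d\n",
    nt, reads, paste(unique(lens), collapse = "-"), x$rng_seed))
  invisible(x)
}

.random_dna <- function(L) sample(BASES, L, replace = TRUE)

.other_base <- function(b) sample(setdiff(BASES, b), 1)

# Derive taxa from a common root by point substitutions at the given
# positions (one position set per taxon).
.derive <- function(root, pos_list) {
  vapply(pos_list, function(pos) {
    s <- root
    if (length(pos))
      s[pos] <- vapply(s[pos], .other_base, "")
    paste(s, collapse = "")
  }, "")
}

# Star derivation with per-taxon substitution counts k; positions disjoint
# when they fit, random otherwise. RNG state is the caller's.
.star_positions <- function(k, L) {
  if (sum(k) <= L) {
    pool <- sample.int(L, sum(k))
    split(pool, rep(seq_along(k), k))[as.character(seq_along(k))]
  } else {
    lapply(k, function(ki) sample.int(L, ki))
  }
}

#' Generate taxon reference sequences at controlled divergences
#'
#' Builds a random root sequence and derives `n_taxa` references from it by
#' point substitutions so that every realized pairwise alignment distance
#' matches its target within a tolerance of 0.005. Targets may be a single
#' value (all pairs equal), a `(min, max)` range, or a full symmetric
#' matrix (fitted by least squares over per-taxon substitution counts, so a
#' matrix must be close to "star-realizable" to be feasible).
#'
#' @param n_taxa Number of references.
#' @param length Reference length in bases.
#' @param divergence Scalar, `c(min, max)` range, or symmetric matrix of
#'   target pairwise distances.
#' @param rng_seed Integer seed; generation is deterministic given the seed.
#' @param max_tries Bounded retries before failing with the worst pair.
#' @return Named character vector of references (`T01`, `T02`, ...), with
#'   the realized pairwise distance matrix in `attr(, "realized")`.
#' @examples
#' refs <- make_references(2, 500, 0.10, rng_seed = 1)
#' attr(refs, "realized")[1, 2]  # within 0.095..0.105
#' @export
make_references <- function(n_taxa, length, divergence, rng_seed,
                            max_tries = 200) {
  L <- as.integer(length)
  ids <- sprintf("T%02d", seq_len(n_taxa))
  .with_seed(rng_seed, {
    root <- .random_dna(L)
    if (n_taxa == 1) {
      refs <- paste(root, collapse = "")
      names(refs) <- ids
      attr(refs, "realized") <- matrix(0, 1, 1, dimnames = list(ids, ids))
      return(refs)
    }
    if (is.matrix(divergence)) {
      stopifnot(nrow(divergence) == n_taxa, ncol(divergence) == n_taxa)
      tol_lo <- divergence - 0.005
      tol_hi <- divergence + 0.005
      if (n_taxa == 2) {
        kk <- L * divergence[1, 2]
        k0 <- as.integer(c(floor(kk / 2), ceiling(kk / 2)))
      } else {
        r <- rowSums(divergence) # diagonal is 0
        K <- L * sum(r) / (2 * (n_taxa - 1))
        k0 <- as.integer(pmax(0, round((L * r - K) / (n_taxa - 2))))
      }
      draw_k <- function() k0
    } else {
      rng <- if (base::length(divergence) == 1)
        c(divergence, divergence) else sort(divergence[1:2])
      if (rng[1] == rng[2]) {
        kk <- L * rng[1]
        tol_lo <- matrix(rng[1] - 0.005, n_taxa, n_taxa)
        tol_hi <- matrix(rng[1] + 0.005, n_taxa, n_taxa)
        draw_k <- function()
          as.integer(floor(kk / 2) + (seq_len(n_taxa) %% 2 == 0) *
                       (ceiling(kk / 2) - floor(kk / 2)))
      } else {
        tol_lo <- matrix(rng[1] - 0.005, n_taxa, n_taxa)
        tol_hi <- matrix(rng[2] + 0.005, n_taxa, n_taxa)
        kmin <- ceiling(L * rng[1] / 2) + 1L
        kmax <- max(kmin, floor(L * rng[2] / 2))
        draw_k <- function() sample(seq(kmin, kmax), n_taxa, replace = TRUE)
      }
    }
    k <- draw_k()
    pos <- .star_positions(k, L)
    worst <- NULL
    for (try in seq_len(max_tries)) {
      refs <- .derive(root, pos)
      names(refs) <- ids
      realized <- distance_matrix(refs)
      viol <- (realized < tol_lo | realized > tol_hi)
      diag(viol) <- FALSE
      if (!any(viol)) {
        attr(refs, "realized") <- realized
        return(refs)
      }
      err <- pmax(tol_lo - realized, realized - tol_hi)
      diag(err) <- -Inf
      worst <- which(err == max(err), arr.ind = TRUE)[1, ]
      # resample the positions (and, in range mode, the count) of the
      # taxon involved in the worst violation
      bad <- worst[[1]]
      k[bad] <- draw_k()[bad]
      pos <- .star_positions(k, L)
    }
    stop(sprintf(
      "infeasible divergence targets after %d tries; worst pair %s-%s (realized %.4f)",
      max_tries, ids[worst[[1]]], ids[worst[[2]]],
      realized[worst[[1]], worst[[2]]]))
  })
}

.mutate_read <- function(refc, sub_rate, indel_rate) {
  chars <- refc
  L <- base::length(chars)
  if (sub_rate > 0) {
    subs <- which(runif(L) < sub_rate)
    if (base::length(subs))
      chars[subs] <- vapply(chars[subs], .other_base, "")
  }
  if (indel_rate > 0) {
    ind <- which(runif(base::length(chars)) < indel_rate)
    for (p in rev(ind)) {
      if (runif(1) < 0.5) {
        if (base::length(chars) > 1) chars <- chars[-p]
      } else {
        chars <- append(chars, sample(BASES, 1), after = p)
      }
    }
  }
  paste(chars, collapse = "")
}

#' Simulate labelled amplicon reads from a community specification
#'
#' Emits `read_count` reads per taxon, each derived from the taxon
#' reference by per-base substitutions and single-base indels at the
#' specified rates. Read ids carry the generating taxon as a
#' `taxon=<label>` header key, recoverable with [parse_taxon_labels()].
#'
#' @param spec A [community_spec()].
#' @return A `seq_records` table of reads (abundance 1 each) with the truth
#'   labels in `attr(, "truth")`.
#' @export
make_reads <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  .with_seed(spec$rng_seed, {
    ids <- character(0)
    seqs <- character(0)
    truth <- character(0)
    for (tx in spec$taxa) {
      refc <- strsplit(tx$reference, "")[[1]]
      b <- vapply(seq_len(tx$read_count),
                  function(i) .mutate_read(refc, tx$sub_rate, tx$indel_rate),
                  "")
      ids <- c(ids, sprintf("%s_r%05d;taxon=%s", tx$taxon_id,
                            seq_len(tx$read_count), tx$taxon_id))
      seqs <- c(seqs, b)
      truth <- c(truth, rep(tx$taxon_id, tx$read_count))
    }
    rec <- new_seq_records(ids, seqs)
    names(truth) <- ids
    attr(rec, "truth") <- truth
    rec
  })
}

# Largest-remainder apportionment of `total` across `props`.
.apportion <- function(props, total) {
  raw <- props * total
  counts <- floor(raw)
  rem <- total - sum(counts)
  if (rem > 0) {
    up <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[up] <- counts[up] + 1
  }
  as.integer(counts)
}

#' Preset benchmark community designs
#'
#' Three ready-made simulation designs used throughout the package's tests
#' and examples:
#'
#' * `stacked60`: 59 bacterial-genus-like taxa, 98 bp (V6-like) references
#'   with pairwise divergences in `[0.06, 0.38]` (floor configurable down to
#'   0.01), per-taxon abundance proportions drawn uniformly in
#'   `[0.001, 0.003]` and renormalized over 2,614 reads at scale 1, read
#'   noise 0.002.
#' * `eleven_taxa`: 11 taxa, 500 bp references, 2,000 reads per taxon at
#'   scale 1; three designated taxa are mutually within 1 percent
#'   divergence while every other pair is at least 5 percent apart, so a
#'   clustering at theta = 0.03 is expected to find 9 OTUs. Per-taxon total
#'   error rates drawn in `[0.002, 0.004]`.
#' * `error_series`: a list of 10 specifications sharing 30 taxa (120 bp,
#'   divergences in `[0.12, 0.30]`, 5,000 reads per taxon at scale 1) whose
#'   total per-base error rate steps through `0.21..0.42` percent.
#'
#' The total error rate is split 90/10 between substitutions and indels by
#' default (`error_split`).
#'
#' @param name One of `"stacked60"`, `"eleven_taxa"`, `"error_series"`.
#' @param scale Fraction of the full design's read counts, in (0, 1].
#' @param rng_seed Integer seed; presets are deterministic given the seed.
#' @param divergence_floor Optional override of the minimum reference
#'   divergence (`stacked60` only; the design's historical 0.01 floor makes
#'   the 59-OTU expectation approximate).
#' @param fixed_counts `stacked60`: use largest-remainder apportionment
#'   instead of multinomial sampling of per-taxon read counts.
#' @param error_split Fraction of the total error rate assigned to
#'   substitutions (rest are indels).
#' @return A [community_spec()], or a list of them for `error_series`.
#' @export
dmsc_preset <- function(name = c("stacked60", "eleven_taxa", "error_series"),
                        scale = 1, rng_seed = 1L, divergence_floor = NULL,
                        fixed_counts = FALSE, error_split = 0.9) {
  name <- match.arg(name)
  stopifnot(scale > 0, scale <= 1)
  rng_seed <- as.integer(rng_seed)
  if (name == "stacked60") {
    lo <- divergence_floor %||% 0.06
    refs <- make_references(59, 98, c(lo, 0.38), rng_seed)
    counts <- .with_seed(rng_seed + 59L, {
      props <- runif(59, 0.001, 0.003)
      props <- props / sum(props)
      total <- max(59L, as.integer(round(2614 * scale)))
      if (fixed_counts) .apportion(props, total)
      else as.integer(rmultinom(1, total, props))
    })
    counts <- pmax(counts, 1L)
    rate <- 0.002
    taxa <- lapply(seq_along(refs), function(i)
      taxon_spec(names(refs)[i], refs[[i]], counts[i],
                 sub_rate = rate * error_split,
                 indel_rate = rate * (1 - error_split)))
    return(community_spec(taxa, rng_seed = rng_seed + 101L,
                          divergence = c(lo, 0.38)))
  }
  if (name == "eleven_taxa") {
    refs <- .eleven_taxa_refs(rng_seed)
    n_reads <- max(1L, as.integer(round(2000 * scale)))
    rates <- .with_seed(rng_seed + 11L, runif(11, 0.002, 0.004))
    taxa <- lapply(seq_along(refs), function(i)
      taxon_spec(names(refs)[i], refs[[i]], n_reads,
                 sub_rate = rates[i] * error_split,
                 indel_rate = rates[i] * (1 - error_split)))
    out <- community_spec(taxa, rng_seed = rng_seed + 211L)
    attr(out, "references") <- refs
    return(out)
  }
  # error_series
  refs <- make_references(30, 120, c(0.12, 0.30), rng_seed)
  n_reads <- max(1L, as.integer(round(5000 * scale)))
  rates <- seq(0.0021, 0.0042, length.out = 10)
  lapply(seq_along(rates), function(i) {
    taxa <- lapply(seq_along(refs), function(j)
      taxon_spec(names(refs)[j], refs[[j]], n_reads,
                 sub_rate = rates[i] * error_split,
                 indel_rate = rates[i] * (1 - error_split)))
    sp <- community_spec(taxa, rng_seed = rng_seed + 1000L + i,
                         divergence = c(0.12, 0.30))
    attr(sp, "error_rate") <- rates[i]
    sp
  })
}

# Eleven-taxon design: a star from the root in which three taxa carry two
# root-disjoint substitutions each (mutual divergence 4/500 = 0.008) and
# the remaining eight carry 23-60 substitutions (every other pair >= 0.05).
.eleven_taxa_refs <- function(rng_seed, max_tries = 50) {
  .with_seed(rng_seed, {
    root <- .random_dna(500)
    ids <- sprintf("T%02d", 1:11)
    for (try in seq_len(max_tries)) {
      k <- c(2L, 2L, 2L, sample(23:60, 8, replace = TRUE))
      pos <- .star_positions(k, 500L)
      refs <- .derive(root, pos)
      names(refs) <- ids
      realized <- distance_matrix(refs)
      close_pairs <- realized[upper.tri(realized)] <= 0.01
      trio_ok <- all(realized[1:3, 1:3][upper.tri(realized[1:3, 1:3])] <= 0.01)
      others_ok <- all(realized[upper.tri(realized)][!close_pairs] >= 0.05)
      if (trio_ok && sum(close_pairs) == 3 && others_ok) {
        attr(refs, "realized") <- realized
        return(refs)
      }
    }
    stop("could not realize the eleven-taxon divergence design")
  })
}
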