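# Independent oracles and fixture builders. Everything here is written
# straight from first principles (plain R, no package internals) so the
# production code paths can be checked against genuinely independent
# computations.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Substitute the given positions of a sequence with a different base
# (cyclic shift of the alphabet so the result is deterministic).
sub_at <- function(s, pos) {
  ch <- strsplit(s, "")[[1]]
  alpha <- c("A", "C", "G", "T")
  ch[pos] <- alpha[(match(ch[pos], alpha)) %% 4 + 1]
  paste(ch, collapse = "")
}

# Quadratic dynamic-programming alignment oracle: unit-cost global
# alignment minimizing (cost, gap columns) lexicographically, packed into
# a single number (fields safe for sequences up to ~500 bases in tests).
# Returns the distance cost / alignment length, with alignment length
# (la + lb + gaps) / 2.
align_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  la <- length(A)
  lb <- length(B)
  PK <- 2048
  gap_step <- PK + 1          # cost + 1, gaps + 1
  prev <- (0:lb) * gap_step
  for (i in seq_len(la)) {
    cur <- numeric(lb + 1)
    cur[1] <- i * gap_step
    for (j in seq_len(lb)) {
      sub <- if (A[i] == B[j] && A[i] != "N") 0 else PK
      cur[j + 1] <- min(prev[j] + sub, prev[j + 1] + gap_step,
                        cur[j] + gap_step)
    }
    prev <- cur
  }
  v <- prev[lb + 1]
  cost <- v %/% PK
  gaps <- v %% PK
  list(cost = cost, gaps = gaps, L = (la + lb + gaps) / 2,
       d = cost / ((la + lb + gaps) / 2))
}

# Exhaustive maximum-clique enumeration on a small distance matrix under a
# strict threshold. Returns all maximum cliques containing vertex 1.
max_cliques_with_seed <- function(dm, theta) {
  n <- nrow(dm)
  best <- list()
  best_size <- 0
  for (m in 1:(2^(n - 1) - 1)) {
    members <- c(1L, which(intToBits(m)[1:(n - 1)] == 1) + 1L)
    k <- length(members)
    ok <- TRUE
    if (k > 1) {
      sub <- dm[members, members]
      ok <- all(sub[upper.tri(sub)] < theta)
    }
    if (ok) {
      if (k > best_size) {
        best <- list(members)
        best_size <- k
      } else if (k == best_size) {
        best <- c(best, list(members))
      }
    }
  }
  best
}

# Textbook NMI oracle via H(U) + H(V) - H(U,V) over the joint table --
# a different decomposition of the mutual information than the package's
# sum over p_ij * log(p_ij / (p_i p_j)).
nmi_oracle <- function(u, v) {
  n <- length(u)
  ent <- function(counts) {
    p <- counts[counts > 0] / n
    -sum(p * log(p))
  }
  hu <- ent(table(u))
  hv <- ent(table(v))
  huv <- ent(table(paste(u, v, sep = "\r")))
  if (hu == 0 && hv == 0) return(1)
  if (hu == 0 || hv == 0) return(0)
  (hu + hv - huv) / sqrt(hu * hv)
}

# Independent plain greedy single-seed clusterer (best-fit, optional
# singleton rescue) operating on a precomputed distance matrix; the
# baseline the algorithm degenerates to when no clique can be formed.
plain_greedy <- function(rec, theta, rescue = TRUE) {
  dm <- distance_matrix(rec)
  n <- nrow(rec)
  seeds <- integer(0)
  assign <- integer(n)
  for (g in seq_len(n)) {
    hit <- 0L
    best <- Inf
    for (k in seq_along(seeds)) {
      d <- dm[g, seeds[k]]
      if (d <= theta && d < best) {
        best <- d
        hit <- k
      }
    }
    if (hit > 0) assign[g] <- hit
    else {
      seeds <- c(seeds, g)
      assign[g] <- length(seeds)
    }
  }
  if (rescue) {
    reads_per <- tapply(rec$abundance, assign, sum)
    singles <- as.integer(names(reads_per)[reads_per == 1])
    targets <- as.integer(names(reads_per)[reads_per > 1])
    if (length(targets) > 0) {
      for (k in singles) {
        g <- which(assign == k)
        dv <- dm[g, seeds[targets]]
        assign[g] <- targets[which.min(dv)]
      }
    }
  }
  out <- match(assign, unique(assign[order(seq_len(n))]))
  names(out) <- rec$id
  out
}

# Canonical co-clustering signature for comparing partitions up to label
# renaming.
partition_signature <- function(labels) {
  f <- match(labels, unique(labels))
  names(f) <- names(labels)
  f
}

# Small labelled community for engine tests: n_taxa well-separated taxa
# with noisy reads.
small_community <- function(n_taxa = 4, reads_per = 40, len = 80,
                            noise = 0.01, seed = 1,
                            divergence = c(0.08, 0.3)) {
  refs <- make_references(n_taxa, len, divergence, rng_seed = seed)
  taxa <- lapply(seq_along(refs), function(i)
    taxon_spec(names(refs)[i], refs[[i]], reads_per,
               sub_rate = noise * 0.9, indel_rate = noise * 0.1))
  make_reads(community_spec(taxa, rng_seed = seed * 13 + 7))
}

# Records with explicit abundances (synthetic member ids), so tests can pin
# the abundance-sorted stream order of distinct sequences.
records_with_abund <- function(seqs, abund) {
  new_seq_records(names(seqs), unname(unlist(seqs)),
                  abundance = as.integer(abund),
                  members = mapply(function(n, k) paste0(n, "#", seq_len(k)),
                                   names(seqs), abund, SIMPLIFY = FALSE))
}
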