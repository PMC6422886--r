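# Fixtures are built by planting substitutions at controlled positions so
# every pairwise distance is known by construction.

test_that("mcs_stats implements the pair-mean and the |M|-1 deviation divisor", {
  base <- strrep("ACGT", 25)  # length 100

  # three identical sequences
  s0 <- c(a = base, b = base, c = base)
  st0 <- mcs_stats(s0)
  expect_equal(st0$mean, 0)
  expect_equal(st0$sigma, 0)

  # pairwise distances 0.01, 0.02, 0.03 by disjoint substitutions
  s <- c(a = base, b = sub_at(base, 1), c = sub_at(base, c(11, 12)))
  dm <- distance_matrix(s)
  expect_equal(sort(dm[upper.tri(dm)]), c(0.01, 0.02, 0.03))
  st <- mcs_stats(s)
  expect_equal(st$mean, 0.02)
  expect_equal(st$sigma, 0.01)  # sqrt(((-.01)^2 + 0 + .01^2) / (3 - 1))

  # four sequences, all pairwise distances equal -> zero spread
  s4eq <- c(b = sub_at(base, 1:2), c = sub_at(base, 11:12),
            d = sub_at(base, 21:22), e = sub_at(base, 31:32))
  dm4eq <- distance_matrix(s4eq)
  expect_true(all(dm4eq[upper.tri(dm4eq)] == 0.04))
  expect_equal(mcs_stats(s4eq)$sigma, 0)

  # star: seed at 0.02 from three satellites that are 0.04 apart
  s4 <- c(a = base, b = sub_at(base, 1:2), c = sub_at(base, 11:12),
          d = sub_at(base, 21:22))
  dm4 <- distance_matrix(s4)

  # divisor variant: pair count - 1 instead of |M| - 1
  stp <- mcs_stats(s, sigma_divisor = "pairs")
  expect_equal(stp$sigma, st$sigma)  # identical when |M| = 3
  st4v <- mcs_stats(s4)
  st4p <- mcs_stats(s4, sigma_divisor = "pairs")
  dv <- dm4[upper.tri(dm4)]
  expect_equal(st4v$sigma, sqrt(sum((dv - mean(dv))^2) / 3))
  expect_equal(st4p$sigma, sqrt(sum((dv - mean(dv))^2) / 5))

  expect_error(mcs_stats(s[1:2]), "at least 3")
})

test_that("greedy pass obeys the threshold rule on minimal inputs", {
  base <- strrep("GATTACA", 10)  # length 70
  one <- dmsc(c(r1 = base), theta = 0.03)
  expect_equal(one$n_otus, 1)

  near <- sub_at(base, 1)        # d = 1/70 < 0.03
  two_close <- dmsc(c(r1 = base, r2 = near), theta = 0.03,
                    rescue_singletons = FALSE)
  expect_equal(two_close$n_otus, 1)

  far <- sub_at(base, 1:10)      # d = 10/70 > 0.03
  two_far <- dmsc(c(r1 = base, r2 = far), theta = 0.03,
                  rescue_singletons = FALSE)
  expect_equal(two_far$n_otus, 2)
})

test_that("a star-shaped cluster yields no clique of 3 and falls back to a single seed", {
  base <- strrep("ACGT", 25)
  # four satellites within theta of the seed but pairwise beyond theta
  sat <- lapply(c(1, 11, 21, 31), function(p) sub_at(base, p + 0:1))
  seqs <- c(seed = base, s1 = sat[[1]], s2 = sat[[2]], s3 = sat[[3]],
            s4 = sat[[4]])
  dm <- distance_matrix(seqs)
  theta <- 0.03
  expect_true(all(dm[1, -1] <= theta))
  expect_true(all(dm[-1, -1][upper.tri(dm[-1, -1])] > theta))
  # brute force confirms the largest clique containing the seed has size 2
  expect_equal(length(max_cliques_with_seed(dm, theta)[[1]]), 2)

  fit <- dmsc(seqs, theta = theta, eta = 5, rescue_singletons = FALSE)
  expect_equal(fit$n_otus, 1)
  expect_equal(unname(fit$mcs_sizes), 0L)            # single-seed fallback
  expect_equal(unname(fit$representatives), "seed")
  expect_false(any(fit$core_flags))
})

test_that("greedy MCS selection recovers a unique maximum clique", {
  base <- strrep("TTAGGCAT", 13)  # length 104
  theta <- 0.05
  seqs <- c(
    m1 = base,
    m2 = sub_at(base, 1),        # 0.0096 from m1
    m3 = sub_at(base, 11:12),
    m4 = sub_at(base, 21:22),
    m5 = sub_at(base, 31:35),    # within theta of m1 only (5 subs)
    m6 = sub_at(base, 41:45)
  )
  dm <- distance_matrix(seqs)
  cl <- max_cliques_with_seed(dm, theta)
  expect_length(cl, 1)                       # unique maximum clique
  expect_equal(cl[[1]], 1:4)

  # descending abundances pin the stream (and hence scan) order to m1..m6
  rec <- records_with_abund(seqs, 7:2)
  fit <- dmsc(rec, theta = theta, eta = 6, rescue_singletons = FALSE)
  expect_equal(fit$n_otus, 1)
  expect_equal(unname(fit$mcs_sizes), 4L)
  expect_setequal(names(fit$core_flags)[fit$core_flags],
                  c("m1", "m2", "m3", "m4"))
  # stats stored in the fit equal a from-scratch recomputation
  info <- fit$clusters[[1]]
  st <- mcs_stats(seqs[info$mcs])
  expect_identical(info$mean, st$mean)
  expect_identical(info$sigma, st$sigma)
})

test_that("the assignment predicate relaxes theta by the MCS spread", {
  q <- dmsc:::.mcs_qualifies
  # mean 0.020, sigma 0.010, mu 3, theta 0.03
  expect_true(q(0.045, 0.020, 0.010, 0.03, 3))   # |0.045-0.020| <= 0.03
  expect_false(q(0.055, 0.020, 0.010, 0.03, 3))  # beyond theta and window
  expect_true(q(0.03, 0, 0, 0.03, 3))            # sigma 0: theta branch
  # literal reading: only |d| <= mu*sigma
  expect_false(q(0.03, 0, 0, 0.03, 3, literal = TRUE))
  expect_true(q(0.025, 0.020, 0.010, 0.03, 3, literal = TRUE))
})

test_that("dynamic MCS updates match full re-selection as the cluster grows", {
  base <- strrep("CCGGAATT", 13)  # length 104
  theta <- 3 / 104
  # six founders forming a clique (single substitutions, pairwise 2/104),
  # then one compatible member and one that the clique must exclude
  founders <- c(list(base), lapply(c(1, 9, 17, 25, 33),
                                   function(p) sub_at(base, p)))
  names(founders) <- paste0("f", 1:6)
  joiner <- sub_at(base, 41)       # within theta of everything
  outlier <- sub_at(base, 49:50)   # 3/104 from every founder but f1
  seqs <- c(unlist(founders), j = joiner, o = outlier)
  dm <- distance_matrix(seqs)
  expect_true(all(dm["j", 1:6] < theta))
  expect_true(any(dm["o", 2:7] >= theta))
  # the outlier's average distance to the core still qualifies it
  expect_lte(mean(dm["o", c(1:6, 7)]), theta)

  rec <- records_with_abund(seqs, 9:2)
  fit <- dmsc(rec, theta = theta, eta = 3, rescue_singletons = FALSE)
  ref <- dmsc_reference(rec, theta = theta, eta = 3,
                        rescue_singletons = FALSE)
  expect_identical(fit$assignments, ref$assignments)
  expect_identical(fit$core_flags, ref$core_flags)
  expect_true(fit$core_flags[["j"]])
  # the incompatible member is in the cluster but not in the MCS
  expect_equal(unname(fit$assignments["o"]), unname(fit$assignments["f1"]))
  expect_false(fit$core_flags[["o"]])
  # stored stats equal recomputation from the final MCS
  info <- fit$clusters[[1]]
  st <- mcs_stats(seqs[info$mcs])
  expect_identical(info$mean, st$mean)
  expect_identical(info$sigma, st$sigma)
})

test_that("finalization rescues isolated reads and preserves totality", {
  base <- strrep("AACCGGTT", 10)  # length 80
  # a 30-member cluster plus one distant singleton read
  members <- c(list(base), lapply(seq_len(29), function(p) sub_at(base, p)))
  names(members) <- paste0("m", 1:30)
  lone <- sub_at(base, seq(1, 45, by = 3))  # 15 subs: d ~ 0.19
  seqs <- c(unlist(members), lone = lone)

  fit <- dmsc(seqs, theta = 0.05, rescue_singletons = TRUE)
  expect_equal(fit$n_otus, 1)
  expect_equal(length(fit$assignments), 31)
  expect_equal(unname(fit$assignments["lone"]), "OTU_0001")

  no_rescue <- dmsc(seqs, theta = 0.05, rescue_singletons = FALSE)
  expect_equal(no_rescue$n_otus, 2)

  # two singletons only: nothing to rescue into, both kept
  two <- dmsc(c(a = base, b = lone), theta = 0.05)
  expect_equal(two$n_otus, 2)

  # a single-record cluster carrying many identical reads is not isolated
  reads <- new_seq_records(paste0("r", 1:8),
                           c(rep(base, 5), rep(lone, 3)))
  fit8 <- dmsc(reads, theta = 0.05, rescue_singletons = TRUE)
  expect_equal(fit8$n_otus, 2)
})

test_that("partitions are input-order invariant and deterministic", {
  reads <- small_community(4, reads_per = 25, seed = 3)
  f1 <- dmsc(reads, theta = 0.1, eta = 8)
  set.seed(99)
  perm <- sample(nrow(reads))
  f2 <- dmsc(reads[perm, ], theta = 0.1, eta = 8)
  # record ids inherit the first-seen read id, so compare the read-level
  # partition and the representative sequences, which must be invariant
  m1 <- otu_map(f1)
  m2 <- otu_map(f2)
  m1 <- m1[order(m1$read_id), ]
  m2 <- m2[order(m2$read_id), ]
  expect_identical(m1$otu_id, m2$otu_id)
  expect_identical(m1$is_core, m2$is_core)
  rep_seq <- function(f) unname(f$records$bases[match(f$representatives,
                                                      f$records$id)])
  expect_identical(rep_seq(f1), rep_seq(f2))

  # byte-identical OTU maps across repeated runs
  t1 <- withr::local_tempfile(fileext = ".tsv")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  write_otu_map(f1, t1)
  write_otu_map(dmsc(reads, theta = 0.1, eta = 8), t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("unattainable cores degenerate to plain single-seed greedy clustering", {
  for (s in c(5, 17)) {
    reads <- small_community(3, reads_per = 30, noise = 0.02, seed = s)
    rec <- dereplicate(reads)
    fit <- dmsc(rec, theta = 0.1, eta = 10^6, min_core = 10^6)
    expect_true(all(fit$mcs_sizes == 0))
    expect_identical(partition_signature(fit$assignments),
                     plain_greedy(rec, 0.1))
  }
})

test_that("empty input yields an empty partition", {
  fit <- dmsc(new_seq_records(character(0), character(0)), theta = 0.03)
  expect_equal(fit$n_otus, 0)
  expect_length(fit$assignments, 0)
})

test_that("predict assigns new reads to fitted OTUs without refitting", {
  reads <- small_community(3, reads_per = 30, seed = 8)
  fit <- dmsc(reads, theta = 0.1, eta = 8)
  refs <- make_references(3, 80, c(0.08, 0.3), rng_seed = 8)
  p <- predict(fit, c(new1 = refs[[1]], new2 = refs[[2]]))
  expect_false(anyNA(p))
  expect_equal(length(unique(p)), 2)
  # a sequence far from everything is unassigned
  far <- predict(fit, c(x = strrep("A", 80)))
  expect_true(is.na(far))
})
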