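test_that("NMI conventions and hand-worked contingency case", {
  # identical partitions with >= 2 clusters
  u <- c(a = "x", b = "x", c = "y", d = "y")
  expect_equal(nmi(u, u), 1)
  # all-in-one prediction against multi-taxon truth
  expect_equal(nmi(u, c(a = "1", b = "1", c = "1", d = "1")), 0)
  # both single-cluster
  expect_equal(nmi(c(a = "1", b = "1"), c(a = "2", b = "2")), 1)
  # truth {a,b | c,d} vs prediction {a,b,c | d}
  v <- c(a = "p", b = "p", c = "p", d = "q")
  expect_equal(nmi(u, v), nmi_oracle(c("x", "x", "y", "y"),
                                     c("p", "p", "p", "q")),
               tolerance = 1e-12)
  expect_error(nmi(u, v[1:3]), "different read sets")
})

test_that("NMI matches an independent entropy-decomposition oracle on random partitions", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    u <- sample(letters[1:sample(2:6, 1)], n, replace = TRUE)
    v <- sample(LETTERS[1:sample(2:6, 1)], n, replace = TRUE)
    expect_equal(nmi(u, v), nmi_oracle(u, v), tolerance = 1e-10)
    # symmetry and label-renaming invariance
    expect_equal(nmi(u, v), nmi(v, u), tolerance = 1e-12)
    relab <- match(u, unique(u))
    expect_equal(nmi(as.character(relab), v), nmi(u, v), tolerance = 1e-12)
  }
})

test_that("pair confusion matches exhaustive enumeration and conserves totals", {
  set.seed(9)
  reads <- small_community(3, reads_per = 12, len = 60, noise = 0.03,
                           seed = 21)
  rec <- dereplicate(reads)
  n <- nrow(rec)
  fit <- dmsc(rec, theta = 0.1)
  conf <- pair_confusion(rec, fit, theta = 0.1)
  expect_equal(conf$tp + conf$tn + conf$fp + conf$fn, choose(n, 2))

  # brute-force double loop
  dm <- distance_matrix(rec)
  otus <- fit$assignments[rec$id]
  tp <- tn <- fp <- fn <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    within <- dm[i, j] <= 0.1
    same <- otus[i] == otus[j]
    if (within && same) tp <- tp + 1
    else if (within) fn <- fn + 1
    else if (same) fp <- fp + 1
    else tn <- tn + 1
  }
  expect_equal(conf$tp, tp)
  expect_equal(conf$tn, tn)
  expect_equal(conf$fp, fp)
  expect_equal(conf$fn, fn)

  # perfectly theta-separated components have no pair errors
  base <- strrep("ACGTTGCA", 10)
  grp <- c(a1 = base, a2 = sub_at(base, 1), b1 = sub_at(base, 1:20),
           b2 = sub_at(base, c(1:19, 21)))
  fit2 <- dmsc(grp, theta = 0.05, rescue_singletons = FALSE)
  conf2 <- pair_confusion(grp, fit2, theta = 0.05)
  expect_equal(conf2$fp, 0)
  expect_equal(conf2$fn, 0)

  # size gate
  expect_error(pair_confusion(rec, fit, theta = 0.1, max_n = 5), "max_n")
})

test_that("MCC formula, degenerate cases, and symmetry under class swap", {
  expect_equal(mcc(list(tp = 10, tn = 20, fp = 0, fn = 0)), 1)
  expect_equal(mcc(list(tp = 0, tn = 0, fp = 5, fn = 7)), -1)
  expect_equal(mcc(list(tp = 4, tn = 3, fp = 1, fn = 2)), 10 / sqrt(600))
  # zero marginal -> 0 by convention
  expect_equal(mcc(list(tp = 0, tn = 5, fp = 0, fn = 3)), 0)
  # invariance under swapping (tp<->tn, fp<->fn)
  set.seed(2)
  for (i in 1:10) {
    x <- as.list(sample(1:30, 4))
    names(x) <- c("tp", "tn", "fp", "fn")
    sw <- list(tp = x$tn, tn = x$tp, fp = x$fn, fn = x$fp)
    expect_equal(mcc(x), mcc(sw))
  }
  expect_error(mcc(list(tp = 0, tn = 0, fp = 0, fn = 0)), "at least one")
})
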