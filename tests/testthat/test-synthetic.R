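test_that("reference generation hits divergence targets and is seed-deterministic", {
  refs <- make_references(2, 500, 0.10, rng_seed = 1)
  d <- attr(refs, "realized")[1, 2]
  expect_gte(d, 0.095)
  expect_lte(d, 0.105)
  expect_equal(d, seq_distance(refs[[1]], refs[[2]]))

  expect_identical(make_references(2, 500, 0.10, rng_seed = 1), refs)
  expect_false(identical(make_references(2, 500, 0.10, rng_seed = 2), refs))

  one <- make_references(1, 120, 0.10, rng_seed = 3)
  expect_length(one, 1)
  expect_equal(nchar(one[[1]]), 120)

  rng <- make_references(6, 200, c(0.08, 0.25), rng_seed = 4)
  dm <- attr(rng, "realized")
  off <- dm[upper.tri(dm)]
  expect_true(all(off >= 0.075 & off <= 0.255))
})

test_that("read simulation honours the error model", {
  refs <- make_references(2, 120, 0.2, rng_seed = 5)
  taxa <- list(taxon_spec("T01", refs[[1]], 10, sub_rate = 0),
               taxon_spec("T02", refs[[2]], 10, sub_rate = 0))
  clean <- make_reads(community_spec(taxa, rng_seed = 6))
  expect_equal(nrow(clean), 20)
  expect_true(all(clean$bases[1:10] == refs[[1]]))
  expect_true(all(clean$bases[11:20] == refs[[2]]))

  # truth labels round-trip through the header convention
  lab <- parse_taxon_labels(clean$id)
  expect_equal(unname(lab), rep(c("T01", "T02"), each = 10))
  expect_identical(unname(attr(clean, "truth")), unname(lab))

  # substitution-only noise: mean mismatch count matches the binomial
  # expectation L * rate within 3 standard errors over 5,000 reads
  rate <- 0.002
  noisy <- make_reads(community_spec(
    list(taxon_spec("T01", refs[[1]], 5000, sub_rate = rate)),
    rng_seed = 7))
  refc <- strsplit(refs[[1]], "")[[1]]
  mism <- vapply(noisy$bases, function(b)
    sum(strsplit(b, "")[[1]] != refc), 0, USE.NAMES = FALSE)
  expected <- 120 * rate
  se <- sqrt(120 * rate * (1 - rate) / 5000)
  expect_lt(abs(mean(mism) - expected), 3 * se)

  # determinism under a fixed seed, divergence under different seeds
  again <- make_reads(community_spec(
    list(taxon_spec("T01", refs[[1]], 5000, sub_rate = rate)),
    rng_seed = 7))
  expect_identical(noisy$bases, again$bases)
})

test_that("presets reproduce the study designs' sizes and structure", {
  sp11 <- dmsc_preset("eleven_taxa", scale = 1, rng_seed = 1)
  expect_length(sp11$taxa, 11)
  expect_equal(sum(vapply(sp11$taxa, function(t) t$read_count, 0L)), 22000L)
  expect_equal(unique(vapply(sp11$taxa, function(t) nchar(t$reference), 0L)),
               500L)
  # exactly three reference pairs within 1 percent; all others >= 5 percent
  realized <- attr(attr(sp11, "references"), "realized")
  off <- realized[upper.tri(realized)]
  expect_equal(sum(off <= 0.01), 3)
  expect_true(all(off[off > 0.01] >= 0.05))

  sp60 <- dmsc_preset("stacked60", scale = 1, rng_seed = 2,
                      fixed_counts = TRUE)
  expect_length(sp60$taxa, 59)
  expect_equal(sum(vapply(sp60$taxa, function(t) t$read_count, 0L)), 2614L)
  expect_equal(unique(vapply(sp60$taxa, function(t) nchar(t$reference), 0L)),
               98L)

  ser <- dmsc_preset("error_series", scale = 1, rng_seed = 3)
  expect_length(ser, 10)
  expect_length(ser[[1]]$taxa, 30)
  expect_equal(sum(vapply(ser[[1]]$taxa, function(t) t$read_count, 0L)),
               150000L)
  rates <- vapply(ser, function(s) attr(s, "error_rate"), 0)
  expect_equal(rates[1], 0.0021)
  expect_equal(rates[10], 0.0042)
  expect_true(all(diff(rates) > 0))
  # the split of the total rate between substitutions and indels
  t1 <- ser[[1]]$taxa[[1]]
  expect_equal(t1$sub_rate + t1$indel_rate, 0.0021)

  expect_error(dmsc_preset("nope"), "arg")
  # preset generation is deterministic
  expect_identical(dmsc_preset("eleven_taxa", scale = 0.01, rng_seed = 9),
                   dmsc_preset("eleven_taxa", scale = 0.01, rng_seed = 9))
})
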