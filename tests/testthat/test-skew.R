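test_that("the leading-strand view reverse complements the second
           replichore only", {
  g <- new_genome("g", strrep("A", 100))
  v <- leading_strand_view(g, 0, 50)
  expect_equal(v, paste0(strrep("A", 50), strrep("T", 50)))
  expect_error(leading_strand_view(g, 10, 10), "differ")
  set.seed(4)
  s <- random_dna(500)
  g2 <- new_genome("g", s)
  v2 <- leading_strand_view(g2, 100, 350)
  expect_equal(nchar(v2), 500)
  expect_equal(substr(v2, 1, 250), circular_subseq(s, 100, 350))
  expect_equal(substr(v2, 251, 500), revcomp(circular_subseq(s, 350, 600)))
})

test_that("word statistics match hand-computed Markov expectations", {
  # independent counting oracle: overlapping matches via fixed gregexpr
  count <- function(w, s) {
    n <- 0L
    for (i in 1:(nchar(s) - nchar(w) + 1))
      if (substr(s, i, i + nchar(w) - 1) == w) n <- n + 1L
    n
  }
  set.seed(6)
  s <- random_dna(3000)
  ws <- word_zscore(s, "GTTG")
  n1 <- count("GTT", s); n2 <- count("TTG", s); n12 <- count("TT", s)
  expect_equal(ws$fwd_count, count("GTTG", s))
  expect_equal(ws$rev_count, count("CAAC", s))
  expect_equal(ws$expected, n1 * n2 / n12)
  v <- ws$expected * (1 - n1 / n12) * (1 - n2 / n12)
  expect_equal(ws$zscore, (ws$fwd_count - ws$expected) / sqrt(v))
  expect_equal(ws$strand_skew,
               (ws$fwd_count - ws$rev_count) / (ws$fwd_count + ws$rev_count))
  # GTTG can overlap itself at period 3 (GTTGTTG); GTTC cannot
  expect_true(ws$self_overlap)
  expect_true(word_zscore(s, "GTGT")$self_overlap)
  expect_false(word_zscore(s, "GTTC")$self_overlap)
  expect_error(word_zscore(s, "GTN"), "4..8|length")
  expect_error(word_zscore(s, "GTNA"), "A,C,G,T")
  expect_error(word_zscore(s, "ACGTACGTA"), "4..8")
})

test_that("an over-planted word scores far above the Markov expectation", {
  set.seed(19)
  s <- random_dna(1e6)
  raw <- charToRaw(s)
  pos <- sample(seq(1, 1e6 - 4, by = 7), 500)
  for (p in pos) raw[p:(p + 3)] <- charToRaw("GTTG")
  # the maximal-order model absorbs roughly half of the planted excess
  # through the inflated sub-word counts, so the z-score is well above the
  # significance range but not at the naive 500/sd scale
  expect_gt(word_zscore(rawToChar(raw), "GTTG")$zscore, 3)
})

test_that("null z-scores on Markov sequences are approximately standard", {
  zs <- vapply(1:30, function(s) {
    seq <- random_markov_sequence(1e5, order = 2, seed = 1000 + s)
    word_zscore(seq, "GTTG")$zscore
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.35)
  expect_gt(sd(zs), 0.7)
  expect_lt(sd(zs), 1.3)
})

test_that("cumulative skew accumulates signed occurrences from oriC", {
  g <- new_genome("g", strrep("C", 20000), oriC = 0L)
  flat <- cumulative_skew(g, "GTTG")
  expect_true(all(flat$values == 0))

  # deterministic construction: GTTG every 500 bp in [0, 10k), CAAC after
  s <- strrep("C", 20000)
  for (p in seq(1, 9800, by = 500)) substr(s, p, p + 3) <- "GTTG"
  for (p in seq(10001, 19800, by = 500)) substr(s, p, p + 3) <- "CAAC"
  g2 <- new_genome("g2", s, oriC = 0L)
  cur <- cumulative_skew(g2, "GTTG", bin = 100)
  expect_equal(max(cur$values), 20)
  sm <- skew_summit(cur)
  # the curve plateaus between the last fwd and first rev occurrence
  # (9600..10000 at 100 bp bins); the summit is the plateau midpoint
  expect_equal(sm$position, 9800)
  expect_equal(sm$angle, 360 * 9800 / 20000)
  # final value equals total forward minus reverse occurrences
  expect_equal(cur$values[length(cur$values)], 0)
  # antisymmetry against the reverse-complement word
  cur_rc <- cumulative_skew(g2, "CAAC", bin = 100)
  expect_equal(cur_rc$values, -cur$values)
})

test_that("the summit rule takes the midpoint of the longest plateau", {
  curve <- structure(list(word = "GTTG",
                          positions = seq(0, 1000, by = 100),
                          values = c(0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2),
                          bin = 100L, L = 1000L, oriC = 0L),
                     class = "skew_curve")
  sm <- skew_summit(curve)
  expect_equal(sm$position, 400)  # plateau 300..500
  unimodal <- curve
  unimodal$values <- c(0, 1, 2, 5, 3, 3, 2, 1, 0, -1, -2)
  expect_equal(skew_summit(unimodal)$position, 300)
})

test_that("a planted polarized word is ranked first and reported in its
           over-represented orientation", {
  cfg <- sim_config(L = 2e5, seed = 23, gene_density = 0, ter_angle = 160)
  g <- plant_polarized_word(random_genome(cfg), cfg)
  r <- rank_asps(g, k_range = 4)
  expect_equal(r$word[1], "GTTG")
  expect_gt(r$median_z[1], 3)
  expect_gt(r$median_skew[1], 0)
  expect_false("CAAC" %in% r$word)
  # palindromic words are excluded by construction
  expect_false(any(r$word %in% c("GATC", "ACGT", "AATT", "GGCC")))
})

test_that("ASPS ranking is invariant under rotation of the coordinate
           origin", {
  cfg <- sim_config(L = 5e4, seed = 29, gene_density = 0, ter_angle = 140)
  g <- plant_polarized_word(random_genome(cfg), cfg)
  r1 <- rank_asps(g, k_range = 4)
  shift <- 12345L
  g2 <- new_genome("g", circular_subseq(g$sequence, shift, shift + g$length),
                   oriC = (g$oriC - shift) %% g$length)
  r2 <- rank_asps(g2, k_range = 4)
  expect_equal(r1$word, r2$word)
  expect_equal(r1$score, r2$score)
})

test_that("an unpolarized genome produces no strong stable signal", {
  hits <- vapply(1:8, function(s) {
    g <- random_genome(sim_config(L = 1e5, seed = 400 + s,
                                  gene_density = 0,
                                  asps_rate_leading = 0,
                                  asps_rate_lagging = 0))
    r <- rank_asps(g, k_range = 4)
    nrow(r) > 0 && r$median_z[1] >= 3
  }, logical(1))
  expect_lte(sum(hits), 1)
})
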