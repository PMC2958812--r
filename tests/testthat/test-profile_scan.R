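test_that("profile probabilities and log-odds follow the pseudocount rule", {
  p <- build_profile(c("A", "A"), pseudocount = 1)
  # P(A) = (2 + 0.25) / 3 = 0.75 against a 0.25 background
  expect_equal(unname(p$matrix["A", 1]), log2(0.75 / 0.25))
  expect_equal(unname(p$matrix["C", 1]), log2((0.25 / 3) / 0.25))
  # column probabilities (before log) sum to 1
  expect_equal(sum(0.25 * 2^p$matrix[, 1]), 1)
  expect_error(build_profile(c("AC", "ACG")), "ragged")
  expect_error(build_profile("AC"), "two sequences")
  expect_error(build_profile(c("AC", "AC"), pseudocount = 0))
  expect_error(build_profile(c("AC", "AC"),
                             background = c(A = 1, C = 0, G = 0, T = 0)),
               "positive")
})

test_that("an identical-sequence profile scores its consensus near 2
           bits per column and above every other word", {
  word <- "ACGTAG"
  prof <- build_profile(rep(word, 4), pseudocount = 1e-6)
  expect_equal(score_sequences(prof, word), 2 * nchar(word),
               tolerance = 1e-4)
  # exhaustive: no 6-mer scores higher than the consensus
  all6 <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 6)), 1,
                paste, collapse = "")
  scores <- score_sequences(prof, all6)
  expect_equal(all6[which.max(scores)], word)
})

test_that("window scores are additive over profile columns", {
  set.seed(3)
  aligned <- replicate(5, random_dna(12))
  prof <- build_profile(aligned)
  for (i in 1:10) {
    s <- random_dna(12)
    manual <- sum(prof$matrix[cbind(match(strsplit(s, "")[[1]],
                                          rownames(prof$matrix)),
                                    seq_len(12))])
    expect_equal(score_sequences(prof, s), manual)
  }
})

test_that("scanning finds a planted consensus site first, symmetrically on
           both strands, over the circular sequence", {
  set.seed(8)
  site <- PAB_SITE
  prof <- build_profile(c(site, site), pseudocount = 0.5)
  seq <- random_dna(4000)
  substr(seq, 2001, 2028) <- site
  g <- new_genome("g", seq)
  hits <- scan_genome(g, prof, threshold = score_sequences(prof, site) - 1)
  expect_gte(nrow(hits), 1L)
  expect_equal(hits$start[1], 2000L)
  expect_equal(hits$strand[1], "+")
  # reverse-complemented genome: same scores, mirrored coordinates
  grc <- new_genome("g", revcomp(seq))
  hits_rc <- scan_genome(grc, prof,
                         threshold = score_sequences(prof, site) - 1)
  expect_equal(hits_rc$score[1], hits$score[1])
  expect_equal(hits_rc$start[1], 4000L - 2028L)
  expect_equal(hits_rc$strand[1], "-")
  # unreachable threshold: empty result
  none <- scan_genome(g, prof, threshold = 2 * prof$width + 1)
  expect_equal(nrow(none), 0L)
  # a site wrapping the coordinate origin is still found
  seq2 <- random_dna(1000)
  g2 <- new_genome("g2", xerscan:::circular_replace(seq2, 986, site))
  hits2 <- scan_genome(g2, prof,
                       threshold = score_sequences(prof, site) - 1)
  expect_true(986 %in% hits2$start)
})

test_that("threshold calibration is reproducible, quantile-correct and
           monotone in alpha", {
  set.seed(14)
  prof <- build_profile(c(PAB_SITE, PAB_SITE), pseudocount = 0.5)
  g <- new_genome("g", random_dna(3000))
  c1 <- calibrate_threshold(prof, g, n_shuffles = 100, alpha = 0, seed = 9)
  expect_equal(c1$score_threshold, max(c1$null_max_scores))
  c2 <- calibrate_threshold(prof, g, n_shuffles = 100, alpha = 0, seed = 9)
  expect_identical(c1$score_threshold, c2$score_threshold)
  c3 <- calibrate_threshold(prof, g, n_shuffles = 100, alpha = 0.2, seed = 9)
  c4 <- calibrate_threshold(prof, g, n_shuffles = 100, alpha = 0.5, seed = 9)
  expect_true(c3$score_threshold <= c1$score_threshold)
  expect_true(c4$score_threshold <= c3$score_threshold)
  expect_error(calibrate_threshold(prof, g, n_shuffles = 50), ">= 100")
})

test_that("a planted site is significant against the shuffled null", {
  set.seed(15)
  seq <- random_dna(20000, gc = 0.45)
  g <- new_genome("g", xerscan:::circular_replace(seq, 10000, PAB_SITE))
  prof <- build_profile(c(PAB_SITE, PAB_SITE), pseudocount = 0.5)
  prof <- calibrate_threshold(prof, g, n_shuffles = 100, alpha = 0.05,
                              seed = 4)
  hits <- scan_genome(g, prof)
  expect_gte(nrow(hits), 1L)
  expect_equal(hits$start[1], 10000L)
  expect_lte(hits$empirical_p[1], 0.05)
})

test_that("the dinucleotide shuffle preserves dinucleotide composition", {
  set.seed(16)
  for (i in 1:15) {
    s <- random_dna(sample(200:2000, 1), gc = runif(1, 0.3, 0.7))
    sh <- xerscan:::cpp_dinuc_shuffle(s)
    dinuc <- function(x) Biostrings::oligonucleotideFrequency(
      Biostrings::DNAString(x), width = 2)
    expect_identical(dinuc(sh), dinuc(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
  }
})

test_that("profiles round-trip through the plain-text format", {
  set.seed(17)
  prof <- build_profile(replicate(4, random_dna(10)), pseudocount = 0.7,
                        background = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3))
  prof$score_threshold <- 5.25
  f <- withr::local_tempfile(fileext = ".txt")
  write_profile(prof, f)
  back <- read_profile(f)
  expect_equal(back$matrix, prof$matrix, tolerance = 1e-6)
  expect_equal(back$background, prof$background)
  expect_equal(back$pseudocount, prof$pseudocount)
  expect_equal(back$score_threshold, prof$score_threshold)
})
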