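test_that("generators are pure functions of the config", {
  cfg <- sim_config(L = 20000, seed = 5)
  g1 <- random_genome(cfg)
  g2 <- random_genome(cfg)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$features, g2$features)
  s1 <- simulate_genome_set(cfg)
  s2 <- simulate_genome_set(cfg)
  expect_identical(lapply(s1, `[[`, "sequence"),
                   lapply(s2, `[[`, "sequence"))
})

test_that("base composition and gene density hit their targets", {
  g <- random_genome(sim_config(L = 1e6, gc = 0.5, seed = 2))
  gc <- mean(strsplit(g$sequence, "")[[1]] %in% c("G", "C"))
  expect_gte(gc, 0.497)
  expect_lte(gc, 0.503)
  dens <- sum(pmin(g$features$end, g$length) - g$features$start +
                pmax(g$features$end - g$length, 0)) / g$length
  expect_lt(abs(dens - 0.85), 0.02)
  g0 <- random_genome(sim_config(L = 5000, gene_density = 0, seed = 1))
  expect_equal(nrow(g0$features), 0L)
  expect_error(random_genome(sim_config(L = 500, gene_len_mean = 5000,
                                        seed = 1)),
               "infeasible")
})

test_that("plant_site places the site intergenically near the target
           angle and is idempotent", {
  cfg <- sim_config(L = 2e5, seed = 12)
  g <- random_genome(cfg)
  g1 <- plant_site(g, cfg$planted_site, 130)
  truth <- g1$truth$sites
  expect_equal(angle_from_origin(truth$start, 0, g$length), 130,
               tolerance = 2)
  # the planted interval does not overlap any gene feature
  f <- g$features
  expect_false(any(truth$start < f$end & truth$end > f$start &
                     toupper(f$kind) %in% c("CDS", "RRNA", "TRNA")))
  # enumeration at defaults recovers the site with its 2 arm mismatches
  cand <- enumerate_ir_candidates(intergenic_regions(g1, 28))
  hit <- cand[cand$start == truth$start & cand$arm_len == 11 &
                cand$spacer_len == 6, ]
  expect_equal(hit$mismatches, 2L)
  g2 <- plant_site(g1, cfg$planted_site, 130)
  expect_identical(g2$sequence, g1$sequence)
  # a fully coding genome has nowhere to put the site
  gfull <- new_genome("x", strrep("A", 1000),
                      data.frame(start = 0, end = 1000, strand = "+",
                                 kind = "CDS"))
  expect_error(plant_site(gfull, cfg$planted_site, 90), "no intergenic")
})

test_that("polarized-word planting records truth and respects its guards", {
  cfg0 <- sim_config(L = 50000, seed = 3, gene_density = 0,
                     asps_rate_leading = 0, asps_rate_lagging = 0)
  g <- random_genome(cfg0)
  expect_identical(plant_polarized_word(g, cfg0)$sequence, g$sequence)

  cfg <- sim_config(L = 50000, seed = 3, gene_density = 0, ter_angle = 120)
  g1 <- plant_polarized_word(g, cfg)
  truth <- g1$truth$asps
  expect_gt(nrow(truth), 30)
  expect_equal(g1$truth$ter, position_at_angle(0, 120, 50000))
  # every recorded placement is really in the sequence
  for (i in sample(nrow(truth), 10)) {
    w <- circular_subseq(g1$sequence, truth$position[i],
                         truth$position[i] + 4)
    expect_equal(w, if (truth$strand[i] == "+") "GTTG" else revcomp("GTTG"))
  }
  expect_error(plant_polarized_word(
    g, sim_config(asps_word = "GATC")), "palindromic")
  expect_error(plant_polarized_word(
    g, sim_config(asps_rate_leading = 300)), "saturate")
})

test_that("divergence spares protected intervals and erodes the rest", {
  cfg <- sim_config(L = 1e5, seed = 8, gene_density = 0.5)
  g <- plant_site(random_genome(cfg), cfg$planted_site, 130)
  same <- diverge_set(g, n = 2, divergence = 0, rate_protected = 0,
                      seed = 1)
  expect_identical(same[[1]]$sequence, g$sequence)
  expect_equal(same[[1]]$id, paste0(g$id, "_1"))

  div <- diverge_set(g, n = 4, divergence = 0.3, rate_protected = 0.025,
                     seed = 2)
  truth <- g$truth$sites
  site_of <- function(gg) circular_subseq(gg$sequence, truth$start,
                                          truth$end)
  prot_id <- sapply(div, function(gg)
    site_similarity(site_of(gg), truth$site))
  expect_true(all(prot_id >= 0.85))
  # background 28-mers drop to ~0.55 mean pairwise identity
  set.seed(33)
  starts <- sample(setdiff(0:(1e5 - 29), (truth$start - 28):truth$end), 200)
  ids <- mapply(function(a, b) {
    mean(vapply(starts, function(st)
      sum(strsplit(circular_subseq(a$sequence, st, st + 28), "")[[1]] ==
            strsplit(circular_subseq(b$sequence, st, st + 28), "")[[1]]) / 28,
      numeric(1)))
  }, div[c(1, 1, 2)], div[c(2, 3, 3)])
  expect_lt(abs(mean(ids) - 0.55), 0.1)
})

test_that("Markov sequence generation honors a fixed transition matrix", {
  # a chain that strongly favors A after everything
  trans <- matrix(rep(c(0.97, 0.01, 0.01, 0.01), each = 16), ncol = 4)
  s <- random_markov_sequence(5000, order = 2, trans = trans, seed = 1)
  expect_gt(mean(strsplit(s, "")[[1]] == "A"), 0.9)
  s1 <- random_markov_sequence(1000, order = 2, seed = 7)
  s2 <- random_markov_sequence(1000, order = 2, seed = 7)
  expect_identical(s1, s2)
})
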