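#' Configuration for the synthetic-genome simulator
#'
#' The generator emulates the statistical structure the analysis assumes: a
#' circular chromosome with a gene/intergenic architecture, a planted
#' quasi-palindromic site conserved (with controlled divergence) across
#' several genomes near a chosen angle, and a short word planted with
#' strand-polarized density whose polarity inverts at a chosen terminus
#' angle. Defaults model an archaeal-like chromosome: 1 Mb, 45% GC, 85%
#' coding, ~900 bp genes; the default planted site is the 28-bp Pyrococcus
#' abyssi dif sequence (11 bp arms, 2 arm mismatches, 6 bp spacer) and the
#' default polarized word is the 4-mer GTTG at 2 vs 0.5 occurrences per kb,
#' inverting at the same angle where the site is planted (the polarity of
#' such words inverts at the dif site in real chromosomes).
#'
#' @param L Genome length (bp).
#' @param gc GC fraction of the random background.
#' @param gene_density Fraction of the genome covered by gene features.
#' @param gene_len_mean Mean gene length (bp).
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @param planted_site DNA string planted as the conserved site.
#' @param site_angle Angle (degrees from oriC) at which the site is planted.
#' @param asps_word Non-palindromic word planted with polarized density.
#' @param asps_rate_leading,asps_rate_lagging Occurrences per kb of the word
#'   in its leading- and lagging-strand orientation.
#' @param ter_angle Terminus angle (degrees from oriC) where the word's
#'   polarity inverts.
#' @param n_genomes Number of diverged copies produced by [diverge_set()].
#' @param divergence Background substitutions per site per copy.
#' @param divergence_protected Substitutions per site per copy inside
#'   protected intervals (the planted site); the expected pairwise identity
#'   of the protected site is about `1 - 2 * divergence_protected`.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(L = 1e6, gc = 0.45, gene_density = 0.85,
                       gene_len_mean = 900, seed = 1L,
                       planted_site = "ATTGGATATAATCGGCCTTATATCTAAA",
                       site_angle = 130, asps_word = "GTTG",
                       asps_rate_leading = 2, asps_rate_lagging = 0.5,
                       ter_angle = 130, n_genomes = 4L, divergence = 0.3,
                       divergence_protected = 0.025) {
  cfg <- list(L = as.integer(L), gc = gc, gene_density = gene_density,
              gene_len_mean = gene_len_mean, seed = as.integer(seed),
              planted_site = toupper(planted_site), site_angle = site_angle,
              asps_word = toupper(asps_word),
              asps_rate_leading = asps_rate_leading,
              asps_rate_lagging = asps_rate_lagging,
              ter_angle = ter_angle, n_genomes = as.integer(n_genomes),
              divergence = divergence,
              divergence_protected = divergence_protected)
  stopifnot(cfg$L > 0, cfg$gc > 0, cfg$gc < 1,
            cfg$gene_density >= 0, cfg$gene_density <= 0.98,
            cfg$asps_rate_leading >= 0, cfg$asps_rate_lagging >= 0,
            cfg$divergence >= 0, cfg$divergence < 1,
            cfg$divergence_protected >= 0, cfg$divergence_protected < 1,
            cfg$n_genomes >= 1)
  structure(cfg, class = "sim_config")
}

#' Random circular genome with gene architecture
#'
#' The sequence is i.i.d. at the configured GC; gene features (kind `CDS`,
#' random strand) alternate with intergenic gaps so that the total coding
#' fraction hits `gene_density` (within rounding). `oriC` is placed at 0.
#' Byte-identical given the same config.
#'
#' @param config A [sim_config()].
#' @return A `Genome` (with empty feature table when `gene_density = 0`).
#' @export
random_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$L
  if (config$gene_density > 0 && config$gene_len_mean > L * config$gene_density)
    stop("infeasible gene density: genes do not fit the genome")
  withr::with_seed(config$seed, {
    p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
           G = config$gc / 2, T = (1 - config$gc) / 2)
    seq <- cpp_random_dna(L, p)
    features <- empty_features()
    if (config$gene_density > 0) {
      target <- round(L * config$gene_density)
      n_genes <- max(1L, round(target / config$gene_len_mean))
      lens <- pmax(90, round(rgamma(n_genes, shape = 9,
                                    rate = 9 / config$gene_len_mean)))
      lens <- round(lens * target / sum(lens))
      lens[n_genes] <- lens[n_genes] + (target - sum(lens))
      if (lens[n_genes] < 1) stop("infeasible gene density")
      gaps <- as.vector(rmultinom(1, L - sum(lens), rep(1, n_genes)))
      starts <- cumsum(c(0L, head(lens + gaps, -1L)))
      offset <- sample.int(L, 1L) - 1L
      features <- data.frame(
        start = (starts + offset) %% L,
        end = (starts + offset) %% L + lens,
        strand = sample(c("+", "-"), n_genes, replace = TRUE),
        kind = "CDS", stringsAsFactors = FALSE)
    }
    new_genome(sprintf("sim_seed%d", config$seed), seq, features, oriC = 0L)
  })
}

#' Plant a site in the intergenic region nearest a target angle
#'
#' Overwrites the genome sequence with `site` at the intergenic position
#' closest to the requested origin-relative angle and records the planted
#' interval as truth. Planting the same site at the same angle twice is
#' idempotent.
#'
#' @param genome A `Genome` with `oriC` set.
#' @param site DNA string to plant.
#' @param angle Target angle (degrees from oriC).
#' @return The modified `Genome`; `genome$truth$sites` gains a row with the
#'   planted `start`, `end` and requested angle.
#' @export
plant_site <- function(genome, site, angle) {
  stopifnot(inherits(genome, "Genome"))
  site <- toupper(site)
  n <- nchar(site)
  oriC <- genome$oriC %||% 0L
  L <- genome$length
  target <- position_at_angle(oriC, angle, L)
  regions <- intergenic_regions(genome, min_length = n)
  if (nrow(regions) == 0L)
    stop("no intergenic region can hold the site")
  # nearest feasible placement start within each region, circular distance
  cand_start <- vapply(seq_len(nrow(regions)), function(i) {
    lo <- regions$start[i]
    hi <- regions$end[i] - n
    d_lo <- (target - lo) %% L
    if (d_lo <= hi - lo) (lo + d_lo) %% L else {
      dd <- c((lo - target) %% L, (target - hi) %% L)
      if (dd[1] <= dd[2]) lo %% L else hi %% L
    }
  }, numeric(1))
  dist <- pmin((cand_start - target) %% L, (target - cand_start) %% L)
  best <- which.min(dist)
  start <- as.integer(cand_start[best])
  genome$sequence <- circular_replace(genome$sequence, start, site)
  genome$truth$sites <- rbind(
    genome$truth$sites,
    data.frame(start = start, end = start + n, site = site,
               angle_requested = angle, stringsAsFactors = FALSE))
  genome
}

#' Plant a strand-polarized word with a terminus polarity switch
#'
#' Places Poisson-distributed occurrences of `asps_word` on the forward
#' strand between oriC and the terminus at `asps_rate_leading` per kb (and
#' its reverse complement at `asps_rate_lagging` per kb), with the mirrored
#' arrangement on the terminus -> oriC segment, emulating KOPS/ASPS polarity
#' that inverts at the terminus. Placements overlapping each other or a
#' previously planted truth site are dropped; all surviving placements are
#' recorded as truth. Deterministic given the config seed.
#'
#' @param genome A `Genome` with `oriC` set.
#' @param config A [sim_config()].
#' @return The modified `Genome`; `genome$truth$asps` records `position`,
#'   `strand`, and `genome$truth$ter` the terminus position.
#' @export
plant_polarized_word <- function(genome, config) {
  stopifnot(inherits(genome, "Genome"), inherits(config, "sim_config"))
  word <- config$asps_word
  k <- nchar(word)
  if (identical(word, revcomp(word)))
    stop("asps_word must not be palindromic")
  if (max(config$asps_rate_leading, config$asps_rate_lagging) * k / 1000 > 1)
    stop("rates would saturate the sequence with overlapping occurrences")
  if (config$asps_rate_leading == 0 && config$asps_rate_lagging == 0)
    return(genome)
  oriC <- genome$oriC %||% 0L
  L <- genome$length
  ter <- position_at_angle(oriC, config$ter_angle, L)
  l1 <- (ter - oriC) %% L
  l2 <- L - l1
  wrc <- revcomp(word)
  withr::with_seed(config$seed + 1L, {
    draw <- function(seg_start, seg_len, rate) {
      npl <- rpois(1, rate * seg_len / 1000)
      if (npl == 0L) return(integer(0))
      (seg_start + sort(sample.int(seg_len - k + 1L, min(npl, seg_len - k + 1L))) - 1L) %% L
    }
    pl <- rbind(
      data.frame(position = draw(oriC, l1, config$asps_rate_leading),
                 strand = "+", stringsAsFactors = FALSE),
      data.frame(position = draw(oriC, l1, config$asps_rate_lagging),
                 strand = "-", stringsAsFactors = FALSE),
      data.frame(position = draw(ter, l2, config$asps_rate_leading),
                 strand = "-", stringsAsFactors = FALSE),
      data.frame(position = draw(ter, l2, config$asps_rate_lagging),
                 strand = "+", stringsAsFactors = FALSE))
  })
  pl <- pl[order(pl$position), , drop = FALSE]
  if (nrow(pl) > 1L) {
    keep <- c(TRUE, diff(pl$position) >= k)
    pl <- pl[keep, , drop = FALSE]
  }
  if (!is.null(genome$truth$sites) && nrow(pl)) {
    protected <- genome$truth$sites
    clash <- vapply(pl$position, function(p) any(
      p + k > protected$start & p < protected$end), logical(1))
    pl <- pl[!clash, , drop = FALSE]
  }
  if (nrow(pl)) {
    raw <- charToRaw(genome$sequence)
    wraw <- charToRaw(word)
    wrcraw <- charToRaw(wrc)
    for (i in seq_len(nrow(pl))) {
      idx <- ((pl$position[i] + 0:(k - 1L)) %% L) + 1L
      raw[idx] <- if (pl$strand[i] == "+") wraw else wrcraw
    }
    genome$sequence <- rawToChar(raw)
  }
  genome$truth$asps <- pl
  genome$truth$ter <- ter
  genome
}

#' Diverged copies of a genome with a protected site
#'
#' Each copy receives i.i.d. substitutions (uniform exchange to one of the
#' three other bases, no indels) at `divergence` per site, except inside
#' `protect` intervals which mutate at the lower `rate_protected`; the
#' expected pairwise identity of a protected site is about
#' `1 - 2 rate_protected`. Features, oriC and truth records are carried
#' over; ids get a `_1..n` suffix.
#'
#' @param genome A `Genome`.
#' @param n Number of copies (>= 2).
#' @param divergence Background substitution rate per site per copy.
#' @param protect `data.frame` with `start`, `end` (0-based half-open) of
#'   protected intervals; defaults to the planted truth sites.
#' @param rate_protected Substitution rate inside protected intervals.
#' @param seed Integer seed.
#' @return List of `n` Genomes.
#' @export
diverge_set <- function(genome, n = 4L, divergence = 0.3, protect = NULL,
                        rate_protected = 0.025, seed = 1L) {
  stopifnot(inherits(genome, "Genome"), n >= 2L)
  L <- genome$length
  protect <- protect %||% genome$truth$sites
  rate <- rep(divergence, L)
  if (!is.null(protect) && nrow(protect)) {
    for (i in seq_len(nrow(protect))) {
      idx <- (seq.int(protect$start[i], protect$end[i] - 1L) %% L) + 1L
      rate[idx] <- rate_protected
    }
  }
  lapply(seq_len(n), function(i) {
    g <- genome
    withr::with_seed(seed + i,
                     g$sequence <- cpp_mutate(g$sequence, rate))
    g$id <- paste0(genome$id, "_", i)
    g
  })
}

#' Simulate a conserved-site quartet (or n-et) of genomes
#'
#' Convenience wrapper running the full generator: random genome, planted
#' conserved site at `site_angle`, planted polarized word switching at
#' `ter_angle`, then `n_genomes` diverged copies with the site protected.
#'
#' @param config A [sim_config()].
#' @return List of `Genome`s of length `config$n_genomes`.
#' @export
simulate_genome_set <- function(config = sim_config()) {
  g <- random_genome(config)
  g <- plant_site(g, config$planted_site, config$site_angle)
  if (config$asps_rate_leading > 0 || config$asps_rate_lagging > 0)
    g <- plant_polarized_word(g, config)
  diverge_set(g, n = config$n_genomes, divergence = config$divergence,
              rate_protected = config$divergence_protected,
              seed = config$seed + 1000L)
}

#' Random sequence from a Markov chain
#'
#' Generates an order-`order` Markov chain over `A,C,G,T`; with `trans =
#' NULL` a random transition matrix is drawn (Dirichlet-like, concentration
#' 5 around uniform). Used for null calibration of [word_zscore()].
#'
#' @param L Sequence length.
#' @param order Markov order (>= 1).
#' @param trans Optional `4^order x 4` row-stochastic matrix (states in
#'   lexicographic order).
#' @param seed Optional integer seed.
#' @return Character scalar.
#' @export
random_markov_sequence <- function(L, order = 2L, trans = NULL, seed = NULL) {
  gen <- function() {
    if (is.null(trans)) {
      trans <- matrix(rgamma(4^order * 4, shape = 5), ncol = 4)
      trans <- trans / rowSums(trans)
    }
    cpp_markov_seq(as.integer(L), trans, as.integer(order))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
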