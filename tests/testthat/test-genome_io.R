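test_that("read_genome reads a single-record FASTA and rejects multi-record", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">chr1 test", "ACGT"), fa)
  g <- read_genome(fa)
  expect_s3_class(g, "Genome")
  expect_equal(g$id, "chr1")
  expect_equal(g$length, 4L)
  expect_equal(nrow(g$features), 0L)

  fa2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "GGCC"), fa2)
  expect_error(read_genome(fa2), "2 records")
})

test_that("GFF3 annotation maps to 0-based half-open internal coordinates", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">chr1", "ACGTACGTAC"), fa)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tCDS\t1\t3\t.\t+\t0\tID=cds1"), gff)
  g <- read_genome(fa, gff)
  expect_equal(g$features$start, 0L)
  expect_equal(g$features$end, 3L)
  expect_equal(g$features$strand, "+")
  expect_equal(g$features$kind, "CDS")

  gff_bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "other\ttest\tCDS\t1\t3\t.\t+\t0\tID=cds1"), gff_bad)
  expect_error(read_genome(fa, gff_bad), "does not match|references")
})

test_that("GenBank feature tables parse locations, strands and kinds", {
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       chr1        40 bp    DNA  circular",
    "FEATURES             Location/Qualifiers",
    "     source          1..40",
    "     CDS             3..11",
    '                     /product="p1"',
    "     tRNA            complement(20..28)",
    "     CDS             join(30..34,36..40)",
    "ORIGIN",
    "//"), gb)
  feats <- xerscan:::parse_genbank_features(gb)
  cds <- feats[feats$kind == "CDS", ]
  expect_equal(cds$start, c(2L, 29L, 35L))
  expect_equal(cds$end, c(11L, 34L, 40L))
  trna <- feats[feats$kind == "tRNA", ]
  expect_equal(trna$strand, "-")
  expect_equal(attr(feats, "locus"), "chr1")
})

test_that("synthetic genomes round-trip through write_genome/read_genome", {
  cfg <- sim_config(L = 5000, seed = 42, gene_density = 0.6,
                    gene_len_mean = 300)
  g <- plant_site(random_genome(cfg), cfg$planted_site, cfg$site_angle)
  dir <- withr::local_tempdir()
  paths <- write_genome(g, dir)
  g2 <- read_genome(paths["fasta"], paths["gff3"])
  expect_identical(g2$sequence, g$sequence)
  expect_equal(g2$features$start, g$features$start)
  expect_equal(g2$features$end, g$features$end)
  expect_equal(g2$features$strand, g$features$strand)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$sites$start, g$truth$sites$start)
})

test_that("prediction writers honor each format's coordinate convention", {
  sites <- data.frame(genome_id = "chr1", start = 100L, end = 128L,
                      strand = "+", score = 5.5)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_predictions(sites, bed, "BED")
  fields <- strsplit(readLines(bed)[1], "\t")[[1]]
  expect_equal(as.integer(fields[2:3]), c(100L, 128L))

  gff <- withr::local_tempfile(fileext = ".gff3")
  write_predictions(sites, gff, "GFF3")
  line <- grep("^chr1\t", readLines(gff), value = TRUE)[1]
  expect_equal(as.integer(strsplit(line, "\t")[[1]][4:5]), c(101L, 128L))

  # round-trip through a standard parser
  gr <- rtracklayer::import(gff)
  expect_equal(GenomicRanges::start(gr), 101L)
  expect_equal(GenomicRanges::end(gr), 128L)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(sites, tsv, "TSV")
  back <- read.delim(tsv)
  expect_equal(back$start, 100L)
  expect_equal(back$end, 128L)

  # empty input still produces a valid header-only file
  write_predictions(sites[0, ], gff, "GFF3")
  expect_equal(readLines(gff)[1], "##gff-version 3")
  expect_error(write_predictions(sites, tsv, "XLS"), "unknown")
})

test_that("intergenic regions complement the gene features on the circle", {
  g <- new_genome("g", strrep("A", 100),
                  data.frame(start = 10, end = 90, strand = "+",
                             kind = "CDS"))
  r <- intergenic_regions(g)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 90L)
  expect_equal(r$end, 110L)
  expect_equal(r$length, 20L)
  expect_equal(nchar(r$sequence), 20L)

  g0 <- new_genome("g", strrep("A", 100))
  r0 <- intergenic_regions(g0)
  expect_equal(r0$length, 100L)

  # non-gene feature kinds do not mask
  g1 <- new_genome("g", strrep("A", 100),
                   data.frame(start = 10, end = 90, strand = "+",
                              kind = "repeat_region"))
  expect_equal(intergenic_regions(g1)$length, 100L)
})

test_that("intergenic extraction matches a boolean-mask oracle", {
  set.seed(11)
  for (rep in 1:300) {
    L <- sample(60:200, 1)
    nf <- sample(1:6, 1)
    start <- sample(0:(L - 1), nf)
    len <- sample(3:25, nf, replace = TRUE)
    feats <- data.frame(start = start, end = start + len, strand = "+",
                        kind = "CDS")
    g <- new_genome("g", strrep("C", L), feats)
    covered <- rep(FALSE, L)
    for (i in seq_len(nf))
      covered[(seq(start[i], start[i] + len[i] - 1) %% L) + 1] <- TRUE
    r <- intergenic_regions(g)
    got <- rep(FALSE, L)
    for (i in seq_len(nrow(r)))
      got[(seq(r$start[i], r$end[i] - 1) %% L) + 1] <- TRUE
    expect_identical(got, !covered)
    # coverage conservation
    expect_equal(sum(r$length), sum(!covered))
  }
})
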