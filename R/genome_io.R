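#' Construct a circular genome object
#'
#' A `Genome` bundles a chromosome sequence with its feature annotation and
#' (optionally) the position of the replication origin. All coordinates are
#' internal 0-based half-open; circular positions are normalized mod `L`, and
#' intervals that wrap around the origin of the coordinate system are
#' represented with `end > L`.
#'
#' @param id Character scalar, genome identifier.
#' @param sequence Character scalar over `A`,`C`,`G`,`T`,`N` (case
#'   insensitive; stored uppercased).
#' @param features `data.frame` with columns `start`, `end` (0-based
#'   half-open), `strand` (`+`/`-`), `kind` (e.g. `"CDS"`, `"rRNA"`,
#'   `"tRNA"`). May be empty.
#' @param oriC Optional replication-origin position in bp (`[0, L)`). If the
#'   origin is known only as an interval, pass its midpoint.
#' @param circular Logical; only circular chromosomes are modelled.
#' @param truth Optional list of planted-truth records (used by the
#'   synthetic-data generator).
#' @return An object of class `Genome`: a list with elements `id`,
#'   `sequence`, `length`, `features`, `oriC`, `circular`, `truth`.
#' @export
new_genome <- function(id, sequence, features = NULL, oriC = NULL,
                       circular = TRUE, truth = list()) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!grepl("^[ACGTN]*$", sequence))
    stop("genome sequence contains characters outside {A,C,G,T,N}")
  L <- nchar(sequence)
  if (L == 0L) stop("genome sequence is empty")
  features <- normalize_features(features, L)
  if (!is.null(oriC)) {
    oriC <- as.integer(oriC %% L)
  }
  structure(
    list(id = id, sequence = sequence, length = L, features = features,
         oriC = oriC, circular = isTRUE(circular), truth = truth),
    class = "Genome"
  )
}

empty_features <- function() {
  data.frame(start = integer(0), end = integer(0),
             strand = character(0), kind = character(0),
             stringsAsFactors = FALSE)
}

normalize_features <- function(features, L) {
  if (is.null(features) || nrow(features) == 0L) return(empty_features())
  stopifnot(all(c("start", "end") %in% names(features)))
  f <- data.frame(start = as.integer(features$start),
                  end = as.integer(features$end),
                  strand = as.character(features$strand %||%
                                          rep("+", nrow(features))),
                  kind = as.character(features$kind %||%
                                        rep("CDS", nrow(features))),
                  stringsAsFactors = FALSE)
  if (any(f$end <= f$start)) stop("features must have end > start")
  if (any(f$end - f$start > L)) stop("feature longer than the genome")
  shift <- f$start %/% L
  f$start <- f$start - shift * L
  f$end <- f$end - shift * L
  f[order(f$start, f$end), , drop = FALSE]
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("<Genome> %s: %s bp circular, %d features%s\n",
              x$id, format(x$length, big.mark = ","), nrow(x$features),
              if (!is.null(x$oriC)) sprintf(", oriC at %d", x$oriC) else ""))
  invisible(x)
}

#' Read a genome and its annotation
#'
#' Reads a single-record FASTA file, optionally with a feature annotation in
#' GFF3 or GenBank flat-file format, into a [new_genome()] object. Feature
#' coordinates are converted to the internal 0-based half-open convention.
#'
#' @param fasta_path Path to a FASTA file containing exactly one record.
#' @param annotation_path Optional path to a GFF3 (`.gff`/`.gff3`) or GenBank
#'   (`.gb`/`.gbk`/`.gbff`) annotation of that record.
#' @param oriC Optional origin position (bp). If `NULL` and a truth JSON
#'   written by [write_genome()] sits next to the FASTA, its `oriC` is used.
#' @return A `Genome`.
#' @export
read_genome <- function(fasta_path, annotation_path = NULL, oriC = NULL) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dna) != 1L)
    stop(sprintf("expected a single-record FASTA, found %d records in %s",
                 length(dna), fasta_path))
  id <- strsplit(names(dna)[1], "\\s+")[[1]][1]
  seq <- as.character(dna[[1]])
  features <- empty_features()
  if (!is.null(annotation_path)) {
    features <- read_annotation(annotation_path, id)
  }
  new_genome(id, seq, features, oriC = oriC)
}

read_annotation <- function(path, genome_id) {
  first <- readLines(path, n = 5L)
  is_gb <- any(grepl("^LOCUS", first)) ||
    grepl("\\.(gb|gbk|gbff)$", path, ignore.case = TRUE)
  if (is_gb) {
    feats <- parse_genbank_features(path)
    locus <- attr(feats, "locus")
    if (!is.null(locus) && !is.na(locus) && nzchar(locus) &&
        !identical(locus, genome_id))
      stop(sprintf("annotation LOCUS '%s' does not match genome id '%s'",
                   locus, genome_id))
    return(feats)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(empty_features())
  seqs <- unique(as.character(GenomicRanges::seqnames(gr)))
  if (!all(seqs == genome_id))
    stop(sprintf("annotation references '%s' but genome id is '%s'",
                 paste(setdiff(seqs, genome_id), collapse = ","), genome_id))
  data.frame(
    start = GenomicRanges::start(gr) - 1L,  # 1-based inclusive -> 0-based
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    kind = as.character(gr$type),
    stringsAsFactors = FALSE
  )
}

# Minimal GenBank flat-file feature-table parser: extracts feature kind,
# location (simple, complement(), join() of simple spans) and strand.
parse_genbank_features <- function(path) {
  lines <- readLines(path)
  locus <- NA_character_
  ll <- grep("^LOCUS", lines, value = TRUE)
  if (length(ll)) locus <- strsplit(sub("^LOCUS\\s+", "", ll[1]), "\\s+")[[1]][1]
  fstart <- grep("^FEATURES", lines)
  if (!length(fstart)) {
    out <- empty_features()
    attr(out, "locus") <- locus
    return(out)
  }
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  fend <- if (length(fend)) min(fend[fend > fstart[1]]) - 1L else length(lines)
  block <- lines[(fstart[1] + 1L):fend]
  # feature headers are indented 5 spaces; qualifiers 21
  hdr <- grepl("^ {5}\\S", block)
  idx <- which(hdr)
  out <- list()
  for (i in idx) {
    kind <- sub("^ {5}(\\S+).*", "\\1", block[i])
    loc <- sub("^ {5}\\S+\\s+", "", block[i])
    j <- i + 1L
    while (j <= length(block) && !hdr[j] && !grepl("^ {21}/", block[j])) {
      loc <- paste0(loc, gsub("\\s", "", block[j]))
      j <- j + 1L
    }
    strand <- if (grepl("complement", loc)) "-" else "+"
    spans <- regmatches(loc, gregexpr("<?\\d+\\.\\.>?\\d+|\\b\\d+\\b", loc))[[1]]
    for (sp in spans) {
      nums <- as.integer(regmatches(sp, gregexpr("\\d+", sp))[[1]])
      a <- nums[1]
      b <- if (length(nums) > 1L) nums[2] else nums[1]
      out[[length(out) + 1L]] <- data.frame(
        start = a - 1L, end = b, strand = strand, kind = kind,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(out)) do.call(rbind, out) else empty_features()
  attr(out, "locus") <- locus
  out
}

#' Extract sequence on a circular genome
#'
#' 0-based half-open access; `end` may exceed the genome length to denote an
#' interval wrapping past the coordinate origin.
#'
#' @param genome A `Genome`, or a character sequence.
#' @param start,end 0-based half-open bounds, `end > start`,
#'   `end - start <= L`.
#' @return Character scalar of length `end - start`.
#' @export
circular_subseq <- function(genome, start, end) {
  seq <- if (inherits(genome, "Genome")) genome$sequence else genome
  L <- nchar(seq)
  stopifnot(end > start, end - start <= L)
  start <- start %% L
  end2 <- start + (end - start)
  if (end2 <= L) return(substr(seq, start + 1L, end2))
  paste0(substr(seq, start + 1L, L), substr(seq, 1L, end2 - L))
}

# overwrite `replacement` into the circular sequence at 0-based `start`
circular_replace <- function(seq, start, replacement) {
  L <- nchar(seq)
  n <- nchar(replacement)
  stopifnot(n <= L)
  start <- start %% L
  if (start + n <= L) {
    substr(seq, start + 1L, start + n) <- replacement
  } else {
    k <- L - start
    substr(seq, start + 1L, L) <- substr(replacement, 1L, k)
    substr(seq, 1L, n - k) <- substr(replacement, k + 1L, n)
  }
  seq
}

# feature kinds that mask the intergenic space
GENE_KINDS <- c("CDS", "RRNA", "TRNA")

#' Intergenic regions of an annotated circular genome
#'
#' Returns the maximal intervals of the chromosome overlapping no gene-class
#' feature (CDS, rRNA, tRNA; other feature kinds such as `repeat_region` do
#' not mask). The interval spanning the coordinate origin is reported once,
#' with `end > L`.
#'
#' @param genome A `Genome`.
#' @param min_length Regions shorter than this are dropped (bp).
#' @return `data.frame` with columns `genome_id`, `start`, `end`, `length`,
#'   `sequence`. With no gene features the whole circle is one region.
#' @export
intergenic_regions <- function(genome, min_length = 1L) {
  stopifnot(inherits(genome, "Genome"))
  L <- genome$length
  f <- genome$features
  f <- f[toupper(f$kind) %in% GENE_KINDS, , drop = FALSE]
  mk <- function(start, end) {
    keep <- (end - start) >= min_length
    start <- start[keep]; end <- end[keep]
    seqs <- character(length(start))
    if (length(start)) {
      dna <- Biostrings::DNAString(genome$sequence)
      wrap <- end > L
      if (any(!wrap))
        seqs[!wrap] <- as.character(Biostrings::extractAt(
          dna, IRanges::IRanges(start = start[!wrap] + 1L, end = end[!wrap])))
      for (i in which(wrap))
        seqs[i] <- circular_subseq(genome, start[i], end[i])
    }
    data.frame(genome_id = rep(genome$id, length(start)),
               start = start, end = end, length = end - start,
               sequence = seqs, stringsAsFactors = FALSE)
  }
  if (nrow(f) == 0L) return(mk(0L, L))
  # split wraparound features into two linear pieces
  s <- f$start; e <- pmin(f$end, L)
  if (any(f$end > L)) {
    w <- f$end > L
    s <- c(s, rep(0L, sum(w))); e <- c(e, f$end[w] - L)
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = s + 1L, end = e))  # 1-based
  gaps <- IRanges::gaps(ir, start = 1L, end = L)
  gs <- IRanges::start(gaps) - 1L
  ge <- IRanges::end(gaps)
  covered_0 <- IRanges::start(ir)[1] == 1L
  covered_L <- IRanges::end(ir)[length(ir)] == L
  if (length(gs) && !covered_0 && !covered_L) {
    # merge the first and last gap across the origin into one wraparound region
    gs_last <- gs[length(gs)]
    ge_first <- ge[1]
    gs <- gs[-1]; ge <- ge[-1]
    ge[length(ge)] <- L + ge_first
    gs[length(gs)] <- gs_last
  }
  if (!length(gs)) return(mk(integer(0), integer(0)))
  out <- mk(as.integer(gs), as.integer(ge))
  rownames(out) <- NULL
  out
}

#' Write predicted sites to GFF3, BED or TSV
#'
#' GFF3 uses 1-based inclusive coordinates, BED 0-based half-open; the TSV
#' keeps every input column verbatim (0-based half-open). Rows are ordered by
#' genome id then start.
#'
#' @param sites `data.frame` with at least `genome_id`, `start`, `end`;
#'   optional `strand`, `score`, further columns kept in the TSV.
#' @param path Output file path.
#' @param format One of `"TSV"`, `"GFF3"`, `"BED"`.
#' @param feature_type GFF3 `type` column value.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(sites, path, format = c("TSV", "GFF3", "BED"),
                              feature_type = "sequence_feature") {
  if (!is.character(format) ||
      !toupper(format[1]) %in% c("TSV", "GFF3", "BED"))
    stop(sprintf("unknown prediction format '%s'", format[1]))
  format <- toupper(format[1])
  req <- c("genome_id", "start", "end")
  if (nrow(sites) > 0 && !all(req %in% names(sites)))
    stop("sites must carry genome_id, start, end")
  if (nrow(sites) > 0)
    sites <- sites[order(sites$genome_id, sites$start), , drop = FALSE]
  if (format == "TSV") {
    write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if (nrow(sites) == 0L) {
    writeLines(if (format == "GFF3") "##gff-version 3" else
      "track name=predictions", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = sites$genome_id,
    ranges = IRanges::IRanges(start = sites$start + 1L, end = sites$end),
    strand = if ("strand" %in% names(sites)) sites$strand else "*")
  if ("score" %in% names(sites)) gr$score <- as.numeric(sites$score)
  nm <- if ("name" %in% names(sites)) sites$name else
    sprintf("site_%04d", seq_along(gr))
  if (format == "GFF3") {
    gr$type <- feature_type
    gr$ID <- nm
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    gr$name <- nm
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}

#' Write a genome as FASTA + GFF3 (+ truth JSON)
#'
#' Emits `<id>.fasta`, `<id>.gff3` and, when planted-truth records exist,
#' `<id>.truth.json` into `dir`. The files round-trip through
#' [read_genome()].
#'
#' @param genome A `Genome`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_genome <- function(genome, dir) {
  stopifnot(inherits(genome, "Genome"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, paste0(genome$id, ".fasta"))
  dna <- Biostrings::DNAStringSet(genome$sequence)
  names(dna) <- genome$id
  Biostrings::writeXStringSet(dna, fa)
  gff <- file.path(dir, paste0(genome$id, ".gff3"))
  f <- genome$features
  if (nrow(f)) {
    gr <- GenomicRanges::GRanges(
      seqnames = genome$id,
      ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
      strand = f$strand)
    gr$type <- f$kind
    gr$ID <- sprintf("feat_%05d", seq_len(nrow(f)))
    rtracklayer::export(gr, gff, format = "gff3")
  } else {
    writeLines("##gff-version 3", gff)
  }
  paths <- c(fasta = fa, gff3 = gff)
  if (length(genome$truth) || !is.null(genome$oriC)) {
    tj <- file.path(dir, paste0(genome$id, ".truth.json"))
    jsonlite::write_json(c(list(oriC = genome$oriC), genome$truth), tj,
                         auto_unbox = TRUE, digits = NA, null = "null")
    paths <- c(paths, truth = tj)
  }
  invisible(paths)
}
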