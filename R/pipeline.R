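#' Multi-genome dif-site discovery pipeline
#'
#' Runs the full comparative workflow: per-genome intergenic extraction and
#' imperfect inverted-repeat enumeration, cross-genome conservation
#' filtering, consensus construction for the top group, flank AT-richness
#' and origin-relative localization of each member. Every stage logs its
#' input/output cardinality so the candidate funnel is auditable.
#'
#' @param genomes List of `Genome` objects (>= 2), or character paths to
#'   FASTA files (annotation read from a same-stem `.gff3` when present).
#' @param params [search_params()] used for enumeration.
#' @param threshold Conservation similarity threshold.
#' @param min_intergenic Minimum intergenic region length searched; defaults
#'   to the smallest site the parameters admit.
#' @param flank Flank width for the AT-richness report (bp).
#' @param out_dir Optional directory for TSV/GFF3 reports.
#' @param verbose Log stage cardinalities with `message()`.
#' @return Object of class `dif_discovery_report`: list with `stages`
#'   (funnel counts), `candidates_by_genome`, `groups`
#'   ([conserved_groups()]), `top_group` (members of the best group, with
#'   `flank_at` and angle columns), `consensus` (of the top group, oriented),
#'   `site_angles`.
#' @export
run_dif_discovery <- function(genomes, params = search_params(),
                              threshold = 0.80, min_intergenic = NULL,
                              flank = 25L, out_dir = NULL, verbose = TRUE) {
  if (is.character(genomes)) {
    genomes <- lapply(genomes, function(p) {
      gff <- sub("\\.(fa|fasta|fna)$", ".gff3", p)
      read_genome(p, if (file.exists(gff) && gff != p) gff else NULL)
    })
  }
  stopifnot(length(genomes) >= 2L,
            all(vapply(genomes, inherits, logical(1), "Genome")))
  ids <- vapply(genomes, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("genome ids must be unique")
  names(genomes) <- ids
  min_intergenic <- min_intergenic %||%
    (2L * params$arm_min + params$spacer_min)
  say <- function(...) if (verbose) message(sprintf(...))
  stages <- list()
  note <- function(stage, genome, n_in, n_out) {
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = stage, genome = genome, n_in = n_in, n_out = n_out,
      stringsAsFactors = FALSE)
    say("[%s] %s: %s -> %s", stage, genome, n_in, n_out)
  }

  candidates <- lapply(genomes, function(g) {
    if (nrow(g$features) == 0L)
      warning(sprintf("genome %s has no annotation; treating the whole %s",
                      g$id, "circle as intergenic"), call. = FALSE)
    regions <- intergenic_regions(g, min_length = min_intergenic)
    note("intergenic", g$id, g$length, sum(regions$length))
    cand <- enumerate_ir_candidates(regions, params)
    note("ir_enumeration", g$id, sum(regions$length), nrow(cand))
    cand
  })

  groups <- conserved_groups(candidates, threshold = threshold)
  note("conservation", "all", sum(vapply(candidates, nrow, integer(1))),
       nrow(groups$summary))

  top_group <- NULL; consensus <- NULL; site_angles <- NULL
  if (nrow(groups$summary)) {
    top_id <- groups$summary$group_id[which.max(groups$summary$min_similarity)]
    top_group <- groups$members[groups$members$group_id == top_id, ,
                                drop = FALSE]
    # orient members against the first member before consensus
    ref <- top_group$canonical_seq[1]
    oriented <- vapply(top_group$canonical_seq, function(s) {
      if (cpp_hamming(ref, s) <= cpp_hamming(ref, revcomp(s))) s else
        revcomp(s)
    }, character(1), USE.NAMES = FALSE)
    consensus <- consensus_iupac(oriented)
    top_group$flank_at <- vapply(seq_len(nrow(top_group)), function(i) {
      g <- genomes[[top_group$genome_id[i]]]
      w <- 2L * top_group$arm_len[i] + top_group$spacer_len[i]
      flank_at_fraction(g, top_group$start[i], top_group$start[i] + w, flank)
    }, numeric(1))
    has_ori <- !vapply(genomes, function(g) is.null(g$oriC), logical(1))
    site_angles <- do.call(rbind, lapply(which(has_ori), function(k) {
      g <- genomes[[k]]
      m <- top_group[top_group$genome_id == g$id, , drop = FALSE]
      if (!nrow(m)) return(NULL)
      mid <- m$start[1] + (2L * m$arm_len[1] + m$spacer_len[1]) / 2
      angle_report(g, mid %% g$length, labels = "top_dif_candidate")
    }))
  }

  report <- structure(
    list(stages = do.call(rbind, stages),
         candidates_by_genome = candidates, groups = groups,
         top_group = top_group, consensus = consensus,
         site_angles = site_angles, threshold = threshold, params = params),
    class = "dif_discovery_report")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.table(report$stages, file.path(out_dir, "stages.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(groups$members, file.path(out_dir, "groups.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(top_group)) {
      sites <- data.frame(genome_id = top_group$genome_id,
                          start = top_group$start,
                          end = top_group$start + 2L * top_group$arm_len +
                            top_group$spacer_len,
                          strand = "+", score = top_group$mismatches,
                          stringsAsFactors = FALSE)
      write_predictions(sites, file.path(out_dir, "top_group.gff3"), "GFF3",
                        feature_type = "recombination_feature")
      write_consensus(consensus, file.path(out_dir, "consensus.tsv"))
    }
  }
  report
}

#' @export
print.dif_discovery_report <- function(x, ...) {
  cat("<dif_discovery_report>\n")
  print(x$stages)
  if (!is.null(x$top_group)) {
    cat(sprintf("top group (min similarity %.3f):\n",
                max(x$groups$summary$min_similarity)))
    print(x$top_group[, c("group_id", "genome_id", "start", "arm_len",
                          "spacer_len", "mismatches", "seq")])
    cat("consensus:", x$consensus$iupac, "\n")
  } else cat("no conserved group found\n")
  invisible(x)
}

#' Single-genome polarized-word (ASPS) analysis
#'
#' Ranks strand-polarized over-represented words with [rank_asps()], builds
#' the cumulative skew curve of the top word and locates its summit. If no
#' word reaches `z_min` median over-representation across rotations the
#' report flags that the genome shows no stable polarized signal.
#'
#' @param genome A `Genome`.
#' @param oriC Origin (bp); defaults to `genome$oriC`.
#' @param k_range Word lengths (4..8).
#' @param grid A [rotation_grid()].
#' @param bin Curve bin width (bp).
#' @param z_min Median z-score below which the top word is not considered a
#'   stable polarized signal.
#' @param out_dir Optional output directory.
#' @return Object of class `asps_report`: `ranking`, `top_word`,
#'   `stable` (logical), `curve`, `summit` (position/angle/value).
#' @export
run_asps_analysis <- function(genome, oriC = genome$oriC, k_range = 4:8,
                              grid = rotation_grid(), bin = 1000L,
                              z_min = 3, out_dir = NULL) {
  if (is.null(oriC)) stop("oriC is required for the ASPS analysis")
  ranking <- rank_asps(genome, oriC = oriC, k_range = k_range, grid = grid)
  if (nrow(ranking) == 0L) {
    report <- structure(list(ranking = ranking, top_word = NA_character_,
                             stable = FALSE, curve = NULL, summit = NULL),
                        class = "asps_report")
    return(report)
  }
  top <- ranking$word[1]
  stable <- is.finite(ranking$median_z[1]) && ranking$median_z[1] >= z_min
  curve <- cumulative_skew(genome, top, oriC = oriC, bin = bin)
  summit <- skew_summit(curve)
  report <- structure(
    list(ranking = ranking, top_word = top, stable = stable, curve = curve,
         summit = summit, genome_id = genome$id),
    class = "asps_report")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.table(ranking, file.path(out_dir, "asps_ranking.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_skew_curve(curve, file.path(out_dir,
                                      paste0("skew_", top, ".tsv")))
  }
  report
}

#' @export
print.asps_report <- function(x, ...) {
  cat("<asps_report>\n")
  if (is.na(x$top_word)) {
    cat("no rankable polarized word\n")
    return(invisible(x))
  }
  cat(sprintf("top word %s (median z %.1f, median skew %.3f)%s\n",
              x$top_word, x$ranking$median_z[1], x$ranking$median_skew[1],
              if (x$stable) "" else " - no stable ASPS signal"))
  cat(sprintf("skew summit at %d bp (%.1f deg from oriC)\n",
              as.integer(x$summit$position), x$summit$angle))
  invisible(x)
}
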