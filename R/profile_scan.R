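#' Build a positional log-odds profile from aligned sites
#'
#' Column probabilities are `(count + pseudocount * background) /
#' (n + pseudocount)` and the profile stores their log2 odds against the
#' background, so the score of a window is the sum of its per-column
#' log-odds (bits). An ungapped fixed-width profile of this form is the
#' match-state core of a profile HMM; insert/delete states are deliberately
#' not modelled since predicted sites align without gaps.
#'
#' @param aligned Character vector of >= 2 equal-length DNA strings
#'   (sites, optionally with flanks).
#' @param pseudocount Total pseudocount weight (> 0) distributed according
#'   to the background.
#' @param background Named base frequencies (`A`,`C`,`G`,`T`), all > 0;
#'   normalized to sum to 1.
#' @return Object of class `dif_profile`: list with `matrix` (4 x width
#'   log2-odds, rows `A,C,G,T`), `width`, `pseudocount`, `background`,
#'   `score_threshold` (`NA` until calibrated).
#' @export
build_profile <- function(aligned, pseudocount = 1,
                          background = c(A = 0.25, C = 0.25,
                                         G = 0.25, T = 0.25)) {
  if (length(aligned) < 2L) stop("profile requires at least two sequences")
  if (length(unique(nchar(aligned))) != 1L)
    stop("ragged alignment: sequences must have equal length")
  stopifnot(pseudocount > 0)
  background <- background[c("A", "C", "G", "T")]
  if (any(is.na(background)) || any(background <= 0))
    stop("background must give positive frequencies for A, C, G, T")
  background <- background / sum(background)
  n <- length(aligned)
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(toupper(aligned)))
  counts <- cm[c("A", "C", "G", "T"), , drop = FALSE]
  probs <- sweep(counts, 1, pseudocount * background, `+`) / (n + pseudocount)
  lo <- log2(sweep(probs, 1, background, `/`))
  structure(list(matrix = lo, width = ncol(lo), pseudocount = pseudocount,
                 background = background, score_threshold = NA_real_,
                 null_max_scores = NULL),
            class = "dif_profile")
}

#' @export
print.dif_profile <- function(x, ...) {
  cat(sprintf("<dif_profile> width %d, pseudocount %g, threshold %s bits\n",
              x$width, x$pseudocount,
              if (is.na(x$score_threshold)) "uncalibrated" else
                sprintf("%.2f", x$score_threshold)))
  invisible(x)
}

#' Score fixed sequences against a profile
#'
#' @param profile A [build_profile()] object.
#' @param seqs Character vector of sequences of the profile width.
#' @return Numeric scores in bits (`NA` for windows containing `N`).
#' @export
score_sequences <- function(profile, seqs) {
  stopifnot(all(nchar(seqs) == profile$width))
  vapply(toupper(seqs), function(s)
    as.numeric(cpp_pwm_scan(s, profile$matrix)), numeric(1), USE.NAMES = FALSE)
}

# log-odds matrix for scanning the minus strand: complement rows, reverse cols
reverse_profile_matrix <- function(mat) {
  mat[c(4, 3, 2, 1), rev(seq_len(ncol(mat))), drop = FALSE]
}

#' Scan a circular genome with a profile
#'
#' Both strands are scanned over the full circle (windows that wrap past the
#' coordinate origin are scored once); hits at or above the threshold are
#' returned sorted by descending score. If the profile has been calibrated
#' ([calibrate_threshold()]) each hit also carries the empirical p-value of
#' its score under the shuffled-genome null (fraction of null genome-wide
#' maximum scores at least as large).
#'
#' @param genome A `Genome`.
#' @param profile A [build_profile()] object.
#' @param threshold Score threshold in bits; defaults to the profile's
#'   calibrated `score_threshold`.
#' @return `data.frame`: `genome_id`, `start` (0-based, mod L), `end`,
#'   `strand`, `score`, `empirical_p`.
#' @export
scan_genome <- function(genome, profile, threshold = profile$score_threshold) {
  stopifnot(inherits(genome, "Genome"), inherits(profile, "dif_profile"))
  W <- profile$width
  if (W > genome$length) stop("profile wider than the genome")
  if (is.na(threshold))
    stop("no threshold: calibrate the profile or pass `threshold`")
  seq <- genome$sequence
  if (genome$circular && genome$length > W)
    seq <- paste0(seq, substr(seq, 1L, W - 1L))
  fwd <- cpp_pwm_scan(seq, profile$matrix)
  rev <- cpp_pwm_scan(seq, reverse_profile_matrix(profile$matrix))
  hit <- function(scores, strand) {
    keep <- which(!is.na(scores) & scores >= threshold)
    if (!length(keep)) return(NULL)
    data.frame(genome_id = genome$id, start = (keep - 1L) %% genome$length,
               end = ((keep - 1L) %% genome$length) + W,
               strand = strand, score = scores[keep],
               stringsAsFactors = FALSE)
  }
  out <- rbind(hit(fwd, "+"), hit(rev, "-"))
  if (is.null(out))
    return(data.frame(genome_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), empirical_p = numeric(0),
                      stringsAsFactors = FALSE))
  nm <- profile$null_max_scores
  out$empirical_p <- if (is.null(nm)) NA_real_ else
    vapply(out$score, function(s) mean(nm >= s), numeric(1))
  out <- out[order(-out$score, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Calibrate a profile score threshold on a shuffled-genome null
#'
#' The null model is the dinucleotide-preserving (Altschul-Erikson) shuffle
#' of the target genome, which keeps its base and dinucleotide composition
#' (in particular the AT richness that dominates archaeal intergenic DNA).
#' The threshold is the `(1 - alpha)` quantile of the genome-wide maximum
#' score (both strands) over `n_shuffles` shuffles; `alpha = 0` gives the
#' most stringent threshold, the largest null maximum. Deterministic given
#' `seed`.
#'
#' @param profile A [build_profile()] object.
#' @param genome A `Genome`.
#' @param n_shuffles Number of shuffles (>= 100).
#' @param alpha Target family-wise false-positive rate per genome.
#' @param seed Integer RNG seed.
#' @return The profile with `score_threshold` set (bits) and the null maxima
#'   stored in `null_max_scores`, so that [scan_genome()] can report
#'   empirical p-values.
#' @export
calibrate_threshold <- function(profile, genome, n_shuffles = 100L,
                                alpha = 0.05, seed = 1L) {
  stopifnot(inherits(profile, "dif_profile"), inherits(genome, "Genome"))
  if (n_shuffles < 100L) stop("n_shuffles must be >= 100")
  stopifnot(alpha >= 0, alpha < 1)
  rmat <- reverse_profile_matrix(profile$matrix)
  maxima <- withr::with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    s <- cpp_dinuc_shuffle(genome$sequence)
    max(cpp_pwm_scan(s, profile$matrix), cpp_pwm_scan(s, rmat), na.rm = TRUE)
  }, numeric(1)))
  threshold <- as.numeric(quantile(maxima, probs = 1 - alpha, type = 1))
  profile$score_threshold <- threshold
  profile$null_max_scores <- maxima
  profile
}

#' Write a profile as plain text
#'
#' Header lines carry the background, pseudocount and calibrated threshold;
#' the body is one row per position with the four log2-odds.
#'
#' @param profile A [build_profile()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# background: %s",
            paste(sprintf("%s=%.6g", names(profile$background),
                          profile$background), collapse = " ")),
    sprintf("# pseudocount: %.6g", profile$pseudocount),
    sprintf("# score_threshold: %.6g", profile$score_threshold),
    paste(c("pos", "A", "C", "G", "T"), collapse = "\t")), con)
  for (j in seq_len(profile$width)) {
    writeLines(paste(c(j, sprintf("%.8g", profile$matrix[, j])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a profile written by [write_profile()]
#'
#' @param path Path to a profile text file.
#' @return A `dif_profile` (without null score distribution).
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  bg_line <- sub("^# background: ", "", lines[1])
  kv <- strsplit(strsplit(bg_line, " ")[[1]], "=")
  background <- setNames(vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
                         vapply(kv, `[[`, character(1), 1))
  pseudocount <- as.numeric(sub("^# pseudocount: ", "", lines[2]))
  threshold <- as.numeric(sub("^# score_threshold: ", "", lines[3]))
  body <- read.delim(textConnection(lines[-(1:3)]), sep = "\t")
  mat <- t(as.matrix(body[, c("A", "C", "G", "T")]))
  dimnames(mat) <- list(c("A", "C", "G", "T"), NULL)
  structure(list(matrix = mat, width = ncol(mat), pseudocount = pseudocount,
                 background = background, score_threshold = threshold,
                 null_max_scores = NULL),
            class = "dif_profile")
}
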