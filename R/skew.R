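#' Rotating-terminus grid
#'
#' Artificial replication-terminus angles used to scan for strand-polarized
#' words: every `step` degrees from `start_angle` to `end_angle` away from
#' oriC (default 120 to 200 in 5-degree steps).
#'
#' @param start_angle,end_angle,step Degrees; `step` must divide
#'   `end_angle - start_angle`.
#' @return Object of class `rotation_grid` carrying the angle vector.
#' @export
rotation_grid <- function(start_angle = 120, end_angle = 200, step = 5) {
  stopifnot(start_angle < end_angle, step > 0,
            (end_angle - start_angle) %% step == 0)
  structure(list(start_angle = start_angle, end_angle = end_angle,
                 step = step,
                 angles = seq(start_angle, end_angle, by = step)),
            class = "rotation_grid")
}

#' Leading-strand view of a circular genome
#'
#' Rewrites the chromosome so both replichores read in the direction of
#' replication-fork travel: the segment oriC -> ter is kept on the given
#' strand and the segment ter -> oriC is reverse complemented. The output has
#' the genome's length and starts at oriC.
#'
#' @param genome A `Genome` (or bare sequence string).
#' @param oriC,ter Origin and terminus positions in bp, distinct.
#' @return Character scalar of length `L`.
#' @export
leading_strand_view <- function(genome, oriC, ter) {
  seq <- if (inherits(genome, "Genome")) genome$sequence else genome
  L <- nchar(seq)
  oriC <- oriC %% L; ter <- ter %% L
  if (oriC == ter) stop("oriC and ter must differ")
  l1 <- (ter - oriC) %% L
  seg1 <- circular_subseq(seq, oriC, oriC + l1)
  seg2 <- circular_subseq(seq, ter, ter + (L - l1))
  paste0(seg1, revcomp(seg2))
}

# self-overlap flag: word has a period < k (Gaussian z is optimistic there)
is_self_overlapping <- function(word) {
  k <- nchar(word)
  any(vapply(seq_len(k - 1), function(p)
    substr(word, 1L, k - p) == substr(word, p + 1L, k), logical(1)))
}

#' Word over-representation under the maximal-order Markov model
#'
#' Observed (overlapping) occurrences of a k-word are compared with the
#' expectation under the Markov model of maximal order `k - 2`, estimated
#' from the sequence itself: `E = N(w[1..k-1]) N(w[2..k]) / N(w[2..k-1])`,
#' with Gaussian variance `E (1 - N(w[1..k-1])/N(w[2..k-1])) (1 -
#' N(w[2..k])/N(w[2..k-1]))`. Words with a nontrivial period are flagged
#' `self_overlap` (the Gaussian approximation is weaker for them; no
#' compound-Poisson correction is applied).
#'
#' @param sequence DNA string (a single strand, e.g. a
#'   [leading_strand_view()]).
#' @param word DNA word, length 4..8, no `N`.
#' @return One-row `data.frame`: `word`, `k`, `fwd_count`, `rev_count`,
#'   `expected`, `zscore`, `strand_skew` (`(fwd-rev)/(fwd+rev)`),
#'   `self_overlap`.
#' @export
word_zscore <- function(sequence, word) {
  word <- toupper(word)
  k <- nchar(word)
  if (k < 4L || k > 8L) stop("word length must be 4..8")
  if (grepl("[^ACGT]", word)) stop("word must be over {A,C,G,T}")
  subject <- Biostrings::DNAString(toupper(sequence))
  cnt <- function(w) Biostrings::countPattern(w, subject)
  n <- cnt(word)
  n1 <- cnt(substr(word, 1L, k - 1L))
  n2 <- cnt(substr(word, 2L, k))
  n12 <- cnt(substr(word, 2L, k - 1L))
  if (n12 == 0L) stop("zero denominator: infix of word absent from sequence")
  expected <- n1 * n2 / n12
  v <- expected * (1 - n1 / n12) * (1 - n2 / n12)
  z <- if (v > 0) (n - expected) / sqrt(v) else NA_real_
  nrc <- cnt(revcomp(word))
  data.frame(word = word, k = k, fwd_count = n, rev_count = nrc,
             expected = expected, zscore = z,
             strand_skew = if (n + nrc > 0) (n - nrc) / (n + nrc) else 0,
             self_overlap = is_self_overlapping(word),
             stringsAsFactors = FALSE)
}

# z-scores and skews of all 4^k words of one length on one strand,
# vectorized through oligonucleotideFrequency
all_word_stats <- function(sequence, k) {
  subject <- Biostrings::DNAString(sequence)
  ck <- Biostrings::oligonucleotideFrequency(subject, width = k)
  c1 <- Biostrings::oligonucleotideFrequency(subject, width = k - 1L)
  c2 <- Biostrings::oligonucleotideFrequency(subject, width = k - 2L)
  words <- names(ck)
  n1 <- c1[substr(words, 1L, k - 1L)]
  n2 <- c1[substr(words, 2L, k)]
  n12 <- c2[substr(words, 2L, k - 1L)]
  expected <- ifelse(n12 > 0, n1 * n2 / n12, NA_real_)
  v <- expected * (1 - n1 / n12) * (1 - n2 / n12)
  z <- ifelse(!is.na(v) & v > 0, (ck - expected) / sqrt(v), NA_real_)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(words)))
  nrc <- ck[rc]
  tot <- ck + nrc
  data.frame(word = words, k = k, fwd_count = as.integer(ck),
             rev_count = as.integer(nrc), expected = as.numeric(expected),
             zscore = as.numeric(z),
             strand_skew = ifelse(tot > 0, (ck - nrc) / tot, 0),
             palindrome = words == rc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank strand-polarized over-represented words (KOPS/ASPS search)
#'
#' For every terminus angle on the rotation grid, the genome is rewritten as
#' its [leading_strand_view()] and every word of each length in `k_range` is
#' scored for over-representation ([word_zscore()] statistic) and strand
#' skew. A word is retained only if its skew keeps the same sign across all
#' rotations; a word and its reverse complement are reported once, in the
#' over-represented (positive-skew) orientation; palindromic words have zero
#' skew by construction and are excluded. The composite ranking score is
#' `median z across rotations x median skew`.
#'
#' @param genome A `Genome` with `oriC` set (or pass `oriC`).
#' @param oriC Origin position (bp); defaults to `genome$oriC`.
#' @param k_range Word lengths, within 4..8.
#' @param grid A [rotation_grid()].
#' @return `data.frame` ranked by descending composite `score`: `word`, `k`,
#'   `median_z`, `median_skew`, `fwd_count`, `rev_count` (at the central
#'   rotation), `self_overlap`, `score`. Attribute `"grid"` carries the grid.
#' @export
rank_asps <- function(genome, oriC = genome$oriC, k_range = 4:8,
                      grid = rotation_grid()) {
  stopifnot(inherits(genome, "Genome"))
  if (is.null(oriC)) stop("oriC is required for ASPS ranking")
  stopifnot(all(k_range >= 4), all(k_range <= 8))
  L <- genome$length
  per_rotation <- lapply(grid$angles, function(theta) {
    ter <- position_at_angle(oriC, theta, L)
    view <- leading_strand_view(genome, oriC, ter)
    do.call(rbind, lapply(sort(k_range), function(k) {
      s <- all_word_stats(view, k)
      s$angle <- theta
      s
    }))
  })
  all <- do.call(rbind, per_rotation)
  dt <- data.table::as.data.table(all)
  zscore <- strand_skew <- palindrome <- NULL  # data.table NSE columns
  agg <- dt[, list(
    k = k[1],
    median_z = stats::median(zscore),
    median_skew = stats::median(strand_skew),
    consistent = all(strand_skew > 0) || all(strand_skew < 0),
    palindrome = palindrome[1]
  ), by = "word"]
  mid <- grid$angles[ceiling(length(grid$angles) / 2)]
  mid_stats <- all[all$angle == mid, ]
  agg <- as.data.frame(agg)
  agg$fwd_count <- mid_stats$fwd_count[match(agg$word, mid_stats$word)]
  agg$rev_count <- mid_stats$rev_count[match(agg$word, mid_stats$word)]
  agg <- agg[!agg$palindrome & agg$consistent & !is.na(agg$median_z), ]
  # keep the over-represented orientation of each word/revcomp pair
  agg <- agg[agg$median_skew > 0, ]
  agg$self_overlap <- vapply(agg$word, is_self_overlapping, logical(1))
  agg$score <- agg$median_z * agg$median_skew
  agg <- agg[order(-agg$score, agg$word),
             c("word", "k", "median_z", "median_skew", "fwd_count",
               "rev_count", "self_overlap", "score")]
  rownames(agg) <- NULL
  attr(agg, "grid") <- grid
  agg
}

#' Cumulative strand-skew curve of a word
#'
#' Walks the circle once starting at oriC and accumulates +1 for each
#' occurrence of `word` on the forward strand and -1 for each occurrence of
#' its reverse complement, reporting the running sum on a `bin`-bp grid. The
#' summit of the curve marks the point where the word's polarity inverts
#' (the replication terminus for KOPS/ASPS-like words).
#'
#' @param genome A `Genome` (or sequence string plus `oriC`).
#' @param word DNA word without `N`.
#' @param oriC Start position of the walk (bp); defaults to `genome$oriC`.
#' @param bin Bin width in bp (default 1000).
#' @return Object of class `skew_curve`: list with `word`, `positions`
#'   (distance from oriC, bp; first element 0), `values` (cumulative skew;
#'   first element 0, last equals total forward minus reverse counts),
#'   `bin`, `L`, `oriC`.
#' @export
cumulative_skew <- function(genome, word, oriC = genome$oriC, bin = 1000L) {
  word <- toupper(word)
  if (grepl("[^ACGT]", word)) stop("word must be over {A,C,G,T}")
  stopifnot(bin >= 1)
  seq <- if (inherits(genome, "Genome")) genome$sequence else genome
  L <- nchar(seq)
  if (is.null(oriC)) stop("oriC is required")
  oriC <- oriC %% L
  rot <- circular_subseq(seq, oriC, oriC + L)
  subject <- Biostrings::DNAString(rot)
  fwd <- Biostrings::start(Biostrings::matchPattern(word, subject))
  rev <- Biostrings::start(Biostrings::matchPattern(revcomp(word), subject))
  breaks <- unique(c(seq(0L, L, by = as.integer(bin)), L))
  fcount <- if (length(fwd)) tabulate(findInterval(fwd - 1L, breaks,
                                                   left.open = FALSE),
                                      nbins = length(breaks) - 1L) else
    integer(length(breaks) - 1L)
  rcount <- if (length(rev)) tabulate(findInterval(rev - 1L, breaks,
                                                   left.open = FALSE),
                                      nbins = length(breaks) - 1L) else
    integer(length(breaks) - 1L)
  values <- c(0, cumsum(fcount - rcount))
  structure(list(word = word, positions = breaks, values = values,
                 bin = as.integer(bin), L = L, oriC = oriC),
            class = "skew_curve")
}

#' Summit of a cumulative skew curve
#'
#' Position of the global maximum of the curve; on a tie the midpoint of the
#' longest maximal plateau (first such plateau if several tie). The angle is
#' the origin-relative angle of the summit position.
#'
#' @param curve A [cumulative_skew()] object.
#' @param L,oriC Overrides for the curve's stored genome length and origin.
#' @return List with `position` (absolute bp), `angle` (degrees in
#'   `(-180, 180]`), `value` (curve maximum).
#' @export
skew_summit <- function(curve, L = curve$L, oriC = curve$oriC) {
  v <- curve$values
  vmax <- max(v)
  at <- which(v == vmax)
  runs <- split(at, cumsum(c(1, diff(at) != 1)))
  lens <- vapply(runs, length, integer(1))
  run <- runs[[which.max(lens)]]
  pos_rel <- (curve$positions[run[1]] + curve$positions[run[length(run)]]) / 2
  position <- (oriC + pos_rel) %% L
  list(position = position,
       angle = angle_from_origin(position, oriC, L),
       value = vmax)
}

#' Write a skew curve as TSV
#'
#' @param curve A [cumulative_skew()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_skew_curve <- function(curve, path) {
  write.table(data.frame(bin_start = curve$positions,
                         cumulative = curve$values),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.skew_curve <- function(x, ...) {
  s <- skew_summit(x)
  cat(sprintf(
    "<skew_curve> word %s, %d bins of %d bp; summit at %d bp (%.1f deg)\n",
    x$word, length(x$values) - 1L, x$bin, as.integer(s$position), s$angle))
  invisible(x)
}
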