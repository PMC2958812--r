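#' Reverse complement
#'
#' Vectorized over the `{A,C,G,T,N}` alphabet (case-insensitive input,
#' uppercase output); any other character is an error.
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  up <- toupper(seq)
  bad <- !grepl("^[ACGTN]*$", up)
  if (any(bad))
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(head(seq[bad], 3), collapse = ", "))
  out <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(up)))
  names(out) <- names(seq)
  out
}

#' Search parameters for imperfect inverted-repeat enumeration
#'
#' Defaults follow the canonical dif-site geometry scan: arms of 11--15 bp
#' around spacers of 4--10 bp. `max_arm_mismatches` is the tolerated Hamming
#' distance between arm 1 and the reverse complement of arm 2; the default of
#' 5 (about 55% arm identity at 11 bp) is deliberately permissive so that
#' diverged copies of a real site survive enumeration and are filtered by
#' cross-genome conservation instead.
#'
#' @param arm_min,arm_max Arm length bounds (bp).
#' @param spacer_min,spacer_max Spacer length bounds (bp).
#' @param max_arm_mismatches Maximum mismatches per arm pair; must be smaller
#'   than `arm_min`.
#' @return An object of class `ir_search_params`.
#' @export
search_params <- function(arm_min = 11L, arm_max = 15L,
                          spacer_min = 4L, spacer_max = 10L,
                          max_arm_mismatches = 5L) {
  p <- list(arm_min = as.integer(arm_min), arm_max = as.integer(arm_max),
            spacer_min = as.integer(spacer_min),
            spacer_max = as.integer(spacer_max),
            max_arm_mismatches = as.integer(max_arm_mismatches))
  stopifnot(p$arm_min <= p$arm_max, p$spacer_min <= p$spacer_max,
            p$arm_min > 0, p$spacer_min >= 0,
            p$max_arm_mismatches >= 0, p$max_arm_mismatches < p$arm_min)
  structure(p, class = "ir_search_params")
}

#' Mismatches between the two arms of an inverted repeat
#'
#' The imperfection of an inverted repeat is the positional Hamming distance
#' between `arm1` and the reverse complement of `arm2`. Vectorized over pairs.
#'
#' @param arm1,arm2 Equal-length DNA strings (no `N`).
#' @return Integer vector of mismatch counts in `[0, arm_len]`.
#' @export
arm_mismatches <- function(arm1, arm2) {
  stopifnot(is.character(arm1), is.character(arm2))
  if (length(arm1) != length(arm2))
    stop("arm1 and arm2 must have the same length")
  if (any(nchar(arm1) != nchar(arm2)))
    stop("arms in a pair must have equal length")
  if (any(grepl("N", toupper(c(arm1, arm2)), fixed = TRUE)))
    stop("arms must not contain N")
  as.integer(cpp_hamming(toupper(arm1), revcomp(arm2)))
}

#' Enumerate imperfect inverted-repeat candidates
#'
#' Reports every `(start, arm_len, spacer_len)` combination within the search
#' bounds whose arms differ from each other's reverse complement by at most
#' `max_arm_mismatches`. Overlapping candidates are all reported; use
#' [best_site()] for a per-locus reduction. Windows containing `N` are
#' skipped.
#'
#' @param region One row of [intergenic_regions()] output, a `data.frame` of
#'   such rows, or a bare DNA string.
#' @param params An [search_params()] object.
#' @return `data.frame` sorted by `(start, arm_len, spacer_len)` with columns
#'   `genome_id`, `start` (0-based, in genome coordinates when a region is
#'   given), `arm_len`, `spacer_len`, `arm1`, `spacer`, `arm2`, `mismatches`,
#'   `seq`, `canonical_seq` (lexicographic minimum of `seq` and its reverse
#'   complement, so the two orientations of a quasi-palindrome compare equal).
#' @export
enumerate_ir_candidates <- function(region, params = search_params()) {
  stopifnot(inherits(params, "ir_search_params"))
  if (is.character(region)) {
    region <- data.frame(genome_id = "seq", start = 0L,
                         sequence = region, stringsAsFactors = FALSE)
  }
  out <- lapply(seq_len(nrow(region)), function(i) {
    seq <- toupper(region$sequence[i])
    d <- cpp_enumerate_ir_full(seq, params$arm_min, params$arm_max,
                               params$spacer_min, params$spacer_max,
                               params$max_arm_mismatches)
    if (nrow(d) == 0L) return(NULL)
    d$genome_id <- region$genome_id[i]
    d$start <- d$start + region$start[i]
    d
  })
  out <- if (all(vapply(out, is.null, logical(1)))) NULL else
    as.data.frame(data.table::rbindlist(out))
  if (!is.null(out)) {
    out$arm1 <- substring(out$seq, 1L, out$arm_len)
    out$spacer <- substring(out$seq, out$arm_len + 1L,
                            out$arm_len + out$spacer_len)
    out$arm2 <- substring(out$seq, out$arm_len + out$spacer_len + 1L,
                          2L * out$arm_len + out$spacer_len)
  }
  if (is.null(out)) {
    out <- data.frame(start = integer(0), arm_len = integer(0),
                      spacer_len = integer(0), mismatches = integer(0),
                      arm1 = character(0), spacer = character(0),
                      arm2 = character(0), seq = character(0),
                      canonical_seq = character(0), genome_id = character(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$start, out$arm_len, out$spacer_len), , drop = FALSE]
  rownames(out) <- NULL
  cols <- c("genome_id", "start", "arm_len", "spacer_len", "arm1", "spacer",
            "arm2", "mismatches", "seq", "canonical_seq")
  out[, cols, drop = FALSE]
}

#' Reduce a candidate list to its single best site
#'
#' Orders candidates by ascending arm mismatch fraction
#' (`mismatches / arm_len`), then by larger arm length, then by larger
#' spacer (at equal arm quality the candidate covering more sequence is the
#' maximal representative of the locus; shorter-spacer versions of the same
#' locus are truncation artifacts), then by smaller start, and returns the
#' first candidate. Deterministic under input permutation.
#'
#' @param candidates Non-empty output of [enumerate_ir_candidates()].
#' @return Single-row `data.frame`.
#' @export
best_site <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L)
    stop("best_site() requires a non-empty candidate list")
  o <- order(candidates$mismatches / candidates$arm_len,
             -candidates$arm_len, -candidates$spacer_len, candidates$start)
  candidates[o[1], , drop = FALSE]
}
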