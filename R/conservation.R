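#' Orientation-maximized ungapped site similarity
#'
#' Fraction of identical positions between two equal-length sites, taking
#' the better of the two orientations of `b` (a quasi-palindromic site and
#' its reverse complement count as the same site). Symmetric in its
#' arguments; vectorized over pairs.
#'
#' @param a,b Equal-length DNA strings (vectors of equal length, or one
#'   scalar recycled).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
site_similarity <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (length(a) == 1L) a <- rep(a, length(b))
  if (length(b) == 1L) b <- rep(b, length(a))
  if (length(a) != length(b)) stop("a and b must pair up")
  if (any(nchar(a) != nchar(b)))
    stop("site_similarity() requires equal-length sequences")
  h <- pmin(cpp_hamming(a, b), cpp_hamming(a, revcomp(b)))
  1 - h / nchar(a)
}

#' Cross-genome conserved candidate groups
#'
#' Matches inverted-repeat candidates across genomes and emits groups that
#' contain exactly one candidate per genome with all pairwise similarities at
#' or above `threshold`. Only candidates with identical geometry
#' (`arm_len`, `spacer_len`) are compared, similarity is orientation-maximized
#' ungapped identity over the full site ([site_similarity()]), and each
#' candidate joins at most one group (greedy by descending minimum pairwise
#' similarity, with deterministic tie-breaking), so the result is invariant
#' under permutation of genome and candidate order.
#'
#' Candidate pairs are found with an exact-seed block filter: at most
#' `floor(w (1-threshold))` mismatches are allowed over a site of width `w`,
#' so two matching sites must share at least one of `floor(w(1-threshold))+1`
#' consecutive blocks exactly (pigeonhole); only block-sharing pairs are
#' scored.
#'
#' @param candidates_by_genome Named list (one element per genome) of
#'   [enumerate_ir_candidates()] outputs.
#' @param threshold Minimum pairwise similarity (default 0.80).
#' @return Object of class `conserved_groups`: list with `members` (long
#'   `data.frame`: `group_id`, `genome_id`, candidate columns), `summary`
#'   (`group_id`, `arm_len`, `spacer_len`, `min_similarity`), and
#'   `threshold`. Zero groups gives empty frames.
#' @export
conserved_groups <- function(candidates_by_genome, threshold = 0.80) {
  stopifnot(is.list(candidates_by_genome))
  if (is.null(names(candidates_by_genome)) ||
      any(!nzchar(names(candidates_by_genome))))
    stop("candidates_by_genome must be a named list (one entry per genome)")
  if (length(candidates_by_genome) < 2L)
    stop("need candidates from at least two genomes")
  gids <- sort(names(candidates_by_genome))
  ng <- length(gids)
  tabs <- lapply(gids, function(g) {
    d <- candidates_by_genome[[g]]
    d <- d[order(d$start, d$arm_len, d$spacer_len), , drop = FALSE]
    d$.idx <- seq_len(nrow(d))
    d
  })
  names(tabs) <- gids

  empty <- structure(list(
    members = cbind(data.frame(group_id = integer(0), genome_id = character(0)),
                    tabs[[1]][0, setdiff(names(tabs[[1]]), c("genome_id", ".idx")),
                              drop = FALSE]),
    summary = data.frame(group_id = integer(0), arm_len = integer(0),
                         spacer_len = integer(0), min_similarity = numeric(0)),
    threshold = threshold), class = "conserved_groups")

  geoms <- Reduce(intersect, lapply(tabs, function(d)
    unique(paste(d$arm_len, d$spacer_len))))
  if (!length(geoms)) return(empty)

  # per-genome geometry splits and precomputed reverse complements
  geom_idx <- lapply(tabs, function(d)
    split(seq_len(nrow(d)), paste(d$arm_len, d$spacer_len)))
  rcs <- lapply(tabs, function(d) as.character(cpp_revcomp(d$canonical_seq)))

  # seed-block hash join per geometry class (cpp_match_pairs), then exact
  # orientation-minimized mismatch counting
  pair_sim <- function(gi, gj) {
    res <- lapply(geoms, function(gm) {
      ia <- geom_idx[[gi]][[gm]]
      jb <- geom_idx[[gj]][[gm]]
      if (is.null(ia) || is.null(jb)) return(NULL)
      w <- nchar(tabs[[gi]]$canonical_seq[ia[1]])
      mm_max <- floor(w * (1 - threshold))
      m <- cpp_match_pairs(tabs[[gi]]$canonical_seq[ia],
                           tabs[[gj]]$canonical_seq[jb],
                           rcs[[gj]][jb], mm_max + 1L, mm_max)
      if (!nrow(m)) return(NULL)
      data.frame(i = ia[m$i], j = jb[m$j], sim = 1 - m$mismatches / w)
    })
    res <- do.call(rbind, res)
    if (is.null(res) || !nrow(res)) return(NULL)
    res[order(res$i, res$j), , drop = FALSE]
  }

  pairs <- list()
  for (ii in 1:(ng - 1)) for (jj in (ii + 1):ng) {
    p <- pair_sim(gids[ii], gids[jj])
    if (is.null(p)) return(empty)  # some genome pair shares nothing
    pairs[[paste(ii, jj)]] <- p
  }

  # candidates of the first genome anchor the tuples
  anchor_nb <- lapply(2:ng, function(jj) {
    p <- pairs[[paste(1, jj)]]
    split(p$j, p$i)
  })
  anchors <- Reduce(intersect, lapply(anchor_nb, function(x)
    as.integer(names(x))))
  if (!length(anchors)) return(empty)

  sim_lookup <- function(ii, jj, i, j) {
    p <- pairs[[paste(ii, jj)]]
    s <- p$sim[p$i == i & p$j == j]
    if (length(s)) s[1] else NA_real_
  }

  tuples <- list()
  for (a in sort(anchors)) {
    nb <- lapply(anchor_nb, function(x) sort(x[[as.character(a)]]))
    sizes <- vapply(nb, length, integer(1))
    if (prod(sizes) > 10000) {
      # degenerate (low-complexity) anchor: keep the best-matching partners
      nb <- lapply(seq_along(nb), function(k) {
        p <- pairs[[paste(1, k + 1)]]
        s <- p$sim[p$i == a][match(nb[[k]], p$j[p$i == a])]
        head(nb[[k]][order(-s, nb[[k]])], 20)
      })
    }
    grid <- do.call(expand.grid, nb)
    for (r in seq_len(nrow(grid))) {
      members <- c(a, as.integer(grid[r, ]))
      sims <- c()
      ok <- TRUE
      for (ii in 1:(ng - 1)) {
        for (jj in (ii + 1):ng) {
          s <- sim_lookup(ii, jj, members[ii], members[jj])
          if (is.na(s) && ii > 1) {
            # pair not pre-screened from the anchor: score it directly
            s <- site_similarity(tabs[[gids[ii]]]$canonical_seq[members[ii]],
                                 tabs[[gids[jj]]]$canonical_seq[members[jj]])
          }
          if (is.na(s) || s < threshold) { ok <- FALSE; break }
          sims <- c(sims, s)
        }
        if (!ok) break
      }
      if (ok) {
        key <- paste(vapply(seq_len(ng), function(k)
          tabs[[gids[k]]]$canonical_seq[members[k]], character(1)),
          collapse = "|")
        tuples[[length(tuples) + 1L]] <- list(
          members = members, min_sim = min(sims), key = key,
          start1 = tabs[[gids[1]]]$start[a])
      }
    }
  }
  if (!length(tuples)) return(empty)

  o <- order(-vapply(tuples, `[[`, numeric(1), "min_sim"),
             vapply(tuples, `[[`, character(1), "key"),
             vapply(tuples, `[[`, numeric(1), "start1"))
  tuples <- tuples[o]
  used <- lapply(seq_len(ng), function(k) integer(0))
  groups <- list()
  for (tp in tuples) {
    if (any(vapply(seq_len(ng), function(k)
      tp$members[k] %in% used[[k]], logical(1)))) next
    for (k in seq_len(ng)) used[[k]] <- c(used[[k]], tp$members[k])
    groups[[length(groups) + 1L]] <- tp
  }

  members <- do.call(rbind, lapply(seq_along(groups), function(gi) {
    tp <- groups[[gi]]
    do.call(rbind, lapply(seq_len(ng), function(k) {
      row <- tabs[[gids[k]]][tp$members[k], , drop = FALSE]
      row$.idx <- NULL
      row$genome_id <- gids[k]
      cbind(data.frame(group_id = gi), row)
    }))
  }))
  rownames(members) <- NULL
  summary <- data.frame(
    group_id = seq_along(groups),
    arm_len = members$arm_len[match(seq_along(groups), members$group_id)],
    spacer_len = members$spacer_len[match(seq_along(groups),
                                          members$group_id)],
    min_similarity = vapply(groups, `[[`, numeric(1), "min_sim"))
  structure(list(members = members, summary = summary, threshold = threshold),
            class = "conserved_groups")
}

#' @export
print.conserved_groups <- function(x, ...) {
  cat(sprintf("<conserved_groups> %d group(s) at threshold %.2f\n",
              nrow(x$summary), x$threshold))
  if (nrow(x$summary)) print(head(x$summary, 10))
  invisible(x)
}

#' IUPAC consensus and per-column information content
#'
#' Builds the per-column base counts of an ungapped alignment, the minimal
#' IUPAC degeneracy code covering the bases observed in each column, and the
#' column information content `2 - H` (bits, Shannon entropy `H` of the
#' observed base frequencies against a uniform background).
#'
#' @param aligned Character vector of >= 2 equal-length DNA strings.
#' @return Object of class `dif_consensus`: list with `counts` (4 x width
#'   matrix), `iupac` (string), `info_content` (bits per column).
#' @export
consensus_iupac <- function(aligned) {
  if (length(aligned) < 2L)
    stop("consensus requires at least two sequences")
  if (length(unique(nchar(aligned))) != 1L)
    stop("ragged alignment: sequences must have equal length")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(toupper(aligned)))
  counts <- cm[c("A", "C", "G", "T"), , drop = FALSE]
  iupac <- vapply(seq_len(ncol(counts)), function(j) {
    present <- rownames(counts)[counts[, j] > 0]
    if (!length(present)) return("N")
    unname(IUPAC_FROM_BASES[paste(sort(present), collapse = "")])
  }, character(1))
  info <- vapply(seq_len(ncol(counts)), function(j) {
    p <- counts[, j] / sum(counts[, j])
    p <- p[p > 0]
    2 + sum(p * log2(p))
  }, numeric(1))
  structure(list(counts = counts, iupac = paste(iupac, collapse = ""),
                 info_content = info),
            class = "dif_consensus")
}

#' @export
print.dif_consensus <- function(x, ...) {
  cat("<dif_consensus>", x$iupac, "\n")
  cat(sprintf("  mean information %.2f bits/column over %d columns\n",
              mean(x$info_content), ncol(x$counts)))
  invisible(x)
}

#' Write a consensus report
#'
#' Plain-text output: the IUPAC string, then a per-column TSV of base counts
#' and information content suitable for logo plotting.
#'
#' @param consensus A [consensus_iupac()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(consensus, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# consensus: ", consensus$iupac),
               paste(c("column", "A", "C", "G", "T", "info_bits"),
                     collapse = "\t")), con)
  for (j in seq_len(ncol(consensus$counts))) {
    writeLines(paste(c(j, consensus$counts[, j],
                       sprintf("%.4f", consensus$info_content[j])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' AT fraction of the flanks of an interval
#'
#' Descriptive statistic for the AT-richness of the sequence surrounding a
#' site on a circular genome (conserved dif flanks are characteristically
#' AT rich); not used as a filter.
#'
#' @param genome A `Genome`.
#' @param start,end Site interval, 0-based half-open.
#' @param flank Flank width on each side (bp).
#' @return Fraction of A/T in the two flanks combined.
#' @export
flank_at_fraction <- function(genome, start, end, flank = 25L) {
  L <- genome$length
  left <- circular_subseq(genome, (start - flank) %% L,
                          (start - flank) %% L + flank)
  right <- circular_subseq(genome, end %% L, end %% L + flank)
  s <- strsplit(paste0(left, right), "")[[1]]
  mean(s %in% c("A", "T"))
}
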