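# Independent oracles used across tests; deliberately naive implementations
# that share no code with the package internals.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "")[[1]]),
        collapse = "")
}

# brute-force triple-loop inverted-repeat enumeration
oracle_enumerate <- function(seq, arm_min = 11, arm_max = 15,
                             spacer_min = 4, spacer_max = 10, max_mm = 3) {
  seq <- toupper(seq)
  n <- nchar(seq)
  rows <- list()
  for (st in 0:(n - 1)) {
    for (a in arm_min:arm_max) {
      for (sp in spacer_min:spacer_max) {
        tot <- 2 * a + sp
        if (st + tot > n) next
        win <- substr(seq, st + 1, st + tot)
        if (grepl("N", win, fixed = TRUE)) next
        arm1 <- strsplit(substr(win, 1, a), "")[[1]]
        arm2rc <- strsplit(oracle_revcomp(substr(win, a + sp + 1, tot)),
                           "")[[1]]
        mm <- sum(arm1 != arm2rc)
        if (mm <= max_mm)
          rows[[length(rows) + 1]] <- data.frame(
            start = st, arm_len = a, spacer_len = sp, mismatches = mm)
      }
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), arm_len = integer(0),
                      spacer_len = integer(0), mismatches = integer(0)))
  d <- do.call(rbind, rows)
  d <- d[order(d$start, d$arm_len, d$spacer_len), ]
  rownames(d) <- NULL
  d
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# minimal candidate table (as produced by enumerate_ir_candidates) for
# conservation tests built from bare sequences
make_candidates <- function(seqs, arm_len = 11L, spacer_len = 6L,
                            starts = NULL) {
  seqs <- toupper(seqs)
  rc <- vapply(seqs, oracle_revcomp, character(1), USE.NAMES = FALSE)
  data.frame(
    genome_id = "g", start = starts %||% seq(0L, by = 100L,
                                             length.out = length(seqs)),
    arm_len = arm_len, spacer_len = spacer_len,
    arm1 = substr(seqs, 1, arm_len),
    spacer = substr(seqs, arm_len + 1, arm_len + spacer_len),
    arm2 = substr(seqs, arm_len + spacer_len + 1, 2 * arm_len + spacer_len),
    mismatches = 0L, seq = seqs,
    canonical_seq = ifelse(seqs <= rc, seqs, rc),
    stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

PAB_OLIGO <- "gttaactatATTGGATATAATCGGCCTTATATCTAAAgtgttg"
PAB_SITE <- "ATTGGATATAATCGGCCTTATATCTAAA"
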