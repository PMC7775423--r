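# Independent brute-force oracles used by the property and acceptance tests.
# These re-derive results from first principles (explicit residue-index sets,
# exhaustive enumeration) and never call the code paths they check.

# Classify a peptide span against a TMD span from explicit residue sets.
oracle_classify <- function(p_start, p_end, t_start, t_end,
                            min_overlap = 2L) {
  p <- seq.int(p_start, p_end)
  t <- seq.int(t_start, t_end)
  i <- intersect(p, t)
  if (all(t %in% p)) {
    return("CONTAINS")
  }
  if (all(p %in% t)) {
    return("WITHIN")
  }
  if (length(i) >= min_overlap) {
    covers_start <- min(t) %in% p
    covers_end <- max(t) %in% p
    if (covers_start && !covers_end) {
      return("N_PARTIAL")
    }
    if (covers_end && !covers_start) {
      return("C_PARTIAL")
    }
  }
  NA_character_
}

# Enumerate all fragments bounded by cleavage sites with <= max_missed
# internal sites, for a plain site-set rule (no exceptions).
oracle_digest <- function(sequence, cleave_after, max_missed = 0L) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(res)
  sites <- which(res[-n] %in% cleave_after)
  boundaries <- c(0L, sites, n)
  k <- length(boundaries)
  out <- list()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      internal <- j - i - 1L
      if (internal > max_missed) break
      out[[length(out) + 1L]] <- c(
        start = boundaries[i] + 1L,
        end = boundaries[j],
        missed = internal
      )
    }
  }
  df <- as.data.frame(do.call(rbind, out))
  df$sequence <- substring(sequence, df$start, df$end)
  df[order(df$start, df$end), c("start", "end", "sequence", "missed")]
}

# Random amino-acid sequence over the 20 canonical residues.
random_protein <- function(len, alphabet = c(
                             "A", "R", "N", "D", "C", "Q", "E", "G", "H",
                             "I", "L", "K", "M", "F", "P", "S", "T", "W",
                             "Y", "V"
                           )) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Tiny fixed proteome used across the io/mapping unit tests.
toy_proteome <- function() {
  tibble::tibble(
    accession = c("P1", "P2", "P3"),
    description = c("single TMD", "two TMDs", "soluble"),
    sequence = c(
      #        TMD at 11..30
      paste0("MKTSDDEGSR", "ILVFAVLWFLVCALFVYLAV", "DDKEGSRQNT"),
      #        TMDs at 6..25 and 36..55
      paste0("SSKDE", "LIVAFLCVMLWVAHIVFALG", "DDRGGSNQTE",
             "FWLVAILVYAVLFIMLAFIV", "KRDDS"),
      "MKTAYDDEGSRILKAAAGGRDDEEGGSSTTKNQR"
    )
  )
}

toy_tmds <- function() {
  tibble::tibble(
    accession = c("P1", "P2", "P2"),
    start = c(11L, 6L, 36L),
    end = c(30L, 25L, 55L),
    ordinal = c(1L, 1L, 2L)
  )
}
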