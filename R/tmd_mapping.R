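#' Locate all occurrences of a peptide in a protein sequence
#'
#' Returns every (including overlapping) 1-based start position of the
#' peptide within the protein. With `il_equivalent = TRUE`, isoleucine and
#' leucine are interchangeable on both sides (isobaric residues that MS
#' cannot distinguish).
#'
#' @param peptide Peptide sequence (single string).
#' @param sequence Protein sequence (single string).
#' @param il_equivalent Treat I and L as identical (default `FALSE`).
#' @return Integer vector of start positions, ascending; empty if absent.
#' @export
#' @examples
#' locate_peptide("AA", "AAAA")  # 1 2 3
locate_peptide <- function(peptide, sequence, il_equivalent = FALSE) {
  stopifnot(
    is.character(peptide), length(peptide) == 1L, nchar(peptide) > 0L,
    is.character(sequence), length(sequence) == 1L
  )
  if (il_equivalent) {
    peptide <- chartr("L", "I", peptide)
    sequence <- chartr("L", "I", sequence)
  }
  # lookahead finds overlapping occurrences
  pat <- paste0("(?=", gsub("([\\W])", "\\\\\\1", peptide, perl = TRUE), ")")
  m <- gregexpr(pat, sequence, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(integer())
  }
  as.integer(m)
}

# Encode every k-mer of a string as an exact base-47 number (alphabet
# ASCII 45 '-' .. 90 'Z'; 47^7 < 2^53 so doubles are exact for k <= 7).
kmer_codes <- function(x, k) {
  v <- utf8ToInt(x) - 44
  n <- length(v)
  if (n < k) {
    return(numeric())
  }
  code <- numeric(n - k + 1L)
  for (j in seq_len(k)) {
    code <- code + v[j:(n - k + j)] * 47^(k - j)
  }
  code
}

# Locate many peptides against a whole proteome in one pass. Proteins are
# concatenated with a '-' separator (outside the residue alphabet) and the
# positions of every k-mer head are indexed numerically; each peptide's
# candidates are then verified by direct substring comparison. Finds all
# occurrences, including overlapping ones.
locate_peptides_proteome <- function(peptides, proteome,
                                     il_equivalent = FALSE) {
  uniq <- unique(peptides)
  empty <- tibble::tibble(
    peptide = character(), accession = character(),
    start = integer(), end = integer()
  )
  if (length(uniq) == 0L || nrow(proteome) == 0L) {
    return(empty)
  }
  seqs <- proteome$sequence
  pats <- uniq
  if (il_equivalent) {
    seqs <- chartr("L", "I", seqs)
    pats <- chartr("L", "I", uniq)
  }
  big <- paste(seqs, collapse = "-")
  offsets <- c(0L, cumsum(nchar(seqs) + 1L))
  k <- min(6L, min(nchar(pats)))
  if (nchar(big) < k) {
    return(empty)
  }
  code <- kmer_codes(big, k)
  ord <- order(code, method = "radix")
  sc <- code[ord]
  m <- length(sc)
  u_start <- which(c(TRUE, sc[-1L] != sc[-m]))
  u_end <- c(u_start[-1L] - 1L, m)
  u_codes <- sc[u_start]
  q <- vapply(pats, function(p) kmer_codes(substr(p, 1L, k), k),
              numeric(1), USE.NAMES = FALSE)
  j <- match(q, u_codes)
  found <- !is.na(j)
  counts <- integer(length(pats))
  counts[found] <- u_end[j[found]] - u_start[j[found]] + 1L
  if (sum(counts) == 0L) {
    return(empty)
  }
  pid <- rep.int(seq_along(pats), counts)
  cand <- ord[sequence(counts[found], from = u_start[j[found]])]
  len <- nchar(pats)[pid]
  ok <- substring(big, cand, cand + len - 1L) == pats[pid]
  pid <- pid[ok]
  cand <- cand[ok]
  if (length(cand) == 0L) {
    return(empty)
  }
  prot <- findInterval(cand - 1L, offsets)
  out <- tibble::tibble(
    peptide = uniq[pid],
    accession = proteome$accession[prot],
    start = cand - offsets[prot],
    end = cand - offsets[prot] + nchar(uniq[pid]) - 1L
  )
  dplyr::arrange(out, .data$peptide, .data$accession, .data$start)
}

#' Classify a peptide span against a TMD span
#'
#' The two mapping rules: (1) a peptide that encompasses the complete
#' predicted TMD (`CONTAINS`) or lies entirely within it (`WITHIN`) is a hit;
#' (2) a peptide crossing exactly one TMD boundary is a hit when the overlap
#' is at least `min_partial_overlap` residues (`N_PARTIAL` crosses the TMD
#' start, `C_PARTIAL` crosses the TMD end). Identical spans resolve to
#' `CONTAINS`. Anything else (no overlap, or a boundary crossing below the
#' minimum) is no hit (`NA`).
#'
#' All arguments are vectorized and recycled.
#'
#' @param p_start,p_end Peptide span (1-based inclusive).
#' @param t_start,t_end TMD span (1-based inclusive).
#' @param min_partial_overlap Minimum residues of overlap for a
#'   boundary-crossing peptide (default 2).
#' @return Character vector: `"CONTAINS"`, `"WITHIN"`, `"N_PARTIAL"`,
#'   `"C_PARTIAL"`, or `NA` for no hit.
#' @export
#' @examples
#' classify_tmd_hit(8, 35, 10, 30)   # CONTAINS
#' classify_tmd_hit(5, 10, 10, 30)   # NA: single-residue boundary overlap
classify_tmd_hit <- function(p_start, p_end, t_start, t_end,
                             min_partial_overlap = 2L) {
  n <- max(length(p_start), length(p_end), length(t_start), length(t_end))
  p_start <- rep_len(as.integer(p_start), n)
  p_end <- rep_len(as.integer(p_end), n)
  t_start <- rep_len(as.integer(t_start), n)
  t_end <- rep_len(as.integer(t_end), n)
  if (any(p_start > p_end) || any(t_start > t_end)) {
    stop("classify_tmd_hit: invalid span (start > end)", call. = FALSE)
  }
  overlap <- pmin(p_end, t_end) - pmax(p_start, t_start) + 1L
  contains <- p_start <= t_start & p_end >= t_end
  within <- p_start >= t_start & p_end <= t_end & !contains
  crosses_start <- p_start < t_start & p_end >= t_start & p_end < t_end
  crosses_end <- p_start > t_start & p_start <= t_end & p_end > t_end
  out <- rep(NA_character_, n)
  out[contains] <- "CONTAINS"
  out[within] <- "WITHIN"
  out[crosses_start & overlap >= min_partial_overlap] <- "N_PARTIAL"
  out[crosses_end & overlap >= min_partial_overlap] <- "C_PARTIAL"
  out
}

#' Map detected peptides to proteins and classify them against TMDs
#'
#' Locates every peptide in the proteome (all overlapping occurrences, in
#' every protein by default), evaluates each occurrence against every TMD of
#' that protein with [classify_tmd_hit()], and records per-protein residue
#' coverage. Peptide sequences are homoserine-normalized before matching.
#'
#' @param peptides Detected-peptide tibble (needs a `sequence` column;
#'   `replicate` / `method` / `claimed_accessions` carried through if
#'   present), or a character vector of sequences.
#' @param proteome Proteome tibble from [read_fasta()].
#' @param tmds TMD interval tibble from [parse_tmhmm()] or
#'   [predict_tmd_surrogate()].
#' @param min_partial_overlap Passed to [classify_tmd_hit()].
#' @param il_equivalent Treat I/L as identical when matching.
#' @param unique_only Keep only peptides matching exactly one protein.
#' @param max_proteins Peptides matching more proteins than this are flagged
#'   promiscuous (message) but still reported. Default 100.
#' @return Object of class `tmd_map`: a list with tibbles `hits` (one row per
#'   peptide occurrence x TMD hit), `matches` (all peptide placements),
#'   `coverage` (per-protein matched residue ranges), and character vector
#'   `orphans` (peptides with no occurrence). `tidy()` returns `hits`;
#'   `glance()` a one-row summary.
#' @export
map_peptides <- function(peptides, proteome, tmds,
                         min_partial_overlap = 2L, il_equivalent = FALSE,
                         unique_only = FALSE, max_proteins = 100L) {
  if (is.character(peptides)) {
    peptides <- tibble::tibble(sequence = peptides)
  }
  stopifnot(is.data.frame(peptides), is.data.frame(proteome),
            is.data.frame(tmds))
  pep <- dplyr::mutate(peptides,
    sequence = normalize_homoserine(.data$sequence)
  )
  uniq_seq <- unique(pep$sequence)
  matches <- locate_peptides_proteome(uniq_seq, proteome,
    il_equivalent = il_equivalent
  )
  orphans <- setdiff(uniq_seq, matches$peptide)
  if (length(orphans) > 0L) {
    message("map_peptides: ", length(orphans),
            " peptide(s) not found in any protein (orphans)")
  }
  n_prot <- matches |>
    dplyr::distinct(.data$peptide, .data$accession) |>
    dplyr::count(.data$peptide, name = "n_proteins")
  promiscuous <- n_prot$peptide[n_prot$n_proteins > max_proteins]
  if (length(promiscuous) > 0L) {
    message("map_peptides: ", length(promiscuous),
            " promiscuous peptide(s) matching > ", max_proteins,
            " proteins (kept)")
  }
  if (unique_only) {
    keep <- n_prot$peptide[n_prot$n_proteins == 1L]
    matches <- dplyr::filter(matches, .data$peptide %in% keep)
  }
  hits <- dplyr::inner_join(matches, tmds,
    by = "accession", relationship = "many-to-many",
    suffix = c("", "_tmd")
  )
  if (nrow(hits) > 0L) {
    hits$category <- classify_tmd_hit(
      hits$start, hits$end, hits$start_tmd, hits$end_tmd,
      min_partial_overlap = min_partial_overlap
    )
    hits$overlap_aa <- pmin(hits$end, hits$end_tmd) -
      pmax(hits$start, hits$start_tmd) + 1L
    hits <- hits |>
      dplyr::filter(!is.na(.data$category)) |>
      dplyr::select(
        "peptide", "accession", "start", "end",
        tmd_start = "start_tmd", tmd_end = "end_tmd",
        tmd_ordinal = "ordinal", "overlap_aa", "category"
      ) |>
      dplyr::arrange(.data$accession, .data$tmd_ordinal, .data$start,
                     .data$peptide)
  } else {
    hits <- tibble::tibble(
      peptide = character(), accession = character(),
      start = integer(), end = integer(), tmd_start = integer(),
      tmd_end = integer(), tmd_ordinal = integer(),
      overlap_aa = integer(), category = character()
    )
  }
  coverage <- matches |>
    dplyr::arrange(.data$accession, .data$start, .data$end) |>
    dplyr::distinct(.data$accession, .data$start, .data$end)
  structure(
    list(
      hits = hits,
      matches = dplyr::arrange(matches, .data$accession, .data$start,
                               .data$peptide),
      coverage = coverage,
      orphans = sort(orphans),
      peptides = pep,
      n_proteome = nrow(proteome),
      n_tmds = nrow(tmds)
    ),
    class = "tmd_map"
  )
}

#' @export
print.tmd_map <- function(x, ...) {
  cat("<tmd_map>\n")
  cat("  peptides mapped:", length(unique(x$matches$peptide)),
      "(", length(x$orphans), "orphan )\n")
  cat("  peptide-TMD hits:", nrow(x$hits), "\n")
  cat("  unique TMDs identified:", count_unique_tmds(x$hits), "\n")
  invisible(x)
}

#' Count distinct TMDs with at least one peptide hit
#'
#' A TMD hit by several peptides is one identified TMD: the count is over
#' distinct (protein accession, TMD ordinal) pairs. The companion
#' `count_peptide_tmd_pairs()` counts distinct peptide-TMD pairs instead,
#' for comparison with per-peptide reporting conventions.
#'
#' @param hits Hit tibble (from a `tmd_map`'s `hits`, or the object itself).
#' @return Integer count.
#' @export
count_unique_tmds <- function(hits) {
  if (inherits(hits, "tmd_map")) {
    hits <- hits$hits
  }
  nrow(dplyr::distinct(hits, .data$accession, .data$tmd_ordinal))
}

#' @rdname count_unique_tmds
#' @export
count_peptide_tmd_pairs <- function(hits) {
  if (inherits(hits, "tmd_map")) {
    hits <- hits$hits
  }
  nrow(dplyr::distinct(hits, .data$peptide, .data$accession,
                       .data$tmd_ordinal))
}

#' Group proteins sharing an identical set of identified peptides
#'
#' Database redundancy makes several accessions explain the same evidence;
#' proteins whose identified peptide sets are exactly equal are merged into
#' one protein group, identified by the lexicographically smallest member
#' accession. The groups partition the identified proteins and the operation
#' is idempotent.
#'
#' @param matches Tibble with `peptide` and `accession` columns (e.g. the
#'   `matches` element of a `tmd_map`).
#' @return Tibble with one row per protein: `group_id`, `accession`,
#'   `n_members`, `peptide_set` (list column, sorted unique peptides).
#' @export
group_proteins <- function(matches) {
  if (inherits(matches, "tmd_map")) {
    matches <- matches$matches
  }
  stopifnot(all(c("peptide", "accession") %in% names(matches)))
  sets <- matches |>
    dplyr::distinct(.data$accession, .data$peptide) |>
    dplyr::arrange(.data$accession, .data$peptide) |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(
      key = paste(.data$peptide, collapse = "\r"),
      peptide_set = list(.data$peptide),
      .groups = "drop"
    )
  sets |>
    dplyr::group_by(.data$key) |>
    dplyr::mutate(
      group_id = min(.data$accession),
      n_members = dplyr::n()
    ) |>
    dplyr::ungroup() |>
    dplyr::select("group_id", "accession", "n_members", "peptide_set") |>
    dplyr::arrange(.data$group_id, .data$accession)
}

#' Write per-protein peptide coverage as BED-like TSV
#'
#' One row per matched residue range, protein accession as the contig.
#' Coordinates are written 0-based half-open (BED convention), stated in the
#' header comment.
#'
#' @param x A `tmd_map` object or its `coverage` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_bed <- function(x, path) {
  cov <- if (inherits(x, "tmd_map")) x$coverage else x
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(
    "# peptide coverage; coordinates 0-based half-open (BED convention)",
    con
  )
  writeLines(
    sprintf("%s\t%d\t%d", cov$accession, cov$start - 1L, cov$end),
    con
  )
  invisible(path)
}
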