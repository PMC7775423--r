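#' Cleavage rule constructor
#'
#' Describes a chemical or enzymatic cleavage: the residues after which the
#' backbone is cut, optional next-residue exceptions that block the cut, and
#' an optional conversion applied to the fragment's terminal residue (CNBr
#' converts its C-terminal methionine to homoserine / homoserine lactone).
#'
#' @param name Rule label.
#' @param cleave_after Character vector of residues cut C-terminally.
#' @param exceptions Residues that, when immediately following a site, block
#'   cleavage (default none; pass `"P"` for the classical KP/RP block).
#' @param terminal_conversion Optional label recorded on fragments whose last
#'   residue is a cleaved site residue (e.g. `"Hse"` for CNBr).
#' @param convert_residues Residues the conversion applies to (default: all
#'   of `cleave_after`; the combined CNBr + trypsin/Lys-C rule converts only
#'   methionine termini).
#' @return A `cleavage_rule` list.
#' @export
#' @examples
#' cleavage_rule("trypsin_lysC", c("K", "R"))
cleavage_rule <- function(name, cleave_after, exceptions = character(),
                          terminal_conversion = NULL,
                          convert_residues = cleave_after) {
  cleave_after <- toupper(cleave_after)
  if (length(cleave_after) == 0L) {
    stop("cleavage_rule: cleave_after must be non-empty", call. = FALSE)
  }
  structure(
    list(
      name = name,
      cleave_after = cleave_after,
      exceptions = toupper(exceptions),
      terminal_conversion = terminal_conversion,
      convert_residues = toupper(convert_residues)
    ),
    class = "cleavage_rule"
  )
}

#' Built-in cleavage rules
#'
#' `rule_trypsin_lysc()` cuts C-terminal of lysine and arginine (no proline
#' exception by default; pass `block_proline = TRUE` for the classical KP/RP
#' block). `rule_cnbr()` cuts C-terminal of methionine and records the Met to
#' homoserine conversion on fragment termini.
#'
#' @param block_proline Block cleavage before proline (default `FALSE`).
#' @return A `cleavage_rule`.
#' @export
rule_trypsin_lysc <- function(block_proline = FALSE) {
  cleavage_rule(
    "trypsin_lysC", c("K", "R"),
    exceptions = if (block_proline) "P" else character()
  )
}

#' @rdname rule_trypsin_lysc
#' @export
rule_cnbr <- function() {
  cleavage_rule("cnbr", "M", terminal_conversion = "Hse")
}

#' @rdname rule_trypsin_lysc
#' @export
#' @details `rule_cnbr_trypsin_lysc()` is the combined FA-CTLC specificity as
#'   a search engine states it: cleavage C-terminal of methionine, arginine
#'   and lysine in one rule, with the homoserine conversion recorded only on
#'   methionine termini. At zero missed cleavages it is equivalent to
#'   [sequential_digest()] with CNBr followed by trypsin/Lys-C.
rule_cnbr_trypsin_lysc <- function(block_proline = FALSE) {
  cleavage_rule(
    "cnbr_trypsin_lysC", c("M", "K", "R"),
    exceptions = if (block_proline) "P" else character(),
    terminal_conversion = "Hse",
    convert_residues = "M"
  )
}

# 0-based cut positions (cut after position i), excluding the C-terminus.
cleavage_sites <- function(residues, rule) {
  n <- length(residues)
  if (n <= 1L) {
    return(integer())
  }
  is_site <- residues[-n] %in% rule$cleave_after
  if (length(rule$exceptions) > 0L) {
    is_site <- is_site & !(residues[-1L] %in% rule$exceptions)
  }
  which(is_site)
}

fragments_from_boundaries <- function(boundaries, max_missed) {
  # boundaries: 0, internal sites..., n (strictly increasing)
  k <- length(boundaries) - 1L
  starts <- ends <- missed <- vector("list", max_missed + 1L)
  for (m in 0:max_missed) {
    if (k - m < 1L) break
    i <- seq_len(k - m)
    starts[[m + 1L]] <- boundaries[i] + 1L
    ends[[m + 1L]] <- boundaries[i + m + 1L]
    missed[[m + 1L]] <- rep.int(m, k - m)
  }
  list(
    start = unlist(starts), end = unlist(ends),
    missed_cleavages = unlist(missed)
  )
}

# plain-vector digestion core; `residues` is strsplit(sequence, "")[[1]]
digest_core <- function(residues, rule, max_missed) {
  n <- length(residues)
  boundaries <- c(0L, cleavage_sites(residues, rule), n)
  frags <- fragments_from_boundaries(boundaries, max_missed)
  conv <- if (is.null(rule$terminal_conversion)) {
    rep(NA_character_, length(frags$start))
  } else {
    ifelse(frags$end < n & residues[frags$end] %in% rule$convert_residues,
      rule$terminal_conversion, NA_character_
    )
  }
  frags$terminal_conversion <- conv
  frags
}

sequential_core <- function(sequence, rules, max_missed_per_stage) {
  residues <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(residues)
  site_sets <- lapply(rules, function(r) cleavage_sites(residues, r))
  if (all(max_missed_per_stage == 0L)) {
    # zero missed at every stage: equivalent to one pass at the union of
    # all stages' site sets
    boundaries <- c(0L, sort(unique(unlist(site_sets))), n)
    frags <- fragments_from_boundaries(boundaries, 0L)
  } else {
    frags <- digest_core(residues, rules[[1L]], max_missed_per_stage[1L])
    frags <- frags[c("start", "end")]
    for (k in seq_along(rules)[-1L]) {
      mm <- max_missed_per_stage[k]
      sites_k <- site_sets[[k]]
      starts <- ends <- vector("list", length(frags$start))
      for (i in seq_along(frags$start)) {
        fs <- frags$start[i]
        fe <- frags$end[i]
        inner <- sites_k[sites_k >= fs & sites_k < fe]
        b <- c(fs - 1L, inner, fe)
        sub <- fragments_from_boundaries(b, mm)
        starts[[i]] <- sub$start
        ends[[i]] <- sub$end
      }
      start <- unlist(starts)
      end <- unlist(ends)
      keep <- !duplicated(start * (n + 1) + end)
      frags <- list(start = start[keep], end = end[keep])
    }
  }
  # missed cleavages and terminal conversions are properties of the
  # fragment's span against the union of all stages' site sets
  all_sites <- sort(unique(unlist(site_sets)))
  frags$missed_cleavages <- if (length(all_sites) == 0L) {
    rep.int(0L, length(frags$start))
  } else {
    findInterval(frags$end - 1L, all_sites) -
      findInterval(frags$start - 1L, all_sites)
  }
  conv <- rep(NA_character_, length(frags$start))
  for (j in seq_along(rules)) {
    lab <- rules[[j]]$terminal_conversion
    if (!is.null(lab)) {
      res_end <- strsplit(sequence, "", fixed = TRUE)[[1L]][frags$end]
      hit <- is.na(conv) & frags$end %in% site_sets[[j]] &
        res_end %in% rules[[j]]$convert_residues
      conv[hit] <- lab
    }
  }
  frags$terminal_conversion <- conv
  o <- order(frags$start, frags$end)
  lapply(frags, `[`, o)
}

#' In-silico cleavage of one sequence
#'
#' Cuts a sequence at every position immediately after a `cleave_after`
#' residue (unless followed by an exception residue) and returns all fragments
#' spanning at most `max_missed` internal uncut sites.
#'
#' @param sequence Single amino-acid sequence.
#' @param rule A [cleavage_rule()].
#' @param max_missed Maximum internal missed cleavage sites (default 0).
#' @return Tibble with columns `start`, `end` (1-based inclusive), `sequence`,
#'   `missed_cleavages`, and `terminal_conversion` (NA or the rule's label
#'   when the fragment ends on a site residue), sorted by `start` then `end`.
#' @export
#' @examples
#' cleave_sequence("AAKGGRDD", rule_trypsin_lysc())
cleave_sequence <- function(sequence, rule, max_missed = 0L) {
  stopifnot(inherits(rule, "cleavage_rule"), max_missed >= 0L)
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L) {
    stop("cleave_sequence: sequence must be a single non-empty string",
      call. = FALSE
    )
  }
  sequence <- toupper(sequence)
  residues <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  frags <- digest_core(residues, rule, max_missed)
  o <- order(frags$start, frags$end)
  tibble::tibble(
    start = frags$start[o],
    end = frags$end[o],
    sequence = substring(sequence, frags$start[o], frags$end[o]),
    missed_cleavages = frags$missed_cleavages[o],
    terminal_conversion = frags$terminal_conversion[o]
  )
}

#' In-silico digestion of a proteome
#'
#' Applies [cleave_sequence()] to each protein of a proteome tibble.
#'
#' @param proteome Tibble with `accession` and `sequence` columns.
#' @inheritParams cleave_sequence
#' @return Tibble of fragments with an `accession` column prepended.
#' @export
cleave <- function(proteome, rule, max_missed = 0L) {
  stopifnot(is.data.frame(proteome),
            all(c("accession", "sequence") %in% names(proteome)))
  digest_proteome(proteome, function(s) {
    digest_core(strsplit(s, "", fixed = TRUE)[[1L]], rule, max_missed)
  })
}

# shared proteome loop: fn(sequence) -> list(start, end, missed_cleavages,
# terminal_conversion); assembles one tibble
digest_proteome <- function(proteome, fn) {
  seqs <- toupper(proteome$sequence)
  parts <- lapply(seqs, fn)
  n_each <- vapply(parts, function(p) length(p$start), integer(1))
  start <- unlist(lapply(parts, `[[`, "start"))
  end <- unlist(lapply(parts, `[[`, "end"))
  out <- tibble::tibble(
    accession = rep(proteome$accession, n_each),
    start = start,
    end = end,
    sequence = substring(rep(seqs, n_each), start, end),
    missed_cleavages = unlist(lapply(parts, `[[`, "missed_cleavages")),
    terminal_conversion = unlist(lapply(parts, `[[`, "terminal_conversion"))
  )
  dplyr::arrange(out, .data$accession, .data$start, .data$end)
}

#' Sequential multi-stage digestion
#'
#' Stage k cleaves every fragment emitted by stage k-1; coordinates stay in
#' protein space throughout. With zero missed cleavages at every stage the
#' result equals a single-pass cleavage at the union of all stages' sites.
#' The FA-CTLC chemistry is `list(rule_cnbr(), rule_trypsin_lysc())`.
#'
#' @param sequence Single amino-acid sequence.
#' @param rules Non-empty ordered list of [cleavage_rule()]s.
#' @param max_missed_per_stage Integer vector, recycled to `length(rules)`.
#' @return Tibble as [cleave_sequence()]; `missed_cleavages` is the total
#'   number of uncut internal sites from any stage's rule.
#' @export
#' @examples
#' sequential_digest_sequence("AKMGRC", list(rule_cnbr(), rule_trypsin_lysc()))
sequential_digest_sequence <- function(sequence, rules,
                                       max_missed_per_stage = 0L) {
  if (length(rules) == 0L) {
    stop("sequential_digest_sequence: rules must be non-empty", call. = FALSE)
  }
  max_missed_per_stage <- rep_len(as.integer(max_missed_per_stage),
                                  length(rules))
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L) {
    stop("sequential_digest_sequence: sequence must be a single non-empty ",
      "string",
      call. = FALSE
    )
  }
  sequence <- toupper(sequence)
  frags <- sequential_core(sequence, rules, max_missed_per_stage)
  tibble::tibble(
    start = frags$start,
    end = frags$end,
    sequence = substring(sequence, frags$start, frags$end),
    missed_cleavages = frags$missed_cleavages,
    terminal_conversion = frags$terminal_conversion
  )
}

#' @rdname sequential_digest_sequence
#' @param proteome Tibble with `accession` and `sequence` columns.
#' @export
sequential_digest <- function(proteome, rules, max_missed_per_stage = 0L) {
  stopifnot(is.data.frame(proteome))
  if (length(rules) == 0L) {
    stop("sequential_digest: rules must be non-empty", call. = FALSE)
  }
  max_missed_per_stage <- rep_len(as.integer(max_missed_per_stage),
                                  length(rules))
  digest_proteome(proteome, function(s) {
    sequential_core(s, rules, max_missed_per_stage)
  })
}

#' Strip homoserine / homoserine-lactone markers from a peptide
#'
#' CNBr converts the methionine it cleaves after into homoserine (Hse) or
#' homoserine lactone (Hsl); search engines annotate this as a variable
#' modification, e.g. `"AAM(Hse)K"`. This strips the markers so the sequence
#' matches the database-space protein substring. Markers on any residue other
#' than methionine are an error.
#'
#' @param sequence Character vector of peptide sequences possibly carrying
#'   `(Hse)` / `(Hsl)` or `[Hse]` / `[Hsl]` markers.
#' @return Character vector of database-space sequences.
#' @export
#' @examples
#' normalize_homoserine("AAM(Hsl)K")  # "AAMK"
normalize_homoserine <- function(sequence) {
  stopifnot(is.character(sequence))
  marker <- "[\\(\\[](Hse|Hsl)[\\)\\]]"
  bad <- stringr::str_detect(
    sequence, stringr::regex(paste0("(^|[^M])", marker))
  )
  if (any(bad, na.rm = TRUE)) {
    stop(
      "normalize_homoserine: Hse/Hsl marker on a non-methionine residue in: ",
      paste(sequence[which(bad)], collapse = ", "),
      call. = FALSE
    )
  }
  stringr::str_remove_all(sequence, stringr::regex(marker))
}
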