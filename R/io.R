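AA_CANONICAL <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

#' Read a protein FASTA file
#'
#' Reads a proteome into a tibble. The accession is the first
#' whitespace-delimited token of each header; the remainder is the
#' description. Sequences are uppercased, line breaks removed, and a trailing
#' `*` stop character stripped.
#'
#' @param path FASTA file path.
#' @param allow_x Admit `X` (unknown residue) in sequences (default `FALSE`).
#' @return Tibble with columns `accession`, `description`, `sequence`.
#' @export
read_fasta <- function(path, allow_x = FALSE) {
  stopifnot(file.exists(path))
  aas <- Biostrings::readBStringSet(path)
  headers <- names(aas)
  accession <- stringr::str_extract(headers, "^\\S+")
  description <- stringr::str_trim(
    stringr::str_remove(headers, "^\\S+\\s*")
  )
  sequence <- stringr::str_remove(toupper(as.character(aas)), "\\*$")
  if (anyNA(accession) || any(accession == "")) {
    stop("read_fasta: record with empty header/accession", call. = FALSE)
  }
  dup <- unique(accession[duplicated(accession)])
  if (length(dup) > 0L) {
    stop("read_fasta: duplicate accession(s): ",
      paste(dup, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(nchar(sequence) == 0L)) {
    stop("read_fasta: empty sequence for accession(s): ",
      paste(accession[nchar(sequence) == 0L], collapse = ", "),
      call. = FALSE
    )
  }
  alphabet <- c(AA_CANONICAL, if (allow_x) "X")
  for (i in seq_along(sequence)) {
    res <- strsplit(sequence[i], "", fixed = TRUE)[[1L]]
    bad <- which(!(res %in% alphabet))
    if (length(bad) > 0L) {
      stop(
        "read_fasta: non-alphabet character '", res[bad[1L]],
        "' at position ", bad[1L], " of ", accession[i],
        if (!allow_x) " (use allow_x = TRUE to admit X)",
        call. = FALSE
      )
    }
  }
  tibble::tibble(
    accession = accession,
    description = description,
    sequence = unname(sequence)
  )
}

#' Write a proteome tibble to FASTA
#'
#' @param proteome Tibble with `accession`, `sequence` and optionally
#'   `description` columns.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path, width = 60L) {
  stopifnot(is.data.frame(proteome))
  desc <- if ("description" %in% names(proteome)) proteome$description else ""
  header <- ifelse(is.na(desc) | desc == "",
    proteome$accession,
    paste(proteome$accession, desc)
  )
  x <- Biostrings::BStringSet(proteome$sequence)
  names(x) <- header
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

parse_tmhmm_long <- function(lines) {
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  line_no <- which(keep)
  fields <- strsplit(lines, "\\s+")
  out <- purrr::map2(fields, line_no, function(f, ln) {
    if (length(f) < 5L) {
      stop("parse_tmhmm: malformed long-dialect line ", ln,
        " (expected 5 fields)",
        call. = FALSE
      )
    }
    if (f[3L] != "TMhelix") {
      return(NULL) # inside / outside lines carry no helix
    }
    start <- suppressWarnings(as.integer(f[4L]))
    end <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start) || is.na(end)) {
      stop("parse_tmhmm: malformed coordinate on line ", ln, call. = FALSE)
    }
    tibble::tibble(accession = f[1L], start = start, end = end)
  })
  dplyr::bind_rows(out)
}

parse_tmhmm_short <- function(lines) {
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  line_no <- which(keep)
  out <- purrr::map2(lines, line_no, function(l, ln) {
    acc <- stringr::str_extract(l, "^\\S+")
    predhel <- stringr::str_match(l, "PredHel=(\\d+)")[, 2L]
    topo <- stringr::str_match(l, "Topology=(\\S+)")[, 2L]
    if (is.na(topo)) {
      stop("parse_tmhmm: short-dialect line ", ln, " lacks Topology=",
        call. = FALSE
      )
    }
    seg <- stringr::str_match_all(topo, "(\\d+)-(\\d+)")[[1L]]
    n_seg <- nrow(seg)
    if (!is.na(predhel) && as.integer(predhel) != n_seg) {
      stop(
        "parse_tmhmm: PredHel=", predhel, " disagrees with ", n_seg,
        " Topology segment(s) for protein ", acc,
        call. = FALSE
      )
    }
    if (n_seg == 0L) {
      return(NULL)
    }
    start <- as.integer(seg[, 2L])
    end <- as.integer(seg[, 3L])
    if (anyNA(start) || anyNA(end)) {
      stop("parse_tmhmm: malformed coordinate on line ", ln, call. = FALSE)
    }
    tibble::tibble(accession = acc, start = start, end = end)
  })
  dplyr::bind_rows(out)
}

#' Parse TMHMM v2-style topology predictions
#'
#' Supports both TMHMM output dialects. The long dialect has one line per
#' topology element (`<acc> TMHMM2.0 TMhelix <start> <end>`; `inside` /
#' `outside` lines are ignored). The short dialect has one line per protein
#' with `PredHel=<n>` and `Topology=` segments such as `o10-32i44-66o`.
#' Coordinates are 1-based inclusive. `dialect = "auto"` inspects the first
#' non-comment line for `Topology=`.
#'
#' @param path File path.
#' @param dialect `"auto"` (default), `"long"` or `"short"`.
#' @return Tibble with columns `accession`, `start`, `end`, `ordinal`
#'   (1-based helix index in N-to-C order within each protein).
#' @export
parse_tmhmm <- function(path, dialect = c("auto", "long", "short")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8")
  if (dialect == "auto") {
    first <- lines[!grepl("^\\s*(#|$)", lines)][1L]
    dialect <- if (!is.na(first) && grepl("Topology=", first, fixed = TRUE)) {
      "short"
    } else {
      "long"
    }
  }
  out <- switch(dialect,
    long = parse_tmhmm_long(lines),
    short = parse_tmhmm_short(lines)
  )
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      accession = character(), start = integer(), end = integer(),
      ordinal = integer()
    ))
  }
  out |>
    dplyr::arrange(.data$accession, .data$start) |>
    dplyr::group_by(.data$accession) |>
    dplyr::mutate(ordinal = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Validate TMD intervals against a proteome
#'
#' Checks 1 <= start <= end <= protein length, non-overlap within each
#' protein, and that `ordinal` matches N-to-C sort order. Intervals for
#' accessions absent from the proteome are an error.
#'
#' @param tmds TMD interval tibble (as from [parse_tmhmm()]).
#' @param proteome Proteome tibble.
#' @return `tmds`, invisibly, if valid; otherwise an error naming the
#'   offending protein.
#' @export
validate_tmds <- function(tmds, proteome) {
  stopifnot(is.data.frame(tmds), is.data.frame(proteome))
  missing <- setdiff(tmds$accession, proteome$accession)
  if (length(missing) > 0L) {
    stop("validate_tmds: accession(s) not in proteome: ",
      paste(utils::head(missing, 5L), collapse = ", "),
      call. = FALSE
    )
  }
  len <- stats::setNames(nchar(proteome$sequence), proteome$accession)
  bad <- tmds$start < 1L | tmds$start > tmds$end |
    tmds$end > len[tmds$accession]
  if (any(bad)) {
    stop("validate_tmds: out-of-bounds interval for protein ",
      tmds$accession[which(bad)[1L]],
      call. = FALSE
    )
  }
  by_prot <- split(tmds, tmds$accession)
  for (d in by_prot) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)])) {
      stop("validate_tmds: overlapping intervals for protein ",
        d$accession[1L],
        call. = FALSE
      )
    }
    if (!identical(as.integer(d$ordinal), seq_len(nrow(d)))) {
      stop("validate_tmds: ordinal out of order for protein ",
        d$accession[1L],
        call. = FALSE
      )
    }
  }
  invisible(tmds)
}

#' Write TMD intervals in TMHMM long dialect
#'
#' @param tmds TMD interval tibble.
#' @param path Output path.
#' @param tool Tool tag written in the second column (default `"TMHMM2.0"`;
#'   the surrogate predictor writes `"surrogate-window"`).
#' @return `path`, invisibly.
#' @export
write_tmhmm_long <- function(tmds, path, tool = "TMHMM2.0") {
  stopifnot(is.data.frame(tmds))
  tmds <- dplyr::arrange(tmds, .data$accession, .data$start)
  if ("source" %in% names(tmds) && nrow(tmds) > 0L) {
    tool <- tmds$source[1L]
  }
  lines <- sprintf(
    "%s\t%s\tTMhelix\t%d\t%d",
    tmds$accession, tool, tmds$start, tmds$end
  )
  writeLines(lines, path)
  invisible(path)
}

strip_peptide_decorations <- function(x) {
  x <- stringr::str_trim(x)
  # flanking-residue decoration X.PEPTIDE.Y (flank may be '-')
  core <- stringr::str_match(x, "^[A-Za-z\\-]\\.(.*)\\.[A-Za-z\\-]$")[, 2L]
  x <- ifelse(is.na(core), x, core)
  mods <- stringr::str_match_all(x, "[\\(\\[]([^\\)\\]]*)[\\)\\]]")
  plain <- stringr::str_remove_all(x, "[\\(\\[][^\\)\\]]*[\\)\\]]")
  list(
    sequence = toupper(plain),
    modifications = purrr::map(mods, ~ .x[, 2L])
  )
}

#' Read a detected-peptide table
#'
#' Reads a delimited (tab or comma; sniffed from the header line) export of
#' identified peptides. Flanking-residue decorations (`K.GGILR.A`) are
#' stripped and modification annotations in brackets/parentheses (e.g.
#' `AAM(Hse)K`) removed to yield the plain uppercase sequence; the
#' modification list is retained in a list column.
#'
#' @param path File path.
#' @param column_map Named list mapping roles to column names; roles:
#'   `peptide` (required), `replicate`, `method`, `proteins` (accessions,
#'   `;`-separated), `category` (functional category). Defaults assume
#'   columns named `peptide`, `replicate`, `method`, `proteins`, `category`.
#' @param min_peptide_length Rows with shorter peptides are dropped with a
#'   warning (default 6).
#' @return Tibble with columns `sequence`, `modifications` (list),
#'   `replicate`, `method`, `claimed_accessions` (list), and
#'   `functional_category`.
#' @export
read_peptide_table <- function(path,
                               column_map = list(
                                 peptide = "peptide",
                                 replicate = "replicate",
                                 method = "method",
                                 proteins = "proteins",
                                 category = "category"
                               ),
                               min_peptide_length = 6L) {
  stopifnot(file.exists(path))
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- readr::read_delim(path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  get_col <- function(role, required = FALSE) {
    nm <- column_map[[role]]
    if (is.null(nm) || !(nm %in% names(df))) {
      if (required) {
        stop("read_peptide_table: mapped column '",
          if (is.null(nm)) role else nm, "' not found",
          call. = FALSE
        )
      }
      return(NULL)
    }
    df[[nm]]
  }
  pep_raw <- get_col("peptide", required = TRUE)
  dec <- strip_peptide_decorations(pep_raw)
  out <- tibble::tibble(
    sequence = dec$sequence,
    modifications = dec$modifications,
    replicate = get_col("replicate") %||% NA_character_,
    method = get_col("method") %||% NA_character_,
    claimed_accessions = purrr::map(
      get_col("proteins") %||% rep(NA_character_, nrow(df)),
      function(p) {
        if (is.na(p) || p == "") character() else strsplit(p, ";")[[1L]]
      }
    ),
    functional_category = get_col("category") %||% NA_character_
  )
  empty <- is.na(out$sequence) | out$sequence == ""
  short <- !empty & nchar(out$sequence) < min_peptide_length
  has_method <- !is.null(column_map$method) &&
    column_map$method %in% names(df)
  has_replicate <- !is.null(column_map$replicate) &&
    column_map$replicate %in% names(df)
  no_label <- !empty &
    ((if (has_method) is.na(out$method) | out$method == "" else FALSE) |
       (if (has_replicate) {
         is.na(out$replicate) | out$replicate == ""
       } else {
         FALSE
       }))
  drop <- empty | short | no_label
  if (any(drop)) {
    warning(
      "read_peptide_table: rejected ", sum(drop), " row(s) (",
      sum(empty), " empty peptide, ", sum(short), " below length ",
      min_peptide_length, ", ", sum(no_label), " missing method/replicate)",
      call. = FALSE
    )
  }
  out[!drop, ]
}

#' Write a tibble as TSV with deterministic row order
#'
#' List columns are collapsed with `;`. Rows are ordered by the given sort
#' columns so outputs are byte-reproducible.
#'
#' @param x Tibble.
#' @param path Output path.
#' @param sort_by Character vector of columns to sort by (those present are
#'   used; default sorts by all shared of accession/start/end).
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path,
                             sort_by = c("accession", "start", "end")) {
  stopifnot(is.data.frame(x))
  keys <- intersect(sort_by, names(x))
  if (length(keys) > 0L) {
    x <- dplyr::arrange(x, dplyr::across(dplyr::all_of(keys)))
  }
  x <- dplyr::mutate(x, dplyr::across(
    dplyr::where(is.list),
    ~ purrr::map_chr(.x, function(v) paste(v, collapse = ";"))
  ))
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
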