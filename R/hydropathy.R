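#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values (dimensionless) for the 20 canonical amino
#' acids. Positive values are hydrophobic; isoleucine (4.5) and arginine
#' (-4.5) bound the scale.
#'
#' @return Named numeric vector of length 20 (one-letter residue codes).
#' @export
#' @examples
#' kyte_doolittle()[["I"]]
kyte_doolittle <- function() {
  c(
    A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
  )
}

#' Grand average of hydropathy (GRAVY)
#'
#' GRAVY is the sum of the per-residue hydropathy values of a sequence divided
#' by its length, i.e. the mean hydropathy per residue. Scores above zero
#' indicate hydrophobic (likely membrane) proteins; scores below zero indicate
#' hydrophilic (likely soluble) proteins.
#'
#' @param sequence Character vector of amino-acid sequences (uppercased
#'   internally).
#' @param scale Named numeric hydropathy scale; default [kyte_doolittle()].
#' @param skip_unknown If `TRUE`, residues absent from `scale` (e.g. `X`) are
#'   excluded from both the sum and the length; if `FALSE` (default) an
#'   unknown residue is an error.
#' @return Numeric vector of GRAVY scores, one per input sequence.
#' @export
#' @examples
#' gravy("IIII")            # 4.5
#' gravy(c("G", "GILV"))
gravy <- function(sequence, scale = kyte_doolittle(), skip_unknown = FALSE) {
  stopifnot(is.character(sequence))
  vapply(toupper(sequence), function(s) {
    if (is.na(s) || nchar(s) == 0L) {
      stop("gravy: sequence must be non-empty", call. = FALSE)
    }
    res <- strsplit(s, "", fixed = TRUE)[[1L]]
    vals <- scale[res]
    unknown <- is.na(vals)
    if (any(unknown)) {
      if (!skip_unknown) {
        stop(
          "gravy: unknown residue(s) ",
          paste(unique(res[unknown]), collapse = ", "),
          " at position(s) ", paste(which(unknown), collapse = ", "),
          call. = FALSE
        )
      }
      vals <- vals[!unknown]
      if (length(vals) == 0L) {
        stop("gravy: no scored residues left after skipping unknowns",
          call. = FALSE
        )
      }
    }
    mean(vals)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Classify a GRAVY score as hydrophobic
#'
#' A protein is called hydrophobic when its GRAVY score is strictly greater
#' than zero; a score of exactly zero is classified not hydrophobic (the
#' membrane-likeness claim is for scores above zero).
#'
#' @param score Numeric vector of GRAVY scores.
#' @return Logical vector, `TRUE` where `score > 0`.
#' @export
classify_hydrophobic <- function(score) {
  stopifnot(is.numeric(score), all(is.finite(score)))
  score > 0
}

#' GRAVY table for a proteome
#'
#' Convenience wrapper scoring every protein in a proteome tibble.
#'
#' @param proteome Tibble with columns `accession` and `sequence`
#'   (as returned by [read_fasta()]).
#' @inheritParams gravy
#' @return Tibble with columns `accession`, `length`, `gravy`, `hydrophobic`.
#' @export
gravy_table <- function(proteome, scale = kyte_doolittle(),
                        skip_unknown = FALSE) {
  stopifnot(is.data.frame(proteome),
            all(c("accession", "sequence") %in% names(proteome)))
  g <- gravy(proteome$sequence, scale = scale, skip_unknown = skip_unknown)
  tibble::tibble(
    accession = proteome$accession,
    length = nchar(proteome$sequence),
    gravy = g,
    hydrophobic = classify_hydrophobic(g)
  )
}

#' Sliding-window hydropathy profile
#'
#' Centred moving average of per-residue hydropathy over an odd window,
#' reported at every position whose window fits inside the sequence.
#'
#' @param sequence Single amino-acid sequence.
#' @param window Odd window width (residues), default 19.
#' @inheritParams gravy
#' @return Tibble with columns `position` (window centre, 1-based) and
#'   `score`.
#' @export
window_profile <- function(sequence, window = 19L, scale = kyte_doolittle()) {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  n <- nchar(sequence)
  if (window %% 2L == 0L) {
    stop("window_profile: window must be odd", call. = FALSE)
  }
  if (window > n) {
    stop("window_profile: window (", window, ") exceeds sequence length (",
      n, ")",
      call. = FALSE
    )
  }
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  vals <- scale[res]
  if (anyNA(vals)) {
    stop("window_profile: unknown residue(s) ",
      paste(unique(res[is.na(vals)]), collapse = ", "),
      call. = FALSE
    )
  }
  half <- (window - 1L) %/% 2L
  sm <- stats::filter(vals, rep(1 / window, window), sides = 2)
  centre <- seq.int(half + 1L, n - half)
  tibble::tibble(position = centre, score = as.numeric(sm[centre]))
}

#' Hydropathy-window transmembrane-segment surrogate predictor
#'
#' A deliberately simple stand-in for an external topology predictor so the
#' whole pipeline can run self-contained: maximal runs of window-averaged
#' hydropathy strictly above `threshold`, kept when at least `min_len`
#' residues long. Output matches [parse_tmhmm()] so downstream mapping is
#' agnostic to the predictor; the `source` column is labelled
#' `"surrogate-window"`, never TMHMM.
#'
#' @param proteome Proteome tibble (`accession`, `sequence`).
#' @param threshold Hydropathy threshold (strict `>`), default 1.6.
#' @param min_len Minimum segment length in residues, default 18.
#' @inheritParams window_profile
#' @return Tibble with columns `accession`, `start`, `end`, `ordinal`,
#'   `source`.
#' @export
predict_tmd_surrogate <- function(proteome, window = 19L, threshold = 1.6,
                                  min_len = 18L, scale = kyte_doolittle()) {
  stopifnot(is.data.frame(proteome))
  out <- purrr::map2(proteome$accession, proteome$sequence, function(acc, s) {
    if (nchar(s) < window) {
      return(NULL)
    }
    prof <- window_profile(s, window = window, scale = scale)
    above <- prof$score > threshold
    if (!any(above)) {
      return(NULL)
    }
    r <- rle(above)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    keep <- r$values
    runs <- tibble::tibble(
      start = prof$position[starts_i[keep]],
      end = prof$position[ends_i[keep]]
    )
    runs <- dplyr::filter(runs, .data$end - .data$start + 1L >= min_len)
    if (nrow(runs) == 0L) {
      return(NULL)
    }
    tibble::tibble(accession = acc, start = runs$start, end = runs$end)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      accession = character(), start = integer(), end = integer(),
      ordinal = integer(), source = character()
    ))
  }
  out |>
    dplyr::arrange(.data$accession, .data$start) |>
    dplyr::group_by(.data$accession) |>
    dplyr::mutate(ordinal = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(source = "surrogate-window")
}
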