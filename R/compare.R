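#' Compare membrane-coverage performance of two or more methods
#'
#' Runs the full comparison analysis on a combined detected-peptide table:
#' per method, peptides are mapped to the proteome and classified against the
#' TMDs, proteins are grouped by shared peptide sets, and the TMD-count
#' histogram, unique-TMD count, GRAVY>0 fraction and replicate
#' reproducibility are computed. Across methods it runs the chi-square
#' goodness of fit of each method's TMD histogram against the proteome-wide
#' distribution, per-bin t-tests on replicate histogram fractions (first two
#' methods), and, when a `functional_category` column is present, binomial
#' category enrichment.
#'
#' @param peptides Tibble with columns `sequence`, `method`, `replicate`
#'   (and optionally `functional_category`), e.g. rows of
#'   [read_peptide_table()] output or [simulate_detection()] output.
#' @param proteome Proteome tibble.
#' @param tmds TMD interval tibble.
#' @param bins,max_single Histogram bins, as in [tmd_histogram()].
#' @param ... Passed to [map_peptides()].
#' @return Object of class `method_comparison`: list with `summary` (one row
#'   per method), `maps` (named list of `tmd_map`), `groups`,
#'   `histograms`, `replicate_fractions`, `gof`, `ttest`,
#'   `reproducibility`, `enrichment` (or `NULL`), and `proteome_histogram`.
#' @export
compare_methods <- function(peptides, proteome, tmds, bins = NULL,
                            max_single = 10L, ...) {
  stopifnot(is.data.frame(peptides),
            all(c("sequence", "method", "replicate") %in% names(peptides)))
  methods <- unique(peptides$method)
  if (length(methods) < 2L) {
    stop("compare_methods: need >= 2 method labels, got ",
      length(methods),
      call. = FALSE
    )
  }
  gr <- gravy_table(proteome)
  ref_hist <- proteome_tmd_histogram(proteome, tmds,
    bins = bins, max_single = max_single
  )
  per_method <- purrr::map(methods, function(m) {
    pep_m <- dplyr::filter(peptides, .data$method == m)
    map <- map_peptides(pep_m, proteome, tmds, ...)
    groups <- group_proteins(map$matches)
    hist <- tmd_histogram(groups, tmds, bins = bins, max_single = max_single)
    reps <- sort(unique(pep_m$replicate))
    rep_sets <- purrr::map(reps, function(r) {
      seqs <- normalize_homoserine(
        unique(pep_m$sequence[pep_m$replicate == r])
      )
      gm <- dplyr::filter(map$matches, .data$peptide %in% seqs)
      group_proteins(gm)
    })
    names(rep_sets) <- reps
    rep_fracs <- purrr::map(rep_sets, function(g) {
      h <- tmd_histogram(g, tmds, bins = bins, max_single = max_single)
      stats::setNames(h$fraction, h$bin)
    })
    reproducibility <- if (length(reps) >= 2L) {
      replicate_reproducibility(
        purrr::map(rep_sets, ~ unique(.x$group_id))
      )
    } else {
      NULL
    }
    rep_gravy <- gr$gravy[match(unique(groups$group_id), gr$accession)]
    list(
      map = map,
      groups = groups,
      hist = hist,
      rep_fractions = do.call(rbind, rep_fracs),
      reproducibility = reproducibility,
      summary = tibble::tibble(
        method = m,
        n_peptides = length(unique(pep_m$sequence)),
        n_protein_groups = length(unique(groups$group_id)),
        n_tmp_groups = attr(hist, "n_tmp"),
        tmp_fraction = attr(hist, "n_tmp") /
          length(unique(groups$group_id)),
        unique_tmd_count = count_unique_tmds(map$hits),
        peptide_tmd_pairs = count_peptide_tmd_pairs(map$hits),
        gravy_positive_fraction = mean(rep_gravy > 0),
        reproducibility_pct = if (is.null(reproducibility)) {
          NA_real_
        } else {
          reproducibility$reproducibility_pct
        }
      )
    )
  })
  names(per_method) <- methods
  gof <- purrr::imap(per_method, function(x, m) {
    tryCatch(
      chi_square_gof(x$hist, ref_hist),
      error = function(e) {
        message("compare_methods: chi-square skipped for ", m, ": ",
                conditionMessage(e))
        NULL
      }
    )
  })
  ttest <- if (length(methods) >= 2L &&
                 nrow(per_method[[1L]]$rep_fractions) >= 2L &&
                 nrow(per_method[[2L]]$rep_fractions) >= 2L) {
    per_bin_ttest(
      per_method[[1L]]$rep_fractions,
      per_method[[2L]]$rep_fractions
    )
  } else {
    NULL
  }
  enrichment <- NULL
  if ("functional_category" %in% names(peptides) &&
        !all(is.na(peptides$functional_category)) &&
        length(methods) >= 2L) {
    cat_counts <- peptides |>
      dplyr::filter(
        !is.na(.data$functional_category),
        .data$method %in% methods[1:2]
      ) |>
      dplyr::distinct(.data$method, .data$sequence,
                      .data$functional_category) |>
      dplyr::count(.data$method, .data$functional_category) |>
      tidyr::pivot_wider(
        names_from = "method", values_from = "n", values_fill = 0L
      )
    names(cat_counts) <- c("category", "count_a", "count_b")
    enrichment <- binomial_enrichment(cat_counts)
  }
  structure(
    list(
      summary = dplyr::bind_rows(purrr::map(per_method, "summary")),
      maps = purrr::map(per_method, "map"),
      groups = purrr::map(per_method, "groups"),
      histograms = purrr::map(per_method, "hist"),
      replicate_fractions = purrr::map(per_method, "rep_fractions"),
      reproducibility = purrr::map(per_method, "reproducibility"),
      gof = gof,
      ttest = ttest,
      enrichment = enrichment,
      proteome_histogram = ref_hist
    ),
    class = "method_comparison"
  )
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison> of", nrow(x$summary), "methods\n\n")
  print(x$summary)
  for (m in names(x$gof)) {
    if (is.null(x$gof[[m]])) next
    cat("\n", m, " vs proteome-wide TMD distribution: ", sep = "")
    print(x$gof[[m]])
  }
  invisible(x)
}
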