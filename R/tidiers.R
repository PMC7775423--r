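#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a peptide-to-TMD mapping
#'
#' @param x A `tmd_map` from [map_peptides()].
#' @param ... Unused.
#' @return The hit tibble (one row per peptide occurrence x TMD hit).
#' @method tidy tmd_map
#' @export
tidy.tmd_map <- function(x, ...) {
  x$hits
}

#' @rdname tidy.tmd_map
#' @return For `glance()`: a one-row summary tibble.
#' @method glance tmd_map
#' @export
glance.tmd_map <- function(x, ...) {
  tibble::tibble(
    n_peptides = nrow(x$peptides),
    n_matched = length(unique(x$matches$peptide)),
    n_orphans = length(x$orphans),
    n_hits = nrow(x$hits),
    unique_tmds = count_unique_tmds(x$hits),
    peptide_tmd_pairs = count_peptide_tmd_pairs(x$hits),
    n_proteome = x$n_proteome,
    n_tmds = x$n_tmds
  )
}

#' Tidy a chi-square goodness-of-fit result
#'
#' @param x A `tmd_gof` from [chi_square_gof()].
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `df`, `p.value`, `n_bins`,
#'   `n_merged`.
#' @method tidy tmd_gof
#' @export
tidy.tmd_gof <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    df = x$df,
    p.value = x$p.value,
    n_bins = nrow(x$table),
    n_merged = length(x$merged)
  )
}

#' Tidy a replicate-reproducibility result
#'
#' @param x A `tmd_reproducibility` from [replicate_reproducibility()].
#' @param ... Unused.
#' @return The pairwise overlap tibble.
#' @method tidy tmd_reproducibility
#' @export
tidy.tmd_reproducibility <- function(x, ...) {
  x$pairwise
}

#' @rdname tidy.tmd_reproducibility
#' @method glance tmd_reproducibility
#' @export
glance.tmd_reproducibility <- function(x, ...) {
  tibble::tibble(
    reproducibility_pct = x$reproducibility_pct,
    n_intersection = x$n_intersection,
    n_union = x$n_union
  )
}

#' Tidy a method comparison
#'
#' @param x A `method_comparison` from [compare_methods()].
#' @param ... Unused.
#' @return For `tidy()`: the per-method summary tibble. For `glance()`: a
#'   one-row tibble with the headline contrasts between the first two
#'   methods (unique-TMD ratio, TMP-fraction and GRAVY-fraction differences).
#' @method tidy method_comparison
#' @export
tidy.method_comparison <- function(x, ...) {
  x$summary
}

#' @rdname tidy.method_comparison
#' @method glance method_comparison
#' @export
glance.method_comparison <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_methods = nrow(s),
    unique_tmd_ratio = s$unique_tmd_count[2L] / s$unique_tmd_count[1L],
    tmp_fraction_diff = s$tmp_fraction[2L] - s$tmp_fraction[1L],
    gravy_positive_diff = s$gravy_positive_fraction[2L] -
      s$gravy_positive_fraction[1L]
  )
}
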