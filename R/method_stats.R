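default_tmd_bins <- function(max_single = 10L) {
  c(as.character(seq_len(max_single)), paste0(">", max_single))
}

bin_tmd_counts <- function(counts, max_single = 10L) {
  ifelse(counts > max_single, paste0(">", max_single), as.character(counts))
}

#' TMD-count histogram over protein groups
#'
#' Bins transmembrane-protein (TMP) groups by their number of predicted TMDs
#' (default bins 1..10 and ">10"). Groups with zero TMDs are not part of the
#' histogram; their count is reported in the `n_zero` attribute. A group's
#' TMD count is the maximum over member proteins by default (conservative:
#' a group is as membrane-bound as its most membrane-bound member), the mean
#' is selectable.
#'
#' @param groups Protein-group tibble from [group_proteins()], or any tibble
#'   with `group_id` and `accession` columns.
#' @param tmds TMD interval tibble.
#' @param bins Bin labels; default `1..max_single` and `">max_single"`.
#' @param max_single Largest single-count bin (default 10).
#' @param group_stat `"max"` (default) or `"mean"` member TMD count.
#' @return Tibble with columns `bin`, `count`, `fraction` (of TMP groups);
#'   attributes `n_zero` (groups without TMDs) and `n_tmp`.
#' @export
tmd_histogram <- function(groups, tmds, bins = NULL, max_single = 10L,
                          group_stat = c("max", "mean")) {
  group_stat <- match.arg(group_stat)
  stopifnot(is.data.frame(groups), is.data.frame(tmds))
  bins <- bins %||% default_tmd_bins(max_single)
  per_protein <- dplyr::count(tmds, .data$accession, name = "n_tmd")
  gc <- groups |>
    dplyr::distinct(.data$group_id, .data$accession) |>
    dplyr::left_join(per_protein, by = "accession") |>
    dplyr::mutate(n_tmd = tidyr::replace_na(.data$n_tmd, 0L)) |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(
      n_tmd = if (group_stat == "max") {
        max(.data$n_tmd)
      } else {
        round(mean(.data$n_tmd))
      },
      .groups = "drop"
    )
  n_zero <- sum(gc$n_tmd == 0L)
  tmp <- gc[gc$n_tmd > 0L, ]
  counts <- table(factor(bin_tmd_counts(tmp$n_tmd, max_single),
                         levels = bins))
  out <- tibble::tibble(
    bin = bins,
    count = as.integer(counts),
    fraction = if (nrow(tmp) > 0L) {
      as.integer(counts) / nrow(tmp)
    } else {
      NA_real_
    }
  )
  attr(out, "n_zero") <- n_zero
  attr(out, "n_tmp") <- nrow(tmp)
  if (nrow(tmp) == 0L) {
    warning("tmd_histogram: no TMP groups; fractions undefined",
      call. = FALSE
    )
  }
  out
}

#' Histogram of TMD counts for a whole proteome
#'
#' Reference (proteome-wide) TMD-count distribution against which an
#' identified set can be tested with [chi_square_gof()]. Every protein is its
#' own group.
#'
#' @param proteome Proteome tibble.
#' @param tmds TMD interval tibble.
#' @inheritParams tmd_histogram
#' @return As [tmd_histogram()].
#' @export
proteome_tmd_histogram <- function(proteome, tmds, bins = NULL,
                                   max_single = 10L) {
  groups <- tibble::tibble(
    group_id = proteome$accession,
    accession = proteome$accession
  )
  tmd_histogram(groups, tmds, bins = bins, max_single = max_single)
}

#' Chi-square goodness of fit of an observed TMD histogram
#'
#' Pearson goodness-of-fit test of observed bin counts against expected
#' proportions (taken from a reference histogram's fractions). Bins whose
#' expected count falls below `min_expected` are merged into their left
#' neighbour (right-to-left), and the merges are recorded. Degrees of freedom
#' are the number of compared bins minus one.
#'
#' @param observed Histogram tibble (`bin`, `count`) — e.g. from
#'   [tmd_histogram()].
#' @param expected Histogram tibble with matching `bin`s; its `fraction`
#'   column (or `count` normalized) gives the null proportions.
#' @param min_expected Merge threshold for expected counts (default 5).
#' @return Object of class `tmd_gof`: list with `statistic`, `df`, `p.value`,
#'   `table` (merged bins with observed and expected counts), and
#'   `merged` (character log of bin merges).
#' @export
chi_square_gof <- function(observed, expected, min_expected = 5) {
  stopifnot(is.data.frame(observed), is.data.frame(expected))
  if (!identical(observed$bin, expected$bin)) {
    stop("chi_square_gof: observed and expected must share the same bins",
      call. = FALSE
    )
  }
  obs <- as.numeric(observed$count)
  if (sum(obs) == 0) {
    stop("chi_square_gof: all-zero observed counts", call. = FALSE)
  }
  prop <- if ("fraction" %in% names(expected) &&
                !anyNA(expected$fraction)) {
    expected$fraction
  } else {
    expected$count / sum(expected$count)
  }
  if (any(prop < 0) || abs(sum(prop) - 1) > 1e-6) {
    stop("chi_square_gof: expected proportions must sum to 1", call. = FALSE)
  }
  labels <- observed$bin
  exp_counts <- prop * sum(obs)
  merged <- character()
  # merge right-to-left into the left neighbour until all expected >= min
  while (length(obs) > 1L && any(exp_counts < min_expected)) {
    i <- max(which(exp_counts < min_expected))
    j <- if (i == 1L) 2L else i - 1L
    merged <- c(
      merged,
      paste0("merged bin '", labels[i], "' into '", labels[j], "'")
    )
    obs[j] <- obs[j] + obs[i]
    exp_counts[j] <- exp_counts[j] + exp_counts[i]
    labels[j] <- paste(labels[j], labels[i], sep = "+")
    obs <- obs[-i]
    exp_counts <- exp_counts[-i]
    labels <- labels[-i]
  }
  if (length(obs) < 2L) {
    stop("chi_square_gof: fewer than 2 bins after merging", call. = FALSE)
  }
  statistic <- sum((obs - exp_counts)^2 / exp_counts)
  df <- length(obs) - 1L
  structure(
    list(
      statistic = statistic,
      df = df,
      p.value = stats::pchisq(statistic, df, lower.tail = FALSE),
      table = tibble::tibble(
        bin = labels, observed = obs, expected = exp_counts
      ),
      merged = merged
    ),
    class = "tmd_gof"
  )
}

#' @export
print.tmd_gof <- function(x, ...) {
  cat("Chi-square goodness of fit: X-squared =",
      format(x$statistic, digits = 5),
      ", df =", x$df,
      ", p-value =", format(x$p.value, digits = 4), "\n")
  if (length(x$merged) > 0L) {
    cat("  ", paste(x$merged, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Reproducibility across replicate identification sets
#'
#' Reproducibility of identifications over biological replicates, defined as
#' the size of the intersection of all sets over the size of their union,
#' in percent. Pairwise Jaccard indices and the full Venn region counts are
#' also returned so alternative definitions can be recomputed.
#'
#' @param replicate_sets Named (or unnamed) list of >= 2 character vectors of
#'   identifiers (e.g. protein-group ids per replicate).
#' @return List of class `tmd_reproducibility`: `reproducibility_pct`,
#'   `pairwise` (tibble set_a, set_b, jaccard, overlap), `venn` (tibble
#'   membership pattern -> count), `n_union`, `n_intersection`.
#' @export
replicate_reproducibility <- function(replicate_sets) {
  stopifnot(is.list(replicate_sets), length(replicate_sets) >= 2L)
  sets <- lapply(replicate_sets, function(s) unique(as.character(s)))
  nm <- names(sets) %||% paste0("rep", seq_along(sets))
  nm[nm == ""] <- paste0("rep", which(nm == ""))
  names(sets) <- nm
  universe <- unique(unlist(sets))
  if (length(universe) == 0L) {
    stop("replicate_reproducibility: union of the sets is empty",
      call. = FALSE
    )
  }
  inter <- Reduce(intersect, sets)
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (is.null(dim(membership))) {
    membership <- matrix(membership, nrow = 1L)
  }
  pattern <- apply(membership, 1L, function(r) {
    paste(nm[r], collapse = "&")
  })
  venn <- tibble::as_tibble(table(pattern), .name_repair = "minimal")
  names(venn) <- c("region", "count")
  venn <- dplyr::arrange(venn, .data$region)
  pairs <- utils::combn(seq_along(sets), 2L)
  pairwise <- tibble::tibble(
    set_a = nm[pairs[1L, ]],
    set_b = nm[pairs[2L, ]],
    overlap = apply(pairs, 2L, function(ij) {
      length(intersect(sets[[ij[1L]]], sets[[ij[2L]]]))
    }),
    jaccard = apply(pairs, 2L, function(ij) {
      length(intersect(sets[[ij[1L]]], sets[[ij[2L]]])) /
        length(union(sets[[ij[1L]]], sets[[ij[2L]]]))
    })
  )
  structure(
    list(
      reproducibility_pct = 100 * length(inter) / length(universe),
      pairwise = pairwise,
      venn = venn,
      n_union = length(universe),
      n_intersection = length(inter)
    ),
    class = "tmd_reproducibility"
  )
}

#' @export
print.tmd_reproducibility <- function(x, ...) {
  cat(sprintf(
    "Reproducibility: %.1f%% (%d of %d in all replicates)\n",
    x$reproducibility_pct, x$n_intersection, x$n_union
  ))
  invisible(x)
}

#' Per-bin two-sample t-tests on replicate histogram fractions
#'
#' Compares two methods bin by bin: each method contributes one fraction per
#' replicate per bin, and a two-sided two-sample Student t-test (equal
#' variance by default; Welch selectable) is run per bin. Significance stars:
#' `*` for p <= 0.05, `**` for p <= 0.01. When both groups have zero variance
#' the test is degenerate: p = 1 if the means are equal, p = 0 (flagged)
#' otherwise.
#'
#' @param frac_a,frac_b Numeric matrices (replicates x bins) or data frames
#'   of per-replicate bin fractions; columns are bins, matched by position
#'   (and by name when both are named).
#' @param var_equal Classical Student test (default `TRUE`); `FALSE` = Welch.
#' @return Tibble: `bin`, `mean_a`, `mean_b`, `p.value`, `stars`,
#'   `degenerate`.
#' @export
per_bin_ttest <- function(frac_a, frac_b, var_equal = TRUE) {
  a <- as.matrix(frac_a)
  b <- as.matrix(frac_b)
  if (ncol(a) != ncol(b)) {
    stop("per_bin_ttest: methods must share the same bins", call. = FALSE)
  }
  if (nrow(a) < 2L || nrow(b) < 2L) {
    stop("per_bin_ttest: need >= 2 replicates per method", call. = FALSE)
  }
  bins <- colnames(a) %||% as.character(seq_len(ncol(a)))
  res <- purrr::map(seq_len(ncol(a)), function(j) {
    x <- a[, j]
    y <- b[, j]
    degenerate <- FALSE
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (isTRUE(all.equal(mean(x), mean(y)))) {
        p <- 1
      } else {
        p <- 0
        degenerate <- TRUE
      }
    } else {
      p <- stats::t.test(x, y, var.equal = var_equal)$p.value
    }
    tibble::tibble(
      bin = bins[j], mean_a = mean(x), mean_b = mean(y),
      p.value = p, degenerate = degenerate
    )
  })
  dplyr::bind_rows(res) |>
    dplyr::mutate(
      stars = dplyr::case_when(
        .data$p.value <= 0.01 ~ "**",
        .data$p.value <= 0.05 ~ "*",
        TRUE ~ ""
      ),
      .before = "degenerate"
    )
}

#' Binomial enrichment of functional categories between two methods
#'
#' For each functional category, an exact two-sided binomial test of the
#' category's count in method A (out of A's total) against the pooled null
#' proportion `(count_A + count_B) / (n_A + n_B)`, with Benjamini-Hochberg
#' adjustment across categories. Raw p-values are retained alongside.
#'
#' @param counts Tibble with columns `category`, `count_a`, `count_b`.
#' @param n_a,n_b Method totals; default the column sums.
#' @return Tibble: `category`, `count_a`, `count_b`, `prop_a`, `prop_b`,
#'   `null_prop`, `direction` (+1 enriched in A, -1 depleted, 0 equal),
#'   `p.value`, `q.value`, sorted by `p.value`.
#' @export
binomial_enrichment <- function(counts, n_a = NULL, n_b = NULL) {
  stopifnot(is.data.frame(counts),
            all(c("category", "count_a", "count_b") %in% names(counts)))
  counts <- dplyr::filter(counts, .data$count_a + .data$count_b > 0)
  n_a <- n_a %||% sum(counts$count_a)
  n_b <- n_b %||% sum(counts$count_b)
  if (n_a <= 0 || n_b <= 0) {
    stop("binomial_enrichment: totals must be positive", call. = FALSE)
  }
  res <- counts |>
    dplyr::mutate(
      prop_a = .data$count_a / n_a,
      prop_b = .data$count_b / n_b,
      null_prop = (.data$count_a + .data$count_b) / (n_a + n_b),
      direction = sign(.data$prop_a - .data$prop_b),
      p.value = purrr::map2_dbl(
        .data$count_a, .data$null_prop,
        ~ stats::binom.test(.x, n_a, p = .y,
                            alternative = "two.sided")$p.value
      )
    )
  res$q.value <- stats::p.adjust(res$p.value, method = "BH")
  dplyr::arrange(res, .data$p.value, .data$category)
}
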