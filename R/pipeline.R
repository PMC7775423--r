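#' Run the full demonstration pipeline
#'
#' One-command end-to-end run on synthetic data: simulate a proteome with
#' planted TMDs and per-method detected-peptide tables, write them to disk,
#' read them back through the standard parsers, map peptides per method,
#' score GRAVY, and run the full method comparison. Every output is
#' deterministic for a fixed seed (no timestamps), so two runs with the same
#' seed produce byte-identical trees.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed driving all randomness.
#' @param config A [sim_config()].
#' @return Invisibly, the `method_comparison` object.
#' @export
run_demo <- function(out_dir, seed = 7L, config = sim_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_dir <- file.path(out_dir, "simulated")
  simulate_dataset(sim_dir, config = config, seed = seed)

  proteome <- read_fasta(file.path(sim_dir, "proteome.fasta"))
  tmds <- parse_tmhmm(file.path(sim_dir, "tmhmm_truth.txt"))
  validate_tmds(tmds, proteome)
  pep_files <- sort(list.files(sim_dir,
    pattern = "^peptides_.*\\.tsv$", full.names = TRUE
  ))
  peptides <- dplyr::bind_rows(purrr::map(pep_files, read_peptide_table))

  cmp <- compare_methods(peptides, proteome, tmds)

  gr <- gravy_table(proteome)
  write_result_tsv(gr, file.path(out_dir, "gravy.tsv"))
  write_result_tsv(cmp$summary, file.path(out_dir, "method_summary.tsv"),
    sort_by = "method"
  )
  hist_tbl <- purrr::imap(cmp$histograms, function(h, m) {
    dplyr::mutate(tibble::as_tibble(h), method = m, .before = 1L)
  }) |>
    dplyr::bind_rows()
  write_result_tsv(hist_tbl, file.path(out_dir, "histogram.tsv"),
    sort_by = "method"
  )
  for (m in names(cmp$maps)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", m)
    write_result_tsv(
      cmp$maps[[m]]$hits,
      file.path(out_dir, sprintf("hits_%s.tsv", safe))
    )
    write_coverage_bed(
      cmp$maps[[m]],
      file.path(out_dir, sprintf("coverage_%s.bed", safe))
    )
  }
  if (!is.null(cmp$ttest)) {
    write_result_tsv(cmp$ttest, file.path(out_dir, "ttest.tsv"),
      sort_by = character()
    )
  }
  gof_lines <- purrr::imap_chr(cmp$gof, function(g, m) {
    if (is.null(g)) {
      return(paste0(m, "\tnot testable (too few bins)"))
    }
    sprintf(
      "%s\tstatistic=%.6g\tdf=%d\tp=%.6g%s",
      m, g$statistic, g$df, g$p.value,
      if (length(g$merged) > 0L) {
        paste0("\t", paste(g$merged, collapse = "; "))
      } else {
        ""
      }
    )
  })
  writeLines(unname(gof_lines), file.path(out_dir, "chisq.txt"))
  repro_tbl <- purrr::imap(cmp$reproducibility, function(r, m) {
    if (is.null(r)) {
      return(NULL)
    }
    tibble::tibble(
      method = m,
      reproducibility_pct = r$reproducibility_pct,
      n_intersection = r$n_intersection,
      n_union = r$n_union
    )
  }) |>
    dplyr::bind_rows()
  write_result_tsv(repro_tbl, file.path(out_dir, "reproducibility.tsv"),
    sort_by = "method"
  )
  if (!is.null(cmp$enrichment)) {
    write_result_tsv(cmp$enrichment, file.path(out_dir, "enrichment.tsv"),
      sort_by = "category"
    )
  }
  writeLines(
    c(
      paste0("tool=tmdcover ", as.character(utils::packageVersion("tmdcover"))),
      paste0("seed=", seed),
      paste0("n_proteins=", config$n_proteins),
      paste0("tmp_fraction=", config$tmp_fraction),
      paste0("replicates=", config$replicates),
      paste0("max_missed=", config$max_missed),
      paste0("methods=", paste(names(config$methods), collapse = ","))
    ),
    file.path(out_dir, "run_config.txt")
  )
  invisible(cmp)
}
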