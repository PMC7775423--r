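# a small configuration keeps the generator tests fast
small_config <- function(...) {
  sim_config(n_proteins = 60L, ...)
}

test_that("the generator is deterministic for a fixed seed", {
  g1 <- generate_proteome(small_config(), seed = 7L)
  g2 <- generate_proteome(small_config(), seed = 7L)
  expect_identical(g1, g2)
  d1 <- simulate_detection(g1$proteome, g1$tmds, small_config(),
                           "FA-CTLC", seed = 7L)
  d2 <- simulate_detection(g2$proteome, g2$tmds, small_config(),
                           "FA-CTLC", seed = 7L)
  expect_identical(d1, d2)
})

test_that("planted TMDs are valid intervals with hydrophobic content", {
  g <- generate_proteome(small_config(), seed = 3L)
  expect_invisible(validate_tmds(g$tmds, g$proteome))
  # TMD stretches score high on hydropathy, loops low
  tm_seq <- substring(
    g$proteome$sequence[match(g$tmds$accession, g$proteome$accession)],
    g$tmds$start, g$tmds$end
  )
  expect_true(all(gravy(tm_seq) > 1))
  soluble <- g$proteome$sequence[!g$proteome$is_tmp]
  expect_true(all(gravy(soluble) < 0))
})

test_that("tmp_fraction zero yields no ground-truth intervals", {
  g <- generate_proteome(small_config(tmp_fraction = 0), seed = 1L)
  expect_equal(nrow(g$tmds), 0L)
  expect_false(any(g$proteome$is_tmp))
})

test_that("the realized TMP fraction matches the configured rate", {
  # binomial sampling: the mean realized fraction over many seeds should sit
  # within 3 standard errors of 0.23
  cfg <- small_config()
  fracs <- vapply(1:50, function(s) {
    mean(generate_proteome(cfg, seed = s)$proteome$is_tmp)
  }, numeric(1))
  se <- sqrt(0.23 * 0.77 / (50 * cfg$n_proteins))
  expect_lt(abs(mean(fracs) - 0.23), 3 * se)
})

test_that("about half of TMPs carry a single TMD", {
  cfg <- small_config()
  one_tmd <- vapply(1:30, function(s) {
    g <- generate_proteome(cfg, seed = s)
    counts <- table(g$tmds$accession)
    c(sum(counts == 1L), length(counts))
  }, numeric(2))
  frac1 <- sum(one_tmd[1L, ]) / sum(one_tmd[2L, ])
  expect_lt(abs(frac1 - 0.5), 0.07)
})

test_that("detection probabilities bound the detected peptide set", {
  cfg0 <- small_config(methods = list(
    none = list(chemistry = "trypsin_lysc",
                p_detect_loop = 0, p_detect_tmd = 0),
    all = list(chemistry = "trypsin_lysc",
               p_detect_loop = 1, p_detect_tmd = 1)
  ))
  g <- generate_proteome(cfg0, seed = 5L)
  none <- simulate_detection(g$proteome, g$tmds, cfg0, "none", seed = 5L)
  expect_equal(nrow(none), 0L)
  all_det <- simulate_detection(g$proteome, g$tmds, cfg0, "all", seed = 5L)
  digest <- cleave(g$proteome, rule_trypsin_lysc())
  in_range <- digest[nchar(digest$sequence) >= cfg0$min_peptide_length &
                       nchar(digest$sequence) <= cfg0$max_peptide_length, ]
  per_rep <- all_det[all_det$replicate == "rep1", ]
  expect_equal(nrow(per_rep), nrow(in_range))
  expect_setequal(per_rep$sequence, in_range$sequence)

  expect_error(
    simulate_detection(g$proteome, g$tmds, cfg0, "nope", seed = 1L),
    "unknown method"
  )
})

test_that("every simulated peptide is locatable at its recorded position", {
  cfg <- small_config()
  g <- generate_proteome(cfg, seed = 9L)
  det <- simulate_detection(g$proteome, g$tmds, cfg, "FA-CTLC", seed = 9L)
  det <- det[!duplicated(det[, c("sequence", "accession", "start")]), ]
  for (i in seq_len(nrow(det))) {
    prot_seq <- g$proteome$sequence[g$proteome$accession == det$accession[i]]
    hits <- locate_peptide(normalize_homoserine(det$peptide[i]), prot_seq)
    expect_true(det$start[i] %in% hits)
  }
})

test_that("adding replicates never perturbs earlier replicate draws", {
  cfg3 <- small_config(replicates = 3L)
  cfg5 <- small_config(replicates = 5L)
  g <- generate_proteome(cfg3, seed = 11L)
  d3 <- simulate_detection(g$proteome, g$tmds, cfg3, "UR-TLC", seed = 11L)
  d5 <- simulate_detection(g$proteome, g$tmds, cfg5, "UR-TLC", seed = 11L)
  expect_identical(d3, d5[d5$replicate %in% paste0("rep", 1:3), ])
})

test_that("simulated datasets on disk are byte-identical across runs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(d1, small_config(), seed = 7L)
  simulate_dataset(d2, small_config(), seed = 7L)
  files <- list.files(d1)
  expect_true(length(files) >= 8L) # fasta + truth + 2 methods x 3 reps
  expect_equal(sort(files), sort(list.files(d2)))
  for (f in files) {
    expect_identical(
      readLines(file.path(d1, f)),
      readLines(file.path(d2, f))
    )
  }
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(tmp_fraction = 1.5))
  expect_error(sim_config(min_peptide_length = 50L,
                          max_peptide_length = 45L))
  expect_error(
    sim_config(methods = list(x = list(
      chemistry = "unknown", p_detect_loop = 0.1, p_detect_tmd = 0.1
    )))
  )
})
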