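test_that("locate_peptide finds all occurrences, including overlapping", {
  expect_equal(locate_peptide("PEP", "AAPEPAA"), 3L)
  expect_equal(locate_peptide("AA", "AAAA"), c(1L, 2L, 3L))
  expect_equal(locate_peptide("ZZ", "AAAA"), integer())
  expect_equal(
    locate_peptide("GIK", "GGLKGIK", il_equivalent = TRUE),
    c(2L, 5L)
  )
  expect_equal(locate_peptide("GIK", "GGLKGIK"), 5L)
})

test_that("the proteome-wide locator agrees with locate_peptide", {
  set.seed(21)
  prot <- tibble::tibble(
    accession = sprintf("P%02d", 1:12),
    sequence = vapply(1:12, function(i) random_protein(sample(30:120, 1L)),
                      character(1))
  )
  peps <- c(
    substr(prot$sequence[1L], 5L, 12L),
    substr(prot$sequence[7L], 1L, 9L),
    "AA", "WWWWWW"
  )
  got <- tmdcover:::locate_peptides_proteome(peps, prot)
  for (p in peps) {
    for (i in seq_len(nrow(prot))) {
      starts <- locate_peptide(p, prot$sequence[i])
      have <- got$start[got$peptide == p & got$accession == prot$accession[i]]
      expect_equal(sort(have), starts)
    }
  }
})

test_that("hit classification covers the rule-1 and rule-2 cases", {
  expect_equal(classify_tmd_hit(8, 35, 10, 30), "CONTAINS")
  expect_equal(classify_tmd_hit(12, 20, 10, 30), "WITHIN")
  expect_equal(classify_tmd_hit(5, 11, 10, 30), "N_PARTIAL")
  expect_equal(classify_tmd_hit(5, 10, 10, 30), NA_character_)
  expect_equal(classify_tmd_hit(29, 40, 10, 30), "C_PARTIAL")
  # identical spans resolve to CONTAINS, never both rule-1 categories
  expect_equal(classify_tmd_hit(10, 30, 10, 30), "CONTAINS")
  expect_error(classify_tmd_hit(5, 4, 10, 30), "invalid span")
})

test_that("lowering the partial-overlap minimum never loses hits", {
  set.seed(13)
  for (i in 1:200) {
    p <- sort(sample(1:60, 2L))
    t <- sort(sample(1:60, 2L))
    at2 <- classify_tmd_hit(p[1L], p[2L], t[1L], t[2L], 2L)
    at1 <- classify_tmd_hit(p[1L], p[2L], t[1L], t[2L], 1L)
    if (!is.na(at2)) {
      expect_false(is.na(at1))
    }
  }
})

test_that("map_peptides evaluates every occurrence x TMD pair", {
  prot <- toy_proteome()
  tmds <- toy_tmds()
  # peptide inside P1's only TMD
  inside <- substr(prot$sequence[1L], 13L, 22L)
  m <- map_peptides(inside, prot, tmds)
  expect_equal(nrow(m$hits), 1L)
  expect_equal(m$hits$category, "WITHIN")
  expect_equal(count_unique_tmds(m), 1L)

  # a peptide occurring twice in one protein, once in each TMD, yields one
  # hit per occurrence; verified against brute force over occurrence x TMD
  motif <- "WAVLIFLV"
  prot2 <- tibble::tibble(
    accession = "R1",
    description = "repeated TMD motif",
    sequence = paste0(
      "DDKEGSRQNT", motif, "GGSRDDEEKN", motif, "TTSSGGKRDD"
    )
  )
  tmds2 <- tibble::tibble(
    accession = "R1", start = c(11L, 29L), end = c(18L, 36L),
    ordinal = c(1L, 2L)
  )
  m2 <- map_peptides(motif, prot2, tmds2)
  brute <- 0L
  for (s in locate_peptide(motif, prot2$sequence)) {
    for (j in seq_len(nrow(tmds2))) {
      cat_ <- oracle_classify(s, s + nchar(motif) - 1L,
                              tmds2$start[j], tmds2$end[j])
      if (!is.na(cat_)) brute <- brute + 1L
    }
  }
  expect_equal(brute, 2L)
  expect_equal(nrow(m2$hits), brute)
  expect_equal(count_unique_tmds(m2), 2L)

  # orphan peptide: no occurrence anywhere
  expect_message(m3 <- map_peptides("WWWWHHHH", prot, tmds), "orphan")
  expect_equal(nrow(m3$hits), 0L)
  expect_equal(m3$orphans, "WWWWHHHH")
})

test_that("mapping output is independent of peptide input order", {
  prot <- toy_proteome()
  tmds <- toy_tmds()
  peps <- c(
    substr(prot$sequence[1L], 13L, 22L),
    substr(prot$sequence[2L], 1L, 10L),
    substr(prot$sequence[3L], 5L, 16L)
  )
  a <- map_peptides(peps, prot, tmds)
  b <- map_peptides(rev(peps), prot, tmds)
  expect_equal(a$hits, b$hits)
  expect_equal(a$matches, b$matches)
})

test_that("homoserine-annotated peptides match their database substring", {
  prot <- tibble::tibble(accession = "P1", sequence = "AADEMGGKTTR")
  tmds <- tibble::tibble(accession = "P1", start = 3L, end = 8L,
                         ordinal = 1L)
  m <- map_peptides("AADEM(Hse)", prot, tmds)
  expect_equal(m$matches$start, 1L)
  expect_equal(nrow(m$hits), 1L)
  expect_equal(m$hits$category, "N_PARTIAL")
})

test_that("unique-TMD counting collapses repeated hits on one TMD", {
  hits <- tibble::tibble(
    peptide = c("A", "B", "C"),
    accession = c("P1", "P1", "P1"),
    tmd_ordinal = c(1L, 1L, 2L)
  )
  expect_equal(count_unique_tmds(hits), 2L)
  expect_equal(count_peptide_tmd_pairs(hits), 3L)
  expect_equal(count_unique_tmds(hits[0, ]), 0L)
})

test_that("protein grouping merges identical peptide sets and partitions", {
  matches <- tibble::tibble(
    peptide = c("pepA", "pepB", "pepA", "pepB", "pepA", "pepB", "pepC"),
    accession = c("P1", "P1", "P2", "P2", "P3", "P3", "P3")
  )
  g <- group_proteins(matches)
  expect_equal(g$group_id[g$accession %in% c("P1", "P2")], c("P1", "P1"))
  expect_equal(g$group_id[g$accession == "P3"], "P3")
  # partition: every protein appears exactly once
  expect_equal(sort(g$accession), c("P1", "P2", "P3"))
  # idempotence: regrouping the group representatives changes nothing
  again <- group_proteins(matches)
  expect_equal(g, again)
})

test_that("unique_only drops peptides shared between proteins", {
  prot <- tibble::tibble(
    accession = c("P1", "P2"),
    sequence = c("AASHAREDKAA", "GGSHAREDKGG")
  )
  tmds <- tibble::tibble(accession = character(), start = integer(),
                         end = integer(), ordinal = integer())
  shared <- "SHAREDK"
  m_all <- map_peptides(shared, prot, tmds)
  expect_equal(nrow(m_all$matches), 2L)
  m_uni <- map_peptides(shared, prot, tmds, unique_only = TRUE)
  expect_equal(nrow(m_uni$matches), 0L)
})

test_that("tidy and glance summarize a mapping", {
  m <- map_peptides(
    substr(toy_proteome()$sequence[1L], 13L, 22L),
    toy_proteome(), toy_tmds()
  )
  expect_equal(tidy(m), m$hits)
  gl <- glance(m)
  expect_equal(gl$n_hits, 1L)
  expect_equal(gl$unique_tmds, 1L)
  expect_equal(gl$n_proteome, 3L)
})

test_that("coverage export writes BED-style half-open coordinates", {
  m <- map_peptides(
    substr(toy_proteome()$sequence[1L], 13L, 22L),
    toy_proteome(), toy_tmds()
  )
  f <- withr::local_tempfile(fileext = ".bed")
  write_coverage_bed(m, f)
  lines <- readLines(f)
  expect_match(lines[1L], "0-based half-open")
  expect_equal(lines[2L], "P1\t12\t22")
})
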