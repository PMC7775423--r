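# Residue composition tables for the generator, fixed so hydropathy-based
# behaviour is stable: loops are rich in charged/polar residues plus enough
# K/R that tryptic peptides fall in the detectable length range; TMDs are
# rich in hydrophobic residues with some Met so CNBr can cut inside them.
LOOP_COMPOSITION <- c(
  D = 0.09, E = 0.10, K = 0.09, R = 0.07, S = 0.10, G = 0.10,
  N = 0.06, Q = 0.06, T = 0.07, P = 0.07, A = 0.09, H = 0.03,
  Y = 0.03, W = 0.01, C = 0.01, M = 0.02
)
TMD_COMPOSITION <- c(
  I = 0.17, L = 0.25, V = 0.15, F = 0.12, A = 0.13, M = 0.06,
  G = 0.06, W = 0.03, T = 0.02, S = 0.01
)

#' Simulation configuration
#'
#' Parameters of the synthetic proteome and of the per-method peptide
#' detection model. Defaults emulate a plant membrane proteome at desk scale:
#' 23% of proteins are transmembrane (TMP), about half of TMPs carry a single
#' TMD (geometric-like count distribution over 1..30), TMDs are 18-25
#' residues, loops exponential with mean 60 residues. The detection model is
#' per-peptide Bernoulli: a candidate peptide overlapping a true TMD by >= 2
#' residues is detected with `p_detect_tmd`, any other with `p_detect_loop`.
#' The urea workflow (`UR-TLC`, trypsin/Lys-C only) barely accesses TMD
#' peptides (0.02); the formic-acid/CNBr workflow (`FA-CTLC`) cleaves inside
#' TMDs and detects them at 0.20. Loop peptides are equally detectable (0.30)
#' under both.
#'
#' @param n_proteins Number of proteins (default 1000).
#' @param tmp_fraction Probability a protein is a TMP (default 0.23).
#' @param tmd_count_probs Probabilities over TMD counts 1..30 (default
#'   geometric with ~0.5 mass at 1, truncated and renormalized).
#' @param tmd_length_range Inclusive TMD length range (default 18:25).
#' @param loop_length_mean Mean loop length, exponential (default 60).
#' @param soluble_length_meanlog,soluble_length_sdlog Lognormal parameters
#'   for non-TMP protein length (default median 300).
#' @param methods Named list of per-method models, each with `chemistry`
#'   (`"trypsin_lysc"` or `"cnbr_trypsin_lysc"`), `p_detect_loop`,
#'   `p_detect_tmd`.
#' @param min_peptide_length,max_peptide_length Detectable length bounds
#'   (default 6 and 45).
#' @param replicates Biological replicates per method (default 3).
#' @param max_missed Missed cleavages in the candidate digest (default 0).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 1000L,
                       tmp_fraction = 0.23,
                       tmd_count_probs = NULL,
                       tmd_length_range = c(18L, 25L),
                       loop_length_mean = 60,
                       soluble_length_meanlog = log(300),
                       soluble_length_sdlog = 0.4,
                       methods = list(
                         `UR-TLC` = list(
                           chemistry = "trypsin_lysc",
                           p_detect_loop = 0.30, p_detect_tmd = 0.02
                         ),
                         `FA-CTLC` = list(
                           chemistry = "cnbr_trypsin_lysc",
                           p_detect_loop = 0.30, p_detect_tmd = 0.20
                         )
                       ),
                       min_peptide_length = 6L,
                       max_peptide_length = 45L,
                       replicates = 3L,
                       max_missed = 0L) {
  if (is.null(tmd_count_probs)) {
    p <- 0.5^seq_len(30L)
    tmd_count_probs <- p / sum(p)
  }
  stopifnot(
    n_proteins >= 1L,
    tmp_fraction >= 0, tmp_fraction <= 1,
    abs(sum(tmd_count_probs) - 1) < 1e-9,
    all(tmd_count_probs >= 0),
    length(tmd_length_range) == 2L,
    tmd_length_range[1L] <= tmd_length_range[2L],
    loop_length_mean > 0,
    min_peptide_length >= 1L,
    min_peptide_length < max_peptide_length,
    replicates >= 1L, max_missed >= 0L
  )
  for (m in methods) {
    stopifnot(
      m$chemistry %in% c("trypsin_lysc", "cnbr_trypsin_lysc"),
      m$p_detect_loop >= 0, m$p_detect_loop <= 1,
      m$p_detect_tmd >= 0, m$p_detect_tmd <= 1
    )
  }
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      tmp_fraction = tmp_fraction,
      tmd_count_probs = tmd_count_probs,
      tmd_length_range = as.integer(tmd_length_range),
      loop_length_mean = loop_length_mean,
      soluble_length_meanlog = soluble_length_meanlog,
      soluble_length_sdlog = soluble_length_sdlog,
      methods = methods,
      min_peptide_length = as.integer(min_peptide_length),
      max_peptide_length = as.integer(max_peptide_length),
      replicates = as.integer(replicates),
      max_missed = as.integer(max_missed)
    ),
    class = "sim_config"
  )
}

sample_residues <- function(n, composition) {
  paste(
    sample(names(composition), n, replace = TRUE, prob = composition),
    collapse = ""
  )
}

sample_loop_length <- function(mean) {
  max(4L, as.integer(round(stats::rexp(1L, rate = 1 / mean))))
}

#' Generate a synthetic proteome with planted TMD architectures
#'
#' TMPs are built as alternating hydrophilic loops and hydrophobic TMDs, so
#' GRAVY and the hydropathy-window surrogate predictor behave sensibly on
#' them; non-TMPs are a single loop-composition stretch. The planted TMD
#' coordinates are returned as ground truth in the same shape as
#' [parse_tmhmm()] output. Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `proteome` (tibble: accession, description, sequence,
#'   is_tmp) and `tmds` (tibble: accession, start, end, ordinal).
#' @export
generate_proteome <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  n <- config$n_proteins
  acc <- sprintf("SYN%04d", seq_len(n))
  is_tmp <- stats::runif(n) < config$tmp_fraction
  records <- vector("list", n)
  tmd_list <- vector("list", n)
  for (i in seq_len(n)) {
    if (is_tmp[i]) {
      k <- sample(seq_along(config$tmd_count_probs), 1L,
                  prob = config$tmd_count_probs)
      parts <- character(2L * k + 1L)
      starts <- integer(k)
      ends <- integer(k)
      pos <- 0L
      for (j in seq_len(k)) {
        loop_len <- sample_loop_length(config$loop_length_mean)
        parts[2L * j - 1L] <- sample_residues(loop_len, LOOP_COMPOSITION)
        pos <- pos + loop_len
        tmd_len <- sample(
          config$tmd_length_range[1L]:config$tmd_length_range[2L], 1L
        )
        parts[2L * j] <- sample_residues(tmd_len, TMD_COMPOSITION)
        starts[j] <- pos + 1L
        ends[j] <- pos + tmd_len
        pos <- pos + tmd_len
      }
      parts[2L * k + 1L] <- sample_residues(
        sample_loop_length(config$loop_length_mean), LOOP_COMPOSITION
      )
      records[[i]] <- paste(parts, collapse = "")
      tmd_list[[i]] <- tibble::tibble(
        accession = acc[i], start = starts, end = ends,
        ordinal = seq_len(k)
      )
    } else {
      len <- max(
        30L,
        as.integer(round(stats::rlnorm(
          1L, config$soluble_length_meanlog, config$soluble_length_sdlog
        )))
      )
      records[[i]] <- sample_residues(len, LOOP_COMPOSITION)
    }
  }
  proteome <- tibble::tibble(
    accession = acc,
    description = ifelse(is_tmp, "synthetic transmembrane protein",
                         "synthetic soluble protein"),
    sequence = unlist(records),
    is_tmp = is_tmp
  )
  tmds <- dplyr::bind_rows(tmd_list)
  if (nrow(tmds) == 0L) {
    tmds <- tibble::tibble(
      accession = character(), start = integer(), end = integer(),
      ordinal = integer()
    )
  }
  list(proteome = proteome, tmds = tmds)
}

chemistry_rules <- function(chemistry) {
  switch(chemistry,
    trypsin_lysc = list(rule_trypsin_lysc()),
    cnbr_trypsin_lysc = list(rule_cnbr(), rule_trypsin_lysc()),
    stop("unknown chemistry: ", chemistry, call. = FALSE)
  )
}

# Deterministic sub-seed per (method index, replicate): adding replicates or
# methods never perturbs earlier ones. Kept below 2^31.
derive_subseed <- function(seed, method_index, replicate) {
  (as.double(seed) * 2654435.0 +
     method_index * 97561.0 + replicate * 1013.0) %% 2147483647
}

#' Simulate per-replicate detected-peptide tables
#'
#' Digests each protein with the method's chemistry (trypsin/Lys-C, or CNBr
#' followed by trypsin/Lys-C), keeps candidate fragments within the
#' detectable length bounds, and detects each candidate independently per
#' replicate: with `p_detect_tmd` if it overlaps any true TMD of its protein
#' by at least 2 residues, else with `p_detect_loop`. Peptides whose
#' C-terminal residue was converted by CNBr are written with the
#' corresponding `(Hse)` annotation, as a search engine would report them.
#'
#' @param proteome Proteome tibble (from [generate_proteome()]).
#' @param tmds Ground-truth TMD tibble.
#' @param config A [sim_config()].
#' @param method Method label; must name an entry of `config$methods`.
#' @param seed Master seed; replicate sub-seeds are derived deterministically.
#' @return Tibble of detected peptides: `peptide` (annotated), `sequence`
#'   (database space), `accession`, `start`, `end`, `is_tmd_peptide`,
#'   `replicate`, `method`.
#' @export
simulate_detection <- function(proteome, tmds, config = sim_config(),
                               method = names(config$methods)[1L],
                               seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  model <- config$methods[[method]]
  if (is.null(model)) {
    stop("simulate_detection: unknown method label '", method, "'",
      call. = FALSE
    )
  }
  method_index <- match(method, names(config$methods))
  rules <- chemistry_rules(model$chemistry)
  frags <- sequential_digest(proteome, rules,
    max_missed_per_stage = config$max_missed
  )
  frags <- dplyr::filter(
    frags,
    nchar(.data$sequence) >= config$min_peptide_length,
    nchar(.data$sequence) <= config$max_peptide_length
  )
  # >= 2-residue overlap with any true TMD of the same protein
  if (nrow(tmds) > 0L && nrow(frags) > 0L) {
    ov <- dplyr::inner_join(
      frags[, c("accession", "start", "end")] |>
        dplyr::mutate(.frag = dplyr::row_number()),
      tmds,
      by = "accession", suffix = c("", "_tmd"),
      relationship = "many-to-many"
    ) |>
      dplyr::filter(
        pmin(.data$end, .data$end_tmd) -
          pmax(.data$start, .data$start_tmd) + 1L >= 2L
      )
    frags$is_tmd_peptide <- seq_len(nrow(frags)) %in% ov$.frag
  } else {
    frags$is_tmd_peptide <- FALSE
  }
  p_detect <- ifelse(frags$is_tmd_peptide, model$p_detect_tmd,
                     model$p_detect_loop)
  out <- purrr::map(seq_len(config$replicates), function(r) {
    set.seed(derive_subseed(seed, method_index, r))
    keep <- stats::runif(nrow(frags)) < p_detect
    d <- frags[keep, ]
    annotated <- ifelse(
      !is.na(d$terminal_conversion),
      paste0(d$sequence, "(", d$terminal_conversion, ")"),
      d$sequence
    )
    tibble::tibble(
      peptide = annotated,
      sequence = d$sequence,
      accession = d$accession,
      start = d$start,
      end = d$end,
      is_tmd_peptide = d$is_tmd_peptide,
      replicate = paste0("rep", r),
      method = method
    )
  })
  dplyr::bind_rows(out)
}

#' Write a simulated dataset to disk
#'
#' Emits `proteome.fasta`, `tmhmm_truth.txt` (TMHMM long dialect), and one
#' `peptides_<method>_rep<k>.tsv` per method and replicate, matching the
#' schema [read_peptide_table()] expects. All outputs are deterministic for
#' a fixed seed.
#'
#' @param out_dir Output directory (created if absent).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Invisibly, the list from [generate_proteome()] plus `detections`.
#' @export
simulate_dataset <- function(out_dir, config = sim_config(), seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_proteome(config, seed = seed)
  write_fasta(gen$proteome, file.path(out_dir, "proteome.fasta"))
  write_tmhmm_long(gen$tmds, file.path(out_dir, "tmhmm_truth.txt"))
  detections <- purrr::map(names(config$methods), function(m) {
    det <- simulate_detection(gen$proteome, gen$tmds, config,
      method = m, seed = seed
    )
    for (r in unique(det$replicate)) {
      d <- det[det$replicate == r, ]
      tab <- tibble::tibble(
        peptide = d$peptide,
        replicate = d$replicate,
        method = d$method,
        proteins = d$accession
      )
      safe <- gsub("[^A-Za-z0-9]+", "_", m)
      write_result_tsv(
        tab, file.path(out_dir, sprintf("peptides_%s_%s.tsv", safe, r)),
        sort_by = c("proteins", "peptide")
      )
    }
    det
  })
  invisible(c(gen, list(detections = dplyr::bind_rows(detections))))
}
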