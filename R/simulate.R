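#' Designated optimal and primary non-optimal codons for simulation
#'
#' Ground-truth codon designations used by the generator: per degenerate
#' amino acid the optimal codon is a C-ending codon where one exists
#' (otherwise G-ending), mirroring the G3/C3 optimal codons of fly
#' genomes, and the designated primary non-optimal codon is an A-ending
#' sister codon where one exists (otherwise T-ending), mirroring the
#' A3/T3/G3 endings of preferred non-optimal codons.
#'
#' @return Tibble with columns `aa`, `optimal`, `primary_nonopt`.
#' @export
designate_codons <- function() {
  tab <- codon_table() |> dplyr::filter(.data$degenerate)
  tab |>
    dplyr::group_by(.data$aa) |>
    dplyr::summarise(
      optimal = pick_by_ending(.data$codon, c("C", "G")),
      .groups = "drop"
    ) |>
    dplyr::left_join(tab, by = "aa", relationship = "one-to-many") |>
    dplyr::filter(.data$codon != .data$optimal) |>
    dplyr::group_by(.data$aa, .data$optimal) |>
    dplyr::summarise(
      primary_nonopt = pick_by_ending(.data$codon, c("A", "T", "G")),
      .groups = "drop"
    )
}

pick_by_ending <- function(codons, endings) {
  for (e in endings) {
    hit <- codons[stringr::str_sub(codons, 3L, 3L) == e]
    if (length(hit) > 0) return(sort(hit)[1L])
  }
  sort(codons)[1L]
}

#' Configuration for the synthetic codon-usage study
#'
#' Defaults emulate the study conditions: 916 testis-biased, 258
#' ovary-biased and 605 unbiased genes with log-normal CDS lengths of
#' median 273, 498 and 269 codons; a ribosomal-protein-like reference set
#' and a genome background; a 59-tissue expression matrix whose
#' specificity regimes give testis-biased genes tau near 0.95,
#' ovary-biased near 0.83 and unbiased near 0.74; per-codon tRNA gene
#' counts with optimal codons either tRNA-rich or wobble (zero
#' exact-match); and residue-level structure tables in which RSA depends
#' on secondary-structure class and is raised by `mu_shift` for residues
#' encoded by the designated primary non-optimal codon.
#'
#' @param n_genes Named vector of gene-set sizes.
#' @param median_len Named vector of median CDS lengths (codons).
#' @param sdlog_len Log-scale SD of CDS length.
#' @param opt_shift Named preference mass moved onto the designated
#'   optimal codon per set.
#' @param nonopt_shift Named preference mass moved onto the designated
#'   primary non-optimal codon per set (`delta`; the testis-set default
#'   0.15 produces the detectable preference regime).
#' @param dirichlet_conc Concentration of the per-gene Dirichlet draw
#'   around the set preference vector (smaller = more between-gene
#'   variation).
#' @param n_tissues Number of tissues/stages in the expression matrix.
#' @param mu_shift Additive RSA offset for residues encoded by the
#'   designated primary non-optimal codon.
#' @param disorder_sd SD of the Gaussian noise linking disorder to RSA.
#' @param ss_block_mean Mean secondary-structure block lengths.
#' @param ss_weights Block-type weights (chosen so residue fractions land
#'   near coil 0.6, helix 0.3, strand 0.1).
#' @param rsa_mean Per-class RSA Beta means.
#' @param rsa_conc Beta concentration (shape1 + shape2).
#' @param structure_sets Gene sets for which residue tables are emitted.
#' @return A `sim_config` list.
#' @export
sim_config <- function(
    n_genes = c(testis = 916, ovary = 258, unbiased = 605,
                ribosomal = 90, background = 1000),
    median_len = c(testis = 273, ovary = 498, unbiased = 269,
                   ribosomal = 170, background = 350),
    sdlog_len = 0.45,
    opt_shift = c(testis = 0, ovary = 0.05, unbiased = 0.10,
                  ribosomal = 0.50, background = 0),
    nonopt_shift = c(testis = 0.15, ovary = 0, unbiased = 0,
                     ribosomal = 0, background = 0),
    dirichlet_conc = 40,
    n_tissues = 59,
    mu_shift = 0.10,
    disorder_sd = 0.2,
    ss_block_mean = c(coil = 8, helix = 10, strand = 5),
    ss_weights = c(coil = 0.60, helix = 0.24, strand = 0.16),
    rsa_mean = c(coil = 0.53, helix = 0.34, strand = 0.13),
    rsa_conc = 8,
    structure_sets = c("testis", "ovary", "unbiased")) {
  sets <- c("testis", "ovary", "unbiased", "ribosomal", "background")
  stopifnot(all(sets %in% names(n_genes)), all(sets %in% names(median_len)),
            all(nonopt_shift >= 0), all(opt_shift >= 0),
            all(opt_shift + nonopt_shift <= 1))
  structure(
    list(n_genes = n_genes, median_len = median_len, sdlog_len = sdlog_len,
         opt_shift = opt_shift, nonopt_shift = nonopt_shift,
         dirichlet_conc = dirichlet_conc, n_tissues = n_tissues,
         mu_shift = mu_shift, disorder_sd = disorder_sd,
         ss_block_mean = ss_block_mean, ss_weights = ss_weights,
         rsa_mean = rsa_mean, rsa_conc = rsa_conc,
         structure_sets = structure_sets),
    class = "sim_config"
  )
}

# amino-acid frequency: uniform over the 18 degenerate amino acids plus a
# little Met/Trp so the exclusion paths are exercised
default_aa_freq <- function() {
  tab <- codon_table()
  deg_aa <- sort(unique(tab$aa[tab$degenerate]))
  freq <- c(stats::setNames(rep(0.97 / 18, 18L), deg_aa), M = 0.02, W = 0.01)
  freq / sum(freq)
}

#' Per-amino-acid codon preference vectors for one gene set
#'
#' Starts from uniform synonymous use and moves probability mass
#' `opt_shift` onto the designated optimal codon and `nonopt_shift` onto
#' the designated primary non-optimal codon of each amino acid.
#'
#' @param designations Codon designations from [designate_codons()].
#' @param opt_shift,nonopt_shift Probability mass in `[0, 1]` moved onto
#'   the designated codons (`opt_shift + nonopt_shift <= 1`).
#' @return Named list (one element per amino acid) of named codon
#'   probability vectors.
#' @export
set_preferences <- function(designations, opt_shift = 0, nonopt_shift = 0) {
  tab <- codon_table() |> dplyr::filter(.data$degenerate)
  prefs <- lapply(split(tab$codon, tab$aa), function(codons) {
    stats::setNames(rep(1 / length(codons), length(codons)), codons)
  })
  for (i in seq_len(nrow(designations))) {
    aa <- designations$aa[i]
    p <- prefs[[aa]] * (1 - opt_shift - nonopt_shift)
    p[designations$optimal[i]] <- p[designations$optimal[i]] + opt_shift
    p[designations$primary_nonopt[i]] <-
      p[designations$primary_nonopt[i]] + nonopt_shift
    prefs[[aa]] <- p
  }
  prefs
}

#' Simulate a set of coding sequences with controlled codon preferences
#'
#' Gene lengths are log-normal; amino acids are drawn i.i.d. from
#' `aa_freq`; each gene draws its own codon preference per amino acid from
#' a Dirichlet centred on the set preference vector, and codons are then
#' drawn i.i.d. per occurrence. A terminal TAA stop is appended.
#'
#' @param n Number of genes.
#' @param median_len Median CDS length in codons.
#' @param sdlog Log-scale SD of length.
#' @param prefs Per-amino-acid codon preference vectors (see
#'   [designate_codons()]).
#' @param aa_freq Named amino-acid frequency vector.
#' @param conc Dirichlet concentration for per-gene preference noise;
#'   `Inf` disables the per-gene draw.
#' @param prefix Gene-id prefix.
#' @param min_len Lower bound on CDS length (codons).
#' @return CDS tibble (`gene_id`, `cds`).
#' @export
sim_gene_set <- function(n, median_len, sdlog, prefs,
                         aa_freq = default_aa_freq(), conc = 40,
                         prefix = "g", min_len = 50L) {
  stopifnot(n >= 1)
  lens <- pmax(min_len,
               round(stats::rlnorm(n, meanlog = log(median_len),
                                   sdlog = sdlog)))
  aa_names <- names(aa_freq)
  cds <- character(n)
  for (i in seq_len(n)) {
    aa_seq <- sample(aa_names, lens[i], replace = TRUE, prob = aa_freq)
    codons <- character(lens[i])
    codons[aa_seq == "M"] <- "ATG"
    codons[aa_seq == "W"] <- "TGG"
    for (a in intersect(unique(aa_seq), names(prefs))) {
      idx <- which(aa_seq == a)
      p <- prefs[[a]]
      if (is.finite(conc)) {
        draw <- stats::rgamma(length(p), shape = conc * p)
        if (sum(draw) > 0) p <- stats::setNames(draw / sum(draw), names(p))
      }
      codons[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
    }
    cds[i] <- paste0(paste(codons, collapse = ""), "TAA")
  }
  tibble::tibble(
    gene_id = sprintf("%s%04d", prefix, seq_len(n)),
    cds = cds
  )
}

# expression regimes per gene set; tissue 1 = testis, tissue 2 = ovary
sim_expression_set <- function(gene_ids, set, n_tissues) {
  n <- length(gene_ids)
  n_other <- n_tissues - 2L
  other <- switch(set,
    testis = stats::rlnorm(n * n_other, log(15), 0.8),
    ovary = stats::rlnorm(n * n_other, log(45), 0.8),
    unbiased = stats::rlnorm(n * n_other, log(45), 0.5),
    ribosomal = stats::rlnorm(n * n_other, log(250), 0.5),
    background = stats::rlnorm(n * n_other, log(30), 1.0)
  )
  focal <- switch(set,
    testis = {
      t_v <- stats::rlnorm(n, log(400), 0.5)
      cbind(t_v, t_v / stats::rlnorm(n, log(70), 0.5))
    },
    ovary = {
      o_v <- stats::rlnorm(n, log(300), 0.5)
      cbind(o_v / stats::rlnorm(n, log(20), 0.5), o_v)
    },
    unbiased = {
      base <- stats::rlnorm(n, log(200), 0.4)
      ratio <- stats::rlnorm(n, 0, 0.3)
      cbind(base * sqrt(ratio), base / sqrt(ratio))
    },
    ribosomal = {
      base <- stats::rlnorm(n, log(300), 0.4)
      cbind(base * stats::rlnorm(n, 0, 0.2), base * stats::rlnorm(n, 0, 0.2))
    },
    background = {
      cbind(stats::rlnorm(n, log(30), 1.0), stats::rlnorm(n, log(30), 1.0))
    }
  )
  mat <- cbind(focal, matrix(other, nrow = n))
  colnames(mat) <- c("testis", "ovary",
                     sprintf("tissue_%02d", seq_len(n_other)))
  dplyr::bind_cols(tibble::tibble(gene_id = gene_ids),
                   tibble::as_tibble(mat))
}

# tRNA gene counts: 12 optimal codons tRNA-rich, 6 wobble (zero); 15
# non-optimal codons tRNA-rich, the rest low
sim_trna <- function(designations) {
  tab <- codon_table()
  wobble_aa <- sample(designations$aa, 6L)
  counts <- integer(nrow(tab))
  names(counts) <- tab$codon
  for (i in seq_len(nrow(designations))) {
    opt <- designations$optimal[i]
    counts[opt] <- if (designations$aa[i] %in% wobble_aa) 0L
                   else sample(6:15, 1L)
  }
  nonopt <- setdiff(tab$codon[tab$degenerate], designations$optimal)
  high <- sample(nonopt, 15L)
  counts[high] <- sample(6:12, 15L, replace = TRUE)
  low <- setdiff(nonopt, high)
  counts[low] <- sample(0:5, length(low), replace = TRUE,
                        prob = c(1, 1, 2, 3, 4, 4))
  counts["ATG"] <- 10L
  counts["TGG"] <- 8L
  tibble::tibble(codon = names(counts), count = unname(counts))
}

#' Simulate residue-level structure tables for a CDS set
#'
#' Secondary-structure classes come in geometric-length blocks; RSA is
#' Beta-distributed with a class-specific mean, shifted up by `mu_shift`
#' for residues encoded by the designated primary non-optimal codon and
#' clipped to `[0, 1]`; disorder is RSA plus Gaussian noise, clipped.
#'
#' @param cds_tbl CDS tibble.
#' @param designations Codon designations from [designate_codons()].
#' @param config A [sim_config()].
#' @return Residue tibble: `gene_id`, `position`, `aa`, `rsa`, `disorder`,
#'   `ss_class`.
#' @export
sim_structure <- function(cds_tbl, designations, config = sim_config()) {
  prim <- stats::setNames(designations$primary_nonopt, designations$aa)
  classes <- names(config$ss_block_mean)
  out <- vector("list", nrow(cds_tbl))
  for (i in seq_len(nrow(cds_tbl))) {
    codons <- split_codons(cds_tbl$cds[i], cds_tbl$gene_id[i])
    len <- length(codons)
    aa <- translate_codons(codons)
    ss <- character(0)
    while (length(ss) < len) {
      cl <- sample(classes, 1L, prob = config$ss_weights)
      ss <- c(ss, rep(cl, stats::rgeom(1L, 1 / config$ss_block_mean[[cl]]) + 1L))
    }
    ss <- ss[seq_len(len)]
    m <- config$rsa_mean[ss]
    rsa <- stats::rbeta(len, m * config$rsa_conc, (1 - m) * config$rsa_conc)
    shifted <- !is.na(prim[aa]) & codons == unname(prim[aa])
    shifted[is.na(shifted)] <- FALSE
    rsa <- pmin(1, pmax(0, rsa + config$mu_shift * shifted))
    disorder <- pmin(1, pmax(0, rsa + stats::rnorm(len, 0, config$disorder_sd)))
    out[[i]] <- tibble::tibble(
      gene_id = cds_tbl$gene_id[i], position = seq_len(len), aa = aa,
      rsa = rsa, disorder = disorder, ss_class = ss
    )
  }
  dplyr::bind_rows(out)
}

#' Simulate a complete codon-usage study with known ground truth
#'
#' Generates every input of the analysis pipeline: CDS sets (testis-like,
#' ovary-like, unbiased, ribosomal reference, genome background) with
#' controlled codon preferences, a 59-tissue expression matrix with
#' class-specific specificity regimes, a tRNA gene-count table, and
#' residue-level structure tables whose RSA depends on the codon class.
#' Output is fully determined by `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return List: `cds` (tibble `gene_id`, `set`, `cds`), `expression`,
#'   `trna`, `structure`, and `ground_truth` (designations, per-gene true
#'   class, the config).
#' @export
simulate_codon_study <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  designations <- designate_codons()
  sets <- names(config$n_genes)
  prefix <- c(testis = "tb", ovary = "ob", unbiased = "ub",
              ribosomal = "rp", background = "bg")
  cds <- purrr::map(sets, function(s) {
    prefs <- set_preferences(designations,
                             opt_shift = config$opt_shift[[s]],
                             nonopt_shift = config$nonopt_shift[[s]])
    sim_gene_set(config$n_genes[[s]], config$median_len[[s]],
                 config$sdlog_len, prefs, conc = config$dirichlet_conc,
                 prefix = prefix[[s]]) |>
      dplyr::mutate(set = s, .after = "gene_id")
  }) |> dplyr::bind_rows()
  expression <- purrr::map(sets, function(s) {
    sim_expression_set(cds$gene_id[cds$set == s], s, config$n_tissues)
  }) |> dplyr::bind_rows()
  trna <- sim_trna(designations)
  struct_cds <- dplyr::filter(cds, .data$set %in% config$structure_sets)
  structure_tbl <- if (nrow(struct_cds) > 0) {
    sim_structure(struct_cds, designations, config)
  } else {
    NULL
  }
  list(
    cds = cds,
    expression = expression,
    trna = trna,
    structure = structure_tbl,
    ground_truth = list(designations = designations,
                        classes = dplyr::select(cds, "gene_id", "set"),
                        config = config)
  )
}

#' A tiny fixed worked-example dataset
#'
#' Eight genes over four tissues, small enough that every intermediate
#' value (RSCU, tau, fold-bias, percent non-optimal) can be checked by
#' hand. Built from constants, so it is identical on every call.
#'
#' @return List with `cds` (`gene_id`, `set`, `cds`), `expression`
#'   (four tissues), and `trna`.
#' @export
worked_example <- function() {
  # ref1/ref2 use GGC/GCC/AAG-heavy codons (reference-preferred); t1/t2
  # leans on GGA/GCA/AAA; others are intermediate
  cds <- tibble::tibble(
    gene_id = c("ref1", "ref2", "bg1", "bg2", "t1", "t2", "o1", "u1"),
    set = c("ribosomal", "ribosomal", "background", "background",
            "testis", "testis", "ovary", "unbiased"),
    cds = c(
      "ATGGGCGGCGGCGCCGCCAAGAAGTTCTAA",
      "ATGGGCGGCGCCGCCGCCAAGTTCTTCTAA",
      "ATGGGCGGAGGTGCCGCAAAGAAATTCTTTTAA",
      "ATGGGAGGCGGGGCTGCCAAAAAGTTTTTCTAA",
      "ATGGGAGGAGGAGCAGCAAAAAAATTTTAA",
      "ATGGGAGGAGCAGCAGCAAAAAAGTTTTAA",
      "ATGGGCGGAGCCGCAAAGAAATTCTTTTAA",
      "ATGGGCGGCGCCGCAAAGAAGTTCTTTTAA"
    )
  )
  expression <- tibble::tibble(
    gene_id = cds$gene_id,
    testis = c(20, 30, 5, 5, 500, 800, 50, 150),
    ovary = c(25, 28, 4, 6, 50, 2, 260, 120),
    tissue_01 = c(22, 29, 5, 5, 10, 1, 40, 100),
    tissue_02 = c(18, 27, 6, 4, 20, 0, 30, 110)
  )
  trna <- tibble::tibble(
    codon = c("GGC", "GGA", "GGT", "GGG", "GCC", "GCA", "GCT", "GCG",
              "AAG", "AAA", "TTC", "TTT"),
    count = c(14L, 8L, 2L, 1L, 12L, 9L, 3L, 1L, 11L, 6L, 10L, 4L)
  )
  list(cds = cds, expression = expression, trna = trna)
}
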