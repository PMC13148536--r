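#' Read coding sequences from a FASTA file
#'
#' The gene id is the header token before the first whitespace. When
#' several records share a gene id (isoforms), the longest CDS is kept.
#'
#' @param path FASTA file (any line width).
#' @return CDS tibble (`gene_id`, `cds`).
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path)
  tibble::tibble(
    gene_id = stringr::str_extract(names(seqs), "^\\S+"),
    cds = unname(as.character(seqs))
  ) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice_max(nchar(.data$cds), n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
}

#' Write coding sequences to a FASTA file
#'
#' @param cds_tbl CDS tibble (`gene_id`, `cds`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds_tbl, path) {
  seqs <- Biostrings::DNAStringSet(cds_tbl$cds)
  names(seqs) <- cds_tbl$gene_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read an expression matrix (TSV)
#'
#' Tab-separated, header row of tissue labels, one row per gene, first
#' column `gene_id`.
#'
#' @param path TSV file.
#' @return Tibble with `gene_id` plus numeric tissue columns.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path,
                               call. = FALSE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(gene_id = readr::col_character(),
                                          .default = readr::col_double()))
}

#' Read a codon-to-tRNA-gene-count table (TSV)
#'
#' Two columns: `codon`, `count`.
#'
#' @param path TSV file.
#' @return Tibble (`codon`, `count`).
#' @export
read_trna_tsv <- function(path) {
  if (!file.exists(path)) stop("tRNA table not found: ", path, call. = FALSE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(codon = readr::col_character(),
                                          count = readr::col_integer()))
}

#' Read a per-residue structure table (TSV)
#'
#' NetsurfP-style columns: `gene_id`, `position`, `aa`, `rsa`, `disorder`,
#' `ss_class` (3- or 8-class codes accepted).
#'
#' @param path TSV file.
#' @return Residue tibble.
#' @export
read_structure_tsv <- function(path) {
  if (!file.exists(path)) stop("structure table not found: ", path,
                               call. = FALSE)
  readr::read_tsv(
    path, show_col_types = FALSE,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      position = readr::col_integer(),
      aa = readr::col_character(),
      rsa = readr::col_double(),
      disorder = readr::col_double(),
      ss_class = readr::col_character()
    )
  )
}

#' Write a simulated study to disk in the pipeline's file dialects
#'
#' Emits `cds.fasta` (all gene sets), `expression.tsv`, `trna.tsv`,
#' `structure.tsv` (when present) and `gene_sets.tsv` (the ground-truth
#' set membership, which also identifies the ribosomal reference ids).
#'
#' @param study Output of [simulate_codon_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cds_fasta(study$cds, file.path(dir, "cds.fasta"))
  readr::write_tsv(study$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(study$trna, file.path(dir, "trna.tsv"))
  if (!is.null(study$structure)) {
    readr::write_tsv(study$structure, file.path(dir, "structure.tsv"))
  }
  readr::write_tsv(study$ground_truth$classes,
                   file.path(dir, "gene_sets.tsv"))
  invisible(dir)
}

#' Run the full codon-optimality analysis pipeline
#'
#' Executes, in order: a priori codon classification (reference vs
#' background delta-RSCU plus tRNA stratification), sex-bias and
#' subclass assignment from the expression matrix, per-gene CAI/Fop,
#' per-codon RSCU contrasts between the gene sets, primary non-optimal
#' codon identification, extreme-use fractions, and (when a structure
#' table is supplied) the RSA analyses. Results are returned as a named
#' list of tibbles and, when `out_dir` is given, written as TSV reports.
#'
#' @param cds CDS tibble (`gene_id`, `cds`) or path to a FASTA file; must
#'   contain the whole gene catalogue (used as background).
#' @param expression Expression tibble or TSV path.
#' @param trna tRNA table or TSV path.
#' @param ribosomal_ids Character vector of gene ids forming the highly
#'   expressed reference set.
#' @param structure Optional residue table or TSV path; when absent the
#'   structure stages are skipped with a warning.
#' @param out_dir Optional report directory.
#' @param min_rpkm,fold,pseudocount Sex-bias thresholds
#'   (see [classify_sex_bias()]).
#' @param extreme_rscu Extreme-use RSCU cutoff.
#' @param length_cutoff,expr_cutoff Subclass cutoffs
#'   (see [subclass_genes()]).
#' @param bin_breaks Percent-non-optimal bin bounds.
#' @param cai_floor Floor weight for reference-absent codons.
#' @param var_equal,p_adjust Contrast t-test options.
#' @param skip_invalid Drop invalid CDS records with a warning.
#' @return Invisibly, a list with elements `classification`,
#'   `gene_classes`, `gene_indices`, `contrast_to`, `contrast_tu`,
#'   `primary_calls`, `extreme_use`, and (with structure input)
#'   `structure_summary`, `bin_rsa`, `ss_composition`, `rsa_by_codon`,
#'   `rsa_disorder`.
#' @export
run_pipeline <- function(cds, expression, trna, ribosomal_ids,
                         structure = NULL, out_dir = NULL,
                         min_rpkm = 100, fold = 5, pseudocount = 0.01,
                         extreme_rscu = 1.5, length_cutoff = 272,
                         expr_cutoff = 200, bin_breaks = c(50, 60),
                         cai_floor = 0.01, var_equal = FALSE,
                         p_adjust = "none", skip_invalid = FALSE) {
  if (is.character(cds)) cds <- read_cds_fasta(cds)
  if (is.character(expression)) expression <- read_expression_tsv(expression)
  if (is.character(trna)) trna <- read_trna_tsv(trna)
  if (is.character(structure)) structure <- read_structure_tsv(structure)

  shared <- intersect(cds$gene_id, expression$gene_id)
  if (length(shared) == 0) {
    stop("no gene ids shared between the CDS and expression inputs",
         call. = FALSE)
  }
  ribosomal_ids <- intersect(ribosomal_ids, cds$gene_id)
  if (length(ribosomal_ids) == 0) {
    stop("none of the ribosomal reference ids are present in the CDS input",
         call. = FALSE)
  }

  ref_cds <- dplyr::filter(cds, .data$gene_id %in% ribosomal_ids)
  classification <- classify_codons(ref_cds, cds, trna,
                                    skip_invalid = skip_invalid)
  optimal_set <- classification$codon[classification$optimality == "optimal"]
  weights <- cai_weights(pool_counts(codon_counts(ref_cds, skip_invalid)),
                         floor = cai_floor)

  gene_classes <- classify_sex_bias(expression, min_rpkm = min_rpkm,
                                    fold = fold,
                                    pseudocount = pseudocount) |>
    subclass_genes(cds, expr_cutoff = expr_cutoff,
                   length_cutoff = length_cutoff)
  study_sets <- list(
    testis = gene_classes$gene_id[gene_classes$sex_class == "testis_biased"],
    ovary = gene_classes$gene_id[gene_classes$sex_class == "ovary_biased"],
    unbiased = gene_classes$gene_id[gene_classes$sex_class == "unbiased"]
  )
  study_sets <- purrr::map(study_sets, ~ intersect(.x, cds$gene_id))
  if (any(lengths(study_sets) < 2L)) {
    stop("gene set(s) too small for contrasts: ",
         paste(names(study_sets)[lengths(study_sets) < 2L], collapse = ", "),
         call. = FALSE)
  }
  mats <- purrr::imap(study_sets, function(ids, nm) {
    rscu_matrix(dplyr::filter(cds, .data$gene_id %in% ids), label = nm,
                skip_invalid = skip_invalid)
  })
  contrast_to <- contrast_rscu(mats$testis, mats$ovary,
                               var_equal = var_equal, p_adjust = p_adjust)
  contrast_tu <- contrast_rscu(mats$testis, mats$unbiased,
                               var_equal = var_equal, p_adjust = p_adjust)
  primary_calls <- identify_primary_nonoptimal(contrast_to, contrast_tu,
                                               classification)
  called <- primary_calls$primary[!is.na(primary_calls$primary)]
  extreme <- purrr::map(called, function(cod) {
    res <- extreme_use_compare(mats, cod, threshold = extreme_rscu)
    dplyr::left_join(res$per_set,
                     dplyr::rename(res$pairwise, set = "set_a"),
                     by = "set")
  }) |> dplyr::bind_rows()

  study_cds <- dplyr::filter(cds, .data$gene_id %in% unlist(study_sets))
  indices <- gene_codon_indices(study_cds, weights, optimal_set)

  out <- list(classification = classification, gene_classes = gene_classes,
              gene_indices = indices, contrast_to = contrast_to,
              contrast_tu = contrast_tu, primary_calls = primary_calls,
              extreme_use = extreme)

  if (is.null(structure)) {
    warning("no structure table supplied; RSA stages skipped",
            call. = FALSE)
  } else {
    residues <- join_cds_structure(study_cds, structure)
    summaries <- gene_structure_summary(study_cds, classification, residues,
                                        bin_breaks = bin_breaks)
    testis_residues <- dplyr::filter(
      residues, .data$gene_id %in% study_sets$testis)
    out$structure_summary <- summaries
    out$bin_rsa <- bin_rsa_comparison(
      dplyr::filter(summaries, .data$gene_id %in% study_sets$testis))
    out$ss_composition <- ss_composition(testis_residues)
    out$rsa_by_codon <- rsa_by_codon(testis_residues, classification,
                                     primary_calls)
    out$rsa_disorder <- rsa_disorder_correlation(residues)
  }

  if (!is.null(out_dir)) write_reports(out, out_dir)
  invisible(out)
}

# TSV report bundle; plain tibbles are written directly, composite results
# are flattened
write_reports <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(x, name) {
    readr::write_tsv(x, file.path(out_dir, paste0(name, ".tsv")))
  }
  emit(tibble::as_tibble(unclass(results$classification)),
       "codon_classification")
  emit(results$gene_classes, "gene_classes")
  emit(results$gene_indices, "gene_indices")
  emit(tidy(results$contrast_to), "contrast_testis_ovary")
  emit(tidy(results$contrast_tu), "contrast_testis_unbiased")
  emit(results$primary_calls, "primary_nonoptimal")
  emit(results$extreme_use, "extreme_use")
  if (!is.null(results$structure_summary)) {
    emit(results$structure_summary, "structure_summary")
    emit(results$bin_rsa$per_bin, "rsa_per_bin")
    emit(results$bin_rsa$pairwise, "rsa_bin_tests")
    emit(results$ss_composition$per_class, "ss_composition")
    emit(tidy(results$rsa_by_codon), "rsa_by_codon")
    emit(glance(results$rsa_by_codon), "rsa_sign_test")
    emit(results$rsa_disorder, "rsa_disorder_correlation")
  }
  invisible(out_dir)
}

#' Plot gene-wide RSA across percent-non-optimal bins
#'
#' @param summaries Output of [gene_structure_summary()].
#' @return A ggplot boxplot.
#' @export
plot_rsa_bins <- function(summaries) {
  dat <- dplyr::filter(summaries, !is.na(.data$bin))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = .data$mean_rsa)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = "percent non-optimal codon use bin",
                  y = "average RSA per gene") +
    ggplot2::theme_minimal()
}
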