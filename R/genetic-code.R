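#' The standard genetic code as a tidy codon table
#'
#' Returns one row per sense codon with its amino acid (single-letter code)
#' and degeneracy (number of synonymous sense codons for that amino acid).
#' Stop codons are excluded unless `include_stops = TRUE`, in which case they
#' appear with `aa = "*"` and `degeneracy = NA`.
#'
#' Under the standard code there are 61 sense codons, 18 amino acids with
#' degeneracy >= 2 ("degenerate amino acids"), and 59 codons belonging to
#' them (61 minus Met and Trp).
#'
#' @param include_stops Include the three stop codons as extra rows.
#' @return A tibble with columns `codon`, `aa`, `degeneracy`, and
#'   `degenerate` (TRUE for codons of amino acids with >= 2 synonyms).
#' @export
#' @examples
#' codon_table()
#' dplyr::count(codon_table(), degenerate)
codon_table <- function(include_stops = FALSE) {
  tab <- codonopt_env$codon_table
  if (!include_stops) tab <- dplyr::filter(tab, .data$aa != "*")
  tab
}

# memoised at load; the table is tiny but referenced everywhere
codonopt_env <- new.env(parent = emptyenv())

build_codon_table <- function() {
  gc_map <- Biostrings::GENETIC_CODE
  tab <- tibble::tibble(codon = names(gc_map), aa = unname(gc_map))
  deg <- tab |>
    dplyr::filter(.data$aa != "*") |>
    dplyr::count(.data$aa, name = "degeneracy")
  tab |>
    dplyr::left_join(deg, by = "aa") |>
    dplyr::mutate(degenerate = !is.na(.data$degeneracy) & .data$degeneracy >= 2) |>
    dplyr::arrange(.data$codon)
}

.onLoad <- function(libname, pkgname) {
  codonopt_env$codon_table <- build_codon_table()
}

#' Codons of the degenerate amino acids
#'
#' The 59 sense codons whose amino acid has two or more synonymous codons
#' (Met and Trp excluded). All optimality statistics are computed over this
#' domain.
#'
#' @return Character vector of 59 codons, alphabetical.
#' @export
degenerate_codons <- function() {
  tab <- codon_table()
  tab$codon[tab$degenerate]
}

stop_codons <- function() {
  tab <- codon_table(include_stops = TRUE)
  tab$codon[tab$aa == "*"]
}

#' Translate codons to amino acids
#'
#' @param codons Character vector of trinucleotides (uppercase DNA).
#' @return Character vector of single-letter amino-acid codes (`"*"` = stop).
#' @export
translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

# Split a CDS string into codons, validating structure.
# Terminal stop codon is stripped; internal stops and non-ACGT characters
# are errors (callers that batch over genes may downgrade to warn + drop).
split_codons <- function(cds, gene_id = "<cds>") {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length of '", gene_id, "' (", nchar(cds),
         " nt) is not divisible by 3", call. = FALSE)
  }
  if (stringr::str_detect(cds, "[^ACGT]")) {
    stop("CDS of '", gene_id, "' contains non-ACGT characters ",
         "(ambiguous bases are not supported)", call. = FALSE)
  }
  n <- nchar(cds) %/% 3L
  codons <- stringr::str_sub(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  if (n > 0L && codons[n] %in% stop_codons()) codons <- codons[-n]
  if (any(codons %in% stop_codons())) {
    pos <- which(codons %in% stop_codons())[1L]
    stop("internal stop codon in '", gene_id, "' at codon position ", pos,
         call. = FALSE)
  }
  codons
}

#' Count sense codons in a coding sequence
#'
#' Tallies codon occurrences in a single CDS. A terminal stop codon is
#' stripped before counting; an internal stop or a length not divisible by 3
#' is an error.
#'
#' @param cds A single CDS string (uppercase DNA).
#' @param gene_id Label used in error messages and the `source` attribute.
#' @return A tibble with columns `codon` and `count`, one row per sense
#'   codon (zeros included).
#' @export
#' @examples
#' dplyr::filter(count_codons("ATGGGAGGA"), count > 0)
count_codons <- function(cds, gene_id = "<cds>") {
  stopifnot(is.character(cds), length(cds) == 1L)
  codons <- split_codons(cds, gene_id)
  tab <- codon_table()
  counts <- tabulate(factor(codons, levels = tab$codon), nbins = nrow(tab))
  out <- tibble::tibble(codon = tab$codon, count = as.integer(counts))
  attr(out, "source") <- gene_id
  out
}

#' Per-gene codon counts for a set of coding sequences
#'
#' Applies [count_codons()] across a CDS table. Invalid genes (internal
#' stop, bad length, ambiguous bases) are errors by default; with
#' `skip_invalid = TRUE` they are dropped with a warning.
#'
#' @param cds_tbl Tibble with columns `gene_id` and `cds`.
#' @param skip_invalid Drop invalid genes with a warning instead of failing.
#' @return Long tibble with columns `gene_id`, `codon`, `count`.
#' @export
codon_counts <- function(cds_tbl, skip_invalid = FALSE) {
  stopifnot(all(c("gene_id", "cds") %in% names(cds_tbl)))
  rows <- purrr::map2(cds_tbl$gene_id, cds_tbl$cds, function(id, cds) {
    res <- tryCatch(count_codons(cds, id), error = function(e) e)
    if (inherits(res, "error")) {
      if (!skip_invalid) stop(res)
      warning("dropping gene '", id, "': ", conditionMessage(res),
              call. = FALSE)
      return(NULL)
    }
    dplyr::mutate(res, gene_id = id, .before = 1L)
  })
  dplyr::bind_rows(rows)
}

#' Pool per-gene codon counts into one concatenated profile
#'
#' @param counts_long Long counts from [codon_counts()].
#' @return Tibble (`codon`, `count`) summed over genes.
#' @export
pool_counts <- function(counts_long) {
  counts_long |>
    dplyr::group_by(.data$codon) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
}

#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of codon c is `degeneracy(aa) * x_c / sum(x)` over the synonymous
#' codons of its amino acid: the observed count divided by the count
#' expected under uniform synonymous use. Values for an amino acid absent
#' from the input are `NA`. Met and Trp, being non-degenerate, have RSCU 1
#' whenever present.
#'
#' @param counts A tibble with columns `codon`, `count` (as returned by
#'   [count_codons()] or [pool_counts()]); codons not listed count as zero.
#' @return Tibble with columns `codon`, `aa`, `degeneracy`, `count`, `rscu`.
#' @export
#' @examples
#' counts <- count_codons("ATGGGAGGAGGAGGC")
#' dplyr::filter(rscu(counts), aa == "G")
rscu <- function(counts) {
  stopifnot(all(c("codon", "count") %in% names(counts)))
  codon_table() |>
    dplyr::left_join(dplyr::select(counts, "codon", "count"), by = "codon") |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::group_by(.data$aa) |>
    dplyr::mutate(
      aa_total = sum(.data$count),
      rscu = dplyr::if_else(.data$aa_total > 0,
                            .data$degeneracy * .data$count / .data$aa_total,
                            NA_real_)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("codon", "aa", "degeneracy", "count", "rscu")
}

#' Relative adaptiveness weights for the codon adaptation index
#'
#' Computes CAI weights from a highly expressed reference gene set:
#' `w_c = RSCU_c / max RSCU` within each amino acid, so the most-used
#' synonymous codon of the reference has weight 1. Codons unobserved in the
#' reference receive a small floor weight (default 0.01) so that the log in
#' the geometric mean stays defined.
#'
#' @param reference_counts Pooled codon counts of the reference set.
#' @param floor Weight assigned to reference-absent codons.
#' @return Tibble with columns `codon`, `aa`, `w`.
#' @export
cai_weights <- function(reference_counts, floor = 0.01) {
  prof <- rscu(reference_counts)
  missing_aa <- prof |>
    dplyr::filter(.data$degeneracy >= 2, is.na(.data$rscu)) |>
    dplyr::distinct(.data$aa)
  if (nrow(missing_aa) > 0) {
    stop("reference set lacks amino acid(s): ",
         paste(missing_aa$aa, collapse = ", "),
         " - inadequate as a CAI reference", call. = FALSE)
  }
  prof |>
    dplyr::group_by(.data$aa) |>
    dplyr::mutate(w = .data$rscu / max(.data$rscu)) |>
    dplyr::ungroup() |>
    dplyr::mutate(w = dplyr::if_else(.data$w <= 0, floor, .data$w)) |>
    dplyr::select("codon", "aa", "w")
}

#' Codon adaptation index of a gene
#'
#' Geometric mean of the reference relative-adaptiveness weights over the
#' gene's codons, restricted to codons of degenerate amino acids (Met, Trp
#' and the stop are excluded). `NA` if the gene has no such codons.
#'
#' @param cds A CDS string.
#' @param weights Weights from [cai_weights()].
#' @param gene_id Label for error messages.
#' @return CAI in (0, 1].
#' @export
cai <- function(cds, weights, gene_id = "<cds>") {
  counts <- count_codons(cds, gene_id)
  cai_from_counts(counts, weights)
}

cai_from_counts <- function(counts, weights) {
  dat <- codon_table() |>
    dplyr::filter(.data$degenerate) |>
    dplyr::left_join(dplyr::select(counts, "codon", "count"), by = "codon") |>
    dplyr::left_join(dplyr::select(weights, "codon", "w"), by = "codon")
  n <- sum(dat$count)
  if (n == 0) return(NA_real_)
  exp(sum(dat$count * log(dat$w)) / n)
}

#' Frequency of optimal codons (Fop)
#'
#' Fraction of a gene's degenerate-amino-acid codons that belong to the
#' optimal set (one optimal codon per degenerate amino acid).
#'
#' @param cds A CDS string.
#' @param optimal_set Character vector of 18 optimal codons, one per
#'   degenerate amino acid.
#' @param gene_id Label for error messages.
#' @return Fraction in `[0, 1]`, or `NA` for a gene with no degenerate-aa
#'   codons.
#' @export
fop <- function(cds, optimal_set, gene_id = "<cds>") {
  counts <- count_codons(cds, gene_id)
  fop_from_counts(counts, optimal_set)
}

fop_from_counts <- function(counts, optimal_set) {
  check_optimal_set(optimal_set)
  dat <- codon_table() |>
    dplyr::filter(.data$degenerate) |>
    dplyr::left_join(dplyr::select(counts, "codon", "count"), by = "codon")
  n <- sum(dat$count)
  if (n == 0) return(NA_real_)
  sum(dat$count[dat$codon %in% optimal_set]) / n
}

check_optimal_set <- function(optimal_set) {
  tab <- codon_table() |> dplyr::filter(.data$degenerate)
  hit <- tab |>
    dplyr::filter(.data$codon %in% optimal_set) |>
    dplyr::count(.data$aa)
  if (nrow(hit) != 18L || any(hit$n != 1L)) {
    stop("optimal_set must contain exactly one codon per degenerate ",
         "amino acid", call. = FALSE)
  }
  invisible(optimal_set)
}

#' Per-gene CAI and Fop for a CDS table
#'
#' @param cds_tbl Tibble with columns `gene_id`, `cds`.
#' @param weights Reference weights from [cai_weights()].
#' @param optimal_set Optional optimal codon set; when supplied a `fop`
#'   column is added.
#' @return Tibble with columns `gene_id`, `n_codons` (degenerate-aa codons),
#'   `cai`, and optionally `fop`.
#' @export
gene_codon_indices <- function(cds_tbl, weights, optimal_set = NULL) {
  counts <- codon_counts(cds_tbl)
  deg <- codon_table() |> dplyr::filter(.data$degenerate)
  per_gene <- counts |>
    dplyr::inner_join(dplyr::select(deg, "codon"), by = "codon") |>
    dplyr::left_join(dplyr::select(weights, "codon", "w"), by = "codon") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_codons = sum(.data$count),
      cai = dplyr::if_else(.data$n_codons > 0,
                           exp(sum(.data$count * log(.data$w)) / .data$n_codons),
                           NA_real_),
      .groups = "drop"
    )
  if (!is.null(optimal_set)) {
    check_optimal_set(optimal_set)
    fop_tbl <- counts |>
      dplyr::inner_join(dplyr::select(deg, "codon"), by = "codon") |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(
        fop = dplyr::if_else(sum(.data$count) > 0,
                             sum(.data$count[.data$codon %in% optimal_set]) /
                               sum(.data$count),
                             NA_real_),
        .groups = "drop"
      )
    per_gene <- dplyr::left_join(per_gene, fop_tbl, by = "gene_id")
  }
  # preserve the input gene order
  per_gene[match(unique(cds_tbl$gene_id), per_gene$gene_id), , drop = FALSE]
}
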