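#' Per-gene RSCU matrix for a gene set
#'
#' One row per gene, one column per degenerate-amino-acid codon (59),
#' entries RSCU within the gene or `NA` where the gene does not use the
#' amino acid at all.
#'
#' @param cds_tbl CDS tibble (`gene_id`, `cds`).
#' @param label Optional gene-set label stored as the `set_label` attribute.
#' @param skip_invalid Passed to [codon_counts()].
#' @return Wide tibble: `gene_id` plus 59 codon columns.
#' @export
rscu_matrix <- function(cds_tbl, label = NULL, skip_invalid = FALSE) {
  if (nrow(cds_tbl) == 0) stop("empty gene set", call. = FALSE)
  counts <- codon_counts(cds_tbl, skip_invalid)
  long <- counts |>
    dplyr::inner_join(codon_table(), by = "codon") |>
    dplyr::filter(.data$degenerate) |>
    dplyr::group_by(.data$gene_id, .data$aa) |>
    dplyr::mutate(
      aa_total = sum(.data$count),
      rscu = dplyr::if_else(.data$aa_total > 0,
                            .data$degeneracy * .data$count / .data$aa_total,
                            NA_real_)
    ) |>
    dplyr::ungroup()
  out <- long |>
    dplyr::select("gene_id", "codon", "rscu") |>
    tidyr::pivot_wider(names_from = "codon", values_from = "rscu")
  out <- out[c("gene_id", degenerate_codons())]
  attr(out, "set_label") <- label
  out
}

#' Per-codon RSCU contrast between two gene sets
#'
#' For each of the 59 degenerate-amino-acid codons, the difference of
#' per-gene RSCU means (`mean_A - mean_B`) with a two-sided two-sample
#' t-test. Genes contribute only where they use the amino acid (pairwise
#' NA deletion). A positive delta marks higher use of the codon in set A.
#'
#' @param mat_a,mat_b RSCU matrices from [rscu_matrix()].
#' @param var_equal Use Student's pooled-variance t-test instead of the
#'   Welch default.
#' @param p_adjust Multiple-testing adjustment passed to
#'   [stats::p.adjust()]; `"none"` (default) reports raw per-codon p.
#' @return A `codon_contrast` tibble: `codon`, `aa`, `delta`,
#'   `t_statistic`, `p_value`, `n_a`, `n_b`; set labels kept as attributes.
#' @export
contrast_rscu <- function(mat_a, mat_b, var_equal = FALSE,
                          p_adjust = "none") {
  codons <- degenerate_codons()
  stopifnot(all(codons %in% names(mat_a)), all(codons %in% names(mat_b)))
  tab <- codon_table()
  rows <- purrr::map(codons, function(cod) {
    a <- mat_a[[cod]][!is.na(mat_a[[cod]])]
    b <- mat_b[[cod]][!is.na(mat_b[[cod]])]
    delta <- if (length(a) > 0 && length(b) > 0) mean(a) - mean(b) else NA_real_
    if (length(a) >= 2 && length(b) >= 2) {
      tt <- tryCatch(
        stats::t.test(a, b, var.equal = var_equal),
        error = function(e) NULL   # e.g. both samples constant
      )
      t_stat <- if (is.null(tt)) NA_real_ else unname(tt$statistic)
      p <- if (is.null(tt)) NA_real_ else tt$p.value
    } else {
      t_stat <- NA_real_
      p <- NA_real_
    }
    tibble::tibble(codon = cod, delta = delta, t_statistic = t_stat,
                   p_value = p, n_a = length(a), n_b = length(b))
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::left_join(dplyr::select(tab, "codon", "aa"), by = "codon") |>
    dplyr::relocate("aa", .after = "codon")
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  attr(out, "label_a") <- attr(mat_a, "set_label")
  attr(out, "label_b") <- attr(mat_b, "set_label")
  class(out) <- unique(c("codon_contrast", class(out)))
  out
}

#' @export
tidy.codon_contrast <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.codon_contrast <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_codons = nrow(x),
    n_positive = sum(x$delta > 0, na.rm = TRUE),
    n_significant = sum(x$p_value < alpha, na.rm = TRUE),
    min_n_a = min(x$n_a),
    min_n_b = min(x$n_b)
  )
}

#' @export
autoplot.codon_contrast <- function(object, alpha = 0.05, ...) {
  dat <- dplyr::mutate(
    tibble::as_tibble(unclass(object)),
    significant = !is.na(.data$p_value) & .data$p_value < alpha
  )
  ggplot2::ggplot(
    dat, ggplot2::aes(x = .data$delta, y = .data$codon,
                      fill = .data$significant)
  ) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$aa), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "delta-RSCU (set A - set B)", y = NULL,
                  fill = paste0("p < ", alpha)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.text.y = ggplot2::element_text(angle = 0))
}

#' Identify the primary non-optimal codon per amino acid
#'
#' Among each degenerate amino acid's non-optimal codons, ranks by the
#' testis-vs-unbiased delta (the better-powered contrast) and calls the
#' top codon "primary" when its delta is positive in both contrasts;
#' otherwise the amino acid gets no primary call. The runner-up is
#' reported as a secondary codon when its testis-vs-unbiased delta reaches
#' `secondary_frac` of the primary's.
#'
#' @param contrast_to Contrast of testis-biased vs ovary-biased sets.
#' @param contrast_tu Contrast of testis-biased vs unbiased sets.
#' @param classification A `codon_classification` (with `optimality`).
#' @param secondary_frac Fraction of the primary delta a runner-up must
#'   reach to be reported as secondary.
#' @param alpha Significance level for the reported flags.
#' @return Tibble, one row per degenerate amino acid: `aa`, `primary`
#'   (codon or `NA`), `delta_to`, `delta_tu`, `sig_to`, `sig_tu`,
#'   `secondary`.
#' @export
identify_primary_nonoptimal <- function(contrast_to, contrast_tu,
                                        classification,
                                        secondary_frac = 0.8, alpha = 0.05) {
  nonopt <- classification |>
    dplyr::filter(.data$optimality == "non_optimal") |>
    dplyr::select("codon", "aa")
  dat <- nonopt |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(unclass(contrast_to)),
                    "codon", delta_to = "delta", p_to = "p_value"),
      by = "codon"
    ) |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(unclass(contrast_tu)),
                    "codon", delta_tu = "delta", p_tu = "p_value"),
      by = "codon"
    )
  dat |>
    dplyr::arrange(.data$aa, dplyr::desc(.data$delta_tu), .data$codon) |>
    dplyr::group_by(.data$aa) |>
    dplyr::group_modify(function(d, key) {
      called <- !is.na(d$delta_to[1L]) && !is.na(d$delta_tu[1L]) &&
        d$delta_to[1L] > 0 && d$delta_tu[1L] > 0
      secondary <- NA_character_
      if (called && nrow(d) >= 2L && !is.na(d$delta_tu[2L]) &&
          d$delta_tu[2L] > 0 &&
          d$delta_tu[2L] >= secondary_frac * d$delta_tu[1L]) {
        secondary <- d$codon[2L]
      }
      tibble::tibble(
        primary = if (called) d$codon[1L] else NA_character_,
        delta_to = d$delta_to[1L],
        delta_tu = d$delta_tu[1L],
        sig_to = !is.na(d$p_to[1L]) && d$p_to[1L] < alpha,
        sig_tu = !is.na(d$p_tu[1L]) && d$p_tu[1L] < alpha,
        secondary = secondary
      )
    }) |>
    dplyr::ungroup()
}

#' Fraction of genes with extreme use of a codon
#'
#' Extreme use is a per-gene RSCU at or above `threshold` (default 1.5).
#' Genes in which the codon's amino acid is absent are excluded from the
#' denominator.
#'
#' @param mat RSCU matrix from [rscu_matrix()].
#' @param codon A codon column name.
#' @param threshold RSCU cutoff, inclusive.
#' @return One-row tibble: `codon`, `n_extreme`, `n_genes`, `fraction`.
#' @export
extreme_use <- function(mat, codon, threshold = 1.5) {
  stopifnot(codon %in% names(mat))
  v <- mat[[codon]][!is.na(mat[[codon]])]
  tibble::tibble(
    codon = codon,
    n_extreme = sum(v >= threshold),
    n_genes = length(v),
    fraction = if (length(v) == 0) NA_real_ else sum(v >= threshold) / length(v)
  )
}

#' Compare extreme codon use between gene sets
#'
#' Pairwise 2x2 chi-square tests (extreme vs not, set vs set) on the
#' extreme-use counts of a codon across named gene sets.
#'
#' @param mats Named list of RSCU matrices.
#' @param codon Codon to test.
#' @param threshold RSCU cutoff, inclusive.
#' @return List with `per_set` (one row per set from [extreme_use()]) and
#'   `pairwise` (set pair, chi-square statistic, p).
#' @export
extreme_use_compare <- function(mats, codon, threshold = 1.5) {
  stopifnot(!is.null(names(mats)), all(names(mats) != ""))
  per_set <- purrr::imap(mats, function(m, nm) {
    dplyr::mutate(extreme_use(m, codon, threshold), set = nm, .before = 1L)
  }) |> dplyr::bind_rows()
  pairs <- utils::combn(names(mats), 2L, simplify = FALSE)
  pairwise <- purrr::map(pairs, function(p) {
    a <- per_set[per_set$set == p[1L], ]
    b <- per_set[per_set$set == p[2L], ]
    tab <- rbind(
      c(a$n_extreme, a$n_genes - a$n_extreme),
      c(b$n_extreme, b$n_genes - b$n_extreme)
    )
    res <- chi_square_test(tab)
    tibble::tibble(set_a = p[1L], set_b = p[2L],
                   statistic = res$statistic, p_value = res$p_value)
  }) |> dplyr::bind_rows()
  list(per_set = per_set, pairwise = pairwise)
}
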