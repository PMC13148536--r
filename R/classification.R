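#' Difference in RSCU between two concatenated profiles
#'
#' Elementwise `rscu_a - rscu_b` over the 59 degenerate-amino-acid codons.
#' Used with a highly expressed reference (e.g. ribosomal protein genes)
#' against the genome background, a positive value marks a codon enriched
#' in the reference. Because both profiles sum to the degeneracy within
#' each amino acid, the differences sum to zero per amino acid.
#'
#' @param rscu_a,rscu_b RSCU profiles from [rscu()] on pooled counts.
#' @return Tibble with columns `codon`, `aa`, `degeneracy`, `delta`.
#' @export
delta_rscu <- function(rscu_a, rscu_b) {
  a <- dplyr::filter(rscu_a, .data$degeneracy >= 2)
  b <- dplyr::filter(rscu_b, .data$degeneracy >= 2)
  dat <- dplyr::inner_join(
    dplyr::select(a, "codon", "aa", "degeneracy", rscu_a = "rscu"),
    dplyr::select(b, "codon", rscu_b = "rscu"),
    by = "codon"
  )
  bad <- dat$codon[is.na(dat$rscu_a) | is.na(dat$rscu_b)]
  if (length(bad) > 0) {
    stop("RSCU is NA for degenerate codon(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         "; both profiles must cover all 18 degenerate amino acids",
         call. = FALSE)
  }
  dat |>
    dplyr::mutate(delta = .data$rscu_a - .data$rscu_b) |>
    dplyr::select("codon", "aa", "degeneracy", "delta")
}

#' Assign the optimal codon per degenerate amino acid
#'
#' For each of the 18 degenerate amino acids, the codon with the largest
#' positive reference-vs-background delta-RSCU is called optimal; its
#' sister codons are non-optimal. Ties are broken towards the
#' alphabetically first codon and flagged (`tie`); an amino acid whose
#' maximum delta is not positive is still assigned its argmax but flagged
#' (`no_positive_optimal`) with a warning.
#'
#' @param delta Tibble from [delta_rscu()] covering all 59 codons.
#' @return A `codon_classification` tibble with columns `codon`, `aa`,
#'   `degeneracy`, `delta_rscu`, `optimality` (`"optimal"`/`"non_optimal"`),
#'   `tie`, `no_positive_optimal`.
#' @export
assign_optimal <- function(delta) {
  stopifnot(all(c("codon", "aa", "delta") %in% names(delta)))
  if (nrow(delta) != 59L) {
    stop("delta must cover exactly the 59 degenerate-amino-acid codons",
         call. = FALSE)
  }
  out <- delta |>
    dplyr::arrange(.data$aa, .data$codon) |>
    dplyr::group_by(.data$aa) |>
    dplyr::mutate(
      optimality = dplyr::if_else(
        seq_along(.data$delta) == which.max(.data$delta),
        "optimal", "non_optimal"
      ),
      tie = sum(.data$delta == max(.data$delta)) > 1L,
      no_positive_optimal = max(.data$delta) <= 0
    ) |>
    dplyr::ungroup() |>
    dplyr::rename(delta_rscu = "delta")
  flagged <- unique(out$aa[out$no_positive_optimal])
  if (length(flagged) > 0) {
    warning("no positive delta-RSCU for amino acid(s) ",
            paste(flagged, collapse = ", "),
            "; argmax assigned anyway (flag no_positive_optimal)",
            call. = FALSE)
  }
  new_codon_classification(out)
}

new_codon_classification <- function(x) {
  class(x) <- unique(c("codon_classification", class(x)))
  x
}

#' Stratify a codon classification by exact-match tRNA gene counts
#'
#' Adds the tRNA abundance status and the combined four-way label. The
#' high/low boundary is the median exact-match tRNA gene count over the 59
#' degenerate-amino-acid codons; counts strictly greater than the median
#' are "high", the rest "low". An optimal codon with zero exact matches is
#' a wobble codon (`Opt_wobble`); a non-optimal codon with zero matches
#' folds into low.
#'
#' @param classification A `codon_classification` from [assign_optimal()].
#' @param trna Tibble with columns `codon`, `count` (exact-match tRNA gene
#'   copy numbers); missing codons count as zero.
#' @return The classification with added columns `trna_count`,
#'   `trna_status` (`high_trna`/`low_trna`/`wobble`), `combined_label`, and
#'   a `trna_threshold` attribute.
#' @export
trna_status <- function(classification, trna) {
  stopifnot(all(c("codon", "count") %in% names(trna)))
  out <- classification |>
    dplyr::left_join(
      dplyr::select(trna, "codon", trna_count = "count"), by = "codon"
    ) |>
    dplyr::mutate(trna_count = dplyr::coalesce(.data$trna_count, 0L))
  threshold <- stats::median(out$trna_count)
  out <- out |>
    dplyr::mutate(
      trna_status = dplyr::case_when(
        .data$trna_count == 0 & .data$optimality == "optimal" ~ "wobble",
        .data$trna_count > threshold ~ "high_trna",
        TRUE ~ "low_trna"
      ),
      combined_label = paste0(
        dplyr::if_else(.data$optimality == "optimal", "Opt", "Non-opt"),
        dplyr::case_when(
          .data$trna_status == "wobble" ~ "_wobble",
          .data$trna_status == "high_trna" ~ "_high-tRNAs",
          TRUE ~ "_low-tRNAs"
        )
      )
    )
  attr(out, "trna_threshold") <- threshold
  new_codon_classification(out)
}

#' A priori codon classification from reference and background gene sets
#'
#' Convenience wrapper: pools codon counts of a highly expressed reference
#' set and of the background set, takes the RSCU difference, assigns one
#' optimal codon per degenerate amino acid, and (when a tRNA table is
#' given) stratifies by tRNA gene abundance.
#'
#' @param reference_cds,background_cds CDS tibbles (`gene_id`, `cds`). The
#'   reference is typically a ribosomal-protein gene set; the background is
#'   the whole gene catalogue.
#' @param trna Optional tRNA count table (`codon`, `count`).
#' @param skip_invalid Passed to [codon_counts()].
#' @return A `codon_classification` tibble; see [assign_optimal()] and
#'   [trna_status()].
#' @export
classify_codons <- function(reference_cds, background_cds, trna = NULL,
                            skip_invalid = FALSE) {
  ref <- rscu(pool_counts(codon_counts(reference_cds, skip_invalid)))
  bg <- rscu(pool_counts(codon_counts(background_cds, skip_invalid)))
  cls <- assign_optimal(delta_rscu(ref, bg))
  if (!is.null(trna)) cls <- trna_status(cls, trna)
  cls
}

#' @export
glance.codon_classification <- function(x, ...) {
  out <- tibble::tibble(
    n_codons = nrow(x),
    n_optimal = sum(x$optimality == "optimal"),
    n_non_optimal = sum(x$optimality == "non_optimal"),
    n_ties = sum(x$tie & x$optimality == "optimal"),
    n_no_positive = sum(x$no_positive_optimal & x$optimality == "optimal")
  )
  if ("trna_status" %in% names(x)) {
    out$n_wobble <- sum(x$trna_status == "wobble")
    out$trna_threshold <- attr(x, "trna_threshold")
  }
  out
}

#' @export
autoplot.codon_classification <- function(object, ...) {
  fill_var <- if ("combined_label" %in% names(object)) "combined_label"
              else "optimality"
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$codon, y = .data$delta_rscu,
                 fill = .data[[fill_var]])
  ) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$aa), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "delta-RSCU (reference - background)",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 90, vjust = 0.5, size = 6))
}
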