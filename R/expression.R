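#' Tissue-specificity index tau
#'
#' `tau = sum(1 - x_i / max(x)) / (n - 1)` over an expression row: 0 for
#' perfectly uniform expression, 1 for single-tissue expression. Computed
#' on the supplied scale; pass `log2(x + 1)`-transformed values if a
#' compressed scale is wanted.
#'
#' @param x Non-negative expression vector over >= 2 tissues.
#' @return tau in `[0, 1]`, or `NA` for an all-zero row.
#' @export
#' @examples
#' tau(c(1, 1, 1, 1))   # 0
#' tau(c(0, 0, 5, 0))   # 1
#' tau(c(1, 0.5))       # 0.5
tau <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("tau needs >= 2 tissues", call. = FALSE)
  if (any(x < 0)) stop("tau is undefined for negative expression", call. = FALSE)
  m <- max(x)
  if (m == 0) return(NA_real_)
  sum(1 - x / m) / (length(x) - 1L)
}

#' Classify genes by sex-biased gonad expression
#'
#' Applies RPKM and fold-change rules over a designated focal tissue pair
#' (default testis vs ovary): a gene is testis-biased when
#' `testis / ovary >= fold` and testis expression is at least `min_rpkm`
#' (ovary-biased symmetrically), unbiased when the fold-bias is below
#' `fold` and at least one focal tissue reaches `min_rpkm`, and excluded
#' otherwise. A pseudocount is added to both focal values before the ratio
#' so that zero expression in one gonad does not produce an infinite fold.
#' tau is computed across all tissue columns.
#'
#' @param expr Tibble with a `gene_id` column and one numeric column per
#'   tissue; must contain both focal tissues.
#' @param focal Length-2 character vector naming the focal pair, in the
#'   order (male tissue, female tissue).
#' @param min_rpkm Minimum focal expression (RPKM) for inclusion.
#' @param fold Fold-bias threshold (inclusive, as in ">= 5-fold").
#' @param pseudocount Added to both focal values before the ratio.
#' @param sex_specific_floor A biased gene is sex-specific when its minor
#'   focal tissue is below this RPKM floor.
#' @param log2_tau Compute tau on `log2(x + 1)` instead of raw values.
#' @return Tibble with columns `gene_id`, the two focal values, `fold_bias`
#'   (>= 1), `sex_class` (`testis_biased`/`ovary_biased`/`unbiased`/
#'   `excluded`), `sex_specific`, `tau`.
#' @export
classify_sex_bias <- function(expr, focal = c("testis", "ovary"),
                              min_rpkm = 100, fold = 5, pseudocount = 0.01,
                              sex_specific_floor = 1, log2_tau = FALSE) {
  stopifnot("gene_id" %in% names(expr), length(focal) == 2L)
  if (!all(focal %in% names(expr))) {
    stop("focal tissue(s) missing from the expression table: ",
         paste(setdiff(focal, names(expr)), collapse = ", "), call. = FALSE)
  }
  tissue_cols <- setdiff(names(expr), "gene_id")
  mat <- as.matrix(expr[tissue_cols])
  if (any(mat < 0, na.rm = TRUE)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  t_val <- expr[[focal[1L]]]
  o_val <- expr[[focal[2L]]]
  missing_focal <- is.na(t_val) | is.na(o_val)
  if (any(missing_focal)) {
    warning(sum(missing_focal), " gene(s) with missing focal expression ",
            "excluded", call. = FALSE)
  }
  ratio <- (t_val + pseudocount) / (o_val + pseudocount)
  fold_bias <- pmax(ratio, 1 / ratio)
  sex_class <- dplyr::case_when(
    missing_focal ~ "excluded",
    ratio >= fold & t_val >= min_rpkm ~ "testis_biased",
    1 / ratio >= fold & o_val >= min_rpkm ~ "ovary_biased",
    fold_bias < fold & pmax(t_val, o_val) >= min_rpkm ~ "unbiased",
    TRUE ~ "excluded"
  )
  tau_mat <- if (log2_tau) log2(mat + 1) else mat
  tau_vals <- apply(tau_mat, 1L, function(row) {
    if (all(is.na(row)) || max(row, na.rm = TRUE) == 0) NA_real_ else tau(row)
  })
  tibble::tibble(
    gene_id = expr$gene_id,
    !!focal[1L] := t_val,
    !!focal[2L] := o_val,
    fold_bias = fold_bias,
    sex_class = sex_class,
    sex_specific = sex_class %in% c("testis_biased", "ovary_biased") &
      pmin(t_val, o_val) < sex_specific_floor,
    tau = tau_vals
  )
}

#' Add expression and CDS-length subclasses to gene class records
#'
#' Splits the studied genes into extremely high (`>= expr_cutoff` RPKM in
#' the more expressed focal tissue) versus high expression, and into long
#' (`>= length_cutoff` codons) versus short CDS classes.
#'
#' @param records Output of [classify_sex_bias()].
#' @param cds_tbl CDS tibble (`gene_id`, `cds`); genes without a CDS get
#'   `length_class = NA`.
#' @param expr_cutoff RPKM boundary between high and extreme (inclusive).
#' @param length_cutoff Codon-count boundary for "long" (inclusive).
#' @param focal Focal tissue column names present in `records`.
#' @return `records` with added columns `focal_rpkm`, `expr_class`
#'   (`extreme`/`high`, `NA` below `min_rpkm` classes), `n_codons`,
#'   `length_class` (`long`/`short`).
#' @export
subclass_genes <- function(records, cds_tbl, expr_cutoff = 200,
                           length_cutoff = 272,
                           focal = c("testis", "ovary")) {
  stopifnot(all(focal %in% names(records)))
  lens <- tibble::tibble(
    gene_id = cds_tbl$gene_id,
    n_codons = purrr::map2_int(cds_tbl$cds, cds_tbl$gene_id,
                               ~ length(split_codons(.x, .y)))
  )
  records |>
    dplyr::mutate(
      focal_rpkm = pmax(.data[[focal[1L]]], .data[[focal[2L]]]),
      expr_class = dplyr::if_else(.data$focal_rpkm >= expr_cutoff,
                                  "extreme", "high")
    ) |>
    dplyr::left_join(lens, by = "gene_id") |>
    dplyr::mutate(
      length_class = dplyr::case_when(
        is.na(.data$n_codons) ~ NA_character_,
        .data$n_codons >= length_cutoff ~ "long",
        TRUE ~ "short"
      )
    )
}
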