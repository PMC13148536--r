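#' Join coding sequences to per-residue structure predictions
#'
#' Pairs codon i of each gene with residue i of its structure table
#' (NetsurfP-style: relative solvent accessibility, disorder probability,
#' secondary-structure class) and validates the pairing: the protein
#' length must equal the codon count and every codon must translate to the
#' reported amino acid. Eight-class secondary-structure codes are folded
#' to three (H, G, I -> helix; E, B -> strand; the rest -> coil).
#'
#' @param cds_tbl CDS tibble (`gene_id`, `cds`).
#' @param residues Tibble with columns `gene_id`, `position` (1-based),
#'   `aa`, `rsa`, `disorder`, `ss_class`.
#' @return Residue tibble with an added `codon` column and normalised
#'   `ss_class` in `helix`/`strand`/`coil`.
#' @export
join_cds_structure <- function(cds_tbl, residues) {
  needed <- c("gene_id", "position", "aa", "rsa", "disorder", "ss_class")
  stopifnot(all(needed %in% names(residues)))
  if (any(residues$rsa < 0 | residues$rsa > 1, na.rm = TRUE) ||
      any(residues$disorder < 0 | residues$disorder > 1, na.rm = TRUE)) {
    stop("rsa and disorder must lie in [0, 1]", call. = FALSE)
  }
  codon_long <- cds_tbl |>
    dplyr::mutate(codon = purrr::map2(.data$cds, .data$gene_id, split_codons)) |>
    dplyr::select("gene_id", "codon") |>
    tidyr::unnest("codon") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(position = dplyr::row_number()) |>
    dplyr::ungroup()
  shared <- intersect(unique(codon_long$gene_id), unique(residues$gene_id))
  if (length(shared) == 0) {
    stop("no genes shared between the CDS and structure tables",
         call. = FALSE)
  }
  len_cds <- codon_long |>
    dplyr::filter(.data$gene_id %in% shared) |>
    dplyr::count(.data$gene_id, name = "n_codons")
  len_res <- residues |>
    dplyr::filter(.data$gene_id %in% shared) |>
    dplyr::count(.data$gene_id, name = "n_residues")
  lens <- dplyr::inner_join(len_cds, len_res, by = "gene_id") |>
    dplyr::filter(.data$n_codons != .data$n_residues)
  if (nrow(lens) > 0) {
    stop("protein length != codon count for gene '", lens$gene_id[1L],
         "' (", lens$n_codons[1L], " codons vs ", lens$n_residues[1L],
         " residues)", call. = FALSE)
  }
  out <- residues |>
    dplyr::filter(.data$gene_id %in% shared) |>
    dplyr::mutate(ss_class = normalize_ss(.data$ss_class)) |>
    dplyr::inner_join(codon_long, by = c("gene_id", "position"))
  mism <- out |>
    dplyr::filter(translate_codons(.data$codon) != .data$aa) |>
    dplyr::arrange(.data$gene_id, .data$position)
  if (nrow(mism) > 0) {
    stop("codon/residue translation mismatch: gene '", mism$gene_id[1L],
         "' position ", mism$position[1L], " (codon ", mism$codon[1L],
         " encodes ", translate_codons(mism$codon[1L]), ", residue says ",
         mism$aa[1L], ")", call. = FALSE)
  }
  dplyr::arrange(out, .data$gene_id, .data$position)
}

# 8-class (DSSP-style) or 3-class secondary-structure vocabulary -> 3-class
normalize_ss <- function(ss) {
  ss <- as.character(ss)
  dplyr::case_when(
    ss %in% c("helix", "strand", "coil") ~ ss,
    ss %in% c("H", "G", "I") ~ "helix",
    ss %in% c("E", "B") ~ "strand",
    TRUE ~ "coil"
  )
}

#' Percent of non-optimal codon use per gene
#'
#' `100 * (non-optimal codons) / (degenerate-amino-acid codons)` per gene;
#' Met, Trp and the stop codon are excluded from the denominator. Genes
#' are binned at the low (<= 50), moderate (> 50 to <= 60) and high
#' (> 60) percent cutoffs.
#'
#' @param cds_tbl CDS tibble (`gene_id`, `cds`).
#' @param classification A `codon_classification` with `optimality`.
#' @param bin_breaks Upper bounds of the low and moderate bins.
#' @return Tibble: `gene_id`, `n_degenerate`, `percent_nonopt`, `bin`
#'   (factor low/moderate/high; `NA` when the gene has no degenerate-aa
#'   codons).
#' @export
percent_nonopt <- function(cds_tbl, classification, bin_breaks = c(50, 60)) {
  stopifnot(length(bin_breaks) == 2L, bin_breaks[1L] < bin_breaks[2L])
  nonopt_codons <- classification$codon[
    classification$optimality == "non_optimal"]
  counts <- codon_counts(cds_tbl) |>
    dplyr::inner_join(codon_table(), by = "codon") |>
    dplyr::filter(.data$degenerate)
  counts |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_degenerate = sum(.data$count),
      percent_nonopt = dplyr::if_else(
        .data$n_degenerate > 0,
        100 * sum(.data$count[.data$codon %in% nonopt_codons]) /
          .data$n_degenerate,
        NA_real_
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      bin = cut(.data$percent_nonopt,
                breaks = c(-Inf, bin_breaks, Inf),
                labels = c("low", "moderate", "high"),
                right = TRUE)
    )
}

#' Per-gene summary joining codon use and structure
#'
#' Combines [percent_nonopt()] with per-gene average RSA over the joined
#' residue records.
#'
#' @param cds_tbl CDS tibble.
#' @param classification A `codon_classification`.
#' @param residues Joined residue records from [join_cds_structure()].
#' @param center `"mean"` (default) or `"median"` per-gene RSA summary.
#' @param bin_breaks Passed to [percent_nonopt()].
#' @return Tibble: `gene_id`, `n_degenerate`, `percent_nonopt`, `bin`,
#'   `mean_rsa`, `n_residues`.
#' @export
gene_structure_summary <- function(cds_tbl, classification, residues,
                                   center = c("mean", "median"),
                                   bin_breaks = c(50, 60)) {
  center <- match.arg(center)
  fun <- if (center == "mean") mean else stats::median
  rsa_per_gene <- residues |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(mean_rsa = fun(.data$rsa),
                     n_residues = dplyr::n(), .groups = "drop")
  percent_nonopt(cds_tbl, classification, bin_breaks) |>
    dplyr::inner_join(rsa_per_gene, by = "gene_id")
}

#' Compare per-gene RSA across percent-non-optimal bins
#'
#' Reports the per-bin median and mean of gene-wide RSA and two-sided
#' Mann-Whitney U tests for every bin pair. A bin with fewer than two
#' genes yields `NA` comparisons with a warning.
#'
#' @param summaries Output of [gene_structure_summary()].
#' @return List with `per_bin` (bin, n, median/mean RSA) and `pairwise`
#'   (bin pair, U statistic, p).
#' @export
bin_rsa_comparison <- function(summaries) {
  dat <- dplyr::filter(summaries, !is.na(.data$bin))
  per_bin <- dat |>
    dplyr::group_by(bin = .data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     median_rsa = stats::median(.data$mean_rsa),
                     mean_rsa = mean(.data$mean_rsa), .groups = "drop")
  bins <- levels(dat$bin)
  pairs <- utils::combn(bins, 2L, simplify = FALSE)
  pairwise <- purrr::map(pairs, function(p) {
    a <- dat$mean_rsa[dat$bin == p[1L]]
    b <- dat$mean_rsa[dat$bin == p[2L]]
    if (length(a) < 2L || length(b) < 2L) {
      warning("bin comparison ", p[1L], " vs ", p[2L],
              " skipped: fewer than 2 genes in a bin", call. = FALSE)
      return(tibble::tibble(bin_a = p[1L], bin_b = p[2L],
                            statistic = NA_real_, p_value = NA_real_,
                            n_a = length(a), n_b = length(b)))
    }
    res <- mwu_test(a, b)
    tibble::tibble(bin_a = p[1L], bin_b = p[2L],
                   statistic = res$statistic, p_value = res$p_value,
                   n_a = length(a), n_b = length(b))
  }) |> dplyr::bind_rows()
  list(per_bin = per_bin, pairwise = pairwise)
}

#' Secondary-structure composition and per-class RSA
#'
#' Residue fractions of helix, strand and coil (summing to one), the
#' median RSA per class, and pairwise Mann-Whitney U tests between
#' classes.
#'
#' @param residues Residue tibble with `ss_class` and `rsa`.
#' @return List with `per_class` (class, n, fraction, median RSA) and
#'   `pairwise` MWU results.
#' @export
ss_composition <- function(residues) {
  if (nrow(residues) == 0) stop("no residues", call. = FALSE)
  dat <- dplyr::mutate(
    residues,
    ss_class = factor(normalize_ss(.data$ss_class),
                      c("helix", "strand", "coil"))
  )
  per_class <- dat |>
    dplyr::group_by(.data$ss_class, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(),
                     median_rsa = stats::median(.data$rsa),
                     .groups = "drop") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
  present <- as.character(per_class$ss_class[per_class$n >= 2L])
  pairwise <- NULL
  if (length(present) >= 2L) {
    pairs <- utils::combn(present, 2L, simplify = FALSE)
    pairwise <- purrr::map(pairs, function(p) {
      res <- mwu_test(dat$rsa[dat$ss_class == p[1L]],
                      dat$rsa[dat$ss_class == p[2L]])
      tibble::tibble(class_a = p[1L], class_b = p[2L],
                     statistic = res$statistic, p_value = res$p_value)
    }) |> dplyr::bind_rows()
  }
  list(per_class = per_class, pairwise = pairwise)
}

#' Per-amino-acid RSA under the primary non-optimal versus optimal codon
#'
#' For every degenerate amino acid with a primary non-optimal call,
#' compares the average RSA of residues encoded by the primary non-optimal
#' codon against residues encoded by the optimal codon, and runs an exact
#' two-sided sign test on the number of amino acids whose non-optimal mean
#' is the higher of the two. Amino acids lacking residues under either
#' codon are excluded from the test (and reported).
#'
#' @param residues Joined residue records from [join_cds_structure()].
#' @param classification A `codon_classification`.
#' @param primary Primary non-optimal calls from
#'   [identify_primary_nonoptimal()].
#' @param center `"mean"` (default, with standard errors) or `"median"`.
#' @return An `rsa_codon_comparison` list: `per_aa` (aa, codons, per-class
#'   RSA summaries, direction), `sign_test` tibble, `n_compared`,
#'   `excluded_aa`.
#' @export
rsa_by_codon <- function(residues, classification, primary,
                         center = c("mean", "median")) {
  center <- match.arg(center)
  fun <- if (center == "mean") mean else stats::median
  opt <- classification |>
    dplyr::filter(.data$optimality == "optimal") |>
    dplyr::select("aa", optimal_codon = "codon")
  calls <- primary |>
    dplyr::filter(!is.na(.data$primary)) |>
    dplyr::select("aa", nonopt_codon = "primary") |>
    dplyr::inner_join(opt, by = "aa")
  per_aa <- calls |>
    dplyr::group_by(.data$aa) |>
    dplyr::group_modify(function(d, key) {
      r_non <- residues$rsa[residues$codon == d$nonopt_codon]
      r_opt <- residues$rsa[residues$codon == d$optimal_codon]
      tibble::tibble(
        nonopt_codon = d$nonopt_codon,
        optimal_codon = d$optimal_codon,
        n_nonopt = length(r_non),
        n_optimal = length(r_opt),
        rsa_nonopt = if (length(r_non)) fun(r_non) else NA_real_,
        rsa_optimal = if (length(r_opt)) fun(r_opt) else NA_real_,
        se_nonopt = if (length(r_non) > 1)
          stats::sd(r_non) / sqrt(length(r_non)) else NA_real_,
        se_optimal = if (length(r_opt) > 1)
          stats::sd(r_opt) / sqrt(length(r_opt)) else NA_real_
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(nonopt_higher = .data$rsa_nonopt > .data$rsa_optimal)
  compared <- dplyr::filter(per_aa, .data$n_nonopt > 0, .data$n_optimal > 0)
  excluded <- setdiff(per_aa$aa, compared$aa)
  st <- if (nrow(compared) >= 5L) {
    sign_test(sum(compared$nonopt_higher), nrow(compared))
  } else {
    tibble::tibble(statistic = NA_integer_, n = nrow(compared),
                   p_value = NA_real_,
                   method = "exact sign test (two-sided, doubled tail)")
  }
  structure(
    list(per_aa = per_aa, sign_test = st,
         n_compared = nrow(compared), excluded_aa = excluded),
    class = "rsa_codon_comparison"
  )
}

#' @export
tidy.rsa_codon_comparison <- function(x, ...) x$per_aa

#' @export
glance.rsa_codon_comparison <- function(x, ...) {
  tibble::tibble(
    n_compared = x$n_compared,
    n_nonopt_higher = sum(x$per_aa$nonopt_higher, na.rm = TRUE),
    sign_test_p = x$sign_test$p_value
  )
}

#' @export
print.rsa_codon_comparison <- function(x, ...) {
  cat("RSA by codon class across", x$n_compared,
      "degenerate amino acids\n")
  cat(" higher RSA under the primary non-optimal codon:",
      sum(x$per_aa$nonopt_higher, na.rm = TRUE), "of", x$n_compared, "\n")
  cat(" sign test p =", format(x$sign_test$p_value, digits = 4), "\n")
  invisible(x)
}

#' @export
autoplot.rsa_codon_comparison <- function(object, ...) {
  dat <- object$per_aa |>
    tidyr::pivot_longer(c("rsa_nonopt", "rsa_optimal"),
                        names_to = "codon_class", values_to = "rsa") |>
    dplyr::mutate(codon_class = dplyr::recode(
      .data$codon_class,
      rsa_nonopt = "primary non-optimal", rsa_optimal = "optimal"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$aa, y = .data$rsa,
                                    fill = .data$codon_class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "amino acid", y = "average RSA", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Correlation between RSA and disorder across residues
#'
#' @param residues Residue tibble with `rsa` and `disorder`.
#' @return One-row tibble from [spearman_test()].
#' @export
rsa_disorder_correlation <- function(residues) {
  if (nrow(residues) < 10L) stop(">= 10 residues required", call. = FALSE)
  spearman_test(residues$rsa, residues$disorder)
}
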