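make_residues <- function(gene_id, codons, rsa = NULL, disorder = NULL,
                          ss = "coil") {
  n <- length(codons)
  tibble::tibble(
    gene_id = gene_id,
    position = seq_len(n),
    aa = translate_codons(codons),
    rsa = if (is.null(rsa)) rep(0.5, n) else rsa,
    disorder = if (is.null(disorder)) rep(0.5, n) else disorder,
    ss_class = rep(ss, length.out = n)
  )
}

test_that("join_cds_structure pairs codons with residues and validates", {
  codons <- c("GGA", "TTC", "AAG")
  cds <- tibble::tibble(gene_id = "g1", cds = make_cds(codons))
  res <- join_cds_structure(cds, make_residues("g1", codons))
  expect_equal(nrow(res), 3L)
  expect_equal(res$codon, codons)

  # length mismatch
  bad_len <- make_residues("g1", c(codons, "GGA"))
  expect_error(join_cds_structure(cds, bad_len), "length")

  # translation mismatch names the first offending position
  bad_aa <- make_residues("g1", codons)
  bad_aa$aa[2] <- "K"
  expect_error(join_cds_structure(cds, bad_aa), "position 2")

  # out-of-range scores
  bad_rsa <- make_residues("g1", codons)
  bad_rsa$rsa[1] <- 1.4
  expect_error(join_cds_structure(cds, bad_rsa), "\\[0, 1\\]")

  # 8-class codes fold to 3
  eight <- make_residues("g1", codons)
  eight$ss_class <- c("H", "E", "S")
  res8 <- join_cds_structure(cds, eight)
  expect_equal(res8$ss_class, c("helix", "strand", "coil"))
})

test_that("percent_nonopt excludes Met/Trp and bins at 50/60", {
  cls <- fixture_classification()
  des <- designate_codons()
  opt <- des$optimal
  non <- des$primary_nonopt

  all_opt <- tibble::tibble(gene_id = "a", cds = make_cds("ATG", opt))
  res <- percent_nonopt(all_opt, cls)
  expect_equal(res$percent_nonopt, 0)
  expect_equal(as.character(res$bin), "low")

  # 73% non-optimal (73 of 100 degenerate codons) -> high bin; Met/Trp
  # padding must not change the denominator
  gene73 <- tibble::tibble(gene_id = "b", cds = make_cds(
    rep("ATG", 5), rep("TGG", 5),
    rep(non[1], 73), rep(opt[1], 27)))
  res73 <- percent_nonopt(gene73, cls)
  expect_equal(res73$percent_nonopt, 73)
  expect_equal(res73$n_degenerate, 100L)
  expect_equal(as.character(res73$bin), "high")

  # boundary: exactly 50 -> low; just above -> moderate; 60 -> moderate
  half <- tibble::tibble(gene_id = "c",
                         cds = make_cds(rep(non[1], 5), rep(opt[1], 5)))
  expect_equal(as.character(percent_nonopt(half, cls)$bin), "low")
  m60 <- tibble::tibble(gene_id = "d",
                        cds = make_cds(rep(non[1], 6), rep(opt[1], 4)))
  expect_equal(as.character(percent_nonopt(m60, cls)$bin), "moderate")
  m61 <- tibble::tibble(gene_id = "e",
                        cds = make_cds(rep(non[1], 61), rep(opt[1], 39)))
  expect_equal(as.character(percent_nonopt(m61, cls)$bin), "high")

  # complement property: percent_opt + percent_nonopt = 100
  set.seed(3)
  rand <- tibble::tibble(gene_id = "r", cds = make_cds(
    sample(degenerate_codons(), 80, replace = TRUE)))
  p <- percent_nonopt(rand, cls)$percent_nonopt
  opt_codons <- cls$codon[cls$optimality == "optimal"]
  counts <- dplyr::filter(codon_counts(rand),
                          codon %in% degenerate_codons())
  p_opt <- 100 * sum(counts$count[counts$codon %in% opt_codons]) /
    sum(counts$count)
  expect_equal(p + p_opt, 100, tolerance = 1e-9)

  # Met-only gene -> NA percent and bin
  met <- tibble::tibble(gene_id = "m", cds = "ATGATGTAA")
  expect_true(is.na(percent_nonopt(met, cls)$percent_nonopt))
})

test_that("bin RSA comparison separates shifted distributions and
           degrades gracefully", {
  set.seed(41)
  # two bins from Beta distributions centred at 0.40 and 0.47
  n <- 200
  summaries <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:(2 * n)),
    n_degenerate = 100L,
    percent_nonopt = c(rep(30, n), rep(70, n)),
    bin = factor(c(rep("low", n), rep("high", n)),
                 levels = c("low", "moderate", "high")),
    mean_rsa = c(rbeta(n, 0.40 * 30, 0.60 * 30),
                 rbeta(n, 0.47 * 30, 0.53 * 30)),
    n_residues = 100L
  )
  expect_warning(res <- bin_rsa_comparison(summaries), "fewer than 2")
  low <- res$per_bin[res$per_bin$bin == "low", ]
  high <- res$per_bin[res$per_bin$bin == "high", ]
  expect_gt(high$median_rsa, low$median_rsa)
  lh <- res$pairwise[res$pairwise$bin_a == "low" &
                       res$pairwise$bin_b == "high", ]
  expect_lt(lh$p_value, 0.05)
  # the empty moderate bin yields NA comparisons
  expect_true(is.na(res$pairwise$p_value[res$pairwise$bin_b == "moderate"][1]))

  # identical distributions -> large p
  null_sum <- summaries
  null_sum$mean_rsa <- rep(rbeta(n, 12, 18), 2)
  res_null <- suppressWarnings(bin_rsa_comparison(null_sum))
  expect_gt(res_null$pairwise$p_value[res_null$pairwise$bin_a == "low" &
                                        res_null$pairwise$bin_b == "high"],
            0.9)
})

test_that("secondary-structure composition sums to one and recovers the
           RSA ordering strand < helix < coil", {
  set.seed(8)
  n <- 400
  residues <- tibble::tibble(
    gene_id = "g",
    position = 1:(3 * n),
    aa = "G",
    rsa = c(rbeta(n, 0.13 * 8, 0.87 * 8),
            rbeta(n, 0.34 * 8, 0.66 * 8),
            rbeta(n, 0.53 * 8, 0.47 * 8)),
    disorder = 0.5,
    ss_class = rep(c("strand", "helix", "coil"), each = n)
  )
  res <- ss_composition(residues)
  expect_equal(sum(res$per_class$fraction), 1)
  med <- res$per_class$median_rsa[match(c("strand", "helix", "coil"),
                                        as.character(res$per_class$ss_class))]
  expect_true(med[1] < med[2] && med[2] < med[3])
  expect_true(all(res$pairwise$p_value < 0.05))

  # all-coil input
  coil_only <- dplyr::mutate(residues, ss_class = "coil")
  res2 <- ss_composition(coil_only)
  expect_equal(res2$per_class$fraction[res2$per_class$ss_class == "coil"], 1)
})

test_that("rsa_by_codon compares per-aa means and applies the exact sign
           test", {
  set.seed(19)
  cls <- fixture_classification()
  des <- designate_codons()
  primary <- tibble::tibble(aa = des$aa, primary = des$primary_nonopt)
  n <- 300
  residues <- purrr::map(seq_len(nrow(des)), function(i) {
    tibble::tibble(
      gene_id = "g",
      position = 1L,
      aa = des$aa[i],
      rsa = c(pmin(1, rbeta(n, 0.45 * 8, 0.55 * 8) + 0.10),
              rbeta(n, 0.45 * 8, 0.55 * 8)),
      disorder = 0.5,
      ss_class = "coil",
      codon = c(rep(des$primary_nonopt[i], n), rep(des$optimal[i], n))
    )
  }) |> dplyr::bind_rows()
  res <- rsa_by_codon(residues, cls, primary)
  expect_s3_class(res, "rsa_codon_comparison")
  expect_equal(res$n_compared, 18L)
  expect_true(all(res$per_aa$nonopt_higher))
  expect_equal(res$sign_test$p_value, 2 * 0.5^18)
  expect_equal(glance(res)$n_nonopt_higher, 18L)

  # row order invariance
  shuffled <- residues[sample(nrow(residues)), ]
  res2 <- rsa_by_codon(shuffled, cls, primary)
  expect_equal(res2$per_aa, res$per_aa)

  # amino acids without residues under one codon class drop out
  partial <- dplyr::filter(residues,
                           !(aa == "K" & codon == des$optimal[des$aa == "K"]))
  res3 <- rsa_by_codon(partial, cls, primary)
  expect_equal(res3$n_compared, 17L)
  expect_true("K" %in% res3$excluded_aa)

  # fewer than 5 comparable amino acids -> sign test NA
  few <- dplyr::filter(residues, aa %in% c("A", "C", "D"))
  res4 <- rsa_by_codon(few, cls, primary[primary$aa %in% c("A", "C", "D"), ])
  expect_true(is.na(res4$sign_test$p_value))
})

test_that("rsa-disorder correlation behaves at the extremes", {
  set.seed(55)
  n <- 300
  rsa <- runif(n)
  exact <- tibble::tibble(gene_id = "g", position = 1:n, aa = "G",
                          rsa = rsa, disorder = rsa, ss_class = "coil")
  expect_equal(rsa_disorder_correlation(exact)$estimate, 1)
  indep <- dplyr::mutate(exact, disorder = runif(n))
  expect_lt(abs(rsa_disorder_correlation(indep)$estimate), 0.15)
  const <- dplyr::mutate(exact, disorder = 0.5)
  expect_true(is.na(rsa_disorder_correlation(const)$estimate))
  expect_error(rsa_disorder_correlation(exact[1:5, ]), ">= 10")
})
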