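test_that("rscu_matrix rows match per-gene profiles, NA where the amino
           acid is absent", {
  cds <- tibble::tibble(gene_id = "g1",
                        cds = make_cds(rep("GGA", 3), "GGC", "TTC"))
  mat <- rscu_matrix(cds)
  prof <- rscu(count_codons(cds$cds))
  expect_equal(mat$GGA, prof$rscu[prof$codon == "GGA"])
  expect_equal(mat$GGA, 3)
  expect_equal(mat$TTC, 2)
  # gene lacking Cys -> NA in both Cys columns
  expect_true(is.na(mat$TGC) && is.na(mat$TGT))
  expect_equal(ncol(mat), 60L)  # gene_id + 59 codons
  expect_error(rscu_matrix(cds[0, ]), "empty")
})

test_that("column means of identical equal-length genes equal the pooled
           profile", {
  cds <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    cds = rep(make_cds(rep("GGA", 2), "GGC", "TTC", "TTT", "AAG"), 3)
  )
  mat <- rscu_matrix(cds)
  pooled <- rscu(pool_counts(codon_counts(cds)))
  for (cod in c("GGA", "GGC", "TTC", "AAG")) {
    expect_equal(mean(mat[[cod]]), pooled$rscu[pooled$codon == cod])
  }
})

test_that("contrast deltas are mean differences with antisymmetry and a
           null self-contrast", {
  set.seed(91)
  des <- designate_codons()
  a <- sim_gene_set(5, 200, 0.2, set_preferences(des, nonopt_shift = 0.3),
                    conc = 20, prefix = "a")
  b <- sim_gene_set(5, 200, 0.2, set_preferences(des), conc = 20,
                    prefix = "b")
  ma <- rscu_matrix(a); mb <- rscu_matrix(b)
  res <- contrast_rscu(ma, mb)

  # brute-force means per codon
  for (cod in c("GGA", "GCC", "AAG", "TTT")) {
    av <- ma[[cod]][!is.na(ma[[cod]])]
    bv <- mb[[cod]][!is.na(mb[[cod]])]
    expect_equal(res$delta[res$codon == cod], mean(av) - mean(bv),
                 tolerance = 1e-12)
  }
  # antisymmetry
  rev <- contrast_rscu(mb, ma)
  expect_equal(res$delta, -rev$delta)
  # self-contrast: zero deltas, p = 1
  self <- contrast_rscu(ma, ma)
  expect_equal(self$delta, rep(0, 59))
  expect_true(all(is.na(self$p_value) | self$p_value > 0.999))
})

test_that("a codon with n < 2 in either set reports delta but no test", {
  one <- rscu_matrix(tibble::tibble(
    gene_id = "a", cds = make_cds("GGA", "GGC", "TTC")))
  many <- rscu_matrix(tibble::tibble(
    gene_id = c("b", "c"),
    cds = c(make_cds("GGA", "GGA", "TTC"), make_cds("GGC", "GGC", "TTT"))))
  res <- contrast_rscu(one, many)
  gga <- res[res$codon == "GGA", ]
  expect_false(is.na(gga$delta))
  expect_true(is.na(gga$t_statistic) && is.na(gga$p_value))
  expect_equal(gga$n_a, 1L)
})

test_that("primary non-optimal calls follow the ranked gate rule", {
  cls <- fixture_classification()
  des <- designate_codons()
  # synthetic contrasts: designated primary has the top positive delta in
  # both; other non-optimal codons negative
  mk <- function(scale) {
    dplyr::filter(codon_table(), degenerate) |>
      dplyr::left_join(des, by = "aa") |>
      dplyr::mutate(
        delta = dplyr::case_when(
          codon == optimal ~ -0.3 * scale,
          codon == primary_nonopt ~ 0.25 * scale,
          TRUE ~ 0.05 * scale / 4
        ),
        t_statistic = 3, p_value = 0.01,
        n_a = 50L, n_b = 50L
      ) |>
      dplyr::select(codon, aa, delta, t_statistic, p_value, n_a, n_b)
  }
  calls <- identify_primary_nonoptimal(mk(1), mk(1.5), cls)
  expect_equal(nrow(calls), 18L)
  expect_equal(calls$primary[match(des$aa, calls$aa)], des$primary_nonopt)
  expect_true(all(calls$sig_tu))

  # 2-fold amino acid: single non-optimal codon is primary iff both
  # deltas positive
  neg <- mk(1)
  neg$delta[neg$aa == "K"] <- -abs(neg$delta[neg$aa == "K"])
  calls2 <- identify_primary_nonoptimal(neg, mk(1.5), cls)
  expect_true(is.na(calls2$primary[calls2$aa == "K"]))
  expect_false(anyNA(calls2$primary[calls2$aa != "K"]))
})

test_that("a close runner-up is reported as a secondary codon", {
  cls <- fixture_classification()
  des <- designate_codons()
  # Gly: designated primary GGA; make GGT reach 90% of its delta
  mk <- function() {
    dplyr::filter(codon_table(), degenerate) |>
      dplyr::left_join(des, by = "aa") |>
      dplyr::mutate(
        delta = dplyr::case_when(
          codon == "GGT" ~ 0.18,
          codon == optimal ~ -0.3,
          codon == primary_nonopt ~ 0.2,
          TRUE ~ -0.01
        ),
        t_statistic = 2, p_value = 0.04, n_a = 50L, n_b = 50L
      ) |>
      dplyr::select(codon, aa, delta, t_statistic, p_value, n_a, n_b)
  }
  calls <- identify_primary_nonoptimal(mk(), mk(), cls)
  expect_equal(calls$primary[calls$aa == "G"], "GGA")
  expect_equal(calls$secondary[calls$aa == "G"], "GGT")
  expect_true(is.na(calls$secondary[calls$aa == "K"]))
  calls80 <- identify_primary_nonoptimal(mk(), mk(), cls,
                                         secondary_frac = 0.95)
  expect_true(is.na(calls80$secondary[calls80$aa == "G"]))
})

test_that("extreme use counts RSCU >= threshold inclusively over non-NA
           genes", {
  mat <- rscu_matrix(tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    cds = c(make_cds(rep("GGA", 4)),          # RSCU 4
            make_cds("GGA", "GGC"),           # RSCU 2
            make_cds("GGA", "GGC", "GGG", "GGT"),  # RSCU 1
            make_cds("TTC"))                  # Gly absent -> NA
  ))
  res <- extreme_use(mat, "GGA")
  expect_equal(res$n_genes, 3L)
  expect_equal(res$fraction, 2 / 3)
  # boundary: exactly 1.5 counts
  mat2 <- rscu_matrix(tibble::tibble(
    gene_id = c("a", "b"),
    cds = c(make_cds(rep("GGA", 3), "GGC"),   # RSCU 4*3/4 = 3
            make_cds(rep("GGA", 3), "GGC", "GGG", "GGT", "GGT", "GGC"))
  ))
  expect_equal(mat2$GGA[2], 1.5)
  expect_equal(extreme_use(mat2, "GGA")$fraction, 1)
  # all extreme / none
  expect_equal(extreme_use(mat, "GGA", threshold = 5)$fraction, 0)
})

test_that("extreme_use_compare runs pairwise chi-square across sets", {
  set.seed(13)
  des <- designate_codons()
  hi <- rscu_matrix(sim_gene_set(40, 120, 0.2,
                                 set_preferences(des, nonopt_shift = 0.5),
                                 conc = 20, prefix = "h"), label = "hi")
  lo <- rscu_matrix(sim_gene_set(40, 120, 0.2, set_preferences(des),
                                 conc = 20, prefix = "l"), label = "lo")
  cod <- des$primary_nonopt[des$aa == "G"]
  res <- extreme_use_compare(list(hi = hi, lo = lo), cod)
  expect_equal(nrow(res$per_set), 2L)
  expect_equal(nrow(res$pairwise), 1L)
  expect_gt(res$per_set$fraction[res$per_set$set == "hi"],
            res$per_set$fraction[res$per_set$set == "lo"])
  expect_lt(res$pairwise$p_value, 0.05)
})

test_that("concatenated-profile contrast deltas conserve zero per amino
           acid", {
  set.seed(77)
  des <- designate_codons()
  a <- sim_gene_set(20, 150, 0.2, set_preferences(des, nonopt_shift = 0.2),
                    conc = 40, prefix = "a")
  b <- sim_gene_set(20, 150, 0.2, set_preferences(des), conc = 40,
                    prefix = "b")
  d <- delta_rscu(rscu(pool_counts(codon_counts(a))),
                  rscu(pool_counts(codon_counts(b))))
  sums <- d |> dplyr::group_by(aa) |> dplyr::summarise(s = sum(delta))
  expect_equal(sums$s, rep(0, 18), tolerance = 1e-9)
})
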