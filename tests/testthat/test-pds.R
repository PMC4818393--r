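test_that("preprocessing imputes medians, z-scores, and reduces dimension", {
  set.seed(3)
  # two perfectly correlated metabolites collapse to one component
  base <- rnorm(10)
  x <- cbind(base, 2 * base + 5)
  expect_equal(ncol(preprocess_pathway_submatrix(x, variance_kept = 0.9)), 1L)

  # a missing cell is replaced by the metabolite's observed median
  x2 <- matrix(rnorm(30), 10, 3)
  x2[4, 2] <- NA
  red <- preprocess_pathway_submatrix(x2, variance_kept = 1)
  imputed <- x2; imputed[4, 2] <- median(x2[-4, 2])
  expect_equal(red, preprocess_pathway_submatrix(imputed, variance_kept = 1))

  # retained variance fractions match an independent eigen-decomposition
  # of the correlation matrix
  x3 <- matrix(rnorm(100), 20, 5)
  red3 <- preprocess_pathway_submatrix(x3, variance_kept = 1, pc_cap = 5)
  ev <- eigen(cor(x3), symmetric = TRUE)$values
  expect_equal(attr(red3, "explained_variance"), (ev / sum(ev))[1:ncol(red3)],
               tolerance = 1e-10)

  expect_warning(preprocess_pathway_submatrix(cbind(x3, 0)), "zero-variance")
  expect_error(preprocess_pathway_submatrix(matrix(1, 10, 3)),
               class = "pdsdiag_degenerate")
})

test_that("collinear pathway data reproduces min-max positions exactly", {
  pos <- c(0, 0.05, 0.1, 0.3, 0.35, 0.5, 0.62, 0.71, 0.8, 0.9, 0.95, 1)
  ab <- line_abundance(pos)
  labels <- tibble::tibble(
    sample_id = ab$sample_id,
    class = c(rep("control", 4), rep("case", 8)))
  pds <- compute_pds(ab, labels, line_pathway_map(ab))
  expect_equal(pds$LINE, (pos - min(pos)) / (max(pos) - min(pos)),
               tolerance = 1e-6)
})

test_that("PDS scores span [0, 1] with the extremes attained", {
  co <- small_cohort(seed = 5)
  pds <- compute_pds(co$abundance, co$labels, co$pathways)
  m <- as.matrix(pds[setdiff(names(pds), "sample_id")])
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(unname(apply(m, 2, min)), rep(0, ncol(m)))
  expect_equal(unname(apply(m, 2, max)), rep(1, ncol(m)))
  d <- pds_diagnostics(pds)
  expect_equal(nrow(d), 6L)
  expect_true(all(!d$dropped))
})

test_that("PDS is invariant to positive rescaling of a metabolite", {
  co <- small_cohort(seed = 8, missing_rate = 0)
  pds1 <- compute_pds(co$abundance, co$labels, co$pathways)
  ab2 <- co$abundance
  ab2[[2]] <- ab2[[2]] * 1000
  ab2[[7]] <- ab2[[7]] * 0.001
  pds2 <- compute_pds(ab2, co$labels, co$pathways)
  expect_equal(as.data.frame(pds1), as.data.frame(pds2), tolerance = 1e-6)
})

test_that("PDS is equivariant under sample permutation and duplication", {
  co <- small_cohort(seed = 9, n_cases = 20, n_controls = 12, n_pathways = 3)
  pds <- compute_pds(co$abundance, co$labels, co$pathways)
  perm <- sample(nrow(co$abundance))
  pds_p <- compute_pds(co$abundance[perm, ], co$labels, co$pathways)
  expect_equal(as.data.frame(pds_p),
               as.data.frame(pds[perm, ]), tolerance = 1e-8,
               ignore_attr = TRUE)

  dup_ab <- dplyr::bind_rows(co$abundance,
                             dplyr::mutate(co$abundance,
                                           sample_id = paste0(sample_id, "_dup")))
  dup_lab <- dplyr::bind_rows(co$labels,
                              dplyr::mutate(co$labels,
                                            sample_id = paste0(sample_id, "_dup")))
  pds_d <- compute_pds(dup_ab, dup_lab, co$pathways)
  n <- nrow(co$abundance)
  m <- as.matrix(pds_d[setdiff(names(pds_d), "sample_id")])
  expect_equal(m[1:n, ], m[(n + 1):(2 * n), ], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a planted pathway separates cases from controls in the right direction", {
  co <- small_cohort(seed = 2, n_cases = 50, n_controls = 30)
  pds <- compute_pds(co$abundance, co$labels, co$pathways)
  is_case <- co$labels$class == "case"
  for (pw in co$truth$planted) {
    expect_gt(mean(pds[[pw]][is_case]), mean(pds[[pw]][!is_case]))
  }
})

test_that("the case-control PDS gap grows with the planted effect size", {
  deltas <- c(0, 0.75, 1.5, 3)
  mean_gap <- sapply(deltas, function(d) {
    gaps <- sapply(1:8, function(s) {
      co <- simulate_cohort(cohort_spec(n_cases = 24, n_controls = 14,
                                        n_pathways = 2, planted = 1,
                                        delta = d, missing_rate = 0,
                                        seed = 100 + s))
      pds <- compute_pds(co$abundance, co$labels, co$pathways)
      is_case <- co$labels$class == "case"
      mean(pds$PW_01[is_case]) - mean(pds$PW_01[!is_case])
    })
    mean(gaps)
  })
  expect_gt(cor(deltas, mean_gap, method = "spearman"), 0)
  expect_gt(mean_gap[4], mean_gap[1])
})

test_that("labels are aligned by sample id, not by row order", {
  co <- small_cohort(seed = 13, n_cases = 12, n_controls = 8, n_pathways = 2)
  shuffled <- co$labels[sample(nrow(co$labels)), ]
  pds1 <- compute_pds(co$abundance, co$labels, co$pathways)
  pds2 <- compute_pds(co$abundance, shuffled, co$pathways)
  expect_equal(as.data.frame(pds1), as.data.frame(pds2))
  expect_error(compute_pds(co$abundance, co$labels[-1, ], co$pathways),
               "no label")
})
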