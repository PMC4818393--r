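# Shared fixtures, built in code at test time.

# A tiny GMT file on disk; returns its path.
tiny_gmt <- function(lines = c("A\tfirst\tHMDB0000001\tHMDB0000002\tHMDB0000003",
                               "B\tsecond\tHMDB0000004\tHMDB0000005")) {
  path <- tempfile(fileext = ".gmt")
  writeLines(lines, path)
  path
}

# Abundance tibble whose single pathway is exactly collinear in the
# preprocessed (log) space: every log-intensity is an affine function
# of a latent position.
line_abundance <- function(pos = seq(0, 1, length.out = 12),
                           slopes = c(2, -1, 0.5, 3),
                           prefix = "HMDB00000") {
  vals <- sapply(seq_along(slopes), function(j) exp(5 + slopes[j] * pos))
  colnames(vals) <- paste0(prefix, seq_along(slopes))
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%02d", seq_along(pos))),
    tibble::as_tibble(as.data.frame(vals)))
}

line_pathway_map <- function(abundance) {
  tibble::tibble(pathway = "LINE", description = "collinear fixture",
                 members = list(setdiff(names(abundance), "sample_id")))
}

# Small labelled cohort for fast pipeline tests.
small_cohort <- function(seed = 1, n_cases = 40, n_controls = 24,
                         n_pathways = 6, planted = 1:2, delta = 2, ...) {
  simulate_cohort(cohort_spec(n_cases = n_cases, n_controls = n_controls,
                              n_pathways = n_pathways, planted = planted,
                              delta = delta, seed = seed, ...))
}

# Per-class train/test partition of a cohort into run_model() inputs.
cohort_split <- function(cohort, train_fraction = 0.8, seed = 1) {
  sp <- split_cohort(cohort$labels, train_fraction, seed = seed)
  pick <- function(ids) {
    list(abundance = cohort$abundance[match(ids, cohort$abundance$sample_id), ,
                                      drop = FALSE],
         labels = cohort$labels[match(ids, cohort$labels$sample_id), ,
                                drop = FALSE])
  }
  list(train = pick(sp$sample_id[sp$split == "train"]),
       test = pick(sp$sample_id[sp$split == "test"]))
}

# Independent brute-force CFS optimum by exhaustive subset enumeration
# (feasible for <= 10 features).
exhaustive_cfs_merit <- function(X, y) {
  X <- as.matrix(X)
  y01 <- as.integer(tolower(as.character(y)) == "case" | y == 1)
  p <- ncol(X)
  stopifnot(p <= 10)
  suppressWarnings({
    rcf <- abs(as.numeric(cor(X, y01))); rff <- abs(cor(X))
  })
  rcf[is.na(rcf)] <- 0; rff[is.na(rff)] <- 0
  best <- 0
  for (code in seq_len(2^p - 1)) {
    s <- which(bitwAnd(code, 2^(seq_len(p) - 1)) > 0)
    k <- length(s)
    mff <- if (k > 1) mean(rff[s, s][lower.tri(rff[s, s])]) else 0
    m <- k * mean(rcf[s]) / sqrt(k + k * (k - 1) * mff)
    if (m > best) best <- m
  }
  best
}

# Independent pairwise-comparison AUC (double loop).
pairwise_auc <- function(scores, y01) {
  ca <- scores[y01 == 1]; co <- scores[y01 == 0]
  tot <- 0
  for (a in ca) tot <- tot + sum(a > co) + 0.5 * sum(a == co)
  tot / (length(ca) * length(co))
}
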