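# Synthetic case/control metabolomics cohorts with planted
# pathway-level dysregulation.  The generator emulates the structure of
# a blood LC/GC-MS profiling study: log-normal intensities, correlated
# within-pathway metabolites, a latent per-case progression axis that
# scales the planted effect, mixed effect signs, and MCAR missingness.

# Stage mix of the emulated plasma cohort (stages I-IV among cases).
STAGE_PROBS <- c(I = 19, II = 49, III = 46, IV = 17) / 131

#' Specify a synthetic cohort
#'
#' Defaults emulate the structure of a two-class blood metabolomics
#' cohort of 132 cases and 76 controls, with 30 pathways of 5
#' metabolites, 5 of them dysregulated with per-metabolite effect size
#' `delta = 2` (z-score units, scaled by the case's latent progression),
#' within-pathway equicorrelation `rho = 0.5`, and 5 % missing values.
#'
#' @param n_cases,n_controls Sample sizes.
#' @param n_pathways Number of pathways.
#' @param metabolites_per_pathway Members per pathway: a single integer
#'   or a length-2 range sampled uniformly per pathway.
#' @param overlap_fraction Fraction of each pathway's members also
#'   listed as members of the next pathway (membership overlap only), in
#'   `[0, 1)`.
#' @param planted Indices of dysregulated pathways; defaults to the
#'   first `min(5, n_pathways)` pathways.  Use `integer(0)` for a fully
#'   null cohort.
#' @param delta Per-metabolite case shift magnitude, in z-score units at
#'   full progression (`t = 1`).
#' @param rho Within-pathway equicorrelation, in `[0, 1)`.
#' @param sigma Metabolite noise standard deviation (log scale).
#' @param missing_rate Missing-completely-at-random cell rate, in
#'   `[0, 1)`.
#' @param sign_mix Fraction of planted members shifted downward rather
#'   than upward (default 0.3: most planted metabolites rise with
#'   disease, a minority falls).
#' @param seed Integer seed; the whole cohort is a deterministic
#'   function of the spec.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_cases = 132L, n_controls = 76L, n_pathways = 30L,
                        metabolites_per_pathway = 5L,
                        overlap_fraction = 0, planted = NULL, delta = 2,
                        rho = 0.5, sigma = 1, missing_rate = 0.05,
                        sign_mix = 0.3, seed = 1L) {
  stopifnot(n_cases >= 1L, n_controls >= 2L, n_pathways >= 1L,
            all(metabolites_per_pathway >= 1L),
            length(metabolites_per_pathway) %in% c(1L, 2L),
            overlap_fraction >= 0, overlap_fraction < 1,
            delta >= 0, rho >= 0, rho < 1, sigma > 0,
            missing_rate >= 0, missing_rate < 1,
            sign_mix >= 0, sign_mix <= 1)
  planted <- as.integer(planted %||% seq_len(min(5L, n_pathways)))
  if (length(planted) > 0L &&
      (min(planted) < 1L || max(planted) > n_pathways)) {
    abort("planted indices must lie in 1..n_pathways")
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_pathways = as.integer(n_pathways),
                 metabolites_per_pathway = as.integer(metabolites_per_pathway),
                 overlap_fraction = overlap_fraction, planted = planted,
                 delta = delta, rho = rho, sigma = sigma,
                 missing_rate = missing_rate, sign_mix = sign_mix,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Controls are drawn, pathway block by pathway block, from a zero-mean
#' Gaussian with equicorrelation `rho`; each case receives a latent
#' progression value `t ~ Uniform(0, 1)` and, in planted pathways, a
#' mean shift of `sign_j * delta * t` on every member metabolite `j`.
#' Values are exponentiated to positive intensities and cells are masked
#' missing completely at random.  Case tumor stages are assigned from
#' the progression value so that later stages correspond to larger
#' dysregulation.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: list with `abundance`
#'   (tibble, `sample_id` + one column per metabolite), `labels`
#'   (tibble: `sample_id`, `class`, `stage`), `pathways` (GMT-style
#'   tibble), `truth` (planted pathway names and per-metabolite effect
#'   signs), and `latent_t` (per-case progression).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  P <- spec$n_pathways
  n1 <- spec$n_cases; n0 <- spec$n_controls
  n <- n1 + n0
  mpp <- spec$metabolites_per_pathway
  m_per <- if (length(mpp) == 2L) {
    sample(seq(mpp[1], mpp[2]), P, replace = TRUE)
  } else rep(mpp, P)
  met_ids <- split(sprintf("HMDB%07d", seq_len(sum(m_per))),
                   rep(seq_len(P), m_per))
  pw_names <- sprintf("PW_%02d", seq_len(P))
  is_case <- c(rep(TRUE, n1), rep(FALSE, n0))
  t_case <- runif(n1)
  t_all <- ifelse(is_case, c(t_case, rep(0, n0)), 0)
  planted <- spec$planted
  signs <- list()
  blocks <- vector("list", P)
  for (p in seq_len(P)) {
    m <- m_per[p]
    # equicorrelation factor construction: sqrt(rho) shared + residual
    shared <- rnorm(n)
    eps <- matrix(rnorm(n * m), n, m)
    g <- spec$sigma * (sqrt(spec$rho) * shared +
                       sqrt(1 - spec$rho) * eps)
    if (p %in% planted) {
      sgn <- ifelse(runif(m) < spec$sign_mix, -1, 1)
      signs[[pw_names[p]]] <- setNames(sgn, met_ids[[p]])
      shift <- outer(t_all * is_case, sgn) * spec$delta * spec$sigma
      g <- g + shift
    }
    colnames(g) <- met_ids[[p]]
    blocks[[p]] <- g
  }
  vals <- exp(do.call(cbind, blocks))
  if (spec$missing_rate > 0) {
    mask <- matrix(runif(length(vals)) < spec$missing_rate,
                   nrow(vals), ncol(vals))
    vals[mask] <- NA_real_
  }
  sample_ids <- c(sprintf("case_%03d", seq_len(n1)),
                  sprintf("ctrl_%03d", seq_len(n0)))
  rownames(vals) <- sample_ids
  stage_breaks <- c(0, cumsum(STAGE_PROBS))
  stage_case <- as.character(cut(t_case, breaks = stage_breaks,
                                 labels = names(STAGE_PROBS),
                                 include.lowest = TRUE))
  labels <- tibble(
    sample_id = sample_ids,
    class = ifelse(is_case, "case", "control"),
    stage = c(stage_case, rep("none", n0)))
  members <- lapply(seq_len(P), function(p) {
    own <- met_ids[[p]]
    borrow <- if (p > 1L && spec$overlap_fraction > 0) {
      prev <- met_ids[[p - 1L]]
      prev[seq_len(floor(spec$overlap_fraction * length(prev) + 0.5))]
    } else character(0)
    unique(c(own, borrow))
  })
  pathways <- tibble(pathway = pw_names,
                     description = ifelse(seq_len(P) %in% planted,
                                          "planted", "background"),
                     members = members)
  abundance <- dplyr::bind_cols(tibble(sample_id = sample_ids),
                                as_tibble(as.data.frame(vals)))
  structure(list(abundance = abundance, labels = labels,
                 pathways = pathways,
                 truth = list(planted = pw_names[planted], signs = signs),
                 latent_t = setNames(t_case, sample_ids[seq_len(n1)]),
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d cases + %d controls, %d metabolites, %d pathways (%d planted)\n",
    sum(x$labels$class == "case"), sum(x$labels$class == "control"),
    ncol(x$abundance) - 1L, nrow(x$pathways), length(x$truth$planted)))
  invisible(x)
}

#' Write a cohort to plain-text files
#'
#' Emits `abundance.csv` (first column `sample_id`, empty cell =
#' missing), `labels.tsv`, `pathways.gmt`, and `truth.json` into
#' `out_dir`.  Refuses to overwrite existing files unless
#' `force = TRUE`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param out_dir Output directory (created if needed).
#' @param force Overwrite existing files (default `FALSE`).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir, force = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(abundance = file.path(out_dir, "abundance.csv"),
             labels = file.path(out_dir, "labels.tsv"),
             pathways = file.path(out_dir, "pathways.gmt"),
             truth = file.path(out_dir, "truth.json"))
  existing <- paths[file.exists(paths)]
  if (length(existing) > 0L && !force) {
    abort(paste0("refusing to overwrite ", existing[1],
                 " (use force = TRUE)"))
  }
  readr::write_csv(cohort$abundance, paths["abundance"], na = "",
                   progress = FALSE)
  readr::write_tsv(cohort$labels, paths["labels"], progress = FALSE)
  write_gmt(cohort$pathways, paths["pathways"])
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = FALSE,
                       digits = NA)
  invisible(paths)
}

#' Read an abundance matrix from CSV
#'
#' First column `sample_id`, header row of metabolite identifiers,
#' empty cells are missing values.
#'
#' @param path CSV file path.
#' @return Samples-by-metabolites tibble.
#' @export
read_abundance <- function(path) {
  d <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(), .default = readr::col_double()),
    na = c("", "NA"), progress = FALSE)
  if (names(d)[1] != "sample_id") abort("first column must be sample_id")
  d
}

#' Read a sample label table from TSV
#'
#' @param path TSV file path with columns `sample_id`, `class`, and
#'   optionally `stage`.
#' @return Label tibble.
#' @export
read_labels <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  stopifnot(all(c("sample_id", "class") %in% names(d)))
  d
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the cohort files.
#' @return List with `abundance`, `labels`, `pathways`, `truth`.
#' @export
read_cohort <- function(dir) {
  list(abundance = read_abundance(file.path(dir, "abundance.csv")),
       labels = read_labels(file.path(dir, "labels.tsv")),
       pathways = read_gmt(file.path(dir, "pathways.gmt")),
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE))
}
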