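#' Read a pathway-metabolite master file in GMT format
#'
#' GMT is the de-facto tab-separated "one set per line" format: pathway
#' name, description, then one field per member.  Members here are HMDB
#' metabolite identifiers, but gene sets work identically, so models
#' trained on metabolomics pathways can be applied to expression data
#' scored against a gene-membership GMT.
#'
#' @param path Path to a GMT file.
#' @return A tibble with one row per pathway and columns `pathway`,
#'   `description`, and `members` (a list-column of character vectors;
#'   duplicates within a line are collapsed, order is not meaningful).
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines(c("A\tfirst\tHMDB01\tHMDB02\tHMDB03", "B\tsecond\tHMDB04\tHMDB05"), gmt)
#' read_gmt(gmt)
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort("empty GMT file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    abort(paste0("malformed GMT line ", bad[1],
                 ": fewer than 3 tab-separated fields"))
  }
  name <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(name)) {
    abort(paste0("duplicate pathway name in GMT: ",
                 name[duplicated(name)][1]))
  }
  members <- lapply(fields, function(f) {
    m <- unique(f[-(1:2)])
    m[nzchar(m)]
  })
  if (any(lengths(members) == 0L)) abort("pathway with no members in GMT")
  tibble(
    pathway = name,
    description = vapply(fields, `[[`, character(1), 2L),
    members = members
  )
}

#' Write a pathway map to a GMT file
#'
#' @param pathways A tibble as returned by [read_gmt()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  stopifnot(is.data.frame(pathways),
            all(c("pathway", "description", "members") %in% names(pathways)))
  lines <- vapply(seq_len(nrow(pathways)), function(i) {
    paste(c(pathways$pathway[i], pathways$description[i],
            pathways$members[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Internal: case-fold, trim, and collapse internal whitespace.
normalize_name <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Read a metabolite synonym dictionary
#'
#' A two-column tab-separated file (no header): raw metabolite name or
#' synonym, then the canonical HMDB identifier.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `name` and `hmdb_id`.
#' @export
read_synonyms <- function(path) {
  d <- readr::read_tsv(path, col_names = c("name", "hmdb_id"),
                       col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  as_tibble(d)
}

# Internal: build a lookup (named character vector) from a synonym table.
# Every canonical ID maps to itself; lookup keys are normalized; a
# normalized name pointing at two different IDs is an error.
synonym_lookup <- function(dict) {
  stopifnot(is.data.frame(dict), all(c("name", "hmdb_id") %in% names(dict)))
  bad <- !grepl("^HMDB[0-9]+$", dict$hmdb_id)
  if (any(bad)) {
    abort(paste0("invalid HMDB identifier in dictionary: ", dict$hmdb_id[bad][1]))
  }
  keys <- c(normalize_name(dict$name), normalize_name(dict$hmdb_id))
  vals <- c(dict$hmdb_id, dict$hmdb_id)
  keep <- !duplicated(paste0(keys, "\r", vals))
  keys <- keys[keep]; vals <- vals[keep]
  if (anyDuplicated(keys)) {
    k <- keys[duplicated(keys)][1]
    abort(paste0("synonym '", k, "' maps to more than one HMDB identifier"))
  }
  setNames(vals, keys)
}

#' Standardize raw metabolite names to HMDB identifiers
#'
#' Resolution is exact after normalization (case-folding, trimming, and
#' collapsing internal whitespace); no fuzzy matching is attempted, so
#' unresolved names are a normal outcome to be curated by hand.
#'
#' @param raw_names Character vector of metabolite names as reported by
#'   the profiling platform.
#' @param dict Synonym table with columns `name`, `hmdb_id` (see
#'   [read_synonyms()]); canonical IDs always resolve to themselves.
#' @return A tibble aligned with the input: `raw_name`, `hmdb_id` (`NA`
#'   where unresolved).  The attribute `"unmapped"` lists each unresolved
#'   raw name exactly once.
#' @examples
#' dict <- tibble::tibble(name = "glycine", hmdb_id = "HMDB0000123")
#' standardize_names(c("Glycine", " GLYCINE ", "mystery"), dict)
#' @export
standardize_names <- function(raw_names, dict) {
  lookup <- synonym_lookup(dict)
  raw_names <- as.character(raw_names)
  resolved <- unname(lookup[normalize_name(raw_names)])
  out <- tibble(raw_name = raw_names, hmdb_id = resolved)
  attr(out, "unmapped") <- unique(raw_names[is.na(resolved)])
  out
}

#' Intersect pathway membership with the measured metabolites
#'
#' A pathway is usable when at least `min_size` of its member
#' metabolites are columns of the abundance table; the rest are excluded
#' with an explicit reason.  Metabolites belonging to several pathways
#' are retained in all of them.
#'
#' @param abundance Samples-by-metabolites data frame; first column
#'   `sample_id`, remaining column names are HMDB identifiers.
#' @param pathways Pathway map tibble from [read_gmt()].
#' @param min_size Minimum number of measured members for a pathway to be
#'   usable (default 3; a principal curve over fewer features is
#'   degenerate).
#' @return A tibble with one row per pathway: `pathway`, `n_members`,
#'   `n_measured`, `usable`, `reason` (`NA` or `"too_few_measured(k)"`),
#'   and `metabolites`, a list-column of the measured member IDs.
#' @export
map_pathways <- function(abundance, pathways, min_size = 3L) {
  if (min_size < 2L) abort("min_size must be >= 2")
  m <- feature_matrix(abundance)
  measured <- colnames(m)
  stopifnot(is.data.frame(pathways), "members" %in% names(pathways))
  hits <- lapply(pathways$members, intersect, x = measured)
  # intersect(x = measured, y = members) keeps matrix column order
  n_meas <- lengths(hits)
  usable <- n_meas >= min_size
  out <- tibble(
    pathway = pathways$pathway,
    n_members = lengths(pathways$members),
    n_measured = n_meas,
    usable = usable,
    reason = ifelse(usable, NA_character_,
                    sprintf("too_few_measured(%d)", n_meas)),
    metabolites = hits
  )
  class(out) <- c("mapped_pathways", class(out))
  out
}
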