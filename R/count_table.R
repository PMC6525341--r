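#' Read a family-by-species gene count table
#'
#' Reads a tab-separated count table whose first column holds orthologous
#' group (family) identifiers and whose remaining columns hold non-negative
#' integer gene counts, one column per species. A column named `Desc` (or
#' `Description`, any case) is tolerated and dropped, matching the common
#' dialect of gene-family count tables.
#'
#' @param path Path to a TSV file with a header row.
#' @return A tibble with a `family` character column followed by one integer
#'   column per species.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("og\tA\tB", "OG1\t1\t2"), tf)
#' read_count_table(tf)
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Count table not found: %s", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) {
    abort("Count table must have a family-id column and at least one species column.")
  }
  drop <- tolower(names(raw)) %in% c("desc", "description")
  raw <- raw[!drop]
  names(raw)[1] <- "family"
  species <- names(raw)[-1]
  if (anyDuplicated(species)) {
    abort(sprintf("Duplicate species columns: %s",
                  paste(unique(species[duplicated(species)]), collapse = ", ")))
  }
  if (anyDuplicated(raw$family)) {
    abort(sprintf("Duplicate family ids: %s",
                  paste(unique(raw$family[duplicated(raw$family)]), collapse = ", ")))
  }
  for (sp in species) {
    vals <- raw[[sp]]
    parsed <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(parsed) | parsed < 0 | parsed != floor(parsed))
    if (length(bad) > 0) {
      abort(sprintf(
        "Non-integer or negative count in row '%s', column '%s': '%s'",
        raw$family[bad[1]], sp, vals[bad[1]]))
    }
    raw[[sp]] <- as.integer(parsed)
  }
  tibble::as_tibble(raw)
}

#' Write a count table to TSV
#'
#' @param counts A count table as returned by [read_count_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  counts <- validate_count_table(counts)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

# Check count-table invariants and return the table with the id column
# renamed to `family`.
validate_count_table <- function(counts) {
  if (!is.data.frame(counts) || ncol(counts) < 2) {
    abort("`counts` must be a data frame: family ids plus species columns.")
  }
  counts <- tibble::as_tibble(counts)
  names(counts)[1] <- "family"
  counts$family <- as.character(counts$family)
  if (anyDuplicated(counts$family)) {
    abort("Family ids must be unique.")
  }
  for (sp in names(counts)[-1]) {
    v <- counts[[sp]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0) || any(v != floor(v))) {
      abort(sprintf("Column '%s' must contain non-negative integers.", sp))
    }
    counts[[sp]] <- as.integer(v)
  }
  counts
}

# Count table -> integer matrix (families x species) with rownames.
count_matrix <- function(counts) {
  counts <- validate_count_table(counts)
  m <- as.matrix(counts[-1])
  storage.mode(m) <- "integer"
  rownames(m) <- counts$family
  m
}

#' Keep only families observed in both species groups
#'
#' Families whose genes occur in only one of the two groups (for the beetle
#' analysis: suborders Adephaga and Polyphaga) carry no information about
#' divergence since the groups' common ancestor and are excluded.
#'
#' @param counts A count table (tibble, `family` column first).
#' @param groups Named list `group -> species` or data frame with columns
#'   `species` and `group`; exactly two groups covering every species column.
#' @return The filtered count table, row order preserved.
#' @export
filter_shared_families <- function(counts, groups) {
  counts <- validate_count_table(counts)
  gm <- as_group_map(groups)
  if (length(gm) != 2) {
    abort("`groups` must define exactly two groups.")
  }
  species <- names(counts)[-1]
  missing <- setdiff(species, unlist(gm))
  if (length(missing) > 0) {
    abort(sprintf("Species missing from `groups`: %s", paste(missing, collapse = ", ")))
  }
  m <- count_matrix(counts)
  in_g1 <- rowSums(m[, intersect(gm[[1]], species), drop = FALSE]) > 0
  in_g2 <- rowSums(m[, intersect(gm[[2]], species), drop = FALSE]) > 0
  counts[in_g1 & in_g2, , drop = FALSE]
}

#' Candidate-category selection rules
#'
#' Default rules mapping protein-domain identifiers (Pfam/InterPro/GO) and
#' UniRef cluster-name keywords to the eight candidate enzyme and transporter
#' categories putatively involved in plant feeding: UDP-glycosyltransferases
#' (UGT), cytochrome P450s (P450), carboxylesterases (CE), glutathione
#' S-transferases (GST), serine proteases (SER), cysteine proteases (CYS),
#' ABC transporters (ABC), and glycoside hydrolases (GH). The row order is
#' also the tie-break order used by [select_candidate_ogs()].
#'
#' @return A tibble with columns `category`, `identifiers` (list column of
#'   accession strings) and `keywords` (list column of case-insensitive
#'   substrings matched against cluster names).
#' @export
default_category_rules <- function() {
  tibble::tibble(
    category = c("UGT", "P450", "CE", "GST", "SER", "CYS", "ABC", "GH"),
    identifiers = list(
      "PF00201",
      "PF00067",
      c("PF02230", "PF00135"),
      c("PF00043", "PF02798"),
      c("PF00450", "PF12146", "PF05577", "GO:0008236"),
      "PF00112",
      c("PF00005", "PF00664"),
      c("IPR000334", "IPR000743", "IPR001360", "IPR001547")
    ),
    keywords = list(
      c("UDP glucuronosyltransferase", "UDP glycosyltransferase"),
      "Cytochrome P450",
      c("carboxylesterase", "carboxylic ester hydrolase"),
      "Glutathione S-transferase",
      c("Serine protease", "Serine peptidase"),
      c("cysteine protease", "cystein protease", "Papain"),
      "ABC",
      "Glycoside hydrolase"
    )
  )
}

split_multi <- function(x) {
  if (is.list(x)) {
    lapply(x, as.character)
  } else {
    strsplit(as.character(x), ";", fixed = TRUE)
  }
}

#' Assign families to candidate categories from annotations
#'
#' A family is assigned to a category when at least one of its genes has both
#' an identifier hit in the category's identifier set and a cluster-name hit
#' containing one of the category's keywords (case-insensitive substring).
#' A family matching several categories is assigned the category with the
#' most matching genes; remaining ties follow the rule order.
#'
#' @param annotations Data frame with columns `gene_id`, `family_id`,
#'   `identifiers`, and `cluster_names`. The latter two are either list
#'   columns or semicolon-separated strings.
#' @param rules Rule table as from [default_category_rules()].
#' @return A tibble `family`, `category` for assigned families; families not
#'   listed are background.
#' @export
select_candidate_ogs <- function(annotations, rules = default_category_rules()) {
  if (!is.data.frame(annotations) ||
      !all(c("gene_id", "family_id", "identifiers", "cluster_names") %in% names(annotations))) {
    abort("`annotations` needs columns gene_id, family_id, identifiers, cluster_names.")
  }
  rules <- tibble::as_tibble(rules)
  if (anyDuplicated(rules$category)) {
    abort("Rule categories must be distinct.")
  }
  ids <- split_multi(annotations$identifiers)
  nms <- split_multi(annotations$cluster_names)
  n_rule <- nrow(rules)
  # matches[g, r]: gene g satisfies rule r (identifier AND keyword)
  matches <- matrix(FALSE, nrow(annotations), n_rule)
  for (r in seq_len(n_rule)) {
    rid <- rules$identifiers[[r]]
    kw <- tolower(rules$keywords[[r]])
    id_hit <- vapply(ids, function(x) any(x %in% rid), logical(1))
    kw_hit <- vapply(nms, function(x) {
      lx <- tolower(x)
      any(vapply(kw, function(k) any(grepl(k, lx, fixed = TRUE)), logical(1)))
    }, logical(1))
    matches[, r] <- id_hit & kw_hit
  }
  fam <- as.character(annotations$family_id)
  out <- lapply(sort(unique(fam)), function(f) {
    rows <- fam == f
    gene_hits <- colSums(matches[rows, , drop = FALSE])
    if (all(gene_hits == 0)) {
      return(NULL)
    }
    best <- which(gene_hits == max(gene_hits))[1] # first index = rule order
    tibble::tibble(family = f, category = rules$category[best])
  })
  dplyr::bind_rows(out)
}
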