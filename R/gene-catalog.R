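#' Build a candidate-gene catalog from flat source files
#'
#' Merges one or more gene-list files (literature review, HPO term gene
#' sets such as Craniosynostosis HP:0001363 and Abnormal skull morphology
#' HP:0000929, PanelApp panels, a core sequencing panel) into a single
#' catalog with per-gene source provenance, OMIM inheritance models and a
#' synonym map.  Each source file is tab-separated with a header and
#' columns `symbol`, and optionally `models` (comma-separated subset of
#' AD,AR,XLD,XLR) and `synonyms` (comma-separated alternate symbols).
#'
#' Symbols are normalised to upper case.  A symbol that appears as a
#' declared synonym of another entry is folded into that entry, so the
#' catalog is independent of the order in which sources are supplied.
#'
#' @param paths named character vector of file paths; the names are used
#'   as source tags (e.g. `literature`, `core17`, `hpo_craniosynostosis`).
#'   Unnamed paths are tagged by their base file name.
#' @return a `crs_gene_catalog` object: a data.frame with columns
#'   `symbol`, `sources`, `omim_models`, `synonyms` (the latter three as
#'   comma-separated strings) and a synonym lookup map attribute.
#' @seealso [catalog_lookup()], [crs_builtin_catalog()]
#' @export
build_catalog <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    nm <- names(paths)
    if (is.null(nm)) nm <- rep("", length(paths))
    miss <- !nzchar(nm)
    nm[miss] <- sub("\\.[^.]*$", "", basename(paths[miss]))
    names(paths) <- nm
  }
  recs <- lapply(seq_along(paths), function(i) {
    read_gene_source(paths[[i]], names(paths)[i])
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs) || nrow(recs) == 0) {
    return(empty_catalog())
  }
  catalog_from_records(recs)
}

read_gene_source <- function(path, source_tag) {
  if (!file.exists(path)) {
    crs_abort(sprintf("gene source file not found: %s", path), "crstrio_io_error")
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!"symbol" %in% names(df)) {
    crs_abort(sprintf("gene source %s lacks a 'symbol' column", path),
              "crstrio_parse_error")
  }
  bad <- which(is.na(df$symbol) | !nzchar(trimws(df$symbol)))
  if (length(bad)) {
    crs_abort(sprintf("gene source %s: empty symbol at data line %d",
                      path, bad[1]), "crstrio_parse_error")
  }
  data.frame(
    symbol = toupper(trimws(df$symbol)),
    models = if ("models" %in% names(df)) toupper(df$models) else "",
    synonyms = if ("synonyms" %in% names(df)) toupper(df$synonyms) else "",
    source = source_tag,
    stringsAsFactors = FALSE
  )
}

# Merge per-source records into the canonical catalog. Canonical symbols
# are those never declared as a synonym of another symbol; records filed
# under a declared synonym are folded into the canonical entry.
catalog_from_records <- function(recs) {
  recs$models[is.na(recs$models)] <- ""
  recs$synonyms[is.na(recs$synonyms)] <- ""
  syn_pairs <- do.call(rbind, lapply(seq_len(nrow(recs)), function(i) {
    syns <- split_tags(recs$synonyms[i])[[1]]
    if (!length(syns)) return(NULL)
    data.frame(synonym = syns, canonical = recs$symbol[i],
               stringsAsFactors = FALSE)
  }))
  syn_map <- character(0)
  if (!is.null(syn_pairs)) {
    syn_pairs <- unique(syn_pairs)
    # a synonym must resolve to exactly one canonical symbol
    dup <- syn_pairs$synonym[duplicated(syn_pairs$synonym)]
    if (length(dup)) {
      conflict <- syn_pairs[syn_pairs$synonym %in% dup, , drop = FALSE]
      conflict <- conflict[conflict$canonical != conflict$synonym, , drop = FALSE]
      if (length(unique(conflict$canonical)) > 1) {
        crs_abort(sprintf("synonym '%s' maps to multiple symbols", dup[1]),
                  "crstrio_parse_error")
      }
    }
    syn_map <- stats::setNames(syn_pairs$canonical, syn_pairs$synonym)
    # refuse cyclic/chained maps (canonical itself declared a synonym)
    chained <- names(syn_map)[syn_map %in% names(syn_map)]
    chained <- chained[syn_map[chained] != chained]
    if (length(chained)) {
      crs_abort(sprintf("synonym map is not flat: '%s' -> '%s' -> ...",
                        chained[1], syn_map[chained[1]]),
                "crstrio_parse_error")
    }
  }
  canon <- ifelse(recs$symbol %in% names(syn_map),
                  unname(syn_map[recs$symbol]), recs$symbol)
  recs$canonical <- canon
  symbols <- sort(unique(canon))
  merged <- lapply(symbols, function(s) {
    sub <- recs[recs$canonical == s, , drop = FALSE]
    models <- sort(unique(unlist(split_tags(sub$models))))
    bad <- setdiff(models, INHERITANCE_MODELS)
    if (length(bad)) {
      crs_abort(sprintf("gene %s: unknown inheritance model '%s'", s, bad[1]),
                "crstrio_parse_error")
    }
    syns <- sort(unique(c(unlist(split_tags(sub$synonyms)),
                          setdiff(sub$symbol, s))))
    data.frame(
      symbol = s,
      sources = paste(sort(unique(sub$source)), collapse = ","),
      omim_models = paste(models, collapse = ","),
      synonyms = paste(syns, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  cat_df <- do.call(rbind, merged)
  syn_lookup <- character(0)
  for (i in seq_len(nrow(cat_df))) {
    syns <- split_tags(cat_df$synonyms[i])[[1]]
    if (length(syns)) {
      syn_lookup <- c(syn_lookup, stats::setNames(rep(cat_df$symbol[i],
                                                      length(syns)), syns))
    }
  }
  structure(cat_df, synonym_map = syn_lookup,
            class = c("crs_gene_catalog", "data.frame"))
}

empty_catalog <- function() {
  structure(
    data.frame(symbol = character(0), sources = character(0),
               omim_models = character(0), synonyms = character(0),
               stringsAsFactors = FALSE),
    synonym_map = character(0),
    class = c("crs_gene_catalog", "data.frame")
  )
}

#' Look up a gene symbol in a catalog
#'
#' Case-insensitive exact match, synonym-aware; no fuzzy matching.
#'
#' @param catalog a catalog from [build_catalog()].
#' @param symbol gene symbol or synonym (any case).
#' @return one-row data.frame for the canonical entry, or `NULL` when the
#'   symbol is absent.
#' @export
catalog_lookup <- function(catalog, symbol) {
  s <- toupper(trimws(symbol))
  syn_map <- attr(catalog, "synonym_map")
  if (s %in% names(syn_map)) s <- unname(syn_map[s])
  hit <- which(catalog$symbol == s)
  if (!length(hit)) return(NULL)
  catalog[hit[1], , drop = FALSE]
}

#' OMIM inheritance models for a set of genes
#'
#' @param catalog a catalog from [build_catalog()].
#' @param genes character vector of symbols (synonyms allowed).
#' @return named list mapping each input gene to its model vector
#'   (character(0) when the gene is absent or has no annotated model).
#' @export
catalog_models <- function(catalog, genes) {
  out <- lapply(genes, function(g) {
    e <- catalog_lookup(catalog, g)
    if (is.null(e)) return(character(0))
    split_tags(e$omim_models)[[1]]
  })
  stats::setNames(out, genes)
}

#' The catalog shipped with the package
#'
#' Builds the bundled candidate-gene catalog for craniosynostosis from the
#' flat files under `extdata/catalog/`: a literature list with OMIM
#' inheritance models, the 17-gene core sequencing panel, HPO-derived gene
#' sets for craniosynostosis and abnormal skull morphology, and PanelApp
#' craniosynostosis/skeletal-dysplasia panels.  This is a compact fixture
#' catalog covering the genes exercised by the synthetic cohort, not a
#' reconstruction of any full 2,259-gene research list.
#'
#' @return a `crs_gene_catalog`.
#' @export
crs_builtin_catalog <- function() {
  dir <- system.file("extdata", "catalog", package = "crstrio")
  paths <- c(
    literature = file.path(dir, "literature_genes.tsv"),
    core17 = file.path(dir, "core17_panel.tsv"),
    hpo_craniosynostosis = file.path(dir, "hpo_craniosynostosis.tsv"),
    hpo_skull = file.path(dir, "hpo_abnormal_skull.tsv"),
    panelapp_crs = file.path(dir, "panelapp_craniosynostosis.tsv"),
    panelapp_skeletal = file.path(dir, "panelapp_skeletal_dysplasia.tsv")
  )
  build_catalog(paths)
}
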