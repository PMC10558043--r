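#' Construct a ligand-receptor pair record
#'
#' A pair links a ligand to a receptor, either of which may be a
#' multi-subunit complex whose activity requires every subunit to be
#' expressed. Subunit order is preserved as given; identity for
#' deduplication uses sorted subunits so permuted complex listings collide.
#'
#' @param ligand Character vector of ligand subunit gene symbols (length >= 1).
#' @param receptor Character vector of receptor subunit gene symbols.
#' @param species `"human"` or `"mouse"`.
#' @param sources Character vector of origin database names.
#' @param evidence Optional character vector of literature identifiers.
#' @return A list of class `lr_pair`.
#' @export
lr_pair <- function(ligand, receptor, species = c("human", "mouse"),
                    sources = character(), evidence = character()) {
  species <- match.arg(species)
  check_subunits <- function(x, side) {
    x <- as.character(x)
    if (length(x) < 1L) {
      stop(sprintf("%s must have at least one subunit", side), call. = FALSE)
    }
    if (any(!nzchar(x))) {
      stop(sprintf("%s contains an empty gene symbol", side), call. = FALSE)
    }
    if (any(grepl("+", x, fixed = TRUE))) {
      stop(sprintf("%s symbols must not contain '+'", side), call. = FALSE)
    }
    if (anyDuplicated(x)) {
      stop(sprintf("%s contains duplicate subunits", side), call. = FALSE)
    }
    x
  }
  structure(
    list(
      ligand = check_subunits(ligand, "ligand"),
      receptor = check_subunits(receptor, "receptor"),
      species = species,
      sources = unique(as.character(sources)),
      evidence = unique(as.character(evidence))
    ),
    class = "lr_pair"
  )
}

canonical_key <- function(pair) {
  paste(
    paste(sort(pair$ligand), collapse = "+"),
    paste(sort(pair$receptor), collapse = "+"),
    pair$species,
    sep = "|"
  )
}

#' @export
format.lr_pair <- function(x, ...) {
  sprintf(
    "%s -> %s [%s]",
    paste(x$ligand, collapse = "+"),
    paste(x$receptor, collapse = "+"),
    x$species
  )
}

#' @export
print.lr_pair <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

new_lridb_table <- function(pairs, species) {
  structure(list(pairs = pairs, species = species), class = "lridb_table")
}

#' @export
print.lridb_table <- function(x, ...) {
  cat(sprintf(
    "Ligand-receptor table: %d %s pair(s)\n", length(x$pairs), x$species
  ))
  invisible(x)
}

#' @export
length.lridb_table <- function(x) length(x$pairs)

#' Convert a ligand-receptor table to a data frame
#'
#' Subunits are joined with `"+"`; sources and evidence with `","`, matching
#' the on-disk TSV layout.
#'
#' @param x An `lridb_table`.
#' @param ... Unused.
#' @return A data frame with columns ligand, receptor, species, source,
#'   evidence.
#' @export
as.data.frame.lridb_table <- function(x, ...) {
  data.frame(
    ligand = vapply(x$pairs, function(p) paste(p$ligand, collapse = "+"), ""),
    receptor = vapply(x$pairs, function(p) paste(p$receptor, collapse = "+"), ""),
    species = vapply(x$pairs, function(p) p$species, ""),
    source = vapply(x$pairs, function(p) paste(p$sources, collapse = ","), ""),
    evidence = vapply(x$pairs, function(p) paste(p$evidence, collapse = ","), ""),
    stringsAsFactors = FALSE
  )
}

split_field <- function(x, sep) {
  if (is.na(x) || !nzchar(x)) return(character())
  trimws(strsplit(x, sep, fixed = TRUE)[[1L]])
}

#' Load a ligand-receptor interaction table
#'
#' Reads a TSV with header columns `ligand`, `receptor`, `species` (and
#' optionally `source`, `evidence`), where multi-subunit complexes are
#' written with `"+"`-joined gene symbols, e.g. `ITGA5+ITGB1`. Rows are
#' restricted to the requested species and deduplicated on the canonical key
#' (sorted ligand subunits, sorted receptor subunits).
#'
#' @param path Path to the TSV file.
#' @param species `"human"` or `"mouse"`.
#' @param case_fold If `TRUE`, gene symbols are upper-cased on load so that
#'   mouse-style and human-style capitalisation match. Default `FALSE`
#'   (case-sensitive symbols).
#' @param verbose Log the retained pair count. Default `TRUE`.
#' @return An `lridb_table`.
#' @export
load_lridb <- function(path, species = c("human", "mouse"),
                       case_fold = FALSE, verbose = TRUE) {
  species <- match.arg(species)
  if (!file.exists(path)) {
    stop(sprintf("ligand-receptor table not found: %s", path), call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  required <- c("ligand", "receptor", "species")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf(
      "ligand-receptor table is missing required column(s): %s",
      paste(missing_cols, collapse = ", ")
    ), call. = FALSE)
  }
  bad <- setdiff(unique(df$species), c("human", "mouse"))
  if (length(bad) > 0L) {
    stop(sprintf("unknown species token(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  df <- df[df$species == species, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop(sprintf("no %s pairs in %s after filtering", species, path),
         call. = FALSE)
  }
  has_source <- "source" %in% names(df)
  has_evidence <- "evidence" %in% names(df)
  pairs <- lapply(seq_len(nrow(df)), function(i) {
    lig <- split_field(df$ligand[i], "+")
    rec <- split_field(df$receptor[i], "+")
    if (case_fold) {
      lig <- toupper(lig)
      rec <- toupper(rec)
    }
    lr_pair(
      ligand = lig, receptor = rec, species = species,
      sources = if (has_source) split_field(df$source[i], ",") else character(),
      evidence = if (has_evidence) split_field(df$evidence[i], ",") else character()
    )
  })
  pairs <- deduplicate_pairs(pairs)
  if (verbose) {
    message(sprintf("Loaded %d %s ligand-receptor pair(s) from %s",
                    length(pairs), species, basename(path)))
  }
  new_lridb_table(pairs, species)
}

#' Deduplicate ligand-receptor pairs
#'
#' Two pairs are duplicates when their canonical keys match: sorted ligand
#' subunits, sorted receptor subunits, species. Direction matters, so a pair
#' and its reverse stay distinct. Sources and evidence of merged duplicates
#' are unioned; first-seen order is preserved.
#'
#' @param pairs List of `lr_pair` records.
#' @return Deduplicated list of `lr_pair` records.
#' @export
deduplicate_pairs <- function(pairs) {
  if (length(pairs) == 0L) return(pairs)
  keys <- vapply(pairs, canonical_key, "")
  out <- list()
  index <- new.env(parent = emptyenv())
  for (i in seq_along(pairs)) {
    k <- keys[i]
    if (is.null(index[[k]])) {
      index[[k]] <- length(out) + 1L
      out[[length(out) + 1L]] <- pairs[[i]]
    } else {
      j <- index[[k]]
      out[[j]]$sources <- union(out[[j]]$sources, pairs[[i]]$sources)
      out[[j]]$evidence <- union(out[[j]]$evidence, pairs[[i]]$evidence)
    }
  }
  out
}

#' Restrict a ligand-receptor table to a gene universe
#'
#' Keeps exactly the pairs whose every ligand and receptor subunit appears in
#' `gene_universe`, e.g. the genes measured in a dataset.
#'
#' @param table An `lridb_table`.
#' @param gene_universe Non-empty character vector of gene symbols.
#' @return A filtered `lridb_table` (possibly empty, with a warning).
#' @export
filter_pairs_to_genes <- function(table, gene_universe) {
  stopifnot(inherits(table, "lridb_table"))
  if (length(gene_universe) == 0L) {
    stop("gene_universe must be non-empty", call. = FALSE)
  }
  keep <- vapply(table$pairs, function(p) {
    all(c(p$ligand, p$receptor) %in% gene_universe)
  }, NA)
  if (!any(keep)) {
    warning("no ligand-receptor pairs survive the gene-universe filter",
            call. = FALSE)
  }
  new_lridb_table(table$pairs[keep], table$species)
}

#' Write a ligand-receptor table as TSV
#'
#' @param table An `lridb_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lridb <- function(table, path) {
  stopifnot(inherits(table, "lridb_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
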