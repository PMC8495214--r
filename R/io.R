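#' Construct an interactome
#'
#' An interactome is one organism's protein-protein functional-association
#' network: an undirected, simple, weighted graph over gene/protein
#' identifiers (typically of the form `taxid.locus`). Edge weights are
#' association confidences in `(0, 1]` (a STRING `combined_score` divided
#' by 1000).
#'
#' @param edges data.frame with columns `from`, `to` (character) and
#'   `weight` (numeric in `(0, 1]`). Symmetric duplicates are collapsed,
#'   keeping the maximum weight; self-loops are dropped with a warning.
#' @param taxon_id organism/taxon identifier (string).
#' @param nodes optional character vector of node identifiers; defaults to
#'   the identifiers appearing in `edges`. Extra entries become isolated
#'   nodes.
#' @param name free-text label for the network.
#' @return An object of class `interactome`: a list with elements
#'   `taxon_id`, `name`, `nodes` (character) and `edges` (data.frame
#'   `from`, `to`, `weight` with `from < to` lexicographically).
#' @export
interactome <- function(edges, taxon_id = "NA", nodes = NULL, name = "") {
  stopifnot(is.data.frame(edges), all(c("from", "to", "weight") %in% names(edges)))
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  weight <- as.numeric(edges$weight)
  loop <- from == to
  if (any(loop)) {
    warning(sprintf("dropping %d self-loop(s)", sum(loop)))
    from <- from[!loop]; to <- to[!loop]; weight <- weight[!loop]
  }
  if (length(weight) && (any(weight <= 0) || any(weight > 1))) {
    stop("edge weights must lie in (0, 1]")
  }
  # canonical unordered representation, max weight wins on duplicates
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    w <- tapply(weight, key, max)
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]
    weight <- as.numeric(w[paste(a, b, sep = "\r")])
  }
  nodes <- sort(unique(c(a, b, as.character(nodes))))
  o <- order(a, b)
  structure(
    list(taxon_id = as.character(taxon_id), name = as.character(name),
         nodes = nodes,
         edges = data.frame(from = a[o], to = b[o], weight = weight[o],
                            stringsAsFactors = FALSE)),
    class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("<interactome> taxon %s%s: %d nodes, %d edges\n",
              x$taxon_id, if (nzchar(x$name)) paste0(" (", x$name, ")") else "",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of nodes / edges of an interactome
#' @param net an `interactome`.
#' @return integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Convert an interactome to an igraph graph
#'
#' @param net an `interactome`.
#' @return an undirected weighted [igraph::graph] whose vertex names are the
#'   interactome's node identifiers (isolated nodes included).
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  igraph::E(g)$weight <- net$edges$weight
  g
}

#' Read a STRING-style protein links file
#'
#' Parses the whitespace-delimited `protein1 protein2 combined_score`
#' dialect used for STRING protein-links downloads (optionally
#' gzip-compressed, optional header line). Scores are integers in
#' `[1, 1000]` and become edge weights `score/1000`. Symmetric duplicate
#' rows collapse to one edge keeping the maximum score; self-loops are
#' dropped with a warning; rows below `min_score` are discarded.
#'
#' @param path path to the links file (plain text or `.gz`).
#' @param min_score minimum `combined_score` to retain an edge (integer in
#'   `[0, 1000]`, default 0 i.e. keep everything).
#' @param taxon_id organism tag; by default inferred from the prefix of the
#'   first node identifier (`taxid.locus`), falling back to the file name.
#' @return an [interactome()].
#' @export
read_string_links <- function(path, min_score = 0, taxon_id = NULL) {
  stopifnot(file.exists(path), min_score >= 0, min_score <= 1000)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("empty interactome: no rows in '%s'", path))
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  start <- 1L
  if (length(fields[[1]]) >= 3 && is.na(suppressWarnings(as.numeric(fields[[1]][3])))) {
    start <- 2L  # header line: third field non-numeric
  }
  if (start > length(fields)) stop(sprintf("empty interactome: only a header in '%s'", path))
  from <- to <- character(length(fields) - start + 1L)
  score <- numeric(length(from))
  for (i in seq_along(from)) {
    f <- fields[[i + start - 1L]]
    if (length(f) < 3) {
      stop(sprintf("malformed line %d in '%s': expected >= 3 fields, got %d",
                   i + start - 1L, path, length(f)))
    }
    s <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || s != round(s) || s < 1 || s > 1000) {
      stop(sprintf("malformed line %d in '%s': combined_score '%s' not an integer in [1,1000]",
                   i + start - 1L, path, f[3]))
    }
    from[i] <- f[1]; to[i] <- f[2]; score[i] <- s
  }
  keep <- score >= min_score
  if (!any(keep)) {
    stop(sprintf("empty interactome: no edges with combined_score >= %d in '%s'",
                 min_score, path))
  }
  if (is.null(taxon_id)) {
    taxon_id <- sub("\\..*$", "", from[keep][1])
    if (identical(taxon_id, from[keep][1])) {
      taxon_id <- sub("\\.(txt|tsv|gz)$", "", basename(path))
    }
  }
  net <- interactome(
    data.frame(from = from[keep], to = to[keep], weight = score[keep] / 1000,
               stringsAsFactors = FALSE),
    taxon_id = taxon_id, name = basename(path))
  if (!nrow(net$edges)) stop(sprintf("empty interactome after filtering '%s'", path))
  net
}

#' Write an interactome in the STRING protein-links dialect
#'
#' Each undirected edge is written once as
#' `protein1 protein2 combined_score` with the score recovered as
#' `round(weight * 1000)`.
#'
#' @param net an `interactome`.
#' @param path output path (`.gz` suffix writes gzip).
#' @param header write the `protein1 protein2 combined_score` header line?
#' @return `path`, invisibly.
#' @export
write_string_links <- function(net, path, header = TRUE) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (header) writeLines("protein1 protein2 combined_score", con)
  writeLines(sprintf("%s %s %d", net$edges$from, net$edges$to,
                     as.integer(round(net$edges$weight * 1000))), con)
  invisible(path)
}

#' Construct a label set
#'
#' Essential / non-essential gene labels for one organism. The essential
#' genes are the positive class; every other gene of the universe (all
#' genes of the organism's interactome) is non-essential.
#'
#' @param essential character vector of essential gene identifiers (must be
#'   a subset of `universe`).
#' @param universe character vector of all gene identifiers.
#' @param organism organism tag.
#' @param version_tag label-source version, e.g. `"DEG10"` or `"DEG15"`.
#' @return An object of class `label_set`: list with `organism`,
#'   `essential`, `universe`, `version_tag`, and `n_unmapped` (ids that
#'   were listed but absent from the universe, when built by
#'   [read_labels()]).
#' @export
label_set <- function(essential, universe, organism = "NA", version_tag = "NA") {
  essential <- unique(as.character(essential))
  universe <- unique(as.character(universe))
  if (!all(essential %in% universe)) {
    stop("essential genes must be a subset of the universe")
  }
  structure(list(organism = as.character(organism),
                 essential = essential, universe = universe,
                 version_tag = as.character(version_tag), n_unmapped = 0L),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("<label_set> %s [%s]: %d essential / %d genes (%d unmapped ids)\n",
              x$organism, x$version_tag, length(x$essential),
              length(x$universe), x$n_unmapped))
  invisible(x)
}

#' Non-essential genes of a label set
#' @param labels a `label_set`.
#' @return character vector: `universe \ essential`.
#' @export
nonessential <- function(labels) setdiff(labels$universe, labels$essential)

#' Read a DEG-style essential-gene label file
#'
#' One gene identifier per line; blank lines and `#` comments are ignored.
#' Listed identifiers not present in `universe` are counted as unmapped and
#' excluded. A file mapping zero essentials raises a warning (such an
#' organism contributes no positives to training).
#'
#' @param path path to the label file.
#' @param universe all genes of the organism's interactome.
#' @param organism organism tag.
#' @param version_tag label-source version tag, e.g. `"DEG10"`.
#' @return a [label_set()] with `n_unmapped` filled in.
#' @export
read_labels <- function(path, universe, organism = "NA", version_tag = "NA") {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  ids <- unique(lines[nzchar(lines)])
  mapped <- intersect(ids, universe)
  if (!length(mapped)) {
    warning(sprintf("no essential genes mapped to the universe for '%s'", organism))
  }
  ls <- label_set(mapped, universe, organism = organism, version_tag = version_tag)
  ls$n_unmapped <- length(ids) - length(mapped)
  ls
}

#' Read an offline gene annotation table
#'
#' Tab-separated `gene_id<TAB>preferred_name<TAB>function`. Lookups for
#' genes absent from the table never fail: they yield the gene id as
#' preferred name and `NA` as function (see [annotate_genes()]).
#'
#' @param path path to the TSV file (a header row `gene_id ...` is
#'   detected and skipped).
#' @return An object of class `annotation_table` (data.frame with columns
#'   `gene_id`, `preferred_name`, `gene_function`).
#' @export
read_annotations <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "#",
                          col.names = c("gene_id", "preferred_name", "gene_function"))
  if (nrow(df) && identical(tolower(df$gene_id[1]), "gene_id")) df <- df[-1, , drop = FALSE]
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in annotation table")
  rownames(df) <- NULL
  structure(df, class = c("annotation_table", "data.frame"))
}

#' Look up annotations for a set of genes
#'
#' @param annotations an `annotation_table`, or `NULL` (everything
#'   unannotated).
#' @param gene_ids character vector of gene identifiers.
#' @return data.frame `gene_id`, `preferred_name`, `gene_function`; genes
#'   missing from the table get `preferred_name = gene_id` and
#'   `gene_function = NA` (the explicit "unannotated" marker).
#' @export
annotate_genes <- function(annotations, gene_ids) {
  gene_ids <- as.character(gene_ids)
  out <- data.frame(gene_id = gene_ids, preferred_name = gene_ids,
                    gene_function = rep(NA_character_, length(gene_ids)),
                    stringsAsFactors = FALSE)
  if (!is.null(annotations) && nrow(annotations)) {
    i <- match(gene_ids, annotations$gene_id)
    hit <- !is.na(i)
    out$preferred_name[hit] <- annotations$preferred_name[i[hit]]
    out$gene_function[hit] <- annotations$gene_function[i[hit]]
  }
  out
}

#' Check that an interactome is large enough for training
#'
#' Training networks are expected to carry at least 50,000 edges so the
#' structural features generalize; smaller networks trigger a warning, not
#' an error.
#'
#' @param net an `interactome`.
#' @param min_edges minimum edge count (default 50000).
#' @param warn emit a warning on failure?
#' @return list with `pass` (logical), `n_edges`, `min_edges`.
#' @export
validate_training_interactome <- function(net, min_edges = 50000, warn = TRUE) {
  ne <- n_edges(net)
  pass <- ne >= min_edges
  if (!pass && warn) {
    warning(sprintf("interactome '%s' has %d edges (< %d); features may not generalize",
                    net$taxon_id, ne, min_edges))
  }
  list(pass = pass, n_edges = ne, min_edges = as.integer(min_edges))
}
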