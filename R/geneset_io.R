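#' Read a GMT (Gene Matrix Transposed) file
#'
#' One gene set per line: `id<TAB>description<TAB>gene1<TAB>gene2...`.
#' The description column is carried as the set's display name but is
#' otherwise ignored. Gene symbols are normalized (uppercased, trimmed)
#' and duplicates within a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @param source_label Provenance label for the collection; defaults to the
#'   file name.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line (fewer than 3 tab-separated fields) at line ",
         bad[1], " of ", path)
  sets <- lapply(fields, function(f)
    gene_set(set_id = f[1], name = f[2], members = f[-(1:2)]))
  gene_set_collection(sets, source_label = source_label)
}

#' Write a gene-set collection as GMT
#'
#' Round-trip safe for set ids and member sets: `read_gmt(write_gmt(x))`
#' reproduces them exactly. Tabs inside ids or names are replaced with
#' spaces so they cannot corrupt the format.
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection$sets) == 0L) stop("refusing to write empty collection")
  sanitize <- function(x) gsub("\t", " ", x, fixed = TRUE)
  lines <- vapply(collection$sets, function(s)
    paste(c(sanitize(s$set_id), sanitize(s$name), s$members), collapse = "\t"),
    character(1))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("cannot write GMT to ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}

#' Read a gene list from a text file
#'
#' One symbol per line, or the first column of a TSV; lines starting with
#' `#` are skipped.
#'
#' @param path Path to the file.
#' @param label Label for the returned [seed_list()].
#' @return A `seed_list`.
#' @export
read_gene_list <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  genes <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1)
  seed_list(genes, label = label)
}

#' Load the packaged MDD study fixtures
#'
#' Returns the transcription of the motivating MDD candidate-gene study's
#' published tables, packaged with mddnet: the seed gene list (union of
#' every pathway's printed seed-gene column plus the candidate genes named
#' in the study's results text; the full 255-gene supplementary list is not
#' published in machine-readable form, so the packaged seed list is the
#' 131-symbol printed subset), the 73 significantly enriched KEGG pathways
#' with their seed-gene restrictions, and the 35 connector genes the
#' study's Steiner subnetwork introduced (non-seed by definition).
#'
#' Deterministic and download-free.
#'
#' @return A list with elements `seeds` ([seed_list()]), `pathways`
#'   ([gene_set_collection()], 73 sets), `connectors`
#'   (`gene_set_collection` holding the connector genes as one set).
#' @export
load_mdd_fixtures <- function() {
  ext <- system.file("extdata", package = "mddnet")
  paths <- file.path(ext, c("mdd_seed_genes.txt", "mdd_pathways.gmt",
                            "mdd_connector_genes.txt"))
  if (!all(file.exists(paths)))
    stop("packaged MDD fixtures are missing or corrupt; reinstall mddnet")
  seeds <- read_gene_list(paths[1], label = "MDDgene")
  pathways <- read_gmt(paths[2], source_label = "MDD enriched KEGG pathways")
  conn <- read_gene_list(paths[3], label = "MDD connector genes")
  connectors <- gene_set_collection(
    list(gene_set("MDD_connectors", conn$genes,
                  name = "Subnetwork connector genes outside the seed list")),
    source_label = "MDD subnetwork connector genes")
  list(seeds = seeds, pathways = pathways, connectors = connectors)
}
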