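## Readers and writers for the plain-text interchange formats used by the
## package: samples x variables TSV matrices with a layer file, BED gene
## regions, edge-list TSV and GraphML networks, dosage/VCF genotypes and
## YAML simulation configs.

#' Read a samples x variables TSV matrix as an omics dataset
#'
#' @param path TSV with a header row of variable names and a first column
#'   of sample identifiers.
#' @param layer_path optional two-column TSV (`variable`, `layer`)
#'   marking each column's layer; defaults to `"endogenous"` for all.
#' @return an `"omics_dataset"`.
#' @export
read_dataset_tsv <- function(path, layer_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  layer <- rep("endogenous", ncol(m))
  names(layer) <- colnames(m)
  if (!is.null(layer_path)) {
    lf <- utils::read.delim(layer_path, check.names = FALSE)
    layer[as.character(lf[[1L]])] <- as.character(lf[[2L]])
  }
  new_omics_dataset(m, layer)
}

#' Write a network's directed edge list to TSV
#'
#' Columns: `parent`, `child`, plus any further edge columns the network
#' carries (layers, coefficients, p-values).
#'
#' @param network a `"layered_network"`, `"sem_network"` or
#'   `"cor_network"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edges_tsv <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a parent/child edge-list TSV back into an edge data frame
#' @param path TSV with at least `parent` and `child` columns.
#' @return data frame.
#' @export
read_edges_tsv <- function(path) {
  e <- utils::read.delim(path, check.names = FALSE,
                         colClasses = NA, stringsAsFactors = FALSE)
  if (!all(c("parent", "child") %in% names(e)))
    stop2("edge list needs 'parent' and 'child' columns")
  e$parent <- as.character(e$parent)
  e$child <- as.character(e$child)
  e
}

#' Convert a package network to an igraph object
#' @param network any network representation accepted by the package.
#' @return an igraph directed graph (undirected for `"cor_network"`).
#' @export
as_igraph <- function(network) {
  directed <- !inherits(network, "cor_network")
  adj <- as_adjacency(network)
  g <- igraph::graph_from_adjacency_matrix(adj * 1, mode =
    if (directed) "directed" else "max")
  if (!is.null(network$layer))
    igraph::V(g)$layer <- unname(network$layer[igraph::V(g)$name])
  g
}

#' Write a network as GraphML
#' @inheritParams write_edges_tsv
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Read BED gene regions
#'
#' 0-based half-open intervals; columns chrom, start, end and optionally
#' name.
#'
#' @param path BED file path.
#' @return data frame with `chrom`, `start`, `end`, `name`.
#' @export
read_regions_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(bed) < 3L) stop2("BED needs at least chrom, start, end")
  out <- data.frame(chrom = as.character(bed[[1L]]),
                    start = as.integer(bed[[2L]]),
                    end = as.integer(bed[[3L]]),
                    name = if (ncol(bed) >= 4L) as.character(bed[[4L]])
                           else sprintf("region_%d", seq_len(nrow(bed))),
                    stringsAsFactors = FALSE)
  out
}

#' Read a two-column disease status TSV
#' @param path TSV with columns sample id and integer status.
#' @return named integer vector of statuses.
#' @export
read_disease_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.integer(df[[2L]]), as.character(df[[1L]]))
}

#' Read genotype dosages from a VCF
#'
#' Extracts 0/1/2 alternate-allele counts from the GT field (requires the
#' vcfR package).
#'
#' @param path VCF path (plain text or gzipped).
#' @return list with `genotypes` (samples x variants 0/1/2 matrix) and
#'   `variant_info` (data frame `chrom`, `pos`, `id`).
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop2("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_integer_)
    sum(as.integer(strsplit(g, "[/|]")[[1L]]) > 0L)
  })
  fix <- vcfR::getFIX(v)
  list(genotypes = t(dose),
       variant_info = data.frame(chrom = fix[, "CHROM"],
                                 pos = as.integer(fix[, "POS"]),
                                 id = fix[, "ID"],
                                 stringsAsFactors = FALSE))
}

#' Read a simulation configuration from YAML
#'
#' Keys mirror the arguments of [sim_config()] (requires the yaml
#' package).
#'
#' @param path YAML file path.
#' @return a `"sim_config"`.
#' @export
read_config_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop2("reading YAML configs requires the yaml package")
  args <- yaml::read_yaml(path)
  do.call(sim_config, args[names(args) %in% names(formals(sim_config))])
}
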